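# Effect of normalizer choice on target-gene differential expression:
# for each candidate normalizer set, normalize the targets and compare
# groups, returning the full target x normalizer grid side by side.

#' Compare target expression under different normalizer sets
#'
#' For each normalizer set: build its normalization factor, compute each
#' target's normalized relative quantities (NRQ), and test
#' tumour-vs-normal differences with a Welch t-test on `log10(NRQ)`.
#' Reports the p-value, the direction of change in the case group, the
#' median fold change and the mean log2 fold change with its CI. A stable
#' normalizer recovers planted effects; a normalizer sharing a target's
#' group shift masks that target's effect (the confounded-reference
#' failure mode).
#'
#' @param rq an [cq_to_rq()] result.
#' @param normalizer_sets named list of character vectors of reference
#'   assays.
#' @param targets character vector of target assays; no target may appear
#'   in the normalizer set used for it.
#' @param samples sample sheet or named group vector (2 groups).
#' @param case_group group treated as the case; default: second group
#'   alphabetically (so tumour for tumour/normal labels).
#' @param alpha significance level for the `significant` flag.
#' @param p_adjust optional multiple-testing correction method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"` (raw p-values).
#' @return data.frame with one row per (target, normalizer set):
#'   `target`, `normalizer_set`, `p_value`, `significant`, `direction`,
#'   `median_fold_change`, `mean_log2_fc`, `n_case`, `n_control`.
#' @export
compare_targets <- function(rq, normalizer_sets, targets, samples,
                            case_group = NULL, alpha = 0.05,
                            p_adjust = "none") {
  if (is.null(names(normalizer_sets)))
    names(normalizer_sets) <- vapply(normalizer_sets, paste,
                                     character(1), collapse = "+")
  gv <- .group_vector(samples)
  rows <- list()
  for (set_name in names(normalizer_sets)) {
    members <- normalizer_sets[[set_name]]
    if (length(members) < 1)
      stop(sprintf("normalizer set '%s' is empty", set_name), call. = FALSE)
    clash <- intersect(members, targets)
    if (length(clash))
      stop(sprintf("target(s) inside normalizer set '%s': %s",
                   set_name, paste(clash, collapse = ", ")), call. = FALSE)
    nf <- normalization_factor(rq, members)
    nt <- normalize_targets(rq, nf, targets, samples = samples)
    tg <- .two_groups(gv[unique(nt$sample_id)], case_group)
    for (target in targets) {
      d <- nt[nt$assay_id == target & !is.na(nt$nrq), ]
      case <- d$nrq[d$group == tg$case]
      ctrl <- d$nrq[d$group == tg$control]
      if (length(case) < 2 || length(ctrl) < 2) {
        warning(sprintf("target %s under set '%s' skipped (< 2 per group)",
                        target, set_name), call. = FALSE)
        next
      }
      tt <- stats::t.test(log10(case), log10(ctrl))
      mean_log2_fc <- (mean(log10(case)) - mean(log10(ctrl))) / log10(2)
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, normalizer_set = set_name,
        p_value = tt$p.value,
        direction = if (mean_log2_fc >= 0) "up" else "down",
        median_fold_change = stats::median(case) / stats::median(ctrl),
        mean_log2_fc = mean_log2_fc,
        n_case = length(case), n_control = length(ctrl),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_value_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value_adj < alpha
  out
}
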