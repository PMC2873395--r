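# Global-mean expression normalization for large assay panels: per-sample
# mean Cq profiles, composite "virtual" normalizer assays, and ranking of
# candidate references by resemblance to the global mean.

#' Per-sample global mean expression profile
#'
#' The per-sample arithmetic mean Cq over qualifying assays: either all
#' detected assays, or only those expressed below a Cq cutoff (strict <,
#' default 35 cycles). On the linear scale this is the geometric mean
#' quantity at equal efficiencies.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param rule `"all_detected"` or `"detected_below_cutoff"`.
#' @param cutoff Cq cutoff for the stricter rule (default 35).
#' @param exclude_samples sample ids to leave out.
#' @return data.frame with `sample_id`, `global_mean_cq`, `n_assays_used`;
#'   attributes `rule` and `cutoff`.
#' @export
global_mean_profile <- function(aggregated,
                                rule = c("all_detected",
                                         "detected_below_cutoff"),
                                cutoff = 35, exclude_samples = character()) {
  rule <- match.arg(rule)
  a <- aggregated[aggregated$detected &
                    !(aggregated$sample_id %in% exclude_samples), ]
  if (rule == "detected_below_cutoff") a <- a[a$mean_cq < cutoff, ]
  all_samples <- setdiff(unique(aggregated$sample_id), exclude_samples)
  grp <- split(a$mean_cq, factor(a$sample_id, levels = all_samples))
  empty <- names(grp)[vapply(grp, length, integer(1)) == 0]
  if (length(empty))
    stop(sprintf("sample(s) with no qualifying assays: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  out <- data.frame(sample_id = names(grp),
                    global_mean_cq = vapply(grp, mean, numeric(1)),
                    n_assays_used = vapply(grp, length, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rule") <- rule
  attr(out, "cutoff") <- cutoff
  out
}

#' Build a composite (virtual) normalizer assay
#'
#' Averages member assays' Cq values per sample (the geometric mean on the
#' linear scale), producing a synthetic assay usable anywhere a real assay
#' is, e.g. to enter the geometric mean of a set of snoRNAs — or the
#' global mean profile itself — into a geNorm comparison. A sample is
#' included only when every member is detected in it.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param member_assays character vector of member assays (>= 1).
#' @param name assay id given to the virtual assay.
#' @return An `aggregated_cq` data.frame of the virtual assay's rows,
#'   rbind-able with `aggregated`.
#' @export
make_virtual_assay <- function(aggregated, member_assays, name) {
  if (length(member_assays) < 1)
    stop("member_assays must not be empty", call. = FALSE)
  a <- aggregated[aggregated$assay_id %in% member_assays &
                    aggregated$detected, ]
  grp <- split(a, a$sample_id)
  keep <- vapply(grp, function(d)
    length(unique(d$assay_id)) == length(member_assays), logical(1))
  grp <- grp[keep]
  m <- length(member_assays)
  out <- do.call(rbind, lapply(grp, function(d) {
    data.frame(sample_id = d$sample_id[1], assay_id = name,
               plate_id = d$plate_id[1],
               mean_cq = mean(d$mean_cq),
               # SE-style combination of member replicate scatter
               replicate_sd = sqrt(sum(d$replicate_sd^2, na.rm = TRUE)) / m,
               n_used = min(d$n_used), detected = TRUE, qc_flag = "pass",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("aggregated_cq", "data.frame")
  out
}

#' Rank candidate references by resemblance to the global mean
#'
#' A candidate's score is the n-1 SD over samples of
#' `Cq(candidate, s) - global_mean(s)`: 0 for a gene tracking the global
#' mean with a constant offset, larger the more its profile departs. The
#' mean absolute deviation is available as an alternative metric. Scores
#' are invariant to sample-wide Cq shifts. Candidates must be detected in
#' every retained sample; others are excluded with a warning. Ties are
#' broken lexicographically by assay id.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param profile a [global_mean_profile()].
#' @param candidates assays to score (default: all in `aggregated`).
#' @param top_k how many leading candidates to flag (default 4).
#' @param metric `"sd"` (default) or `"mad"` (mean absolute deviation).
#' @return data.frame with `assay_id`, `resemblance_score`, `rank`,
#'   `n_samples_used`, `selected` (rank <= top_k), sorted by rank.
#' @export
score_candidates <- function(aggregated, profile, candidates = NULL,
                             top_k = 4, metric = c("sd", "mad")) {
  metric <- match.arg(metric)
  gm <- stats::setNames(profile$global_mean_cq, profile$sample_id)
  a <- aggregated[aggregated$detected &
                    aggregated$sample_id %in% names(gm), ]
  candidates <- candidates %||% unique(a$assay_id)
  n_samples <- length(gm)
  rows <- lapply(candidates, function(g) {
    d <- a[a$assay_id == g, ]
    if (nrow(d) < n_samples) return(NULL)   # not ubiquitously detected
    diffs <- d$mean_cq - gm[d$sample_id]
    score <- if (metric == "sd") stats::sd(diffs)
             else mean(abs(diffs - mean(diffs)))
    data.frame(assay_id = g, resemblance_score = score,
               n_samples_used = nrow(d), stringsAsFactors = FALSE)
  })
  dropped <- candidates[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning(sprintf("excluded (not detected in all samples): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no candidate detected in all samples", call. = FALSE)
  out <- out[order(out$resemblance_score, out$assay_id), ]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= top_k
  rownames(out) <- NULL
  out
}
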