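# Validation statistics for candidate reference genes: differential
# expression pre-check on logged Cq values, Bartlett variance-homogeneity
# across genes, CI-inclusion equivalence testing against a fold-change
# bound, and a Kolmogorov-Smirnov normality screen.

# Extract per-assay log2 expression (and group labels) from either an
# aggregated_cq table (log2 expression = -mean_cq up to an additive
# constant) or an rq_matrix (log2 RQ).
.log2_expression <- function(x, samples) {
  gv <- .group_vector(samples)
  if (inherits(x, "rq_matrix")) {
    y <- log2(x$values)
    keep <- intersect(colnames(y), names(gv))
    list(mat = y[, keep, drop = FALSE], groups = gv[keep])
  } else {
    a <- x[x$detected & x$sample_id %in% names(gv), ]
    assays <- sort(unique(a$assay_id))
    samples_u <- sort(unique(a$sample_id))
    y <- matrix(NA_real_, length(assays), length(samples_u),
                dimnames = list(assays, samples_u))
    y[cbind(match(a$assay_id, assays), match(a$sample_id, samples_u))] <-
      -a$mean_cq
    list(mat = y, groups = gv[samples_u])
  }
}

#' Differential-expression pre-check for candidate references
#'
#' Two-sample t-test per assay between the two groups, on `log10(Cq)` by
#' default (the double-log transform used for reference-gene screening) or
#' on raw Cq. Welch's unequal-variance variant. Assays passing (p > alpha)
#' satisfy the assumption of the stability algorithms that references are
#' not differentially expressed; failures gate downstream analysis.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param samples sample sheet or named group vector (2 groups).
#' @param transform `"log10_cq"` (default) or `"cq"`.
#' @param alpha significance level for the pass flag (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame with `assay_id`, `statistic`, `p_value`,
#'   `test_name`, `transform`, `pass`; assays with fewer than 2 detected
#'   values in a group are skipped with a warning.
#' @export
differential_precheck <- function(aggregated, samples,
                                  transform = c("log10_cq", "cq"),
                                  alpha = 0.05, var_equal = FALSE) {
  transform <- match.arg(transform)
  gv <- .group_vector(samples)
  a <- aggregated[aggregated$detected & aggregated$sample_id %in% names(gv), ]
  a$group <- gv[a$sample_id]
  lev <- sort(unique(a$group))
  if (length(lev) != 2) stop("exactly 2 groups required", call. = FALSE)
  x <- if (transform == "log10_cq") log10(a$mean_cq) else a$mean_cq
  rows <- lapply(sort(unique(a$assay_id)), function(g) {
    sel <- a$assay_id == g
    v1 <- x[sel & a$group == lev[1]]
    v2 <- x[sel & a$group == lev[2]]
    if (length(v1) < 2 || length(v2) < 2) {
      warning(sprintf("assay %s skipped (< 2 values in a group)", g),
              call. = FALSE)
      return(NULL)
    }
    if (stats::sd(c(v1, v2)) == 0) {
      # identical values in both groups: no evidence of difference
      return(data.frame(assay_id = g, statistic = 0, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(v1, v2, var.equal = var_equal)
    data.frame(assay_id = g, statistic = unname(tt$statistic),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$test_name <- if (var_equal) "two-sample t" else "Welch t"
  out$transform <- transform
  out$pass <- out$p_value > alpha
  out
}

#' Variance homogeneity across genes (Bartlett's test)
#'
#' Tests whether the candidate genes' per-sample Cq distributions share a
#' common variance; a small p-value indicates heterogeneous stability
#' among the candidates.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param genes assays to compare (default: all; >= 2).
#' @return one-row data.frame with `statistic`, `df`, `p_value`,
#'   `test_name`, `n_genes`.
#' @export
variance_homogeneity <- function(aggregated, genes = NULL) {
  a <- aggregated[aggregated$detected, ]
  genes <- genes %||% sort(unique(a$assay_id))
  if (length(genes) < 2) stop("at least 2 genes required", call. = FALSE)
  vals <- lapply(genes, function(g) a$mean_cq[a$assay_id == g])
  n <- vapply(vals, length, integer(1))
  if (any(n < 2))
    stop(sprintf("gene(s) with < 2 values: %s",
                 paste(genes[n < 2], collapse = ", ")), call. = FALSE)
  zero_var <- vapply(vals, function(v) stats::var(v) == 0, logical(1))
  if (any(zero_var))
    stop(sprintf("zero variance; Bartlett statistic undefined for: %s",
                 paste(genes[zero_var], collapse = ", ")), call. = FALSE)
  bt <- stats::bartlett.test(vals)
  data.frame(statistic = unname(bt$statistic), df = unname(bt$parameter),
             p_value = bt$p.value, test_name = "Bartlett",
             n_genes = length(genes), stringsAsFactors = FALSE)
}

#' Equivalence test against a fold-change bound
#'
#' Per assay, the mean difference in log2 expression between the two
#' groups with a symmetric t-based confidence interval. The assay is
#' declared equivalently expressed when the whole interval lies strictly
#' inside `(-log2(cutoff), +log2(cutoff))`: a fold-change cutoff of 2
#' gives bounds of +/-1, a cutoff of 3 bounds of +/-1.58. A 90% interval
#' corresponds to two one-sided tests at alpha = 0.05. Supports unpaired
#' (Welch) and paired (per-patient) modes.
#'
#' @param x an `aggregated_cq` table (log2 expression taken as `-mean_cq`)
#'   or an [cq_to_rq()] `rq_matrix` (log2 RQ).
#' @param samples sample sheet (needs `patient_id` for paired mode) or
#'   named group vector.
#' @param assays assays to test (default: all in `x`).
#' @param fold_change_cutoff equivalence bound on the linear scale (> 1;
#'   default 3).
#' @param ci_level confidence level of the symmetric interval (default 0.90).
#' @param paired pair tumour/normal per `patient_id` instead of unpaired.
#' @param case_group group treated as the case (difference = case -
#'   control); default: second group alphabetically.
#' @return data.frame with `assay_id`, `mean_log2_diff`, `ci_low`,
#'   `ci_high`, `bound`, `equivalent`, `ci_level`, `n_case`, `n_control`.
#' @export
equivalence_test <- function(x, samples, assays = NULL,
                             fold_change_cutoff = 3, ci_level = 0.90,
                             paired = FALSE, case_group = NULL) {
  if (fold_change_cutoff <= 1)
    stop("fold_change_cutoff must be > 1", call. = FALSE)
  bound <- log2(fold_change_cutoff)
  le <- .log2_expression(x, samples)
  tg <- .two_groups(le$groups, case_group)
  assays <- assays %||% rownames(le$mat)
  patient <- NULL
  if (paired) {
    if (!is.data.frame(samples) || !"patient_id" %in% names(samples))
      stop("paired mode needs a sample sheet with 'patient_id'",
           call. = FALSE)
    patient <- stats::setNames(samples$patient_id, samples$sample_id)
  }
  rows <- lapply(assays, function(g) {
    v <- le$mat[g, ]
    case <- v[le$groups == tg$case & !is.na(v)]
    ctrl <- v[le$groups == tg$control & !is.na(v)]
    if (length(case) < 2 || length(ctrl) < 2) {
      warning(sprintf("assay %s skipped (< 2 values in a group)", g),
              call. = FALSE)
      return(NULL)
    }
    if (paired) {
      pc <- patient[names(case)]; pn <- patient[names(ctrl)]
      shared <- intersect(pc, pn)
      d <- case[match(shared, pc)] - ctrl[match(shared, pn)]
      if (length(d) < 2) {
        warning(sprintf("assay %s skipped (< 2 complete pairs)", g),
                call. = FALSE)
        return(NULL)
      }
      tt <- stats::t.test(d, conf.level = ci_level)
      n_case <- n_ctrl <- length(d)
    } else {
      tt <- stats::t.test(case, ctrl, conf.level = ci_level)
      n_case <- length(case); n_ctrl <- length(ctrl)
    }
    est <- if (paired) unname(tt$estimate) else
      unname(tt$estimate[1] - tt$estimate[2])
    ci <- tt$conf.int
    data.frame(assay_id = g, mean_log2_diff = est, ci_low = ci[1],
               ci_high = ci[2], bound = bound,
               equivalent = ci[1] > -bound && ci[2] < bound,
               ci_level = ci_level, n_case = n_case, n_control = n_ctrl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normality screen (one-sample Kolmogorov-Smirnov)
#'
#' Per assay (and per group when a sample sheet is given), a one-sample KS
#' test of the Cq values against a Normal with the sample's estimated mean
#' and SD. Advisory only: it flags but never blocks the pipeline. Cells
#' with fewer than `min_n` values are skipped; constant cells are flagged
#' degenerate, not tested.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param samples optional sample sheet / group vector for per-group tests.
#' @param alpha flagging level (default 0.05).
#' @param min_n minimum values per tested cell (default 5).
#' @return data.frame with `assay_id`, `group`, `n`, `statistic`,
#'   `p_value`, `flag` (`ok`, `non_normal`, `degenerate`).
#' @export
normality_check <- function(aggregated, samples = NULL, alpha = 0.05,
                            min_n = 5) {
  a <- aggregated[aggregated$detected, ]
  if (!is.null(samples)) {
    gv <- .group_vector(samples)
    a <- a[a$sample_id %in% names(gv), ]
    a$group <- gv[a$sample_id]
  } else {
    a$group <- "all"
  }
  cells <- unique(a[, c("assay_id", "group")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    v <- a$mean_cq[a$assay_id == cells$assay_id[i] &
                     a$group == cells$group[i]]
    if (length(v) < min_n) return(NULL)
    if (stats::sd(v) == 0) {
      return(data.frame(assay_id = cells$assay_id[i],
                        group = cells$group[i], n = length(v),
                        statistic = NA_real_, p_value = NA_real_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    }
    ks <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
    data.frame(assay_id = cells$assay_id[i], group = cells$group[i],
               n = length(v), statistic = unname(ks$statistic),
               p_value = ks$p.value,
               flag = if (ks$p.value < alpha) "non_normal" else "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
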