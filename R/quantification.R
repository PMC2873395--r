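# Efficiency-corrected relative quantification with log2-scale error
# propagation, multi-reference normalization factors and normalized
# relative quantities (NRQ) of target assays.

#' Convert aggregated Cq to efficiency-corrected relative quantities
#'
#' `RQ(i, s) = AF_i ^ (Cq_ref(i) - Cq(i, s))` where `AF_i` is the assay's
#' amplification factor (from the panel's fitted efficiency when present,
#' else `default_af`) and the reference point is the assay's minimum Cq
#' (highest expressor, classic geNorm input; the per-assay maximum RQ is
#' then 1) or its mean Cq (qbase convention; the geometric mean RQ is then
#' 1). The choice rescales assay rows and does not change stability values
#' or group statistics. Log2-scale standard errors are
#' `replicate_sd / sqrt(n_used) * log2(AF)`.
#'
#' @param aggregated output of [aggregate_replicates()] (one row per
#'   sample x assay; calibrate and drop the calibrator first if plates
#'   were used).
#' @param panel optional assay panel with an `efficiency` column (percent).
#' @param reference_point `"min_cq"` (default) or `"mean_cq"`.
#' @param default_af amplification factor used when no efficiency is known
#'   (default 2, E = 100%).
#' @param exclude_samples sample ids to leave out (e.g. the calibrator).
#' @return An `rq_matrix`: list with `values` (assay x sample matrix of
#'   RQs, NA where undetected), `log2_se`, `amplification_factors`,
#'   `reference_point`.
#' @export
cq_to_rq <- function(aggregated, panel = NULL,
                     reference_point = c("min_cq", "mean_cq"),
                     default_af = 2, exclude_samples = character()) {
  reference_point <- match.arg(reference_point)
  a <- aggregated[!(aggregated$sample_id %in% exclude_samples), ]
  key <- paste(a$sample_id, a$assay_id, sep = "\r")
  if (anyDuplicated(key))
    stop("multiple rows per (sample, assay); collapse plates or exclude the calibrator",
         call. = FALSE)
  assays <- sort(unique(a$assay_id))
  samples <- sort(unique(a$sample_id))
  cq <- matrix(NA_real_, length(assays), length(samples),
               dimnames = list(assays, samples))
  se_cq <- cq
  det <- a$detected
  cq[cbind(match(a$assay_id[det], assays),
           match(a$sample_id[det], samples))] <- a$mean_cq[det]
  se_cq[cbind(match(a$assay_id[det], assays),
              match(a$sample_id[det], samples))] <-
    a$replicate_sd[det] / sqrt(a$n_used[det])

  af <- stats::setNames(rep(default_af, length(assays)), assays)
  if (!is.null(panel) && "efficiency" %in% names(panel)) {
    has <- panel$assay_id %in% assays & !is.na(panel$efficiency)
    af[panel$assay_id[has]] <- 1 + panel$efficiency[has] / 100
  }
  ref <- apply(cq, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    if (reference_point == "min_cq") min(v) else mean(v)
  })
  values <- sweep(cq, 1, ref, function(cqv, refv) refv - cqv)
  values <- exp(sweep(values, 1, log(af), `*`))
  log2_se <- sweep(se_cq, 1, log2(af), `*`)
  structure(list(values = values, log2_se = log2_se,
                 amplification_factors = af,
                 reference_point = reference_point),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("<rq_matrix> %d assays x %d samples (reference point: %s)\n",
              nrow(x$values), ncol(x$values), x$reference_point))
  invisible(x)
}

#' Multi-reference normalization factor
#'
#' `NF(s)` is the geometric mean of the member reference assays' relative
#' quantities in sample `s`; it is defined only where every member is
#' detected. Its log2 standard error is `(1/m) * sqrt(sum(se_i^2))` for
#' `m` members (quadrature under independence).
#'
#' @param rq an [cq_to_rq()] result.
#' @param reference_assays character vector of member assays (>= 1).
#' @return A `normalization_factor`: list with per-sample `nf`, `log2_se`,
#'   `member_assays`.
#' @export
normalization_factor <- function(rq, reference_assays) {
  if (length(reference_assays) < 1)
    stop("at least one reference assay is required", call. = FALSE)
  missing <- setdiff(reference_assays, rownames(rq$values))
  if (length(missing))
    stop(sprintf("reference assay(s) not in RQ matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  v <- rq$values[reference_assays, , drop = FALSE]
  se <- rq$log2_se[reference_assays, , drop = FALSE]
  nf <- apply(v, 2, function(col)
    if (anyNA(col)) NA_real_ else exp(mean(log(col))))
  nf_se <- apply(se, 2, function(col)
    if (anyNA(col)) NA_real_ else sqrt(sum(col^2)) / length(col))
  structure(list(nf = nf, log2_se = nf_se,
                 member_assays = reference_assays),
            class = "normalization_factor")
}

#' Normalize target assays by a normalization factor
#'
#' `NRQ = RQ_target / NF`, with log2-scale SEs combined in quadrature:
#' `se(NRQ) = sqrt(se(target)^2 + se(NF)^2)`. When all assays share one
#' amplification factor, sample-wide Cq shifts cancel exactly in NRQ.
#'
#' @param rq an [cq_to_rq()] result.
#' @param nf a [normalization_factor()].
#' @param target_assays character vector of target assays.
#' @param samples optional sample sheet; when given, the group label is
#'   attached to each row.
#' @return data.frame of class `normalized_targets` with `assay_id`,
#'   `sample_id`, `nrq`, `log2_se` (and `group` when available).
#' @export
normalize_targets <- function(rq, nf, target_assays, samples = NULL) {
  missing <- setdiff(target_assays, rownames(rq$values))
  if (length(missing))
    stop(sprintf("target assay(s) not in RQ matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  shared <- intersect(colnames(rq$values), names(nf$nf))
  shared <- shared[!is.na(nf$nf[shared])]
  if (!length(shared))
    stop("no samples with a defined normalization factor", call. = FALSE)
  out <- do.call(rbind, lapply(target_assays, function(a) {
    data.frame(assay_id = a, sample_id = shared,
               nrq = rq$values[a, shared] / nf$nf[shared],
               log2_se = sqrt(rq$log2_se[a, shared]^2 +
                                nf$log2_se[shared]^2),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!is.null(samples)) {
    gv <- .group_vector(samples)
    out$group <- unname(gv[out$sample_id])
  }
  class(out) <- c("normalized_targets", "data.frame")
  out
}
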