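# Replicate aggregation with QC, inter-plate calibration against a
# repeated calibrator sample, and per-assay Cq summaries.

#' Aggregate replicate Cq values with quality control
#'
#' Per (sample, assay, plate): mean and n-1 sample SD over detected
#' replicates. A reaction is called detected when at least `min_detected`
#' replicates report a Cq. The replicate-scatter QC flag uses a strict
#' threshold: SD exactly equal to `sd_threshold` still passes. Flagged
#' measurements are retained, never dropped; downstream stages decide.
#'
#' @param dataset a validated [cq_dataset()].
#' @param sd_threshold replicate SD above which (strictly) the measurement
#'   is flagged `high_replicate_sd`; default 0.3 cycles.
#' @param min_detected minimum detected replicates for a detected call.
#' @return data.frame of class `aggregated_cq` with columns `sample_id`,
#'   `assay_id`, `plate_id`, `mean_cq`, `replicate_sd`, `n_used`,
#'   `detected`, `qc_flag`.
#' @export
aggregate_replicates <- function(dataset, sd_threshold = 0.3,
                                 min_detected = 2) {
  validate_cq_dataset(dataset)
  m <- dataset$measurements
  key <- interaction(m$sample_id, m$assay_id, m$plate_id, drop = TRUE,
                     sep = "\r")
  grp <- split(m$cq, key)
  ids <- do.call(rbind, strsplit(names(grp), "\r", fixed = TRUE))
  n_used <- vapply(grp, function(v) sum(!is.na(v)), integer(1))
  mean_cq <- vapply(grp, function(v) {
    d <- v[!is.na(v)]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  rep_sd <- vapply(grp, function(v) {
    d <- v[!is.na(v)]
    if (length(d) >= 2) stats::sd(d) else NA_real_
  }, numeric(1))
  detected <- n_used >= min_detected
  # strict ">": SD exactly at the threshold passes (tiny tolerance guards
  # against floating-point noise in the variance computation)
  qc <- ifelse(!detected, "insufficient_replicates",
               ifelse(!is.na(rep_sd) & rep_sd > sd_threshold + 1e-9,
                      "high_replicate_sd", "pass"))
  mean_cq[!detected] <- NA_real_
  out <- data.frame(sample_id = ids[, 1], assay_id = ids[, 2],
                    plate_id = ids[, 3], mean_cq = mean_cq,
                    replicate_sd = rep_sd, n_used = n_used,
                    detected = detected, qc_flag = qc,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$sample_id, out$assay_id, out$plate_id), ]
  rownames(out) <- NULL
  class(out) <- c("aggregated_cq", "data.frame")
  out
}

#' Calibrate Cq values across plates
#'
#' Uses a calibrator sample repeated on every plate: per (plate, assay) the
#' offset `calibrator Cq on that plate - mean calibrator Cq across plates`
#' is subtracted from every measurement on that plate, aligning plates
#' while preserving within-plate Cq differences exactly. Additive on the
#' Cq scale (multiplicative on the linear scale).
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param calibrator_sample_id the repeated sample's id.
#' @return Calibrated `aggregated_cq` (calibrator rows included, centred).
#' @export
calibrate_plates <- function(aggregated, calibrator_sample_id) {
  a <- aggregated
  if (!calibrator_sample_id %in% a$sample_id)
    stop(sprintf("calibrator sample '%s' not present", calibrator_sample_id),
         call. = FALSE)
  cal <- a[a$sample_id == calibrator_sample_id & a$detected, ]
  for (assay in unique(a$assay_id)) {
    rows <- a$assay_id == assay
    plates <- unique(a$plate_id[rows])
    if (length(plates) <= 1) next
    cal_a <- cal[cal$assay_id == assay, ]
    missing <- setdiff(plates, cal_a$plate_id)
    if (length(missing))
      stop(sprintf("calibrator missing for assay '%s' on plate(s): %s",
                   assay, paste(missing, collapse = ", ")), call. = FALSE)
    offs <- stats::setNames(cal_a$mean_cq - mean(cal_a$mean_cq),
                            cal_a$plate_id)
    a$mean_cq[rows] <- a$mean_cq[rows] - offs[a$plate_id[rows]]
  }
  a
}

#' Summarize per-assay Cq distributions
#'
#' Per assay, over detected per-sample mean Cq values: minimum, maximum,
#' range (max - min), mean and n-1 SD (absent for a single sample). Assays
#' with no detected values are omitted with a warning.
#'
#' @param aggregated output of [aggregate_replicates()].
#' @param exclude_samples sample ids to leave out (e.g. the calibrator).
#' @return data.frame with `assay_id`, `cq_range`, `cq_min`, `cq_max`,
#'   `mean_cq`, `sd_cq`, `n`.
#' @export
summarize_assays <- function(aggregated, exclude_samples = character()) {
  a <- aggregated[aggregated$detected &
                    !(aggregated$sample_id %in% exclude_samples), ]
  all_assays <- unique(aggregated$assay_id)
  grp <- split(a$mean_cq, factor(a$assay_id, levels = all_assays))
  empty <- names(grp)[vapply(grp, length, integer(1)) == 0]
  if (length(empty))
    warning(sprintf("no detected values; assay(s) omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  grp <- grp[!names(grp) %in% empty]
  out <- data.frame(
    assay_id = names(grp),
    cq_range = vapply(grp, function(v) max(v) - min(v), numeric(1)),
    cq_min = vapply(grp, min, numeric(1)),
    cq_max = vapply(grp, max, numeric(1)),
    mean_cq = vapply(grp, mean, numeric(1)),
    sd_cq = vapply(grp, function(v)
      if (length(v) >= 2) stats::sd(v) else NA_real_, numeric(1)),
    n = vapply(grp, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
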