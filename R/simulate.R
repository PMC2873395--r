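# Synthetic two-group Cq studies with known ground truth. The generator
# mirrors a tumour/normal validation cohort: per-gene baseline Cq,
# gene-specific biological noise, planted group shifts, sample-wide and
# plate-wide technical shifts, triplicate replicate noise, and detection
# censoring at a Cq ceiling. All noise is Normal on the Cq (log2) scale.

#' Declare one simulated assay
#'
#' @param assay_id assay name, unique within a plan.
#' @param base_cq baseline Cq (typical 20-32).
#' @param group_shift_log2 planted log2 fold change in the tumour group; a
#'   positive value means up-regulation in tumours (the Cq is lowered by
#'   this amount, since Cq is inversely log2-related to abundance).
#' @param intra_sd gene-specific biological noise SD (cycles) within each group.
#' @param role `"reference_candidate"`, `"target"` or `"control"`.
#' @return A one-row data.frame usable in [study_config()].
#' @export
gene_plan <- function(assay_id, base_cq, group_shift_log2 = 0, intra_sd = 0,
                      role = c("reference_candidate", "target", "control")) {
  role <- match.arg(role)
  .check(base_cq > 0, "base_cq", "must be > 0")
  .check(intra_sd >= 0, "intra_sd", "must be >= 0")
  data.frame(assay_id = assay_id, base_cq = base_cq,
             group_shift_log2 = group_shift_log2, intra_sd = intra_sd,
             role = role, stringsAsFactors = FALSE)
}

#' Configure a simulated two-group Cq study
#'
#' @param gene_plans data.frame of [gene_plan()] rows.
#' @param n_tumour,n_normal group sizes (each >= 2).
#' @param sample_shift_sd SD (cycles) of the sample-wide technical shift.
#' @param replicate_sd SD (cycles) of the per-replicate technical noise.
#' @param n_replicates replicates per reaction (default 3, triplicates).
#' @param detection_ceiling Cq at or above which a reaction is reported
#'   undetected (default 40, the instrument cycle limit).
#' @param n_plates number of plates; samples are assigned round-robin.
#' @param plate_shift_sd SD (cycles) of the per-plate shift.
#' @param include_calibrator add a calibrator sample measured on every plate
#'   (default: yes when `n_plates > 1`), enabling inter-plate calibration.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return A validated `study_config` list.
#' @export
study_config <- function(gene_plans, n_tumour = 35, n_normal = 39,
                         sample_shift_sd = 0.5, replicate_sd = 0.15,
                         n_replicates = 3, detection_ceiling = 40,
                         n_plates = 1, plate_shift_sd = 0,
                         include_calibrator = n_plates > 1, seed = 1L) {
  gp <- as.data.frame(gene_plans)
  .check(nrow(gp) >= 1, "gene_plans", "at least one gene required")
  .check(!anyDuplicated(gp$assay_id), "gene_plans", "assay_id must be unique")
  .check(all(gp$base_cq > 0), "gene_plans", "base_cq must be > 0")
  .check(all(gp$intra_sd >= 0), "gene_plans", "intra_sd must be >= 0")
  .check(n_tumour >= 2, "n_tumour", "must be >= 2")
  .check(n_normal >= 2, "n_normal", "must be >= 2")
  .check(n_replicates >= 1, "n_replicates", "must be >= 1")
  .check(sample_shift_sd >= 0, "sample_shift_sd", "must be >= 0")
  .check(replicate_sd >= 0, "replicate_sd", "must be >= 0")
  .check(plate_shift_sd >= 0, "plate_shift_sd", "must be >= 0")
  .check(n_plates >= 1, "n_plates", "must be >= 1")
  structure(list(gene_plans = gp, n_tumour = n_tumour, n_normal = n_normal,
                 sample_shift_sd = sample_shift_sd,
                 replicate_sd = replicate_sd, n_replicates = n_replicates,
                 detection_ceiling = detection_ceiling, n_plates = n_plates,
                 plate_shift_sd = plate_shift_sd,
                 include_calibrator = include_calibrator,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Simulate a two-group Cq study with recorded ground truth
#'
#' Draws Cq(sample s, gene i, replicate r) =
#' `base_cq_i - shift_i * [s is tumour] + u_s + p_plate(s) + e_is + eps_isr`
#' with `u ~ N(0, sample_shift_sd^2)`, `p ~ N(0, plate_shift_sd^2)`,
#' `e ~ N(0, intra_sd_i^2)` drawn once per sample x gene, and
#' `eps ~ N(0, replicate_sd^2)` per replicate. Values at or above the
#' detection ceiling are emitted as undetected. A calibrator sample, when
#' included, carries only plate and replicate noise and is measured on
#' every plate (replicate indices offset per plate so keys stay unique).
#'
#' @param config a [study_config()].
#' @return A `simulated_study`: list with `dataset` (a [cq_dataset()]) and
#'   `truth` (per-gene shift, noise, role and an `instability` index,
#'   `intra_sd + |group_shift_log2|`, whose ascending order is the expected
#'   stability ordering).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "study_config")) {
    config <- do.call(study_config, config)
  }
  set.seed(config$seed)
  gp <- config$gene_plans
  tum <- sprintf("T%02d", seq_len(config$n_tumour))
  nor <- sprintf("N%02d", seq_len(config$n_normal))
  sample_ids <- c(tum, nor)
  groups <- rep(c("tumour", "normal"), c(config$n_tumour, config$n_normal))
  n_s <- length(sample_ids); n_g <- nrow(gp); n_r <- config$n_replicates

  plate_of <- sprintf("P%02d", ((seq_len(n_s) - 1) %% config$n_plates) + 1)
  plate_ids <- sprintf("P%02d", seq_len(config$n_plates))
  p_shift <- stats::setNames(
    stats::rnorm(config$n_plates, 0, config$plate_shift_sd), plate_ids)
  u <- stats::rnorm(n_s, 0, config$sample_shift_sd)

  # sample x gene biological noise, then replicate noise
  e <- matrix(stats::rnorm(n_s * n_g, 0, rep(gp$intra_sd, each = n_s)),
              nrow = n_s, ncol = n_g)
  is_tum <- as.numeric(groups == "tumour")
  base <- outer(rep(1, n_s), gp$base_cq) - outer(is_tum, gp$group_shift_log2)
  mu <- base + u + p_shift[plate_of] + e   # n_s x n_g expected Cq

  m <- expand.grid(replicate = seq_len(n_r), sample_idx = seq_len(n_s),
                   gene_idx = seq_len(n_g), KEEP.OUT.ATTRS = FALSE)
  cq <- mu[cbind(m$sample_idx, m$gene_idx)] +
    stats::rnorm(nrow(m), 0, config$replicate_sd)
  cq[cq >= config$detection_ceiling] <- NA_real_
  meas <- data.frame(sample_id = sample_ids[m$sample_idx],
                     assay_id = gp$assay_id[m$gene_idx],
                     replicate = m$replicate,
                     plate_id = plate_of[m$sample_idx],
                     cq = cq, stringsAsFactors = FALSE)

  samples <- data.frame(sample_id = sample_ids, group = groups,
                        stringsAsFactors = FALSE)

  if (isTRUE(config$include_calibrator)) {
    cal <- expand.grid(replicate = seq_len(n_r),
                       plate_idx = seq_len(config$n_plates),
                       gene_idx = seq_len(n_g), KEEP.OUT.ATTRS = FALSE)
    cal_cq <- gp$base_cq[cal$gene_idx] + p_shift[cal$plate_idx] +
      stats::rnorm(nrow(cal), 0, config$replicate_sd)
    cal_cq[cal_cq >= config$detection_ceiling] <- NA_real_
    cal_meas <- data.frame(
      sample_id = "CAL",
      assay_id = gp$assay_id[cal$gene_idx],
      replicate = (cal$plate_idx - 1L) * n_r + cal$replicate,
      plate_id = plate_ids[cal$plate_idx],
      cq = cal_cq, stringsAsFactors = FALSE)
    meas <- rbind(meas, cal_meas)
    samples <- rbind(samples,
                     data.frame(sample_id = "CAL", group = "calibrator",
                                stringsAsFactors = FALSE))
  }

  panel <- data.frame(assay_id = gp$assay_id, rna_class = "miRNA",
                      role = gp$role, stringsAsFactors = FALSE)
  truth <- gp
  truth$instability <- truth$intra_sd + abs(truth$group_shift_log2)
  truth <- truth[order(truth$instability, truth$assay_id), ]
  structure(list(dataset = cq_dataset(meas, samples, panel), truth = truth,
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study>\n")
  print(x$dataset)
  cat("  expected stability ordering:",
      paste(utils::head(x$truth$assay_id, 4), collapse = " < "), "...\n")
  invisible(x)
}

#' Simulate a qPCR dilution series
#'
#' Generates `(log10 input, Cq)` pairs for a serial dilution of a template
#' amplified with a given per-cycle amplification factor: each `step`-fold
#' dilution raises the Cq by `log(step)/log(amplification_factor)` cycles,
#' plus optional Normal noise. Feed the result to [fit_standard_curve()].
#'
#' @param amplification_factor per-cycle gain (> 1; 2 = perfect doubling).
#' @param n_points number of dilution points (>= 3).
#' @param step fold dilution per point (default 10).
#' @param noise_sd SD (cycles) of Cq noise.
#' @param start_cq Cq of the most concentrated point.
#' @param seed optional integer seed (used only when `noise_sd > 0`).
#' @param assay_id label for the series.
#' @return A `dilution_series`: list with `assay_id` and a `points`
#'   data.frame (`log10_input`, `cq`).
#' @export
make_dilution_series <- function(amplification_factor, n_points = 6,
                                 step = 10, noise_sd = 0, start_cq = 20,
                                 seed = NULL, assay_id = "assay") {
  if (amplification_factor <= 1)
    stop("amplification_factor must be > 1", call. = FALSE)
  if (n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  log10_input <- -(seq_len(n_points) - 1) * log10(step)
  cq <- start_cq - log10_input / log10(amplification_factor)
  if (noise_sd > 0) cq <- cq + stats::rnorm(n_points, 0, noise_sd)
  structure(list(assay_id = assay_id,
                 points = data.frame(log10_input = log10_input, cq = cq)),
            class = "dilution_series")
}
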