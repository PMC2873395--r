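# Pipeline orchestration: run every stage of the reference-gene workflow
# from a single structured config, write CSV outputs plus a machine-
# readable manifest. Stage order follows the study design: load/simulate
# -> aggregate -> calibrate -> efficiency -> global-mean scoring ->
# pre-checks -> geNorm + NormFinder -> equivalence -> target comparison.

#' Load a pipeline configuration
#'
#' Reads a YAML config file (or passes a list through) and fills defaults.
#' Recognised keys: `input` (either `simulate:` with [study_config()]
#' fields and a `gene_plans` table, or `paths:` with `cq`, `samples`,
#' `panel`, optional `format`), `params` (any of `sd_threshold`,
#' `min_detected`, `calibrator_sample_id`, `reference_point`,
#' `default_amplification_factor`, `global_mean_rule`, `cutoff`, `top_k`,
#' `v_threshold`, `fold_change_cutoff`, `ci_level`, `reference_assays`,
#' `normalizer_sets`, `targets`, `seed`) and `stages` (logical toggles:
#' `global_mean`, `precheck`, `stability`, `equivalence`, `targets`).
#'
#' @param config a list or a path to a YAML file.
#' @return A `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- config$params %||% list()
  defaults <- list(sd_threshold = 0.3, min_detected = 2,
                   calibrator_sample_id = NULL,
                   reference_point = "min_cq",
                   default_amplification_factor = 2,
                   global_mean_rule = "all_detected", cutoff = 35,
                   top_k = 4, v_threshold = 0.15, fold_change_cutoff = 3,
                   ci_level = 0.90, reference_assays = NULL,
                   normalizer_sets = NULL, targets = NULL, seed = 1L)
  for (k in names(defaults)) p[[k]] <- p[[k]] %||% defaults[[k]]
  stages <- config$stages %||% list()
  for (k in c("global_mean", "precheck", "stability", "equivalence",
              "targets")) stages[[k]] <- stages[[k]] %||% TRUE
  structure(list(input = config$input, params = p, stages = stages),
            class = "pipeline_config")
}

.write_stage <- function(x, outdir, name) {
  path <- file.path(outdir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  basename(path)   # manifest records relative names (reproducible reruns)
}

#' Run the full reference-gene identification pipeline
#'
#' Executes the enabled stages in order on a loaded or simulated dataset,
#' writing one CSV per result table and a JSON manifest recording
#' parameters, per-stage record counts and the package version. The
#' manifest carries no timestamps, so a rerun with identical config and
#' seed produces byte-identical outputs. On a stage failure the error is
#' recorded in the manifest (with partial outputs retained) and re-thrown.
#'
#' @param config a [pipeline_config()], a config list, or a YAML path.
#' @param outdir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  p <- cfg$params
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("mirnorm")),
                   params = p[!vapply(p, is.null, logical(1))],
                   stages = list())
  files <- character()
  record <- function(stage, n) {
    manifest$stages[[stage]] <<- list(status = "complete", records = n)
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  # validate target/normalizer disjointness before any computation
  if (!is.null(p$targets) && !is.null(p$normalizer_sets)) {
    for (nm in names(p$normalizer_sets)) {
      clash <- intersect(unlist(p$normalizer_sets[[nm]]), p$targets)
      if (length(clash))
        stop(sprintf("config error: target(s) in normalizer set '%s': %s",
                     nm, paste(clash, collapse = ", ")), call. = FALSE)
    }
  }

  # ---- load or simulate -------------------------------------------------
  ds <- run_stage("load", {
    inp <- cfg$input
    if (!is.null(inp$simulate)) {
      sim_args <- inp$simulate
      gp <- do.call(rbind, lapply(sim_args$gene_plans, function(g)
        do.call(gene_plan, g)))
      sim_args$gene_plans <- gp
      sim_args$seed <- sim_args$seed %||% p$seed
      sim <- simulate_study(do.call(study_config, sim_args))
      save_dataset(sim$dataset, file.path(outdir, "dataset.csv"))
      sim$dataset
    } else if (!is.null(inp$paths)) {
      load_dataset(inp$paths$cq, inp$paths$samples, inp$paths$panel,
                   format = inp$paths$format %||% "long")
    } else stop("config must provide input$simulate or input$paths")
  })
  record("load", nrow(ds$measurements))
  cal_id <- p$calibrator_sample_id %||%
    if ("CAL" %in% ds$samples$sample_id) "CAL" else NULL
  excl <- if (is.null(cal_id)) character() else cal_id

  # ---- aggregate + calibrate -------------------------------------------
  agg <- run_stage("aggregate", {
    a <- aggregate_replicates(ds, sd_threshold = p$sd_threshold,
                              min_detected = p$min_detected)
    if (!is.null(cal_id) && length(unique(a$plate_id)) > 1)
      a <- calibrate_plates(a, cal_id)
    a
  })
  files["aggregated"] <- .write_stage(agg, outdir, "aggregated")
  record("aggregate", nrow(agg))

  summ <- run_stage("summarize", summarize_assays(agg, exclude_samples = excl))
  files["cq_summary"] <- .write_stage(summ, outdir, "cq_summary")
  record("summarize", nrow(summ))

  # ---- efficiency -------------------------------------------------------
  if (!is.null(cfg$input$paths$dilutions)) {
    eff <- run_stage("efficiency", {
      dil <- utils::read.csv(cfg$input$paths$dilutions,
                             stringsAsFactors = FALSE)
      do.call(rbind, lapply(split(dil, dil$assay_id), function(d) {
        f <- fit_standard_curve(structure(
          list(assay_id = d$assay_id[1],
               points = d[, c("log10_input", "cq")]),
          class = "dilution_series"))
        data.frame(assay_id = f$assay_id, slope = f$slope,
                   efficiency_percent = f$efficiency_percent,
                   amplification_factor = f$amplification_factor,
                   r_squared = f$r_squared, stringsAsFactors = FALSE)
      }))
    })
    files["efficiency"] <- .write_stage(eff, outdir, "efficiency")
    record("efficiency", nrow(eff))
    ds$panel <- merge(ds$panel,
                      eff[, c("assay_id", "efficiency_percent")],
                      by = "assay_id", all.x = TRUE)
    names(ds$panel)[names(ds$panel) == "efficiency_percent"] <- "efficiency"
  }

  # ---- global mean scoring ---------------------------------------------
  if (isTRUE(cfg$stages$global_mean)) {
    gmres <- run_stage("global_mean", {
      prof <- global_mean_profile(agg, rule = p$global_mean_rule,
                                  cutoff = p$cutoff,
                                  exclude_samples = excl)
      scores <- score_candidates(agg, prof, top_k = p$top_k)
      list(profile = prof, scores = scores)
    })
    files["global_mean_profile"] <-
      .write_stage(gmres$profile, outdir, "global_mean_profile")
    files["candidate_scores"] <-
      .write_stage(gmres$scores, outdir, "candidate_scores")
    record("global_mean", nrow(gmres$scores))
  }

  samples2 <- ds$samples[!(ds$samples$sample_id %in% excl), ]
  ref_assays <- p$reference_assays %||%
    ds$panel$assay_id[ds$panel$role == "reference_candidate"]

  # ---- pre-checks -------------------------------------------------------
  if (isTRUE(cfg$stages$precheck)) {
    pre <- run_stage("precheck", {
      agg_ref <- agg[agg$assay_id %in% ref_assays, ]
      list(ttest = differential_precheck(agg_ref, samples2),
           bartlett = variance_homogeneity(agg_ref, ref_assays),
           normality = normality_check(agg_ref, samples2))
    })
    files["precheck"] <- .write_stage(pre$ttest, outdir, "precheck")
    files["bartlett"] <- .write_stage(pre$bartlett, outdir, "bartlett")
    files["normality"] <- .write_stage(pre$normality, outdir, "normality")
    record("precheck", nrow(pre$ttest))
  }

  # ---- relative quantities + stability ---------------------------------
  rq <- run_stage("quantify",
    cq_to_rq(agg, panel = ds$panel, reference_point = p$reference_point,
             default_af = p$default_amplification_factor,
             exclude_samples = excl))
  record("quantify", sum(!is.na(rq$values)))

  if (isTRUE(cfg$stages$stability)) {
    gn <- run_stage("genorm", genorm(rq, ref_assays,
                                     v_threshold = p$v_threshold))
    files["genorm_m"] <- .write_stage(gn$m_trajectory, outdir, "genorm_m")
    if (!is.null(gn$v_series))
      files["genorm_v"] <- .write_stage(gn$v_series, outdir, "genorm_v")
    record("genorm", length(gn$ranking))
    nf_rank <- run_stage("normfinder", {
      r <- normfinder_rank(rq, ref_assays, samples2)
      bp <- normfinder_best_pair(rq, ref_assays, samples2)
      r$table$best_pair <- paste(bp$pair, collapse = "/")
      r$table$pair_stability <- bp$pair_stability
      r$table
    })
    files["normfinder"] <- .write_stage(nf_rank, outdir, "normfinder")
    record("normfinder", nrow(nf_rank))
    manifest$genorm <- list(final_pair = gn$final_pair,
                            recommended_n = gn$recommended_n)
    manifest$normfinder <- list(best_gene = nf_rank$gene[1],
                                best_pair = nf_rank$best_pair[1])
  }

  # ---- equivalence ------------------------------------------------------
  if (isTRUE(cfg$stages$equivalence)) {
    eq <- run_stage("equivalence",
      equivalence_test(agg[agg$assay_id %in% ref_assays, ], samples2,
                       fold_change_cutoff = p$fold_change_cutoff,
                       ci_level = p$ci_level))
    files["equivalence"] <- .write_stage(eq, outdir, "equivalence")
    record("equivalence", nrow(eq))
  }

  # ---- target comparison ------------------------------------------------
  if (isTRUE(cfg$stages$targets) && !is.null(p$targets)) {
    sets <- p$normalizer_sets
    if (is.null(sets)) {
      gn_pair <- manifest$genorm$final_pair %||% ref_assays[1:2]
      sets <- list(best_pair = gn_pair)
    }
    tc <- run_stage("targets",
      compare_targets(rq, sets, p$targets, samples2))
    files["target_comparison"] <- .write_stage(tc, outdir,
                                               "target_comparison")
    record("targets", nrow(tc))
  }

  manifest$files <- as.list(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
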