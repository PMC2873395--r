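# Fixture builders shared across tests.

# Aggregated table from a gene x sample Cq matrix (all detected, clean QC).
agg_from_matrix <- function(cq, replicate_sd = 0.1, n_used = 3,
                            plate_id = "P01") {
  stopifnot(!is.null(rownames(cq)), !is.null(colnames(cq)))
  out <- expand.grid(assay_id = rownames(cq), sample_id = colnames(cq),
                     stringsAsFactors = FALSE)
  out$plate_id <- plate_id
  out$mean_cq <- cq[cbind(out$assay_id, out$sample_id)]
  out$replicate_sd <- replicate_sd
  out$n_used <- n_used
  out$detected <- !is.na(out$mean_cq)
  out$mean_cq[!out$detected] <- NA_real_
  out$qc_flag <- ifelse(out$detected, "pass", "insufficient_replicates")
  class(out) <- c("aggregated_cq", "data.frame")
  out
}

# rq_matrix directly from a gene x sample matrix of relative quantities.
rq_from_matrix <- function(values, log2_se = NULL, af = 2) {
  structure(list(values = values,
                 log2_se = log2_se %||%
                   matrix(0, nrow(values), ncol(values),
                          dimnames = dimnames(values)),
                 amplification_factors =
                   stats::setNames(rep(af, nrow(values)), rownames(values)),
                 reference_point = "min_cq"),
            class = "rq_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random gene x sample RQ matrix (log-normal), for property tests.
random_rq <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  v <- matrix(2^rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  rq_from_matrix(v)
}

# A minimal dataset: n_samples x n_assays x n_reps long table.
tiny_dataset <- function(n_samples = 3, n_assays = 2, n_reps = 3,
                         seed = 1) {
  set.seed(seed)
  g <- expand.grid(replicate = seq_len(n_reps),
                   assay_id = paste0("a", seq_len(n_assays)),
                   sample_id = paste0("s", seq_len(n_samples)),
                   stringsAsFactors = FALSE)
  g$plate_id <- "P01"
  g$cq <- round(25 + rnorm(nrow(g), 0, 0.2), 3)
  cq_dataset(g[, c("sample_id", "assay_id", "replicate", "plate_id", "cq")],
             data.frame(sample_id = paste0("s", seq_len(n_samples)),
                        group = rep(c("tumour", "normal"),
                                    length.out = n_samples)),
             data.frame(assay_id = paste0("a", seq_len(n_assays)),
                        rna_class = "miRNA", role = "reference_candidate"))
}

# Standard planted-truth study config: 2 stable references among
# unstable candidates plus dysregulated targets, at the validation-cohort
# scale unless overridden.
planted_config <- function(seed, n_tumour = 20, n_normal = 20,
                           n_replicates = 3) {
  gp <- rbind(
    gene_plan("stable1", 24.0, 0, 0.2),
    gene_plan("stable2", 25.0, 0, 0.2),
    gene_plan("unstable1", 26.0, 0, 1.5),
    gene_plan("unstable2", 27.0, 1.2, 1.2),
    gene_plan("unstable3", 28.0, 0, 1.2),
    gene_plan("unstable4", 23.0, -1.2, 1.4),
    gene_plan("unstable5", 26.5, -1.5, 1.8),
    gene_plan("unstable6", 24.5, 1.5, 1.3))
  study_config(gp, n_tumour = n_tumour, n_normal = n_normal,
               sample_shift_sd = 0.5, replicate_sd = 0.15,
               n_replicates = n_replicates, seed = seed)
}

# Simulate -> aggregate -> RQ for a config; returns list(rq, samples, agg).
sim_to_rq <- function(config) {
  sim <- simulate_study(config)
  agg <- aggregate_replicates(sim$dataset)
  rq <- cq_to_rq(agg, sim$dataset$panel)
  list(rq = rq, samples = sim$dataset$samples, agg = agg, sim = sim)
}
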