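# geNorm from scratch: pairwise log-ratio variations, the stability
# measure M, stepwise exclusion of the least stable gene, and the
# sequential-normalization-factor pairwise variation V used to choose the
# optimal number of reference genes. All SDs are n-1 sample SDs; log base
# 2 throughout. M and V are invariant to per-gene rescaling of the
# relative quantities, hence to the reference-point choice upstream.

#' Pairwise variation matrix
#'
#' `V_jk` is the n-1 SD over shared samples of `log2(RQ_j / RQ_k)`: 0 for
#' two genes in constant ratio, growing with discordance. Pairwise-complete
#' samples are used per pair.
#'
#' @param rq an [cq_to_rq()] result.
#' @param genes assays to include (default: all, >= 2).
#' @return Symmetric gene x gene matrix with NA diagonal.
#' @export
pairwise_variation_matrix <- function(rq, genes = NULL) {
  genes <- genes %||% rownames(rq$values)
  if (length(genes) < 2) stop("at least 2 genes required", call. = FALSE)
  y <- log2(rq$values[genes, , drop = FALSE])
  G <- length(genes)
  V <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  for (j in seq_len(G - 1)) {
    for (k in (j + 1):G) {
      r <- y[j, ] - y[k, ]
      r <- r[!is.na(r)]
      if (length(r) < 2)
        stop(sprintf("genes %s and %s share fewer than 2 samples",
                     genes[j], genes[k]), call. = FALSE)
      V[j, k] <- V[k, j] <- stats::sd(r)
    }
  }
  V
}

# M_j = mean of V_jk over the other genes, given a pairwise matrix.
.m_values <- function(V) {
  vapply(seq_len(nrow(V)), function(j) mean(V[j, -j]), numeric(1)) |>
    stats::setNames(rownames(V))
}

#' geNorm stability ranking by stepwise exclusion
#'
#' At each step every remaining gene's stability `M` (its mean pairwise
#' variation against the other remaining genes) is computed and the gene
#' with the largest `M` is excluded, until two genes remain; those two
#' share the SD of their mutual log-ratio as a common `M`. Ties are broken
#' lexicographically by assay id (the lexicographically last of the tied
#' genes is excluded), making results deterministic.
#'
#' @param rq an [cq_to_rq()] result.
#' @param genes assays to rank (>= 3 for any exclusion; >= 2 accepted).
#' @return A `genorm_result`: list with `m_trajectory` (long data.frame:
#'   step, gene, m), `exclusion_order` (least stable first), `final_pair`,
#'   `ranking` (most stable first; the final pair leads, ordered
#'   lexicographically), `final_m` (the pair's common M), and the full
#'   pairwise variation matrix.
#' @export
genorm_rank <- function(rq, genes = NULL) {
  genes <- genes %||% rownames(rq$values)
  if (length(genes) < 2) stop("at least 2 genes required", call. = FALSE)
  V <- pairwise_variation_matrix(rq, genes)
  remaining <- sort(genes)
  excluded <- character()
  traj <- list()
  step <- 0L
  while (length(remaining) > 2) {
    step <- step + 1L
    m <- .m_values(V[remaining, remaining, drop = FALSE])
    traj[[step]] <- data.frame(step = step, gene = names(m), m = unname(m),
                               stringsAsFactors = FALSE)
    # largest M excluded; on ties the lexicographically last gene goes
    worst <- max(m)
    drop_gene <- utils::tail(sort(names(m)[m == worst]), 1)
    excluded <- c(excluded, drop_gene)
    remaining <- setdiff(remaining, drop_gene)
  }
  final_pair <- sort(remaining)
  final_m <- if (length(final_pair) == 2)
    V[final_pair[1], final_pair[2]] else NA_real_
  traj[[step + 1L]] <- data.frame(
    step = step + 1L, gene = final_pair,
    m = rep(final_m, length(final_pair)), stringsAsFactors = FALSE)
  structure(list(
    m_trajectory = do.call(rbind, traj),
    exclusion_order = excluded,
    final_pair = final_pair,
    ranking = c(final_pair, rev(excluded)),
    final_m = final_m,
    pairwise_variation = V), class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result>\n")
  cat("  ranking (most stable first):", paste(x$ranking, collapse = ", "), "\n")
  cat(sprintf("  final pair: %s (M = %.4f)\n",
              paste(x$final_pair, collapse = " / "), x$final_m))
  invisible(x)
}

#' Sequential normalization-factor pairwise variation (V series)
#'
#' `NF_n(s)` is the geometric mean RQ of the `n` most stable genes;
#' `V(n, n+1)` is the n-1 SD over samples of `log2(NF_n / NF_{n+1})`. The
#' recommended number of references is the smallest `n` whose `V(n, n+1)`
#' falls below `v_threshold` (canonical guidance 0.15); when no `n`
#' qualifies, the `n` minimizing `V` is recommended (adding further genes
#' is then unnecessary). Samples missing any ranked gene are dropped with
#' a warning count.
#'
#' @param rq an [cq_to_rq()] result.
#' @param ranked_genes genes ordered most to least stable (>= 3).
#' @param v_threshold pairwise-variation threshold (default 0.15).
#' @return list with `v_series` (data.frame: n, v), `recommended_n`,
#'   `threshold_met` (logical).
#' @export
pairwise_variation_series <- function(rq, ranked_genes, v_threshold = 0.15) {
  G <- length(ranked_genes)
  if (G < 3) stop("at least 3 ranked genes required", call. = FALSE)
  y <- log2(rq$values[ranked_genes, , drop = FALSE])
  complete <- colSums(is.na(y)) == 0
  n_drop <- sum(!complete)
  if (n_drop > 0)
    warning(sprintf("%d sample(s) dropped (missing a ranked gene)", n_drop),
            call. = FALSE)
  y <- y[, complete, drop = FALSE]
  if (ncol(y) < 2) stop("fewer than 2 complete samples", call. = FALSE)
  # log2 NF_n per sample = mean of the top-n genes' log2 RQs
  log_nf <- apply(y, 2, function(col) cumsum(col) / seq_along(col))
  v <- vapply(2:(G - 1), function(n)
    stats::sd(log_nf[n, ] - log_nf[n + 1, ]), numeric(1))
  vs <- data.frame(n = 2:(G - 1), v = v)
  below <- vs$n[vs$v < v_threshold]
  threshold_met <- length(below) > 0
  recommended_n <- if (threshold_met) min(below) else vs$n[which.min(vs$v)]
  list(v_series = vs, recommended_n = recommended_n,
       threshold_met = threshold_met, v_threshold = v_threshold)
}

#' Full geNorm analysis
#'
#' Runs [genorm_rank()] then [pairwise_variation_series()] on the ranking.
#'
#' @inheritParams genorm_rank
#' @inheritParams pairwise_variation_series
#' @return A `genorm_result` augmented with `v_series`, `recommended_n`,
#'   `threshold_met`.
#' @export
genorm <- function(rq, genes = NULL, v_threshold = 0.15) {
  res <- genorm_rank(rq, genes)
  if (length(res$ranking) >= 3) {
    vs <- pairwise_variation_series(rq, res$ranking, v_threshold)
    res$v_series <- vs$v_series
    res$recommended_n <- vs$recommended_n
    res$threshold_met <- vs$threshold_met
  }
  res
}
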