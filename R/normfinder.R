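# NormFinder-style model-based stability estimation for a two-group
# design. Works on log2 relative quantities, centred per sample across
# genes (which removes sample-wide shifts and per-gene scaling). Each
# gene's stability combines its de-biased intra-group variance with a
# shrunken estimate of its between-group expression difference; lower is
# more stable.
#
# Estimator chain (G genes, K = 2 groups, n_g samples in group g):
#   z_igj  = y_igj - mean_i y_igj                   (per-sample centring)
#   s2_ig  = n-1 residual variance of z_igj about its gene-group mean
#   sig2_ig = max(0, (s2_ig - sum_i' s2_i'g / (G(G-1))) / (1 - 2/G))
#   dhat_ig = zbar_ig - mean_g zbar_ig
#   gamma2  = max(0, sum_ig dhat_ig^2 / ((G-1)(K-1))
#                   - mean_ig(sig2_ig / n_g))
#   dtil_ig = dhat_ig * gamma2 / (gamma2 + sig2_ig / n_g)   (0 if gamma2=0)
#   rho_i   = mean_g [ |dtil_ig| +
#                      sqrt((sig2_ig/n_g) * gamma2/(gamma2 + sig2_ig/n_g)) ]

# Shared internal machinery -------------------------------------------------

# Centre log2 RQs per sample and compute panel-level quantities reused by
# single-gene and pair evaluation.
.nf_setup <- function(rq, genes, groups) {
  y <- log2(rq$values[genes, , drop = FALSE])
  complete <- colSums(is.na(y)) == 0
  y <- y[, complete, drop = FALSE]
  g <- groups[colnames(y)]
  if (anyNA(g)) stop("samples missing a group label", call. = FALSE)
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("exactly 2 groups required", call. = FALSE)
  n_g <- table(factor(g, levels = lev))
  if (any(n_g < 3)) stop("each group needs >= 3 samples", call. = FALSE)
  G <- length(genes)
  if (G < 3) stop("at least 3 genes required", call. = FALSE)
  z <- sweep(y, 2, colMeans(y))           # centre per sample across genes
  # per gene x group: mean and n-1 residual variance
  zbar <- s2 <- matrix(NA_real_, G, 2, dimnames = list(genes, lev))
  for (k in 1:2) {
    zk <- z[, g == lev[k], drop = FALSE]
    zbar[, k] <- rowMeans(zk)
    s2[, k] <- apply(zk, 1, stats::var)
  }
  corr <- colSums(s2) / (G * (G - 1))     # per-group de-bias term
  sig2 <- pmax(sweep(s2, 2, corr) / (1 - 2 / G), 0)
  dhat <- zbar - rowMeans(zbar)
  gamma2 <- max(0, sum(dhat^2) / ((G - 1) * (2 - 1)) -
                  mean(sweep(sig2, 2, as.numeric(n_g), `/`)))
  list(z = z, g = g, lev = lev, n_g = as.numeric(n_g), G = G,
       zbar = zbar, s2 = s2, corr = corr, sig2 = sig2, dhat = dhat,
       gamma2 = gamma2)
}

# Stability of one centred series (a gene's row of z, or a pair composite),
# using the panel-level de-bias term and gamma2.
.nf_stability <- function(series, setup) {
  lev <- setup$lev
  zbar <- s2 <- numeric(2)
  for (k in 1:2) {
    sk <- series[setup$g == lev[k]]
    zbar[k] <- mean(sk)
    s2[k] <- stats::var(sk)
  }
  sig2 <- pmax(0, (s2 - setup$corr) / (1 - 2 / setup$G))
  dhat <- zbar - mean(zbar)
  v <- sig2 / setup$n_g
  shrink <- if (setup$gamma2 > 0) setup$gamma2 / (setup$gamma2 + v) else
    rep(0, 2)
  dtil <- dhat * shrink
  rho <- mean(abs(dtil) + sqrt(v * shrink))
  list(rho = rho, sig2 = sig2, dhat = dhat, dtil = dtil)
}

#' NormFinder stability ranking
#'
#' Model-based two-group variance decomposition on log2 relative
#' quantities: per-sample centring across genes, de-biased intra-group
#' variance estimates, shrunken inter-group differences, and a per-gene
#' stability value (lower = more stable). Requires at least 3 genes,
#' exactly 2 groups with at least 3 samples each, and complete cases
#' across the gene set (incomplete samples are dropped).
#'
#' @param rq an [cq_to_rq()] result.
#' @param genes assays to rank (default: all).
#' @param groups a sample sheet data.frame (`sample_id`, `group`) or a
#'   named group vector; exactly two groups among the RQ samples.
#' @return A `normfinder_result`: list with `table` (gene, stability,
#'   per-group variance and shrunken difference, sorted by stability with
#'   lexicographic tie-break), `best_gene`, `gamma2`, `groups`.
#' @export
normfinder_rank <- function(rq, genes = NULL, groups) {
  genes <- genes %||% rownames(rq$values)
  gv <- .group_vector(groups)
  setup <- .nf_setup(rq, genes, gv[intersect(names(gv), colnames(rq$values))])
  per_gene <- lapply(genes, function(gn)
    .nf_stability(setup$z[gn, ], setup))
  tab <- data.frame(
    gene = genes,
    stability = vapply(per_gene, `[[`, numeric(1), "rho"),
    sigma2_g1 = vapply(per_gene, function(p) p$sig2[1], numeric(1)),
    sigma2_g2 = vapply(per_gene, function(p) p$sig2[2], numeric(1)),
    dtilde_g1 = vapply(per_gene, function(p) p$dtil[1], numeric(1)),
    dtilde_g2 = vapply(per_gene, function(p) p$dtil[2], numeric(1)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$stability, tab$gene), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, best_gene = tab$gene[1],
                 gamma2 = setup$gamma2, group_levels = setup$lev,
                 setup = setup),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("<normfinder_result>\n")
  print(x$table[, c("rank", "gene", "stability")], row.names = FALSE)
  cat(sprintf("  best gene: %s; between-gene group-difference variance %.4g\n",
              x$best_gene, x$gamma2))
  invisible(x)
}

#' NormFinder best reference pair
#'
#' Evaluates every gene pair's composite centred series
#' `(z_i + z_i')/2` with the same estimator chain (the panel-level
#' de-bias term and shrinkage variance are held fixed) and returns the
#' pair minimizing the composite stability. Group effects of opposite
#' sign cancel in the composite, which is why a pair can beat both its
#' members.
#'
#' @inheritParams normfinder_rank
#' @return list with `pair` (sorted), `pair_stability`, and `pair_table`
#'   (all pairs, sorted by stability; ties broken lexicographically).
#' @export
normfinder_best_pair <- function(rq, genes = NULL, groups) {
  genes <- genes %||% rownames(rq$values)
  if (length(genes) < 2) stop("at least 2 genes required", call. = FALSE)
  setup <- .nf_setup(rq, genes, .group_vector(groups)[
    intersect(names(.group_vector(groups)), colnames(rq$values))])
  pairs <- utils::combn(sort(genes), 2)
  rho <- apply(pairs, 2, function(p) {
    comp <- (setup$z[p[1], ] + setup$z[p[2], ]) / 2
    .nf_stability(comp, setup)$rho
  })
  tab <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    stability = rho, stringsAsFactors = FALSE)
  tab <- tab[order(tab$stability, tab$gene_a, tab$gene_b), ]
  rownames(tab) <- NULL
  list(pair = c(tab$gene_a[1], tab$gene_b[1]),
       pair_stability = tab$stability[1], pair_table = tab)
}
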