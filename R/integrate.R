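#' Select differentially expressed genes for correlation analysis
#'
#' The gene-side cascade: keep genes that are significant at `fdr`, belong
#' to the supplied pathway set (e.g. a gastrointestinal-cancer pathway
#' membership list), and have absolute log2 fold change strictly greater
#' than `min_abs_lfc`.
#'
#' @param de data.frame of differential results (feature_id, log2fc, q)
#' @param pathway_genes character vector of pathway member gene IDs
#' @param fdr q-value cutoff (strict <), default 0.05
#' @param min_abs_lfc absolute log2 fold-change cutoff (strict >), default 0.35
#' @return character vector of selected gene IDs
#' @export
select_genes <- function(de, pathway_genes, fdr = 0.05, min_abs_lfc = 0.35) {
  keep <- de$q < fdr & de$feature_id %in% pathway_genes &
    abs(de$log2fc) > min_abs_lfc
  out <- de$feature_id[keep]
  if (!length(out)) warning("gene selection returned no genes")
  out
}

#' Read a gene subset list (one gene ID per line)
#' @param path plain-text file; blank lines and #-comments ignored
#' @return character vector
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Centered log-ratio transform
#'
#' Per sample: add `pseudocount` to every count, then subtract the sample's
#' mean log from each log count, mapping the composition into unconstrained
#' real space where standard correlation is meaningful. Input is expected to
#' be the genus-collapsed, prevalence-filtered table (collapse, then filter,
#' then CLR).
#'
#' @param table a counts `feature_table`
#' @param pseudocount added to every count before the log (default 1);
#'   must be > 0 whenever zeros are present
#' @return a `clr_matrix`: list(taxon_ids, sample_ids, values) with each
#'   sample column summing to 0
#' @export
clr_transform <- function(table, pseudocount = 1) {
  v <- table$values
  if (pseudocount <= 0 && any(v == 0)) {
    stop("pseudocount must be > 0 when the table contains zeros")
  }
  lx <- log(v + pseudocount)
  clr <- sweep(lx, 2L, colMeans(lx), "-")
  structure(list(taxon_ids = rownames(v), sample_ids = colnames(v),
                 values = clr),
            class = "clr_matrix")
}

# Permutation matrices for the exact Spearman null, cached per n.
.perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(matrix(v, nrow = 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm_rec(v[-i]))
    }))
  }
  P <- perm_rec(seq_len(n))
  .perm_cache[[key]] <- P
  P
}

# Exact two-sided permutation p for Spearman rho with tie-free ranks.
spearman_exact_p <- function(xr, yr, rho_obs) {
  n <- length(xr)
  P <- all_permutations(n)
  xc <- xr - mean(xr)
  yc <- yr - mean(yr)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  rho_all <- (matrix(yc[P], nrow(P), n) %*% xc) / denom
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

#' Spearman screen of all gene-taxon pairs
#'
#' Correlates every selected gene's normalized expression with every taxon's
#' CLR abundance across the shared samples: tie-aware Spearman rho (Pearson
#' on mid-ranks), with a two-sided p from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df, or the exact permutation
#' null when n <= 9 and the pair is tie-free. Pairs with a constant vector
#' have undefined rho and are reported with rho 0, p 1 and a flag.
#'
#' @param gene_expr a `feature_table` of normalized expression over the
#'   selected genes (e.g. counts divided by size factors)
#' @param clr a `clr_matrix` over the filtered taxa
#' @return data.frame with one row per gene x taxon pair: gene_id, taxon_id,
#'   rho, p, flag (q is added by [qvalues()] downstream)
#' @export
spearman_screen <- function(gene_expr, clr) {
  samples <- align_ids(sample_ids(gene_expr), clr$sample_ids,
                       what = "samples (expression vs CLR)")
  if (length(samples) < 4L) stop("need >= 4 shared samples")
  n <- length(samples)
  g <- gene_expr$values[, samples, drop = FALSE]
  tx <- clr$values[, samples, drop = FALSE]
  gr <- t(apply(g, 1L, rank))        # mid-ranks, tie-aware
  tr <- t(apply(tx, 1L, rank))
  const_g <- apply(g, 1L, function(x) length(unique(x)) == 1L)
  const_t <- apply(tx, 1L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(stats::cor(t(gr), t(tr)))
  rho[!is.finite(rho)] <- 0
  tied_g <- apply(gr, 1L, anyDuplicated) > 0L
  tied_t <- apply(tr, 1L, anyDuplicated) > 0L
  genes <- rownames(g); taxa <- rownames(tx)
  res <- data.frame(
    gene_id = rep(genes, times = length(taxa)),
    taxon_id = rep(taxa, each = length(genes)),
    rho = as.numeric(rho),
    p = NA_real_,
    flag = "",
    stringsAsFactors = FALSE
  )
  # t approximation, vectorized over all pairs
  r <- pmin(pmax(res$rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  res$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  res$p <- pmin(res$p, 1)
  i_idx <- rep(seq_along(genes), times = length(taxa))
  j_idx <- rep(seq_along(taxa), each = length(genes))
  const_pair <- const_g[i_idx] | const_t[j_idx]
  if (any(const_pair)) {
    res$rho[const_pair] <- 0
    res$p[const_pair] <- 1
    res$flag[const_pair] <- "constant_vector"
  }
  if (n <= 9L) {
    exact_pair <- which(!const_pair & !tied_g[i_idx] & !tied_t[j_idx])
    for (k in exact_pair) {
      res$p[k] <- spearman_exact_p(gr[i_idx[k], ], tr[j_idx[k], ], res$rho[k])
    }
  }
  res$p <- pmax(res$p, .Machine$double.xmin)
  res
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution on the
#' lambda grid 0.05, 0.10, ..., 0.95 with a cubic smoothing spline evaluated
#' at the largest lambda, then scales the BH step-up adjustment by pi0.
#' When the spline estimate falls outside (0, 1] the estimator falls back to
#' pi0 = 1, which reproduces BH exactly.
#'
#' @param p numeric vector of p-values in (0, 1]
#' @param pi0 optional override of the null-proportion estimate (pi0 = 1
#'   forces BH)
#' @return numeric vector of q-values
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)
  if (pi0 <= 0 || pi0 > 1) pi0 <- 1
  pmin(pi0 * bh_adjust(p), 1)
}

#' Estimate the null proportion pi0 (Storey's smoother)
#' @param p numeric vector of p-values
#' @param lambda grid of tail cutoffs
#' @return scalar pi0 estimate in (0, 1]
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  if (m < 20L) return(1)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
  fit <- tryCatch(stats::smooth.spline(lambda, pi0_l, df = 3),
                  error = function(e) NULL)
  if (is.null(fit)) return(1)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) 1 else pi0
}

#' Significant gene-taxon pairs
#'
#' @param pairs data.frame from [spearman_screen()] with a `q` column
#' @param q_threshold strict q cutoff, default 0.1
#' @return the significant rows, sorted by |rho| descending
#' @export
significant_pairs <- function(pairs, q_threshold = 0.1) {
  if (!"q" %in% names(pairs)) stop("pairs need a q column; run qvalues() first")
  out <- pairs[pairs$q < q_threshold, , drop = FALSE]
  out[order(-abs(out$rho)), , drop = FALSE]
}

#' Size-factor-normalized expression
#'
#' Divides counts by per-sample size factors. Spearman correlation is
#' rank-based, so any per-sample-consistent monotone normalization gives the
#' same screen result; this is the simplest such choice.
#'
#' @param table a counts `feature_table`
#' @param sf size factors (default: computed)
#' @return a `feature_table` of normalized expression (kind "counts", since
#'   the values are depth-corrected counts, not compositions)
#' @export
normalize_expression <- function(table, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(table)
  sf <- sf[sample_ids(table)]
  structure(list(values = sweep(table$values, 2L, sf, "/"), kind = "counts"),
            class = "feature_table")
}
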