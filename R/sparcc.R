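#' SparCC configuration
#'
#' Published defaults of the sparse compositional correlation algorithm: 20
#' resampled estimation iterations (median-aggregated), up to 10
#' strongest-pair exclusion rounds per iteration at threshold 0.1, Dirichlet
#' posterior fractions with alpha = counts + 1, and 100 randomized datasets
#' for pseudo p-values.
#'
#' @param n_estimation_iters outer resampling iterations
#' @param n_exclusion_iters maximum strong-pair exclusions per iteration
#' @param exclusion_threshold |r| above which the strongest pair is excluded
#'   from the sparsity system
#' @param n_null randomized datasets for pseudo p-values
#' @param seed integer seed
#' @return a `sparcc_config` list
#' @export
sparcc_config <- function(n_estimation_iters = 20L, n_exclusion_iters = 10L,
                          exclusion_threshold = 0.1, n_null = 100L, seed = 1L) {
  cfg <- list(n_estimation_iters = as.integer(n_estimation_iters),
              n_exclusion_iters = as.integer(n_exclusion_iters),
              exclusion_threshold = as.numeric(exclusion_threshold),
              n_null = as.integer(n_null), seed = as.integer(seed))
  if (cfg$n_estimation_iters < 1L || cfg$n_exclusion_iters < 1L || cfg$n_null < 1L)
    stop("iteration counts must be positive")
  if (cfg$exclusion_threshold <= 0 || cfg$exclusion_threshold >= 1)
    stop("exclusion_threshold must be in (0, 1)")
  structure(cfg, class = "sparcc_config")
}

# Solve the basis-variance system under the sparsity assumption.
# t_mat: D x D log-ratio variation matrix; excluded: 2-column matrix of
# excluded pair indices. Returns the basis variance vector omega.
solve_basis_variances <- function(t_mat, excluded = NULL) {
  d <- nrow(t_mat)
  M <- matrix(1, d, d)
  diag(M) <- d - 1
  t_eff <- t_mat
  if (!is.null(excluded) && nrow(excluded)) {
    for (k in seq_len(nrow(excluded))) {
      i <- excluded[k, 1L]; j <- excluded[k, 2L]
      M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
      M[i, j] <- M[i, j] - 1; M[j, i] <- M[j, i] - 1
      t_eff[i, j] <- 0; t_eff[j, i] <- 0
    }
  }
  drop(solve(M, rowSums(t_eff)))
}

# One SparCC estimation pass on a fixed fraction matrix (D x n, columns sum
# to 1): variation matrix, basis solve, iterative strong-pair exclusion.
# Returns the D x D correlation estimate (NaN rows for unresolvable basis
# variances).
sparcc_single <- function(fractions, n_exclusion_iters, exclusion_threshold) {
  logf <- log(fractions)
  cv <- stats::cov(t(logf))
  d <- nrow(cv)
  t_mat <- outer(diag(cv), diag(cv), "+") - 2 * cv
  excluded <- matrix(integer(), 0L, 2L)
  corr_from <- function(omega) {
    bad <- omega <= 0 | !is.finite(omega)
    om <- ifelse(bad, NA_real_, omega)
    r <- (outer(om, om, "+") - t_mat) / (2 * sqrt(outer(om, om)))
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r[bad, ] <- NaN; r[, bad] <- NaN
    r
  }
  omega <- solve_basis_variances(t_mat, excluded)
  r <- corr_from(omega)
  for (it in seq_len(n_exclusion_iters)) {
    cand <- abs(r)
    diag(cand) <- 0
    cand[is.na(cand)] <- 0
    if (nrow(excluded)) cand[excluded] <- 0
    cand[lower.tri(cand)] <- 0
    top <- arrayInd(which.max(cand), dim(cand))
    if (cand[top] <= exclusion_threshold) break
    excluded <- rbind(excluded, top)
    omega <- solve_basis_variances(t_mat, excluded)
    r <- corr_from(omega)
  }
  r
}

#' SparCC basis correlations from a count table
#'
#' Estimates correlations between underlying (basis) abundances from
#' compositional counts: per estimation iteration, component fractions are
#' drawn from a per-sample Dirichlet(counts + 1) posterior; the pairwise
#' log-ratio variation matrix t_ij = var(log(f_i/f_j)) is converted to basis
#' variances by solving the linear system implied by the sparsity assumption
#' (most correlations near zero); pairs whose estimated |r| exceeds the
#' exclusion threshold are iteratively removed from the system and the
#' basis re-solved. The final estimate is the element-wise median over
#' iterations. Pairs whose basis variance could not be resolved are NaN and
#' flagged (they are later dropped from network assembly).
#'
#' @param table a counts `feature_table` over the screened taxa (at least 4
#'   taxa; at least 8 samples recommended)
#' @param cfg a `sparcc_config`
#' @return data.frame: taxon_i, taxon_j (i < j in table order), r, flag
#' @export
sparcc <- function(table, cfg = sparcc_config()) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  d <- nrow(v)
  if (d < 4L) stop("SparCC needs >= 4 taxa (basis system under-determined)")
  if (ncol(v) < 8L) gn_log("fewer than 8 samples; SparCC estimates will be noisy",
                           level = "warning")
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  r_med <- sparcc_r_matrix(v, cfg)
  idx <- which(upper.tri(r_med), arr.ind = TRUE)
  taxa <- rownames(v)
  data.frame(taxon_i = taxa[idx[, 1L]], taxon_j = taxa[idx[, 2L]],
             r = r_med[idx],
             flag = ifelse(is.nan(r_med[idx]), "unresolved_basis", ""),
             stringsAsFactors = FALSE)
}

# Median-aggregated SparCC correlation matrix. Consumes the current RNG
# stream (callers set the seed).
sparcc_r_matrix <- function(counts, cfg) {
  d <- nrow(counts); n <- ncol(counts)
  acc <- array(NA_real_, c(d, d, cfg$n_estimation_iters))
  for (b in seq_len(cfg$n_estimation_iters)) {
    g <- matrix(stats::rgamma(d * n, shape = counts + 1, rate = 1), d, n)
    fractions <- sweep(g, 2L, colSums(g), "/")
    acc[, , b] <- sparcc_single(fractions, cfg$n_exclusion_iters,
                                cfg$exclusion_threshold)
  }
  r <- apply(acc, c(1L, 2L), function(x) {
    x <- x[!is.nan(x)]
    if (length(x)) stats::median(x) else NaN
  })
  dimnames(r) <- list(rownames(counts), rownames(counts))
  r
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Builds `cfg$n_null` randomized datasets by independently permuting each
#' taxon's counts across samples (breaking all associations while preserving
#' marginals), re-estimates SparCC on each, and reports the two-sided
#' add-one pseudo p-value `(1 + #{|r_null| >= |r_obs|}) / (1 + n_null)` per
#' pair.
#'
#' @param table the counts `feature_table` used for [sparcc()]
#' @param observed data.frame returned by [sparcc()]
#' @param cfg a `sparcc_config`
#' @return `observed` with columns pseudo_p and n_null added
#' @export
sparcc_pseudo_p <- function(table, observed, cfg = sparcc_config()) {
  v <- table$values
  d <- nrow(v); n <- ncol(v)
  set.seed(derive_seed(cfg$seed, 500L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  r_obs <- observed$r
  exceed <- integer(length(r_obs))
  valid <- integer(length(r_obs))
  for (b in seq_len(cfg$n_null)) {
    perm <- v
    for (i in seq_len(d)) perm[i, ] <- v[i, sample.int(n)]
    r_null <- sparcc_r_matrix(perm, cfg)[idx]
    ok <- !is.nan(r_null) & !is.nan(r_obs)
    exceed[ok] <- exceed[ok] + (abs(r_null[ok]) >= abs(r_obs[ok]))
    valid[ok] <- valid[ok] + 1L
  }
  observed$pseudo_p <- ifelse(valid > 0, (1 + exceed) / (1 + valid), NA_real_)
  observed$n_null <- valid
  observed
}

#' Assemble the mixed gene-taxon network
#'
#' Gene-taxon edges are Spearman pairs with q strictly below `q_threshold`;
#' taxon-taxon edges are SparCC pairs with |r| at or above `r_threshold`
#' (inclusive) AND pseudo p strictly below `p_threshold`. Nodes are exactly
#' the endpoints of retained edges. SparCC pairs with unresolved (NaN) r are
#' never turned into edges.
#'
#' @param gene_taxon data.frame from [spearman_screen()] + [qvalues()]
#'   (columns gene_id, taxon_id, rho, q)
#' @param taxon_taxon data.frame from [sparcc_pseudo_p()] (columns taxon_i,
#'   taxon_j, r, pseudo_p); may be NULL
#' @param q_threshold strict cutoff for gene-taxon q, default 0.1
#' @param r_threshold inclusive cutoff for |SparCC r|, default 0.1
#' @param p_threshold strict cutoff for pseudo p, default 0.05
#' @return a `gutnet_network`
#' @export
build_network <- function(gene_taxon, taxon_taxon = NULL, q_threshold = 0.1,
                          r_threshold = 0.1, p_threshold = 0.05) {
  gt <- gene_taxon[gene_taxon$q < q_threshold, , drop = FALSE]
  edges <- data.frame(source = gt$gene_id, target = gt$taxon_id,
                      edge_type = rep("gene_taxon", nrow(gt)),
                      weight = gt$rho, significance = gt$q,
                      stringsAsFactors = FALSE)
  if (!is.null(taxon_taxon) && nrow(taxon_taxon)) {
    tt <- taxon_taxon[!is.na(taxon_taxon$r) & !is.nan(taxon_taxon$r) &
                        abs(taxon_taxon$r) >= r_threshold &
                        taxon_taxon$pseudo_p < p_threshold, , drop = FALSE]
    if (nrow(tt)) {
      edges <- rbind(edges,
                     data.frame(source = tt$taxon_i, target = tt$taxon_j,
                                edge_type = "taxon_taxon", weight = tt$r,
                                significance = tt$pseudo_p,
                                stringsAsFactors = FALSE))
    }
  }
  genes <- unique(edges$source[edges$edge_type == "gene_taxon"])
  taxa <- unique(c(edges$target[edges$edge_type == "gene_taxon"],
                   edges$source[edges$edge_type == "taxon_taxon"],
                   edges$target[edges$edge_type == "taxon_taxon"]))
  clash <- intersect(genes, taxa)
  if (length(clash)) {
    stop("ID(s) typed as both gene and taxon: ", paste(clash, collapse = ", "))
  }
  nodes <- data.frame(id = c(genes, taxa),
                      node_type = c(rep("gene", length(genes)),
                                    rep("taxon", length(taxa))),
                      stringsAsFactors = FALSE)
  gutnet_network(nodes, edges)
}

#' Degree and sign summary of a network
#'
#' The bookkeeping behind hub statements: per-node degree and count of
#' positive/negative edges, plus the mean degree per node type (genes vs
#' taxa).
#'
#' @param net a `gutnet_network`
#' @return list: `nodes` (data.frame id, node_type, degree, n_positive,
#'   n_negative), `mean_degree` (named by node type); both empty for an
#'   empty network
#' @export
network_stats <- function(net) {
  validate_network(net)
  if (!nrow(net$nodes)) {
    return(list(nodes = data.frame(id = character(), node_type = character(),
                                   degree = integer(), n_positive = integer(),
                                   n_negative = integer()),
                mean_degree = setNames(numeric(), character())))
  }
  ends <- c(net$edges$source, net$edges$target)
  wts <- rep(net$edges$weight, 2L)
  deg <- vapply(net$nodes$id, function(id) sum(ends == id), integer(1L))
  npos <- vapply(net$nodes$id, function(id) sum(ends == id & wts > 0), integer(1L))
  nneg <- vapply(net$nodes$id, function(id) sum(ends == id & wts < 0), integer(1L))
  nodes <- data.frame(id = net$nodes$id, node_type = net$nodes$node_type,
                      degree = deg, n_positive = npos, n_negative = nneg,
                      stringsAsFactors = FALSE, row.names = NULL)
  mean_degree <- tapply(nodes$degree, nodes$node_type, mean)
  list(nodes = nodes, mean_degree = mean_degree)
}
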