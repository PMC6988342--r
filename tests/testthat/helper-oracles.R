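# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, enumeration) so they never share code paths
# with the implementation they check.

# -- alpha diversity / distances -------------------------------------------

chao1_brute <- function(x) {
  s_obs <- 0; f1 <- 0; f2 <- 0
  for (v in x) {
    if (v > 0) s_obs <- s_obs + 1
    if (v == 1) f1 <- f1 + 1
    if (v == 2) f2 <- f2 + 1
  }
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

shannon_brute <- function(x) {
  tot <- sum(x)
  h <- 0
  for (v in x) {
    if (v > 0) {
      p <- v / tot
      h <- h - p * log(p)
    }
  }
  h
}

bray_brute <- function(x, y) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  num / den
}

# -- multiple testing -------------------------------------------------------

bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # step-up: q for the i-th smallest is min over j >= i of m*p_(j)/j
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# -- hypergeometric enumeration for the contaminant score ------------------

# P(X >= k_ctrl) where X ~ Hypergeometric: draw n_ctrl of the n_ctrl+n_real
# samples, with k_ctrl+k_real of them "present".
hyper_tail_brute <- function(k_ctrl, n_ctrl, k_real, n_real) {
  k_tot <- k_ctrl + k_real
  n_tot <- n_ctrl + n_real
  total <- choose(n_tot, n_ctrl)
  num <- 0
  for (x in 0:n_ctrl) {
    if (x >= k_ctrl && x <= k_tot && (n_ctrl - x) <= (n_tot - k_tot)) {
      num <- num + choose(k_tot, x) * choose(n_tot - k_tot, n_ctrl - x)
    }
  }
  num / total
}

# -- fixtures ---------------------------------------------------------------

random_count_table <- function(n_feat = 6L, n_samp = 4L, max_count = 50L,
                               prefix = "F") {
  m <- matrix(as.double(sample.int(max_count + 1L, n_feat * n_samp, replace = TRUE) - 1L),
              n_feat, n_samp,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n_feat)),
                              sprintf("S%02d", seq_len(n_samp))))
  # avoid all-zero columns, which relative-abundance conversion rejects
  for (j in seq_len(n_samp)) if (sum(m[, j]) == 0) m[1L, j] <- 1
  feature_table(m, kind = "counts")
}

two_group_metadata <- function(n_cf, n_healthy, n_controls = 0L) {
  ids <- c(sprintf("CF_%02d", seq_len(n_cf)), sprintf("H_%02d", seq_len(n_healthy)))
  geno <- c(rep(c("CF_df508", "CF_other"), length.out = n_cf),
            rep("Healthy", n_healthy))
  if (n_controls > 0L) {
    ids <- c(ids, sprintf("NC_%02d", seq_len(n_controls)))
    geno <- c(geno, rep(NA_character_, n_controls))
  }
  sample_metadata(
    sample_id = ids,
    condition = c(rep("CF", n_cf), rep("Healthy", n_healthy),
                  rep(NA_character_, n_controls)),
    genotype = geno,
    is_negative_control = c(rep(FALSE, n_cf + n_healthy), rep(TRUE, n_controls))
  )
}

# truth with nothing planted except what the caller asks for
bare_truth <- function(n_taxa, links = NULL, basis = NULL, da = NULL,
                       contaminants = character()) {
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  if (is.null(basis)) {
    basis <- diag(n_taxa)
    dimnames(basis) <- list(taxa, taxa)
  }
  sim_truth(
    de_genes = data.frame(gene_id = character(), log2fc = numeric()),
    da_taxa = if (is.null(da)) data.frame(taxon_id = character(), log2fc = numeric()) else da,
    contaminants = contaminants,
    basis_correlation = basis,
    gene_taxon_links = if (is.null(links))
      data.frame(gene_id = character(), taxon_id = character(), strength = numeric())
    else links
  )
}
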