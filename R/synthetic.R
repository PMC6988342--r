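#' Simulation configuration
#'
#' Defaults mirror the scale of a small paired biopsy study: 10 CF and 12
#' healthy mucosal samples, 2 blank-extraction negative controls, a 16S
#' sequencing depth floor of 9551 reads, and a gene-count dispersion typical
#' of bulk human RNA-seq.
#'
#' @param n_cf,n_healthy,n_controls sample counts (controls may be 0)
#' @param n_genes,n_taxa feature counts
#' @param seq_depth_range integer (min, max) sequencing depth per sample
#' @param nb_dispersion negative-binomial dispersion of gene counts
#' @param seed integer master seed; every stochastic operation derives its
#'   stream from it (Mersenne-Twister + inversion, R >= 3.6 sampling)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_cf = 10L, n_healthy = 12L, n_controls = 2L,
                       n_genes = 2000L, n_taxa = 35L,
                       seq_depth_range = c(9551L, 50000L),
                       nb_dispersion = 0.1, seed = 1L) {
  cfg <- list(n_cf = as.integer(n_cf), n_healthy = as.integer(n_healthy),
              n_controls = as.integer(n_controls), n_genes = as.integer(n_genes),
              n_taxa = as.integer(n_taxa),
              seq_depth_range = as.integer(seq_depth_range),
              nb_dispersion = as.numeric(nb_dispersion), seed = as.integer(seed))
  with(cfg, {
    if (n_cf < 1L || n_healthy < 1L || n_genes < 1L || n_taxa < 1L)
      stop("all counts must be >= 1 (n_controls may be 0)")
    if (n_controls < 0L) stop("n_controls must be >= 0")
    if (length(seq_depth_range) != 2L || seq_depth_range[1L] > seq_depth_range[2L])
      stop("seq_depth_range must be (min, max) with min <= max")
    if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  })
  structure(cfg, class = "sim_config")
}

#' Planted ground truth for a synthetic dataset
#'
#' @param de_genes data.frame (gene_id, log2fc): differentially expressed genes
#' @param da_taxa data.frame (taxon_id, log2fc): differentially abundant taxa
#' @param contaminants character vector of contaminant taxon IDs
#' @param basis_correlation symmetric PSD matrix over taxa (unit diagonal)
#' @param gene_taxon_links data.frame (gene_id, taxon_id, strength) with
#'   strength the target Spearman correlation in (-1, 1)
#' @return a `sim_truth` list
#' @export
sim_truth <- function(de_genes, da_taxa, contaminants, basis_correlation,
                      gene_taxon_links) {
  bc <- as.matrix(basis_correlation)
  if (nrow(bc) != ncol(bc) || max(abs(bc - t(bc))) > 1e-10)
    stop("basis_correlation must be symmetric")
  if (any(abs(diag(bc) - 1) > 1e-10)) stop("basis_correlation needs unit diagonal")
  off <- bc[upper.tri(bc)]
  if (length(off) && any(abs(off) >= 1)) stop("off-diagonal |correlation| must be < 1")
  ev <- eigen(bc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("basis_correlation is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev)))
  }
  if (nrow(gene_taxon_links) && any(abs(gene_taxon_links$strength) >= 1))
    stop("link strengths must lie in (-1, 1)")
  structure(list(de_genes = de_genes, da_taxa = da_taxa,
                 contaminants = as.character(contaminants),
                 basis_correlation = bc,
                 gene_taxon_links = gene_taxon_links),
            class = "sim_truth")
}

#' A default planted truth matching a config
#'
#' Plants 10% of genes as DE (59% of them upregulated, mirroring the typical
#' direction bias of an inflamed epithelium), 8 DA taxa at |log2fc| 1-2, two
#' reagent contaminants, one strongly correlated basis pair (r = 0.8), and
#' 10 gene-taxon links at |strength| 0.75.
#'
#' @param cfg a `sim_config`
#' @param n_links number of planted gene-taxon links
#' @param link_strength absolute target Spearman of planted links
#' @param basis_pair_r basis correlation of the single planted taxon pair
#' @return a `sim_truth`
#' @export
default_truth <- function(cfg, n_links = 10L, link_strength = 0.75,
                          basis_pair_r = 0.8) {
  genes <- gene_names(cfg$n_genes)
  taxa <- taxon_names(cfg$n_taxa)
  set.seed(derive_seed(cfg$seed, 101L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  n_de <- max(1L, round(0.1 * cfg$n_genes))
  de_ids <- sample(genes, n_de)
  up <- stats::rbinom(n_de, 1L, 0.59) == 1L
  de_lfc <- ifelse(up, 1, -1) * stats::runif(n_de, 0.5, 3)
  n_da <- min(8L, cfg$n_taxa)
  da_ids <- sample(taxa, n_da)
  da_lfc <- sample(c(-1, 1), n_da, replace = TRUE) * stats::runif(n_da, 1, 2)
  n_cont <- if (cfg$n_controls > 0L) min(2L, cfg$n_taxa) else 0L
  contaminants <- if (n_cont) sample(setdiff(taxa, da_ids), n_cont) else character()
  bc <- diag(cfg$n_taxa)
  dimnames(bc) <- list(taxa, taxa)
  if (cfg$n_taxa >= 2L) bc[1L, 2L] <- bc[2L, 1L] <- basis_pair_r
  gene_pool <- setdiff(genes, de_ids)
  taxon_pool <- setdiff(taxa, contaminants)
  n_links <- min(n_links, length(gene_pool), length(taxon_pool))
  link_genes <- sample(gene_pool, n_links)
  link_taxa <- sample(taxon_pool, n_links)
  links <- data.frame(gene_id = link_genes, taxon_id = link_taxa,
                      strength = sample(c(-1, 1), n_links, replace = TRUE) * link_strength,
                      stringsAsFactors = FALSE)
  sim_truth(
    de_genes = data.frame(gene_id = de_ids, log2fc = de_lfc, stringsAsFactors = FALSE),
    da_taxa = data.frame(taxon_id = da_ids, log2fc = da_lfc, stringsAsFactors = FALSE),
    contaminants = contaminants,
    basis_correlation = bc,
    gene_taxon_links = links
  )
}

gene_names <- function(n) sprintf("gene_%04d", seq_len(n))
taxon_names <- function(n) sprintf("taxon_%03d", seq_len(n))

# Deterministic derived seeds so each simulate_* call has its own stream.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1000L + as.integer(offset)) %% 2147483629L
}

sim_sample_ids <- function(cfg) {
  list(cf = sprintf("CF_%02d", seq_len(cfg$n_cf)),
       healthy = sprintf("H_%02d", seq_len(cfg$n_healthy)),
       controls = if (cfg$n_controls > 0L) sprintf("NC_%02d", seq_len(cfg$n_controls)) else character())
}

#' Metadata for a simulated dataset
#'
#' CF samples alternate between the homozygous delta-F508 category and the
#' other-mutation category, giving the three-level genotype structure the
#' likelihood-ratio test expects.
#'
#' @param cfg a `sim_config`
#' @return a `sample_metadata` data.frame
#' @export
simulate_metadata <- function(cfg) {
  ids <- sim_sample_ids(cfg)
  geno_cf <- rep(c("CF_df508", "CF_other"), length.out = cfg$n_cf)
  sample_metadata(
    sample_id = c(ids$cf, ids$healthy, ids$controls),
    condition = c(rep("CF", cfg$n_cf), rep("Healthy", cfg$n_healthy),
                  rep(NA_character_, cfg$n_controls)),
    genotype = c(geno_cf, rep("Healthy", cfg$n_healthy),
                 rep(NA_character_, cfg$n_controls)),
    is_negative_control = c(rep(FALSE, cfg$n_cf + cfg$n_healthy),
                            rep(TRUE, cfg$n_controls))
  )
}

#' Simulate host gene counts
#'
#' Counts follow a negative binomial with mean `s_j * mu_i * 2^(log2fc_i *
#' CF_j)` and common dispersion `cfg$nb_dispersion`. Gene base means are
#' log-normal across genes; per-sample size factors derive from library
#' depths drawn log-uniformly over `seq_depth_range` and are normalized to
#' geometric mean 1 so counts stay on the base-mean scale.
#'
#' @param cfg a `sim_config`
#' @param truth a `sim_truth`
#' @return a `feature_table` of counts with a `sim` attribute carrying the
#'   generating means, size factors and condition (used by
#'   [plant_gene_taxon_links()])
#' @export
simulate_gene_counts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  genes <- gene_names(cfg$n_genes)
  unknown <- setdiff(truth$de_genes$gene_id, genes)
  if (length(unknown)) stop("de_genes outside the gene set: ",
                            paste(unknown, collapse = ", "))
  ids <- sim_sample_ids(cfg)
  samples <- c(ids$cf, ids$healthy)
  is_cf <- c(rep(1, cfg$n_cf), rep(0, cfg$n_healthy))
  set.seed(derive_seed(cfg$seed, 1L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  mu <- stats::rlnorm(cfg$n_genes, meanlog = log(50), sdlog = 1.3)
  names(mu) <- genes
  lr <- log(cfg$seq_depth_range)
  depth <- exp(stats::runif(length(samples), lr[1L], lr[2L]))
  s <- depth / exp(mean(log(depth)))
  names(s) <- samples
  lfc <- setNames(rep(0, cfg$n_genes), genes)
  lfc[truth$de_genes$gene_id] <- truth$de_genes$log2fc
  mean_mat <- outer(mu, rep(1, length(samples))) *
    outer(2^lfc, is_cf, function(f, x) f^x) *
    matrix(s, cfg$n_genes, length(samples), byrow = TRUE)
  counts <- matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                                  size = 1 / cfg$nb_dispersion),
                   cfg$n_genes, length(samples),
                   dimnames = list(genes, samples))
  ft <- feature_table(counts, kind = "counts")
  attr(ft, "sim") <- list(mu = mu, size_factors = s, is_cf = is_cf, lfc = lfc)
  ft
}

#' Simulate a mucosal microbiome count table
#'
#' A logistic-normal + multinomial composition model: per sample, log basis
#' abundances are multivariate normal with the planted correlation structure
#' (unit log-scale SD per taxon), shifted by the planted condition effects in
#' CF samples; exponentiated and normalized fractions are multinomially
#' sampled at a depth drawn uniformly from `seq_depth_range`. Contaminant
#' taxa are thinned in true samples to prevalence <= 0.2. A random coalescent
#' tree over taxa and a one-genus-per-taxon taxonomy accompany the table.
#'
#' @param cfg a `sim_config`
#' @param truth a `sim_truth` (basis_correlation must be n_taxa x n_taxa)
#' @return list with elements `table` (a counts `feature_table` over real
#'   samples), `taxonomy` (a `taxonomy_map`), `tree` (an ape `phylo`), and
#'   `basis` (taxa x samples matrix of log basis abundances)
#' @export
simulate_microbiome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  if (nrow(truth$basis_correlation) != cfg$n_taxa) {
    stop("basis_correlation dimension must equal n_taxa")
  }
  taxa <- taxon_names(cfg$n_taxa)
  ids <- sim_sample_ids(cfg)
  samples <- c(ids$cf, ids$healthy)
  n <- length(samples)
  is_cf <- c(rep(1, cfg$n_cf), rep(0, cfg$n_healthy))
  set.seed(derive_seed(cfg$seed, 2L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  # uneven baseline abundances across taxa, fixed within the dataset
  base_mu <- stats::rnorm(cfg$n_taxa, 0, 1.5)
  ev <- eigen(truth$basis_correlation, symmetric = TRUE)
  rot <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), cfg$n_taxa)
  z <- matrix(stats::rnorm(cfg$n_taxa * n), cfg$n_taxa, n)
  basis <- rot %*% z + base_mu
  lfc <- setNames(rep(0, cfg$n_taxa), taxa)
  if (nrow(truth$da_taxa)) lfc[truth$da_taxa$taxon_id] <- truth$da_taxa$log2fc
  basis <- basis + outer(lfc * log(2), is_cf)
  dimnames(basis) <- list(taxa, samples)
  fractions <- apply(exp(basis), 2L, function(x) x / sum(x))
  depth_grid <- seq.int(cfg$seq_depth_range[1L], cfg$seq_depth_range[2L])
  depth <- depth_grid[sample.int(length(depth_grid), n, replace = TRUE)]
  counts <- vapply(seq_len(n), function(j)
    as.numeric(stats::rmultinom(1L, depth[j], fractions[, j])), numeric(cfg$n_taxa))
  dimnames(counts) <- list(taxa, samples)
  # contaminants live in reagents, not tissue: thin to low, sparse counts
  max_present <- floor(0.2 * n)
  for (tx in intersect(truth$contaminants, taxa)) {
    present <- which(stats::rbinom(n, 1L, 0.05) == 1L)
    if (length(present) > max_present) present <- sample(present, max_present)
    row <- rep(0, n)
    row[present] <- stats::rpois(length(present), 5) + 1
    counts[tx, ] <- row
  }
  tree <- ape::rcoal(cfg$n_taxa, tip.label = sample(taxa))
  lin <- data.frame(
    kingdom = rep("Bacteria", cfg$n_taxa),
    phylum = paste0("Phylum_", (seq_len(cfg$n_taxa) - 1L) %/% 7L + 1L),
    class = paste0("Class_", (seq_len(cfg$n_taxa) - 1L) %/% 5L + 1L),
    order = paste0("Order_", (seq_len(cfg$n_taxa) - 1L) %/% 3L + 1L),
    family = paste0("Family_", seq_len(cfg$n_taxa)),
    genus = paste0("Genus_", seq_len(cfg$n_taxa)),
    stringsAsFactors = FALSE
  )
  list(table = feature_table(counts, kind = "counts"),
       taxonomy = taxonomy_map(taxa, lin),
       tree = tree,
       basis = basis)
}

#' Simulate negative-control samples
#'
#' Blank-extraction controls carry the planted contaminant taxa at high
#' prevalence (each control is positive with probability 0.95, topped up so
#' overall contaminant prevalence is at least 0.9) while non-contaminant taxa
#' leak in only through low-rate cross-talk (per-control presence probability
#' 0.025).
#'
#' @param cfg a `sim_config`
#' @param truth a `sim_truth` with non-empty `contaminants` if n_controls > 0
#' @return a counts `feature_table` with `cfg$n_controls` sample columns
#'   (zero columns when n_controls = 0)
#' @export
simulate_negative_controls <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  taxa <- taxon_names(cfg$n_taxa)
  ids <- sim_sample_ids(cfg)
  if (cfg$n_controls == 0L) {
    m <- matrix(numeric(), cfg$n_taxa, 0L, dimnames = list(taxa, character()))
    return(structure(list(values = m, kind = "counts"), class = "feature_table"))
  }
  if (!length(truth$contaminants)) {
    stop("truth$contaminants must be non-empty when n_controls > 0")
  }
  set.seed(derive_seed(cfg$seed, 3L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  nc <- cfg$n_controls
  counts <- matrix(0, cfg$n_taxa, nc, dimnames = list(taxa, ids$controls))
  min_present <- ceiling(0.9 * nc)
  for (tx in taxa) {
    if (tx %in% truth$contaminants) {
      present <- which(stats::rbinom(nc, 1L, 0.95) == 1L)
      if (length(present) < min_present) {
        extra <- sample(setdiff(seq_len(nc), present),
                        min_present - length(present))
        present <- c(present, extra)
      }
      counts[tx, present] <- stats::rnbinom(length(present), mu = 50, size = 5) + 1
    } else {
      present <- which(stats::rbinom(nc, 1L, 0.025) == 1L)
      counts[tx, present] <- stats::rpois(length(present), 2) + 1
    }
  }
  feature_table(counts, kind = "counts")
}

#' Plant gene-taxon correlations into a simulated gene table
#'
#' For each planted link, the linked gene's counts are re-drawn from a
#' negative binomial whose mean is multiplied by `exp(beta * z)`, where `z`
#' is the standardized log basis abundance of the linked taxon across
#' samples. `beta` comes from a pre-computed monotone lookup (Monte-Carlo
#' calibration of expected Spearman rho vs beta at the package's reference
#' dispersion) so the realized correlation matches the requested strength to
#' about +/- 0.1 at biopsy-scale n.
#'
#' @param gene_table a `feature_table` from [simulate_gene_counts()] (its
#'   `sim` attribute supplies the generating means and size factors)
#' @param microbiome_basis taxa x samples matrix of log basis abundances, as
#'   returned in `simulate_microbiome()$basis`
#' @param truth a `sim_truth` with `gene_taxon_links`
#' @param cfg the `sim_config` used to build the inputs
#' @return the gene `feature_table` with linked genes re-drawn
#' @export
plant_gene_taxon_links <- function(gene_table, microbiome_basis, truth, cfg) {
  links <- truth$gene_taxon_links
  if (!nrow(links)) return(gene_table)
  if (any(abs(links$strength) >= 1)) stop("requested |strength| must be < 1")
  sim <- attr(gene_table, "sim")
  if (is.null(sim)) stop("gene_table lacks the sim attribute from simulate_gene_counts()")
  missing_g <- setdiff(links$gene_id, feature_ids(gene_table))
  missing_t <- setdiff(links$taxon_id, rownames(microbiome_basis))
  if (length(missing_g) || length(missing_t)) {
    stop("link IDs absent from tables: ",
         paste(c(missing_g, missing_t), collapse = ", "))
  }
  samples <- align_ids(sample_ids(gene_table), colnames(microbiome_basis),
                       what = "samples (gene table vs basis)")
  v <- gene_table$values
  set.seed(derive_seed(cfg$seed, 4L), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  jj <- match(samples, sample_ids(gene_table))
  for (k in seq_len(nrow(links))) {
    strength <- links$strength[k]
    if (strength == 0) next
    g <- links$gene_id[k]; tx <- links$taxon_id[k]
    zb <- microbiome_basis[tx, samples]
    z <- as.numeric(scale(zb))
    beta <- sign(strength) * strength_to_beta(abs(strength))
    mean_vec <- sim$size_factors[samples] * sim$mu[[g]] *
      2^(sim$lfc[[g]] * sim$is_cf[jj]) * exp(beta * z)
    v[g, samples] <- stats::rnbinom(length(samples), mu = mean_vec,
                                    size = 1 / cfg$nb_dispersion)
  }
  out <- feature_table(v, kind = "counts")
  attr(out, "sim") <- sim
  out
}

# Monotone lookup: target absolute Spearman rho -> multiplier beta.
# The table ships in inst/extdata and is regenerated by
# scripts/make_beta_lookup.R (beta grid x Monte-Carlo at large n).
strength_to_beta <- function(target_rho) {
  lut <- beta_lookup()
  if (target_rho > max(lut$rho)) {
    stop(sprintf("target |strength| %.2f exceeds calibrated range (max %.2f)",
                 target_rho, max(lut$rho)))
  }
  stats::approx(lut$rho, lut$beta, xout = target_rho, rule = 2L)$y
}

beta_lookup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "spearman_beta_lookup.tsv", package = "gutnet")
      if (!nzchar(path)) stop("calibration lookup missing from installed package")
      cache <<- utils::read.delim(path)
    }
    cache
  }
})

#' Simulate a complete paired dataset
#'
#' Convenience wrapper running every generator with one config and truth:
#' gene counts (with links planted), microbiome counts with negative-control
#' columns appended, taxonomy, tree and metadata.
#'
#' @param cfg a `sim_config`
#' @param truth a `sim_truth`; defaults to [default_truth()]
#' @return list with `genes`, `otu` (controls included), `taxonomy`, `tree`,
#'   `metadata`, `basis`, `truth`, `cfg`
#' @export
simulate_dataset <- function(cfg, truth = default_truth(cfg)) {
  mb <- simulate_microbiome(cfg, truth)
  genes <- simulate_gene_counts(cfg, truth)
  genes <- plant_gene_taxon_links(genes, mb$basis, truth, cfg)
  otu <- mb$table
  if (cfg$n_controls > 0L) {
    nc <- simulate_negative_controls(cfg, truth)
    otu <- feature_table(cbind(otu$values, nc$values), kind = "counts")
  }
  list(genes = genes, otu = otu, taxonomy = mb$taxonomy, tree = mb$tree,
       metadata = simulate_metadata(cfg), basis = mb$basis,
       truth = truth, cfg = cfg)
}

#' Write a simulated dataset to a directory
#'
#' Writes gene.tsv, otu.tsv, taxonomy.tsv, tree.nwk, metadata.tsv and
#' truth.json (plus a run manifest).
#'
#' @param ds result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(ds$genes, file.path(dir, "gene.tsv"))
  write_feature_table(ds$otu, file.path(dir, "otu.tsv"))
  write_taxonomy(ds$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  write_metadata(ds$metadata, file.path(dir, "metadata.tsv"))
  truth <- ds$truth
  truth$basis_correlation <- unname(apply(truth$basis_correlation, 1L, identity,
                                          simplify = FALSE))
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(file.path(dir, "manifest.json"), "simulate",
                 params = unclass(ds$cfg))
  invisible(dir)
}
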