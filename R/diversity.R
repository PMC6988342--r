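#' Rarefy a count table to even depth
#'
#' Subsamples every sample column without replacement to exactly `depth`
#' total reads, the classical correction for uneven sequencing effort.
#'
#' @param table a counts `feature_table`
#' @param depth target depth; must not exceed any column sum
#' @param seed integer seed
#' @return a counts `feature_table` whose columns all sum to `depth`
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (table$kind != "counts") stop("rarefaction requires a counts table")
  v <- table$values
  cs <- colSums(v)
  short <- cs < depth
  if (any(short)) {
    stop("depth ", depth, " exceeds the read count of sample(s): ",
         paste(colnames(v)[short], collapse = ", "))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  out <- apply(v, 2L, function(col) {
    pool <- rep.int(seq_along(col), col)
    drawn <- if (length(pool) == depth) pool else sample(pool, depth)
    tabulate(drawn, nbins = length(col))
  })
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(v)
  feature_table(out, kind = "counts")
}

# Single-vector alpha metrics (counts in, scalar out).
alpha_metric <- function(x, metric) {
  x <- x[x > 0]
  switch(metric,
    observed_otus = length(x),
    chao1 = {
      f1 <- sum(x == 1); f2 <- sum(x == 2)
      length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
    },
    shannon = {
      p <- x / sum(x)
      -sum(p * log(p))
    },
    stop("unknown alpha-diversity metric: ", metric)
  )
}

#' Resampling-based alpha diversity
#'
#' Computes each sample's richness/diversity as the mean of the metric over
#' `n_resamples` independent rarefactions to `depth`, removing depth bias the
#' same way repeated subsampling at the minimum read depth does. Metrics:
#' `chao1` (S_obs + F1(F1-1)/(2(F2+1))), `observed_otus`, `shannon`
#' (natural log).
#'
#' @param table a counts `feature_table`
#' @param metric "chao1", "observed_otus" or "shannon"
#' @param depth rarefaction depth (default: minimum column sum)
#' @param n_resamples number of independent rarefaction draws (>= 1)
#' @param seed master seed; each draw uses a derived substream
#' @return data.frame: sample_id, metric, value, n_resamples, depth
#' @export
alpha_diversity <- function(table, metric = c("chao1", "observed_otus", "shannon"),
                            depth = NULL, n_resamples = 100L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "feature_table"), n_resamples >= 1L)
  if (is.null(depth)) depth <- min(colSums(table$values))
  acc <- matrix(0, ncol(table$values), n_resamples)
  for (r in seq_len(n_resamples)) {
    rt <- rarefy(table, depth, seed = derive_seed(seed, r))
    acc[, r] <- apply(rt$values, 2L, alpha_metric, metric = metric)
  }
  data.frame(sample_id = sample_ids(table), metric = metric,
             value = rowMeans(acc), n_resamples = as.integer(n_resamples),
             depth = as.integer(depth), stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test of alpha diversity between conditions
#'
#' Two-sided; exact null when the pooled n is at most 20 and there are no
#' ties, normal approximation with tie correction otherwise.
#'
#' @param results data.frame from [alpha_diversity()]
#' @param meta a `sample_metadata` data.frame
#' @return list(statistic = rank-sum W, p = two-sided p-value)
#' @export
alpha_group_test <- function(results, meta) {
  validate_metadata(meta)
  cond <- condition_of(meta, results$sample_id)
  groups <- split(results$value, cond)
  if (length(groups) != 2L) stop("need exactly two conditions, got: ",
                                 paste(names(groups), collapse = ", "))
  if (any(lengths(groups) < 2L)) stop("each condition needs >= 2 samples")
  x <- groups[[1L]]; y <- groups[[2L]]
  if (length(unique(c(x, y))) == 1L) {
    # fully tied pooled values: no evidence against the null
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis dissimilarity, or phylogenetic UniFrac (unweighted: fraction
#' of branch length leading to tips found in exactly one of the two samples;
#' weighted, normalized: branch-length-weighted difference of subtree
#' proportions). Typically run on a table already rarefied to even depth.
#'
#' @param table a `feature_table`
#' @param metric "bray_curtis", "unweighted_unifrac" or "weighted_unifrac"
#' @param tree rooted `phylo` covering all features (UniFrac only)
#' @return list of class `gutnet_dist`: sample_ids, matrix, metric
#' @export
beta_diversity <- function(table,
                           metric = c("bray_curtis", "unweighted_unifrac",
                                      "weighted_unifrac"),
                           tree = NULL) {
  metric <- match.arg(metric)
  v <- table$values
  n <- ncol(v)
  d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  if (metric == "bray_curtis") {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      x <- v[, i]; y <- v[, j]
      tot <- sum(x + y)
      d[i, j] <- d[j, i] <- if (tot == 0) 0 else sum(abs(x - y)) / tot
    }
  } else {
    if (is.null(tree)) stop("UniFrac requires a phylogenetic tree")
    bm <- branch_tip_map(tree, rownames(v))
    # per-sample per-branch totals
    prop <- sweep(v, 2L, colSums(v), "/")
    branch_prop <- bm$incidence %*% prop       # branches x samples
    branch_pres <- (bm$incidence %*% (v > 0)) > 0
    b <- bm$lengths
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (metric == "unweighted_unifrac") {
        ai <- branch_pres[, i]; aj <- branch_pres[, j]
        denom <- sum(b[ai | aj])
        d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(b[xor(ai, aj)]) / denom
      } else {
        A <- branch_prop[, i]; B <- branch_prop[, j]
        denom <- sum(b * (A + B))
        d[i, j] <- d[j, i] <- if (denom == 0) 0 else sum(b * abs(A - B)) / denom
      }
    }
  }
  structure(list(sample_ids = colnames(v), matrix = d, metric = metric),
            class = "gutnet_dist")
}

# Branch x tip incidence matrix for the features in `tips`, plus branch
# lengths. Every feature must be a tree tip.
branch_tip_map <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("feature(s) missing from the tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  # postorder accumulation of descendant tips per edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1L]; child <- ord$edge[k, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  inc <- matrix(0, nedge, length(tips),
                dimnames = list(NULL, tips))
  tip_index <- match(tips, tree$tip.label)
  for (k in seq_len(nedge)) {
    under <- desc[[tree$edge[k, 2L]]]
    inc[k, match(intersect(under, tip_index), tip_index)] <- 1
  }
  list(incidence = inc, lengths = tree$edge.length)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the Gower-centered matrix -D^2/2. Negative
#' eigenvalues are reported as-is (no correction); percent variance is taken
#' over the positive eigenvalues only.
#'
#' @param dm a `gutnet_dist`
#' @param k number of axes to return (default: all positive)
#' @return list: coordinates (samples x axes), eigenvalues, pct_variance
#' @export
pcoa <- function(dm, k = NULL) {
  d <- dm$matrix
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix contains non-finite values")
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- eig$values > 1e-10
  if (is.null(k)) k <- sum(pos)
  k <- min(k, sum(pos))
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k)]), k)
  rownames(coords) <- dm$sample_ids
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = eig$values,
       pct_variance = 100 * eig$values[pos] / sum(eig$values[pos]))
}

#' PERMANOVA (Adonis-style) test on a distance matrix
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and compares the observed pseudo-F against a
#' permutation null built by freely permuting group labels.
#'
#' @param dm a `gutnet_dist`
#' @param meta a `sample_metadata` data.frame
#' @param grouping metadata column to test (default "condition")
#' @param n_permutations number of label permutations
#' @param seed integer seed
#' @return list: pseudo_F, R2, p, n_permutations
#' @export
permanova <- function(dm, meta, grouping = "condition",
                      n_permutations = 999L, seed = 1L) {
  validate_metadata(meta)
  if (!grouping %in% names(meta)) stop("unknown grouping column: ", grouping)
  labels <- meta[[grouping]][match(dm$sample_ids, meta$sample_id)]
  if (anyNA(labels)) stop("grouping does not cover all samples in the distance matrix")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need >= 2 groups")
  if (any(table(labels) == 0L)) stop("a group has size 0")
  d2 <- dm$matrix^2
  n <- nrow(d2)
  a <- nlevels(droplevels(labels))
  f_stat <- function(lab) {
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in levels(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1L) {
        sub <- d2[idx, idx]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ssb <- sst - ssw
    c(F = (ssb / (a - 1)) / (ssw / (n - a)), R2 = ssb / sst)
  }
  obs <- f_stat(labels)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  exceed <- 0L
  for (p in seq_len(n_permutations)) {
    perm <- f_stat(labels[sample.int(n)])
    if (perm[["F"]] >= obs[["F"]]) exceed <- exceed + 1L
  }
  list(pseudo_F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
       p = (1 + exceed) / (1 + n_permutations),
       n_permutations = as.integer(n_permutations))
}

#' Write a distance matrix as square TSV
#' @param dm a `gutnet_dist`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(dm, path) {
  m <- dm$matrix
  header <- paste(c("#SampleID", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], digits = 15L, trim = TRUE)),
          collapse = "\t"), character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
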