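#' Agglomerate features at a taxonomic rank
#'
#' Features sharing the lineage prefix down to `rank` are summed. Features
#' unassigned at `rank` are grouped by their last characterized level and
#' labelled with that level's rank prefix (e.g. `f__Ruminococcaceae` for an
#' OTU known only to family when collapsing at genus).
#'
#' @param table a `feature_table`
#' @param taxonomy a `taxonomy_map` covering all features
#' @param rank one of kingdom, phylum, class, order, family, genus
#' @return an agglomerated `feature_table`
#' @export
agglomerate <- function(table, taxonomy, rank = "genus") {
  ranks <- taxonomy_ranks()
  if (!rank %in% ranks) stop("unknown rank: ", rank)
  idx <- match(rank, ranks)
  missing <- setdiff(feature_ids(table), taxonomy$feature_id)
  if (length(missing)) {
    stop("taxonomy missing for feature(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  tm <- taxonomy[match(feature_ids(table), taxonomy$feature_id), , drop = FALSE]
  lin <- as.matrix(tm[ranks[seq_len(idx)]])
  lin[is.na(lin)] <- ""
  keys <- apply(lin, 1L, paste, collapse = "|")
  ukeys <- unique(keys)
  labels <- vapply(ukeys, function(k) {
    row <- lin[match(k, keys), , drop = TRUE]
    names(row) <- ranks[seq_len(idx)]
    glom_label(row, rank)
  }, character(1L))
  labels <- setNames(make.unique(unname(labels), sep = "#"), ukeys)
  out <- rowsum(table$values, group = keys, reorder = FALSE)
  rownames(out) <- unname(labels[rownames(out)])
  feature_table(out, kind = table$kind)
}

#' Prevalence/abundance filter for rare taxa
#'
#' Keeps a feature iff its per-sample relative abundance reaches
#' `min_rel_abund` (inclusive) in at least half (ceiling) of the number of
#' samples in the condition with fewer samples. Only real (non-control)
#' samples participate; the returned table keeps the original counts of the
#' surviving features.
#'
#' @param table a counts `feature_table`
#' @param meta a `sample_metadata` data.frame with two conditions present
#' @param min_rel_abund relative-abundance floor in (0, 1); default 0.001
#' @return the filtered counts `feature_table` (real samples only)
#' @export
prevalence_abundance_filter <- function(table, meta, min_rel_abund = 0.001) {
  if (min_rel_abund <= 0 || min_rel_abund >= 1) {
    stop("min_rel_abund must be in (0, 1)")
  }
  ids <- real_samples(table, meta)
  cond <- condition_of(meta, ids)
  tab <- table(cond)
  if (length(tab) != 2L) stop("need both conditions present, got: ",
                              paste(names(tab), collapse = ", "))
  need <- ceiling(min(tab) / 2)
  sub <- subset_table(table, samples = ids)
  rel <- relative_abundance(sub)$values
  keep <- rowSums(rel >= min_rel_abund) >= need
  gn_log(sprintf("prevalence/abundance filter: kept %d of %d features (>= %.4g%% in >= %d samples)",
                 sum(keep), length(keep), 100 * min_rel_abund, need))
  subset_table(sub, features = feature_ids(sub)[keep])
}

#' Median-of-ratios size factors
#'
#' The library-size normalization convention for count models: each sample's
#' factor is the median ratio of its counts to the per-feature geometric
#' mean. When no feature is positive in every sample (typical 16S sparsity),
#' the "poscounts" fallback computes geometric means over positive entries
#' only (zeros still count in the denominator n).
#'
#' @param table a counts `feature_table`
#' @param fallback use the poscounts fallback when no feature is all-positive
#' @return named numeric vector of positive size factors (raw medians, not
#'   recentered)
#' @export
size_factors <- function(table, fallback = TRUE) {
  v <- table$values
  if (ncol(v) == 1L) return(setNames(1, colnames(v)))
  all_pos <- rowSums(v > 0) == ncol(v)
  if (any(all_pos)) {
    lv <- log(v[all_pos, , drop = FALSE])
    logratio <- lv - rowMeans(lv)
    s <- exp(apply(logratio, 2L, stats::median))
  } else {
    if (!fallback) {
      stop("no feature has all-positive counts; enable the poscounts fallback")
    }
    logsum <- apply(v, 1L, function(x) sum(log(x[x > 0])))
    geo <- exp(logsum / ncol(v))
    usable <- geo > 0
    s <- vapply(seq_len(ncol(v)), function(j) {
      r <- v[usable, j] / geo[usable]
      stats::median(r[v[usable, j] > 0])
    }, numeric(1L))
  }
  if (any(!is.finite(s) | s <= 0)) stop("degenerate size factor(s); check for empty samples")
  setNames(s, colnames(v))
}

# ---- negative-binomial GLM machinery --------------------------------------

# IRLS fit of an NB GLM with log link, fixed dispersion alpha and offset.
# Returns beta, se, loglik, converged.
fit_nb_glm <- function(y, X, offset, alpha, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- tryCatch(
    stats::qr.solve(X, log(y + 0.5) - offset),
    error = function(e) rep(0, p)
  )
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(X * w)
    new_beta <- tryCatch(solve(xtw %*% X, xtw %*% z), error = function(e) NULL)
    if (is.null(new_beta)) break
    new_beta <- drop(new_beta)
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  ll <- sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  list(beta = beta, se = se, loglik = ll, converged = converged, mu = mu)
}

# Method-of-moments dispersion per feature on size-factor-normalized counts,
# pooled within groups, then shrunk 50/50 in log space toward a log-log
# mean-dispersion trend fitted across features. Returns a list with the
# final alpha vector and base means.
estimate_dispersions <- function(counts, sf, group) {
  k <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(k)
  xi <- mean(1 / sf)
  groups <- split(seq_along(group), group)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (idx in groups) {
    if (length(idx) < 2L) next
    m <- rowMeans(k[, idx, drop = FALSE])
    v <- apply(k[, idx, drop = FALSE], 1L, stats::var)
    w <- length(idx) - 1L
    num <- num + w * (v - m * xi)
    den <- den + w * m^2
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  raw[!is.na(raw) & raw <= 0] <- NA_real_
  ok <- !is.na(raw) & base_mean > 0 & raw > 1e-8
  if (sum(ok) >= 10L) {
    fit <- stats::lm(log(raw[ok]) ~ log(base_mean[ok]))
    trend <- exp(stats::predict(fit, newdata = list(base_mean = base_mean)))
    trend <- exp(fit$coefficients[[1L]] + fit$coefficients[[2L]] * log(pmax(base_mean, 1e-8)))
  } else if (any(ok)) {
    trend <- rep(exp(stats::median(log(raw[ok]))), nrow(counts))
  } else {
    trend <- rep(0.1, nrow(counts))
  }
  trend <- pmax(trend, 1e-8)
  final <- ifelse(is.na(raw),
                  trend,
                  exp(0.5 * log(raw) + 0.5 * log(trend)))
  final <- pmin(pmax(final, 1e-8), 100)
  list(alpha = final, base_mean = base_mean, raw = raw, trend = trend)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m * p_(j) / j, capped
#' at 1.
#'
#' @param p numeric vector of p-values in (0, 1]
#' @return numeric vector of q-values, same order as `p`
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / rev(seq_len(m)) * p[ord]))[order(ord)]
  q
}

#' Negative-binomial Wald test for a two-level design
#'
#' Per feature, fits the GLM `log mu = beta0 + beta1 * [condition == CF] +
#' log s_j` by IRLS with a fixed method-of-moments dispersion (trend-shrunk;
#' see Details), then tests `beta1 = 0` with a two-sided normal Wald test.
#' This is a deliberately simplified stand-in for the full DESeq2 estimator:
#' no Cox-Reid adjusted likelihood, no dispersion outlier handling, no
#' independent filtering and no fold-change shrinkage, so per-feature results
#' differ from DESeq2's even on identical input.
#'
#' All-zero features are flagged and reported with log2fc 0 and p 1.
#' Features entirely zero in one condition are fitted with a 0.5-count ridge
#' so the fold change stays finite, and flagged.
#'
#' @param table a counts `feature_table`
#' @param meta a `sample_metadata` data.frame
#' @param sf size factors (default: computed via [size_factors()])
#' @return data.frame of per-feature results: feature_id, base_mean, log2fc
#'   (CF relative to Healthy), se (log2 scale), statistic, p, q, test, flag
#' @export
nb_wald <- function(table, meta, sf = NULL) {
  ids <- real_samples(table, meta)
  tab <- subset_table(table, samples = ids)
  cond <- condition_of(meta, ids)
  if (length(unique(cond)) != 2L) stop("need a two-level condition")
  if (any(table(cond) < 2L)) stop("each condition needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(tab)
  sf <- sf[ids]
  x <- as.numeric(cond == "CF")
  X <- cbind(1, x)
  counts <- tab$values
  disp <- estimate_dispersions(counts, sf, cond)
  offset <- log(sf)
  n_feat <- nrow(counts)
  log2fc <- se <- stat <- p <- numeric(n_feat)
  flag <- character(n_feat)
  for (i in seq_len(n_feat)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      log2fc[i] <- 0; se[i] <- NA_real_; stat[i] <- 0; p[i] <- 1
      flag[i] <- "all_zero"
      next
    }
    zero_group <- any(tapply(y, cond, function(g) all(g == 0)))
    y_fit <- if (zero_group) y + 0.5 else y
    fit <- fit_nb_glm(y_fit, X, offset, disp$alpha[i])
    if (!fit$converged || anyNA(fit$se)) {
      log2fc[i] <- fit$beta[2L] / log(2); se[i] <- NA_real_
      stat[i] <- 0; p[i] <- 1
      flag[i] <- "no_convergence"
      next
    }
    log2fc[i] <- fit$beta[2L] / log(2)
    se[i] <- fit$se[2L] / log(2)
    stat[i] <- fit$beta[2L] / fit$se[2L]
    p[i] <- 2 * stats::pnorm(-abs(stat[i]))
    if (zero_group) flag[i] <- "zero_group_ridge"
  }
  p <- pmax(p, .Machine$double.xmin)
  n_flagged <- sum(nzchar(flag))
  if (n_flagged) gn_log(sprintf("nb_wald: %d feature(s) flagged", n_flagged))
  data.frame(feature_id = feature_ids(tab), base_mean = disp$base_mean,
             log2fc = log2fc, se = se, statistic = stat, p = p,
             q = bh_adjust(p), test = "wald", flag = flag,
             stringsAsFactors = FALSE)
}

#' Negative-binomial likelihood-ratio test across genotype categories
#'
#' Compares the full model `~ genotype` (three categories: Healthy,
#' CF_df508, CF_other) against the intercept-only reduced model, per
#' feature, using twice the log-likelihood difference against chi-square
#' with 2 degrees of freedom. Dispersion is estimated once per feature
#' (within-genotype moments, trend-shrunk) and shared by both fits.
#'
#' @param table a counts `feature_table`
#' @param meta a `sample_metadata` data.frame whose real samples span all
#'   three genotype categories (>= 2 samples each)
#' @param sf size factors (default: computed)
#' @return data.frame of per-feature results (log2fc is the CF_df508 vs
#'   Healthy contrast from the full fit)
#' @export
nb_lrt <- function(table, meta, sf = NULL) {
  ids <- real_samples(table, meta)
  tab <- subset_table(table, samples = ids)
  geno <- meta$genotype[match(ids, meta$sample_id)]
  sizes <- table(geno)
  if (any(sizes < 2L)) {
    stop("genotype category with < 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  geno <- factor(geno, levels = c("Healthy", "CF_df508", "CF_other"))
  if (anyNA(geno)) stop("unknown genotype level present")
  if (is.null(sf)) sf <- size_factors(tab)
  sf <- sf[ids]
  X_full <- stats::model.matrix(~geno)
  X_red <- matrix(1, length(ids), 1L)
  counts <- tab$values
  disp <- estimate_dispersions(counts, sf, geno)
  offset <- log(sf)
  n_feat <- nrow(counts)
  log2fc <- stat <- p <- numeric(n_feat)
  se <- rep(NA_real_, n_feat)
  flag <- character(n_feat)
  for (i in seq_len(n_feat)) {
    y <- counts[i, ]
    if (all(y == 0)) {
      stat[i] <- 0; p[i] <- 1; flag[i] <- "all_zero"
      next
    }
    zero_group <- any(tapply(y, geno, function(g) all(g == 0)))
    y_fit <- if (zero_group) y + 0.5 else y
    full <- fit_nb_glm(y_fit, X_full, offset, disp$alpha[i])
    red <- fit_nb_glm(y_fit, X_red, offset, disp$alpha[i])
    if (!full$converged || !red$converged) {
      stat[i] <- 0; p[i] <- 1; flag[i] <- "no_convergence"
      next
    }
    log2fc[i] <- full$beta[2L] / log(2)    # CF_df508 vs Healthy contrast
    se[i] <- full$se[2L] / log(2)
    stat[i] <- max(0, 2 * (full$loglik - red$loglik))
    p[i] <- stats::pchisq(stat[i], df = ncol(X_full) - 1L, lower.tail = FALSE)
    if (zero_group) flag[i] <- "zero_group_ridge"
  }
  p <- pmax(p, .Machine$double.xmin)
  data.frame(feature_id = feature_ids(tab), base_mean = disp$base_mean,
             log2fc = log2fc, se = se, statistic = stat, p = p,
             q = bh_adjust(p), test = "lrt", flag = flag,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test on a relative-abundance table
#'
#' For pathway-style tables (e.g. predicted functional profiles): features
#' are first filtered to those exceeding `min_rel_abund` (strict >) in at
#' least `min_fraction` of ALL samples (note: all samples, unlike the
#' condition-wise OTU filter), then tested feature-by-feature with a
#' two-sided Wilcoxon rank-sum between conditions, with BH adjustment.
#'
#' @param rel_table a `feature_table` with kind "relative"
#' @param meta a `sample_metadata` data.frame
#' @param min_rel_abund relative-abundance floor (strict), default 0.001
#' @param min_fraction fraction of all samples required, default 0.5
#' @return data.frame of per-feature results (log2fc is the log2 ratio of
#'   CF to Healthy group means; se is NA for this rank test)
#' @export
wilcoxon_feature_test <- function(rel_table, meta, min_rel_abund = 0.001,
                                  min_fraction = 0.5) {
  if (rel_table$kind != "relative") {
    stop("wilcoxon_feature_test expects a relative-abundance table; ",
         "normalize counts with relative_abundance() first")
  }
  ids <- real_samples(rel_table, meta)
  tab <- subset_table(rel_table, samples = ids)
  cond <- condition_of(meta, ids)
  need <- ceiling(min_fraction * length(ids))
  keep <- rowSums(tab$values > min_rel_abund) >= need
  gn_log(sprintf("pathway filter: kept %d of %d features (> %.4g%% in >= %d of %d samples)",
                 sum(keep), length(keep), 100 * min_rel_abund, need, length(ids)))
  tab <- subset_table(tab, features = feature_ids(tab)[keep])
  v <- tab$values
  is_cf <- cond == "CF"
  eps <- min(v[v > 0]) / 2
  res <- t(apply(v, 1L, function(row) {
    x <- row[is_cf]; y <- row[!is_cf]
    lfc <- log2((mean(x) + eps) / (mean(y) + eps))
    if (length(unique(row)) == 1L) {
      return(c(W = length(x) * length(y) / 2, p = 1, lfc = lfc))
    }
    exact <- length(row) <= 20L && !anyDuplicated(row)
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    c(W = unname(ht$statistic), p = ht$p.value, lfc = lfc)
  }))
  p <- pmax(res[, "p"], .Machine$double.xmin)
  data.frame(feature_id = feature_ids(tab), base_mean = rowMeans(v),
             log2fc = res[, "lfc"], se = NA_real_, statistic = res[, "W"],
             p = p, q = bh_adjust(p), test = "wilcoxon", flag = "",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Up/down summary of a differential result
#'
#' The reporting utility behind statements like "919 of 1543 differentially
#' expressed genes (59%) were upregulated": counts significant features by
#' fold-change direction and reports the percentage upregulated.
#'
#' @param de data.frame of differential results (needs log2fc and q)
#' @param fdr significance cutoff on q (default 0.05)
#' @return list: n_significant, n_up, n_down, pct_up
#' @export
de_direction_summary <- function(de, fdr = 0.05) {
  sig <- de[de$q < fdr, , drop = FALSE]
  n_up <- sum(sig$log2fc > 0)
  n_down <- sum(sig$log2fc < 0)
  list(n_significant = nrow(sig), n_up = n_up, n_down = n_down,
       pct_up = if (nrow(sig)) 100 * n_up / nrow(sig) else NA_real_)
}
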