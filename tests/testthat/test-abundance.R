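make_tax <- function(ids, genus, family = NULL, phylum = "P1") {
  n <- length(ids)
  taxonomy_map(ids, data.frame(
    kingdom = rep("Bacteria", n), phylum = rep_len(phylum, n),
    class = rep("C1", n), order = rep("O1", n),
    family = if (is.null(family)) paste0("Fam_", genus) else family,
    genus = genus, stringsAsFactors = FALSE))
}

test_that("agglomeration sums lineage groups and conserves totals", {
  m <- matrix(c(3, 5, 2, 1, 4, 9), 3, 2,
              dimnames = list(c("o1", "o2", "o3"), c("S1", "S2")))
  ft <- feature_table(m, kind = "counts")
  tax <- make_tax(c("o1", "o2", "o3"), c("GenA", "GenA", "GenB"))
  g <- agglomerate(ft, tax, "genus")
  expect_identical(nrow(g$values), 2L)
  expect_equal(unname(g$values["g__GenA", ]), unname(m["o1", ] + m["o2", ]))
  expect_equal(colSums(g$values), colSums(m))

  # conservation holds at every rank
  for (rk in taxonomy_ranks()) {
    expect_equal(colSums(agglomerate(ft, tax, rk)$values), colSums(m),
                 label = rk)
  }
  expect_error(agglomerate(ft, tax, "species"), "unknown rank")
})

test_that("agglomeration at an already-collapsed rank is the identity", {
  m <- matrix(c(3, 5, 2, 1), 2, 2,
              dimnames = list(c("pA", "pB"), c("S1", "S2")))
  ft <- feature_table(m, kind = "counts")
  tax <- taxonomy_map(c("pA", "pB"), data.frame(
    kingdom = "Bacteria", phylum = c("PhyA", "PhyB"), class = "", order = "",
    family = "", genus = "", stringsAsFactors = FALSE))
  g <- agglomerate(ft, tax, "phylum")
  expect_identical(unname(g$values), unname(m))
  expect_identical(feature_ids(g), c("p__PhyA", "p__PhyB"))
})

test_that("features unassigned at the target rank group at the last characterized level", {
  m <- matrix(c(2, 7, 4, 1, 3, 5), 3, 2,
              dimnames = list(c("o1", "o2", "o3"), c("S1", "S2")))
  ft <- feature_table(m, kind = "counts")
  tax <- taxonomy_map(c("o1", "o2", "o3"), data.frame(
    kingdom = "Bacteria", phylum = "P1", class = "C1", order = "O1",
    family = c("Ruminococcaceae", "Ruminococcaceae", "Lachnospiraceae"),
    genus = c("", "", "Blautia"), stringsAsFactors = FALSE))
  g <- agglomerate(ft, tax, "genus")
  expect_setequal(feature_ids(g), c("f__Ruminococcaceae", "g__Blautia"))
  expect_equal(unname(g$values["f__Ruminococcaceae", ]),
               unname(m["o1", ] + m["o2", ]))
})

test_that("prevalence/abundance filter applies the condition-wise threshold", {
  # 10 CF + 12 healthy -> need >= ceil(10/2) = 5 qualifying samples
  md <- two_group_metadata(10L, 12L)
  n <- 22L
  m <- matrix(1000, 3, n,
              dimnames = list(c("common", "four_hits", "five_hits"), md$sample_id))
  # each column sums to ~3000; 0.1% of 3000 = 3 reads
  m["four_hits", ] <- 0; m["four_hits", 1:4] <- 10
  m["five_hits", ] <- 0; m["five_hits", 1:5] <- 10
  ft <- feature_table(m, kind = "counts")
  kept <- prevalence_abundance_filter(ft, md, min_rel_abund = 0.001)
  expect_true("five_hits" %in% feature_ids(kept))
  expect_false("four_hits" %in% feature_ids(kept))
  expect_true("common" %in% feature_ids(kept))

  # exact boundary: rel abundance exactly 0.1% counts (>= is inclusive)
  m2 <- matrix(0, 2, n, dimnames = list(c("filler", "edge"), md$sample_id))
  m2["filler", ] <- 1998
  m2["edge", 1:5] <- 2      # 2/2000 = 0.1% exactly in 5 samples
  m2["filler", 1:5] <- 1998
  ft2 <- feature_table(m2, kind = "counts")
  kept2 <- prevalence_abundance_filter(ft2, md, min_rel_abund = 0.001)
  expect_true("edge" %in% feature_ids(kept2))

  # ubiquitous features -> identity
  m3 <- matrix(100, 4, n, dimnames = list(paste0("F", 1:4), md$sample_id))
  ft3 <- feature_table(m3, kind = "counts")
  expect_identical(feature_ids(prevalence_abundance_filter(ft3, md)),
                   feature_ids(ft3))

  expect_error(prevalence_abundance_filter(ft3, md, min_rel_abund = 0), "0, 1")
})

test_that("filter is invariant to feature order and per-sample scaling", {
  set.seed(40)
  md <- two_group_metadata(5L, 6L)
  tab <- random_count_table(n_feat = 20L, n_samp = 11L, max_count = 80L)
  colnames(tab$values) <- md$sample_id
  base <- feature_ids(prevalence_abundance_filter(tab, md, 0.01))

  shuf <- feature_table(tab$values[sample(nrow(tab$values)), ], kind = "counts")
  expect_setequal(feature_ids(prevalence_abundance_filter(shuf, md, 0.01)), base)

  scaled <- feature_table(sweep(tab$values, 2, c(rep(3, 5), rep(7, 6)), "*"),
                          kind = "counts")
  expect_setequal(feature_ids(prevalence_abundance_filter(scaled, md, 0.01)), base)
})

test_that("size factors follow the median-of-ratios convention", {
  m <- matrix(c(1, 2, 2, 4), 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  s <- size_factors(feature_table(m, kind = "counts"))
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- matrix(c(5, 9, 5, 9, 5, 9), 2, 3,
                  dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  s2 <- size_factors(feature_table(ident, kind = "counts"))
  expect_true(all(abs(s2 - s2[1]) < 1e-12))

  single <- matrix(c(3, 4), 2, 1, dimnames = list(c("A", "B"), "S1"))
  expect_identical(unname(size_factors(feature_table(single, kind = "counts"))), 1)

  # poscounts fallback on a sparse table where no feature is all-positive
  sp <- matrix(c(0, 4, 6, 3, 0, 9, 5, 8, 0), 3, 3,
               dimnames = list(paste0("F", 1:3), paste0("S", 1:3)))
  sft <- feature_table(sp, kind = "counts")
  expect_error(size_factors(sft, fallback = FALSE), "poscounts")
  s3 <- size_factors(sft)
  expect_true(all(is.finite(s3) & s3 > 0))
})

test_that("BH equals the brute-force step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(50)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("nb_wald flags degenerate features and recovers planted effects", {
  set.seed(60)
  n_feat <- 200L
  md <- two_group_metadata(20L, 20L)
  cond <- md$condition
  mu <- 100; lfc <- 2; alpha <- 0.1
  counts <- t(vapply(seq_len(n_feat), function(i) {
    m <- ifelse(cond == "CF", mu * 2^lfc, mu)
    stats::rnbinom(40L, mu = m, size = 1 / alpha)
  }, numeric(40L)))
  dimnames(counts) <- list(sprintf("F%03d", seq_len(n_feat)), md$sample_id)
  counts[1L, ] <- 0   # degenerate feature
  ft <- feature_table(counts, kind = "counts")
  # every feature carries the planted effect, so median-of-ratios would
  # absorb it into the size factors; supply the generating factors (all 1)
  res <- nb_wald(ft, md, sf = setNames(rep(1, 40L), md$sample_id))
  expect_identical(res$flag[1], "all_zero")
  expect_identical(res$p[1], 1)
  expect_identical(res$log2fc[1], 0)
  est <- res$log2fc[res$flag == ""]
  expect_gt(median(est), 1.7)
  expect_lt(median(est), 2.3)
  expect_true(all(sign(res$statistic) == sign(res$log2fc) |
                    res$statistic == 0))
})

test_that("nb_wald Wald CIs cover the simulated effect about 95% of the time", {
  set.seed(61)
  md <- two_group_metadata(12L, 12L)
  n_feat <- 400L
  beta1 <- log(2) * 1.5   # natural-log effect
  counts <- t(vapply(seq_len(n_feat), function(i) {
    m <- 80 * exp(beta1 * (md$condition == "CF"))
    stats::rnbinom(24L, mu = m, size = 1 / 0.15)
  }, numeric(24L)))
  dimnames(counts) <- list(sprintf("F%03d", seq_len(n_feat)), md$sample_id)
  res <- nb_wald(feature_table(counts, kind = "counts"), md,
                 sf = setNames(rep(1, 24L), md$sample_id))
  ok <- res$flag == ""
  covered <- abs(res$log2fc[ok] - 1.5) <= 1.96 * res$se[ok]
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.98)
})

test_that("nb_lrt detects a planted monotone genotype trend", {
  set.seed(62)
  n <- 24L
  ids <- sprintf("S%02d", seq_len(n))
  geno <- rep(c("Healthy", "CF_other", "CF_df508"), each = 8L)
  md <- sample_metadata(ids,
                        condition = ifelse(geno == "Healthy", "Healthy", "CF"),
                        genotype = geno, is_negative_control = FALSE)
  n_feat <- 100L
  counts <- t(vapply(seq_len(n_feat), function(i) {
    stats::rnbinom(n, mu = 100, size = 1 / 0.1)
  }, numeric(n)))
  # planted gradient: healthy < CF_other < CF_df508 (like an increasing
  # severity trend in a phylum's abundance)
  trend_mu <- 100 * 2^c(Healthy = 0, CF_other = 1, CF_df508 = 2)[geno]
  counts[1L, ] <- stats::rnbinom(n, mu = trend_mu, size = 1 / 0.1)
  dimnames(counts) <- list(sprintf("F%03d", seq_len(n_feat)), ids)
  res <- nb_lrt(feature_table(counts, kind = "counts"), md)
  expect_lte(rank(res$p)[1], 0.05 * n_feat)
  expect_true(all(res$p > 0 & res$p <= 1))

  md_small <- md[md$sample_id %in% c(ids[1:8], ids[9]), ]
  class(md_small) <- class(md)
  expect_error(nb_lrt(feature_table(counts[, 1:9], kind = "counts"), md_small),
               "< 2 samples")
})

test_that("identical full and reduced designs give zero deviance difference", {
  set.seed(63)
  y <- stats::rnbinom(12L, mu = 50, size = 10)
  X <- cbind(1, rep(c(0, 1), each = 6))
  off <- rep(0, 12)
  full <- gutnet:::fit_nb_glm(y, X, off, 0.1)
  same <- gutnet:::fit_nb_glm(y, X, off, 0.1)
  expect_equal(2 * (full$loglik - same$loglik), 0, tolerance = 1e-10)
})

test_that("wilcoxon pathway test enforces its contract", {
  md <- two_group_metadata(10L, 12L)
  n <- 22L
  m <- matrix(0, 3, n, dimnames = list(c("pw_common", "pw_ten", "pw_eleven"),
                                       md$sample_id))
  m["pw_common", ] <- 0.9
  m["pw_ten", 1:10] <- 0.05
  m["pw_eleven", 1:11] <- 0.05
  # make columns sum to one via a filler row
  m <- rbind(m, filler = 1 - colSums(m))
  ft <- feature_table(m, kind = "relative")
  res <- wilcoxon_feature_test(ft, md, min_rel_abund = 0.001, min_fraction = 0.5)
  expect_false("pw_ten" %in% res$feature_id)     # 10 of 22 < 11 required
  expect_true("pw_eleven" %in% res$feature_id)

  counts <- feature_table(matrix(5, 2, n, dimnames = list(c("a", "b"), md$sample_id)),
                          kind = "counts")
  expect_error(wilcoxon_feature_test(counts, md), "normalize")

  # identical group distributions -> p = 1
  res_common <- res[res$feature_id == "pw_common", ]
  expect_equal(res_common$p, 1)
})

test_that("dispersion estimation is sane on its own model", {
  set.seed(64)
  md <- two_group_metadata(15L, 15L)
  alpha_true <- 0.2
  counts <- t(vapply(1:300, function(i) {
    stats::rnbinom(30L, mu = 200, size = 1 / alpha_true)
  }, numeric(30L)))
  dimnames(counts) <- list(sprintf("F%03d", 1:300), md$sample_id)
  disp <- gutnet:::estimate_dispersions(counts, setNames(rep(1, 30), md$sample_id),
                                        md$condition)
  expect_gt(median(disp$alpha), alpha_true * 0.6)
  expect_lt(median(disp$alpha), alpha_true * 1.6)
})

test_that("de_direction_summary reports the up/down split", {
  de <- data.frame(feature_id = sprintf("g%d", 1:5),
                   log2fc = c(1, -1, 2, 0.5, -0.2),
                   q = c(0.01, 0.01, 0.2, 0.04, 0.04))
  s <- de_direction_summary(de, fdr = 0.05)
  expect_identical(s$n_significant, 4L)
  expect_identical(s$n_up, 2L)
  expect_equal(s$pct_up, 50)
})
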