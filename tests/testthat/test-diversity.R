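test_that("rarefaction subsamples to exact depth and handles edge cases", {
  m <- matrix(c(10, 0, 6, 4), 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  ft <- feature_table(m, kind = "counts")

  # identity: depth equals the column total
  same <- rarefy(ft, 10, seed = 1)
  expect_identical(same$values[, "S1"], m[, "S1"])

  # forced: only one taxon present
  r <- rarefy(feature_table(matrix(c(10, 0), 2, 1,
                                   dimnames = list(c("A", "B"), "S1")),
                            kind = "counts"), 5, seed = 1)
  expect_identical(unname(r$values[, 1]), c(5, 0))

  set.seed(3)
  big <- random_count_table(n_feat = 12L, n_samp = 6L, max_count = 30L)
  depth <- min(colSums(big$values))
  rb <- rarefy(big, depth, seed = 9)
  expect_true(all(colSums(rb$values) == depth))
  expect_true(all(rb$values <= big$values))

  expect_error(rarefy(big, max(colSums(big$values)) + 1), "exceeds")
})

test_that("alpha metrics match hand computations", {
  x <- c(4, 1, 1, 2, 3)
  ft <- feature_table(matrix(x, 5, 1, dimnames = list(paste0("F", 1:5), "S1")),
                      kind = "counts")
  res <- alpha_diversity(ft, "chao1", depth = sum(x), n_resamples = 1)
  expect_equal(res$value, 5.5)   # 5 + 2*1/(2*2)

  uni <- feature_table(matrix(rep(10, 4), 4, 1,
                              dimnames = list(paste0("F", 1:4), "S1")),
                       kind = "counts")
  res2 <- alpha_diversity(uni, "shannon", depth = 40, n_resamples = 1)
  expect_equal(res2$value, log(4), tolerance = 1e-12)

  # no singletons/doubletons -> chao1 equals observed richness
  nf <- feature_table(matrix(c(5, 7, 9), 3, 1,
                             dimnames = list(paste0("F", 1:3), "S1")),
                      kind = "counts")
  expect_equal(alpha_diversity(nf, "chao1", depth = 21, n_resamples = 1)$value,
               alpha_diversity(nf, "observed_otus", depth = 21, n_resamples = 1)$value)
})

test_that("alpha/bray oracles agree with brute force on random tables", {
  set.seed(21)
  for (rep in 1:50) {
    tab <- random_count_table(n_feat = sample(3:10, 1), n_samp = 2L,
                              max_count = 20L)
    x <- tab$values[, 1]; y <- tab$values[, 2]
    expect_equal(gutnet:::alpha_metric(x, "chao1"), unname(chao1_brute(x)),
                 tolerance = 1e-12)
    expect_equal(gutnet:::alpha_metric(x, "shannon"), unname(shannon_brute(x)),
                 tolerance = 1e-12)
    dm <- beta_diversity(tab, "bray_curtis")
    expect_equal(dm$matrix[1, 2], unname(bray_brute(x, y)), tolerance = 1e-12)
  }
})

test_that("resampled alpha diversity is reproducible and bounded by single draws", {
  set.seed(5)
  tab <- random_count_table(n_feat = 30L, n_samp = 4L, max_count = 40L)
  depth <- min(colSums(tab$values))
  a1 <- alpha_diversity(tab, "observed_otus", depth = depth, n_resamples = 20,
                        seed = 77)
  a2 <- alpha_diversity(tab, "observed_otus", depth = depth, n_resamples = 20,
                        seed = 77)
  expect_identical(a1, a2)
  singles <- vapply(1:20, function(r) {
    rt <- rarefy(tab, depth, seed = gutnet:::derive_seed(77, r))
    apply(rt$values, 2, function(col) sum(col > 0))
  }, numeric(4L))
  expect_true(all(a1$value >= apply(singles, 1, min) - 1e-12))
  expect_true(all(a1$value <= apply(singles, 1, max) + 1e-12))
})

test_that("alpha group test matches exact enumeration and symmetries", {
  res <- data.frame(sample_id = paste0("S", 1:6),
                    value = c(1, 2, 3, 4, 5, 6))
  md <- sample_metadata(paste0("S", 1:6),
                        condition = rep(c("CF", "Healthy"), each = 3),
                        genotype = rep(c("CF_other", "Healthy"), each = 3),
                        is_negative_control = FALSE)
  out <- alpha_group_test(res, md)
  expect_equal(out$p, 0.1)   # 2/C(6,3) * ... exact two-sided enumeration

  # identical pooled values -> p = 1
  res_tie <- res; res_tie$value <- rep(2, 6)
  expect_equal(alpha_group_test(res_tie, md)$p, 1)

  # swapping group labels leaves p unchanged
  md_sw <- md
  md_sw$condition <- rev(md$condition)
  md_sw$genotype <- rev(md$genotype)
  expect_equal(alpha_group_test(res, md_sw)$p, out$p)
})

test_that("bray-curtis hits its boundary cases", {
  m <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  dm <- beta_diversity(feature_table(m, kind = "counts"), "bray_curtis")
  expect_equal(dm$matrix["S1", "S2"], 1)

  m2 <- matrix(c(3, 4, 3, 4), 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  dm2 <- beta_diversity(feature_table(m2, kind = "counts"), "bray_curtis")
  expect_equal(dm2$matrix["S1", "S2"], 0)
})

test_that("bray-curtis agrees with vegan", {
  set.seed(31)
  tab <- random_count_table(n_feat = 15L, n_samp = 6L, max_count = 40L)
  dm <- beta_diversity(tab, "bray_curtis")
  ref <- as.matrix(vegan::vegdist(t(tab$values), method = "bray"))
  expect_equal(unname(dm$matrix), unname(ref), tolerance = 1e-12)
})

test_that("UniFrac follows the branch-length definitions", {
  # 2-tip star: samples on different tips share no branch length
  tree2 <- ape::read.tree(text = "(A:1,B:1);")
  m <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  ft <- feature_table(m, kind = "counts")
  du <- beta_diversity(ft, "unweighted_unifrac", tree = tree2)
  expect_equal(du$matrix["S1", "S2"], 1)
  dw <- beta_diversity(ft, "weighted_unifrac", tree = tree2)
  expect_equal(dw$matrix["S1", "S2"], 1)

  # all tips shared with equal proportions -> both metrics 0
  m0 <- matrix(c(5, 5, 10, 10), 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  f0 <- feature_table(m0, kind = "counts")
  expect_equal(beta_diversity(f0, "unweighted_unifrac", tree = tree2)$matrix["S1", "S2"], 0)
  expect_equal(beta_diversity(f0, "weighted_unifrac", tree = tree2)$matrix["S1", "S2"], 0)

  # hand-computed 4-tip case: ((A:1,B:1):1,(C:1,D:1):1);
  tree4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m4 <- matrix(c(1, 1, 0, 0,
                 1, 0, 1, 0), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("S1", "S2")))
  f4 <- feature_table(m4, kind = "counts")
  # unique branches: B tip (1) + C tip (1) + CD stem? S1 has A,B; S2 has A,C.
  # branches: A(shared), B(S1 only), C(S2 only), D(neither), AB stem (shared),
  # CD stem (S2 only). unique = 1+1+1 = 3; union total = 1+1+1+1+1 = 5.
  expect_equal(beta_diversity(f4, "unweighted_unifrac", tree = tree4)$matrix["S1", "S2"],
               3 / 5)

  # monotone in unshared branch length: lengthening the B tip increases it
  tree4b <- ape::read.tree(text = "((A:1,B:3):1,(C:1,D:1):1);")
  expect_gt(beta_diversity(f4, "unweighted_unifrac", tree = tree4b)$matrix["S1", "S2"],
            beta_diversity(f4, "unweighted_unifrac", tree = tree4)$matrix["S1", "S2"])

  # missing tip errors with the IDs
  bad <- feature_table(matrix(c(1, 1), 2, 1, dimnames = list(c("A", "Z"), "S1")),
                       kind = "counts")
  expect_error(beta_diversity(bad, "unweighted_unifrac", tree = tree4), "Z")
})

test_that("PCoA recovers geometry", {
  # two points at distance d -> coordinates +/- d/2 on axis 1
  d <- 3.4
  dm <- structure(list(sample_ids = c("S1", "S2"),
                       matrix = matrix(c(0, d, d, 0), 2, 2,
                                       dimnames = list(c("S1", "S2"), c("S1", "S2"))),
                       metric = "test"), class = "gutnet_dist")
  res <- pcoa(dm)
  expect_equal(unname(sort(res$coordinates[, 1])), c(-d / 2, d / 2),
               tolerance = 1e-9)

  # Euclidean distances from known 2-D points are reproduced exactly
  set.seed(8)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  dmat <- as.matrix(stats::dist(pts))
  dimnames(dmat) <- list(paste0("S", 1:10), paste0("S", 1:10))
  dm2 <- structure(list(sample_ids = rownames(dmat), matrix = dmat,
                        metric = "euclidean"), class = "gutnet_dist")
  res2 <- pcoa(dm2)
  rec <- as.matrix(stats::dist(res2$coordinates))
  expect_equal(unname(rec), unname(dmat), tolerance = 1e-9)

  # a duplicated sample lands on identical coordinates
  dmat3 <- dmat[c(1, 1, 2:10), c(1, 1, 2:10)]
  rownames(dmat3)[2] <- colnames(dmat3)[2] <- "S1b"
  dm3 <- structure(list(sample_ids = rownames(dmat3), matrix = dmat3,
                        metric = "euclidean"), class = "gutnet_dist")
  res3 <- pcoa(dm3)
  expect_equal(res3$coordinates["S1", ], res3$coordinates["S1b", ],
               tolerance = 1e-8)
})

test_that("PERMANOVA separates clusters and respects invariances", {
  # two tight, far-apart clusters: p hits the permutation floor
  set.seed(12)
  pts <- rbind(matrix(rnorm(6, 0, 0.01), 3), matrix(rnorm(6, 10, 0.01), 3))
  dmat <- as.matrix(stats::dist(pts))
  ids <- paste0("S", 1:6)
  dimnames(dmat) <- list(ids, ids)
  dm <- structure(list(sample_ids = ids, matrix = dmat, metric = "euclidean"),
                  class = "gutnet_dist")
  md <- sample_metadata(ids, condition = rep(c("CF", "Healthy"), each = 3),
                        genotype = rep(c("CF_other", "Healthy"), each = 3),
                        is_negative_control = FALSE)
  res <- permanova(dm, md, n_permutations = 719, seed = 4)
  # permutations preserving the 3v3 partition reproduce F exactly (72 of the
  # 720 orderings), so the attainable floor for this design is ~0.1, not
  # 1/720; assert the observed p sits at that enumeration floor
  expect_lte(res$p, 0.15)
  expect_gt(res$R2, 0.9)

  # permuting samples consistently in dm leaves F unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  dmp <- structure(list(sample_ids = ids[perm],
                        matrix = dmat[perm, perm], metric = "euclidean"),
                   class = "gutnet_dist")
  res_p <- permanova(dmp, md, n_permutations = 99, seed = 4)
  expect_equal(res_p$pseudo_F, res$pseudo_F, tolerance = 1e-12)

  expect_gte(res$p, 1 / 720)

  # a group of size zero errors
  md_bad <- md
  md_bad$condition <- rep("CF", 6)
  md_bad$genotype <- rep("CF_other", 6)
  expect_error(permanova(dm, md_bad, n_permutations = 99), "2 groups")
})

test_that("PERMANOVA pseudo-F and R2 agree with vegan::adonis2", {
  set.seed(19)
  tab <- random_count_table(n_feat = 20L, n_samp = 10L, max_count = 60L)
  md <- two_group_metadata(5L, 5L)
  colnames(tab$values) <- md$sample_id
  dm <- beta_diversity(tab, "bray_curtis")
  res <- permanova(dm, md, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(dm$matrix) ~ condition,
                        data = data.frame(condition = md$condition),
                        permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
})
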