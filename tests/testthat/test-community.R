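test_that("Hellinger transform normalises rows of square roots", {
  expect_equal(hellingerTransform(matrix(c(4, 0), 1))[1, ], c(1, 0))
  k <- 5
  expect_equal(unname(hellingerTransform(matrix(rep(3, k), 1))[1, ]),
               rep(1 / sqrt(k), k))
  set.seed(1)
  m <- matrix(rpois(60, 8), 6, 10)
  h <- hellingerTransform(m)
  expect_equal(unname(rowSums(h^2)), rep(1, 6))
  m0 <- m; m0[2, ] <- 0
  rownames(m0) <- paste0("s", 1:6)
  expect_error(hellingerTransform(m0), "s2")
})

test_that("rarefaction preserves depth and the hypergeometric mean", {
  set.seed(4)
  m <- matrix(rpois(40, 30), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  r <- rarefyCounts(m, 50, seed = 9)
  expect_true(all(rowSums(r) == 50))
  expect_true(all(r <= m))
  expect_true(all(r >= 0) && all(r == round(r)))
  # depth equal to library size returns the same multiset of counts
  row <- matrix(c(5, 3, 2), 1)
  expect_equal(unname(rarefyCounts(row, 10, seed = 2)[1, ]), c(5, 3, 2))
  expect_error(rarefyCounts(m, 0), "positive")
  # Monte-Carlo mean of a feature equals depth x proportion
  row <- matrix(c(40, 10, 50), 1)
  draws <- vapply(1:500, function(s)
    rarefyCounts(row, 20, seed = s)[1, 1], numeric(1))
  expect_equal(mean(draws), 20 * 0.4, tolerance = 0.03)
  # deterministic given the seed
  expect_identical(rarefyCounts(m, 50, seed = 7), rarefyCounts(m, 50, seed = 7))
})

test_that("Bray-Curtis matches its definition, brute force and vegan", {
  expect_equal(brayCurtisMatrix(rbind(c(2, 2), c(1, 3)))[1, 2], 0.25)
  expect_equal(brayCurtisMatrix(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  expect_equal(brayCurtisMatrix(rbind(c(3, 0), c(0, 7)))[1, 2], 1)
  set.seed(2)
  m <- matrix(rpois(80, 6), 10, 8, dimnames = list(paste0("s", 1:10), NULL))
  bc <- brayCurtisMatrix(m)
  expect_lt(max(abs(bc - bruteBrayCurtis(m))), 1e-12)
  expect_lt(max(abs(bc - as.matrix(vegan::vegdist(m, "bray")))), 1e-12)
  expect_true(isSymmetric(bc))
  expect_equal(unname(diag(bc)), rep(0, 10))
  mz <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_error(brayCurtisMatrix(mz), "undefined")
  expect_true(is.nan(brayCurtisMatrix(mz, strict = FALSE)[1, 2]))
})

test_that("permanova partitions like adonis2 and reduces to classical ANOVA", {
  set.seed(7)
  m <- matrix(rpois(20 * 6, 15), 20, 6)
  rownames(m) <- paste0("s", 1:20)
  fac <- data.frame(g = rep(c("a", "b"), 10), h = rep(c("x", "y"), each = 10))
  bc <- brayCurtisMatrix(m)
  mine <- permanova(bc, fac, n_perm = 199, seed = 1)
  ref <- as.data.frame(vegan::adonis2(as.dist(bc) ~ g + h, data = fac,
                                      permutations = 199, by = "terms"))
  expect_equal(mine$SS, ref$SumOfSqs, tolerance = 1e-10)
  expect_equal(mine$F[1:2], ref$F[1:2], tolerance = 1e-10)
  expect_equal(mine$R2[1:2], ref$R2[1:2], tolerance = 1e-10)
  # partition identity
  expect_equal(sum(mine$R2[1:3]), 1, tolerance = 1e-9)

  # Euclidean one-factor case equals one-way ANOVA F exactly
  y <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  pm <- permanova(as.matrix(dist(y)), data.frame(g = g), n_perm = 99)
  expect_equal(pm$F[1], unname(summary(aov(y ~ g))[[1]]$`F value`[1]),
               tolerance = 1e-10)

  # strong planted shift reaches the smallest attainable p
  m2 <- matrix(rpois(16 * 4, 10), 16, 4)
  m2[1:8, 1] <- m2[1:8, 1] + 200
  p <- permanova(brayCurtisMatrix(m2),
                 data.frame(g = rep(c("a", "b"), each = 8)),
                 n_perm = 199, seed = 3)$p[1]
  expect_equal(p, 1 / 200)
  expect_error(permanova(bc, data.frame(g = rep("a", 20))), "constant")
})

test_that("mantel statistic equals vegan's and behaves at the extremes", {
  set.seed(3)
  d1 <- as.matrix(dist(matrix(rnorm(30), 10)))
  d2 <- as.matrix(dist(matrix(rnorm(30), 10)))
  mt <- mantelTest(d1, d2, n_perm = 199, seed = 1)
  vg <- vegan::mantel(d1, d2, method = "spearman", permutations = 199)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)
  expect_equal(mantelTest(d1, d1, n_perm = 99)$r, 1)
  expect_equal(mt$n_perm, 199)
  expect_error(mantelTest(d1[1:3, 1:3], d2[1:3, 1:3]), "at least 4")
  # dimname alignment
  rownames(d1) <- colnames(d1) <- paste0("s", 1:10)
  d2n <- d2; rownames(d2n) <- colnames(d2n) <- paste0("s", 1:10)
  perm <- sample(1:10)
  expect_equal(mantelTest(d1, d2n[perm, perm], n_perm = 99, seed = 2)$r,
               mantelTest(d1, d2n, n_perm = 99, seed = 2)$r)
})

test_that("community resistance scores are paired negative dissimilarities", {
  md <- data.frame(
    sample_id = c("c1", "t1", "c4", "t4"),
    site = "A1", country = "AT",
    treatment = c("control", "heat", "control", "heat"),
    sampling = c("S1", "S1", "S4", "S4"))
  m <- rbind(c1 = c(10, 10), t1 = c(10, 10), c4 = c(20, 0), t4 = c(0, 20))
  sc <- communityResistance(m, md, hellinger = FALSE)
  expect_equal(sc$score[sc$sampling == "S1"], 0)       # identical profiles
  expect_equal(sc$score[sc$sampling == "S4"], -1)      # disjoint profiles
  expect_equal(sc$kind, c("resistance", "resilience"))
  expect_equal(sc$log_score[sc$sampling == "S1"], -log(1e-6))

  # a missing control pair is skipped with a warning
  md2 <- md[md$sample_id != "c4", ]
  expect_warning(communityResistance(m[rownames(m) != "c4", ], md2,
                                     hellinger = FALSE), "skipped")
})

test_that("larger planted impacts produce lower community resistance", {
  d <- buildDesign(4, 3, exclusions = list())
  taxa <- sprintf("t%03d", 1:40)
  strat <- data.frame(
    taxon_id = c(taxa[1:8], taxa[1:2]),
    treatment = c(rep("heat", 8), rep("drought", 2)),
    impact = c(rep(0.04, 8), rep(0.02, 2)), slope = 0)
  sim <- simulateAsvCounts(d, strat,
                           communitySimParams(n_taxa = 40, rng_seed = 5))
  m <- t(SummarizedExperiment::assay(sim$counts))
  sc <- communityResistance(m, sim$metadata)
  res <- sc[sc$kind == "resistance", ]
  mheat <- mean(res$score[res$treatment == "heat"])
  mdr <- mean(res$score[res$treatment == "drought"])
  expect_lt(mheat, mdr)
})
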