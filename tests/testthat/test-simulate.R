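test_that("tree-and-effects generator is seed-deterministic and lambda-aware", {
  a <- simulateTreeAndEffects(30, lambda = 1, seed = 99)
  b <- simulateTreeAndEffects(30, lambda = 1, seed = 99)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$impact, b$impact)
  expect_error(simulateTreeAndEffects(30, lambda = 1.2), "lambda")
  expect_error(simulateTreeAndEffects(2), "at least 3")

  # lambda = 0: trait distances uncorrelated with tree distances
  s0 <- simulateTreeAndEffects(40, lambda = 0, seed = 7)
  td <- ape::cophenetic.phylo(s0$tree)
  ed <- as.matrix(dist(s0$impact[, "heat"][rownames(td)]))
  mt <- mantelTest(td, ed, n_perm = 199, seed = 1)
  expect_gt(mt$p, 0.05)
})

test_that("count simulator respects library sizes and plants displacements", {
  d <- buildDesign(3, 3, exclusions = list())
  sim <- simulateAsvCounts(d, NULL, communitySimParams(n_taxa = 30,
                                                       rng_seed = 3))
  cnt <- SummarizedExperiment::assay(sim$counts)
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  expect_equal(unname(colSums(cnt)), sim$metadata$libsize)

  # planted displacement: Monte-Carlo mean over replicate S1 pairs
  strat <- data.frame(taxon_id = "t001", treatment = "heat",
                      impact = 0.05, slope = 0)
  disp <- unlist(lapply(1:25, function(s) {
    sm <- simulateAsvCounts(d, strat,
                            communitySimParams(n_taxa = 30, rng_seed = s))
    m <- t(SummarizedExperiment::assay(sm$counts))
    md <- sm$metadata
    rel <- m[, "t001"] / md$libsize
    s1 <- md$sampling == "S1"
    # per-site paired displacement
    vapply(unique(md$site), function(st)
      rel[s1 & md$site == st & md$treatment == "heat"] -
        rel[s1 & md$site == st & md$treatment == "control"], numeric(1))
  }))
  expect_length(disp, 225)          # >= 200 replicate pairs
  expect_equal(mean(disp), 0.05, tolerance = 0.005)

  expect_error(simulateAsvCounts(
    d, NULL, communitySimParams(n_taxa = 10, libsize_meanlog = -5)),
    "library size")
  expect_error(communitySimParams(overdispersion = -1), "non-negative")
  expect_error(simulateAsvCounts(
    d, data.frame(taxon_id = "zzz", treatment = "heat", impact = 1,
                  slope = 0), communitySimParams(n_taxa = 10)),
    "unknown taxa")
})

test_that("null communities give well-calibrated permutation p-values", {
  d <- buildDesign(2, 3, exclusions = list())
  ps <- vapply(1:10, function(s) {
    sim <- simulateAsvCounts(d, NULL, communitySimParams(
      n_taxa = 20, rng_seed = 100 + s))
    m <- t(SummarizedExperiment::assay(sim$counts))
    md <- sim$metadata
    s1 <- md$sampling == "S1"
    bc <- brayCurtisMatrix(hellingerTransform(m[s1, ]))
    permanova(bc, data.frame(treatment = md$treatment[s1]),
              n_perm = 99, seed = s)$p[1]
  }, numeric(1))
  # no systematic rejection under exchangeability
  expect_gt(mean(ps), 0.2)
  expect_gt(min(ps), 0.01)
})

test_that("functional profile simulator follows the hierarchy contract", {
  h <- makeFunctionalHierarchy(50, 20, 10, 5)
  expect_equal(nrow(h), 50)
  expect_equal(length(unique(h$level1)), 5)
  # nested: every protein has exactly one ancestor path
  expect_equal(anyDuplicated(h$protein), 0)
  path_per_l3 <- tapply(paste(h$level2, h$level1), h$level3,
                        function(z) length(unique(z)))
  expect_true(all(path_per_l3 == 1))
  expect_error(makeFunctionalHierarchy(10, 20, 5, 2), "coarser")

  d <- buildDesign(3, 3, exclusions = list())
  sim <- simulateFunctionalProfiles(d, h, NULL, seed = 2)
  cnt <- SummarizedExperiment::assay(sim$counts)
  expect_equal(unname(colSums(cnt)), sim$metadata$libsize)
  # S1 and S4 only
  expect_setequal(unique(sim$metadata$sampling), c("S1", "S4"))

  # an oversized negative shift is clipped with a warning
  sh <- data.frame(category = h$protein[1], treatment = "heat",
                   delta = -0.9, resilient = FALSE)
  expect_warning(simulateFunctionalProfiles(d, h, sh, seed = 3),
                 "clipped")
  expect_error(simulateFunctionalProfiles(
    d, h, data.frame(category = "nope", treatment = "heat", delta = 0.1),
    seed = 1), "unknown category")
})

test_that("covariate generator emits 20 grouped properties and a surface", {
  fam <- propertyFamilies()
  expect_equal(lengths(fam), c(temperature = 4L, precipitation = 4L,
                               carbon_nitrogen = 8L, water_holding = 3L,
                               ph = 1L))
  d <- buildDesign(4, 3, exclusions = list())
  cv <- simulateCovariates(d, noise_sd = 0.1, seed = 5)
  expect_equal(ncol(cv$covariates) - 2L, 20L)   # site + country + 20
  expect_equal(nrow(cv$covariates), 12L)
  expect_setequal(unique(cv$truth$treatment),
                  c("drought", "flood", "freeze", "heat"))
  # zero effect map: flat surface
  cv0 <- simulateCovariates(d, effect_map = list(), noise_sd = 0.1,
                            seed = 5)
  expect_true(all(cv0$truth$true_response == 0))
  # determinism
  cv2 <- simulateCovariates(d, noise_sd = 0.1, seed = 5)
  expect_identical(cv$covariates, cv2$covariates)
})

test_that("soil-function generator links measurements to profiles", {
  fam <- soilFunctionFamilies()
  expect_equal(lengths(fam), c(enzymes = 4L, substrate_use = 8L,
                               carbon_nitrogen = 4L, gas_fluxes = 3L))
  set.seed(8)
  p <- matrix(rgamma(20 * 12, 2), 20, 12,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:12)))
  sf <- simulateSoilFunctions(p, noise_sd = 0.01, seed = 1)
  expect_equal(dim(sf$measurements), c(20L, 19L))

  # nonzero loadings: functional distance predicts measurement distance
  d1 <- brayCurtisMatrix(p)
  d2 <- as.matrix(dist(as.matrix(sf$measurements)))
  mt <- mantelTest(d1, d2, n_perm = 199, seed = 2)
  expect_gt(mt$r, 0)
  expect_lt(mt$p, 0.05)

  # zero loadings: no association
  sf0 <- simulateSoilFunctions(p, loadings = 0, noise_sd = 0.1, seed = 3)
  mt0 <- mantelTest(d1, as.matrix(dist(as.matrix(sf0$measurements))),
                    n_perm = 199, seed = 2)
  expect_gt(mt0$p, 0.05)
  expect_error(simulateSoilFunctions(p, loadings = matrix(0, 3, 3)),
               "categories x")
})

test_that("read simulator follows the circular coverage law", {
  model <- makeGenomeModel(8000, seed = 2)
  expect_equal(nchar(model$dif_motif), 28L)
  r <- simulateMarkerReads(model, rho = 0, n_reads = 8000, seed = 4)
  st <- attr(r, "starts")
  near <- function(p, w = 400) mean(pmin(abs(st - p),
                                         model$length - abs(st - p)) < w)
  # rho = 0: flat coverage
  expect_equal(near(model$origin_pos) / near(model$terminus_pos), 1,
               tolerance = 0.15)
  # rho = 1: origin coverage ~ 2x terminus coverage
  r1 <- simulateMarkerReads(model, rho = 1, n_reads = 20000, seed = 5)
  st <- attr(r1, "starts")
  expect_equal(near(model$origin_pos) / near(model$terminus_pos), 2,
               tolerance = 0.15)
  # deterministic
  expect_identical(as.character(simulateMarkerReads(model, 1, 100, seed = 9)),
                   as.character(simulateMarkerReads(model, 1, 100, seed = 9)))
  expect_error(simulateMarkerReads(model, -1, 100), "rho")
  expect_error(simulateMarkerReads(model, 1, 0), "n_reads")
  expect_error(simulateMarkerReads(model, 1, 10, read_length = 9000),
               "genome length")
})
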