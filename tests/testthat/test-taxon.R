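# build a synthetic converged fit with chosen coefficients/p-values
mockFit <- function(impact, impact_p, slope, slope_p, treatment = "heat") {
  structure(list(
    taxon_id = "tX",
    coefficients = data.frame(treatment = treatment,
                              impact = impact, impact_se = 1,
                              impact_p = impact_p, slope = slope,
                              slope_se = 1, slope_p = slope_p),
    converged = TRUE, fit = NULL), class = "taxonFit")
}

test_that("strategy grid covers all sign/significance combinations once", {
  combos <- expand.grid(imp = c(-1, 0, 1), slo = c(-1, 0, 1))
  labels <- apply(combos, 1, function(z) {
    f <- mockFit(impact = ifelse(z["imp"] == 0, 0.1, z["imp"]),
                 impact_p = ifelse(z["imp"] == 0, 0.5, 0.01),
                 slope = ifelse(z["slo"] == 0, 0.1, z["slo"]),
                 slope_p = ifelse(z["slo"] == 0, 0.5, 0.01))
    classifyStrategy(f)$label
  })
  expect_equal(sort(unique(labels)),
               sort(c("fully_resistant", "late_negative", "late_positive",
                      "negative impact, diverging",
                      "negative impact, resilient",
                      "negative impact, stable",
                      "positive impact, diverging",
                      "positive impact, resilient",
                      "positive impact, stable")))
  expect_equal(length(labels), 9L)   # every combination mapped exactly once
})

test_that("classification follows the stated impact/dynamics definitions", {
  # significant positive impact, non-significant slope
  c1 <- classifyStrategy(mockFit(0.02, 0.001, 0.001, 0.7))
  expect_equal(c1$label, "positive impact, stable")
  # nothing significant
  c2 <- classifyStrategy(mockFit(0.02, 0.2, 0.001, 0.7))
  expect_equal(c2$label, "fully_resistant")
  # negative impact with significant opposite slope = resilient
  c3 <- classifyStrategy(mockFit(-0.02, 0.001, 0.001, 0.01))
  expect_equal(c3$dynamics, "resilient")
  # same-sign significant slope = diverging
  c4 <- classifyStrategy(mockFit(-0.02, 0.001, -0.001, 0.01))
  expect_equal(c4$dynamics, "diverging")
  # late divergence requires no significant impact
  c5 <- classifyStrategy(mockFit(0.01, 0.4, 0.002, 0.01))
  expect_equal(c5$label, "late_positive")
})

test_that("per-taxon model recovers planted impacts and flags degenerate taxa", {
  d <- buildDesign(5, 3, exclusions = list())
  strat <- data.frame(taxon_id = "t001", treatment = "heat",
                      impact = 0.05, slope = 0)
  sim <- simulateAsvCounts(d, strat, communitySimParams(n_taxa = 30,
                                                        rng_seed = 17))
  m <- t(SummarizedExperiment::assay(sim$counts))
  fit <- fitTaxonModel(m, sim$metadata, "t001")
  expect_true(fit$converged)
  co <- fit$coefficients
  expect_equal(co$impact[co$treatment == "heat"], 0.05, tolerance = 0.2)
  expect_lt(co$impact_p[co$treatment == "heat"], 0.05)
  # non-planted treatments stay quiet
  expect_gt(min(co$impact_p[co$treatment != "heat"]), 0.001)

  # a taxon absent from every sample cannot converge
  m0 <- cbind(m, zero = 0L)
  f0 <- fitTaxonModel(m0, sim$metadata, "zero")
  expect_false(f0$converged)
  expect_equal(classifyStrategy(f0)$label, "model_failed")
  expect_error(fitTaxonModel(m, sim$metadata, "not_there"), "not in table")
})

test_that("with variance terms off, balanced estimates match OLS", {
  d <- buildDesign(4, 3, exclusions = list())
  sim <- simulateAsvCounts(d, NULL, communitySimParams(n_taxa = 12,
                                                       rng_seed = 31))
  m <- t(SummarizedExperiment::assay(sim$counts))
  md <- sim$metadata
  fit <- fitTaxonModel(m, md, "t005", variance = "none")
  rel <- m[, "t005"] / md$libsize
  ols <- lm(rel ~ stats::relevel(factor(md$treatment), "control") * md$day)
  expect_equal(unname(fit$coefficients$impact),
               unname(coef(ols)[2:5]), tolerance = 1e-6)
})

test_that("classification is invariant to sample order", {
  d <- buildDesign(3, 3, exclusions = list())
  sim <- simulateAsvCounts(d, NULL, communitySimParams(n_taxa = 10,
                                                       rng_seed = 23))
  m <- t(SummarizedExperiment::assay(sim$counts))
  md <- sim$metadata
  perm <- sample(nrow(m))
  f1 <- fitTaxonModel(m, md, "t003", variance = "sampling")
  f2 <- fitTaxonModel(m[perm, ], md, "t003", variance = "sampling")
  expect_lt(max(abs(f1$coefficients$impact - f2$coefficients$impact)),
            1e-5)
  expect_identical(classifyStrategy(f1)$label, classifyStrategy(f2)$label)
})

test_that("strategy census tallies proportions per treatment", {
  calls <- rbind(
    classifyStrategy(mockFit(0.02, 0.001, 0, 0.9, "heat")),
    classifyStrategy(mockFit(0.02, 0.9, 0, 0.9, "heat")),
    classifyStrategy(mockFit(-0.02, 0.001, 0, 0.9, "drought")),
    classifyStrategy(structure(list(taxon_id = "bad", coefficients = NULL,
                                    converged = FALSE, fit = NULL),
                               class = "taxonFit")))
  cen <- strategyCensus(calls)
  heat <- cen[cen$treatment == "heat", ]
  expect_equal(sum(heat$proportion), 1)
  expect_true("model_failed" %in% cen$label)
  expect_true(is.na(cen$proportion[cen$label == "model_failed"]))
  expect_error(strategyCensus(calls[0, ]), "no strategy calls")
})

test_that("census recovers which treatment lost the most resistant taxa", {
  d <- buildDesign(4, 3, exclusions = list())
  taxa <- sprintf("t%03d", 1:20)
  strat <- data.frame(taxon_id = taxa[1:6], treatment = "heat",
                      impact = 0.05 * rep(c(1, -1), 3), slope = 0)
  sim <- simulateAsvCounts(d, strat, communitySimParams(n_taxa = 20,
                                                        rng_seed = 41))
  m <- t(SummarizedExperiment::assay(sim$counts))
  res <- classifyAllTaxa(m, sim$metadata, taxa = taxa[1:10],
                         variance = "sampling")
  cen <- strategyCensus(res$calls)
  resist <- cen[cen$label == "fully_resistant", ]
  p_heat <- resist$proportion[resist$treatment == "heat"]
  expect_true(all(p_heat <= resist$proportion[resist$treatment != "heat"]))
})
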