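test_that("marker scanning agrees with brute-force window search", {
  model <- makeGenomeModel(6000, peptide_length = 60, seed = 13)
  db <- markerDb(model)
  reads <- simulateMarkerReads(model, rho = 0.5, n_reads = 250,
                               read_length = 120, error_rate = 0.01,
                               seed = 21)
  # terminus: oracle scans every window on both strands
  got <- scanMarkers(reads, db, "terminus", max_mismatch = 4)
  want <- bruteTerminusHits(reads, db$terminus, 4)
  expect_identical(unname(attr(got, "hits")), unname(want))

  # origin: oracle scans all offsets of all six frames
  got_o <- scanMarkers(reads, db, "origin", k = 12, min_score = 40)
  want_o <- bruteOriginHits(reads, as.character(db$origin), k = 12,
                            min_score = 40,
                            submat = extremesoil:::.blosum62())
  expect_identical(unname(attr(got_o, "hits")), unname(want_o))
})

test_that("scan handles planted fragments, misses absent motifs", {
  model <- makeGenomeModel(4000, peptide_length = 40, seed = 3)
  db <- markerDb(model)
  # read carrying a verbatim fragment of the initiator ORF
  frag <- substr(model$genome, model$origin_pos, model$origin_pos + 119)
  expect_equal(as.integer(scanMarkers(frag, db, "origin")), 1L)
  # reverse complement is found too (strand invariance)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(frag)))
  expect_equal(as.integer(scanMarkers(rc, db, "origin")), 1L)

  set.seed(9)
  rnd <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  expect_equal(as.integer(scanMarkers(rnd, db, "terminus",
                                      max_mismatch = 0)), 0L)
  expect_error(scanMarkers(character(0), db, "origin"), "no reads")
  bad <- db; bad$terminus <- Biostrings::DNAStringSet("ACGT")
  expect_error(scanMarkers(rnd, bad, "terminus"), "28 bp")
})

test_that("relative growth is the paired difference of log2 ratios", {
  md <- data.frame(sample_id = c("c", "t", "t2"), site = "A1",
                   treatment = c("control", "heat", "flood"),
                   sampling = "S1")
  cnt <- data.frame(sample_id = c("c", "t", "t2"),
                    O = c(100, 200, 0), T = c(50, 100, 80))
  gr <- relativeGrowth(cnt, md)
  # equal ratios cancel exactly up to the pseudocount
  expect_equal(gr$G_rel[gr$treatment == "heat"],
               log2(200.5 / 100.5) - log2(100.5 / 50.5))
  expect_true(is.finite(gr$G_rel[gr$treatment == "flood"]))  # O = 0 ok
  # a sample paired with itself gives exactly zero
  self <- relativeGrowth(data.frame(sample_id = c("c", "x"),
                                    O = c(10, 10), T = c(7, 7)),
                         data.frame(sample_id = c("c", "x"), site = "A1",
                                    treatment = c("control", "heat"),
                                    sampling = "S1"))
  expect_equal(self$G_rel, 0)
  # missing pair skipped with warning
  expect_warning(relativeGrowth(
    data.frame(sample_id = "t", O = 1, T = 1),
    data.frame(sample_id = "t", site = "B9", treatment = "heat",
               sampling = "S1")), "without paired control")
})

test_that("scan counts are invariant to read order", {
  model <- makeGenomeModel(5000, seed = 5)
  db <- markerDb(model)
  reads <- simulateMarkerReads(model, 1, n_reads = 400, seed = 6)
  o1 <- as.integer(scanMarkers(reads, db, "origin"))
  o2 <- as.integer(scanMarkers(rev(reads), db, "origin"))
  expect_equal(o1, o2)
  t1 <- as.integer(scanMarkers(reads, db, "terminus"))
  t2 <- as.integer(scanMarkers(Biostrings::reverseComplement(reads), db,
                               "terminus"))
  expect_equal(t1, t2)
})

test_that("growth capacity is the abundance-weighted copy number", {
  md <- data.frame(sample_id = c("c", "t"), site = "A1",
                   treatment = c("control", "heat"), sampling = "S1")
  m <- rbind(c = c(10, 10), t = c(5, 15))
  colnames(m) <- c("tA", "tB")
  # all copy numbers 1: capacity 1, difference 0
  cap1 <- growthCapacity(m, c(tA = 1, tB = 1), md)
  expect_equal(cap1$capacity, c(1, 1))
  expect_equal(cap1$delta_capacity[cap1$treatment == "heat"], 0)
  # equal abundances of copies 1 and 3 average to 2
  cap <- growthCapacity(m, c(tA = 1, tB = 3), md)
  expect_equal(cap$capacity[cap$sample_id == "c"], 2)
  # more high-copy abundance raises the mean
  expect_gt(cap$capacity[cap$sample_id == "t"], 2)
  expect_error(growthCapacity(m, c(zz = 2), md), "no taxa")
  expect_error(growthCapacity(m, c(tA = 0.5, tB = 1), md), ">= 1")
})

test_that("relative growth tracks the planted replication gradient", {
  model <- makeGenomeModel(20000, seed = 31)
  db <- markerDb(model)
  rhos <- c(0, 0.5, 1, 1.5)
  est <- vapply(seq_along(rhos), function(i) {
    trt <- simulateMarkerReads(model, rhos[i], n_reads = 10000,
                               seed = 40 + i)
    ctl <- simulateMarkerReads(model, 0, n_reads = 10000, seed = 60 + i)
    cnt <- countMarkers(list(t = trt, c = ctl), db)
    md <- data.frame(sample_id = c("t", "c"), site = "A1",
                     treatment = c("heat", "control"), sampling = "S1")
    relativeGrowth(cnt, md)$G_rel
  }, numeric(1))
  # monotone trend in the planted peak-to-trough difference
  expect_gt(est[4], est[1])
  expect_gt(cor(rhos, est), 0.8)
})

test_that("growth model keeps a strong planted fungal interaction", {
  d <- buildDesign(7, 3, exclusions = list())
  md <- sampleRecords(d, "metagenome", include_initial = FALSE,
                      samplings = c("S1", "S4"))
  md <- md[md$treatment != "control", ]
  set.seed(77)
  md$bact_dist <- runif(nrow(md), 0.1, 0.5)
  md$fung_dist <- runif(nrow(md), 0.1, 0.6)
  md$G_rel <- -0.2 + 1.2 * md$fung_dist * (md$treatment == "heat") +
    rnorm(nrow(md), 0, 0.12)
  gm <- fitGrowthModel(md)
  expect_true(gm$converged)
  kept <- attr(terms(gm$minimal_formula), "term.labels")
  expect_true("treatment:fung_dist" %in% kept)
  hn <- grep("heat.*fung_dist", rownames(gm$tTable), value = TRUE)
  expect_gt(gm$tTable[hn[1], "Value"], 0)
  # minimal model is nested in the full model
  full_terms <- attr(terms(G_rel ~ treatment * day * bact_dist *
                             fung_dist), "term.labels")
  expect_true(all(kept %in% full_terms))
  expect_equal(gm$aic_path$dropped[1], "<full>")
})

test_that("growth model drops a null fungal interaction", {
  d <- buildDesign(7, 3, exclusions = list())
  md <- sampleRecords(d, "metagenome", include_initial = FALSE,
                      samplings = c("S1", "S4"))
  md <- md[md$treatment != "control", ]
  dropped <- vapply(1:3, function(s) {
    set.seed(300 + s)
    md$bact_dist <- runif(nrow(md), 0.1, 0.5)
    md$fung_dist <- runif(nrow(md), 0.1, 0.6)
    md$G_rel <- -0.2 + rnorm(nrow(md), 0, 0.15)
    kept <- attr(terms(fitGrowthModel(md)$minimal_formula), "term.labels")
    !("treatment:fung_dist" %in% kept)
  }, logical(1))
  expect_gte(sum(dropped), 2L)   # dropped in the majority of replicates
})
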