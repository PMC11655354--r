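# End-to-end orchestration: configuration, seed fan-out, stage execution,
# manifest and run summary.

#' Deterministic per-stage seed derived from a global seed
#'
#' Stage seeds are a deterministic function of the global seed and the
#' stage name, so a single configured seed reproduces every stochastic
#' stage independently.
#'
#' @param global_seed integer global seed.
#' @param stage stage name.
#' @return integer seed in [0, 2^31).
#' @export
stageSeed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483647)
}

#' Default pipeline configuration
#'
#' Desk-scale settings: a reduced factorial design, a 60-taxon community
#' with a handful of planted responders, a 40-protein functional hierarchy
#' with one planted dormancy-like shift, small toy genomes and modest read
#' counts.  Every block can be overridden by the corresponding element of
#' \code{...} (recursively merged).
#'
#' @param ... named overrides merged over the defaults.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    design = list(countries = 4L, sites = 3L),
    simulate = list(
      n_taxa = 60L, lambda = 0.8,
      impact_taxa = 6L, impact_size = 0.03,
      functional = list(n_protein = 40L,
                        shift_category = "L1_01",
                        shift_treatment = "heat", shift_delta = 0.02),
      reads = list(enabled = FALSE, genome_length = 5000L,
                   n_reads = 2000L, rho_disturbed = 1, rho_control = 0.2),
      covariates = list(noise_sd = 0.1)
    ),
    analysis = list(
      community = TRUE, taxa = TRUE, functions = TRUE, phylo = TRUE,
      growth = TRUE, predict = TRUE,
      taxa_top_n = 12L, n_perm = 199L,
      cv = list(n_trees = 200L, split_budget = 30L)
    )
  )
  o <- list(...)
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_rec(cfg, o)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return configuration list merged over \code{\link{defaultRunConfig}}.
#' @export
readRunConfig <- function(path) {
  do.call(defaultRunConfig, yaml::read_yaml(path))
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order — simulate the inputs,
#' then community statistics, per-taxon strategies, functional responses,
#' phylogenetic signal, growth metrics and the predictive model — writing
#' every result table under \code{outdir} together with a JSON manifest of
#' stage seeds and output files.  Identical configurations produce
#' byte-identical outputs.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages, or \code{"all"}; simulation
#'   always runs because every analysis consumes its outputs.
#' @return the manifest (invisibly also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = tempfile(),
                        stages = "all") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("community", "taxa", "functions", "phylo", "growth",
                  "predict")
  if (identical(stages, "all")) stages <- all_stages
  want <- function(s) s %in% stages &&
    isTRUE(config$analysis[[if (s == "predict") "predict" else s]])
  manifest <- list(package_version =
                     as.character(utils::packageVersion("extremesoil")),
                   global_seed = config$seed, stages = list(),
                   outputs = character(0))
  note <- function(stage, seed, files) {
    files <- basename(files)     # manifest is location-independent
    manifest$stages[[stage]] <<- list(seed = seed, outputs = files)
    manifest$outputs <<- c(manifest$outputs, files)
  }

  ## -- simulate ---------------------------------------------------------
  design <- buildDesign(config$design$countries, config$design$sites)
  sim_seed <- stageSeed(config$seed, "simulate")
  tfx <- simulateTreeAndEffects(config$simulate$n_taxa,
                                lambda = config$simulate$lambda,
                                seed = sim_seed)
  n_imp <- config$simulate$impact_taxa
  strategies <- data.frame(
    taxon_id = rep(tfx$tree$tip.label[seq_len(n_imp)], each = 1),
    treatment = rep_len(setdiff(design@treatments$name, "control"), n_imp),
    impact = config$simulate$impact_size *
      rep_len(c(1, -1), n_imp),
    slope = 0)
  comm <- simulateAsvCounts(design, strategies,
                            communitySimParams(
                              n_taxa = config$simulate$n_taxa,
                              rng_seed = sim_seed),
                            taxa = tfx$tree$tip.label)
  fcfg <- config$simulate$functional
  hier <- makeFunctionalHierarchy(fcfg$n_protein,
                                  n_level3 = max(2L, fcfg$n_protein %/% 3L),
                                  n_level2 = max(2L, fcfg$n_protein %/% 6L),
                                  n_level1 = max(2L, fcfg$n_protein %/% 10L))
  shifts <- data.frame(category = fcfg$shift_category,
                       treatment = fcfg$shift_treatment,
                       delta = fcfg$shift_delta, resilient = FALSE)
  func <- simulateFunctionalProfiles(design, hier, shifts,
                                     seed = stageSeed(config$seed,
                                                      "functional"))
  covs <- simulateCovariates(design,
                             noise_sd = config$simulate$covariates$noise_sd,
                             seed = stageSeed(config$seed, "covariates"))
  files <- c(
    .writeTsv(comm$metadata, file.path(outdir, "sample_metadata.tsv")),
    .writeTsv(as.data.frame(SummarizedExperiment::assay(comm$counts)),
              file.path(outdir, "taxon_counts.tsv")),
    .writeTsv(hier, file.path(outdir, "functional_hierarchy.tsv")),
    .writeTsv(as.data.frame(SummarizedExperiment::assay(func$counts)),
              file.path(outdir, "functional_counts.tsv")),
    .writeTsv(covs$covariates, file.path(outdir, "covariates.tsv")))
  ape::write.tree(tfx$tree, file.path(outdir, "tree.nwk"))
  files <- c(files, file.path(outdir, "tree.nwk"))
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(strategies = strategies,
                            lambda = tfx$lambda,
                            functional_shifts = shifts,
                            covariate_effects = covs$effect_map),
                       truth_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, truth_path)
  note("simulate", sim_seed, files)

  taxon_mat <- t(SummarizedExperiment::assay(comm$counts))
  md <- comm$metadata

  ## -- community --------------------------------------------------------
  if (want("community")) {
    seed <- stageSeed(config$seed, "community")
    hel <- hellingerTransform(taxon_mat)
    # subsample for the permutation test to keep the run quick
    bc <- brayCurtisMatrix(hel)
    pm <- permanova(bc, md[c("country", "site", "treatment", "sampling")],
                    n_perm = config$analysis$n_perm, seed = seed)
    scores <- communityResistance(taxon_mat, md)
    f <- c(.writeTsv(pm, file.path(outdir, "permanova.tsv")),
           .writeTsv(scores, file.path(outdir, "community_scores.tsv")))
    note("community", seed, f)
  }

  ## -- taxa -------------------------------------------------------------
  calls <- NULL
  if (want("taxa")) {
    seed <- stageSeed(config$seed, "taxa")
    top <- names(sort(colSums(taxon_mat), decreasing = TRUE))[
      seq_len(min(config$analysis$taxa_top_n, ncol(taxon_mat)))]
    res <- classifyAllTaxa(taxon_mat, md, taxa = top,
                           variance = "sampling")
    calls <- res$calls
    f <- c(.writeTsv(calls, file.path(outdir, "strategy_calls.tsv")),
           .writeTsv(strategyCensus(calls),
                     file.path(outdir, "strategy_census.tsv")))
    note("taxa", seed, f)
    fits <- res$fits
  }

  ## -- functions --------------------------------------------------------
  if (want("functions")) {
    seed <- stageSeed(config$seed, "functions")
    fmat <- t(SummarizedExperiment::assay(func$counts))
    fi <- functionalImpactTable(fmat, func$metadata, hier,
                                level = "level1", n_draws = 2e4,
                                seed = seed)
    f <- .writeTsv(fi$table, file.path(outdir, "functional_impacts.tsv"))
    note("functions", seed, f)
  }

  ## -- phylo ------------------------------------------------------------
  if (want("phylo") && want("taxa") && !is.null(calls)) {
    seed <- stageSeed(config$seed, "phylo")
    sig <- try(signalOfResponses(tfx$tree, fits), silent = TRUE)
    if (!inherits(sig, "try-error")) {
      f <- .writeTsv(sig, file.path(outdir, "phylo_signal.tsv"))
      note("phylo", seed, f)
    } else

      manifest$stages[["phylo"]] <- list(seed = seed,
                                         failed = as.character(sig))
  }

  ## -- growth -----------------------------------------------------------
  if (want("growth")) {
    seed <- stageSeed(config$seed, "growth")
    rcfg <- config$simulate$reads
    if (isTRUE(rcfg$enabled)) {
      model <- makeGenomeModel(rcfg$genome_length, seed = seed)
      db <- markerDb(model)
      sites1 <- head(unique(md$site), 3)
      reads <- list()
      for (s in sites1) {
        for (tr in c("control", "heat")) {
          sid <- md$sample_id[md$site == s & md$treatment == tr &
                                md$sampling == "S1"][1]
          if (is.na(sid)) next
          rho <- if (tr == "control") rcfg$rho_control else
            rcfg$rho_disturbed
          reads[[sid]] <- simulateMarkerReads(
            model, rho, n_reads = rcfg$n_reads,
            seed = seed + length(reads))
        }
      }
      cnt <- countMarkers(reads, db)
      gr <- relativeGrowth(cnt, md)
      f <- .writeTsv(gr, file.path(outdir, "growth_estimates.tsv"))
    } else {
      # copy-number capacity path only (no read simulation requested)
      set.seed(seed)
      cn <- setNames(sample(1:10, ncol(taxon_mat), TRUE,
                            prob = 1 / (1:10)), colnames(taxon_mat))
      cap <- growthCapacity(taxon_mat, cn, md)
      f <- .writeTsv(cap, file.path(outdir, "growth_capacity.tsv"))
    }
    note("growth", seed, f)
  }

  ## -- predict ----------------------------------------------------------
  if (want("predict")) {
    seed <- stageSeed(config$seed, "predict")
    tab <- merge(covs$responses, covs$covariates, by = c("site", "country"))
    tab <- standardizePredictors(tab)
    props <- intersect(unlist(propertyFamilies()), names(tab))
    sp <- enumerateSiteSplits(design,
                              records = sampleRecords(design, "metagenome"))
    cvr <- fitGroupedCV(tab, sp$splits, response = "response",
                        predictors = c(props, "treatment", "sampling"),
                        regressor = rangerRegressor(
                          n_trees = config$analysis$cv$n_trees,
                          seed = seed),
                        split_budget = config$analysis$cv$split_budget,
                        seed = seed)
    f <- .writeTsv(cvr$per_split, file.path(outdir, "cv_per_split.tsv"))
    note("predict", seed, f)
    manifest$cv_r2 <- c(mean = cvr$r2_mean, sd = cvr$r2_sd)
  }

  manifest$config <- config
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Collates headline numbers from a run's output directory: the strategy
#' census, significant functional categories, growth estimates and
#' cross-validated R-squared.  Missing stage outputs are reported as
#' absent, not fatal.
#'
#' @param outdir run directory containing \code{manifest.json}.
#' @return list report (also printable as text via \code{print}).
#' @export
summarizeRun <- function(outdir) {
  mpath <- file.path(outdir, "manifest.json")
  if (!file.exists(mpath)) {
    warning("no manifest found in ", outdir)
    return(list(stages = character(0), absent = "manifest"))
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rep <- list(global_seed = manifest$global_seed,
              stages = names(manifest$stages), absent = character(0))
  grab <- function(file) {
    p <- file.path(outdir, file)
    if (file.exists(p)) utils::read.delim(p) else {
      rep$absent <<- c(rep$absent, file)
      NULL
    }
  }
  census <- grab("strategy_census.tsv")
  if (!is.null(census)) rep$strategy_census <- census
  fi <- grab("functional_impacts.tsv")
  if (!is.null(fi))
    rep$significant_functions <- sum(fi$significant, na.rm = TRUE)
  gr <- grab("growth_estimates.tsv")
  if (!is.null(gr))
    rep$mean_G_rel <- tapply(gr$G_rel, gr$treatment, mean)
  if (!is.null(manifest$cv_r2)) rep$cv_r2 <- manifest$cv_r2
  pm <- grab("permanova.tsv")
  if (!is.null(pm)) rep$permanova <- pm
  rep
}
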