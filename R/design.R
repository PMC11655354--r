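# Factorial design construction, exclusion handling, and the two grouped
# cross-validation split spaces (leave-one-site-out within country and
# leave-countries-out).

#' Default disturbance treatment specifications
#'
#' The five microcosm conditions: an undisturbed control (18 degrees C, 60%
#' of water-holding capacity) and four extreme climatic events — drought
#' (18, 10), flood (18, 100), freeze (-20, 60) and heat (35, 60).
#'
#' @return data.frame with columns \code{name}, \code{temperature} (degrees
#'   Celsius) and \code{moisture} (percent of water-holding capacity).
#' @export
defaultTreatments <- function() {
  data.frame(
    name        = c("control", "drought", "flood", "freeze", "heat"),
    temperature = c(18, 18, 18, -20, 35),
    moisture    = c(60, 10, 100, 60, 60),
    stringsAsFactors = FALSE
  )
}

#' Default sampling occasions
#'
#' Four harvests: the end of the disturbance (S1, day 0) and 1, 8 and 26
#' days into the recovery phase (S2-S4).
#'
#' @return data.frame with columns \code{label} and \code{day}.
#' @export
defaultSamplings <- function() {
  data.frame(label = c("S1", "S2", "S3", "S4"),
             day = c(0, 1, 8, 26),
             stringsAsFactors = FALSE)
}

#' Default country codes
#'
#' Ten European grassland regions; the two UK locations (Oxford, Lancaster)
#' count as separate regions.
#'
#' @return character vector of length 10.
#' @export
defaultCountries <- function() {
  c("AT", "DE", "EE", "ES", "GR", "IS", "La", "Ox", "RU", "SE")
}

#' Default sample exclusion rules
#'
#' Ships the standard exclusions: ten Russian microcosms at S2 (all assays;
#' the affected pots are not individually identified, so the rule removes
#' two whole replicate sites at S2 — 2 sites x 5 treatments — keeping the
#' exclusion declarative and idempotent), and two Spanish replicate sites
#' (ES1, ES3) for sequencing-based assays only.
#'
#' @return list of exclusion rules; see \code{\link{applyExclusions}}.
#' @export
defaultExclusions <- function() {
  list(
    list(site = c("RU1", "RU2"), sampling = "S2"),
    list(site = "ES1", assay = c("amplicon", "metagenome"),
         stage = "analysis", include_initial = TRUE),
    list(site = "ES3", assay = c("amplicon", "metagenome"),
         stage = "analysis", include_initial = TRUE)
  )
}

#' Build a factorial microcosm design
#'
#' Constructs the full factorial layout: one microcosm sample record per
#' (country, site, treatment, sampling) cell plus one initial (pre-
#' acclimatization) record per site.  Sample identifiers are deterministic
#' concatenations \code{country_site_treatment_sampling} so that repeated
#' builds are bit-identical and joins are reproducible.
#'
#' @param countries either a count (uses the first \code{n} of
#'   \code{\link{defaultCountries}}, recycling with numeric suffixes if more
#'   than ten are requested) or a character vector of codes.
#' @param sites number of replicate sites per country.
#' @param treatments data.frame of treatment specifications
#'   (default \code{\link{defaultTreatments}()}).
#' @param samplings data.frame of sampling occasions
#'   (default \code{\link{defaultSamplings}()}).
#' @param exclusions list of exclusion rules stored with the design (not
#'   applied here; see \code{\link{sampleRecords}}).
#' @return a \code{\linkS4class{MicrocosmDesign}}.
#' @examples
#' d <- buildDesign()
#' nMicrocosms(d)   # 600
#' @export
buildDesign <- function(countries = 10, sites = 3,
                        treatments = defaultTreatments(),
                        samplings = defaultSamplings(),
                        exclusions = defaultExclusions()) {
  if (is.numeric(countries)) {
    n <- as.integer(countries)
    if (n < 1) stop("need at least one country")
    pool <- defaultCountries()
    countries <- if (n <= length(pool)) pool[seq_len(n)] else
      c(pool, paste0("C", seq_len(n - length(pool))))
  }
  sites <- as.integer(sites)
  if (sites < 1) stop("need at least one site per country")
  if (anyDuplicated(treatments$name))
    stop("duplicate treatment labels")
  if (anyDuplicated(samplings$label))
    stop("duplicate sampling labels")

  site_map <- lapply(countries, function(cc) paste0(cc, seq_len(sites)))
  names(site_map) <- countries

  grid <- expand.grid(
    sampling = samplings$label,
    treatment = treatments$name,
    site_idx = seq_len(sites),
    country = countries,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$site <- paste0(grid$country, grid$site_idx)
  grid$day <- samplings$day[match(grid$sampling, samplings$label)]
  micro <- data.frame(
    sample_id = paste(grid$country, grid$site, grid$treatment, grid$sampling,
                      sep = "_"),
    country = grid$country, site = grid$site,
    treatment = grid$treatment, sampling = grid$sampling, day = grid$day,
    stringsAsFactors = FALSE
  )
  init <- data.frame(
    sample_id = paste(rep(countries, each = sites),
                      unlist(site_map), "initial", sep = "_"),
    country = rep(countries, each = sites),
    site = unlist(site_map),
    treatment = NA_character_, sampling = "initial", day = NA_real_,
    stringsAsFactors = FALSE
  )
  samples <- rbind(micro, init)
  rownames(samples) <- NULL
  # silently drop shipped rules that reference design cells absent from a
  # reduced design; user-supplied rules still warn at application time
  all_sites <- unlist(site_map, use.names = FALSE)
  exclusions <- Filter(function(r) {
    (is.null(r$country) || any(r$country %in% countries)) &&
      (is.null(r$site) || any(r$site %in% all_sites)) &&
      (is.null(r$sampling) || any(r$sampling %in% samplings$label))
  }, exclusions)
  new("MicrocosmDesign", countries = countries, sites = site_map,
      treatments = treatments, samplings = samplings,
      samples = samples, exclusions = exclusions)
}

#' Number of microcosms in a design (before exclusions)
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @return integer count of microcosm records (initial samples not counted).
#' @export
nMicrocosms <- function(design) {
  sum(design@samples$sampling != "initial")
}

#' Treatment table of a design
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @export
designTreatments <- function(design) design@treatments

#' Sampling table of a design
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @export
designSamplings <- function(design) design@samplings

#' Site map of a design
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @return named list, country code -> site identifiers.
#' @export
designSites <- function(design) design@sites

#' Remove sample records matching declarative exclusion rules
#'
#' Each rule is a named list with any subset of the fields \code{country},
#' \code{site}, \code{treatment}, \code{sampling} and \code{assay}; a record
#' is removed when it matches every field a rule specifies (fields may hold
#' several admissible values).  An optional integer field \code{n} caps the
#' number of records a rule removes; matches are taken in the deterministic
#' row order of the record table, so re-runs remove the same records
#' (field-only rules are idempotent; an \code{n}-capped rule applied to an
#' already-filtered table can remove further matches).  A
#' rule that specifies \code{assay} only applies when \code{assay} is one of
#' its values; a rule with \code{stage = "analysis"} marks a post-hoc
#' analysis exclusion (the sample was processed but is dropped from
#' statistics) and is skipped when filtering at \code{stage = "sequencing"}.
#' Initial samples are kept unless a rule sets \code{include_initial} or
#' targets \code{sampling} explicitly.  Removal is idempotent: applying the
#' same rules twice leaves the result unchanged.
#'
#' @param records data.frame of sample records (as in
#'   \code{\link{buildDesign}}).
#' @param rules list of exclusion rules; an empty list returns the input.
#' @param assay assay context for assay-scoped rules (default
#'   \code{"soil_function"}).
#' @param stage \code{"analysis"} (apply every rule) or \code{"sequencing"}
#'   (apply only whole-study rules).
#' @return the filtered record data.frame.
#' @export
applyExclusions <- function(records, rules, assay = "soil_function",
                            stage = c("analysis", "sequencing")) {
  stage <- match.arg(stage)
  if (length(rules) == 0L) return(records)
  drop <- rep(FALSE, nrow(records))
  for (rule in rules) {
    if (!is.null(rule$assay) && !(assay %in% rule$assay)) next
    if (stage == "sequencing" && identical(rule$stage, "analysis")) next
    hit <- rep(TRUE, nrow(records))
    for (f in intersect(names(rule), c("country", "site", "treatment",
                                       "sampling"))) {
      hit <- hit & records[[f]] %in% rule[[f]]
    }
    if (is.null(rule$sampling) && !isTRUE(rule$include_initial))
      hit <- hit & records$sampling != "initial"
    if (!any(hit)) {
      warning("exclusion rule matched no records: ",
              paste(names(rule), unlist(lapply(rule, paste, collapse = "/")),
                    sep = "=", collapse = ", "))
      next
    }
    if (!is.null(rule$n)) {
      idx <- which(hit & !drop)
      hit <- rep(FALSE, nrow(records))
      hit[head(idx, rule$n)] <- TRUE
    }
    drop <- drop | hit
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retained sample records for an assay
#'
#' Applies the design's stored exclusion rules in the context of a given
#' assay and optionally restricts to a subset of sampling occasions (for
#' example metagenomes are only taken at S1 and S4).
#'
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @param assay one of \code{"amplicon"}, \code{"metagenome"},
#'   \code{"soil_function"}.
#' @param include_initial keep the pre-experiment initial samples?
#' @param samplings optional character vector of sampling labels to retain
#'   (initial samples are unaffected).
#' @param stage passed to \code{\link{applyExclusions}};
#'   \code{"sequencing"} counts every sample that was processed,
#'   \code{"analysis"} (default) additionally drops post-hoc exclusions.
#' @return data.frame of sample records with an \code{assay} column.
#' @examples
#' d <- buildDesign()
#' # 620 amplicon samples were sequenced (30 initial + 590 microcosms)
#' nrow(sampleRecords(d, "amplicon", stage = "sequencing"))
#' @export
sampleRecords <- function(design,
                          assay = c("soil_function", "amplicon",
                                    "metagenome"),
                          include_initial = TRUE, samplings = NULL,
                          stage = "analysis") {
  assay <- match.arg(assay)
  rec <- applyExclusions(design@samples, design@exclusions, assay = assay,
                         stage = stage)
  if (!include_initial) rec <- rec[rec$sampling != "initial", , drop = FALSE]
  if (!is.null(samplings))
    rec <- rec[rec$sampling %in% c(samplings, "initial"), , drop = FALSE]
  rec$assay <- assay
  rownames(rec) <- NULL
  rec
}

#' Enumerate site-level grouped cross-validation splits
#'
#' Every way of holding out one replicate site per country: in each country
#' that retains exactly three sites, two sites train and the third tests.
#' With k complete countries this yields 3^k distinct splits.  Countries
#' retaining fewer than three sites contribute their remaining sites to
#' every training set and never appear in test sets.
#'
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @param records optional data.frame of retained records (defaults to the
#'   design's metagenome records); the retained site set is derived from it.
#' @return list with elements \code{splits} (list of
#'   \code{list(train=, test=)} site-id vectors, in deterministic order) and
#'   \code{complete_countries}.
#' @export
enumerateSiteSplits <- function(design, records = NULL) {
  if (is.null(records)) records <- sampleRecords(design, "metagenome")
  site_tab <- unique(records[records$sampling != "initial",
                             c("country", "site")])
  per_country <- split(site_tab$site, site_tab$country)
  per_country <- lapply(per_country, sort)
  n_sites <- lengths(per_country)
  if (any(n_sites > 3))
    stop("site-level splits require at most 3 retained sites per country")
  complete <- names(per_country)[n_sites == 3]
  complete <- sort(complete)
  if (length(complete) == 0L)
    stop("no country retains three sites; site-level split space is empty")
  always_train <- unlist(per_country[setdiff(names(per_country), complete)],
                         use.names = FALSE)
  # index grid over which of the three sites is held out in each country
  choice <- expand.grid(rep(list(1:3), length(complete)),
                        KEEP.OUT.ATTRS = FALSE)
  splits <- lapply(seq_len(nrow(choice)), function(i) {
    test <- vapply(seq_along(complete), function(j)
      per_country[[complete[j]]][choice[i, j]], character(1))
    train <- c(unlist(lapply(seq_along(complete), function(j)
      per_country[[complete[j]]][-choice[i, j]]), use.names = FALSE),
      always_train)
    list(train = sort(train), test = sort(test))
  })
  list(splits = splits, complete_countries = complete)
}

#' Enumerate country-level grouped cross-validation splits
#'
#' All distinct ways of choosing \code{n_train} training countries; the
#' complement forms the test set.
#'
#' @param design a \code{\linkS4class{MicrocosmDesign}}
#' @param n_train number of training countries, between 1 and one less than
#'   the number of countries.
#' @return list of \code{list(train=, test=)} country-code vectors.
#' @export
enumerateCountrySplits <- function(design, n_train) {
  cc <- sort(design@countries)
  n_train <- as.integer(n_train)
  if (n_train < 1L || n_train >= length(cc))
    stop("n_train must be between 1 and ", length(cc) - 1L)
  combos <- combn(cc, n_train, simplify = FALSE)
  lapply(combos, function(tr) list(train = tr, test = setdiff(cc, tr)))
}

#' Write a sample metadata sheet
#'
#' @param records sample record data.frame
#' @param path output TSV path
#' @return the path, invisibly.
#' @export
writeSampleSheet <- function(records, path) {
  cols <- intersect(c("sample_id", "country", "site", "treatment",
                      "sampling", "day", "assay"), names(records))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
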