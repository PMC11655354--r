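# Synthetic functional-gene profiles (4-level nested hierarchy with
# planted treatment shifts), site-level covariates with a known resistance
# surface, and soil-function measurements loaded on functional categories.

#' Build a nested 4-level functional hierarchy
#'
#' Emulates a subsystems-style classification: proteins nested in level3
#' groups, nested in level2, nested in level1.  Membership is deterministic
#' (round-robin) so hierarchies are reproducible without a seed.
#'
#' @param n_protein number of finest-scale categories (proteins).
#' @param n_level3,n_level2,n_level1 group counts at the coarser levels.
#' @return data.frame with columns \code{protein}, \code{level3},
#'   \code{level2}, \code{level1}; one row per protein.
#' @export
makeFunctionalHierarchy <- function(n_protein = 50, n_level3 = 20,
                                    n_level2 = 10, n_level1 = 5) {
  if (n_level3 > n_protein || n_level2 > n_level3 || n_level1 > n_level2)
    stop("levels must be successively coarser")
  protein <- sprintf("prot%03d", seq_len(n_protein))
  l3 <- sprintf("L3_%02d", 1 + (seq_len(n_protein) - 1) %% n_level3)
  l3u <- sort(unique(l3))
  l2_of_l3 <- sprintf("L2_%02d", 1 + (seq_along(l3u) - 1) %% n_level2)
  names(l2_of_l3) <- l3u
  l2 <- l2_of_l3[l3]
  l2u <- sort(unique(l2))
  l1_of_l2 <- sprintf("L1_%02d", 1 + (seq_along(l2u) - 1) %% n_level1)
  names(l1_of_l2) <- l2u
  l1 <- l1_of_l2[l2]
  data.frame(protein = protein, level3 = unname(l3), level2 = unname(l2),
             level1 = unname(l1), stringsAsFactors = FALSE)
}

#' Simulate functional-gene profiles with planted treatment shifts
#'
#' Per-sample protein compositions are drawn from a Dirichlet-multinomial
#' around site-specific base compositions.  Each planted shift adds a
#' signed displacement \code{delta} to the expected proportion of one
#' category (a protein, or a higher-level group whose proteins share the
#' displacement proportionally) in one treatment at the end of the
#' disturbance; a shift with \code{resilient = TRUE} decays linearly to
#' zero by the final sampling, otherwise it persists.
#'
#' @param design a \code{\linkS4class{MicrocosmDesign}}.
#' @param hierarchy data.frame from \code{\link{makeFunctionalHierarchy}}.
#' @param shifts NULL, or data.frame with columns \code{category},
#'   \code{treatment}, \code{delta} and optional logical \code{resilient}.
#' @param seed integer RNG seed.
#' @param concentration Dirichlet concentration (higher = less
#'   compositional noise).
#' @param libsize_meanlog,libsize_sdlog lognormal library-size parameters.
#' @param site_sd lognormal SD of site-level base-composition multipliers.
#' @param samplings sampling occasions with metagenomes (default S1, S4).
#' @return list with \code{counts} (\code{SummarizedExperiment}, proteins x
#'   samples), \code{metadata}, \code{hierarchy} and \code{truth}.
#' @export
simulateFunctionalProfiles <- function(design,
                                       hierarchy = makeFunctionalHierarchy(),
                                       shifts = NULL, seed = 1L,
                                       concentration = 5000,
                                       libsize_meanlog = log(5e4),
                                       libsize_sdlog = 0.2,
                                       site_sd = 0.2,
                                       samplings = c("S1", "S4")) {
  set.seed(seed)
  records <- sampleRecords(design, "metagenome", include_initial = FALSE,
                           samplings = samplings)
  n <- nrow(records)
  prot <- hierarchy$protein
  np <- length(prot)

  base <- rlnorm(np, 0, 1)
  base <- base / sum(base)
  names(base) <- prot
  sites <- unique(records$site)
  u_site <- matrix(rnorm(length(sites) * np, 0, site_sd),
                   length(sites), np, dimnames = list(sites, prot))

  max_day <- max(design@samplings$day)
  delta_for <- function(treatment, day) {
    d <- numeric(np)
    if (is.null(shifts) || !nrow(shifts)) return(d)
    for (r in seq_len(nrow(shifts))) {
      if (shifts$treatment[r] != treatment) next
      cat_id <- shifts$category[r]
      members <- if (cat_id %in% prot) cat_id else {
        lvl <- c("level3", "level2", "level1")[
          c(cat_id %in% hierarchy$level3, cat_id %in% hierarchy$level2,
            cat_id %in% hierarchy$level1)]
        if (!length(lvl)) stop("unknown category in shifts: ", cat_id)
        hierarchy$protein[hierarchy[[lvl[1]]] == cat_id]
      }
      dec <- if (isTRUE(shifts$resilient[r])) max(0, 1 - day / max_day) else 1
      w <- base[members] / sum(base[members])
      d[match(members, prot)] <- d[match(members, prot)] +
        shifts$delta[r] * dec * w
    }
    d
  }

  libsize <- pmax(1000L, as.integer(round(
    rlnorm(n, libsize_meanlog, libsize_sdlog))))
  counts <- matrix(0L, np, n, dimnames = list(prot, records$sample_id))
  clipped <- 0L
  for (i in seq_len(n)) {
    p <- base * exp(u_site[records$site[i], ])
    p <- p / sum(p)
    tr <- records$treatment[i]
    if (!is.na(tr) && tr != "control")
      p <- p + delta_for(tr, records$day[i])
    if (any(p < 0)) clipped <- clipped + 1L
    p <- pmax(p, 0)
    p <- p / sum(p)
    w <- rgamma(np, shape = concentration * p, rate = 1)
    if (sum(w) == 0) w <- p
    counts[, i] <- rmultinom(1, libsize[i], w)
  }
  if (clipped) warning(clipped, " sample(s) had shifted proportions ",
                       "clipped at zero")
  md <- records
  md$libsize <- libsize
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(md, row.names = md$sample_id))
  list(counts = se, metadata = md, hierarchy = hierarchy,
       truth = list(base = base, shifts = shifts, seed = seed,
                    concentration = concentration))
}

#' Canonical initial-property names
#'
#' The 20 site-level soil and climate properties: four temperature, four
#' precipitation, eight carbon/nitrogen, three water-holding, and pH.
#'
#' @return named list of character vectors, one per property family.
#' @export
propertyFamilies <- function() {
  list(
    temperature = c("T_mean", "T_max", "T_min", "T_length"),
    precipitation = c("P_mean", "P_max", "P_min", "P_length"),
    carbon_nitrogen = c("TotalC", "TotalN", "CN_ratio", "DOC", "DON",
                        "TotalDissolvedN", "Nitrate", "Ammonium"),
    water_holding = c("WHC100", "WHC", "Moisture"),
    ph = "pH"
  )
}

#' Simulate site-level covariates and a known resistance surface
#'
#' Generates the 20 initial properties per site (country-level latent
#' climate and soil axes plus site noise, giving realistic within-family
#' cross-correlation) and a deterministic "true" resistance for every
#' (site, treatment) pair from a stated effect map, plus Gaussian noise.
#' The default effect map makes heat resistance increase with the
#' mean-annual-temperature analogue, drought resistance with temperature
#' and dryness, flood resistance with soil moisture, and freeze resistance
#' decrease with temperature — with one temperature-by-moisture interaction
#' on heat.
#'
#' @param design a \code{\linkS4class{MicrocosmDesign}}.
#' @param effect_map NULL for the default, or a named list
#'   (per treatment) of named coefficient vectors over standardized
#'   properties; an entry named \code{"T_mean:WHC"} denotes the product
#'   interaction.
#' @param noise_sd SD of the Gaussian noise added to the true surface when
#'   emitting observed responses.
#' @param seed integer RNG seed.
#' @return list with \code{covariates} (site x 20 data.frame, plus
#'   \code{site}/\code{country} columns), \code{truth} (long data.frame of
#'   the noiseless response per site x treatment), \code{responses} (truth
#'   + noise, duplicated over samplings S1/S4) and \code{effect_map}.
#' @export
simulateCovariates <- function(design, effect_map = NULL, noise_sd = 0.1,
                               seed = 1L) {
  set.seed(seed)
  fams <- propertyFamilies()
  props <- unlist(fams, use.names = FALSE)
  if (length(props) != 20L) stop("expected exactly 20 properties")
  site_tab <- unique(design@samples[design@samples$sampling != "initial",
                                    c("country", "site")])
  ns <- nrow(site_tab)

  # latent country axes: climate (warm/dry vs cold/wet) and fertility
  cc <- unique(site_tab$country)
  clim <- setNames(rnorm(length(cc)), cc)
  fert <- setNames(rnorm(length(cc)), cc)
  lat_c <- clim[site_tab$country] + rnorm(ns, 0, 0.4)
  lat_f <- fert[site_tab$country] + rnorm(ns, 0, 0.4)

  cov <- data.frame(site = site_tab$site, country = site_tab$country,
                    stringsAsFactors = FALSE)
  mk <- function(load_c, load_f, sd = 0.5)
    load_c * lat_c + load_f * lat_f + rnorm(ns, 0, sd)
  cov$T_mean <- mk(1, 0); cov$T_max <- mk(0.9, 0); cov$T_min <- mk(0.8, 0)
  cov$T_length <- cov$T_max - cov$T_min + rnorm(ns, 0, 0.2)
  cov$P_mean <- mk(-0.8, 0.2); cov$P_max <- mk(-0.7, 0.2)
  cov$P_min <- mk(-0.6, 0.1)
  cov$P_length <- cov$P_max - cov$P_min + rnorm(ns, 0, 0.2)
  cov$TotalC <- mk(-0.3, 1); cov$TotalN <- mk(-0.2, 0.9)
  cov$CN_ratio <- cov$TotalC - cov$TotalN + rnorm(ns, 0, 0.3)
  cov$DOC <- mk(-0.2, 0.7); cov$DON <- mk(-0.1, 0.7)
  cov$TotalDissolvedN <- mk(0, 0.8); cov$Nitrate <- mk(0.1, 0.6)
  cov$Ammonium <- mk(-0.1, 0.6)
  cov$WHC100 <- mk(-0.6, 0.4); cov$WHC <- mk(-0.5, 0.4)
  cov$Moisture <- mk(-0.7, 0.3)
  cov$pH <- mk(0.5, -0.4)

  if (is.null(effect_map)) {
    effect_map <- list(
      heat = c(T_mean = 0.5, Moisture = -0.2, "T_mean:Moisture" = 0.15),
      drought = c(T_mean = 0.3, P_mean = -0.3),
      flood = c(Moisture = 0.4, WHC100 = 0.2),
      freeze = c(T_mean = -0.4, TotalC = 0.2)
    )
  }
  z <- scale(as.matrix(cov[props]))
  surf <- function(tr) {
    co <- effect_map[[tr]]
    if (is.null(co)) return(numeric(ns))
    val <- numeric(ns)
    for (nm in names(co)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      v <- z[, parts[1]]
      if (length(parts) == 2) v <- v * z[, parts[2]]
      val <- val + co[[nm]] * v
    }
    val
  }
  trts <- setdiff(design@treatments$name, "control")
  truth <- do.call(rbind, lapply(trts, function(tr) data.frame(
    site = cov$site, country = cov$country, treatment = tr,
    true_response = surf(tr), stringsAsFactors = FALSE)))

  responses <- do.call(rbind, lapply(c("S1", "S4"), function(s) {
    r <- truth
    r$sampling <- s
    r$response <- r$true_response + rnorm(nrow(r), 0, noise_sd)
    r
  }))
  rownames(truth) <- rownames(responses) <- NULL
  list(covariates = cov, truth = truth, responses = responses,
       effect_map = effect_map, noise_sd = noise_sd, seed = seed)
}

#' Soil-function measurement families
#'
#' The four measured families and their variables: enzyme activities (4),
#' substrate-induced respiration (8), carbon/nitrogen availability (4) and
#' greenhouse-gas fluxes (3).
#'
#' @return named list of character vectors.
#' @export
soilFunctionFamilies <- function() {
  list(
    enzymes = c("phosphatase", "beta_glucosidase",
                "leucine_aminopeptidase", "acetylesterase"),
    substrate_use = c("water", "alanine", "cellulose", "citric_acid",
                      "fructose", "glucose", "glycine", "malic_acid"),
    carbon_nitrogen = c("DOC", "DON", "nitrate", "ammonium"),
    gas_fluxes = c("CO2", "CH4", "N2O")
  )
}

#' Simulate soil-function measurements from functional profiles
#'
#' Measurements are a linear map of per-sample functional-category
#' proportions plus Gaussian noise:
#' \eqn{M = P L + \epsilon}.  With nonzero loadings, samples with similar
#' functional profiles have similar measurements, which the Mantel test
#' downstream should detect.
#'
#' @param x functional count matrix (samples in rows) or
#'   \code{SummarizedExperiment}; converted to proportions internally.
#' @param loadings categories x 19 loading matrix; NULL draws a random
#'   dense loading matrix (seeded); 0 gives pure-noise measurements.
#' @param noise_sd measurement noise SD.
#' @param seed integer RNG seed.
#' @return list with \code{measurements} (samples x 19 data.frame, columns
#'   named by \code{\link{soilFunctionFamilies}}), \code{loadings} and
#'   \code{families}.
#' @export
simulateSoilFunctions <- function(x, loadings = NULL, noise_sd = 0.05,
                                  seed = 1L) {
  m <- .asSampleMatrix(x)
  p <- m / rowSums(m)
  fams <- soilFunctionFamilies()
  vars <- unlist(fams, use.names = FALSE)
  set.seed(seed)
  if (is.null(loadings)) {
    loadings <- matrix(rnorm(ncol(p) * length(vars), 0, 1),
                       ncol(p), length(vars),
                       dimnames = list(colnames(p), vars))
  } else if (identical(loadings, 0)) {
    loadings <- matrix(0, ncol(p), length(vars),
                       dimnames = list(colnames(p), vars))
  }
  if (nrow(loadings) != ncol(p) || ncol(loadings) != length(vars))
    stop("loading matrix must be categories x ", length(vars))
  meas <- p %*% loadings + matrix(rnorm(nrow(p) * length(vars), 0, noise_sd),
                                  nrow(p), length(vars))
  colnames(meas) <- vars
  list(measurements = as.data.frame(meas), loadings = loadings,
       families = fams)
}
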