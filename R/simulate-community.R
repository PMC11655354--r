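# Synthetic taxon communities: a phylogeny with lambda-structured planted
# effects, and factorial count tables with known per-taxon response
# strategies.  All generators are seed-deterministic and return their
# planted quantities in a ground-truth ledger.

#' Simulate a phylogeny with phylogenetically structured planted effects
#'
#' Draws a random coalescent tree and, for each requested treatment, a
#' per-taxon planted impact effect as a lambda-weighted mixture of a
#' Brownian-motion realisation on the tree and independent white noise:
#' \eqn{e = \sigma(\sqrt{\lambda}\, b + \sqrt{1-\lambda}\, z)} where
#' \eqn{b} is Brownian on the tree scaled to unit tip variance and
#' \eqn{z} is iid standard normal.  At \code{lambda = 1} effects are pure
#' Brownian (full phylogenetic signal); at \code{lambda = 0} they are
#' independent of the tree.
#'
#' @param n_taxa number of tips (at least 3).
#' @param lambda signal strength in [0, 1].
#' @param seed integer RNG seed.
#' @param treatments character vector of effect names (default the four
#'   disturbances).
#' @param effect_sd marginal standard deviation of the planted effects, on
#'   the relative-abundance displacement scale.
#' @param slope_sd marginal SD of the planted recovery-slope effects (same
#'   mixture construction, independent draw).
#' @return list with \code{tree} (an \code{ape} \code{phylo}),
#'   \code{impact} and \code{slope} (taxa x treatment matrices) and
#'   \code{lambda}.
#' @export
simulateTreeAndEffects <- function(n_taxa, lambda = 1, seed = 1L,
                                   treatments = c("drought", "flood",
                                                  "freeze", "heat"),
                                   effect_sd = 0.02, slope_sd = 0.001) {
  if (n_taxa < 3) stop("need at least 3 taxa")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  set.seed(seed)
  tree <- ape::rcoal(n_taxa, tip.label = sprintf("t%03d", seq_len(n_taxa)))
  C <- ape::vcv(tree)
  C <- C / mean(diag(C))          # unit tip variance
  L <- chol(C)
  draw <- function(sd) {
    b <- drop(crossprod(L, rnorm(n_taxa)))
    z <- rnorm(n_taxa)
    e <- sd * (sqrt(lambda) * b + sqrt(1 - lambda) * z)
    names(e) <- rownames(C)
    e[tree$tip.label]
  }
  impact <- vapply(treatments, function(tr) draw(effect_sd),
                   numeric(n_taxa))
  slope <- vapply(treatments, function(tr) draw(slope_sd),
                  numeric(n_taxa))
  rownames(impact) <- rownames(slope) <- tree$tip.label
  list(tree = tree, impact = impact, slope = slope, lambda = lambda)
}

#' Default community simulation parameters
#'
#' Desk-scale defaults: 200 taxa with a lognormal baseline abundance
#' profile, multiplicative country and site random intercepts, moderate
#' gamma overdispersion and lognormal library sizes around 10,000 reads.
#'
#' @param ... overrides for any parameter.
#' @return named list of parameters.
#' @export
communitySimParams <- function(...) {
  p <- list(
    n_taxa = 200L,
    baseline_meanlog = 0,       # relative scale; normalised to proportions
    baseline_sdlog = 1.5,
    country_sd = 0.30,          # multiplicative intercept SDs (log-normal)
    site_sd = 0.15,
    overdispersion = 0.002,     # gamma dispersion of per-sample proportions
    libsize_meanlog = log(1e4),
    libsize_sdlog = 0.30,
    rng_seed = 1L
  )
  stopifnot(all(names(list(...)) %in% names(p)))
  p <- modifyList(p, list(...))
  if (p$country_sd < 0 || p$site_sd < 0 || p$overdispersion < 0 ||
      p$baseline_sdlog < 0 || p$libsize_sdlog < 0)
    stop("variance parameters must be non-negative")
  p
}

#' Simulate a factorial taxon count table with planted response strategies
#'
#' Expected relative abundance of taxon j in sample i is
#' \deqn{p_{ij} = b_j u_{c(i),j} u_{s(i),j} + \delta_{j,t(i)} +
#'       \gamma_{j,t(i)} \cdot day_i}
#' where \eqn{b_j} is the baseline proportion, \eqn{u} are lognormal
#' country and site multipliers, \eqn{\delta} is the planted impact
#' (displacement from control at the end of the disturbance) and
#' \eqn{\gamma} the planted recovery slope per day, both zero in the
#' control.  Proportions are clipped at zero, renormalised, perturbed by a
#' gamma draw with the stated overdispersion and sampled as a multinomial
#' of the drawn library size, so each count row sums exactly to its library
#' size (a negative-binomial scheme conditioned on the total).
#'
#' @param design a \code{\linkS4class{MicrocosmDesign}}.
#' @param strategies data.frame of planted effects with columns
#'   \code{taxon_id}, \code{treatment}, \code{impact}, \code{slope}; taxa
#'   absent from it are fully resistant (both zero).  NULL plants nothing.
#' @param params list from \code{\link{communitySimParams}}.
#' @param taxa optional taxon ids (default \code{t001..}); baselines are
#'   drawn per taxon.
#' @param records optional pre-filtered sample records (default: amplicon
#'   records without initial samples).
#' @return list with \code{counts}
#'   (a \code{SummarizedExperiment}, taxa x samples, assay
#'   \code{"counts"}), \code{metadata}, and \code{truth} (the ground-truth
#'   ledger: baselines, strategy table, parameters).
#' @export
simulateAsvCounts <- function(design, strategies = NULL,
                              params = communitySimParams(),
                              taxa = NULL, records = NULL) {
  set.seed(params$rng_seed)
  n_taxa <- params$n_taxa
  if (is.null(taxa)) taxa <- sprintf("t%03d", seq_len(n_taxa))
  n_taxa <- length(taxa)
  if (is.null(records))
    records <- sampleRecords(design, "amplicon", include_initial = FALSE)
  n <- nrow(records)

  baseline <- rlnorm(n_taxa, params$baseline_meanlog, params$baseline_sdlog)
  baseline <- baseline / sum(baseline)
  names(baseline) <- taxa

  countries <- unique(records$country)
  sites <- unique(records$site)
  u_country <- matrix(rnorm(length(countries) * n_taxa, 0,
                            params$country_sd),
                      length(countries), n_taxa,
                      dimnames = list(countries, taxa))
  u_site <- matrix(rnorm(length(sites) * n_taxa, 0, params$site_sd),
                   length(sites), n_taxa, dimnames = list(sites, taxa))

  imp <- matrix(0, n_taxa, 0)
  if (!is.null(strategies) && nrow(strategies)) {
    trts <- setdiff(design@treatments$name, "control")
    imp <- matrix(0, n_taxa, length(trts), dimnames = list(taxa, trts))
    slp <- imp
    ok <- strategies$taxon_id %in% taxa & strategies$treatment %in% trts
    if (!all(ok)) stop("strategies reference unknown taxa or treatments")
    imp[cbind(match(strategies$taxon_id, taxa),
              match(strategies$treatment, trts))] <- strategies$impact
    slp[cbind(match(strategies$taxon_id, taxa),
              match(strategies$treatment, trts))] <- strategies$slope
  } else slp <- imp

  libsize <- as.integer(round(
    rlnorm(n, params$libsize_meanlog, params$libsize_sdlog)))
  if (any(libsize < 1)) stop("drawn library size below 1; ",
                             "raise libsize_meanlog")

  # base compositions: baseline x site/country multipliers, renormalised
  Q <- baseline * exp(t(u_country[records$country, , drop = FALSE] +
                          u_site[records$site, , drop = FALSE]))
  Q <- sweep(Q, 2L, colSums(Q), "/")        # taxa x samples

  # planted displacements are applied on the realised proportion scale:
  # targeted taxa move by exactly impact + slope*day; the remaining taxa
  # are rescaled so compositions still sum to one (slight dilution)
  P <- Q
  if (ncol(imp)) {
    for (i in seq_len(n)) {
      tr <- records$treatment[i]
      if (is.na(tr) || tr == "control" || !tr %in% colnames(imp)) next
      eff <- imp[, tr] + slp[, tr] * records$day[i]
      tgt <- eff != 0
      if (!any(tgt)) next
      p <- Q[, i]
      p_t <- pmin(pmax(p[tgt] + eff[tgt], 0), 1)
      denom <- 1 - sum(p[tgt])
      if (denom > 0 && sum(p_t) < 1) {
        p[!tgt] <- p[!tgt] * (1 - sum(p_t)) / denom
      }
      p[tgt] <- p_t
      P[, i] <- p / sum(p)
    }
  }
  if (any(colSums(P) == 0))
    stop("all expected proportions zero in sample ",
         records$sample_id[which(colSums(P) == 0)[1]])

  counts <- matrix(0L, n_taxa, n, dimnames = list(taxa, records$sample_id))
  if (params$overdispersion > 0) {
    W <- matrix(rgamma(length(P), shape = P / params$overdispersion,
                       rate = 1), n_taxa, n)
    zero <- colSums(W) == 0
    W[, zero] <- P[, zero]
  } else W <- P
  for (i in seq_len(n)) counts[, i] <- rmultinom(1, libsize[i], W[, i])

  md <- records
  md$libsize <- libsize
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(md, row.names = md$sample_id))
  list(counts = se, metadata = md,
       truth = list(baseline = baseline, strategies = strategies,
                    impact = imp, slope = slp, params = params))
}
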