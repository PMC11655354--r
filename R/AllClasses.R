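#' @import methods
#' @importFrom stats rnorm rbinom rgamma rpois rnbinom runif sd var cor
#'   coef anova as.formula model.matrix optimize pchisq pf pt qchisq qnorm
#'   quantile setNames aggregate complete.cases p.adjust predict terms
#'   as.dist hclust pnorm rmultinom vcov qt
#' @importFrom utils combn head modifyList
NULL

#' Factorial microcosm experiment design
#'
#' An S4 container for the factorial layout of a multi-site disturbance
#' microcosm experiment: a set of countries, replicate sites nested in
#' country, disturbance treatments (including the undisturbed control) and
#' post-disturbance sampling occasions.  One physical microcosm exists per
#' (country, site, treatment, sampling) cell, plus one pre-experiment
#' "initial" sample per site.
#'
#' @slot countries character vector of country codes.
#' @slot sites named list mapping country code to its site identifiers.
#' @slot treatments data.frame with columns \code{name}, \code{temperature}
#'   (degrees Celsius) and \code{moisture} (percent of water-holding
#'   capacity); the control treatment must be present and named
#'   \code{"control"}.
#' @slot samplings data.frame with columns \code{label} and \code{day}
#'   (days after the end of the disturbance; the end-of-disturbance harvest
#'   is day 0).
#' @slot samples data.frame of sample records, one row per microcosm plus
#'   one per initial sample (columns \code{sample_id}, \code{country},
#'   \code{site}, \code{treatment}, \code{sampling}, \code{day}).
#' @slot exclusions list of declarative exclusion rules (see
#'   \code{\link{applyExclusions}}).
#'
#' @seealso \code{\link{buildDesign}}, \code{\link{sampleRecords}},
#'   \code{\link{enumerateSiteSplits}}
#' @export
setClass("MicrocosmDesign",
  representation(
    countries  = "character",
    sites      = "list",
    treatments = "data.frame",
    samplings  = "data.frame",
    samples    = "data.frame",
    exclusions = "list"
  )
)

setValidity("MicrocosmDesign", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@countries))
    msg <- c(msg, "country codes must be unique")
  if (!setequal(names(object@sites), object@countries))
    msg <- c(msg, "sites must be a named list keyed by every country")
  tr <- object@treatments
  if (!all(c("name", "temperature", "moisture") %in% names(tr)))
    msg <- c(msg, "treatments needs columns name, temperature, moisture")
  else if (anyDuplicated(tr$name))
    msg <- c(msg, "treatment names must be unique")
  sp <- object@samplings
  if (!all(c("label", "day") %in% names(sp)))
    msg <- c(msg, "samplings needs columns label, day")
  else {
    if (anyDuplicated(sp$label)) msg <- c(msg, "sampling labels must be unique")
    if (is.unsorted(sp$day, strictly = TRUE))
      msg <- c(msg, "sampling days must be strictly increasing")
  }
  if (anyDuplicated(object@samples$sample_id))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn MicrocosmDesign compact description of the design
#' @param object a \code{MicrocosmDesign}
#' @export
setMethod("show", "MicrocosmDesign", function(object) {
  n_sites <- sum(lengths(object@sites))
  n_micro <- sum(object@samples$sampling != "initial")
  cat("MicrocosmDesign:",
      length(object@countries), "countries x",
      n_sites, "sites,",
      nrow(object@treatments), "treatments x",
      nrow(object@samplings), "samplings\n")
  cat("  microcosms:", n_micro,
      " initial samples:", sum(object@samples$sampling == "initial"), "\n")
  cat("  exclusion rules:", length(object@exclusions), "\n")
})
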