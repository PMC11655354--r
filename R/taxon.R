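# Per-taxon disturbance models and ecological response-strategy
# classification.

#' Fit the per-taxon disturbance mixed model
#'
#' Relative abundance (count over un-rarefied library size) of one taxon is
#' modelled as \code{treatment + day + treatment:day} with random
#' intercepts for country and site within country (REML).  The treatment
#' main effects are the displacements from control at the end of the
#' disturbance (day 0, the "impact"); the treatment-by-day interactions are
#' the control-relative recovery slopes.  Heteroscedasticity is modelled by
#' a constant-plus-proportional residual variance in the inverse square
#' root of sequencing depth, multiplied by a per-sampling-occasion factor;
#' both are estimated jointly with the fixed effects.  Wald p-values are
#' reported uncorrected.
#'
#' @param x count matrix (samples in rows) or \code{SummarizedExperiment}.
#' @param metadata data.frame with \code{sample_id}, \code{country},
#'   \code{site}, \code{treatment}, \code{sampling}, \code{day} and
#'   \code{libsize}; if \code{libsize} is absent row sums of the counts are
#'   used.
#' @param taxon_id taxon (feature) to model.
#' @param variance one of \code{"depth_sampling"} (default: both variance
#'   terms), \code{"sampling"}, or \code{"none"}.
#' @return object of class \code{taxonFit}: list with \code{taxon_id},
#'   \code{coefficients} (data.frame per treatment: \code{impact},
#'   \code{impact_se}, \code{impact_p}, \code{slope}, \code{slope_se},
#'   \code{slope_p}), \code{converged}, and the underlying \code{lme} fit.
#' @export
fitTaxonModel <- function(x, metadata, taxon_id,
                          variance = c("depth_sampling", "sampling",
                                       "none")) {
  variance <- match.arg(variance)
  m <- .asSampleMatrix(x)
  if (!taxon_id %in% colnames(m)) stop("taxon not in table: ", taxon_id)
  md <- as.data.frame(metadata)
  md <- md[match(rownames(m), md$sample_id), , drop = FALSE]
  depth <- if ("libsize" %in% names(md)) md$libsize else rowSums(m)
  df <- data.frame(
    rel = m[, taxon_id] / depth,
    treatment = stats::relevel(factor(md$treatment), ref = "control"),
    day = md$day, sampling = factor(md$sampling),
    country = factor(md$country), site = factor(md$site),
    inv_sqrt_depth = 1 / sqrt(depth)
  )
  df <- df[complete.cases(df), , drop = FALSE]

  wts <- switch(variance,
    depth_sampling = nlme::varComb(
      nlme::varConstProp(form = ~ inv_sqrt_depth),
      nlme::varIdent(form = ~ 1 | sampling)),
    sampling = nlme::varIdent(form = ~ 1 | sampling),
    none = NULL)

  fit <- try(suppressWarnings(nlme::lme(
    rel ~ treatment * day, data = df,
    random = ~ 1 | country / site, weights = wts, method = "REML",
    control = nlme::lmeControl(opt = "optim", maxIter = 150,
                               msMaxIter = 150, niterEM = 50,
                               returnObject = FALSE))), silent = TRUE)

  if (inherits(fit, "try-error")) {
    return(structure(list(taxon_id = taxon_id, coefficients = NULL,
                          converged = FALSE, fit = NULL),
                     class = "taxonFit"))
  }
  tt <- summary(fit)$tTable
  trts <- setdiff(levels(df$treatment), "control")
  co <- do.call(rbind, lapply(trts, function(tr) {
    ti <- paste0("treatment", tr)
    si <- paste0("treatment", tr, ":day")
    data.frame(treatment = tr,
               impact = tt[ti, "Value"], impact_se = tt[ti, "Std.Error"],
               impact_p = tt[ti, "p-value"],
               slope = tt[si, "Value"], slope_se = tt[si, "Std.Error"],
               slope_p = tt[si, "p-value"],
               stringsAsFactors = FALSE)
  }))
  rownames(co) <- NULL
  bad <- !is.finite(co$impact_se) | co$impact_se <= 0 |
    !is.finite(co$slope_se) | co$slope_se <= 0
  structure(list(taxon_id = taxon_id, coefficients = co,
                 converged = !any(bad), fit = fit),
            class = "taxonFit")
}

#' @export
print.taxonFit <- function(x, ...) {
  cat("taxon model:", x$taxon_id,
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 3)
  invisible(x)
}

#' Classify a taxon's response to one disturbance
#'
#' Deterministic mapping from the signs and significance of the impact
#' (displacement at the end of the disturbance) and slope (recovery-phase
#' trend) coefficients to an ecological response strategy:
#' \itemize{
#'   \item significant impact, non-significant slope: \emph{stable}
#'     positive/negative impact;
#'   \item significant impact and slope of opposite sign: \emph{resilient};
#'   \item significant impact and slope of the same sign: \emph{diverging};
#'   \item no significant impact but a significant slope: late positive or
#'     late negative divergence;
#'   \item nothing significant: \emph{fully resistant}.
#' }
#' The grid covers every sign/significance combination exactly once: eight
#' responsive classes plus full resistance (and a separate model-failure
#' label for non-converged fits).
#'
#' @param fit a \code{taxonFit} from \code{\link{fitTaxonModel}}.
#' @param treatment treatment to classify (default: all in the fit).
#' @param alpha two-tailed Wald significance level (default 0.05,
#'   uncorrected; set \code{fdr = TRUE} to BH-adjust within the fit).
#' @param fdr apply Benjamini-Hochberg adjustment across this taxon's
#'   impact (and, separately, slope) p-values before thresholding?
#' @return data.frame with \code{taxon_id}, \code{treatment},
#'   \code{impact} (negative/none/positive), \code{dynamics} (stable/
#'   resilient/diverging/late_positive/late_negative/none), \code{label}
#'   and \code{converged}.
#' @export
classifyStrategy <- function(fit, treatment = NULL, alpha = 0.05,
                             fdr = FALSE) {
  if (!fit$converged || is.null(fit$coefficients)) {
    trts <- if (is.null(treatment)) NA_character_ else treatment
    return(data.frame(taxon_id = fit$taxon_id, treatment = trts,
                      impact = NA, dynamics = NA, label = "model_failed",
                      converged = FALSE, stringsAsFactors = FALSE))
  }
  co <- fit$coefficients
  if (!is.null(treatment)) co <- co[co$treatment %in% treatment, ,
                                    drop = FALSE]
  ip <- if (fdr) p.adjust(co$impact_p, "BH") else co$impact_p
  sp <- if (fdr) p.adjust(co$slope_p, "BH") else co$slope_p
  imp_sig <- ip <= alpha
  slo_sig <- sp <= alpha
  impact <- ifelse(!imp_sig, "none",
                   ifelse(co$impact > 0, "positive", "negative"))
  dynamics <- ifelse(imp_sig & !slo_sig, "stable",
    ifelse(imp_sig & slo_sig & sign(co$impact) != sign(co$slope),
           "resilient",
    ifelse(imp_sig & slo_sig, "diverging",
    ifelse(!imp_sig & slo_sig & co$slope > 0, "late_positive",
    ifelse(!imp_sig & slo_sig, "late_negative", "none")))))
  label <- ifelse(impact == "none" & dynamics == "none", "fully_resistant",
    ifelse(impact == "none", dynamics,
           paste(impact, "impact,", dynamics)))
  data.frame(taxon_id = fit$taxon_id, treatment = co$treatment,
             impact = impact, dynamics = dynamics, label = label,
             converged = TRUE, stringsAsFactors = FALSE)
}

#' Fit and classify every taxon in a table
#'
#' @param x count matrix or \code{SummarizedExperiment}.
#' @param metadata sample metadata (see \code{\link{fitTaxonModel}}).
#' @param taxa taxa to process (default all features).
#' @param alpha significance level for \code{\link{classifyStrategy}}.
#' @param ... passed to \code{\link{fitTaxonModel}}.
#' @return list with \code{fits} (named list of \code{taxonFit}) and
#'   \code{calls} (row-bound strategy calls).
#' @export
classifyAllTaxa <- function(x, metadata, taxa = NULL, alpha = 0.05, ...) {
  m <- .asSampleMatrix(x)
  if (is.null(taxa)) taxa <- colnames(m)
  fits <- lapply(taxa, function(tx) fitTaxonModel(m, metadata, tx, ...))
  names(fits) <- taxa
  calls <- do.call(rbind, lapply(fits, classifyStrategy, alpha = alpha))
  rownames(calls) <- NULL
  list(fits = fits, calls = calls)
}

#' Strategy frequency census per treatment
#'
#' Counts and proportions of each response strategy per treatment.
#' Non-converged taxa are tallied separately and excluded from the
#' proportion denominator.
#'
#' @param calls strategy-call data.frame from
#'   \code{\link{classifyStrategy}} (row-bound over taxa).
#' @return data.frame with \code{treatment}, \code{label}, \code{n},
#'   \code{proportion}; model failures appear with \code{proportion = NA}.
#' @export
strategyCensus <- function(calls) {
  if (is.null(calls) || !nrow(calls)) stop("no strategy calls supplied")
  ok <- calls[calls$label != "model_failed", , drop = FALSE]
  out <- as.data.frame(table(treatment = ok$treatment, label = ok$label),
                       stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  tot <- tapply(out$n, out$treatment, sum)
  out$proportion <- out$n / as.numeric(tot[out$treatment])
  nf <- sum(calls$label == "model_failed")
  if (nf > 0) {
    out <- rbind(out, data.frame(treatment = "(all)",
                                 label = "model_failed", n = nf,
                                 proportion = NA_real_))
  }
  out[order(out$treatment, -out$n), ]
}
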