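# Functional-category response models: arcsine square-root proportions,
# hierarchical mixed models with nested-category random effects,
# Dunnett-style control contrasts and FDR across categories.

#' Aggregate counts to a hierarchy level
#'
#' Sums protein-level counts within each category of the requested level.
#'
#' @param x count matrix (samples in rows, proteins in columns) or
#'   \code{SummarizedExperiment}.
#' @param hierarchy data.frame (protein, level3, level2, level1).
#' @param level \code{"protein"}, \code{"level3"}, \code{"level2"} or
#'   \code{"level1"}.
#' @return count matrix, samples x categories.
#' @export
aggregateToLevel <- function(x, hierarchy, level = "level1") {
  m <- .asSampleMatrix(x)
  if (level == "protein") return(m)
  if (!level %in% names(hierarchy)) stop("unknown level: ", level)
  grp <- hierarchy[[level]][match(colnames(m), hierarchy$protein)]
  if (anyNA(grp)) stop("features missing from the hierarchy")
  t(rowsum(t(m), grp))
}

#' Arcsine square-root transformed relative abundances
#'
#' \eqn{\arcsin(\sqrt{p})} of per-sample proportions after aggregation to
#' the requested hierarchy level; the transform stabilises the variance of
#' proportions near 0 and 1.
#'
#' @inheritParams aggregateToLevel
#' @return transformed matrix, samples x categories.
#' @export
arcsineSqrtProportions <- function(x, hierarchy = NULL,
                                   level = "protein") {
  m <- .asSampleMatrix(x)
  agg <- if (is.null(hierarchy) || level == "protein") m
         else aggregateToLevel(m, hierarchy, level)
  p <- agg / rowSums(m)[rownames(agg)]
  if (any(p < 0 | p > 1)) stop("proportions outside [0, 1]")
  asin(sqrt(p))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR across a family of tests;
#' order-preserving (delegates to \code{stats::p.adjust}).
#'
#' @param p vector of p-values in (0, 1].
#' @return vector of q-values, same order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (!length(p)) stop("empty p-value list")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must be in (0,1]")
  p.adjust(p, method = "BH")
}

#' Dunnett-style adjusted p-values for several contrasts against control
#'
#' Family-wise adjusted p-value for contrast \eqn{i}:
#' \eqn{P(\max_j |T_j| \ge |t_i|)} under the joint null of the estimated
#' contrast distribution — multivariate t with the correlation implied by
#' the contrast covariance — evaluated by seeded Monte-Carlo.
#'
#' @param estimates contrast estimates (treatment minus control).
#' @param covariance their estimated covariance matrix.
#' @param df residual degrees of freedom (\code{Inf} for the normal
#'   reference).
#' @param n_draws Monte-Carlo draws (default 2e5).
#' @param seed integer RNG seed.
#' @return data.frame with \code{estimate}, \code{se}, \code{t},
#'   \code{p_raw} (two-tailed, unadjusted) and \code{p_adjusted}.
#' @export
dunnettAdjust <- function(estimates, covariance, df = Inf,
                          n_draws = 2e5, seed = 1L) {
  k <- length(estimates)
  covariance <- as.matrix(covariance)
  se <- sqrt(diag(covariance))
  R <- covariance / tcrossprod(se)
  ch <- tryCatch(chol(R), error = function(e)
    stop("contrast covariance is singular"))
  tobs <- estimates / se
  p_raw <- if (is.finite(df)) 2 * pt(-abs(tobs), df) else
    2 * pnorm(-abs(tobs))
  set.seed(seed)
  Z <- matrix(rnorm(n_draws * k), n_draws, k) %*% ch
  if (is.finite(df)) {
    w <- sqrt(stats::rchisq(n_draws, df) / df)
    Z <- Z / w
  }
  mx <- do.call(pmax, as.data.frame(abs(Z)))
  p_adj <- vapply(abs(tobs), function(t0) mean(mx >= t0), numeric(1))
  # Monte-Carlo zero means "below resolution", report at resolution
  p_adj <- pmax(p_adj, 1 / n_draws)
  data.frame(estimate = estimates, se = se, t = tobs,
             p_raw = p_raw, p_adjusted = pmax(p_adj, p_raw))
}

#' Mixed model for one functional category
#'
#' Response: arcsine square-root proportion of reads of each protein under
#' the category, per sample.  Fixed effects: treatment, day and their
#' interaction.  Random intercepts: site in country, and the nested
#' sub-hierarchy below the category (whatever levels remain between the
#' category and proteins; a single-protein category collapses to no
#' nesting).  Heteroscedasticity across countries is approximated by
#' per-country residual-variance weights estimated in one re-weighting
#' pass.  Treatment-versus-control contrasts are Dunnett-adjusted; the
#' omnibus treatment test is a Wald F on the impact contrasts.
#'
#' @param x protein-level count matrix (samples in rows) or
#'   \code{SummarizedExperiment}.
#' @param metadata data.frame with \code{sample_id}, \code{country},
#'   \code{site}, \code{treatment}, \code{day}.
#' @param hierarchy data.frame (protein, level3, level2, level1).
#' @param category category id at \code{level}.
#' @param level hierarchy level of \code{category}.
#' @param n_draws,seed Monte-Carlo settings for
#'   \code{\link{dunnettAdjust}}.
#' @param reweight estimate per-country residual weights?
#' @return object of class \code{functionFit}: list with \code{category},
#'   \code{level}, \code{impacts} (per treatment: delta, se, Dunnett p),
#'   \code{slopes}, \code{omnibus_F}, \code{omnibus_p}, \code{converged}.
#' @export
fitFunctionModel <- function(x, metadata, hierarchy, category,
                             level = "level1", n_draws = 2e5, seed = 1L,
                             reweight = TRUE) {
  m <- .asSampleMatrix(x)
  md <- as.data.frame(metadata)
  md <- md[match(rownames(m), md$sample_id), , drop = FALSE]
  prots <- if (level == "protein") category else
    hierarchy$protein[hierarchy[[level]] == category]
  if (!length(prots)) stop("unknown category: ", category)
  prots <- intersect(prots, colnames(m))

  tot <- rowSums(m)
  long <- do.call(rbind, lapply(prots, function(pr) {
    data.frame(y = asin(sqrt(m[, pr] / tot)), protein = pr,
               sample_id = md$sample_id, country = md$country,
               site = md$site, treatment = md$treatment, day = md$day,
               stringsAsFactors = FALSE)
  }))
  long$treatment <- stats::relevel(factor(long$treatment), ref = "control")
  hrow <- hierarchy[match(long$protein, hierarchy$protein), ]
  long$level3 <- hrow$level3
  long$level2 <- hrow$level2

  # random-effect structure: nested sub-levels that still vary
  re <- c("(1 | country/site)")
  nested <- switch(level,
    level1 = c("level2", "level3", "protein"),
    level2 = c("level3", "protein"),
    level3 = "protein",
    protein = character(0))
  nested <- nested[vapply(nested, function(v)
    length(unique(long[[v]])) > 1, logical(1))]
  if (length(nested))
    re <- c(re, paste0("(1 | ", paste(nested, collapse = ":"), ")"))
  f <- as.formula(paste("y ~ treatment * day +",
                        paste(re, collapse = " + ")))

  fit1 <- try(suppressMessages(suppressWarnings(
    lme4::lmer(f, data = long, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                 lme4::.makeCC(action = "ignore", tol = 1e-4))))),
    silent = TRUE)
  if (inherits(fit1, "try-error")) {
    return(structure(list(category = category, level = level,
                          impacts = NULL, slopes = NULL,
                          omnibus_F = NA, omnibus_p = NA,
                          converged = FALSE), class = "functionFit"))
  }
  fit <- fit1
  if (reweight && length(unique(long$country)) > 1) {
    rv <- tapply(stats::resid(fit1), long$country, function(r)
      mean(r^2))
    rv <- pmax(rv, 1e-12)
    wt <- 1 / rv[long$country]
    fit2 <- try(suppressMessages(suppressWarnings(
      stats::update(fit1, weights = wt))), silent = TRUE)
    if (!inherits(fit2, "try-error")) fit <- fit2
  }

  b <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  trts <- setdiff(levels(long$treatment), "control")
  inames <- paste0("treatment", trts)
  snames <- paste0("treatment", trts, ":day")
  n_obs <- nrow(long)
  df_res <- n_obs - length(b)

  dn <- dunnettAdjust(b[inames], V[inames, inames, drop = FALSE],
                      df = df_res, n_draws = n_draws, seed = seed)
  impacts <- data.frame(treatment = trts, delta = dn$estimate,
                        se = dn$se, p_raw = dn$p_raw,
                        p_dunnett = dn$p_adjusted)
  ds <- dunnettAdjust(b[snames], V[snames, snames, drop = FALSE],
                      df = df_res, n_draws = n_draws, seed = seed + 1L)
  slopes <- data.frame(treatment = trts, slope = ds$estimate,
                       se = ds$se, p_raw = ds$p_raw,
                       p_dunnett = ds$p_adjusted)

  # omnibus Wald F on the treatment impact contrasts
  bi <- b[inames]
  Vi <- V[inames, inames, drop = FALSE]
  Fstat <- drop(crossprod(bi, solve(Vi, bi))) / length(bi)
  pF <- pf(Fstat, length(bi), df_res, lower.tail = FALSE)

  structure(list(category = category, level = level, impacts = impacts,
                 slopes = slopes, omnibus_F = Fstat, omnibus_p = pF,
                 df = c(length(bi), df_res), converged = TRUE,
                 fit = fit), class = "functionFit")
}

#' @export
print.functionFit <- function(x, ...) {
  cat("function model:", x$category, "(", x$level, ")",
      if (x$converged) "\n" else " NOT converged\n")
  if (x$converged) {
    cat(sprintf("  omnibus F = %.2f, p = %.3g\n", x$omnibus_F,
                x$omnibus_p))
    print(x$impacts, digits = 3)
  }
  invisible(x)
}

#' Fit all categories at a level and summarise impacts
#'
#' Fits \code{\link{fitFunctionModel}} per category, applies BH-FDR across
#' the omnibus p-values of the level ("multiple models"), and tabulates
#' per-treatment impact estimates with Dunnett significance, mirroring a
#' per-category x treatment effect panel.
#'
#' @inheritParams fitFunctionModel
#' @param alpha significance threshold applied to \code{q_omnibus} and
#'   \code{p_dunnett}.
#' @param n_draws Monte-Carlo draws for the Dunnett adjustment (smaller
#'   values speed up many-category sweeps).
#' @return list with \code{table} (category x treatment rows: delta, se,
#'   p_dunnett, q_omnibus, direction, significant), \code{failed}
#'   (non-converged category ids) and \code{fits}.
#' @export
functionalImpactTable <- function(x, metadata, hierarchy,
                                  level = "level1", alpha = 0.05,
                                  n_draws = 2e4, seed = 1L) {
  cats <- sort(unique(hierarchy[[level]]))
  fits <- lapply(cats, function(cg)
    fitFunctionModel(x, metadata, hierarchy, cg, level = level,
                     n_draws = n_draws, seed = seed))
  names(fits) <- cats
  ok <- vapply(fits, `[[`, logical(1), "converged")
  q <- rep(NA_real_, length(cats))
  if (any(ok))
    q[ok] <- bhFdr(vapply(fits[ok], `[[`, numeric(1), "omnibus_p"))
  tab <- do.call(rbind, lapply(which(ok), function(i) {
    im <- fits[[i]]$impacts
    data.frame(category = cats[i], treatment = im$treatment,
               delta = im$delta, se = im$se, p_dunnett = im$p_dunnett,
               q_omnibus = q[i],
               direction = ifelse(im$delta > 0, "increase", "decrease"),
               significant = q[i] <= alpha & im$p_dunnett <= alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, failed = cats[!ok], fits = fits)
}
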