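# Phylogenetic signal of per-taxon response estimates: Pagel's lambda by
# phylogenetic generalized least squares with an intercept-only mean.

# log-likelihood of an intercept-only Gaussian model with covariance
# sigma^2 * V(lambda); sigma^2 and the mean are profiled out analytically
.lambdaLoglik <- function(lambda, C, y) {
  V <- lambda * C
  diag(V) <- diag(C)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  n <- length(y)
  logdet <- 2 * sum(log(diag(ch)))
  one <- rep(1, n)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Vi_r) / n          # ML estimate
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Estimate Pagel's lambda for a trait on a tree
#'
#' Maximizes the Gaussian likelihood of an intercept-only phylogenetic
#' model whose covariance is \eqn{V(\lambda)}: off-diagonal shared path
#' lengths scaled by \eqn{\lambda \in [0, 1]}, tip depths on the diagonal.
#' A 21-point grid pre-scan guards against local optima before bounded
#' refinement around the best grid cell.  Missing or non-matching tips are
#' dropped with a warning.
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths.
#' @param trait named numeric vector (names = tip labels).
#' @param grid_points size of the pre-scan grid.
#' @return object of class \code{lambdaSignal}: list with \code{lambda},
#'   \code{loglik}, \code{loglik0} (lambda = 0), \code{n}, \code{trait},
#'   plus the tree/trait needed for profiling.
#' @export
pglsLambda <- function(tree, trait, grid_points = 21L) {
  trait <- trait[!is.na(trait)]
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < length(trait) ||
      length(common) < length(tree$tip.label)) {
    if (length(setdiff(names(trait), tree$tip.label)))
      warning("trait values without matching tips dropped")
    tree <- ape::keep.tip(tree, common)
  }
  y <- trait[tree$tip.label]
  if (length(y) < 10) stop("need at least 10 tips with trait values")
  if (var(y) == 0) stop("trait has zero variance")
  C <- ape::vcv(tree)

  grid <- seq(0, 1, length.out = grid_points)
  ll <- vapply(grid, .lambdaLoglik, numeric(1), C = C, y = y)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_points, i + 1)]
  opt <- optimize(.lambdaLoglik, c(lo, hi), C = C, y = y,
                  maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  loglik <- opt$objective
  # boundary candidates can beat the interior optimum
  for (b in c(0, 1)) {
    lb <- .lambdaLoglik(b, C, y)
    if (lb >= loglik) { lambda <- b; loglik <- lb }
  }
  structure(list(lambda = lambda, loglik = loglik,
                 loglik0 = .lambdaLoglik(0, C, y),
                 n = length(y), C = C, y = y,
                 grid = grid, grid_loglik = ll),
            class = "lambdaSignal")
}

#' @export
print.lambdaSignal <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.3f (logLik %.2f, n = %d tips)\n",
              x$lambda, x$loglik, x$n))
  invisible(x)
}

#' Profile-likelihood confidence interval for lambda
#'
#' The set \eqn{\{\lambda : 2(L(\hat\lambda) - L(\lambda)) \le
#' \chi^2_{1,level}\}}, with endpoints clipped to [0, 1].  A likelihood
#' that is flat in lambda (a star phylogeny) yields the full [0, 1]
#' interval.
#'
#' @param fit a \code{lambdaSignal} from \code{\link{pglsLambda}}.
#' @param level confidence level (default 0.95).
#' @return numeric vector \code{c(lower, upper)}.
#' @export
lambdaProfileCI <- function(fit, level = 0.95) {
  cut <- fit$loglik - qchisq(level, 1) / 2
  f <- function(l) .lambdaLoglik(l, fit$C, fit$y) - cut
  lower <- 0
  if (f(0) < 0 && fit$lambda > 0) {
    lower <- stats::uniroot(f, c(0, fit$lambda), tol = 1e-6)$root
  }
  upper <- 1
  if (f(1) < 0 && fit$lambda < 1) {
    upper <- stats::uniroot(f, c(fit$lambda, 1), tol = 1e-6)$root
  }
  c(lower = max(0, lower), upper = min(1, upper))
}

#' Phylogenetic signal of taxon response estimates
#'
#' Runs \code{\link{pglsLambda}} for each treatment on the impact
#' (resistance) and slope (resilience) coefficients from per-taxon fits;
#' non-converged taxa are excluded listwise.
#'
#' @param tree \code{phylo} whose tips are taxon ids.
#' @param fits named list of \code{taxonFit} objects (names = taxon ids).
#' @param level CI level.
#' @return data.frame (treatment, trait_kind, lambda, ci_lo, ci_hi,
#'   loglik, n).
#' @export
signalOfResponses <- function(tree, fits, level = 0.95) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) < 10) stop("fewer than 10 converged taxa")
  trts <- unique(ok[[1]]$coefficients$treatment)
  rows <- list()
  for (tr in trts) {
    for (kind in c("impact", "slope")) {
      v <- vapply(ok, function(f) {
        co <- f$coefficients
        co[[kind]][co$treatment == tr]
      }, numeric(1))
      names(v) <- vapply(ok, `[[`, character(1), "taxon_id")
      est <- pglsLambda(tree, v)
      ci <- lambdaProfileCI(est, level)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, trait_kind = kind, lambda = est$lambda,
        ci_lo = ci[1], ci_hi = ci[2], loglik = est$loglik, n = est$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
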