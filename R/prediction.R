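# Predicting community resistance/resilience from initial soil and climate
# properties: standardization, grouped cross-validation with a pluggable
# tree-ensemble regressor, partial dependence, and rank-correlation maps.

#' Standardize predictor columns
#'
#' Z-scores each property column (sample standard deviation) over the full
#' table; categorical columns (treatment, sampling, ids) pass through.
#' Standardizing over all rows mirrors the usual practice of scaling once
#' before cross-validation; set \code{within} to a logical mask to
#' standardize on a training subset only (applied to all rows) when
#' leakage-free scaling is wanted.
#'
#' @param table data.frame.
#' @param properties character vector of numeric columns to scale (default:
#'   the 20 canonical properties present in the table).
#' @param within optional logical mask of rows defining the
#'   standardization set.
#' @return the table with scaled property columns; attributes
#'   \code{"centers"} and \code{"scales"}.
#' @export
standardizePredictors <- function(table, properties = NULL,
                                  within = NULL) {
  if (is.null(properties))
    properties <- intersect(unlist(propertyFamilies()), names(table))
  if (!length(properties)) stop("no property columns found")
  ref <- if (is.null(within)) table else table[within, , drop = FALSE]
  centers <- scales <- setNames(numeric(length(properties)), properties)
  for (p in properties) {
    v <- ref[[p]]
    if (!is.numeric(v)) stop("property not numeric: ", p)
    s <- sd(v)
    if (!is.finite(s) || s == 0) stop("constant property column: ", p)
    centers[p] <- mean(v); scales[p] <- s
    table[[p]] <- (table[[p]] - centers[p]) / s
  }
  attr(table, "centers") <- centers
  attr(table, "scales") <- scales
  table
}

#' Tree-ensemble regressor contract (ranger backend)
#'
#' Returns a regressor object for \code{\link{fitGroupedCV}}: a list with
#' \code{fit(X, y)} and \code{predict(model, X)}.  The default backend is a
#' random regression forest with bootstrap rows and one-third of the
#' predictors sampled per split.
#'
#' @param n_trees number of trees (default 500).
#' @param mtry predictors sampled per split (default \code{floor(p/3)}).
#' @param seed integer seed forwarded to each fit.
#' @return regressor contract list.
#' @export
rangerRegressor <- function(n_trees = 500L, mtry = NULL, seed = 1L) {
  fac <- function(X) {
    X <- as.data.frame(X)
    for (j in seq_along(X)) if (is.character(X[[j]]))
      X[[j]] <- factor(X[[j]])
    X
  }
  list(
    fit = function(X, y) {
      d <- data.frame(y = y, fac(X), check.names = TRUE)
      ranger::ranger(y ~ ., data = d, num.trees = n_trees,
                     mtry = if (is.null(mtry)) max(1L, floor(ncol(X) / 3))
                            else mtry,
                     respect.unordered.factors = "order",
                     seed = seed, num.threads = 1L)
    },
    predict = function(model, X) {
      d <- data.frame(fac(X), check.names = TRUE)
      predict(model, data = d, num.threads = 1L)$predictions
    }
  )
}

#' Linear regressor contract
#'
#' An ordinary-least-squares backend for \code{\link{fitGroupedCV}},
#' optionally expanding interactions between one categorical column (for
#' example the treatment indicator) and every other predictor.  Useful as
#' a consistency check of the cross-validation machinery: on a noiseless
#' response that is linear (per treatment) in the predictors it recovers
#' the planted surface exactly, so any shortfall in test R-squared comes
#' from the splitting logic, not the learner.
#'
#' @param interaction_var column name interacted with all others (NULL for
#'   a purely additive fit).
#' @param formula optional explicit right-hand-side model formula over the
#'   predictor columns (overrides \code{interaction_var}); use it to fit a
#'   model class known to contain a planted surface.
#' @return regressor contract list.
#' @export
linearRegressor <- function(interaction_var = NULL, formula = NULL) {
  prep <- function(X) {
    X <- as.data.frame(X)
    for (j in seq_along(X)) if (is.character(X[[j]]))
      X[[j]] <- factor(X[[j]])
    X
  }
  list(
    fit = function(X, y) {
      d <- data.frame(y = y, prep(X), check.names = TRUE)
      f <- if (!is.null(formula))
        stats::update(formula, y ~ .)
      else if (!is.null(interaction_var) && interaction_var %in% names(d))
        as.formula(paste("y ~", interaction_var, "* .")) else y ~ .
      xl <- lapply(d[-1], function(v) if (is.factor(v)) levels(v))
      m <- stats::lm(f, data = d)
      list(m = m, xlev = xl)
    },
    predict = function(model, X) {
      d <- prep(X)
      for (nm in names(model$xlev)) if (!is.null(model$xlev[[nm]]))
        d[[nm]] <- factor(d[[nm]], levels = model$xlev[[nm]])
      unname(suppressWarnings(predict(model$m, newdata = d)))
    }
  )
}

#' Grouped cross-validation of a resistance/resilience predictor
#'
#' Fits one regressor per training set defined by grouped splits (site- or
#' country-held-out, from \code{\link{enumerateSiteSplits}} /
#' \code{\link{enumerateCountrySplits}}) and evaluates the coefficient of
#' determination on each test set:
#' \eqn{R^2 = 1 - \sum (y - \hat y)^2 / \sum (y - \bar y_{test})^2}
#' (which can be negative for predictions worse than the test mean).  When
#' more splits are supplied than \code{split_budget}, a seeded random
#' subset of splits is drawn.  Per-site mean predictions are accumulated
#' over all test occurrences, and observed-versus-mean-predicted Pearson
#' correlations are reported per perturbation.
#'
#' @param table data.frame containing the response, the predictors and a
#'   grouping column.
#' @param splits list of \code{list(train=, test=)} group-id vectors.
#' @param response response column name (e.g. the negative-log Bray-Curtis
#'   score).
#' @param predictors predictor column names (properties + treatment +
#'   sampling indicators are used as supplied).
#' @param group column holding the grouping unit (\code{"site"} or
#'   \code{"country"}).
#' @param regressor regressor contract (default
#'   \code{\link{rangerRegressor}()}).
#' @param split_budget maximum number of splits fitted (default 200).
#' @param seed seed for the split subsample.
#' @return object of class \code{cvResult}: list with \code{per_split}
#'   (data.frame split, r2, n_test), \code{r2_mean}, \code{r2_sd},
#'   \code{site_predictions} (per group x perturbation observed mean and
#'   predicted mean), \code{correlations} (per perturbation Pearson r) and
#'   \code{n_splits_used}.
#' @export
fitGroupedCV <- function(table, splits, response, predictors,
                         group = "site", regressor = rangerRegressor(),
                         split_budget = 200L, seed = 1L) {
  table <- as.data.frame(table)
  stopifnot(response %in% names(table), group %in% names(table),
            all(predictors %in% names(table)))
  gvals <- table[[group]]
  known <- unique(gvals)
  for (s in splits) {
    if (length(intersect(s$train, s$test)))
      stop("split has overlapping train and test groups")
    if (!all(c(s$train, s$test) %in% known))
      stop("split references unknown groups: ",
           paste(setdiff(c(s$train, s$test), known), collapse = ", "))
  }
  if (length(splits) > split_budget) {
    set.seed(seed)
    splits <- splits[sort(sample.int(length(splits), split_budget))]
  }

  X <- table[predictors]
  y <- table[[response]]
  pred_sum <- pred_n <- setNames(numeric(length(known)), known)
  per_split <- data.frame(split = seq_along(splits), r2 = NA_real_,
                          n_test = NA_integer_)
  site_pred_rows <- list()
  for (i in seq_along(splits)) {
    tr <- gvals %in% splits[[i]]$train
    te <- gvals %in% splits[[i]]$test
    model <- regressor$fit(X[tr, , drop = FALSE], y[tr])
    yhat <- regressor$predict(model, X[te, , drop = FALSE])
    yt <- y[te]
    per_split$r2[i] <- 1 - sum((yt - yhat)^2) / sum((yt - mean(yt))^2)
    per_split$n_test[i] <- sum(te)
    site_pred_rows[[i]] <- data.frame(group = gvals[te], obs = yt,
                                      pred = yhat,
                                      perturbation = if ("treatment" %in%
                                        names(table)) table$treatment[te]
                                        else NA)
  }
  allpred <- do.call(rbind, site_pred_rows)
  site_predictions <- aggregate(cbind(obs, pred) ~ group + perturbation,
                                data = allpred, FUN = mean)
  correlations <- vapply(split(site_predictions,
                               site_predictions$perturbation),
                         function(d) if (nrow(d) >= 3)
                           cor(d$obs, d$pred) else NA_real_,
                         numeric(1))
  structure(list(per_split = per_split,
                 r2_mean = mean(per_split$r2),
                 r2_sd = sd(per_split$r2),
                 site_predictions = site_predictions,
                 correlations = correlations,
                 n_splits_used = length(splits)),
            class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
  cat(sprintf("grouped CV over %d splits: R2 = %.3f +/- %.3f\n",
              x$n_splits_used, x$r2_mean, x$r2_sd))
  invisible(x)
}

#' Fit a single predictive model on the full table
#'
#' @inheritParams fitGroupedCV
#' @return list with the fitted \code{model}, the \code{regressor}
#'   contract and \code{predictors}, for use with
#'   \code{\link{partialDependence}}.
#' @export
fitPredictiveModel <- function(table, response, predictors,
                               regressor = rangerRegressor()) {
  X <- as.data.frame(table)[predictors]
  y <- as.data.frame(table)[[response]]
  list(model = regressor$fit(X, y), regressor = regressor,
       predictors = predictors, X = X)
}

#' Partial dependence profile of one predictor
#'
#' For each grid value v of the variable, the average model prediction
#' over all observed rows with the variable replaced by v — the marginal
#' effect of the variable accounting for the average effect of the other
#' predictors.  The grid spans the observed range of the variable.
#'
#' @param fit result of \code{\link{fitPredictiveModel}}.
#' @param variable predictor name.
#' @param grid_size number of grid values (default 20).
#' @return data.frame with \code{value} and \code{yhat}.
#' @export
partialDependence <- function(fit, variable, grid_size = 20L) {
  if (!variable %in% fit$predictors) stop("unknown variable: ", variable)
  v <- fit$X[[variable]]
  grid <- if (is.numeric(v))
    seq(min(v), max(v), length.out = grid_size) else unique(v)
  yhat <- vapply(grid, function(g) {
    Xg <- fit$X
    Xg[[variable]] <- g
    mean(fit$regressor$predict(fit$model, Xg))
  }, numeric(1))
  data.frame(value = grid, yhat = yhat)
}

#' Rank correlations between initial properties and responses
#'
#' Spearman correlation (average ranks on ties) of each initial property
#' with the resistance/resilience score of each perturbation-by-kind
#' column; rows are ordered by complete-linkage hierarchical clustering of
#' the properties' correlation profiles (Euclidean distance).
#'
#' @param properties data.frame with a \code{site} column and the property
#'   columns.
#' @param scores data.frame as from \code{\link{communityResistance}}
#'   (needs \code{site}, \code{treatment}, \code{kind} and a score
#'   column).
#' @param score_col which score to correlate (default \code{"score"}).
#' @return list with \code{grid} (property x response matrix of rho, rows
#'   in clustered order), \code{flagged} (cells undefined because of a
#'   fully tied vector) and \code{hclust}.
#' @export
propertyResponseCorrelations <- function(properties, scores,
                                         score_col = "score") {
  props <- intersect(unlist(propertyFamilies()), names(properties))
  if (!length(props)) stop("no property columns found")
  combos <- unique(scores[c("treatment", "kind")])
  combos <- combos[order(combos$kind, combos$treatment), ]
  grid <- matrix(NA_real_, length(props), nrow(combos),
                 dimnames = list(props, paste(combos$treatment,
                                              combos$kind, sep = ".")))
  flagged <- character(0)
  for (j in seq_len(nrow(combos))) {
    sel <- scores$treatment == combos$treatment[j] &
      scores$kind == combos$kind[j]
    agg <- aggregate(scores[[score_col]][sel],
                     by = list(site = scores$site[sel]), FUN = mean)
    mrg <- merge(agg, properties, by = "site")
    if (nrow(mrg) < 4) stop("fewer than 4 paired observations for ",
                            colnames(grid)[j])
    for (p in props) {
      if (length(unique(mrg[[p]])) == 1L || length(unique(mrg$x)) == 1L) {
        flagged <- c(flagged, paste(p, colnames(grid)[j], sep = "/"))
        next
      }
      grid[p, j] <- cor(mrg[[p]], mrg$x, method = "spearman")
    }
  }
  hc <- hclust(stats::dist(grid), method = "complete")
  list(grid = grid[hc$order, , drop = FALSE], flagged = flagged,
       hclust = hc)
}
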