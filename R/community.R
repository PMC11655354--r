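# Community-level transforms, dissimilarities, permutation tests and the
# paired resistance/resilience statistic.

# Accept either a plain matrix with samples in rows (vegan orientation) or
# a SummarizedExperiment with features in rows (Bioconductor orientation).
.asSampleMatrix <- function(x, assay = "counts") {
  if (is(x, "SummarizedExperiment"))
    x <- t(SummarizedExperiment::assay(x, assay))
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  m
}

#' Hellinger transform of a count table
#'
#' Square root of relative abundance: entry \eqn{\sqrt{x_{ij} / n_i}} where
#' \eqn{n_i} is the library size of sample \eqn{i}.  After transformation
#' each sample's squared entries sum to one, which damps the influence of
#' double zeros and large counts before distance computation.
#'
#' @param x count matrix (samples in rows) or
#'   \code{SummarizedExperiment} (features in rows).
#' @return numeric matrix, samples in rows.
#' @export
hellingerTransform <- function(x) {
  m <- .asSampleMatrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[rs == 0][1]
    stop("sample has zero total count: ", bad)
  }
  sqrt(m / rs)
}

#' Rarefy a count table to even depth
#'
#' Draws, for each sample, a without-replacement subsample of its counts
#' summing exactly to \code{depth} (multivariate hypergeometric).  A single
#' draw is taken per table; the seed makes it reproducible.
#'
#' @param x count matrix (samples in rows) or
#'   \code{SummarizedExperiment}.
#' @param depth target library size; must be positive.
#' @param seed integer RNG seed.
#' @param drop_small drop samples with fewer than \code{depth} reads (with a
#'   warning) instead of erroring.
#' @return integer matrix of rarefied counts with attribute
#'   \code{"rarefaction_seed"}.
#' @export
rarefyCounts <- function(x, depth, seed = 1L, drop_small = FALSE) {
  m <- .asSampleMatrix(x)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be positive")
  rs <- rowSums(m)
  if (any(rs < depth)) {
    if (!drop_small)
      stop("samples below target depth: ",
           paste(rownames(m)[rs < depth], collapse = ", "))
    warning(sum(rs < depth), " sample(s) below depth dropped")
    m <- m[rs >= depth, , drop = FALSE]
  }
  set.seed(seed)
  out <- t(apply(m, 1L, function(row) {
    pool <- rep.int(seq_along(row), row)
    keep <- sample(pool, depth)
    tabulate(keep, nbins = length(row))
  }))
  dimnames(out) <- dimnames(m)
  attr(out, "rarefaction_seed") <- seed
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}: 0 for identical
#' profiles, 1 for profiles with disjoint support.
#'
#' @param x non-negative matrix (samples in rows) or
#'   \code{SummarizedExperiment}.
#' @param strict if TRUE (default), a pair of all-zero samples (undefined
#'   dissimilarity) is an error; otherwise the pair is NaN.
#' @return symmetric matrix of dissimilarities with zero diagonal.
#' @export
brayCurtisMatrix <- function(x, strict = TRUE) {
  m <- .asSampleMatrix(x)
  if (any(m < 0)) stop("entries must be non-negative")
  man <- as.matrix(stats::dist(m, method = "manhattan"))
  rs <- rowSums(m)
  tot <- outer(rs, rs, "+")
  if (any(tot == 0)) {
    if (strict) stop("pair(s) of all-zero samples: Bray-Curtis undefined")
    bc <- man / tot          # 0/0 -> NaN
    diag(bc) <- 0
  } else bc <- man / tot
  bc
}

# Gower-centred inner-product matrix of a squared-dissimilarity matrix;
# the engine behind distance-based anova.
.gowerCentre <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a dissimilarity matrix by the factors in \code{terms} using
#' sequential (Type-I) sums of squares on the Gower-centred inner-product
#' matrix.  Pseudo-F statistics are referred to a permutation distribution
#' obtained by freely shuffling sample labels (optionally within strata);
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' @param d symmetric dissimilarity matrix.
#' @param terms data.frame of factors, rows aligned with \code{d}; terms are
#'   added in column order.
#' @param n_perm number of permutations (at least 99).
#' @param seed integer RNG seed.
#' @param strata optional factor restricting permutations to occur within
#'   its levels.
#' @return data.frame with one row per term plus a residual and total row:
#'   columns \code{term}, \code{df}, \code{SS}, \code{R2}, \code{F},
#'   \code{p}; attribute \code{"n_perm"}.
#' @export
permanova <- function(d, terms, n_perm = 999, seed = 1L, strata = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  terms <- as.data.frame(terms)
  if (nrow(terms) != n) stop("terms must align with the distance matrix")
  if (n_perm < 99) stop("use at least 99 permutations")
  for (nm in names(terms)) {
    terms[[nm]] <- factor(terms[[nm]])
    if (nlevels(terms[[nm]]) < 2) stop("constant factor: ", nm)
  }
  G <- .gowerCentre(d)
  ss_tot <- sum(diag(G))

  # cumulative hat matrices for sequential partitioning
  k <- ncol(terms)
  hats <- vector("list", k)
  dfs <- integer(k)
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  for (j in seq_len(k)) {
    X <- cbind(X, model.matrix(~ terms[[j]] - 1))
    q <- qr(X)
    hats[[j]] <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
    dfs[j] <- q$rank - rank_prev
    rank_prev <- q$rank
  }
  df_res <- n - rank_prev

  ss_of <- function(Gp) {
    cum <- vapply(hats, function(h) sum(h * Gp), numeric(1))
    ss <- diff(c(0, cum))
    c(ss, ss_tot - cum[k])
  }
  obs <- ss_of(G)
  ss_terms <- obs[seq_len(k)]
  ss_res <- obs[k + 1L]
  Fobs <- (ss_terms / dfs) / (ss_res / df_res)

  set.seed(seed)
  exceed <- numeric(k)
  for (b in seq_len(n_perm)) {
    p <- if (is.null(strata)) sample.int(n) else {
      idx <- seq_len(n)
      for (lev in split(idx, strata)) idx[lev] <- sample(lev)
      idx
    }
    sp <- ss_of(G[p, p])
    Fp <- (sp[seq_len(k)] / dfs) / (sp[k + 1L] / df_res)
    exceed <- exceed + (Fp >= Fobs)
  }
  pval <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(names(terms), "residual", "total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(ss_terms, ss_res, ss_tot),
    R2 = c(ss_terms, ss_res, ss_tot) / ss_tot,
    F = c(Fobs, NA, NA),
    p = c(pval, NA, NA)
  )
  attr(out, "n_perm") <- n_perm
  out
}

#' Mantel test between two distance matrices
#'
#' Rank (Spearman) correlation between the lower triangles of two distance
#' matrices over the same samples; significance by simultaneous row/column
#' permutation of the second matrix (two-tailed by default).
#'
#' @param d1,d2 symmetric dissimilarity matrices over identical sample sets
#'   (matching order, or matching dimnames which are used to align).
#' @param n_perm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}.
#' @return list with \code{r}, \code{p}, \code{n_perm}, \code{n}.
#' @export
mantelTest <- function(d1, d2, n_perm = 999, seed = 1L,
                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices cover different samples")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 samples")
  lt <- lower.tri(d1)
  r1 <- rank(d1[lt])
  # rank matrix of d2: simultaneous row/col permutation permutes the lower
  # triangle as a multiset, so permuted rank vectors can be read off by
  # indexing into the symmetric rank matrix
  rk2 <- matrix(0, n, n)
  rk2[lt] <- rank(d2[lt])
  rk2 <- rk2 + t(rk2)
  robs <- stats::cor(r1, rk2[lt])

  pair <- which(lt, arr.ind = TRUE)
  set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(n)))
  # n_perm x n_pairs matrix of permuted rank vectors of d2
  permuted <- matrix(0, n_perm, nrow(pair))
  for (k in seq_len(nrow(pair))) {
    permuted[, k] <- rk2[cbind(perms[, pair[k, 1]], perms[, pair[k, 2]])]
  }
  c1 <- r1 - mean(r1)
  cp <- permuted - rowMeans(permuted)
  rstar <- (cp %*% c1) / sqrt(rowSums(cp^2) * sum(c1^2))
  hit <- if (alternative == "two.sided") abs(rstar) >= abs(robs) - 1e-12
         else rstar >= robs - 1e-12
  list(r = robs, p = (1 + sum(hit)) / (1 + n_perm),
       n_perm = n_perm, n = n)
}

#' Community resistance and resilience scores
#'
#' For each disturbed sample at the end of the disturbance (S1) and after
#' the recovery period (S4), the score is the negative Bray-Curtis
#' dissimilarity to the paired control sample from the same site and
#' sampling occasion: 0 means the disturbed community is indistinguishable
#' from its control (maximal resistance/resilience), -1 means complete
#' turnover.  A negative-log variant, \eqn{-\log(BC + \epsilon)}, is also
#' returned for use as a regression response.
#'
#' @param x count matrix (samples in rows) or \code{SummarizedExperiment};
#'   Hellinger transformation is applied before the dissimilarity when
#'   \code{hellinger = TRUE} (default).
#' @param metadata data.frame with \code{sample_id}, \code{site},
#'   \code{treatment}, \code{sampling} (and \code{country} if present,
#'   carried through).
#' @param samplings sampling occasions to score; S1 is labelled resistance
#'   and S4 resilience, other labels pass through.
#' @param hellinger transform counts before the dissimilarity?
#' @param eps pseudo-dissimilarity inside the log variant (default 1e-6).
#' @return data.frame with one row per scored sample: \code{sample_id},
#'   \code{country} (if available), \code{site}, \code{treatment},
#'   \code{sampling}, \code{kind}, \code{bc}, \code{score} (= -bc) and
#'   \code{log_score} (= -log(bc + eps)).
#' @export
communityResistance <- function(x, metadata, samplings = c("S1", "S4"),
                                hellinger = TRUE, eps = 1e-6) {
  m <- .asSampleMatrix(x)
  md <- as.data.frame(metadata)
  md <- md[match(rownames(m), md$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata missing some samples")
  if (hellinger) m <- hellingerTransform(m)

  kind_of <- function(s) switch(s, S1 = "resistance", S4 = "resilience", s)
  rows <- list()
  for (s in samplings) {
    sel <- which(md$sampling == s)
    for (site in unique(md$site[sel])) {
      here <- sel[md$site[sel] == site]
      ctrl <- here[md$treatment[here] == "control"]
      trt <- here[md$treatment[here] != "control"]
      if (length(ctrl) != 1L) {
        if (length(trt)) warning("no unique control for site ", site,
                                 " at ", s, "; skipped")
        next
      }
      for (i in trt) {
        bc <- sum(abs(m[i, ] - m[ctrl, ])) / sum(m[i, ] + m[ctrl, ])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = rownames(m)[i],
          country = if ("country" %in% names(md)) md$country[i] else NA,
          site = site, treatment = md$treatment[i], sampling = s,
          kind = kind_of(s), bc = bc, score = -bc,
          log_score = -log(bc + eps), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no scoreable treatment/control pairs found")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
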