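# Community growth estimation from replication markers: translated
# seed-and-extend search for origin (initiator protein) markers, mismatch
# scanning for terminus (28-bp dimer-resolution) motifs, the paired
# origin:terminus log2 ratio, copy-number growth capacity, and the growth
# mixed model.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.readsAsDNAStringSet <- function(reads) {
  if (is(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    return(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  Biostrings::DNAStringSet(reads)
}

# all k-mers of a character vector of peptides -> data.frame(read, pos, kmer)
.peptideKmers <- function(peps, k) {
  nk <- pmax(nchar(peps) - k + 1L, 0L)
  idx <- rep.int(seq_along(peps), nk)
  pos <- sequence(nk)
  data.frame(read = idx, pos = pos,
             kmer = substring(peps[idx], pos, pos + k - 1L),
             stringsAsFactors = FALSE)
}

# ungapped extension of an exact seed: seed score plus best leftward and
# rightward cumulative-sum extensions under BLOSUM62
.extendSeed <- function(read_pep, marker_pep, qpos, spos, k, submat) {
  rq <- strsplit(read_pep, "")[[1]]
  rs <- strsplit(marker_pep, "")[[1]]
  ok <- function(a) a %in% rownames(submat)
  sc <- function(a, b) ifelse(ok(a) & ok(b), submat[cbind(a, b)], -4)
  seed_score <- sum(sc(rq[qpos:(qpos + k - 1)], rs[spos:(spos + k - 1)]))
  left <- 0
  if (qpos > 1 && spos > 1) {
    nl <- min(qpos, spos) - 1L
    v <- sc(rq[(qpos - 1):(qpos - nl)], rs[(spos - 1):(spos - nl)])
    left <- max(0, cummax(cumsum(v))[nl])
  }
  right <- 0
  qe <- qpos + k; se <- spos + k
  if (qe <= length(rq) && se <= length(rs)) {
    nr <- min(length(rq) - qe, length(rs) - se) + 1L
    v <- sc(rq[qe:(qe + nr - 1)], rs[se:(se + nr - 1)])
    right <- max(0, cummax(cumsum(v))[nr])
  }
  seed_score + left + right
}

#' Count reads matching origin or terminus replication markers
#'
#' Origin mode performs a translated search: each read is translated in all
#' six reading frames; a read hits when any frame shares an exact
#' \code{k}-residue peptide seed with any origin marker and the ungapped
#' extension of that seed (BLOSUM62) reaches \code{min_score}.  Terminus
#' mode scans both strands for any 28-bp marker motif with at most
#' \code{max_mismatch} mismatches.  Each read is counted at most once.
#'
#' @param reads a \code{DNAStringSet}, character vector of sequences, or a
#'   FASTA/FASTQ(.gz) path.
#' @param db marker database from \code{\link{markerDb}} (or any list with
#'   \code{origin}/\code{terminus} string sets).
#' @param mode \code{"origin"} or \code{"terminus"}.
#' @param k peptide seed length (origin mode).
#' @param min_score ungapped extension score threshold (origin mode).
#' @param max_mismatch motif mismatch allowance (terminus mode).
#' @return integer count of reads with at least one qualifying match, with
#'   attribute \code{"hits"} (logical per read).
#' @export
scanMarkers <- function(reads, db, mode = c("origin", "terminus"),
                        k = 12L, min_score = 40, max_mismatch = 4L) {
  mode <- match.arg(mode)
  reads <- .readsAsDNAStringSet(reads)
  if (length(reads) == 0L) stop("no reads supplied")
  n <- length(reads)

  if (mode == "terminus") {
    motifs <- Biostrings::DNAStringSet(db$terminus)
    if (any(Biostrings::width(motifs) != 28L))
      stop("terminus motifs must be exactly 28 bp")
    hit <- rep(FALSE, n)
    for (i in seq_along(motifs)) {
      m <- motifs[[i]]
      hit <- hit |
        Biostrings::vcountPattern(m, reads,
                                  max.mismatch = max_mismatch) > 0 |
        Biostrings::vcountPattern(Biostrings::reverseComplement(m), reads,
                                  max.mismatch = max_mismatch) > 0
      if (all(hit)) break
    }
    out <- sum(hit)
    attr(out, "hits") <- hit
    return(out)
  }

  markers <- as.character(Biostrings::AAStringSet(db$origin))
  mk <- .peptideKmers(markers, k)
  if (!nrow(mk)) stop("origin markers shorter than the seed length")

  submat <- .blosum62()
  hit <- rep(FALSE, n)
  rc <- Biostrings::reverseComplement(reads)
  for (strand in 1:2) {
    rr <- if (strand == 1) reads else rc
    for (f in 1:3) {
      w <- Biostrings::width(rr) - f + 1L
      w <- (w %/% 3L) * 3L
      keep <- which(w >= 3L * k & !hit)
      if (!length(keep)) next
      sub <- Biostrings::subseq(rr[keep], start = f, width = w[keep])
      peps <- as.character(suppressWarnings(Biostrings::translate(
        sub, if.fuzzy.codon = "solve")))
      qk <- .peptideKmers(peps, k)
      hitm <- match(qk$kmer, mk$kmer)
      cand <- which(!is.na(hitm))
      if (!length(cand)) next
      # one extension per candidate read-frame (first seed suffices when it
      # fails only in pathological cases; all seeds of a read are tried)
      for (ci in cand) {
        ridx <- qk$read[ci]
        if (hit[keep[ridx]]) next
        mrow <- mk[hitm[ci], ]
        score <- .extendSeed(peps[ridx], markers[mrow$read],
                             qk$pos[ci], mrow$pos, k, submat)
        if (score >= min_score) hit[keep[ridx]] <- TRUE
      }
    }
  }
  out <- sum(hit)
  attr(out, "hits") <- hit
  out
}

#' Per-sample origin and terminus marker counts
#'
#' Convenience wrapper running \code{\link{scanMarkers}} in both modes over
#' a named list of read sets.
#'
#' @param read_sets named list of read sets (see \code{\link{scanMarkers}}).
#' @param db marker database.
#' @param ... passed to \code{\link{scanMarkers}}.
#' @return data.frame with \code{sample_id}, \code{O}, \code{T}.
#' @export
countMarkers <- function(read_sets, db, ...) {
  stopifnot(!is.null(names(read_sets)))
  data.frame(
    sample_id = names(read_sets),
    O = vapply(read_sets, function(r)
      as.integer(scanMarkers(r, db, "origin", ...)), integer(1)),
    T = vapply(read_sets, function(r)
      as.integer(scanMarkers(r, db, "terminus", ...)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Control-relative community growth from origin:terminus counts
#'
#' \deqn{G_{rel} = \log_2\frac{O_t + c}{T_t + c} -
#'       \log_2\frac{O_c + c}{T_c + c}}
#' for each treatment sample against the control sample from the same site
#' and sampling occasion; \eqn{c} is a symmetric pseudocount guarding
#' against zero terminus counts.
#'
#' @param counts data.frame with \code{sample_id}, \code{O}, \code{T}.
#' @param metadata data.frame with \code{sample_id}, \code{site},
#'   \code{treatment}, \code{sampling} (extra columns carried through).
#' @param pseudocount added to all four counts (default 0.5).
#' @return data.frame of treatment samples with \code{log2_ratio} (own
#'   ratio) and \code{G_rel}.
#' @export
relativeGrowth <- function(counts, metadata, pseudocount = 0.5) {
  md <- merge(metadata, counts, by = "sample_id")
  if (any(md$O < 0 | md$T < 0)) stop("negative marker counts")
  md$log2_ratio <- log2((md$O + pseudocount) / (md$T + pseudocount))
  ctrl <- md[md$treatment == "control", ]
  trt <- md[md$treatment != "control", ]
  key <- function(d) paste(d$site, d$sampling)
  m <- match(key(trt), key(ctrl))
  if (anyNA(m)) {
    warning(sum(is.na(m)), " sample(s) without paired control skipped")
    trt <- trt[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  trt$G_rel <- trt$log2_ratio - ctrl$log2_ratio[m]
  rownames(trt) <- NULL
  trt
}

#' Abundance-weighted growth capacity from rRNA operon copy numbers
#'
#' Per-sample weighted average expected copy number
#' \eqn{\sum_i a_i c_i / \sum_i a_i} over taxa with known copy numbers,
#' and its difference from the paired control sample.
#'
#' @param x taxon count matrix (samples in rows) or
#'   \code{SummarizedExperiment}.
#' @param copy_numbers named numeric vector of per-taxon copy numbers
#'   (>= 1).
#' @param metadata data.frame with \code{sample_id}, \code{site},
#'   \code{treatment}, \code{sampling}.
#' @return data.frame with per-sample \code{capacity} and, for treatment
#'   samples, \code{delta_capacity} vs the paired control.
#' @export
growthCapacity <- function(x, copy_numbers, metadata) {
  m <- .asSampleMatrix(x)
  shared <- intersect(colnames(m), names(copy_numbers))
  if (!length(shared)) stop("no taxa with copy numbers present in table")
  if (any(copy_numbers[shared] < 1)) stop("copy numbers must be >= 1")
  a <- m[, shared, drop = FALSE]
  cap <- drop(a %*% copy_numbers[shared]) / rowSums(a)
  out <- data.frame(sample_id = rownames(m), capacity = cap,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- merge(metadata, out, by = "sample_id")
  ctrl <- out[out$treatment == "control", ]
  key <- function(d) paste(d$site, d$sampling)
  mm <- match(key(out), key(ctrl))
  out$delta_capacity <- out$capacity - ctrl$capacity[mm]
  out$delta_capacity[out$treatment == "control"] <- NA_real_
  out
}

# terms of a formula that can be dropped respecting marginality
.droppableTerms <- function(tt) {
  labs <- attr(tt, "term.labels")
  ord <- attr(tt, "order")
  fac <- attr(tt, "factors")
  keep <- vapply(seq_along(labs), function(i) {
    higher <- which(ord > ord[i])
    !any(vapply(higher, function(j)
      all(fac[fac[, i] > 0, j] > 0), logical(1)))
  }, logical(1))
  labs[keep]
}

#' Mixed model of community growth with community-impact interactions
#'
#' Fits the full model of control-relative growth on treatment, sampling
#' day, the Bray-Curtis distances of the bacterial and fungal communities
#' from control and all their interactions, with random site-in-country
#' intercepts and treatment-specific residual variance; the full model is
#' then reduced by backward elimination on AIC (maximum-likelihood fits,
#' respecting marginality) and the minimal model refitted by REML.
#'
#' @param data data.frame with columns \code{G_rel}, \code{treatment},
#'   \code{day}, \code{bact_dist}, \code{fung_dist}, \code{country},
#'   \code{site}.
#' @param formula full fixed-effects formula (default all interactions of
#'   the four predictors).
#' @param heteroscedastic treatment-specific residual variances?
#' @param criterion information criterion for the backward elimination:
#'   \code{"BIC"} (default; consistent, prunes null interactions) or
#'   \code{"AIC"}.
#' @return list with \code{full} and \code{minimal} (both \code{lme} fits),
#'   \code{aic_path} (data.frame of dropped terms and criterion values),
#'   \code{tTable} of the minimal model and \code{converged}.
#' @export
fitGrowthModel <- function(data,
                           formula = G_rel ~ treatment * day * bact_dist *
                             fung_dist,
                           heteroscedastic = TRUE,
                           criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  data <- as.data.frame(data)
  data$treatment <- factor(data$treatment)
  k_pen <- if (criterion == "BIC") log(nrow(data)) else 2
  ic <- function(fit) stats::AIC(stats::logLik(fit), k = k_pen)
  w <- if (heteroscedastic) nlme::varIdent(form = ~ 1 | treatment) else NULL
  fit_ml <- function(f) {
    nlme::lme(f, data = data, random = ~ 1 | country / site, weights = w,
              method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, returnObject = TRUE))
  }
  full <- try(fit_ml(formula), silent = TRUE)
  if (inherits(full, "try-error"))
    return(list(full = NULL, minimal = NULL, aic_path = NULL,
                tTable = NULL, converged = FALSE))

  current <- formula
  fit <- full
  path <- data.frame(dropped = "<full>", IC = ic(fit),
                     stringsAsFactors = FALSE)
  repeat {
    tt <- terms(current)
    cands <- .droppableTerms(tt)
    if (!length(cands)) break
    ics <- vapply(cands, function(trm) {
      f2 <- stats::update(current, paste(". ~ . -", trm))
      ft <- try(fit_ml(f2), silent = TRUE)
      if (inherits(ft, "try-error")) Inf else ic(ft)
    }, numeric(1))
    best <- which.min(ics)
    if (ics[best] >= ic(fit) - 1e-8) break
    current <- stats::update(current, paste(". ~ . -", cands[best]))
    fit <- fit_ml(current)
    path <- rbind(path, data.frame(dropped = cands[best],
                                   IC = ics[best]))
  }
  minimal <- nlme::lme(current, data = data,
                       random = ~ 1 | country / site, weights = w,
                       method = "REML",
                       control = nlme::lmeControl(opt = "optim",
                                                  returnObject = TRUE))
  list(full = full, minimal = minimal, aic_path = path,
       minimal_formula = current,
       tTable = summary(minimal)$tTable, converged = TRUE)
}
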