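# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths.

bruteBrayCurtis <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  out
}

bruteSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# step-up definition applied literally
bruteStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- p[o][i:n] * n / (i:n)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# terminus oracle: every window of every read (both strands) against every
# motif, counting mismatches character by character
bruteTerminusHits <- function(reads, motifs, max_mismatch) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  reads <- as.character(reads)
  motifs <- as.character(motifs)
  vapply(reads, function(r) {
    for (strand_seq in c(r, revcomp(r))) {
      rs <- strsplit(strand_seq, "")[[1]]
      for (m in motifs) {
        ms <- strsplit(m, "")[[1]]
        L <- length(ms)
        if (length(rs) < L) next
        for (s in seq_len(length(rs) - L + 1)) {
          if (sum(rs[s:(s + L - 1)] != ms) <= max_mismatch) return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
}

# origin oracle: best ungapped alignment score over ALL offsets of all six
# reading-frame translations against each marker, requiring a k-residue
# exact seed inside the best-scoring window
bruteOriginHits <- function(reads, markers, k, min_score, submat) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  translate1 <- function(s) {
    n3 <- (nchar(s) %/% 3) * 3
    if (n3 < 3) return("")
    codons <- substring(s, seq(1, n3 - 2, 3), seq(3, n3, 3))
    paste(vapply(codons, function(cd) {
      a <- Biostrings::GENETIC_CODE[[cd]]
      if (is.null(a)) "X" else a
    }, character(1)), collapse = "")
  }
  score_pair <- function(a, b) {
    if (a %in% rownames(submat) && b %in% rownames(submat))
      submat[a, b] else -4
  }
  reads <- as.character(reads)
  vapply(reads, function(r) {
    frames <- character(0)
    for (s0 in c(r, revcomp(r)))
      for (f in 1:3) frames <- c(frames, translate1(substring(s0, f)))
    for (pep in frames) {
      pp <- strsplit(pep, "")[[1]]
      if (length(pp) < k) next
      for (mk in markers) {
        mm <- strsplit(mk, "")[[1]]
        for (off in (-(length(pp) - k)):(length(mm) - k)) {
          # alignment: pep[i] vs mm[i + off]
          idx <- which(seq_along(pp) + off >= 1 &
                         seq_along(pp) + off <= length(mm))
          if (length(idx) < k) next
          sc <- vapply(idx, function(i)
            score_pair(pp[i], mm[i + off]), numeric(1))
          eq <- vapply(idx, function(i) pp[i] == mm[i + off], logical(1))
          # exact k-seed runs
          runs <- rle(eq)
          has_seed <- any(runs$values & runs$lengths >= k)
          if (!has_seed) next
          # best contiguous segment containing a seed: max subarray that
          # includes at least one full seed run; approximate by maximal
          # extension around each seed (matches the production definition)
          ends <- cumsum(runs$lengths)
          starts <- ends - runs$lengths + 1
          for (ri in which(runs$values & runs$lengths >= k)) {
            for (s1 in starts[ri]:(ends[ri] - k + 1)) {
              seed_sc <- sum(sc[s1:(s1 + k - 1)])
              left <- 0
              if (s1 > 1) {
                v <- rev(cumsum(rev(sc[seq_len(s1 - 1)])))
                left <- max(0, max(v))
              }
              right <- 0
              if (s1 + k <= length(sc)) {
                v <- cumsum(sc[(s1 + k):length(sc)])
                right <- max(0, max(v))
              }
              if (seed_sc + left + right >= min_score) return(TRUE)
            }
          }
        }
      }
    }
    FALSE
  }, logical(1))
}
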