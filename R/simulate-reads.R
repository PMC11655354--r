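# Toy circular genomes with an origin-to-terminus replication gradient,
# and shotgun reads sampled from them.

#' Build a toy circular genome model with origin and terminus markers
#'
#' A random circular genome carrying a replication-initiator (dnaA-like)
#' open reading frame at the origin and a 28-bp dimer-resolution (dif-like)
#' binding site at the terminus (antipodal by default).  The planted marker
#' sequences double as the marker database for
#' \code{\link{scanMarkers}}.
#'
#' @param genome_length circular genome length in bp (default 20 kb).
#' @param peptide_length length of the origin-marker peptide (aa).
#' @param seed integer RNG seed.
#' @param terminus_pos terminus position (default antipodal to the origin).
#' @return list with \code{genome} (character), \code{length},
#'   \code{origin_pos}, \code{terminus_pos}, \code{dnaA_peptide}
#'   (character), \code{dif_motif} (28-bp character).
#' @export
makeGenomeModel <- function(genome_length = 20000L, peptide_length = 150L,
                            seed = 1L, terminus_pos = NULL) {
  set.seed(seed)
  genome_length <- as.integer(genome_length)
  bases <- c("A", "C", "G", "T")
  g <- sample(bases, genome_length, replace = TRUE)

  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]   # 20-letter alphabet
  pep <- paste(sample(aa, peptide_length, replace = TRUE), collapse = "")
  codon_tab <- Biostrings::GENETIC_CODE
  codons <- split(names(codon_tab), codon_tab)
  dna <- vapply(strsplit(pep, "")[[1]],
                function(a) sample(codons[[a]], 1), character(1))
  orf <- strsplit(paste(dna, collapse = ""), "")[[1]]

  origin_pos <- 1L
  g[seq_along(orf)] <- orf
  if (is.null(terminus_pos))
    terminus_pos <- as.integer(genome_length / 2)
  dif <- sample(bases, 28, replace = TRUE)
  g[terminus_pos + seq_len(28) - 1L] <- dif

  list(genome = paste(g, collapse = ""), length = genome_length,
       origin_pos = origin_pos, terminus_pos = terminus_pos,
       dnaA_peptide = pep, dif_motif = paste(dif, collapse = ""))
}

#' Marker database from one or more genome models
#'
#' @param models a genome model from \code{\link{makeGenomeModel}} or a
#'   list of them.
#' @return list with \code{origin} (\code{AAStringSet} of initiator
#'   peptides) and \code{terminus} (\code{DNAStringSet} of 28-bp motifs).
#' @export
markerDb <- function(models) {
  if (!is.null(models$genome)) models <- list(models)
  list(
    origin = Biostrings::AAStringSet(
      vapply(models, `[[`, character(1), "dnaA_peptide")),
    terminus = Biostrings::DNAStringSet(
      vapply(models, `[[`, character(1), "dif_motif"))
  )
}

#' Simulate shotgun reads under a circular replication coverage gradient
#'
#' Read start positions are sampled proportionally to
#' \eqn{2^{\rho (1 - 2 d(x))}} where \eqn{d(x) \in [0, 0.5]} is the
#' normalized circular distance of position \eqn{x} from the origin and
#' \eqn{\rho \ge 0} the log2 peak-to-trough (origin:terminus) coverage
#' ratio: at \eqn{\rho = 0} coverage is flat, at \eqn{\rho = 1} origin
#' coverage is twice terminus coverage.  Reads wrap around the circular
#' genome, are placed on either strand with equal probability, and receive
#' independent substitution errors.
#'
#' @param model genome model from \code{\link{makeGenomeModel}}.
#' @param rho log2 peak-to-trough ratio (>= 0).
#' @param n_reads number of reads (> 0).
#' @param read_length read length in bp (< genome length).
#' @param error_rate per-base substitution probability.
#' @param seed integer RNG seed.
#' @return \code{DNAStringSet} of reads with attributes \code{"rho"} and
#'   \code{"starts"}.
#' @export
simulateMarkerReads <- function(model, rho, n_reads = 20000L,
                                read_length = 150L, error_rate = 0.005,
                                seed = 1L) {
  if (n_reads <= 0) stop("n_reads must be positive")
  if (rho < 0) stop("rho must be non-negative")
  L <- model$length
  if (read_length >= L) stop("read length must be below genome length")
  set.seed(seed)

  x <- seq_len(L)
  dist_o <- abs(x - model$origin_pos)
  d <- pmin(dist_o, L - dist_o) / L
  w <- 2^(rho * (1 - 2 * d))
  starts <- sample.int(L, n_reads, replace = TRUE, prob = w)

  g2 <- paste0(model$genome, substr(model$genome, 1L, read_length))
  reads <- substring(g2, starts, starts + read_length - 1L)

  nerr <- rbinom(n_reads, read_length, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0)) {
    pos <- sample.int(read_length, nerr[i])
    s <- strsplit(reads[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    reads[i] <- paste(s, collapse = "")
  }

  revc <- runif(n_reads) < 0.5
  out <- Biostrings::DNAStringSet(reads)
  out[revc] <- Biostrings::reverseComplement(out[revc])
  names(out) <- sprintf("read%06d", seq_len(n_reads))
  attr(out, "rho") <- rho
  attr(out, "starts") <- starts
  out
}
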