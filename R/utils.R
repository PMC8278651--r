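#' @useDynLib akkpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test cutree hclust as.dist cmdscale lm coef
#'   pnorm qnorm quantile rbinom rlnorm rnorm runif rpois p.adjust sd
#'   uniroot wilcox.test complete.cases setNames var qlogis plogis
#'   as.formula
#' @importFrom utils write.table head combn adist
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases. Uses the session RNG; seed upstream for
#' reproducibility.
#'
#' @param n sequence length in nucleotides
#' @return a single character string
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

# substitute each site independently: with probability q the site is
# redrawn uniformly from {A,C,G,T} (so the per-site substitution probability
# is 3q/4). This "scatter" move composes multiplicatively along branches:
# divergence after branches q1..qB is (3/4) * (1 - prod(1 - qb)).
scatter_mutate <- function(seq, q) {
  if (q <= 0) return(seq)
  r <- charToRaw(seq)
  idx <- which(runif(length(r)) < q)
  if (length(idx)) {
    r[idx] <- charToRaw(paste(sample(DNA_BASES, length(idx), replace = TRUE),
                              collapse = ""))[seq_along(idx)]
  }
  rawToChar(r)
}

# scatter probability q for a single branch so that the *pairwise* divergence
# across two such branches is d: (3/4)(1 - (1-q)^2) = d
scatter_for_pairwise <- function(d) {
  stopifnot(d >= 0, d < 0.75)
  1 - sqrt(1 - (4 / 3) * d)
}

# divergence produced along a path with scatter probs qs
scatter_divergence <- function(qs) (3 / 4) * (1 - prod(1 - qs))

# per-site identity between two equal-length strings
seq_identity <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  mean(ra == rb)
}

# cut a sequence into consecutive tiles of tile_len; a terminal remainder
# shorter than min_last is merged into the previous tile (or kept whole if it
# is the only piece)
tile_sequence <- function(seq, tile_len = 150L, min_last = 50L) {
  n <- nchar(seq)
  if (n <= tile_len) return(seq)
  starts <- seq(1L, n, by = tile_len)
  ends <- pmin(starts + tile_len - 1L, n)
  k <- length(starts)
  if (k > 1L && (ends[k] - starts[k] + 1L) < min_last) {
    ends[k - 1L] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }
  substring(seq, starts, ends)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), filepath = path)
  invisible(path)
}

# write a TSV with comment header lines (used by the pipeline stages)
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# small deterministic FNV-1a hash of a string, hex; used to stamp outputs
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# derive a child seed from a base seed and a stage tag, kept below 2^31
derive_seed <- function(seed, tag) {
  (seed * 7919 + sum(utf8ToInt(tag))) %% 2147483647L
}
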