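#' Construct a genome record
#'
#' Bundles an assembly's contigs with its quality metrics and gene
#' annotations. Coordinates are 1-based inclusive and validated against
#' contig bounds.
#'
#' @param id genome identifier
#' @param sequences named list (or character vector) of contig sequences
#' @param completeness,contamination estimated completeness/contamination in
#'   percent (as produced by tools like CheckM); may be `NA`
#' @param source_host host category the genome was recovered from
#' @param gene_annotations data frame with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand` and optionally `family_label` (and extras)
#' @return an object of class `genome_record`
#' @export
genome_record <- function(id, sequences, completeness = NA_real_,
                          contamination = NA_real_, source_host = NA_character_,
                          gene_annotations = NULL) {
  sequences <- as.list(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    names(sequences) <- paste0("ctg", seq_along(sequences))
  if (!is.na(completeness) && (completeness < 0 || completeness > 100))
    stop("completeness must be in [0, 100]")
  if (!is.na(contamination) && (contamination < 0 || contamination > 100))
    stop("contamination must be in [0, 100]")
  if (!is.null(gene_annotations)) {
    stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in%
                    names(gene_annotations)))
    lens <- vapply(sequences, nchar, integer(1))
    bad <- gene_annotations$start < 1 |
      gene_annotations$end > lens[gene_annotations$contig] |
      gene_annotations$start > gene_annotations$end
    if (any(bad)) stop("gene coordinates outside contig bounds for: ",
                       paste(head(gene_annotations$gene_id[bad]), collapse = ", "))
  }
  structure(list(id = id, sequences = sequences, completeness = completeness,
                 contamination = contamination, source_host = source_host,
                 gene_annotations = gene_annotations),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "-", length(x$sequences), "contig(s),",
      sum(vapply(x$sequences, nchar, integer(1))), "nt;",
      "completeness", x$completeness, "%, contamination", x$contamination,
      "%\n")
  invisible(x)
}

#' Extract annotated gene sequences from a genome record
#'
#' Minus-strand genes are reverse complemented so sequences are returned in
#' gene orientation.
#'
#' @param genome a [genome_record()]
#' @param classes optional filter on the annotation `class` column
#' @return named character vector (names are `gene_id`s)
#' @export
extract_gene_seqs <- function(genome, classes = NULL) {
  ann <- genome$gene_annotations
  if (is.null(ann) || nrow(ann) == 0) return(character(0))
  if (!is.null(classes) && "class" %in% names(ann))
    ann <- ann[ann$class %in% classes, , drop = FALSE]
  if (nrow(ann) == 0) return(character(0))
  seqs <- vapply(seq_len(nrow(ann)), function(i)
    substring(genome$sequences[[ann$contig[i]]], ann$start[i], ann$end[i]),
    character(1))
  neg <- ann$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  setNames(seqs, ann$gene_id)
}

#' Quality-filter a genome collection
#'
#' Keeps genomes with completeness at or above `min_completeness` and
#' contamination at or below `max_contamination` (both boundaries inclusive).
#' Genomes with missing metrics are rejected. Input order is preserved; the
#' rejected genomes and reasons are attached as attribute `"rejected"`.
#'
#' @param genomes list of [genome_record()]s
#' @param min_completeness,max_contamination thresholds in percent
#' @return the kept sublist, with a `"rejected"` attribute data frame
#' @export
qc_filter <- function(genomes, min_completeness = 90, max_contamination = 5) {
  reason <- vapply(genomes, function(g) {
    if (is.na(g$completeness) || is.na(g$contamination)) "missing QC metric"
    else if (g$completeness < min_completeness) "low completeness"
    else if (g$contamination > max_contamination) "high contamination"
    else ""
  }, character(1))
  kept <- genomes[reason == ""]
  rejected <- data.frame(
    genome_id = vapply(genomes[reason != ""], `[[`, character(1), "id"),
    reason = reason[reason != ""], stringsAsFactors = FALSE)
  if (nrow(rejected)) message(nrow(rejected), " genome(s) failed QC")
  attr(kept, "rejected") <- rejected
  kept
}

#' Bottom-s MinHash sketch of a genome
#'
#' Hashes every canonical k-mer (lexicographic minimum of a k-mer and its
#' reverse complement) with a 64-bit avalanche hash and keeps the `s`
#' smallest distinct values, as in Mash.
#'
#' @param genome a [genome_record()], or a character vector of contigs
#' @param k k-mer length (default 21, the Mash default)
#' @param s sketch size (default 1000, the Mash default)
#' @return an object of class `akk_sketch`
#' @export
sketch_genome <- function(genome, k = 21, s = 1000) {
  if (inherits(genome, "genome_record")) {
    id <- genome$id
    contigs <- unlist(genome$sequences, use.names = FALSE)
  } else {
    id <- attr(genome, "id") %||% NA_character_
    contigs <- as.character(genome)
  }
  if (sum(nchar(contigs)) <= k) stop("genome shorter than k")
  hashes <- cpp_sketch(contigs, as.integer(k), as.integer(s))
  structure(list(genome_id = id, k = as.integer(k), s = as.integer(s),
                 hashes = hashes), class = "akk_sketch")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index j from the bottom-s sketch of the union of the
#' two hash sets and converts it with the Mash estimator
#' d = -(1/k) ln(2j / (1 + j)), capped at 1; d = 0 when j = 1 and d = 1 when
#' j = 0.
#'
#' @param a,b `akk_sketch` objects with identical k and s
#' @return distance as a fraction
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "akk_sketch"), inherits(b, "akk_sketch"))
  if (a$k != b$k) stop("sketches built with different k")
  if (a$s != b$s) stop("sketches built with different sketch size")
  s <- min(a$s, length(a$hashes) + length(b$hashes))
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(s, length(u)))]
  shared <- sum(u %in% a$hashes & u %in% b$hashes)
  j <- shared / length(u)
  if (j >= 1) return(0)
  if (j <= 0) return(1)
  min(1, -(1 / a$k) * log(2 * j / (1 + j)))
}

#' ANI estimate from a Mash distance
#'
#' The Mash distance estimates the per-site substitution rate d through the
#' Poisson model for k-mer survival, so identity is recovered as exp(-d)
#' (equivalently (2j/(1+j))^(1/k)); the frequently quoted `1 - d` is the
#' first-order expansion of the same quantity and is visibly biased below
#' ~90% identity.
#'
#' @param a,b `akk_sketch` objects
#' @return estimated average nucleotide identity as a fraction
#' @export
mash_ani <- function(a, b) exp(-mash_distance(a, b))

#' Pairwise Mash distance (or ANI) matrix for a genome collection
#'
#' @param genomes list of [genome_record()]s
#' @param k,s sketch parameters, see [sketch_genome()]
#' @param what `"distance"` or `"ani"`
#' @return symmetric matrix with genome ids as labels
#' @export
mash_matrix <- function(genomes, k = 21, s = 1000, what = c("distance", "ani")) {
  what <- match.arg(what)
  sketches <- lapply(genomes, sketch_genome, k = k, s = s)
  ids <- vapply(genomes, `[[`, character(1), "id")
  n <- length(genomes)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
  if (what == "ani") m <- exp(-m)
  m
}

#' Cluster genomes into species-level genome bins (SGBs)
#'
#' Average-linkage agglomerative clustering of a genome distance matrix cut
#' at `threshold` (5% whole-genome distance corresponds to the conventional
#' 95% ANI species boundary). Clusters are labeled `SGB01`, `SGB02`, ...
#' deterministically, ordered by each cluster's lexicographically smallest
#' member id, so the labeling does not depend on input order.
#'
#' @param dm symmetric distance matrix with genome ids as dimnames
#' @param threshold cut height
#' @return named character vector: genome id -> SGB label
#' @export
cluster_sgbs <- function(dm, threshold = 0.05) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) == 1) return(setNames("SGB01", rownames(dm)))
  hc <- hclust(as.dist(dm), method = "average")
  grp <- cutree(hc, h = threshold)
  smallest <- vapply(split(names(grp), grp), min, character(1))
  ord <- order(smallest)
  relabel <- setNames(sprintf("SGB%02d", seq_along(ord)),
                      names(smallest)[ord])
  setNames(unname(relabel[as.character(grp)]), names(grp))
}

# global alignment (linear gap penalty) of two sequences; returns edit
# distance over alignment length, following the full-length-gene contract
global_distance <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(pat, "")[[1]]; sc <- strsplit(sub, "")[[1]]
  edits <- sum(pc != sc)  # mismatches plus gap columns
  edits / length(pc)
}

#' Pairwise distances among 16S rRNA gene sequences
#'
#' Applies the two published filters -- sequences must be longer than
#' `min_len` nucleotides, and sequences with more than `contaminant_identity`
#' whole-gene identity to any contaminant reference (e.g. 16S genes from
#' unrelated families) are removed -- then computes pairwise edit distance
#' divided by alignment length on end-to-end global alignments
#' (match +1 / mismatch -1 / gap -2).
#'
#' @param seqs named character vector of candidate 16S sequences
#' @param min_len minimum exclusive length (default 1000)
#' @param contaminant_refs optional named character vector of references
#' @param contaminant_identity identity above which a sequence is dropped
#' @return symmetric distance matrix over the surviving sequences (empty,
#'   with a warning, if fewer than two survive)
#' @export
rrna_distances <- function(seqs, min_len = 1000, contaminant_refs = NULL,
                           contaminant_identity = 0.98) {
  seqs <- seqs[nchar(seqs) > min_len]
  if (length(seqs) && length(contaminant_refs)) {
    contaminated <- vapply(seqs, function(s)
      any(vapply(contaminant_refs, function(r)
        1 - global_distance(s, r) > contaminant_identity, logical(1))),
      logical(1))
    if (any(contaminated))
      message("removed ", sum(contaminated), " contaminant-like 16S sequence(s)")
    seqs <- seqs[!contaminated]
  }
  if (length(seqs) < 2) {
    warning("fewer than 2 sequences survive the 16S filters")
    return(matrix(numeric(0), 0, 0))
  }
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- global_distance(seqs[[i]], seqs[[j]])
  m
}
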