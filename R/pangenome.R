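# Tile-scan comparison of a query sequence against a target: the query is cut
# into ~150-nt tiles and each tile is placed ungapped (either strand) at its
# best position in the target. Sensitivity is exact down to the pigeonhole
# bound of the 9-mer seeds (~90% per-tile identity); tiles below it report 0.
tile_scan <- function(query, target_contigs, min_identity, tile_len = 150L,
                      seed_q = 9L) {
  tiles <- tile_sequence(query, tile_len)
  best <- rep(0, length(tiles))
  for (ctg in target_contigs) {
    ids <- cpp_tile_identities(tiles, ctg, min_identity, as.integer(seed_q))
    best <- pmax(best, ids)
  }
  list(tiles = tiles, lens = nchar(tiles), identity = best)
}

#' Greedy centroid clustering of genes into families
#'
#' Sequences are processed longest-first (ties broken by lexicographic order
#' of the sequence) and joined to the first existing centroid they match at
#' more than `identity` mean identity over more than `coverage` of the
#' centroid's length; otherwise they found a new family. Identity and
#' coverage are measured by ungapped placement of ~150-nt tiles of the gene
#' on the centroid (both strands).
#'
#' @param genes data frame with columns `gene_id`, `genome_id`, `seq`
#' @param identity exclusive identity threshold (default 0.90)
#' @param coverage exclusive centroid-coverage threshold (default 0.80)
#' @return list with `families` (data frame: `family_id`, `centroid_gene`,
#'   `centroid_seq`, `n_members`), `members` (data frame: `family_id`,
#'   `genome_id`, `gene_id`) and `presence` (binary genome x family matrix)
#' @export
cluster_families <- function(genes, identity = 0.90, coverage = 0.80) {
  if (is.null(genes) || nrow(genes) == 0)
    return(list(families = data.frame(), members = data.frame(),
                presence = matrix(0, 0, 0)))
  stopifnot(all(c("gene_id", "genome_id", "seq") %in% names(genes)))
  ord <- order(-nchar(genes$seq), genes$seq)
  genes <- genes[ord, , drop = FALSE]
  cidx <- cpp_greedy_cluster(genes$seq, identity, coverage)
  centroid_rows <- sort(unique(cidx))
  assignment <- match(cidx, centroid_rows)
  centroid_seq <- genes$seq[centroid_rows]
  centroid_gene <- genes$gene_id[centroid_rows]
  fam_ids <- sprintf("F%04d", seq_along(centroid_seq))
  members <- data.frame(family_id = fam_ids[assignment],
                        genome_id = genes$genome_id,
                        gene_id = genes$gene_id, stringsAsFactors = FALSE)
  genomes <- sort(unique(genes$genome_id))
  presence <- matrix(0L, length(genomes), length(fam_ids),
                     dimnames = list(genomes, fam_ids))
  presence[cbind(members$genome_id, members$family_id)] <- 1L
  families <- data.frame(family_id = fam_ids, centroid_gene = centroid_gene,
                         centroid_seq = centroid_seq,
                         n_members = as.integer(table(factor(members$family_id,
                                                             levels = fam_ids))),
                         stringsAsFactors = FALSE)
  list(families = families, members = members, presence = presence)
}

#' Per-clade core gene families
#'
#' A family is core for a clade when it is present in at least
#' `core_fraction` of the clade's genomes (boundary inclusive, following the
#' "at least 80%" definition).
#'
#' @param presence binary genome x family matrix
#' @param clades named vector: genome id -> clade
#' @param core_fraction inclusive presence threshold
#' @return named list: clade -> character vector of core family ids
#' @export
core_genes <- function(presence, clades, core_fraction = 0.80) {
  stopifnot(all(rownames(presence) %in% names(clades)))
  lapply(split(rownames(presence), clades[rownames(presence)]), function(gs) {
    if (length(gs) == 0) stop("clade with zero genomes")
    frac <- colMeans(presence[gs, , drop = FALSE])
    colnames(presence)[frac >= core_fraction]
  })
}

#' Fragment-level presence of a gene in a genome
#'
#' The gene is split into consecutive non-overlapping `frag_len`-nt fragments
#' (a terminal remainder shorter than `frag_len` is dropped); the gene is
#' present when at least one fragment has an ungapped hit on either strand of
#' the genome with at most `max_mm` mismatches. A gene shorter than
#' `frag_len` is evaluated as a single whole-gene fragment.
#'
#' @param gene_seq gene nucleotide sequence
#' @param genome a [genome_record()] or character vector of contigs
#' @param frag_len fragment length (default 150)
#' @param max_mm mismatch tolerance per fragment (default 5, roughly the
#'   tolerance of a sensitive short-read mapper over 150 nt)
#' @return logical scalar
#' @export
fragment_presence <- function(gene_seq, genome, frag_len = 150L, max_mm = 5L) {
  contigs <- if (inherits(genome, "genome_record"))
    unlist(genome$sequences, use.names = FALSE) else as.character(genome)
  frags <- gene_fragments(gene_seq, frag_len)
  any(cpp_fragment_hits(frags, contigs, as.integer(max_mm)))
}

# non-overlapping fragments, terminal remainder dropped; short genes are one
# whole-gene fragment
gene_fragments <- function(gene_seq, frag_len = 150L) {
  n <- nchar(gene_seq)
  if (n < frag_len) {
    message("gene shorter than frag_len; evaluated as one whole-gene fragment")
    return(gene_seq)
  }
  k <- n %/% frag_len
  starts <- (seq_len(k) - 1L) * frag_len + 1L
  substring(gene_seq, starts, starts + frag_len - 1L)
}

#' Select clade-specific marker genes
#'
#' A clade's core gene becomes a marker when, for every other clade, the
#' fraction of that clade's genomes in which the gene is fragment-present
#' ([fragment_presence()]) does not exceed `exclusivity` (strictly "more than
#' 1%" excludes, so a gene found in exactly 1% of another clade's genomes is
#' kept).
#'
#' @param core_lists named list clade -> core family ids (from [core_genes()])
#' @param family_seqs named character vector: family id -> centroid sequence
#' @param genomes_by_clade named list clade -> list of [genome_record()]s
#' @param exclusivity inclusive tolerance (default 0.01)
#' @param frag_len,max_mm fragment mapping contract, see [fragment_presence()]
#' @return named list of `marker_set` objects, one per clade, each with
#'   `clade_id`, `markers` (data frame `family_id`, `seq`) and `fragments`
#'   (list of per-marker fragment vectors)
#' @export
select_markers <- function(core_lists, family_seqs, genomes_by_clade,
                           exclusivity = 0.01, frag_len = 150L, max_mm = 5L) {
  clades <- names(core_lists)
  stopifnot(!is.null(clades), all(clades %in% names(genomes_by_clade)))
  cand <- unique(unlist(core_lists))
  fam_frags <- lapply(setNames(family_seqs[cand], cand), gene_fragments,
                      frag_len = frag_len)
  nfr <- lengths(fam_frags)
  allfr <- unlist(fam_frags, use.names = FALSE)
  # fraction of each clade's genomes in which each candidate family is
  # fragment-present; one indexed scan per genome covers all candidates
  pres_frac <- lapply(clades, function(other) {
    hits <- vapply(genomes_by_clade[[other]], function(g) {
      contigs <- unlist(g$sequences, use.names = FALSE)
      h <- cpp_fragment_hits(allfr, contigs, as.integer(max_mm))
      vapply(split(h, rep(cand, nfr)), any, logical(1))[cand]
    }, logical(length(cand)))
    if (is.null(dim(hits))) hits <- matrix(hits, nrow = length(cand))
    rownames(hits) <- cand
    rowMeans(hits)
  })
  names(pres_frac) <- clades
  out <- lapply(clades, function(cl) {
    fams <- core_lists[[cl]]
    ok <- vapply(fams, function(f) {
      others <- setdiff(clades, cl)
      all(vapply(others, function(o) pres_frac[[o]][f] <= exclusivity,
                 logical(1)))
    }, logical(1))
    sel <- fams[ok]
    if (length(sel) == 0)
      warning("clade ", cl, " has no marker genes and cannot be profiled")
    structure(list(clade_id = cl,
                   markers = data.frame(family_id = sel,
                                        seq = unname(family_seqs[sel]),
                                        stringsAsFactors = FALSE),
                   fragments = lapply(setNames(family_seqs[sel], sel),
                                      gene_fragments, frag_len = frag_len)),
              class = "marker_set")
  })
  setNames(out, clades)
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set>", x$clade_id, "-", nrow(x$markers), "marker gene(s)\n")
  invisible(x)
}

#' Screen genomes for a named reference gene set
#'
#' Each reference sequence is cut into ~150-nt tiles placed ungapped at their
#' best position in the genome (either strand); a reference is present in a
#' genome when the tiles found cover at least `min_coverage` of its length
#' with mean identity at least `min_identity` (the "at least 50% of the
#' sequence at 70% identity" plasmid-screen semantics).
#'
#' @param genomes list of [genome_record()]s
#' @param refs named character vector of reference nucleotide sequences
#' @param min_identity,min_coverage inclusive thresholds in (0, 1]
#' @return binary genome x reference matrix with mean-identity attribute
#' @export
screen_gene_set <- function(genomes, refs, min_identity = 0.70,
                            min_coverage = 0.50) {
  if (length(refs) == 0) stop("empty reference set")
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  ids <- vapply(genomes, `[[`, character(1), "id")
  pres <- matrix(0L, length(genomes), length(refs),
                 dimnames = list(ids, names(refs)))
  iden <- matrix(NA_real_, length(genomes), length(refs),
                 dimnames = list(ids, names(refs)))
  for (gi in seq_along(genomes)) {
    contigs <- unlist(genomes[[gi]]$sequences, use.names = FALSE)
    for (ri in seq_along(refs)) {
      scan <- tile_scan(refs[[ri]], contigs, min_identity = min_identity)
      found <- scan$identity > 0
      cov <- sum(scan$lens[found]) / sum(scan$lens)
      if (any(found)) {
        mid <- sum((scan$identity * scan$lens)[found]) / sum(scan$lens[found])
        iden[gi, ri] <- mid
        if (cov >= min_coverage && mid >= min_identity) pres[gi, ri] <- 1L
      }
    }
  }
  attr(pres, "mean_identity") <- iden
  pres
}

#' Assign a genome to one of two operon archetypes
#'
#' Counts how many member genes of each archetype are detectable in the
#' genome ([screen_gene_set()] per gene); the archetype with more detected
#' genes wins, provided at least `min_genes_detected` of its genes are found.
#' Ties and below-threshold genomes are `"unassigned"`.
#'
#' @param genome a [genome_record()]
#' @param archetype_a,archetype_b named character vectors of member gene
#'   sequences (disjoint sets)
#' @param min_genes_detected minimum detected genes for an assignment
#' @param min_identity,min_coverage detection thresholds per gene
#' @return one of `"A"`, `"B"`, `"unassigned"` (named by the archetype
#'   argument names where supplied)
#' @export
assign_operon_archetype <- function(genome, archetype_a, archetype_b,
                                    min_genes_detected = 1L,
                                    min_identity = 0.70, min_coverage = 0.50) {
  pa <- screen_gene_set(list(genome), archetype_a, min_identity, min_coverage)
  pb <- screen_gene_set(list(genome), archetype_b, min_identity, min_coverage)
  na_ <- sum(pa); nb <- sum(pb)
  if (na_ == nb || max(na_, nb) < min_genes_detected) return("unassigned")
  if (na_ > nb) "A" else "B"
}
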