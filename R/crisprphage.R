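#' Detect CRISPR arrays in a genome
#'
#' A deliberately simple repeat-chain finder: it looks for chains of at least
#' `min_repeats` near-identical repeats (length 23-50, each within
#' `max_mm` mismatches of the chain consensus) separated by non-repeat
#' spacers of 20-60 nt. Candidate chains are seeded by 20-mers that recur
#' with periods compatible with repeat+spacer lengths, then extended around
#' the seed by column-majority consensus.
#'
#' @param genome a [genome_record()] or character vector of contigs
#' @param min_repeats minimum repeats per array (default 3)
#' @param repeat_len_range,spacer_len_range admissible lengths
#' @param max_mm per-repeat mismatch tolerance to the consensus
#' @return data frame of spacers with columns `contig`, `array`, `repeat_consensus`,
#'   `spacer_id`, `spacer`, `start`, `end` (empty when no array is found)
#' @export
detect_arrays <- function(genome, min_repeats = 3L,
                          repeat_len_range = c(23L, 50L),
                          spacer_len_range = c(20L, 60L), max_mm = 2L) {
  contigs <- if (inherits(genome, "genome_record")) genome$sequences
             else as.list(genome)
  if (is.null(names(contigs))) names(contigs) <- paste0("ctg", seq_along(contigs))
  gid <- if (inherits(genome, "genome_record")) genome$id else "genome"
  out <- list()
  arr_i <- 0L
  k <- 20L
  min_period <- repeat_len_range[1] + spacer_len_range[1]
  max_period <- repeat_len_range[2] + spacer_len_range[2]
  for (cn in names(contigs)) {
    seqc <- contigs[[cn]]
    L <- nchar(seqc)
    if (L < min_repeats * min_period) next
    kmers <- substring(seqc, 1:(L - k + 1L), k:L)
    dup <- names(which(table(kmers) >= min_repeats))
    if (length(dup) == 0) next
    cand <- list()
    for (km in dup) {
      pos <- which(kmers == km)
      # greedy chains of occurrences with inter-occurrence gaps in range
      i <- 1L
      while (i <= length(pos)) {
        chain <- pos[i]
        while (i < length(pos) &&
               (pos[i + 1L] - chain[length(chain)]) >= min_period &&
               (pos[i + 1L] - chain[length(chain)]) <= max_period) {
          chain <- c(chain, pos[i + 1L]); i <- i + 1L
        }
        if (length(chain) >= min_repeats)
          cand[[length(cand) + 1L]] <- chain
        i <- i + 1L
      }
    }
    if (length(cand) == 0) next
    # prefer longer chains; accept chains not overlapping an accepted one
    cand <- cand[order(-lengths(cand))]
    accepted <- list()
    for (chain in cand) {
      span <- c(chain[1], chain[length(chain)] + k)
      clash <- any(vapply(accepted, function(a)
        span[1] <= a[2] && a[1] <= span[2], logical(1)))
      if (!clash) accepted[[length(accepted) + 1L]] <- span else next
      # extend the repeat around the seed by column majority
      t_occ <- chain
      ext_l <- 0L; ext_r <- k - 1L
      repeat {
        p <- t_occ - ext_l - 1L
        if (any(p < 1L) || (ext_l + ext_r + 2L) > repeat_len_range[2]) break
        col <- substring(seqc, p, p)
        if (max(table(col)) / length(col) < 0.9) break
        ext_l <- ext_l + 1L
      }
      repeat {
        p <- t_occ + ext_r + 1L
        if (any(p > L) || (ext_l + ext_r + 2L) > repeat_len_range[2]) break
        col <- substring(seqc, p, p)
        if (max(table(col)) / length(col) < 0.9) break
        ext_r <- ext_r + 1L
      }
      r_starts <- t_occ - ext_l
      r_len <- ext_l + k + (ext_r - k + 1L)
      if (r_len < repeat_len_range[1] || r_len > repeat_len_range[2]) next
      reps <- substring(seqc, r_starts, r_starts + r_len - 1L)
      cons <- consensus_string(reps)
      mm <- vapply(reps, function(r)
        sum(charToRaw(r) != charToRaw(cons)), integer(1))
      keepr <- mm <= max_mm
      if (sum(keepr) < min_repeats) next
      r_starts <- r_starts[keepr]
      # spacers between consecutive repeats
      sp_start <- r_starts[-length(r_starts)] + r_len
      sp_end <- r_starts[-1] - 1L
      sp_len <- sp_end - sp_start + 1L
      oks <- sp_len >= spacer_len_range[1] & sp_len <= spacer_len_range[2]
      if (!any(oks)) next
      arr_i <- arr_i + 1L
      out[[length(out) + 1L]] <- data.frame(
        contig = cn, array = arr_i, repeat_consensus = cons,
        spacer_id = sprintf("%s_a%d_s%02d", gid, arr_i, seq_len(sum(oks))),
        spacer = substring(seqc, sp_start[oks], sp_end[oks]),
        start = sp_start[oks], end = sp_end[oks], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), array = integer(0),
                      repeat_consensus = character(0),
                      spacer_id = character(0), spacer = character(0),
                      start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

consensus_string <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2, function(col) names(which.max(table(col)))), collapse = "")
}

#' Type a CRISPR-Cas locus from annotated Cas genes
#'
#' Type I-C requires Cas3, Cas5, Cas8c, Cas7, Cas4, Cas1 and Cas2; the locus
#' is additionally flagged as the novel-variant orientation when Cas3, Cas5,
#' Cas8c and Cas7 share a strand opposite to Cas4, Cas1 and Cas2. Type II-C
#' requires Cas9, Cas1 and Cas2 without any I-C signature gene (Cas3, Cas5,
#' Cas8c, Cas7). Anything else is untyped.
#'
#' @param cas_genes data frame with columns `name` and `strand` (ordered as
#'   on the locus)
#' @return list with `locus_type` (`"I-C"`, `"II-C"` or `"untyped"`) and
#'   `novel_variant` (logical)
#' @export
type_locus <- function(cas_genes) {
  vocab <- c("Cas1", "Cas2", "Cas3", "Cas4", "Cas5", "Cas7", "Cas8c", "Cas9")
  unknown <- setdiff(cas_genes$name, vocab)
  if (length(unknown)) {
    warning("ignoring unknown Cas gene(s): ", paste(unknown, collapse = ", "))
    cas_genes <- cas_genes[cas_genes$name %in% vocab, , drop = FALSE]
  }
  have <- function(g) g %in% cas_genes$name
  ic_set <- c("Cas3", "Cas5", "Cas8c", "Cas7", "Cas4", "Cas1", "Cas2")
  ic_sig <- c("Cas3", "Cas5", "Cas8c", "Cas7")
  if (all(vapply(ic_set, have, logical(1)))) {
    s <- setNames(cas_genes$strand, cas_genes$name)
    grp1 <- s[ic_sig]; grp2 <- s[c("Cas4", "Cas1", "Cas2")]
    novel <- length(unique(grp1)) == 1 && length(unique(grp2)) == 1 &&
      grp1[1] != grp2[1]
    return(list(locus_type = "I-C", novel_variant = novel))
  }
  if (have("Cas9") && have("Cas1") && have("Cas2") &&
      !any(vapply(ic_sig, have, logical(1))))
    return(list(locus_type = "II-C", novel_variant = FALSE))
  list(locus_type = "untyped", novel_variant = FALSE)
}

#' Filter putative viral contigs on the published metadata rules
#'
#' Keeps contigs that are (a) longer than 1500 bp (strict), (b) from viromes
#' with enrichment >= 50x, (c) binned in the same species-level genome bin in
#' fewer than 30 metagenomes, and (d) found in the unbinned fraction of more
#' than 20 metagenomes. Contigs with missing metadata are excluded and
#' reported.
#'
#' @param meta data frame with columns `contig`, `length`, `enrichment`,
#'   `n_binned_same_sgb`, `n_unbinned_metagenomes`
#' @return the kept subset, with excluded-for-missing ids in attribute
#'   `"excluded_missing"`
#' @export
filter_viral_contigs <- function(meta) {
  need <- c("contig", "length", "enrichment", "n_binned_same_sgb",
            "n_unbinned_metagenomes")
  stopifnot(all(need %in% names(meta)))
  miss <- !complete.cases(meta[, need])
  if (any(miss))
    message(sum(miss), " contig(s) excluded for missing metadata")
  m <- meta[!miss, , drop = FALSE]
  keep <- m$length > 1500 & m$enrichment >= 50 &
    m$n_binned_same_sgb < 30 & m$n_unbinned_metagenomes > 20
  out <- m[keep, , drop = FALSE]
  attr(out, "excluded_missing") <- meta$contig[miss]
  out
}

# mean tile identity of the shorter contig placed on the longer (both
# strands); unplaced tiles count as zero identity
contig_identity <- function(a, b, min_identity) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  scan <- tile_scan(a, b, min_identity = min_identity)
  sum(scan$identity * scan$lens) / sum(scan$lens)
}

# fraction of the shorter contig's tiles placed at >= identity id_thr
shared_fraction <- function(a, b, id_thr) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  scan <- tile_scan(a, b, min_identity = id_thr)
  sum(scan$lens[scan$identity >= id_thr]) / sum(scan$lens)
}

#' Cluster viral contigs into viral clusters (VCs)
#'
#' Stage 1: greedy centroid clustering at >= `stage1_identity` overall
#' identity (both strands, longest-first). Stage 2: clusters are merged
#' (transitively) whenever any cross-cluster contig pair shares more than
#' `stage2_frac` of the shorter contig at >= `stage2_identity` identity.
#' The representative of a VC is its longest member.
#'
#' @param contigs named character vector of contig sequences
#' @param stage1_identity overall-identity threshold (default 0.70)
#' @param stage2_identity local-identity threshold for merging (default 0.90)
#' @param stage2_frac shared-fraction threshold (default 1/3, exclusive)
#' @return data frame: `contig`, `vc`, `representative`
#' @export
cluster_vcs <- function(contigs, stage1_identity = 0.70,
                        stage2_identity = 0.90, stage2_frac = 1 / 3) {
  stopifnot(length(contigs) > 0, !is.null(names(contigs)))
  ord <- order(-nchar(contigs), names(contigs))
  contigs <- contigs[ord]
  centroids <- integer(0)
  member_of <- integer(length(contigs))
  for (i in seq_along(contigs)) {
    hit <- 0L
    for (ci in centroids) {
      if (contig_identity(contigs[[i]], contigs[[ci]],
                          stage1_identity) >= stage1_identity) { hit <- ci; break }
    }
    if (hit == 0L) { centroids <- c(centroids, i); hit <- i }
    member_of[i] <- hit
  }
  # stage 2: union-find over stage-1 clusters
  cl_ids <- unique(member_of)
  parent <- setNames(cl_ids, cl_ids)
  find <- function(x) { while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]; x }
  if (length(cl_ids) > 1) {
    for (a in seq_along(cl_ids)[-length(cl_ids)]) {
      for (b in (a + 1):length(cl_ids)) {
        ia <- which(member_of == cl_ids[a]); ib <- which(member_of == cl_ids[b])
        merged <- FALSE
        for (x in ia) {
          for (y in ib) {
            if (shared_fraction(contigs[[x]], contigs[[y]],
                                stage2_identity) > stage2_frac) {
              ra <- find(cl_ids[a]); rb <- find(cl_ids[b])
              if (ra != rb) parent[[as.character(rb)]] <- ra
              merged <- TRUE; break
            }
          }
          if (merged) break
        }
      }
    }
  }
  root <- vapply(member_of, find, numeric(1))
  # deterministic VC labels ordered by longest member (input order stable)
  uroot <- unique(root)
  vc_lab <- setNames(sprintf("VC%03d", seq_along(uroot)), uroot)
  rep_of <- setNames(vapply(uroot, function(r) {
    mem <- which(root == r)
    names(contigs)[mem[which.max(nchar(contigs[mem]))]]
  }, character(1)), as.character(uroot))
  data.frame(contig = names(contigs), vc = unname(vc_lab[as.character(root)]),
             representative = unname(rep_of[as.character(root)]),
             stringsAsFactors = FALSE)
}

#' Match CRISPR spacers against contigs at bounded edit distance
#'
#' Semi-global Levenshtein matching (spacer global, free ends on the contig)
#' on both strands; every site with edit distance <= `max_edit` is reported
#' with its minimal-distance alignment, together with the `upstream` bases
#' immediately 5' of the protospacer in protospacer orientation (where the
#' PAM lives for type I-C systems).
#'
#' @param spacers named character vector (20-60 nt)
#' @param contigs named character vector
#' @param max_edit inclusive edit-distance bound (default 2)
#' @param upstream_n upstream context width (default 5)
#' @return data frame: `spacer_id`, `contig_id`, `start`, `end`, `strand`,
#'   `edit_distance`, `upstream_context`
#' @export
match_spacers <- function(spacers, contigs, max_edit = 2L, upstream_n = 5L) {
  stopifnot(!is.null(names(spacers)), !is.null(names(contigs)))
  res <- list()
  for (sp in names(spacers)) {
    spseq <- spacers[[sp]]
    rcseq <- revcomp(spseq)
    for (cn in names(contigs)) {
      ctg <- contigs[[cn]]
      fwd <- cpp_semiglobal_matches(spseq, ctg, as.integer(max_edit))
      if (nrow(fwd)) {
        up <- ifelse(fwd$start > upstream_n,
                     substring(ctg, fwd$start - upstream_n, fwd$start - 1L),
                     NA_character_)
        res[[length(res) + 1L]] <- data.frame(
          spacer_id = sp, contig_id = cn, start = fwd$start, end = fwd$end,
          strand = "+", edit_distance = fwd$dist, upstream_context = up,
          stringsAsFactors = FALSE)
      }
      rev_ <- cpp_semiglobal_matches(rcseq, ctg, as.integer(max_edit))
      if (nrow(rev_)) {
        up <- ifelse(rev_$end + upstream_n <= nchar(ctg),
                     revcomp(substring(ctg, rev_$end + 1L,
                                       rev_$end + upstream_n)),
                     NA_character_)
        res[[length(res) + 1L]] <- data.frame(
          spacer_id = sp, contig_id = cn, start = rev_$start, end = rev_$end,
          strand = "-", edit_distance = rev_$dist, upstream_context = up,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(spacer_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), edit_distance = integer(0),
                      upstream_context = character(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reconstruct a PAM model from spacer match upstream contexts
#'
#' Upstream contexts are stacked right-aligned at the protospacer boundary;
#' the position frequency matrix, the per-column majority consensus and the
#' per-column information content (2 - Shannon entropy, bits) are returned.
#'
#' @param matches data frame from [match_spacers()] with `upstream_context`
#' @return an object of class `pam_model`: `pfm` (4 x width), `consensus`,
#'   `information`, `n_sites`
#' @export
reconstruct_pam <- function(matches) {
  ctx <- matches$upstream_context
  ctx <- ctx[!is.na(ctx)]
  if (length(ctx) == 0) stop("no matches with upstream context")
  w <- min(nchar(ctx))
  ctx <- substring(ctx, nchar(ctx) - w + 1L, nchar(ctx))  # right-aligned
  m <- do.call(rbind, strsplit(ctx, ""))
  pfm <- apply(m, 2, function(col)
    table(factor(col, levels = DNA_BASES)) / length(col))
  rownames(pfm) <- DNA_BASES
  consensus <- paste(DNA_BASES[apply(pfm, 2, which.max)], collapse = "")
  info <- apply(pfm, 2, function(p) {
    p <- p[p > 0]; 2 + sum(p * log2(p))
  })
  structure(list(pfm = pfm, consensus = consensus, information = info,
                 n_sites = length(ctx)), class = "pam_model")
}

#' @export
print.pam_model <- function(x, ...) {
  cat("<pam_model>", x$n_sites, "sites, consensus", x$consensus, "\n")
  cat("information (bits):", paste(sprintf("%.2f", x$information),
                                   collapse = " "), "\n")
  invisible(x)
}

#' Clade-by-VC interaction table from spacer matches
#'
#' For each (clade, VC) pair, the fraction of the clade's genomes with at
#' least one spacer hit against any member contig of the VC (a genome counts
#' once per VC regardless of how many members it hits). A VC is "considered"
#' when the fraction reaches `consider_frac` for at least one clade
#' (inclusive), and a pair is "putatively interacting" when the fraction
#' strictly exceeds `interact_frac`.
#'
#' @param matches data frame from [match_spacers()]
#' @param spacer_genome named vector: spacer id -> genome id
#' @param clades named vector: genome id -> clade
#' @param vc_membership named vector: contig id -> VC id
#' @param consider_frac,interact_frac thresholds (default 0.05 / 0.10)
#' @return data frame: `clade`, `vc`, `fraction`, `considered`, `interacting`
#' @export
interaction_table <- function(matches, spacer_genome, clades, vc_membership,
                              consider_frac = 0.05, interact_frac = 0.10) {
  stopifnot(all(names(clades) != ""), length(clades) > 0)
  all_vcs <- sort(unique(vc_membership))
  all_clades <- sort(unique(unname(clades)))
  clade_size <- table(factor(unname(clades), levels = all_clades))
  hit <- unique(data.frame(
    genome = spacer_genome[matches$spacer_id],
    vc = vc_membership[matches$contig_id], stringsAsFactors = FALSE))
  out <- expand.grid(clade = all_clades, vc = all_vcs,
                     stringsAsFactors = FALSE)
  out$fraction <- mapply(function(cl, vc) {
    g <- hit$genome[hit$vc == vc]
    sum(unname(clades[g]) == cl) / clade_size[[cl]]
  }, out$clade, out$vc)
  vc_considered <- tapply(out$fraction, out$vc, function(f)
    any(f >= consider_frac))
  out$considered <- as.logical(vc_considered[out$vc])
  out$interacting <- out$fraction > interact_frac
  out
}
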