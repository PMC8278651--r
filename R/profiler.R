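#' Map reads against target sequences
#'
#' Seed-and-extend mapping: exact 31-mer seeds locate candidate placements,
#' which are extended ungapped end-to-end inside the target; the score is
#' -6 per mismatch (matches score 0), and the best placement per read is kept
#' when its score exceeds `min_score` (the published "alignment score greater
#' than -50" contract, i.e. at most 8 mismatches for a 100-nt read). Reads
#' whose best score is tied across different targets are dropped, since
#' clade-exclusive markers make such ties uninformative.
#'
#' @param reads character vector of read sequences
#' @param targets named character vector of target sequences
#' @param min_score exclusive score threshold (default -50)
#' @param seed_len exact seed length (default 31)
#' @param mismatch_penalty score penalty per mismatch (default 6)
#' @return data frame: `read`, `target`, `pos`, `strand`, `mismatches`,
#'   `score`
#' @export
map_reads <- function(reads, targets, min_score = -50, seed_len = 31L,
                      mismatch_penalty = 6) {
  stopifnot(length(targets) > 0)
  df <- cpp_map_reads(unname(as.character(reads)),
                      unname(as.character(targets)),
                      as.integer(seed_len), mismatch_penalty, min_score)
  df$target <- names(targets)[df$target] %||% df$target
  if (!is.null(names(reads))) df$read <- names(reads)[df$read]
  df
}

#' Profile a metagenomic sample with clade-specific markers
#'
#' Reads are mapped against the pooled marker sequences of all clades; a
#' marker's depth is its mapped bases divided by its length; a clade's depth
#' is the 10% trimmed mean of its marker depths (robust to marker dropout on
#' incomplete genomes). A clade is detected when at least `min_marker_frac`
#' of its markers receive at least one read; relative abundance is the
#' clade's depth over the summed depth of all detected clades.
#'
#' @param reads character vector of reads
#' @param marker_sets named list of `marker_set` objects (one per clade)
#' @param min_marker_frac detection threshold on the fraction of hit markers
#' @param trim trimming fraction for the robust depth mean
#' @param min_score mapping score threshold, see [map_reads()]
#' @return data frame with one row per clade: `clade`, `n_markers`,
#'   `frac_markers_hit`, `depth`, `detected`, `abundance`
#' @export
profile_sample <- function(reads, marker_sets, min_marker_frac = 0.2,
                           trim = 0.1, min_score = -50) {
  stopifnot(length(marker_sets) > 0)
  marker_tbl <- do.call(rbind, lapply(marker_sets, function(ms)
    if (nrow(ms$markers))
      data.frame(clade = ms$clade_id, family = ms$markers$family_id,
                 seq = ms$markers$seq, stringsAsFactors = FALSE)))
  if (is.null(marker_tbl) || nrow(marker_tbl) == 0)
    stop("no clade has markers")
  targets <- setNames(marker_tbl$seq,
                      paste(marker_tbl$clade, marker_tbl$family, sep = "|"))
  reads <- unname(as.character(reads))
  aln <- map_reads(reads, targets, min_score = min_score)
  read_len <- nchar(reads)
  mapped_bases <- tapply(read_len[aln$read],
                         factor(aln$target, levels = names(targets)), sum)
  mapped_bases[is.na(mapped_bases)] <- 0
  n_reads_hit <- tapply(rep(1, nrow(aln)),
                        factor(aln$target, levels = names(targets)), sum)
  n_reads_hit[is.na(n_reads_hit)] <- 0
  depth_per_marker <- mapped_bases / nchar(marker_tbl$seq)
  out <- do.call(rbind, lapply(split(seq_len(nrow(marker_tbl)),
                                     marker_tbl$clade), function(idx) {
    d <- depth_per_marker[idx]
    frac_hit <- mean(n_reads_hit[idx] > 0)
    depth <- mean(d, trim = trim)
    detected <- frac_hit >= min_marker_frac && depth > 0
    data.frame(clade = marker_tbl$clade[idx[1]], n_markers = length(idx),
               frac_markers_hit = frac_hit,
               depth = if (detected) depth else 0,
               detected = detected, stringsAsFactors = FALSE)
  }))
  total <- sum(out$depth)
  out$abundance <- if (total > 0) out$depth / total else 0
  rownames(out) <- NULL
  out
}

#' Prevalence of clades across profiled samples
#'
#' Prevalence is the fraction of samples in which a clade was detected; the
#' genus-level prevalence is the fraction of samples with at least one clade
#' detected.
#'
#' @param profiles list of per-sample data frames from [profile_sample()]
#' @param grouping optional vector assigning each sample to a group
#' @return data frame: `group`, `clade` (or `"genus"`), `prevalence`, `n`
#' @export
prevalence <- function(profiles, grouping = NULL) {
  if (is.null(grouping)) grouping <- rep("all", length(profiles))
  stopifnot(length(grouping) == length(profiles))
  keep <- !is.na(grouping)
  if (!all(keep)) warning("dropping samples with empty group")
  profiles <- profiles[keep]; grouping <- grouping[keep]
  det <- t(vapply(profiles, function(p) setNames(p$detected, p$clade),
                  logical(nrow(profiles[[1]]))))
  do.call(rbind, lapply(split(seq_len(nrow(det)), grouping), function(idx) {
    sub <- det[idx, , drop = FALSE]
    rbind(data.frame(group = grouping[idx[1]], clade = colnames(sub),
                     prevalence = colMeans(sub), n = length(idx),
                     stringsAsFactors = FALSE, row.names = NULL),
          data.frame(group = grouping[idx[1]], clade = "genus",
                     prevalence = mean(rowSums(sub) > 0), n = length(idx),
                     stringsAsFactors = FALSE))
  }))
}

#' Breadth and depth of coverage per contig
#'
#' Breadth is the fraction of positions covered by at least one alignment
#' (computed by interval union); depth is total aligned bases over contig
#' length.
#'
#' @param alignments data frame with columns `target`, `pos` and either
#'   `read_len` or an `end` column (1-based inclusive)
#' @param contig_lengths named integer vector of contig lengths
#' @return data frame: `contig`, `length`, `breadth`, `mean_depth`
#' @export
coverage_summary <- function(alignments, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  if (nrow(alignments) && is.null(alignments$end))
    alignments$end <- alignments$pos + alignments$read_len - 1L
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    a <- alignments[alignments$target == ctg, , drop = FALSE]
    if (nrow(a) == 0)
      return(data.frame(contig = ctg, length = len, breadth = 0,
                        mean_depth = 0, stringsAsFactors = FALSE))
    s <- pmax(1L, a$pos); e <- pmin(len, a$end)
    ord <- order(s)
    s <- s[ord]; e <- e[ord]
    covered <- 0L; cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] <= cur_e + 1L) cur_e <- max(cur_e, e[i])
      else { covered <- covered + (cur_e - cur_s + 1L); cur_s <- s[i]; cur_e <- e[i] }
    }
    covered <- covered + (cur_e - cur_s + 1L)
    data.frame(contig = ctg, length = len, breadth = covered / len,
               mean_depth = sum(e - s + 1) / len, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect viral clusters by breadth of coverage
#'
#' A viral cluster (VC) is detected in a sample when at least one member
#' contig has breadth of coverage at least `min_breadth` (boundary
#' inclusive).
#'
#' @param vc_membership named vector: contig id -> VC id
#' @param coverage data frame from [coverage_summary()]
#' @param min_breadth inclusive breadth threshold (default 0.5)
#' @return data frame: `vc`, `max_breadth`, `detected`
#' @export
detect_vc <- function(vc_membership, coverage, min_breadth = 0.5) {
  stopifnot(all(coverage$contig %in% names(vc_membership)))
  vc <- vc_membership[coverage$contig]
  mb <- tapply(coverage$breadth, vc, max)
  data.frame(vc = names(mb), max_breadth = as.numeric(mb),
             detected = as.numeric(mb) >= min_breadth,
             stringsAsFactors = FALSE, row.names = NULL)
}
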