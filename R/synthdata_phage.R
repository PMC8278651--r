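#' Specification for synthetic phages and CRISPR loci
#'
#' @param n_phages number of phage genomes
#' @param genome_len phage genome length (nt)
#' @param pam protospacer adjacent motif planted immediately 5' of every
#'   protospacer (protospacer-strand orientation), length 2-6
#' @param n_protospacers_per_host planted spacers per host genome
#' @param spacer_edit_noise edits (substitution/insertion/deletion) applied
#'   to each planted spacer relative to its protospacer, 0-2
#' @param seed integer seed
#' @param n_random_spacers additional random (unmatched) spacers per locus
#' @param n_decoys_per_host spacers planted at exactly 3 edits from a phage
#'   window (never matchable at the <=2-edit criterion), for specificity tests
#' @param repeat_len CRISPR repeat length (28-37 per the locus contract)
#' @param spacer_len_range spacer length range (30-35)
#' @param minus_strand_frac fraction of protospacers planted on the phage
#'   minus strand
#' @param within_lineage_divergence divergence among contigs of one phage
#'   lineage when several contigs per phage are emitted
#' @return an object of class `phage_sim_spec`
#' @export
phage_sim_spec <- function(n_phages = 3, genome_len = 20000, pam = "TTC",
                           n_protospacers_per_host = 4,
                           spacer_edit_noise = 1, seed = 1,
                           n_random_spacers = 2, n_decoys_per_host = 0,
                           repeat_len = 32, spacer_len_range = c(30, 35),
                           minus_strand_frac = 0.3,
                           within_lineage_divergence = 0.03) {
  stopifnot(nchar(pam) >= 2, nchar(pam) <= 6,
            spacer_edit_noise >= 0, spacer_edit_noise <= 2,
            repeat_len >= 28, repeat_len <= 37)
  structure(list(n_phages = n_phages, genome_len = genome_len, pam = pam,
                 n_protospacers_per_host = n_protospacers_per_host,
                 spacer_edit_noise = spacer_edit_noise, seed = seed,
                 n_random_spacers = n_random_spacers,
                 n_decoys_per_host = n_decoys_per_host,
                 repeat_len = repeat_len,
                 spacer_len_range = spacer_len_range,
                 minus_strand_frac = minus_strand_frac,
                 within_lineage_divergence = within_lineage_divergence),
            class = "phage_sim_spec")
}

# apply exactly n_edits random edits; resample until the Levenshtein distance
# to the original is exactly n_edits (independent arithmetic via adist)
apply_edits <- function(seq, n_edits) {
  if (n_edits == 0) return(seq)
  repeat {
    s <- strsplit(seq, "")[[1]]
    for (e in seq_len(n_edits)) {
      op <- sample(c("sub", "ins", "del"), 1)
      pos <- sample(length(s), 1)
      if (op == "sub") s[pos] <- sample(setdiff(DNA_BASES, s[pos]), 1)
      else if (op == "ins") s <- append(s, sample(DNA_BASES, 1), after = pos)
      else if (length(s) > 1) s <- s[-pos]
    }
    out <- paste(s, collapse = "")
    if (drop(adist(seq, out)) == n_edits) return(out)
  }
}

# a decoy spacer at semi-global edit distance exactly n_edits from its source
# phage: interior substitutions only (edits at the spacer ends would be
# absorbed by the free text ends of a semi-global matcher), then verified
# against both strands of the whole phage
make_decoy <- function(protospacer, phage, n_edits = 3L) {
  repeat {
    s <- strsplit(protospacer, "")[[1]]
    pos <- sample(4:(length(s) - 3), n_edits)
    for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
    out <- paste(s, collapse = "")
    ok <- nrow(cpp_semiglobal_matches(out, phage, n_edits - 1L)) == 0 &&
      nrow(cpp_semiglobal_matches(revcomp(out), phage, n_edits - 1L)) == 0
    if (ok) return(out)
  }
}

#' Simulate phage genomes and insert CRISPR loci into host genomes
#'
#' Generates `n_phages` random phage genomes with non-overlapping protospacer
#' windows, each immediately preceded (5', protospacer orientation) by the
#' planted PAM. Each host genome receives one CRISPR locus -- a chain of
#' identical repeats alternating with spacers -- appended as an extra contig;
#' planted spacers are copies of protospacers from the clade's cognate phage
#' with at most `spacer_edit_noise` edits, mixed with random spacers (and
#' optional 3-edit decoys). Everything planted is recorded in the truth
#' table.
#'
#' @param genomes named list of [genome_record()]s
#' @param spec a [phage_sim_spec()]
#' @param clades optional named vector genome id -> clade; clades are
#'   assigned cognate phages round-robin (default: one clade)
#' @return list with `phages` (named character vector), `genomes` (records
#'   with the CRISPR contig added), `truth` (data frame of planted spacers:
#'   genome, spacer_id, spacer_seq, phage, start, end, strand, edits, type)
#'   and `protospacers` (data frame of phage windows with PAM coordinates)
#' @export
simulate_crispr_and_phages <- function(genomes, spec, clades = NULL) {
  stopifnot(inherits(spec, "phage_sim_spec"), length(genomes) > 0)
  set.seed(spec$seed)
  if (is.null(clades))
    clades <- setNames(rep("clade1", length(genomes)), names(genomes))
  pam <- toupper(spec$pam)
  pam_len <- nchar(pam)

  phage_ids <- sprintf("phage%02d", seq_len(spec$n_phages))
  phages <- setNames(vapply(seq_len(spec$n_phages), function(i)
    random_dna(spec$genome_len), character(1)), phage_ids)

  # non-overlapping protospacer windows per phage, with margin for PAM and
  # upstream context on either strand
  n_sites <- max(12, spec$n_protospacers_per_host * 4)
  proto <- list()
  for (ph in phage_ids) {
    len <- nchar(phages[[ph]])
    taken <- integer(0)
    sites <- 0
    while (sites < n_sites) {
      sl <- sample(spec$spacer_len_range[1]:spec$spacer_len_range[2], 1)
      st <- sample(seq(pam_len + 10, len - sl - pam_len - 10), 1)
      if (any(abs(st - taken) < (max(spec$spacer_len_range) + pam_len + 12))) next
      strand <- if (runif(1) < spec$minus_strand_frac) "-" else "+"
      # write the PAM immediately 5' of the protospacer in its orientation
      if (strand == "+") {
        substr(phages[[ph]], st - pam_len, st - 1) <- pam
      } else {
        substr(phages[[ph]], st + sl, st + sl + pam_len - 1) <- revcomp(pam)
      }
      window <- substring(phages[[ph]], st, st + sl - 1)
      pspacer <- if (strand == "+") window else revcomp(window)
      proto[[length(proto) + 1]] <- data.frame(
        phage = ph, start = st, end = st + sl - 1, strand = strand,
        protospacer = pspacer, stringsAsFactors = FALSE)
      taken <- c(taken, st)
      sites <- sites + 1
    }
  }
  proto <- do.call(rbind, proto)

  clade_levels <- unique(clades[names(genomes)])
  cognate <- setNames(phage_ids[(seq_along(clade_levels) - 1) %% length(phage_ids) + 1],
                      clade_levels)

  truth <- list()
  out_genomes <- genomes
  for (gid in names(genomes)) {
    g <- genomes[[gid]]
    ph <- cognate[[clades[[gid]]]]
    sites <- proto[proto$phage == ph, , drop = FALSE]
    n_p <- min(spec$n_protospacers_per_host, nrow(sites))
    pick <- if (n_p > 0) sites[sample(nrow(sites), n_p), , drop = FALSE] else sites[0, ]
    spacers <- character(0); stypes <- character(0)
    srec <- list()
    if (n_p > 0) for (i in seq_len(n_p)) {
      edits <- if (spec$spacer_edit_noise > 0)
        sample(0:spec$spacer_edit_noise, 1) else 0L
      sp <- apply_edits(pick$protospacer[i], edits)
      spacers <- c(spacers, sp); stypes <- c(stypes, "planted")
      srec[[length(srec) + 1]] <- data.frame(
        genome = gid, spacer_seq = sp, phage = ph, start = pick$start[i],
        end = pick$end[i], strand = pick$strand[i], edits = edits,
        type = "planted", stringsAsFactors = FALSE)
    }
    if (spec$n_decoys_per_host > 0) {
      dsites <- sites[sample(nrow(sites), spec$n_decoys_per_host), , drop = FALSE]
      for (i in seq_len(nrow(dsites))) {
        sp <- make_decoy(dsites$protospacer[i], phages[[ph]], n_edits = 3L)
        spacers <- c(spacers, sp); stypes <- c(stypes, "decoy")
        srec[[length(srec) + 1]] <- data.frame(
          genome = gid, spacer_seq = sp, phage = ph, start = dsites$start[i],
          end = dsites$end[i], strand = dsites$strand[i], edits = 3L,
          type = "decoy", stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(spec$n_random_spacers)) {
      sp <- random_dna(sample(spec$spacer_len_range[1]:spec$spacer_len_range[2], 1))
      spacers <- c(spacers, sp); stypes <- c(stypes, "random")
      srec[[length(srec) + 1]] <- data.frame(
        genome = gid, spacer_seq = sp, phage = NA_character_, start = NA_integer_,
        end = NA_integer_, strand = NA_character_, edits = NA_integer_,
        type = "random", stringsAsFactors = FALSE)
    }
    if (length(spacers) < 2)
      stop("locus needs at least 2 spacers (3 repeats); increase spacer counts")
    ord <- sample(length(spacers))
    spacers <- spacers[ord]
    srec <- srec[ord]
    rep_seq <- random_dna(spec$repeat_len)
    locus <- paste0(rep_seq,
                    paste(vapply(spacers, function(s) paste0(s, rep_seq),
                                 character(1)), collapse = ""))
    pad_l <- random_dna(400); pad_r <- random_dna(400)
    ctg_name <- paste0(gid, "_crispr")
    g$sequences[[ctg_name]] <- paste0(pad_l, locus, pad_r)
    out_genomes[[gid]] <- g
    srec_df <- do.call(rbind, srec)
    srec_df$spacer_id <- sprintf("%s_sp%02d", gid, seq_len(nrow(srec_df)))
    truth[[gid]] <- srec_df
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(phages = phages, genomes = out_genomes, truth = truth,
       protospacers = proto, cognate = cognate)
}

#' Simulate shotgun reads from a sequence
#'
#' Poisson-distributed read count (expectation depth x length / read_len),
#' uniform start positions, random strand, and i.i.d. substitution errors.
#'
#' @param seqs named character vector (or single string) of source sequences
#' @param depth target fold-coverage (>= 0)
#' @param read_len read length
#' @param error_rate per-base substitution error probability
#' @param seed integer seed
#' @return character vector of reads (possibly empty), named by source
#' @export
simulate_reads <- function(seqs, depth, read_len = 100L, error_rate = 0.001,
                           seed = 1) {
  stopifnot(depth >= 0)
  set.seed(seed)
  seqs <- unlist(as.list(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- character(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (read_len > L) stop("read_len exceeds length of ", nm)
    n <- rpois(1, depth * L / read_len)
    if (n == 0) next
    starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
    reads <- substring(s, starts, starts + read_len - 1L)
    flip <- runif(n) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    if (error_rate > 0) {
      reads <- vapply(reads, scatter_mutate, character(1),
                      q = error_rate * 4 / 3)
    }
    out <- c(out, setNames(reads, sprintf("%s_r%06d", nm, seq_len(n))))
  }
  out
}
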