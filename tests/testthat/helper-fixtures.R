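# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the standard 5-species x 20-genome pangenome used by the marker and SGB
# checks (interspecies ANI 88%, conserved core, planted unique genes)
pangenome_fixture <- function() {
  fixture("pangenome", function() {
    sim <- simulate_species_genomes(species_sim_spec(seed = 42))
    clades <- setNames(sim$truth$species$species, sim$truth$species$genome_id)
    gene_tbl <- do.call(rbind, lapply(sim$genomes, function(g) {
      s <- extract_gene_seqs(g, classes = c("core", "operon", "unique",
                                            "accessory"))
      data.frame(gene_id = names(s), genome_id = g$id, seq = unname(s),
                 stringsAsFactors = FALSE)
    }))
    fams <- cluster_families(gene_tbl)
    cores <- core_genes(fams$presence, clades)
    genomes_by_clade <- split(sim$genomes, clades[names(sim$genomes)])
    family_seqs <- setNames(fams$families$centroid_seq,
                            fams$families$family_id)
    markers <- select_markers(cores, family_seqs, genomes_by_clade)
    list(sim = sim, clades = clades, fams = fams, cores = cores,
         genomes_by_clade = genomes_by_clade, family_seqs = family_seqs,
         markers = markers)
  })
}

# small 2-species set with CRISPR loci and phages
crispr_fixture <- function() {
  fixture("crispr", function() {
    sim <- simulate_species_genomes(
      species_sim_spec(n_species = 2, n_genomes_per_species = 3, seed = 5))
    clades <- setNames(sim$truth$species$species, sim$truth$species$genome_id)
    ph <- simulate_crispr_and_phages(
      sim$genomes,
      phage_sim_spec(seed = 11, n_decoys_per_host = 1, spacer_edit_noise = 2),
      clades = clades)
    arrays <- do.call(rbind, lapply(ph$genomes, detect_arrays))
    list(sim = sim, clades = clades, ph = ph, arrays = arrays)
  })
}

# exact Jaccard of canonical k-mer sets, computed from the k-mer strings
# themselves (independent of the hashing path)
exact_canonical_jaccard <- function(a, b, k = 21) {
  kmer_set <- function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1), k:n)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    unique(ifelse(km <= rc, km, rc))
  }
  sa <- kmer_set(a); sb <- kmer_set(b)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# sketch-based Jaccard estimate (merged bottom-s), mirroring the Mash
# estimator's j so it can be compared against the exact oracle
sketch_jaccard <- function(sa, sb) {
  u <- sort(unique(c(sa$hashes, sb$hashes)))
  u <- u[seq_len(min(sa$s, length(u)))]
  sum(u %in% sa$hashes & u %in% sb$hashes) / length(u)
}

# brute-force semi-global minimum edit distance of a pattern in a text via
# adist over all windows (quadratic oracle)
oracle_semiglobal <- function(pattern, text, slack = 6) {
  m <- nchar(pattern); n <- nchar(text)
  best <- Inf
  for (len in max(1, m - slack):min(n, m + slack)) {
    if (len > n) next
    subs <- substring(text, 1:(n - len + 1), len:n)
    best <- min(best, min(adist(pattern, subs)))
  }
  best
}

# exhaustive Dollo oracle: root present, no absent->present edge, minimize
# present->absent transitions over all internal-state assignments
oracle_dollo <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  states <- logical(ntip + nint)
  states[seq_len(ntip)] <- as.logical(presence[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    st <- states
    st[ntip + seq_len(nint)] <- bitwAnd(mask, 2^(seq_len(nint) - 1)) > 0
    if (!st[ntip + 1]) next  # root must be present (single origin)
    losses <- 0L; ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- st[tree$edge[e, 1]]; ch <- st[tree$edge[e, 2]]
      if (!p && ch) { ok <- FALSE; break }   # regain forbidden
      if (p && !ch) losses <- losses + 1L
    }
    if (ok) best <- min(best, losses)
  }
  best
}

# random additive distance matrix from a random tree with known branch
# lengths
random_additive_dm <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}
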