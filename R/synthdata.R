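#' Specification for a synthetic multi-species genome collection
#'
#' Describes a set of species-level clades with controlled average nucleotide
#' identity (ANI), a deliberately conserved 16S-like gene, and a planted
#' core/accessory pangenome with clade-unique marker genes.
#'
#' Two substitution-rate regimes are supported. In the default `"two-class"`
#' regime core genes (and a corrin-like operon) evolve slowly
#' (`core_gene_divergence` between species) while intergenic sequence evolves
#' fast enough that the genome-wide identity matches `ani`; this mirrors real
#' bacterial genomes, where housekeeping genes are far more conserved than the
#' genomic background, and it is what makes clade-unique genes the *only*
#' sequences that pass a fragment-level exclusivity screen. In the
#' `"uniform"` regime every site (except the 16S gene) evolves at the single
#' rate implied by `ani`, which makes ANI a well-defined per-site quantity --
#' the regime used to validate MinHash ANI estimation.
#'
#' @param n_species number of species-level clades
#' @param ani genome-wide identity between species: either a single fraction
#'   applied to every pair or a symmetric matrix with unit diagonal
#' @param n_genomes_per_species genomes per clade (recycled)
#' @param core_fraction fraction of each clade's gene families that are core
#' @param n_unique_genes_per_species planted clade-unique (marker-truth) genes
#' @param rrna_divergence upper bound on pairwise 16S divergence; must be
#'   smaller than the smallest interspecies divergence
#' @param seed integer seed; all outputs are deterministic given it
#' @param n_core_genes shared single-copy core genes
#' @param gene_len,intergenic_len,rrna_len element lengths (nt)
#' @param core_gene_divergence realized interspecies divergence of core genes
#'   in the two-class regime (`NULL` selects the uniform regime)
#' @param within_divergence pairwise divergence between genomes of a species
#' @param accessory_presence per-genome presence probability of accessory
#'   (non-core) clade genes
#' @param n_operon_genes,operon_loss_species corrin-like operon planted in the
#'   conserved class and deleted wholesale from the listed species (indices),
#'   for gene-loss parsimony and gene-set screening tests
#' @return an object of class `species_sim_spec`
#' @export
species_sim_spec <- function(n_species = 5, ani = 0.88,
                             n_genomes_per_species = 20,
                             core_fraction = 0.8,
                             n_unique_genes_per_species = 8,
                             rrna_divergence = 0.015,
                             seed = 1,
                             n_core_genes = 30,
                             gene_len = 900,
                             intergenic_len = 300,
                             rrna_len = 1500,
                             core_gene_divergence = 0.04,
                             within_divergence = 0.005,
                             accessory_presence = 0.4,
                             n_operon_genes = 8,
                             operon_loss_species = c(1, 2, 3)) {
  if (is.matrix(ani)) {
    stopifnot(nrow(ani) == n_species, isSymmetric(ani),
              all(diag(ani) == 1))
    ani_matrix <- ani
  } else {
    stopifnot(length(ani) == 1, ani > 0, ani < 1)
    ani_matrix <- matrix(ani, n_species, n_species)
    diag(ani_matrix) <- 1
  }
  stopifnot(core_fraction > 0, core_fraction <= 1,
            rrna_divergence > 0, within_divergence >= 0)
  if (n_species > 1) {
    min_div <- min(1 - ani_matrix[upper.tri(ani_matrix)])
    if (rrna_divergence >= min_div)
      stop("infeasible spec: rrna_divergence (", rrna_divergence,
           ") must be below the smallest interspecies divergence (",
           signif(min_div, 3), ")")
    if (!is.null(core_gene_divergence) && core_gene_divergence >= min_div)
      stop("infeasible spec: core_gene_divergence must be below the ",
           "interspecies divergence implied by the ANI matrix")
  }
  operon_loss_species <- operon_loss_species[operon_loss_species <= n_species]
  structure(list(
    n_species = n_species, ani_matrix = ani_matrix,
    n_genomes_per_species = rep_len(n_genomes_per_species, n_species),
    core_fraction = core_fraction,
    n_unique_genes_per_species = n_unique_genes_per_species,
    rrna_divergence = rrna_divergence, seed = seed,
    n_core_genes = n_core_genes, gene_len = gene_len,
    intergenic_len = intergenic_len, rrna_len = rrna_len,
    core_gene_divergence = core_gene_divergence,
    within_divergence = within_divergence,
    accessory_presence = accessory_presence,
    n_operon_genes = n_operon_genes,
    operon_loss_species = operon_loss_species), class = "species_sim_spec")
}

# solve per-species branch scatter probabilities so that the pairwise
# divergence on a site class matches target_d (matrix), after accounting for
# the two within-species genome branches (scatter q_w each).
solve_branch_scatter <- function(target_d, q_w) {
  k <- nrow(target_d)
  # (1-q_i)(1-q_j)(1-q_w)^2 = 1 - (4/3) d_ij  =>  x_i + x_j = C_ij (logs)
  C <- log(pmax(1 - (4 / 3) * target_d, 1e-9)) - 2 * log(1 - q_w)
  if (k == 1) return(0)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), k)
  for (r in seq_len(nrow(pairs))) A[r, pairs[r, ]] <- 1
  x <- if (nrow(pairs) >= k) as.vector(qr.solve(A, C[pairs]))
       else rep(C[pairs][1] / 2, k)  # two species: split evenly
  q <- 1 - exp(pmin(x, 0))
  if (any(q > 0.9999)) stop("infeasible ANI matrix for branch solver")
  q
}

#' Simulate a genome collection with planted species structure
#'
#' Generates one circular-less (single backbone contig) genome per requested
#' genome: a shared colinear backbone of core genes, intergenic spacers and a
#' 16S-like gene, plus a per-species cassette of clade-unique and accessory
#' genes. Substitutions are i.i.d. per site with no indels inside orthologs,
#' so realized identity is analytic; gene gain/loss is whole-gene. A
#' generator self-check asserts that realized backbone identity is within
#' 0.5 percentage points of the requested ANI for every species pair.
#'
#' @param spec a [species_sim_spec()]
#' @return a list with elements `genomes` (list of `genome_record`s), `truth`
#'   (species assignment, marker-truth families, operon loss pattern, realized
#'   ANI matrix) and `families` (data frame of planted family metadata)
#' @export
simulate_species_genomes <- function(spec) {
  stopifnot(inherits(spec, "species_sim_spec"))
  set.seed(spec$seed)
  ns <- spec$n_species
  div_target <- 1 - spec$ani_matrix

  # --- ancestral elements ---------------------------------------------------
  n_core <- spec$n_core_genes
  n_op <- spec$n_operon_genes
  core_seqs <- replicate(n_core, random_dna(spec$gene_len))
  operon_seqs <- if (n_op > 0) replicate(n_op, random_dna(spec$gene_len)) else character(0)
  rrna_seq <- random_dna(spec$rrna_len)
  n_ig <- n_core + n_op + 2
  ig_seqs <- replicate(n_ig, random_dna(spec$intergenic_len))

  # backbone layout: IG (G IG)*ncore rRNA IG (OP IG)*nop
  elements <- list()
  el_class <- character(0); el_id <- character(0)
  add <- function(seq, cls, id) {
    elements[[length(elements) + 1]] <<- seq
    el_class[length(el_class) + 1] <<- cls
    el_id[length(el_id) + 1] <<- id
  }
  ig_i <- 0
  next_ig <- function() { ig_i <<- ig_i + 1; add(ig_seqs[ig_i], "intergenic", paste0("ig", ig_i)) }
  next_ig()
  for (g in seq_len(n_core)) { add(core_seqs[g], "core", sprintf("core%02d", g)); next_ig() }
  add(rrna_seq, "rrna", "rrna16S")
  next_ig()
  if (n_op > 0) for (g in seq_len(n_op)) { add(operon_seqs[g], "operon", sprintf("operon%02d", g)); next_ig() }
  el_len <- vapply(elements, nchar, integer(1))
  el_start <- cumsum(c(1L, el_len[-length(el_len)]))
  el_end <- el_start + el_len - 1L

  # --- rates ----------------------------------------------------------------
  q_w <- scatter_for_pairwise(spec$within_divergence)    # per genome branch
  slow_classes <- c("core", "operon")
  uniform <- is.null(spec$core_gene_divergence)
  if (uniform) {
    # truly homogeneous regime: every site -- the 16S gene included -- evolves
    # at the single rate implied by the target ANI, so that per-site identity
    # and k-mer survival agree (any conserved fraction, however small,
    # inflates MinHash identity estimates at low ANI)
    d_fast <- div_target
    d_slow <- div_target
  } else {
    d_slow <- matrix(spec$core_gene_divergence, ns, ns); diag(d_slow) <- 0
    # identity budget over the always-present backbone: core + 16S +
    # intergenic (the operon is excluded since it is absent in loss clades)
    L_slow <- sum(el_len[el_class == "core"])
    L_rrna <- sum(el_len[el_class == "rrna"])
    L_fast <- sum(el_len[el_class == "intergenic"])
    L_bb <- L_slow + L_rrna + L_fast
    d_rrna_t <- 0.5 * spec$rrna_divergence
    # fast-site divergence so that backbone-wide divergence hits the target
    d_fast <- (div_target * L_bb - d_slow * L_slow -
                 matrix(d_rrna_t, ns, ns) * L_rrna) / L_fast
    diag(d_fast) <- 0
    if (ns > 1 && any(d_fast[upper.tri(d_fast)] >= 0.70))
      stop("infeasible spec: target ANI too low for the conserved fraction")
    if (ns > 1 && any(d_fast[upper.tri(d_fast)] <= 0))
      stop("infeasible spec: target ANI too high given core_gene_divergence")
  }
  q_slow <- if (ns > 1) solve_branch_scatter(d_slow, q_w) else 0
  q_fast <- if (ns > 1) solve_branch_scatter(d_fast, q_w) else 0
  # 16S: species-level branches only, no within-species substitutions
  # (uniform regime: 16S evolves at the genome rate like everything else)
  d_rrna <- if (uniform) d_fast
            else { m <- matrix(0.5 * spec$rrna_divergence, ns, ns)
                   diag(m) <- 0; m }
  q_rrna <- if (ns > 1) solve_branch_scatter(d_rrna, q_w = 0) else 0

  # --- species-specific cassettes -------------------------------------------
  n_uni <- spec$n_unique_genes_per_species
  n_core_total <- n_core + n_uni  # core families of a clade (approx; operon extra)
  n_acc <- max(0L, round(n_core_total * (1 - spec$core_fraction) / spec$core_fraction))
  species_ids <- sprintf("sp%02d", seq_len(ns))
  cassette <- lapply(seq_len(ns), function(i) {
    list(unique = setNames(replicate(n_uni, random_dna(spec$gene_len)),
                           sprintf("%s_uniq%02d", species_ids[i], seq_len(n_uni))),
         acc = setNames(replicate(n_acc, random_dna(spec$gene_len)),
                        if (n_acc) sprintf("%s_acc%02d", species_ids[i], seq_len(n_acc)) else character(0)),
         igs = replicate(n_uni + n_acc, random_dna(spec$intergenic_len)))
  })

  # --- species references ---------------------------------------------------
  mutate_class <- function(seqs, classes, i) {
    vapply(seq_along(seqs), function(e) {
      q <- switch(classes[e],
                  core = , operon = if (ns > 1) q_slow[i] else 0,
                  rrna = if (ns > 1) q_rrna[i] else 0,
                  if (ns > 1) q_fast[i] else 0)
      scatter_mutate(seqs[[e]], q)
    }, character(1))
  }
  sp_refs <- lapply(seq_len(ns), function(i) {
    bb <- mutate_class(elements, el_class, i)
    uni <- cassette[[i]]$unique
    acc <- cassette[[i]]$acc
    list(bb = bb, uni = uni, acc = acc)
  })

  # --- genomes --------------------------------------------------------------
  genomes <- list()
  species_of <- character(0)
  sp_bb <- vector("list", ns)  # first genome's backbone elements, for self-check
  gene_strand_pool <- c("+", "+", "+", "-")  # ~25% minus-strand genes
  for (i in seq_len(ns)) {
    drop_operon <- i %in% spec$operon_loss_species
    for (g in seq_len(spec$n_genomes_per_species[i])) {
      gid <- sprintf("%s_g%03d", species_ids[i], g)
      ref <- sp_refs[[i]]
      bb <- vapply(seq_along(ref$bb), function(e) {
        qw <- if (el_class[e] == "rrna") 0 else q_w
        scatter_mutate(ref$bb[e], qw)
      }, character(1))
      if (g == 1) sp_bb[[i]] <- setNames(bb, el_id)
      keep_el <- if (drop_operon) el_class != "operon" else rep(TRUE, length(bb))
      # drop operon intergenic partners too? keep spacers: only genes dropped
      bb_seqs <- bb[keep_el]
      bb_class <- el_class[keep_el]
      bb_id <- el_id[keep_el]
      # cassette genes for this genome
      uni_keep <- rep(TRUE, n_uni)
      acc_keep <- if (n_acc) runif(n_acc) < spec$accessory_presence else logical(0)
      cas_seqs <- c(ref$uni[uni_keep],
                    if (n_acc) ref$acc[acc_keep] else character(0))
      cas_seqs <- vapply(cas_seqs, scatter_mutate, character(1), q = q_w)
      cas_ids <- c(names(ref$uni)[uni_keep],
                   if (n_acc) names(ref$acc)[acc_keep] else character(0))
      cas_class <- c(rep("unique", sum(uni_keep)), rep("accessory", sum(acc_keep)))
      # interleave cassette genes with species-level intergenic spacers
      cas_parts <- character(0); cas_pid <- character(0); cas_pclass <- character(0)
      for (e in seq_along(cas_seqs)) {
        ig <- scatter_mutate(cassette[[i]]$igs[e], q_w)
        cas_parts <- c(cas_parts, cas_seqs[e], ig)
        cas_pid <- c(cas_pid, cas_ids[e], paste0("casig", e))
        cas_pclass <- c(cas_pclass, cas_class[e], "intergenic")
      }
      all_seqs <- c(bb_seqs, cas_parts)
      all_class <- c(bb_class, cas_pclass)
      all_id <- c(bb_id, cas_pid)
      # strands: deterministic per family so orthologs share orientation
      strands <- ifelse(all_class %in% c("intergenic"), "+",
                        gene_strand_pool[(match(all_id, c(el_id, names(ref$uni),
                                                          names(ref$acc))) %% 4) + 1])
      emit <- ifelse(strands == "-", revcomp(all_seqs), all_seqs)
      lens <- nchar(emit)
      starts <- cumsum(c(1L, lens[-length(lens)]))
      ends <- starts + lens - 1L
      chrom <- paste(emit, collapse = "")
      is_gene <- all_class != "intergenic"
      ann <- data.frame(
        gene_id = paste0(gid, ":", all_id[is_gene]),
        contig = "chr", start = starts[is_gene], end = ends[is_gene],
        strand = strands[is_gene], family_label = all_id[is_gene],
        class = all_class[is_gene], stringsAsFactors = FALSE)
      genomes[[gid]] <- genome_record(
        id = gid, sequences = list(chr = chrom),
        completeness = round(runif(1, 95, 100), 1),
        contamination = round(runif(1, 0, 2), 1),
        source_host = "human", gene_annotations = ann)
      species_of[gid] <- species_ids[i]
    }
  }

  # --- truth + self-check ---------------------------------------------------
  truth_species <- data.frame(genome_id = names(species_of),
                              species = unname(species_of),
                              stringsAsFactors = FALSE)
  truth_markers <- do.call(rbind, lapply(seq_len(ns), function(i)
    data.frame(species = rep(species_ids[i], n_uni),
               family = names(cassette[[i]]$unique),
               stringsAsFactors = FALSE)))
  operon_presence <- setNames(!(seq_len(ns) %in% spec$operon_loss_species),
                              species_ids)

  realized <- realized_backbone_ani(sp_bb, species_ids,
                                    el_id[el_class != "operon"])
  if (ns > 1) {
    # realized identity fluctuates binomially around the target; allow the
    # larger of 0.5 percentage points and 4.5 binomial SDs of the backbone
    L_bb_chk <- sum(nchar(sp_bb[[1]][el_id[el_class != "operon"]]))
    dev <- abs(realized - spec$ani_matrix)
    div <- 1 - spec$ani_matrix
    tol <- pmax(0.005, 4.5 * sqrt(div * (1 - div) / L_bb_chk))
    if (any(dev[upper.tri(dev)] > tol[upper.tri(tol)]))
      stop("generator self-check failed: realized ANI off by ",
           signif(max(dev[upper.tri(dev)]), 3))
  }

  fam <- data.frame(
    family = c(el_id[el_class %in% c("core", "operon", "rrna")],
               unlist(lapply(cassette, function(cs) c(names(cs$unique), names(cs$acc))))),
    class = c(el_class[el_class %in% c("core", "operon", "rrna")],
              unlist(lapply(cassette, function(cs)
                c(rep("unique", length(cs$unique)), rep("accessory", length(cs$acc)))))),
    stringsAsFactors = FALSE)

  list(genomes = genomes,
       truth = list(species = truth_species, markers = truth_markers,
                    operon_presence = operon_presence,
                    realized_ani = realized, spec = spec),
       families = fam)
}

# realized per-site identity on the always-present colinear backbone (core
# genes, intergenic spacers, 16S; the operon is excluded since it is deleted
# in some clades), computed between the first genome of each species pair
realized_backbone_ani <- function(sp_bb, species_ids, keep_ids) {
  ns <- length(species_ids)
  out <- matrix(1, ns, ns, dimnames = list(species_ids, species_ids))
  if (ns < 2) return(out)
  cat_bb <- vapply(sp_bb, function(bb) paste(bb[keep_ids], collapse = ""),
                   character(1))
  for (i in 1:(ns - 1)) for (j in (i + 1):ns)
    out[i, j] <- out[j, i] <- seq_identity(cat_bb[i], cat_bb[j])
  out
}
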