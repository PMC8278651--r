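#' Default pipeline configuration
#'
#' One nested list holding every stage threshold with its published default:
#' QC 90/5, SGB cut 0.05, family clustering 90/80, core fraction 0.80,
#' marker exclusivity 0.01, 150-nt fragments, spacer edit bound 2, VC breadth
#' 0.5, subspecies identity 0.98, ordination prevalence filter 0.03, 10% FDR,
#' VC differential-abundance alpha 0.01 and the 5%/10% interaction fractions.
#'
#' @param seed master seed; every stage derives its own stream from it
#' @return a `run_config` list
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    stages = list(genomes = TRUE, sgb = TRUE, markers = TRUE, profile = TRUE,
                  crispr = TRUE, stats = TRUE, phylo = TRUE),
    qc = list(min_completeness = 90, max_contamination = 5),
    sgb = list(k = 21, sketch_size = 1000, threshold = 0.05),
    rrna = list(min_len = 1000, contaminant_identity = 0.98),
    families = list(identity = 0.90, coverage = 0.80),
    markers = list(core_fraction = 0.80, exclusivity = 0.01,
                   frag_len = 150, max_mm = 5),
    profile = list(min_score = -50, min_marker_frac = 0.2, trim = 0.1),
    crispr = list(max_edit = 2, upstream_n = 5, min_breadth = 0.5,
                  consider_frac = 0.05, interact_frac = 0.10),
    stats = list(fdr = 0.10, vc_alpha = 0.01),
    phylo = list(subspecies_identity = 0.98, subspecies_min_size = 3,
                 pcoa_prevalence = 0.03),
    sim = list(n_species = 5, n_genomes = 4, ani = 0.88,
               n_phages = 3, n_mixture_samples = 4)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and thresholds outside their documented domain.
#'
#' @param config a `run_config` list
#' @return the config, invisibly, or an error
#' @export
validate_config <- function(config) {
  ref <- default_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  for (sec in setdiff(names(ref), c("seed", "stages", "sim"))) {
    extra <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(extra))
      stop("unknown key(s) in '", sec, "': ", paste(extra, collapse = ", "))
  }
  frac01 <- function(x) is.numeric(x) && x >= 0 && x <= 1
  with(config, {
    stopifnot(qc$min_completeness >= 0, qc$min_completeness <= 100,
              qc$max_contamination >= 0, qc$max_contamination <= 100,
              sgb$threshold > 0, sgb$threshold < 1,
              frac01(families$identity), frac01(families$coverage),
              frac01(markers$core_fraction), frac01(markers$exclusivity),
              markers$frag_len > 0,
              crispr$max_edit >= 0, frac01(crispr$min_breadth),
              frac01(crispr$consider_frac), frac01(crispr$interact_frac),
              frac01(stats$fdr), frac01(phylo$pcoa_prevalence),
              frac01(phylo$subspecies_identity))
  })
  invisible(config)
}

#' Run the full pipeline on synthetic data
#'
#' Executes every stage in dependency order on generated data with known
#' ground truth: genome simulation and QC, MinHash/SGB clustering, 16S
#' distances, gene-family clustering, core-gene and marker selection,
#' profiling of planted read mixtures, CRISPR-phage simulation with spacer
#' matching and PAM reconstruction, viral-cluster detection, cohort
#' meta-analysis and co-exclusion, and the phylogenetic stage (NJ tree,
#' gene-loss parsimony, ordination). Stage outputs are written as TSV files
#' stamped with the package version and a config hash; identical config and
#' seed reproduce identical outputs.
#'
#' @param config a `run_config`, see [default_config()]
#' @param outdir output directory (created if needed)
#' @return list of in-memory stage results, invisibly
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("akkrun")) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ver <- as.character(utils::packageVersion("akkpop"))
  stamp <- c(paste0("akkpop ", ver),
             paste0("config ", fnv1a_hash(paste(deparse(config), collapse = ""))),
             paste0("seed ", config$seed))
  log_msg <- function(...) message("[akkpop] ", ...)
  res <- list()

  # --- synthetic genomes ----------------------------------------------------
  log_msg("simulating ", config$sim$n_species, " species x ",
          config$sim$n_genomes, " genomes")
  spec <- species_sim_spec(n_species = config$sim$n_species,
                           ani = config$sim$ani,
                           n_genomes_per_species = config$sim$n_genomes,
                           seed = derive_seed(config$seed, "genomes"))
  sim <- simulate_species_genomes(spec)
  res$sim <- sim
  genomes <- qc_filter(sim$genomes, config$qc$min_completeness,
                       config$qc$max_contamination)

  # --- SGBs and 16S ---------------------------------------------------------
  dm <- mash_matrix(genomes, k = config$sgb$k, s = config$sgb$sketch_size)
  sgbs <- cluster_sgbs(dm, config$sgb$threshold)
  res$sgbs <- sgbs
  write_tsv(data.frame(genome_id = names(sgbs), sgb = sgbs),
            file.path(outdir, "sgb_assignments.tsv"), stamp)
  rr <- lapply(genomes, function(g) extract_gene_seqs(g, classes = "rrna"))
  rr <- unlist(rr)
  names(rr) <- sub("\\..*$", "", names(rr))
  rrna_dm <- rrna_distances(rr, min_len = config$rrna$min_len)
  res$rrna_max_distance <- max(rrna_dm)

  # --- pangenome + markers --------------------------------------------------
  log_msg("clustering gene families")
  gene_tbl <- do.call(rbind, lapply(genomes, function(g) {
    seqs <- extract_gene_seqs(g, classes = c("core", "operon", "unique",
                                             "accessory"))
    data.frame(gene_id = names(seqs), genome_id = g$id, seq = unname(seqs),
               stringsAsFactors = FALSE)
  }))
  fams <- cluster_families(gene_tbl, config$families$identity,
                           config$families$coverage)
  cores <- core_genes(fams$presence, sgbs, config$markers$core_fraction)
  genomes_by_clade <- split(genomes, sgbs[vapply(genomes, `[[`, character(1), "id")])
  family_seqs <- setNames(fams$families$centroid_seq, fams$families$family_id)
  markers <- select_markers(cores, family_seqs, genomes_by_clade,
                            exclusivity = config$markers$exclusivity,
                            frag_len = config$markers$frag_len,
                            max_mm = config$markers$max_mm)
  res$markers <- markers
  write_tsv(data.frame(clade = rep(names(markers),
                                   vapply(markers, function(m) nrow(m$markers), 0L)),
                       family = unlist(lapply(markers, function(m) m$markers$family_id))),
            file.path(outdir, "markers.tsv"), stamp)

  # --- profiling planted mixtures -------------------------------------------
  log_msg("profiling synthetic mixtures")
  set.seed(derive_seed(config$seed, "profile"))
  clade_of_species <- sgbs[vapply(genomes, `[[`, character(1), "id")]
  profiles <- list(); mix_truth <- list()
  for (m in seq_len(config$sim$n_mixture_samples)) {
    n_cl <- sample(1:min(3, length(markers)), 1)
    cls <- sample(names(markers), n_cl)
    depths <- runif(n_cl, 2, 20)
    reads <- character(0)
    for (ci in seq_along(cls)) {
      gs <- genomes_by_clade[[cls[ci]]]
      g <- gs[[sample(length(gs), 1)]]
      reads <- c(reads, simulate_reads(g$sequences, depth = depths[ci],
                                       seed = derive_seed(config$seed,
                                                          paste0("mix", m, ci))))
    }
    profiles[[m]] <- profile_sample(reads, markers,
                                    min_marker_frac = config$profile$min_marker_frac,
                                    trim = config$profile$trim,
                                    min_score = config$profile$min_score)
    mix_truth[[m]] <- setNames(depths / sum(depths), cls)
  }
  res$profiles <- profiles
  res$mixture_truth <- mix_truth
  res$prevalence <- prevalence(profiles)

  # --- CRISPR / phages ------------------------------------------------------
  log_msg("simulating phages and matching spacers")
  clades_named <- sgbs
  ph <- simulate_crispr_and_phages(
    genomes, phage_sim_spec(seed = derive_seed(config$seed, "phage"),
                            n_phages = config$sim$n_phages),
    clades = clades_named)
  arrays <- do.call(rbind, lapply(ph$genomes, detect_arrays))
  spacer_seqs <- setNames(arrays$spacer, arrays$spacer_id)
  spacer_genome <- setNames(sub("_a\\d+_s\\d+$", "", arrays$spacer_id),
                            arrays$spacer_id)
  vcs <- cluster_vcs(ph$phages)
  vc_membership <- setNames(vcs$vc, vcs$contig)
  matches <- match_spacers(spacer_seqs, ph$phages,
                           max_edit = config$crispr$max_edit,
                           upstream_n = config$crispr$upstream_n)
  res$matches <- matches
  res$pam <- if (nrow(matches)) reconstruct_pam(matches) else NULL
  res$interactions <- interaction_table(matches, spacer_genome, clades_named,
                                        vc_membership,
                                        config$crispr$consider_frac,
                                        config$crispr$interact_frac)
  write_tsv(matches, file.path(outdir, "spacer_matches.tsv"), stamp)

  # --- cohorts: meta-analysis + co-exclusion --------------------------------
  log_msg("cohort statistics")
  co <- simulate_cohorts(cohort_sim_spec(seed = derive_seed(config$seed, "cohort")))
  tab <- co$table
  per_study <- lapply(split(tab, tab$study), function(d) {
    ps <- partial_spearman(d$focal_abundance, d$bmi, d[, c("age", "sex")])
    data.frame(rho = ps$rho, n = ps$n, s = ps$s)
  })
  res$meta_bmi <- meta_pool_correlations(do.call(rbind, per_study))
  res$coexclusion <- coexclusion(as.matrix(tab[, co$truth$species]),
                                 fdr = config$stats$fdr)
  write_tsv(res$coexclusion$pairs, file.path(outdir, "coexclusion.tsv"), stamp)

  # --- phylogenetics --------------------------------------------------------
  log_msg("phylogenetics")
  ani <- exp(-dm)
  sp_reps <- vapply(split(names(sgbs), sgbs), `[[`, character(1), 1)
  sp_dm <- dm[sp_reps, sp_reps]
  rownames(sp_dm) <- colnames(sp_dm) <- names(sp_reps)
  if (nrow(sp_dm) >= 3) {
    res$species_tree <- nj_tree(sp_dm)
    op_pres <- sim$truth$operon_presence
    sp_of_rep <- sim$truth$species$species[match(sp_reps, sim$truth$species$genome_id)]
    pres <- setNames(op_pres[sp_of_rep], names(sp_reps))
    res$operon_losses <- gene_loss_parsimony(res$species_tree, pres)
  }
  res$pcoa <- jaccard_pcoa(fams$presence,
                           min_prevalence = config$phylo$pcoa_prevalence)
  write_tsv(data.frame(genome = rownames(res$pcoa$coordinates),
                       res$pcoa$coordinates),
            file.path(outdir, "pcoa.tsv"), stamp)

  log_msg("done; outputs in ", outdir)
  res$outdir <- outdir
  invisible(res)
}
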