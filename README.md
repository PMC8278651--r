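# akkpop

Population genomics of closely related gut bacterial species complexes, built
around the *Akkermansia* genus as the motivating system. Five candidate
species of *Akkermansia* co-inhabit the human gut while sharing a nearly
identical 16S rRNA gene (<2% divergence) despite genome-wide identities of
only 85–90%, almost never co-occur in the same host, and carry CRISPR spacers
that record their encounters with gut phages. `akkpop` implements the full
analytical chain needed to study such a complex from genome collections and
metagenomes:

- **Species delineation** — bottom-*s* MinHash sketches of canonical k-mers
  with the Mash distance estimator `d = -ln(2j/(1+j))/k`, average-linkage
  clustering into species-level genome bins (SGBs) at 5% distance, and
  global-alignment 16S distance analysis with length (>1000 nt) and
  contaminant (>98% foreign identity) filters.
- **Pangenome and markers** — greedy centroid gene-family clustering
  (>90% identity over >80% of the centroid), per-clade core genes (≥80%
  presence), and clade-specific marker selection: core genes whose 150-nt
  fragments are found in more than 1% of any other clade's genomes are
  rejected.
- **Metagenomic profiling** — seed-and-extend read mapping against marker
  genes (alignment score −6 per mismatch, reads kept above −50), robust
  trimmed-mean marker depth, relative abundances and prevalences; breadth-
  of-coverage detection of viral clusters (detected at ≥50% breadth).
- **CRISPR–phage interactions** — a repeat-chain CRISPR array finder, Cas
  locus typing (type I-C with a split-strand "novel variant" flag, type
  II-C), viral-contig filters and two-stage viral clustering (70% identity,
  then one-third-of-length at 90%), semi-global spacer matching at edit
  distance ≤2, and PAM reconstruction from upstream contexts (the planted
  and recovered type I-C motif is TTC).
- **Ecology and epidemiology** — partial Spearman correlations pooled
  across studies with Fisher-Z / Paule-Mandel random-effects meta-analysis,
  covariate-adjusted standardized mean differences, co-exclusion analysis
  with BH correction at 10% FDR, and Wilcoxon tests with generalized fold
  changes for phage–host differential abundance.
- **Phylogenetics** — neighbor-joining trees, subspecies delineation
  (≥98% core identity, monophyly, minimum size), Dollo gene-loss parsimony
  for the corrin-ring (vitamin B12) operon, distance–distance Mantel
  correlation, and Jaccard PCoA of gene content with a 3% prevalence filter.
- **Synthetic data with ground truth** — seeded generators for genome
  collections at controlled ANI with a conserved 16S gene and planted
  clade-unique genes, CRISPR loci with protospacers copied from synthetic
  phages (≤2 edits, planted PAM), shotgun reads, and multi-study cohorts
  with planted partial correlations, between-study heterogeneity and
  co-exclusion odds. Every planted feature is recorded in machine-readable
  truth tables so each stage can be validated exactly.

## Worked example

Simulate a five-species collection (20 genomes per species, 88% interspecies
identity, conserved 16S), recover the species, select markers, and profile a
planted 70:30 mixture:

```r
library(akkpop)

sim <- simulate_species_genomes(species_sim_spec(seed = 42))
dm  <- mash_matrix(sim$genomes)            # pairwise Mash distances
sgb <- cluster_sgbs(dm, threshold = 0.05)
truth <- setNames(sim$truth$species$species, sim$truth$species$genome_id)
table(sgb, truth[names(sgb)])
#> sgb     sp01 sp02 sp03 sp04 sp05
#>   SGB01   20    0    0    0    0
#>   SGB02    0   20    0    0    0
#>   SGB03    0    0   20    0    0
#>   SGB04    0    0    0   20    0
#>   SGB05    0    0    0    0   20
```

Each SGB contains exactly the 20 genomes of one planted species: the Mash
distances between species (~0.06–0.08) sit well above the 0.05 species cut,
the within-species distances (~0.005) well below it. Marker-based profiling
of a read mixture then recovers the planted composition:

```r
genes <- do.call(rbind, lapply(sim$genomes, function(g) {
  s <- extract_gene_seqs(g, classes = c("core", "operon", "unique", "accessory"))
  data.frame(gene_id = names(s), genome_id = g$id, seq = unname(s))
}))
fams    <- cluster_families(genes)
cores   <- core_genes(fams$presence, sgb)
markers <- select_markers(cores,
                          setNames(fams$families$centroid_seq,
                                   fams$families$family_id),
                          split(sim$genomes, sgb[names(sim$genomes)]))

reads <- c(simulate_reads(sim$genomes$sp01_g002$sequences, depth = 14, seed = 1),
           simulate_reads(sim$genomes$sp03_g005$sequences, depth = 6,  seed = 2))
profile_sample(reads, markers)[, c("clade", "detected", "abundance")]
#>   clade detected abundance
#> 1 SGB01     TRUE 0.6900958
#> 2 SGB02    FALSE 0.0000000
#> 3 SGB03     TRUE 0.3099042
#> 4 SGB04    FALSE 0.0000000
#> 5 SGB05    FALSE 0.0000000
```

The recovered abundances (0.690 / 0.310) match the planted 70:30 mixture to
within the profiler's documented ±0.05 error. `run_pipeline(default_config())`
chains all stages (genomes → SGBs → markers → profiles → CRISPR/phages →
cohort statistics → phylogenetics) on synthetic data and writes stamped TSV
outputs; reruns with the same config and seed are byte-identical.

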