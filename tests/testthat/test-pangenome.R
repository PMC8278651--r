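test_that("greedy family clustering follows the identity/coverage contract", {
  set.seed(20)
  g <- random_dna(600)
  genes <- data.frame(
    gene_id = paste0("g", 1:5),
    genome_id = paste0("G", 1:5),
    seq = c(g, g, g, g, g), stringsAsFactors = FALSE)
  cf <- cluster_families(genes)
  expect_equal(nrow(cf$families), 1)
  expect_equal(sum(cf$presence), 5)

  # two genes at ~85% identity split into two families
  far <- akkpop:::scatter_mutate(g, 0.20)  # ~15% divergence
  cf2 <- cluster_families(data.frame(gene_id = c("a", "b"),
                                     genome_id = c("G1", "G2"),
                                     seq = c(g, far)))
  expect_equal(nrow(cf2$families), 2)

  # high identity but only 75% centroid coverage -> new family
  frag <- substr(g, 1, 450)
  cf3 <- cluster_families(data.frame(gene_id = c("a", "b"),
                                     genome_id = c("G1", "G2"),
                                     seq = c(g, frag)))
  expect_equal(nrow(cf3$families), 2)

  # near-identical full-length gene joins
  near <- akkpop:::scatter_mutate(g, 0.02)
  cf4 <- cluster_families(data.frame(gene_id = c("a", "b"),
                                     genome_id = c("G1", "G2"),
                                     seq = c(g, near)))
  expect_equal(nrow(cf4$families), 1)

  # determinism under input permutation (longest-first with lexicographic
  # tie-break makes order irrelevant)
  set.seed(21)
  pool <- replicate(12, akkpop:::scatter_mutate(g, sample(c(0.01, 0.3), 1)))
  genes5 <- data.frame(gene_id = paste0("g", 1:12),
                       genome_id = paste0("G", 1:12), seq = pool)
  cf5a <- cluster_families(genes5)
  cf5b <- cluster_families(genes5[sample(12), ])
  expect_identical(cf5a$presence[rownames(cf5b$presence),
                                 colnames(cf5b$presence)], cf5b$presence)
})

test_that("core gene calling uses the inclusive 80% boundary", {
  pm <- matrix(0L, 10, 3, dimnames = list(paste0("g", 1:10),
                                          c("f1", "f2", "f3")))
  pm[, "f1"] <- 1L            # everywhere
  pm[1:8, "f2"] <- 1L         # exactly 80%
  pm[1:7, "f3"] <- 1L         # 70%
  clades <- setNames(rep("A", 10), rownames(pm))
  cg <- core_genes(pm, clades, 0.80)
  expect_setequal(cg$A, c("f1", "f2"))

  # random matrix equals the brute-force per-column count
  set.seed(6)
  pm2 <- matrix(rbinom(20 * 50, 1, 0.6), 20, 50,
                dimnames = list(paste0("g", 1:20), paste0("f", 1:50)))
  clades2 <- setNames(rep(c("A", "B"), each = 10), rownames(pm2))
  cg2 <- core_genes(pm2, clades2, 0.8)
  brute <- colnames(pm2)[colSums(pm2[1:10, ]) >= 8]
  expect_setequal(cg2$A, brute)
  expect_error(core_genes(pm, setNames(rep("A", 10), paste0("x", 1:10))))
})

test_that("fragment presence obeys the <=5 mismatch / 150 nt contract", {
  set.seed(7)
  gene <- random_dna(450)
  genome <- paste0(random_dna(2000), gene, random_dna(2000))
  expect_true(fragment_presence(gene, genome))
  expect_true(fragment_presence(gene, revcomp(genome)))
  expect_false(fragment_presence(random_dna(450), genome))

  # plant exactly 3 substitutions inside one fragment of an otherwise
  # foreign gene: that fragment still maps
  foreign <- random_dna(450)
  f2 <- strsplit(foreign, "")[[1]]
  f2[c(200, 220, 240)] <- vapply(f2[c(200, 220, 240)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  genome2 <- paste0(random_dna(1000),
                    substr(paste(f2, collapse = ""), 151, 300),
                    random_dna(1000))
  expect_true(fragment_presence(foreign, genome2))
  # 6 substitutions in every fragment -> absent
  f3 <- strsplit(foreign, "")[[1]]
  for (off in c(0, 150, 300))
    f3[off + c(10, 35, 60, 85, 110, 135)] <- vapply(
      f3[off + c(10, 35, 60, 85, 110, 135)], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  genome3 <- paste0(random_dna(500), paste(f3, collapse = ""), random_dna(500))
  expect_false(fragment_presence(foreign, genome3))
  expect_message(fragment_presence(random_dna(80), genome), "whole-gene")
})

test_that("marker selection recovers exactly the planted unique genes", {
  px <- pangenome_fixture()
  mk <- px$markers
  cg <- setNames(px$fams$families$centroid_gene, px$fams$families$family_id)
  truth <- px$sim$truth$markers
  for (cl in names(mk)) {
    got <- sort(unname(sub(".*:", "", cg[mk[[cl]]$markers$family_id])))
    want <- sort(truth$family[truth$species == cl])
    expect_identical(got, want)
  }
})

test_that("marker exclusivity is inclusive at exactly 1%", {
  set.seed(8)
  gene <- random_dna(300)
  own <- lapply(1:3, function(i)
    genome_record(paste0("A", i), paste0(random_dna(200), gene,
                                         random_dna(200))))
  # 100 other-clade genomes, exactly one carrying the gene -> fraction 0.01
  other <- lapply(1:100, function(i) {
    s <- if (i == 1) paste0(random_dna(100), gene, random_dna(100))
         else random_dna(500)
    genome_record(paste0("B", i), s)
  })
  core_lists <- list(A = "fam1", B = character(0))
  mk <- suppressWarnings(select_markers(
    core_lists, c(fam1 = gene), list(A = own, B = other)))
  expect_identical(mk$A$markers$family_id, "fam1")
  # two carriers (2%) -> excluded
  other2 <- other
  other2[[2]] <- genome_record("B2", paste0(random_dna(100), gene,
                                            random_dna(100)))
  mk2 <- suppressWarnings(select_markers(
    core_lists, c(fam1 = gene), list(A = own, B = other2)))
  expect_equal(nrow(mk2$A$markers), 0)
})

test_that("single-clade marker selection is vacuous", {
  set.seed(9)
  gene <- random_dna(300)
  own <- lapply(1:2, function(i)
    genome_record(paste0("A", i), paste0(random_dna(50), gene)))
  mk <- select_markers(list(A = "f"), c(f = gene), list(A = own))
  expect_identical(mk$A$markers$family_id, "f")
})

test_that("gene-set screening applies the coverage-at-identity rule", {
  set.seed(10)
  ref <- random_dna(1000)
  g_in <- genome_record("in", paste0(random_dna(300), ref, random_dna(300)))
  g_part <- genome_record("part", paste0(random_dna(300),
                                         substr(ref, 1, 400),
                                         random_dna(300)))
  g_out <- genome_record("out", random_dna(1600))
  pres <- screen_gene_set(list(g_in, g_part, g_out), c(ref = ref),
                          min_identity = 0.70, min_coverage = 0.50)
  expect_equal(unname(pres[, "ref"]), c(1L, 0L, 0L))
  expect_error(screen_gene_set(list(g_in), character(0)), "empty")

  # planted corrin-like operon loss pattern is recovered by screening
  px <- pangenome_fixture()
  reps <- vapply(split(names(px$clades), px$clades), `[[`, character(1), 1)
  operon_refs <- extract_gene_seqs(px$sim$genomes[[reps[["sp04"]]]],
                                   classes = "operon")
  names(operon_refs) <- sub(".*:", "", names(operon_refs))
  scr <- screen_gene_set(px$sim$genomes[reps], operon_refs)
  carried <- rowSums(scr) == length(operon_refs)
  want <- px$sim$truth$operon_presence[px$clades[reps]]
  expect_identical(unname(carried), unname(want))
})

test_that("operon archetype assignment picks the better-supported set", {
  set.seed(12)
  a_genes <- setNames(replicate(3, random_dna(400)), paste0("a", 1:3))
  b_genes <- setNames(replicate(3, random_dna(400)), paste0("b", 1:3))
  gA <- genome_record("gA", paste0(random_dna(100),
                                   paste(a_genes, collapse = ""),
                                   random_dna(100)))
  gN <- genome_record("gN", random_dna(1500))
  expect_identical(assign_operon_archetype(gA, a_genes, b_genes), "A")
  expect_identical(assign_operon_archetype(gN, a_genes, b_genes), "unassigned")
})
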