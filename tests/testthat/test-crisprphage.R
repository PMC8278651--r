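test_that("planted CRISPR arrays are recovered exactly", {
  set.seed(60)
  rep_seq <- random_dna(32)
  spacers <- vapply(1:4, function(i) random_dna(33), character(1))
  locus <- paste0(rep_seq, paste(vapply(spacers, function(s)
    paste0(s, rep_seq), character(1)), collapse = ""))
  contig <- paste0(random_dna(600), locus, random_dna(600))
  arr <- detect_arrays(contig)
  expect_equal(nrow(arr), 4)
  expect_setequal(arr$spacer, spacers)
  expect_identical(arr$repeat_consensus[1], rep_seq)

  # random sequence: no arrays; two repeats only: below the chain minimum
  expect_equal(nrow(detect_arrays(random_dna(5000))), 0)
  two <- paste0(random_dna(300), rep_seq, random_dna(33), rep_seq,
                random_dna(300))
  expect_equal(nrow(detect_arrays(two)), 0)

  # generator-planted loci across genomes
  cx <- crispr_fixture()
  planted <- cx$ph$truth[cx$ph$truth$type == "planted", ]
  expect_true(all(planted$spacer_seq %in% cx$arrays$spacer))
})

test_that("locus typing follows the gene-set and strand rules", {
  ic <- data.frame(name = c("Cas3", "Cas5", "Cas8c", "Cas7",
                            "Cas4", "Cas1", "Cas2"),
                   strand = c("+", "+", "+", "+", "-", "-", "-"))
  t1 <- type_locus(ic)
  expect_identical(t1$locus_type, "I-C")
  expect_true(t1$novel_variant)
  ic2 <- ic; ic2$strand <- "+"
  t2 <- type_locus(ic2)
  expect_identical(t2$locus_type, "I-C")
  expect_false(t2$novel_variant)
  t3 <- type_locus(data.frame(name = c("Cas9", "Cas1", "Cas2"),
                              strand = c("+", "+", "+")))
  expect_identical(t3$locus_type, "II-C")
  expect_identical(type_locus(data.frame(name = character(0),
                                         strand = character(0)))$locus_type,
                   "untyped")
  expect_warning(t5 <- type_locus(data.frame(name = c("Cas9", "Cas1", "Cas2",
                                                      "CasX"),
                                             strand = "+")), "unknown")
  expect_identical(t5$locus_type, "II-C")
})

test_that("viral contig filters reproduce rules (a)-(d)", {
  expect_equal(nrow(filter_viral_contigs(data.frame(
    contig = "v1", length = 2000, enrichment = 60, n_binned_same_sgb = 10,
    n_unbinned_metagenomes = 25))), 1)
  # boundary semantics
  expect_equal(nrow(filter_viral_contigs(data.frame(
    contig = "v2", length = 1500, enrichment = 60, n_binned_same_sgb = 10,
    n_unbinned_metagenomes = 25))), 0)

  set.seed(61)
  meta <- data.frame(contig = sprintf("v%d", 1:8),
                     length = sample(c(1400, 1500, 1501, 3000), 8, TRUE),
                     enrichment = sample(c(40, 50, 80), 8, TRUE),
                     n_binned_same_sgb = sample(c(5, 29, 30, 40), 8, TRUE),
                     n_unbinned_metagenomes = sample(c(10, 20, 21, 50), 8, TRUE))
  kept <- filter_viral_contigs(meta)
  brute <- meta[meta$length > 1500 & meta$enrichment >= 50 &
                  meta$n_binned_same_sgb < 30 &
                  meta$n_unbinned_metagenomes > 20, ]
  expect_identical(kept$contig, brute$contig)
  # missing metadata -> excluded, logged
  meta$enrichment[1] <- NA
  expect_message(k2 <- filter_viral_contigs(meta), "missing")
  expect_false("v1" %in% k2$contig)
  expect_identical(attr(k2, "excluded_missing"), "v1")
})

test_that("VC clustering separates lineages and merges mosaics", {
  set.seed(62)
  base_a <- random_dna(8000); base_b <- random_dna(6000)
  contigs <- c(a1 = base_a,
               a2 = akkpop:::scatter_mutate(base_a, 0.03),
               a3 = substr(akkpop:::scatter_mutate(base_a, 0.02), 1000, 7000),
               b1 = base_b,
               b2 = akkpop:::scatter_mutate(base_b, 0.04))
  vc <- cluster_vcs(contigs)
  expect_equal(length(unique(vc$vc)), 2)
  byvc <- split(vc$contig, vc$vc)
  expect_true(any(vapply(byvc, function(x)
    setequal(x, c("a1", "a2", "a3")), logical(1))))
  # identical contigs: one VC
  vc2 <- cluster_vcs(c(x = base_a, y = base_a))
  expect_equal(length(unique(vc2$vc)), 1)
  expect_identical(unique(vc2$representative), "x")

  # mosaic: 40% of a1 at ~97% identity embedded in junk -> stage-2 merge
  mosaic <- paste0(akkpop:::scatter_mutate(substr(base_a, 1, 3200), 0.015),
                   random_dna(4800))
  vc3 <- cluster_vcs(c(contigs, m = mosaic))
  expect_identical(vc3$vc[vc3$contig == "m"], vc3$vc[vc3$contig == "a1"])
})

test_that("spacer matching agrees with a brute-force Levenshtein oracle", {
  set.seed(63)
  for (rep in 1:60) {
    ctg <- random_dna(300)
    sp <- random_dna(sample(25:35, 1))
    # half the time embed a mutated copy so matches actually occur
    if (rep %% 2 == 0) {
      pos <- sample(100, 1)
      ins <- akkpop:::apply_edits(sp, sample(0:2, 1))
      ctg <- paste0(substr(ctg, 1, pos), ins,
                    substr(ctg, pos + 1, nchar(ctg)))
    }
    hits <- akkpop:::cpp_semiglobal_matches(sp, ctg, 2L)
    oracle <- oracle_semiglobal(sp, ctg)
    if (nrow(hits) > 0) {
      expect_equal(min(hits$dist), oracle)
      # reported window really is at the reported distance
      i <- which.min(hits$dist)
      expect_equal(drop(adist(sp, substring(ctg, hits$start[i], hits$end[i]))),
                   hits$dist[i])
    } else {
      expect_gt(oracle, 2)
    }
  }
})

test_that("planted spacers match, decoys do not, and the PAM is recovered", {
  cx <- crispr_fixture()
  arr <- cx$arrays
  sp <- setNames(arr$spacer, arr$spacer_id)
  m <- match_spacers(sp, cx$ph$phages, max_edit = 2)
  matched_seqs <- sp[unique(m$spacer_id)]
  planted <- cx$ph$truth[cx$ph$truth$type == "planted", ]
  decoys <- cx$ph$truth[cx$ph$truth$type == "decoy", ]
  expect_true(all(planted$spacer_seq %in% matched_seqs))
  expect_false(any(decoys$spacer_seq %in% matched_seqs))
  expect_true(all(m$edit_distance <= 2))
  pam <- reconstruct_pam(m)
  expect_gte(pam$n_sites, 10)
  expect_identical(substring(pam$consensus, nchar(pam$consensus) - 2),
                   "TTC")
  # PFM columns sum to one
  expect_equal(unname(colSums(pam$pfm)), rep(1, ncol(pam$pfm)))

  # degenerate single-context model is one-hot
  one <- reconstruct_pam(data.frame(upstream_context = "AATTC"))
  expect_identical(one$consensus, "AATTC")
  expect_equal(unname(one$information), rep(2, 5))
  expect_error(reconstruct_pam(data.frame(upstream_context = NA_character_)),
               "no matches")
})

test_that("interaction fractions and thresholds follow the 5%/10% rules", {
  clades <- setNames(rep(c("A", "B"), each = 20),
                     sprintf("g%02d", 1:40))
  vc_membership <- c(c1 = "VC1", c2 = "VC1", c3 = "VC2")
  # 3 of 20 genomes of A hit VC1 (one twice); exactly 2 of 20 of B hit VC2
  matches <- data.frame(
    spacer_id = c("s1", "s2", "s3", "s3b", "s4", "s5"),
    contig_id = c("c1", "c2", "c1", "c2", "c3", "c3"),
    stringsAsFactors = FALSE)
  spacer_genome <- c(s1 = "g01", s2 = "g02", s3 = "g03", s3b = "g03",
                     s4 = "g21", s5 = "g22")
  it <- interaction_table(matches, spacer_genome, clades, vc_membership)
  a_vc1 <- it[it$clade == "A" & it$vc == "VC1", ]
  expect_equal(a_vc1$fraction, 0.15)
  expect_true(a_vc1$considered)
  expect_true(a_vc1$interacting)
  b_vc2 <- it[it$clade == "B" & it$vc == "VC2", ]
  expect_equal(b_vc2$fraction, 0.10)
  expect_true(b_vc2$considered)
  expect_false(b_vc2$interacting)  # strictly more than 10% required
  expect_equal(it$fraction[it$clade == "B" & it$vc == "VC1"], 0)

  # no matches at all
  it0 <- interaction_table(matches[0, ], spacer_genome, clades, vc_membership)
  expect_true(all(it0$fraction == 0))
  expect_false(any(it0$considered))
})
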