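test_that("neighbor joining recovers additive matrices exactly", {
  # hand 4-taxon additive matrix: ((a:1,b:2):1,(c:3,d:4):1)
  tr0 <- ape::read.tree(text = "((a:1,b:2):0.5,(c:3,d:4):0.5);")
  dm <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(dm)
  expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(as.vector(ape::cophenetic.phylo(tr))),
               sort(as.vector(dm)), tolerance = 1e-10)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")

  # property: random additive matrices, n <= 12
  set.seed(70)
  for (i in 1:25) {
    ra <- random_additive_dm(sample(4:12, 1))
    tr <- nj_tree(ra$dm)
    expect_equal(ape::dist.topo(ape::unroot(ra$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(ra$dm),
                                                   colnames(ra$dm)] - ra$dm)),
                 0, tolerance = 1e-8)
  }
})

test_that("NJ groups genomes by planted species", {
  px <- pangenome_fixture()
  sub <- px$sim$genomes[seq(1, 100, by = 10)]
  dm <- mash_matrix(sub)
  tr <- nj_tree(dm)
  for (sp in unique(px$clades)) {
    tips <- intersect(names(px$clades)[px$clades == sp], tr$tip.label)
    if (length(tips) >= 2)
      expect_true(ape::is.monophyletic(ape::unroot(tr), tips))
  }
})

test_that("Dollo parsimony solves the corrin-operon worked example", {
  tree <- ape::read.tree(
    text = "(Aglyc,((SGB9223,SGB9224),((Amuc,SGB9228),SGB9227)));")
  presence <- c(Aglyc = TRUE, SGB9223 = FALSE, SGB9224 = FALSE,
                Amuc = FALSE, SGB9228 = TRUE, SGB9227 = TRUE)
  res <- gene_loss_parsimony(tree, presence)
  expect_equal(res$n_losses, 2)
  expect_setequal(res$loss_branches, c("Amuc", "SGB9223+SGB9224"))
  # all present -> no losses
  allp <- gene_loss_parsimony(tree, setNames(rep(TRUE, 6), names(presence)))
  expect_equal(allp$n_losses, 0)
})

test_that("Dollo counts equal exhaustive enumeration on random instances", {
  set.seed(71)
  for (i in 1:120) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    pres <- setNames(runif(n) < 0.5, tr$tip.label)
    if (!any(pres)) pres[sample(n, 1)] <- TRUE
    expect_equal(gene_loss_parsimony(tr, pres)$n_losses,
                 oracle_dollo(tr, pres))
  }
})

test_that("Fitch option agrees with phangorn parsimony", {
  skip_if_not_installed("phangorn")
  set.seed(72)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    pres <- setNames(runif(n) < 0.5, tr$tip.label)
    states <- matrix(ifelse(pres[tr$tip.label], "p", "a"), ncol = 1,
                     dimnames = list(tr$tip.label, NULL))
    pd <- phangorn::phyDat(states, type = "USER", levels = c("p", "a"))
    expect_equal(gene_loss_parsimony(tr, pres, method = "fitch")$n_changes,
                 phangorn::parsimony(tr, pd))
  }
})

test_that("subspecies require identity, monophyly and minimum size", {
  # 2 clean subclades + outliers; paraphyletic high-identity group rejected
  tr <- ape::read.tree(text = paste0(
    "(((a1:0.001,a2:0.001):0.001,a3:0.002):0.05,",
    "((b1:0.001,b2:0.001):0.001,b3:0.002):0.05,out:0.2);"))
  ids <- c(paste0("a", 1:3), paste0("b", 1:3), "out")
  im <- matrix(0.95, 7, 7, dimnames = list(ids, ids))
  im[1:3, 1:3] <- 0.995; im[4:6, 4:6] <- 0.995; diag(im) <- 1
  im["out", ] <- 0.90; im[, "out"] <- 0.90; im["out", "out"] <- 1
  sub <- delineate_subspecies(tr, im, min_identity = 0.98, min_size = 3)
  expect_equal(length(unique(sub[1:3])), 1)
  expect_false(sub[["a1"]] == "unassigned")
  expect_false(sub[["a1"]] == sub[["b1"]])
  expect_identical(sub[["out"]], "unassigned")

  # same identity structure but a-group paraphyletic in the tree
  tr2 <- ape::read.tree(text = paste0(
    "(((a1:0.001,b1:0.001):0.001,a3:0.002):0.05,",
    "((a2:0.001,b2:0.001):0.001,b3:0.002):0.05,out:0.2);"))
  sub2 <- delineate_subspecies(tr2, im, min_identity = 0.98, min_size = 3)
  expect_true(all(sub2[c("a1", "a2", "a3")] == "unassigned"))

  # everything one tight clade -> a single subspecies, nobody unassigned
  im3 <- im[1:3, 1:3]
  tr3 <- ape::read.tree(text = "((a1:0.001,a2:0.001):0.001,a3:0.002);")
  sub3 <- delineate_subspecies(tr3, im3, min_size = 3)
  expect_true(all(sub3 == "subsp01"))
})

test_that("distance-distance correlation behaves under monotone maps and null", {
  set.seed(73)
  n <- 10
  m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  dc <- distance_correlation(m, 2 * m, nperm = 199)
  expect_equal(dc$rho, 1)
  expect_lt(dc$p, 0.05)
  # independent matrices: small rho, non-significant most of the time
  m2 <- matrix(runif(n * n), n, n); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  dimnames(m2) <- dimnames(m)
  dc2 <- distance_correlation(m, m2, nperm = 199)
  expect_lt(abs(dc2$rho), 0.5)
  expect_error(distance_correlation(m[1:3, 1:3], m2[1:3, 1:3]), "at least 4")
})

test_that("distance correlation is high for planted proportional divergence", {
  px <- pangenome_fixture()
  keep <- names(px$clades)[px$clades %in% c("sp04", "sp05")]
  keep <- keep[seq(1, length(keep), by = 4)]
  core_d <- operon_d <- matrix(0, length(keep), length(keep),
                               dimnames = list(keep, keep))
  seqs_core <- lapply(px$sim$genomes[keep], function(g)
    paste(extract_gene_seqs(g, classes = "core")[1:5], collapse = ""))
  seqs_op <- lapply(px$sim$genomes[keep], function(g)
    paste(extract_gene_seqs(g, classes = "operon"), collapse = ""))
  for (i in seq_along(keep)[-1]) for (j in 1:(i - 1)) {
    core_d[i, j] <- core_d[j, i] <-
      1 - akkpop:::seq_identity(seqs_core[[i]], seqs_core[[j]])
    operon_d[i, j] <- operon_d[j, i] <-
      1 - akkpop:::seq_identity(seqs_op[[i]], seqs_op[[j]])
  }
  # cross-species pairs are perfectly ordered in both matrices; within-species
  # pairs carry independent Poisson realization noise on the two gene sets,
  # which bounds the achievable rank correlation below 1
  dc <- distance_correlation(core_d, operon_d, nperm = 199)
  expect_gt(dc$rho, 0.75)
  expect_lt(dc$p, 0.01)
})

test_that("Jaccard PCoA distances match the set formula and separate content", {
  pm <- matrix(c(1, 1, 0, 0,
                 1, 0, 1, 0,
                 0, 0, 1, 1), 3, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), paste0("f", 1:4)))
  res <- jaccard_pcoa(pm, min_prevalence = 0, n_axes = 2)
  jac <- function(a, b) 1 - length(intersect(a, b)) / length(union(a, b))
  sets <- apply(pm, 1, function(r) colnames(pm)[r == 1], simplify = FALSE)
  expect_equal(res$distance["g1", "g2"], jac(sets$g1, sets$g2))
  expect_equal(res$distance["g1", "g3"], jac(sets$g1, sets$g3))
  expect_equal(res$distance["g2", "g3"], jac(sets$g2, sets$g3))
  # triangle inequality
  d <- res$distance
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)

  # identical genomes coincide
  pm2 <- rbind(pm, g4 = pm["g1", ])
  res2 <- jaccard_pcoa(pm2, min_prevalence = 0)
  expect_equal(res2$distance["g1", "g4"], 0)
  expect_equal(res2$coordinates["g1", ], res2$coordinates["g4", ],
               tolerance = 1e-9)

  # planted two-archetype gene content separates on axis 1
  set.seed(74)
  block <- function(n, on) t(replicate(n, {
    v <- integer(20); v[on] <- 1L
    v[sample(20, 2)] <- 1L - v[sample(20, 2)]  # noise
    v
  }))
  pm3 <- rbind(block(10, 1:8), block(10, 13:20))
  rownames(pm3) <- paste0("g", 1:20); colnames(pm3) <- paste0("f", 1:20)
  res3 <- jaccard_pcoa(pm3, min_prevalence = 0.03)
  ax1 <- res3$coordinates[, 1]
  expect_true(max(ax1[1:10]) < min(ax1[11:20]) ||
                min(ax1[1:10]) > max(ax1[11:20]))
})
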