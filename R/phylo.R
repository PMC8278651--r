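#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbor joining (via ape), with negative branch
#' lengths clamped to zero and optional rooting on an outgroup taxon.
#'
#' @param dm symmetric distance matrix with taxon labels
#' @param outgroup optional outgroup label to root on
#' @return an `ape::phylo` tree
#' @export
nj_tree <- function(dm, outgroup = NULL) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    stopifnot(outgroup %in% tr$tip.label)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Delineate subspecies from a tree and a core-genome identity matrix
#'
#' Candidate groups are maximal average-linkage clusters of genomes at core
#' identity >= `min_identity`; a group is promoted to a named subspecies only
#' when it is monophyletic in the tree and has at least `min_size` members.
#' All remaining genomes are left unassigned, mirroring the practice of
#' naming only clean monophyletic subclades.
#'
#' @param tree `phylo` tree whose tips include the matrix labels
#' @param identity_matrix symmetric core-genome identity matrix (fractions)
#' @param min_identity within-subspecies identity threshold (default 0.98)
#' @param min_size minimum genomes per named subspecies (default 3)
#' @return named character vector: genome id -> subspecies label or
#'   `"unassigned"`
#' @export
delineate_subspecies <- function(tree, identity_matrix, min_identity = 0.98,
                                 min_size = 3L) {
  labs <- rownames(identity_matrix)
  stopifnot(all(labs %in% tree$tip.label))
  if (length(labs) < 2)
    return(setNames(rep("unassigned", length(labs)), labs))
  d <- 1 - identity_matrix
  hc <- hclust(as.dist(d), method = "average")
  grp <- cutree(hc, h = 1 - min_identity)
  out <- setNames(rep("unassigned", length(labs)), labs)
  lab_i <- 0L
  groups <- split(labs, grp)
  groups <- groups[order(vapply(groups, min, character(1)))]
  for (g in groups) {
    if (length(g) >= min_size && ape::is.monophyletic(tree, g)) {
      lab_i <- lab_i + 1L
      out[g] <- sprintf("subsp%02d", lab_i)
    }
  }
  out
}

#' Minimal gene-loss scenario under Dollo parsimony
#'
#' Assuming the character (e.g. a biosynthetic operon) was present in the
#' root ancestor and can be lost but never regained, the minimal number of
#' present-to-absent transitions explaining the tip pattern equals the number
#' of maximal all-absent subtrees. Computed by a post-order traversal; the
#' branches bearing the losses are returned (identified by the tip label or,
#' for internal branches, by the sorted tip set below the branch).
#'
#' @param tree `phylo` tree
#' @param presence named logical vector over all tips (TRUE = present)
#' @param method `"dollo"` (default) or `"fitch"` (unordered parsimony count
#'   allowing regain, for comparison)
#' @return for `"dollo"`: list with `n_losses`, `loss_branches` (character),
#'   `node_present` (logical per node); for `"fitch"`: list with `n_changes`
#' @export
gene_loss_parsimony <- function(tree, presence, method = c("dollo", "fitch")) {
  method <- match.arg(method)
  stopifnot(all(tree$tip.label %in% names(presence)))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  if (method == "fitch") return(list(n_changes = fitch_count(tree, presence)))
  # post-order: does the clade below each node contain any present tip?
  any_present <- logical(nnode)
  any_present[seq_len(ntip)] <- as.logical(presence[tree$tip.label])
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    any_present[par] <- any_present[par] || any_present[child]
  }
  loss_edge <- which(any_present[po$edge[, 1]] & !any_present[po$edge[, 2]])
  root <- ntip + 1L
  losses <- character(0)
  for (e in loss_edge) {
    child <- po$edge[e, 2]
    losses <- c(losses, if (child <= ntip) tree$tip.label[child]
                else paste(sort(tips_below(tree, child)), collapse = "+"))
  }
  n <- length(loss_edge)
  if (!any_present[root]) { n <- 1L; losses <- "root" }
  list(n_losses = n, loss_branches = sort(losses), node_present = any_present)
}

#' @rdname gene_loss_parsimony
#' @export
dollo_losses <- function(tree, presence) gene_loss_parsimony(tree, presence, "dollo")

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

# Fitch parsimony changes for a binary character (small-parsimony count)
fitch_count <- function(tree, presence) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- if (presence[[tree$tip.label[i]]]) "p" else "a"
  changes <- 0L
  po <- ape::reorder.phylo(tree, "postorder")
  kids_of <- split(po$edge[, 2], po$edge[, 1])
  for (node in unique(po$edge[, 1])) {
    ks <- kids_of[[as.character(node)]]
    inter <- Reduce(intersect, sets[ks])
    if (length(inter)) sets[[node]] <- inter
    else { sets[[node]] <- Reduce(union, sets[ks]); changes <- changes + length(ks) - 1L }
  }
  changes
}

#' Spearman correlation between two distance matrices with permutation test
#'
#' Mantel-style: Spearman rho over the upper-triangle entries restricted to
#' shared labels; the p-value permutes the labels of the second matrix
#' (`nperm` permutations, one-sided for positive association by default).
#'
#' @param dmA,dmB symmetric distance matrices with labels
#' @param nperm permutations (default 999)
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return list with `rho`, `p`, `n_labels`, `nperm`
#' @export
distance_correlation <- function(dmA, dmB, nperm = 999,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  shared <- intersect(rownames(dmA), rownames(dmB))
  if (length(shared) < 4) stop("need at least 4 shared labels")
  a <- dmA[shared, shared]; b <- dmB[shared, shared]
  ut <- upper.tri(a)
  rho <- cor(a[ut], b[ut], method = "spearman")
  perm <- replicate(nperm, {
    p <- sample(length(shared))
    bp <- b[p, p]
    cor(a[ut], bp[ut], method = "spearman")
  })
  p <- if (alternative == "greater") (1 + sum(perm >= rho)) / (nperm + 1)
       else (1 + sum(abs(perm) >= abs(rho))) / (nperm + 1)
  list(rho = rho, p = p, n_labels = length(shared), nperm = nperm)
}

#' Jaccard-distance principal coordinates analysis of gene presence/absence
#'
#' Families with prevalence below `min_prevalence` are removed, pairwise
#' Jaccard distances (shared over union of present families; double-absences
#' ignored) are computed, and classical scaling (double-centering plus
#' eigendecomposition) returns the requested axes. Negative eigenvalues are
#' reported unmodified.
#'
#' @param pm binary genome x family matrix
#' @param min_prevalence minimum family prevalence kept (default 0.03)
#' @param n_axes number of ordination axes (default 2)
#' @return list with `coordinates` (genomes x axes), `eigenvalues`,
#'   `distance` (the Jaccard matrix), `degenerate` flag
#' @export
jaccard_pcoa <- function(pm, min_prevalence = 0.03, n_axes = 2) {
  stopifnot(nrow(pm) >= 3)
  pm <- pm[, colMeans(pm > 0) >= min_prevalence, drop = FALSE]
  m <- (pm > 0) * 1L
  inter <- m %*% t(m)
  size <- rowSums(m)
  uni <- outer(size, size, "+") - inter
  d <- 1 - ifelse(uni > 0, inter / uni, 1)
  dimnames(d) <- list(rownames(pm), rownames(pm))
  if (all(d == 0)) {
    warning("all genomes identical after the prevalence filter")
    return(list(coordinates = matrix(0, nrow(pm), n_axes,
                                     dimnames = list(rownames(pm), NULL)),
                eigenvalues = rep(0, nrow(pm) - 1), distance = d,
                degenerate = TRUE))
  }
  sc <- cmdscale(as.dist(d), k = min(n_axes, nrow(pm) - 1), eig = TRUE)
  list(coordinates = sc$points, eigenvalues = sc$eig, distance = d,
       degenerate = FALSE)
}
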