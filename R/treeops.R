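## Tree utilities: mean-path-length ultrametricization, stem-branch
## scaling for the sensitivity analysis, and uniform random labeled
## topologies for the permutation null.

#' Make a rooted tree ultrametric by the mean-path-length recursion
#'
#' Bottom-up, each internal node's height is set to the mean over its
#' children of (child height + connecting branch length); parents are then
#' lifted to at least their tallest child so no edge is negative. Heights
#' are rescaled so total depth equals the mean of the original root-to-tip
#' path lengths.
#'
#' @param tree rooted `phylo` with branch lengths
#' @return ultrametric `phylo`
#' @export
ultrametricize <- function(tree) {
  if (!ape::is.rooted(tree)) stop("rooting-required error: tree is unrooted")
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  h <- numeric(n + tree$Nnode)
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  for (node in unique(po$edge[, 1])) {
    e <- kids[[as.character(node)]]
    ch <- po$edge[e, 2]
    h[node] <- max(mean(h[ch] + po$edge.length[e]), max(h[ch]))
  }
  root <- n + 1L
  depths <- ape::node.depth.edgelength(tree)
  target <- mean(depths[seq_len(n)])
  if (h[root] > 0) h <- h * target / h[root]
  out <- tree
  out$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  ## tips sit at height zero by construction
  out$edge.length[tree$edge[, 2] <= n] <- h[tree$edge[tree$edge[, 2] <= n, 1]]
  out
}

#' Scale the stem branch of a clade
#'
#' Multiplies by `factor` the single edge subtending the most recent common
#' ancestor of `clade_tips`; everything else is unchanged.
#'
#' @param tree rooted `phylo`
#' @param clade_tips tip labels; must be monophyletic in `tree`
#' @param factor positive multiplier
#' @return modified `phylo`
#' @export
scale_clade_stem <- function(tree, clade_tips, factor) {
  stopifnot(factor > 0)
  n <- length(tree$tip.label)
  idx <- match(clade_tips, tree$tip.label)
  if (anyNA(idx)) stop("clade error: unknown tips")
  if (length(idx) == 1L) {
    mrca <- idx
  } else {
    mrca <- ape::getMRCA(tree, idx)
    desc <- ape::extract.clade(tree, mrca)$tip.label
    if (!setequal(desc, clade_tips))
      stop("clade error: tip set is not monophyletic")
  }
  if (mrca == n + 1L) stop("no-stem error: MRCA is the root")
  e <- which(tree$edge[, 2] == mrca)
  tree$edge.length[e] <- tree$edge.length[e] * factor
  tree
}

#' Uniform random unrooted binary labeled topology
#'
#' Sequential random edge addition: start from the 3-tip star and attach
#' each further tip to a uniformly chosen edge, which yields the uniform
#' distribution over unrooted binary labeled topologies. All branch
#' lengths are 1.
#'
#' @param labels tip labels (>= 3)
#' @param seed optional RNG seed
#' @return unrooted `phylo` with unit branch lengths
#' @export
random_labeled_topology <- function(labels, seed = NULL) {
  n <- length(labels)
  if (n < 3L) stop("size error: need >= 3 labels")
  if (!is.null(seed)) set.seed(seed)
  root <- n + 1L
  edge <- matrix(c(root, root, root, 1L, 2L, 3L), 3, 2)
  next_id <- n + 2L
  if (n > 3L) for (t in 4L:n) {
    e <- sample.int(nrow(edge), 1L)
    p <- edge[e, 1]; ch <- edge[e, 2]
    v <- next_id; next_id <- next_id + 1L
    edge[e, ] <- c(p, v)
    edge <- rbind(edge, c(v, ch), c(v, t))
  }
  structure(list(edge = edge, edge.length = rep(1, nrow(edge)),
                 tip.label = labels, Nnode = n - 2L),
            class = "phylo")
}
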