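## Neighbor joining (Saitou-Nei with Studier-Keppler updates), written for
## deterministic tie-breaking: among equal-minimum Q entries the pair with
## the lowest (row, column) index in the current matrix order is joined.
## Negative branch-length estimates are clamped to zero.

#' Neighbor-joining tree from a distance matrix
#'
#' @param D symmetric distance matrix with labels as dimnames (e.g. from
#'   [pairwise_distance()])
#' @return an unrooted `phylo` tree (trifurcating root node)
#' @export
neighbor_joining <- function(D) {
  labs <- rownames(D)
  n <- nrow(D)
  if (is.null(labs)) stop("distance matrix must have dimnames")
  if (n < 3L) stop("size error: need >= 3 taxa")
  if (any(!is.finite(D))) stop("saturated (non-finite) distances in matrix")
  ids <- seq_len(n)                       # active node ids (tips 1..n)
  edges <- matrix(numeric(0), 0, 3)       # parent, child, length
  next_id <- n + 1L
  Dm <- D
  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    d <- Dm[i, j]
    vi <- max(0, d / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- max(0, d - (d / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(u, ids[i], vi), c(u, ids[j], vj))
    dnew <- (Dm[i, ] + Dm[j, ] - d) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    ids <- c(ids[keep], u)
  }
  ## final 3-way join
  a <- Dm[1, 2]; b <- Dm[1, 3]; cc <- Dm[2, 3]
  v <- pmax(0, c((a + b - cc) / 2, (a + cc - b) / 2, (b + cc - a) / 2))
  root <- next_id
  edges <- rbind(edges, cbind(root, ids, v))
  .edges_to_phylo(edges, labs, root)
}

## Convert an arbitrary-id edge list into a valid ape phylo: tips keep ids
## 1..n, internal nodes renumbered n+1.. with the root first.
.edges_to_phylo <- function(edges, tip_labels, root) {
  n <- length(tip_labels)
  internal <- unique(edges[, 1])
  internal <- c(root, setdiff(internal, root))
  map <- integer(max(c(edges[, 1], edges[, 2])))
  map[seq_len(n)] <- seq_len(n)
  map[internal] <- n + seq_along(internal)
  phy <- structure(list(
    edge = cbind(map[edges[, 1]], map[edges[, 2]]),
    edge.length = edges[, 3],
    tip.label = tip_labels,
    Nnode = length(internal)), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and annotates each internal edge of the point-estimate
#' tree with the proportion of replicates containing the same bipartition.
#' Replicates producing saturated (non-finite) distances are dropped (and
#' counted in attribute `n_dropped`).
#'
#' @inheritParams pairwise_distance
#' @param n bootstrap replicates (0 = point tree without support)
#' @param seed optional RNG seed
#' @return a `phylo`; `node.label` holds support proportions (root `NA`)
#' @export
bootstrap_support <- function(aln, model = c("TN93G", "K2P"), alpha = 0.78,
                              n = 1000, seed = NULL) {
  model <- match.arg(model)
  mat <- if (inherits(aln, "codon_alignment")) aln$mat else aln
  if (!is.null(seed)) set.seed(seed)
  main <- neighbor_joining(pairwise_distance(mat, model, alpha))
  if (n == 0) return(main)
  reps <- vector("list", n)
  dropped <- 0L
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    Db <- tryCatch(pairwise_distance(mat[, cols, drop = FALSE], model, alpha),
                   error = function(e) NULL)
    if (is.null(Db) || any(!is.finite(Db))) { dropped <- dropped + 1L; next }
    reps[[b]] <- neighbor_joining(Db)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supp <- counts / length(reps)
  supp[1] <- NA                                  # root "bipartition"
  main$node.label <- supp
  attr(main, "n_dropped") <- dropped
  attr(main, "n_replicates") <- length(reps)
  main
}
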