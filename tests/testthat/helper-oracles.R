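## Independent oracles: deliberately written as brute-force enumerations /
## dense linear algebra, sharing no code paths with the package internals.

.ORACLE_GC <- Biostrings::GENETIC_CODE
.ORACLE_BASES <- c("A", "C", "G", "T")

oracle_is_ts <- function(x, y) {
  pur <- c("A", "G")
  (x %in% pur) == (y %in% pur)
}

## NG86 site counts by direct enumeration of the nine mutants.
oracle_site_counts <- function(codon, R = 0.5) {
  b <- strsplit(codon, "")[[1]]
  aa0 <- .ORACLE_GC[[codon]]
  syn <- 0
  for (p in 1:3) {
    alts <- setdiff(.ORACLE_BASES, b[p])
    muts <- sapply(alts, function(a) paste0(replace(b, p, a), collapse = ""))
    w <- sapply(alts, function(a) if (oracle_is_ts(b[p], a)) R else 0.5)
    keep <- .ORACLE_GC[muts] != "*"
    w <- w[keep] / sum(w[keep])
    syn <- syn + sum(w[.ORACLE_GC[muts[keep]] == aa0])
  }
  c(syn, 3 - syn)
}

## NG86 pathway differences by recursive enumeration of all orderings.
oracle_codon_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (!length(dpos)) return(c(0, 0))
  paths <- list()
  walk <- function(cur, remaining, s, n, hit_stop) {
    if (!length(remaining)) {
      paths[[length(paths) + 1]] <<- list(s = s, n = n, stop = hit_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- replace(cur, p, b2[p])
      cs <- paste0(cur, collapse = ""); ns <- paste0(nxt, collapse = "")
      step_syn <- .ORACLE_GC[[cs]] == .ORACLE_GC[[ns]]
      walk(nxt, setdiff(remaining, p), s + step_syn, n + !step_syn,
           hit_stop || .ORACLE_GC[[ns]] == "*")
    }
  }
  walk(b1, dpos, 0, 0, FALSE)
  ok <- !sapply(paths, `[[`, "stop")
  use <- if (any(ok)) paths[ok] else paths
  c(mean(sapply(use, `[[`, "s")), mean(sapply(use, `[[`, "n")))
}

## Sankoff small parsimony with unit costs (works on multifurcations).
oracle_sankoff <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  st <- as.character(tip_states[tree$tip.label])
  states <- unique(st)
  S <- length(states)
  BIG <- 1e9
  cost <- matrix(BIG, n + tree$Nnode, S)
  cost[cbind(seq_len(n), match(st, states))] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    # accumulate child into parent: parent cost starts at 0 implicitly
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (all(cost[par, ] == BIG)) cost[par, ] <- 0
    trans <- sapply(seq_len(S), function(s)
      min(cost[ch, ] + (seq_len(S) != s)))
    cost[par, ] <- cost[par, ] + trans
  }
  min(cost[n + 1, ])
}

## Dense multivariate-normal BM log-likelihood built from shared root-path
## edge lengths (clade-A edges incl. stem scaled by rel_rate_a).
oracle_bm_lnL <- function(tree, values, split, mu, sigma2, rel_rate_a = 1) {
  n <- length(tree$tip.label)
  root <- n + 1
  tips_below <- function(node) {
    if (node <= n) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  }
  edge_rate <- sapply(seq_len(nrow(tree$edge)), function(e) {
    if (all(tips_below(tree$edge[e, 2]) %in% split$a)) rel_rate_a else 1
  })
  path_edges <- function(tip) {
    nodes <- ape::nodepath(tree, root, tip)
    sapply(seq_len(length(nodes) - 1), function(i)
      which(tree$edge[, 1] == nodes[i] & tree$edge[, 2] == nodes[i + 1]))
  }
  pe <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(pe[[i]], pe[[j]])
    V[i, j] <- sigma2 * sum(tree$edge.length[shared] * edge_rate[shared])
  }
  x <- values[tree$tip.label]
  m <- ifelse(tree$tip.label %in% split$a,
              if (length(mu) == 2) mu[1] else mu,
              if (length(mu) == 2) mu[2] else mu)
  r <- x - m
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% solve(V, r)))
}

## Random two-clade ultrametric tree with the root at the split.
helper_bm_tree <- function(n_a, n_b, depth = 1, stem_frac = 0.3) {
  piece <- function(k, pref) {
    if (k == 1) return(sprintf("%s1:%g", pref, depth))
    t <- ape::rcoal(k, tip.label = paste0(pref, seq_len(k)))
    t$edge.length <- t$edge.length * depth * (1 - stem_frac) /
      max(ape::node.depth.edgelength(t))
    paste0(sub(";$", "", ape::write.tree(t)), ":", depth * stem_frac)
  }
  tr <- ape::read.tree(text = sprintf("(%s,%s);",
                                      piece(n_a, "a"), piece(n_b, "b")))
  list(tree = tr,
       split = clade_split(grep("^a", tr$tip.label, value = TRUE),
                           grep("^b", tr$tip.label, value = TRUE)))
}

## Tip-to-tip path distances (explicit, avoids cophenetic S3 dispatch).
helper_tip_dists <- function(tr) {
  n <- length(tr$tip.label)
  D <- ape::dist.nodes(tr)[seq_len(n), seq_len(n)]
  dimnames(D) <- list(tr$tip.label, tr$tip.label)
  D
}

## Additive distance matrix from a random unrooted tree with random
## branch lengths; the generating tree is returned for comparison.
helper_additive_case <- function(n) {
  tr <- random_labeled_topology(paste0("t", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, D = helper_tip_dists(tr))
}

## Tiny random codon alignment matrix (gap-free, stop-free).
helper_random_codon_mat <- function(n_seq, n_codons) {
  sense <- names(.ORACLE_GC)[.ORACLE_GC != "*"]
  m <- t(sapply(seq_len(n_seq), function(i)
    unlist(strsplit(sample(sense, n_codons, replace = TRUE), ""))))
  rownames(m) <- paste0("s", seq_len(n_seq))
  m
}
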