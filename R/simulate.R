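## Synthetic data with the statistical structure the analysis assumes:
## a two-clade ultrametric tree of species carrying allele subtrees (plus
## an outgroup), codon alignments evolved with transition bias, partition-
## dependent selection (acceptance-rejection on nonsynonymous proposals)
## and third-position GC bias, and Brownian-motion traits.

#' Simulation configuration
#'
#' Defaults emulate the empirical setting: 16 songbird species with 3-13
#' allele-like paralogs each, 17 non-passerine species, 88-codon
#' alignments, diversifying selection confined to the PBR
#' (`omega_pbr = 4` vs `omega_nonpbr = 0.5`), third-position GC targets of
#' 0.70 (songbirds) vs 0.78 (non-passerines), and a lizard-like outgroup.
#'
#' @param seed RNG seed
#' @param n_species_a,n_species_b species per clade (A = songbirds)
#' @param alleles_per_species inclusive range for the per-species allele
#'   count
#' @param alleles_per_species_b range for clade B (default `c(1, 3)`:
#'   database-derived non-passerine sets are smaller per species)
#' @param n_codons codons per sequence
#' @param omega_pbr,omega_nonpbr acceptance dN/dS targets per partition
#' @param kappa transition/transversion rate ratio
#' @param gc3_target_a,gc3_target_b stationary third-position GC fractions
#' @param tree_depth root-to-tip depth, expected proposals/site
#' @param allele_depth depth of the within-species allele subtrees
#' @param stem_frac fraction of `tree_depth` in each clade stem
#' @param mut_scale multiplier on the proposal rate (deepens divergence
#'   without changing the tree)
#' @param outgroup attach an outgroup lineage below the root?
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1, n_species_a = 16, n_species_b = 17,
                       alleles_per_species = c(3, 13),
                       alleles_per_species_b = c(1, 3),
                       n_codons = 88, omega_pbr = 4, omega_nonpbr = 0.5,
                       kappa = 2, gc3_target_a = 0.70, gc3_target_b = 0.78,
                       tree_depth = 0.35, allele_depth = 0.05,
                       stem_frac = 0.3, mut_scale = 1, outgroup = TRUE) {
  cfg <- as.list(environment())
  stopifnot(n_species_a >= 1, n_species_b >= 1, n_codons >= 1,
            omega_pbr > 0, omega_nonpbr > 0,
            gc3_target_a > 0, gc3_target_a < 1,
            gc3_target_b > 0, gc3_target_b < 1,
            allele_depth + 1e-9 < tree_depth * (1 - stem_frac))
  class(cfg) <- "sim_config"
  cfg
}

## newick fragment (no trailing length) for one clade: species coalescent
## rescaled to depth_total - allele_depth, each species tip replaced by an
## allele coalescent of depth allele_depth.
.clade_newick <- function(prefix, n_sp, allele_range, depth_total,
                          allele_depth) {
  spnames <- sprintf("%s%02d", prefix, seq_len(n_sp))
  ks <- sample(seq(allele_range[1], allele_range[2]), n_sp, replace = TRUE)
  sp_depth <- depth_total - allele_depth
  ## every species tip is replaced by a "(...)" allele piece of depth
  ## allele_depth (k = 1 gives a singleton node, collapsed after parsing),
  ## so the clade stays ultrametric with no branch-length text surgery
  allele_piece <- function(sp, k) {
    if (k == 1L) return(sprintf("(%s_1:%s)", sp, .nwk_num(allele_depth)))
    at <- ape::rcoal(k, tip.label = paste0(sp, "_", seq_len(k)))
    at$edge.length <- at$edge.length * allele_depth /
      max(ape::node.depth.edgelength(at))
    sub(";$", "", ape::write.tree(at))
  }
  if (n_sp == 1L)
    return(list(nwk = allele_piece(spnames, ks[1]), depth = allele_depth))
  st <- ape::rcoal(n_sp, tip.label = spnames)
  st$edge.length <- st$edge.length * sp_depth /
    max(ape::node.depth.edgelength(st))
  nwk <- sub(";$", "", ape::write.tree(st))
  for (i in seq_len(n_sp))
    nwk <- sub(paste0(spnames[i], ":"),
               paste0(allele_piece(spnames[i], ks[i]), ":"),
               nwk, fixed = TRUE)
  list(nwk = nwk, depth = depth_total)
}

.nwk_num <- function(x) {
  ## reproduce ape::write.tree's number formatting for exact substitution
  sprintf("%s", format(x, digits = 10, scientific = FALSE, trim = TRUE))
}

#' Simulate a two-clade species/allele tree
#'
#' A root splits clade A and clade B; within each clade a coalescent
#' species tree whose tips carry shallow allele subtrees; an optional
#' outgroup is attached below the root. The tree is ultrametric. Tip
#' metadata (id, species, family, clade) is attached as attribute
#' `"metadata"`.
#'
#' @param cfg a [sim_config()]
#' @return ultrametric `phylo`
#' @export
simulate_two_clade_tree <- function(cfg) {
  set.seed(cfg$seed)
  depth <- cfg$tree_depth * (1 - cfg$stem_frac)
  stem <- cfg$tree_depth * cfg$stem_frac
  a <- .clade_newick("spA", cfg$n_species_a, cfg$alleles_per_species,
                     depth, cfg$allele_depth)
  b <- .clade_newick("spB", cfg$n_species_b, cfg$alleles_per_species_b,
                     depth, cfg$allele_depth)
  stem_a <- cfg$tree_depth - a$depth
  stem_b <- cfg$tree_depth - b$depth
  core <- sprintf("(%s:%s,%s:%s)", a$nwk, .nwk_num(stem_a),
                  b$nwk, .nwk_num(stem_b))
  nwk <- if (isTRUE(cfg$outgroup)) {
    xo <- 0.25 * cfg$tree_depth
    sprintf("(%s:%s,outgroup_1:%s);", core, .nwk_num(xo),
            .nwk_num(cfg$tree_depth + xo))
  } else paste0(core, ";")
  tree <- ape::collapse.singles(ape::read.tree(text = nwk))
  sp <- sub("_[0-9]+$", "", tree$tip.label)
  clade <- ifelse(grepl("^spA", sp), "songbird",
                  ifelse(grepl("^spB", sp), "nonpasserine", "outgroup"))
  spu <- unique(sp)
  fam <- setNames(ifelse(grepl("^spA", spu),
                         sprintf("famA%02d", (match(spu, spu) - 1) %% 14 + 1),
                         sub("^sp", "fam", spu)), spu)
  meta <- data.frame(id = tree$tip.label, species = sp,
                     family = unname(fam[sp]), clade = clade)
  attr(tree, "metadata") <- meta
  tree
}

## GC bias weights at third positions calibrated so the stationary GC of
## the per-site jump chain equals the target g (see methods vignette).
.gc_weights <- function(g, kappa) {
  gcshare <- function(x) {
    zg <- kappa * (1 - x) / 2 + 1 / 2
    za <- kappa * x / 2 + 1 / 2
    x * zg / (x * zg + (1 - x) * za)
  }
  x <- uniroot(function(x) gcshare(x) - g, c(1e-4, 1 - 1e-4))$root
  c(A = (1 - x) / 2, C = x / 2, G = x / 2, T = (1 - x) / 2)
}

#' Simulate a codon alignment on a tree
#'
#' The root sequence is drawn stop-free with third-position GC at the
#' clade-A target. Along each edge, Poisson(`3 n_codons x length x
#' mut_scale`) mutation events are proposed: a uniform site, a replacement
#' base drawn with transition bias `kappa` and (at third positions) GC
#' bias calibrated to the lineage's clade target; proposals creating stop
#' codons are rejected; nonsynonymous proposals are accepted with
#' probability `min(1, omega)` for the codon's partition, synonymous ones
#' always.
#'
#' @param tree a `phylo` whose tip labels carry clade metadata (attribute
#'   `"metadata"` as from [simulate_two_clade_tree()], or `spA`/`spB`
#'   prefixes)
#' @param cfg a [sim_config()]
#' @param scheme a [partition_scheme()]
#' @param seed RNG seed (default `cfg$seed + 1`)
#' @return a [codon_alignment()]
#' @export
simulate_codon_alignment <- function(tree, cfg, scheme,
                                     seed = cfg$seed + 1) {
  if (!is.null(seed)) set.seed(seed)
  meta <- attr(tree, "metadata")
  if (is.null(meta)) {
    sp <- sub("_[0-9]+$", "", tree$tip.label)
    clade <- ifelse(grepl("^spA", sp), "songbird",
                    ifelse(grepl("^spB", sp), "nonpasserine", "outgroup"))
    meta <- data.frame(id = tree$tip.label, species = sp, family = sp,
                       clade = clade)
  }
  L <- 3L * cfg$n_codons
  pbr <- rep(FALSE, cfg$n_codons)
  pbr[pbr_alignment_codons(scheme, cfg$n_codons)] <- TRUE
  aa <- osc_aa(); cods <- osc_codons()
  ## root sequence
  root_seq <- character(L)
  for (j in seq_len(cfg$n_codons)) {
    repeat {
      c12 <- sample(.BASES, 2, replace = TRUE)
      b3 <- if (runif(1) < cfg$gc3_target_a) sample(c("G", "C"), 1)
            else sample(c("A", "T"), 1)
      cd <- c(c12, b3)
      if (aa[match(paste0(cd, collapse = ""), cods)] != "*") break
    }
    root_seq[(3 * j - 2):(3 * j)] <- cd
  }
  fw <- list(A = .gc_weights(cfg$gc3_target_a, cfg$kappa),
             B = .gc_weights(cfg$gc3_target_b, cfg$kappa))
  a_tips <- meta$id[meta$clade == "songbird"]
  b_tips <- meta$id[meta$clade == "nonpasserine"]
  edge_clade <- rep("A", nrow(tree$edge))
  if (length(b_tips)) edge_clade[.edges_in_clade(tree, b_tips)] <- "B"
  evolve <- function(seqv, len, cl) {
    nev <- rpois(1, L * len * cfg$mut_scale)
    w3 <- fw[[cl]]
    for (e in seq_len(nev)) {
      s <- sample.int(L, 1L)
      p <- (s - 1L) %% 3L + 1L
      j <- (s - 1L) %/% 3L + 1L
      cur <- seqv[s]
      cand <- setdiff(.BASES, cur)
      w <- ifelse(is_transition(cur, cand), cfg$kappa, 1)
      if (p == 3L) w <- w * w3[cand]
      nb <- sample(cand, 1L, prob = w)
      old_cod <- seqv[(3 * j - 2):(3 * j)]
      new_cod <- old_cod; new_cod[p] <- nb
      a2 <- aa[match(paste0(new_cod, collapse = ""), cods)]
      if (a2 == "*") next
      a1 <- aa[match(paste0(old_cod, collapse = ""), cods)]
      om <- if (pbr[j]) cfg$omega_pbr else cfg$omega_nonpbr
      ## accept nonsynonymous proposals w.p. min(1, omega) and synonymous
      ## w.p. min(1, 1/omega), so the realized dN/dS tracks omega on both
      ## sides of 1
      acc <- if (a1 != a2) min(1, om) else min(1, 1 / om)
      if (runif(1) >= acc) next
      seqv[s] <- nb
    }
    seqv
  }
  ## preorder traversal carrying sequences down the tree
  n <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", n + tree$Nnode)
  seqs[[n + 1L]] <- root_seq
  tipmat <- matrix(NA_character_, n, L, dimnames = list(tree$tip.label, NULL))
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
    cl <- edge_clade[which(tree$edge[, 1] == par & tree$edge[, 2] == ch)]
    sq <- evolve(seqs[[par]], pre$edge.length[k], cl)
    if (ch <= n) tipmat[ch, ] <- sq else seqs[[ch]] <- sq
  }
  codon_alignment(tipmat, meta)
}

#' Simulate a Brownian-motion trait on a two-clade tree
#'
#' Each clade's lineage starts at its clade mean at the root (the split);
#' normal increments accumulate per edge with variance
#' `sigma2 * rate * length`, clade-A edges (stem included) using rate
#' `rel_rate_a`.
#'
#' @inheritParams bm_loglik
#' @param mu_a,mu_b clade means
#' @param seed optional RNG seed
#' @return named numeric vector of tip values
#' @export
simulate_bm_trait <- function(tree, split, mu_a, mu_b, sigma2,
                              rel_rate_a = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_split(tree, split)
  .check_clade_ultrametric(tree, split)
  n <- length(tree$tip.label)
  in_a <- logical(nrow(tree$edge))
  in_a[.edges_in_clade(tree, split$a)] <- TRUE
  pre <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  val <- numeric(n + tree$Nnode)
  val[n + 1L] <- NA                      # root value never used directly
  for (k in seq_len(nrow(pre$edge))) {
    par <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
    rate <- if (in_a[ord[k]]) rel_rate_a else 1
    start <- if (par == n + 1L) {
      if (in_a[ord[k]]) mu_a else mu_b
    } else val[par]
    val[ch] <- start + rnorm(1, 0, sqrt(sigma2 * rate * pre$edge.length[k]))
  }
  setNames(val[seq_len(n)], tree$tip.label)
}

#' Simulate a full dataset (tree, alignment, optional files)
#'
#' @param cfg a [sim_config()]
#' @param scheme a [partition_scheme()] (default standard PBR set)
#' @param outdir optional directory; when given, writes `alignment.fasta`,
#'   `metadata.tsv` and `tree.nwk`
#' @return list with `tree`, `aln`, `cfg`
#' @export
simulate_dataset <- function(cfg = sim_config(), scheme = partition_scheme(),
                             outdir = NULL) {
  tree <- simulate_two_clade_tree(cfg)
  aln <- simulate_codon_alignment(tree, cfg, scheme)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_codon_alignment(aln, file.path(outdir, "alignment.fasta"),
                          file.path(outdir, "metadata.tsv"))
    ape::write.tree(tree, file.path(outdir, "tree.nwk"))
  }
  list(tree = tree, aln = aln, cfg = cfg)
}
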