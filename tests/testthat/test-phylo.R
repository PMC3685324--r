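test_that("K2P and TN93G distances: closed forms and model relations", {
  ## identical sequences -> 0
  m <- helper_random_codon_mat(1, 20)
  mat <- rbind(a = m[1, ], b = m[1, ])
  expect_equal(unname(pairwise_distance(mat, "K2P")[1, 2]), 0)
  expect_equal(unname(pairwise_distance(mat, "TN93G")[1, 2]), 0)

  ## 100 sites, 10 transitions, no transversions
  a <- rep(c("A", "C", "G", "T"), 25)
  b <- a; b[seq(1, 37, by = 4)] <- "G"     # 10 A->G transitions
  mat <- rbind(a = a, b = b)
  expect_equal(sum(a != b), 10)
  k2p <- pairwise_distance(mat, "K2P")[1, 2]
  expect_equal(unname(k2p), -0.5 * log(1 - 2 * 0.1) - 0.25 * log(1),
               tolerance = 1e-12)

  ## gamma correction inflates TN93 distances
  tg <- pairwise_distance(mat, "TN93G", alpha = 0.78)[1, 2]
  t0 <- pairwise_distance(mat, "TN93G", alpha = Inf)[1, 2]
  expect_gt(tg, t0)
})

test_that("TN93 agrees with ape::dist.dna on two-sequence alignments", {
  set.seed(23)
  for (rep in 1:5) {
    a <- helper_random_codon_mat(1, 60)[1, ]
    b <- a
    mut <- sample(length(a), 25)              # ~14% divergence, unsaturated
    b[mut] <- sapply(a[mut], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1))
    mat <- rbind(s1 = a, s2 = b)
    dna <- ape::as.DNAbin(mat)
    for (g in c(Inf, 0.78)) {
      mine <- pairwise_distance(mat, "TN93G", alpha = g)[1, 2]
      ref <- if (is.finite(g))
        ape::dist.dna(dna, model = "TN93", gamma = g)[1]
      else ape::dist.dna(dna, model = "TN93")[1]
      expect_equal(unname(mine), ref, tolerance = 1e-10)
    }
    mine <- pairwise_distance(mat, "K2P")[1, 2]
    expect_equal(unname(mine), ape::dist.dna(dna, model = "K80")[1],
                 tolerance = 1e-10)
  }
})

test_that("neighbor_joining: 3-taxon closed form and additive recovery", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3L)
  co <- helper_tip_dists(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(co, D, tolerance = 1e-12)
  expect_error(neighbor_joining(D[1:2, 1:2]), "size")

  set.seed(31)
  for (rep in 1:10) {
    case <- helper_additive_case(sample(6:8, 1))
    tr <- neighbor_joining(case$D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(case$tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(helper_tip_dists(tr)[rownames(case$D), colnames(case$D)],
                 case$D, tolerance = 1e-8)
  }
})

test_that("neighbor_joining agrees with ape::nj on generic matrices", {
  set.seed(37)
  for (rep in 1:5) {
    n <- 7
    M <- matrix(runif(n * n, 0.1, 1), n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap_support: signal vs no-signal, proportions in [0,1]", {
  ## two clearly separated groups
  cfg <- sim_config(seed = 41, n_species_a = 2, n_species_b = 2,
                    alleles_per_species = c(2, 2), alleles_per_species_b = c(2, 2),
                    n_codons = 80, stem_frac = 0.6, outgroup = FALSE)
  sim <- simulate_dataset(cfg)
  tr <- bootstrap_support(sim$aln, "TN93G", n = 50, seed = 1)
  supp <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(supp >= 0 & supp <= 1))
  a_tips <- sim$aln$meta$id[sim$aln$meta$clade == "songbird"]
  mrca <- ape::getMRCA(tr, a_tips)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, a_tips)
  central <- tr$node.label[mrca - ape::Ntip(tr)]
  expect_gte(central, 0.9)

  ## permuted columns destroy the signal
  set.seed(2)
  noise <- sim$aln
  for (j in seq_len(ncol(noise$mat)))
    noise$mat[, j] <- sample(noise$mat[, j])
  trn <- bootstrap_support(noise, "TN93G", n = 50, seed = 1)
  suppn <- trn$node.label[!is.na(trn$node.label)]
  expect_lt(min(suppn), 0.7)

  ## n = 0: no annotations
  expect_null(bootstrap_support(sim$aln, "TN93G", n = 0)$node.label)
})

test_that("ultrametricize: fixed point, 2-tip arithmetic, postcondition", {
  t2 <- ape::read.tree(text = "(a:1,b:3);")
  u2 <- ultrametricize(t2)
  d <- ape::node.depth.edgelength(u2)[1:2]
  expect_equal(d, c(2, 2))

  um <- ape::rcoal(8)
  expect_equal(ultrametricize(um)$edge.length, um$edge.length,
               tolerance = 1e-10)

  set.seed(43)
  tr <- ape::rtree(10)                      # rooted, non-ultrametric
  u <- ultrametricize(tr)
  depths <- ape::node.depth.edgelength(u)[1:10]
  expect_lt(diff(range(depths)), 1e-10)
  expect_true(all(u$edge.length >= 0))
  ## depth preserved as mean original root-to-tip distance
  expect_equal(mean(depths),
               mean(ape::node.depth.edgelength(tr)[1:10]), tolerance = 1e-10)
  expect_error(ultrametricize(ape::unroot(tr)), "unrooted")
})

test_that("scale_clade_stem scales exactly one edge", {
  tr <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  s1 <- scale_clade_stem(tr, c("a", "b"), 1)
  expect_equal(s1$edge.length, tr$edge.length)
  s5 <- scale_clade_stem(tr, c("a", "b"), 0.5)
  mrca <- ape::getMRCA(tr, c("a", "b"))
  e <- which(tr$edge[, 2] == mrca)
  expect_equal(s5$edge.length[e], 1)
  expect_equal(s5$edge.length[-e], tr$edge.length[-e])
  expect_false(ape::is.ultrametric(s5, tol = 1e-8))
  expect_error(scale_clade_stem(tr, c("a", "c"), 0.5), "monophyletic")
  expect_error(scale_clade_stem(tr, c("a", "b", "c", "d"), 0.5), "root")
})

test_that("random_labeled_topology: determinism, 3-taxon case, uniformity", {
  expect_equal(ape::write.tree(random_labeled_topology(letters[1:5], seed = 9)),
               ape::write.tree(random_labeled_topology(letters[1:5], seed = 9)))
  t3 <- random_labeled_topology(c("a", "b", "c"))
  expect_equal(ape::Ntip(t3), 3L); expect_equal(t3$Nnode, 1L)

  ## 4 taxa: the three topologies should be ~uniform
  set.seed(47)
  sib_of_a <- replicate(3000, {
    tr <- random_labeled_topology(c("a", "b", "c", "d"))
    po <- tr$edge
    ## find a's sibling: the other child of a's parent (if internal cherry)
    pa <- po[po[, 2] == 1, 1]
    sibs <- setdiff(po[po[, 1] == pa, 2], 1)
    tips <- sibs[sibs <= 4]
    if (length(tips) == 1) tr$tip.label[tips] else "none"
  })
  tab <- table(factor(sib_of_a[sib_of_a != "none"], c("b", "c", "d")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})
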