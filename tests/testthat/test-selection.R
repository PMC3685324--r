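test_that("ng86_site_counts: worked examples and error cases", {
  sc <- ng86_site_counts("TTT", R = 0.5)
  expect_equal(sc[["syn"]], 1 / 3, tolerance = 1e-12)
  expect_equal(sc[["nonsyn"]], 8 / 3, tolerance = 1e-12)
  ## 4-fold degenerate third position
  expect_gte(ng86_site_counts("GGG", R = 2)[["syn"]], 1)
  expect_error(ng86_site_counts("TAA"), "stop")
  expect_error(ng86_site_counts("AT-"), "ambiguous")
})

test_that("site counts sum to 3 and match the enumeration oracle", {
  sense <- osc_codons()[!is_stop_codon(osc_codons())]
  for (R in c(0.5, 1, 2)) {
    for (cod in sense) {
      sc <- ng86_site_counts(cod, R)
      expect_equal(sum(sc), 3, tolerance = 1e-12)
      expect_equal(unname(sc), oracle_site_counts(cod, R), tolerance = 1e-12)
    }
  }
})

test_that("ng86_codon_differences: pathway examples, symmetry, oracle", {
  expect_equal(unname(ng86_codon_differences("TTT", "TTT")), c(0, 0))
  d <- ng86_codon_differences("TTT", "GTA")
  expect_equal(d[["syn"]], 0.5); expect_equal(d[["nonsyn"]], 1.5)
  d2 <- ng86_codon_differences("AAA", "AGG")
  expect_equal(unname(d2), oracle_codon_diffs("AAA", "AGG"))
  expect_error(ng86_codon_differences("TAA", "TTT"), "stop")

  set.seed(11)
  sense <- osc_codons()[!is_stop_codon(osc_codons())]
  for (i in 1:100) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    a <- ng86_codon_differences(c1, c2)
    b <- ng86_codon_differences(c2, c1)
    expect_equal(unname(a), unname(b), tolerance = 1e-12)  # symmetry
    expect_equal(unname(a), oracle_codon_diffs(c1, c2), tolerance = 1e-12)
    expect_equal(sum(a), sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]))
  }
})

test_that("stop-blocked pathways fall back with a flag", {
  ## TGT <-> TAC: via TAT ok; via TGC ok... construct a genuinely blocked
  ## pair instead: TGG <-> TAA is invalid (stop endpoint); use TGG -> CAG:
  ## paths via CGG (ok) and TAG (stop) -> one valid path remains, no flag
  d <- ng86_codon_differences("TGG", "CAG")
  expect_null(attr(d, "stop_pathways_included"))
  expect_equal(sum(d), 2)
})

test_that("jc69_correct closed form and domain", {
  expect_equal(jc69_correct(0), 0)
  expect_equal(jc69_correct(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_equal(jc69_correct(0.3), 0.3831, tolerance = 1e-4)
  expect_error(jc69_correct(0.75), "saturation")
  expect_error(jc69_correct(-0.1), "saturation")
})

test_that("partitioned_dnds: identical sequences give zero everywhere", {
  m <- helper_random_codon_mat(1, 30)
  mat <- rbind(s1 = m[1, ], s2 = m[1, ], s3 = m[1, ])
  meta <- data.frame(id = rownames(mat), species = "x", family = "f",
                     clade = "songbird")
  aln <- codon_alignment(mat, meta)
  dd <- partitioned_dnds(aln, partition_scheme(frame_offset = 0), n_boot = 0)
  expect_equal(dd$dN, rep(0, 3)); expect_equal(dd$dS, rep(0, 3))
})

test_that("partitioned_dnds matches a direct two-sequence oracle", {
  set.seed(13)
  rep_done <- 0
  while (rep_done < 5) {
    mat <- helper_random_codon_mat(2, 3)
    ## skip JC-saturated draws (p >= 3/4 has no finite corrected distance)
    sat <- FALSE
    for (cols in list(1:2, 3, 1:3)) {
      S <- N <- sd_ <- nd_ <- 0
      for (j in cols) {
        c1 <- paste0(mat[1, (3 * j - 2):(3 * j)], collapse = "")
        c2 <- paste0(mat[2, (3 * j - 2):(3 * j)], collapse = "")
        s1 <- oracle_site_counts(c1, 0.5); s2 <- oracle_site_counts(c2, 0.5)
        S <- S + (s1[1] + s2[1]) / 2; N <- N + (s1[2] + s2[2]) / 2
        df <- oracle_codon_diffs(c1, c2)
        sd_ <- sd_ + df[1]; nd_ <- nd_ + df[2]
      }
      rs <- sd_ / S; rn <- nd_ / N
      if (!is.finite(rs) || !is.finite(rn) || rs >= 0.75 || rn >= 0.75)
        sat <- TRUE
    }
    if (sat) next
    rep_done <- rep_done + 1
    meta <- data.frame(id = rownames(mat), species = "x", family = "f",
                       clade = "songbird")
    aln <- codon_alignment(mat, meta)
    scheme <- partition_scheme(pbr_exon_codons = 1:2, frame_offset = 0)
    dd <- partitioned_dnds(aln, scheme, n_boot = 0, R = 0.5)
    ## oracle: enumerate sites and pathways per codon directly
    for (part in c("PBR", "nonPBR", "all")) {
      cols <- switch(part, PBR = 1:2, nonPBR = 3, all = 1:3)
      S <- N <- sd_ <- nd_ <- 0
      for (j in cols) {
        c1 <- paste0(mat[1, (3 * j - 2):(3 * j)], collapse = "")
        c2 <- paste0(mat[2, (3 * j - 2):(3 * j)], collapse = "")
        s1 <- oracle_site_counts(c1, 0.5); s2 <- oracle_site_counts(c2, 0.5)
        S <- S + (s1[1] + s2[1]) / 2; N <- N + (s1[2] + s2[2]) / 2
        df <- oracle_codon_diffs(c1, c2)
        sd_ <- sd_ + df[1]; nd_ <- nd_ + df[2]
      }
      jc <- function(p) -0.75 * log(1 - 4 * p / 3)
      row <- dd[dd$partition == part, ]
      expect_equal(row$dS, jc(sd_ / S), tolerance = 1e-10)
      expect_equal(row$dN, jc(nd_ / N), tolerance = 1e-10)
    }
  }
})

test_that("partitioned_dnds is invariant to sequence order; n_boot=0 -> no SEs", {
  cfg <- sim_config(seed = 17, n_species_a = 2, n_species_b = 2,
                    alleles_per_species = c(2, 3), n_codons = 40)
  sim <- simulate_dataset(cfg)
  sch <- partition_scheme()
  d1 <- partitioned_dnds(sim$aln, sch, n_boot = 0)
  perm <- sim$aln
  ord <- sample(nrow(perm$mat))
  perm$mat <- perm$mat[ord, , drop = FALSE]
  perm$meta <- perm$meta[ord, ]
  d2 <- partitioned_dnds(perm, sch, n_boot = 0)
  expect_equal(d1$dN, d2$dN, tolerance = 1e-12)
  expect_equal(d1$dS, d2$dS, tolerance = 1e-12)
  expect_true(all(is.na(d1$se_dN)))
  d3 <- partitioned_dnds(sim$aln, sch, n_boot = 30, seed = 1)
  expect_true(all(is.finite(d3$se_dN)))
  ## seeded bootstrap is reproducible
  d4 <- partitioned_dnds(sim$aln, sch, n_boot = 30, seed = 1)
  expect_equal(d3$se_dN, d4$se_dN)
})

test_that("pbr_alignment_codons maps exon coordinates through the offset", {
  sch <- partition_scheme()
  expect_equal(pbr_alignment_codons(sch, 88),
               c(5, 7, 8, 9, 23, 25, 38, 60, 61, 62, 65, 66, 68, 73) - 4)
  ## out-of-range codons are dropped
  expect_equal(pbr_alignment_codons(sch, 40),
               setdiff(c(1, 3, 4, 5, 19, 21, 34), integer(0)))
  expect_error(pbr_alignment_codons(partition_scheme(90, 0), 20), "partition")
})
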