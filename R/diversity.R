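## Per-repertoire polymorphism summaries: number of segregating sites (S),
## mean pairwise differences (k) and per-site nucleotide diversity (pi).
## Gaps and N are treated as missing and excluded pairwise.

#' Number of polymorphic (segregating) sites
#'
#' Counts alignment columns with at least two distinct non-gap, non-N bases.
#'
#' @param aln a [codon_alignment()] or character matrix
#' @return integer count
#' @export
polymorphic_sites <- function(aln) {
  mat <- if (inherits(aln, "codon_alignment")) aln$mat else aln
  if (nrow(mat) < 2L) stop("undefined error: need >= 2 sequences")
  sum(apply(mat, 2, function(col) {
    length(unique(col[col %in% .BASES])) >= 2L
  }))
}

#' Mean pairwise differences (k) and nucleotide diversity (pi)
#'
#' `k` is the mean, over all unordered sequence pairs, of the number of
#' differing columns (columns with a gap or N in either sequence are
#' excluded for that pair). `pi` is the mean over pairs of differences
#' divided by compared sites, i.e. per-pair per-site diversity averaged
#' with equal pair weight.
#'
#' @inheritParams polymorphic_sites
#' @return list with `k` and `pi`
#' @export
pairwise_diff_stats <- function(aln) {
  mat <- if (inherits(aln, "codon_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2L) stop("undefined error: need >= 2 sequences")
  pr <- combn(n, 2)
  dif <- numeric(ncol(pr)); per <- numeric(ncol(pr))
  for (p in seq_len(ncol(pr))) {
    a <- mat[pr[1, p], ]; b <- mat[pr[2, p], ]
    ok <- a %in% .BASES & b %in% .BASES
    dif[p] <- sum(a[ok] != b[ok])
    per[p] <- if (any(ok)) dif[p] / sum(ok) else NA_real_
  }
  list(k = mean(dif), pi = mean(per, na.rm = TRUE))
}

#' Per-species diversity and selection summary table
#'
#' For each species: filters to putative alleles, then reports Na (alleles
#' retained), S, pi, k and, when a [partition_scheme()] is supplied, the
#' PBR and non-PBR dN/dS ratios from [partitioned_dnds()].
#'
#' @param aln a [codon_alignment()]
#' @param scheme optional [partition_scheme()] for the omega columns
#' @param min_nt_diff allele filtering threshold, see
#'   [filter_putative_alleles()]
#' @param R transition/transversion weighting for the dN/dS counter
#' @param clades clades to include (default songbirds only, matching the
#'   per-species repertoire analysis)
#' @return data.frame with one row per species
#' @export
species_diversity_table <- function(aln, scheme = NULL, min_nt_diff = 3,
                                    R = 0.5, clades = "songbird") {
  meta <- aln$meta[aln$meta$clade %in% clades, , drop = FALSE]
  out <- lapply(unique(meta$species), function(sp) {
    ids <- meta$id[meta$species == sp]
    f <- filter_putative_alleles(aln$mat[ids, , drop = FALSE], min_nt_diff)
    na <- nrow(f$retained)
    n_pseudo <- sum(grepl("stop_codon|frameshift_gap", f$discarded$reason))
    row <- data.frame(species = sp, Na = na, n_pseudogenes = n_pseudo,
                      S = NA_integer_, pi = NA_real_, k = NA_real_,
                      omega_PBR = NA_real_, omega_nonPBR = NA_real_)
    if (na >= 2L) {
      row$S <- polymorphic_sites(f$retained)
      st <- pairwise_diff_stats(f$retained)
      row$pi <- st$pi; row$k <- st$k
      if (!is.null(scheme)) {
        sub <- codon_alignment(f$retained,
                               aln$meta[aln$meta$id %in% rownames(f$retained), ])
        dd <- partitioned_dnds(sub, scheme, R = R, n_boot = 0)
        row$omega_PBR <- dd$omega[dd$partition == "PBR"]
        row$omega_nonPBR <- dd$omega[dd$partition == "nonPBR"]
      }
    }
    row
  })
  do.call(rbind, out)
}
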