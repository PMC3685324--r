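## Modified Nei-Gojobori dN/dS with Jukes-Cantor correction, partitioned
## into peptide-binding-region (PBR) and non-PBR codon sets.
##
## Site counting: at each codon position the three single-base mutants are
## weighted by the transition/transversion ratio R (the transition mutant
## has weight R, each transversion weight 1/2, so R = 0.5 recovers the
## unweighted classic NG86 counting).  Mutants producing stop codons are
## excluded and the position's unit weight renormalizes over the remaining
## mutants, so synonymous + nonsynonymous sites always sum to 3 per codon.
##
## Difference counting: all mutational pathways between two codons are
## enumerated (d! orderings of the d differing positions); pathways passing
## through a stop codon are excluded and the remaining pathways averaged
## with equal weight.

#' PBR codon partition scheme
#'
#' Maps exon-3 codon numbers to alignment codon indices. The default PBR
#' set is the a-priori avian peptide-binding codon list
#' {5,7,8,9,23,25,38,60,61,62,65,66,68,73}; `frame_offset` is the number of
#' exon codons missing from the alignment start (default 4: the amplicon
#' excludes the first four, largely conserved, exon codons, so exon codon 5
#' maps to alignment codon 1).
#'
#' @param pbr_exon_codons exon-coordinate codon numbers in the PBR
#' @param frame_offset exon codons absent from the alignment start
#' @return object of class `partition_scheme`
#' @export
partition_scheme <- function(pbr_exon_codons = c(5, 7, 8, 9, 23, 25, 38, 60,
                                                 61, 62, 65, 66, 68, 73),
                             frame_offset = 4) {
  structure(list(pbr_exon_codons = as.integer(pbr_exon_codons),
                 frame_offset = as.integer(frame_offset)),
            class = "partition_scheme")
}

#' Alignment codon indices of the PBR under a scheme
#' @param scheme a [partition_scheme()]
#' @param n_codons number of codons in the alignment
#' @return integer vector of alignment codon indices
#' @export
pbr_alignment_codons <- function(scheme, n_codons) {
  idx <- scheme$pbr_exon_codons - scheme$frame_offset
  idx <- idx[idx >= 1L & idx <= n_codons]
  if (!length(idx)) stop("partition error: no PBR codons map into alignment")
  sort(idx)
}

#' Read a partition file (one exon codon number per line)
#' @param path file path
#' @param frame_offset see [partition_scheme()]
#' @export
read_partition_scheme <- function(path, frame_offset = 4) {
  partition_scheme(as.integer(readLines(path)), frame_offset)
}

#' Synonymous/nonsynonymous site counts for one codon
#'
#' @param codon a 3-character string over ACGT (no gaps, not a stop)
#' @param R transition/transversion ratio; 0.5 = unweighted classic NG86
#' @return named vector `c(syn =, nonsyn =)`, summing to 3
#' @export
ng86_site_counts <- function(codon, R = 0.5) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("site error: ambiguous codon ", codon)
  aa <- osc_aa()[match(codon, osc_codons())]
  if (aa == "*") stop("site error: stop codon ", codon)
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    alts <- setdiff(.BASES, b[p])
    w <- ifelse(is_transition(b[p], alts), R, 0.5)
    mut <- vapply(alts, function(a) {
      bb <- b; bb[p] <- a; paste0(bb, collapse = "")
    }, character(1))
    maa <- osc_aa()[match(mut, osc_codons())]
    keep <- maa != "*"
    if (!any(keep)) stop("site error: all mutants are stops at position ", p)
    w <- w[keep] / sum(w[keep])
    syn <- syn + sum(w[maa[keep] == aa])
  }
  c(syn = syn, nonsyn = 3 - syn)
}

#' Synonymous/nonsynonymous differences between two codons
#'
#' Enumerates all orderings of the differing positions; pathways through
#' stop codons are excluded (if every pathway hits a stop, the count falls
#' back to including them, flagged via attribute `stop_pathways_included`).
#'
#' @param c1,c2 3-character codon strings (valid sense codons)
#' @return named vector `c(syn =, nonsyn =)` summing to the number of
#'   differing positions
#' @export
ng86_codon_differences <- function(c1, c2) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  for (cc in c(c1, c2)) {
    if (!grepl("^[ACGT]{3}$", cc)) stop("site error: ambiguous codon ", cc)
    if (is_stop_codon(cc)) stop("site error: stop codon ", cc)
  }
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  d <- length(dpos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  aa <- osc_aa(); cods <- osc_codons()
  orders <- .permutations(dpos)
  count_path <- function(ord, allow_stop) {
    cur <- b1; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b2[p]
      a1 <- aa[match(paste0(cur, collapse = ""), cods)]
      a2 <- aa[match(paste0(nxt, collapse = ""), cods)]
      if (a2 == "*" && !allow_stop) return(NULL)
      if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(orders, count_path, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  flagged <- FALSE
  if (!length(res)) {
    res <- lapply(orders, count_path, allow_stop = TRUE)
    flagged <- TRUE
  }
  m <- colMeans(do.call(rbind, res))
  out <- c(syn = m[[1]], nonsyn = m[[2]])
  if (flagged) attr(out, "stop_pathways_included") <- TRUE
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` for a proportion of differences `p`.
#'
#' @param p proportion of differences per site, in `[0, 0.75)`
#' @return corrected distance
#' @export
jc69_correct <- function(p) {
  if (any(p < 0)) stop("saturation error: negative proportion")
  if (any(p >= 0.75)) stop("saturation error: p >= 0.75, estimate undefined")
  -0.75 * log(1 - 4 * p / 3)
}

## Cached 64x64 pathway-difference tables and per-R site-count table.
.ng_tables <- function(R) {
  key <- sprintf("ng_%.10g", R)
  if (!is.null(.osc_cache[[key]])) return(.osc_cache[[key]])
  cods <- osc_codons(); aa <- osc_aa()
  sense <- which(aa != "*")
  SYN <- NONSYN <- matrix(NA_real_, 64, 64)
  for (i in sense) for (j in sense) {
    if (j < i) next
    d <- ng86_codon_differences(cods[i], cods[j])
    SYN[i, j] <- SYN[j, i] <- d[["syn"]]
    NONSYN[i, j] <- NONSYN[j, i] <- d[["nonsyn"]]
  }
  S <- N <- rep(NA_real_, 64)
  for (i in sense) {
    sc <- ng86_site_counts(cods[i], R)
    S[i] <- sc[["syn"]]; N[i] <- sc[["nonsyn"]]
  }
  tab <- list(SYN = SYN, NONSYN = NONSYN, S = S, N = N)
  .osc_cache[[key]] <- tab
  tab
}

#' Partitioned dN/dS by the modified Nei-Gojobori method
#'
#' For each codon partition (PBR, non-PBR, all), computes per sequence pair
#' the proportions of synonymous and nonsynonymous differences per
#' synonymous/nonsynonymous site (site counts averaged over the pair,
#' codons with gaps/N/stops deleted pairwise), applies the Jukes-Cantor
#' correction per pair, and averages over pairs. Standard errors come from
#' bootstrap resampling of codon columns within the partition.
#'
#' @param aln a [codon_alignment()]
#' @param scheme a [partition_scheme()]
#' @param group optional character vector of sequence ids to include
#' @param R transition/transversion ratio for site counting (0.5 =
#'   unweighted)
#' @param n_boot bootstrap replicates for SEs (0 = no SEs)
#' @param seed optional RNG seed for the bootstrap
#' @param partitions which partitions to report
#' @return data.frame with one row per partition: dN, dS, se_dN, se_dS,
#'   omega, site-count proportions and pair/codon counts
#' @export
partitioned_dnds <- function(aln, scheme, group = NULL, R = 0.5,
                             n_boot = 1000, seed = NULL,
                             partitions = c("PBR", "nonPBR", "all")) {
  mat <- aln$mat
  if (!is.null(group)) mat <- mat[rownames(mat) %in% group, , drop = FALSE]
  if (nrow(mat) < 2L) stop("undefined error: need >= 2 sequences in group")
  if (!is.null(seed)) set.seed(seed)
  tab <- .ng_tables(R)
  ci <- codon_index_matrix(mat)            # n x C, NA for gap/N/stop codons
  nC <- ncol(ci)
  pbr <- pbr_alignment_codons(scheme, nC)
  part_idx <- list(PBR = pbr, nonPBR = setdiff(seq_len(nC), pbr),
                   all = seq_len(nC))
  pr <- combn(nrow(ci), 2)
  np <- ncol(pr)
  ## per-pair per-codon arrays (0 where the codon is deleted for that pair)
  i1 <- ci[pr[1, ], , drop = FALSE]; i2 <- ci[pr[2, ], , drop = FALSE]
  ok <- !is.na(i1) & !is.na(i2)
  idx <- cbind(as.vector(i1), as.vector(i2))
  Sd <- matrix(tab$SYN[idx], np, nC);  Sd[!ok] <- 0
  Nd <- matrix(tab$NONSYN[idx], np, nC); Nd[!ok] <- 0
  Ss <- (matrix(tab$S[i1], np, nC) + matrix(tab$S[i2], np, nC)) / 2
  Ns <- (matrix(tab$N[i1], np, nC) + matrix(tab$N[i2], np, nC)) / 2
  Ss[!ok] <- 0; Ns[!ok] <- 0

  jc_safe <- function(p) {
    d <- rep(NA_real_, length(p))
    okp <- is.finite(p) & p >= 0 & p < 0.75
    d[okp] <- -0.75 * log(1 - 4 * p[okp] / 3)
    d
  }
  point <- function(cols) {
    ps <- rowSums(Sd[, cols, drop = FALSE]) / rowSums(Ss[, cols, drop = FALSE])
    pn <- rowSums(Nd[, cols, drop = FALSE]) / rowSums(Ns[, cols, drop = FALSE])
    c(dN = mean(jc_safe(pn), na.rm = TRUE), dS = mean(jc_safe(ps), na.rm = TRUE))
  }

  out <- lapply(partitions, function(pn) {
    cols <- part_idx[[pn]]
    if (!length(cols)) stop("partition error: empty partition ", pn)
    est <- point(cols)
    se <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      reps <- vapply(seq_len(n_boot), function(b) {
        point(sample(cols, length(cols), replace = TRUE))
      }, numeric(2))
      se <- apply(reps, 1, sd, na.rm = TRUE)
    }
    syn_sites <- mean(rowSums(Ss[, cols, drop = FALSE]))
    nonsyn_sites <- mean(rowSums(Ns[, cols, drop = FALSE]))
    data.frame(partition = pn, n_codons = length(cols), n_pairs = np,
               dN = est[["dN"]], dS = est[["dS"]],
               se_dN = se[[1]], se_dS = se[[2]],
               omega = if (is.finite(est[["dS"]]) && est[["dS"]] > 0)
                 est[["dN"]] / est[["dS"]] else NA_real_,
               prop_nonsyn_sites = nonsyn_sites / (syn_sites + nonsyn_sites),
               prop_syn_sites = syn_sites / (syn_sites + nonsyn_sites))
  })
  do.call(rbind, out)
}
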