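## GC content by codon position and Welch's unequal-variance t test.

#' Per-sequence GC content by codon position
#'
#' Percent G+C at each codon position (over non-gap, non-N bases at that
#' position) and over all positions.
#'
#' @param aln a [codon_alignment()], character matrix, or single sequence
#'   string/character vector (length a multiple of 3)
#' @return data.frame with columns `id`, `gc1`, `gc2`, `gc3`, `gc_all`
#'   (percent; `NaN` when a position has no scorable base)
#' @export
gc_profile <- function(aln) {
  mat <- if (inherits(aln, "codon_alignment")) aln$mat
         else if (is.matrix(aln)) aln
         else {
           b <- if (length(aln) == 1L) strsplit(toupper(aln), "")[[1]]
                else toupper(aln)
           matrix(b, 1, dimnames = list("seq1"))
         }
  if (ncol(mat) %% 3L != 0L) stop("frame error: length not a multiple of 3")
  pos <- rep(1:3, length.out = ncol(mat))
  one <- function(x) {
    gc_at <- function(sel) {
      v <- x[sel]; v <- v[v %in% .BASES]
      if (!length(v)) return(NaN)
      100 * mean(v %in% c("G", "C"))
    }
    c(gc1 = gc_at(pos == 1), gc2 = gc_at(pos == 2), gc3 = gc_at(pos == 3),
      gc_all = gc_at(rep(TRUE, length(x))))
  }
  prof <- t(apply(mat, 1, one))
  data.frame(id = rownames(mat), prof, row.names = NULL)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. Sign convention: `t` is computed as
#' `mean(a) - mean(b)` over the pooled standard error.
#'
#' @param a,b numeric vectors (each of length >= 2)
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("test error: each group needs >= 2 values")
  va <- var(a) / length(a); vb <- var(b) / length(b)
  if (va + vb == 0) stop("test error: degenerate (zero) variance")
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Clade GC comparison (GC3 and all positions)
#'
#' Computes per-sequence GC profiles (outgroup excluded) and Welch tests
#' comparing songbirds (group a) with non-passerines (group b).
#'
#' @param aln a [codon_alignment()] with clade metadata
#' @return list with `profiles` (data.frame incl. clade), `gc3` and
#'   `gc_all` Welch results
#' @export
clade_gc_tests <- function(aln) {
  prof <- gc_profile(aln)
  prof$clade <- aln$meta$clade[match(prof$id, aln$meta$id)]
  keep <- prof$clade != "outgroup"
  a <- prof[keep & prof$clade == "songbird", ]
  b <- prof[keep & prof$clade == "nonpasserine", ]
  list(profiles = prof,
       gc3 = welch_test(a$gc3, b$gc3),
       gc_all = welch_test(a$gc_all, b$gc_all))
}
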