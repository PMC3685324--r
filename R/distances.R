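## Pairwise nucleotide distances: Kimura 2-parameter and Tamura-Nei 1993
## with gamma rate-variation correction.  Gaps and N are deleted pairwise;
## base frequencies for TN93 are estimated per pair over the compared
## sites.

#' Pairwise distance matrix
#'
#' @param aln a [codon_alignment()] or character matrix
#' @param model `"TN93G"` (Tamura-Nei with gamma correction) or `"K2P"`
#' @param alpha gamma shape for TN93G (default 0.78); ignored for K2P.
#'   `alpha = Inf` gives plain TN93.
#' @return symmetric numeric matrix with sequence ids as dimnames;
#'   saturated pairs are `Inf`
#' @export
pairwise_distance <- function(aln, model = c("TN93G", "K2P"), alpha = 0.78) {
  model <- match.arg(model)
  mat <- if (inherits(aln, "codon_alignment")) aln$mat else aln
  n <- nrow(mat)
  if (n < 2L) stop("size error: need >= 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- a %in% .BASES & b %in% .BASES
    if (!any(ok)) stop("size error: zero compared sites for pair ",
                       rownames(mat)[i], "/", rownames(mat)[j])
    d <- if (model == "K2P") .k2p_dist(a[ok], b[ok])
         else .tn93_dist(a[ok], b[ok], alpha)
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "model") <- model
  D
}

.k2p_dist <- function(a, b) {
  L <- length(a)
  diff <- a != b
  ts <- diff & is_transition(a, b)
  P <- sum(ts) / L
  Q <- sum(diff & !ts) / L
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1) - 0.25 * log(w2)
}

.tn93_dist <- function(a, b, alpha = 0.78) {
  L <- length(a)
  f <- (table(factor(a, .BASES)) + table(factor(b, .BASES))) / (2 * L)
  pA <- f[["A"]]; pC <- f[["C"]]; pG <- f[["G"]]; pT <- f[["T"]]
  pR <- pA + pG; pY <- pC + pT
  diff <- a != b
  P1 <- sum(diff & a %in% c("A", "G") & b %in% c("A", "G")) / L
  P2 <- sum(diff & a %in% c("C", "T") & b %in% c("C", "T")) / L
  Q <- sum(diff & is_transition(a, b) == FALSE) / L
  if (pA * pG == 0 || pC * pT == 0 || pR * pY == 0) return(Inf)
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pT * pC / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pT * pC * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(Inf)
  if (is.finite(alpha)) {
    alpha * (k1 * w1^(-1 / alpha) + k2 * w2^(-1 / alpha) +
               k3 * w3^(-1 / alpha) - (k1 + k2 + k3))
  } else {
    -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  }
}
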