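## Codon bookkeeping shared by the classifier, the dN/dS counters and the
## simulator.  The standard nuclear code is taken from Biostrings; codons
## are indexed 1..64 in the order of `osc_codons()`.

.BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#' @return character vector of length 64
#' @keywords internal
osc_codons <- function() {
  if (!is.null(.osc_cache$codons)) return(.osc_cache$codons)
  cod <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  cod <- sort(cod)
  .osc_cache$codons <- cod
  cod
}

#' Amino acid translation of the 64 codons (standard code, "*" = stop)
#' @keywords internal
osc_aa <- function() {
  if (!is.null(.osc_cache$aa)) return(.osc_cache$aa)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[osc_codons()])
  .osc_cache$aa <- aa
  aa
}

is_stop_codon <- function(codon) {
  aa <- osc_aa()[match(codon, osc_codons())]
  !is.na(aa) & aa == "*"
}

#' Is the single-base change b1 -> b2 a transition?
#' @keywords internal
is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") & b2 %in% c("A", "G")) |
    (b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}

## Integer codon indices (1..64, NA for anything containing gap/N/ambiguity
## and for stop codons when drop_stops = TRUE).
codon_index_matrix <- function(mat, drop_stops = TRUE) {
  stopifnot(ncol(mat) %% 3 == 0)
  nc <- ncol(mat) / 3L
  cods <- osc_codons()
  out <- matrix(NA_integer_, nrow(mat), nc)
  for (j in seq_len(nc)) {
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    cstr <- paste0(mat[, cols[1]], mat[, cols[2]], mat[, cols[3]])
    idx <- match(cstr, cods)
    out[, j] <- idx
  }
  if (drop_stops) {
    stops <- which(osc_aa() == "*")
    out[out %in% stops] <- NA_integer_
  }
  rownames(out) <- rownames(mat)
  out
}
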