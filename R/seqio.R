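## Codon alignments: a character matrix of aligned bases plus per-sequence
## metadata (species, family, clade).  Clades follow the three-way labelling
## used throughout: "songbird", "nonpasserine", "outgroup".

.CLADES <- c("songbird", "nonpasserine", "outgroup")

#' Construct a codon alignment
#'
#' @param mat character matrix of single upper-case characters over
#'   `A,C,G,T,N,-`; rows are sequences, rownames are sequence ids.
#' @param meta data.frame with columns `id`, `species`, `family`, `clade`;
#'   one row per sequence. Row order is matched to `mat` by `id`.
#' @return an object of class `codon_alignment` with elements `mat`,
#'   `meta` and `n_codons`.
#' @export
codon_alignment <- function(mat, meta) {
  if (is.null(rownames(mat))) stop("alignment matrix must have rownames (ids)")
  if (anyDuplicated(rownames(mat))) stop("duplicated sequence ids")
  if (ncol(mat) %% 3L != 0L)
    stop("frame error: alignment length ", ncol(mat), " is not a multiple of 3")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alphabet error: unexpected characters: ", paste(bad, collapse = " "))
  need <- c("id", "species", "family", "clade")
  if (!all(need %in% names(meta)))
    stop("metadata error: metadata must have columns ", paste(need, collapse = ", "))
  miss <- setdiff(rownames(mat), meta$id)
  if (length(miss))
    stop("metadata error: no metadata for: ", paste(miss, collapse = ", "))
  if (!all(meta$clade %in% .CLADES))
    stop("metadata error: clade must be one of ", paste(.CLADES, collapse = "/"))
  meta <- meta[match(rownames(mat), meta$id), need, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(mat = mat, meta = meta, n_codons = ncol(mat) %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x$mat), "sequences x", x$n_codons,
      "codons (", ncol(x$mat), "sites )\n")
  cat("clades:", paste(sprintf("%s=%d", names(table(x$meta$clade)),
                               table(x$meta$clade)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned FASTA plus metadata TSV into a codon alignment
#'
#' The FASTA must be a gapped alignment whose records all have the same
#' length, divisible by 3. The metadata file is a 4-column, header-bearing
#' TSV (`id`, `species`, `family`, `clade`).
#'
#' @param fasta_path path to the aligned FASTA file
#' @param metadata_path path to the metadata TSV
#' @return a [codon_alignment()]
#' @export
read_codon_alignment <- function(fasta_path, metadata_path) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0) stop("format error: empty FASTA")
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("format error: ragged alignment (record lengths differ)")
  mat <- toupper(as.character(as.matrix(dna)))
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     colClasses = "character", fileEncoding = "UTF-8")
  codon_alignment(mat, meta)
}

#' Write a codon alignment to FASTA (and optionally metadata TSV)
#'
#' @param aln a [codon_alignment()]
#' @param fasta_path output FASTA path
#' @param metadata_path optional output TSV path
#' @export
write_codon_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  ids <- rownames(aln$mat)
  seqs <- apply(aln$mat, 1, paste0, collapse = "")
  writeLines(paste0(">", ids, "\n", seqs), fasta_path)
  if (!is.null(metadata_path))
    write.table(aln$meta, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}

#' Classify a sequence as putatively functional or pseudogene
#'
#' A sequence is non-functional if any ungapped codon translates to a stop
#' under the standard code, or if any codon contains one or two gap
#' characters (a whole-codon gap is read as a clean codon deletion and
#' tolerated).
#'
#' @param bases a gapped nucleotide string or character vector of bases
#'   (length a multiple of 3)
#' @param id sequence id carried through to the result
#' @return list with `id`, `functional` and `reasons` (one or more of
#'   `"stop_codon"`, `"frameshift_gap"`, `"none"`)
#' @export
classify_sequence <- function(bases, id = NA_character_) {
  if (length(bases) == 1L) bases <- strsplit(bases, "")[[1]]
  bases <- toupper(bases)
  bad <- setdiff(unique(bases), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("alphabet error: unexpected characters: ", paste(bad, collapse = " "))
  if (length(bases) %% 3L != 0L)
    stop("frame error: length not a multiple of 3")
  cods <- matrix(bases, nrow = 3L)
  ngap <- colSums(cods == "-")
  reasons <- character(0)
  if (any(ngap %in% c(1L, 2L))) reasons <- c(reasons, "frameshift_gap")
  full <- which(ngap == 0L)
  if (length(full)) {
    cstr <- apply(cods[, full, drop = FALSE], 2, paste0, collapse = "")
    aa <- osc_aa()[match(cstr, osc_codons())]   # NA for codons containing N
    if (any(!is.na(aa) & aa == "*")) reasons <- c(reasons, "stop_codon")
  }
  reasons <- intersect(c("stop_codon", "frameshift_gap"), reasons)
  if (!length(reasons)) reasons <- "none"
  list(id = id, functional = identical(reasons, "none"), reasons = reasons)
}

## Pairwise Hamming distance with pairwise deletion of gap (and N) columns.
.hamming_pd <- function(a, b) {
  ok <- a %in% .BASES & b %in% .BASES
  sum(a[ok] != b[ok])
}

#' Filter sequences to putative alleles
#'
#' Implements the allele-validity rule used for clone-derived repertoires:
#' discard sequences with stop codons or frame-disrupting gaps, then
#' cluster the remaining sequences by single linkage at pairwise Hamming
#' distance below `min_nt_diff` (columns where either sequence has a gap or
#' N are ignored) and keep one representative per cluster, the first in
#' input order. Every retained pair therefore differs at `>= min_nt_diff`
#' sites.
#'
#' @param mat character matrix of aligned sequences (rows) from one
#'   individual or species, or a [codon_alignment()]
#' @param min_nt_diff minimum number of nucleotide differences between
#'   distinct alleles (default 3)
#' @return list with `retained` (character matrix of kept rows) and
#'   `discarded` (data.frame: id, reason)
#' @export
filter_putative_alleles <- function(mat, min_nt_diff = 3) {
  if (inherits(mat, "codon_alignment")) mat <- mat$mat
  stopifnot(min_nt_diff >= 1)
  if (is.null(mat) || nrow(mat) == 0L)
    return(list(retained = mat, discarded = data.frame(id = character(0),
                                                       reason = character(0))))
  cls <- lapply(rownames(mat), function(id) classify_sequence(mat[id, ], id))
  fun <- vapply(cls, `[[`, logical(1), "functional")
  disc <- data.frame(
    id = vapply(cls[!fun], `[[`, character(1), "id"),
    reason = vapply(cls[!fun], function(z) paste(z$reasons, collapse = ";"),
                    character(1)))
  fm <- mat[fun, , drop = FALSE]
  n <- nrow(fm)
  if (n <= 1L) return(list(retained = fm, discarded = disc))
  ## single-linkage clusters: union-find over pairs with distance < min_nt_diff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (.hamming_pd(fm[i, ], fm[j, ]) < min_nt_diff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- !duplicated(roots)           # first member of each cluster
  dup <- data.frame(id = rownames(fm)[!keep],
                    reason = rep("below_min_diff", sum(!keep)))
  list(retained = fm[keep, , drop = FALSE],
       discarded = rbind(disc, dup))
}
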