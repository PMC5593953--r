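#' @keywords internal
"_PACKAGE"

#' @useDynLib tgloc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median pchisq rbinom rmultinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

# random DNA string over A/C/G/T (uniform); caller controls the RNG state
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# vectorized reverse complement on plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# single base at 0-based offset i0
chr_at <- function(s, i0) substring(s, i0 + 1L, i0 + 1L)

# 0-based half-open interval overlap width
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Canonical junction positions under microhomology. An ungapped aligner
# extends a read's genome segment as far as the bases keep matching, so at a
# genome|insert junction whose flanks share h identical bases the reported
# clip boundary is the maximal genome extension: rightmost for the left
# (genome -> insert) junction, leftmost for the right (insert -> genome)
# junction. The truth set records the same maximal-extension positions so
# that split-read calls and truth agree exactly. Plus-orientation inserts
# only; minus-orientation junctions keep their construction coordinate.
extend_junction_right <- function(genome_seq, insert_seq, p, v) {
  gl <- nchar(genome_seq); il <- nchar(insert_seq)
  while (p < gl && v < il &&
         chr_at(genome_seq, p) == chr_at(insert_seq, v)) {
    p <- p + 1L; v <- v + 1L
  }
  c(genome_pos = p, vector_pos = v)
}

extend_junction_left <- function(genome_seq, insert_seq, p, v) {
  while (p > 0L && v > 0L &&
         chr_at(genome_seq, p - 1L) == chr_at(insert_seq, v - 1L)) {
    p <- p - 1L; v <- v - 1L
  }
  c(genome_pos = p, vector_pos = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tgloc <- function(...) stop(..., call. = FALSE)
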