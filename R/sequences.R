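DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Rotate a circular sequence
#'
#' Left-rotates `x` by `k` positions: the first `k` characters are moved to
#' the end. Monomer consensus sequences are circular, so all rotations of a
#' monomer spell the same repeat.
#'
#' @param x a single DNA string.
#' @param k integer rotation (any integer; taken modulo `nchar(x)`).
#' @return the rotated string.
#' @export
rotate_seq <- function(x, k) {
  n <- nchar(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

#' Canonical form of a circular monomer
#'
#' Returns the lexicographically smallest rotation over both strands, so
#' that consensus sequences are comparable across runs regardless of the
#' phase and strand in which they were assembled.
#'
#' @param x a single DNA string.
#' @return the canonical rotation.
#' @export
canonical_rotation <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  rots <- function(s) vapply(seq_len(n) - 1L, function(k) rotate_seq(s, k), "")
  min(c(rots(x), rots(revcomp(x))))
}

# uniform random DNA with a target A+T fraction; assumes RNG state is set
random_dna <- function(n, at_fraction = 0.5) {
  p <- c(at_fraction / 2, (1 - at_fraction) / 2, (1 - at_fraction) / 2,
         at_fraction / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

check_dna <- function(x, arg = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(arg, " must be a single non-empty DNA string", call. = FALSE)
  x <- toupper(x)
  if (grepl("[^ACGTN]", x))
    stop(arg, " contains characters other than A/C/G/T/N", call. = FALSE)
  x
}

# classify aligned columns of two equal-length gapped strings into matches,
# transitions (A<->G, C<->T), transversions and gap columns. N columns are
# mismatches but are excluded from the substitution counts.
classify_columns <- function(a_aln, b_aln) {
  a <- strsplit(a_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(b_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(a) == length(b))
  gap <- a == "-" | b == "-"
  amb <- !gap & (a == "N" | b == "N")
  mat <- !gap & !amb & a == b
  sub <- !gap & !amb & a != b
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- sub & (pur[a] == pur[b])
  tv <- sub & !ts
  list(columns = length(a), matches = sum(mat), transitions = sum(ts),
       transversions = sum(tv), gap_columns = sum(gap),
       ambiguous = sum(amb))
}
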