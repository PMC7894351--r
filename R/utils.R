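#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T; other letters become N).
#' @return Character vector of reverse complements, names preserved.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) .rc_cpp(as.character(x))

#' Generate random DNA
#'
#' Uniform i.i.d. bases; uses the current RNG stream.
#'
#' @param n Sequence length in bp.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Half-up rounding (round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Number of mismatching positions between two equal-length strings.
seq_mismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# 1-based positions at which two equal-length strings differ.
mismatch_positions <- function(a, b) .mismatch_positions_cpp(a, b)

# Substitute bases at 1-based positions of a sequence string.
substitute_bases <- function(seq, pos, bases) {
  if (length(pos) == 0L) return(seq)
  r <- charToRaw(seq)
  r[pos] <- charToRaw(paste(bases, collapse = ""))
  rawToChar(r)
}

# For each base, a different base drawn uniformly from the other three.
mutate_bases <- function(bases) {
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  idx <- sample.int(3L, length(bases), replace = TRUE)
  vapply(seq_along(bases), function(i) {
    substr(alt[[bases[i]]], idx[i], idx[i])
  }, character(1))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
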