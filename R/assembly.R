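#' Assembly configuration
#'
#' Parameters for read baiting and de Bruijn assembly. Baiting with
#' `k_filter = 21` and `min_shared_kmers = 2` tolerates ~90 SNPs/kb of
#' divergence between reads and bait on 150 bp reads (at that density a read
#' still carries clean 21-mer windows between substitutions).
#'
#' @param k_filter Baiting k-mer size (odd, default 21).
#' @param min_shared_kmers Minimum shared canonical k-mer windows for a read
#'   pair to be retained (default 2).
#' @param k_asm Assembly k-mer size (odd, default 31, must be below the read
#'   length).
#' @param min_kmer_count Solid k-mer threshold (default 3).
#' @param max_iterations Maximum bait-assemble iterations (default 10).
#' @return Object of class `assembly_config`.
#' @export
assembly_config <- function(k_filter = 21L, min_shared_kmers = 2L,
                            k_asm = 31L, min_kmer_count = 3L,
                            max_iterations = 10L) {
  stopifnot(k_filter %% 2L == 1L, k_asm %% 2L == 1L,
            k_filter <= 31L, k_asm <= 31L,
            min_shared_kmers >= 1L, min_kmer_count >= 1L, max_iterations >= 1L)
  structure(list(k_filter = as.integer(k_filter),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 k_asm = as.integer(k_asm),
                 min_kmer_count = as.integer(min_kmer_count),
                 max_iterations = as.integer(max_iterations)),
            class = "assembly_config")
}

#' Filter read pairs by k-mer sharing with a bait
#'
#' A pair is retained iff either mate has at least `min_shared_kmers` k-mer
#' windows whose canonical k-mer occurs in the bait set. Output order is the
#' input order; the filter is a pure function of each pair and the bait k-mer
#' set.
#'
#' @param r1,r2 Character vectors of mate sequences (equal length), or `r1`
#'   may be a `read_set`.
#' @param bait Character vector of bait sequences (non-empty).
#' @param cfg An [assembly_config()].
#' @return List with retained `r1`, `r2` and the logical `retained` mask.
#' @export
kmer_filter_reads <- function(r1, r2 = NULL, bait, cfg = assembly_config()) {
  if (inherits(r1, "read_set")) {
    rs <- r1
    r1 <- rs$r1
    r2 <- rs$r2
  }
  stopifnot(length(bait) >= 1L, length(r1) == length(r2))
  if (length(r1) == 0L) {
    return(list(r1 = r1, r2 = r2, retained = logical(0)))
  }
  c1 <- .shared_kmer_counts_cpp(unname(as.character(r1)), as.character(bait), cfg$k_filter)
  c2 <- .shared_kmer_counts_cpp(unname(as.character(r2)), as.character(bait), cfg$k_filter)
  keep <- c1 >= cfg$min_shared_kmers | c2 >= cfg$min_shared_kmers
  list(r1 = r1[keep], r2 = r2[keep], retained = keep)
}

#' de Bruijn assembly of unitigs
#'
#' Builds the graph of solid canonical `k_asm`-mers (count at or above
#' `min_kmer_count`) and emits every maximal non-branching path exactly once.
#' Components forming perfect cycles are emitted with the first
#' `(k_asm - 1)`-mer duplicated at the end (the terminal-overlap signature of
#' a circular molecule). Contigs are reported in canonical orientation,
#' ordered by length descending then lexicographically.
#'
#' @param reads Character vector of reads, or a `read_set`.
#' @param cfg An [assembly_config()].
#' @return List of [circular_genome()] contigs (with `circular` flags);
#'   attribute `n_solid_kmers`.
#' @export
debruijn_assemble <- function(reads, cfg = assembly_config()) {
  if (inherits(reads, "read_set")) reads <- c(reads$r1, reads$r2)
  stopifnot(length(reads) >= 1L)
  res <- .assemble_cpp(unname(as.character(reads)), cfg$k_asm, cfg$min_kmer_count)
  contigs <- res$contigs
  circ <- res$circular
  if (length(contigs) > 0L) {
    ord <- order(-nchar(contigs), contigs)
    contigs <- contigs[ord]
    circ <- circ[ord]
  }
  out <- lapply(seq_along(contigs), function(i) {
    circular_genome(sprintf("contig_%03d", i), contigs[i], circular = circ[i])
  })
  attr(out, "n_solid_kmers") <- res$n_solid_kmers
  out
}

#' Normalize a circular sequence's rotation and strand
#'
#' The canonical form is the lexicographically minimal rotation of the
#' lexicographically smaller strand; two assemblies of the same circle always
#' normalize to the same string.
#'
#' @param seq DNA string representing a full circle (no duplicated overlap).
#' @return Normalized string.
#' @export
rotation_normalize <- function(seq) {
  norm_one <- function(s) {
    i <- .min_rotation_cpp(s)
    paste0(substr(s, i + 1L, nchar(s)), substr(s, 1L, i))
  }
  a <- norm_one(seq)
  b <- norm_one(revcomp(seq))
  if (a <= b) a else b
}

#' Test a contig for circularity
#'
#' A contig is circular when its first `(k_asm - 1)`-mer equals its last
#' `(k_asm - 1)`-mer (the closure signature left by [debruijn_assemble()]).
#' If circular, the duplicated terminal overlap is trimmed and the sequence
#' rotation/strand-normalized ([rotation_normalize()]).
#'
#' @param contig A [circular_genome()] or DNA string.
#' @param cfg An [assembly_config()] supplying `k_asm`.
#' @return List: `circular` flag and `sequence` (normalized if circular,
#'   unchanged otherwise).
#' @export
detect_circularity <- function(contig, cfg = assembly_config()) {
  seq <- if (inherits(contig, "circular_genome")) contig$sequence else contig
  k <- cfg$k_asm
  n <- nchar(seq)
  if (n <= k) {
    warning("contig shorter than k_asm; not circular")
    return(list(circular = FALSE, sequence = seq))
  }
  ov <- k - 1L
  circ <- substr(seq, 1L, ov) == substr(seq, n - ov + 1L, n)
  if (!circ) return(list(circular = FALSE, sequence = seq))
  core <- substr(seq, 1L, n - ov)
  list(circular = TRUE, sequence = rotation_normalize(core))
}

#' Iterative reference-baited organelle assembly
#'
#' Repeats bait -> filter -> assemble -> circularity test, re-baiting each
#' iteration with the previous iteration's contigs, until a single circular
#' contig is obtained or `max_iterations` is reached. Each round lets read
#' overhangs extend the bait into genome regions absent from the seed
#' reference, so a diverged or incomplete seed converges in a few rounds.
#'
#' @param r1,r2 Mate sequences (equal-length vectors), or `r1` may be a
#'   `read_set`.
#' @param seed_reference Character vector of seed sequences (non-empty).
#' @param cfg An [assembly_config()].
#' @return Object of class `assembly_result`: `contigs` (list of
#'   [circular_genome()]; circular contigs rotation-normalized),
#'   `iterations_used`, `converged`, `log` (per-iteration reads retained,
#'   contig counts).
#' @export
iterative_assemble <- function(r1, r2 = NULL, seed_reference,
                               cfg = assembly_config()) {
  if (inherits(r1, "read_set")) {
    rs <- r1
    r1 <- rs$r1
    r2 <- rs$r2
  }
  stopifnot(length(seed_reference) >= 1L)
  bait <- as.character(seed_reference)
  log <- data.frame(iteration = integer(0), reads_retained = integer(0),
                    n_contigs = integer(0), n_circular = integer(0))
  contigs <- list()
  converged <- FALSE
  it <- 0L
  while (it < cfg$max_iterations) {
    it <- it + 1L
    flt <- kmer_filter_reads(r1, r2, bait, cfg)
    reads <- c(flt$r1, flt$r2)
    if (length(reads) == 0L) {
      log <- rbind(log, data.frame(iteration = it, reads_retained = 0L,
                                   n_contigs = 0L, n_circular = 0L))
      break
    }
    contigs <- debruijn_assemble(reads, cfg)
    # short leftover contigs are routine here; their warning is for direct use
    checked <- lapply(contigs, function(ct) {
      suppressWarnings(detect_circularity(ct, cfg))
    })
    contigs <- lapply(seq_along(contigs), function(i) {
      circular_genome(contigs[[i]]$id, checked[[i]]$sequence,
                      circular = checked[[i]]$circular)
    })
    n_circ <- sum(vapply(contigs, function(ct) ct$circular, logical(1)))
    log <- rbind(log, data.frame(iteration = it,
                                 reads_retained = sum(flt$retained),
                                 n_contigs = length(contigs),
                                 n_circular = n_circ))
    if (n_circ == 1L) {
      converged <- TRUE
      break
    }
    bait <- vapply(contigs, function(ct) ct$sequence, character(1))
    if (length(bait) == 0L) break
  }
  structure(list(contigs = contigs, iterations_used = it,
                 converged = converged, log = log),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> %s after %d iteration(s), %d contig(s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations_used, length(x$contigs)))
  print(x$log, row.names = FALSE)
  invisible(x)
}
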