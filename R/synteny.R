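#' Find unique shared k-mer anchors between two genomes
#'
#' Anchors are k-mers occurring exactly once (canonical counting, both
#' strands) in each genome, matched across genomes with orientation.
#' Circular genomes are scanned with a wrap so k-mers spanning the origin
#' are counted; positions are 0-based on each genome's forward strand.
#'
#' @param genome_a,genome_b [circular_genome()] objects or DNA strings.
#' @param k Anchor k-mer size (default 31; at this size chance collisions
#'   are negligible at the 100 kb organelle scale).
#' @return Data frame of class `anchor_set`, sorted by `position_a`:
#'   `position_a`, `position_b`, `orientation` (`"forward"`/`"reverse"`);
#'   attribute `k`.
#' @export
find_anchors <- function(genome_a, genome_b, k = 31L) {
  get_seq <- function(g) if (inherits(g, "circular_genome")) g$sequence else g
  get_circ <- function(g) if (inherits(g, "circular_genome")) g$circular else FALSE
  a <- get_seq(genome_a)
  b <- get_seq(genome_b)
  stopifnot(nchar(a) >= k, nchar(b) >= k, k <= 31L)
  out <- .unique_anchors_cpp(a, b, as.integer(k), get_circ(genome_a),
                             get_circ(genome_b))
  attr(out, "k") <- as.integer(k)
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Chain anchors into collinear synteny blocks
#'
#' Greedy chaining of same-orientation anchors with a consistent diagonal:
#' consecutive anchors must satisfy `|dA - dB| <= max_gap` (forward) or
#' `|dA + dB| <= max_gap` with B decreasing (reverse). Runs shorter than
#' `min_anchors` are dropped. Block intervals are 0-based half-open bounding
#' boxes including the final k-mer.
#'
#' @param anchors An `anchor_set` from [find_anchors()] (sorted by
#'   `position_a`).
#' @param max_gap Maximum diagonal drift between consecutive anchors (bp).
#' @param min_anchors Minimum anchors per reported block (default 10).
#' @return Data frame of class `synteny_blocks`: `start_a`, `end_a`,
#'   `start_b`, `end_b`, `orientation`, `n_anchors`.
#' @export
chain_anchors <- function(anchors, max_gap = 2000L, min_anchors = 10L) {
  k <- attr(anchors, "k") %||% 31L
  n <- nrow(anchors)
  blocks <- list()
  if (n > 0L) {
    pa <- anchors$position_a
    pb <- anchors$position_b
    ori <- anchors$orientation
    start <- 1L
    flush <- function(from, to) {
      if (to - from + 1L < min_anchors) return(NULL)
      ia <- pa[from:to]
      ib <- pb[from:to]
      # alignment diagonal: forward b = a + diag; reverse b = anti - a
      data.frame(start_a = min(ia), end_a = max(ia) + k,
                 start_b = min(ib), end_b = max(ib) + k,
                 orientation = ori[from], n_anchors = to - from + 1L,
                 diag = stats::median(ib - ia),
                 anti = stats::median(ia + ib + k - 1L),
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(n)[-1]) {
      da <- pa[i] - pa[i - 1L]
      db <- pb[i] - pb[i - 1L]
      diag_ok <- if (ori[i] == "forward") {
        db > 0L && abs(da - db) <= max_gap
      } else {
        db < 0L && abs(da + db) <= max_gap
      }
      compatible <- ori[i] == ori[i - 1L] && diag_ok
      if (!compatible) {
        blocks[[length(blocks) + 1L]] <- flush(start, i - 1L)
        start <- i
      }
    }
    blocks[[length(blocks) + 1L]] <- flush(start, n)
  }
  out <- do.call(rbind, Filter(Negate(is.null), blocks))
  if (is.null(out)) {
    out <- data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      orientation = character(0), n_anchors = integer(0),
                      diag = integer(0), anti = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "k") <- k
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' Report inversions from synteny blocks
#'
#' Reverse-orientation blocks are inversions. Without sequences, breakpoints
#' are the anchor bounding-box bounds on genome A; anchors thin out near
#' breakpoints at high divergence (no clean shared k-mer survives), so when
#' the two genome sequences are supplied each breakpoint is refined as the
#' changepoint between the flanking collinear diagonal and the inverted
#' anti-diagonal that minimizes total base mismatches across the junction.
#'
#' @param blocks A `synteny_blocks` data frame from [chain_anchors()].
#' @param genome_a,genome_b Optional sequences ([circular_genome()] or
#'   strings) for breakpoint refinement.
#' @return Data frame of class `inversion_set`: `start_a`, `end_a`,
#'   `start_b`, `end_b`, `n_anchors`.
#' @export
detect_inversions <- function(blocks, genome_a = NULL, genome_b = NULL) {
  out <- blocks[blocks$orientation == "reverse", , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(genome_a) && !is.null(genome_b) && nrow(out) > 0L) {
    get_seq <- function(g) if (inherits(g, "circular_genome")) g$sequence else g
    a_chr <- seq_chars(get_seq(genome_a))
    b_chr <- seq_chars(get_seq(genome_b))
    bc_chr <- seq_chars(chartr("ACGT", "TGCA", get_seq(genome_b)))
    k <- attr(blocks, "k") %||% 31L
    fwd <- blocks[blocks$orientation == "forward", , drop = FALSE]
    # mismatch of A base at 0-based j against B on a forward diagonal d
    mism_f <- function(j, d) {
      bj <- j + d
      ok <- bj >= 0L & bj < length(b_chr)
      res <- rep(TRUE, length(j))
      res[ok] <- a_chr[j[ok] + 1L] != b_chr[bj[ok] + 1L]
      res
    }
    # mismatch of A base at j against complemented B on anti-diagonal c
    mism_r <- function(j, cc) {
      bj <- cc - j
      ok <- bj >= 0L & bj < length(bc_chr)
      res <- rep(TRUE, length(j))
      res[ok] <- a_chr[j[ok] + 1L] != bc_chr[bj[ok] + 1L]
      res
    }
    # changepoint x in [lo, hi] minimizing left-regime + right-regime mismatches
    changepoint <- function(lo, hi, mism_left, mism_right) {
      lo <- max(0L, lo)
      hi <- min(length(a_chr), hi)
      if (hi <= lo) return(lo)
      j <- lo:(hi - 1L)
      ml <- mism_left(j)
      mr <- mism_right(j)
      # total(x) = sum(ml[j < x]) + sum(mr[j >= x]); x in lo..hi
      tot <- c(0, cumsum(ml)) + rev(c(0, cumsum(rev(mr))))
      lo + which.min(tot) - 1L
    }
    for (r in seq_len(nrow(out))) {
      cc <- out$anti[r]
      left_f <- fwd[fwd$end_a <= out$start_a[r] + k, , drop = FALSE]
      if (nrow(left_f) > 0L) {
        f <- left_f[which.max(left_f$end_a), ]
        out$start_a[r] <- changepoint(f$end_a - k, out$start_a[r] + k,
                                      function(j) mism_f(j, f$diag),
                                      function(j) mism_r(j, cc))
      }
      right_f <- fwd[fwd$start_a >= out$end_a[r] - k, , drop = FALSE]
      if (nrow(right_f) > 0L) {
        f <- right_f[which.min(right_f$start_a), ]
        out$end_a[r] <- changepoint(out$end_a[r] - k, f$start_a + k,
                                    function(j) mism_r(j, cc),
                                    function(j) mism_f(j, f$diag))
      }
      out$start_b[r] <- cc - (out$end_a[r] - 1L)
      out$end_b[r] <- cc - out$start_a[r] + 1L
    }
  }
  out <- out[, c("start_a", "end_a", "start_b", "end_b", "n_anchors"), drop = FALSE]
  class(out) <- c("inversion_set", "data.frame")
  out
}

#' Pairwise synteny comparison
#'
#' Convenience wrapper: anchors, chained blocks and inversions between two
#' genomes.
#'
#' @inheritParams find_anchors
#' @inheritParams chain_anchors
#' @return List with `anchors`, `blocks`, `inversions`.
#' @export
compare_synteny <- function(genome_a, genome_b, k = 31L, max_gap = 2000L,
                            min_anchors = 10L) {
  anchors <- find_anchors(genome_a, genome_b, k)
  blocks <- chain_anchors(anchors, max_gap, min_anchors)
  list(anchors = anchors, blocks = blocks,
       inversions = detect_inversions(blocks, genome_a, genome_b))
}
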