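# Shared fixtures and independent oracles used across test files.

# A tiny two-species panel spec for fast tests.
tiny_panel_spec <- function(cp_div = c(0, 35), mt_div = c(0, 20),
                            intra = 0, cp_len = 10000L, mt_len = 6000L,
                            r45s_diffs = c(0L, 20L), ...) {
  species_panel_spec(c("alpha", "beta"),
                     cp_length_bp = cp_len, mt_length_bp = mt_len,
                     cp_divergence_per_kb = cp_div,
                     mt_divergence_per_kb = mt_div,
                     intra_divergence_per_kb = intra,
                     r45s_length_bp = 1500L, r45s_copy_number = 100L,
                     r45s_fixed_diffs = r45s_diffs,
                     cp_genes = 6L, mt_genes = 4L, ...)
}

quiet_strain <- function(id, sp, seed, ...) {
  strain_spec(id, sp, seed = seed, contaminant_fraction = 0, ...)
}

# Brute-force canonical k-mer set of a sequence (oracle, string-based).
oracle_kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    rc <- revcomp(km)
    out <- c(out, pmin(km, rc))
  }
  unique(out)
}

# Brute-force count of read k-mer windows present in a bait k-mer set.
oracle_shared_count <- function(read, bait_set, k) {
  n <- nchar(read)
  if (n < k) return(0L)
  km <- substring(read, 1:(n - k + 1), k:n)
  canon <- pmin(km, revcomp(km))
  sum(canon %in% bait_set)
}

# Brute-force all-positions minimum-mismatch placement of a read on a
# circular reference; returns list(pos, strand, mismatches).
oracle_place_read <- function(read, ref) {
  L <- nchar(ref)
  rl <- nchar(read)
  doubled <- paste0(ref, substr(ref, 1, rl))
  windows <- substring(doubled, 1:L, rl:(L + rl - 1))
  score <- function(q) {
    vapply(windows, function(w) sum(charToRaw(w) != charToRaw(q)), numeric(1),
           USE.NAMES = FALSE)
  }
  mf <- score(read)
  mr <- score(revcomp(read))
  best_f <- min(mf)
  best_r <- min(mr)
  if (best_f <= best_r) {
    list(pos = which.min(mf) - 1L, strand = "+", mismatches = best_f)
  } else {
    list(pos = which.min(mr) - 1L, strand = "-", mismatches = best_r)
  }
}

# Brute-force non-trivial bipartitions of a phylo tree via edge removal and
# graph connectivity (independent of the package's prop.part-based keys).
oracle_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  edges <- tree$edge
  keys <- character(0)
  anchor <- sort(tree$tip.label)[1]
  for (e in seq_len(nrow(edges))) {
    adj <- edges[-e, , drop = FALSE]
    # BFS from the child node of the removed edge
    reach <- edges[e, 2]
    repeat {
      nxt <- unique(c(adj[adj[, 1] %in% reach, 2], adj[adj[, 2] %in% reach, 1]))
      new <- setdiff(nxt, reach)
      if (length(new) == 0) break
      reach <- c(reach, new)
    }
    side <- tree$tip.label[reach[reach <= nt]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) <= 1 || length(side) >= nt - 1) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# 99% binomial CI half-width for a count with success probability p over n.
ci99_halfwidth <- function(n, p) 2.576 * sqrt(n * p * (1 - p))
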