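#' Pairwise evolutionary distances from aligned sequences
#'
#' p-distance (mismatches / compared sites) or its Jukes-Cantor correction
#' `-(3/4) * log(1 - 4p/3)`. The JC69 distance is undefined (reported `NA`
#' with a warning) when p >= 0.75.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param model `"p"` or `"JC69"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(seqs, model = c("p", "JC69")) {
  model <- match.arg(model)
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)), all(nchar(seqs) == nchar(seqs[[1]])))
  L <- nchar(seqs[[1]])
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- seq_mismatches(seqs[[i]], seqs[[j]]) / L
      v <- if (model == "p") {
        p
      } else if (p >= 0.75) {
        warning("JC69 distance undefined at p >= 0.75; reporting NA")
        NA_real_
      } else {
        -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining on a distance matrix (Q-criterion). Ties are
#' broken toward the lexicographically smallest pair of cluster
#' representatives; negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch.
#'
#' @param d Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, !is.null(rownames(d)))
  if (anyNA(d)) stop("distance matrix contains NA")
  labels <- rownames(d)
  n <- nrow(d)
  frag <- labels                 # newick fragment per active node
  repr <- labels                 # lexicographically smallest leaf in cluster
  D <- unname(d)
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.10g", max(0, x))
  clamp2 <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(0, li), max(0, lj))
  }
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      rp <- sort(c(repr[active[ij[1]]], repr[active[ij[2]]]))
      paste(rp, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    bl <- clamp2(li, lj)
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(bl[1]), frag[aj], fmt(bl[2]))
    new_repr <- min(repr[ai], repr[aj])
    # distances from the new node to the others
    others <- active[-c(i, j)]
    newd <- (D[ai, others] + D[aj, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    idx <- nrow(D)
    D[idx, others] <- newd
    D[others, idx] <- newd
    frag <- c(frag, new_frag)
    repr <- c(repr, new_repr)
    active <- c(others, idx)
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[a[1]], fmt(l1), frag[a[2]], fmt(l2), frag[a[3]], fmt(l3))
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an unrooted tree as canonical string keys:
# the side not containing the alphabetically first tip, sorted, joined by "|".
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Neighbor-joining tree with bootstrap support
#'
#' Site-resampling bootstrap: alignment columns are resampled with
#' replacement `n_reps` times, a NJ tree is built per replicate, and each
#' internal edge of the point-estimate tree is annotated with the fraction
#' of replicates containing its bipartition (stored in `node.label`, and
#' returned as a named vector).
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @param model Distance model passed to [pairwise_distances()].
#' @return List of class `bootstrap_tree`: `tree` (point-estimate `phylo`
#'   with supports as node labels), `support` (named vector keyed by
#'   bipartition), `n_reps`.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 1L,
                              model = "JC69") {
  stopifnot(length(seqs) >= 3L)
  L <- nchar(seqs[[1]])
  chars <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  n <- nrow(chars)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # per-column mismatch indicators for every pair (pairs x L)
  mism <- matrix(FALSE, nrow(pairs), L)
  for (r in seq_len(nrow(pairs))) {
    mism[r, ] <- chars[pairs[r, 1], ] != chars[pairs[r, 2], ]
  }
  dist_from_cols <- function(cols) {
    p <- rowMeans(mism[, cols, drop = FALSE])
    if (model == "JC69") {
      if (any(p >= 0.75)) return(NULL)
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d <- matrix(0, n, n, dimnames = list(rownames(chars), rownames(chars)))
    d[cbind(pairs[, 1], pairs[, 2])] <- p
    d[cbind(pairs[, 2], pairs[, 1])] <- p
    d
  }
  point <- nj_tree(dist_from_cols(seq_len(L)))
  point_bp <- tree_bipartitions(point)
  hits <- setNames(numeric(length(point_bp)), point_bp)
  used <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      db <- dist_from_cols(cols)
      if (is.null(db)) next
      used <- used + 1L
      bp <- tree_bipartitions(nj_tree(db))
      ok <- point_bp %in% bp
      hits[ok] <- hits[ok] + 1
    }
  })
  support <- if (used > 0L) hits / used else hits * NA_real_
  # attach as node labels in the tree's internal-node order
  tree <- point
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(tree$tip.label)[1]
  node_support <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) return(NA_real_)
    unname(support[paste(sort(side), collapse = "|")])
  }, numeric(1))
  tree$node.label <- ifelse(is.na(node_support), "",
                            sprintf("%.3f", node_support))
  structure(list(tree = tree, support = support, n_reps = used),
            class = "bootstrap_tree")
}

#' Robinson-Foulds agreement between two trees
#'
#' RF distance is the size of the symmetric difference of the non-trivial
#' bipartition sets, normalized by `2 * (n - 3)`. When `species` labels are
#' given, the cluster-mapping table reports, per species, whether its strain
#' set is a clade (one side of some bipartition, or trivial) in each tree.
#'
#' @param tree_1,tree_2 `phylo` trees on the same leaf set.
#' @param species Optional named vector mapping tip label -> species.
#' @return List of class `tree_agreement`: `rf`, `normalized_rf`,
#'   `agreement` (1 - normalized RF), `cluster_mapping` (data frame or
#'   `NULL`).
#' @export
tree_agreement <- function(tree_1, tree_2, species = NULL) {
  t1 <- sort(tree_1$tip.label)
  t2 <- sort(tree_2$tip.label)
  if (!identical(t1, t2)) stop("trees must share one leaf set")
  b1 <- tree_bipartitions(tree_1)
  b2 <- tree_bipartitions(tree_2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(t1)
  denom <- 2 * (n - 3)
  nrf <- if (denom > 0) rf / denom else 0
  cluster_mapping <- NULL
  if (!is.null(species)) {
    is_clade <- function(tree, tips_in) {
      all_tips <- tree$tip.label
      if (length(tips_in) <= 1L || length(tips_in) >= length(all_tips) - 1L)
        return(TRUE)
      anchor <- sort(all_tips)[1]
      side <- if (anchor %in% tips_in) setdiff(all_tips, tips_in) else tips_in
      key <- paste(sort(side), collapse = "|")
      key %in% tree_bipartitions(tree)
    }
    sp <- unique(species)
    cluster_mapping <- data.frame(
      species = sp,
      clade_in_tree_1 = vapply(sp, function(s) {
        is_clade(tree_1, names(species)[species == s])
      }, logical(1)),
      clade_in_tree_2 = vapply(sp, function(s) {
        is_clade(tree_2, names(species)[species == s])
      }, logical(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(rf = rf, normalized_rf = nrf, agreement = 1 - nrf,
                 cluster_mapping = cluster_mapping),
            class = "tree_agreement")
}
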