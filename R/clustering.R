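#' Build a strains x sites SNP matrix
#'
#' Takes per-strain variant tables against one common reference and codes the
#' union of variant positions as 0 (reference), 1 (alternate), 0.5
#' (heterozygous) or `NA` (no call). Columns are ordered by position; a
#' column exists only where at least one strain is non-reference.
#'
#' @param variant_tables Named list of `variant_table` objects
#'   ([call_variants()]) sharing one reference.
#' @param max_missing Maximum fraction of missing genotypes per column;
#'   columns above it are dropped.
#' @return Numeric matrix (strains x sites) of class `snp_matrix`; column
#'   names are 0-based positions.
#' @export
build_snp_matrix <- function(variant_tables, max_missing = 0.5) {
  stopifnot(length(variant_tables) >= 1L, !is.null(names(variant_tables)))
  refs <- vapply(variant_tables, attr, character(1), "reference_id")
  if (length(unique(refs)) != 1L)
    stop("variant tables must share one reference")
  pos <- sort(unique(unlist(lapply(variant_tables, function(v) {
    v$position[v$call %in% c("variant", "heterozygous")]
  }))))
  m <- matrix(0, nrow = length(variant_tables), ncol = length(pos),
              dimnames = list(names(variant_tables), as.character(pos)))
  for (i in seq_along(variant_tables)) {
    v <- variant_tables[[i]]
    j <- match(v$position, pos)
    ok <- !is.na(j)
    code <- c(variant = 1, heterozygous = 0.5, no_call = NA_real_)[v$call[ok]]
    m[i, j[ok]] <- code
  }
  if (ncol(m) > 0L) {
    miss <- colMeans(is.na(m))
    m <- m[, miss <= max_missing, drop = FALSE]
  }
  class(m) <- c("snp_matrix", class(m))
  m
}

#' Principal component analysis of a SNP matrix
#'
#' Columns are centered on the mean genotype `p` and scaled by
#' `sqrt(p * (1 - p))` (allele-frequency scaling); missing genotypes are
#' imputed to `p`. Coordinates are projections of strains onto the top
#' eigenvectors of the strain covariance; each component's sign is fixed so
#' its largest-magnitude strain coordinate is positive.
#'
#' @param m A `snp_matrix` (or plain numeric matrix, strains in rows).
#' @param n_components Number of components to return.
#' @return List of class `snp_pca`: `coordinates` (strains x components),
#'   `explained` (variance fractions, non-increasing), `sdev`.
#' @export
snp_pca <- function(m, n_components = 5L) {
  m <- unclass(m)
  stopifnot(nrow(m) >= 2L)
  if (ncol(m) == 0L) {
    warning("zero-variance SNP matrix; coordinates are all zero")
    coords <- matrix(0, nrow(m), n_components,
                     dimnames = list(rownames(m), paste0("PC", seq_len(n_components))))
    return(structure(list(coordinates = coords,
                          explained = rep(0, n_components),
                          sdev = rep(0, n_components)), class = "snp_pca"))
  }
  p <- colMeans(m, na.rm = TRUE)
  sc <- sqrt(p * (1 - p))
  sc[sc == 0] <- 1
  x <- sweep(m, 2, p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sc, "/")
  if (all(abs(x) < 1e-12)) {
    warning("zero-variance SNP matrix; coordinates are all zero")
  }
  s <- svd(x)
  k <- min(n_components, length(s$d))
  coords <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k)
  # sign convention: largest-magnitude coordinate positive
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  if (k < n_components) {
    coords <- cbind(coords, matrix(0, nrow(m), n_components - k))
  }
  dimnames(coords) <- list(rownames(m), paste0("PC", seq_len(ncol(coords))))
  ev <- s$d^2
  explained <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  explained <- c(explained, rep(0, max(0, n_components - length(explained))))[seq_len(n_components)]
  structure(list(coordinates = coords, explained = explained,
                 sdev = s$d[seq_len(k)] / sqrt(max(1, nrow(m) - 1))),
            class = "snp_pca")
}

#' Delimit clusters by single-linkage gap
#'
#' Single-linkage hierarchical clustering on the pairwise SNP-count distance
#' (sum of absolute genotype differences), cut at the first relative gap
#' between consecutive merge heights that exceeds `linkage_gap_factor` --
#' i.e. at the lowest height where within-group merges end and between-group
#' merges begin, which yields the finest delimitation consistent with the
#' gap criterion (a deeper, larger gap would lump related species). The
#' cluster count is emergent; with no qualifying gap all strains form one
#' cluster (with a warning).
#'
#' @param m A `snp_matrix`.
#' @param linkage_gap_factor Minimum ratio of consecutive merge heights at
#'   the cut (default 5).
#' @return List of class `cluster_assignment`: `cluster` (named integer
#'   vector), `n_clusters`, `cut_height`, `merge_heights`.
#' @export
delimit_clusters <- function(m, linkage_gap_factor = 5) {
  m <- unclass(m)
  stopifnot(nrow(m) >= 2L)
  # missing genotypes are excluded pairwise (dist rescales by column count)
  d <- if (ncol(m) == 0L) dist(matrix(0, nrow(m), 1L)) else dist(m, method = "manhattan")
  if (anyNA(d)) {
    finite_max <- suppressWarnings(max(d, na.rm = TRUE))
    d[is.na(d)] <- if (is.finite(finite_max)) finite_max * 2 else 0
  }
  hc <- hclust(d, method = "single")
  h <- hc$height
  # ratios between consecutive merge heights (0 -> positive counts as Inf)
  ratio <- rep(0, length(h))
  if (length(h) >= 2L) {
    prev <- h[-length(h)]
    nxt <- h[-1]
    ratio[-1] <- ifelse(prev <= 0, ifelse(nxt > 0, Inf, 0), nxt / prev)
  }
  qualifying <- which(ratio > linkage_gap_factor)
  best <- if (length(qualifying)) qualifying[1] else which.max(ratio)
  if (ratio[best] <= linkage_gap_factor) {
    warning("no merge-height gap exceeds linkage_gap_factor; one cluster")
    cl <- setNames(rep(1L, nrow(m)), rownames(m))
    return(structure(list(cluster = cl, n_clusters = 1L,
                          cut_height = Inf, merge_heights = h),
                     class = "cluster_assignment"))
  }
  # cut between merge best-1 and best: keep merges below h[best]
  cut_h <- (h[best - 1L] + h[best]) / 2
  cl <- cutree(hc, h = cut_h)
  # renumber clusters deterministically by first strain occurrence
  cl <- setNames(match(cl, unique(cl)), rownames(m))
  structure(list(cluster = cl, n_clusters = length(unique(cl)),
                 cut_height = cut_h, merge_heights = h),
            class = "cluster_assignment")
}

#' Assign a species label by barcode identity
#'
#' Compares a barcode sequence to a labeled reference panel by per-position
#' identity (equal-length sequences; matches / compared positions) and
#' returns the best label; equal-identity labels are all reported as ties.
#'
#' @param barcode Query barcode DNA string.
#' @param panel Named character vector of labeled reference barcodes.
#' @return List: `label` (best label, or all tied labels), `identity`
#'   (fraction), `tied` flag, `identities` (full vector).
#' @export
assign_species <- function(barcode, panel) {
  stopifnot(length(panel) >= 1L, !is.null(names(panel)))
  ident <- vapply(panel, function(ref) {
    stopifnot(nchar(ref) == nchar(barcode))
    1 - seq_mismatches(barcode, ref) / nchar(barcode)
  }, numeric(1))
  best <- max(ident)
  labels <- names(panel)[ident == best]
  list(label = labels, identity = best, tied = length(labels) > 1L,
       identities = ident)
}
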