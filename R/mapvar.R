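#' Map reads to a reference and build a pileup
#'
#' Ungapped seed-and-extend mapping: candidate placements are exact
#' `k_seed`-mer hits on either strand (circular wrap allowed); among
#' candidates the placement with the fewest mismatches wins, ties resolved to
#' the forward strand and then the lowest coordinate. Reads whose best
#' placement exceeds `max_mismatch_frac` mismatches are left unmapped and
#' counted.
#'
#' @param reads A `read_set` from [simulate_reads()] (both mates are used),
#'   or a character vector of read sequences.
#' @param reference A [circular_genome()] or a DNA string.
#' @param k_seed Seed k-mer length (default 15).
#' @param max_mismatch_frac Maximum mismatch fraction of a mapped read.
#' @param circular Override the reference's circularity flag.
#' @return An object of class `pileup`: `reference_id`, `reference`
#'   (sequence), `counts` (4 x L base-count matrix, rows A/C/G/T), `depth`,
#'   `placements` (per read: `pos` 0-based, `strand`, `mismatches`,
#'   `mapped`), `n_reads`, `n_mapped`.
#' @export
map_reads <- function(reads, reference, k_seed = 15L, max_mismatch_frac = 0.2,
                      circular = NULL) {
  if (inherits(reads, "read_set")) reads <- c(reads$r1, reads$r2)
  if (inherits(reference, "circular_genome")) {
    ref_seq <- reference$sequence
    ref_id <- reference$id
    circ <- circular %||% reference$circular
  } else {
    ref_seq <- reference
    ref_id <- names(reference) %||% "ref"
    circ <- circular %||% TRUE
  }
  if (nchar(ref_seq) <= max(nchar(reads), 0L))
    stop("reference must be longer than the reads")
  res <- .map_reads_cpp(unname(as.character(reads)), ref_seq, as.integer(k_seed),
                        max_mismatch_frac, isTRUE(circ))
  counts <- res$pileup
  rownames(counts) <- c("A", "C", "G", "T")
  placements <- data.frame(read_id = names(reads) %||% as.character(seq_along(reads)),
                           pos = res$pos, strand = res$strand,
                           mismatches = res$mismatches, mapped = res$mapped,
                           stringsAsFactors = FALSE)
  structure(list(reference_id = ref_id, reference = ref_seq, counts = counts,
                 depth = colSums(counts), placements = placements,
                 n_reads = length(reads), n_mapped = sum(res$mapped)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> vs %s (%d bp): %d/%d reads mapped, mean depth %.1f\n",
              x$reference_id, nchar(x$reference), x$n_mapped, x$n_reads,
              mean(x$depth)))
  invisible(x)
}

#' Merge pileups over the same reference
#'
#' @param ... `pileup` objects sharing one reference.
#' @return A pooled `pileup` (placements dropped).
#' @export
merge_pileups <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !inherits(ps[[1]], "pileup"))
    ps <- ps[[1]]
  stopifnot(length(ps) >= 1L, all(vapply(ps, inherits, logical(1), "pileup")))
  ref <- ps[[1]]$reference
  stopifnot(all(vapply(ps, function(p) identical(p$reference, ref), logical(1))))
  counts <- Reduce(`+`, lapply(ps, `[[`, "counts"))
  structure(list(reference_id = ps[[1]]$reference_id, reference = ref,
                 counts = counts, depth = colSums(counts), placements = NULL,
                 n_reads = sum(vapply(ps, `[[`, integer(1), "n_reads")),
                 n_mapped = sum(vapply(ps, `[[`, integer(1), "n_mapped"))),
            class = "pileup")
}

#' Build a pileup from a SAM file
#'
#' Minimal import for externally mapped reads: ungapped alignments only
#' (CIGAR of the form `<n>M`); others are skipped with a warning.
#'
#' @param path SAM file.
#' @param reference A [circular_genome()] or DNA string the alignments refer to.
#' @return A `pileup`.
#' @export
read_sam_pileup <- function(path, reference) {
  if (inherits(reference, "circular_genome")) {
    ref_seq <- reference$sequence
    ref_id <- reference$id
  } else {
    ref_seq <- reference
    ref_id <- "ref"
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- matrix(0L, 4, nchar(ref_seq), dimnames = list(c("A", "C", "G", "T"), NULL))
  n_skip <- 0L
  n_mapped <- 0L
  L <- nchar(ref_seq)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    cigar <- f[6]
    seq <- f[10]
    if (!grepl("^[0-9]+M$", cigar) || seq == "*") { n_skip <- n_skip + 1L; next }
    pos <- as.integer(f[4]) - 1L
    bases <- seq_chars(seq)
    idx <- match(bases, c("A", "C", "G", "T"))
    at <- ((pos + seq_along(bases) - 1L) %% L) + 1L
    keep <- !is.na(idx)
    for (j in which(keep)) counts[idx[j], at[j]] <- counts[idx[j], at[j]] + 1L
    n_mapped <- n_mapped + 1L
  }
  if (n_skip > 0L) warning(n_skip, " non-ungapped alignments skipped")
  structure(list(reference_id = ref_id, reference = ref_seq, counts = counts,
                 depth = colSums(counts), placements = NULL,
                 n_reads = length(lines), n_mapped = n_mapped),
            class = "pileup")
}

#' Call variants from a pileup
#'
#' Per position: depth below `min_depth` gives `no_call`; otherwise the top
#' non-reference base fraction at or above `hom_threshold` gives `variant`,
#' within `het_band` gives `heterozygous`, else `ref`. Only non-`ref` rows
#' are returned; positions absent from the table are reference calls.
#'
#' @param pileup A `pileup`.
#' @param min_depth Minimum depth for any call (default 10).
#' @param hom_threshold Alt fraction for a homozygous variant (default 0.9).
#' @param het_band Closed interval of alt fractions called heterozygous.
#' @return A data frame of class `variant_table` with columns `position`
#'   (0-based), `ref_allele`, `alt_allele`, `alt_count`, `ref_count`,
#'   `alt_fraction`, `depth`, `call`; attributes `reference_id`,
#'   `reference_length`, `min_depth`.
#' @export
call_variants <- function(pileup, min_depth = 10L, hom_threshold = 0.9,
                          het_band = c(0.2, 0.8)) {
  stopifnot(inherits(pileup, "pileup"))
  counts <- pileup$counts
  L <- ncol(counts)
  depth <- pileup$depth
  bases <- c("A", "C", "G", "T")
  ref_idx <- match(seq_chars(pileup$reference), bases)
  lin <- cbind(ref_idx, seq_len(L))
  ref_count <- integer(L)
  ok <- !is.na(ref_idx)
  ref_count[ok] <- counts[lin[ok, , drop = FALSE]]
  masked <- counts
  masked[lin[ok, , drop = FALSE]] <- -1L
  alt_idx <- max.col(t(masked), ties.method = "first")
  alt_count <- counts[cbind(alt_idx, seq_len(L))]
  alt_fraction <- ifelse(depth > 0, alt_count / depth, 0)
  call <- rep("ref", L)
  call[alt_fraction >= het_band[1] & alt_fraction <= het_band[2]] <- "heterozygous"
  call[alt_fraction >= hom_threshold] <- "variant"
  call[depth < min_depth] <- "no_call"
  keep <- call != "ref"
  out <- data.frame(position = which(keep) - 1L,
                    ref_allele = bases[ref_idx[keep]],
                    alt_allele = bases[alt_idx[keep]],
                    alt_count = alt_count[keep],
                    ref_count = ref_count[keep],
                    alt_fraction = alt_fraction[keep],
                    depth = depth[keep],
                    call = call[keep],
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- pileup$reference_id
  attr(out, "reference_length") <- L
  attr(out, "min_depth") <- min_depth
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Build a per-strain consensus from variant calls
#'
#' Homozygous variants substitute the alternate allele; heterozygous sites
#' take the majority base (ties keep the reference base); `no_call` positions
#' keep the reference base and are reported in the `no_call_positions`
#' attribute.
#'
#' @param reference A [circular_genome()] or DNA string.
#' @param variants A `variant_table` from [call_variants()].
#' @return Consensus DNA string with attribute `no_call_positions` (0-based).
#' @export
build_consensus <- function(reference, variants) {
  ref_seq <- if (inherits(reference, "circular_genome")) reference$sequence else reference
  if (anyDuplicated(variants$position))
    stop("conflicting rows for one position in variant table")
  if (nrow(variants) > 0 && max(variants$position) >= nchar(ref_seq))
    stop("variant position outside reference")
  sub <- variants$call == "variant" |
    (variants$call == "heterozygous" & variants$alt_count > variants$ref_count)
  out <- substitute_bases(ref_seq, variants$position[sub] + 1L,
                          variants$alt_allele[sub])
  attr(out, "no_call_positions") <- variants$position[variants$call == "no_call"]
  out
}

#' SNP density per kilobase, printed-table style
#'
#' `1000 * n_snps / length_bp`, half-up rounded to one decimal; values of
#' 100 or more are reported as integers (matching the reporting style of the
#' inter-specific divergence tables).
#'
#' @param n_snps SNP count.
#' @param length_bp Sequence length in bp (> 0).
#' @return Density in SNPs/kb.
#' @export
#' @examples
#' snp_density(5230, 63775) # 82
#' snp_density(5512, 24854) # 222
snp_density <- function(n_snps, length_bp) {
  stopifnot(all(length_bp > 0))
  d <- 1000 * n_snps / length_bp
  ifelse(d >= 100, round_half_up(d, 0), round_half_up(d, 1))
}

#' Coding-sequence interval set
#'
#' @param annotation Data frame with `gene_id`, `start`, `end`, `strand`
#'   (0-based half-open). Rows are kept in the given order.
#' @return Object of class `cds_set` with the annotation and its total
#'   concatenated length.
#' @export
cds_set <- function(annotation) {
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(annotation)),
            all(annotation$end > annotation$start))
  structure(list(genes = annotation,
                 concat_length = sum(annotation$end - annotation$start)),
            class = "cds_set")
}

#' Extract and concatenate coding sequence
#'
#' Genes are extracted in the row order of the `cds_set` (minus-strand genes
#' reverse-complemented). To compare strains across an inversion, build the
#' `cds_set` in a shared gene order (e.g. sorted by `gene_id`): the inversion
#' transplants gene coordinates and flips strands, so per-gene extraction
#' returns every gene in its ancestral orientation.
#'
#' @param genome A [circular_genome()] or DNA string.
#' @param cds A [cds_set()]; defaults to the genome's annotation sorted by
#'   `gene_id`.
#' @return Concatenated coding sequence string.
#' @export
extract_concat_cds <- function(genome, cds = NULL) {
  if (is.null(cds)) {
    stopifnot(inherits(genome, "circular_genome"), !is.null(genome$annotation))
    ann <- genome$annotation
    cds <- cds_set(ann[order(ann$gene_id), , drop = FALSE])
  }
  seq <- if (inherits(genome, "circular_genome")) genome$sequence else genome
  g <- cds$genes
  if (any(g$end > nchar(seq))) stop("CDS interval outside genome")
  parts <- substring(seq, g$start + 1L, g$end)
  minus <- g$strand == "-"
  parts[minus] <- revcomp(parts[minus])
  out <- paste(parts, collapse = "")
  stopifnot(nchar(out) == cds$concat_length)
  out
}

# Majority consensus across equal-length sequences; ties take the first
# sequence's base. Returns list(consensus, tie_positions).
majority_consensus <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  if (length(seqs) == 1L) return(list(consensus = seqs[[1]], tie_positions = integer(0)))
  L <- nchar(seqs[[1]])
  stopifnot(all(nchar(seqs) == L))
  raws <- vapply(seqs, charToRaw, raw(L))
  bases <- charToRaw("ACGT")
  cnt <- vapply(bases, function(b) rowSums(raws == b), numeric(L))  # L x 4
  maxc <- pmax(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4])
  n_at_max <- rowSums(cnt == maxc)
  winner <- max.col(cnt, ties.method = "first")
  cons <- rawToChar(bases[winner])
  ties <- which(n_at_max > 1)
  if (length(ties)) {
    first <- charToRaw(seqs[[1]])
    cr <- charToRaw(cons)
    cr[ties] <- first[ties]
    cons <- rawToChar(cr)
  }
  list(consensus = cons, tie_positions = ties)
}

#' Inter-specific SNP statistics vs a reference species
#'
#' For each strain, counts mismatching positions between its (coding)
#' consensus and the reference species' majority consensus, averages the
#' counts within species, and normalizes by length ([snp_density()]).
#'
#' @param consensuses Named character vector of equal-length per-strain
#'   sequences (typically concatenated CDS from [extract_concat_cds()]).
#' @param species_labels Species of each strain (recycled names must match
#'   `consensuses` order).
#' @param reference_species Species whose majority consensus is the baseline.
#' @param cds Optional [cds_set()]; its concatenated length is the density
#'   denominator (defaults to the sequence length).
#' @return Data frame: `species`, `n_strains`, `mean_snps`, `snps_per_kb`.
#' @export
interspecific_stats <- function(consensuses, species_labels, reference_species,
                                cds = NULL) {
  stopifnot(length(consensuses) == length(species_labels),
            reference_species %in% species_labels)
  L <- nchar(consensuses[[1]])
  stopifnot(all(nchar(consensuses) == L))
  len <- if (is.null(cds)) L else cds$concat_length
  ref_cons <- majority_consensus(consensuses[species_labels == reference_species])$consensus
  counts <- vapply(consensuses, seq_mismatches, numeric(1), b = ref_cons)
  agg <- tapply(counts, species_labels, mean)
  species <- unique(species_labels)
  mean_snps <- as.numeric(agg[species])
  data.frame(species = species,
             n_strains = as.integer(table(species_labels)[species]),
             mean_snps = mean_snps,
             snps_per_kb = snp_density(mean_snps, len),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intra-specific SNP statistics
#'
#' Per species: the species consensus is the per-position majority over its
#' strains (ties keep the first strain's base); each strain's SNP count is
#' taken against it and normalized to SNPs/kb; `total_variant_sites` counts
#' positions where any strain differs from the species consensus.
#'
#' @param consensuses Named character vector of equal-length per-strain
#'   sequences (typically whole-genome consensuses).
#' @param species_labels Species of each strain.
#' @param cds Optional [cds_set()] used as the density denominator
#'   (default: sequence length, i.e. the whole genome).
#' @return Data frame: `species`, `n_strains`, `mean_snps_per_kb`,
#'   `sd_snps_per_kb` (`NA` for a single strain), `total_variant_sites`.
#' @export
intraspecific_stats <- function(consensuses, species_labels, cds = NULL) {
  stopifnot(length(consensuses) == length(species_labels))
  L <- nchar(consensuses[[1]])
  len <- if (is.null(cds)) L else cds$concat_length
  species <- unique(species_labels)
  rows <- lapply(species, function(sp) {
    seqs <- consensuses[species_labels == sp]
    cons <- majority_consensus(seqs)$consensus
    per_strain <- vapply(seqs, seq_mismatches, numeric(1), b = cons)
    all_pos <- unique(unlist(lapply(seqs, mismatch_positions, b = cons)))
    dens <- 1000 * per_strain / len
    data.frame(species = sp, n_strains = length(seqs),
               mean_snps_per_kb = mean(dens),
               sd_snps_per_kb = if (length(seqs) >= 2L) sd(dens) else NA_real_,
               total_variant_sites = length(all_pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
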