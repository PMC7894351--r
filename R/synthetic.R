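#' Circular genome container
#'
#' Holds a DNA sequence, a circularity flag and a BED-style gene annotation
#' (0-based half-open intervals).
#'
#' @param id Genome identifier.
#' @param sequence DNA string over A/C/G/T.
#' @param circular Logical circularity flag.
#' @param annotation Data frame with columns `gene_id`, `start`, `end`,
#'   `strand`, or `NULL`.
#' @return An object of class `circular_genome`.
#' @export
circular_genome <- function(id, sequence, circular = TRUE, annotation = NULL) {
  len <- nchar(sequence)
  if (!is.null(annotation)) {
    stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(annotation)),
              all(annotation$start >= 0L), all(annotation$end <= len),
              all(annotation$end > annotation$start))
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 annotation = annotation),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, %s, %d genes\n", x$id,
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              if (is.null(x$annotation)) 0L else nrow(x$annotation)))
  invisible(x)
}

#' Species panel specification for the sequencing-design simulator
#'
#' Describes a panel of species sharing a chloroplast, a mitochondrion and a
#' multi-copy 45S rDNA unit on a common coordinate system. Inter-specific
#' divergence follows a star model: each species carries a private branch
#' whose substitution density (SNPs/kb) is its entry in
#' `ref_divergence_per_kb`, measured against the reference species (first
#' entry, density 0). Branch mutation sites are disjoint across species, so
#' the pairwise divergence between species `j` and `k` is additive:
#' `d[j] + d[k]`. A full pairwise matrix may be supplied instead but must be
#' star-additive with respect to the first species.
#'
#' @param species Character vector of species names; the first is the
#'   reference species.
#' @param cp_length_bp,mt_length_bp Chloroplast / mitochondrial genome length
#'   (shared across species: the mutation model is substitution-only).
#' @param cp_divergence_per_kb,mt_divergence_per_kb Per-species divergence
#'   densities vs the reference species (SNPs/kb); first entry must be 0.
#' @param cp_ref_branch_per_kb,mt_ref_branch_per_kb Private branch density
#'   of the reference species itself (its share of each vs-reference
#'   divergence). A positive value gives the reference species its own
#'   derived alleles, so it forms a clade like every other species.
#' @param r45s_ref_fixed The reference species' share of each pairwise 45S
#'   fixed-difference count.
#' @param intra_divergence_per_kb Per-species intra-specific density
#'   (SNPs/kb), recycled if scalar.
#' @param inversion_clade Species carrying the reverse-complemented
#'   chloroplast segment.
#' @param inversion_segment Length-2 integer, 0-based half-open segment on
#'   the chloroplast, or `NULL` to place it automatically over interior genes.
#' @param r45s_length_bp Length of the 45S repeat unit.
#' @param r45s_copy_number Number of 45S copies per strain (>= 100 emulates a
#'   high-copy rDNA array).
#' @param r45s_fixed_diffs Per-species count of fixed 45S differences vs the
#'   reference species (planted exactly; sites disjoint across species).
#' @param cp_genes,mt_genes Number of annotated genes.
#' @param cp_cds_total_bp,mt_cds_total_bp Total concatenated CDS length.
#' @param inter_divergence_cp,inter_divergence_mt Optional full pairwise
#'   density matrices (checked for symmetry, zero diagonal and
#'   star-additivity); override the per-kb vectors.
#' @return An object of class `species_panel_spec`.
#' @export
species_panel_spec <- function(species,
                               cp_length_bp,
                               mt_length_bp,
                               cp_divergence_per_kb,
                               mt_divergence_per_kb,
                               cp_ref_branch_per_kb = 0,
                               mt_ref_branch_per_kb = 0,
                               r45s_ref_fixed = 0L,
                               intra_divergence_per_kb = 0.2,
                               inversion_clade = character(0),
                               inversion_segment = NULL,
                               r45s_length_bp = 5000L,
                               r45s_copy_number = 100L,
                               r45s_fixed_diffs = 0L,
                               cp_genes = 10L,
                               mt_genes = 6L,
                               cp_cds_total_bp = NULL,
                               mt_cds_total_bp = NULL,
                               inter_divergence_cp = NULL,
                               inter_divergence_mt = NULL) {
  n <- length(species)
  stopifnot(n >= 2L, !anyDuplicated(species))
  as_branches <- function(mat, vec, ref_branch, what) {
    if (!is.null(mat)) {
      stopifnot(is.matrix(mat), nrow(mat) == n, ncol(mat) == n)
      if (any(mat < 0)) stop(what, ": divergence densities must be >= 0")
      if (any(abs(mat - t(mat)) > 1e-8)) stop(what, ": divergence matrix must be symmetric")
      if (any(diag(mat) != 0)) stop(what, ": divergence matrix diagonal must be 0")
      b1 <- max(0, (mat[1, 2] + mat[1, 3] - mat[2, 3]) / 2)
      b <- c(b1, mat[1, -1] - b1)
    } else {
      stopifnot(length(vec) == n, vec[1] == 0, all(vec >= 0),
                all(vec[-1] >= ref_branch))
      b <- c(ref_branch, vec[-1] - ref_branch)
    }
    if (any(b < 0)) stop(what, ": divergence matrix is not star-realizable")
    implied <- outer(b, b, "+")
    diag(implied) <- 0
    if (!is.null(mat) && any(abs(mat - implied) > 1e-6))
      stop(what, ": divergence matrix is not star-additive")
    b
  }
  cp_b <- as_branches(inter_divergence_cp, cp_divergence_per_kb,
                      cp_ref_branch_per_kb, "chloroplast")
  mt_b <- as_branches(inter_divergence_mt, mt_divergence_per_kb,
                      mt_ref_branch_per_kb, "mitochondrion")
  if (max(outer(cp_b, cp_b, "+")) > 1000 || max(outer(mt_b, mt_b, "+")) > 1000)
    stop("requested pairwise divergence exceeds 1000 SNPs/kb (saturation)")
  if (sum(cp_b) > 950 || sum(mt_b) > 950)
    stop("total branch densities too high for disjoint site placement")
  intra <- rep_len(intra_divergence_per_kb, n)
  stopifnot(all(intra >= 0), all(inversion_clade %in% species),
            r45s_copy_number >= 1L, r45s_length_bp >= 100L)
  diffs <- rep_len(as.integer(r45s_fixed_diffs), n)
  stopifnot(diffs[1] == 0L, all(diffs >= 0L),
            all(diffs[-1] >= r45s_ref_fixed))
  diffs <- c(as.integer(r45s_ref_fixed), diffs[-1] - as.integer(r45s_ref_fixed))
  stopifnot(sum(diffs) < r45s_length_bp)
  structure(list(species = species,
                 cp_length_bp = as.integer(cp_length_bp),
                 mt_length_bp = as.integer(mt_length_bp),
                 cp_branch_per_kb = as.numeric(cp_b),
                 mt_branch_per_kb = as.numeric(mt_b),
                 intra_divergence_per_kb = intra,
                 inversion_clade = inversion_clade,
                 inversion_segment = inversion_segment,
                 r45s_length_bp = as.integer(r45s_length_bp),
                 r45s_copy_number = as.integer(r45s_copy_number),
                 r45s_branch_fixed = diffs,
                 cp_genes = as.integer(cp_genes),
                 mt_genes = as.integer(mt_genes),
                 cp_cds_total_bp = cp_cds_total_bp,
                 mt_cds_total_bp = mt_cds_total_bp),
            class = "species_panel_spec")
}

#' Default species panel emulating the study design
#'
#' Six foliose Ulva-like species. Branch densities vs the reference species
#' follow the observed inter-specific coding-sequence SNP densities
#' (chloroplast up to ~91 SNPs/kb, mitochondrion up to ~222 SNPs/kb); three
#' species form a clade carrying a large chloroplast inversion; the 45S unit
#' carries fixed inter-specific differences (65 between the reference and the
#' most diverged species at full scale). `scale = "unit"` shrinks genome
#' sizes for fast tests; `scale = "full"` uses the printed organelle genome
#' and concatenated CDS sizes (63,775 bp chloroplast CDS over 69 genes,
#' 24,854 bp mitochondrial CDS over 29 genes).
#'
#' @param scale `"unit"` (small, fast) or `"full"` (printed sizes).
#' @param intra_divergence_per_kb Intra-specific density, default 0.2 SNPs/kb.
#' @return A `species_panel_spec`.
#' @export
default_panel_spec <- function(scale = c("unit", "full"),
                               intra_divergence_per_kb = 0.2) {
  scale <- match.arg(scale)
  species <- c("laetevirens", "rigida", "gigantea",
               "australis", "fenestrata", "pseudorotundata")
  cp_div <- c(0, 6.1, 35.3, 82, 79.8, 91.5)
  mt_div <- c(0, 5.6, 86.1, 196, 194, 222)
  clade <- c("australis", "fenestrata", "pseudorotundata")
  if (scale == "full") {
    species_panel_spec(species,
                       cp_length_bp = 103444L, mt_length_bp = 79723L,
                       cp_divergence_per_kb = cp_div,
                       mt_divergence_per_kb = mt_div,
                       cp_ref_branch_per_kb = 2, mt_ref_branch_per_kb = 2,
                       r45s_ref_fixed = 3L,
                       intra_divergence_per_kb = intra_divergence_per_kb,
                       inversion_clade = clade,
                       r45s_length_bp = 5000L, r45s_copy_number = 100L,
                       r45s_fixed_diffs = c(0L, 15L, 25L, 40L, 40L, 65L),
                       cp_genes = 69L, mt_genes = 29L,
                       cp_cds_total_bp = 63775L, mt_cds_total_bp = 24854L)
  } else {
    species_panel_spec(species,
                       cp_length_bp = 12000L, mt_length_bp = 8000L,
                       cp_divergence_per_kb = cp_div,
                       mt_divergence_per_kb = mt_div,
                       cp_ref_branch_per_kb = 2, mt_ref_branch_per_kb = 2,
                       r45s_ref_fixed = 2L,
                       intra_divergence_per_kb = intra_divergence_per_kb,
                       inversion_clade = clade,
                       r45s_length_bp = 2000L, r45s_copy_number = 100L,
                       r45s_fixed_diffs = c(0L, 8L, 10L, 16L, 16L, 26L),
                       cp_genes = 10L, mt_genes = 6L,
                       cp_cds_total_bp = 7500L, mt_cds_total_bp = 5100L)
  }
}

# Lay out `n_genes` non-overlapping genes with alternating strand over a
# genome of length `len`, totalling `cds_total` bp of CDS. The first two
# chloroplast genes are the barcode loci (rbcL- and tufA-like).
make_annotation <- function(len, n_genes, cds_total, barcode = FALSE) {
  stopifnot(cds_total < len, n_genes >= 1L)
  lens <- rep(cds_total %/% n_genes, n_genes)
  extra <- cds_total - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  if (barcode && n_genes >= 2L) {
    # give the barcode loci realistic, distinct lengths within the total
    target <- c(min(1425L, lens[1] + lens[3] %/% 2), min(1230L, lens[2] + lens[4] %/% 2))
    if (n_genes >= 4L && cds_total > 6000L) {
      delta <- target - lens[1:2]
      lens[3:4] <- lens[3:4] - delta
      lens[1:2] <- target
    }
  }
  stopifnot(all(lens > 0L))
  gap <- (len - cds_total) %/% (n_genes + 1L)
  stopifnot(gap >= 1L)
  starts <- integer(n_genes)
  pos <- gap
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    pos <- pos + lens[i] + gap
  }
  ids <- sprintf("gene_%02d", seq_len(n_genes))
  if (barcode && n_genes >= 2L) ids[1:2] <- c("rbcL", "tufA")
  data.frame(gene_id = ids, start = starts, end = starts + lens,
             strand = rep_len(c("+", "-"), n_genes), stringsAsFactors = FALSE)
}

# Reflect annotation coordinates through an inverted segment [s, e).
invert_annotation <- function(annotation, s, e) {
  inside <- annotation$start >= s & annotation$end <= e
  if (any(annotation$start < e & annotation$end > s & !inside))
    stop("inversion breakpoint would split a gene")
  ann <- annotation
  old_start <- ann$start[inside]
  old_end <- ann$end[inside]
  ann$start[inside] <- s + (e - old_end)
  ann$end[inside] <- s + (e - old_start)
  ann$strand[inside] <- ifelse(ann$strand[inside] == "+", "-", "+")
  ann[order(ann$start), , drop = FALSE]
}

# Reverse-complement segment [s, e) (0-based half-open) of a sequence.
invert_segment <- function(seq, s, e) {
  paste0(substr(seq, 1L, s), revcomp(substr(seq, s + 1L, e)),
         substr(seq, e + 1L, nchar(seq)))
}

# Draw `counts[j]` sites per species, disjoint across species, from 1..len.
disjoint_sites <- function(len, counts) {
  total <- sum(counts)
  stopifnot(total <= len)
  pool <- sample.int(len, total)
  split(pool, rep(seq_along(counts), counts))
}

#' Simulate a species panel
#'
#' Realizes the panel specification: ancestral chloroplast, mitochondrial and
#' 45S sequences; per-species branch substitutions at disjoint sites (so
#' pairwise divergence is additive and recorded exactly); the
#' reverse-complemented chloroplast segment in the inversion clade, with gene
#' annotation transplanted through the inversion; and a truth table of every
#' introduced substitution in ancestral (pre-inversion) coordinates.
#'
#' @param spec A [species_panel_spec()].
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `species_panel` with elements `species` (per
#'   species: `chloroplast`, `mitochondrion` ([circular_genome()]),
#'   `r45s_unit` string), `truth` (data frame: `molecule`, `species`,
#'   `position` 1-based, `ancestral`, `derived`), `inversion_segment`,
#'   `spec`.
#' @export
simulate_panel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "species_panel_spec"))
  with_seed(seed, {
    n <- length(spec$species)
    cp_anc <- random_dna(spec$cp_length_bp)
    mt_anc <- random_dna(spec$mt_length_bp)
    r45_anc <- random_dna(spec$r45s_length_bp)
    cp_ann <- make_annotation(spec$cp_length_bp, spec$cp_genes,
                              spec$cp_cds_total_bp %||% floor(spec$cp_length_bp * 0.6),
                              barcode = TRUE)
    mt_ann <- make_annotation(spec$mt_length_bp, spec$mt_genes,
                              spec$mt_cds_total_bp %||% floor(spec$mt_length_bp * 0.6))

    seg <- spec$inversion_segment
    if (is.null(seg) && length(spec$inversion_clade) > 0) {
      # span an interior run of genes, breakpoints mid-intergenic
      i1 <- max(2L, ceiling(spec$cp_genes * 0.3))
      i2 <- min(spec$cp_genes - 1L, ceiling(spec$cp_genes * 0.6))
      seg <- c((cp_ann$end[i1 - 1L] + cp_ann$start[i1]) %/% 2L,
               (cp_ann$end[i2] + cp_ann$start[i2 + 1L]) %/% 2L)
    }

    branch_sub <- function(anc, branch_per_kb, molecule) {
      len <- nchar(anc)
      counts <- rbinom(n, len, pmin(branch_per_kb / 1000, 1))
      counts[branch_per_kb == 0] <- 0L
      sites <- disjoint_sites(len, counts)
      anc_chars <- seq_chars(anc)
      truth <- vector("list", n)
      seqs <- character(n)
      for (j in seq_len(n)) {
        pos <- sort(sites[[as.character(j)]] %||% integer(0))
        if (is.null(sites[[as.character(j)]])) pos <- integer(0)
        from <- anc_chars[pos]
        to <- if (length(pos)) mutate_bases(from) else character(0)
        seqs[j] <- substitute_bases(anc, pos, to)
        truth[[j]] <- if (length(pos)) {
          data.frame(molecule = molecule, species = spec$species[j],
                     position = pos, ancestral = from, derived = to,
                     stringsAsFactors = FALSE)
        }
      }
      list(seqs = seqs, truth = do.call(rbind, truth))
    }

    fixed_sub <- function(anc, counts, molecule) {
      len <- nchar(anc)
      sites <- disjoint_sites(len, counts)
      anc_chars <- seq_chars(anc)
      truth <- vector("list", n)
      seqs <- character(n)
      for (j in seq_len(n)) {
        pos <- sort(sites[[as.character(j)]] %||% integer(0))
        if (is.null(sites[[as.character(j)]])) pos <- integer(0)
        from <- anc_chars[pos]
        to <- if (length(pos)) mutate_bases(from) else character(0)
        seqs[j] <- substitute_bases(anc, pos, to)
        truth[[j]] <- if (length(pos)) {
          data.frame(molecule = molecule, species = spec$species[j],
                     position = pos, ancestral = from, derived = to,
                     stringsAsFactors = FALSE)
        }
      }
      list(seqs = seqs, truth = do.call(rbind, truth))
    }

    cp <- branch_sub(cp_anc, spec$cp_branch_per_kb, "chloroplast")
    mt <- branch_sub(mt_anc, spec$mt_branch_per_kb, "mitochondrion")
    r45 <- fixed_sub(r45_anc, spec$r45s_branch_fixed, "r45s")

    species <- vector("list", n)
    names(species) <- spec$species
    for (j in seq_len(n)) {
      cp_seq <- cp$seqs[j]
      ann <- cp_ann
      if (spec$species[j] %in% spec$inversion_clade) {
        cp_seq <- invert_segment(cp_seq, seg[1], seg[2])
        ann <- invert_annotation(cp_ann, seg[1], seg[2])
      }
      species[[j]] <- list(
        chloroplast = circular_genome(paste0(spec$species[j], "_cp"), cp_seq,
                                      TRUE, ann),
        mitochondrion = circular_genome(paste0(spec$species[j], "_mt"),
                                        mt$seqs[j], TRUE, mt_ann),
        r45s_unit = r45$seqs[j])
    }
    truth <- rbind(cp$truth, mt$truth, r45$truth)
    if (is.null(truth)) {
      truth <- data.frame(molecule = character(0), species = character(0),
                          position = integer(0), ancestral = character(0),
                          derived = character(0), stringsAsFactors = FALSE)
    }
    structure(list(species = species, truth = truth,
                   inversion_segment = seg, spec = spec),
              class = "species_panel")
  })
}

#' Strain specification
#'
#' @param strain_id Strain name.
#' @param species_id Species of the strain. For a hybrid this is the
#'   cytoplasm donor (its organelles are inherited uniparentally).
#' @param is_hybrid Is this strain an inter-specific F1 hybrid?
#' @param hybrid_parents Ordered pair of parental species (both contribute
#'   the nuclear 45S); required iff `is_hybrid`.
#' @param cytoplasm_donor Which parent donates the organelles (defaults to
#'   `species_id`).
#' @param coverage_cp,coverage_mt,coverage_45s Fold coverages (> 0). The 45S
#'   default emulates the high-copy rDNA coverage (>1000x) seen against the
#'   nuclear background.
#' @param read_length Read length in bp (Illumina paired-end, default 150).
#' @param insert_mean,insert_sd Fragment-length model in bp.
#' @param error_rate Per-base substitution error probability.
#' @param r45s_hybrid_ratio Expected fraction of 45S copies from the first
#'   parent in a hybrid.
#' @param contaminant_fraction Fraction of additional read pairs drawn from a
#'   random non-homologous contaminant sequence.
#' @param seed Integer seed for read simulation.
#' @return An object of class `strain_spec`.
#' @export
strain_spec <- function(strain_id, species_id, is_hybrid = FALSE,
                        hybrid_parents = NULL, cytoplasm_donor = species_id,
                        coverage_cp = 40, coverage_mt = 40,
                        coverage_45s = 1000,
                        read_length = 150L, insert_mean = 400, insert_sd = 50,
                        error_rate = 0.001, r45s_hybrid_ratio = 0.5,
                        contaminant_fraction = 0.1, seed = 1L) {
  if (is_hybrid) {
    stopifnot(length(hybrid_parents) == 2L, cytoplasm_donor %in% hybrid_parents)
  } else if (!is.null(hybrid_parents)) {
    stop("hybrid_parents must be NULL unless is_hybrid = TRUE")
  }
  stopifnot(coverage_cp > 0, coverage_mt > 0, coverage_45s > 0,
            read_length >= 30L, error_rate >= 0, error_rate < 1)
  structure(list(strain_id = strain_id, species_id = species_id,
                 is_hybrid = isTRUE(is_hybrid),
                 hybrid_parents = hybrid_parents,
                 cytoplasm_donor = cytoplasm_donor,
                 coverage_cp = coverage_cp, coverage_mt = coverage_mt,
                 coverage_45s = coverage_45s,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate,
                 r45s_hybrid_ratio = r45s_hybrid_ratio,
                 contaminant_fraction = contaminant_fraction,
                 seed = as.integer(seed)),
            class = "strain_spec")
}

#' Default strain table for a panel
#'
#' Distributes `n_strains` across the panel's species and plants one F1
#' hybrid between the two most closely related species (reference species as
#' cytoplasm donor), mirroring a survey in which a single hybrid is found.
#'
#' @param panel_spec A [species_panel_spec()].
#' @param n_strains Total number of strains including the hybrid.
#' @param with_hybrid Plant one F1 hybrid?
#' @param seed Base seed; strain `i` gets seed `seed * 1000 + i`.
#' @param ... Passed to [strain_spec()] (coverages, error rate, ...).
#' @return List of `strain_spec` objects.
#' @export
default_strain_table <- function(panel_spec, n_strains = 20L,
                                 with_hybrid = TRUE, seed = 1L, ...) {
  sp <- panel_spec$species
  n_pure <- n_strains - as.integer(with_hybrid)
  stopifnot(n_pure >= length(sp))
  assign_sp <- rep_len(sp, n_pure)
  strains <- vector("list", n_strains)
  for (i in seq_len(n_pure)) {
    strains[[i]] <- strain_spec(sprintf("U%02d", i), assign_sp[i],
                                seed = seed * 1000L + i, ...)
  }
  if (with_hybrid) {
    # parents: reference species and its closest relative on the chloroplast
    b <- panel_spec$cp_branch_per_kb
    closest <- sp[-1][which.min(b[-1])]
    strains[[n_strains]] <- strain_spec(sprintf("U%02d", n_strains),
                                        species_id = sp[1], is_hybrid = TRUE,
                                        hybrid_parents = c(sp[1], closest),
                                        cytoplasm_donor = sp[1],
                                        seed = seed * 1000L + n_strains, ...)
  }
  names(strains) <- vapply(strains, `[[`, character(1), "strain_id")
  strains
}

# Apply intra-specific substitutions at `density` SNPs/kb to a sequence;
# returns list(seq, truth rows).
intra_sub <- function(seq, density, molecule, strain_id) {
  len <- nchar(seq)
  n_mut <- rbinom(1L, len, min(density / 1000, 1))
  if (n_mut == 0L) {
    return(list(seq = seq, truth = NULL))
  }
  pos <- sort(sample.int(len, n_mut))
  from <- seq_chars(substr(seq, 1L, len))[pos]
  to <- mutate_bases(from)
  list(seq = substitute_bases(seq, pos, to),
       truth = data.frame(molecule = molecule, strain = strain_id,
                          position = pos, ancestral = from, derived = to,
                          stringsAsFactors = FALSE))
}

#' Simulate the genomes of one strain
#'
#' Non-hybrid strains derive their organelles and 45S copies from one species
#' plus intra-specific substitutions at the panel's per-species density.
#' A hybrid receives only the cytoplasm donor's organellar haplotypes
#' (homoplasmy by construction) while its 45S copies are drawn from both
#' parents' haplotypes (each copy independently from parent 1 with
#' probability `r45s_hybrid_ratio`).
#'
#' @param panel A [simulate_panel()] result.
#' @param strain A [strain_spec()].
#' @return List of class `strain_genomes`: `cp`, `mt` ([circular_genome()]),
#'   `r45s_copies` (character vector), `r45s_parent` (per-copy parent
#'   species), `truth` (intra-specific substitutions), `strain`.
#' @export
simulate_strain_genomes <- function(panel, strain) {
  stopifnot(inherits(panel, "species_panel"), inherits(strain, "strain_spec"))
  sp <- panel$spec$species
  donor <- strain$cytoplasm_donor
  if (!donor %in% sp) stop("unknown species: ", donor)
  with_seed(strain$seed, {
    intra <- panel$spec$intra_divergence_per_kb[match(donor, sp)]
    src <- panel$species[[donor]]
    cpm <- intra_sub(src$chloroplast$sequence, intra, "chloroplast", strain$strain_id)
    mtm <- intra_sub(src$mitochondrion$sequence, intra, "mitochondrion", strain$strain_id)
    ncopy <- panel$spec$r45s_copy_number
    if (strain$is_hybrid) {
      if (!all(strain$hybrid_parents %in% sp))
        stop("unknown species in hybrid_parents")
      from_p1 <- runif(ncopy) < strain$r45s_hybrid_ratio
      parent <- ifelse(from_p1, strain$hybrid_parents[1], strain$hybrid_parents[2])
    } else {
      parent <- rep(donor, ncopy)
    }
    copies <- vapply(parent, function(p) panel$species[[p]]$r45s_unit,
                     character(1), USE.NAMES = FALSE)
    truth <- do.call(rbind, Filter(Negate(is.null), list(cpm$truth, mtm$truth)))
    structure(list(
      cp = circular_genome(paste0(strain$strain_id, "_cp"), cpm$seq, TRUE,
                           src$chloroplast$annotation),
      mt = circular_genome(paste0(strain$strain_id, "_mt"), mtm$seq, TRUE,
                           src$mitochondrion$annotation),
      r45s_copies = copies, r45s_parent = parent,
      truth = truth, strain = strain), class = "strain_genomes")
  })
}

# Sample paired-end fragments from one molecule. `seq` is doubled for
# circular molecules so fragments may wrap the origin.
sample_pairs <- function(seq, circular, n_pairs, read_length, insert_mean,
                         insert_sd, molecule) {
  len <- nchar(seq)
  if (read_length > len) stop("read_length exceeds molecule length")
  if (n_pairs == 0L) {
    return(list(r1 = character(0), r2 = character(0),
                truth = data.frame(molecule = character(0), start = integer(0),
                                   fragment = integer(0), stringsAsFactors = FALSE)))
  }
  frag <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                    read_length), len)
  if (circular) {
    start <- sample.int(len, n_pairs, replace = TRUE) - 1L
    doubled <- paste0(seq, seq)
    r1 <- substring(doubled, start + 1L, start + read_length)
    r2 <- revcomp(substring(doubled, start + frag - read_length + 1L, start + frag))
  } else {
    start <- vapply(frag, function(f) sample.int(len - f + 1L, 1L), integer(1)) - 1L
    r1 <- substring(seq, start + 1L, start + read_length)
    r2 <- revcomp(substring(seq, start + frag - read_length + 1L, start + frag))
  }
  list(r1 = r1, r2 = r2,
       truth = data.frame(molecule = molecule, start = start,
                          fragment = as.integer(frag), stringsAsFactors = FALSE))
}

# Inject per-base substitution errors into a character vector of reads.
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads)
  total <- sum(rl)
  n_err <- rbinom(1L, total, error_rate)
  if (n_err == 0L) return(reads)
  flat <- sort(sample.int(total, n_err))
  ends <- cumsum(rl)
  idx <- findInterval(flat - 1L, c(0L, ends), rightmost.closed = FALSE)
  offset <- flat - c(0L, ends)[idx]
  for (i in unique(idx)) {
    pos <- offset[idx == i]
    from <- seq_chars(reads[i])[pos]
    reads[i] <- substitute_bases(reads[i], pos, mutate_bases(from))
  }
  reads
}

#' Simulate paired-end reads for a strain
#'
#' Pairs are sampled uniformly over circular coordinates (fragments may wrap
#' the origin); the number of pairs per molecule is
#' `round(coverage * length / (2 * read_length))`; 45S pairs are drawn from
#' the strain's copy pool; contaminant pairs from a random non-homologous
#' sequence are appended. Per-base substitution errors occur at
#' `error_rate`.
#'
#' @param genomes A [simulate_strain_genomes()] result.
#' @param strain The [strain_spec()] (defaults to the one in `genomes`).
#' @param molecules Subset of `c("cp", "mt", "r45s")` to sequence.
#' @return List of class `read_set`: `r1`, `r2` (named character vectors),
#'   `truth` (per-pair placement: molecule, 0-based fragment start, fragment
#'   length, 45S copy index), `strain`.
#' @export
simulate_reads <- function(genomes, strain = genomes$strain,
                           molecules = c("cp", "mt", "r45s")) {
  stopifnot(inherits(genomes, "strain_genomes"))
  with_seed(strain$seed + 500000L, {
    rl <- strain$read_length
    parts <- list()
    if ("cp" %in% molecules) {
      n <- round(strain$coverage_cp * nchar(genomes$cp$sequence) / (2 * rl))
      parts$cp <- sample_pairs(genomes$cp$sequence, TRUE, n, rl,
                               strain$insert_mean, strain$insert_sd, "cp")
      parts$cp$truth$copy <- NA_integer_
    }
    if ("mt" %in% molecules) {
      n <- round(strain$coverage_mt * nchar(genomes$mt$sequence) / (2 * rl))
      parts$mt <- sample_pairs(genomes$mt$sequence, TRUE, n, rl,
                               strain$insert_mean, strain$insert_sd, "mt")
      parts$mt$truth$copy <- NA_integer_
    }
    if ("r45s" %in% molecules) {
      # the rDNA copies form a tandem array; sample pairs over the whole
      # array (circularly, so no artificial coverage dip at unit edges)
      unit_len <- nchar(genomes$r45s_copies[1])
      array_seq <- paste(genomes$r45s_copies, collapse = "")
      n <- round(strain$coverage_45s * unit_len / (2 * rl))
      pp <- sample_pairs(array_seq, TRUE, n, rl,
                         strain$insert_mean, strain$insert_sd, "r45s")
      pp$truth$copy <- (pp$truth$start %/% unit_len) + 1L
      parts$r45s <- pp
    }
    n_real <- sum(vapply(parts, function(p) length(p$r1), integer(1)))
    if (strain$contaminant_fraction > 0 && n_real > 0) {
      contam <- random_dna(max(5L * rl, 20000L))
      n <- round(n_real * strain$contaminant_fraction)
      if (n > 0) {
        parts$contaminant <- sample_pairs(contam, FALSE, n, rl,
                                          strain$insert_mean, strain$insert_sd,
                                          "contaminant")
        parts$contaminant$truth$copy <- NA_integer_
      }
    }
    r1 <- unlist(lapply(parts, `[[`, "r1"), use.names = FALSE)
    r2 <- unlist(lapply(parts, `[[`, "r2"), use.names = FALSE)
    truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
    rownames(truth) <- NULL
    r1 <- inject_errors(r1, strain$error_rate)
    r2 <- inject_errors(r2, strain$error_rate)
    ids <- sprintf("%s_%06d", strain$strain_id, seq_along(r1))
    truth$read_id <- ids
    structure(list(r1 = setNames(r1, ids), r2 = setNames(r2, ids),
                   truth = truth, strain = strain), class = "read_set")
  })
}
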