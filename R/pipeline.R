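#' Pipeline configuration
#'
#' Bundles the simulation design and every stage parameter with a single
#' global seed. Per-stage seeds are derived from the global seed so stages
#' are individually reproducible.
#'
#' @param scale `"unit"` (small genomes, fast) or `"full"` (printed genome
#'   and CDS sizes).
#' @param n_strains Number of strains including the planted hybrid.
#' @param with_hybrid Plant one F1 hybrid?
#' @param seed Global integer seed.
#' @param coverage_cp,coverage_mt,coverage_45s Fold coverages per strain.
#' @param error_rate Per-base read error probability.
#' @param intra_divergence_per_kb Intra-specific density (SNPs/kb).
#' @param zero_divergence Collapse all inter- and intra-specific divergence
#'   (and the inversion and hybrid) to zero: a degenerate single-species
#'   control design.
#' @param bootstrap_reps Bootstrap replicates for the marker trees.
#' @param assembly An [assembly_config()].
#' @param run_assembly Run the per-species iterative assembly validation
#'   stage (slowest stage; set `FALSE` to skip).
#' @param out_dir Optional directory for stage outputs (FASTA/VCF/TSV and a
#'   Markdown summary); `NULL` keeps everything in memory.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scale = c("unit", "full"), n_strains = 20L,
                            with_hybrid = TRUE, seed = 1L,
                            coverage_cp = 40, coverage_mt = 40,
                            coverage_45s = 1000,
                            error_rate = 0.001,
                            intra_divergence_per_kb = 0.2,
                            zero_divergence = FALSE,
                            bootstrap_reps = 100L,
                            assembly = assembly_config(),
                            run_assembly = TRUE,
                            out_dir = NULL) {
  scale <- match.arg(scale)
  structure(list(scale = scale, n_strains = as.integer(n_strains),
                 with_hybrid = isTRUE(with_hybrid), seed = as.integer(seed),
                 coverage_cp = coverage_cp, coverage_mt = coverage_mt,
                 coverage_45s = coverage_45s, error_rate = error_rate,
                 intra_divergence_per_kb = intra_divergence_per_kb,
                 zero_divergence = isTRUE(zero_divergence),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 assembly = assembly, run_assembly = isTRUE(run_assembly),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Adjusted Rand-free simple Rand index between two labelings.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}

#' Run the full analysis pipeline on a simulated design
#'
#' Mirrors the study's order of analysis on synthetic data: simulate the
#' species panel, strains and reads; validate the iterative organelle
#' assembly per species; map and call variants (each strain against the
#' common chloroplast reference for clustering, and against its own species
#' reference for consensus statistics); delimit species clusters by SNP PCA
#' + single linkage and assign names by barcode identity; compute inter- and
#' intra-specific SNP-density tables; build barcode/CDS/45S neighbor-joining
#' trees and their agreement; detect the chloroplast inversion; and screen
#' for F1 hybrids from 45S allele frequencies with organellar homoplasmy
#' checks.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with per-stage results and a
#'   `summary` list (cluster count, Rand index vs truth, hybrid verdicts,
#'   inversion counts, tree agreement, stats tables). Deterministic given
#'   the config seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed0 <- config$seed
  ## --- stage 1: simulation -------------------------------------------------
  if (config$zero_divergence) {
    spec <- default_panel_spec(config$scale, intra_divergence_per_kb = 0)
    spec$cp_branch_per_kb[] <- 0
    spec$mt_branch_per_kb[] <- 0
    spec$r45s_branch_fixed[] <- 0L
    spec$inversion_clade <- character(0)
    spec$inversion_segment <- NULL
    with_hybrid <- FALSE
  } else {
    spec <- default_panel_spec(config$scale, config$intra_divergence_per_kb)
    with_hybrid <- config$with_hybrid
  }
  panel <- simulate_panel(spec, seed = seed0 * 101L)
  strains <- default_strain_table(spec, config$n_strains,
                                  with_hybrid = with_hybrid, seed = seed0,
                                  coverage_cp = config$coverage_cp,
                                  coverage_mt = config$coverage_mt,
                                  coverage_45s = config$coverage_45s,
                                  error_rate = config$error_rate)
  genomes <- lapply(strains, simulate_strain_genomes, panel = panel)
  reads <- lapply(genomes, simulate_reads)
  truth_species <- vapply(strains, `[[`, character(1), "species_id")
  ref_sp <- spec$species[1]
  ref_cp <- panel$species[[ref_sp]]$chloroplast
  ref_45s <- panel$species[[ref_sp]]$r45s_unit

  ## --- stage 2: clustering against the common chloroplast reference -------
  cp_common <- lapply(reads, map_reads, reference = ref_cp)
  cp_common_var <- lapply(cp_common, call_variants)
  snp_m <- build_snp_matrix(cp_common_var)
  pca <- suppressWarnings(snp_pca(snp_m))
  clusters <- suppressWarnings(delimit_clusters(snp_m))
  rand <- rand_index(unname(clusters$cluster), unname(truth_species))

  ## barcode species assignment (barcode genes lie outside the inversion)
  ann <- ref_cp$annotation
  barcode_cds <- cds_set(ann[ann$gene_id %in% c("rbcL", "tufA"), , drop = FALSE])
  panel_barcodes <- vapply(panel$species, function(s) {
    extract_concat_cds(s$chloroplast$sequence, barcode_cds)
  }, character(1))
  cp_common_cons <- mapply(function(p, v) build_consensus(p$reference, v),
                           cp_common, cp_common_var, SIMPLIFY = TRUE)
  strain_barcode <- vapply(cp_common_cons, extract_concat_cds,
                           character(1), cds = barcode_cds)
  assignment <- lapply(strain_barcode, assign_species, panel = panel_barcodes)
  assigned_sp <- vapply(assignment, function(a) a$label[1], character(1))
  ## species label per cluster = majority barcode assignment in the cluster
  cluster_species <- vapply(seq_len(clusters$n_clusters), function(k) {
    names(sort(table(assigned_sp[clusters$cluster == k]), decreasing = TRUE))[1]
  }, character(1))
  species_of <- cluster_species[clusters$cluster]
  names(species_of) <- names(clusters$cluster)

  ## --- stage 3: per-species assembly validation ----------------------------
  assembly_tbl <- NULL
  if (config$run_assembly) {
    seed_bait <- list(chloroplast = ref_cp$sequence,
                      mitochondrion = panel$species[[ref_sp]]$mitochondrion$sequence)
    rows <- lapply(seq_len(clusters$n_clusters), function(k) {
      rep_strain <- names(clusters$cluster)[clusters$cluster == k][1]
      sp <- cluster_species[k]
      per_org <- lapply(names(seed_bait), function(org) {
        res <- iterative_assemble(reads[[rep_strain]],
                                  seed_reference = seed_bait[[org]],
                                  cfg = config$assembly)
        circ <- Filter(function(ct) ct$circular, res$contigs)
        got <- vapply(circ, function(ct) ct$sequence, character(1))
        org_key <- c(chloroplast = "cp", mitochondrion = "mt")[[org]]
        truth_norm <- rotation_normalize(genomes[[rep_strain]][[org_key]]$sequence)
        data.frame(cluster = k, species = sp, strain = rep_strain,
                   organelle = org, iterations = res$iterations_used,
                   converged = res$converged, n_circular = length(circ),
                   matches_truth = as.integer(truth_norm %in% got),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_org)
    })
    assembly_tbl <- do.call(rbind, rows)
  }

  ## --- stage 4: per-species mapping, consensus, SNP statistics -------------
  own_cp <- own_mt <- vector("list", length(strains))
  names(own_cp) <- names(own_mt) <- names(strains)
  for (sid in names(strains)) {
    sp <- species_of[sid]
    own_cp[[sid]] <- if (identical(sp, ref_sp)) cp_common[[sid]] else
      map_reads(reads[[sid]], panel$species[[sp]]$chloroplast)
    own_mt[[sid]] <- map_reads(reads[[sid]], panel$species[[sp]]$mitochondrion)
  }
  cons_of <- function(pileups) {
    vapply(names(pileups), function(sid) {
      build_consensus(pileups[[sid]]$reference, call_variants(pileups[[sid]]))
    }, character(1))
  }
  cp_cons <- cons_of(own_cp)
  mt_cons <- cons_of(own_mt)
  cds_of <- function(cons, organelle) {
    vapply(names(cons), function(sid) {
      g <- panel$species[[species_of[sid]]][[organelle]]
      gcds <- cds_set(g$annotation[order(g$annotation$gene_id), , drop = FALSE])
      extract_concat_cds(cons[[sid]], gcds)
    }, character(1))
  }
  cp_cds <- cds_of(cp_cons, "chloroplast")
  mt_cds <- cds_of(mt_cons, "mitochondrion")
  inter_cp <- interspecific_stats(cp_cds, species_of, ref_sp)
  inter_mt <- interspecific_stats(mt_cds, species_of, ref_sp)
  intra_cp <- intraspecific_stats(cp_cons, species_of)
  intra_mt <- intraspecific_stats(mt_cons, species_of)

  ## --- stage 5: 45S mapping and consensus ----------------------------------
  r45_pile <- lapply(reads, function(r) {
    # the unit is a tandem repeat, so reads crossing a copy boundary wrap
    map_reads(r, ref_45s, circular = TRUE)
  })
  r45_var <- lapply(r45_pile, call_variants)
  r45_cons <- mapply(function(p, v) build_consensus(p$reference, v),
                     r45_pile, r45_var, SIMPLIFY = TRUE)

  ## --- stage 6: marker trees and agreement ---------------------------------
  gene_cds <- function(gene) {
    cds_set(ann[ann$gene_id == gene, , drop = FALSE])
  }
  markers <- list(
    rbcl = vapply(cp_common_cons, extract_concat_cds, character(1),
                  cds = gene_cds("rbcL")),
    tufa = vapply(cp_common_cons, extract_concat_cds, character(1),
                  cds = gene_cds("tufA")),
    cds = cp_cds,
    r45s = r45_cons)
  trees <- lapply(seq_along(markers), function(i) {
    seqs <- markers[[i]]
    if (length(unique(seqs)) < 2L) return(NULL)
    bootstrap_support(seqs, n_reps = config$bootstrap_reps,
                      seed = seed0 * 577L + i, model = "p")
  })
  names(trees) <- names(markers)
  agreement <- NULL
  built <- !vapply(trees, is.null, logical(1))
  if (sum(built) >= 2L) {
    base_tree <- trees[[which(built)[1]]]$tree
    agreement <- lapply(trees[built][-1], function(bt) {
      tree_agreement(base_tree, bt$tree, species = species_of)
    })
  }

  ## --- stage 7: synteny / inversion detection ------------------------------
  other_sp <- setdiff(spec$species, ref_sp)
  cp_inv <- lapply(other_sp, function(sp) {
    compare_synteny(ref_cp, panel$species[[sp]]$chloroplast)$inversions
  })
  names(cp_inv) <- other_sp
  n_inv <- vapply(cp_inv, nrow, integer(1))
  ## distinct inversions: merge intervals on the reference that overlap
  all_iv <- do.call(rbind, cp_inv[n_inv > 0])
  n_distinct_cp_inv <- if (is.null(all_iv) || nrow(all_iv) == 0L) 0L else {
    iv <- all_iv[order(all_iv$start_a), , drop = FALSE]
    sum(c(TRUE, iv$start_a[-1] > cummax(iv$end_a)[-nrow(iv)]))
  }
  inverted_clade <- other_sp[n_inv > 0]
  mt_pair <- if (length(inverted_clade) > 0) inverted_clade[1] else
    other_sp[length(other_sp)]
  mt_inv <- compare_synteny(panel$species[[ref_sp]]$mitochondrion,
                            panel$species[[mt_pair]]$mitochondrion)$inversions

  ## --- stage 8: hybrid detection -------------------------------------------
  ## flag heterozygosity outliers first, then pool species 45S reads
  ## excluding them (one hybrid must not erode its species' fixed alleles)
  n_het <- vapply(r45_var, function(v) sum(v$call == "heterozygous"), integer(1))
  het_outlier <- n_het >= pmax(5, 3 * stats::median(n_het))
  species_pools <- lapply(spec$species, function(sp) {
    members <- names(species_of)[species_of == sp & !het_outlier]
    if (length(members) == 0L) members <- names(species_of)[species_of == sp]
    if (length(members) == 0L) return(NULL)
    merge_pileups(r45_pile[members])
  })
  names(species_pools) <- spec$species
  species_data <- lapply(spec$species, function(sp) {
    members <- names(species_of)[species_of == sp & !het_outlier]
    if (length(members) == 0L) members <- names(species_of)[species_of == sp]
    list(cp_consensus = if (length(members)) majority_consensus(cp_cons[members])$consensus else
           panel$species[[sp]]$chloroplast$sequence,
         mt_consensus = if (length(members)) majority_consensus(mt_cons[members])$consensus else
           panel$species[[sp]]$mitochondrion$sequence,
         r45s_consensus = if (length(members)) majority_consensus(r45_cons[members])$consensus else
           panel$species[[sp]]$r45s_unit,
         r45s_pileup = species_pools[[sp]])
  })
  names(species_data) <- spec$species
  strain_data <- lapply(names(strains), function(sid) {
    list(organelle_species = unname(species_of[sid]),
         r45s_pileup = r45_pile[[sid]],
         cp_pileup = own_cp[[sid]], mt_pileup = own_mt[[sid]])
  })
  names(strain_data) <- names(strains)
  hybrids <- call_hybrids(strain_data, species_data)

  ## --- summary --------------------------------------------------------------
  summary <- list(
    n_strains = length(strains),
    n_clusters = clusters$n_clusters,
    rand_index_vs_truth = rand,
    species_counts = as.list(table(species_of)),
    n_f1_hybrids = hybrids$summary$F1_hybrid,
    f1_strains = hybrids$report$strain[hybrids$report$verdict == "F1_hybrid"],
    n_cp_inversions = n_distinct_cp_inv,
    n_mt_inversions = nrow(mt_inv),
    inversion_clade = inverted_clade,
    assembly = assembly_tbl,
    inter_cp = inter_cp, inter_mt = inter_mt,
    intra_cp = intra_cp, intra_mt = intra_mt)
  result <- structure(list(config = config, panel = panel, strains = strains,
                           snp_matrix = snp_m, pca = pca, clusters = clusters,
                           species_of = species_of,
                           truth_species = truth_species,
                           assignment = assignment,
                           consensuses = list(cp = cp_cons, mt = mt_cons,
                                              r45s = r45_cons),
                           trees = trees, agreement = agreement,
                           cp_inversions = cp_inv, mt_inversions = mt_inv,
                           hybrids = hybrids, summary = summary),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  strains: %d  clusters: %d (Rand vs truth %.3f)\n",
              s$n_strains, s$n_clusters, s$rand_index_vs_truth))
  cat(sprintf("  F1 hybrids: %d %s\n", s$n_f1_hybrids,
              if (length(s$f1_strains)) paste0("(", paste(s$f1_strains, collapse = ", "), ")")
              else ""))
  cat(sprintf("  chloroplast inversions: %d (clade: %s); mitochondrial: %d\n",
              s$n_cp_inversions, paste(s$inversion_clade, collapse = ", "),
              s$n_mt_inversions))
  invisible(x)
}

# Serialize the main stage outputs of a pipeline run (deterministic content:
# no timestamps, so identical seeds give identical files).
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_fasta(result$consensuses$cp, file.path(out_dir, "consensus_cp.fasta"))
  write_fasta(result$consensuses$mt, file.path(out_dir, "consensus_mt.fasta"))
  write_fasta(result$consensuses$r45s, file.path(out_dir, "consensus_45s.fasta"))
  tsv(data.frame(strain = names(result$species_of),
                 cluster = unname(result$clusters$cluster),
                 species = unname(result$species_of),
                 truth = unname(result$truth_species)), "clusters.tsv")
  tsv(as.data.frame(result$pca$coordinates), "pca_coordinates.tsv")
  tsv(result$summary$inter_cp, "interspecific_cp.tsv")
  tsv(result$summary$inter_mt, "interspecific_mt.tsv")
  tsv(result$summary$intra_cp, "intraspecific_cp.tsv")
  tsv(result$summary$intra_mt, "intraspecific_mt.tsv")
  tsv(result$hybrids$report, "hybrid_report.tsv")
  if (!is.null(result$summary$assembly)) tsv(result$summary$assembly, "assembly.tsv")
  for (nm in names(result$trees)) {
    if (!is.null(result$trees[[nm]]))
      ape::write.tree(result$trees[[nm]]$tree,
                      file.path(out_dir, paste0("tree_", nm, ".nwk")))
  }
  s <- result$summary
  md <- c("# Pipeline summary", "",
          sprintf("- strains analyzed: %d", s$n_strains),
          sprintf("- species clusters: %d (Rand index vs truth: %.3f)",
                  s$n_clusters, s$rand_index_vs_truth),
          sprintf("- F1 hybrids detected: %d%s", s$n_f1_hybrids,
                  if (length(s$f1_strains)) paste0(" (", paste(s$f1_strains, collapse = ", "), ")") else ""),
          sprintf("- chloroplast inversions (distinct): %d", s$n_cp_inversions),
          sprintf("- inversion clade: %s", paste(s$inversion_clade, collapse = ", ")),
          sprintf("- mitochondrial inversions: %d", s$n_mt_inversions))
  writeLines(md, file.path(out_dir, "summary.md"))
  jsonlite::write_json(
    s[c("n_strains", "n_clusters", "rand_index_vs_truth", "n_f1_hybrids",
        "n_cp_inversions", "n_mt_inversions")],
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
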