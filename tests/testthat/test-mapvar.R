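test_that("mapping error-free own reads gives full depth and no variants", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 51)
  st <- quiet_strain("s", "alpha", seed = 52, coverage_cp = 30, error_rate = 0)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g, molecules = "cp")
  pile <- map_reads(rs, g$cp)
  expect_equal(pile$n_mapped, pile$n_reads)
  expect_equal(mean(pile$depth), 30, tolerance = 0.05)
  v <- call_variants(pile)
  expect_equal(sum(v$call %in% c("variant", "heterozygous")), 0)
})

test_that("a single substituted read lands at its true locus with one alt base", {
  set.seed(53)
  ref <- random_dna(3000)
  read <- substr(ref, 1001, 1150)
  substr(read, 75, 75) <- if (substr(read, 75, 75) == "A") "C" else "A"
  pile <- map_reads(read, ref, circular = FALSE)
  expect_true(pile$placements$mapped[1])
  expect_equal(pile$placements$pos[1], 1000)
  expect_equal(pile$placements$mismatches[1], 1)
  alt_positions <- which(colSums(pile$counts) > 0 &
                           pile$counts[cbind(match(ulvapop:::seq_chars(ref),
                                                   c("A", "C", "G", "T")),
                                             seq_len(3000))] == 0)
  expect_equal(alt_positions, 1075)
})

test_that("placements match the brute-force minimum-mismatch oracle", {
  spec <- species_panel_spec(c("a", "b"), cp_length_bp = 2000L,
                             mt_length_bp = 1000L,
                             cp_divergence_per_kb = c(0, 2),
                             mt_divergence_per_kb = c(0, 0),
                             intra_divergence_per_kb = 0,
                             r45s_length_bp = 500L, r45s_copy_number = 10L,
                             cp_genes = 2L, mt_genes = 1L)
  p <- simulate_panel(spec, seed = 54)
  st <- quiet_strain("s", "b", seed = 55, coverage_cp = 2, error_rate = 0.005)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g, molecules = "cp")
  ref <- p$species$a$chloroplast$sequence
  pile <- map_reads(rs, ref)
  reads <- c(rs$r1, rs$r2)
  for (i in seq_len(min(25, length(reads)))) {
    o <- oracle_place_read(reads[[i]], ref)
    expect_equal(pile$placements$pos[i], o$pos)
    expect_equal(pile$placements$mismatches[i], o$mismatches)
    expect_equal(pile$placements$strand[i], o$strand)
  }
})

test_that("variant calling applies depth and fraction thresholds", {
  ref <- strrep("A", 50)
  mk_pile <- function(counts) {
    structure(list(reference_id = "r", reference = ref, counts = counts,
                   depth = colSums(counts), placements = NULL,
                   n_reads = 0L, n_mapped = 0L), class = "pileup")
  }
  counts <- matrix(0L, 4, 50, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", ] <- 30L
  counts[, 10] <- c(0L, 30L, 0L, 0L)   # 30 reads all alt -> variant
  counts[, 20] <- c(15L, 15L, 0L, 0L)  # 15/15 -> heterozygous
  counts[, 30] <- c(5L, 0L, 0L, 0L)    # depth 5 -> no_call
  counts[, 40] <- c(26L, 4L, 0L, 0L)   # 13% alt -> ref
  v <- call_variants(mk_pile(counts))
  expect_equal(v$call[v$position == 9], "variant")
  expect_equal(v$call[v$position == 19], "heterozygous")
  expect_equal(v$call[v$position == 29], "no_call")
  expect_false(39 %in% v$position)
})

test_that("consensus substitutes variants, resolves het by majority, logs no-calls", {
  ref <- "AAAAAAAAAA"
  v <- data.frame(position = c(1L, 3L, 5L, 7L),
                  ref_allele = "A", alt_allele = c("C", "G", "T", "C"),
                  alt_count = c(30L, 18L, 15L, 0L),
                  ref_count = c(0L, 12L, 15L, 2L),
                  alt_fraction = c(1, 0.6, 0.5, 0),
                  depth = c(30L, 30L, 30L, 2L),
                  call = c("variant", "heterozygous", "heterozygous", "no_call"),
                  stringsAsFactors = FALSE)
  cons_full <- build_consensus(ref, v)
  expect_equal(attr(cons_full, "no_call_positions"), 7L)
  cons <- c(cons_full)  # drop attributes for substring comparisons
  expect_equal(substr(cons, 2, 2), "C")   # variant
  expect_equal(substr(cons, 4, 4), "G")   # het majority alt
  expect_equal(substr(cons, 6, 6), "A")   # het tie -> reference
  expect_equal(substr(cons, 8, 8), "A")   # no_call -> reference
  expect_identical(c(build_consensus(ref, v[0, ])), ref)
  expect_error(build_consensus(ref, rbind(v, v[1, ])), "conflicting")
})

test_that("consensus round-trip reproduces the strain truth at 20x error-free coverage", {
  spec <- tiny_panel_spec(intra = 0.5)
  p <- simulate_panel(spec, seed = 56)
  st <- quiet_strain("s", "beta", seed = 57, coverage_cp = 20, error_rate = 0)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g, molecules = "cp")
  pile <- map_reads(rs, p$species$beta$chloroplast)
  v <- call_variants(pile)
  cons <- build_consensus(pile$reference, v)
  covered <- setdiff(seq_len(nchar(cons)) - 1L, attr(cons, "no_call_positions"))
  expect_identical(ulvapop:::seq_chars(cons)[covered + 1L],
                   ulvapop:::seq_chars(g$cp$sequence)[covered + 1L])
})

test_that("snp_density reproduces the printed-table normalization", {
  expect_equal(snp_density(5230, 63775), 82)
  expect_equal(snp_density(5512, 24854), 222)
  expect_equal(snp_density(2249, 63775), 35.3)
  expect_equal(snp_density(2139, 24854), 86.1)
  expect_equal(snp_density(5090, 63775), 79.8)
  expect_equal(snp_density(391, 63775), 6.1)
  expect_equal(snp_density(140, 24854), 5.6)
  expect_equal(snp_density(0, 12345), 0)
  expect_error(snp_density(1, 0))
})

test_that("inter/intra-specific statistics compute the documented arithmetic", {
  # two-strain toy with 3 planted CDS SNPs over 1,000 bp
  ref <- random_dna(1000)
  alt <- ulvapop:::substitute_bases(ref, c(10, 500, 900), c("A", "A", "A"))
  alt <- if (identical(alt, ref))
    ulvapop:::substitute_bases(ref, c(10, 500, 900), c("C", "C", "C")) else alt
  cons <- c(r1 = ref, s1 = alt)
  stats <- interspecific_stats(cons, c("refsp", "other"), "refsp")
  expect_equal(stats$mean_snps[stats$species == "other"],
               ulvapop:::seq_mismatches(ref, alt))
  expect_equal(stats$snps_per_kb[stats$species == "other"],
               snp_density(ulvapop:::seq_mismatches(ref, alt), 1000))
  expect_equal(stats$mean_snps[stats$species == "refsp"], 0)
  # identical strains: all zeros
  same <- c(a = ref, b = ref, c = ref)
  i0 <- intraspecific_stats(same, rep("sp", 3))
  expect_equal(i0$mean_snps_per_kb, 0)
  expect_equal(i0$sd_snps_per_kb, 0)
  expect_equal(i0$total_variant_sites, 0)
  # 3 strains each with one private SNP on 10 kb -> 0.1 +- 0.0, total 3
  base <- random_dna(10000)
  mk <- function(pos) {
    b <- ulvapop:::seq_chars(base)[pos]
    ulvapop:::substitute_bases(base, pos, ulvapop:::mutate_bases(b))
  }
  set.seed(58)
  three <- c(a = mk(100), b = mk(5000), c = mk(9000))
  # majority consensus equals the base sequence; each strain differs by 1
  i3 <- intraspecific_stats(three, rep("sp", 3))
  expect_equal(i3$mean_snps_per_kb, 0.1)
  expect_equal(i3$sd_snps_per_kb, 0)
  expect_equal(i3$total_variant_sites, 3)
  # single strain: SD absent
  i1 <- intraspecific_stats(c(a = ref), "sp")
  expect_true(is.na(i1$sd_snps_per_kb))
})

test_that("intraspecific density recovers the generator parameter", {
  spec <- tiny_panel_spec(intra = 0.2, cp_len = 20000L)
  p <- simulate_panel(spec, seed = 59)
  strains <- lapply(1:29, function(i) {
    simulate_strain_genomes(p, quiet_strain(sprintf("s%02d", i), "alpha",
                                            seed = 600 + i))
  })
  cons <- vapply(strains, function(g) g$cp$sequence, character(1))
  names(cons) <- sprintf("s%02d", 1:29)
  st <- intraspecific_stats(cons, rep("alpha", 29))
  # mean per-strain density ~ 0.2/kb (majority consensus absorbs none of the
  # private SNPs at 29 strains); 99% CI on the pooled count
  n_total <- st$mean_snps_per_kb * 29 * 20
  expect_lt(abs(n_total - 0.2 * 20 * 29), ci99_halfwidth(29 * 20000, 2e-4))
})

test_that("concatenated CDS extraction is strand-resolved with exact length", {
  seq <- "AAACCCGGGTTTAAACCCGGGTTT"
  ann <- data.frame(gene_id = c("g1", "g2"), start = c(3L, 12L),
                    end = c(9L, 18L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  cds <- cds_set(ann)
  expect_equal(cds$concat_length, 12)
  out <- extract_concat_cds(seq, cds)
  # minus-strand gene covers "AAACCC"; its reverse complement is GGGTTT
  expect_equal(out, paste0("CCCGGG", "GGGTTT"))
  expect_error(extract_concat_cds(substr(seq, 1, 10), cds), "outside")
  g <- circular_genome("g", seq, TRUE, ann)
  expect_equal(nchar(extract_concat_cds(g)), 12)
})

test_that("truth-table densities equal read-pipeline densities at error 0 (oracle equivalence)", {
  spec <- tiny_panel_spec(cp_div = c(0, 20), intra = 0)
  p <- simulate_panel(spec, seed = 61)
  st <- quiet_strain("s", "beta", seed = 62, coverage_cp = 30, error_rate = 0)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g, molecules = "cp")
  pile <- map_reads(rs, p$species$alpha$chloroplast)
  v <- call_variants(pile)
  called <- sort(v$position[v$call == "variant"])
  truth_beta <- p$truth[p$truth$molecule == "chloroplast", ]
  truth_pos <- sort(truth_beta$position) - 1L
  no_call <- v$position[v$call == "no_call"]
  expect_identical(setdiff(truth_pos, no_call), setdiff(called, no_call))
})

test_that("SAM import reproduces the internal pileup for ungapped alignments", {
  set.seed(63)
  ref <- random_dna(500)
  starts <- c(1, 101, 301)
  reads <- substring(ref, starts, starts + 99)
  sam <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6",
             sprintf("r%d\t0\tref\t%d\t60\t100M\t*\t0\t0\t%s\tIIII", 1:3, starts, reads))
  writeLines(lines, sam)
  pile <- read_sam_pileup(sam, ref)
  expect_equal(pile$n_mapped, 3)
  expect_equal(sum(pile$depth), 300)
  v <- call_variants(pile, min_depth = 1L)
  expect_equal(sum(v$call == "variant"), 0)
})

test_that("variant tables export as minimal VCF with 1-based positions", {
  v <- data.frame(position = c(4L, 9L), ref_allele = c("A", "G"),
                  alt_allele = c("T", "C"), alt_count = c(28L, 15L),
                  ref_count = c(2L, 15L), alt_fraction = c(0.93, 0.5),
                  depth = c(30L, 30L),
                  call = c("variant", "heterozygous"), stringsAsFactors = FALSE)
  attr(v, "reference_id") <- "cp_ref"
  path <- tempfile(fileext = ".vcf")
  write_vcf(v, path, sample = "U01")
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "##fileformat=VCF"))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[1], "cp_ref")
  expect_equal(f[2], "5")  # 0-based 4 -> 1-based 5
  expect_equal(f[4], "A")
  expect_equal(f[5], "T")
  expect_match(body[2], "HET")
})
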