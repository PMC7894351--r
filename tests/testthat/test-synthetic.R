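test_that("panel simulation is deterministic and honors zero divergence", {
  spec <- tiny_panel_spec(cp_div = c(0, 0), mt_div = c(0, 0),
                          r45s_diffs = c(0L, 0L))
  p1 <- simulate_panel(spec, seed = 42)
  p2 <- simulate_panel(spec, seed = 42)
  expect_identical(p1, p2)
  # zero inter-specific rate: identical sequences for the pair
  expect_identical(p1$species$alpha$chloroplast$sequence,
                   p1$species$beta$chloroplast$sequence)
  expect_identical(p1$species$alpha$r45s_unit, p1$species$beta$r45s_unit)
  expect_equal(nrow(p1$truth), 0)
  # a different seed gives different sequences
  p3 <- simulate_panel(spec, seed = 43)
  expect_false(identical(p1$species$alpha$chloroplast$sequence,
                         p3$species$alpha$chloroplast$sequence))
})

test_that("realized inter-specific divergence matches the requested density", {
  # 82 SNPs/kb over a 63,775 bp coding complement: the realized count must
  # sit within the 99% binomial interval of 5,230
  spec <- species_panel_spec(c("ref", "other"),
                             cp_length_bp = 63775L, mt_length_bp = 5000L,
                             cp_divergence_per_kb = c(0, 82),
                             mt_divergence_per_kb = c(0, 0),
                             intra_divergence_per_kb = 0,
                             r45s_length_bp = 1000L, r45s_copy_number = 100L,
                             cp_genes = 4L, mt_genes = 2L)
  p <- simulate_panel(spec, seed = 5)
  n <- seq_mismatches(p$species$ref$chloroplast$sequence,
                      p$species$other$chloroplast$sequence)
  expect_lt(abs(n - 5230), ci99_halfwidth(63775, 0.082))
  # the truth table records exactly the realized variant sites
  tt <- p$truth[p$truth$molecule == "chloroplast", ]
  expect_equal(nrow(tt), n)
})

test_that("divergence densities are recovered across seeds and saturation is rejected", {
  spec <- tiny_panel_spec(cp_div = c(0, 35), intra = 0)
  counts <- vapply(1:20, function(s) {
    p <- simulate_panel(spec, seed = s)
    seq_mismatches(p$species$alpha$chloroplast$sequence,
                   p$species$beta$chloroplast$sequence)
  }, numeric(1))
  expected <- 35 / 1000 * 10000
  expect_lt(abs(mean(counts) - expected),
            ci99_halfwidth(20 * 10000, 0.035) / 20)
  expect_error(tiny_panel_spec(cp_div = c(0, 1200)), "saturation")
})

test_that("the inversion clade carries the reverse-complemented segment with transplanted genes", {
  spec <- species_panel_spec(c("a", "b", "c"),
                             cp_length_bp = 12000L, mt_length_bp = 5000L,
                             cp_divergence_per_kb = c(0, 10, 40),
                             mt_divergence_per_kb = c(0, 5, 10),
                             intra_divergence_per_kb = 0,
                             inversion_clade = "c",
                             r45s_length_bp = 1000L, r45s_copy_number = 100L,
                             cp_genes = 8L, mt_genes = 3L)
  p <- simulate_panel(spec, seed = 9)
  seg <- p$inversion_segment
  a_seq <- p$species$a$chloroplast$sequence
  c_seq <- p$species$c$chloroplast$sequence
  # outside the segment: only branch substitutions; inside: reverse complement
  uninv <- ulvapop:::invert_segment(c_seq, seg[1], seg[2])
  d_direct <- seq_mismatches(a_seq, uninv)
  expect_lt(d_direct / 12, 60)  # ~50/kb, far below the ~75% of misaligned RC
  # annotation transplanted: extracting CDS in gene_id order returns every
  # gene in ancestral orientation, so concatenated CDS differ only by SNPs
  cds_a <- extract_concat_cds(p$species$a$chloroplast)
  cds_c <- extract_concat_cds(p$species$c$chloroplast)
  expect_equal(nchar(cds_a), nchar(cds_c))
  expect_lt(seq_mismatches(cds_a, cds_c) / nchar(cds_a), 0.06)
  # a gene inside the segment flips strand
  ann_a <- p$species$a$chloroplast$annotation
  ann_c <- p$species$c$chloroplast$annotation
  inside <- ann_a$start >= seg[1] & ann_a$end <= seg[2]
  expect_true(any(inside))
  flipped <- ann_c[match(ann_a$gene_id[inside], ann_c$gene_id), "strand"]
  expect_true(all(flipped != ann_a$strand[inside]))
})

test_that("strain genomes: zero intra density reproduces the species reference; hybrid is homoplasmic", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 3)
  st <- quiet_strain("s1", "beta", seed = 11)
  g <- simulate_strain_genomes(p, st)
  expect_identical(g$cp$sequence, p$species$beta$chloroplast$sequence)
  expect_identical(g$mt$sequence, p$species$beta$mitochondrion$sequence)
  expect_true(all(g$r45s_copies == p$species$beta$r45s_unit))
  expect_error(simulate_strain_genomes(p, quiet_strain("sx", "gamma", 1)),
               "unknown species")
  # hybrid: organelles are the cytoplasm donor's haplotype only
  hy <- strain_spec("h1", "alpha", is_hybrid = TRUE,
                    hybrid_parents = c("alpha", "beta"),
                    cytoplasm_donor = "alpha", contaminant_fraction = 0,
                    seed = 12)
  gh <- simulate_strain_genomes(p, hy)
  expect_identical(gh$cp$sequence, p$species$alpha$chloroplast$sequence)
  expect_identical(gh$mt$sequence, p$species$alpha$mitochondrion$sequence)
})

test_that("hybrid 45S copy pool splits ~50/50 between parents", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 3)
  fracs <- vapply(1:20, function(s) {
    hy <- strain_spec("h", "alpha", is_hybrid = TRUE,
                      hybrid_parents = c("alpha", "beta"),
                      contaminant_fraction = 0, seed = s)
    gh <- simulate_strain_genomes(p, hy)
    mean(gh$r45s_parent == "alpha")
  }, numeric(1))
  # each draw is Binomial(100, 0.5)/100: all within 4 sd, mean near 0.5
  expect_true(all(abs(fracs - 0.5) <= 4 * sqrt(0.25 / 100)))
  expect_lt(abs(mean(fracs) - 0.5), 4 * sqrt(0.25 / (100 * 20)))
})

test_that("read counts follow coverage arithmetic and error-free reads are genome substrings", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 3)
  st <- quiet_strain("s1", "alpha", seed = 4, coverage_cp = 20,
                     coverage_mt = 10, coverage_45s = 30, error_rate = 0)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g)
  # coverage 20x of a 10,000 bp genome with 150 bp reads -> 667 pairs
  expect_equal(sum(rs$truth$molecule == "cp"), 667)
  expect_equal(sum(rs$truth$molecule == "mt"),
               round(10 * 6000 / (2 * 150)))
  doubled_cp <- paste0(g$cp$sequence, g$cp$sequence)
  cp_ids <- rs$truth$read_id[rs$truth$molecule == "cp"]
  hits1 <- vapply(rs$r1[cp_ids], function(r) grepl(r, doubled_cp, fixed = TRUE),
                  logical(1))
  hits2 <- vapply(rs$r2[cp_ids], function(r) {
    grepl(r, doubled_cp, fixed = TRUE) || grepl(revcomp(r), doubled_cp, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits1))
  expect_true(all(hits2))
  # determinism: same strain seed, byte-identical reads
  rs2 <- simulate_reads(g)
  expect_identical(rs$r1, rs2$r1)
  expect_identical(rs$r2, rs2$r2)
  expect_error(simulate_reads(g, strain_spec("x", "alpha", read_length = 7000L,
                                             contaminant_fraction = 0, seed = 1)),
               "read_length")
})

test_that("realized read error rate matches the requested rate", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 3)
  st <- quiet_strain("s1", "alpha", seed = 8, coverage_cp = 30,
                     coverage_mt = 0.1, coverage_45s = 0.1, error_rate = 0.01)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g, molecules = "cp")
  doubled <- paste0(g$cp$sequence, g$cp$sequence)
  tt <- rs$truth
  mm <- 0L
  total <- 0L
  for (i in seq_len(nrow(tt))) {
    frag <- substr(doubled, tt$start[i] + 1, tt$start[i] + tt$fragment[i])
    r1_true <- substr(frag, 1, 150)
    r2_true <- revcomp(substr(frag, nchar(frag) - 149, nchar(frag)))
    mm <- mm + seq_mismatches(rs$r1[[tt$read_id[i]]], r1_true) +
      seq_mismatches(rs$r2[[tt$read_id[i]]], r2_true)
    total <- total + 300L
  }
  expect_gte(total, 1e5)
  expect_lt(abs(mm - 0.01 * total), ci99_halfwidth(total, 0.01))
})

test_that("FASTA/FASTQ/BED round-trips preserve content", {
  seqs <- c(g1 = "ACGTACGTAAATTTCCCGGG", g2 = strrep("ACGT", 50))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
  fq1 <- tempfile(fileext = ".fq")
  fq2 <- tempfile(fileext = ".fq")
  write_fastq_pairs(c("ACGT", "TTTT"), c("GGGG", "AAAA"), fq1, fq2,
                    ids = c("r1", "r2"))
  expect_identical(unname(read_fastq(fq1)), c("ACGT", "TTTT"))
  expect_identical(names(read_fastq(fq2)), c("r1/2", "r2/2"))
  ann <- data.frame(gene_id = c("a", "b"), start = c(0L, 100L),
                    end = c(50L, 220L), strand = c("+", "-"))
  bed <- tempfile(fileext = ".bed")
  write_bed(ann, "chr", bed)
  back <- read_bed(bed)
  expect_equal(back[, c("gene_id", "start", "end", "strand")], ann)
})
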