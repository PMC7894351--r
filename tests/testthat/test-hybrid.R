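# Build a pileup directly from base counts on a reference.
counts_pileup <- function(ref, counts) {
  structure(list(reference_id = "r45s", reference = ref, counts = counts,
                 depth = colSums(counts), placements = NULL,
                 n_reads = 0L, n_mapped = 0L), class = "pileup")
}

# Pileup for a clean haploid sample: every position covered `depth`x by
# `seq`, with optional per-site mixtures given as list(position = c(base = n)).
clean_pileup <- function(ref, seq = ref, depth = 100L, mixtures = list()) {
  L <- nchar(ref)
  counts <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(ulvapop:::seq_chars(seq), c("A", "C", "G", "T"))
  counts[cbind(idx, seq_len(L))] <- depth
  for (pos in names(mixtures)) {
    p <- as.integer(pos)
    counts[, p] <- 0L
    mix <- mixtures[[pos]]
    counts[match(names(mix), c("A", "C", "G", "T")), p] <- as.integer(mix)
  }
  counts_pileup(ref, counts)
}

test_that("informative sites are consensus differences fixed within species", {
  set.seed(81)
  a <- random_dna(400)
  pos <- c(50L, 150L, 300L)
  b <- ulvapop:::substitute_bases(a, pos, ulvapop:::mutate_bases(
    ulvapop:::seq_chars(a)[pos]))
  expect_warning(empty <- find_informative_sites(a, a), "no informative")
  expect_equal(nrow(empty), 0)
  sites <- find_informative_sites(a, b)
  expect_equal(sites$position, pos - 1L)
  expect_equal(sites$allele_a, ulvapop:::seq_chars(a)[pos])
  expect_equal(sites$allele_b, ulvapop:::seq_chars(b)[pos])
  # a site polymorphic within species A at 0.9 is excluded at threshold 0.95
  pa <- clean_pileup(a, depth = 100L,
                     mixtures = setNames(list(setNames(c(90L, 10L),
                                                       c(ulvapop:::seq_chars(a)[50],
                                                         ulvapop:::seq_chars(b)[50]))),
                                         "50"))
  sites2 <- find_informative_sites(a, b, pileup_a = pa)
  expect_false(49 %in% sites2$position)
  expect_true(all(c(149, 299) %in% sites2$position))
})

test_that("planted 45S fixed differences are recovered exactly as informative sites", {
  # the scenario of ~65 fixed differences in a ~5 kb repeat between the two
  # most diverged species
  spec <- species_panel_spec(c("laet", "pseudo"),
                             cp_length_bp = 5000L, mt_length_bp = 2000L,
                             cp_divergence_per_kb = c(0, 10),
                             mt_divergence_per_kb = c(0, 10),
                             intra_divergence_per_kb = 0,
                             r45s_length_bp = 5000L, r45s_copy_number = 100L,
                             r45s_fixed_diffs = c(0L, 65L),
                             cp_genes = 3L, mt_genes = 2L)
  p <- simulate_panel(spec, seed = 82)
  sites <- find_informative_sites(p$species$laet$r45s_unit,
                                  p$species$pseudo$r45s_unit)
  truth_pos <- sort(p$truth$position[p$truth$molecule == "r45s"]) - 1L
  expect_equal(nrow(sites), 65)
  expect_equal(sites$position, truth_pos)
})

test_that("allele profiles report parental-allele frequencies with noise separated", {
  set.seed(83)
  a <- random_dna(300)
  pos <- c(40L, 120L, 200L)
  b <- ulvapop:::substitute_bases(a, pos, ulvapop:::mutate_bases(
    ulvapop:::seq_chars(a)[pos]))
  sites <- find_informative_sites(a, b)
  # pure-A strain, no error: all frequencies 1
  prof <- allele_profile(clean_pileup(a, depth = 500L), sites)
  expect_equal(prof$freq_a, rep(1, 3))
  # a site with 60/40 mixture plus third-base noise
  third <- setdiff(c("A", "C", "G", "T"),
                   c(ulvapop:::seq_chars(a)[120], ulvapop:::seq_chars(b)[120]))[1]
  mix <- setNames(c(600L, 400L, 10L),
                  c(ulvapop:::seq_chars(a)[120], ulvapop:::seq_chars(b)[120], third))
  prof2 <- allele_profile(clean_pileup(a, depth = 1000L,
                                       mixtures = setNames(list(mix), "120")),
                          sites)
  row <- prof2[prof2$position == 119, ]
  expect_equal(row$freq_a, 0.6)
  expect_equal(row$noise, 10)
  # sites below depth are dropped
  prof3 <- allele_profile(clean_pileup(a, depth = 5L), sites)
  expect_equal(nrow(prof3), 0)
})

test_that("nuclear classification separates pure, F1 and chimeric patterns", {
  set.seed(84)
  a <- random_dna(2000)
  pos <- sort(sample.int(2000, 12))
  b <- ulvapop:::substitute_bases(a, pos, ulvapop:::mutate_bases(
    ulvapop:::seq_chars(a)[pos]))
  sites <- find_informative_sites(a, b)
  prof_pure <- allele_profile(clean_pileup(a, depth = 1000L), sites)
  expect_equal(classify_nuclear(prof_pure)$call, "A")
  prof_b <- allele_profile(clean_pileup(a, seq = b, depth = 1000L), sites)
  expect_equal(classify_nuclear(prof_b)$call, "B")
  # all frequencies 0.5 at depth 1000
  mixes <- lapply(seq_len(nrow(sites)), function(i) {
    setNames(c(500L, 500L), c(sites$allele_a[i], sites$allele_b[i]))
  })
  names(mixes) <- as.character(sites$position + 1L)
  prof_het <- allele_profile(clean_pileup(a, depth = 1000L, mixtures = mixes),
                             sites)
  expect_equal(classify_nuclear(prof_het)$call, "heterozygous_AB")
  # half the sites fixed A, half fixed B: chimera, not F1
  half <- mixes
  for (i in seq_along(half)) {
    full <- if (i %% 2 == 0) sites$allele_a[i] else sites$allele_b[i]
    half[[i]] <- setNames(1000L, full)
  }
  prof_chim <- allele_profile(clean_pileup(a, depth = 1000L, mixtures = half),
                              sites)
  expect_equal(classify_nuclear(prof_chim)$call, "ambiguous")
  # too few usable sites
  expect_equal(classify_nuclear(prof_pure[1:3, ])$call, "ambiguous")
})

test_that("homoplasmy check returns donor species and flags read mixtures", {
  set.seed(85)
  a <- random_dna(1000)
  pos <- sort(sample.int(1000, 20))
  b <- ulvapop:::substitute_bases(a, pos, ulvapop:::mutate_bases(
    ulvapop:::seq_chars(a)[pos]))
  # pure-A organelle reads
  h <- check_homoplasmy(clean_pileup(a, depth = 60L), a, b, c("spA", "spB"))
  expect_equal(h$call, "spA")
  expect_true(h$homoplasmic)
  # donor-B organelle
  hb <- check_homoplasmy(clean_pileup(a, seq = b, depth = 60L), a, b,
                         c("spA", "spB"))
  expect_equal(hb$call, "spB")
  expect_true(hb$homoplasmic)
  # 70/30 mixture: called for the majority species but not homoplasmic
  mixes <- lapply(seq_along(pos), function(i) {
    setNames(c(42L, 18L), c(ulvapop:::seq_chars(a)[pos[i]],
                            ulvapop:::seq_chars(b)[pos[i]]))
  })
  names(mixes) <- as.character(pos)
  hm <- check_homoplasmy(clean_pileup(a, depth = 60L, mixtures = mixes),
                         a, b, c("spA", "spB"))
  expect_equal(hm$call, "spA")
  expect_false(hm$homoplasmic)
})

test_that("a simulated F1 shows ~0.5 pooled allele frequency and is called a hybrid", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 86)
  hy <- strain_spec("h", "alpha", is_hybrid = TRUE,
                    hybrid_parents = c("alpha", "beta"),
                    coverage_45s = 1000, contaminant_fraction = 0, seed = 87)
  gh <- simulate_strain_genomes(p, hy)
  rs <- simulate_reads(gh, molecules = "r45s")
  pile <- map_reads(rs, p$species$alpha$r45s_unit, circular = TRUE)
  sites <- find_informative_sites(p$species$alpha$r45s_unit,
                                  p$species$beta$r45s_unit)
  prof <- allele_profile(pile, sites, strain_id = "h")
  copy_frac <- mean(gh$r45s_parent == "alpha")
  # each site's frequency reflects the copy draw within 3 binomial SD
  expect_true(all(abs(prof$freq_a - copy_frac) < 3 * sqrt(0.25 / 100) + 0.05))
  expect_equal(classify_nuclear(prof)$call, "heterozygous_AB")
  # and the organelles are homoplasmic for the cytoplasm donor
  rso <- simulate_reads(gh, molecules = c("cp", "mt"))
  cp_pile <- map_reads(rso, p$species$alpha$chloroplast)
  hcp <- check_homoplasmy(cp_pile, p$species$alpha$chloroplast$sequence,
                          p$species$beta$chloroplast$sequence,
                          c("alpha", "beta"))
  expect_equal(hcp$call, "alpha")
  expect_true(hcp$homoplasmic)
})

test_that("pure strains with 1% read error keep parental frequencies near 0/1", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 88)
  st <- quiet_strain("s", "beta", seed = 89, coverage_45s = 1000,
                     error_rate = 0.01)
  g <- simulate_strain_genomes(p, st)
  rs <- simulate_reads(g, molecules = "r45s")
  pile <- map_reads(rs, p$species$alpha$r45s_unit, circular = TRUE)
  sites <- find_informative_sites(p$species$alpha$r45s_unit,
                                  p$species$beta$r45s_unit)
  prof <- allele_profile(pile, sites)
  expect_true(all(prof$freq_a <= 0.02))
  expect_equal(classify_nuclear(prof)$call, "B")
})

test_that("call_hybrids flags only the planted hybrid in a small panel", {
  spec <- tiny_panel_spec(intra = 0.2)
  p <- simulate_panel(spec, seed = 90)
  species_data <- lapply(p$species, function(s) {
    list(cp_consensus = s$chloroplast$sequence,
         mt_consensus = s$mitochondrion$sequence,
         r45s_consensus = s$r45s_unit, r45s_pileup = NULL)
  })
  make_strain_data <- function(g, sp) {
    rs <- simulate_reads(g)
    list(organelle_species = sp,
         r45s_pileup = map_reads(rs, p$species$alpha$r45s_unit, circular = TRUE),
         cp_pileup = map_reads(rs, p$species[[sp]]$chloroplast),
         mt_pileup = map_reads(rs, p$species[[sp]]$mitochondrion))
  }
  sd <- list()
  for (i in 1:2) {
    sp <- c("alpha", "beta")[i]
    g <- simulate_strain_genomes(p, quiet_strain(paste0("p", i), sp,
                                                 seed = 900 + i,
                                                 coverage_45s = 300))
    sd[[paste0("p", i)]] <- make_strain_data(g, sp)
  }
  hy <- strain_spec("hyb", "alpha", is_hybrid = TRUE,
                    hybrid_parents = c("alpha", "beta"),
                    coverage_45s = 300, contaminant_fraction = 0, seed = 903)
  sd$hyb <- make_strain_data(simulate_strain_genomes(p, hy), "alpha")
  rep <- call_hybrids(sd, species_data)
  expect_equal(rep$summary$F1_hybrid, 1)
  expect_equal(rep$report$verdict[rep$report$strain == "hyb"], "F1_hybrid")
  expect_equal(sum(rep$report$verdict == "pure"), 2)
  # nuclear A with organelles B and no heterozygosity is discordant_non_F1
  g_b <- simulate_strain_genomes(p, quiet_strain("disc", "beta", seed = 904,
                                                 coverage_45s = 300))
  rs_b <- simulate_reads(g_b)
  sd_disc <- list(disc = list(
    organelle_species = "beta",
    # nuclear reads claim alpha: reuse a pure-alpha strain's 45S pileup
    r45s_pileup = sd$p1$r45s_pileup,
    cp_pileup = map_reads(rs_b, p$species$beta$chloroplast),
    mt_pileup = map_reads(rs_b, p$species$beta$mitochondrion)))
  rep2 <- call_hybrids(sd_disc, species_data)
  expect_equal(rep2$report$verdict, "discordant_non_F1")
})

test_that("the hybrid lies between the parental clusters on the allele-frequency PCA axis", {
  spec <- tiny_panel_spec(intra = 0)
  p <- simulate_panel(spec, seed = 91)
  piles <- list()
  labels <- c()
  for (i in 1:3) {
    for (sp in c("alpha", "beta")) {
      id <- paste0(sp, i)
      g <- simulate_strain_genomes(p, quiet_strain(id, sp, seed = 910 + 10 * i +
                                                     (sp == "beta"),
                                                   coverage_45s = 300))
      rs <- simulate_reads(g, molecules = "r45s")
      piles[[id]] <- map_reads(rs, p$species$alpha$r45s_unit, circular = TRUE)
      labels[id] <- sp
    }
  }
  hy <- strain_spec("hyb", "alpha", is_hybrid = TRUE,
                    hybrid_parents = c("alpha", "beta"),
                    coverage_45s = 300, contaminant_fraction = 0, seed = 939)
  gh <- simulate_strain_genomes(p, hy)
  piles$hyb <- map_reads(simulate_reads(gh, molecules = "r45s"),
                         p$species$alpha$r45s_unit, circular = TRUE)
  labels["hyb"] <- "hybrid"
  m <- allele_freq_matrix(piles)
  pc <- snp_pca(m, 2)
  # discriminating axis = the component separating the parental centroids most
  sep <- vapply(1:2, function(j) {
    abs(mean(pc$coordinates[labels == "alpha", j]) -
          mean(pc$coordinates[labels == "beta", j]))
  }, numeric(1))
  ax <- which.max(sep)
  ca <- mean(pc$coordinates[labels == "alpha", ax])
  cb <- mean(pc$coordinates[labels == "beta", ax])
  h <- pc$coordinates["hyb", ax]
  expect_true(h > min(ca, cb) && h < max(ca, cb))
  # and roughly midway
  expect_lt(abs(h - (ca + cb) / 2), 0.3 * abs(ca - cb))
})
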