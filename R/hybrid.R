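#' Find informative sites between two species
#'
#' Informative sites are positions where the two species' consensus
#' sequences carry different alleles and, when pooled per-species pileups
#' are supplied, each species' reads support its own allele at or above
#' `fixation_threshold` (sites polymorphic within a species are excluded).
#'
#' @param consensus_a,consensus_b Equal-length species consensus strings on
#'   common coordinates.
#' @param pileup_a,pileup_b Optional pooled `pileup` objects for the two
#'   species (used for the fixation check).
#' @param fixation_threshold Minimum within-species support for the species'
#'   own allele (default 0.95).
#' @param min_depth Minimum pooled depth for the fixation check.
#' @return Data frame of class `informative_sites`: `position` (0-based),
#'   `allele_a`, `allele_b`, sorted by position. Empty with a warning when
#'   no site qualifies.
#' @export
find_informative_sites <- function(consensus_a, consensus_b,
                                   pileup_a = NULL, pileup_b = NULL,
                                   fixation_threshold = 0.95,
                                   min_depth = 10L) {
  stopifnot(nchar(consensus_a) == nchar(consensus_b))
  pos <- mismatch_positions(consensus_a, consensus_b)  # 1-based
  allele_a <- seq_chars(consensus_a)[pos]
  allele_b <- seq_chars(consensus_b)[pos]
  keep <- rep(TRUE, length(pos))
  check_fixed <- function(pileup, alleles) {
    cnt <- pileup$counts[, pos, drop = FALSE]
    depth <- colSums(cnt)
    own <- cnt[cbind(match(alleles, rownames(cnt)), seq_along(pos))]
    depth >= min_depth & own >= fixation_threshold * depth
  }
  if (!is.null(pileup_a)) keep <- keep & check_fixed(pileup_a, allele_a)
  if (!is.null(pileup_b)) keep <- keep & check_fixed(pileup_b, allele_b)
  out <- data.frame(position = pos[keep] - 1L,
                    allele_a = allele_a[keep], allele_b = allele_b[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no informative sites found")
  class(out) <- c("informative_sites", "data.frame")
  out
}

#' Allelic-frequency profile of a strain at informative sites
#'
#' Per site, the frequency of allele A among reads carrying either parental
#' allele; other bases are counted separately as noise. Sites below
#' `min_depth` are dropped.
#'
#' @param pileup The strain's 45S `pileup` (on the common 45S reference).
#' @param sites An `informative_sites` data frame.
#' @param min_depth Minimum parental-allele depth per site (default 10).
#' @param strain_id Strain identifier carried in the result.
#' @return Data frame of class `allele_profile`: `position`, `count_a`,
#'   `count_b`, `noise`, `depth`, `freq_a`; attributes `strain_id`,
#'   `mean_freq_a`.
#' @export
allele_profile <- function(pileup, sites, min_depth = 10L,
                           strain_id = "strain") {
  stopifnot(inherits(pileup, "pileup"), nrow(sites) >= 0L)
  idx <- sites$position + 1L
  cnt <- pileup$counts[, idx, drop = FALSE]
  ca <- cnt[cbind(match(sites$allele_a, rownames(cnt)), seq_along(idx))]
  cb <- cnt[cbind(match(sites$allele_b, rownames(cnt)), seq_along(idx))]
  tot <- colSums(cnt)
  out <- data.frame(position = sites$position,
                    count_a = ca, count_b = cb,
                    noise = tot - ca - cb,
                    depth = ca + cb,
                    freq_a = ifelse(ca + cb > 0, ca / (ca + cb), NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[out$depth >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strain_id") <- strain_id
  attr(out, "mean_freq_a") <- if (nrow(out)) mean(out$freq_a) else NA_real_
  class(out) <- c("allele_profile", "data.frame")
  out
}

#' Classify a strain's nuclear 45S state
#'
#' `heterozygous_AB` requires (i) at least `site_majority` of informative
#' sites inside `het_band` after widening it per site by three binomial
#' standard errors of the read sampling noise, `3 * sqrt(0.25 / depth)`
#' (all sites share one underlying copy ratio, so per-site excursions at
#' moderate depth are sampling noise, not evidence against heterozygosity),
#' and (ii) no site rejecting the band by exact binomial test against the
#' nearest band edge at Bonferroni-corrected `alpha` (a pooled ratio of 0.5
#' with tolerance for parental rDNA copy-number imbalance; a site fixed at
#' 0 or 1, as in a chimeric pattern, rejects decisively). Because reads
#' resample a finite rDNA copy pool, the test's effective sample size is
#' capped at the copy number (`max_test_n`): beyond it, extra depth adds no
#' information about the underlying copy ratio. `A` (`B`) requires
#' `site_majority` of frequencies above 0.9 (below 0.1); anything else is
#' `ambiguous`.
#'
#' @param profile An [allele_profile()].
#' @param het_band Frequency band treated as heterozygous (default
#'   `c(0.35, 0.65)`, tolerant of parental rDNA copy-number imbalance).
#' @param site_majority Fraction of sites that must agree (default 0.9).
#' @param alpha Family-wise error rate for the per-site binomial tests.
#' @param min_informative_sites Minimum usable sites (default 5).
#' @param max_test_n Effective-depth cap, the assumed rDNA copy number
#'   (default 100).
#' @return List of class `nuclear_call`: `call` (one of `"A"`, `"B"`,
#'   `"heterozygous_AB"`, `"ambiguous"`), `reason`, `n_sites`,
#'   `frac_in_band`, `min_p_value`.
#' @export
classify_nuclear <- function(profile, het_band = c(0.35, 0.65),
                             site_majority = 0.9, alpha = 0.01,
                             min_informative_sites = 5L, max_test_n = 100L) {
  n <- nrow(profile)
  result <- function(call, reason, frac = NA_real_, minp = NA_real_) {
    structure(list(call = call, reason = reason, n_sites = n,
                   frac_in_band = frac, min_p_value = minp),
              class = "nuclear_call")
  }
  if (n < min_informative_sites) {
    return(result("ambiguous", sprintf("only %d informative sites with depth (need %d)",
                                       n, min_informative_sites)))
  }
  f <- profile$freq_a
  if (mean(f > 0.9) >= site_majority) {
    return(result("A", "allele A fixed at most sites"))
  }
  if (mean(f < 0.1) >= site_majority) {
    return(result("B", "allele B fixed at most sites"))
  }
  noise <- 3 * sqrt(0.25 / profile$depth)
  frac_band <- mean(f >= het_band[1] - noise & f <= het_band[2] + noise)
  pvals <- vapply(seq_len(n), function(i) {
    x <- profile$count_a[i]
    d <- profile$depth[i]
    if (d > max_test_n) {
      x <- round(x / d * max_test_n)
      d <- max_test_n
    }
    fr <- x / d
    if (fr < het_band[1]) {
      binom.test(x, d, het_band[1], alternative = "less")$p.value
    } else if (fr > het_band[2]) {
      binom.test(x, d, het_band[2], alternative = "greater")$p.value
    } else {
      1
    }
  }, numeric(1))
  if (frac_band >= site_majority && min(pvals) >= alpha / n) {
    return(result("heterozygous_AB", "pooled allele ratio ~0.5 at informative sites",
                  frac_band, min(pvals)))
  }
  result("ambiguous", "frequency pattern fits neither pure nor F1 expectation",
         frac_band, min(pvals))
}

#' Check organellar homoplasmy between two candidate species
#'
#' At diagnostic sites (where the two species' organellar consensuses
#' differ), the strain is called for the species whose alleles dominate
#' overall (near-even signal is `ambiguous`); it is homoplasmic when its
#' overall dominance reaches `1 - max_minor` and no site shows a genuine
#' allele mixture. A site fully fixed for the other species' allele is a
#' private substitution, not a second haplotype, and does not break
#' homoplasmy; a site with both parental alleles at intermediate fraction
#' does.
#'
#' @param pileup The strain's organelle `pileup` (common coordinates with
#'   the consensuses).
#' @param consensus_a,consensus_b Species organellar consensus strings.
#' @param labels Species names for sides a and b.
#' @param max_minor Maximum tolerated minor-allele fraction (default 0.05).
#' @param min_depth Minimum per-site depth to assess a site.
#' @param min_minor_count A site only counts as heteroplasmic when the
#'   minor allele also reaches this read count (default 5): with thousands
#'   of diagnostic sites, one or two sequencing errors hitting the partner
#'   allele at a single site must not overturn homoplasmy.
#' @return List: `call` (species label or `"ambiguous"`), `homoplasmic`
#'   flag, `n_sites`, `frac_a` (overall fraction of a-side alleles).
#' @export
check_homoplasmy <- function(pileup, consensus_a, consensus_b,
                             labels = c("A", "B"), max_minor = 0.05,
                             min_depth = 10L, min_minor_count = 5L) {
  sites <- find_informative_sites(consensus_a, consensus_b)
  if (nrow(sites) == 0L) {
    return(list(call = "ambiguous", homoplasmic = FALSE, n_sites = 0L,
                frac_a = NA_real_))
  }
  idx <- sites$position + 1L
  cnt <- pileup$counts[, idx, drop = FALSE]
  ca <- cnt[cbind(match(sites$allele_a, rownames(cnt)), seq_along(idx))]
  cb <- cnt[cbind(match(sites$allele_b, rownames(cnt)), seq_along(idx))]
  ok <- ca + cb >= min_depth
  if (!any(ok)) {
    return(list(call = "ambiguous", homoplasmic = FALSE, n_sites = 0L,
                frac_a = NA_real_))
  }
  ca <- ca[ok]
  cb <- cb[ok]
  frac_a <- sum(ca) / sum(ca + cb)
  per_site_a <- ca / (ca + cb)
  # genuinely mixed site: both parental alleles present at real fraction
  mixed <- per_site_a > max_minor & per_site_a < 1 - max_minor &
    pmin(ca, cb) >= min_minor_count
  if (frac_a > 0.6) {
    call <- labels[1]
    hom <- frac_a >= 1 - max_minor && !any(mixed)
  } else if (frac_a < 0.4) {
    call <- labels[2]
    hom <- frac_a <= max_minor && !any(mixed)
  } else {
    return(list(call = "ambiguous", homoplasmic = FALSE,
                n_sites = sum(ok), frac_a = frac_a))
  }
  list(call = call, homoplasmic = hom, n_sites = sum(ok), frac_a = frac_a)
}

#' Detect F1 hybrids across a strain panel
#'
#' For each strain, the organellar species call `O` is taken as side A; the
#' partner species `B` is the other species whose 45S alleles are best
#' represented in the strain's reads. The strain's nuclear state is
#' classified from its 45S allelic-frequency profile and combined with
#' chloroplast and mitochondrial homoplasmy checks: an `F1_hybrid` is
#' heterozygous at the informative nuclear sites with both organelles
#' homoplasmic for a single parent; `pure` strains agree across all three
#' genomes; a pure nuclear call that contradicts the organelles is
#' `discordant_non_F1`.
#'
#' @param strain_data Named list (per strain) of lists with elements
#'   `organelle_species`, `r45s_pileup`, `cp_pileup`, `mt_pileup`.
#' @param species_data Named list (per species) of lists with elements
#'   `r45s_consensus`, `cp_consensus`, `mt_consensus`, and optionally
#'   `r45s_pileup` (pooled, for the fixation check).
#' @param fixation_threshold,het_band,site_majority,alpha,min_informative_sites,max_test_n,max_minor,min_depth
#'   Passed to the component checks.
#' @return List of class `hybrid_report`: `report` (per-strain data frame
#'   with `nuclear_call`, `nuclear_partner`, `cp_call`, `mt_call`,
#'   homoplasmy flags and `verdict`), `summary` (verdict counts).
#' @export
call_hybrids <- function(strain_data, species_data,
                         fixation_threshold = 0.95,
                         het_band = c(0.35, 0.65), site_majority = 0.9,
                         alpha = 0.01, min_informative_sites = 5L,
                         max_test_n = 100L, max_minor = 0.05,
                         min_depth = 10L) {
  species <- names(species_data)
  rows <- lapply(names(strain_data), function(sid) {
    sd <- strain_data[[sid]]
    O <- sd$organelle_species
    stopifnot(O %in% species)
    others <- setdiff(species, O)
    # partner = species whose private 45S alleles show the strongest support
    partner_score <- vapply(others, function(X) {
      sites <- suppressWarnings(find_informative_sites(
        species_data[[O]]$r45s_consensus, species_data[[X]]$r45s_consensus,
        species_data[[O]]$r45s_pileup, species_data[[X]]$r45s_pileup,
        fixation_threshold, min_depth))
      if (nrow(sites) == 0L) return(NA_real_)
      prof <- allele_profile(sd$r45s_pileup, sites, min_depth, sid)
      if (nrow(prof) == 0L) return(NA_real_)
      mean(1 - prof$freq_a)
    }, numeric(1))
    if (all(is.na(partner_score))) {
      return(data.frame(strain = sid, organelle_species = O,
                        nuclear_call = "ambiguous", nuclear_partner = NA_character_,
                        cp_call = NA_character_, mt_call = NA_character_,
                        cp_homoplasmic = NA, mt_homoplasmic = NA,
                        verdict = "ambiguous", stringsAsFactors = FALSE))
    }
    B <- others[which.max(partner_score)]
    sites <- suppressWarnings(find_informative_sites(
      species_data[[O]]$r45s_consensus, species_data[[B]]$r45s_consensus,
      species_data[[O]]$r45s_pileup, species_data[[B]]$r45s_pileup,
      fixation_threshold, min_depth))
    prof <- allele_profile(sd$r45s_pileup, sites, min_depth, sid)
    nuc <- classify_nuclear(prof, het_band, site_majority, alpha,
                            min_informative_sites, max_test_n)
    nuclear_call <- switch(nuc$call, A = O, B = B,
                           heterozygous_AB = "heterozygous_AB",
                           "ambiguous")
    cp_h <- check_homoplasmy(sd$cp_pileup, species_data[[O]]$cp_consensus,
                             species_data[[B]]$cp_consensus, c(O, B),
                             max_minor, min_depth)
    mt_h <- check_homoplasmy(sd$mt_pileup, species_data[[O]]$mt_consensus,
                             species_data[[B]]$mt_consensus, c(O, B),
                             max_minor, min_depth)
    organelles_one_parent <- cp_h$homoplasmic && mt_h$homoplasmic &&
      cp_h$call == mt_h$call && cp_h$call %in% c(O, B)
    verdict <- if (nuclear_call == "heterozygous_AB" && organelles_one_parent) {
      "F1_hybrid"
    } else if (nuclear_call %in% c(O, B) && organelles_one_parent &&
               nuclear_call == cp_h$call) {
      "pure"
    } else if (nuclear_call %in% c(O, B)) {
      "discordant_non_F1"
    } else {
      "ambiguous"
    }
    data.frame(strain = sid, organelle_species = O,
               nuclear_call = nuclear_call, nuclear_partner = B,
               cp_call = cp_h$call, mt_call = mt_h$call,
               cp_homoplasmic = cp_h$homoplasmic,
               mt_homoplasmic = mt_h$homoplasmic,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  tab <- table(factor(report$verdict,
                      levels = c("pure", "F1_hybrid", "discordant_non_F1", "ambiguous")))
  structure(list(report = report, summary = as.list(tab)),
            class = "hybrid_report")
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat(sprintf("<hybrid_report> %d strains: %d pure, %d F1 hybrid, %d discordant, %d ambiguous\n",
              nrow(x$report), x$summary$pure, x$summary$F1_hybrid,
              x$summary$discordant_non_F1, x$summary$ambiguous))
  invisible(x)
}

#' Allele-frequency matrix for PCA across strains
#'
#' Builds a strains x positions matrix of non-reference allele fractions on
#' a shared reference (typically the 45S unit), restricted to positions
#' where at least one strain shows an alternate fraction at or above
#' `min_alt_fraction`. Feeding this into [snp_pca()] reproduces the
#' allelic-frequency ordination in which an F1 hybrid sits midway between
#' its parental clusters.
#'
#' @param pileups Named list of per-strain `pileup` objects on one reference.
#' @param min_alt_fraction Column inclusion threshold (default 0.2).
#' @param min_depth Depth below which a cell is `NA`.
#' @return Numeric matrix (strains x positions) of alt-allele fractions.
#' @export
allele_freq_matrix <- function(pileups, min_alt_fraction = 0.2,
                               min_depth = 10L) {
  stopifnot(length(pileups) >= 2L, !is.null(names(pileups)))
  ref <- pileups[[1]]$reference
  bases <- c("A", "C", "G", "T")
  ref_idx <- match(seq_chars(ref), bases)
  L <- nchar(ref)
  fr <- vapply(pileups, function(p) {
    stopifnot(identical(p$reference, ref))
    counts <- p$counts
    depth <- colSums(counts)
    masked <- counts
    masked[cbind(ref_idx, seq_len(L))] <- -1L
    alt <- masked[cbind(max.col(t(masked), ties.method = "first"), seq_len(L))]
    out <- ifelse(depth >= min_depth, alt / pmax(depth, 1L), NA_real_)
    out
  }, numeric(L))
  m <- t(fr)
  keep <- apply(m, 2, function(col) any(!is.na(col) & col >= min_alt_fraction))
  m <- m[, keep, drop = FALSE]
  colnames(m) <- as.character(which(keep) - 1L)
  class(m) <- c("snp_matrix", class(m))
  m
}
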