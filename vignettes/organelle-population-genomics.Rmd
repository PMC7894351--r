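---
title: "Organellar population genomics of foliose Ulva: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organellar population genomics of foliose Ulva: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulvapop)
```

## The scientific problem

Foliose *Ulva* (sea lettuce) species are morphologically similar but
genetically distinct. Short-read sequencing of many strains gives access to
three high-copy compartments — the circular chloroplast (~95–118 kb) and
mitochondrial (~59–88 kb) genomes and the nuclear 45S rDNA tandem repeat
(~5 kb unit, ≥100 copies) — that together answer three questions:

1. How many species are present, and which strain belongs to which
   (SNP-matrix PCA and clustering, barcode assignment)?
2. How much divergence separates and how much variation lies within species
   (inter-/intra-specific SNP densities over coding sequence; structural
   differences such as a large chloroplast inversion)?
3. Do species hybridize in the wild? An inter-specific F1 carries both
   parents' alleles at every fixed nuclear difference — visible as ~50:50
   pooled allele ratios on the multi-copy 45S — while its organelles, being
   uniparentally inherited, come from a single parent (homoplasmy).

`ulvapop` implements this whole chain of analysis, together with a
synthetic sequencing-design generator so that every stage can be exercised
and verified end to end without any external data.

## The simulator: what it emulates, and what it does not

`species_panel_spec()` / `simulate_panel()` realize a panel of species on a
**common coordinate system** with a **substitution-only** mutation model:

* **Star divergence model.** Each species carries a private branch of
  substitutions relative to a shared ancestor. Branch mutation sites are
  drawn **disjointly** across species, so pairwise divergence is exactly
  additive (branch of one plus branch of the other) and the truth table
  enumerates every variant site with no homoplasy. A consequence is that a
  full pairwise divergence matrix must be star-additive; the constructor
  validates this and builds the default matrix from the per-species
  divergences against the reference species.
* **Reference species with its own branch.** Divergences are specified
  against the reference species, and by default the reference keeps a
  private branch of 2 SNPs/kb (carved out of each vs-reference value, which
  is therefore preserved). Without it the reference would sit exactly at
  the star's center and could never be monophyletic in any tree — whereas
  all six species form clades in every marker tree in the data this design
  emulates.
* **Divergence defaults** follow the observed coding-sequence densities:
  chloroplast up to ~91 SNPs/kb and mitochondrion up to ~222 SNPs/kb
  against the reference species; intra-specific variation defaults to
  0.2 SNPs/kb for every species, a representative value within the
  observed 0.03–2 SNPs/kb range (per-species values are configurable).
* **The inversion.** Three of the six species carry a reverse-complemented
  chloroplast segment (~30% of the genome, breakpoints placed
  mid-intergenic so genes are transplanted whole, with flipped strand and
  reflected coordinates). Extracting CDS per gene in a shared gene order
  therefore returns every gene in ancestral orientation, which is what
  makes cross-clade CDS comparison meaningful.
* **45S fixed differences** are planted as exact per-species counts (65
  between the reference and the most diverged species at full scale), not
  binomial draws: informative-site counts are small and the analyses
  require a guaranteed minimum.
* **Reads.** Paired 150 bp reads with a Gaussian fragment model are drawn
  uniformly over circular coordinates (fragments wrap the origin);
  `round(coverage x length / (2 x read_length))` pairs per molecule;
  uniform per-base substitution errors; optional contaminant pairs from a
  random non-homologous sequence emulate the bacterial read background.
  45S pairs are drawn from the **tandem copy array** (concatenated copies,
  sampled circularly), so unit edges get full coverage, copy-boundary
  chimeras occur, and — in a hybrid — each copy is independently inherited
  from either parent (ratio 0.5 by default, Binomial at the copy number).

Not emulated: indels (the mapper is ungapped and coordinates stay shared),
base-quality structure (qualities are fixed), genome-size differences
between species (substitution-only implies equal lengths; the defaults use
one printed size per organelle), long reads, and realistic contaminant
genomes. Passing tests therefore demonstrate correctness of the analysis
logic under the stated statistical structure, not robustness to indel
alignment error or quality-dependent artifacts in real libraries.

## Assembly by iterative read baiting

`iterative_assemble()` repeats: bait reads by canonical k-mer sharing
(`k_filter = 21`, a pair is kept when either mate shares ≥ 2 k-mer windows
with the bait), assemble the retained reads into unitigs of the de Bruijn
graph of solid canonical 31-mers (`min_kmer_count = 3`), test circularity,
and re-bait with the contigs. Seeding with a diverged reference that lacks
a region entirely still converges: each round, pairs whose mates map near
the covered boundary pull the missing region in by roughly one insert
length per side, until the graph closes into a single cycle.

Numerical/representation choices:

* A cycle is emitted with its first `(k-1)`-mer duplicated at the end;
  `detect_circularity()` recognizes that terminal overlap, trims it, and
  normalizes to the lexicographically minimal rotation of the smaller
  strand (Booth's algorithm), making assembled-vs-truth comparison a string
  equality.
* Error handling is solid-k-mer thresholding only (no bubble popping):
  error rates are low in the emulated design and the contract is exactness
  on clean reads.
* Paired-end information is used for joint retention only, not
  scaffolding; unitigs stand in for scaffolds, which suffices because the
  simulated organelles are repeat-sparse at `k = 31`.

## Mapping, variant calls, consensus, SNP statistics

`map_reads()` is an ungapped seed-and-extend mapper: exact 15-mer seeds
propose candidate placements on either strand (with circular wrap); the
fewest-mismatch candidate wins (ties: forward strand, then lowest
coordinate — so placements equal a brute-force minimum-mismatch search
whenever the true placement retains one exact seed); reads above 20%
mismatches stay unmapped. Each placed read is **soft-clipped** to its
maximal-scoring subsegment (match +1, mismatch −3) before entering the
pileup: reads spanning an inversion breakpoint otherwise deposit
~75%-mismatch overhangs that masquerade as heterozygous sites near the
breakpoints. This mirrors local-alignment mapping as used in practice.

`call_variants()` uses explicit thresholds (`min_depth = 10`,
`hom_threshold = 0.9`, `het_band = [0.2, 0.8]`); at the default coverages a
1% error rate cannot reach the heterozygous band. `build_consensus()`
substitutes homozygous alternates, resolves heterozygous sites to the
majority base (ties keep the reference), and logs no-call positions.

`snp_density()` reproduces the reporting convention of the divergence
tables: `1000 x n / L`, half-up rounded to one decimal, integers at ≥ 100.
`interspecific_stats()` averages per-strain mismatch counts against the
reference species' majority consensus; `intraspecific_stats()` compares
strains to their species' majority consensus (ties resolve to the first
strain's base) and counts total variant sites. Intra-specific densities
are normalized by the full sequence supplied (the whole genome by
default); supplying a `cds_set()` switches the denominator.

## Clustering and species assignment

`build_snp_matrix()` codes the union of variant positions against one
common reference as 0 / 1 / 0.5 (heterozygous) / `NA` (no call). The 0.5
coding is what lets a hybrid fall midway between its parents' clusters in
the allele-frequency ordination. `snp_pca()` centers each column on its
mean genotype `p` and scales by `sqrt(p(1-p))` (allele-frequency scaling;
missing values imputed to `p`), with the sign of each component fixed so
its largest-magnitude coordinate is positive.

`delimit_clusters()` runs single linkage on the Manhattan (SNP-count)
distance — missing genotypes excluded pairwise — and cuts at the **first**
ratio between consecutive merge heights that exceeds `linkage_gap_factor`
(default 5). The first qualifying gap is the boundary where within-group
merges end, i.e. the species level; the globally largest gap can instead
sit at a deeper split (e.g. between the two closest species jointly and
the rest) and would lump related species. With no qualifying gap the
strains form one cluster, with a warning. `assign_species()` labels
clusters by per-position barcode identity against a labeled reference
panel, reporting ties.

## Trees and their agreement

`pairwise_distances()` offers p-distances and JC69. For data generated by
this package's simulator, **p-distances are the right choice**: the
mutation model is substitution-only and homoplasy-free, so p-distances are
exactly additive, while the convex JC correction distorts short central
edges enough that neighbor joining (ours and the reference implementation
alike) can break the reference species' short shared branch. JC69 is
provided for real data, where multiple hits do occur; it is undefined
(`NA` with a warning) at p ≥ 0.75.

`nj_tree()` is standard neighbor joining with deterministic tie-breaking
(lexicographically smallest pair of cluster representatives) and negative
branch lengths clamped to zero with the deficit moved to the sister
branch. `bootstrap_support()` resamples alignment columns, rebuilds the
tree per replicate, and annotates each internal edge with the fraction of
replicates containing its bipartition. `tree_agreement()` computes the
Robinson–Foulds distance over non-trivial bipartitions (normalized by
`2(n-3)`) and, given species labels, reports per species whether its
strain set is a clade in each tree — the operational form of "all marker
trees show the same species clusters".

## Synteny and the inversion

`find_anchors()` matches k-mers unique in both genomes (canonical
counting, k = 31: chance collisions are negligible at the 100 kb scale);
`chain_anchors()` greedily chains same-orientation anchors on a consistent
diagonal and drops runs below `min_anchors`. `detect_inversions()` reports
reverse blocks; when the sequences are supplied, each breakpoint is
refined as the changepoint between the flanking collinear diagonal and the
inverted anti-diagonal that minimizes total base mismatches across the
junction. Refinement matters: at ~80 SNPs/kb divergence, clean shared
31-mers thin out near breakpoints and the anchor bounding box alone can be
off by hundreds of bases; the changepoint estimate is exact to a few bases
because the mismatch rate jumps from the SNP density (~8%) to ~75% at the
junction.

## Hybrid detection

`find_informative_sites()` keeps positions where two species' consensuses
differ and (when pooled per-species pileups are supplied) each species'
reads support its own allele at ≥ 95% — a site polymorphic within a
species is not diagnostic. `allele_profile()` reports, per informative
site, the frequency of the first species' allele among reads carrying
either parental allele, with other bases counted as noise.

`classify_nuclear()` treats the 45S as a pooled allele population (copy
number ≫ 2). The heterozygous call requires (i) at least 90% of sites
inside the heterozygous band `[0.35, 0.65]` after widening it per site by
three binomial standard errors of the read-sampling noise
(`3·sqrt(0.25/depth)`) — all informative sites share one underlying copy
ratio, so per-site excursions at moderate depth are sampling noise, not
evidence — and (ii) no site rejecting the band by an exact binomial test
against the nearest band edge at Bonferroni-corrected α = 0.01. Two
deliberate choices here:

* The band, not the point 0.5, is the null: the hybrid's true pooled ratio
  is itself a Binomial draw at the copy number (sd 0.05 at 100 copies), so
  a point-0.5 test at high depth rejects genuine F1s whose arrays split,
  say, 55:45. The band encodes exactly the tolerated copy-number
  imbalance; a chimeric site fixed at 0 or 1 still rejects decisively.
* The test's effective sample size is capped at the rDNA copy number
  (default 100): reads resample a finite pool of copies, so sequencing
  deeper than the copy number adds no information about the copy ratio.

`check_homoplasmy()` calls the organelle for the species whose alleles
dominate at the diagnostic sites and flags heteroplasmy only for genuine
mixtures — both parental alleles at intermediate fraction with at least 5
minor-allele reads. A site *fixed* for the partner allele is a private
substitution, not a second haplotype: with thousands of diagnostic sites,
each strain's handful of private SNPs will occasionally land on one and
match the partner allele by chance, and isolated sequencing errors must
not overturn homoplasmy either.

`call_hybrids()` combines the calls: F1 requires nuclear heterozygosity
with both organelles homoplasmic for a single parent; concordant strains
are pure; a pure nuclear call contradicting the organelles is flagged
`discordant_non_F1` (introgression or a later-generation hybrid — which
this system, with a single nuclear marker, cannot resolve further; ploidy
is likewise not asserted). In the pipeline, strains with outlying 45S
heterozygosity are excluded from their species' pooled read support before
informative sites are fixed — one hybrid among few strains would otherwise
erode its own species' fixed alleles below the fixation threshold.

## The pipeline and scales

`run_pipeline(pipeline_config(...))` chains the stages in the study's
order: simulate → cluster on the common chloroplast reference (PCA +
single linkage; barcode assignment) → validate per-species iterative
assembly → per-species mapping, consensus and divergence tables → marker
trees (rbcL-like, tufA-like, concatenated CDS, 45S) with bootstrap and
agreement → synteny/inversion detection → hybrid screen. A single global
seed fans out to per-stage substreams, and outputs contain no timestamps,
so a rerun with the same configuration is byte-identical.

Two scale presets define the problem sizes used throughout the package's
tests: `"unit"` (12 kb chloroplast, 8 kb mitochondrion, 2 kb 45S unit,
20 strains, 40x organelle and 1000x 45S coverage) for fast end-to-end
runs, and `"full"` (the printed organelle sizes with 69 + 29 annotated
genes totalling 63,775 and 24,854 bp of CDS) for the divergence-recovery
statistics, which need no read simulation. Bootstrap replicates default to
100 at unit scale; 1,000 replicates are the documented choice for real
analyses.

## Known limitations

* The substitution-only model cannot represent length variation between
  species; real inter-specific comparison needs an external gapped aligner
  (SAM import is provided for that route).
* Divergence matrices must be star-additive; arbitrary tree-structured
  inter-specific histories are out of scope of the generator (though the
  analysis functions do not assume them).
* NJ trees on near-star data place very short internal edges at the mercy
  of distance noise; bootstrap support is the guard, and species-level
  claims should be read from the cluster-mapping table rather than fine
  topology.
* F2/backcross hybrids and rDNA copy phasing are out of scope; one nuclear
  marker cannot distinguish them from an F1 in every configuration.
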