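---
title: "Tracking donor phage engraftment after FMT: models and methods"
author: "phagetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking donor phage engraftment after FMT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Fecal microbiota transplantation (FMT) transfers an entire gut community —
bacteria and their phages — from healthy donors into recipients. Whether a
*donor phage engrafts* (establishes itself in a recipient and persists) is a
clone-tracking problem: the same phage strain must be recognized in donor and
recipient assemblies, and distinguished from related strains the recipient
already carried. phagetrack implements the full desk-side analysis for a
sex-stratified, placebo-controlled FMT trial design: screening assembled
contigs into uncultivated virus genomes (UViGs), clustering them into viral
operational taxonomic units (vOTUs), detecting clone pairs, calling
engraftment events, and quantifying the longitudinal consequences for the
recipients' phageome (diversity, variability, stability, lifestyle
composition).

Because raw trial sequencing data cannot be shipped inside a package, a
synthetic cohort generator with full ground truth is a first-class component:
every stage of the pipeline is validated against simulations whose correct
answer is known by construction.

# Screening contigs into UViGs

Each assembled contig arrives with annotation counts from upstream viral
prediction tools (viral genes, host genes, hallmark genes, a screening score
in [0, 1], completeness in [0, 100]). The decision rules are:

* **Inclusion** — a contig is a putative viral contig when it has at least
  one viral gene, or no host genes, or a screening score of at least 0.95,
  or at least three hallmark genes.
* **False-positive removal** — an included contig is discarded when it has
  more than 4 host genes, or a host-to-viral gene ratio (HVR) above 0.386.
  Both comparisons are strict: a contig with exactly 4 host genes or an HVR
  of exactly 0.386 is kept. When a contig has no viral genes, HVR is defined
  as `+Inf` if host genes exist (flagged) and 0 otherwise; inclusion
  normally requires a viral clause first, so this convention only matters
  for robustness.
* **High quality** — downstream analyses keep only vOTUs whose
  representative has completeness of at least 90% (boundary inclusive). The
  filter is also available at the UViG level as a pre-filter flag; the
  default applies it at the representative level.

These three rules partition every input contig into exactly one of
excluded / false positive / retained, and each stage logs its counts so the
whole screening funnel is auditable.

# ANI, alignment fraction, and the two thresholds

Pairwise similarity uses a fragment-mapping estimator of average nucleotide
identity (ANI). The shorter sequence of a pair is tiled into non-overlapping
1000 bp fragments (trailing partial fragments dropped); each fragment is
placed on the longer sequence by exact 16-mer seeding followed by gapless
extension, and counts as *mapped* when its best placement reaches 80%
identity. ANI is the mean identity of mapped fragments; the alignment
fraction (AF) is the fraction of the shorter sequence's fragments that
mapped, so identical sequences always give AF = 1 and an exact subsequence
maps completely relative to itself. A pair with no mapped fragment reports
ANI = 0 and AF = 0 (not missing), so thresholds evaluate false.

Two nested thresholds drive everything downstream:

* **vOTU membership**: ANI ≥ 95% over AF ≥ 0.85 (the species-rank standard
  for uncultivated virus genomes);
* **clones**: ANI ≥ 99.4% over AF ≥ 0.85, evaluated only within a vOTU.
  Clone pairs are treated as symmetric evidence and are not forced to be
  transitive.

Gapless placement assumes collinear, substitution-dominated divergence. That
assumption is exact for the simulator (substitution-only mutation, so
alignment-free Hamming identity is an oracle the estimator is tested
against) and reasonable for same-lineage contigs, but it will underestimate
similarity for rearranged or indel-rich pairs; for such data an externally
computed similarity table (e.g. FastANI output, via `readFastANITable()`)
can be supplied to the clustering functions unchanged.

Clustering is greedy centroid clustering: records are visited in
length-descending order (ties broken lexicographically by id), and each
record joins the first existing centroid meeting the thresholds, else founds
a new cluster. The published workflow does not state whether membership used
first-hit or best-hit assignment; first-hit is the default here and best-hit
is available (`assign = "best"`). Candidate centroids are prescreened with a
value-sampled k-mer sketch purely as an accelerator — membership is always
decided by the full ANI/AF computation.

# Abundance: gene catalog, CPM, medians, sums

Gene coordinates (0-based half-open throughout the package) are clustered
into a non-redundant catalog with the same greedy kernel at 95%/85%, with
the fragment length capped at min(gene length, 300) bp. Counts are summed
over each cluster's member genes (as if all reads mapped to the centroid),
length-normalized to RPK (reads per kilobase of centroid), and rescaled per
sample to copies per million (CPM), so every sample with nonzero counts sums
to exactly one million.

A UViG's abundance in a sample is the **median CPM over all its catalog
genes, zeros included** — excluding zero-count genes would make
presence/absence circular. The zero-excluding variant is available
(`includeZeros = FALSE`). When catalog clustering merges genes from several
UViGs, each cluster's CPM is attributed to every UViG contributing a member
gene (the alternative, centroid-owner-only, is available via
`attribution = "centroid"`). vOTU abundance is the sum over member UViGs,
and a vOTU counts as *identified* in a sample when its value is strictly
positive (no published detection threshold exists, so the minimal one is
used).

# Engraftment events, donors, partitions

A donor phage is **engrafted** when a clonal UViG of a sex-matched donor
UViG appears in a recipient at week 6 or later, with no donor-clone of that
vOTU present in the recipient's baseline sample. Events are keyed by
(vOTU, recipient): one engrafted strain observed at several timepoints is a
single event whose first detection is the earliest qualifying timepoint.
Placebo recipients are processed identically; any placebo "event" is a
pipeline false positive, which makes the placebo arm a built-in specificity
control.

Every donor carrying the event's vOTU is credited (events carried by more
than one donor are tagged as multi-donor and count toward each carrying
donor's engrafted total, since the true origin cannot be resolved). A
donor's **engraftment efficacy** is the fraction of its identified vOTUs
that engrafted in at least one recipient; homogeneity across donors is
tested with Pearson's chi-squared on the engrafted/not-engrafted by donor
table, with standardized-residual post hoc analysis under BH-FDR.

Each recipient sample's identified vOTUs are partitioned into
*shared with donors* (clone-level donor evidence by default, vOTU-level by
flag), else *conserved from baseline*, else *novel*. A vOTU that is both
donor-shared and present at baseline is labeled shared (but is still not an
engraftment event — baseline presence disqualifies). Baseline samples have
no novel class.

# Longitudinal statistics

* **Alpha diversity**: Shannon index in natural-log units (vegan's
  convention; the base is configurable). All-zero profiles are undefined
  and reported missing.
* **Beta diversity / variability**: Bray-Curtis dissimilarities. Phageome
  variability is the dissimilarity between each subject's week-6 profile
  and weeks 12/26, compared between arms by sex and timepoint with Wilcoxon
  rank-sum tests (exact for small untied samples, normal approximation with
  continuity correction otherwise) under BH-FDR.
* **Stability**: each recipient vOTU is classified by how many of the four
  timepoints it is detected at; the per-sex 2×4 treatment-by-category
  tables are tested with Pearson's chi-squared plus residual post hoc.
* **Treatment contrasts over time**: linear mixed-effects models
  `value ~ treatment * timepoint + (1 | subject)` fit by REML, with
  FMT-minus-placebo contrasts at each timepoint (emmeans, Satterthwaite
  degrees of freedom). Singular fits fall back to the fixed-effects model
  with a logged warning. The default response for diversity and lifestyle
  analyses is each subject's *change from baseline* (the raw-value
  alternative is available); for donor-convergence the raw dissimilarities
  are modelled per donor. FDR families follow the analyses: within sex for
  diversity and lifestyle contrasts, collectively across donors and
  timepoints for convergence.
* Every p-value adjustment is Benjamini-Hochberg, through one function
  (`fdrAdjust`).

# The synthetic cohort generator

The generator emulates the trial design: 4 donors per sex sampled at
donation; sex-matched FMT and placebo recipients (10 per sex per arm by
default) sampled at baseline and weeks 6, 12, 26. Its moving parts:

* **Donor pools** of 12–30 phage lineages per donor, with a couple of
  lineages seeded into two same-sex donors to exercise the multi-donor
  attribution path. Lineage base abundances are log-normal (sdlog 1), with
  log-normal per-timepoint jitter (sdlog 0.4); donor Shannon diversity is
  computed from the realized profile.
* **Transfers**: each FMT recipient receives, per sex-matched donor phage,
  a clone with probability `plogis(intercept + slope * donor Shannon)`.
  Only the positive association is known from the trial, so any bounded
  monotone link suffices; the logistic is used. The intercept (−5.5 by
  default) keeps per-recipient transfer probabilities low enough that donor
  efficacy — a union over ~10 recipients — stays well off its ceiling,
  which both matches the observed wide spread of donor efficacies and
  preserves a recoverable diversity-efficacy correlation. Transferred
  clones diverge from the donor reference by 0.001 substitutions/site
  (≈99.9% identity, safely above the 99.4% clone cut) and appear from week
  6 onward in all later samples (stable engraftment). Placebo recipients
  never receive transfers.
* **Baseline communities**: 12 lineages per recipient, of which 4 are
  *distractors* — relatives of sex-matched donor phages at 0.03
  substitutions/site, i.e. inside the donor phage's vOTU but outside the
  clone threshold. These are the adversarial cases for engraftment calling:
  vOTU-level matching would mistake them for donor strains; clone-level
  matching must not. Baseline lineages persist at each later timepoint with
  probability 0.8.
* **Novel lineages**: Poisson-injected per post-baseline timepoint (rate 4
  in FMT, 2 in placebo recipients), each present at a single timepoint —
  reproducing the observed excess of transient, single-timepoint vOTUs in
  FMT recipients.
* **Lifestyles**: 15% of lineages temperate. The temperate post-FMT fold
  (default 3) multiplies the *normalized* truth abundance of temperate
  lineages in FMT recipients after baseline, without renormalizing: the
  fold models a true biological increase in temperate load that leaves
  other lineages untouched. Renormalization — the compositional squeeze —
  belongs to the measurement layer: simulated read counts scale each
  sample to its expected depth, and the pipeline's CPM renormalizes again,
  so measured (CPM-scale) virulent totals do dip slightly when temperate
  load rises, exactly as a real sequencing experiment would show. The
  design-level recovery checks therefore test the statistical layer
  against biological truth, while the sequence-level pipeline exhibits the
  realistic compositional coupling. The temperate fraction is kept small
  partly for this reason: with a minority temperate community the
  compositional spillover onto virulent totals stays within noise.
* **Genomes**: uniform-random nucleotide sequences of 5–12 kb tiled with
  non-overlapping genes of 300–1500 bp covering ≥70% of the genome;
  annotations are drawn so every simulated genome passes the contig screen
  (the screen's rejection behavior is tested on constructed tables, not on
  the generator). Mutation is substitution-only — no indels or
  recombination — so Hamming identity is an exact oracle for the ANI
  estimator on simulated pairs. Gene counts are negative-binomial
  (dispersion 0.5) with expectation proportional to lineage abundance ×
  gene length, scaled to 1e5 reads per sample.

Fixed seeds give byte-identical outputs. The generator emits ground truth
(transfers, clone pairs with realized substitution counts, lineage and
lifestyle maps) for parameter-recovery tests.

**What the simulations do not emulate**: real read-level error and mapping
ambiguity (counts are drawn, not aligned), indels and rearrangements between
strains, strain-level gene gain/loss, multiple donation rounds, prophage
boundary effects, and database-dependent annotation quality. Passing the
recovery suite therefore demonstrates the pipeline's logic and statistics
are sound under the stated generative model, not that upstream assembly and
annotation of real stool metagenomes are error-free.

# Numerical choices and problem sizes

* All published thresholds are implemented with their printed comparators
  exactly; boundary cases are asserted in the tests.
* Unmapped pairs report ANI 0/AF 0 rather than missing, so threshold
  comparisons never propagate NA.
* Ties in clustering order are broken lexicographically by id, making runs
  deterministic for fixed input.
* The AF denominator counts full-length fragments only (trailing partial
  fragments are excluded from numerator and denominator alike); including
  the trailing remainder in the denominator would make *identical*
  sequences of unlucky lengths fail the 0.85 cut, which is indefensible.
* Validation problem sizes were chosen to run comfortably on a single CPU:
  the full sequence-level cohort (8 donors, 40 recipients, 4 timepoints,
  ~2400 UViGs, ~22k genes) runs once end-to-end for engraftment recovery;
  statistical calibration (type-I error, correlation recovery, temperate
  recovery) uses the generator's design level (truth abundances and
  transfer tables, no sequence assembly) over 20–200 replicates, which
  exercises exactly the same statistical functions on the same data
  shapes.
* Shannon uses natural logarithms; donor profiles for the transfer model
  use the realized simulated profile, not the nominal richness.

# Known limitations

* The fragment estimator's gapless extension is tuned to clone/vOTU
  discrimination among same-lineage assemblies; divergent-but-related
  genomes with indels need the external-similarity path.
* CPM is compositional within the viral catalog: a genuine increase in one
  group's load necessarily depresses every other group's CPM. Lifestyle
  contrasts on CPM-scale data should be read with this in mind.
* Attribution of multi-donor vOTUs to every carrying donor slightly
  inflates per-donor engrafted counts relative to an (unidentifiable)
  single-origin truth; the alternative of excluding shared vOTUs is not
  implemented because the trial's analysis kept them.
* With one donation round per donor, donor intra-individual variability is
  not modelled; `donation_round` is carried through the metadata so a
  multi-round design is expressible.
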