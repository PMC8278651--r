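---
title: "Models and methods behind akkpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind akkpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`akkpop` studies species complexes like the gut genus *Akkermansia*: several
species-level clades at 85–90% genome-wide identity that share a nearly
identical 16S rRNA gene, exclude one another ecologically, and interact with
gut phages through CRISPR immunity. This vignette explains the models and
numerical choices behind each stage, what the synthetic-data generator does
and does not emulate, and the design decisions that were genuinely open.

## Genome sketching and species delineation

Genomes are compared with bottom-*s* MinHash sketches (defaults `k = 21`,
`s = 1000`, the defaults of the Mash tool this stage emulates; the analyses
this package mirrors do not state their sketching parameters, so the tool
defaults are adopted and exposed as configuration). Every canonical k-mer (the
lexicographic minimum of the k-mer and its reverse complement) is hashed
with a 64-bit avalanche (murmur-finalizer) hash on the packed 2-bit
encoding; determinism across platforms comes from the fixed integer hash,
not from R's RNG. The Jaccard index `j` is estimated from the bottom-*s*
sketch of the union, and converted with the Mash estimator
`d = -ln(2j/(1+j))/k`.

**ANI convention.** Under the Poisson substitution model, `2j/(1+j)`
estimates the fraction of k-mers surviving unmutated, `(1-p)^k`, so the
per-site identity is recovered *exactly* as `exp(-d)`. The frequently used
`1 - d` is the first-order expansion of the same quantity and is biased by
about 1.3 percentage points at 85% identity — material for a genus whose
species differ by 10–15%. `mash_ani()` therefore reports `exp(-d)`.

Two caveats the sketch estimator inherits from its model, both demonstrated
by the generator: (i) with `s = 1000`, the binomial noise of the sketch
Jaccard translates to roughly ±1 percentage point per genome pair at 85%
identity, so ANI accuracy claims are made about the *mean* error over many
pairs, not per pair; (ii) under substitution-rate heterogeneity the
surviving k-mers come disproportionately from conserved regions, so MinHash
"ANI" sits above the per-site mean identity — even a ~5% conserved fraction
(one rRNA operon) visibly inflates the estimate at low ANI. The ANI
validation fixtures therefore use the generator's homogeneous-rate regime,
where per-site identity is a single well-defined quantity.

Species-level genome bins (SGBs) are average-linkage clusters of the Mash
distance matrix cut at 0.05 (the conventional 95% ANI species boundary).
Average linkage is used because the upstream literature this stage follows
does not state its linkage and average linkage resists chaining; the
threshold is configurable. QC follows the inclusive reading — completeness
≥90%, contamination ≤5% — which is the headline definition in the source
analysis (its methods section uses the strict variant; both are one
argument away).

16S distances are computed on end-to-end global alignments (match +1,
mismatch −1, linear gap −2) as edit distance over alignment length, after
dropping sequences of ≤1000 nt and sequences with >98% whole-gene identity
to a foreign-family reference.

## Gene families, core genes, markers

Gene families are built by greedy centroid clustering, longest sequence
first (ties broken lexicographically, which makes the clustering invariant
to input order): a gene joins the first centroid it matches at >90% mean
identity over >80% of the centroid length, otherwise it founds a family.
Identity and coverage are measured by placing ~150-nt tiles of the gene
ungapped at their best position on the centroid (both strands), seeded with
9-mers. The pigeonhole bound of the seeding makes the per-tile scan exact
down to 90% identity; placements below that may be missed, so the effective
decision boundary for joining a family is sharp at the contract's 90% and
conservative below it. This matters only for genes hovering at the
boundary; planted families sit at ≥96% (members) or ≤90% (non-members).

Core genes of a clade are families present in at least 80% of its genomes
(boundary inclusive). A core gene becomes a clade-specific *marker* iff, for
every other clade, the fraction of genomes in which the gene is
fragment-present is at most 1% — and "more than 1%" excludes, so exactly 1%
is kept. Fragment presence cuts the gene into consecutive non-overlapping
150-nt fragments (a terminal remainder shorter than 150 nt is dropped, to
avoid length-dependent sensitivity; genes shorter than one fragment are
evaluated whole, with a message) and asks whether any fragment has an
ungapped hit with ≤5 mismatches on either strand — a crisp, testable
stand-in for the sensitivity of a short-read mapper at its sensitive
setting. The fragments tile the gene rather than overlap; the source is
silent on this and tiling gives each base one vote.

Gene-set screening (corrin-ring operon, plasmid- and resistance-gene
queries) uses the same tile placement: a reference is present when found
tiles cover ≥50% of its length at ≥70% mean identity (both thresholds
configurable, matching the published plasmid-screen semantics). The seeded
scan is exact down to ~90% per-tile identity; in the synthetic data all
true positives sit at ≥94%, and the vignette notes that screening highly
diverged homologs (70–90%) would need an alignment-based scan instead.

## Metagenomic profiling

Reads are mapped with exact 31-mer seeds and ungapped end-to-end extension;
the score is −6 per mismatch and alignments scoring ≤ −50 are discarded,
giving the published "alignment score > −50" rule a concrete meaning (≤8
mismatches on a 100-nt read). Multi-mapping reads with tied best scores on
different targets are dropped: markers are clade-exclusive by construction,
so ties indicate noise. A clade's depth is the 10% trimmed mean of its
per-marker depths (mapped bases over marker length), a robust estimator in
the spirit of MetaPhlAn's; a clade is detected when ≥20% of its markers
receive at least one read (the profiler it emulates does not publish its
internal detection rule, so this fraction is a declared, configurable
stand-in), and relative abundance is depth over the summed depth of
detected clades. Viral-cluster detection uses breadth of coverage by
interval union: a VC is detected when any member contig reaches ≥50%
breadth.

## CRISPR arrays, spacer matching, PAM

The array finder looks for ≥3 near-identical repeats (23–50 nt, ≤2
mismatches to the chain consensus) separated by 20–60-nt spacers: recurring
20-mers whose occurrence periods are compatible with repeat+spacer lengths
seed a chain, which is extended outward while ≥90% of occurrences agree per
column. A spacer whose first base coincides across most repeats can still
be clipped by one position — an ambiguity intrinsic to boundary detection
by consensus. Cas-locus typing consumes provided gene annotations (the HMM
machinery of dedicated typers is out of scope): the full type I-C gene set
with Cas3/Cas5/Cas8c/Cas7 on one strand and Cas4/Cas1/Cas2 on the other is
flagged as the split-strand novel-variant arrangement.

Spacer–phage matching is exact semi-global Levenshtein (spacer global, free
ends on the contig) at edit distance ≤2, strictly more sensitive at that
bound than the short-word BLAST parameters it replaces, and verified
against a quadratic dynamic-programming oracle. The upstream context (5 nt
immediately 5′ of the protospacer in protospacer orientation — the type I-C
convention) feeds the PAM model: a position frequency matrix, a majority
consensus, and per-column information content. The planted TTC motif is
recovered whenever ≥10 planted matches exist; spacers carrying one planted
indel shift their upstream window by one position, which is visible as
reduced information content in the flanking columns, exactly as in real
logos.

Viral clusters are built in two stages: greedy centroid clustering at ≥70%
overall identity (mean best-tile identity of the shorter contig on the
longer, both strands; unplaced tiles count as zero), then transitive
merging of clusters when any cross pair shares more than one third of the
shorter contig at ≥90% identity. Contig filters (a)–(d) — length strictly
>1500 bp, enrichment ≥50×, same-SGB binning in <30 metagenomes, unbinned
occurrence in >20 — are plain row filters with missing metadata excluded
and logged.

## Ecological statistics and meta-analysis

Partial Spearman correlations rank-transform all variables and read the
partial correlation off the inverse of the rank-correlation matrix.
Fisher-Z pooling uses `z = atanh(rho)` with variance `1/(n − s − 3)` (`s`
covariates) — the convention of the `pcor`-style tooling the analysis
follows; the ≈1.06 variance inflation specific to Spearman correlations is
deliberately omitted to match that convention, at the cost of slightly
anti-conservative CIs (coverage ~91–95% in simulation, inside the accepted
90–98% band). Between-study variance uses the Paule–Mandel moment
estimator: the unique τ² ≥ 0 with generalized Q equal to k−1, found by
bisection-free root finding (Q is monotone decreasing in τ²), with τ² = 0
whenever Q(0) ≤ k−1. The implementation is cross-checked against an
independent reference implementation in the test suite but does not depend
on it.

Covariate-adjusted standardized mean differences divide the OLS group
coefficient by the residual SD, with the standard SMD variance
`1/n1 + 1/n2 + d²/(2(n1+n2))`, and pool through the same Paule–Mandel
machinery.

Co-exclusion computes pairwise Spearman correlations with BH correction at
10% FDR on the genus-positive sample set (samples where at least one clade
is present), as in the published 4171-sample analysis, plus the
co-occurrence summary (samples with ≥1, exactly 2, >2 clades; co-occurrence
rate). One statistical property deserves emphasis: conditioning on "any
clade present" makes even *independent* sparse clades appear negatively
correlated (a Berkson-type selection effect), so the genus-positive design
overstates exclusion under the null. The package therefore exposes
`restrict = "all"`, under which the Spearman+BH procedure is calibrated
(null significant fraction at the nominal FDR in simulation), and the
calibration properties are stated for that mode; planted exclusion at odds
0.05 is detected with power ~1 under either mode.

The VC differential-abundance test is a two-sided rank-sum test (exact
enumeration when both groups have ≤10 samples and no ties) with the
generalized fold change: the mean difference of `log10(abundance + 1e-5)`
quantiles over the grid 0.05, 0.10, …, 0.95, absent minus present, so
negative values mean higher abundance when the VC is detected.

## Phylogenetics, subspecies, gene loss

Distance-based neighbor joining (standard Q-criterion, negative branches
clamped to zero, optional outgroup rooting) replaces maximum-likelihood
inference: the claims being tested are clade-level, and NJ recovers
additive matrices exactly — a property the test suite verifies on random
additive matrices up to 12 taxa. Subspecies are average-linkage clusters at
≥98% core-genome identity that are monophyletic in the tree and have at
least 3 members (the minimum size is this package's formalization — the
published subspecies were drawn visually on an ML tree, and singleton
"subspecies" are not meaningful); everything else stays unassigned.

Gene loss uses Dollo parsimony — present at the root, lost possibly many
times, never regained — which matches the loss-only reasoning for the
corrin-ring (vitamin B12) operon: the minimal number of losses is the
number of maximal all-absent subtrees, computed in one post-order pass and
verified against exhaustive enumeration of internal states. Fitch parsimony
(regain allowed) is available for comparison. On the published species
topology with the operon absent in *A. muciniphila*, SGB9223 and SGB9224,
the minimum is two losses: one on the SGB9223+SGB9224 stem and one on the
*A. muciniphila* branch.

Distance–distance association (e.g. operon distances vs core-genome
distances) is a Mantel-style Spearman correlation over upper-triangle
entries with label permutation (999 by default, one-sided for positive
association). Jaccard PCoA drops families below 3% prevalence, computes
set-based Jaccard distances, and applies classical scaling; negative
eigenvalues are reported unmodified.

## The synthetic-data generator

The generator is the package's instrument for validation, and its defaults
are the study conditions all tests run under.

**Genomes.** An ancestral backbone of 30 single-copy core genes (900 nt), a
1500-nt 16S-like gene, an 8-gene corrin-like operon and 300-nt intergenic
spacers evolves by i.i.d. substitutions with no indels inside orthologs, so
identity is analytic; mutations are applied as "scatter" events (a site is
redrawn uniformly over the four bases with probability q), which compose
multiplicatively along branches and make the divergence of any path exact
in expectation. Gene gain and loss are whole-gene events: eight
clade-unique genes per species (the marker truth), accessory genes present
in ~40% of genomes (tuning the core fraction to 0.8), and the operon
deleted wholesale in a configurable set of species (defaults: three of
five, mirroring the loss pattern in the genus that motivated the package).

Two rate regimes are provided. The default **two-class** regime keeps core
genes (and the operon) at ~4% interspecies divergence — as purifying
selection does for housekeeping genes — and solves the intergenic rate so
the backbone-wide identity hits the target ANI exactly (species branch
rates are obtained from the pairwise log-identity equations by least
squares, which is exact for any additive target matrix). This conservation
is not cosmetic: it is what makes shared core families merge across clades
(>90% identity) and be caught by the 150-nt fragment exclusivity screen, so
that exactly the planted unique genes survive marker selection. With a
uniform rate at 85–90% ANI, every core ortholog would evade the fragment
screen and marker precision would be structurally below one. The
**uniform** regime (`core_gene_divergence = NULL`) instead evolves every
site — 16S included — at the single rate implied by the target ANI; it is
the regime in which "ANI" is a well-defined per-site quantity and is used
for MinHash validation. The generator self-checks the realized backbone
identity of every species pair against the target, allowing the larger of
0.5 percentage points and 4.5 binomial standard deviations of the backbone
length.

The 16S gene in the two-class regime evolves only on species branches,
planted at half the requested divergence bound so that the realized maximum
(bound 2%) holds with margin under sampling noise.

**CRISPR and phages.** Phage genomes are uniform random sequences with
non-overlapping protospacer windows; the PAM is written immediately 5′ of
each protospacer in its orientation (~30% of protospacers on the minus
strand). Each host genome receives one locus — identical repeats of 32 nt
alternating with 30–35-nt spacers — appended as a separate contig; planted
spacers are protospacer copies with 0–2 random edits, mixed with random
spacers and, on request, decoys carrying exactly three interior
substitutions verified to sit at semi-global distance ≥3 from the whole
phage (edits at spacer ends would be absorbed by the matcher's free text
ends).

**Cohorts.** Per-study effects are drawn as N(atanh ρ, τ²) on the Fisher-Z
scale; abundance and BMI are built on a Gaussian copula whose latent
Pearson correlation is `2 sin(π ρ_s / 6)`, so the conditional rank
correlation given age and sex converges to the study effect, and the focal
abundance is a log-normal (monotone, hence rank-preserving) transform of
the latent score. The co-exclusion block draws clade presence sequentially
with a log-odds penalty when any other clade is already present
(`coexclusion_odds = 1` recovers independence exactly), with log-normal
abundances for present clades — the zero-inflated log-normal sparsity
pattern the co-exclusion statistics must handle. Default conditions: 10
studies of 300 samples, planted partial ρ = −0.2 (the direction of the
BMI association reported for *A. muciniphila*), τ² = 0.02, co-exclusion
odds 0.05.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: sequencing indels and platform error
profiles; recombination and horizontal transfer (orthologs evolve
clonally); rearrangements (genomes are colinear); within-species rate
variation beyond a single within-clade divergence; compositional bias of
real genomes (uniform base composition); read-depth biases (GC, edge
effects); and confounding structures in cohorts beyond age/sex/BMI.
Results on real data additionally depend on assembly and binning quality,
which are upstream of this package's scope.

## Problem sizes and runtime

The validation suite runs at deliberately desk-scale sizes, chosen so each
property is measured with useful precision: the marker pangenome uses 5
species × 20 genomes (~50-kb genomes); ANI recovery uses 50 independent
genome pairs of ~26 kb; mixture profiling uses 8 mixtures of 1–5 clades at
1–50× depth; the spacer oracle uses 200 random instances; meta-analysis
calibration uses 1000 null and 1000 heterogeneity replicates; co-exclusion
power/FDR use 40 replicates of 500 samples; the Dollo oracle uses 500
random trees of up to 10 leaves. The full suite and the acceptance script
each complete in a few minutes on one CPU.

## Interfaces

The exported R functions are the package's interface; `run_pipeline()`
chains all stages from one validated configuration object and writes
stamped TSV outputs (package version, config hash, seed), with
byte-identical reruns for identical config and seed. The package
deliberately ships no shell entry point: its users drive analyses from R,
and the pipeline function plays the orchestration role a command-line
wrapper otherwise would.
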