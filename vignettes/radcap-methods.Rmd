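---
title: "Target capture of ddRAD loci: models, filters and design choices"
author: "radcapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target capture of ddRAD loci: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Double-digest RAD sequencing (ddRADseq) reduces a genome to fragments
bounded by two restriction sites, giving thousands of anonymous loci
without prior genomic resources — but a mutation inside a restriction site
silently removes one allele from the library (allele dropout), and the
missing-data burden grows with divergence, making cross-species
comparisons fragile. In-solution target capture inverts the trade-off:
120-mer probes designed *from* ddRAD loci pull the same fragments out of
sonicated libraries regardless of restriction-site state, giving
repeatable, low-missingness data across related species and even degraded
museum extracts. `radcapkit` implements the complete computational side of
such an experiment — probe-template curation, capture-read processing,
reference construction, hard-filtered variant calling, deamination
handling and population summaries — together with a synthetic-experiment
generator so the whole chain is testable offline with known truth.

# The synthetic experiment

`simConfig()`/`simulateTruth()`/`emitReads()` emulate a multi-species
capture study at desk scale:

* **Loci.** `n_loci` ancestral sequences drawn uniformly over A/C/G/T,
  lengths uniform in `locus_length_range` (default 140–220 bp, the
  size-selection window of a typical ddRAD library), flanked by fixed
  6 bp restriction half-sites at both ends.
* **Divergence.** One haplotype per species, derived by equal-rates
  (Jukes–Cantor-style) substitution at the configured divergence. The
  equal-rates model was chosen because it has closed forms that the tests
  can check (e.g. a transition:transversion count ratio of 1:2, and a
  dropout probability of $1-(1-d)^{12}$ for 6 bp half-sites).
* **Individuals.** Diploid genotypes with per-site heterozygosity
  `theta_het`; both alleles start from the species haplotype.
* **Dropout.** An allele whose restriction half-site carries any
  substitution is lost from the ddRAD library with probability
  `dropout_per_substitution` (default 1: if the cut site is gone, the
  fragment is not cut). Capture mode ignores dropout — the probes bind
  the locus body — which is exactly the contrast the missing-data
  comparison asserts.
* **Capture efficiency.** Expected per-locus coverage is scaled by
  $2^{-d/\text{halflife}}$ (default half-life 0.1 substitutions/site),
  reflecting the reported decay of capture efficiency with target
  divergence; it never reaches exactly zero.
* **Fragments.** ddRAD fragments are the full locus in fixed (adapter
  -directional) orientation. Capture fragments are sonication inserts:
  length from a truncated normal (inverse-CDF sampling, so no probability
  atom at the bounds, which would fake PCR duplicates by coordinate
  collision), start uniform, strand random. Museum-era inserts use a
  shorter truncated normal (`fragmentation_mean`, default 90 bp); the
  choice of a truncated normal over a geometric is ours and exposed in
  the configuration.
* **Damage.** Museum fragments receive terminal deamination before
  sequencing error (so both coexist on a read): C→T at 5′ position $p$
  and G→A at distance $p$ from the 3′ end, each with probability
  $\delta\lambda^{p-1}$.
* **Duplicates.** A configurable fraction of emitted fragments are exact
  PCR copies (same locus, start, length, strand) of an existing fragment.
* **Qualities.** Constant per read and Phred-calibrated to the injected
  `error_rate` (capped at Q37 modern / Q30 museum). Calibration matters:
  a caller that trusts overstated qualities overcalls heterozygotes.
  A consequence worth knowing: the whole-pair discard below mean Phred 33
  used on real data is a pass-through only when the library's constant
  quality exceeds 33; on simulated reads calibrated below that, the
  threshold is set to the simulated quality floor
  (`readProcParams(min_mean_phred = ...)`), otherwise the filter would
  discard every read by construction.

What the generator does **not** emulate: indels (substitutions only),
realistic position-dependent Illumina error profiles, coalescent
genealogies within species, GC-dependent capture bias, or contaminated
libraries (contaminants are injected explicitly in tests). Passing tests
therefore demonstrate the pipeline's arithmetic and decision rules, not
robustness to alignment-gap or demographic complications.

# Catalogue building and probe design

`clusterWithinSample()` is a greedy, abundance-ordered (ties broken
lexicographically — deterministic without the original tools) clusterer:
a read joins a seed when diagonal identity ≥ 95% *and* mismatches ≤ 3;
consensus is majority with a two-base IUPAC code where two bases each
exceed 25% of column depth; clusters with more than 0.5 of their columns
ambiguous are discarded ("site heterozygosity" read as the fraction of
ambiguous consensus columns). Identity is matches over alignment columns
with terminal length differences counted as mismatches; internal gaps are
not modelled anywhere in the package because neither the simulator nor
the locus comparisons need them — this is a stated non-goal, not an
approximation of one.

`buildCatalog()` clusters per-sample consensi across samples (95% within
species, 85% combined) and flags putative paralogs two ways: a column
ambiguous in more than 4 individuals (shared heterozygosity), or a column
showing more than 3 distinct bases across samples — our reading of a
"paralog filter of three", exposed as `paralog_filter`.
`synonymizeRedundant()` merges loci present in multiple assemblies
(identity ≥ 90% over ≥ 55% of the shorter consensus, transitive closure
by union–find, longer consensus kept). `purgeSimilarLoci()` flags *both*
members of any pair above the same 90%/55% rule; the 75% pre-grouping
threshold mentioned alongside it is subsumed, since any pair above 90%
is above 75%. `maskLowComplexity()` flags homopolymer runs ≥ 10 bp and
windows (64 bp, step 32) whose DUST-style triplet score
$\sum_t c_t(c_t-1)/2 / (n-1)$ exceeds 2 — thresholds at the standard
DUST operating point. `screenMitochondrial()` is strand-aware at
80% identity over 50% of the locus; those thresholds are ours (only the
reference genome is given by the protocol), and mito-flagged loci stay
eligible as probe templates by default because the published panel kept
its eight mitochondrial loci.

`tileProbes()` places 120-mers at offsets 0, 60, 120, … and right-anchors
the final probe at `length − 120` when a stepped probe would overrun;
duplicate offsets collapse. End-anchoring is the only tiling under which
2 probes cover every template in (120, 180] bp — which is what makes
2 × 2,366 = 4,732 probes for templates in that range, the worked example
in the acceptance checks.

# Read processing

The four processing stages run in protocol order: adapter/quality trim
(3′ bases < Q20, whole-pair discard below the mean-quality floor),
contaminant screen, overlap merge, dual-index demultiplex. The
contaminant screen is a deliberate simplification of taxonomic
classification: a read is removed when ≥ 50% of its 31-mers occur in the
contaminant set (canonical, both strands); only keep/remove decisions are
in scope. Merging scans all overlaps ≥ 20 bp, requires mismatch fraction
≤ 10%, takes the best score (matches − mismatches, ties to the longer
overlap), resolves conflicts to the higher-quality base, caps merged
fragments at 220 bp and, in ddRAD-catalogue mode, discards fragments
< 140 bp. A statistical overlap-significance test was deliberately left
out for determinism. Demultiplexing requires both indexes within 1
mismatch of a sheet entry and rejects sheets whose index pairs are closer
than 3 mismatches, making assignment unambiguous by construction; the
built-in simulated indexes are Reed–Solomon codewords at pairwise
distance ≥ 6.

# Mapping, duplicates, reference building

`mapReads()` is a seed-and-extend placer: 15-mer index, best shared
diagonal per locus and strand, ungapped scoring (matches − mismatches).
Mapping quality is `min(60, best − second_best)` across loci — the
published aligner's formula is not public and only the maQ ≥ 5 cutoff is
used downstream, so the margin definition is ours; ties give maQ 0 and
are excluded. `markDuplicates()` groups fragments within a sample by
(locus, start, insert length, strand) and keeps the highest summed base
quality — capture fragments are sonication products, so equal-length
same-start fragments are overwhelmingly PCR copies; the marking is
idempotent.

`buildReference()` greedily clusters merged modern reads at 90% identity
(strand-aware, k-mer seeded, overlap ≥ 60 bp), drops clusters under 40
reads, merges cluster consensi overlapping ≥ 120 bp at ≥ 85% identity
(union–find; the longest member represents the merged locus — cluster
consensus, not longest read, represents a cluster), and labels loci
on-target by reciprocal best hit against the probe set at ≥ 75% identity
— chosen with margin below the ~12% divergence probes tolerate, and
configurable. Consensi whose 5′ and 3′ halves best-hit different probe
templates are flagged chimeric and excluded. Coordinates are 0-based,
half-open throughout.

# Variant calling and hard filters

Genotype likelihoods per sample and site use the standard diploid model:
$P(b\mid RR) = 1-e$ for the reference base and $e/3$ otherwise, a
heterozygote emitting either allele at ½, flat prior (none is given by
the protocol), MAP genotype, GQ as the phred gap to the second-best
genotype. Site QUAL is the phred-scaled probability that *all* samples
are homozygous reference. Annotations: QD = QUAL over summed depth of
alt-carrying samples; MQ = root-mean-square maQ of covering reads;
FS = −10·log10 of the exact two-sided Fisher strand p (computed by
hypergeometric enumeration; the tests cross-check it against
`fisher.test`); ReadPosZ = tie-corrected Mann–Whitney z of alt vs ref
distances to the nearer read end. "Phred quality < 40" is read as site
QUAL (genotype-level quality is also emitted as GQ, since the text does
not decide between them), and "reads rank position < −12 bp" as the
rank-sum z — the reading most compatible with a rank statistic; the
filter is only applied to sites carrying heterozygote calls. The
haplotype-score filter of the original caller is intentionally absent:
it is an internal annotation with no published closed form. Hard
thresholds: QD < 4, MQ < 18, QUAL < 40, FS > 60, fewer than 8 samples at
5X, ReadPosZ < −12 (het-driven sites), biallelic only; all strict as
printed, every failure reason recorded.

Multi-allelic detection is noise-robust: an alt allele must reach
max(2, ⌈2% of site depth⌉) reads, so scattered sequencing errors at high
depth do not spuriously fail real biallelic sites.

# Museum samples

`profileDamage()` accumulates reference-C→read-T frequencies by 5′
position and reference-G→read-A by 3′ distance (reads oriented as
sequenced; duplicates excluded) and fits $\delta\lambda^{p-1}$ by
weighted least squares. The background mismatch rate is estimated from
interior positions 11..P because "no damage" is not defined numerically
anywhere; a profile is called damage-free when $\hat\delta$ is under
twice that background, and unreliable under 1,000 informative terminal
positions. `qcExclude()` removes samples under 2.0X mean target coverage
(strictly: 1.99X goes, 2.00X stays) and attaches the purity
(A260/A280 ≤ 1.0) and yield (≤ 30 ng/µL) rules of thumb as warnings
only. `deaminationFilter()` removes whole sites whose major→minor
direction is C→T or G→A, from modern and museum samples alike —
deamination is directional, so T→C and A→G sites stay. Site-wise removal
(the whole variant dropped for every sample) is the default reading of
removing "intervals"; major/minor alleles are determined globally by
default with a per-species option, ties breaking toward the reference
base.

# Population statistics

`siteFilters()` removes sites with > 10% missing data or minor allele
frequency < 0.05 (strict, so a site at exactly 0.05 is kept) and fixed
sites; it is idempotent. `ldPrune()` uses 50-site windows stepping by 5
with an r² cap of 0.5 — common defaults, since none are stated — and a
deterministic drop rule (more missing data, then lower MAF, then later
position). `wcFst()` computes the Weir–Cockerham variance components a
(among populations), b (among individuals within populations) and c
(within individuals) per biallelic site and reports both per-site
θ = a/(a+b+c) and the ratio-of-sums global estimate Σa/Σ(a+b+c) — the
standard aggregation for this estimator, not a mean of ratios.
`diversityAndSharing()` emits per-site MAF and both observed and
expected heterozygosity (the published mean ± SD does not say which, so
both are reported), the k-of-n species locus-sharing histogram (presence
= at least one genotyped individual), and per-sample missingness.
`pcaGenotypes()` centres dosages at 2p with site-mean imputation, scales
by √(p(1−p)), and fixes signs by making the largest-magnitude loading of
each component positive, so runs are reproducible.

# Problem sizes used in the checks

The verification suite simulates at desk scale, chosen so every stage
still operates in its intended regime: 300 loci × 3 species × 8
individuals for end-to-end locus recovery, 100 loci × 16 samples at
~20X for genotype concordance, ~20,000 museum reads for damage-parameter
recovery, 500 sites × 100 individuals for the panmictic Fst control, and
2,366 templates for the probe-tiling worked example. Headline counts of
any particular sequencing study (locus totals, shared-locus counts,
data-bound Fst values) depend on the authors' libraries and are not
reproduced; the checks are property-based instead.

# Known limitations

Ungapped comparison throughout means indel-bearing data would need a
different aligner behind the same interfaces. The contaminant screen has
no taxonomic resolution. The duplicate-rate estimate inflates slightly
(< 1% absolute at default settings) from genuine coordinate collisions,
which is inherent to fragment-identity marking. The museum
fragment-length law and several screen thresholds (mito 80%/50%,
background damage window) are package choices where the underlying
protocol is silent; all are exposed as parameters.
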