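# radcapkit

Target capture of ddRAD loci, end to end: an R toolkit for population
genomics across closely related (and museum-preserved) specimens.

## The problem

ddRAD sequencing yields thousands of anonymous loci without genomic
resources, but a mutation in a restriction site silently drops an allele
from the library — missing data piles up with divergence and cross-species
comparison becomes unreliable. Hybridization capture with 120-mer probes
designed *from* a ddRAD locus catalogue pulls the same loci out of
sonicated libraries regardless of restriction-site state, so the same
marker panel works across related species and even degraded museum
extracts. `radcapkit` implements the computational chain of such an
experiment:

* **catalogue building** — greedy within-sample clustering (identity ≥
  0.95, ≤ 3 mismatches, ≤ 0.5 site heterozygosity), across-sample
  catalogues (0.95 within / 0.85 combined), paralog flags (shared
  heterozygosity in > 4 individuals; > 3 bases per column), redundancy
  synonymization and a 90 %/55 % similarity purge, low-complexity (DUST)
  and mitochondrial screens, and 2X-tiled, end-anchored 120-mer probes;
* **read processing** — adapter/quality trimming with a whole-pair
  mean-Phred discard, canonical 31-mer contaminant screen, overlap
  merging (≥ 20 bp, ≤ 10 % mismatch, ≤ 220 bp), dual-index
  demultiplexing (1 mismatch per index);
* **mapping & reference building** — seed-and-extend placement with
  maQ = min(60, best − second best), PCR-duplicate marking by fragment
  identity (locus, start, insert length, strand), 90 % read clustering
  with a 40-read floor, 120 bp/85 % consensus merging, reciprocal-best-hit
  on/off-target labelling;
* **variant calling** — diploid genotype likelihoods, site QUAL, and the
  hard filters QD < 4, MQ(rms) < 18, QUAL < 40, FS > 60, < 8 samples at
  5X, heterozygote read-position rank z < −12, biallelic only;
* **museum DNA** — empirical C→T/G→A terminal damage profiles with a
  δ·λ^(p−1) fit, 2.0X coverage exclusion, and the directional
  deamination site filter;
* **population statistics** — Weir–Cockerham Fst
  (θ = a/(a+b+c) per site, ratio-of-sums globally), missingness/MAF site
  filters, LD pruning, locus sharing across species, PCA.

A synthetic-experiment generator (`simConfig()`, `simulateTruth()`,
`emitReads()`) produces multi-species capture/ddRAD reads with known
truth — restriction-site allele dropout, divergence-dependent capture
efficiency, PCR duplicates, terminal deamination, sequencing error — so
every stage is testable without sequencing data.

## Worked example

```r
library(radcapkit)

cfg <- simConfig(seed = 1, n_loci = 50,
                 species_divergences = c(edw = 0.02, ver = 0.05, fro = 0.08),
                 n_individuals_per_species = 6)
truth <- simulateTruth(cfg)
reads <- emitReads(truth, cfg, mode = "capture")
proc  <- processReads(reads, params = readProcParams(min_mean_phred = 20))

probes <- tileProbes(ancestralLoci(truth)[1:35])   # panel on 35 of 50 loci
ref    <- buildReference(proc$fragments, probes)
aln    <- markDuplicates(mapReads(proc$fragments, refSeqs(ref)))
vs     <- hardFilter(callVariants(aln, refSeqs(ref)))
fst    <- wcFst(siteFilters(genotypeMatrix(passSites(vs))))
```

which prints, object by object:

```
TruthSet: 50 loci, 3 species, 18 individuals; 710 ddRAD dropout alleles
ReadPairSet: 12828 read pairs, 18 samples; 0 PCR duplicates
ProbeSet: 87 probes on 35 template loci
ReferenceSet: 50 loci ( 35 on-target, 15 off-target ); 0 flagged
AlignmentSet: 12482 alignments on 50 loci; 15 duplicates flagged; 12482 with maQ >= 5
VariantSet: 2110 sites x 18 samples; 1473 PASS
FstEstimate: global theta = 0.9818 over 1022 sites, 3 pops
```

Reading it: 710 of the 1,800 simulated alleles would have been lost to
restriction-site dropout in a ddRAD library, yet capture mode recovers
all 50 loci — 35 labelled on-target (they have probes) and 15 off-target
— with essentially no missing data. Of 2,110 candidate variant sites,
1,473 survive the hard filters, and the near-fixed differences between
three species at 2–8 % divergence drive the global Weir–Cockerham θ to
0.98. Within a single panmictic pool the same estimator sits at 0
(`fst_panmictic_abs` below).

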