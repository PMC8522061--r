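---
title: "Modelling heavy-water SIP viromics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heavy-water SIP viromics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostphage)
```

## The problem this package models

In heavy-water stable isotope probing (SIP), a soil community is incubated
with H~2~^18^O. Every organism that synthesizes DNA during the incubation
builds ^18^O into it, making that DNA denser. CsCl density-gradient
ultracentrifugation then separates labeled (active) from unlabeled (dormant
or relic) DNA, and shotgun sequencing of the dense gradient fractions reads
out *who was active*. Applied to viruses, the same logic identifies viral
populations (vOTUs) that replicated — in a host — during the incubation,
and CRISPR spacers plus shared genomic content link those viruses to the
microbial genomes (MAGs) they infect.

`frostphage` implements this whole inference chain at desk scale, together
with a seeded synthetic community generator, so that every stage — presence
calling, read subtraction, fold-change testing, linkage, the
activity-by-linkage cross-tabulation, and the ecology statistics — can be
scored against a known ground truth without any external data or tools.

## The gradient model

Unlabeled DNA bands at

$$\rho(gc) = \rho_0 + s \cdot gc$$

with defaults $\rho_0 = 1.660$ g/ml and $s = 0.098$ g/ml per unit G+C
fraction, the classical CsCl GC–density relation. Labeling shifts the band
mean by

$$\Delta\rho = \Delta_{max} \cdot a \cdot f_{new}$$

where $\Delta_{max} = 0.036$ g/ml is the fully labeled shift at 100 atom%,
$a$ is the atom fraction excess of the incubation water (0.97 for the
labeled arm, 0 for natural abundance), and $f_{new}$ is the fraction of the
entity's DNA synthesized during the incubation. The band itself is a
Gaussian with sd `band_sigma` (default 0.003 g/ml); the mass in each of the
five gradient bins is the Gaussian integral over the bin. Only the two
heaviest bins — medium-heavy (MH, 1.717–1.725 g/ml) and heavy (H,
1.725–1.750 g/ml) — are sequenced; the three light bins are modelled and
discarded.

These constants are not fitted to anything: the inference only uses their
qualitative consequence (label → heavier), and all of them are arguments of
`density_model()`. With the defaults, a fully labeled genome at 50% G+C
bands at 1.744 g/ml (inside H) while its unlabeled twin bands at 1.709 g/ml
(below MH) — the physical premise of the treatment contrast. Note one edge
the defaults imply: a fully labeled genome above ~60% G+C bands beyond the
modelled gradient top (1.750 g/ml); `fractionate()` reports such
out-of-range mass as its `tail` attribute rather than silently dropping it.

### Labeling truth is cumulative

Heavy water is present for the entire incubation, so labeling accumulates:
after an interval with multiplicative growth $g > 1$, the labeled fraction
updates as $f' = (f + (g - 1))/g$, and decay (loss of DNA) leaves the
*fraction* unchanged while the pool shrinks. A population that grew only in
the first half-year therefore still carries labeled DNA at 370 d; whether it
is *detected* as labeled then depends on how much of its pool survives.
This is exactly how the "no longer detected as labeled" trajectory class
arises: the generator lets formerly active virion pools decay strongly
(`lost_decay`, default 0.1 per interval), so their label persists but their
abundance falls below the detection floor.

## The synthetic community

`community_config()` fixes the study design: 20 hosts and 40 viruses by
default, two treatments (97 atom% H~2~^18^O vs natural abundance), two
timepoints (184 and 370 d), three replicates, and the two sequenced density
fractions — 24 fraction samples per community. Design choices that deserve
explanation:

* **Genome scale.** Hosts default to 50–100 kb and viruses to 10–13 kb.
  These are deliberately reduced scales: the package's sequencing model
  draws 2,000 reads of 300 bp per fraction sample (the 300 bp default
  represents the total sequenced yield of one paired-end 2×151 bp fragment
  as a single read; the read model is substitution-only, fixed length,
  constant FASTQ quality). For the ≥75%-breadth presence gate to be
  *informative* rather than vacuously failing, an active population must
  be able to reach ~1.4× coverage in at least one replicate's heavy
  fractions; with ~18 active viral populations sharing ~70% of a
  replicate's 1.2 Mbp of heavy-fraction sequence, that fixes the viral
  genome scale near 10–15 kb. All scales are config knobs; raising depth
  proportionally supports larger genomes.
* **Phylum GC profiles.** Host G+C is drawn from stylized phylum profiles
  in which the fermentative, psychrotolerant lineages that stay active
  under sub-freezing anoxic conditions (Firmicutes, Bacteroidota,
  Acidobacteriota analogues) are low-GC, and the dormant background
  (Chloroflexota, Actinomycetota analogues) is high-GC. This has an
  important consequence the inference relies on: the natural-abundance
  heavy fractions are dominated by high-GC *inactive* genomes, which is
  what makes both the presence rule ("present in ^18^O, absent in ^16^O")
  and the read-subtraction reference meaningful. The GC values are
  stylized, not taxonomic claims; scenarios that correlate activity with
  high GC (label/GC confounding, a known SIP failure mode) can be built
  by editing `default_phyla()` and raising `band_sigma`.
* **Activity structure.** Host activity is a fixed count (30% of hosts,
  active at both timepoints). Viral activity patterns are fixed cohort
  counts (25% active at both timepoints, 20% newly active at 370 d, 10%
  active only at 184 d, 45% never active), randomized only in assignment —
  the cohort sizes are part of the study design, like the replicate count.
  Growth over an active interval is uniform on 3–6×; a population active
  in both intervals grows at a saturated 1.2–2× in the second (resources
  draw down; nothing compounds a 6× expansion for a full year).
* **Linkage plan.** Every true virus–host pair is recorded in the host's
  CRISPR memory (an array of 3 spacers copied verbatim from the virus,
  with a configurable mismatch count). 43% of viruses are temperate; 80%
  of those are integrated as a provirus into a true host whose activity
  pattern matches the virus's own — prophages replicate with the host
  chromosome, so an activity-mismatched integration would make the
  ground-truth label ambiguous.
* **Marker genes.** Viral hallmark genes (for marker-mode detection),
  lysogeny genes (integrase/parA analogues, for temperate classification)
  and an auxiliary metabolic gene are fixed synthetic sequences planted
  into viral genomes. Each planted copy is mutated at 20% — marker genes
  behave like members of a gene family, not identical repeats. This
  matters: identical marker copies across genomes would constitute real
  shared content between unrelated virus–host pairs and flood the
  70%-identity content-linkage channel; at 20% per-copy divergence two
  instances agree at ~68%, below the gate, while the marker searcher
  (70% identity over 75% of the marker, 11-mer seeded) still finds every
  copy.

## The inference chain and its gates

All sequence-matching engines are exact k-mer seeded, ungapped
diagonal-block aligners (the read-subtraction gate additionally allows one
indel via a split-diagonal scan). Ungapped alignment is the correct model
here because the generator introduces substitutions only; every engine is
tested for exact agreement with an exhaustive brute-force oracle on small
instances. Read-side seeds are sampled every 4 positions (stride), which
provably finds any shared exact run of at least k+3 bases — near-identical
reads have error-free runs an order of magnitude longer.

| Stage | Gate | Default |
|---|---|---|
| Contig filter | length | ≥ 10 kb |
| vOTU clustering | ANI over aligned blocks / aligned fraction of shorter | ≥ 95% / ≥ 85% |
| Read mapping | read identity / read aligned fraction | ≥ 90% / ≥ 90% |
| Presence | breadth of reference | ≥ 75% |
| vOTU activity | present in ≥1 ^18^O replicate and 0 ^16^O replicates | — |
| Read subtraction | read identity, indels | ≥ 97%, ≤ 1 |
| MAG activity (subtraction) | active-read depth / breadth | ≥ 0.5× / ≥ 10% |
| MAG activity (fold change) | BH q / log2 fold change | < 0.05 / > 0 |
| Spacer match | full-length substitutions | ≤ 1 |
| Content link | block identity / total aligned | ≥ 70% / ≥ 500 bp |
| Provirus | vOTU containment (temperate only) | ≥ 90% |

Decisions where the procedure was genuinely open:

* **Presence pooling.** "Present in the H~2~^18^O samples" is evaluated per
  biological replicate on the union of its two sequenced density fractions
  (`pool_replicates()`): a population whose band straddles the MH/H edge
  is split between bins but is one labeled population. Absence on the
  ^16^O side is strict: zero of three replicates.
* **Clustering reference.** The 95/85 rule is applied against the cluster
  *representative* (greedy, length-descending, founder = longest member),
  the common dereplication practice.
* **Read subtraction instead of re-assembly.** The active (^18^O-distinct)
  reads are attributed directly to the known MAG references and gated on
  depth and breadth, rather than re-assembled and re-binned; assembly and
  binning engines are outside this package's scope, and attribution
  preserves the inferential content (which genomes the distinct ^18^O
  reads support). The unlabeled reference itself is mock-assembled from
  the ^16^O samples: any genome reaching 25% pooled breadth contributes
  its sequence.
* **Zero-inflated log-normal test.** Counts are a point mass at zero
  (probability π, estimated from the pooled zero fraction) or log-normal.
  Size factors are median-of-ratios over entities non-zero in every sample
  of a (timepoint, fraction) stratum — a closed-form stand-in for
  compositional normalization — with a library-size fallback. The log2
  fold change is the difference of arm means of log2(normalized count +
  0.5) over non-zero observations, shrunk by (1−π); an all-zero arm enters
  at the pseudocount. The p-value is a pooled-variance two-sample t on the
  non-zero values (an all-zero arm contributes its pseudocounted values,
  i.e. a point mass); this is exact under the shared-variance log-normal
  null and retains power under zero inflation, where including zeros as
  pseudocounts would inflate the variance several-fold. Under a
  zero-inflated null the raw p is mildly anti-conservative (~0.07 at
  π = 0.2), but the Benjamini–Hochberg step keeps the realized false-call
  fraction far below the 5% FDR target; the clean log-normal null is
  calibrated to nominal size.
* **Provirus direction.** The containment criterion is read as "≥ 90% of
  the vOTU contig contained in the MAG ⇒ provirus"; the raw fraction is
  recorded on every link so the opposite reading can be recomputed.
* **Timepoint comparison.** Welch's t on outlier-filtered per-sample
  values (fences at 2.2 × IQR beyond type-7 quartiles, two-sided).
  Welch is mildly conservative at n = 6 per group (true size ≈ 0.04);
  the tests assert validity (never anti-conservative), not exact
  nominality.
* **Cross-tabulation counts.** A "match" is one raw evidence item (one
  spacer hit or one content link); groups 1–4 are determined solely by the
  partners' activity calls. The totals row is the column sum over groups;
  because an entity can appear in several groups, the distinct-overall
  counts can be smaller and are reported separately as the
  `distinct_overall` attribute.

## What the tests do and do not show

The acceptance suite scores the full chain on seeds 1–10 of the default
design: active-vOTU precision/recall ≥ 0.95, active-MAG recall ≥ 0.9 by
each method, planted-pair recall ≥ 0.9 at precision ≥ 0.95, and perfect
temperate recall, with recall denominators restricted to truth-labeled
populations above a detectability floor (relative abundance ≥ 0.005 — a
population below it cannot contribute enough reads at 2,000 reads/sample
for any method to see, and excluding it is the standard benchmarking
convention). A no-label experiment (atom excess 0 in both arms) yields
zero presence-rule calls and a fold-change false-positive fraction within
the FDR target.

Passing these tests shows the *rules* are implemented correctly and are
recoverable under the stated physics — it does not show the pipeline works
on real soil metagenomes. Real data add assembly fragmentation and
chimerism, GC-coverage bias, strain heterogeneity below the 95% ANI
horizon, relic DNA with partial label, paired-end and quality structure,
and detector (VirSorter/DeepVirFinder-class) false negatives — all
explicitly outside the generator (external detection and assembly tools
are represented by truth-driven mocks). The stress knobs that exist —
`band_sigma`, `marker_divergence`, spacer mismatches, GC/activity
correlation via `default_phyla()` — probe the failure modes the model
*does* contain.

Problem sizes were chosen so the whole suite runs comfortably on a
single CPU: 10-seed recovery on the 20-host/40-virus design, oracle
fixtures of ≤ 12 contigs, 120 reads, 30 spacers, 36 content pairs. The
same scales are used by `scripts/acceptance.R`, which recomputes every
headline number from scratch (5 seeds) and writes them as JSON.

## Conventions

Coordinates are 0-based, half-open, plus strand throughout the R objects;
GFF3 output converts to the format's 1-based closed convention and the
reader converts back (round-trip tested). Sequences are plain upper-case
ACGT strings; FASTA/FASTQ/GFF3 I/O goes through Biostrings and
rtracklayer. All randomness flows from explicit integer seeds; a community
plus experiment is byte-reproducible from `(config, seed)`.
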