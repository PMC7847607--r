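---
title: "Phased siRNA locus discovery: model, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phased siRNA locus discovery: model, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasloc)
```

## The screening model

`phasloc` searches transcript space (cDNA sequences, not the genome) for
precursors of phased siRNAs. The model rests on three pieces of
small-RNA biochemistry:

1. **Register geometry.** After a trigger-guided cut sets an anchor
   $a$, Dicer processes the downstream duplex every $k$ nt
   ($k \in \{21, 24\}$). Each duplex has 2-nt 3′ overhangs, which places
   the bottom strand of the duplex at top-start $t$ two nt to the left
   on the sense scale, its 5′ end at $t + k - 3$. Hence the in-phase
   condition: plus-strand 5′ ends $\equiv a \pmod k$, minus-strand 5′
   ends $\equiv a + k - 3 \pmod k$. The $k-3$ offset is not stated in
   most phasiRNA reports; it is forced by the overhang geometry, and we
   derive it rather than fit it.
2. **Occupancy.** A *candidate production region* is a maximal run of
   tandem duplexes, each with at least one exactly mapped $k$-nt read on
   either strand, of length ≥ `min_duplexes` (default 5). "Detectable"
   defaults to mapped RPM > 0; `min_duplex_rpm` exposes an abundance
   floor for noisier libraries.
3. **Phasing score.** In a window of five consecutive registers,
   $\mathrm{score} = (n-2)\,\ln\!\bigl(1 + 10\,\Sigma p / (1+\Sigma U)\bigr)$,
   with $n$ the occupied registers, $\Sigma p$ the **total count** of
   in-phase $k$-nt reads and $\Sigma U$ the number of **unique**
   out-of-phase $k$-nt reads. The asymmetry (counts vs unique reads) is
   deliberate and kept: abundance should reward phasing, while
   out-of-phase *complexity*, not depth, should penalize it. A locus
   passes iff its maximum window score is strictly above 1. Windows
   slide register by register (step $k$); both strands contribute via
   the phase rule. Whether $\Sigma U$ should include non-$k$-length
   reads is genuinely open; we count only $k$-nt reads, which makes the
   statistic a pure within-class contrast.

Degradome (PARE) 5′-tag libraries supply the validation layer: tags map
sense-strand only (they are 5′ fragments of cleaved mRNA), pile up at
their 5′ coordinates, and a position is a *cleavage signal* when its RPM
≥ `min_rpm` (default 1) and dominates the highest neighbour within ±50
nt by ≥ `min_dominance` (default 2, with a 0.1-RPM background floor).
Published analyses in this area mark "dominant" peaks by eye; these two
thresholds are our quantification of that judgement and are exposed in
`phas_params()`.

## Triggers, targets and the cut-site rule

RISC cleaves opposite guide position 10, i.e. at `binding_end − 9` in
1-based closed coordinates. Read literally, a "10–11 nt from the 5′ end
of the binding site" rule is ambiguous for 22-nt guides; the
position-10 form reproduces every published (binding site → cleavage
site) pair we bundle as fixtures (`reference_phas_loci()`,
`reference_tasirna_targets()`), for 21- and 22-nt triggers alike, so it
is the implemented rule. One published interaction prints a 22-nt miRU
interval for a 21-nt tasiRNA; we keep the printed values in the fixture
(the cut-site rule still holds on it) but the package itself always
emits intervals of length $k$.

Complementarity is scored with an ungapped miRU-style penalty:
Watson–Crick 0, G:U wobble 0.5, mismatch 1, all doubled at guide
positions 2–7, cutoff 3.0. The original algorithm is only cited "with
default parameters" in the literature this mirrors; these constants are
the conventional plant-target-prediction set and are fixed here (gapped
alignment is excluded by design — at penalty ≤ 3 a gap is almost never
admissible anyway). Trigger candidates are all library reads of 18–24 nt
plus any supplied known-miRNA set; a candidate is accepted when its
predicted cut passes the flank check (within 2 nt of the region start,
or register-concordant) and is *validated* when ≥ 1 degradome library
has a dominant signal exactly at the cut (`jitter` relaxes this).

phasiRNAs are enumerated from the trigger-cut anchor with the field's
D-position nomenclature (`Locus(anchor)k 3'D<i>(±)`; `5'D` counts into
the upstream fragment). Published tables show several anchors for one
locus (wobble cleavage registers); the package does not guess a single
one — each anchor defines its own grid and is reported separately.
Region output likewise reports both maximal runs and the merged per-phase
hull (`region_hull()`), because published region spans are often longer
than a single gap-free run.

## RdDM analysis

24-nt phasiRNA targeting of promoters is a zero-mismatch, full-length
string match of the reverse complement (exact search — no heuristic
seeding is needed at promoter scale; identical-strand matches are
reported under a separate flag). Bisulfite reads are mapped by
three-letter matching (C→T collapse against the plus strand, G→A against
the reverse complement), keeping only uniquely mapping reads. Each
covered cytosine is classified CG/CHG/CHH (H = A/C/T; truncated 3′
triplets default to CHH) and reported two ways: methylated coverage in
RPM of the library, and the conventional methylated fraction. The
literature's "total coverage of individual cytosines in RPM" can be read
either way, so both columns are emitted and the per-context totals use
the RPM form. The RdDM consistency call is deliberately narrow: CHH
methylation higher **and** target expression lower in the
phasiRNA-expressing tissue; CG/CHG are reported but never enter the
call, since they are maintained by siRNA-independent pathways.

DCL dependence is a fold change of in-phase RPM within the region,
wild type over mutant, with a 0.1-RPM pseudo-floor and a default
threshold of 2 — "relatively higher" quantified once and exposed.

## What the generator emulates — and what it does not

`make_phas_scenario()` plants one locus among uniform i.i.d. background
transcripts: per-duplex strand counts are Poisson(`depth` = 20),
out-of-phase noise is added at `noise_rate` = 0.1 of the in-phase total
(uniform positions and strands, k-nt length), the trigger is a perfect
complement whose position-10 cut equals the anchor, and degradome tags
pile up there (Poisson depth 50) over a sparse unit background.
`make_mutant_library()` binomially thins the planted reads (retention
0.05 by default, emulating a dcl knockdown). `make_rddm_scenario()`
plants 24-mer complements in a 220-nt promoter and draws bisulfite reads
with per-context tissue rates (CHH 0.6 vs 0.05 between tissues, CG
0.8/CHG 0.4 in both, conversion 1.0) and RNA-seq depths 20 vs 200 for
the target gene. These defaults were chosen once as a realistic
desk-scale emulation of tissue-contrasted rice libraries and are the
conditions under which the recovery guarantees below are tested.

What passing these tests shows: the detection geometry, scoring,
validation logic and threshold boundaries are correct on data matching
the model's assumptions. What it does not show: robustness to
sequencing error, mismatched mapping, isoforms, repetitive genomes,
length heterogeneity of real sRNA populations, or bisulfite
non-conversion — none of which the generator models.

## Numerical and interface choices

- Coordinates are 1-based closed everywhere, so published table values
  can be used verbatim as fixtures; a 21-nt binding site 424–444 spans
  21 nt.
- All matching is exact and in the DNA alphabet (U→T on input; sRNA
  sequences are displayed as RNA). RPM uses the pre-filter library
  total; reads outside 15–30 nt stay in the total but are excluded from
  analysis.
- Degradome peak ties are broken toward the smaller position; trigger
  ranking is (penalty, −RPM).
- Degenerate inputs: spans shorter than five registers give an empty
  profile with a warning; an empty profile is an error for the maximum;
  empty libraries are an error for normalization.
- The pipeline surface is the R functions themselves
  (`run_phas_discovery()`, `run_rddm()`, the generators): this is an
  analysis package driven from R scripts, and a shell wrapper would add
  nothing but argument plumbing. Every threshold appears in the result's
  `log` component, and all randomness is seed-controlled in the
  generators, so report tables are reproducible byte for byte.

## Problem sizes

The test suite works at desk scale, chosen to exercise every code path
while keeping a full run near twenty seconds: transcripts of 0.3–2 kb,
libraries of tens of unique reads, 20-seed recovery and negative-control
sweeps, a 40-replicate trigger-ranking study, and brute-force oracle
comparisons on instances ≤ 2 kb. The acceptance script reruns the
standard planted-locus condition (8 duplexes, depth 20, 10% noise) and
reports the maximum five-register phasing score over the recovered
region.

## Known limitations

Transcript-space only (no intronic or intergenic PHAS discovery);
mismatch-free mapping; no 22-nt phasiRNA enumeration (no published
generation rule to implement); no replicate-level statistics for DCL
dependence (single libraries per genotype); promoter-local bisulfite
analysis rather than genome-wide alignment; network output is an edge
table, not a rendered graph.
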