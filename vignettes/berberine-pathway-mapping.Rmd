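---
title: "Mapping pathway orthologs to infer a taxon-restricted essential enzyme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pathway orthologs to infer a taxon-restricted essential enzyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbrpath)
```

## The inference this package implements

Berberine (BBR) is a plant isoquinoline alkaloid increasingly used as a
botanical pesticide. Its biodegradation in soil water appears to be carried
by a bacterial community rather than by any single cultivable strain: when
the compound disappears, particular genera — above all *Methylotenera* —
bloom transiently, yet every strain that can be brought into culture fails
to degrade the compound alone or in consortium.

`bbrpath` packages the comparative-genomics argument that connects these
observations. Because no bacterial degradation pathway for BBR is known,
the plant biosynthesis pathway is used as a mirror: its numbered enzymes
serve as protein queries, and each bacterial genome is searched for
orthologs of every query. Cross-classifying the resulting presence/absence
matrix against two evidence classes —

* **enriched-genus genomes**: genomes of genera whose relative abundance
  rises sharply only while the compound is degraded, and
* **non-degrader isolates**: cultivable strains from the same water that
  do not degrade the compound —

singles out enzymes present in the enriched genus but absent from every
cultivable non-degrader. Such an enzyme is a *candidate essential,
taxon-restricted step*: the reaction the culturable part of the community
cannot supply. In the motivating system that candidate is the
S-adenosylmethionine-dependent tetrahydroisoquinoline N-methyltransferase
("enzyme 9" in pathway numbering), found only in *Methylotenera*. The
output label is deliberately "candidate": set logic over presence calls
proves no enzymatic function.

## Alignment model

Genomes are unannotated nucleotide contigs, queries are proteins, so every
contig is translated in all six reading frames (bacterial code; codons
containing `N` become `X`, stops become `*`) and queries are aligned to the
translations by Smith–Waterman local alignment under Gotoh's affine-gap
recurrence. Defaults reproduce BLASTP scoring: BLOSUM62, gap open 11, gap
extend 1 (a gap of length $k$ costs $11 + k$).

Three conventions matter for borderline presence calls and are therefore
fixed rather than left to an external aligner:

* **`X` and `*` score −4 against everything**, including themselves.
  Frame translations are full of stops; alignments may *span* them (no ORF
  calling is performed, so genes broken across fragmented reading frames
  are still findable), but stops can never contribute positively.
* **Identity and similarity are per-column over all aligned columns, gaps
  included in the denominator.** Identity counts identical columns;
  similarity additionally counts positive-scoring substitutions (BLAST
  "positives"). A column is never "similar but not identical-or-positive",
  which keeps identity ≤ similarity structurally.
* **Deterministic tie-breaking**: among equal-scoring end cells the
  smallest (subject end, query end) wins; the traceback prefers diagonal,
  then up, then left. Two runs on the same input give byte-identical
  alignments.

The DP kernels are small C++ routines; a brute-force oracle (exhaustive
enumeration of substring pairs, each scored by an independent global
alignment) and `Biostrings::pairwiseAlignment` verify the scores in the
test suite.

## The presence rule

An enzyme is *present* in a genome when its best hit — the maximum-score
alignment over all contigs, frames or proteins — satisfies

$$\text{similarity} > 30\% \quad\text{and}\quad \text{query coverage} \ge 50\%.$$

The 30% threshold (strict, on similarity rather than identity) is the
field's conventional twilight-zone cut for calling orthologs from pairwise
alignment. The coverage floor is this package's extension, and it is not
optional in practice: the best *local* alignment of a 300-residue query
against ~100 kb of translated random sequence is typically a 15–25 column
segment whose per-column similarity lies far above 30%. Requiring half the
query to align removes exactly this failure mode. Calibration on the
package's own generator (50 kb genomes, 300-residue queries) gives:
orthologs planted at ≥ 45% amino-acid identity are detected in 50/50
replicates; genomes with no planted ortholog are never called present
(0/100). The boundary of the rule sits near 15–20% planted identity, where
a genuine distant homolog occasionally (≈ 2% of replicates) still crosses
both thresholds — which is a property of distant homology, not a false
positive of the rule.

Both parameters, the metric (similarity vs identity) and the scoring
matrix are configurable; presence is monotone in the threshold and the
coverage floor by construction.

The rule's residual false-positive rate deserves honesty. Roughly 30–37%
of the columns of *any* random gapped alignment score positively under
BLOSUM62, so the similarity threshold by itself has almost no power
against chance; discrimination comes from the coverage floor. Chance
alignments long enough to cross it arise almost exclusively inside long
stop-free translation windows — which planted orthologs and decoy ORFs
necessarily create, just as real coding regions do. Measured on the
generator at full scale, about 0.2% of enzyme × genome searches (4 in
~2,000) produce such a crossing (scores 52–74, similarity 31–37%,
coverage 50–58%, each score confirmed independently by
`Biostrings::pairwiseAlignment`). A full 26 × 9 matrix therefore carries
roughly a one-in-three chance of a single spurious presence call
somewhere; when that call lands in the enriched genome it adds a second,
spurious essential candidate. BLAST suppresses exactly these hits with
E-value statistics, which are out of scope here; the package instead
reports the alignments behind every call so borderline cells can be
inspected.

## Essentiality set logic

Given roles for every genome (`enriched_genus`, `nondegrader_isolate`,
`other`), each enzyme is classified as

* `essential_candidate` — present in ≥ 1 enriched genome (configurably:
  all) and in **no** isolate;
* `shared`, `isolate_only`, or `absent` otherwise.

No statistical test is attached: with one enriched genome and eight
isolates there is nothing to test, and the original deduction is exactly
this set intersection. Adding isolate evidence can only shrink the
candidate set — the direction in which more culturing makes the inference
stricter.

## Community profiling

Relative abundance is reads-of-genus over total reads per sample per day;
an `Other` row keeps each day's fractions summing to one. A degradation
curve is labelled `degraded` when the final concentration is ≤ 10% of the
initial (configurable), and its onset day is the first day below 90% of
initial — the end of the lag (adaptation) phase.

"Enrichment" is nowhere quantified in the motivating observations, so the
package states its own policy: a genus is enriched within a group when in
*every* sample of that group its peak abundance reaches 5% and exceeds 5×
its day-0 baseline (floored at one read's worth of abundance so that
zero baselines do not divide away). A genus is *degradation-associated*
when enriched among degraders and not among non-degraders — the exclusion
arm matters, since some genera bloom under the compound in both degrading
and non-degrading water and must not be credited to degradation.

## Motif stage

Families of N-methyltransferase homologs are aligned with a center-star
MSA built on the same pairwise engine (global mode): the center maximises
summed pairwise scores, others are merged under "once a gap, always a
gap", and merging proceeds in id order so the result is independent of
input order. Center-star trades a bounded loss of alignment quality for
exact determinism, which is the right trade for motif coordinates.
Column conservation is the modal-residue fraction with gaps counting
against conservation. `scan_motif` then slides a wildcard pattern
(`GCGxG`; `x` matches any residue, gaps match nothing) over the columns
and reports windows matched by at least 80% of sequences — the glycine-rich
cofactor-binding motif of these methyltransferases sits at the active site
and survives far more divergence than the rest of the sequence.

## Hit-table summary

For the genus-level distribution of homologs, the top 500 hits by
similarity are taken (ties broken by subject id) and per-genus percentages
are computed **on the genus-resolved denominator**: with 219 of 500 hits
resolved to a genus and 11 of them *Methylotenera*, the share is
11/219 = 5.02%, not 11/500 = 2.20%. Only the resolved denominator
reproduces the quoted 5.02%, which is why both counts are always reported.
Percentages round half-up to two decimals.

## The synthetic generator — what it does and does not show

All tests run on generated data with known truth, because the original
genomes and search outputs are not redistributable inputs of this package.
The generator's defaults *are* the study conditions:

| parameter | default | why |
|---|---|---|
| pathway size | 26 enzymes, labels "1".."26" | numbered pathway with subsets {1,2,3,9,24} / {1,2,3,24} |
| enriched subset | {1, 2, 3, 9, 24} | enzymes found in the enriched genus |
| isolate subset | {1, 2, 3, 24} | enzymes found in all cultivable isolates |
| planted identity | 60% | mid-range ortholog divergence, comfortably above the rule |
| genome length | 50 kb | large enough for realistic chance-hit background |
| isolates | 8 (5 *Pseudomonas*, 2 *Sphingobacterium*, 1 *Agrobacterium*) | the isolate panel's genus tallies |
| decoy ORFs | 0.1 per kb, 250 aa | unrelated coding background |
| amplicon days | 0, 3, 6, 10, 14 at depth 20,000 | the sampling grid |
| curve | 100 µg/mL, 5-day lag, decay to ≈1% by day 8 | lag-then-rapid-decay shape |

Orthologs are planted by seeded mutation (distinct positions, uniform
replacement residues) followed by reverse translation with uniform
synonymous codons, on a random strand and frame. Uniform — not
BLOSUM-biased — replacements are a deliberate choice: conservative
replacements would make even 15%-identity mutants score like close
homologs, destroying the sharp detection boundary the calibration relies
on; at ≥ 45% identity detection is carried by identity itself either way.
Community dynamics are piecewise-linear genus templates with multinomial
read noise (no kinetic model is implied by the data being emulated); the
focal genus peaks at day 3 in degrading samples only, a successor genus
rises after day 3, and a control genus blooms in both groups.

Passing on this generator demonstrates that the pipeline's logic recovers
planted truth under realistic noise, divergence, strand/frame placement
and decoy background. It does **not** demonstrate performance on real
genomes, where gene fragmentation, compositional bias, paralogy and
horizontally transferred near-duplicates can all blur presence calls;
those failure modes are listed, not simulated.

## Numerical and degenerate-input choices

* Day fractions must sum to 1 within 1e−9; a zero-read day is an error
  (there is no defensible imputation).
* `mutate_protein` errors when the identity target is unreachable within
  ±2 points at the sequence's granularity (e.g. 5% on a 10-mer).
* A zero-score best hit is "absent", not an alignment with empty strings.
* Reported problem sizes in tests: module tests use 6–12 kb genomes and
  80–200 residue proteins; the acceptance suite runs the full 50 kb / 300
  residue defaults, ten end-to-end replicates, and the 50 + 100 replicate
  calibration.

## Known limitations

* Presence is judged on the single maximum-score alignment; a
  lower-scoring but higher-coverage secondary alignment never rescues a
  call (acceptable at the default thresholds, visible near the boundary).
* Center-star MSA is not profile-quality; for gappy, low-identity
  families, motif columns may fragment.
* Six-frame search has no splice/frameshift recovery: a planted gene is
  assumed intact within one frame, as bacterial genes are.
* The essentiality logic treats presence calls as exchangeable evidence;
  it does not weight by alignment quality or genome completeness.
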