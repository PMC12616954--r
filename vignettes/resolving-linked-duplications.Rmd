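---
title: "Resolving linked interspersed duplications with optical-map spanning molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving linked interspersed duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogmtopo)
```

## The problem

Interspersed chromosomal duplications — two or more duplicated segments
separated by copy-neutral (NML) sequence whose extra copies are physically
joined by abnormal junctions — are a recurrent outcome of replicative
repair (chromoanasynthesis). Short-read sequencing pins down the
duplicated intervals, their copy numbers, and the oriented break junctions
to base-pair precision, but it cannot say *where the extra copies sit*: for
the simplest DUP-NML-DUP event there are already three derivative
structures (two cis arrangements and one involving both homologues) that
produce identical read-depth and junction evidence, and for more complex
events the catalog grows quickly. The arrangements can place the same
duplicated enhancer or gene into very different regulatory neighbourhoods,
so resolving the true structure matters for pathogenicity assessment and
recurrence-risk counselling.

Optical genome mapping (OGM) images fluorescent labels at a sequence motif
along intact DNA molecules hundreds of kilobases long. A single molecule
that *completely spans* one copy of a duplicated segment also shows the
label pattern of the flanking sequence on both sides, and that
left-context / spanned-copy / right-context triple — the **spanning
signature** — discriminates between candidate structures. This package
implements that reasoning as a reusable pipeline:

1. **`rearrangement model`** — segment and junction tables (TSV, VCF
   breakend import, BED export), reference tiling into copy-neutral blocks
   and telomere anchors;
2. **`topology enumeration`** — all derivative-chromosome structures
   compatible with the junctions and copy-number gains
   (`enumerate_archetype()`, `enumerate_general()`);
3. **`signature analysis`** — the abnormal spanning signatures of each
   structure, their diagnostic uniqueness, and the segments that must be
   spanned to decide a structure pair (`derive_signatures()`,
   `diagnostic_matrix()`, `required_spans()`);
4. **`OGM synthesis`** — label-map assembly and a synthetic molecule
   generator with realistic noise (`make_fixture()`, `sample_molecules()`);
5. **`molecule classification`** — a banded dynamic-programming aligner
   plus the informative-molecule criterion (`classify_set()`);
6. **`resolution and power`** — set-logical structure resolution from
   signature counts and the expected spanning-molecule yield as a function
   of duplication size (`resolve_structures()`, `expected_spanning()`,
   `estimate_size_limit()`).

## The enumeration model

A configuration is the reference tiling of each involved chromosome into
telomere anchors, copy-neutral blocks and duplicated segments, plus a set
of junctions given as oriented segment pairs (`+13.3:+13.1` means a
forward copy of 13.3 is immediately followed by a forward copy of 13.1;
junctions are symmetric under reading direction and are normalized to
unordered breakend pairs). A candidate structure is one or two *derivative
haplotypes*: walks over oriented copies of the tiles that start at a pter
anchor and end at a qter anchor, both forward — nothing lies beyond a
telomere, so anchors can never invert.

Diploid accounting fixes the copy budgets: with `h` modified homologues of
a chromosome, each segment must appear `gain + h` times across the
modified walks, so that modified plus unmodified homologues together carry
`2 + gain` copies. Each junction is used exactly once (each was observed
once), and consecutive copies must be joined either by the reference
adjacency (traversed in the walk's current orientation, which is how
inverted copy-neutral blocks arise between two junctions) or by an unused
junction whose breakends match the abutting copy edges.

`enumerate_general()` performs a depth-first walk over this breakpoint
multigraph and is the reference implementation; `brute_force_oracle()`
re-derives the same sets by exhaustive sequence enumeration with a
pairwise validity filter and is used in the tests. For the archetype case
(all junctions chain into a single cycle — the *cassette* — and all gains
are 1), `enumerate_archetype()` constructs the catalog directly: one cis
structure per resolvable cut segment (cutting the cycle at a segment
inserts the remaining cassette copies at that segment's locus) plus one
two-homologue (trans) structure per pair of resolvable cut segments that
carry the same orientation in the cycle. The orientation condition is not
cosmetic: an arc that arrives at its second cut segment inverted cannot
rejoin the reference and terminate at a forward telomere, and such pairs
fail copy-count validation. For cycles of direct duplications this count
reduces to `k + choose(k, 2)` over the `k` resolvable segments, giving the
familiar three alternatives for a two-segment cassette.

Worked example (bundled case 1: 323 kb + 148 bp inverted + 244 kb linked
duplications on chromosome 13):

```{r case1}
cfg <- case_config("case1")
sts <- case_structures("case1", config = cfg)
cat(render_structure(sts$Alt2), sep = "\n")
derive_signatures(sts$Alt2, cfg, resolution_bp = 500)[, c("signature", "target", "size")]
```

Structure labels for the bundled cases follow the published figure
panels of the corresponding case reports; the label-to-cut-site mapping is
stored with the case registry because panel order is presentation
metadata, not derivable from coordinates.

For the bundled chromoanasynthesis case (four duplications plus a
triplication on chromosome 20, inherited, so only one homologue can be
involved), the general enumerator returns 12 structures, of which 4 carry
the central 2.3 Mb copy-neutral block inverted — enumeration under exact
copy-neutral accounting reproduces the published catalog size exactly.

## Spanning signatures and their resolution logic

For every copy of a duplicated segment at least `resolution_bp` long
(default 500 bp, the practical resolving power of the labelling chemistry
— segments below it, like the 148 bp sliver in case 1, are collapsed),
the flanking context on each side is `NML` if the walk continues along the
reference in the copy's own orientation, and otherwise the first
resolvable segment encountered. Only abnormal triples (at least one
non-NML side) are reported. Because molecules are unoriented, a signature
equals its reversal with all orientations flipped; between the two
equivalent forms we canonicalize to the one with more forward-oriented
elements (tie: target forward). This keeps classes such as `16-17-NML`
and `NML-17-16` distinct — they differ in the relative orientation of
context and target, and they are genuinely different molecule readings —
while printing an inverted sub-resolution target in reference order
(`13.1-13.2-13.3`). Class identity for counting is the canonical display
label.

`resolve_structures()` is deliberately set-logical, not probabilistic: a
candidate is excluded as soon as an observed class (with at least
`min_support` molecules) is absent from its signature set, mirroring how
such evidence is read in practice. The default `min_support = 1` means a
single clean molecule excludes; source analyses acted on 3–5 molecules,
and we recommend reporting counts rather than auto-deciding below 3. For
tied candidates the report lists `required_spans()` — the segments whose
spanning would decide the pair — and notes when the smallest deciding
span exceeds a feasibility bound (default 550 kb) so that an orthogonal
method such as FISH is advisable.

## The synthetic-data generator

No public single-molecule data accompany the bundled cases, so the
generator produces labelled molecules from candidate structures with the
noise characteristics that matter for this analysis:

* **label density**: homogeneous Poisson labels, mean spacing 5 kb (one
  label per several kb, typical of DLE-1-style chemistry), merged below
  the 500 bp instrument resolution; each segment's label set is drawn once
  and reused wherever the segment appears, so duplicated copies are
  indistinguishable by content — exactly the property that makes the
  problem hard;
* **molecule lengths**: geometric over 100 kb bins (survival 0.5 per bin,
  inside the 35–55% per-bin decline band seen in real molecule sets) above
  a 150 kb minimum;
* **noise**: 10% label dropout, 0.8 false labels per 100 kb, 2% sizing
  error per inter-label interval, and 1% chimeric molecules (two
  independent fragments read as one);
* **reads are unoriented**: direction is random and unrecorded, forcing
  reversal-aware alignment downstream.

None of these values is a measured instrument constant; they are declared,
configurable assumptions chosen once to be realistic for routine runs.
The generator does **not** model raw images, instrument QC, or any
sequence-level feature (SNVs that could phase non-identical copies are
out of scope), so passing tests demonstrate correctness of the
reconstruction logic under the stated noise model, not instrument-level
fidelity. Scenario geometries (`make_fixture()`) are reduced-scale
analogues (maps of 2–5 Mb) of the bundled cases so that simulation and
classification stay fast; they keep the qualitative ordering — a small
spannable duplication, a large unspannable one, a sub-resolution inverted
sliver, an adjacent triplication block.

## Molecule classification

`align_molecule()` is a banded dynamic program over molecule/map label
indices: matched pairs score by relative inter-label interval agreement,
skipped map labels and unmatched molecule labels pay penalties, the
molecule aligns near-globally and the map end-free. It is implemented in
C++ and checked against an exhaustive placement oracle in the tests.

A molecule is **informative** for a signature when (criterion 1) its
placement fully spans the duplicated-segment copy with at least
`min_flank_labels = 4` matched labels on each flank, and (criterion 2) the
reference pattern appears on at most one flank — copies with reference
context on both sides are **reference-like**. "Distinctively matched" is
operationalized through competing placements: every placement within a 5%
score margin of the best must imply the same reading (the same signature
set, or reference-like, or nothing); disagreement yields an
`uninformative` verdict. This conservative rule is what protects the
set-logical resolution step from single miscalled molecules.

Chimeric molecules are the main hazard: a composite of two genuine
fragments can align end-to-end to the *wrong* candidate map and fabricate
an exclusive signature. Three defenses are applied, in order: a label
density check (overall or in any 50 kb window, against 3x the densest map),
a split-alignment check (a long unexplained label block at a molecule
end), and an interval-break scan along the matched pairs (one gross
molecule/map interval disagreement, or a cluster of at least three
>1.5 kb disagreements within ten transitions — far beyond the 2% sizing
noise or the 250 bp label-merge displacement). Readings must additionally
explain at least 75% of the molecule's labels at a score of at least 0.65
per matched label; clean placements sit near 0.85–0.9.

## Power: how large a duplication can be resolved

A molecule informs on a duplication of size `D` only if it spans
`S = D + 2F`, where `F` is the bp-equivalent of the flank requirement
(default 4 labels x 5 kb spacing = 20 kb). For molecules dropped uniformly
over a genome of length `G`, a molecule of length `L` spans a fixed such
interval with probability `max(0, L - S) / G`, so the expected informative
count is the sum of interval excesses — evaluated in closed form under
the geometric length model (exact per-bin integration) or by Monte-Carlo
placement, which agree within simulation error. `estimate_size_limit()`
bisects (1 kb granularity; the expected count is strictly decreasing in
`D`) for the largest `D` keeping the expected count above `min_count`,
and reports its inputs alongside the estimate — the limit is a property
of the configured length distribution, coverage and flank rule, not an
instrument constant. With study-like settings (400x coverage, 4-label
flanks, survival 0.5, 150 kb minimum length) the limit falls in the
several-hundred-kb range:

```{r power}
estimate_size_limit(length_model_geometric(), coverage = 400,
                    F_bp = 4 * 5000, min_count = 3)
```

## Numerical and design choices

* Coordinates are 1-based inclusive; `size = end - start + 1` (validated
  against all bundled printed sizes). BED export converts to 0-based
  half-open at the boundary. Thousands separators and unicode minus signs
  are accepted on input, never emitted.
* Copy number is stored as `gain` relative to one reference haplotype
  (a printed copy number of 3 on the rearranged complement is `gain = 2`).
* Gap tiles below 1 bp are dropped, so adjacent duplications share an
  edge with no intervening copy-neutral tile.
* Junction multiplicity is fixed at one use per junction; enumeration is
  deterministic (DFS ordered by junction id and reference adjacency,
  output sorted by canonical key) and capped at 10,000 structures.
* Chromosome lengths and centromere positions are configuration inputs
  with bundled defaults; a centromere-count check (exactly one per
  derivative) applies only when positions are supplied.
* Test and acceptance runs use reduced problem sizes chosen for quick
  iteration: 2 Mb generic maps at 35x coverage for replicate studies,
  5 Mb maps for the large-duplication scenarios; the classifier
  pre-filters molecules below the smallest informative span, the same
  down-sampling-to-long-molecules step used on real data.

## Known limitations

* The resolution step is set-logical; no likelihood over miscalled
  signatures is computed, so borderline evidence should be read from the
  reported counts, not the verdict alone.
* The aligner is a deliberately simple banded DP, adequate for simulated
  label data; it is not a replacement for a production OGM assembler and
  has no consensus/assembly stage, so pileup haplotype-switching artefacts
  of automated assembly pipelines are out of scope (and are one reason
  spanning-molecule reasoning is needed in the first place).
* Mechanism annotations (MMBIR/NHEJ and chromosomal-origin phasing) are
  carried as free text only; no mechanism inference is attempted.
* The chimera defenses are heuristics tuned to the declared noise model;
  grossly different instrument behaviour would need re-tuning.
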