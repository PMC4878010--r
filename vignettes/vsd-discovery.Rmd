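---
title: "Discovering voltage-sensing domains and designing chimeric voltage indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering voltage-sensing domains and designing chimeric voltage indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdscout)
```

## The problem

Voltage-sensing domains (VSDs) are four-helix transmembrane bundles
(S1–S4) whose S4 helix carries the gating charges that move with
membrane potential. They are the engine of voltage-gated channels and
of genetically encoded voltage indicators (GEVIs), where a VSD is fused
to a fluorescent protein. Finding new VSDs in sequenced genomes is
attractive because each voltage-sensor family tunes its S4 charges
differently, and a more diverse donor pool means more raw material for
sensor engineering.

`vsdscout` implements a sequence-only discovery strategy built on a
conserved S2-helix architecture rather than on S4 charges: a bulky
hydrophobic anchor residue, an acidic residue three positions
downstream, and a basic residue seven positions downstream. Searching
on S2 avoids biasing the hit list toward any one family's S4 charge
pattern; the S4 periodicity is then used afterwards, to *classify* the
hits.

## The motif scanner

`scan_motif()` applies the pattern

* strict: `F x x [E,D] x x x [R,K]`
* relaxed: `[F,Y,W] x x [E,D] x x x [R,K]`

at every position, reporting all (including overlapping) occurrences
with 1-based coordinates. Relaxing the anchor to Y/W widens the net —
for example to plant voltage sensors — at the cost of specificity, so
the mode is explicit everywhere and relaxed hits always form a superset
of strict hits.

Masked residues are handled conservatively: `X` never satisfies any of
the eight motif positions, wildcards included. A masked stretch can
therefore hide a motif but never fabricate one. The scanner is checked
against a brute-force per-position oracle (exact hit-set equality on
random sequences) in the test suite.

## Transmembrane helix prediction

The architecture caller needs to know where membrane-spanning helices
are. This module predicts them from windowed Kyte–Doolittle hydropathy:
`hydropathy_profile()` computes the mean scale value in a sliding
window (scores defined only where the full window fits), and
`predict_tm_helices()` calls maximal runs of window centres at or above
a threshold, merges runs separated by fewer than `min_gap` residues,
and discards merged runs shorter than `min_helix_len`.

Defaults — window 19, threshold 1.6, minimum length 15, gap 3 — are the
standard operating point of the Kyte–Doolittle scale for
membrane-spanning segments; all four are exposed in the run
configuration. This is a deliberately simple, fully documented stand-in
for HMM-based topology predictors: it predicts no loop orientation and
no signal peptides, only candidate helix spans, which is the only
information the architecture caller consumes. `X` residues score 0 so
masked positions neither promote nor suppress a helix call.

Two numerical details are intentional. Scores are compared to the
threshold with a `1e-9` tolerance so a window whose mean lands exactly
on the threshold is treated identically regardless of floating-point
summation order (this keeps predictions exactly mirror-symmetric under
sequence reversal). And merging runs before applying the length filter
means two above-threshold stretches interrupted by a 1–2-residue dip
are treated as one helix, which is how such dips behave in smoothed
hydropathy profiles.

## Architecture assembly

`assemble_vsd()` turns motif hits and helices into S1–S4 calls. A hit
whose full 8-residue span lies inside a helix nominates it as S2; the
nearest preceding helix becomes S1 and the two nearest following
helices S3 and S4. When several helices could serve, the nearest are
chosen — a deterministic proximity rule. Calls are vetoed when any
inter-helix loop exceeds `max_loop` (default 80 residues) or the
S1-start…S4-end extent exceeds `max_span` (default 300): VSDs are
compact bundles, and without bounds the caller would happily chain
helices across unrelated domains of a multi-domain protein. The bounds
are configuration-exposed; the defaults accommodate every natural VSD
architecture we are aware of with generous margin. Multiple motif hits
inside one helix yield one candidate per hit (identical S1–S4 spans can
be deduplicated downstream).

## S4 fingerprinting and family classification

`fingerprint_s4()` records the positions of R and K in the S4 sequence,
their successive spacings and their count. Histidine is excluded from
the fingerprint — it is only partially charged at physiological pH —
except where a template slot explicitly admits it.

`classify_s4()` matches slot-list templates contiguously at every
offset. Exactly two templates are built in, the two families whose S4
consensus is textually established: Hv (`R-x-x-R-x-x-R`) and VSP
(`R-x-x-R-x-x-I-x-x-R-x-x-(R/H)`). Consensus patterns for Nav/Kv/Cav
are deliberately *not* invented; they can be supplied as user templates
(`read_s4_templates()`, `--templates`). Basic slots admit R or K by
default, mirroring the R/K equivalence the S2 motif itself uses; a
`strict_arg` flag restores arginine-only matching. The VSP terminal
slot admits R or H in either case. The label is taken from the longest
matching template (longer patterns constrain more positions, so length
stands in for specificity), ties broken by declaration order; with no
match the call is `unclassified`. Note that a VSP match whose terminal
slot is occupied by histidine contributes only three R/K residues to
the fingerprint, not four.

## Candidate clustering

`nj_tree()` clusters candidate VSD spans: pairwise global
Needleman–Wunsch alignment (BLOSUM62; affine gaps, a length-L run
costing `gap_open + L * gap_extend`, defaults −10/−1), p-distance (the
mismatch fraction over columns ungapped in both sequences; a fully
gap-separated pair is assigned distance 1 with a warning), and
neighbor joining. The NJ implementation is deterministic: Q-criterion
ties are broken by the lowest (row, column) index pair in current label
order, and negative intermediate branch lengths are clamped to zero
with the deficit shifted to the sister branch so the pair sum is
preserved. On additive matrices it reconstructs the generating topology
and branch lengths exactly (tested to 1e-9 against trees the distances
were generated from, and cross-checked against an independent NJ
implementation). Trees are emitted unrooted with a basal trifurcation
and serialized to Newick at full double precision, quoting labels that
contain reserved characters.

This pairwise-distance route replaces progressive multiple alignment:
it is fully specifiable and testable against closed forms, which
matters more for the clustering role the tree plays here than MSA-grade
alignment quality. No bootstrap values, likelihood models or tree
drawing are provided.

## Chimera design

`build_chimera()` swaps a donor candidate's S1-start…S4-end span into a
scaffold sensor defined by three spans (N-terminus, VSD, linker+FP)
that partition its sequence. The product is a verbatim concatenation,
so the swap is exactly invertible — swapping the scaffold's own VSD
back reproduces the scaffold byte-for-byte — and the product length is
always `scaffold − scaffold-VSD + donor-VSD`. A part map records the
provenance and product coordinates of each segment, and
`flank_for_cloning()` annotates the swapped segment as the BamHI/EcoRV
cassette of the corresponding cloning scheme. Everything is
protein-level: reverse translation and codon optimization are out of
scope, and no scaffold sequence is bundled — scaffolds are user data.

## The synthetic proteome generator

`generate_planted_proteome()` emits proteins with known ground truth:
hydrophilic background (G/S/T/N at weights 0.40/0.30/0.28/0.02),
four planted hydrophobic helices (L/I/V/F at 0.30/0.30/0.30/0.10;
S1/S3/S4 25 residues, S2 27), a strict S2 motif centred in helix 2, and
an S4 segment built from the requested family template centred in helix
4, whose wildcard positions draw from I/V only. These compositions were
chosen by worst-case window arithmetic, not tuning: even an all-F helix
flanked by unusually hydrophilic background keeps every in-helix window
above threshold, and the charged motif/template residues cost less
hydropathy than the margin the compositions provide. That makes
noise-free recovery a sharp contract — on clean fixtures the pipeline
recovers 100% of planted architectures with the called S4 covering the
full charged core — rather than a statistical tendency.

At `mutation_rate > 0`, point substitutions land anywhere, including
the constrained motif and template slots, by design: the generator's
job includes exercising failure modes. Per-position mutation draws are
consumed whether or not they fire, so the mutation sets at two rates
under the same seed are nested and recovery is monotonically
non-increasing in the rate. The generator restores the caller's RNG
state and identical arguments give byte-identical output.

What the fixtures do *not* emulate: real amino-acid composition
statistics, homology structure between proteins, signal peptides,
re-entrant loops, or the length diversity of natural S4 helices.
Passing the planted-recovery tests therefore demonstrates the
pipeline's internal consistency, not its sensitivity/specificity on
real proteomes — on real data the hydropathy caller, not the motif, is
the accuracy bottleneck, and its simple threshold model will miss
marginal helices an HMM would catch.

## Problem sizes and runtime choices

The shipped test suite and the acceptance script run at the scale the
toolkit's contracts are stated for: 10,000 random 200-mers for
scanner-oracle equivalence, a 100-protein planted proteome (50 Hv, 50
VSP) for end-to-end recovery, 50 random 5–10-leaf additive matrices for
NJ exactness, 200 random length-≤8 pairs for exhaustive alignment
enumeration, and 20 random chimera round trips. These sizes keep the
brute-force oracles (which are exponential or quadratic by design)
comfortably tractable while being large enough that a systematic defect
cannot hide.

## Known limitations

* The helix caller is a windowed-hydropathy method, not an HMM; no
  topology states or orientations.
* Only Hv and VSP family templates ship; other families need user
  templates.
* Pairwise p-distance + NJ is a clustering device, not a phylogenetic
  inference; no support values.
* PHI-BLAST-style database homology search (scoring, E-values) is out
  of scope: the scanner applies the pattern directly to sequences you
  supply.
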