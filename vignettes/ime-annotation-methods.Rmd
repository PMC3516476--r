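---
title: "Methods: annotating integrative mobilizable elements on circular replicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating integrative mobilizable elements on circular replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imescan)
```

## The problem

Small plasmids that spread degradative gene clusters through soil bacteria
often behave as *integrative mobilizable elements* (IMEs): they carry a
vegetative replication origin (oriV) with tandem iterons, a DnaA box and an
AT-rich region; a transfer origin (oriT) recognisable as a hairpin in a
GC-rich context; an integrase whose attachment site (attP) is identical to
the 3' terminus of a host tRNA gene; and cargo bounded by Tn3-family
terminal repeats that can transpose as a composite unit.  None of these
signals requires similarity search against external databases — each is a
well-defined sequence property.  This package turns those properties into
deterministic detectors on a single circular-coordinate convention, plus a
truth-labelled generator so that every detector is testable end to end
without downloading anything.

All coordinates are 1-based inclusive; a feature spanning the circular
origin carries a wrap flag (end < start permitted).  External formats keep
their native conventions (GenBank/GFF3 1-based, BED 0-based half-open) and
are converted at the boundary.

## GC skew and the ori/ter call

For windows of length $w$ tiling the molecule at a fixed step, the raw skew
is $(G-C)/(G+C)$; windows without G or C are flagged degenerate and
contribute 0, keeping window indexing uniform.  The weighted variant
multiplies by $w/c$, the ratio of window length to total sequence length.
The origin is called at the minimum of the cumulative skew curve and the
terminus at the maximum; because the strand orientation of a deposited
plasmid is arbitrary, `predict_ori_ter(convention = "max_ori")` flips the
assignment.

One numerical choice matters on circles: the plain running sum depends on
where the deposited sequence happens to start, because any nonzero
whole-molecule skew adds a linear drift.  `window_skew()` therefore also
reports the *detrended* cumulative curve (running sum minus its linear
trend), and the ori/ter call uses it for circular molecules.  The
detrended curve is rotation-equivariant up to an additive constant, so the
argmin/argmax are well defined whatever rotation the record was deposited
in; this equivariance is verified by test on random circular sequences.
Defaults are $w = 500$ bp and step 100 bp; neither is critical for a
two-arm replichore structure, and both are exposed.

## att-site prediction

Candidate attP/attB sites are **maximal exact matches** between the 3'
terminus of a tRNA gene and the target replicon, on either strand, with
circular wrap honoured.  At the word lengths involved (a 10 bp floor, cores
typically 10-25 bp) with identity semantics, maximal exact matching *is*
the criterion, so no heuristic aligner is involved: a reported candidate
cannot be extended by one base on either end and remain exact.  `N` never
participates in a match.  By default the match must include the tRNA's 3'
terminal base (`require_terminus_anchor = TRUE`); a configurable offset
relaxes this for workflows that cross-reference externally predicted
genomic islands, whose intervals are consumed as BED.

Candidates are ranked, not thresholded, by an expectation score: the
expected number of equal-or-longer exact matches under a mononucleotide
null of the target,

$$E = S \cdot L \cdot \prod_{b \in \mathrm{core}} p(b),$$

with $S = 2$ when both strands are searched, $L$ the target length and
$p(\cdot)$ the target's base composition.  The score is deterministic,
strictly decreasing in match length for fixed composition, and calibrated:
over 1000 simulated targets the observed anchored-match count agrees with
the summed score within Monte-Carlo error (a packaged acceptance check).
Ties are broken by ascending target coordinate.

A candidate is *intergenic* iff its span overlaps no annotated CDS or tRNA
feature; intergenic candidates at low expectation score are the attP
calls.  `integrate_replicons()` then performs the Campbell-type single
crossover within the shared core: host up to the end of the attB core,
plasmid rotated to begin just after its attP core, a second core copy, and
the host remainder.  Length is conserved, the core is duplicated at the
attL/attR junctions, and `excise_cointegrate()` inverts the operation (the
plasmid returns up to rotation, which is all a circular molecule defines).

## Repeat detectors

**Inverted repeats** (oriT hairpins, operator sites, terminal repeats) are
reported in a canonical form: for each spacer interval of length up to
`max_spacer`, the arms are extended outward greedily within the
substitution budget, and trimmed so that both the innermost and the
outermost base pairs match.  This makes "maximal" well defined — exactly
one pair per qualifying spacer interval — while still reporting nested and
overlapping pairs.  The scan visits the middle copy of a tripled text on
circular molecules, so origin-crossing pairs are seen exactly once.  An
equivalent quadratic brute-force enumeration over all arm placements
serves as the oracle in the test suite.  For an oriT call, the pair with
minimal spacer among overlapping alternatives is the natural hairpin
report; alternatives remain in the table at larger spacers.

**Iterons** are tandem direct-repeat arrays: for each unit length in a
search range (default 15-25 bp, matching typical Rep-binding iterons), a
lag-$u$ self-comparison finds runs of at least three adjacent copies, each
within a per-copy substitution budget of the per-column majority
consensus.  Overlapping reports merge to the longest span; spans tie-break
to the array with the fewest total mismatches, then the smallest unit and
start — so an exact planted array wins over one-off phase-shifted variants
that a mismatch budget necessarily also admits.  A low-complexity guard
(Shannon entropy below 1 bit/symbol) suppresses homopolymer artifacts.

**Motifs** (the DnaA box, default consensus `TTATCCACA` with at most one
substitution) are scanned on both strands via `Biostrings::matchPattern`;
**AT-rich regions** are merged unions of sliding windows whose A+T
fraction reaches a threshold (default 50 bp at 0.8).

**Composite transposons**: all copies of a terminal repeat (a supplied
seed, or the longest de-novo inverted-repeat arm) are located on both
strands at a minimum identity (default 90%, i.e. 3 substitutions on a
canonical 38 bp Tn3-family repeat).  Transposon ends are inverted repeats
facing each other, so every plus-strand copy paired with a downstream
minus-strand copy bounds a unit; with three copies in +,+,- orientation
this yields exactly the nested outer and inner units of a composite
element.  When no opposed pair exists but two or more copies are present,
the span between the outermost copies is reported.

## ORF calling and statistics

ORFs are called in six frames with bacterial code 11 (stops TAA/TAG/TGA;
starts ATG/GTG/TTG).  Within each stop-to-stop segment, the reading from
the *first* start codon is reported — the longest-ORF convention that
replaces homology-based start correction, which is out of scope here.  On
circular molecules each strand is scanned over a doubled text and one
representative per circular position kept, so ORFs may wrap the origin;
the contract is pinned by a doubled-string brute-force oracle in the test
suite.  GC content is $100 (G+C)/(A+C+G+T)$ with N excluded from both
sides, reported to 2 decimals; coding density is the union of CDS spans
over the molecule length (overlaps counted once, wrap-around handled),
reported to 1 decimal.  `module_report()` groups features into
replication, partition/maintenance, mobilization, integration,
degradation and mobile-element modules by a configurable keyword map, and
cross-references the skew-based ori call against iteron arrays within
2 kb.

## The synthetic generator and what it does (not) show

`make_plasmid()` draws a 37 kb circular background i.i.d. at 62% GC with a
position-dependent G/C bias of amplitude 0.3 switching sign at the planted
ori and ter — two replichore arms, no higher-order structure.  Into it are
planted, at fixed default coordinates laid out like a degradative IME: a
4 x 21 bp iteron array, the DnaA box, an 80 bp AT-rich window, a 12+6+12
oriT hairpin in GC-rich context, a 14 bp att core in an intergenic gap
near the integrase region, and three copies of a 38 bp terminal repeat in
+,+,- orientation (nested transposable units).  CDS features fill the gaps
to roughly 90% coding density.  `make_host()` places a tRNA gene whose 3'
terminus ends in the shared att core into a 20 kb host.

Three generator details exist so that the truth table means what it says.
Guard bases flanking the hairpin and the iteron array break accidental
outward extension and periodic phase shifts, so exact-coordinate recovery
is well defined.  The AT-rich payload is drawn with its *exact* declared
composition (e.g. 72 of 80 bases A/T at fraction 0.9) rather than
binomially, so the planted window is AT-rich in fact and every 50 bp
subwindow clears a 0.8 threshold by construction; a binomially drawn
window would occasionally contradict its own truth label.  Finally, the
generator checks that planted payloads occur uniquely on the molecule and
redraws (deterministically, from the seed) on the rare collision.

Generation is seeded everywhere; there is no unseeded path.  Because the
background is i.i.d., passing recovery tests demonstrates detector
correctness and ranking behaviour under realistic composition and length —
it does *not* demonstrate robustness to repeat-rich natural backgrounds,
codon structure, or horizontally acquired composition mosaics, which real
plasmids have and the null model deliberately omits.

## Problem sizes and tolerances

The packaged checks run the detectors at full scale (37 kb plasmids, 20
generator seeds) but keep oracle comparisons at sizes where exhaustive
enumeration is exact and fast: att matching versus a suffix-by-position
oracle on 200 instances up to 5 kb, inverted repeats versus the quadratic
oracle on 100 instances of 2 kb, ORFs and circular subsequence versus
doubled-string oracles on toys of a few hundred bp.  Skew recovery is
asserted to one window (500 bp); exact-match detectors to 0 bp; the
composition-based AT-rich interval to one window of slack on each
boundary; match-count calibration to three standard errors over 1000
replicates.

## Known limitations

- GenBank support is a deliberately minimal flat-file subset (LOCUS
  topology, feature locations including origin-spanning `join`s,
  qualifiers, ORIGIN); records using exotic location operators will not
  round-trip.
- Features spanning the origin are exported to GFF3 as two segments
  sharing an ID; re-import does not re-join them.
- The expectation score uses a mononucleotide null; it is a ranking
  device, not a significance test against structured backgrounds.
- `find_iterons` reports arrays that fit within the scanned extension of a
  circular molecule (eight unit lengths past the origin); arrays longer
  than that which also span the origin are truncated.
- Genomic-island prediction is out of scope; GI intervals are consumed as
  BED input only.
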