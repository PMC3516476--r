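# imescan

Sequence-based annotation of small circular replicons that spread as
**integrative mobilizable elements (IMEs)** — plasmids that cannot
self-transfer but carry an oriT for mobilization and an integrase/attP
pair for chromosomal integration, typically alongside a degradative cargo
bounded by Tn3-family terminal repeats.  The package is aimed at
plasmid/mobile-element bioinformaticians who want the signature elements
of such replicons called from sequence alone, deterministically and
offline.

## What it computes

* **Replication origin/terminus from GC skew.**  Windowed raw skew
  $(G-C)/(G+C)$, the length-weighted variant $\times\, w/c$ (window over
  total length), and the cumulative curve; the origin is called at the
  cumulative minimum and the terminus at the maximum (the convention is
  flippable, since deposited strand orientation is arbitrary).  On
  circular molecules the call uses the detrended cumulative curve, which
  is rotation-equivariant.
* **attP/attB attachment sites** as maximal exact matches anchored at
  tRNA 3′ termini (≥ 10 bp by default), both strands, circular wrap
  honoured.  Candidates are ranked by an expectation score
  $E = S\,L\prod_b p(b)$ — the expected count of equal-or-longer matches
  under a mononucleotide null — and flagged as intergenic / inside
  externally supplied genomic-island intervals (BED).
  `integrate_replicons()` builds the Campbell-type cointegrate
  (length-conserving, core duplicated at attL/attR);
  `excise_cointegrate()` inverts it.
* **Repeats**: all maximal inverted-repeat pairs (oriT hairpins, operator
  sites) against a mismatch budget; tandem iteron arrays with per-column
  consensus and a low-complexity guard; DnaA-box motif scanning
  (`TTATCCACA`, ≤ 1 substitution by default); AT-rich windows; and
  composite-transposon delineation from terminal-repeat copies, reporting
  nested units when three copies occur in +,+,− orientation.
* **Annotation**: six-frame ORF calling (code 11, wrap-aware), GC content,
  coding density as the union of CDS spans, and a functional-module report
  grouping features into replication / partition / mobilization /
  integration / degradation / mobile-element modules.
* **Synthetic replicons with ground truth** (`make_plasmid()`,
  `make_host()`): a seeded ~37 kb circular plasmid with two skew arms, an
  oriV block (iterons + DnaA box + AT-rich window), an oriT hairpin, an
  intergenic att core shared with a host tRNA 3′ terminus, a
  terminal-repeat trio and ~90 % coding density — so the whole pipeline is
  testable with no downloads.

I/O: FASTA, GenBank flat file, GFF3 (+ companion FASTA), BED; one
1-based circular-coordinate convention internally, with explicit wrap
flags.  A thin command-line front end lives at
`inst/cli/ime-scan.R` (subcommands `convert`, `skew`, `repeats`,
`transposon`, `att`, `integrate`, `annotate`, `synth`, `all`).

## Worked example

```r
library(imescan)

pl <- make_plasmid(plasmid_spec(), seed = 42)   # 37 kb synthetic IME + truth
replicon_stats(pl$replicon)
#> <replicon stats> synthetic_plasmid: 37000 bp, GC 61.93%, 39 CDS, coding density 89.3%

predict_ori_ter(window_skew(pl$replicon, 500, 100))
#> <ori/ter call> ori @ 18950 (-54.9399), ter @ 450 (0.5549), confidence 55.4948
```

The planted replichore boundary sits at 19,000 bp; the call lands one
window-step away (18,950), with the terminus likewise within one window of
its planted position (500).  The confidence is the amplitude (max − min)
of the cumulative curve.

```r
find_iterons(pl$replicon, 15, 25, 3, 1)[, 1:5]
#>   start   end unit_length copies             consensus
#> 1 19100 19183          21      4 AACATGTCTTGTACGAACGGA

host <- make_host(pl$att_core, seed = 43,
                  upstream_base = substr(pl$replicon$sequence, 29999, 29999))
lib <- build_trna_library(host$replicon)
cands <- find_att_candidates(lib, pl$replicon, min_match_bp = 10)
cands[1, c("match_length", "target_start", "target_end", "expect_score")]
#>   match_length target_start target_end expect_score
#> 1           14        30000      30013 0.0004797423
```

The top-ranked candidate is the planted 14 bp att core at its exact
coordinates; its expectation score says ~5 × 10⁻⁴ such matches were
expected by chance on a molecule of this length and composition.

```r
delineate_transposon(pl$replicon, repeat_seed = pl$terminal_repeat)
#> <transposon calls> 3 terminal-repeat copies, 2 unit(s)
#>   unit_start unit_end left_copy right_copy nesting
#> 1       2000    16037         1          3   outer
#> 2       8000    16037         2          3  nested
```

Three terminal-repeat copies in +,+,− orientation delineate the composite
outer unit and the nested inner element, mirroring the architecture of
degradative transposons.  Campbell integration of the plasmid at the host
attB conserves total length (37,000 + 20,000 = 57,000 bp) and duplicates
the core at the attL/attR junctions.

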