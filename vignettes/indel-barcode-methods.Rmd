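---
title: "InDel barcode panels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{InDel barcode panels: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelbarcode)
```

## The identification problem

A germplasm collection of a selfing crop holds dozens to hundreds of
accessions that must be told apart reliably and cheaply. Markers typed
by PCR product size are the most laboratory-friendly option: an
insertion/deletion (InDel) of 10–20 bp inside a ~150–230 bp amplicon
shifts the band visibly on a 3% agarose gel, and because both alleles
amplify, heterozygotes show both bands — the marker is co-dominant.
`indelbarcode` covers the desk side of building such a system: marker
selection from resequencing variant calls, in-silico amplification,
profile encoding and barcoding, and panel-quality statistics.

## Variant model and zygosity accounting

Variants are biallelic, VCF-anchored length polymorphisms: one REF and
one ALT allele of different lengths, 1-based anchor coordinate.
Multi-allelic records are decomposed into one biallelic record per
alternate allele; a genotype allele belonging to a different alternate
is treated as missing for the decomposed record. Diploidy is assumed
(selfing crop material); a non-diploid GT is an error rather than a
silent reinterpretation.

The per-accession heterozygous rate is reported as
`het / (het + hom_alt)`: the share of heterozygous calls among the
variants at which an accession differs from the reference variety.
Reference-identical and missing calls are excluded from the denominator
because sites identical to the reference carry no evidence of residual
heterozygosity; the choice is stated here because other denominators
(all sites, all called sites) are defensible and would give much
smaller numbers. Panels derived from material advanced by single-seed
descent typically show rates near 0.10 under this definition, which is
the generator's default.

## Marker selection

The filter chain is a conjunction of three per-site predicates, applied
in a fixed order only so that the per-stage survivor counts and each
rejected site's attributed rule are reproducible:

1. **length**: `min_abs_len ≤ |len(alt) − len(ref)| ≤ max_abs_len`,
   default 10–20 bp. Shorter events do not separate on agarose; much
   longer events are rarer and amplify less evenly.
2. **panel zygosity**: no heterozygous call in the panel. A selection
   panel of inbred accessions should be homozygous at a trustworthy
   site; residual heterozygosity flags either outcrossing or an
   unreliable call.
3. **polymorphism**: at least one accession homozygous-alternate and at
   least one homozygous-reference, otherwise the marker cannot separate
   anything from the reference variety.

Because the outcome is a conjunction, reordering the stages cannot
change the surviving set — a property the test suite checks against an
independent predicate evaluation.

## In-silico PCR

Primer binding is modeled as Hamming matching on the aligned primer
with no indels in the binding site: the forward primer on the plus
strand, the reverse-complement of the reverse primer downstream. When
mismatches are allowed (`max_primer_mismatch > 0`), the 3'-terminal
base of each primer must still match exactly, since polymerase
extension from a mismatched 3' end generally fails. Product length runs
from the forward primer's 5' end to the reverse primer's 5' end,
inclusive of both primers. This is deliberately the simplest defensible
e-PCR semantics: no melting temperature, GC or secondary-structure
modeling — primer design itself is upstream of this package and is
consumed, not performed.

By default a marker must yield exactly one reference amplicon
(`max_products = 1`); the alternate-allele product is then predicted by
substituting the ALT allele into the template, and the two sizes differ
by exactly the absolute indel length (a conservation law the tests
enforce). The amplicon window of 150–231 bp keeps products separable
from primer dimers at the low end while retaining single-base-per-cm
resolution of 10–20 bp differences on agarose at the high end. Both
allele products must fit the window.

## Profile encoding and barcodes

Relative to the reference variety each marker call is one symbol:
`a` (same amplicon as the reference), `b` (different), `h` (both bands),
`-` (failed/missing). A profile over the ordered panel `TB1..TBn` maps
to a barcode: white cell for `a`, black for `b`. Two layouts are
provided: a 1D strip (one module per marker — deliberately *not* a
checksummed retail symbology, since the figure conveys marker states,
not EAN semantics) and a 2D block grid, default 5 × 10 filled row-major
in panel order, which displays a 50-marker panel compactly. The grid
dimensions and marker order are recorded in the image and in a JSON
sidecar so that decoding is lossless; `decode_barcode()` is the exact
inverse of `encode_barcode()` on `{a,b}` profiles for every layout with
`rows × cols ≥ n`.

Heterozygous and missing calls have no published binary rendering, so
the strict default refuses to encode them (naming the offending
markers); a lenient mode renders `h` half-tone and `-` light grey,
both excluded from homology computations.

## Panel statistics

Pattern frequencies are per-accession *pattern* shares at one marker —
each accession contributes one pattern (`a`, `b` or `h`), missing calls
leave the denominator. These are not chromosome-count allele
frequencies; with 73 accessions, counts such as 41/73 = 0.5616 are the
natural scale.

Two PIC forms are computed:

- simple: $\mathrm{PIC}_i = 1 - \sum_j p_{ij}^2$
- Botstein: $\mathrm{PIC}_i = 1 - \sum_j p_{ij}^2 -
  \sum_j \sum_{k>j} 2\, p_{ij}^2 p_{ik}^2$

Published InDel-panel statistics are frequently computed with the
Botstein form even where the simple formula is printed; at pattern
frequencies (0.5616, 0.4384) the two forms give 0.3712 and 0.4924
respectively, and panel tables reporting a maximum of 0.3712 at that
frequency are therefore Botstein-form values. For this reason
`panel_summary()` defaults to `pic_variant = "botstein"` and reports
both forms per locus. For a biallelic marker the Botstein form is
strictly decreasing in the major-pattern frequency on (0.5, 1], so the
panel's PIC range endpoints are attained by the loci with the extreme
major-pattern frequencies.

Homology between two profiles is the fraction of compared markers with
identical calls (missing excluded, the used denominator reported);
`1 − homology` is the simple-matching distance. The mean pairwise
difference is reported alongside the per-accession difference from the
reference profile because "average difference" is ambiguous between
the two; both are computed explicitly.

## Tree building and ordination

`nj_tree()` is canonical Saitou–Nei neighbor joining with the
Studier–Keppler Q-criterion. Weighted NJ variants exist in
distance-based phylogeny programs but are not specified precisely
enough in the applied literature to reimplement faithfully; canonical
NJ is the documented, reproducible baseline, and the choice is recorded
in the tree's `method` attribute. Determinism is guaranteed by breaking
Q ties (1e−12 relative tolerance) toward the lexicographically smallest
sorted label pair; negative branch lengths are clamped to zero with the
total deficit recorded as an attribute. Simple-matching distances can
violate the triangle inequality; nothing in the implementation assumes
it, and on additive matrices the generating tree is recovered exactly
(tested on simulated 5–12 leaf trees, and against an independent NJ
implementation with Robinson–Foulds distance 0 on random matrices).

PCA codes calls as alternate-dosage fractions (`a` = 0, `h` = 0.5,
`b` = 1), mean-imputes missing calls per locus, centers columns, and
eigendecomposes the covariance. Components are sign-fixed so the
largest-magnitude locus loading is positive, making coordinates
comparable across eigensolvers. Admixture/cluster inference itself is
out of scope; `write_structure()` exports the 2-rows-per-accession
integer format those tools consume (missing = −9).

## The synthetic generator: what it emulates and what it does not

`generate_panel()` emulates the *statistical shape* of a germplasm
resequencing study: 73 accessions, 50 planted markers with 10–20 bp
InDels inside 150–231 bp primer-flanked amplicons, per-locus
major-pattern frequencies drawn from 0.55–0.99, heterozygous calls at
10% of non-reference genotypes, and decoy variants that each violate
exactly one selection rule (length, panel heterozygosity,
monomorphism, or amplicon window — the last class carries its own
primers so only the amplicon filter can remove it). Reference fragments
are independent random sequences, one per marker region, rather than a
chromosome-scale genome: nothing in scope needs linkage, and desk-scale
fragments keep the full pipeline in seconds. `generate_matrix()` plants
per-locus major-pattern frequencies directly; its exact-count mode
assigns `round(p·n)` major-pattern accessions so printed count-based
frequencies (41/73, 72/73) are reproduced exactly, while sampling mode
draws i.i.d. calls for recovery and power checks.

What the generator does **not** emulate: linkage disequilibrium and
shared population structure across loci (each locus is drawn
independently, so synthetic trees have no geographic signal), sequencing
error and depth-dependent genotype quality, primer thermodynamics, and
gel-scoring noise. Passing tests on synthetic data therefore demonstrate
the correctness of the computations and the selection logic, not the
field performance of any particular wet-lab panel.

## Numerical and interface choices

- Coordinates are 1-based inclusive throughout (VCF/IRanges
  convention).
- Frequencies and statistics are kept at full double precision
  internally; tables are written at 4 decimals.
- Frequency vectors must sum to 1 within 1e−6; negative frequencies are
  errors, not clamped.
- A pair of profiles with zero comparable markers is an error naming
  the pair (silent NA distances would poison the NJ step downstream).
- Degenerate inputs: an all-reference accession gets heterozygous rate
  0 with an `undefined_rate` flag; a monomorphic marker has PIC 0; an
  all-identical matrix yields resolved-pair fraction 0.
- Problem sizes used in the tests (73 × 50 matrices, 500-decoy funnels,
  50-replicate tree checks, 200-template e-PCR oracle comparisons) were
  chosen as the smallest scales at which the binomial and combinatorial
  bounds being asserted are sharp; all complete in well under a minute.

## Known limitations

- The wet-lab attrition step of real panel building (candidate primer
  pairs failing PCR for reasons invisible in silico) is not modeled;
  the in-silico funnel recovers exactly the loci that satisfy the
  stated rules, no fewer.
- The e-PCR mismatch model is Hamming-only; primer-template bulges and
  thermodynamic effects are not considered.
- `h` handling in distances counts any `h`-vs-`a`/`b` comparison as a
  mismatch; dosage-aware distances are available only through the PCA
  coding.
- Canonical NJ is used where some published analyses use weighted NJ
  variants; topologies on well-separated panels agree, but branch
  lengths may differ from those programs.
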