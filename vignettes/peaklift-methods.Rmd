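---
title: "Migrating CAGE TSS peak sets across genome assemblies"
author: "peaklift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migrating CAGE TSS peak sets across genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaklift)
```

## The problem

CAGE sequencing reads the capped 5′ ends of transcripts; clustering the
observed single-base tag positions (CTSS) yields TSS peaks that stand in
for promoters. A promoter atlas built on one reference assembly accretes
identifiers, short names, annotations and expression tables, all of which
downstream users cite. When the reference assembly is updated, re-calling
peaks from scratch would orphan all of that; simply converting coordinates
would trust the lift blindly. `peaklift` takes the middle road used by
large promoter atlases: convert coordinates through alignment chains under
the strictest acceptance rule, then *verify* every converted peak against
the realigned read evidence, resolve the inconsistencies the conversion
itself introduces, merge in genuinely new peaks called on the new
assembly, and requantify.

## Chain lifting and the minMatch rule

A UCSC chain describes one pairwise alignment as ordered ungapped blocks
separated by `dt` (old-side) and `dq` (new-side) gaps; the old side is
always the plus strand, and minus-strand chains express the new side in
reverse-complement coordinates. `lift_interval()` selects, among chains on
the interval's chromosome, the one covering the most interval bases with
aligned blocks (ties: higher score, then lexicographically smaller chain
id — a tie at full coverage indicates a pathological chain file). With
coverage fraction below `min_match` the interval drops, with a reason:

* `unmapped` — no aligned base under any chain;
* `split` — only a combination of several chains reaches `min_match`
  (a single chain has a single target, so such intervals cannot be mapped
  coherently);
* `partial` — a single chain covers some but not enough.

Otherwise the first and last covered bases are mapped through block
arithmetic and the result spans their images. Two consequences are worth
stating explicitly. First, an interval straddling a `dq` gap *stretches*
by the insertion length — this is how "unintentional stretch" artefacts
arise, and why length changes are checked downstream. Second, with the
default `min_match = 1` an interval overlapping any `dt` gap (a deletion)
always drops; partial mapping only occurs when `min_match < 1`.

The implementation is validated against a brute-force oracle that maps
every base individually and takes the span — on random chains the two
agree exactly, including the matched fraction (see
`tests/testthat/test-chain_liftover.R` and the acceptance suite).

## QC classification

Checks run in a fixed order on the mapped peaks:

1. **Support.** A peak must contain, within its half-open interval, at
   least one pooled CTSS on its own strand with a positive tag count. The
   pooled (summed over all libraries) signal is used: any read evidence
   anywhere in the atlas counts, with no count threshold beyond ≥ 1. A
   converted peak without support usually sits in sequence that became
   duplicated in the new assembly, where realigned reads are discarded for
   ambiguous mapping.
2. **Length change.** Flagged when |new length − old length| > 1. The
   one-base tolerance is deliberate: single-base edge wobble is common and
   harmless, whereas multi-base stretches indicate an indel inside the
   peak.
3. **Overlap groups and resolution.** Converted peaks must not overlap on
   the same strand (their defining property at call time). Overlap groups
   are connected components (size ≥ 2) of the same-strand ≥ 1 bp overlap
   graph. Within a group, peaks are excluded greedily until no overlap
   remains, prioritising (i) length-changed members — the stretch case —
   then (ii) shorter members, with coordinate order breaking ties
   deterministically. This codifies the manual choices a curator makes
   ("keep the longer peak"); the curation table can override any of it.
4. **Curation.** `rescue_to_fair` and `keep_problematic` force a state;
   `set_interval` replaces the interval and re-runs the support check (a
   curated interval without evidence stays problematic, with a warning);
   `keep_as_is` records the inspection. Every override is appended to the
   peak's provenance string.

Every input peak ends in exactly one of fair / problematic / dropped; this
conservation, the pairwise non-overlap of the fair set, and the support of
every non-rescued fair peak are asserted globally in the test suite.

## Merging newly called peaks

Peaks called directly on the new assembly represent promoters in sequence
that did not exist (or was mis-assembled) before. A new peak joins the
merged set iff it overlaps no fair peak on the same strand by at least one
base — plain `-s` intersection semantics with no reciprocal-fraction
requirement, because a single shared base already indicates the same
promoter signal. The new set is required to be internally non-overlapping
(a property of the peak caller) and this is validated, not assumed.

## Identifiers

Coordinate IDs use BED coordinates verbatim (0-based, half-open) —
`chr1:564639..564649,+` — so an ID can be parsed back to the exact
interval. Accessions `hg_<serial>.<version>` decouple citation from
coordinates: serials are never reused, fresh serials continue from the
registry maximum in genomic sort order (the assignment order is otherwise
arbitrary; sorting makes reruns deterministic), and all first-round
versions are 1 (version bumps are reserved for future coordinate revisions
of the same peak). The full ID concatenates origin assembly, coordinate ID
and accession (`hg19::chr1:564639..564649,+;hg_2.1`), keeping backward
traceability in the name itself; peaks born on the new assembly use the
new assembly's label.

## Annotation

A transcript is a candidate for a peak when it lies on the same chromosome
and strand and its TSS falls within a flanking window of the peak: 500 bp
for Pol-II transcripts, 50 bp for 5′ ends not produced by Pol-II
initiation (snoRNA-like classes, whose 5′ ends are processing products
rather than initiation sites — a wide window would annotate them to
unrelated promoters). Windows are inclusive at exactly the boundary
("within 500 bp" read as ≤ 500). Distance is 0 inside the peak and
edge-to-TSS otherwise (signed, negative to the genomic left). All
minimum-distance transcripts are recorded; the gene/protein link follows
the priority winner (curated source rank, then transcript id —
deterministic). Gene symbols prefer the nomenclature symbol (HGNC/MGI) and
fall back to the bare gene id. Short names `p<serial>@<symbol>` keep any
carried-over prior name; new serials per gene are the smallest free ones,
assigned in descending pooled-expression order so `p1@X` is the strongest
promoter of X; unannotated peaks get `p@<coord_id>`.

## Quantification

Raw counts accumulate CTSS tags per peak and library (same strand,
half-open interval). RLE factors are the median across all-positive peaks
of the count/geometric-mean ratios, computed on raw counts (not
per-million values; the two differ only by factor scale) and rescaled to
geometric mean 1 so they are pure composition corrections. Even-length
medians are the arithmetic midpoint of the central ratios. TPM divides by
the genome-wide tag total times the factor, so editing the peak set never
perturbs the TPM of untouched peaks. `DESeq2`'s median-of-ratios
implementation serves as an independent cross-check in the tests.

## The synthetic fixture

`simulate_fixture(seed)` emulates the real inputs at desk scale: one
~120 kb chromosome, an edit script of substitutions, insertions,
deletions, duplications and inversions, and the chain set that encodes
exactly the unedited segments (deletions → `dt` gaps; insertions and
duplicated destination copies → `dq` gaps, the copy deliberately left
unchained to mimic ambiguous new sequence; substitutions → double-sided
gaps; inversions → an extra minus-strand chain). Planted peaks cover five
fates in controlled proportions (default 240 peaks: 60% clean, 10% each
dropped / unsupported / overlap / length-changed, plus 20 DPI peaks in
novel inserted sequence):

* *dropped* peaks sit inside deletions;
* *unsupported* peaks simply have their CTSS withheld;
* *length-changed* peaks straddle an insertion of ≥ 2 bp (under
  `min_match = 1` a deletion inside a peak drops it, so insertions are
  the only way a mapped peak changes length — matching the stretch
  artefacts seen in practice);
* *overlap* pairs are planted overlapping in unedited regions. In real
  migrations overlaps arise when distinct old loci fuse into one new
  locus, which no single-genome edit script can express under
  `min_match = 1`; planting the overlap directly exercises the identical
  detection/resolution code path, and is the one place the fixture input
  deviates from the ideal non-overlapping peak set.

CTSS counts follow a per-position base rate (uniform 5–50 for peak
positions, 1–5 for background) × per-library scale factor (default 1, 2,
4) × lognormal noise (σ = 0.05), Poisson-sampled — a
negative-binomial-like model whose known scales make RLE recovery a
parameter-recovery test rather than a tautology. Background positions in
peak-free zones keep library totals strictly larger than in-peak sums, so
the TPM denominator choice is exercised.

What the fixture does **not** emulate: locus fusion between assemblies
(above), read-level artefacts (mapping-quality filtering happens upstream
of the CTSS files), multi-chromosome chain files at scale, and realistic
genome repeat structure. Passing the truth-recovery tests therefore shows
the *logic* is right under the stated conditions, not that any particular
real migration is error-free.

## Numerical and design choices

* Coordinates are BED (0-based half-open) everywhere, in memory and on
  disk; nothing ever emits 1-based coordinates. The typographic minus
  (U+2212) occasionally found in published tables is normalised to `-` on
  input.
* Readers are strict by default — a malformed line is a hard error naming
  the line — with an opt-in skip-and-warn mode; for an archival migration,
  reproducibility beats permissiveness.
* Peaks lifting onto non-primary scaffolds are reported as mapped;
  restricting to primary chromosomes is a QC-level policy (filter by
  chromosome) rather than a lift-level one.
* `min_match` defaults to 1.0; the chain-selection tie-break (score, then
  chain id) only matters for pathological chain files.
* The OSC header metadata set is minimal (`FormatVersion`, `ValueType`,
  plus caller-supplied entries), as no richer schema is standardised.
* The pipeline consults no random source; reruns on identical inputs are
  byte-identical (asserted in the tests), and all fixture randomness flows
  from one seed.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 240-peak
fixtures on a ~120 kb chromosome with 3 libraries, 1,000-case random
chain/interval oracle comparisons, and 20–200-case property loops. These
sizes were chosen so the full suite characterises every code path in well
under a minute of compute per file; the algorithms are linear or
near-linear in peaks × chains and scale to atlas-sized inputs (hundreds of
thousands of peaks) without modification.

## Known limitations

* Overlap-after-lift via locus fusion is exercised through planted
  overlaps, not through multi-chain fusion fixtures (see above).
* `split` drops are detected per interval; the package does not attempt
  multi-chain stitching (deliberately, per the single-chain rule).
* Annotation consumes a prepared transcript table (TSS already 5′-end
  oriented); GTF parsing and biotype→class mapping are left to standard
  importers upstream.
* The registry models accession stability and version fields, but version
  increments for coordinate revisions of an existing peak are not driven
  by any shipped workflow step.
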