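---
title: "In silico AFLP marker landscapes: models, conventions and limits"
author: "aflpscan developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico AFLP marker landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An AFLP assay is, at its core, a deterministic function of a genome
sequence and an enzyme pair. `aflpscan` models it in four stages:

1. **Cut-site scanning.** Every occurrence of the recognition sequence on
   the top strand is a cut; for non-palindromic enzymes the reverse
   complement of the motif is scanned as well, because physical digestion
   is strand-symmetric. An occurrence containing any non-ACGT base never
   matches: digestion is undefined across un-sequenced nucleotides. A cut
   is represented as a single cut point, `occurrence start + cut offset`
   (mirrored, `start + length − offset`, for reverse-strand occurrences).
2. **Fragmentation and typing.** The two enzymes' cut points are merged
   per chromosome; each pair of adjacent cuts bounds one restriction
   fragment labelled by its flanking enzymes. Only fragments with one
   rare-cutter end and one frequent-cutter end (either orientation) can
   acquire both adapters and amplify, so only those are AFLP fragments.
   Chromosome-terminal segments have a single enzyme end and are dropped.
   Fragments containing non-ACGT bases are dropped.
3. **Size selection and selective nucleotides.** Fragments of 40–440 nt
   (inclusive; the standard experimental window, corresponding to
   72–472 nt PCR products after the 32 nt of adapters/primers) are kept.
   Optionally, a selective-nucleotide filter keeps a fragment only if the
   base immediately interior to each recognition remnant belongs to the
   allowed set for that end; the right-hand interior base is read as its
   complement because the selective primer anneals to the opposite strand.
   An allowed set containing all four bases constrains nothing; fragments
   too short to expose an interior base beyond both remnants cannot be
   selectively amplified and fail the filter.
4. **Band collapse.** Fragments with byte-identical sequences co-migrate
   and are scored as one electrophoretic band; the band's representative
   is the member with the lowest (chromosome order, start). Collapse is by
   *sequence*, not by length: with only 401 possible lengths in the
   selection window, length-collapse would cap the genome-wide band count
   at 401 and erase the landscape signal. Length-class collapse remains
   available (`collapse_bands(..., by = "length")`) for size-homoplasy
   studies.

## Statistics

With a marker set (fragments or bands) and a gene set:

* `pct_markers_within(d)` — the percentage of markers whose distance to the
  nearest gene is at most `d`. Distance is the interval gap in bp; `d = 0`
  means **overlap of at least one base** ("within the gene sequence or
  overlapping it"), so an interval merely touching a gene end-to-start is
  at distance 0 but not in the `d = 0` class. The classes are cumulative
  by construction.
* The **random expectation** of the `d = 0` marker percentage is the share
  of the sequenced genome covered by the union of gene intervals (N bases
  excluded from numerator and denominator): the hit probability of a
  uniformly placed marker.
* `pct_genes_with_marker_within(d)` — the gene-side marginal. A marker
  overlapping two genes counts once on the marker side and once for each
  gene; the two blocks are marginals over markers and over genes.
* The **Poisson expectation** of the `d = 0` gene percentage is
  100(1 − e^(−λ)) with λ the observed mean number of overlapping fragments
  per gene. It assumes equal gene lengths; with heterogeneous lengths the
  placement mixture is over-dispersed and the observed zero class exceeds
  the Poisson zero class (Jensen: E[e^(−λᵢ)] ≥ e^(−E λᵢ)), so observed
  gene-side percentages fall below this expectation. The per-gene count
  histogram (`gene_fragment_histogram`) shows the full comparison.
* Markers on chromosomes that carry no gene have infinite distance and
  stay in every denominator: they are real markers that are far from genes.
* **Landscapes** assign each feature to exactly one window by its start
  coordinate (bands by their representative's start); the final short
  window is kept and GC is normalised by its actual ACGT bases.
* The **density regression** is OLS of marker count on genome size in Mb,
  with intercept by default (a through-origin option exists); R² is the
  squared correlation. `markers_per_cM` is the pure unit conversion
  density/kb × kb/cM.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| size selection | 40–440 | nt | standard AFLP gel window; inclusive so that both bounds map to the 72/472 nt PCR anchors |
| PCR adapter addition | +32 | nt | fixed by the standard primer chemistry |
| window size | 200 000 | bp | the scale at which pericentromeric accumulation is visible; 100 kb supported |
| distance thresholds | 0, 1 k, 10 k (genome-wide); + 100 k (candidates) | bp | the scales relevant for linkage to selected loci |
| cut offsets | EcoRI G^AATTC 1, MseI T^TAA 1, TaqI T^CGA 1, SacI GAGCT^C 5, HpaII C^CGG 1, BsmI 6 | bp | documented cut chemistry where known; BsmI (cuts outside its site) is modelled at its 3′ recognition boundary. Offsets shift lengths by ≤ 5 bp and are configurable |

## Coordinate and tie conventions

* Internally everything is 1-based, closed — the Bioconductor convention —
  so `GRanges`/`IRanges` machinery applies directly. GFF3 is native; BED is
  converted on read; cut *points* are 0-based boundary counts (a fragment
  between cuts `a < b` occupies bases `[a+1, b]`, length `b − a`).
* If both enzymes cut at the same coordinate, the cut point carries both
  labels and satisfies whichever end the AFLP-type rule needs (rare-left
  preferred when both orientations qualify). This is vanishingly rare for
  the catalogue enzymes.
* Fragment lengths are cut-to-cut. Under asymmetric cut offsets this makes
  the *length* multiset change by a per-fragment constant (±2 bp for
  EcoRI/MseI) when a chromosome is reverse-complemented, because an E–M
  fragment becomes an M–E fragment; the strand-invariant quantity, which
  the test suite asserts, is the site-to-site span (fragment plus both
  recognition remnants). Fragment *identity and count* are invariant.
* All IUPAC ambiguity codes other than ACGT are excluded from GC and from
  site matching, but only runs of N are reported as un-sequenced intervals.
* A gene is the outermost span of a GFF3 `gene` feature; overlapping genes
  are kept as distinct records and their union is taken only where coverage
  is needed.

## The synthetic generator: what it emulates, what it does not

`generate_genome` draws intergenic bases i.i.d. at one GC and genic bases
at a higher GC — the single compositional contrast that drives every
directional effect the statistics measure (GC-rich recognition sites hit
genes more often; AT-rich sites hit intergenic DNA). Gene lengths are
log-normal with configurable mean/SD (defaults 2.1/1.6 kb, an
Arabidopsis-like regime, at ~280 genes/Mb with genic GC 0.393 vs intergenic
0.313); genes are placed uniformly without overlap by rejection sampling,
with an explicit infeasibility error. Pericentromeric arrays are exact
tandem copies of a unit carrying one rare and one frequent cut site spaced
to yield one AFLP fragment per copy; a post-write scan mutates away any
accidental site inside the unit or across tandem junctions so copy numbers
are exact. Planted cassettes (rare site + scrubbed filler + frequent site)
put single AFLP fragments at explicit coordinates, and an optional
genome-wide scrub removes *all* accidental sites of a pair, giving fully
deterministic marker landscapes for tests.

One geometric point deserves a note: a tandem unit of length `L` containing
one cut of each enzyme produces within-array fragments of lengths `d` and
`L − d` — a cut-to-cut fragment as long as the unit itself is impossible.
A 117-bp repeat unit therefore yields, e.g., an 80-bp marker fragment per
copy (the complementary 37-bp fragment falls below size selection); the
published centromeric repeat scenarios with ~unit-length products must have
arisen from longer units or a remnant-inclusive length convention. The
generator takes the planted fragment length as an explicit parameter.

What a green test on synthetic data does **not** establish: real genomes
have dinucleotide and codon structure, isochores, and repeat families —
none of which the i.i.d. model reproduces. Absolute marker counts and
percentages on real genomes will differ; the synthetic tests validate the
*computations* and the *directions* (GC bias, Poisson over-dispersion,
band-vs-fragment collapse), not species-specific values, which additionally
depend on assembly and annotation versions.

## Numerical and design choices

* Deterministic throughout: one seed controls the generator; digestion and
  statistics are seed-free functions of their inputs. The RNG state is
  restored after generation.
* Percentages are kept at full precision in objects; the table writers
  round the way comparative reports do (integers genome-wide, two decimals
  for candidate subsets, kb to one decimal).
* Empty-denominator cases (no markers, no genes, all-N windows, empty
  intergenic stratum) return `NA` with a warning rather than 0, except where
  the value is genuinely 0 (e.g. genes with no marker within `d`).
* Mean inter-marker distance is the mean of within-chromosome start-to-start
  gaps pooled over chromosomes; genome size / marker count is reported
  alongside as the coarse alternative.
* The deterministic acceptance scenario for the band-vs-fragment property
  plants a fixed number of cassettes per window under a genome-wide scrub,
  so the median window count is exact and the band-count bound is tested
  without Monte-Carlo slack.
* Whether "genes with a given number of fragments within their sequence"
  should mean overlap or full containment is ambiguous; overlap is used for
  consistency with the `d = 0` class (the λ that feeds the Poisson
  expectation counts the same overlap pairs).

## Known limitations

Partial digestion, methylation sensitivity (HpaII vs MspI), star activity,
amplification bias and gel mobility artefacts are out of scope; fragment
boundary conventions of legacy digestion software may differ from the
cut-to-cut convention by a few bp; genetic-map analyses are limited to the
markers-per-cM conversion.
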