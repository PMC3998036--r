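---
title: "splicewise: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicewise: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicewise)
```

This vignette documents the models and conventions behind `splicewise`: how
splicing events are defined and detected, how isoform fractions and
switches are computed, how the ORF/NMD annotation works, what the
synthetic-data generator does and does not emulate, and the design choices
made where the problem admitted more than one sensible answer.

## Coordinates

All internal coordinates are 0-based half-open `[start, end)`; interval
arithmetic (lengths, gaps, adjacency) then needs no ±1 corrections. The
GTF reader/writer and the genePred reader are the only code that converts
to and from 1-based inclusive coordinates, and the event table serializes
element coordinates 1-based inclusive (`chrom:start-end`) for browser
interoperability. Transcript coordinates are 0-based and run 5′→3′ in
transcript orientation, so position 0 on a minus-strand transcript is its
genomically 3′-most exonic base.

Book-ended exons (one ending where the next starts) are merged at parse
time with a warning: a zero-length intron is a file artifact, and a
reference "intron" must have positive length to be a retention candidate.

## The comparison reference

Events are defined relative to a per-gene reference:

* **pre-RNA** (`build_pre_rna()`): the union of every isoform's exons,
  overlapping or book-ended intervals merged. Its introns are exactly the
  gene-span regions exonic in *no* isoform.
* **most-expressed** (`select_most_expressed()`): the exon chain of the
  isoform with the highest expression in one user-named condition
  (default: the first condition, read as the control). Ties break to the
  lexicographically smallest transcript id; if every isoform is
  unexpressed in that condition the pre-RNA is used instead, with a
  warning.

One consequence of the union construction deserves emphasis: **a retained
intron can never be observed against the gene's own pre-RNA.** The
retaining isoform makes the intron exonic in the union, so the reference
has no intron there, for any isoform of the gene; conversely the normally
spliced isoforms now splice out a region *interior to a merged reference
exon*, which is not a whole-exon skip, a boundary shift, or a retention
under the definitions below, and is deliberately left unreported rather
than given an ad-hoc class. IR analysis should therefore use
`reference_mode = "most_expressed"`, where the dominant isoform supplies
the intron structure and a retention in a minor isoform is visible; this
is also the mode under which the package's planted-truth validation runs.
The `classify_transcript()` primitive itself accepts any (transcript,
reference) pair, so callers with an external reference chain (an annotated
principal isoform, say) get IR against it as well.

## Event definitions

`classify_transcript(t, r)` applies a deterministic decision procedure;
orientation words (5′/3′, donor/acceptor, first/last) are
transcript-strand-relative, so a mirrored gene on the opposite strand
classifies identically.

1. **ATSS** — if `t`'s first exon shares no base with the reference's
   first merged exon, one event whose elements are the maximal
   reference-exonic intervals strictly 5′ of `t`'s transcription start.
   When that territory spans several reference exons the event has several
   elements but remains one event (one biological choice of start site,
   not several skips).
2. **ATTS** — symmetric at the 3′ end.
3. **IR** — each reference intron fully contained within a single exon of
   `t` yields one retention event; the element is the intron.
4. **ESI/MESI** — between `t`'s first and last exon, each maximal run of
   `k` consecutive reference exons with no base overlap with `t`:
   `k = 1` is an ESI, `k ≥ 2` one MESI carrying `k` elements (one decision
   of the spliceosome, one event — not `k` ESIs).
5. **A5/A3** — a transcript exon boundary on its internal (spliced) side
   lying strictly inside a reference exon, with the remainder of that
   reference exon contained in the adjacent transcript intron, yields an
   alternative donor (A5) or acceptor (A3); the element is the spliced-out
   sliver. Terminal exons contribute only on their spliced side.

Two asymmetries are intentional. First, ATSS/ATTS take precedence over
skipping at the gene termini: reference exons 5′ of an alternative start
are reported inside the single ATSS event, never double-counted as ESI.
Second, a transcript first exon that *overlaps* the reference first exon
but starts inside it is not an ATSS and the uncovered sliver is not an
event at all: assemblers trim transcript ends non-biologically, and
reporting terminal coordinate wobble would flood the ATSS and A3 counts.

**MEE** is detected between transcript pairs (`detect_mee()`), not against
the pre-RNA — the union contains both exons of an exclusive pair, so
exclusivity is only observable pairwise. Exons `a ∈ Ta`, `b ∈ Tb` form an
MEE when they do not overlap, neither shares a base with any exon of the
other transcript, and both lie between two exons with identical
coordinates in both transcripts with no other exon of either in between.
Events are deduplicated across pairs by element coordinates, but the same
skipped exon in two different transcripts is two events: counts are
transcript-level.

Every event records the reference boundaries flanking its element span
(`flank_5`, `flank_3`, strand-oriented) for downstream motif extraction,
and `events_to_bed()` emits BED6 elements for external tools.

### Validation strategy

The decision procedure is validated three ways, all in the test suite: the
definitional toy cases with exact coordinates; an independent brute-force
re-implementation (`oracle_classify()`, `oracle_mee()`) that re-derives
structure from exhaustive per-base membership vectors rather than interval
algebra; and planted ground truth from the generator. The acceptance run
uses 500 seeded random genes (spans under 10 kb, at most 6 isoforms) — a
size chosen to exercise every class and strand many times over while the
per-base oracle stays cheap.

## Isoform fractions and switches

IF = transcript expression / gene expression × 100 (percent); dIF =
IF(condition 2) − IF(condition 1) in percentage points. dIF is a *signed*
difference — the switch definition needs the sign — and "change in
absolute terms" is read as percentage points, never `|dIF|`. When gene
expression is zero the IF is undefined and excluded from dIF rather than
forced to zero.

IF is not re-normalized when gene expression differs from the sum of the
isoforms' expressions (upstream estimators compute the two independently);
genes whose IFs sum outside [90, 110] are worth inspecting as a QC signal.
IF values inherit all the noise of the underlying quantification and are
best treated as a ranking statistic. The one attached statistical
procedure is `subset_if_distributions()`: the two condition-wise IF
vectors over a transcript subset plus a two-sided Mann–Whitney U test
(normal approximation with continuity correction under ties, the
`stats::wilcox.test` behaviour).

`detect_switches()` calls one switch per gene when some isoform has
dIF ≥ τ and another dIF ≤ −τ and the gene is expressed at
`min_gene_expr` or more in both conditions, pairing the extreme up and
down isoforms (ties by id). Defaults: **τ = 25 percentage points** — a
quarter of the gene's output shifting is conservatively "large" and far
above quantification jitter on moderately expressed genes — and
**min_gene_expr = 1** in the input's expression units (FPKM-like), a
floor below which IFs are mostly noise. Both are deliberately explicit,
visible in the CLI help, and overridable; they are *not* calibrated to
reproduce any particular switch count on external data, and raising τ can only remove
calls (a tested monotonicity). With ORF annotations supplied, `nmd_gain`
flags switches where the falling isoform is PTC-negative and the rising
one PTC-positive.

## ORF and NMD annotation

For each transcript the *most upstream compatible* annotated start codon
is selected: an annotated start is compatible when its genomic first base
(transcript orientation) maps into the transcript's exons and three bases
of transcript sequence remain for the codon. Compatibility is positional
only — the annotation's downstream exon structure is not required to
match, because annotating *novel* isoforms against known starts is the
point — and the mapped codon is not required to read ATG (annotated
non-AUG starts pass; `strict_atg = TRUE` adds the check). Translation then
walks codons to the first in-frame TAA/TAG/TGA.

The NMD rule: a transcript is PTC-positive when its stop codon lies more
than `ptc_threshold` nt (default 50) upstream of the final exon–exon
junction. The distance is measured **from the last base of the stop codon
to the last base of the penultimate exon**, both in transcript
coordinates, making the boundary well defined: distance 51 is a PTC,
distance 50 is not (strict inequality). Other conventions (first base of
the stop) differ by at most 2 nt and can be absorbed by adjusting the
threshold. Single-exon transcripts have no junction and are never
PTC-positive; transcripts with a compatible start but no in-frame stop
are conservatively PTC-negative with status `no_stop_found` (no PTC is
demonstrable). `utr5 + orf + utr3 = transcript length` holds exactly for
every annotated transcript and is asserted across all fixtures.

## The synthetic-data generator

`generate_dataset()` / `simulate_gene()` build what the pipeline's
upstream tools would supply: a reference exon chain per gene (by default
4+ exons of 120–260 nt separated by introns of 80–200 nt, enlarged as
needed by the planted events — ordinary metazoan internal-exon scale), a
canonical transcript spanning it, and one derived transcript per planted
event. Planting is subtractive (drop exons, shrink boundaries, merge
across an intron), so every derived isoform is classifiable against the
canonical chain with a single known event; MEE is realized as two
isoforms each skipping one of two adjacent exons, which against the
canonical reference are additionally two ESIs — the ground truth lists
all three events. Event territories are separated by at least one
untouched exon, which provably prevents unplanned MEE pairs between
derived isoforms.

Genome sequence is uniform random with planted splice-site dinucleotides:
each distinct donor site receives GT and each acceptor AG with
probability `canonical_frac` (default 0.93, a typical canonical-motif
rate for assembled transcript models), else a random non-canonical
dinucleotide — so the splice-site QC report (`splice_site_report()`) has
a known planted rate to recover. Coding sequence is then written through
the canonical transcript's coordinate map: a start codon (ATG where
possible), stop-free filler codons, and a stop placed either in the final
exon (`canonical_stop`) or at an exact stop-to-junction distance
(`ptc_at_distance`, used to pin the 49/50/51 boundary). Codon filling
respects already-planted motif bases (alternative donor/acceptor sites of
sibling isoforms can fall inside canonical exons); a codon with locked
bases is completed so it is never a premature stop, and layouts where the
planted stop itself collides are re-drawn. ORF ground truth is therefore
exact by construction for the canonical transcript of every gene and for
all 500 transcripts of the dedicated `simulate_orf_transcripts()` set.

Expression is generated with gene expression equal to the sum of isoform
expressions (so per-gene IFs sum to 100 and dIFs to 0 — a tested
invariant), the canonical isoform most expressed in the reference
condition (making the most-expressed reference deterministic), and
planted switches of ±35 IF points in a configurable fraction of genes
against per-condition gene totals of 100 and 80.

What the generator does **not** emulate: quantification noise and
uncertainty, assembler fragmentation and terminal-end wobble, shared
exons between overlapping genes, multi-chromosome or antisense
structures, non-canonical splice chemistry beyond the dinucleotide flip,
and biased codon usage. Passing the planted-truth suite therefore
demonstrates the correctness of the algorithms on well-formed input, not
robustness to noisy real assemblies; on real data the status/expression
filters (`filter_dataset()`) are the first defence.

## Degenerate inputs and tie-breaks

* Transcripts of one gene on conflicting chromosomes or strands are a hard
  input error (the pre-RNA is undefined across strands).
* Missing expression values are coerced to 0 with a message, matching the
  upstream convention of emitting zeros for unquantifiable models;
  duplicated (transcript, condition) rows are an error.
* An alternative start 5′ of every reference exon (possible only against
  a most-expressed reference) has no representable reference element and
  emits no event.
* All orderings are deterministic: events sort by (gene, transcript,
  genomic position, class), ties in switch pairing and reference
  selection break lexicographically, and no output embeds timestamps —
  reruns are byte-identical.

## Limitations

Statistical testing of differential splicing is out of scope by design
(status flags and p-values are carried through for external tools), as are
PSI/read-level support counting, coding-potential regression for
transcripts without a compatible annotated start, selenocysteine
readthrough, and fusion/circular transcripts. The browser colour ramp
(`if_to_color()`: grayscale, channel `round(200 × (1 − IF/100))`) is this
package's declared encoding, carried in a `color` attribute plus an
`itemRgb` track default, since GTF has no native colour column.
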