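---
title: "Circular ring images of prokaryote genome comparisons: methods and design"
author: "GenomeRings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular ring images of prokaryote genome comparisons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomeRings)
```

## The picture being computed

A circular comparison image answers one question at a glance: which parts of
a reference genome are present, absent or diverged in each of a set of other
genomes? The reference — a complete chromosome, an ordered set of draft
contigs, or a concatenated panel of genes — forms the coordinate circle.
Every other dataset becomes one annulus ("ring") around it:

* **BLAST rings.** Each query genome (or a *collated* group of genomes) is
  compared against the reference with `blastn`, `blastx` or `tblastx`, the
  reference acting as the subject database. Every local alignment becomes an
  arc over its subject interval, and the arc's opacity encodes percent
  identity (see below). Regions of the reference with no hit stay white:
  absence is rendered as blankness. Because hits are computed from the
  reference's perspective, sequence present in a query but absent from the
  reference is invisible by construction.
* **Graph rings.** Any piecewise-constant numeric signal over reference
  coordinates — GC content, GC skew, read-mapping coverage, expression
  values from a user file — drawn as radial bars.
* **Contig rings.** Alternating red/blue segments marking contig boundaries
  of a draft reference.
* **Annotation rings.** Labelled feature spans (from GenBank/EMBL feature
  tables, custom tables, or the headers of a multi-FASTA reference).

The pipeline is: parse sequences → build the concatenated coordinate system
→ run or load comparisons → compute tracks → resolve rings into an
`ImageModel` → render SVG. Every step after the BLAST invocation is a pure
function, so a given profile and dataset always produce byte-identical
output.

## Coordinate conventions

Internally every interval is **0-based, half-open** `[start, end)`. All
format boundaries convert at the parser edge: GenBank/EMBL feature spans,
BLAST subject/query coordinates and SAM positions (all 1-based inclusive)
are converted on read, and re-converted on write. A single arithmetic
convention through the middle of the pipeline is the cheapest known defence
against off-by-one drift; the tests exercise the conversions at the
boundaries where they can fail.

Multi-record references (multi-FASTA, or multi-record GenBank/EMBL, which
are treated symmetrically) are concatenated in file order. Segment *i*
starts at the sum of the lengths of segments 0..*i*−1; the `ReferenceMap`
validity method enforces that the segments tile `[0, totalLength)` exactly.

Angles: position 0 sits at 12 o'clock and angles increase clockwise,
`theta = 2*pi*p/L`. This is the convention of the field's circular genome
maps and is the renderer's single geometric contract.

## The identity gradient

A ring's `lowerIdentity`/`upperIdentity` thresholds control its dynamic
range. A hit with identity *p* maps to opacity

* omitted entirely when `p < lower` (absence must look blank, not faint);
* `1` when `p >= upper`;
* otherwise linearly, `0.1 + 0.9 * (p - lower)/(upper - lower)`.

The published description of this display idiom says only that matches are
coloured "on a sliding scale"; the exact curve is not public, so this
package commits to a continuous linear map and documents it. The floor of
0.1 keeps the faintest retained match visible against white; both
thresholds are per-ring settings. Filtering by identity and E-value is
inclusive on both boundaries (`pident >= min`, `evalue <= max`), so a hit
at exactly the cutoff is kept.

Overlapping hits are **not** merged. They are painted in ascending bitscore
order with increasing z, so the strongest evidence is drawn last and ends
up on top — a stable sort, so equal scores preserve input order and output
stays deterministic.

## GC statistics

GC content is `(G+C)/(A+C+G+T)` and GC skew is `(G−C)/(G+C)` per window,
the standard replication-strand statistic whose sign changes tend to mark
origin and terminus in prokaryote chromosomes. Defaults are a 10 kb window
with step = window (non-overlapping); no published defaults exist for this
display, and 10 kb resolves the large-scale skew structure of a megabase
chromosome without producing hundreds of thousands of bins. Windows wrap
around the origin only when the reference is circular (the default for a
single complete sequence, off for concatenated panels). Counting is
case-insensitive; ambiguity codes are excluded from numerator and
denominator, and an all-ambiguous (or AT-only, for skew) window takes value
0 rather than NaN so downstream scaling never sees undefined bins.

## Coverage semantics

**SAM.** A reference position is covered by a read if a CIGAR `M`, `=` or
`X` operation consumes it; `D`/`N` spans consume reference without
coverage; unmapped (0x4), secondary (0x100) and supplementary (0x800)
records are skipped. These are common pileup semantics; the test suite
pins them against an independent brute-force oracle that increments a
counter for every aligned base of the truth placements.

**ACE.** Consed/Phrap and GS De Novo Assembler ACE files store padded
coordinates. Coverage is accumulated on the padded consensus — a position
is covered by every read whose padded placement spans it — and pad (`*`)
columns are then dropped, yielding ungapped contig coordinates. Whether
the original tool computed on padded or depadded coordinates is not
published; padded-then-depad is the self-consistent reading of the format
and is flagged here as an assumption.

**Anomalies.** Coverage "spikes" are maximal runs of bins deviating from
the track mean by more than *k* **population** standard deviations
(two-sided; one-sidedness is not documented anywhere authoritative, and
two-sided also flags low-coverage troughs, which are equally diagnostic).
Mean and SD are length-weighted so run-length compaction does not bias
them. A constant track has SD 0 and, by the strict inequality, no
anomalies.

**Remapping.** When draft contigs are reordered after assembly, coverage
computed on the original assembly is transported through a blastn
comparison of old vs new sequence: each hit becomes a 1:1 interval mapping
(spans truncated from their starts to the shorter length when gaps make
them unequal), each new position takes the value of its mapped old
position, reversed within minus-orientation entries, and where mappings
conflict the highest-bitscore entry wins — the same principle as z-order
painting. Unmapped positions get 0.

## Rendering choices

* Image default 3000×3000 px; the ring stack starts at 25% of the
  half-width. Ring widths are relative units; if the stack plus label
  margin would overflow the image the widths are scaled down uniformly
  with a warning rather than erroring.
* A minimum visible sweep equal to the angle subtending one pixel at the
  ring's outer radius: a single 1 kb gene on a 5 Mb circle must not vanish.
  Narrower arcs are widened symmetrically about their midpoint.
* Full-circle sweeps are emitted as two joined half-annuli, because a
  single SVG arc command cannot represent a closed 2π sweep.
* All numbers are printed with a fixed `%.4f` format and element order is
  fully determined by the model, so repeated renders are byte-identical;
  SVGZ is the gzip stream of those same bytes.
* Labels that would collide are nudged clockwise by a deterministic greedy
  pass over angle-sorted labels — no randomised layout, preserving
  determinism.
* Native output is SVG/SVGZ. Raster formats are deliberately not produced
  in-package; SVG is the faithful, diffable, testable artifact and can be
  rasterised by any external converter.

## Profiles and the command line

A session persists as a JSON profile with an explicit `formatVersion`:
reference descriptor, declared data sources (id → path/format/role),
ordered ring specifications, BLAST settings and image settings. Loading
validates the version and that every ring member is a declared source.
Default BLAST thresholds are the program's own (identity 0, E-value 10);
templates written by `init` state their thresholds explicitly. The
`render` subcommand accepts precomputed tabular files in place of live
BLAST runs, so the whole pipeline runs without BLAST+ installed; `--dry-run`
validates a profile and prints the planned invocations without executing
anything. One practical caveat worth repeating from the BLAST manual:
the low-complexity filter is on by default and can punch short (~30 bp)
blank windows across all rings that are easily misread as unique reference
regions; pass `extraOptions = c("-dust", "no")` (or `-seg no` for protein
searches) to disable it.

## What the synthetic data emulate — and what they do not

The generator produces i.i.d.-base genomes at a chosen GC fraction,
variants with known deletions and never-silent SNPs, uniformly placed
substitution-error reads, all-M SAM alignments, and tabular hit files that
reproduce chosen reference intervals exactly. Each generator is a pure
function of its arguments including the seed (the global RNG state is
saved and restored).

This emulates exactly the structure the pipeline measures: presence/
absence, identity degradation, pileup depth. It does **not** emulate real
genomes (no repeats, no gene structure, no skewed replichores), real
sequencer error models (no indels, no quality-dependent errors), or real
assemblers (no misassembly, no true padding complexity). Passing tests
therefore demonstrate the correctness of the computations, not robustness
to every pathology of real data; in particular, repeat-rich genomes will
produce overlapping self-hits whose visual interpretation relies on the
z-order rule, and low-complexity regions interact with BLAST's filters as
described above.

## Study conditions used by the checks

The end-to-end checks run at sizes chosen to exercise every code path at
desk scale: a 50 kb synthetic genome (GC 0.5) for the self-comparison and
deletion-recovery BLAST runs; three 2 kb deletions with a 0.5% SNP rate
for the variant; 1,000 reads of 100 bp for the coverage oracle; a 20 bp
two-read ACE fixture computed by hand; 2 kb tracks for remapping. Deletion
recovery is scored per deletion as the best Jaccard overlap between the
truth interval and an uncovered ("blank") reference interval.

## Known limitations

* GenBank/EMBL parsing covers the flat-file subset needed here (LOCUS/ID,
  DEFINITION/DE, feature keys with qualifiers, ORIGIN/SQ); rich location
  semantics (fuzzy ends, trans-splicing) are flattened to outer spans with
  strand kept only as the arrow decoration.
* Feature selection by qualifier substring searches *all* qualifier values
  of a feature, case-sensitively; tools differ on this and the choice is
  documented rather than configurable.
* Collated rings use a single color per ring; per-source coloring within
  one lane is out of scope.
* BAM/CRAM are not read directly; convert to SAM text first. MUMmer-based
  comparisons and computing difference coordinates as first-class output
  are out of scope.
* The renderer produces no interactive preview; the profile/template
  workflow is the intended iteration loop.
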