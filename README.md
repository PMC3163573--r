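# GenomeRings

Circular multi-ring comparison images for prokaryote genomes, in R.

Comparing a newly sequenced bacterial genome against dozens of relatives is
a routine need: which regions are shared, which are strain-specific, where
do prophages or pathogenicity islands sit, and how does a draft assembly's
read coverage behave? GenomeRings turns one or more **reference**
sequences (FASTA, GenBank or EMBL — a complete chromosome, ordered draft
contigs, or a concatenated gene panel) plus any number of **query**
datasets (genomes, contigs, or unassembled reads) into a single circular
SVG: the reference is the coordinate circle, and each query is one
concentric ring whose arcs are BLAST matches shaded by percent identity.
It is aimed at microbial genomicists who want scripted, reproducible
figures rather than hand-assembled ones.

## The model

The reference is the BLAST *subject*: sequences are concatenated in input
order into a coordinate system of total length *L*, and every hit's
subject interval `[min(sstart, send) - 1, max(sstart, send))` becomes an
arc at angle `θ = 2πp/L` (position 0 at 12 o'clock, clockwise). A hit with
identity *p* in a ring with thresholds `[lower, upper]` is drawn with
opacity

```
opacity(p) = 0.1 + 0.9 · (p − lower)/(upper − lower)   for lower ≤ p < upper
           = 1                                          for p ≥ upper
           (omitted entirely for p < lower)
```

so absent sequence stays blank and diverged sequence fades. Overlapping
hits are painted in ascending bitscore order — the strongest match is
drawn last and wins visually. Around this core the package computes GC
content and GC skew `(G−C)/(G+C)` in sliding windows, per-base read
coverage from SAM or ACE assembly files (with anomaly intervals beyond
*k* standard deviations of the mean), contig-boundary rings, custom graph
and annotation tracks, and can transport a coverage track onto a reordered
assembly through a blastn interval mapping. Rendering is deterministic:
identical inputs give byte-identical SVG (or SVGZ, its gzip stream).

## Worked example

Compare a mutated variant (three known 2 kb deletions, 0.5% SNPs) against
its 50 kb source genome and render a two-ring image:

```r
library(GenomeRings)

g  <- synthGenome(50000, 0.5, seed = 1, name = "ref")
writeFasta(g, "ref.fasta")
mv <- mutateGenome(g, data.frame(start = c(10000, 25000, 40000),
                                 length = 2000),
                   snpRate = 0.005, seed = 2, name = "variant")
writeFasta(mv$variant, "variant.fasta")

db   <- makeBlastDb("ref.fasta", "nucl", out = "refdb")
tab  <- runComparison("blastn", "variant.fasta", db,
                      hitFilter(maxEvalue = 1e-5))
hits <- filterHits(parseBlastTabular(tab), hitFilter(minIdentity = 70))

refmap <- buildReferenceMap(g)
refmap
#> ReferenceMap: 1 segment(s), 50,000 bp total, circular
#>   name offset length
#> 1  ref      0  50000

uncoveredIntervals(hits, refLength(refmap))
#>   start   end
#> 1 10000 11996
#> 2 25000 27000
#> 3 40002 41999
```

The three blank (uncovered) reference intervals recover the three planted
deletions to within a few bases — this is how gene absence reads off the
final image as white gaps in a ring.

```r
skew  <- gcSkew(g, window = 1000)
model <- assembleImage(refmap,
  rings   = list(RingSpec("graph", "skew", color = "#663399"),
                 RingSpec("blast", "variant", color = "#CC0000",
                          lowerIdentity = 70, legendText = "variant")),
  hitSets = list(variant = hits), tracks = list(skew = skew),
  title   = "variant vs reference")
model
#> ImageModel: 50,000 bp reference, 2 ring(s), 0 annotation(s)

renderSVG(model, "image.svg", imageSize = 1500)
```

`image.svg` shows the GC-skew ring (signed bars about the ring midline)
inside a red BLAST ring that is fully opaque where the variant matches at
~100% identity and blank across the three deletions.

The same run can be captured as a JSON profile and repeated from a shell
via the bundled script (`inst/scripts/genomerings`):

```sh
Rscript inst/scripts/genomerings render --profile profile.json --out image.svg
Rscript inst/scripts/genomerings render --profile profile.json --out image.svg --dry-run
```

Subcommands `blast`, `coverage`, `remap`, `annotate` and `init` expose the
individual pipeline stages; exit codes are 0 (success), 2 (validation),
3 (external tool), 4 (I/O).

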