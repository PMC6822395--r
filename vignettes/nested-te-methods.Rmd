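---
title: "Detecting and dating nested transposable-element insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating nested transposable-element insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestedTE)
```

## The biological problem

Transposable elements (TEs) do not always act alone. A young SINE can
retrotranspose into an old one — an Alu element landing inside a
Mammalian-wide Interspersed Repeat (MIR), for example — and the combined
sequence can acquire functions neither element had on its own. When such a
pair sits in antisense orientation inside an intron, the two elements can
jointly supply everything a spliceosome needs to define a new exon: an AG
acceptor from one element, a GT donor from the other, and a branch-point
adenosine upstream of the acceptor. The exonized sequence then alters the
encoded peptide, typically replacing the reference C-terminus and
truncating it at a new stop codon.

`nestedTE` implements the computational side of this analysis as a
reusable, fully tested pipeline:

1. parse UCSC-dialect repeat (`rmsk.txt`) and gene-model (`refGene.txt`)
   tables;
2. reassemble fragmented repeats and detect combined host/guest
   configurations, with orientation concordance and the two hallmarks of
   target-primed reverse transcription (TPRT): the target-site duplication
   (TSD) and the poly-A tail;
3. classify each combination against gene models (intergenic, intronic
   with transcription-order intron ordinal, or exon-overlapping);
4. enumerate exonization candidates from canonical splice dinucleotides,
   re-splice candidate transcripts, and report peptide effects under the
   first-start ORF rule;
5. score branch-point adenosines with a position-weight model;
6. date insertions on a calibrated species tree from presence/absence
   profiles under a single-gain (Dollo) model.

Because the genome-scale inputs are large, version-dependent downloads,
the package ships a synthetic-genome generator that plants every
configuration of interest with a machine-readable truth manifest, so each
stage is validated against known ground truth.

## Coordinates and formats

All internal coordinates are 0-based, half-open, the native convention of
the rmsk, refGene and BED dialects; `coords_to_1based()` converts at
report boundaries only. The rmsk and refGene parsers autodetect the
optional leading `bin` column by column count, read gzip transparently,
and validate interval and exon-list invariants on read. Unknown repeat
classes are preserved verbatim. Writers invert the readers field-for-field
(round-trip identity is property-tested).

## Reassembly and the definition of "together"

RepeatMasker emits one row per alignment fragment; fragments of one
original insertion share the table's linkage `id`. `assemble_elements()`
groups rows by `(chrom, id, repeat name, strand)`; a group with more than
one row is a *fragmented* element. Overlapping rows within a group are
tolerated with a warning and a merged span, since real tables contain
them.

The annotation dialect never defines what it means for two TEs to be
"together", so the package fixes two relations:

- **nested** — the guest element lies strictly inside the outer span of a
  fragmented host. This is the actual biological configuration of
  interest: the guest interrupted the host, splitting its annotation.
- **adjacent** — two assembled elements are consecutive on the chromosome
  with a gap of at most `max_gap` bp (default 0, i.e. touching). This is
  kept configurable for sensitivity analysis, because published combined
  counts may have included adjacency.

A pair is reported once, nesting taking precedence. Counts are reported
both per assembled element and per raw row, since either convention may
be wanted when comparing against published tallies.

## TPRT hallmarks

`detect_tsd()` looks for the longest exact (optionally
mismatch-tolerant) match between the `max_len = 20` bases directly in
front of and directly behind an element, accepting lengths from
`min_len = 2` — the published 2–20 bp TSD length rule. Because a 2–4 nt
flanking match arises easily by chance, TSDs shorter than 5 nt are
flagged low-confidence rather than suppressed; heavily diverged old
elements (MIR sits at roughly 25–35% divergence from consensus) often
retain only such short, uncertain candidates.

The poly-A tail is measured as the maximal terminal segment under an
A-rich score (+1 per A, −4 per other base, scanned up to 50 nt inward;
ties resolve to the shorter segment). Any reported tract is therefore at
least 80% A, while the score maximum pins the tract boundary to the last
adenosine rather than overshooting into downstream A-poor sequence, which
a plain windowed-fraction rule does. Tracts shorter than `min_polya = 8`
report 0. On minus-strand elements the scan runs over the leading
T-tract.

## Genomic context

A combination span is *intragenic* only when fully contained in a
transcript interval — the conservative reading of "inside the gene"; a
span overhanging a transcript boundary is intergenic. Within a gene,
zero exon overlap makes it *intronic*, and the containing intron's
ordinal is reported in transcription order (intron 1 abuts the 5'-most
exon), so a "4th intron" means the same thing for plus- and minus-strand
genes; genomic-order indexing is available behind a flag. One call is
emitted per containing transcript: no isoform collapsing is attempted.
Both coding (`NM_`) and non-coding (`NR_`) transcripts are classified;
callers wanting the coding-only convention can subset the gene table by
name prefix before classification.

## Exonization candidates and peptide effects

Only canonical dinucleotides are considered (AG acceptor, GT donor, read
on the gene's sense strand) — the motivating sites are canonical, and
splice-strength models are out of scope. Candidates are all
acceptor–donor pairs in transcript orientation with exon length within
25–500 nt (defaults; configurable). Several acceptors sharing a donor
yield several candidates — the two-variant (V1/V2-like) situation — and
are labelled by descending exon length per donor.

`splice_in()` inserts a candidate exon at its genomic position and
re-splices the mRNA; inserting into intron 4 of a 5-exon gene yields a
6-exon transcript whose length is the reference length plus the exon
length exactly. ORF selection follows the first-start rule: among
ATG-initiated frames that reach an in-frame stop, the 5'-most ATG wins;
no minimum ORF length is imposed by default. `compare_peptides()` reports
the first differing residue and flags a premature stop when the variant
either terminates earlier than the reference or diverges within the
reference span (its C-terminus then derives from a new stop codon).

## Branch-point scoring

The published analyses used external branch-point predictors as black
boxes. Reimplementing their trained models is out of scope; instead the
package defines a fully specified, reproducible scorer:

- a 7-nt position-weight matrix (log-odds against a uniform background,
  pseudocount 0.01) built from a yUnAy-style mammalian consensus, with
  the branch adenosine at window position 6 (matching reported heptamers
  such as `GCTTTAC` and `TTTTGAG`, whose adenosine is the 6th base);
- a distance prior, maximal for adenosines 21–25 nt upstream of the 3'
  splice site — the canonical band — and decreasing linearly at 0.05
  score units per nt outside it; the search window is 15–100 nt, covering
  "near the canonical region" with margin;
- a polypyrimidine-tract term: the pyrimidine fraction between the
  branch adenosine and the 3'SS AG, weighted 1.0 relative to the motif
  score.

Ties in total score resolve toward the adenosine closer to the 3'SS.
Distance is counted from the branch adenosine through the final G of the
intron. The scorer's ranking is verified against an exhaustive
brute-force oracle, and planted consensus heptamers in the canonical band
are recovered from random background in at least 95% of trials. These
scores are model-defined units: they are comparable between sequences
scored with the same model, not with any external program's output.

## Phyletic dating

`infer_integration_window()` implements single-gain (Dollo) logic: the
insertion arose once, on the stem branch of the minimal clade containing
every carrier, and is never precisely excised. The window is bounded
below by that clade's crown age and above by its parent node's age — open
above when the carriers span the whole tree. Profiles whose carriers are
not monophyletic (given the `absent` leaves; `unknown` leaves are
excluded from the test but reported) raise a typed error rather than
attempting loss-aware reconstruction, which would need a different model.

The packaged fixture tree has ten leaves mirroring the surveyed taxa,
with the three decisive calibrations as arguments (root 63 myr,
catarrhine/platyrrhine 40 myr, hominoid/cercopithecoid 25 myr). The
calibrations are treated as exact inputs; the uncertainty of
"approximately 63 myr" is not modelled. Remaining node ages are fixed
round figures (human/chimpanzee 6, hominoid crown 20, macaques 5,
cercopithecine 13, Old World monkey crown 18, New World monkey crown 20
myr) chosen from the primate literature only to respect the topology's
ordering constraints; none of them affects the windows of interest.
`profile_from_amplicons()` converts PCR band sizes into a profile against
the two expected sizes, with everything ambiguous marked `unknown` — band
size alone can mislead, since an independent similar-length insertion
mimics presence.

## The synthetic-genome generator

`simulate_te_genome()` plants, per configuration: MIR-like hosts (260 nt
toy consensus, 30% per-site divergence — the reported MIR range is
25–35%), AluSp-like guests (300 nt consensus, 10% divergence), TSDs of
4–16 bp (inside the published 2–20 bp rule), poly-A tails of 8–30 nt,
and 5-exon genes whose 4th intron hosts antisense nested pairs carrying
planted AG/GT/branch-point signals with the branch adenosine 21–25 nt
upstream of the acceptor. Defaults describe the study conditions used
throughout the tests: one 1 Mb chromosome, 40 hosts, 30 guests,
`p_nested = 0.8`, giving 24 nested pairs per genome.

Deliberate generator properties, chosen so the truth manifest is exact:

- substitution-only divergence (no indels), keeping planted coordinates
  reconcilable with the emitted tables base-for-base;
- `p_nested` is realized deterministically as
  `round(p_nested * min(n_guest, n_host))` nested pairs, so planted
  counts are reproducible rather than binomially variable;
- the insertion point is re-drawn until the planted TSD is the *longest*
  flanking duplication (spurious one-base extensions would otherwise
  arise by chance), and the guest body's 3'-terminal 12 nt are kept
  A-free so the planted tail length is unambiguous;
- nesting always fragments the host into exactly two pieces, the common
  annotation presentation.

What the generator does **not** emulate: realistic substitution
processes (no rate matrices, no rate heterogeneity), indels, tandem or
>2-fragment nesting, annotation errors (wrong linkage ids, truncated
calls), or non-canonical splice sites. Passing the planted-truth tests
therefore demonstrates correctness of the detection logic under clean
annotation, not robustness to annotation noise — on real tables, linkage
ids are occasionally wrong and recall will be correspondingly lower.

`simulate_exonization_locus()` is a second, fully controlled fixture: a
single 5-exon gene whose 4th intron carries an antisense nested pair
with exactly two acceptors sharing one donor, a canonical-band branch
point, hallmark TSD/poly-A, and a stop cluster covering all three frames
inside the candidate exons. Outside the planted motifs the cassette
contains no AG or GT at all (the sequence is sampled from a
dinucleotide-constrained walk), so enumeration over the TE region is
provably exhaustive. Its host/guest bodies are constrained random
sequence, not the simulator's consensi — the point of this locus is
exact bookkeeping, not sequence realism.

## Numerical and degenerate-input choices

- Zero-row tables flow through every stage and yield empty, correctly
  typed outputs; an empty combination set reports `NA` orientation
  percentage rather than 0/0.
- Orientation percentage is `round(100 * same/total)` to match the
  convention of published integer percentages.
- Branch-point scoring of non-ACGT characters uses the worst base at
  that window position, so masked sequence can only lower a score.
- `infer_integration_window()` on a single carrier returns the terminal
  branch (lower bound 0 myr); the root returns an open upper bound
  (`Inf`).
- All simulation randomness derives from one integer seed; reruns are
  byte-identical, and `apply_divergence()` with an explicit seed uses a
  private RNG stream that leaves the caller's stream untouched.

## Problem sizes

The shipped tests validate the pipeline on twenty 1 Mb genomes
(24 planted nested pairs each), 1,000 random context classifications
against a per-base oracle, 200 random introns against an exhaustive
branch-point oracle, and 500 planted branch-point recovery trials —
sizes chosen so the full suite completes in about a minute while every
code path and invariant is exercised many times over.

## A short example

```{r example, eval = FALSE}
res <- run_te_pipeline(simulation_config(seed = 1))
res$summary
res$reconciliation
```

The summary reports element and row counts, the number of detected
combinations, the orientation percentage, the context breakdown, the
exonization candidates, and the truth-manifest reconciliation (recall
and precision of nested-pair detection, both 1 under the default
conditions).
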