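# nestedTE

Detection and evolutionary analysis of **nested transposable-element (TE)
insertions** — configurations in which a young SINE (an Alu-like "guest")
has retrotransposed into an old one (a MIR-like "host"), splitting the
host's annotation into fragments — and of the downstream consequences such
combined sequences can have: intronic **exonization** through jointly
supplied splice signals, altered peptides, and lineage-specific timing of
the insertions.

The package is aimed at comparative genomicists working with standard
UCSC-dialect annotation tables (`rmsk.txt`, `refGene.txt`) and genome
FASTA, and at anyone who needs a tested, self-contained reference
implementation of this analysis: every stage is exercised against a
synthetic-genome generator that plants ground truth with a
machine-readable manifest.

## What it computes

- **Combined TE detection.** Annotation rows sharing a RepeatMasker
  linkage id are reassembled into elements; a *nested* pair is a guest
  strictly inside the outer span of a fragmented host, an *adjacent* pair
  two consecutive elements with gap ≤ `max_gap`. Orientation concordance
  is summarised as `round(100 · same/total)` %.
- **TPRT hallmarks.** The target-site duplication is the longest exact
  flanking match with length in the published 2–20 bp band (matches < 5 nt
  flagged low-confidence); the poly-A tail is the maximal-scoring terminal
  A-tract (+1 per A, −4 otherwise, hence ≥ 80 % A), T-tract on the minus
  strand.
- **Genomic context.** Combinations fully contained in a transcript are
  intragenic; with zero exon overlap they are intronic, with the intron
  ordinal in transcription order (strand-aware).
- **Exonization candidates.** All canonical acceptor–donor (AG…GT) pairs
  on the gene sense strand with exon length in bounds; candidate
  transcripts are re-spliced and translated under the first-start ORF
  rule (5'-most ATG with an in-frame stop), and variant peptides are
  compared to the reference (divergence point, premature stop).
- **Branch points.** Every adenosine 15–100 nt upstream of the 3' splice
  site is scored as `PWM(7-nt window) + distance prior (maximal at
  21–25 nt) + py_weight · pyrimidine fraction`; ties break toward the
  3'SS.
- **Insertion dating.** Under a single-gain (Dollo) model, the insertion
  arose on the stem branch of the minimal clade containing all carrier
  taxa: the integration window is `[crown age, parent-node age]`, open
  above at the root. A calibrated 10-leaf primate fixture tree is
  packaged (root 63 myr, catarrhine/platyrrhine 40 myr,
  hominoid/cercopithecoid 25 myr).

## Worked example

```r
library(nestedTE)

res <- run_te_pipeline(simulation_config(seed = 1))
res$summary
#> $element_counts
#> total  SINE AluSp   MIR
#>    70    70    30    40
#> $combinations            24
#> $nested                  24
#> $percent_same_orientation 62
#> $intragenic_intronic      8
#> $recall                   1
#> $precision                1

res$reconciliation
#>   planted detected matched recall precision
#> 1      24       24      24      1         1
```

The default configuration simulates one 1 Mb chromosome with 40 MIR-like
hosts and 30 AluSp-like guests, 24 of which are planted nested (8 of them
antisense pairs inside the 4th intron of a gene, carrying splice
signals). The summary shows that all 24 planted nested pairs — and
nothing else — were detected (`recall` and `precision` 1), that 62 % of
detected pairs are orientation-concordant in this replicate, and that the
8 intronic pairs were classified `intragenic_intronic`.

Dating an insertion carried by hominoids and Old World monkeys but absent
from New World monkeys and the prosimian:

```r
tr <- primate_fixture_tree()
carriers <- c("human", "chimpanzee", "gibbon", "rhesus_macaque",
              "crab_eating_macaque", "african_green_monkey",
              "colobus_monkey")
infer_integration_window(tr, phyletic_profile(
  present = carriers, absent = setdiff(tr$tip.label, carriers)))
#> Integration window: 25 myr (crown of 7 carrier leaves) to 40 myr

infer_integration_window(tr, phyletic_profile(present = tr$tip.label))
#> Integration window: 63 myr (crown of 10 carrier leaves) to open (older than the root)
```

The guest insertion dates to the 25–40 myr branch (after the split from
New World monkeys, before the hominoid/Old World monkey divergence); an
insertion shared by all ten taxa predates the 63 myr root.

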