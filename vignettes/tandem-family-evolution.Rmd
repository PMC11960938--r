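---
title: "Reconstructing tandem gene-family evolution from intergenic homology"
author: "tandemtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tandem gene-family evolution from intergenic homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemtrace)
```

## The problem

Expanded gene families in eukaryotic genomes — here modelled on a
secreted alginate-lyase family acquired by a heterotrophic diatom through
horizontal gene transfer from a marine bacterium — typically spread by two
mechanisms operating at different genomic scales. Unequal crossing over
between misaligned repeats duplicates a gene *together with its
downstream intergenic region*, building head-to-tail tandem arrays.
Transposition then disperses copies to unlinked loci elsewhere in the
genome. `tandemtrace` reconstructs both layers of this history from
standard inputs (assembly FASTA, gene GFF3, per-gene domain hits, a
bootstrap-annotated domain phylogeny) and ships a ground-truth simulator
so every inference step can be validated end to end without external
data.

## Dating tandem duplications from intergenic homology

The central idea: because unequal crossing over copies the intergenic
region along with the gene, the two intergenic regions flanking a young
junction start out identical and then decay by neutral drift, while the
coding copies are preserved by selection. Residual homology between
*consecutive* intergenic regions therefore dates the duplication.

Each locus is segmented into left flank, genes, intergenic regions and
right flank (`segment_locus()`, default 2.5 kb flanks, truncated at
contig ends) and all segment pairs are aligned with an overlap
Needleman–Wunsch alignment (`align_overlap()`):

* free end gaps at both sequence ends, so segments of unequal length can
  nest without terminal penalties;
* affine gap costs with a run of length $L$ costing
  $\mathrm{open} + \mathrm{extend}\cdot L$, by default $25 + 10L$ — much
  stiffer than typical defaults, deliberately favouring contiguous blocks
  of high similarity over gap-riddled alignments of dubious homology;
* the standard NUC.4.4 (EDNAFULL) substitution matrix (+5 match, −4
  mismatch, graded ambiguity scores).

Percent identity is summarized as
$\mathrm{PID3} = 100 \cdot \frac{\text{identical columns}}{\text{length of shorter sequence}}$,
which is insensitive to the length of the longer partner — appropriate
when one intergenic region carries an indel or a partial duplication.

Because overlap alignments of short random sequences can attain inflated
PID3 (the aligner is free to dock a short segment wherever it fits best),
"high homology" is made operational rather than visual: each consecutive
intergenic pair is compared against a mononucleotide shuffle null
(`shuffle_null()`, default 100 shuffles) and called recent only when the
observed PID3 exceeds the empirical 95th percentile of that null *and*
clears an absolute floor of 50%. The floor matters: a junction diverged
by ~0.8 substitutions per site still retains ~35–45% PID3, comfortably
above the ~30% shuffle null of same-composition sequences, yet far from
the near-identity expected of a recent event. Intergenic regions shorter
than 30 bp are reported as not assessable instead of being aligned —
PID3 on tiny segments is meaningless.

### Numerical choices

* Traceback ties prefer diagonal over gap-in-second over gap-in-first
  moves, and endpoint ties prefer the cell consuming most of both
  sequences, so alignments are deterministic.
* The dynamic program is a full three-state $O(nm)$ affine DP; locus
  segments here are at most a few kb, so no banding is needed.
* Sequences are uppercased on ingestion; soft-masking is ignored.
* Intergenic sequences are compared on the forward strand. Tandem arrays
  of this kind are co-oriented, so a reverse-complement channel is
  unnecessary by default.

## Gene families from domain architecture

Family assignment follows overall domain organization, applied in strict
rule order to each gene's ordered domain string (`classify_family()`):

1. any transmembrane segment C-terminal to the last catalytic (A) domain
   with no carbohydrate-binding (C) domain → `AnTMD`;
2. at least two A domains and at least one C domain → `AnCn`;
3. otherwise → `CA`, with subfamilies `CCA` (duplicated C, architecture
   containing C-C-A) and `A_only` (C lost).

Domain hits come from HMMER `--domtblout` files (hand-parsed — the fixed
22-column format has no R reader) or a simple TSV, filtered at an
independent-domain E-value of 1e-3 (1e-10 for CAZyme annotation), with
nested hits resolved by keeping the lower-E-value hit and dropping
overlaps above 50% of the shorter hit. Signal peptides and transmembrane
segments are ingested as annotations from upstream predictors, not
predicted here.

Three sequence-level audits accompany the classifier:

* `audit_catalytic_motifs()` checks the three catalytic regions
  (`R.E[LV]R`, `Q[IV]H`, `YFK.G.Y.Q`) of each A domain;
* `detect_insertion()` aligns an A-domain against a reference with end
  gaps *penalized* and reports the longest internal gap opened in the
  reference — a shared in-frame insertion (≥15 bp, divisible by 3) at one
  position across genes marks descent from a common ancestor;
* `count_tarp_repeats()` counts non-overlapping `T[APSV]RP` tetrapeptide
  units in the low-complexity linkers. Greedy left-to-right scanning is
  used; exact tetrapeptide units cannot overlap, but the greedy rule
  guards degenerate inputs.

## Transposition from supported monophyly across unlinked loci

Two loci are *unlinked* when they lie on different contigs or are
separated by more than 10 kb of unique sequence (`loci_unlinked()`).
`infer_transpositions()` reports maximal clades whose bootstrap support
reaches 100, whose leaves span two or more pairwise-unlinked loci, and
which contain at least half of each involved locus's domains. The
coverage fraction operationalizes "most genes of the locus" — no exact
fraction is canonical, so it is exposed as a parameter and reported per
event so either stricter or looser readings can be audited. Unrooted
trees are midpoint rooted first; nested qualifying clades collapse into
the maximal one. The strict support-100 default errs toward false
negatives by design; it is a parameter for sensitivity analyses.

Loci themselves are called by single-linkage clustering of family genes
with a 20 kb default gap (`call_loci()`): tandem arrays are far tighter
than that, while the 10 kb unlinkedness scale guarantees that distinct
loci under this definition cannot be confused with a single array. Locus
numbering follows position on contigs ordered from largest to smallest.

## Supporting procedures

* **Telomere census** (`find_telomeric_ends()`): a contig end is
  telomeric when ≥3 tandem copies of TTAGGG (or its reverse complement)
  occur within 500 bp of the end; requiring a tandem block suppresses
  chance hexamers (a single TTAGGG occurs every ~2 kb of random
  sequence). Minimum chromosome number is ⌈ends/2⌉.
* **CAZyme profiles** (`profile_percentages()`, `cluster_profiles()`):
  per-species family counts are normalized to percentages of the
  species' total CAZyme complement and clustered with Bray–Curtis
  dissimilarity. The agglomeration linkage is unspecified in common
  practice descriptions; average linkage (UPGMA) is the conventional
  partner of Bray–Curtis heatmaps and is the default, exposed as a
  parameter.
* **Bit-score-binned sampling** (`sample_blast_hits()`): hits are binned
  by bit score into 10 bins of width 50 anchored at the minimum observed
  score (scores above the top boundary join the last bin — the simplest
  scheme consistent with fixed-width bins), 25 hits are drawn uniformly
  per bin, then description filtering and one-per-species deduplication
  (keeping the best-scoring representative) are applied. Anchoring at
  the minimum is a design choice; no anchor is canonical.

## The simulator: what it emulates and what it does not

`simulate_family_genome()` and its building blocks
(`make_ancestral_genome()`, `apply_unequal_crossover()`,
`apply_transposition()`, `plant_domain_event()`, `mutate_jc()`) generate
a genome whose history is known exactly:

* an ancestral SP–C–A gene with nine TARP linker units and intact
  catalytic motifs, in random flanking sequence;
* head-to-tail tandem expansion duplicating gene + downstream intergenic
  region (800 bp by default), so new junctions start identical;
* neutral drift on intergenic DNA under Jukes–Cantor: each copy of a
  junction aged `t` is mutated independently for time `t`, giving the
  pair `2t` expected substitutions per site — the natural meaning of
  "time since the duplication". Coding regions are held fixed,
  emulating purifying selection on the retained copies;
* transposition of gene blocks to unlinked contigs;
* domain duplication/loss, TMD gain, in-frame insertions and motif
  knockouts with full coordinate bookkeeping.

The drift model deliberately omits indels (an optional channel would
only blur the recency signal the tests quantify), selection on
intergenic DNA, GC bias and recombination-rate variation. Passing tests
therefore demonstrate that the *inference machinery* is correct under a
clean neutral model — not that real intergenic decay is purely neutral
or indel-free. Similarly, simulated bootstrap supports are planted, not
estimated: `simulate_support_tree()` tests clade extraction, not tree
inference, which is upstream of this package.

Every generator is a deterministic function of `(config, seed)`; emitted
FASTA/GFF3/TSV/Newick/JSON reproduce byte-for-byte under the same seed,
and the truth log records every event.

## Validation surface and problem sizes

The test suite validates the aligner against exhaustive enumeration of
all alignments (hundreds of random pairs up to length 7, both end-gap
modes) and against an independent overlap aligner on longer pairs; the
recency caller against 50 simulated loci (25 junctions at 0.02 and 25 at
0.8 substitutions per site per copy, 800 bp intergenic regions), where
sensitivity and specificity both reach 1.0 at the default thresholds;
the transposition caller against 20 simulated trees with planted
100-support clades and support-80 decoys (precision = recall = 1, no
decoy ever reported); Jukes–Cantor drift against its closed-form
substitution probability at 10 kb over 20 seeds; and the full staged
pipeline against the simulator truth log. These sizes keep the whole
battery to a few minutes on one core while leaving each statistical
check overwhelming power for the effect sizes involved.

`scripts/acceptance.R --seed N --out results/acceptance.json` re-runs
this battery from scratch and writes every quantity as JSON.

## Worked example

```{r example, eval = FALSE}
library(tandemtrace)

fg <- simulate_family_genome(seed = 7)
loci <- call_loci(fg$sim$genes, fg$sim$genes$gene_id, fg$sim$contigs)
seg <- segment_locus(loci[[1]], fg$sim$contigs)
pm <- pairwise_pid_matrix(seg)
call_recent_duplications(pm, seg, seed = 11)
#>   locus_id igr_a igr_b   pid3 null_quantile assessable is_recent
#> 1        1  IGR1  IGR2 97.625           100       TRUE      TRUE
#> 2        1  IGR2  IGR3 46.250           100       TRUE     FALSE
```

The recent junction (97.6% PID3) is flagged; the ancient one retains
46% residual identity — above the shuffle null but below the 50% floor,
exactly the regime the floor exists for.

## Optional real-data drop-ins

Two gated checks run only when real annotation extracts are placed under
`inst/extdata/real/`: `aly1_linker.txt` (one line, the linker protein
sequence of the family's first member; its TARP count is asserted to be
nine) and the pair `family_table.tsv` / `loci_census.tsv` (the package's
own `classify_families()` / `orientation_census()` output schemas for
the full 91-gene family, whose census is asserted to be 91 members, 77
with a C domain, 73 CA, 30 loci, 20 tandem, 15 unidirectional). These
files are not bundled; all other tests are self-contained.

## Known limitations

* The recency caller dates junctions ordinally (recent vs not), not in
  years; calibrating a molecular clock is out of scope.
* Locus calling with any fixed gap parameter may merge or split loci
  relative to expert manual assignment; the parameter is exposed rather
  than asserting a canonical locus count.
* The dot-plot utility (`dotplot_self()`) is a qualitative diagnostic;
  no display-parameter conventions are asserted.
* Genome-scale discovery (assembly, gene prediction, HMM search, tree
  building) is upstream; this package starts from their outputs.
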