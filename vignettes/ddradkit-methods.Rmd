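---
title: "Designing and analysing ddRADseq experiments with ddradkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analysing ddRADseq experiments with ddradkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradkit)
```

Double-digest RADseq (ddRADseq) builds a reduced-representation
sequencing library from the fragments a pair of restriction enzymes cuts
out of a genome, keeping only fragments with one end from each enzyme
("AB" fragments) inside a tight size window. Because every individual's
library samples the *same* deterministic fragment set, coverage
concentrates on a tunable number of loci and many individuals fit in one
sequencing lane. `ddradkit` implements both halves of the method's
computational content: a design simulator that predicts how many loci a
given enzyme pair, size selection, and read budget will recover, and a
reference-free analysis pipeline that turns raw multiplexed reads into
genotyper-ready pseudo-reference alignments.

This vignette explains the models, the tunable parameters and the design
decisions; the README shows a worked example.

## The design simulator

### In-silico digest

`double_digest()` applies a complete-digest model: every occurrence of
either recognition site is cut, on both strands, at the REBASE cut
offset (EcoRI `G^AATTC`, MspI `C^CGG`, NlaIII `CATG^`, MluCI `^AATT`,
SbfI, SphI are shipped; any enzyme can be supplied via
`restriction_enzyme()`). Fragments tile each input sequence exactly and
are classed `AB`, `AA`, `BB` or `end`. Coordinates are 0-based
half-open internally; SAM output is 1-based. Recognition sites never
match across `N`; fragments may contain `N` and are counted by default
(an `exclude_N` option exists), and size windows are closed intervals.
Two modelling choices are deliberate: fragment length is the genomic
insert only (adapter contributions are a constant offset users can fold
into the window), and assemblies are used as supplied, without repeat
masking.

### Size selection and coverage

Size selection is modelled as a normal sampling density over fragment
length: a fragment of length $L_i$ enters the library with weight
$w_i \propto \phi\!\left((L_i - \mu)/\sigma\right)$, optionally truncated
by a hard window, normalised so $\sum_i w_i = 1$. The mean $\mu$ is the
selection target; $\sigma$ captures sizing precision — roughly 10–30 bp
for automated size selection and much larger for gel excision. With $R$
total reads allocated multinomially over the weights, per-fragment counts
are approximately Poisson ($R$ large, $w_i$ small), so the expected
number of loci at coverage $\geq c$ is

$$E(R) = \sum_i P\left(\mathrm{Pois}(R\,w_i) \geq c\right),$$

computed by `expected_regions_at_coverage()` with the default threshold
$c = 7$, the depth generally needed for confident short-read genotypes.
`simulate_read_allocation()` keeps the exact multinomial path for
validation; the test suite checks the two agree within Monte-Carlo error.

**Saturation.** Region accumulation in $R$ is sigmoidal: a lag phase,
a logistic rise, then an asymptote where new reads mostly deepen loci
already covered. `saturation_read_count()` operationalises the
asymptote as the first read budget, on a geometric grid, at which the
marginal gain $\mathrm{d}E/\mathrm{d}R$ falls below $\varepsilon$ after
having first exceeded it (skipping the lag phase). The default
$\varepsilon = 0.02$ regions/read — fewer than 2% of new reads hitting
new regions — is this package's operationalisation; no exact published
rule exists. It is exposed as a parameter and the saturating budget is
monotone in it.

**Fitting $\sigma$ to data.** Without a reference, observed regions
cannot be matched to genomic fragments, so `fit_selection_sd()` compares
rank-ordered coverage vectors: for each candidate $\sigma$ on a grid
(default 1–100 bp, step 0.5) it computes expected per-fragment coverage,
sorts both vectors (zero-padding the observed one to the fragment count),
and scores the Pearson $r^2$ of $\log(\mathrm{coverage}+1)$. Parameter
recovery on simulated data is exact to the grid step at realistic read
budgets (hundreds of thousands of reads over ~1000 fragments).

### Read budgeting

`reads_for_mean_coverage(n, c)` is the uniform-allocation budget
$R = n \times c$: 10,000 regions at 20× mean coverage cost 200,000 reads
per individual, so a 200M-read lane carries over 1000 individuals. The
correlated-recovery property — two samples of the same library design
show highly correlated per-locus coverage, unlike randomly sheared
libraries — is what makes this budgeting reliable, and is verified in the
test suite.

## The analysis pipeline

### Demultiplexing

Samples are identified combinatorially: an in-line barcode occupying the
first $k$ cycles of the genomic read, optionally crossed with a multiplex
index read. The sample sheet is a plain TSV/CSV (flowcell, lane, barcode,
index, sample_id). A read is assigned iff exactly one barcode of its
lane's set lies within one Hamming mismatch of its first $k$ bases; ties
are `ambiguous`, misses are `no_match`, and barcode bases are trimmed on
output so unique-sequence identity downstream excludes them. Distance is
substitution-only, matching the mismatch-based assignment rule; barcode
indels are not modelled. Index matching is exact, since index reads are
short and usually pre-binned by the sequencer. With a barcode set of
minimum pairwise distance 2 — `make_barcodes()` constructs such sets
deterministically from a parity-check code — a single sequencing error
can never re-route a read to the wrong sample, a property the suite
checks exhaustively over all single mutations of every barcode. Reads
are assigned on sequence alone; barcode base qualities are ignored.

### Collapsing

`collapse_reads()` merges character-identical reads into unique-sequence
records carrying per-sample counts, the arithmetic mean per-position
Phred quality (stored real, rounded only at SAM emission), and optional
mate associations. Nothing is filtered here — no singleton removal, no
quality gate — because most sequencing errors fall at non-polymorphic
sites and the affected reads still vote for the right locus in
clustering. Collapsing is order-invariant and lane results merge with
count-weighted qualities (`merge_collapsed()`).

### Clustering

All unique sequences are compared pairwise and clustered:

1. **Seeding.** Only pairs sharing an exact 11-mer are aligned
   (`kmer_candidate_pairs()`). By pigeonhole, 36 bp sequences with at
   most two mismatches always share an 11-mer, so the seed is lossless
   for the similarity range that matters; like any seeded aligner it can
   miss pathologically evenly-spaced divergence.
2. **Alignment.** Global Needleman–Wunsch with match +1, mismatch −1,
   linear gap −2 (Rcpp); identity = matches / alignment columns, so gaps
   and mismatches dilute identity the same way and the measure is
   read-length invariant. Reverse-complement candidates are also checked
   and flagged; ddRAD geometry makes same-locus reads co-oriented, but
   the check costs little and catches library artefacts.
3. **Graph.** An edge joins pairs with identity ≥ 0.80, weighted by
   identity. The floor is deliberately permissive: multi-SNP and
   indel-bearing haplotypes of one locus (say 4 SNPs in 36 bp, ~89%)
   stay connected — precisely the cases fixed-mismatch "stacking"
   heuristics drop — while the ~60% alignable identity between unrelated
   loci sits far below it. The floor exists for graph sparsity; no
   published value constrains it.
4. **Markov clustering.** `mcl_cluster()` implements MCL on the
   column-stochastic weighted adjacency with uniform self-loops:
   expansion (matrix power 2), inflation (elementwise power 2.0 with
   renormalisation), pruning of entries below 1e−5, iterated to a 1e−6
   fixed point; clusters are the connected components of the converged
   flow matrix. Since MCL can never merge disconnected components, it
   runs independently per component on sparse matrices, which keeps the
   cost linear in practice. Extraction order is deterministic. Inflation
   and all numerical knobs are exposed; the defaults are this package's
   calibration, as the original external-binary settings are unpublished.

### Ploidy-aware filtering

For each cluster and each individual with at least `min_reads` (default
5) reads in it, the filter computes the fraction of that individual's
reads outside its `ploidy` (default 2) most frequent unique sequences.
A cluster is discarded iff any evaluated individual's fraction strictly
exceeds `max_fraction` (default 0.10) — so tallies of 45/45/10 (exactly
10%) are retained and 40/40/20 discarded. The logic: in a true
single-copy diploid locus, non-top-two reads can only be errors, and at
per-base error rates of ~0.2% about `31 × e` ≈ 6% of ~31 bp reads carry
an error, comfortably under 10% (`expected_error_read_fraction()`);
whereas a cluster that collapses two loci shows the second locus's
haplotypes as a large excess. Coverage-based paralog filters assume
random coverage across loci, which correlated ddRAD recovery violates —
hence this count-based rule. Two choices are ours: the rule is applied
per individual with *every* evaluated individual required to pass (one
bad individual indicates collapse), and individuals under 5 reads are
not evaluated, since one error read among three would spuriously exceed
10%. A side effect worth knowing: at borderline coverage (tens of reads
per individual) the binomial tail of the ~6% error-read rate
occasionally crosses 10%, so marginal loci are sometimes discarded —
conservative, by construction.

### Pseudo-reference and SAM output

The pseudo-reference of a retained cluster is the most-counted of its
longest members (ties: lexicographically smallest). Members are
multiple-aligned by center-star progressive alignment: guide order is
descending count then length, each member is pairwise-aligned to the
first (the center) with the clustering scoring, and alignments merge
under "once a gap, always a gap". A star topology rather than a full
guide tree is sufficient here because cluster members are near-identical
short reads differing by a few substitutions or 1–2 bp indels; the
center — the most frequent sequence — is an excellent profile anchor.
`export_sam()` emits one `@SQ` per cluster (the ungapped pseudo-reference,
also written to FASTA), one `@RG` per sample, and per-observation records
with 1-based POS and CIGAR read off the alignment columns (reference-gap
columns → `I`, member-gap columns → `D`, else `M`). MAPQ is 255
(unavailable) and FLAG 0 after orientation normalisation. By default
each observation becomes its own record so depth-weighting genotypers
see true depth; `expand = FALSE` writes one record per member/sample
with an `XC:i:count` tag instead. Genotype calling itself is left to
standard tools (samtools/GATK) on the emitted BAM + FASTA.

## The synthetic-data generator

The generator exists so every stage is testable against known truth with
no downloads. Its defaults are the study conditions the pipeline is
validated under:

* genome: 1 Mb i.i.d. sequence at GC 0.42 (typical vertebrate);
* divergence: two parental lines with homozygous differences planted at
  1e−3 per base (a realistic fixed-difference rate between sister
  species); the first two samples are the pure parents, the rest draw
  each haplotype from either line (recombination-free F2-like
  genotypes); an outbred mode plants segregating variants with uniform
  allele frequencies instead;
* library: EcoRI + MspI, normal size selection (μ = 300, σ = 25),
  36-cycle reads of which 5 are barcode, 20,000 reads per each of 8
  individuals, substitution errors at 2e−3 per base with constant
  quality Q = −10·log10(e). Test-suite runs scale the genome and read
  counts down (0.1–0.5 Mb, 2–10 k reads/sample) to keep the default run
  fast; the acceptance script uses the full defaults.

Reads start at the enzyme-A (barcoded-adapter) cut end, matching ddRAD
geometry; paired mates from the B end are out of scope. The generator
does **not** emulate PCR duplicates, GC bias, quality decay along
cycles, indel sequencing errors, or lane-to-lane yield variation — so
passing tests demonstrate the algorithmic correctness of each stage
under a clean substitution-error model, not robustness to every
real-library artefact. `evaluate_recovery()` scores demultiplexing
accuracy, co-clustering of same-locus reads, read incorporation into
retained clusters, locus recovery at ≥7×, and planted-SNP
recall/precision by majority-matching unique sequences to their true
loci.

## Numerical and degenerate-case conventions

* Alignment traceback prefers diagonal, then gap-in-second-sequence,
  deterministically; identity of two empty-overlap sequences is defined
  by alignment columns, never 0/0.
* MCL non-convergence at `max_iter` returns the current state with a
  warning; empty graphs yield singleton clusters.
* A digest with no sites returns one `end` fragment; empty sequences
  return empty cut lists, not errors.
* All-zero selection weights (window excludes every fragment) is an
  error, as is fitting σ on fewer than 10 observed regions.
* Every stochastic function takes an explicit seed or respects the
  session RNG; identical seeds reproduce byte-identical outputs.

## Known limitations

* Complete digestion is assumed; partial digestion and methylation
  sensitivity are not modelled.
* Cut-site-disrupting variants cause allele dropout; the simulator
  reproduces this (truth keys are coordinate-based) but the pipeline,
  like the method itself, simply sees a locus with fewer haplotypes.
* The per-individual filter at low coverage trades locus count for
  paralog safety, as described above.
* The center-star MSA is exact for the near-identical members the
  pipeline produces but is not a general MSA tool.
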