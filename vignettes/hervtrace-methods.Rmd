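---
title: "Models and methods behind hervtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hervtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hervtrace` mines full-length endogenous retroviruses (ERVs) from genome
sequences and reconstructs their evolutionary history: which insertions are
shared between species by descent, which elements have exchanged sequence
with each other, and which overlap annotated ncRNAs. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic cohort used for validation does and does not
establish about real data.

## The alignment engine

Every stage reduces to local pairwise alignment, so the package carries its
own engine rather than shelling out to an external aligner. The core is
affine-gap Smith–Waterman in C++ with the BLAST gap convention (a gap of
length $L$ costs $open + L \cdot ext$) and a three-state traceback, so the
reported score is always the true score of the reported alignment path.

* Small problems (up to $2.5\times10^5$ DP cells) are solved by full
  dynamic programming — this covers every correctness-critical comparison
  (oracle tests, classification, LTR matrices).
* Larger problems use exact $k$-mer seeding ($k = 12$ nt, $k = 4$ aa),
  diagonal clustering (singleton seeds are discarded as noise), and banded
  dynamic programming around each cluster (±75 diagonals). A hit is kept
  only above a noise floor (raw 24 nt / 45 aa); within a cluster the
  aligner recurses on the flanking sub-windows so that co-linear matches
  split by stop codons or low-identity gaps are all reported. The heuristic
  decides only *where* to align; its scores are exact for the paths it
  reports, and the test suite holds the top hit equal to a brute-force
  dynamic-programming oracle (an independent prefix-max formulation kept in
  `tests/testthat/helper-oracle.R`).

Translated search translates the subject in all six frames (cached codon
lookup); stop codons are made unalignable (score $-10^6$), which terminates
open frames exactly, and gapped alignment never crosses frames —
frameshift-aware alignment is out of scope. Subject coordinates are mapped
back to forward-strand nucleotide space; identity and coverage are counted
in amino-acid columns.

Scores are normalised by Karlin–Altschul statistics,
$bit = (\lambda S - \ln K)/\ln 2$ and $E = K\,m\,n\,e^{-\lambda S}$, with
megablast-like constants for nucleotides ($+1/-2$, gap open = extend = 2.5,
$\lambda = 1.28$, $K = 0.46$) and ungapped BLOSUM62 constants for
translated searches ($\lambda = 0.318$, $K = 0.134$, gaps 11/1). These are
declared stand-ins for unstated aligner defaults, not fitted values; the
pipeline consumes only identity, coverage and bit score, all of which are
insensitive to the exact constants at the thresholds used. N (and X)
symbols align as mismatches and never count as identities.

## Discovery

The screen is anchored on reverse transcriptase (RT), the most conserved
retroviral region:

1. **RT screen** — translated search of a labelled RT panel against every
   contig at e ≤ $10^{-5}$ (the cutoff used by every search in the
   package).
2. **Merge** — footprints on one contig closer than 1,000 bp (strictly
   less) are coordinate-merged via `IRanges::reduce`; merging is
   order-invariant and preserves the footprint union.
3. **Competitive filter** — each candidate is searched against ERV, host
   and exogenous-virus protein panels and labelled by the best bit score;
   ties retain the candidate (erv > other_virus > host), a deliberately
   conservative choice because later stages can still reject it.
4. **LTR detection** — the candidate is extended 10,000 bp each side
   (clipped at contig edges) and the highest-scoring pair of direct repeats
   with one copy on each side is taken as the LTR pair, subject to length
   100–3,000 bp, a length ratio ≤ 2, and pair identity ≥ 80%
   (LTR-Harvest-like defaults). Raw local-alignment endpoints misplace
   boundaries in two ways: terminal mutations trim a few bases, and gapped
   extension through unrelated sequence occasionally keeps a barely-positive
   chance tail. The detector therefore refines each end, trimming any
   terminal alignment segment whose net score falls at or below 0.35 per
   column — the break-even line of a ~78% identity repeat, far below
   anything a qualifying LTR pair produces — and placing the boundary on
   the outermost retained match. The recovery contract is ±5 bp for the
   overwhelming majority of elements; residual errors of a few extra bases
   occur when mutations cluster at a terminus or a chance tail scores above
   the line.
5. **Gene annotation** — gag/pro/pol/env panels are searched against the
   internal region; per-gene footprints are merged with the same <1,000 bp
   rule (so a gene split by a short insertion re-merges), and annotations
   under 100 aa are discarded.
6. **Full-length call** — requires a `pol` annotation overlapping an RT
   footprint and gene order along the element strand consistent with
   gag–pro–pol–env (a subsequence; adjacent duplicate annotations of one
   gene are tolerated). The element strand is the strand of the best RT
   hit, the only strand signal that is always present. Candidates with LTRs
   but a failing call are retained with `is_full_length = FALSE` so every
   filter is auditable.
7. **Classification** — nearest RT reference by amino-acid identity, with
   `Unknown` below 60%; ties break by bit score then label, making the call
   deterministic. This replaces phylogenetic placement deliberately:
   similarity-based assignment is the package's design choice for a
   self-contained tool, and maximum-likelihood trees are out of scope.

Overlapping elements reached from different RT seeds are de-duplicated by
footprint overlap (the first, highest-sorted locus wins) — the merge step
makes genuine duplicates rare, and this is recorded as an assumption rather
than a rule inherited from any upstream definition.

## Vertical transmission

Orthologous insertions are recognised by the three-condition pair test on
elements with ~2,000 bp flanks ("~2,000" is implemented as exactly 2,000
with clipping at contig edges; flanks shorter than 250 bp auto-fail the
coverage condition rather than erroring):

1. element alignment with coverage and identity ≥ 90% — coverage is always
   measured against the **shorter** element, the symmetric reading of an
   otherwise ambiguous denominator;
2. both flank pairs (upstream–upstream, downstream–downstream, in element
   orientation) at identity > 90% — flanks alone are compared, not
   flank+LTR, the stricter of the two possible readings;
3. flank coverage > 25% on both sides and ≥ 80% on at least one.

All three flags are evaluated and reported even for failing pairs.
Same-species pairs are excluded before the graph stage: within-genome
similarity is paralogy or recombination signal and is handled by the
recombination module. Accepted pairs form a graph whose connected
components are the events (components, not cliques: one failed comparison
inside a true orthology group should not split the event); single-element
components are discarded. Each event is dated at the MRCA of its species
set on the ultrametric input tree — a *minimum* integration age.

A cheap seed-support prefilter (fraction of query positions inside exact
shared 12-mers) short-circuits element alignment for pairs that provably
cannot reach 90% identity (threshold 0.05, corresponding to roughly 78%
identity — far below any pair the test could accept).

The 90% thresholds impose a detection horizon: with flank divergence
$\approx 2 \cdot rate \cdot t_{MRCA}$, orthologs older than roughly
$0.05/rate$ MY fall below 90% identity and are correctly not recovered.
On the fixture tree at rate 0.002/site/MY the horizon sits at ~25 MYA:
root-age (29.4 MYA) insertions are expected to resurface only at shallower
nodes, and the validation treats them as out of envelope rather than as
recovery failures.

## Recombination

Within each (species × supergroup) stratum — recombination is only
meaningful between similar elements in one genome — all 5′/3′ LTR records
are aligned pairwise (full DP, both orientations, score-only) into a bit
matrix. An element is *non-clustered* when another element's LTR beats its
own partner LTR; a *call* requires the reciprocal pattern, with both
elements' own-pair scores exceeded, the two LTRs mapping to the two
distinct LTRs of the partner, and — one screw the score surrogate needs
that a tree does not — every cross match significant at e ≤ $10^{-5}$ for
its search space. Without that floor, two elements that each recombined
with *third* parties have noise-level own-pair scores, and noise-level
cross matches can exceed them. Ties never flag (the conservative reading of
"higher"). The two-sided requirement (both elements' own pairs exceeded) is
the package's resolution of an ambiguity; the weaker one-sided variant
would only add calls. Tests hold the score-based flags to ≥ 95% agreement
with a neighbour-joining cherry oracle built from independent alignment
distances.

## ncRNA co-option

Strand-aware interval intersection retains pairs with ≥ 1 bp overlap where
at least one feature's coverage is exactly 100% (full containment),
evaluated on full genomic spans, not exon structure. The packaged human
annotation table (107 records) is parsed as 1-based inclusive coordinates
and converted to the package's 0-based half-open convention on read; the
element's own span and supergroup are parsed from its name
(`species_chrom_start-end-CLASS`). A few printed records have ncRNA and
element spans that do not physically overlap; a validator flags them as
inconsistent but keeps them for the per-chromosome and per-class summaries
— the table is an annotation record, and silently dropping rows would
falsify the tallies. Whether those printed spans are ncRNA or merged
coordinates is unknowable from the table itself; the validator records, and
does not resolve, the discrepancy.

## The synthetic cohort

The simulator is the package's ground truth. It evolves an ancestral
segment down a timed species tree: an insertion assigned to node $N$ is
planted once in the ancestral sequence (so all of $N$'s descendants inherit
it at orthologous positions with identical flanking context), sequences
then diverge independently along each branch by per-site Jukes–Cantor
substitution, and per-insertion `missing` species model lineage loss by
excision at the leaf. Defaults are the fixture study conditions:

* a six-primate tree with splits at 6.7, 9.1, 15.8, 20.2 and 29.4 MYA;
* substitution rate 0.002 substitutions/site/MY, so leaf–leaf divergence of
  any orthologous region is $2 \cdot rate \cdot t_{MRCA}$ (≈ 4% identity
  loss per 10 MY of divergence time); indels are off — the simplest model
  that exercises the identity-threshold mechanics;
* 400 bp LTRs, identical at insertion; twin-LTR divergence accrues at
  $2 \cdot rate \cdot age$;
* gag 450 aa, pro 150 aa, pol 850 aa (with a 250 aa RT core), env 500 aa,
  back-translated with random synonymous codons **per insertion**, so
  same-family copies share proteins but sit near 75–80% nucleotide identity
  — as real family copies do, and low enough that cross-element condition-1
  tests and chimeric LTR pairings cannot fire;
* twelve orthology groups: two per internal node, two species-private ones
  (negative controls for single-species events), and one homininae-branch
  group lost in *Pan troglodytes*, which must surface as a Homo+Gorilla
  event dated 9.1 MYA;
* recombination is planted by exchanging the 5′ LTR sequences of two
  same-species, same-family elements, each swapped copy then mutated 2%;
* ncRNA features fully contain half of one species' elements on the same
  strand, with an opposite-strand container and element-free decoys as
  controls.

What passing against this simulator shows: the thresholds, coordinate
conventions, graph logic and dating arithmetic behave exactly as specified
on sequence data with known truth, at realistic divergences. What it does
not show: robustness to indels and segmental duplications, nested or
solo-LTR elements, assembly gaps, isochore composition, or selection —
real-genome features the model deliberately omits. Problem sizes used
throughout validation (a 50-element genome of ~0.7 Mb, the six-species
cohort of ~0.8 Mb total, 100 swap-free replicate strata, 200 oracle pairs,
500 × 500 feature sets) were chosen as the smallest scales at which every
rule of the method is exercised with comfortable statistical margins.

## Degenerate inputs and tie-breaking, in one place

* Empty sequences, non-IUPAC symbols, empty panels, strandless features in
  strand-aware mode, unknown species labels and unknown tree nodes raise
  classed input errors naming the offender.
* Missing flanks fail condition 3; elements missing an LTR are skipped from
  recombination with a warning; unparseable element names count as
  `Unknown` with a warning.
* Competitive-filter ties retain the ERV label; classification ties break
  by bit then label; recombination ties never flag; merged intervals with
  discordant strands carry `"."` until the RT hit decides.
* All coordinates are 0-based half-open internally; conversion to 1-based
  inclusive happens only at report boundaries (GTF output, the annotation
  table dialect).

## Interfaces

Tabular results are tibbles; result objects carry `tidy()`, `glance()` and
`autoplot()` methods. `run_pipeline()` drives the stages over files
(FASTA/BED/GTF/TSV/newick/YAML) and writes a `manifest.yml` with input
checksums, the config snapshot and the stage-count funnel; the thin
command-line wrapper in `inst/scripts/hervtrace.R` exposes the same six
subcommands. The `transmit` stage accepts the `discover` stage's BED
unmodified (species and supergroup are recovered from element names);
`recombine` needs the full element TSV, because BED6 cannot carry LTR
coordinates.
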