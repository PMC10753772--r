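---
title: "Comparative analysis of reduced plastomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of reduced plastomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastocomp)
```

## The scientific problem

Parasitic plants relax selection on photosynthesis genes, and their plastid
genomes shrink: inverted-repeat (IR) copies are lost, *ndh* genes are deleted
or pseudogenized, and whole gene blocks disappear. In the hemiparasitic vine
genus *Cassytha* (Lauraceae), all sequenced plastomes are single circular
molecules of roughly 114 kb that lack the canonical quadripartite
LSC/IRa/SSC/IRb layout. Comparing several conspecific and congeneric
plastomes answers three questions: which mutation types shape these genomes
(substitutions, slipped-strand indels, hairpin-mediated micro-inversions),
where the divergence hotspots useful for DNA barcoding lie, and whether
individuals group by species.

`plastocomp` implements that comparative workflow as testable components:
variant calling on a whole-plastome multiple alignment, micro-inversion and
hairpin-stem characterization, sliding-window nucleotide diversity,
p-distance matrices with neighbor joining, and structural comparison against
a quadripartite reference. A synthetic-plastome generator plants every event
class with a machine-readable truth ledger, so each caller can be scored at
exact precision and recall without downloading data.

## Coordinates and containers

All coordinates are 1-based inclusive, the R/Bioconductor (IRanges)
convention. GFF3 and GenBank are natively 1-based inclusive, so the package
has no coordinate conversion at format boundaries; the cost is borne once,
in this documented convention, rather than at every I/O call. Genomes are
`genome_record` objects (sequence over `{A,C,G,T,N}` plus named, stranded,
possibly multi-interval features); ambiguity codes other than `N` are
rejected at read time because the analyses assume resolved assemblies.
Circular genomes are rotated on read so that `trnH-GUG`, when annotated,
starts at position 1 — the conventional plastome linearization — making
coordinates comparable across individuals. Trees are `ape` "phylo" objects;
FASTA goes through Biostrings and GFF3 through rtracklayer. GenBank flat
files are read and written by a minimal parser covering the feature subset
the package emits (gene/tRNA/rRNA/misc keys, `join()` and `complement()`
locations, `/pseudo`); its output is conformance-tested against an
independent parser.

## Event models

**Substitutions.** A substitution is a polymorphic alignment column among
the evaluated rows. Columns containing a gap in any row are excluded — they
belong to indel events — and `N` is missing data: it never makes a column
polymorphic. Columns inside called micro-inversions are masked before
substitution calling so that inversion mismatches are not double-counted as
SNPs; this keeps the mutation tally additive
(`total = substitutions + indels + inversions`).

**Indel events.** An indel event is a *maximal run of columns sharing one
gap/non-gap row pattern*; adjacent columns with different bearer patterns
are distinct events. Counting events rather than gap columns matches how
indels are tallied in published plastome comparisons (hundreds of events
across a 114-kb alignment, not thousands of gap columns).

**SSR classification.** Published comparisons split indels into SSR
(slipped-strand) and non-SSR events without defining the rule. The package's
explicit rule: an event is SSR iff its fragment is an integer number of
copies of some motif of length 1–6 bp *and* at least one additional adjacent
copy of that motif flanks the event site in a gap-free row. The smallest
qualifying motif is reported. Both parameters (`max_motif`,
`min_extra_copies`) are exposed. The classifier is validated against a
brute-force motif enumeration.

**Micro-inversions.** Between two rows, an inversion appears as a maximal
run of mismatching, gap-free columns whose segment on one row equals the
reverse complement of the other row's segment (identity excluded). Detected
loops of 2–46 bp are in range; longer runs are reported but flagged. One
limitation follows from the mismatch-run formulation: a loop with a position
complementary to its reverse counterpart produces an interior matching
column that splits the run, so such loops are not recoverable as single
events. The generator therefore plants loops in which every position
differs after inversion; real loops violating this would be reported as
split or missed events.

**Hairpin stems.** The flanking inverted-repeat pair is searched on the
genome around each loop: the longest window pair (3–23 bp by default), each
at most 5 bp from the loop, with upstream = revcomp(downstream) up to
`max_mismatch` mismatches. Ties break toward longer stems, then smaller gap
to the loop, then leftmost. Both stems are reported as read 5'→3' on the
forward strand, the convention of published hairpin tables. The default is
exact pairing (`max_mismatch = 0`); the bundled 24-record hairpin table
contains two records (psbM-trnD and the second ycf2) whose printed stems are
not exact reverse complements, and the package *reports* them as
non-palindromic rather than forcing them to validate — whether they are
typographic or reflect a mismatch-tolerant stem definition cannot be decided
from the published table, so both behaviors are supported and neither is
asserted as truth.

## Diversity and distances

Nucleotide diversity π is the mean over unordered row pairs of per-site
differences, under *complete deletion*: only columns free of gaps and `N`
across the whole evaluated subset count (the default behavior of the
standard desktop tool for this analysis). The two-sequence distance uses
*pairwise deletion* — with two rows the two conventions coincide. Divergence
is the uncorrected p-distance by default: at the 10⁻⁵–10⁻² scale of
conspecific plastomes, multiple-hit correction is numerically negligible;
Jukes–Cantor is available as an option. The sliding scan uses 600-bp windows
at 200-bp steps over aligned coordinates (window coordinates are alignment
coordinates, not one genome's physical coordinates; hotspot labels map
through the designated reference row). The last window is truncated; windows
with fewer than 100 net sites are excluded from hotspot *ranking*, because a
near-empty terminal window would otherwise top the per-site ranking on a
single substitution. Columns of called micro-inversions can be excluded from
π: their mismatches are inversion events, not substitutional diversity, and
a single 46-bp loop otherwise outweighs a genuine hotspot.

The within/between-species summary reports
`ratio = mean_between / mean_within`. On the bundled eight-plastome
divergence matrix this ratio is about 10.5, consistent with the published
claim that between-species differences exceed within-species differences
more than six-fold (the max-within/min-between reading gives only 5.5×, so
the mean ratio is the only consistent interpretation).

## Structural comparison

`find_ir()` locates the longest pair of disjoint intervals where one equals
the reverse complement of the other, by exact 21-mer seed matching between
the sequence and its reverse complement followed by ungapped extension;
assembled plastome IR copies are near-identical, so exact seeds suffice, and
`min_ir = 1000` bp separates true IRs (tens of kb in references) from small
dispersed repeats. `missing_segments()` works in gene-name space, the space
in which published comparisons reason: maximal runs of reference genes
absent from the query, bounded by shared genes, with reference coordinates
and flanking gene names. `call_pseudogenes()` flags a shared protein-coding
gene on any of three evidence types: observed length below 90% of the
reference length (truncation; published ψ*ndh* length ratios are 0.14–0.55,
far below this threshold), length not divisible by 3 (frameshift), or a
premature stop under the bacterial/plastid genetic code (NCBI table 11).
Genome summaries count unique gene names (IR duplicates once) and exclude
pseudogenes from all categories.

## Distance trees

`neighbor_joining()` is the standard Saitou–Nei agglomeration with a
deterministic tie-break (lexicographically smallest pair of subtree lead
labels). Negative branch-length estimates are clamped to zero and counted in
the tree's `clamped` attribute, per common practice. On additive matrices NJ
is consistent, and the implementation is tested for exact recovery of
generating trees and cross-checked against an independent NJ implementation.
`is_reciprocally_monophyletic()` asks whether any single edge of the
unrooted tree splits the leaves exactly into the two species groups.

## The synthetic study design

The generator emulates a two-species, four-individuals-per-species plastome
study on a 30-kb genome (tractable for test suites; the machinery is
length-agnostic up to full plastome size). Events are scaled from the
published 114-kb spectrum by genome length: 50 SSR indels, 14 non-SSR
indels and 6 micro-inversions (≈ 30/114 of 195, 54 and 24).

**Ancestor.** A quadripartite circular genome: LSC/IRa/SSC/IRb with
IRb = revcomp(IRa) and mirrored features; 73 protein-coding + 30 tRNA +
4 rRNA = 107 functional genes in near-canonical order, including all 11
*ndh* genes; intergenic spacers seeded with mono- and dinucleotide SSR runs
(the slippage substrate); coding sequences built from non-stop codons with a
single terminal stop, so intact genes translate cleanly.

**Structural reduction.** Applied to the ancestor before the species split,
mirroring the biology (reduction precedes divergence): one IR copy deleted;
two three-gene *ndh* blocks excised (*ndhC/K/J* and *ndhG/I/A* with their
spacers); five *ndh* genes truncated to pseudogenes at kept fractions
0.55/0.28/0.52/0.14/0.46 — the published ψ/intact length ratios.

**Mutation process.** A two-level model reproduces the within/between
divergence hierarchy: each species receives a stem mutation set shared by
its individuals (binomial draw at `subst_rate_between/2` per site), each
individual a private set (at `subst_rate_within/2`). Defaults 5.7×10⁻³ and
5×10⁻⁴ give expected pairwise substitution distances on the published scale.
The realized whole-alignment p-distance between species modestly exceeds the
substitution rate because micro-inversion loop columns also mismatch — as
they would in a real whole-plastome distance. A designated long spacer
(downstream of `trnQ-UUG`) receives 40 additional species-stem
substitutions, creating the planted diversity hotspot.

**Placement discipline.** All point events are placed in intergenic
regions, non-overlapping, with at least 4 bp spacing (rejection sampling,
retry cap 1000; non-SSR indels block a 6-bp flank so later substitutions
cannot create SSR context around them). Keeping events out of coding
sequence means planted point mutations never confound the
pseudogene/structure oracle, and spacing ≥ 2 guarantees substitutions never
form two-column mismatch runs that could masquerade as inversions. The
emitted alignment is the *truth* alignment — no realigner runs — so recovery
tests are exact by design: they validate the callers' logic, not an
aligner's robustness. Consequently, passing recovery says nothing about
MAFFT-induced gap-placement ambiguity in real data, about events inside
coding sequence, or about rate heterogeneity and recombination, none of
which the generator models.

**Determinism.** One integer seed drives everything through a private RNG
scope; identical configurations produce byte-identical outputs.

## Numerical and degenerate-input choices

* π is `NA` (not 0) when a window has no net sites.
* `find_stems()` returns an explicit no-stem result, not an error.
* Zero comparable columns between two rows is an error (a distance of 0
  would be a silent lie).
* NJ requires n ≥ 3; equal-distance matrices resolve as stars with
  zero-length internal edges.
* Base composition of synthetic genomes is uniform; observed GC (~50%) is
  higher than real plastomes (~37%). No analysis in the package depends on
  base composition, so realism here was traded for simplicity.

## Problem sizes used by the test suite

The suite validates recovery on twenty 30-kb two-species designs,
oracle-checks π on random alignments up to 10 rows × 1 kb against a
brute-force pairwise computation (tolerance 10⁻¹²), and NJ on additive
matrices of 4–8 taxa against exact tree recovery. These sizes exercise every
code path; nothing in the implementation is specific to them.

## A worked example

```{r example, eval = FALSE}
library(plastocomp)

sim <- simulate_plastomes(sim_config(seed = 1))
rec <- recovery_report(sim)
str(rec[c("substitutions", "indels", "inversions")])

# published record tables bundled as plain text
hp <- validate_hairpins(cassytha_hairpins())
range(hp$loop_size)      # 2 46
sum(!hp$palindromic)     # 2

cd <- cassytha_divergence()
group_summary(cd$matrix, cd$partition)$ratio   # ~10.5
tree <- neighbor_joining(cd$matrix)
is_reciprocally_monophyletic(tree, cd$partition)  # TRUE
```

## Known limitations

Alignment computation (e.g. MAFFT) is upstream and out of scope; the
callers consume a given alignment. Micro-inversion detection is pairwise
against a designated reference row and merges calls by interval identity;
nested or overlapping inversions are not modeled. IR detection is
exact-match; highly diverged IR copies would need mismatch-tolerant
extension. The pseudogene caller reasons from annotation lengths and
translation, not from expression evidence.
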