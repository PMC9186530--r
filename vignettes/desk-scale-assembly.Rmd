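---
title: "Desk-scale string-graph assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale string-graph assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`graphasm` re-creates, at desk scale, the assembly methodology used for
complete telomere-to-telomere human genome reconstruction: a bidirected
string graph built from homopolymer-compressed accurate long reads,
ultra-long noisy reads to arbitrate repeat tangles, a sparse de Bruijn
"morph" assembler for rDNA-like tandem arrays, and a validation suite
based on coverage uniformity, unique k-mer markers and windowed identity.
Every stage is exercised against a synthetic genome and read simulator
that carries full ground truth, so the package is self-verifying without
any external data.

"Desk scale" means problem sizes of tens to hundreds of kilobases and
read lengths scaled accordingly (accurate reads around 20 kbp, ultra-long
reads around 100 kbp, as in the real technologies; genomes around 200 kbp
rather than gigabases). The vignette records the models, the tunable
parameters with their defaults and rationale, the numerical choices, and
the design decisions taken where the method description leaves the design
open.

# The assembly model

## Homopolymer compression

Accurate long reads err almost exclusively by lengthening or shortening
homopolymer runs. Collapsing every run to a single base (`hpc_compress`)
removes that error mode while keeping a bidirectional coordinate map and
the run lengths, so the transform is exactly invertible
(`hpc_decompress`) and compressed-space coordinates can be lifted back.
All overlapping, correction and graph construction happen in compressed
space; run lengths re-enter only at consensus time.

The simulator mirrors this: 80% of simulated accurate-read errors are
homopolymer-length ±1 indels targeted at existing runs, the remainder
substitutions. In compressed space the indels vanish and the residual
error rate drops by more than half — which is precisely the rationale for
the transform.

## Correction and masking

All compressed reads are aligned to one another (`all_pairs_align`:
shared sampled k-mer seeding, banded edit-distance verification at an
identity floor of 0.98 — checked on *both* ends of long overlaps, since
an alignment can be homologous at one end and garbage at the other, as
when a repeat-internal match runs into non-homologous flank) and
corrected by a strict per-column majority (`correct_reads`): a symbol is
replaced only when the majority has at least `min_depth = 4` supporting
reads and at least `min_support_ratio = 4` times the read's own symbol
count. Ties are never corrected — a 50/50 column is a putative repeat or
heterozygous difference, not an error.

Columns inside simple-sequence-repeat masks (`find_microsatellites`,
period ≤ 6, ≥ 3 copies, ≥ 10 bases, defaults chosen here and
configurable) are treated specially: substitutions there never count as
differences during overlapping (wildcards), and corrections require a
much stricter super-majority (`mask_ratio`, default twice
`min_support_ratio`). The stricter rule matters because a repeat-length
error changes the *compressed length* of a read, and position-wise exact
overlapping then fails for every read carrying one; normalising tract
lengths toward an overwhelming pileup consensus restores overlap
compatibility, while genuinely polymorphic repeats (a split pileup) are
still never touched.

The correction is implemented over banded pairwise alignments rather than
gapless columns so that all three compressed-space error forms are
correctable: substitutions, spurious extra bases (majority gap), and
missing bases (majority insertion). The last class matters: a substitution
inside a run merges two runs and deletes a compressed base; without
insertion-restoring correction essentially every read would retain one
such error and no exact overlap would survive. A single pass over the
uncorrected read set is used, so the result is order-independent;
`correction_rounds` allows iteration but one pass suffices at the
simulated error rates.

## Exact overlaps and the bidirected graph

After compression, correction and masking, only exact suffix–prefix
overlaps are considered (`exact_overlaps`), with masked positions acting
as wildcards and containments flagged separately (excluded from edges,
retained for depth). The graph is bidirected: every element has a forward
and a reverse vertex and every edge has a complement; unitigs are maximal
chains after Myers transitive reduction. `simplify_graph` then iterates
transitive reduction, tip clipping and small-bubble popping to
convergence (cap 10 iterations).

Two scale-dependent defaults are set from the data rather than fixed:

* `min_overlap` defaults to 40% of the median compressed read length.
  The near-identical repeat copies the simulator produces (99.9%
  identity means one difference per ~1,000 compressed bases) admit
  *exact* cross-copy overlaps wherever a difference-free window longer
  than `min_overlap` exists; at 40% of a read length such windows are
  rare, so the copies stay separated and are instead resolved by reads
  spanning them. At the spec's literal 500 bp default the copies braid
  together at these problem sizes.
* `tip_len` defaults to 1.6 median read lengths. A read with a residual
  error near one end forms a dead-end node of nearly read length — tips
  here are read-scale objects, not short stubs.

One further construction step proved necessary at desk scale: reads whose
only placement is on below-noise (multiplicity-0) nodes are purged and
the graph rebuilt. A read with one mid-read residual error otherwise
becomes a low-depth *bridge* through which transitive reduction removes
the true long overlaps between its neighbours, and the artifact node then
interrupts every walk. The purge spares one class of low-depth node: a
read whose overlap partners fall into two different components of the
purged graph is the *only* read spanning a thin junction — a genuine
bridge, kept with multiplicity 1, not an artifact.

## Multiplicity and walks

Node multiplicity is the rounded ratio of node depth to the base depth
(median depth of the longest decile of nodes), with depth below 0.2 of
base flagged as multiplicity 0 (candidate artifact). When the base depth
is estimated automatically, a flow-consistency refinement is applied: if
every in-neighbour of a node end has out-degree 1, each of their
traversals must continue into the node, so its visits are at least the
sum of their multiplicities. This corrects repeat cores shorter than
about two read lengths, whose recorded depth is diluted because the
flanking unitig chains absorb most repeat-spanning reads.

`enumerate_candidates` lists all ways to cover a component with walks
that traverse each node exactly its multiplicity, starting from free node
ends and extending while possible, capped at `max_candidates = 10000`
(beyond the cap the result is reported ambiguous rather than sampled).
Candidates are *walk sets* because one component can legitimately carry
several chromosomes that share a repeat; among the enumerated sets only
the most parsimonious (fewest walks) are kept — extra walks arise from
early termination, not alternative structures.

`align_ont_to_graph` threads ultra-long reads through the graph by unique
anchor k-mers and adjacency-constrained chaining. Because edge overlaps
duplicate sequence between neighbouring node chains, each overlap region
is indexed on only one node (the shorter one, so short repeat cores stay
anchorable). `select_walk` counts *discriminating* reads — multi-node
paths consistent with some but not all candidates — and resolves when the
winner has `min_margin = 2` times the runner-up's support. This
generalises "a read supports a walk if it fully traverses a repeat node":
partial repeat entries are consistent with every candidate and carry no
evidence, while the generalisation also arbitrates ambiguities between
multiplicity-1 nodes that the literal rule can never resolve.

## Consensus

`walk_consensus` lays out the chosen walk, trims edge overlaps, and sets
each compressed position's run length to the modal run length among the
reads placed there, ties broken toward the smaller run (deterministic,
and biased with the left tail of the accurate-read run-length error
distribution). Positions with no read support emit the compressed base
with run length 1 and are recorded as low-coverage issues.

# The rDNA-like morph assembler

Tandem arrays of near-identical units defeat the string graph: identical
within-morph copies produce exact overlaps at unit shifts. The morph
module instead works in unit space:

1. `build_sparse_dbg` samples canonical k-mers by hash (`hash %% stride
   == 0`), so every read samples the same genome k-mers regardless of
   its start or strand — positional striding would give each noisy read
   a private node set. Edges are recorded between consecutive *solid*
   k-mers per read (two-pass build) with the intervening sequence.
2. `extract_walks` threads each read through its clean solid anchors and
   re-renders the sequence from the best-supported short edges; at
   detectable branches (a second edge carrying ≥ 25% of the support — the
   signature of a morph-distinguishing variant) it refuses to impute and
   falls back to the read's own bases.
3. `segment_units` cuts the sequence at approximate occurrences of the
   reference unit origin (the unit phase convention is position 0 of the
   provided reference). Complete units are within 10% of the reference
   length at ≥ 90% identity; flanking partials are marked incomplete.
4. `polish_units` aligns every unit to the reference (affine-gap),
   projects it onto reference columns, and corrects each column to the
   majority — except *polymorphic* columns, where the majority does not
   dominate the rest of the column fourfold: those are never corrected,
   for any unit, because that is where morph variation lives. A second
   phase exploits allele linkage: at a 5% read error rate roughly one
   unit in eight carries an error exactly at a morph-distinguishing
   column, and since those columns are protected, per-column majorities
   can never fix it — but a unit whose genotype over the polymorphic
   columns sits within one-third Hamming distance of exactly one
   well-supported pattern is repaired to that pattern. Without this,
   "one-flip" units bridge the single-linkage clusters at some seeds.
   Working in reference coordinates collapses length variation; morphs
   that differ only by insertions would not survive this polish
   (documented limitation — the simulator's morphs are
   substitution-diverged).
5. `cluster_morphs` single-links the polished units at 99.5% pairwise
   identity (the default sits between within-array unit identity, often
   100%, and the 99.4–99.7% observed between arrays) and takes a
   majority consensus per cluster.
6. Copy numbers come from the array-spanning reads (`spanning_walks`
   verifies that both terminal fragments are flank sequence, not mid-unit
   pieces): each spanning read observes the whole array, so the morph's
   copy number is its unit observations divided by the number of spanning
   reads, rounded with ties up, minimum 1.
7. `layout_array` searches unit orders consistent with the morph graph
   adjacencies and the read paths (full-array read paths are candidate
   orders themselves, which keeps the search robust to an off-by-one
   copy-number total). A unique sufficiently-supported order is emitted
   with `model = FALSE`; otherwise morphs are arranged in descending
   copy-number blocks and flagged `model = TRUE` — a model sequence whose
   internal order is not read-supported, never silently presented as
   resolved.

The package-level analysis (`analyze_rdna_array`) segments the *raw*
ultra-long reads and relies on the reference-coordinate polish for
denoising. The graph walks remain available (`extract_walks`) and
measurably reduce read error, but morph variants whose k-mers happen to
escape the hash sampling are invisible to the branch detector and would
be silently imputed toward the majority morph, producing occasional
chimeric units that bridge single-linkage clusters; unit-space polishing
with polymorphic-column protection does not have that failure mode.

# The simulator

`simulate_genome` builds a haploid genome from a seed-determined
specification: random backbone (one or more chromosomes), repeat families
diverged to a given identity by uniform point mutation, satellite-like
arrays, an rDNA-like array that is a tandem of morph units in a shuffled
or block arrangement (the true order is recorded), optional
homopolymer-dense tracts, and GA-rich tracts. `simulate_hifi` and
`simulate_ont` draw reads to a target depth with truncated-normal and
lognormal length distributions respectively; read starts overhang
chromosome ends and are clipped, so terminal coverage is uniform. All
outputs are deterministic functions of (specification, seed).

GA-dropout is modelled as suppression (probability 0.98) of reads whose
span would cross the tract: the sequencing of such molecules fails. Pure
start-point suppression cannot reproduce the observed coverage-collapse
phenotype when reads are longer than the tract, because spanning reads
would still cover it.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: diploidy and heterozygosity, chimeric or
adapter-bearing reads, quality strings, context-dependent error hotspots
beyond homopolymers and the GA model, satellite-specific coverage biases,
and mappability structure at chromosome scale. Results on this generator
demonstrate algorithmic correctness under controlled conditions, not
performance on real sequencing runs.

# Validation statistics

* `coverage_profile` / `flag_coverage`: per-position depth, with the
  in-band region mean ± 3 s.d.; perfectly constant coverage (s.d. 0)
  counts as fully in-band by convention. Below-band intervals become
  `low_coverage` issues, above-band intervals `error` candidates.
* `unique_markers`: canonical k-mers (default k = 21) occurring exactly
  once assembly-wide; `marker_assign` sends each multi-mapping read to
  the candidate span containing the most markers also present in the
  read, keeping the primary alignment (flagged low-confidence) when no
  marker agrees anywhere.
* `allele_ratio`: per-window primary/(primary + best secondary) support;
  windows under 0.8 at ≥ 10× depth are flagged heterozygous-variant
  candidates.
* `window_identity`: per-window maximum identity against any window of
  the partner sequence (shared-k-mer prefilter, banded global alignment),
  boxcar-smoothed; identical sequences give 100%, 1%-mutated about 99%,
  unrelated DNA about 45–50% (the background of unit-cost global
  alignment of random sequences).
* `assembly_stats`: contigs split at runs of ≥ 3 Ns; NG50 relative to a
  fixed genome size; `issue_catalog` merges issues per kind and reports
  the affected fraction.

# Problem sizes and determinism

The shipped tests and the acceptance script use: a 200 kbp single
chromosome (15 kbp two-copy repeat at 99.9%, 12-unit two-morph array) at
30×/40×; a pair of 24 kbp chromosomes sharing an identical 8 kbp repeat
(longer than the 5 kbp accurate reads) at 20×/25× over 20 seeds; and a
14 kbp genome hosting the morph array at 40×. These sizes keep each
analysis in the minutes range on one CPU while preserving the structural
phenomena of interest (repeats longer than reads, arrays with identical
units, coverage-diluted repeat cores). The rDNA toy unit is 800 bp: at
99.0% inter-morph identity that is eight distinguishing substitutions per
unit, enough to cluster at a 99.5% threshold; much shorter units would
carry too few differences for the thresholds to be meaningful.

Every random quantity flows from an explicit seed: the genome from its
specification seed, each read set from its own seed, and the acceptance
script derives all of its seeds from the single `--seed` argument. No
stage reads the system clock or global state.

# Known limitations

* Multiplicity estimation assumes roughly uniform coverage; strong
  coverage biases would propagate into wrong repeat counts (the flow
  refinement corrects topologically forced cases only, and only when
  repeat copies lie in the same orientation).
* Walk enumeration is exhaustive with a cap; components whose tangles
  exceed the cap are reported ambiguous rather than sampled.
* The GA-dropout gaps are reported as separate contigs and flagged; no
  patching against a prior assembly is attempted.
* Morphs distinguished only by insertions relative to the reference unit
  collapse under reference-coordinate polishing.
* Inter-chromosomal repeats in opposite orientations can defeat the
  flow-based multiplicity refinement; the enumeration then sees a
  multiplicity-1 core and reports the component ambiguous.
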