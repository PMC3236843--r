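---
title: "Methods: homology-transferred reference networks from ESTs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-transferred reference networks from ESTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(korefnet)
library(dplyr)
```

## The annotation-transfer model

The package annotates ESTs of an organism with no curated pathway
information by transferring KEGG Orthology (KO) labels from curated model
organisms. The underlying assumptions are the standard ones of best-hit
orthology transfer:

* gene structure and function are conserved enough that the most
  significant homology hit of a short expressed fragment usually lands in
  the true ortholog group;
* a KO group is a good unit of transfer — any member gene of the right KO,
  in any reference organism, yields the same functional label;
* pathway topology is conserved, so a reference KGML map with the
  organism's matched KO nodes highlighted is a meaningful first sketch of
  that organism's network.

These assumptions fail for fast-evolving families, lineage-specific
paralog expansions, and chimeric or low-quality ESTs; the benchmark
module exists precisely to quantify how often they hold.

### Best-hit selection

For each query and reference organism, hits are read from BLAST tabular
output and filtered at an E-value cutoff of 10 (the permissive BLAST
default). The boundary is inclusive: only hits *strictly above* the
cutoff carry no statistical support and are discarded. Among survivors
one hit is selected under the total order

> E-value ↑, bitscore ↓, percent identity ↓, identity count ↓,
> subject id ↑ (lexicographic).

The first four keys are the quantities a homology search reports about
alignment quality; the final lexicographic key exists purely to make the
order *total*, so selection is deterministic and independent of input
row order. Per-organism winners are then consolidated to one global best
hit per query under the same order. Applying the cutoff per organism
first and consolidating afterwards mirrors how per-organism searches are
actually run (each with the shared default cutoff); since consolidation
is a further minimum, the result is identical to filtering the pooled
table.

Reverse-frame coordinates (`qstart > qend`, as translated searches emit
for minus-strand frames) are accepted verbatim; frame information plays
no role in ranking. For 12-column input without an `nident` column the
identity count is derived as `round(pident × length / 100)`, rounding
half away from zero — a fixed rule rather than locale-dependent
behaviour.

### KO assignment

The selected subject gene is looked up in its organism's gene → KO
table. A gene may legitimately carry several KO labels; the query
inherits the full set, and the lexicographically smallest member is
designated `primary_koid` for single-label outputs. This loses no
information while keeping every downstream artifact deterministic. A
best hit whose subject gene is unannotated leaves the query *unassigned*
— there is deliberately no fallback to the second-best hit, because
selection is defined as maximum-one-target; a fallback would silently
change the method.

### Pathway graphs and projection

KGML maps are parsed into explicit graph objects: entries (nodes) with
their KO id sets, relations and reactions (edges), and graphics
attributes kept verbatim so a map re-serializes byte-for-byte. The
gene-level *interaction graph* of a map keeps ortholog/gene/enzyme
entries as nodes; group entries (complexes) are expanded onto their
members, so a relation touching a complex is shared by every member.
Compound and map-link elements are navigation and chemistry rather than
gene regulation and are dropped from the interaction view (but preserved
in the graph object). Whether reaction co-membership also counts as an
edge is a genuinely open modelling choice: we include those edges by
default on metabolic (and unclassified) maps, where shared catalysis is
the interaction of interest, and exclude them on non-metabolic maps —
overridable via `include_reactions`.

A query maps to a pathway exactly when its KO set intersects the KO set
of some node of the map — pure set intersection, no scores. Matched
nodes are flagged for highlighting (red by default, matching the
long-standing convention for "present in this organism") and relabelled
with the smallest matched KO. Exports (SIF, GraphML, TSV, annotated
KGML) order nodes and edges deterministically so identical inputs give
byte-identical files.

Pathway classification into metabolic vs non-metabolic uses a
user-supplied two-column table; for map numbers absent from the table we
fall back to the KEGG numbering convention (map numbers below 02000 are
the metabolism block). Keeping the truth table external makes the
classification overridable when KEGG reorganises categories.

### Coverage accounting

Coverage statistics count queries mapped to metabolic maps, to
non-metabolic maps, and to both, at the *query* level: a query touching
at least one map of each class is counted once in each class total and
once in "both". This is the only reading under which the class totals
and the union obey inclusion-exclusion
(`n_met + n_nonmet − n_both = n_mapped`), which the test suite asserts on
every generated mapping.

### Benchmark

The leave-one-organism-out benchmark withholds a curated organism,
re-annotates ESTs derived from its genes using the remaining organisms,
and scores a gene as matched when its assigned KO set intersects its
curated KO set. The denominator is *all* curated genes, assigned or not
— an unassigned gene is a failure of the transfer, not a unit to be
dropped. Set intersection (rather than primary-vs-primary equality) is
the default so multi-KO genes are not penalised for an arbitrary label
ordering; `strict = TRUE` gives the harsher criterion. Accuracy is
reported to one decimal, rounding half away from zero.

## The synthetic world

The generator builds everything the pipeline consumes, with ground truth
recorded: one ancestral 900-nt gene per KO; per organism, descendants
mutated from the ancestor; ESTs as contiguous 300-nt fragments of
uniformly chosen source genes with per-base substitutions; per-organism
annotation tables; KGML maps over random KO subsets; and a category
table alternating metabolic / non-metabolic so both classes are always
populated in coverage tests.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `gene_len` | 900 nt | a typical modest ORF length |
| `fragment_len` | 300 nt | a single-pass EST read |
| `divergence` | 0.05 /base | cross-taxon divergence of conserved orthologs; makes organisms distinct but keeps true hits dominant |
| `mutation_rate` | 0.05 /base | sequencing error plus query-lineage divergence |
| `hit_noise` / `decoy_hit_rate` | on / 0.1 | occasional spurious hit per query-organism pair, as real searches produce |
| `relation_density` | 0.3 | sparse but connected maps |

Hit tables are emitted directly rather than by running an aligner, with
a transparent pseudo-score scheme: `nident` is the identity count of the
true ungapped alignment (at the fragment's source coordinates for true
hits, at the best offset along a wrong-KO gene for decoys),
`bitscore = 2 × nident`, and
`evalue = query_len × subject_len × 2^(−bitscore)`, floored at 1e-180.
The scheme is monotone in alignment identity and spans realistic
magnitudes while remaining auditable by hand. One structural consequence
is worth stating: an unrelated 300-nt decoy aligns at roughly 25%
identity (~95/300 at its best offset), while a true hit at even a 30%
query mutation rate retains far higher identity, so under this scheme
decoys are strictly inferior throughout the moderate mutation range and
the benchmark's accuracy-vs-mutation curve is flat (at 100%) over the
sweep `{0.05, 0.15, 0.30}` — the monotone non-increase that the tests
assert holds with equality. Decoys would only overtake near random
identity levels; we did not distort the scoring to manufacture earlier
degradation.

What the generator does **not** emulate: indels and codon structure (the
pipeline consumes tabular hits, so alignment mechanics are out of
scope), translated-frame logic (reverse-frame hit rows are emitted only
to exercise parsers), paralog interference across KO groups, chimeric
ESTs, and realistic E-value statistics. Passing tests therefore show the
*pipeline contracts* are honoured — selection, assignment, mapping,
accounting, determinism — not that any particular accuracy will be
achieved on real database contents.

## Numerical and degenerate-input choices

* E-value exactly at the cutoff is retained (the discard rule is
  strictly-greater).
* All rounding of derived integers and percentages is half away from
  zero.
* Empty inputs are valid everywhere: empty hit files, empty KO tables,
  maps with no entries, empty KO groups and empty mappings all produce
  empty (not erroring) results; errors are reserved for *malformed*
  input (wrong column counts, bad KO patterns, dangling KGML
  references), always with a line number or identifier.
* Unknown KGML entry types degrade to `"other"` with a warning; unknown
  attributes are carried through untouched, so newer KGML dialects parse
  and round-trip.
* The pseudo-E-value floor (1e-180) keeps values in double range;
  floored ties are broken by bitscore, which is not floored.

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances chosen to exercise every code path many times over: worlds of
8–20 KOs, 2–4 organisms, 25–150 ESTs and 2–6 maps; 200 randomised hit
tables for the selection-oracle property; 3 seeds × 3 mutation rates for
the sweep. These sizes make the brute-force oracles (exhaustive sort,
triple loop) affordable while leaving the statistics stable.

## Known limitations

* One-way best hit is weaker than bidirectional-best-hit or tree-aware
  orthology; transfer accuracy on diverged lineages will be
  correspondingly optimistic for conserved families and pessimistic
  elsewhere.
* Pathway presence is binary; no enrichment statistics are computed.
* The interaction view treats all relation subtypes alike (the subtype
  is carried as an edge label, not interpreted).
* Coverage counts depend on the map collection supplied; reference
  ("ko") maps are assumed rather than organism-specific variants.
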