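---
title: "From host-plant records to polyphagy scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From host-plant records to polyphagy scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostbreadth)
```

# The problem

Records of what caterpillars feed on accumulate in overlapping databases
that disagree on plant and moth nomenclature, mix observations from
natural environments with rearing experiments, and duplicate each other.
`hostbreadth` builds a single qualitative dataset from such sources and
derives two summary products: a per-species food-plant breadth table and
a per-genus polyphagy table whose central statistic is a phylogenetic
diversity score.

This vignette explains the model and the procedure, the parameters that
matter, the synthetic data used for validation, and the design choices
made where there was genuine freedom.

# The record model

The unit of information is a *record*: a unique combination of moth
species, plant identity and source database. Two consequences follow.

* **Qualitative use only.** Repeated observations of the same association
  carry no weight: all counting is over distinct names. Record frequency
  confounds observation effort, local plant availability and season, so
  the pipeline never interprets it.
* **Sources are part of the key.** Merging keeps one record per source
  for the same association; deduplication collapses only within-source
  repetition. This preserves the provenance structure of the merged
  dataset without affecting any breadth statistic (which are all unions
  of names).

Two further fields qualify every record. The *setting* flag separates
wild observations from captivity or introduced plants; these two worlds
never mix — the per-species table carries parallel wild and captive
column blocks, and every per-genus statistic is defined on wild records
only. The *questionable* flag marks records the source curators
distrusted; they are removed up front and only counted in the audit log.
The deduplication key is (moth species, plant identity, source, setting):
including the setting means a wild and a captive observation of the same
association are both retained, since they feed different column blocks.

Plant identity in the key is taken at the finest resolved rank: a record
resolved to species is never collapsed with one resolved only to genus,
because they carry different amounts of information. Genus-only records
(e.g. `"Quercus sp."`) count toward plant genus, family and order breadth
but never toward species breadth.

# Name resolution

Verbatim names are canonicalised before lookup: whitespace squashed,
hybrid markers (`×`) removed, genus capitalised, epithet lower-cased,
and everything after the binomial dropped. A second token is accepted as
an epithet only if written entirely in lower-case letters; anything
capitalised or punctuated is treated as an author citation
(`"Quercus L."` → genus only). Rank qualifiers (`sp.`, `spp.`, `cf.`,
`aff.`, `nr.`) mark the name genus-only. Subspecific epithets are
truncated to the binomial so that keys stay stable across sources that
differ in infraspecific detail. The function is idempotent, which the
test suite checks on varied inputs.

Resolution then runs against a *local* lookup table (genus → family →
order, plus an angiosperm/gymnosperm group per family) and an optional
synonym map applied before rank lookup — first on the full canonical
name, then on the genus token alone. A local table rather than a live
nomenclatural web service keeps runs reproducible and offline. Unknown
genera yield *unresolved* records: these are retained and reported
(audit log), excluded from all breadth counts, and never silently
dropped. Fuzzy matching is deliberately out of scope; a wrong silent
match is worse than an honest unresolved name.

# The summary tables

The per-species table has 21 columns: moth family/subfamily/tribe/
genus/species, then for each setting the count and the alphabetically
sorted, `"; "`-joined list of plant genera, species, families and
orders. Counts always equal list lengths, families never outnumber
genera, orders never outnumber families — invariants enforced by
`validate_ds1()` and exercised on random inputs.

The per-genus table has 13 columns. A species is *sampled* when it has
at least one wild record that resolved at any rank; species known only
from captivity are not sampled and enter no genus statistic, because
every per-genus column is defined on natural-environment feeding. (The
choice to exclude captive-only species from the averages was open; we
exclude them and document it here.) Totals are cardinalities of the
union of per-species name sets — never sums, which would double-count
shared plants. Averages are arithmetic means of per-species counts over
sampled species. The described-species count per genus comes from the
checklist and gives the sampling coverage denominator; a genus missing
from the checklist keeps its row with an empty total and a warning.

# The polyphagy score

For one moth species with wild angiosperm family set $S$ on a dated,
rooted family-level tree, the score is Faith's phylogenetic diversity:
the summed branch lengths of the minimal subtree connecting $S$,

$$\mathrm{PD}(S) \;=\; \sum_{e \,\in\, \mathrm{spanning}(S)} \ell(e),$$

in the time units of the tree. Implementation: one postorder pass counts
how many selected tips lie below each edge; an edge is in the spanning
subtree iff its count is positive, and under the rootless convention iff
the count is also smaller than $|S|$ (edges carrying the whole set form
the MRCA-to-root path). This is $O(\text{edges})$ per species.

Three rules precede the computation:

* **Gymnosperms are excluded.** The angiosperm–gymnosperm split is so
  deep that a single gymnosperm record would dominate the score. A
  species feeding on gymnosperms only has an *undefined* score (empty
  cell, never zero), and a genus whose species all have undefined scores
  is itself undefined.
* **Families absent from the tree are dropped with a warning**, not an
  error — name mismatches between a lookup and any given published tree
  are a fact of life, and the per-species PD table reports how many
  families each score actually used and how many were missing.
* **Root convention.** The default includes the root path
  (`include_root = TRUE`), matching the default of the classic community
  phylogenetics implementation of this metric; a single-family diet then
  scores its root-to-tip depth rather than 0. Because conventions differ
  across the literature, the flag is exposed everywhere and both variants
  are tested. Scores under the two conventions differ by the MRCA-to-root
  path length and are not comparable across runs with different settings.

Genus scores are arithmetic means of the defined species scores. Trees
with finer-than-family tips can be collapsed with
`collapse_tips_to_families()`, which keeps the lexicographically first
tip per family — a deterministic tie-break; on an ultrametric tree any
exemplar gives the same root-to-tip depth, so the choice only matters
for non-ultrametric inputs.

Numerical choices: branch-length sums are plain double accumulation;
tests compare PD values at $10^{-9}$ relative tolerance; written outputs
round real values to 6 significant digits and leave undefined values as
empty cells.

# Synthetic data and what passing tests mean

`simulate_dataset()` generates the full input bundle from one seed, with
ground truth computed by direct bookkeeping at generation time —
independently of the pipeline code, down to using the deliberately naive
`pd_bruteforce()` (explicit path-union over edge identifiers) instead of
`faith_pd()` for the true scores.

Default conditions (tunable via `sim_config()`): 60 plant families
carrying 300 genera, 60 moth genera with 300 species, 3 sources, host
breadth $1 + \mathrm{Poisson}(4)$ plant species per moth (mean 5, so
every species has at least one host, as in any real per-species row),
15% cross-source duplication, 10% captive records, 5% gymnosperm
families, 5% synonym-variant names plus 20% formatting noise (case,
spacing, author strings). These sizes keep a full run in seconds while
leaving every code path exercised — several species per genus, several
genera per family, gymnosperm-only diets, captive-only species. The
family tree is pure-birth (Yule, rate 1) rescaled to root height 100
time units: simple, ultrametric and sufficient for testing; it is not a
claim about plant history. The test suite runs the pipeline against the
truth for 20 random configurations up to 200 moth species and 50 plant
families, checks `faith_pd()` against the brute-force oracle (and
against the established community-phylogenetics implementation) on over
a thousand random tree/subset instances, and verifies that a noisy run
with a complete synonym map equals the clean run exactly.

What this does *not* show about real data: the generator's name noise is
drawn from a known, complete synonym map, whereas real reconciliation
maps are incomplete and partly manual; host breadth is independent of
phylogeny, whereas real diets are phylogenetically structured; and
record duplication is uniform rather than effort-biased. Passing tests
demonstrate that the pipeline computes its definitions exactly, not that
any particular real dataset is error-free.

# Limitations

* Name reconciliation is lookup-based; the quality of the output is the
  quality of the supplied lookup, synonym map and checklist.
* Breadth statistics are human abstractions over heterogeneous records:
  species- and genus-level polyphagy need not reflect the plasticity of
  individual caterpillars or local populations.
* Only presence information is used; the pipeline cannot express
  preference or frequency even where a source records it.
* The PD score depends on the supplied tree's dating and taxon sampling;
  scores from different trees or root conventions are not comparable.
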