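---
title: "Detecting convergent ortholog expression across growth forms"
author: "orthoconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent ortholog expression across growth forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoconv)
```

# The analysis model

`orthoconv` asks whether a growth form that evolved repeatedly — lianas
are the motivating case — leaves a convergent footprint in gene
expression. Because de novo transcriptomes of different species are not
directly comparable, every species is first projected onto one reference
proteome: each assembled transcript is aligned against the reference and
assigned to its best-matching protein. After that projection, "expression"
of a reference ortholog by a species is a Boolean event (at least one
transcript mapped to it), and the whole community reduces to a
species-by-ortholog presence matrix. All downstream statements are set
algebra over that matrix:

* **Core**: present in *every* analysis unit. With $U$ units this is an
  all-units conjunction, so it measures what the entire community
  transcribes under the sampled conditions.
* **Exclusive at level $k$**: present in exactly $k$ focal units and in
  zero background units. Level $k \ge 2$ is the convergence signal —
  several independent lineages of the focal growth form expressing an
  ortholog that no background species expresses. Level 1 is computed and
  reported too, but it is single-lineage evidence, not convergence, so it
  is kept apart.
* **Group-absent ("co-downregulated")**: present in zero focal units and
  in at least `minBackgroundSupport` background units. Because background
  species do express these genes, their absence from the focal group is
  read as transcriptional downregulation rather than gene loss.

The three compartments are pairwise disjoint by construction; everything
else is "mixed". Orthologs, not transcripts, are the analysis grain, and
*units* rather than raw species: congeneric taxa can be collapsed into one
unit beforehand (element-wise OR of their rows), the convention used for
the two *Smilax* species in the motivating dataset.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `evalueMax` | `1e-9` | e-value ceiling of the hit filter (inclusive) |
| `queryCovMin` | `0.9` | minimum aligned fraction of the query (inclusive) |
| `minScore` | `400` | STRING combined-score cutoff, 0–1000 scale |
| `nShells` | `2` | BFS expansion depth around seed sets |
| `minBackgroundSupport` | `1` | background presences required for "absent" |
| `alpha` | `0.05` | adjusted-p threshold for enrichment calls |

The filter defaults are the reference pipeline's stated thresholds. Both
filter boundaries are *inclusive* (`<=` for e-value, `>=` for coverage),
matching common search-tool semantics; coverage is computed as
`(qend - qstart + 1) / query length` from a supplied query-length table,
since the 12-column tabular format does not carry query lengths. The
STRING cutoff of 400 is the conventional "medium confidence" value and is
exposed because the source study does not state its threshold.
`minBackgroundSupport = 1` means presence in any single background unit
suffices to call an ortholog co-downregulated; raising it demands broader
background support and can only shrink the set.

Best-hit resolution orders by bit score, then e-value, then subject id.
The last tie-break is arbitrary but makes the mapping deterministic under
any permutation of the input hits, which in turn makes the entire
pipeline byte-reproducible.

# Subnetwork semantics

Seed-based extraction labels every node with its unweighted shortest-path
distance (shell) to the seed set and keeps nodes with shell at most
`nShells`. Two edge conventions are offered because the source analysis
does not specify one: `induced` (default) keeps *all* edges among
retained nodes, including edges internal to the outermost shell; `tree`
keeps only edges linking consecutive shells. Seeds missing from the edge
list are retained as isolated shell-0 nodes — classified orthologs
without interaction evidence should stay visible in exports, and in the
motivating data more orthologs are classified (2684 co-downregulated)
than have interactome hits (1687). Merging two subnetworks is a plain
graph union: maximum score per shared edge, node categories joined into a
sorted multi-label, shells combined by minimum (a node's distance to the
union of two seed sets is at most its distance to either).

# Enrichment statistics

Over-representation uses the exact hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, summed on the log
scale from log binomial coefficients (`lchoose`), which keeps it accurate
for universes of $10^5$ genes. The universe defaults to the orthologs of
the presence matrix rather than the full reference proteome: only genes
that *could* have been detected belong in the null. Terms annotating no
universe gene are skipped instead of being reported at $p = 1$, so they
do not inflate the multiple-testing burden. Correction is
Benjamini–Hochberg step-up by default (Bonferroni as an option); the
original study used a web tool whose built-in correction is tool-specific
and unpublished in closed form, so a standard, transparent method is
preferred here. BH can only raise a p-value, adjusted values are capped
at one, and the adjustment is invariant under permutation of the input.

# What the synthetic generator emulates — and what it does not

`generateCommunity()` plants a known partition (core, per-level
exclusive, group-absent, mixed filler) into a community with the study's
shape (10 focal + 37 background species; the ortholog universe defaults
to 2000 instead of the full 33,568 to keep simulations quick). Detection
noise is independent Bernoulli dropout per (species, expressed ortholog);
spurious alignments are Poisson-distributed decoys per species whose
scores are drawn to fail the filter unambiguously (e-value in
(1e-8, 1e-3) or coverage in (0.3, 0.85) — straddling neither boundary, so
boundary behaviour is tested by explicit fixtures, not by luck of the
draw). Passing hits are drawn safely inside the filter (e-value
$\le 10^{-12}$, coverage $\ge 0.95$) for the same reason. Filler genes
are anchored with at least one focal and one background presence so that,
noise-free, no filler can masquerade as exclusive or absent: exact
planted-set recovery is then a structural property of the generator, not
a probabilistic one. The default dropout of 0.05 is a choice, not a
calibration — the study reports no per-species detection sensitivity
(BUSCO completeness spanned 52–92%), so the parameter is exposed and the
default is merely a plausible mid-scale value.

The generator deliberately does *not* emulate: sequence-level reality
(no reads, no assembly — it starts at the hit-table level), phylogenetic
correlation between species (presences are independent given the planted
pattern), transcript redundancy (exactly one transcript per detected
ortholog), or abundance (presence is Boolean). Tests passing on this
generator therefore validate the *set algebra, graph operations and
statistics* — they do not certify performance on real transcriptomes,
where dropout is correlated with assembly quality and phylogeny.

# Numerical and degenerate-input choices

Presence classification is vectorised row-count arithmetic and is checked
in the tests against an exhaustive per-ortholog predicate scan on random
matrices. Shell extraction is a hand-rolled BFS checked against
all-pairs shortest distances. Hypergeometric tails are anchored at the
largest log term before exponentiating; the pmf sums to one within
1e-12 across parameter grids. Edge lists are deduplicated keeping the
maximum score, self-loops are dropped with a warning, and empty networks,
empty hit tables and empty query sets all return typed empty results
rather than errors. Malformed hit-table rows are dropped with a warning
(or abort in `strict` mode) with line numbers reported.

# Known limitations

* **The strict core is extremely dropout-sensitive.** A core call is a
  conjunction over all $U$ units, so a gene survives as "core" with
  probability $(1-d)^U$ under dropout $d$: with $d = 0.05$ and $U = 47$,
  only $0.95^{47} \approx 9\%$ of true core genes are recovered. This is
  a property of the all-units definition itself, faithfully implemented;
  analyses of noisy communities should either collapse species into
  fewer, better-supported units or treat near-core prevalence thresholds
  upstream. The exclusive sets degrade far more gracefully (a dropped
  focal presence moves a gene one level down rather than out of the
  classification).
* Presence/absence carries no abundance information: "co-downregulated"
  means "not detected", which conflates true silencing with expression
  below assembly sensitivity.
* The interactome model is an undirected simple graph on combined scores
  only; evidence channels and directionality are out of scope.
* Annotations are flat term–gene sets; no ontology-hierarchy propagation
  is performed.

# Problem sizes used by the test-suite and acceptance script

Unit tests run on communities of 6–13 species and 80–300 orthologs;
oracle-equivalence checks use 100 random matrices up to 30 units × 1000
orthologs and 100 random graphs up to 50 nodes; the end-to-end recovery
checks use the full 47-species shape at 2000 orthologs; Monte-Carlo
checks of the hypergeometric tail use 100,000 draws per case and the
binomial dropout check 120 replicate communities. These sizes keep the
whole suite under a minute while leaving every code path exercised at
the study's community shape.
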