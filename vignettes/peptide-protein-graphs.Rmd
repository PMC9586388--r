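---
title: "Characterizing bipartite peptide-protein graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing bipartite peptide-protein graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pepgraph)
```

## The model

Bottom-up proteomics measures peptides, not proteins. Because a peptide
sequence can occur in several proteins of the search database, inferring
and quantifying proteins from peptide evidence is ambiguous, and the
ambiguity structure of a data set is exactly captured by a bipartite
graph: protein nodes on one side ($N_1$), peptide nodes on the other
($N_2$), and an edge whenever the peptide belongs to the protein. The
graph can be built at two levels — from *all theoretical peptides* of an
in silico digest of the database, or from *only the peptides actually
quantified* in a given experiment — and comparing the two levels shows
how much harder quantification is in practice than the database alone
suggests.

`pepgraph` implements this construction and its characterization:

1. **Digestion** (`digest_database()`): trypsin cuts after K and R
   unless followed by P; all peptides with up to `max_missed` missed
   cleavage sites and length within `[min_len, max_len]` are kept. The
   inverted result is a peptide → accession-set map, the uncollapsed
   biadjacency.
2. **Collapsing** (`collapse_nodes()`): accessions with identical
   peptide sets are indistinguishable and merge into one protein node
   (a protein group); peptide sequences with identical *protein-node*
   support then merge into one peptide node. Proteins are collapsed
   first, then peptides; one pass of each kind provably reaches the
   fixed point, and the constructor re-verifies this on every call.
   Uniqueness is defined on nodes: a peptide node is unique if it
   touches exactly one protein node.
3. **Decomposition** (`connected_components()`): the collapsed graph
   splits into connected components — the natural units of protein
   inference and quantification.
4. **Isomorphism classes** (`classify_components()`): components with
   the same shape carry the same inference problem. Shape equality is
   *type-preserving* isomorphism: the bijection must map protein nodes
   to protein nodes. We fold the node type into the vertex colors of a
   BLISS canonical labeling (igraph's `canonical_permutation`), so one
   canonical key decides typed isomorphism. The classic example of why
   the type matters: an M-shaped graph (two proteins, each with a
   unique peptide, joined by a shared one) and a W-shaped graph (three
   proteins chained by two shared peptides, no unique peptide at all)
   are isomorphic as plain graphs but pose completely different
   quantification problems. An independent brute-force permutation
   oracle (`brute_force_isomorphic()`) validates the canonical keys in
   the test suite; it is never used in the pipeline itself.
5. **Characterization** (`summarize_dataset()`,
   `node_count_distributions()`, `uniqueness_breakdown()`,
   `isoform_crosstab()`): aggregate counts, node-count histograms with
   a pooled `10+` bin, the unique/shared breakdowns over peptide and
   protein nodes, and the peptide-level cross-tabulation of uniqueness
   with and without isoforms in the database.

```{r m-vs-w}
cfg <- digest_config(min_len = 5, max_missed = 0)
m_db <- protein_db_from_headers(c("A", "B"), c("AAAAKVVVVK", "CCCCKVVVVK"))
w_db <- protein_db_from_headers(c("A", "B", "C"),
                                c("AAAAK", "AAAAKCCCCK", "CCCCK"))
m <- components_from_map(digest_database(m_db, cfg))[[1]]
w <- components_from_map(digest_database(w_db, cfg))[[1]]
igraph::isomorphic(component_igraph(m), component_igraph(w))  # plain: TRUE
identical(canonical_form(m), canonical_form(w))               # typed: FALSE
```

## The quantitative level

`run_quant_level()` mirrors standard label-free preprocessing: rows
stemming only from decoy proteins are dropped, intensities of
modification variants of the same sequence are summed
(`aggregate_ptm_rows()`; missing counts as zero unless every variant is
missing), sequences outside the digestion length window are removed for
comparability with the theoretical peptides, and zero intensities become
missing values. Replicates of a state are combined as the arithmetic
mean when at least `min_valid` (default 2) values are present, the
triplicate rule "two or more missing means missing". For every pairwise
state comparison the peptide ratio is the ratio of the two aggregated
means — ratio of means on raw intensities, not means of ratios and not
logs, because aggregation happens before the ratio; the direction is
fixed by the states' sort order (earlier state in the numerator) and
recorded in the output. Only peptides with a valid (non-missing) ratio
enter that comparison's graph; quantified peptides are mapped to
proteins by substring search against the full database, mirroring how
search engines assign peptides. Components from all comparisons are
pooled as a multiset — the same shape arising in two comparisons counts
twice — and classified jointly.

## The synthetic-data generator

Real databases and quant tables are large downloads; the generator
plants known structure instead, so every stage can be validated against
analytic ground truth. Protein sequences are concatenations of globally
unique random tryptic *blocks*: residues drawn from an alphabet without
K, R and P, terminated by K or R. Since no block contains an internal
cleavage site and no block is followed by P, a 0-missed-cleavage digest
returns exactly the planted blocks, and sharing is controlled purely by
reusing a block in several proteins of one motif. Ground truth is exact
at `max_missed = 0`; with missed cleavages allowed, M and N motifs keep
their shapes (the missed-cleavage peptides collapse into the planted
nodes) but W motifs gain a unique peptide node for the middle protein,
which is why recovery checks pin `max_missed = 0`.

Generator defaults are fixed once as the study conditions: 100
components mixed as 55% smallest, 20% M, 10% N, 5% W, 10% random
(matching the rank order seen in real databases, where the
single-protein graph dominates and M is second), a 5-state × 3-replicate
design as in classic spike-in experiments, 80% peptide detection, 10%
per-replicate missingness, log-normal intensities with meanlog
`log(1e7)` and sdlog 1 (typical LFQ intensity scales). "Smallest"
proteins get two blocks so that isoforms — a parent copy with one block
deleted — can be planted on them; isoforms are planted *only* on
proteins whose blocks are all their own, which makes "isoform peptides
are never shared across base accessions" true by construction.
Detection, intensity and missingness draws use separate seed streams,
so changing one parameter never perturbs the draws of another.

What the generator deliberately does not emulate: realistic intensity
response to abundance, retention-time or detectability bias (detection
is i.i.d. per peptide, while in real data short and hydrophilic
peptides are lost preferentially), correlated missingness, and the
heavy-tailed component-size distribution of real proteomes, whose
largest component can span most of the database at permissive length
thresholds. Passing tests therefore demonstrate correctness of the
graph machinery, not realism of any particular biological claim.

```{r degradation}
spec <- synth_spec(n_components = 40, n_states = 2, seed = 5)
gen <- generate_database(spec, cfg)
tab <- generate_quant_table(gen$db, spec, cfg)
db_res <- run_fasta_level(gen$db, cfg, verbose = FALSE)
q_res <- run_quant_level(gen$db, tab, cfg, verbose = FALSE)
str(degradation_report(db_res$components, q_res$components))
```

The report shows the two opposing effects of unquantified peptides:
undetected *shared* peptides make graphs fall apart (single-protein
graphs become more frequent — the easy case), while undetected *unique*
peptides strip protein nodes of their anchors (protein nodes with only
shared peptides become more frequent — the hard case).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_len` | 7 aa | shortest peptide kept; 5 is an extreme lower bound, 6–7 are search-engine defaults, 9 is the HPP requirement. Short peptides are disproportionately shared, so this setting dominates the size of the largest component. |
| `max_len` | 50 aa | longest peptide kept (inclusive). |
| `max_missed` | 2 | missed cleavage sites allowed; miscleaved peptides usually collapse into the same node as their fragments but can be unique where the fragment is shared. |
| `min_valid` | 2 | non-missing replicates required per state before the mean counts. |
| `decoy_prefix` | `"DECOY_"` | header prefix marking decoys; configurable because conventions vary. |

## Numerical and design choices

* Length bounds are inclusive; "between five and 50" is read as
  $[5, 50]$.
* A peptide's missed-cleavage count is the number of internal positions
  satisfying the cleavage rule; K followed by P contributes zero.
  Within-protein duplicate sequences collapse to one entry with the
  smallest count (the biadjacency is binary).
* I/L are never merged and non-standard residues (B, J, O, U, X, Z) are
  ordinary characters: only sequence identity matters here, no masses
  are computed.
* Component order (descending protein-node count, then peptide-node
  count, then smallest member accession) and node order within
  components (smallest member label) are fixed so repeated runs are
  byte-identical; class ties at equal count break by ascending size
  signature, then key.
* Edge counts are reported at the collapsed level throughout: the
  collapsed graph is the object of interest, and its edge set is what
  the class signatures use.
* Degenerate inputs are defined: an empty component list summarizes to
  zeros, a single component reports a zero second-largest graph, an
  empty peptide map yields a 0×0 biadjacency and no components.
* The isoform cross-tabulation switches to accession-level uniqueness
  (`unique` = one accession), unlike the node-level notion used
  everywhere else; both notions exist side by side because they answer
  different questions.

## Problem sizes

The shipped analyses and checks run on deliberately small instances:
300 planted components in the simulated study, 500 random databases of
up to 5 components for the collapsing invariants, a corpus of ~40
components with at most 10 nodes (and 220+ pairs) for the
canonical-key/oracle agreement, and 2,000 planted M motifs for the
detection Monte Carlo, where the intact fraction must land within three
standard errors of $d^3 = 0.512$ at $d = 0.8$. These sizes give stable
statistics while keeping a full run in the minutes range; all of them
are plain function arguments, so larger sweeps are one call away.

## Known limitations

* Only the trypsin/no-P rule is implemented; other enzymes, semi-tryptic
  peptides and N-terminal methionine clipping are out of scope.
* Quantified peptides are mapped by exact substring search; peptides
  with amino-acid substitutions or search-engine-specific equivalences
  (e.g. I/L folding) will not map.
* The brute-force oracle is limited to 12 nodes by design; it exists to
  validate the canonical keys, not to classify real data.
* Pinned reproduction of published whole-proteome tables requires the
  exact database releases; the pipeline accepts any FASTA, but no
  downloads are bundled.
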