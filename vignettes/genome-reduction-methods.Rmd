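---
title: "Methods: genome reduction, metabolic network trees, and the PIC screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome reduction, metabolic network trees, and the PIC screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqpipe)
```

# The scientific question

Free-living photosynthetic picoeukaryotes (PPEs) are among the few
free-living eukaryotes with strongly reduced genomes. Two mechanisms are
commonly proposed. Under Black Queen dynamics, metabolites that leak into
the aquatic medium act as public goods, so genes for synthesising *soluble*
products become dispensable and are preferentially lost, while pathways for
*insoluble* products must be retained. Under the proteomic constraint, a
smaller coding information content means a smaller mutational target and a
lower total mutation load, which relaxes selection on DNA repair and other
informational-fidelity genes; their copy numbers should therefore correlate
with proteome size. `bqpipe` implements the comparative-genomics chain that
operationalises both predictions — orthogroups, consensus KO annotation,
compound-level metabolic networks, network distance trees and their
congruence with the species tree, and a phylogenetically corrected
category-size correlation screen — together with a generative simulator so
every stage is testable without genome downloads.

# Orthogroups and the pangenome

An orthogroup (OG) is the set of genes descended from one ancestral gene
across the species compared; it contains orthologs and paralogs and is the
unit of comparison throughout. Tables follow the OrthoFinder file
conventions (`Orthogroups.tsv`, `Orthogroups.GeneCount.csv`); singleton
genes placed in no OG are kept in a per-species `unassigned` slot, so
"percent of genes assigned" statistics have the same meaning as in
OrthoFinder reports. The pangenome partition classifies OGs as *core*
(present in all species), *shared* (more than one but not all) or *unique*
(exactly one species); the three classes are exhaustive and disjoint.
Reported percentages round half-up (one decimal for assignment, integers
for the two-gene-OG share), alongside their unrounded values.

# Consensus KO propagation

KO annotation arrives as per-species two-column files (gene id, K number,
`K` + five digits). Because an orthogroup consists of homologous genes of
related function, a K observed on any member is evidence for the rest:
the *consensus* of an OG is the modal K among its directly annotated
members, counted at the gene level so paralog multiplicity matters, with
ties broken deterministically to the lexicographically smallest K. The
consensus fills gaps only — a direct annotation is never overwritten —
which makes the propagated map a superset of the direct map, propagation
provably idempotent, and the efficiency gain monotone. (The alternative
reading, overwriting every member with the consensus, would make the
operation destructive and non-monotone; gap-filling preserves direct
evidence.) Whether the mode should instead be computed per species is not
determined by the method's description; gene-level counting is the default
and the only mode implemented, flagged here as a design choice.

# Metabolic networks and the four distances

Each K maps to KEGG reactions (rn) and each reaction to the compounds
(cpd) it involves. A genome's network is the undirected weighted graph on
compounds where every annotated gene contributes one unit of weight to
every unordered compound pair of each of its reactions — *clique
expansion*. Substrate/product orientation is not modelled (the mapping
format does not distinguish them); single-compound reactions contribute
isolated nodes; no "currency metabolite" filter is applied by default
(an exclusion list argument exists, off by default). K numbers absent
from the map are tallied and reported, never fatal.

Species networks are compared four ways. The unweighted Jaccard distance
acts on compound *sets*. The weighted measures act on *node-abundance*
vectors (summed incident edge weight per compound) laid over the union
compound universe: weighted Jaccard `1 − Σmin/Σmax`, Canberra
`Σ|xᵢ−yᵢ|/(|xᵢ|+|yᵢ|)` with jointly-zero terms contributing 0, and the
Adkins form of Canberra, the Canberra sum divided by `NZ`. `NZ` is read
as the number of positions nonzero in *either* vector — this makes the
Adkins form the mean of the active Canberra terms, bounded in [0, 1];
the stricter both-nonzero reading is available (`nz = "both"`) but is
unbounded and undefined on disjoint supports. Whether abundance vectors
should be node- or edge-indexed is likewise underdetermined;
node-indexing is used, consistent with comparing shared *nodes* between
networks.

# Network trees and congruence

Distance matrices feed a neighbor-joining implementation (Saitou–Nei
Q-criterion). Numerical conventions: ties in Q are broken by the
lexicographically smallest pair of cluster representative labels, so
results are reproducible; negative branch lengths from the NJ formulas are
clamped to zero with a warning; matrices must be symmetric with zero
diagonal and at least three taxa. Matrices export in PHYLIP
lower-triangular format (strict 10-character names by default, a relaxed
mode otherwise).

Congruence between the network tree and the species tree is the
percentage of shared nontrivial unrooted bipartitions (splits). The
denominator is configurable (`reference` — the species tree's splits, the
default — `union`, or `average`); the Robinson–Foulds distance is reported
alongside. "Shared nodes" of tree-comparison parlance is operationalised
as unrooted splits, the reading robust to root placement. A fully
degenerate case exists: if all networks are identical the distance matrix
is zero and no NJ topology is defined; the pipeline flags this instead of
reporting a congruence number.

# The PIC screen

Species are not independent samples, so category gene counts are
correlated with proteome size *after* Felsenstein's phylogenetic
independent contrasts: at each internal node of the rooted binary species
tree the standardized contrast is `(x_L − x_R)/√(v_L + v_R)`, ancestral
values are precision-weighted averages, and parent branches are extended
by `v_L v_R/(v_L + v_R)`. Because contrast signs are arbitrary, the
correlation is computed through the origin,
`R = Σuw / √(Σu² Σw²)`, with a two-sided p-value from
`t = R √((m−1)/(1−R²))` on `m − 1` degrees of freedom (`m` = number of
contrasts; the t-formulation is a documented choice — the screen's source
describes only "PIC correction"). A category is flagged when `R > 0.5`
and `p < 0.05` on the raw p-value — deliberately with no multiple-testing
correction, matching how such screens are reported; a Benjamini–Hochberg
flag is available but off by default. Polytomies must be resolved first
(`resolve_polytomies()` inserts zero-length branches); degenerate traits
(constant, hence zero contrast variance up to floating-point residue
~1e−15·|trait|) are flagged rather than producing meaningless R values.
`slope_reduction`, the percent drop in fitted gene count from the largest
to the smallest proteome along the ordinary least-squares line on raw
species values, is a descriptive companion of our own construction, not a
PIC quantity.

# The proteomic-constraint relation

`μ = k (2 Nₑ s̄ π P)⁻¹` relates mutation rate μ to effective population
size Nₑ, mean deleterious selection coefficient s̄, per-bp heterozygosity
π, and proteome size P (amino acids); `k` is a dimensionless scale with no
calibrated default. The relation enters the package as exact arithmetic
(evaluation plus algebraic inversion for any single parameter, with
round-trip identity), not as an estimator: no data set in scope pins its
constants, and the scale symmetries (scaling any denominator factor by c
is equivalent to scaling any other) encode the observation that π and s̄
shift in opposite directions with Nₑ and tend to cancel.

# The synthetic world

The simulator's role is to state, generatively, the world the analysis
assumes, so that downstream stages can be tested against ground truth.

**Process.** A rooted binary species tree is drawn with uniform branch
lengths; tips are labelled in cladewise order and the first `n_ppe` labels
are the designated reduced ("PPE") lineages — a fixed, reproducible and
partly clustered choice. Gene content starts complete at the root (one
copy per OG plus Poisson(0.3) extra paralogs) and each copy survives a
branch of length L with probability `exp(−rate·L)`: Poisson thinning, the
simplest process exhibiting lineage-specific loss gradients. The rate is
`base_loss_rate`, multiplied by the category's `ppe_loss_multiplier` on
branches all of whose descendant tips are PPE. Informational categories
are additionally multiplied by `1 + λ(1 − P/P_root)` where P is the
parent node's current gene total — an explicit encoding of the proteomic
constraint's directionality (already-reduced lineages lose fidelity genes
faster) without committing to an unstated functional form; λ is
`info_lambda`. Each species also carries a lineage-specific complement of
singleton genes outside any OG (unassigned), with a lognormally varying
mean. Each OG owns one K number; a gene is directly annotated with its
OG's K with probability `annotation_fraction` (an `annotation_noise`
option substitutes a wrong K, to exercise consensus tie-breaking). The
KO→rn→cpd map draws each reaction's 2–3 compounds from a category-specific
pool plus occasional shared hub compounds, giving category-structured but
overlapping networks.

**Defaults and why.** 16 species with 7 reduced lineages mirror the
motivating data set. The default category set spans four
soluble-biosynthesis, three insoluble-biosynthesis, three informational
and one neutral category, 50 OGs each. `base_loss_rate = 0.005` keeps
background turnover small — insoluble pathways are *retained*, and, just
as important, background loss is shared between every category's counts
and the proteome total, so a large background rate would confound the
insoluble null. Multipliers 300 (soluble) and 200 (informational)
concentrate loss in the reduced lineages (survival across a typical
all-PPE path is ~0.1–0.5 versus ~0.97 background). `unassigned_lambda =
230` makes species-specific genes ≈ 24% of each proteome, matching the
share reported for real orthogroup analyses of these taxa, and
`unassigned_sigma = 0.25` gives that complement several-fold lineage
variation — the realistic, loss-independent component of proteome-size
variation that decouples insoluble categories from proteome size.
`annotation_fraction = 0.3` leaves most genes for consensus propagation
to recover, as in the real two-step annotation. No quantitative loss-rate
estimates exist for these lineages; the defaults are illustrative effect
sizes chosen once, by the reasoning above, to encode the stated
qualitative structure strongly.

**What a green test establishes — and what it does not.** The simulated
world has exchangeable gene copies, one K per OG, no sequence evolution,
no annotation bias, and branch-length-driven loss only. Green end-to-end
tests establish that the pipeline's machinery detects the encoded
structure (preferential soluble/informational loss; insoluble
decoupling); they say nothing about whether real PPE genomes exhibit it,
nor do they reproduce any published effect size. One statistical property
of the screen is worth stating plainly: with three null (insoluble)
categories tested at raw `p < 0.05`, `R > 0.5` on 15 contrasts, a null
category exceeds the flag threshold in ~2.5–3% of seeds by chance, so
roughly one seed in sixteen flags *some* insoluble category no matter how
decoupled the world is. Acceptance therefore checks per-category rates
across seeds (each true category flagged in ≥90% of runs, each insoluble
category unflagged in ≥90%) rather than demanding every run be
simultaneously perfect.

# Numerical choices, degenerate inputs, limitations

- Ties: modal-K ties → smallest K; NJ Q-ties → smallest label pair;
  splits are canonicalised by the side containing the smallest tip label.
- Clamping: negative NJ branch lengths → 0 with a warning.
- Zero handling: 0/0 Canberra terms contribute 0; `NZ = 0` →
  Adkins–Canberra 0 with a warning; two empty sets → Jaccard 0.
- Degeneracy: identical networks → flagged, no NJ tree; constant traits →
  flagged, no R; polytomies → explicit error with a resolution helper.
- Determinism: every stochastic stage derives its stream from one master
  seed (`derive_seed`), so identical configurations yield byte-identical
  fixture files and identical summaries.
- Limitations: no reaction directionality, flux, or gap-filling; no
  sequence-level simulation; no running of orthology inference or
  phylogenetics tools (their outputs are inputs here); the p-value of the
  origin-constrained contrast correlation is t-approximate, and the screen
  intentionally applies no multiple-testing correction by default.

```{r example, eval = FALSE}
m <- run_pipeline(scenario_config(seed = 1L), out_dir = tempfile())
m$summary$congruence_pct
m$screen[m$screen$significant, c("category", "r", "p")]
```
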