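---
title: "Methods: functional persistence analysis of longitudinal metaproteomes"
author: "ProteoPersist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional persistence analysis of longitudinal metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and rationale

`ProteoPersist` analyses longitudinal shotgun metaproteomes of
host-associated microbial communities. The guiding observation it is built
to quantify is a hierarchy of stability: individual protein repertoires in
the gut turn over rapidly across time and differ strongly between people,
KEGG Orthology (KO) functions are markedly more stable, and curated
metabolic modules — sets of enzymatic steps converting one gut-relevant
compound into another — are the most persistent layer, often carried by
different phyla at different times. The package takes as input material that
is routinely produced upstream of any such analysis (per-individual protein
sequence databases, FDR-filtered peptide-spectrum-match tables, orthology
and taxonomy annotations, and a module catalogue) and produces protein
groups, balanced spectral counts, phylum-stratified module calls, and the
persistence, redundancy, functional-influence and similarity statistics.

This vignette documents the model and every numerical decision a maintainer
might want to revisit.

# From sequences to protein groups

## Pairwise identity

Two protein sequences are compared by global alignment with affine gap
costs: match `+1`, mismatch `-1`, a gap of length $L$ costs $5 + L$ (opening
5, extension 1 per residue). Identity is

$$\mathrm{id}(a,b) = \frac{\#\{\text{identical aligned residue pairs}\}}
{\#\{\text{alignment columns}\}},$$

where the denominator counts *all* columns of the global alignment,
including gap columns at either end. Equivalently, since every column
consumes a residue from at least one sequence, the column count equals
$|a| + |b| - (\text{residue-pair columns})$, which is how the implementation
computes it from match/mismatch counts without materialising the alignment.
Counting terminal gap columns means a fragment is *not* automatically 100%
identical to its full-length parent; a one-residue truncation of a
ten-residue sequence scores 9/10. The measure is symmetric.

Isoleucine and leucine are isobaric and indistinguishable in most MS
searches; the package nevertheless treats them as distinct residues by
default, because collapsing them is an assumption about the upstream search
engine. `ileLeuEquivalent = TRUE` switches the alignment *and* the peptide
matching to a collapsed I/L alphabet consistently.

## Greedy centroid clustering

`clusterProteins()` groups sequences at a configurable identity threshold
(default 0.90). The algorithm is deterministic greedy centroid clustering:
sequences are visited in order of decreasing length, ties broken by
lexicographic accession; each sequence joins the *first* existing seed whose
identity to it reaches the threshold, otherwise it founds a new group. No
k-mer prefilter or heuristic acceleration is used — the only shortcut is an
exact bound (identity cannot exceed the shorter/longer length ratio, because
matches are bounded by the shorter sequence and columns by the longer), so
skipped alignments could never have joined. The result therefore equals the
brute-force computation, which the test suite verifies against an
independent dynamic-programming aligner on small databases.

Groups partition the database; each group's *seed* donates its annotation
downstream. The choice of a deterministic greedy scheme over a specific
external clustering tool trades replication of any particular heuristic for
exact reproducibility at the scale this package targets.

## Peptides, identification and spectral balancing

Peptides are mapped to groups by exact substring containment against every
member sequence; a peptide contained in exactly one group is *unique*, in
several *shared*, in none *unmapped* (reported, then excluded). Uniqueness
is defined at the group level, because grouping precedes identification.

A group counts as **identified** in a sample when its observed peptides
include at least two distinct sequences, at least one of them unique to the
group. "Distinct" means distinct amino-acid strings after the I/L policy;
modified peptide forms are out of scope. Identification strictly precedes
quantification: only identified groups receive spectra.

**Spectral balancing** distributes each sample's peptide counts in a single
pass: unique peptides give their full count to their group; each shared
peptide's count is then split across its *identified* carrier groups in
proportion to the groups' unique-count totals from the first pass, or
equally if all carriers lack unique evidence. Peptides whose carriers are
all unidentified are dropped from the conserved total and logged. The
scheme conserves totals exactly (column sums equal retained counts, checked
to 1e-9 relative tolerance in the tests), is independent of peptide and
group processing order, and reduces to raw per-group sums when nothing is
shared. Balanced counts are kept as reals; no rounding is applied, and the
rank-based statistics downstream are unaffected by scale. An iterative
re-balancing variant (re-weighting by balanced rather than unique totals)
was deliberately not implemented.

# Annotation and module inference

Each group inherits the KO term, phylum and genus of its seed sequence.
Seeds labelled `human` yield category `human` (never a phylum); seeds with
a phylum are `microbial`; everything else — including seeds missing from
the annotation table — is `unassigned`. `ambiguityReport()` quantifies how
often members positively disagree with their seed on KO or phylum;
unannotated members never count as disagreement. Seed-wins is applied
unconditionally even for discordant groups. Genus is carried through for
reporting but drives nothing: the analysis treats the phylum as the most
informative taxonomic level.

A module catalogue is an ordered list of enzymatic steps; each step has
AND-components, each component a set of OR-alternative KO terms. The
plain-text dialect (`MF####<TAB>name` header, tab-separated components,
comma-separated alternatives, `///` terminator) matches the published gut
metabolic module distribution, so that catalogue can be dropped in
unchanged.

A KO is *detected* for a (sample, phylum) stratum when at least one
identified microbial group carries that KO and phylum. A step is covered
when every AND-component has at least one detected alternative. A module is
**inferred** in a stratum when the covered fraction of its steps reaches
one third. The comparison is `>=` against `1/3`: a 3-step module with one
covered step is inferred. Both sides of the comparison are the same binary
double (`1/3`), so no decimal-threshold edge case arises. Coverage is
evaluated within each phylum separately; pooling evidence across phyla is
never done, which is what makes phylum redundancy observable at all.

Module abundance is reported two ways: `abundance_mean`, the mean balanced
count of the phylum's identified groups whose KO appears anywhere in the
module; and `abundance_fraction`, their summed balanced counts over the
sample's total retained spectra. Averaging over mapping groups (rather than
over module steps) is a deliberate choice; the step-mean variant would
weight steps equally regardless of how many enzymes support them. A KO
appearing in several modules contributes to each independently, matching
the per-module view of the source catalogues; the fractions of modules with
disjoint KO sets sum to at most 1 per sample.

Redundancy classes summarise, per module, the set of phyla that ever
provided inference: a single phylum, two or more, or all four major gut
phyla (Firmicutes, Bacteroidetes, Actinobacteria, Proteobacteria).
`phylumSwitchEvents()` reports consecutive same-individual time points at
which the (non-empty) sets of inferring phyla differ — the signature of one
function moving between carriers.

# Persistence and similarity statistics

Presence matrices are built at three entity levels, all gated by the same
identification rule: microbial protein groups (identification matrix), KO
terms (detected in any phylum), and modules (inferred in any phylum). Each
observed entity falls in exactly one category per individual — present at
all time points, at more than one but not all, or at exactly one — and
analogously across individuals. The categories partition the observed
entities, which is asserted at every level.

*Functional influence* of a phylum in a sample is the number of KO terms
detected in that (sample, phylum) stratum divided by the number of distinct
KO terms predicted in the sample's own protein database — a measure of how
much of an individual's genomically encoded function a phylum expresses.

Sample similarity uses Spearman correlation between balanced-count columns
over the union of entities, with absent entities as zeros entering the
ranking as ties (dropping them pairwise would make each pair's correlation
refer to a different entity set). Samples are clustered agglomeratively
with average linkage on the Euclidean distance between rows of the
correlation matrix. Two open choices are exposed as configuration rather
than hidden: the linkage method (`average` is a robust default for
correlation-derived distances) and the distance mode — Euclidean distance
between correlation rows (default) or `1 - rho` directly. Columns are
processed in sample-id order so that ties break deterministically; the tree
is also exported as a Newick string with merge heights as branch lengths.

Personalisation is quantified by (i) the fraction of samples whose
highest-correlation partner belongs to the same individual and (ii) the
adjusted Rand index between individual labels and the k-cluster cut of the
dendrogram at k = number of individuals.

# The synthetic cohort generator

Real raw data for this kind of study is large and partly inaccessible; the
generator produces a cohort with the statistical structure the analysis
assumes, plus full ground truth, so every stage is testable offline.

What it emulates, and how:

* **Individual-specific repertoires with shared function.** KO terms are
  assigned to one phylum or, for a configurable redundant fraction
  (default 0.8), to 2–4 major phyla. Each (KO, phylum) pair owns one or two
  sequence *families*: a base sequence of length 80–600 drawn from a
  uniform residue model, from which each carrying individual gets its own
  variants at ~98% identity (substitutions only, so family members share
  length and the length-ratio bound in clustering stays tight). Distinct
  families are unrelated random sequences, so clustering collapses families
  and keeps them apart; cross-individual variants of one family co-cluster,
  which is what makes protein groups comparable across individuals.
* **Host background.** A configurable fraction (default 0.05) of each
  database consists of host proteins — identical sequences in every
  individual's database, expressed stably at elevated abundance, annotated
  `human`. About 8% of each database is unannotated microbial sequence.
* **Personalised expression.** Each individual expresses ~40% of its
  microbial repertoire at a time (real databases dwarf the expressed
  proteome, and turnover needs unexpressed same-KO spares to draw from).
  Baseline log-abundance per protein is the family mean plus an
  individual-specific family offset with standard deviation
  `individualEffect` (default 2) plus protein- and sample-level noise
  (sd 0.3 and 0.2). With a large `individualEffect` the cohort clusters
  perfectly by individual; as it approaches 0 the shared family structure
  dominates and label recovery decays.
* **Turnover with functional preservation.** Between consecutive time
  points a `turnover` fraction (default 0.5) of expressed microbial
  proteins is replaced. With probability `koPreservation` (default 0.9)
  the replacement shares the departing protein's KO (any phylum — this is
  what makes module evidence switch phyla); otherwise it is a random
  protein new to this time point. Replacements are drawn from proteins not
  expressed at the previous time point, so departing proteins cannot
  bounce back within one transition; when no same-KO spare exists the
  protein is retained. This one mechanism produces the full persistence
  hierarchy: volatile groups, stable KO sets, persistent modules.
* **Spectral sampling.** Expressed proteins are digested in silico
  (cleave after K/R except before P, no missed cleavages, peptides of 6–40
  residues retained) and `depth` spectra (default 20,000) are drawn from a
  multinomial over (protein, peptide) pairs weighted by protein abundance,
  then aggregated per peptide into the five-column PSM table.

The module catalogue (20 modules of 2–5 steps, 1–3 alternatives per
component, occasional two-component AND steps) is drawn from the simulated
KO pool.

Everything is determined by a single integer seed: the static cohort, the
expression dynamics and each sample's multinomial draw use fixed derived
seeds, and re-running writes byte-identical files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real amino-acid composition and homology
structure (uniform residue model), modified peptides, missed cleavages,
acquisition noise and dynamic range compression, FDR-controlled
misidentifications, chimeric assemblies, and annotation errors. Results on
synthetic data validate the *machinery and its invariants*, not biological
effect sizes.

## Default cohort dimensions

The shipped defaults describe five individuals sampled five times ~90 days
apart, about 200 annotated microbial proteins per individual database over
a 50-term KO universe, and 20,000 spectra per sample — a deliberately
desk-scale cohort that the whole pipeline traverses in about a minute while
still exercising every stage with realistic structure. At these settings
the pipeline recovers perfect individual clustering (nearest-neighbour
fraction and adjusted Rand both 1), a persistence hierarchy with modules
above 0.8 and protein groups below 0.5 within-individual all-time-point
fractions, and a few hundred phylum-switch events.

# Numerical and degenerate-input policy

* Thresholds live in `(0, 1]` and are validated; the module threshold is
  compared with `>=`.
* Zero-count PSM rows and sub-floor peptides (default floor 6) are dropped
  with warnings; negative counts and malformed KO terms are errors.
* An empty FASTA yields an empty database with a warning; duplicate
  accessions, non-canonical residues and zero-length sequences are errors.
* Zero-variance abundance columns make Spearman correlation undefined and
  raise an error naming the sample rather than propagating `NA`.
* Entities never observed are excluded from presence matrices; persistence
  fractions over zero observed entities are reported as 0.
* Single-time-point individuals are rejected in within-individual
  persistence; fewer than two individuals are rejected across individuals.

# Known limitations

* Greedy centroid clustering is order-dependent by design (deterministic,
  but a different visiting order could produce different groups near the
  threshold); it is faithful to the class of tools it models, not to any
  specific binary.
* The balancing scheme is the standard single-pass unique-evidence
  allocation; iterative schemes can differ on heavily shared databases.
* Module coverage treats the catalogue's step/AND/OR structure as flat;
  richer branching topologies are not represented.
* All-zero entities are ranked as ties in the Spearman computation, which
  slightly compresses correlations between sparse samples relative to
  pairwise-complete alternatives; this is intentional (one entity universe
  per comparison).
* The alignment identity denominator counts terminal gaps, so fragments of
  long proteins do not collapse into their parents unless within 10% of
  full length. Databases with heavy fragmentary redundancy would need a
  different identity definition.
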