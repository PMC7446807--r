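---
title: "Methods: predicting and contextualising prokaryotic transcription factors"
author: "TFRepertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting and contextualising prokaryotic transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TFRepertoire)
```

## The problem

DNA-binding transcription factors (TFs) are the primary layer of gene
regulation in bacteria and archaea: activators and repressors that bind
operator sites near promoters, excluding sigma factors and RNA-polymerase
subunits. Two robust empirical observations organise the analysis this
package implements. First, TFs are built from a limited vocabulary of
DNA-binding domain families (helix-turn-helix variants dominate, with
noncanonical folds such as LytTR, ribbon-helix-helix and zinc-binding
domains making up the rest), so domain composition is a strong predictor
of regulatory function. Second, the number of TFs a genome encodes grows
super-linearly with genome size: small endosymbionts carry a handful,
while large free-living genomes devote several percent of their gene
products to regulation.

## The two prediction routes and their merge

**Domain route.** A protein is called a TF when it has at least one hit
to a TF-associated PFAM family with E-value at or below `domain_e_max`
(default 10^-3, inclusive). All overlapping within-clan hits are retained
at parse time (clan-overlap reporting); the family label is the single
best qualifying hit, with a fully deterministic tie-break: minimum
E-value, then maximum bit score, then lexically smallest accession. The
TF-associated family list is an input (one accession per line); accession
version suffixes are stripped at parse time on both sides so the list
matches any PFAM release.

**Orthology route.** A protein is called a TF when it forms a reciprocal
best hit (RBH) with a member of a curated catalog of experimentally
validated regulators. A similarity hit qualifies at E-value at or below
`ortho_e_max` (default 10^-5) and coverage at least `cov_min` (default
0.70). Coverage is computed per side as aligned span over sequence
length; the default policy requires *both* query and subject coverage to
pass, which is the stricter reading of a single "coverage ≥ 70%"
criterion — a one-sided option (`twoSided = FALSE`) is exposed for
sensitivity analysis. Best hits are ranked by bit score, with ties broken
by E-value and then lexical subject id, so runs are reproducible. RBH is
computed per genome against the catalog: pooling genomes would let one
catalog entry's single best hit suppress orthologs in every other genome.

We use plain RBH rather than a graph-clustering extension: against a
fixed reference collection the pairwise mutual-best criterion is the
auditable core of the method, and it is what the brute-force oracle in
the test suite enumerates. Orthology-only calls carry no PFAM family
label (`NA`): inheriting the catalog partner's family would blur the
provenance distinction the merge is designed to preserve, and the domain
route did not qualify any family for them.

**Merge.** The union of the two call sets is partitioned into
`domain_only`, `both` and `orthology_only`. The partition is disjoint and
covers the union exactly — an invariant the tests exercise on random
sets — and the three counts are the quantities usually reported when
benchmarking the routes against a well-studied genome.

Note one subtlety we deliberately do not paper over: RBH pair sets are
*not* monotone under threshold relaxation. Admitting a new higher-bit hit
can redirect a query's best match and dissolve a previously mutual pair.
Monotonicity holds for the domain route and for the qualifying-hit
filter, and that is what the property tests assert.

## Genomic context

Coordinates are 1-based inclusive throughout (GFF3 convention). The
intergenic distance between an ordered gene pair is
`start(downstream) - end(upstream) - 1` — the number of bases strictly
between them; abutting genes get 0, and overlapping genes get 0 plus an
explicit overlap flag rather than a negative distance, so histograms stay
on a physical scale while the overlap information is preserved.

**Transcription units.** Operons are predicted by the standard
strand-and-gap heuristic: maximal runs of consecutive same-strand genes
whose pairwise intergenic gaps do not exceed `tu_gap_max`. The default of
50 bp is the conventional figure for prokaryotic operon calling — intra-
operon spacings cluster tightly below ~50 bp while unrelated adjacent
genes are usually separated by well over 100 bp — and it is exposed in
the configuration. Replicons are linear by default; with
`circular = TRUE` (and a known replicon length) adjacency wraps, and the
first and last runs merge when same-stranded within the gap threshold.

**Context classes.** Each TF gene receives exactly one of three
relations. *Divergent*: the neighbor on the TF's upstream
(promoter-proximal) side lies on the opposite strand with both genes
transcribed away from the shared intergenic region — a TF on `+` with its
left neighbor on `-`, or a TF on `-` with its right neighbor on `+`. This
keys on the upstream side because the canonical regulator/target
architecture places both promoters in one shared region; a downstream
opposite-strand neighbor is convergent, not divergent. *in_tu*: the TF
shares a predicted TU with at least one other gene. *isolated*:
neither. The classes are exhaustive and mutually exclusive by
construction — a divergent upstream neighbor is on the opposite strand
and therefore can never be a co-TU member. At a linear replicon edge the
missing upstream neighbor simply cannot support a divergent call; the
remaining neighbor decides TU membership.

The divergent-distance histogram bins shared intergenic distances into
half-open 50-bp bins and reports the fraction at or below 100 bp, the
signature of compact shared regulatory regions.

## Functional layers

**Enzymes.** A protein is enzyme-associated when it carries at least one
valid EC assignment. EC strings must match `a.b.c.d` with digits or `-`
placeholders and a top-level class 1–6; partial ECs (trailing `-`) still
count, since the class is carried by the first field. Malformed strings
are rejected with diagnostics, never silently dropped.

**Virulence.** A protein is virulence-associated when it forms an RBH
pair with a member of a virulence-factor reference set, under exactly the
same thresholds as ortholog detection. The implementation *is*
`findOrthologsRBH` restricted to that reference — an equivalence the
tests assert directly.

**The per-family table.** For the `top_k_families` most abundant
families (default 10), counts are pooled across genomes: member TFs that
are divergent, in multi-gene TUs, enzyme-associated and
virulence-associated. Following the conventional presentation of such
tables, the divergent column is reported as a *fraction* of the family
total while the remaining columns are *percentages*; the mixed scale is
reproduced as printed rather than harmonised. Denominators are always the
family's total TF count. When a gene-to-protein map for partner genes is
available, the same enzyme/virulence tabulations are added for the
divergent partners in separate `*_neighbor_*` columns, since the
regulated neighbor's function is usually the biological point of
interest.

## Enrichment statistics

For each focal family, the PFAM domains of its divergent-neighbor genes
(foreground) are tested for over-representation against a background gene
set with a one-tailed Fisher exact test — the upper-tail hypergeometric
probability P[X ≥ a] under fixed margins, computed exactly. Only the
enrichment direction is tested; depletion is out of scope. P-values are
adjusted with the Benjamini–Hochberg step-up procedure (order-preserving,
monotone, identity at m = 1), and domains are flagged significant at
FDR ≤ `alpha` (default 0.05). Significant domains are annotated with GO
terms through a pfam2go mapping.

The background is a genuine modelling choice with no canonical answer.
The default is the pooled divergent neighbors of all analysed families:
it asks "what distinguishes *this* family's neighborhood from TF
neighborhoods generally", which is the sharper comparative question and
is robust to genome-wide compositional effects. The alternative
(`background = "all"`, every protein in the collection) asks the absolute
question and yields systematically smaller p-values; both are exposed.

## Scaling analysis

`fitScaling` fits both candidate abundance models: the power law by OLS
on log-transformed values — deterministic, closed-form, and the
convention for scaling-law exponents, though a nonlinear least-squares
fit could differ in the third decimal — and the straight line by OLS on
the raw scale. Goodness of fit (r²) and the Pearson correlation are
reported on each model's own fitting scale. Zero-TF genomes cannot enter
a log fit and are excluded from the power fit with a warning.

`selectModelPerDivision` picks the model with the higher r² within each
taxonomic division, because only the better-fitting functional form is
typically reported and no explicit criterion accompanies such statements.
Two numerical guards matter: divisions with fewer than 10 genomes are
skipped (the comparison is meaningless at small n), and an r² margin
below 0.01 is reported as `"ambiguous"` rather than forced to a winner.
The ambiguity case is real, not hypothetical: a straight line through the
origin *is* a b = 1 power law, so near-proportional data fit both models
essentially equally.

## The synthetic-data generator

`generateCollection` emulates the statistical structure the analysis
assumes, with known ground truth:

* **Abundance.** ORF counts log-uniform over `orf_range` (default
  500–12000); TF counts `round(a * n^b * exp(eps))` with
  `a = 7e-4`, `b = 1.5283` and `eps ~ Normal(0, 0.2^2)`, clipped to the
  feasible range. At census level the same model is exposed cheaply via
  `generateScalingPoints`, which is what large-n recovery experiments
  use.
* **Layout.** One circular replicon per genome, fixed 900-bp genes
  (typical prokaryotic ORF; only the gaps matter downstream). Each TF is
  planted as a divergent pair (shared gap geometric with mean 60 bp, so
  ~81 % fall at or below 100 bp), inside an operon run (length
  2 + Geom(0.5), intra-run gaps uniform 5–40 bp), or isolated behind a
  same-strand guard gene; unrelated genes are separated by at least
  150 bp. Because the intra-TU and between-block gap distributions are
  separated from the 50-bp TU threshold, the planted context is exactly
  recoverable — by design, so context tests are sharp.
* **Evidence.** Domain hits for domain-detectable TFs (E-values 10^-30
  to 10^-4), per-genome mutual-best similarity hits against a synthetic
  668-entry catalog for orthology-detectable TFs, virulence RBH against a
  reference id set, and EC strings drawn from configurable class
  frequencies (transferases most abundant). Every bundle contains
  mandatory near-threshold decoys: an extra hit at exactly E = 10^-3, a
  hit just above it, a similarity pair at exactly (10^-5, 0.70), a
  0.65-coverage pair, a weak-E pair and a one-directional best — so
  boundary behaviour is always exercised. Coverages are quantised to
  spans over a nominal 300-aa length so external-format round trips are
  exact. One deliberate consistency cap: orthology detectability requires
  a distinct catalog partner per protein (colliding mutual bests would
  silently demote one claimant), so in genomes with more orthology-flagged
  TFs than catalog entries the excess flags are turned off *before* the
  truth table is emitted — truth and evidence can never disagree.
* **Catalog.** `generateCatalog` draws entries with family frequencies
  led by TetR/AcrR (9.8 %) and OmpR/PhoB (7.9 %), roles 29.4 % repressor
  / 23.9 % dual / 18.1 % activator / 28.6 % undefined, domain counts
  dominated by one- (41.77 %) and two-domain (50.22 %) architectures, and
  one to three evidence codes per entry weighted by how common each code
  is in curated collections (the per-entry multiplicity is not published,
  so 1–3 is a modelling choice).
* **Division panels.** `generateDivisionPanel` builds labeled censuses
  under declared models for selection-recovery experiments. Its linear
  divisions use strongly negative intercepts (-40 to -60 at slopes
  0.05–0.07 over 1000–12000 ORFs): identifiability demands it, since a
  near-proportional line is indistinguishable from a power law under the
  0.01 ambiguity margin. This is what "separated panels" means
  operationally.

All randomness flows from a single seeded stream per bundle
(`withr::with_seed`); identical configuration and seed give byte-identical
emitted files.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: actual protein sequences (ids and
lengths are placeholders; there is no alignment, only planted hit
tables), variable gene lengths and overlapping genes beyond the flagged
divergent overlaps, multi-replicon genomes and plasmids, phylogenetic
correlation among genomes (every genome is drawn independently), leaky
operon boundaries whose gap distributions straddle the TU threshold, and
domain-scan noise structure (real profile scans produce correlated
E-values across clan members). Perfect context recovery on synthetic
bundles demonstrates correctness of the classification logic, not the
accuracy of the 50-bp heuristic on real operons, which published
benchmarks put near 80–90 %.

## Numerical choices and degenerate inputs

* All thresholds are inclusive (≤ for E-values, ≥ for coverage), so
  boundary evidence qualifies; the generator plants evidence exactly at
  the boundaries to pin this behaviour.
* Every best-hit selection has a total deterministic order (score, then
  E-value, then lexical id); no run-to-run jitter.
* Overlapping gene pairs get distance 0 with a flag; distances are never
  negative.
* Empty inputs return typed empty results (empty GRanges, empty tables);
  genuinely invalid inputs (unknown sequence id, foreground not inside
  background, p-values outside (0, 1], all-zero Fisher margins handled as
  p = 1) fail fast with the offending value named.
* Parsers reject rows individually with diagnostics and report rejected
  counts (`attr(, "nRejected")` / `metadata()$nRejected`); they never
  silently drop data. This row-level policy is why the GFF3 reader works
  from the raw nine-column table instead of a whole-file importer that
  aborts on the first invalid record.

## Problem sizes in the shipped tests

The suite favours many small, sharp cases: collections of 2–3 genomes of
150–400 ORFs for pipeline and consistency tests; n = 10000 / 5000
catalogs for frequency recovery; 2000 census points for slope
convergence; 500 genomes for exponent recovery; 100-seed loops for the
RBH oracle and model-selection accuracy; exhaustive Fisher enumeration up
to margin 12. These sizes give comfortable statistical margins for every
asserted tolerance while keeping the whole suite around half a minute.

## Known limitations

* TU prediction uses strand and gap only; conservation-based refinements
  (phylogenetic profiles, adjacency conservation) are out of scope.
* The orthology route is pairwise RBH against a reference collection,
  not full ortholog-group clustering; co-orthologs in one genome
  compete and only one wins.
* Enrichment reports the machinery (counts, p, FDR, GO terms); with
  synthetic neighbor sets the specific significant domains are
  generator artefacts, not biology.
* The divergent classification has no distance cap: a divergent pair
  separated by several kilobases is still "divergent". Downstream
  consumers should use the reported `intergenic_bp` to filter if a
  shared-promoter interpretation is intended.
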