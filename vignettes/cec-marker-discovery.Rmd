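---
title: "Marker discovery for human corneal endothelial cells"
author: "cecmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery for human corneal endothelial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Corneal endothelial cells (CECs) form the pumping monolayer on the inner
corneal surface; engineered CEC grafts are a candidate therapy for
endothelial blindness, but no single gene distinguishes a CEC from its
look-alikes. The classical immunostains (ZO-1, Na+/K+-ATPase) mark tight
junctions and ion transport in many epithelia. What a quality-control assay
needs is a small panel of genes that are (i) highly expressed in CECs from
young **and** old donors, (ii) retained in expanded CEC cultures, and
(iii) low or absent in corneal stroma keratocytes and the stromal
fibroblasts that routinely contaminate CEC cultures.

`cecmarker` implements that screen as a reusable pipeline over gene-level
bulk RNA-seq count tables of four sample classes — `cec_young`, `cec_old`,
`cec_culture`, `stroma` — followed by qPCR validation statistics. It ships
the published summary tables of the human CEC screen as plain-text fixtures
(`cecExampleTable()`) so every stage is regression-tested against printed
numbers, and a seeded simulator so every stage is also testable against a
known ground truth.

## Normalization and fold changes

Counts are scaled to reads per million (RPM):
`rpm(g, s) = count(g, s) / librarySize(s) * 1e6`, where the library size is
the sample's total uniquely mapped reads from the metadata — not the column
sum, because a table may cover a subset of genes. There is no
between-sample normalization beyond depth scaling (no TMM or quantile
step), and no pseudocount anywhere: a fold change `a / b` with `b = 0` is
an explicit *undefined* sentinel (`NA`, rendered `"n/a"`), never a finite
stand-in. Display rounding is half-up (`25.65` prints `25.7`), matching how
the reference tables were typeset; base R's half-to-even `round()` is never
used for display.

### Why the selection folds are compared at printed precision

The selection thresholds below compare fold changes at one decimal (half-up)
rather than on the raw ratio. This is deliberate. The bundled reference
tables print RPMs as integers and folds at one decimal, and they are only
self-consistent under that reading: e.g. the retained gene TMEM66 (young 632,
stroma 321) has raw ratio 1.97 — below a raw `>= 2` cut for *any* unrounded
values compatible with the printed integers — while its printed fold is 2.0.
The same applies to the two-sided young/old criterion, where the retained
genes ID3 (ratio 0.478, printed 0.5) and P4HA2 (printed 2.0) force rounded,
inclusive bounds `[0.5, 2.0]`. RPM floors, by contrast, are strict raw
comparisons (`> 10`, `< 1`), which is also why the transcription-factor
table's CTBP1 row (old-CEC RPM printed exactly 10) cannot clear the floor
from integer input.

Two cells of the bundled top-expressed table are transcription repairs: the
printed old-CEC values of GAPDH ("6,6498", a malformed digit group) and
P4HA2 (231, which contradicts the same row's printed young/old fold 2.0 and
young/stroma fold 5.5 beyond any rounding tolerance) are stored as the
values reconstructed from each row's own fold columns (6649 and 286). The
stroma-absent table is stored verbatim, including its duplicated UPRT row —
duplicate gene identifiers are a hard parse error by design, so that table
doubles as the error fixture, and analyses use the first occurrence.

## The selection cascade

`filterCriteria()` defaults encode the published screen:

| threshold | default | meaning |
|---|---|---|
| `minRpmExpressed` | 10 | RPM floor (strict `>`) in `cec_young`, `cec_old`, `cec_culture` |
| `minFoldVsStroma` | 2 | young/stroma fold (rounded, inclusive); undefined fold (stroma RPM 0) passes — zero stroma signal is maximal contrast |
| `maxAgeFold` | 2 | two-sided young/old window on the rounded fold, `[0.5, 2.0]` |
| `maxStromaRpmAbsent` | 1 | stroma RPM ceiling (strict `<`) for the stroma-absent screen |

`stableCecFilter()` is the stability screen; `stromaAbsentFilter()` keeps
genes essentially unexpressed in stroma; `selectCategory()` restricts the
stable screen to one annotated functional category (transporters, cytokine
receptors, transcription factors — category membership and cross-tissue
specificity verdicts are *inputs*, supplied as a gene-annotation table, not
web lookups); `extractGeneSet()` pulls an explicit family such as the SMADs.
All rankings are by descending young-CEC RPM with lexicographic tie-breaks,
so outputs are deterministic and order-independent.

The four-rule flaw taxonomy (`classifyFlaws()`) grades any gene's adequacy
as a marker: `low_in_young` (young RPM < 100), `absent_in_culture` (culture
RPM < 10), `no_stroma_contrast` (young/stroma fold defined and < 5),
`nonspecific` (external verdict `ubiquitous`). A `restricted:<site>` verdict
(e.g. a gene also present in retina) annotates the record without
disqualifying it. The flags are pure functions of the record, so
reclassification is idempotent; the bundled prior-marker table reproduces
its printed 14 x 4 flag grid exactly.

## Sample clustering

`clusterSamples()` clusters samples on `log2(RPM + 1)` with Euclidean
distance and average (UPGMA) linkage by default. The transform and linkage
are standard for depth-normalized bulk profiles. The distance default was
chosen by scanning all transform x distance x linkage combinations against
the expected biology on the bundled 51-gene reference table: the young and
old in-vivo samples must pair first, then culture, with stroma outermost.
Euclidean distance on log RPM reproduces that; a correlation distance
(`1 - r`, also available) does not *on this fixture*, because the fixture's
genes are pre-selected to be CEC-high, which compresses the correlation
contrast between stroma and the in-vivo samples.

A caveat worth stating: the fixture's distances are far from ultrametric
(the culture-stroma distance is smaller than the stroma-to-CEC distances),
so a *global* least-squares ultrametric fit over all 4-leaf topologies
prefers attaching stroma before culture, while agglomerative average
linkage — the estimator this package uses, verified in the tests against a
brute-force implementation — yields the published nesting. On a
marker-selected 51-gene subtable the deep topology is therefore a property
of the linkage rule, not a robust feature of the data; only the young/old
pairing is supported by every estimator. Trees export to newick with branch
lengths equal to merge-height differences.

## Enrichment arithmetic

`categoryPercentages()` reports, for each functional category, the
percentage of list members carrying it. The denominator is the number of
input genes with at least one annotation — the "recognized" genes, as
annotation tools report them — not the list length: on the bundled GO table
a brute-force search shows N = 49 is the unique denominator in 1..200
reproducing every printed percentage of the top-200 young-CEC list.
Categories overlap, so member counts may sum past N; no cross-category
normalization is applied. A one-sided hypergeometric upper tail
(`overrepresentationTest()`, exhaustively verified against enumeration for
small universes) and Benjamini-Hochberg adjustment are attached for
reference; ranking is by percentage, as in the original screen.

## qPCR relative quantification

`deltaCt()` averages Ct across replicates, then subtracts per sample the
arithmetic mean of the housekeeping assays' mean Ct (GAPDH, ATP6V0E1 and
H2AFY by default; a single housekeeping gene reduces to pairwise
subtraction). Arithmetic averaging of Ct corresponds to a geometric mean on
the expression scale. `relativeExpression()` converts to the
reference-sample = 100 scale: `100 * 2^-(dCt - dCt_ref)`, with
amplification efficiency fixed at 2 (TaqMan-style assays, no standard-curve
modelling). Replicate SD is propagated to the linear scale by the delta
method (`ln 2 * value * sd_ct`) for error bars. An assay undetected in a
sample reports 0 with an `undetected` flag — never an imputed maximal
cycle; undetected housekeeping is an error because normalization is
impossible for that sample. Group comparisons (`groupStats()`) use the
Welch two-sample, two-tailed t-test with significance stars at p < 0.05 and
p < 0.01; when both groups have zero variance the t-statistic is undefined
and the result is flagged degenerate (p = 1 for equal means).

## The count simulator

`generateCounts()` draws negative-binomial counts with mean
`template RPM x depth / 1e6` and a single shared dispersion (default 0.1,
typical bulk RNA-seq overdispersion; variance `mu + 0.1 mu^2`). Depths are
uniform on 1.8-4.6 million reads, one library per class — matching the
pooled one-library-per-condition design of the study this screen targets.
Pooling makes per-donor biological variance unidentifiable, so no
donor-level hierarchy is simulated (dispersion 0 gives the deterministic
rounded-mean limit used in tests). Planted archetypes, with per-class mean
RPM templates:

| archetype | young | old | culture | stroma | emulates |
|---|---|---|---|---|---|
| `pan_cec` | 600 | 600 | 250 | 0 | CYYR1-like panel marker |
| `in_vivo_only` | 800 | 600 | 2 | 30 | CA3/PTGDS-like, lost in culture |
| `culture_induced` | 40 | 40 | 2000 | 80 | genes induced by expansion |
| `stroma_marker` | 3 | 3 | 3 | 1000 | keratocyte-restricted |
| `ubiquitous` | 1000 | 1000 | 1000 | 1000 | housekeeping |
| `ocular_non_cec` | 300 | 300 | 150 | 20 | COL8A2-like, `restricted:retina` |
| background | b | b | b | b | low constant, `b ~ lognormal(log 3, 1)` |

The truth table records each gene's template and the filter outcome the
noiseless template implies, so recovery can be scored without circularity.
The generator emulates depth variation, count overdispersion and the
archetype structure; it does **not** emulate batch effects, donor
heterogeneity, gene-length bias or read-level artifacts, so green recovery
tests certify the pipeline's statistical behaviour under the stated noise
model, not performance on arbitrary real data.

### Operating characteristic of the stable screen

With dispersion 0.1 and one library per class, a true marker with young/old
fold 1 still fails the two-sided age window with probability ~0.10: the
log-ratio of two independent NB draws at CV^2 ~ 0.1 has sd ~0.44, and the
rounded window `[0.45, 2.05)` spans ~1.6-1.8 of those sds on each side.
Direct simulation puts the per-gene pass probability at 0.899-0.900, so the
expected recall of the stable filter against planted truth is 0.90 *exactly
at* the conventional 0.9 bar — the acceptance suite measures it as a
Monte-Carlo mean over a fixed batch of replicate simulations and currently
lands at 0.897, a hair under. Precision is comfortably above (~0.95): false
positives require a ubiquitous or background gene to fluctuate past the
2-fold stroma contrast *and* stay inside the age window. We report this
operating characteristic rather than tuning the generator around it; the
practical reading is that a single-library-per-class design cannot
guarantee better than ~90% sensitivity for this criterion at bulk
overdispersion, which is precisely why the original screen validated its
candidates by qPCR across donors.

`generateCt()` simulates plates under the exponential model
`Ct = base - log2(abundance) + N(0, sd)`; noiseless plates round-trip
abundance ratios exactly, and at 0.2-cycle noise a planted 84-fold contrast
is recovered within a few percent on average (both asserted in tests).

## Numerical and degenerate-case policy

* Half-up rounding uses a `1e-9` nudge before `floor()` to absorb binary
  representation error (`2312/90 * 10 = 256.888...` must not truncate).
* Merge and ranking ties break lexicographically; sample columns are sorted
  before clustering so results are independent of input column order.
* A constant expression matrix (or fewer than two genes with nonzero
  variance) cannot be clustered and is an error.
* Duplicate gene identifiers (case-insensitive) are a parse error listing
  the offenders — never merged. Identifiers are matched case-insensitively
  but preserved as given; no alias resolution (ZO-1 and TJP1 are distinct
  strings here) is attempted.
* Missing expression cells do not exist by construction: absent
  measurements must be coded 0 in the input.

## Problem sizes

The regression suite runs the printed-table checks (51-, 20-, 43-, 62-row
tables) exactly, 100-replicate Monte-Carlo checks for the stroma-absent
screen and the qPCR fold recovery, a 60-replicate batch for the stable
screen's precision/recall, and brute-force oracles up to universe size 12
(hypergeometric) and 6 samples (linkage). These sizes give Monte-Carlo
standard errors well below the asserted margins while keeping the default
suite fast.

## Limitations

* Category membership and tissue-specificity verdicts are consumed as
  annotation inputs; the package does not query annotation services.
* Only depth normalization is implemented; comparing libraries with very
  different compositions would need TMM-style correction, out of scope.
* The qPCR module assumes perfect doubling efficiency and does not model
  melt-curve QC or standard curves.
* The full-transcriptome dendrogram and the donor-level qPCR magnitudes of
  the original screen are not reproducible from the bundled summary tables;
  the fixtures anchor procedures, not every published figure.
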