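---
title: "Simulating clonal evolution: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating clonal evolution: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesim)
```

# The simulation model

`clonesim` simulates what a longitudinal bulk-sequencing experiment
would observe in an evolving tumor. The object of interest is a clonal
phylogeny: a rooted tree whose nodes are clones (populations of tumor
cells sharing a mutational profile) and whose root is the germline.
Each clone has a cancer cell fraction (CCF) at each of `n_timepoints`
samples, on a percent scale. CCFs are **cumulative** — a clone's CCF
counts all cells carrying its variants, including every descendant
clone. This convention is forced by two facts: the constraint that the
direct children of a clone may jointly not exceed the parent only makes
sense for cumulative fractions, and the diploid heterozygous
expectation `VAF = CCF/2` relates read support to the fraction of all
cells carrying the variant, descendants included.

## Constraints

A phylogeny is accepted only if, at every time point,

1. each child's CCF is at most its parent's (the germline bound is
   100%),
2. the direct children of any clone sum to at most that clone, and the
   clones attached directly to the germline sum to at most 100%,
3. an eradicated clone stays eradicated (once 0, always 0),
4. every clone reaches the detection threshold `minth` at one or more
   time points, and
5. every pair of clones differs by at least `mindist` at one or more
   time points.

Constraint 4 reflects assay sensitivity: a clone that never rises above
the detection threshold could not have been called in any sample and
would be invisible ground truth. Constraint 5 guarantees that the
simulated clustering problem is well-posed — two clones closer than the
minimum clonal distance everywhere would be statistically
indistinguishable. The pairwise-distance constraint is enforced for
*all* pairs of clones, not merely adjacent ones, since it is meant to
separate every pair of clusters.

## Tunable parameters

| parameter | unit | default | range | role |
|---|---|---|---|---|
| `model` | — | linear | 3 models | topology of new clones |
| `n_timepoints` | samples | 3 | 1–50 | longitudinal depth |
| `n_clones` | clusters | 5 | 1–50 | difficulty of deconvolution |
| `n_variants` | SNVs+CNVs | 20 | 1–200 | evidence per cluster |
| `detection_threshold` (`minth`) | % CCF | 2 | 0–50 | assay sensitivity |
| `min_clonal_distance` (`mindist`) | % CCF | 4 | 0–50 | cluster separation |
| `mean_coverage` | reads | 300 | >0 | sequencing depth |
| `purity` | fraction | 1 | 0–1 | normal-cell dilution |
| `cnv_types` | — | all three | subset | CNV repertoire |

The defaults (3 time points, 5 clones, 20 variants, 300x) are the
baseline configuration of the benchmark grid and are typical of
targeted/WES monitoring of hematologic malignancies.

## Generation algorithm

The founding clone's CCFs are drawn uniformly on [0, 100] per time
point. Subsequent clones pick a parent according to the model:

* **linear** — always the most recently simulated clone, giving a
  single chain;
* **branched dependent** — clone 2 develops linearly from clone 1 and
  clone 3 is the first branch off clone 1; each later clone flips a
  fair coin between a linear step (parent = latest clone) and a
  dependent branch whose parent is chosen uniformly among all existing
  clones;
* **branched independent** — clone 2 branches directly off the
  germline; each later clone flips a fair coin between a linear step
  and a new germline branch.

The coin and the uniform parent choice are our design choices; the
models fix only the first branch. New-clone CCFs are drawn uniformly on
`[0, capacity]` per time point, where the capacity is the parent's CCF
minus the CCFs of its existing children — so constraints 1–2 hold by
construction and rejection only has to handle 3–5. Draws are rounded to
one decimal (the precision carried through the whole pipeline, matching
the integer granularity of `minth`/`mindist`); a draw that hits 0 is
propagated as 0 to all later time points, so eradication is permitted
but never forced. A clone gets up to 100 draws; if none is accepted the
whole simulation restarts with a new founding clone, up to 700
restarts, after which generation fails with an error. With the default
thresholds the restart budget is never approached for the benchmark's
problem sizes (up to 10 clones and 10 time points).

Variant counts assign one variant to every clone; the surplus
`n_variants - n_clones` is split uniformly (each surplus variant picks
a clone independently).

`edit_phylogeny()` exposes the same validator for manual fine-tuning:
any combination of CCF, parent, variant-count, clone, and time-point
edits is applied transactionally — either the edited phylogeny passes
every constraint and is returned (together with the updated parameter
set, since edits may change the dimensions), or the named violations
are raised and the original object is left untouched.

# Variants

CNVs are simulated first: uniform type (after forcing each selected
type to occur once), uniform chromosome among the 22 GRCh37 autosomes,
uniform length on 1–10,000 bp, uniform placement within the
chromosome, and uniform clone assignment subject to the per-clone
variant budget. Chromosome choice is uniform per chromosome rather
than length-weighted; for the purposes of overlap simulation only the
interval arithmetic matters. SNVs are then placed uniformly
genome-wide under the infinite-allele assumption (all positions
unique) and any SNV falling inside a CNV by chance is redrawn, so
overlaps occur only where explicitly configured.

## Scenarios of overlap and the VAF model

When an SNV and a CNV overlap, the genotype of the double-hit cells
depends on the order of events. Four scenarios are distinguished, with
the following copy states (`m` mutated of `t` total copies) for the
SNV+CNV population:

| CNV type | cnv_first | snv_first_affected | snv_first_unaffected | cnv-only | total copies |
|---|---|---|---|---|---|
| deletion | 1/1 (B) | 0/1 (A) | 1/1 (B) | 0/1 | 1 |
| duplication | 1/3 (AAB) | 2/3 (ABB) | 1/3 (AAB) | 0/3 | 3 |
| LOH | 1/2 (AB) | 2/2 (BB) | 0/2 (AA) | 0/2 | 2 |

SNV-only cells are always heterozygous diploid (1/2, AB); under
`parallel` the SNV-only and CNV-only populations are disjoint. Note the
copy-neutral consequence: for LOH under `cnv_first` and `parallel` the
SNV-bearing population keeps copy number 2 and genotype AB, so those
data are indistinguishable from CNV-free SNVs for a clustering tool.

The expected VAF is the copy-weighted population sum
`100 * sum(f_p m_p) / sum(f_p t_p)` with population fractions derived
from the cumulative CCFs: under `cnv_first` the SNV clone is nested in
the CNV clone (double-hit fraction = SNV clone CCF, CNV-only fraction =
difference), under `snv_first_*` the converse, and under `parallel`
both fractions enter unchanged. All tumor fractions are scaled by
`purity`; remaining cells (normal or tumor without either variant)
contribute `m = 0, t = 2`.

## Feasibility of the `parallel` scenario

The clonal relation implied by a scenario restricts which clone may
carry the overlapped SNV: a descendant of (or the same clone as) the
CNV clone for `cnv_first`, an ancestor or the same clone for
`snv_first_*`. For `parallel` we require a *distinct* clone whose CCF,
added to the CNV clone's, stays within 100% at every time point — the
condition under which the two cell populations can be disjoint. This
CCF-capacity reading strictly generalizes topological incomparability
(any two clones in different branches satisfy it automatically via the
children-sum constraints) and is the only reading under which parallel
overlaps can be configured on a linear phylogeny, as the benchmark's
sim44/sim48/sim52 data sets require. Its known limitation: on a chain,
a low-CCF clone pair is treated as disjoint for the VAF computation
even though, under cumulative CCF semantics, one population is in fact
nested in the other; the resulting VAFs are exactly those a CCF-table
driven simulation produces. When no clone satisfies the relation,
`configure_overlap()` fails with a "scenario infeasible" error naming
the CNV and scenario.

Overlapped SNVs are repositioned uniformly inside their CNV and their
clone is reassigned uniformly among the feasible clones, subject to
every clone keeping at least one variant; the phylogeny's per-clone
variant counts are updated to the realized assignment.

## Read simulation

Depths are drawn per SNV and time point from a log-normal with
`meanlog = log(mean_coverage)` and `sdlog = |log(0.7)| ~ 0.357`, an
empirical match to targeted/WES coverage spread. The scale parameter
of a log-normal must be positive, so the magnitude of `log(0.7)` is
used. Observed VAFs add N(0, 1) noise on the *percent* scale to the
expected VAF, clamped to [0, 100] and rounded to one decimal;
supporting reads are `round(depth * vaf / 100)`. The additive-normal
noise model is deliberate (rather than binomial read resampling): it
keeps the noise level independent of depth, which is how the simulated
data are defined here. Consequently VAF noise does *not* shrink with
coverage — coverage effects enter through the depth column that
clustering tools consume.

# Evaluation metrics

**Variation of information.** `VI = H(a) + H(b) - 2 I(a; b)` over the
joint label distribution, computed with natural logarithms (nats) — the
base is a convention and is documented rather than configurable. VI is
a true metric on partitions (label-invariant, symmetric, triangle
inequality), bounded by `2 log n` for `n` variants.

**Discrete spectral distance.** Clonal trees are directed
parent-to-child graphs including the germline node (so single-clone
trees remain comparable). Because the directed adjacency matrix of any
tree is nilpotent — every eigenvalue 0, making all pairs of trees
indistinguishable — the adjacency is symmetrized (`A + t(A)`, clipped
to 0/1) before the spectrum is taken. The distance is the Euclidean
norm between the sorted spectra; when trees differ in size the shorter
spectrum is zero-padded, allowing a truth to be scored against under-
or over-clustered reconstructions. Whether the underlying distance is
better taken on adjacency or Laplacian spectra is a modelling choice;
adjacency is the default and `spectra = "laplacian"` is exposed as an
option. When a tool reports several trees, `average_tree_distance()`
takes the arithmetic mean of the distances.

# Export format

`export_bundle()` writes three files with fixed column order and
formatting — CCFs and VAFs with one decimal, read counts as integers —
so export → import → export is byte-identical and a re-imported bundle
reproduces the in-memory objects exactly. `ref`/`alt` alleles (drawn
uniformly with `ref != alt`; needed for VCF export) are included in the
variant table. Expected VAFs are not serialized: they are a pure
function of the phylogeny, the overlap annotations, and the purity, and
are recomputed on demand. Imports re-run the full constraint validator,
so hand-edited files that break a constraint are rejected with the
violation message.

# The benchmark corpus

`build_benchmark_configs()` enumerates 88 configurations in three
groups: a clustering baseline varying time points (1–10), clones
(1–10), SNVs (5–50), and coverage (10x–2000x) under linear evolution; a
CNV group (sim41–sim52) crossing the three CNV types with the four
scenarios of overlap, each patient carrying 20 SNVs and 6 CNVs that
overlap 1+1+1+2+2+3 = 10 of them; and a tree-reconstruction group
crossing the two branched models with time points 1–10 and clones 3–10.
`run_benchmark()` simulates 10 patients per configuration (880 total)
with per-patient seeds derived deterministically from the base seed,
the configuration index, and the patient index, so the corpus is
reproducible as a whole and per patient, and patients are independent.
When a drawn phylogeny happens to make the configured overlap scenario
infeasible (possible for `parallel`), the patient is resimulated with a
freshly derived seed (up to 25 attempts) before the failure is
propagated; failures never abort the remaining patients. The full
corpus generates in about a minute on a single core.

# What the generator does and does not emulate

The simulation captures the features the evaluated reconstruction
tools actually consume: CCF trajectories with realistic detectability
and separation, depth variability, VAF displacement by overlapping
CNVs, and purity dilution. It does **not** emulate sequencing-error
base substitutions, germline SNPs, mapping artifacts, FASTQ/BAM-level
data, subclonal CNV fractions beyond the clone CCFs (no B-allele
frequencies), or clinically structured dynamics (therapy-induced birth
and death rates). Passing benchmarks on these data therefore
demonstrates correct handling of clonal structure and CNV overlap
arithmetic, not robustness to upstream variant-calling noise.

# Problem sizes used by the test suite

The package's tests validate every generated phylogeny with an
independent validator over 1,000 seeds per model of evolution,
regenerate the full 880-patient corpus once, and estimate the coverage
distribution parameters from 10,000 simulated depths (3% relative
tolerance); distances and VAFs are checked against hand-computed
values and dense-eigensolver / population-bookkeeping oracles on small
explicit cases.
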