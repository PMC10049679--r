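# clonesim

Simulation of tumor clonal evolution for benchmarking subclonal
reconstruction.

Deconvolving bulk-sequencing data into clones and a clonal evolution
tree is a core task of precision oncology, and the tools that automate
it (variant clustering: PyClone, sciClone, QuantumClone, ...; tree
reconstruction: ClonEvol, SCHISM, ...) need ground-truth data to be
evaluated against. `clonesim` generates that ground truth: random but
constraint-valid clonal phylogenies with cancer-cell-fraction (CCF)
trajectories over longitudinal samples, single-nucleotide variants
(SNVs) and overlapping copy number variants (CNVs) with
scenario-adjusted variant allele frequencies (VAFs), and read-level
data as it would be observed in a sequencing experiment. It also ships
the two scores used to compare reconstructions with the simulated
truth, and a generator for a systematic 88-configuration benchmark.

## The model

A simulated patient is a rooted clone tree (root = germline) with a
CCF matrix `[n_clones x n_timepoints]` on the percent scale. CCFs are
*cumulative*: a clone's CCF counts every cell carrying its variants,
descendants included. Trajectories are drawn uniformly at random and
accepted only under the constraints of clonal evolution:

* a child clone never exceeds its parent at any time point;
* a clone's direct children sum to at most the clone itself, and
  clones attached to the germline sum to at most 100%;
* an eradicated clone (CCF 0) never re-appears;
* every clone reaches the detection threshold `minth` (default 2%) at
  some time point;
* every pair of clones is separated by at least `mindist` (default 4%)
  at some time point.

Rejected draws are repeated (up to 100 per clone, 700 restarts of the
whole phylogeny). Three models of evolution are supported: **linear**
(each clone develops from the latest one), **branched dependent**
(branches arise from tumor clones), and **branched independent**
(branches arise from normal cells).

Variants are placed on GRCh37 autosomes under the infinite-allele
assumption; CNVs (deletions, duplications, copy-neutral LOH, each at
most 10 kb) may overlap SNVs under four scenarios — *CNV first*, *SNV
first (affected / un-affected allele)*, and *parallel* — which
determine the genotype of double-hit cells. The expected VAF is the
copy-weighted population sum

```
VAF = 100 * sum_p(f_p * m_p) / sum_p(f_p * t_p)
```

over the cell populations `p` at the locus (`f_p` fraction of cells,
`m_p` of `t_p` copies mutated; normal cells contribute `m=0, t=2`).
Without a CNV this reduces to the familiar `VAF = purity * CCF / 2`;
with one it does not — e.g. a clonal SNV (CCF 100%) whose un-affected
allele is deleted in a 50% subclone is observed at 67%, not 50%:

```r
expected_vaf(100, 50, "deletion", "snv_first_unaffected")
#> [1] 66.66667
```

Read depths are log-normal (`meanlog = log(mean_coverage)`,
`sdlog = |log(0.7)|`), and observed VAFs add N(0, 1) percent noise.

Reconstructions are scored against the simulated truth with the
**variation of information** (VI, in nats; 0 iff the clusterings agree
up to relabeling) and the **discrete spectral distance** (DSD) between
the eigenvalue spectra of the symmetrized adjacency matrices of the
clonal trees.

## Worked example

```r
library(clonesim)
params <- sim_params(model = "branched_dependent", n_variants = 26, seed = 101)
bundle <- simulate_patient(params, n_cnvs = 6,
                           overlap = list(multiplicities = c(1, 1, 1, 2, 2, 3),
                                          scenario = "cnv_first"))
print(bundle$phylogeny)
#> Clonal phylogeny: 5 clones, 3 time points
#>  clone parent n_variants   t1  t2   t3
#>      1      0          3 37.2 4.4 71.0
#>      2      1          8 24.5 1.1 21.3
#>      3      1          3  7.4 1.1 30.9
#>      4      3          6  4.4 0.9  6.9
#>      5      4          6  0.2 0.6  6.6
```

Clone 1 is the founding clone (parent 0 = germline) with branches into
clones 2 and 3; the CCF columns trace each clone over the three
samples — e.g. the tumor regresses at t2 and relapses at t3. The 26
variants (20 SNVs + 6 CNVs) are split across the clones, ten SNVs
overlap a CNV, and each SNV carries per-time-point read counts:

```r
bundle$snvs[1:4, c("id", "clone", "overlap_cnv_id", "scenario",
                   "depth_t1", "alt_t1", "VAF_t1")]
#>     id clone overlap_cnv_id  scenario depth_t1 alt_t1 VAF_t1
#> 1 snv1     4           cnv4 cnv_first      426     10    2.3
#> 2 snv2     4           <NA>      <NA>      379      9    2.4
#> 3 snv3     2           cnv5 cnv_first      362     42   11.7
#> 4 snv4     2           cnv3 cnv_first      385     49   12.7
```

Scoring a (here: deliberately under-clustered) reconstruction and a
wrong tree topology against the truth:

```r
truth <- truth_clustering(bundle$snvs, bundle$cnvs)
merged <- transform(truth, cluster = pmin(cluster, 4))  # merge clones 4 and 5
variation_of_information(truth, merged)
#> [1] 0.3199141
discrete_spectral_distance(tree_to_adjacency(bundle$phylogeny),
                           tree_to_adjacency(c(0L, 1L, 2L, 3L, 4L)))
#> [1] 0.6529879
```

`export_bundle()` / `import_bundle()` round-trip a simulation through
plain TSV/YAML files, `export_vcf()` writes the SNVs as VCF 4.2, and
`run_benchmark(build_benchmark_configs(), base_seed, out_dir)`
regenerates the full benchmark corpus — 88 configurations x 10
patients, each with ground-truth clusters and tree. A thin command-line
wrapper is provided in `inst/cli/clonesim.R`.

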