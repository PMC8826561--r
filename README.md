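# polyorigins

Coalescent simulation and approximate Bayesian inference of polyploid
origins.

## What problem this solves, and for whom

Mixed-ploidy species complexes — a diploid and a tetraploid that are
morphologically near-identical, hybridize where they meet, and share most
of their variation through incomplete lineage sorting — resist the usual
phylogenetic toolkit. Whether the tetraploid arose by autopolyploidy
(whole-genome duplication within one lineage, possibly one that is now
extinct) or allopolyploidy (hybrid formation between two lineages), and
whether its chromosomes segregate tetrasomically or disomically, cannot be
read off a tree: the competing histories predict overlapping patterns.
`polyorigins` is for population geneticists who want to *test* these
histories instead of describing them, using multilocus phased sequence
data of the kind produced by anchored hybrid enrichment.

The package provides the full chain:

* **Polyploid-aware data processing** — ploidy classification from the
  pairwise distances of four phased alleles (`train_ploidy_classifier`),
  MIN/MAX subgenome assignment against the diploid consensus
  (`assign_subgenomes`), flank-filtered SNP extraction and fixed /
  shared / private polymorphism classification, SNP-density phaseability
  profiling, and the D3 introgression statistic.
* **A structured-coalescent simulator** (`simulate_locus`,
  `simulate_dataset`) of polyploid speciation scenarios: {auto-, allo-,
  auto-from-extant} formation x {tetrasomic, disomic, heterosomic}
  inheritance x five interploid migration patterns, with infinite-sites
  mutation and per-locus clock rates.
* **Multilocus summary statistics** (`locus_stats`,
  `dataset_stat_vector`) — per-site diversity, Watterson's theta,
  Tajima's D, Dxy, Da, Hudson FST, polymorphism partitions — plus folded
  site-frequency spectra with the 50%-frequency mass diagnostic of
  disomic inheritance (`folded_sfs`, `simulate_model_grid`,
  `rank_models_by_sfs`).
* **ABC model choice and parameter estimation** (`abc_model_choice`,
  `abc_parameter_posterior`) by rejection with Epanechnikov weighting and
  neural-network regression adjustment, robustness assessment on
  pseudo-observed data, and Bayes-factor model probabilities from
  log-marginal likelihoods (`model_probabilities_from_lnml`).
* **A synthetic-study generator** (`generate_study`) that emits
  truth-labelled phased FASTA alignments with configurable missing-data
  and phasing-error rates, so every stage is testable end to end.

## The statistic at the core

For model choice, a dataset is reduced to the vector of across-locus means
and SDs of the per-locus summary statistics. Given a reference table of
simulated draws from models *M1..Mk*, ABC retains the fraction *tol* of
rows nearest the observed vector under Euclidean distance on MAD-scaled
statistics, weights them by the Epanechnikov kernel
*w_i = 1 − (d_i/d_max)²*, and estimates posterior model probabilities by
regressing the model indicator on the statistics with an ensemble of 35
feed-forward networks (10 hidden units), aggregated by the median. For an
externally computed set of Bezier log-marginal likelihoods, equal-prior
model probabilities are

```
p_i = exp(lnML_i − max_j lnML_j) / Σ_k exp(lnML_k − max_j lnML_j)
```

The inheritance diagnostic uses the folded SFS of the pooled tetraploid
sample: once subgenomes stop recombining (disomy), their fixed differences
sit at exactly 50% sample frequency, so an excess of `mass_at_half`
separates disomic and heterosomic histories from tetrasomic ones.

## A worked example

```r
library(polyorigins)

# a miniature synthetic study: 10 loci, 6 diploids, 4 tetraploids,
# autopolyploid history with diploid-to-tetraploid migration
cfg <- pipeline_config(
  study = study_config(
    n_loci = 10L, locus_length_mean = 800, locus_length_sd = 60,
    n_diploid = 6L, n_tetraploid = 4L,
    params = scenario_parameters(m_dip_to_A = 1e-5, m_dip_to_B = 1e-5),
    missing_rate = 0.01, phase_error_rate = 0.01),
  n_sims_per_model = 40L, n_loci_sim = 10L,
  tolerance = 0.15, n_nets = 6L, n_hidden = 4L, n_keep = 30L,
  master_seed = 7L)
report <- run_end_to_end(cfg)
report$model_posterior
#> <abc_model_posterior> method: neural_network | retained: 36
#>   allopolyploid.tetrasomic.unidirectional_dip_to_AB       0.7711
#>   autopolyploid.tetrasomic.bidirectional_AB               0.1232
#>   allopolyploid.tetrasomic.none                           0.0752
#>   allopolyploid.tetrasomic.bidirectional_AB               0.0218
#>   autopolyploid.tetrasomic.unidirectional_dip_to_AB       0.0087
#>   autopolyploid.tetrasomic.none                           0.0000
```

Read this output the way a practitioner would. The study was generated
under the autopolyploid model with unidirectional diploid-to-tetraploid
migration. The posterior concentrates on models *with* migration (the two
no-migration models get essentially nothing) — migration history is the
strongly identified axis. But the top model is the *allopolyploid*
one-way-migration history: at this miniature scale (10 loci, 40
simulations per model) the auto/allo contrast is genuinely confounded,
because the two models differ only in where the tetraploid's lineages
re-attach at the duplication event, and interploid gene flow erodes
exactly that signal. Larger reference tables and more loci sharpen but do
not eliminate this confusion; the vignette discusses it, and the
`robustness_assessment()` function quantifies it for any model pair.

Converting published Bezier log-marginal likelihoods of descendance models
into model probabilities:

```r
lnml <- migrate_lnml_table()
round(model_probabilities_from_lnml(setNames(lnml$MW, lnml$model)), 2)
#> EC no migration CC no migration    CC migration WC no migration    WC migration
#>            0.01            0.00            0.01            0.00            0.03
#> NE no migration    NE migration SW no migration    SW migration
#>            0.88            0.04            0.00            0.04
```

The MW tetraploid lineage is overwhelmingly supported (0.88) as a
descendant of the NE tetraploid lineage without ongoing migration from it.

## Scope notes

Raw-read processing, assembly, orthology assessment, tree inference, and
the migrate-n MCMC itself are out of scope: the package consumes phased
alignments and (for descendance testing) externally computed log-marginal
likelihoods. See the vignette
(`vignettes/polyploid-origin-inference.Rmd`) for the model, its
assumptions, and the package's design choices.
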