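# cichlidDE

Stage-wise differential expression and equivalence testing for 3' mRNA-seq
counts from multiple brain regions sampled within individuals of two
closely related species.

## The problem

In a brain-region atlas experiment — two congeneric cichlid species, five
female individuals each, six macroanatomical brain parts (BS, CE, DI, OB,
OT, TE) dissected per individual, 60 libraries — every gene carries many
research questions at once: is it differentially expressed between each
part and the average of the others, within each species (12 contrasts)? Do
part-to-part differences differ between species (15 interaction contrasts)?
Is a fold change *biologically large* (|log2FC| > 2)? And are the two
species' fold changes statistically *equivalent* (within ±2 log2 units)?
Because the six samples of an individual are clustered, and because dozens
of hypotheses are tested per gene, naive per-contrast FDR control does not
control the rate of genes with any false claim.

cichlidDE implements the full analysis as a tested, reusable pipeline:

* low-count filtering (≥ 15 CPM in ≥ 4 samples) and TMM normalization;
* MDS sample maps from leading-log-fold-change or common top-gene distances;
* gene-wise negative binomial GLMs with log link — counts
  `y ~ NB(mean = exp(offset + individual + part + species:part), phi)` —
  with fixed individual effects absorbing the clustered design (and the
  confounded species main effect);
* Cox–Reid adjusted profile likelihood dispersions, an abundance trend, and
  empirical-Bayes quasi-likelihood squeezing; QL F-tests;
* stage-wise testing: BH screening of each gene's global null at 5% FDR,
  then within-gene Holm confirmation at the screening-adjusted level
  `alpha * R / G` — controlling the *gene-level* FDR at 5%;
* threshold (|log2FC| > 2) tests and offset-shift TOST equivalence tests
  per contrast and globally across all 15 interaction contrasts;
* competitive gene-set enrichment with an inter-gene correlation (VIF)
  correction;
* a negative binomial simulator of the whole design with known truth, and
  scoring of FDR, power and log2FC recovery against that truth.

## Worked example

```r
library(cichlidDE)

sim <- simulate_experiment(sim_config(n_genes = 2000, seed = 7))
res <- run_pipeline(sim$counts, sim$samples, out_dir = "results")

res$stagewise_within
#> stagewise_result (within_species): 205 of 2000 genes screened at FDR 0.05;
#>   confirmation level 0.005125
#> 446 significant gene x contrast flags

glance(res$stagewise_within)
#> # A tibble: 1 × 6
#>   family         n_genes n_screened alpha alpha_adj n_significant
#>   <chr>            <int>      <int> <dbl>     <dbl>         <int>
#> 1 within_species    2000        205  0.05   0.00512           446

evaluate_fdr(res$stagewise_within, sim$truth, family = "within")
#> # A tibble: 1 × 4
#>   n_flagged gene_fdr power hypothesis_fdr
#>       <int>    <dbl> <dbl>          <dbl>
#> 1       197   0.0152 0.951        0.00673

res$equivalence$per_contrast$mean_prop_equivalent
#> [1] 0.9565667
```

Read: of the 2000 simulated genes, 205 were screened as showing any part
effect, and 446 individual part-versus-average claims were confirmed across
197 genes. The observed gene-level FDR against the simulation truth is 1.5%
(guaranteed ≤ 5%), with 95% power; on average 95.7% of genes are declared
equivalent
between species per interaction contrast — this simulation planted
species-specific effects in only 2% of genes.

Result objects are tibble-first: `tidy()` on any stage-wise result,
dispersion model or MDS result returns a tidy table, `glance()` a one-row
summary, and `autoplot()` draws the standard MDS, dispersion-trend,
p-value-histogram and heatmap figures with ggplot2.
`candidate_gene_report()` extracts per-part fold changes and adjusted
p-values for a list of genes of interest. A thin command-line wrapper lives
at `inst/scripts/pipeline.R`.

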