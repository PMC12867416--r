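# guildnet

Guild-level analysis of case/control microbiome cohorts.

Microbiome studies of metabolic disease increasingly find that the
informative unit is not the single taxon but the **guild**: a set of OTUs
that co-occur as a module of the association network. guildnet implements an
end-to-end, fully seeded pipeline for asking whether guilds reorganize
between a healthy and a diseased state, whether a **stable core guild**
persists across both, whether transitional "**grey zone**" samples sit
between the two ecologies, and whether guild abundance carries
epidemiological risk across cohorts. Everything is testable without external
data through a ground-truthed synthetic-cohort generator.

## What it computes

* **Compositional preprocessing** — depth filter (samples below 10,000 reads
  excluded), prevalence (<10%) and mean-relative-abundance (<5e-5) OTU
  filters, centered log-ratio transform with half-count pseudocount:
  `clr_i = log(x_i + 0.5) - mean_j log(x_j + 0.5)`.
* **Co-occurrence networks** — Spearman rank correlation between CLR
  profiles; one Benjamini–Hochberg family across all pairs; edge iff
  `q < 0.05` and `|ρ| ≥ 0.3`; signed, undirected, with topology metrics
  (density `2E/(N(N−1))`, degree centralities, mean local clustering,
  path length on the largest component, negative-edge fraction).
* **Stable network & guilds** — edges significant in *both* condition
  networks with the same sign; Louvain modularity maximization on |ρ|
  weights (Newman–Girvan `Q = Σ_g [e_g/m − (d_g/2m)²]`); Guimerà–Amaral
  Zi–Pi node roles (`pi = 1 − Σ_g (k_g/k)²`); per-sample guild abundance;
  cross-group bridging subgraphs.
* **Null models & robustness** — node-subset permutation tests
  (`z = (obs − mean_null)/sd_null`, smoothed two-sided permutation p) and
  attack-robustness curves of the largest connected component under
  targeted-by-degree vs random removal.
* **Grey-zone stratification** — stratified 7:3 split, SMOTE balancing,
  L1 feature selection + pluggable cross-validated classifier, Mann–Whitney
  AUC; zones: grey iff `0.4 ≤ P ≤ 0.6`, Clear case iff `P ≥ 0.7` and
  clinically case, Clear control iff `P ≤ 0.3` and clinically control,
  otherwise unassigned; per-bin misclassification; cross-model grey-zone
  concordance.
* **Guild epidemiology** — median dichotomization (ties low), 2×2 odds
  ratios with Haldane–Anscombe correction, inverse-variance fixed-effect
  meta-analysis with Cochran's Q and `I² = max(0,(Q−df)/Q)·100`,
  covariate-adjusted OLS group differences.
* **Synthetic cohorts** — logistic-normal multinomial counts with planted
  correlated guild blocks, grey mixture samples, a calibratable planted
  odds ratio, and maternal–offspring transmission coupling.

## Worked example

```r
library(guildnet)

guilds <- guild_spec(sizes = c(10, 8), rho_intra_case = 0.7,
                     abundance_log_shift = c(0.6, 0))
cohort <- cohort_spec(n_case = 150, n_control = 150, n_noise_otus = 32,
                      depth_mean = 30000, seed = 11)
sim <- generate_cohort(guilds, cohort)
sim$table
#> otu_table: 300 samples x 50 OTUs
#>   total reads: 8910693 | depth range: 10355-63902

tab <- filter_otus(filter_samples_by_depth(sim$table))
clr <- clr_transform(tab)
state <- sim$truth$sample_state[rownames(clr)]
net_case <- build_network(clr[state == "case", ], label = "case")
net_ctrl <- build_network(clr[state == "control", ], label = "control")
net_case
#> cooccurrence_network 'case' : 20 nodes, 152 edges
#>   thresholds: |rho| >= 0.3 , BH q < 0.05
#>   negative edges: 79

stable <- stable_network(net_case, net_ctrl)
part <- detect_guilds(stable, seed = 1)
part
#> guild_partition: 2 guilds over 18 nodes ( louvain )
#>   modularity Q = 0.0530
#> guild
#>  0  1
#> 10  8
adjusted_rand_index(part$assignment,
                    sim$truth$membership[names(part$assignment)])
#> [1] 1
```

Both planted guilds are recovered exactly (adjusted Rand index 1). Is the
first guild unusually cohesive within the case network? Test it against
1,000 random node subsets of the same size (background keeps isolated OTUs,
so the null reflects the whole community):

```r
net_bg <- build_network(clr[state == "case", ], label = "case",
                        retain_isolates = TRUE)
subset_permutation_test(net_bg, names(part$assignment)[part$assignment == 0],
                        n_perm = 1000, seed = 2)
#> node-subset permutation test (10 targets, 1000 permutations)
#>                   metric observed null_mean null_sd     z   p_perm degenerate
#> 1                density        1    0.1221 0.09869 8.896 0.000999      FALSE
#> 2        mean_clustering        1    0.3087 0.19264 3.589 0.000999      FALSE
#> 3 mean_degree_centrality        1    0.1221 0.09869 8.896 0.000999      FALSE
#> 4  max_degree_centrality        1    0.2932 0.15382 4.595 0.000999      FALSE
#> 5                n_edges       45    5.4930 4.44091 8.896 0.000999      FALSE
```

The guild's density sits ~9 null standard deviations above random subsets
(p is the smoothed permutation floor 1/1001): a genuinely non-random module.
Finally, does carrying a lot of this guild associate with case status across
(here, artificially split) cohorts?

```r
ab <- guild_abundance(tab, part, guild = 0)
cond <- setNames(sim$metadata$condition, sim$metadata$sample_id)[names(ab)]
cohorts <- setNames(rep(c("A", "B", "C"), length.out = length(ab)), names(ab))
guild_meta_analysis(ab, cond, cohorts)
#> fixed-effect meta-analysis of 3 cohort(s)
#>   pooled OR = 3.517 (95% CI 2.182-5.669), p = 2.42e-07
#>   heterogeneity: Q = 2.226 on 2 df, I^2 = 10.2%
```

The pooled odds ratio of 3.5 brackets the planted ground truth
(`sim$truth$planted_or` is 3.03): samples above the median guild abundance
have ~3.5-fold higher odds of being cases, with low cross-cohort
heterogeneity.

## Command line

```sh
Rscript inst/cli/guildnet.R simulate --n-case 100 --n-control 100 \
    --guild-sizes 17,15,12 --rho-intra-case 0.7 --seed 1 --out-dir sim/
Rscript inst/cli/guildnet.R network --table sim/otu_table.tsv \
    --metadata sim/metadata.tsv --group case --out-prefix sim/case
Rscript inst/cli/guildnet.R guilds --table sim/otu_table.tsv \
    --metadata sim/metadata.tsv --seed 1 --out-prefix sim/guilds
```

Other subcommands: `nulltest`, `robustness`, `stratify`, `meta`.

## Documentation

`vignettes/guild-dynamics.Rmd` explains the statistical model, every
default and threshold, the simulator's stated world and its limits, and the
design decisions taken where the design was genuinely open.
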