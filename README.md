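# kinrates

Do words for kin change more slowly when people say them more often?
`kinrates` is an R package for relating the **rate of lexical replacement**
of word meanings — here the ten consanguineal kin types (B, D, F, M, MB, MZ,
MZD, MZS, S, Z) — to their **usage frequency in corpora**, on dated language
phylogenies. It is aimed at quantitative historical linguists and cultural
evolution researchers who want the complete chain from raw word lists to a
mixed-model estimate of the frequency effect, with every stage testable on
synthetic data.

## What it computes

1. **Cognate classes** per meaning: normalized Levenshtein distance between
   word forms, flat average-linkage (UPGMA) clustering cut at θ = 0.4, with
   expert-override support and provenance tracking.
2. **Replacement rates** per meaning: a k-state frequency-scaled CTMC
   (F81-style, `q_ij = μ π_j`) on a posterior sample of dated trees.
   Felsenstein pruning with the closed-form kernel
   `p_ij(t) = π_j + (δ_ij − π_j) e^{−μt}`, Metropolis–Hastings sampling of
   `log μ` with uniform tree-swap proposals, and the global replacement
   rate reported per 10,000 years:

   `R = −Σ_i π_i q_ii = μ (1 − Σ_i π_i²)`

   plus stepping-stone marginal likelihoods (100 stones × 1,000 iterations)
   and split-chain Gelman–Rubin diagnostics over replicate chains.
3. **clfpm**: centered log frequency per million — log fpm centered within
   each corpus and averaged across corpora per word per language, with
   core-vocabulary duplicates of kin concepts (mother, father, husband,
   wife) excluded.
4. **The frequency effect**: `lme4` maximum-likelihood fit of
   `log(mean_rate) ~ clfpm * lexical_class` with AIC-selected random
   effects, reported as estimate / standard error / Wald t.

A synthetic-data generator (`make_study_fixture()`) produces full studies —
jittered tree samples, evolving word forms with true cognate classes, and
Poisson corpus counts log-linearly coupled to the true rates — so the whole
pipeline can be exercised and validated without any external data.

## A worked example

```r
library(kinrates)

# a dated tree and one simulated kin-term character
tr <- simulate_tree(20, root_age = 8700, seed = 42)
ch <- simulate_character(tr, R = 2, mode = "infinite_alleles",
                         seed = 43, meaning = "MZ")
ch
#> Multistate character 'MZ' : 20 taxa, 6 observed state(s), 0 missing

# three replicate chains, pooled after a convergence check
chains <- lapply(1:3, function(j)
  mcmc_rate(ch, tr, schedule = scaled_down_schedule(),
            seed = 100 + j, tree_mode = "fixed"))
gelman_rubin(chains)
#> Gelman-Rubin PSRF = 0.9995 over 3 chains: pass (< 1.1)
summarize_rates(chains)
#>   meaning mean_rate  ci_lower ci_upper     psrf n_draws
#> 1      MZ   2.89079 0.5420912 17.75364 0.999523    3000
```

The character was simulated at a true rate of 2 replacements per 10,000
years; the pooled posterior mean is 2.9 with a broad 95% credible interval
(0.54–17.8) — a single character is weakly informative, which is why the
study design averages over many meanings and why replicate characters can
be analysed jointly (pass `mcmc_rate()` a list).

Cognate coding of the grandparent terms from Swedish, Polish and English:

```r
d <- distance_matrix(c(Swedish = "farfar", SwedishMF = "morfar",
                       Polish = "dziadek", English = "grandfather"))
flat_cluster(d, 0.4)
#>   Swedish SwedishMF    Polish   English
#>         1         1         2         3
```

*farfar* and *morfar* (distance 1/3) fall in one class; *dziadek* and
*grandfather* are each their own class — three cognate classes for the
grandfather meanings.

Regression on a synthetic table generated with slope −0.58 and
interaction 0.18:

```r
tab <- simulate_regression_table(n_languages = 20, n_kin = 10,
                                 n_swadesh = 90, seed = 314)
fit_model(tab)
#> Rate ~ frequency x class fit (log outcome, random: (1 | language))
#>                            estimate std_error  t_value
#> (Intercept)                  0.3583    0.0819   4.3735
#> clfpm                       -0.5994    0.0221 -27.0790
#> lexical_classswadesh         0.2237    0.0220  10.1747
#> clfpm:lexical_classswadesh   0.1977    0.0232   8.5116
#> AIC 901.29  logLik -444.64  n = 2000
```

The `clfpm` row is the frequency effect for kin terms (negative: frequent
terms are replaced more slowly); the interaction row is how much weaker the
effect is for core vocabulary.

The whole chain — simulate, code cognates, estimate rates, build clfpm,
fit — runs with one call:

```r
fit <- run_all(pipeline_config(out_dir = "study_out", seed = 42))
```

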