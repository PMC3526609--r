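# mirord

Bayesian inference of microRNA–mRNA regulatory interactions from
**partially ordered** paired expression data, combined with sequence-based
target-prediction scores.

## The problem

MicroRNAs (miRs) regulate mRNAs, typically by repressing them. Two noisy
evidence sources are commonly combined to infer which predicted
miR–target pairs are real: paired miR/mRNA expression profiles, and
sequence-based target predictions (TargetScan *context+* scores, miRanda
*mirSVR* scores). Most integration methods ignore any natural ordering of
the samples. But in staged studies — time courses, developmental series,
disease progressions such as the Durie–Salmon stages of multiple
myeloma — samples close in the ordering should have similar expression,
and interactions that act *stage-to-stage* are exactly the ones of
biological interest. `mirord` exploits that structure.

## The model

Samples are grouped into **stages**, the nodes of a user-declared DAG
(the *partial order*). For miR $i$ at a non-initial stage $s$ with
parents $P(s)$ and per-edge *development distances* $\delta_{ps} > 0$,
the latent log expression is normal with

$$
\mu_{is} \;=\;
\frac{\sum_{p \in P(s)} \tfrac{1}{\delta_{ps}}\left(x_{ip} + \tau_i\,\delta_{ps}\right)}
     {\sum_{p \in P(s)} \tfrac{1}{\delta_{ps}}},
\qquad
\text{precision} \;=\; \lambda_i \sum_{p \in P(s)} \tfrac{1}{\delta_{ps}},
$$

so a nearby parent (small $\delta$) dominates the prior and tightens it,
and $\tau_i$ is the miR's **trend** per unit of development. mRNA
expression $y_{gs}$ follows the same propagation with the trend term
replaced by an **interaction effect** $(r_g \cdot x_s)\,\delta_{ps}$ —
the dot product of the gene's interaction coefficients with the latent
expression of its candidate miRs. Each coefficient has a
prediction-informed prior

$$
r_{jg} \sim \mathcal N\!\left(c_{jg}^{\top} \beta,\; \phi_r^{-1}\right),
$$

where $c_{jg}$ stacks per-algorithm indicators and scores and $\beta$ is
estimated jointly with everything else; interactions may be positive or
negative. Observations sit under a two-level technical noise hierarchy
(expression set = array, then within-array replicates). The posterior is
approximated by mean-field variational Bayes coordinate ascent with a
monotone evidence lower bound (ELBO); development distances are point
values updated by maximizing the bound.

Pairs are ranked by the posterior z-score of $r_{jg}$; per-miR trends
with $|z| > 3$ make the trend table. A Pearson-correlation baseline and
the *average relative rank* statistic (mean elementwise ratio of two
ascending rank lists of the same validated pairs) support evaluation
against validated-target databases.

## Worked example

Simulate a staged study with known ground truth (28 miRs, 100 genes,
four Durie–Salmon-like stages plus a branch, 2 arrays per stage with 2
replicate spots), fit, and rank:

```r
library(mirord)
cfg <- synthetic_config("default", n_gene = 100, sets_per_stage = 2, reps_per_set = 2)
sim <- generate_synthetic(cfg, seed = 42)
fit <- vb_fit(sim$dataset, sim$order, sim$predictions, n_iter = 200, seed = 42)
head(rank_interactions(fit), 5)
#>   rank     mir     gene   mean     sd     z       predicted_by
#> 1    1 miR-001 GENE0014 -0.251 0.0144 -17.5 targetscan,miranda
#> 2    2 miR-001 GENE0087 -0.234 0.0178 -13.1 targetscan,miranda
#> 3    3 miR-013 GENE0093 -0.247 0.0216 -11.4 targetscan,miranda
#> 4    4 miR-001 GENE0064 -0.175 0.0156 -11.2         targetscan
#> 5    5 miR-002 GENE0066 -0.293 0.0263 -11.2 targetscan,miranda
head(significant_trends(fit, z_threshold = 3), 3)
#>       mir direction    z
#> 1 miR-015         - 52.6
#> 2 miR-024         + 28.6
#> 3 miR-004         + 23.3
```

Every top-ranked interaction is negative (repression), with posterior
mean effect sizes around −0.2 to −0.3 on the standardized scale, and the
three strongest trend calls are exactly three of the five miRs the
generator gave a drift of ±1 (miR-015 −, miR-024 +, miR-004 +), with the
right directions. Recovery against the full ground truth:

```r
recovery_report(sim$truth, fit)
#> $r_correlation        0.414
#> $sign_agreement       0.974
#> $active_top_quartile  0.291
#> $trend_recovery       0.8
```

Comparing a model ranking with a correlation baseline through validated
pairs found at ranks 63, 229, 234, 273, 612 (model) and 341, 402, 819,
877, 893 (absolute correlation):

```r
average_relative_rank(c(63, 229, 234, 273, 612), c(341, 402, 819, 877, 893))
#> [1] 0.407
```

i.e. on average the model places validated pairs at 0.41 times the
baseline's rank — a direct estimate of the relative experimental effort
to reach the same number of validations.

Real studies enter through TSV readers (`read_expression_tsv`,
`read_annotation_tsv`, `read_prediction_table` with TargetScan/miRanda
dialects), the preprocessing pipeline (`preprocess_dataset`: quantile
normalization → probewise ANOVA filter → predicted-pair restriction →
z-scaling), and the three ordering builders (`build_grouped_ordered`,
`build_individual_ordered`, `build_individual_reference`). A thin CLI
wrapper (`inst/cli/mirord.R`) exposes
`simulate / preprocess / fit / rank / eval` subcommands over one YAML
config.

## Vignette

`vignettes/mirord-methods.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, what the synthetic
generator does and does not emulate, numerical choices, and known
limitations (including which parameters are only jointly identified).
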