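# grnlab

Tools for benchmarking kinetic parameter estimation and network topology
inference on gene regulatory networks, in the style of community
"hidden-model" challenges: an ODE-simulated network whose parameters you
cannot see, a priced catalogue of noisy in-silico experiments bought
against a credit budget, challenge scoring with resampling null models,
wisdom-of-crowds aggregation of submissions, and a baseline
maximum-likelihood estimation pipeline with identifiability analysis.

It is aimed at people developing or teaching parameter-inference and
experimental-design methods for systems biology who want a fully
reproducible, self-contained benchmark harness.

## The models and statistics

Two model classes are supported. Transcription–translation models carry one
mRNA and one protein per gene,

    d mRNA_i/dt = pro_i * prod_r f_r(P_source(r)) - mRNA_i
    d P_i/dt    = rbs_i * mRNA_i - delta_p * P_i

with Hill regulation terms `f(P) = 1/(1+(P/Kd)^h)` (repression) or
`(P/Kd)^h/(1+(P/Kd)^h)` (activation), non-dimensional time in units of the
mRNA half-life, and one shared protein degradation rate. Protein-only
models drop transcription and combine per-regulation synthesis terms
additively, with per-gene degradation and basal rates for unregulated
genes; regulations may drive a two-gene operon.

Experiments (deletion, siRNA knockdown, RBS decrease; fluorescence /
microarray / mass-spec read-outs; gel shift) are priced in credits and
measured through the noise model `v_noisy = v + 0.1 g1 + 0.2 g2 v`, clipped
at zero.

Submissions are scored by the challenge statistics

    D_prot  = 1/(3(N-11)) * sum_k sum_{i=11..N} (pred - sim)^2 / (0.1^2 + 0.2^2 sim^2)
    D_param = 1/Np * sum_i log10(v_pred/v_real)^2
    Score1  = -log10(p_prot * p_param),   Score2 = -log10(p_netw)

with p-values from resampling "relative" nulls built out of the submission
pool itself, and topology predictions scored by the 6/12-point full-credit,
partial-credit link rules.

## Worked example

Open a challenge session over the bundled 9-gene benchmark, buy data, and
score a submission:

```r
library(grnlab)

m1 <- model1_fixture()                      # 9 genes, 45 parameters
ch <- make_challenge(m1, budget = 5000, seed = 11)

d0 <- ch$initial_data()                     # free low-res wildtype microarray
d1 <- ch$buy(list(), measurement_request("fluorescence",
                                         targets = c("p_g3", "p_g5")))
ch$balance()
#> [1] 4600                                 # 5000 - 400 credit fluorescence

# the scored prediction condition: r9 Kd /10, rbs3 x2, rbs5 x10
cond <- list(perturbation("parameter_scale", "r9_Kd", 0.1),
             perturbation("parameter_scale", "g3_rbs", 2),
             perturbation("parameter_scale", "g5_rbs", 10))
gold <- ch$gold_predictions(cond, c("p_g3", "p_g5", "p_g8"))

set.seed(1)
pred <- pmax(gold * exp(rnorm(length(gold), 0, 0.15)), 0)
protein_distance(pred, gold)
#> [1] 0.2362497                            # variance-weighted mean sq. distance

set.seed(2)
sub <- m1$params * exp(rnorm(45, 0, 0.3))   # a parameter submission
ch$score_parameters(sub)
#> [1] 0.02159062                           # mean squared log10 ratio

score1(1.21e-25, 3.25e-3)                   # combined score from two p-values
#> [1] 27.40533
```

`protein_distance` is the noise-variance-weighted mean squared prediction
error over the scored window (from the 11th time point on);
`score_parameters` returns the mean squared log10 parameter ratio, so 0.022
means a typical mismatch of a factor `10^sqrt(0.022) ≈ 1.4`. The estimation
side (`fit_multistart`, `profile_likelihood`, `rank_experiments`,
`steady_state_init`, `solve_regulation`) is demonstrated in the vignette
(`vignettes/grn-challenge-toolkit.Rmd`), and a thin command-line wrapper
lives at `inst/cli/grnlab.R`.

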