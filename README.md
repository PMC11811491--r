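# senadapt

An adaptive intervention engine for social-skill training in children with
autism spectrum disorder (ASD), built for methodologists working on dynamic
treatment regimes and just-in-time adaptive interventions. The package
implements, end to end and with simulation-based validation:

- **attention-weighted engagement scoring** — per interaction, cue
  intensities $x \in [0,1]^M$ are weighted by a softmax over alignment
  scores $e_j = x_j g_j$ with a skill-goal vector $g$, giving
  $E = \sum_j a_j x_j$;
- **a gated latent interaction state**
  $z_i = \Gamma(x_i, z_{i-1}) \odot (\phi(x_i) + \sum_{j<i} e^{-\rho(i-j)} A z_j) + \varepsilon$
  with decaying memory;
- **a dynamic transition model**
  $z_{i+1} = a_i \odot (\delta_i g(z_i) + (1{-}\delta_i) h(x_{i+1})) + \varepsilon$
  with context-dependent decay and attention modulation, fitted by
  regularized least squares with monotone line-searched gradient descent;
- **a reward stack** $R = s + \alpha \Delta s$, discounted cumulative and
  predictive variants, and a flat penalty for sub-threshold improvement;
- **a tabular TD(0) intervention policy**
  $Q(s,j) \leftarrow Q(s,j) + \beta (R + \gamma \max_{j'} Q(s',j') - Q(s,j))$
  over discretized engagement states with epsilon-greedy exploration;
- **confidence-based adjustment** — intervention frequency and intensity
  follow $c = \exp(-\mathrm{Var}_K(E))$, the rolling-window engagement
  stability;
- **a seeded synthetic cohort simulator** with known ground-truth effects
  (mean-reverting AR(1) engagement, additive intervention effects), so TD
  correctness, parameter recovery and policy improvement are all checked
  against analytic references.

The methods vignette
(`vignettes/adaptive-intervention-engine.Rmd`) documents the models, every
tunable parameter, and the design decisions.

## Worked example

Train the adaptive policy on a simulated cohort in which one of three
interventions truly raises next-step engagement by +0.3, then compare it
with baselines:

```r
library(senadapt)

cc  <- cohort_config(n_children = 20, n_interactions = 30, seed = 42)
res <- train_policy(cc, n_sessions = 200)

q_values(res$q, "b6")           # learned Q at score bin [0.6, 0.7)
#> video_modeling  social_prompt  reinforcement
#>       8.714644       8.589551       8.634471

ev <- evaluate_policies(
  cc,
  list(adaptive = senadapt:::policy_from_q(res$q),
       random   = senadapt:::policy_random(cc$catalog),
       never    = senadapt:::policy_never()),
  n_sessions = 100, discount = 0.9, seed = 1)
print(ev$summary, digits = 3)
#>     policy mean_return sd_return n_sessions
#> 1 adaptive        9.51     0.087        100
#> 2   random        7.55     1.299        100
#> 3    never        4.78     1.190        100

round(res$adjust$smoothed_intensities, 2)
#> video_modeling  social_prompt  reinforcement
#>           2.00           0.67           0.64
```

The learned table prefers `video_modeling` (the truly effective
intervention) in every visited bin; its mean per-session discounted return
(9.51) exceeds the uniform-random baseline (7.55) and never-intervening
(4.78); and the intensity controller has pushed the effective
intervention's delivered intensity to its cap while backing off the null
ones.

## Command line

A thin CLI over the same functions ships at `inst/cli/senadapt.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "senadapt.R", package = "senadapt"))')
Rscript "$CLI" simulate     --seed 7 --out cohort.jsonl
Rscript "$CLI" score        --seed 7 --in cohort.jsonl --out scores.csv
Rscript "$CLI" fit          --seed 7 --in cohort.jsonl --out params.json
Rscript "$CLI" run-adaptive --seed 7 --out training.jsonl
Rscript "$CLI" evaluate     --seed 7 --out eval.csv
```

Every command accepts a YAML `--config` (see `default_config()` for the
documented keys and defaults), writes a manifest with the effective
configuration, seed and input digests next to each artifact, and is
byte-deterministic: the same configuration and seed reproduce identical
outputs.

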