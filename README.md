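# lcnet

Latent cause inference with context-indexed neural networks.

## The problem

When an agent processes a continuous stream of experience, the underlying
context ("latent cause", LC) is hidden, temporally persistent, and changes at
unpredictable moments. Splitting experience by inferred cause prevents
interference between contexts (the word for *water* differs between two
similar languages), but a model that dedicates a separate memory to every
cause can never exploit what contexts share (*book* is the same word in
both). `lcnet` implements a network model that reconciles the two: a single
predictive network stores shared structure in its weights, while
context-specific structure enters through a fixed random Gaussian **context
vector** per inferred cause, fed to the hidden layer. Because random
high-dimensional vectors are nearly orthogonal, causes occupy well-separated
regions of hidden space without growing the parameter count.

Cause assignment is Bayesian and nonparametric. With `K` causes inferred so
far, a sticky Chinese Restaurant Process prior scores cause `k` at time `t`:

    P(z_t = k | z_{1:t-1}) ∝  count_k + λ·1[z_{t-1} = k]   for k ≤ K
                              α                             for k = K+1

so well-used causes and the currently active cause are favoured, and mass α
is reserved for a brand-new cause. The likelihood of each cause is how well
the network explains the current observation when modulated by that cause's
context vector: `loss_k = MSE(f(x_{t-1}, c_k), x_t)`, with the new-cause loss
computed from a preallocated candidate vector, and
`likelihood = softmax(−loss / T)`. The model commits to the maximum a
posteriori cause (local MAP) and takes one stochastic-gradient step under it.
Switches of the inferred cause are **event boundaries**.

The package ships the inference engine, three predictive architectures (a
context-indexed feedforward network, a context-indexed GRU, a context-blind
baseline, and a one-network-per-cause expert ensemble), seeded generators for
three task environments, segmentation metrics (cluster purity, adjusted
mutual information, point-biserial correlation with achievable-range scaling,
permutation tests), and runners for three simulation studies:

1. **Polynomial function learning** — shared vs idiosyncratic structure,
   catastrophic interference, reuse, and a lesion analysis of the context
   pathway.
2. **Schema learning** — a two-context transition graph learned under
   blocked vs interleaved curricula, with two-alternative forced-choice
   accuracy and latent-cause purity.
3. **Event segmentation** — a recurrent model trained on next-frame
   prediction over a synthetic naturalistic event corpus, scored against
   ground-truth event labels and simulated annotator boundary probabilities.

## A worked example

Fit the recurrent model to one synthetic video stream and score its
boundaries against the simulated annotators:

```r
library(lcnet)

set.seed(42)
corpus <- generate_event_corpus(n_videos = 1, n_classes = 4,
                                frames_per_video = 400, persistence = 0.98)

fit <- lcnet(corpus$frames[[1]], architecture = "gru",
             alpha = 0.5, stickiness = 1, temperature = 0.1,
             context_dim = 16, learning_rate = 0.03,
             ctx_init_gain = 0, ctx_grad_mult = 10, seed = 7)
print(fit)
#> Latent-cause network fit (gru)
#>   400 observations, 3 latent cause(s), 24 boundaries
#>   alpha = 0.5, stickiness = 1, temperature = 0.1

b   <- extract_boundaries(fit)
spb <- scaled_point_biserial(b, corpus$subject_prob[[1]])
permutation_pvalue(spb, b, corpus$subject_prob[[1]], n_perm = 999)
#> scaled point-biserial: 0.417   permutation p: 0.009
```

The model inferred 3 latent causes and 24 boundary frames; its boundaries
align with the pooled annotator presses far better than chance (the scaled
correlation rescales the raw point-biserial value by the best and worst
achievable placements of the same number of boundaries, so 0 is the worst
possible agreement and 1 the best).

The curriculum study, at reduced scale:

```r
cfg <- default_config(2)
cfg$n_runs <- 5L
res <- run_sim2(cfg)
#> test 2AFC accuracy, blocked    : 0.978
#> test 2AFC accuracy, interleaved: 0.72
#> test LC purity,     blocked    : 0.945
#> test LC purity,     interleaved: 0.61
```

Blocked training matches the sticky prior's assumption that contexts persist,
so the model separates the two schemas cleanly and answers the
forced-choice probes far above the interleaved condition — the direction
observed in human learners.

From a shell, the same runners are available as a command-line tool:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","lcnet",package="lcnet"))') \
    run sim2 --seed 0 --n-runs 10 --out results/sim2
```

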