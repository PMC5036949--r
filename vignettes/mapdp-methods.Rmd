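---
title: "MAP inference in Dirichlet process mixtures: models, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAP inference in Dirichlet process mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`mapdp` clusters a data matrix $X = (x_1, \dots, x_N)$ without fixing the
number of clusters. The generative model is a Chinese restaurant process (CRP)
mixture: cluster assignments $z_1,\dots,z_N$ follow a CRP with concentration
("prior count") $N_0$, and each cluster $k$ draws its observations from an
exponential-family likelihood whose parameters carry a conjugate prior
$\theta_0$ and are integrated out (collapsed / Rao-Blackwellized). What
remains after collapsing is the posterior predictive density
$f(x \mid \theta_k)$ of each cluster, available in closed form for every
supported family:

| family (data type)          | prior                   | predictive                |
|-----------------------------|-------------------------|---------------------------|
| spherical Gaussian, known variance | Normal on the centroid | Normal, inflated variance |
| full Gaussian               | Normal-inverse-Wishart  | multivariate Student-t    |
| Bernoulli (yes/no)          | Beta                    | Beta-Bernoulli            |
| binomial (fixed ordinal scale) | Beta                 | Beta-binomial             |
| categorical (nominal)       | Dirichlet               | Dirichlet-multinomial     |
| Poisson (count)             | Gamma                   | negative binomial         |

Mixed-type tables use the *elliptical* (factorized) model: an independent
family per feature, so the joint log predictive is the sum of per-feature
terms. This is what makes clinical-style tables (ratings, yes/no items,
counts, continuous measurements) clusterable in a single model, and it is also
what allows missing entries to be marginalized out exactly.

## The algorithm

Inference maximizes the joint posterior of the assignments. Writing
$d_{i,k} = -\ln f(x_i \mid \theta_k^{-i})$, where $\theta_k^{-i}$ is cluster
$k$'s posterior computed from all of its points *except* $x_i$, the negative
log joint (up to an assignment-independent constant $C(N_0, N)$) is

$$E = \sum_{k=1}^K \sum_{i: z_i = k} d_{i,k} \;-\; K \ln N_0
      \;-\; \sum_{k=1}^K \ln \Gamma(N_k).$$

Starting from a single cluster containing every point, the algorithm sweeps
the data, setting each $z_i$ to
$\arg\min_{k \in 1..K+1} \left[ d_{i,k} - \ln N_k^{-i} \right]$ with
$N_{K+1}^{-i} \equiv N_0$ and $d_{i,K+1} = -\ln f(x_i \mid \theta_0)$: a point
joins the cluster that predicts it best, weighted by a rich-get-richer count
term, or opens a new cluster if the prior predicts it better than any
existing cluster does. Sweeps repeat until $|E_{\text{old}} - E_{\text{new}}|
< \epsilon$. $K$ therefore grows and shrinks during fitting (a cluster whose
last member leaves is dropped and labels are compacted).

Implementation contracts worth knowing:

* **Incremental statistics.** Per-cluster sufficient statistics are updated
  by add/remove of single points; every predictive is recomputed lazily from
  them. Tests pin equality with naive batch recomputation.
* **Objective evaluation.** $E$ is re-evaluated at the end of each sweep from
  the current assignments (not accumulated from in-flight costs), which keeps
  the monotonicity check clean.
* **Convergence test.** $|E_{old} - E_{new}| < \epsilon$ in absolute value:
  for large $N_k$ the $\ln\Gamma$ terms carry round-off that can push $E$ up
  by a hair. Default $\epsilon = 10^{-6}$, with a `max_iterations` guard
  (500) absent from the mathematical description but protecting against
  pathological cycling at round-off scale.
* **First-iteration reinforcement fix.** With everything in one initial
  cluster, the $-\ln N_k^{-i}$ term alone can trap the fit at $K = 1$. On the
  first sweep only, the count term of the initial cluster is overridden to 1
  (its geometry term is untouched). On by default; the package tests include
  a two-blob configuration that stays at $K = 1$ without it.
* **Restarts.** The algorithm is deterministic given a visiting order, so
  restarts permute the order: `restarts = r` runs the natural order plus `r`
  random permutations and returns the lowest final $E$. Ties in the argmin go
  to the lowest cluster index, with the new-cluster option last, so results
  are reproducible bit-for-bit under a fixed seed.
* **Constants.** All log predictives keep their normalizing constants, so $E$
  is comparable across restarts; $C(N_0, N)$ is added back (option
  `include_constant`, used by the hyperparameter search) whenever objectives
  are compared across different $N_0$.
* **Engines.** A compiled engine (RcppArmadillo) runs the two Gaussian
  families at benchmark scale; a generic R engine runs every family,
  including the factorized mixed-type model, and serves as the reference
  implementation. The two are tested for exact agreement on the Gaussian
  families.

## Parameters that matter

* `n0` (concentration, dimensionless): expected cluster count grows as
  $\sum_{i<N} N_0/(N_0+i) \approx N_0 \ln N$. The synthetic benchmarks fix
  `n0 = 3`; `map_n0()` (Gamma-prior MAP), `greedy_restart_search()` and
  `cv_select()` estimate it when prior knowledge is absent.
* `theta0`: by default from `empirical_bayes_theta0()` / `eb_full_gaussian()`
  -- maximum-likelihood moment matching on the pooled data with
  unit-information strength (`kappa0 = 1`; `nu0 = D + 2`, the smallest df
  giving the inverse-Wishart a finite mean, hence heavy but integrable
  Student-t tails; `S0` set so the prior expected covariance equals the
  pooled covariance). For spherical-Gaussian features the known cluster
  variance cannot be identified from pooled moments; the default takes a
  tenth of the pooled variance and should be overridden when the measurement
  variance is actually known.
* `epsilon`, `max_iterations`, `restarts`, `seed`: see above. The benchmark
  protocol uses 10 visiting orders (`restarts = 9`).

## Missing data

Masked entries are latent variables handled inside the fit (elliptical model
only): they are *marginalized out* of all costs and sufficient statistics
during the first assignment sweep, then set to the posterior-predictive mode
of the point's cluster (excluding the point; per-feature modes, with discrete
ties keeping the previous value), and thereafter alternate with assignment
sweeps; convergence is judged on the observed-entries objective, which the
tests check is non-increasing. Initial prior-predictive draws
(`initialize_missing()`) provide concrete placeholder values but deliberately
do not drive the first sweep: letting pooled-scale prior noise into the first
assignment pass measurably corrupts the clustering (the hard MAP alternation
cannot escape the self-consistent local optima it creates), which we observed
directly on three-cluster toys. Missingness is assumed ignorable; the model
cannot detect informative missingness.

A structural caveat: if two cluster means coincide on some coordinate, a
point missing every *other* coordinate is genuinely ambiguous between them,
and hard posterior-mode imputation will lock in whichever cluster wins the
first assignment. The synthetic scenarios avoid exactly-collinear means for
this reason; real data with such symmetry should not be imputed this way.

## Out-of-sample prediction

For a new point, the indicator is either integrated out
(`mixture_predictive()`: weights $N_k/(N_0+N)$ and $N_0/(N_0+N)$ for a fresh
cluster, log-sum-exp stabilized) or point-estimated (`map_predictive()`).
Cluster posteriors use all $N$ training points: the new point is not in the
training set, so no exclusion is needed. Held-out log likelihood (sum of
mixture log densities) is the cross-validation score.

## The synthetic benchmark

Six two-dimensional, three-component Gaussian scenarios with $N = 4000$
emulate the classic K-means failure modes: unequal radii (`s5_1`, radii
1:2:3), unequal density (`s5_2`, 69/29/2%), outliers (`s5_3`, two pairs far
from three equal clusters, each pair its own ground-truth label), rotation
(`s5_4`, equal-volume ellipses, one at 60 degrees), trivial separation
(`s5_5`, 12/28/60%) and significant overlap (`s5_6`, 30/5/65%). Exact means
and covariances are not prescribed by the scenario descriptions, so this
package freezes one concrete instantiation per scenario (see
`mapdp:::scenario_table`), chosen to satisfy the qualitative constraints:
well-separated means where separation is stated, outliers far enough that
K-means prefers spending a centroid on one outlier group over splitting the
merged clusters, and overlap in `s5_6` strong enough that NMI drops
noticeably below 1. Component counts are the rounded stated proportions, not
multinomial draws, so compositions are exact.

What a green benchmark establishes: on *this* instantiation, MAP-DP with
`n0 = 3` and empirical-Bayes priors recovers the generating partitions at the
reported NMI levels and estimates $K = 5$ under outliers, while K-means with
the true $K$ degrades in the stated directions. What it does not establish:
performance under model misspecification (non-Gaussian clusters, correlated
mixed-type features), high dimensionality ($M \gg N$), or the authors' exact
numbers, since their generating parameters are not public. Two deliberate
geometry choices are documented above (outlier distances in `s5_3`;
non-collinear means in `s5_5`).

## Baselines

`kmeans_fit()` is Lloyd's algorithm with K-means++ seeding (emptied clusters
are re-seeded at the farthest point); `gmm_em()` is full-covariance E-M with
a diagonal-jitter guard and an optional fixed spherical covariance, whose
small-variance limit reproduces K-means assignments (tested). `bic_select()`
scores K-means solutions with the spherical classification likelihood
(pooled variance MLE) penalized by $(KD+1)/2 \cdot \ln N$; the BIC variant is
stated explicitly because selected-$K$ values are sensitive to it, and is
checked only directionally (1 blob selects $K=1$, 3 separated blobs $K=3$).

## Known limitations

Hard assignments mean no uncertainty quantification on $z$ or $K$; the
restart mechanism mitigates but cannot eliminate local optima; the
factorized model ignores within-cluster feature correlation; imputation is
modal, so it understates variance in imputed values; and the CRP's
rich-get-richer preference can absorb small true clusters into large ones
when geometry does not separate them.

A practical consequence users should expect: on factorized mixed-type models
the estimated $K$ tends to *overshoot* by a few micro-clusters. A handful of
points that are simultaneously extreme on several features are predicted
poorly by their parent cluster's sharp posterior predictive, and splitting
them off genuinely lowers the joint objective (we verified on synthetic
mixed-type data that such $K{=}4$ solutions beat the generating $K{=}3$
partition's objective — it is the model's preference, not a search failure,
and more restarts do not remove it). Downstream analyses should treat
clusters holding a fraction of a percent of the data as candidate outlier
groups rather than substantive subtypes. When the number of clusters is known
a priori, setting the concentration by solving $E[K^+] = \sum_{i<N}
N_0/(N_0+i) = K_{\text{target}}$ (see `expected_clusters()`) markedly reduces
the overshoot.
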