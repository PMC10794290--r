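---
title: "Methods: empirical Bayes LFDR calling of germline SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical Bayes LFDR calling of germline SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfdrsnv)
```

## The model

`lfdrsnv` treats germline SNV calling in a single sample as a large
collection of simultaneous two-group hypothesis tests, one per genomic
site. At site $i$, $K_i$ reads are split into $R_i$ reference reads,
$M_i$ reads of the *dominant* alternative base (the most frequent
non-reference base), and $X_{1i} \ge X_{2i}$ reads of the two remaining
bases. The dominant alternative allele frequency $\theta_i$ is zero at a
non-mutant site and positive at a mutant one:

$$P(\theta_i = 0) = \pi_0, \qquad \theta_i \mid \theta_i > 0 \sim g(\cdot),$$

with $\pi_0$ the proportion of non-mutant sites and $g$ the (unknown)
allele-frequency density at mutant sites. Each read is miscalled with
probability $e_i$, the error landing uniformly on the three wrong bases,
so the counts are multinomial with category probabilities

$$p_R = \theta_i \tfrac{e_i}{3} + (1-\theta_i)(1-e_i), \quad
  p_M = \theta_i (1-e_i) + (1-\theta_i)\tfrac{e_i}{3}, \quad
  p_{X_1} = p_{X_2} = \tfrac{e_i}{3},$$

which sum to one for every $\theta_i$ and $e_i$. The null likelihood has
the closed form $\binom{K}{R,M,X_1,X_2}(1-e)^R (e/3)^{K-R}$; the
alternative marginalizes the fixed-$\theta$ likelihood over $g$.

The score for every site is its **local false discovery rate** — the
posterior probability of no variant:

$$\psi_i = \frac{\pi_0 P(X_i \mid \theta_i = 0)}
  {\pi_0 P(X_i \mid \theta_i = 0) + (1-\pi_0) P(X_i \mid \theta_i > 0)}.$$

Because $\psi$ is a probability, the calling threshold $\tau$ is directly
interpretable, and varying it traces the precision/sensitivity tradeoff.

## Error rates from qualities

For each base $U$ the count extractor reports mean base-call and mapping
qualities $BQ^U$, $MQ^U$; the package averages them per class,
$Q^U = (BQ^U + MQ^U)/2$, forms the count-weighted site quality
$Q_i = (\sum_U Q^U n_U) / K_i$ (classes with zero count are excluded —
their quality may be missing), and sets $e_i = 10^{-Q_i/10}$. A quality
of 20 thus corresponds to $e = 0.01$. Two numerical guards are applied:
$e$ is clamped to $[10^{-10}, 0.75]$. The lower bound keeps the
minor-allele terms $\log(e/3)$ finite; the upper bound is the point at
which the three wrong bases would jointly be likelier than the right one,
beyond which a read carries no information. `error_rate = 0.01` switches
every site to a single global rate, which costs little accuracy and
removes the per-site quality dependence.

## Estimating $\pi_0$ and $g$

$g$ is estimated *empirically* as an equal-weight atom set
$\{\theta_l\}_{l \in \mathcal I_s}$ of observed allele frequencies
$M_i/K_i$ at suspected-mutant sites; the alternative likelihood becomes
the plain average of the fixed-$\theta$ likelihoods over the atoms. The
difficulty is choosing $\mathcal I_s$: taking *all* sites with $M_i > 0$
floods the set with error-driven artifacts at low frequencies. The caller
therefore iterates:

1. score every site with the current $(\hat\pi_0, \text{atoms})$;
2. take tentative calls $\{i : \psi_i \le \tau\}$;
3. update $\hat\pi_0 \leftarrow 1 - |\text{calls}|/p$;
4. update the atoms to the tentative calls' allele frequencies
   (except in `uniform` mode);
5. stop when consecutive $\hat\pi_0$ differ by less than
   $\varepsilon = 0.001$ (or at `max_iter`, default 100 — a guard far
   above the 2–7 iterations seen in practice).

Three estimation modes are provided. `empirical` initializes the atoms
from all non-zero observed frequencies; `uniform-empirical` initializes
them as $N = 1000$ seeded Uniform(0,1) draws but updates them empirically
from the first pass on — after one update both modes operate on the same
atom set and in our simulations produce identical final call sets;
`uniform` keeps the uniform draws throughout and never updates them. The
initial $\hat\pi_0$ is the fraction of sites with $M_i = 0$ (configurable
via `pi0_init`); it only has to be good enough for the first pass, since
the update is driven by the calls. If a pass produces no tentative calls
the atom set is kept (there is nothing to re-estimate from) and
$\hat\pi_0$ moves to 1, which makes the next pass score every site as
null and the loop converge.

One open choice is whether a site contributing its own allele frequency
to the atom set should be scored against it. We include it by default —
with hundreds of atoms the contribution of any single one is negligible,
and inclusion keeps the pass a pure function of $(\hat\pi_0,
\text{atoms})$. `exclude_self = TRUE` removes the site's own term in log
space for the purists; it changes scores only when the atom set is tiny.

## Decisions and filters

With losses $l_I$ (false call) and $l_{II}$ (missed variant), calling has
posterior expected loss $l_I \psi_i$ and not calling $l_{II}(1-\psi_i)$,
so the risk-minimizing rule calls iff $\psi_i \le l_{II}/(l_I + l_{II})$,
boundary inclusive; `loss_threshold()` implements exactly this. In
practice a direct threshold is supplied instead, and the default is
$\tau = 10^{-20}$ — within the $10^{-100}$–$10^{-20}$ band that gives the
best precision/sensitivity balance on targeted germline panels, strict
enough to exclude error-driven sites by dozens of orders of magnitude yet
loose by the same margin for true heterozygous sites at moderate depth.

Pre-filters drop sites with weighted mean $BQ < 20$ or $MQ < 30$
(defaults aimed at real data; see below for why the simulator tests relax
them). Post-filters retain calls with allele frequency $M/K \ge 0.01$ and
depth $K \ge 10$. They are applied *after* estimation by default, so that
$\hat\pi_0$ refers to the full assayed site set; `filter_first = TRUE`
moves them before estimation, changing what $\hat\pi_0$ refers to.

## Numerical design

Every likelihood is computed in natural-log space and surfaced as
$\log_{10}\psi$. This is not cosmetic: useful thresholds reach
$10^{-300}$ and likelihood ratios at deep coverage exceed
$10^{1000}$, far beyond double-precision linear range. The mixture over
atoms uses log-sum-exp (with duplicate atoms aggregated into weights —
algebraically identical to the multiset mean); the posterior uses
$\log\psi = a - \mathrm{logsumexp}(a, b)$, exact at $\pi_0 \in \{0, 1\}$.
Conventions: $0\log 0 \equiv 0$ for zero-count classes, so atoms at
$\theta = 1$ with $e = 0$ simply contribute nothing for sites with
$R > 0$; a site where both likelihoods underflow to $-\infty$ gets an
`NA` score rather than a silent number; dominant-allele count ties are
broken by higher class quality, then alphabetically; `L10LFDR` is the
authoritative VCF score, with `LFDR` clamped to the 32-bit float range
(rendered 0 below $10^{-38}$).

## The prioritizer

`prioritize()` re-scores a variant list from *any* external caller in a
single pass, with the caller itself supplying the estimates: $\hat\pi_0$
is the fraction of assayed sites the caller did not call, and the atoms
are the empirical allele frequencies at its called sites. The external
ALT allele is trusted ($M$ is that allele's read count, even when another
base dominates — the disagreement is reported), and calls are ranked by
ascending $\log_{10}\psi$. Thresholding the ranking can only remove
calls, so sensitivity against any truth set can never increase, while
error-driven false positives — which score $\psi$ near 1 — are removed
wholesale, raising precision sharply.

## What the simulator does and does not emulate

`simulate_readcounts()` draws from the generative model itself: sites are
non-mutant with probability $\pi_0$; mutant allele frequencies come from
a bimodal mixture with equal weight on a heterozygous component (Beta
matched to mean 0.5, sd 0.035) and a near-homozygous component (Beta
matched to mean 0.99, sd 0.007) — germline allele frequencies concentrate
around 0.5 and 1, and the specific shapes and spreads are this package's
choice, made once and configurable; counts are multinomial at the chosen
depth and error rate (realized by sequential binomials, which is
distributionally identical). Qualities are emitted as
$BQ = MQ = -10\log_{10} e$ uniformly across classes so that the error
model recovers the simulated rate exactly. A consequence: at $e = 0.01$
the emitted qualities are 20, below the default real-data mapping-quality
filter of 30, so simulation-driven examples and tests call
`lfdr_call(..., min_bq = 0, min_mq = 0)` — on synthetic data the
qualities encode the error rate and are not artifact indicators.

The simulator does **not** emulate mapping artifacts, strand bias,
quality miscalibration, correlated errors within reads, copy-number or
contamination effects on allele frequency, or indels. Passing tests on
simulated data therefore demonstrate correctness of the estimation
machinery under the model's own assumptions, not robustness to the full
artifact spectrum of real sequencing — on real data the quality filters
and post-filters carry that weight, and genuinely model-violating sites
will still mis-score.

## Problem sizes and verification

The test suite verifies the likelihoods against a naive linear-domain
oracle over all count compositions up to depth 15, checks the decision
rule against exhaustive enumeration of all $2^p$ decision vectors up to
$p = 12$, and exercises parameter recovery end to end on simulations of
20{,}000 sites at depth 100, $\pi_0 = 0.95$, $e = 0.01$ — where the
caller recovers $\pi_0$ to within 0.01, converges in a handful of
iterations, and the empirical and uniform-empirical modes return
identical call sets. `scripts/acceptance.R` re-runs these study-scale
computations from scratch at a caller-supplied seed. Smaller sizes
(hundreds to a few thousand sites) are used where only mechanics, not
rates, are under test.

## Known limitations

Single-sample, SNV-only: no indels, no multi-sample joint calling, no
tumor/normal pairing, no replicate conflict resolution. $\hat\pi_0$ is
tied to the assayed region: on a panel where most sites are non-mutant it
is well-conditioned, but on a site set pre-enriched for variants it
shrinks accordingly (the prioritizer exploits exactly this). The
empirical $g$ cannot extrapolate below the smallest observed allele
frequency, so very-low-frequency variants compete with the error model on
the error model's terms.
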