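---
title: "Modelling TF motif-family evolution with a birth-death-cis-innovation process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TF motif-family evolution with a birth-death-cis-innovation process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdifam)
```

## Motif families

Transcription factors (TFs) bind DNA through their DNA-binding domain
(DBD), and related TFs — paralogs produced by gene duplication — often
retain overlapping sequence preferences. Annotation resources in the
CIS-BP style associate each TF with a set of position weight matrices
(PWMs), some measured directly and some transferred by DBD homology.
`bdifam` represents these associations as a bipartite network (TF nodes,
PWM-identifier nodes) and projects it onto the TFs: two TFs are linked
when they share at least one PWM identifier. The connected components of
that projection are the *motif families*. Components rather than cliques
are used because sharing is not transitive at the edge level, yet a chain
of shared identifiers still traces common descent; in practice most
components are cliques. Size-1 components count as families — a
repertoire's many isolated TFs are exactly the part of the distribution
the model must explain, and the reference totals (for the human
repertoire, 906 TFs in 424 families with mean size ≈ 2.14) are only
jointly consistent when singletons are counted.

Two conventions are worth stating. TFs with no PWM at all (the `"."`
token in annotation tables) are retained by the reader but excluded from
family analysis by default, since they cannot be placed in the network;
the reader reports both counts so either convention is reproducible.
Projection uses *identity of motif IDs*, never matrix similarity:
merging PWMs measured by heterogeneous methods into consensus matrices
is deliberately avoided.

## The stochastic model

Each TF is an element of a family; families evolve by four Markov
processes with time-constant rates:

* **birth** λ per element — duplication, family moves up one size class;
* **death** δ per element — loss, family moves down one class
  (empty families disappear);
* **cis-innovation** μ per element — a mutation changes one TF's binding
  preference so it founds a new size-1 family; the source family moves
  down one class, and the total element count N is conserved;
* **de-novo innovation** ν globally — an entirely new family of size 1.

The master equation for the class counts $f_i(t)$ (families of size
$i$, truncation $M$) is

$$\frac{df_1}{dt} = -(\lambda+\delta+\mu)f_1 + 2(\delta+\mu)f_2 + \mu N + \nu,$$
$$\frac{df_i}{dt} = (i{-}1)\lambda f_{i-1} - i(\lambda+\delta+\mu)f_i + (i{+}1)(\delta+\mu)f_{i+1},$$
$$\frac{df_M}{dt} = (M{-}1)\lambda f_{M-1} - M(\delta+\mu)f_M.$$

Substituting $\delta' = \delta + \mu$ and $\nu' = \nu + \mu N$ maps this
onto the classical birth–death–innovation system, whose stationary state
is $f_i = (\nu'/\lambda)\,\theta^i/i$ with
$\theta = \lambda/(\delta+\mu)$. `bdi_stationary_counts()` evaluates this
solution and `bdi_master_rhs()` the right-hand side; plugging one into
the other yields residuals at machine precision, which the test suite
asserts below $10^{-8}$ for $M = 500$.

Constancy of the mean element count requires $N(\delta-\lambda)=\nu$.
`check_balance()` reports violations as warnings rather than errors, so
off-balance regimes remain explorable. In the regime the analysis
targets, de-novo innovation is negligible ($\nu \to 0$, hence
$\lambda = \delta$) and the spectrum collapses to the one-parameter law

$$f_i = N(1-\theta)\,\frac{\theta^{i-1}}{i}, \qquad
  p_i = \frac{1}{-\ln(1-\theta)}\frac{\theta^i}{i},$$

the logarithmic series. The families-per-element ratio follows as
$F/N = \frac{1-\theta}{\theta}\sum_{i\le M}\theta^i/i \simeq
\frac{\theta-1}{\theta}\ln(1-\theta)$.

One contract subtlety: a de-novo event must add an element (class 1
gains a family of size one), otherwise $N = \sum_i i f_i$ cannot hold;
the simulator therefore increments N on de-novo events, consistent with
the $+\nu$ inflow in the master equation. With the default ν = 0 this
never arises.

## Estimation

Because the log-likelihood of the untruncated law depends on the data
only through $(F, N)$, the mean size $\bar k = N/F$ is sufficient and
the MLE is closed-form via the lower real Lambert branch:

```{r}
theta_mle(906 / 424)
```

The Lambert argument $-(1/\bar k)e^{-1/\bar k}$ lies in $(-1/e, 0)$ for
every $\bar k > 1$, so the branch is always real; samples with
$\bar k \le 1$ (all singletons) have no interior MLE and are rejected
with an explicit error. With a finite truncation $M$ the same moment
condition is solved by `uniroot` on the partial sums; for the repertoire
scales analysed here the two modes agree to better than $10^{-3}$
(asserted in the tests), because the neglected tail mass
$\sum_{i>M}\theta^i/i$ is astronomically small at $\theta \approx 0.74$,
$M \gtrsim 400$.

At 400 families the sampling standard deviation of the estimator ranges
from ≈ 0.029 at θ = 0.3 to ≈ 0.009 at θ = 0.9 (delta method on the
sufficient statistic); since the estimator is the exact MLE of a
one-parameter exponential-family reduction, this is the efficiency
floor, and the recovery tests are calibrated against it.

### Goodness of fit

The Kolmogorov–Smirnov distance is taken over the full discrete support
up to the largest observed size. Its null distribution under a *fitted*
law is obtained by parametric bootstrap in the Clauset style: each of
`n_boot` replicates draws the same number of families from the fitted
law, is refit, and contributes the KS distance to its own best fit.
Replicate draws use a finite support capped at the sample's element
total — the largest size any family could reach. The p-value is the
fraction of replicate distances **greater than or equal to** the
empirical one; counting ties is the conservative choice for a discrete
statistic. All-singleton replicates (possible at small F, low θ) are
redrawn and counted, with a hard cap to guarantee termination. Under
the null this p-value is uniform, which the acceptance suite verifies
with 500 trials of 200 replicates each.

### The trim scan

The scan grids a size-exclusion threshold $T$ (families of size $\ge T$
removed — the convention under which removing the three largest human
families corresponds to $T = 25$) against a count $N_s$ of removed
size-1 families. Singletons are exchangeable, so removal decrements
$f_1$ without any identity choice. Each cell refits and bootstraps
independently with a derived sub-seed; the selected $T^*$ is the largest
grid value whose column reaches the acceptance level (default
$p \ge 0.75$) at some $N_s$. One caveat is intrinsic to the design:
once the planted (or real) deviations are removed, the remaining core is
a *bona fide* draw from the law and its p-value is uniform, so whether a
given clean cell clears a 0.75 bar is partly chance. The scan is
therefore best read as a descriptive heatmap; the analysis driver falls
back to the highest-p cell when no cell clears the bar.

## Simulation

`bdi_simulate()` is an exact continuous-time (Gillespie) event
simulator — event counts per trajectory are modest at repertoire scale,
so exactness is cheap; the event loop is compiled (Rcpp) and draws from
R's RNG, so trajectories are reproducible from `set.seed()`. A
cis-innovation on a size-1 family is counted but is structurally a
relabel (F unchanged); this per-event bookkeeping is asserted in the
tests, as is the accounting identity
`N_final = N_init + births − deaths + denovo`.

The F/N envelope re-creates the per-DBD comparison: many replicates in
the balanced regime ($\lambda=\delta$, a critical random walk in N),
each started from a **single ancestral family** (a DBD class founded by
one ancestor; an all-singleton start is available by flag), run to a
relaxation horizon of $20/\mu$ time units or 200 events per initial
element, whichever is first — F/N decorrelates on the cis-innovation
timescale $1/\mu$, so this is deep in the stationary regime under the
default rates. Extinct replicates (inevitable with $\lambda=\delta$,
ν = 0) have no defined F/N; they are excluded and counted. Surviving
replicates are binned by final N on a log grid into mean ± sd bands;
DBD classes are placed by interpolating the bands at the class size and
classified as within 1 sd, within 3 sd, or outliers beyond 3 sd
(classes of size 1 are flagged uninformative). Because expectations of
the linear master equation are exact, the pooled simulated spectrum is
an unbiased realization of the analytic law — the acceptance suite
checks this by chi-square on an ensemble of 150 trajectories and checks
the ensemble F/N ratio (element-weighted, over replicates with final
N ≥ 200, where finite-size corrections are below one percent) against
the closed form within three standard errors.

## PWM similarity and the robustness sweep

The family construction leans on homology-based PWM transfer, so
`augment_by_similarity()` tests its robustness: add TF–TF links wherever
two PWMs are similar enough, and watch whether they merely thicken
existing families or bridge distinct ones. Similarity is the Jaccard
index of *threshold word sets*: all words of the overlap length are
enumerated exhaustively (capped at length 12), scored by summed log
probabilities with a $10^{-3}$ pseudocount on zeros, and kept when the
score reaches `word_threshold` of the way from the window's minimum to
its maximum attainable score — the `min.score` convention of
`Biostrings::matchPWM`, adopted because a threshold expressed as a pure
fraction of the (negative) maximum score would be unsatisfiable.
Unequal lengths are handled by sliding the shorter matrix along the
longer and maximizing over offsets, and over the reverse complement by
default, since strand and register are not identifiable from the data
model. Both conventions are deliberate package choices where the
upstream definition is underdetermined; the parameters stay exposed.

## The synthetic-data generator

`generate_dataset()` emulates the structure the analysis assumes:
background family sizes drawn from the stationary law at a chosen θ
(default 0.74 over 424 families — the human-regime point estimate),
optional planted spikes (default 41/34/25, the sizes of the three
over-expanded reference families), an optional singleton excess
(default 50, the centre of the 40–80 range the reference analysis
attributes to duplication-averse singleton genes), DBD-class labels
with optional per-class θ overrides (a low-θ class emulates the
fast-diversifying zinc-finger phenomenology), and one unique pool of
sharpened random PWMs (lengths 6–10, one dominant base per position)
shared by all members of each family. Family-unique pools make every
planted family a clique and the planted partition exactly recoverable,
which the tests exploit; ground truth is always emitted so tests never
reverse-engineer it.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: partially overlapping PWM pools between
families, heterogeneous PWM provenance and quality, within-family PWM
similarity structure, and any correlation between DBD class and family
size beyond the explicit θ overrides. Conclusions about real
repertoires must come from running the pipeline on a real extract.

## Numerical choices and problem sizes

* Sampling is inverse-CDF on a precomputed finite-support table
  (default cap $10^4$, or the sample's element total in bootstraps) —
  no rejection, exactly reproducible across platforms.
* `log1p(-theta)` is used throughout for $\ln(1-\theta)$; cumulative
  tables are clamped to 1 to keep `findInterval` monotone.
* Degenerate inputs fail loudly: θ outside (0,1), $\bar k \le 1$,
  means unattainable under a finite truncation, PWM rows off by more
  than the read tolerance ($10^{-3}$, then renormalized exactly).
* Bootstrap ties count toward the p-value; trim-scan cells with
  infeasible $N_s$ are marked invalid rather than silently skipped.
* The shipped analysis uses deliberately moderate problem sizes —
  ensembles of 150–2000 trajectories, 200–1000 bootstrap replicates,
  500-class master-equation checks — chosen so the whole workflow and
  test suite run on a laptop-class single core in minutes while keeping
  every statistical check well-powered at its stated level.

## Limitations

The model assumes time-constant rates, no selection, and no rate
heterogeneity across families; bursty (punctuated) dynamics are outside
its scope, which is precisely why over-expanded families and
singleton-gene excesses appear as deviations rather than fitted
features. The θ-versus-repertoire-size scaling fit is an empirical
description over the observed range only — θ is bounded above by 1, so
the power law cannot extrapolate. The exact word-set convention behind
the PWM Jaccard index is a package choice among several reasonable
ones; results of the robustness sweep should be read qualitatively.
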