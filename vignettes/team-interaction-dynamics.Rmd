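---
title: "Methods: recurrence, topics and marginal models for small-group interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrence, topics and marginal models for small-group interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teamdyn)
```

This vignette is the package's account of its own methods: the models
it fits, the assumptions they make, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the
numerical choices taken where the design was genuinely open.

## The analysis in one paragraph

A group session is observed as a log of coded interaction events
("member 2 addresses member 4", "member 1 addresses the whole team").
Ordered in time, these events form a categorical symbol sequence whose
self-similarity structure — the recurrence plot — is summarised by
three measures: recurrence rate (stability), percent determinism
(predictability) and diagonal-line entropy (complexity). In parallel,
the session transcript is reduced to stems and fitted with a latent
Dirichlet allocation topic model, with the number of topics selected
by held-out perplexity. Finally, each participant's questionnaire
subscale score (quality of participation; social support) is regressed
on their group's three recurrence measures with generalized estimating
equations, which respect the group clustering without modelling it
parametrically.

## Categorical recurrence quantification

For a sequence of symbols $s_1,\dots,s_N$, the recurrence plot is
$R_{ij} = \mathbf{1}[s_i = s_j]$. For categorical data the similarity
threshold of continuous-signal recurrence analysis degenerates to
exact equality — there is no embedding dimension, delay or radius to
tune.

**Line of identity.** Every state trivially matches itself, so the
main diagonal is excluded from all three measures (Theiler window 1,
configurable upward). This is required for the recurrence rate to
attain its documented 0–100 range: a sequence of all-distinct symbols
then scores exactly 0, a constant sequence exactly 100.

**Recurrence rate** is $100 \sum_{|i-j|\ge 1} R_{ij} / (N^2 - N)$;
symmetric cells are counted on both sides in numerator and denominator
alike, so the ratio is unaffected by the convention.

**Line histogram.** Determinism and entropy are computed from the
histogram of *maximal* diagonal runs on the upper triangle only — by
symmetry the lower triangle duplicates every line and cannot change
either measure. A length-$l$ run contributes one count at $l$, never
nested sub-runs. A run ends at a non-recurrent cell or the matrix
edge.

**Determinism** divides the recurrent points on lines of length
$\ge l_{\min}$ by all recurrent points (lengths $\ge 1$). The default
$l_{\min} = 2$ is the conventional minimum for coded group
interaction: a single isolated recurrence carries no predictability
information. **Entropy** is the Shannon entropy of the line-length
distribution restricted to $l \ge l_{\min}$, in bits by default (the
base is configurable; the literature rarely states its units).

**Degenerate inputs are errors, not numbers.** Determinism is
undefined when a plot has no off-diagonal recurrence at all, and
entropy when no line reaches $l_{\min}$; both raise explicit errors
rather than returning 0 or NaN, because a silent 0 would be
indistinguishable from a genuinely random-but-recurrent sequence.

## Sequence encoding

Dyads are **unordered** by default: events (1→2) and (2→1) both encode
as `1-2`. The coding scheme this mirrors records which pair interacts,
not direction; a directed mode (`a>b` symbols) is available for coding
schemes that preserve direction. A member addressing the whole team is
its own symbol `a-T`. The alphabet is always the *full* set of
$\binom{m}{2}$ dyads plus $m$ member-team symbols for an $m$-member
group, so same-sized groups are measured on the same state space
regardless of which dyads happened to occur. Events are ordered by
timestamp with stable ties — simultaneous events keep file order, with
no reordering heuristics. The 12 behavioural categories carried by the
event log (Bales' Interaction Process Analysis scheme) are ingested
and retained for frequency export but do not enter the recurrence
alphabet: the recurrence analysis here is over who-interacts-with-whom,
and crossing dyads with 12 categories would inflate the alphabet
beyond what sessions of a few hundred events can populate.

Coder agreement uses ICC(2,1) — two-way random effects, single
measures, absolute agreement — computed from the two-way ANOVA mean
squares. The single-measures form is the conservative choice when the
published analysis names only the model family.

## Transcript preprocessing and topic model

Tokens are maximal runs of alphabetic characters after lowercasing
(digits and punctuation are never tokens). Stop words are removed
first, then tokens shorter than 3 or longer than 14 characters, and
the survivors are Porter-stemmed (the original 1980 algorithm, steps
1a–5b, implemented in full). The stop-word list is shipped with the
package and overridable by file: reproducibility requires knowing the
exact list, not "a standard list". Note that stemming is not
idempotent in general (`responsibilities → respons`, and a second pass
gives `respon`); downstream code therefore never re-stems stemmed
output.

The topic model is fitted by collapsed Gibbs sampling with the
conditional $p(z_i = t) \propto \frac{n_{wt} + \beta}{n_t + V\beta}
(n_{dt} + \alpha)$. Defaults: symmetric $\alpha = 50/T$, $\beta =
0.01$ (the classical toolbox defaults), 1000 sweeps with 500 warm-up,
single seeded chain. $\Phi$ and $\Theta$ are estimated from the final
counts with the same smoothing; a per-sweep training log-likelihood
trace is kept so convergence can be inspected.

**Held-out perplexity and why it uses document completion.** The
number of topics is chosen by fitting each candidate $T$ on a seeded
90% document partition and scoring perplexity
$\exp(-\sum \log p(w|d)/N)$ on the held-out 10%. Held-out
document-topic weights must be estimated somehow; the naive choice —
fold-in Gibbs on the held-out document, then scoring the same tokens —
makes perplexity improve essentially monotonically with $T$, because a
larger $T$ gives every document more free parameters that are fitted
to the very tokens being scored. In our synthetic checks that
estimator selected the largest candidate in every seed even when the
true $T$ was known and small. The package therefore scores by
**document completion**: each held-out document is split into
alternating halves, $\hat\theta$ is estimated by fold-in (50 sweeps,
$\Phi$ frozen, averaged over 3 chains) on one half, and perplexity is
computed on the other. With completion the selection lands on the
planted topic count (or its grid neighbour) in the recovery
simulations. Plain fold-in remains available
(`perplexity(..., method = "fold-in")`). Ties in the curve resolve to
the smallest candidate.

Model-selection simulations fit candidates with the generating
hyperparameters ($\alpha = 0.1$, $\beta = 0.01$) rather than $50/T$:
with $\alpha = 10$ per document at $T = 5$, the heavy $\Theta$
smoothing is itself a gross misspecification of a corpus generated at
$\alpha = 0.1$ and masks the selection signal entirely.

## Marginal models

The association stage fits, per outcome, a Gaussian identity-link GEE
with exchangeable working correlation: participants are exchangeable
members of their group, and the outcome is individual-level (their own
subscale mean) while the predictors are group-level recurrence
measures — the clustering is exactly why GEE is used. Estimation
alternates generalized least squares for $\beta$ with a moment update
of the common within-cluster correlation $\hat\rho$ from Pearson
residuals, to convergence ($\max|\Delta\beta| < 10^{-8}$, at most 100
iterations); $\hat\rho$ is clamped with a warning into
$(-1/(n_{\max}-1), 1)$. Standard errors come from the robust sandwich
covariance, Wald statistics are $(B/SE)^2$ on 1 df, and 95% intervals
use the normal quantile 1.96 — matching the symmetric intervals of the
published table layout this reproduces. With independence working
correlation (or singleton clusters) the estimator reduces exactly to
ordinary least squares with HC0 sandwich errors, which the tests
exploit as a closed-form oracle. QIC follows Pan's definition,
$-2\,QL_{indep} + 2\,\mathrm{tr}(\hat\Omega_I \hat V_R)$; SPSS's
variant differs in small details and is not chased. Predictor variance
inflation factors are reported and flagged above 10.

Scale scores are plain means (items per participant, participants per
group); internal consistency is Cronbach's alpha from the standard
variance decomposition with $n-1$ denominators.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; real study data of this kind are typically not shareable,
so every stage is tested by recovery from data with known truth.

**Interaction sequences** follow a first-order Markov mixture: with
probability `stability` repeat the previous symbol, with probability
`determinism_strength` follow a fixed cyclic successor map in alphabet
order, otherwise draw uniformly from the alphabet. The two weights map
directly onto the recurrence-rate and determinism constructs, which
makes recovery tests interpretable. The generator conditions on all
three recurrence measures being defined: a group whose (rare, short)
sequence yields no diagonal line of length 2 has its sequence seed
redrawn deterministically.

**Study design defaults** emulate the target design: 28 groups of 3–5
members; sequence lengths Normal(157, 67) floored at 10 (the floor
keeps recurrence defined); per-group mixture weights drawn uniformly
from stability ∈ (0.05, 0.30) and determinism ∈ (0.10, 0.40). Those
ranges were calibrated once so that the default study's group-mean
recurrence rate and determinism land near the published descriptive
means (≈11.5% and ≈35.7%) — the published coding base rates are
unknown, so this is a convenience anchor, not a claim — and were not
revisited afterwards. The per-group variation in the weights is
essential: with constant weights the three recurrence predictors would
be near-constant across groups and the association design singular.

**Questionnaires.** The latent social-support score is
$\beta_0 + \beta_{rr}\,RR + \beta_{det}\,DET + u_{group} + e_{individual}$,
with defaults $\beta_{rr} = 0.022$ and $\beta_{det} = -0.008$ (the
published point estimates) and $\beta_0 = 4.8$ placing the mean near
4.78; participation has latent mean 5.68 and no recurrence effect.
Each of the 5 items per subscale adds its own noise before rounding
and clamping to 1–7. Rounding-plus-clamping was chosen over latent
cutpoints as the simplest mechanism producing bounded ordinal data;
with the default means far from the scale ends, clamping is rare and
slope attenuation negligible. Noise defaults (group 0.4, individual
0.5, item 0.6) put Cronbach's alpha near 0.8, in the vicinity of the
published reliabilities. Because the latent model uses the *measured*
recurrence values of each group's generated sequence, regression
recovery is exact in expectation rather than attenuated by
measurement error.

**Corpora** follow the standard LDA generative process (topic-word
rows from Dirichlet($\beta$), document mixtures from
Dirichlet($\alpha$), lengths Poisson, floored at one token). The
vocabulary is pronounceable pseudo-words of 4–8 alphabetic characters,
so synthetic transcripts survive the real preprocessing path; the
generator makes no attempt at realistic dialogue, speaker structure,
or behavioural-category semantics.

**What passing therefore shows — and does not.** Recovery under this
generator demonstrates that the estimators are correct for data whose
generative structure they assume (Markovian symbol dynamics, bag-of-
words topics, linear group-level effects with Gaussian noise). Real
coded interactions have non-stationary dynamics, real transcripts have
syntax and speaker turns, and real Likert data have response styles;
none of that is emulated, so passing tests validate the computation,
not the substantive theory.

## Problem sizes and reproducibility

All randomness is seeded; identical configuration and seed give
byte-identical pipeline outputs, and the run manifest records the
configuration hash and per-artifact checksums. The test suite uses:
200 random sequences (alphabet 2–8, length ≤ 60) for the brute-force
recurrence oracle; corpora of $T = 5$, $V = 200$, $D = 200$, mean
length 100 for topic recovery (3 seeds) and selection (5 seeds, grid
2/5/10/20, 800 sweeps); and 50 replicates of 100-group studies for
regression recovery (planted slope 0.02, mean recovery within ±25%,
interval coverage within [0.90, 0.99]). The analysis scripts run the
default 28-group study with a 5–30 topic grid at 400 sweeps.

## Known limitations

- Continuous-signal recurrence analysis (embedding, radius), cross-
  recurrence, and laminarity/trapping-time measures are out of scope.
- The Gibbs sampler runs a single chain; label switching across
  restarts is handled in evaluation (greedy matching) but no
  multi-chain convergence diagnostic is computed.
- GEE small-sample corrections beyond the sandwich (e.g. bias-reduced
  variance estimators) are not implemented; with few clusters the
  robust errors are known to be anticonservative.
- Perplexity-based selection is high-variance on very small document
  collections (a 10% split of 28 transcripts holds out 3 documents);
  the default analysis reports the full curve so flat regions are
  visible rather than hidden behind a single argmin.
- The published complexity statistic for this design is reported on a
  scale inconsistent with Shannon line-length entropy in bits or nats;
  the package computes entropy in bits and does not attempt to match
  that scale.
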