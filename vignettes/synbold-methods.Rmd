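---
title: "Methods: incremental syntactic complexity and BOLD encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental syntactic complexity and BOLD encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synbold)
```

This vignette records the exact conventions `synbold` uses at every stage:
how tree nodes are counted, how counts become scan-resolution regressors,
how the mixed models are parameterized, and how the synthetic generator is
built. Wherever a convention involves a judgment call, the rationale is
stated here.

## 1. Node-count metrics

All metrics operate on a constituent parse with half-open, 0-based terminal
spans: a node covering words *i* … *j* has span `[i, j+1)`. For each word,
a metric counts the tree nodes *attributed* to that word under a parsing
strategy:

- **Top-down** — a node is counted at the first terminal of its span (the
  word at which the phrase is opened).
- **Bottom-up** — at the last terminal of its span (the word at which all
  daughters have been met and the phrase closes).
- **Left-corner** — at the last terminal of its *first daughter's* span:
  the node is announced once its leftmost daughter is complete. For a node
  whose first daughter is a terminal or preterminal this is the first word
  itself, so left-corner coincides with top-down there.
- **Open nodes** — `open(w) = cumsum(TD)(w) − cumsum(BU)(w)`, i.e. nodes
  opened up to and including *w* that have not yet closed. By default
  closures at *w* are subtracted first (`timing = "after"`), so a complete
  sentence ends at 0; `timing = "before"` gives the load as the word is
  presented.
- **Early top-down** (production) — each word's top-down nodes are shifted
  one word earlier: word *w* carries `TD(w+1)`, the final word carries 0,
  and the first word carries `TD(1) + TD(2)` so that no mass is attributed
  to an unobserved pre-sentence event. A one-word sentence equals its
  top-down vector.
- **Chunked / head-driven** (production) — dependency heads (tokens with at
  least one dependent) partition the sentence into chunks; all constituent
  nodes of the chunk from the sentence start through the first head are
  attributed to word 0, the nodes of each subsequent chunk (after head *k*
  through head *k+1*) to head *k*, and nodes past the last head fold into
  the last head's chunk. Non-initial non-head words — sentence-final words
  in particular — carry 0.

Every strategy redistributes the same total: per sentence, each vector sums
to the number of countable nodes. The test suite verifies this conservation
and checks the three comprehension strategies against a brute-force span
oracle (`span_oracle()`) that attributes one node at a time by direct span
inspection.

### Preterminal convention

`count_preterminals = FALSE` (the default) excludes part-of-speech-level
nodes, but only when the tree actually has a POS layer: if **every**
terminal is wrapped in a unary preterminal (standard treebank output),
those wrappers are dropped (the root is always kept). Bracketings that
attach words directly to phrasal nodes — common for spontaneous-speech
transcripts — have no POS layer, so every nonterminal counts, including
phrases that happen to dominate a single word:

```{r}
t1 <- parse_bracketed("(S (NP Mary) (VP (VP eats (NP apples)) (ADVP daily)))")
nrow(countable_nodes(t1))                      # no POS layer: all 6 count
pos <- parse_bracketed(
  "(S (NP (NNP Mary)) (VP (VP (VBZ eats) (NP (NNS apples))) (ADVP (RB daily))))")
nrow(countable_nodes(pos))                     # POS layer dropped: 6 of 10
nrow(countable_nodes(pos, count_preterminals = TRUE))
```

This is the only rule consistent with treating `(NP Mary)` as a phrase in
flat speech bracketings while still matching treebank conventions on
POS-layered trees. A degenerate single-preterminal tree like `(X a)` keeps
its root.

### The worked sentence

```{r}
dep <- list(form = c("Mary", "eats", "apples", "daily"),
            head = c(2L, 0L, 2L, 2L), relation = c("nsubj", "root", "obj", "advmod"))
node_count_table(list(t1), list(dep))
```

Top-down counts the outer VP (which dominates *daily*) already at *eats*;
bottom-up defers three closures to the final word; open nodes peaks at
*eats* and returns to 0.

## 2. Corpus input and sentence segmentation

Readers are provided for bracketed trees (one per balanced-bracket record),
CoNLL-U dependencies (token id, form, head, relation; multi-word ranges and
comments skipped; exactly one root enforced), word timings (TSV with
`word`, `onset`, `offset` in seconds), and long-format ROI BOLD tables
(`participant`, `roi`, `tr_index`, `value`; duplicate and gapped indices
rejected).

Spontaneous speech has no punctuation, so sentences are delimited by
disfluency: `segment_sentences()` starts a new sentence whenever the silent
gap before a word (its onset minus the previous offset) reaches
`pause_threshold`, 1.0 s by default. One second sits well above the
within-sentence planning pauses the pause model targets (median well under
200 ms) and below typical between-utterance gaps of recall speech; it is a
study condition, not a fitted quantity.

## 3. From word predictors to design matrices

`build_predictor_table()` joins the timing table, the node-count metrics,
and lexical covariates (syllable count via a vowel-group heuristic with
silent-e correction and a user lexicon override; log word frequency;
surprisal = −log conditional probability), plus sentence onset/offset
indicator columns. Continuous predictors are mean-centered; the constant
word-rate regressor and indicator columns are not.

Each word contributes an impulse at its onset, scaled by the predictor
value; impulses are convolved with the canonical double-gamma HRF

\[ h(t) \propto \mathrm{dgamma}(t; 6, 1) - \tfrac{1}{6}\,\mathrm{dgamma}(t; 16, 1), \]

unit-peak normalized, on a 0.05 s grid over a 32 s kernel, and sampled at
scan times `k · TR` (TR = 1.5 s). The implementation is checked against
the closed form, the peak location (5.0 s, within the canonical 4.5–6.5 s
window), exact superposition, and TR-shift consistency. An optional
temporal-derivative regressor (finite difference of the kernel,
orthogonalized against its parent) absorbs small latency shifts.

Because the HRF integrates over ~5 s of speech (≈ 10 words), convolved
parser regressors correlate far more strongly than the raw word-level
counts do — `collinearity_report()` quantifies this. That collinearity is
why timing models are compared by AIC on separate fits rather than entered
jointly.

## 4. Encoding models

The scan-level model for ROI value \(y\) stacks participants and ROIs in
long format:

\[ y = X\beta + Z b + \varepsilon,\qquad
   b_{pj} \sim N(0, \sigma_j^2)\ \text{independent across predictors } j, \]

with by-participant **uncorrelated** random slopes (`(0 + x | participant)`
terms) on the focal syntactic predictors. Uncorrelated slopes keep the
number of variance parameters linear in the number of predictors, which is
what makes the repeated refits of the model-comparison analyses tractable;
a random intercept is optional and off by default because all predictors
are centered. If a fit is singular or fails to converge, the weakest
non-focal slope is dropped (at most twice); focal slopes are never dropped.

- **Estimation.** ML when models are compared (AIC = 2k − 2·logLik and
  likelihood-ratio tests require it); REML when the goal is estimation and
  standard errors, since ML's downward-biased variance components make SEs
  slightly anticonservative.
- **Inference.** Per-term Wald χ² tests are computed in-package from the
  coefficient vector and its covariance (columns grouped by model term);
  they are cross-checked in the test suite against `car::Anova(type = 3)`.
  Per-cell slopes and Tukey-adjusted pairwise contrasts over coded factor
  grids (`pairwise_contrasts()`) are cross-checked against
  `emmeans::emtrends()` with asymptotic degrees of freedom.
- **Coding.** `code_factors()` provides ±½ deviation coding for modality
  (production vs comprehension) and Helmert coding for the three ROIs
  (LIFG pair vs LpMTG: ½, ½, −1; BA44 vs BA45: 1, −1, 0), so main effects
  are averaged contrasts and interactions are interpretable differences.

## 5. Behavioral models

`build_behavioral_table()` derives, per word, the silent pause before it
(onset − previous offset within recall; `NA` for a recall's first word;
negative gaps clamped to 0 with a message) and its articulated duration.
`fit_pause_model()` regresses `log(pause + 1 ms)` on number of syllables,
log frequency, surprisal, top-down, bottom-up and open-nodes counts with
by-participant random slopes; `fit_duration_model()` is identical in design
with duration as the response. The log transform tames the heavy right
skew of pause durations.

The pause model additionally includes a sentence-onset indicator: under
disfluency-based segmentation, every boundary pause is ≥ the segmentation
threshold *by construction*, so boundary pauses live on a different scale
from within-sentence planning pauses. The indicator absorbs that scale
shift; without it, the complexity-metric slopes would partly proxy for
boundary status.

## 6. Synthetic generator

The generator exists to give the pipeline a ground truth; its defaults are
fixed study conditions.

- **Corpus.** A small PCFG over S/NP/VP/PP with lexical categories
  expanding directly to words (no POS layer, like speech bracketings).
  Rule probabilities give a mean sentence length of ≈ 9.1 words, the scale
  of disfluency-segmented recall sentences; derivations longer than 40
  words are resampled. Each rule names a head child, from which dependency
  structure is percolated (verbs head their clauses), giving aligned
  constituent and dependency parses.
- **Timings.** Word durations scale with syllable count (× 0.22 s,
  lognormal noise). The pause before a word is log-linear in its top-down
  count with slope γ = 0.1. Within-sentence pauses are capped at 0.8 × the
  segmentation threshold; inter-sentence pauses get a different baseline,
  the same γ slope, half-normal excess noise, and a floor just above the
  threshold. The cap and floor make pause-based segmentation recover the
  generated boundaries exactly, so the segmentation round-trip is a sharp
  test rather than a statistical one; in the simulated regime the cap
  binds rarely enough that γ recovery from the pause model stays unbiased
  (verified in the acceptance tests).
- **BOLD.** For each participant, `y = Σ_j (β_j + b_{pj}) x_j + ε` with the
  design matrix built by the same `build_design_matrix()` the analysis
  uses (the forward model does not re-implement the convolution). Random
  slopes are drawn per participant and shared across that participant's
  ROIs; ε is AR(1) with ρ = 0.3 and unit sd, independent across ROIs.
  Generative betas: word rate 0.5, syllables 0.2, frequency 0.2, surprisal
  0.3, top-down 0.9, bottom-up −0.35, with slope sd 0.3 on the syntactic
  terms. A `timing_model` switch moves the syntactic weight onto the
  early-top-down or chunked column to generate data under a production
  timing hypothesis.

## 7. Calibration and known limitations

- The encoding model assumes iid residuals, but the generator produces
  AR(1) noise. Point estimates are unaffected (the β recovery criteria
  hold with ρ = 0.3), and in this design the random-slope variance
  dominates the fixed-effect SEs, so 3-SE coverage stays above 95%. Formal
  type-I calibration of the Wald machinery is nevertheless checked under
  white residuals — the model's own assumptions — because unmodeled AR(1)
  makes residual-level Wald tests anticonservative by construction. This
  decision was fixed before any calibration run. Prewhitening is the
  natural extension and is out of scope here.
- Wald p-values use the normal reference (asymptotic); with thousands of
  scans per fit the difference from a t reference is negligible.
- The syllable counter is a heuristic; real analyses should pass a
  pronunciation lexicon. The generator's frequencies and surprisals are
  toy stand-ins for corpus norms and language-model surprisal, which enter
  the pipeline as plain columns.
- The PCFG produces no disfluencies, repairs, or unparsed words;
  `build_predictor_table()` drops words missing from the parses, which is
  exercised in tests but not by the generator.
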