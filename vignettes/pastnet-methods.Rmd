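---
title: "Methods: a constructivist two-pathway model of English past-tense inflection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a constructivist two-pathway model of English past-tense inflection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Neuroimaging studies of English past-tense production report dissociations
between regular verbs (*look--looked*) and irregular verbs (*sing--sang*,
*hit--hit*, *go--went*): some brain regions respond more to one class than
the other. A dual-mechanism reading takes this as evidence for a mental rule
plus an associative lexicon. `pastnet` implements the single-mechanism
alternative: a network with **one** associative learning mechanism but
**two** anatomical pathways whose division of labour emerges through
experience-dependent structural development. After training, "synthetic
brain imaging" (SBI) of the two pathways reproduces regular/irregular
dissociations even though regularity is never encoded in the input -- the
dissociations trace back to frequency, phonological complexity, and
friend/enemy neighbourhood statistics.

## The model

The network maps an 84-unit phonological encoding of a verb stem to a
97-unit encoding of its past tense (84 stem positions plus a 13-bit VC
suffix block).

* **Direct pathway.** Input and output layers are fully connected from the
  start (weights `W_direct`, initialised uniformly in ±`init_w`, default
  0.1).
* **Indirect pathway.** A hidden layer of Gaussian receptive-field units,
  initially empty. Unit $h$ responds to input $x$ with
  $a_h = \exp(-\lVert x - c_h\rVert^2 / 2\sigma_h^2)$; lateral inhibition is
  modelled as winner-take-all, so at most one hidden unit contributes to any
  forward pass.
* **Output decision.** Targets are ternary ($-1, 0, +1$), so net input is
  quantised with a dead zone: $-1$ below $-\theta$, $+1$ above $+\theta$,
  $0$ in between ($\theta = 0.5$). The perceptron rule then updates both
  pathways from the ternary error $t_o - \mathrm{out}_o$ at rate
  $\lambda = 0.01$.
* **Receptive-field adaptation.** The winner's centre moves a step
  $\eta_c = 0.01$ toward the current input. Its width tracks the distance of
  the inputs it wins, $\sigma \mathrel{+}= \eta_w(\lVert x - c\rVert -
  \sigma)$ with $\eta_w = 0.005$, clipped to $[0.5, 10]$: units that respond
  to a range of different verbs widen, dedicated units shrink.
* **Growth.** Each hidden unit accumulates the network's output error into a
  local error counter while it is the winner. When the mean pattern error
  over the last 10,000 tokens is no lower than over the preceding 30,000
  (non-overlapping windows, reset after every insertion), three new units
  are inserted as jittered copies (per-dimension N(0, 0.01²)) of the unit
  with the highest local error counter, with fresh random output weights;
  the donor's counter resets. The very first insertion, from an empty
  layer, is placed at the current input.
* **Pruning.** Units that have not won for 30,000 presentations are removed
  (checked every 1,000 tokens, and once more at the end of a run).

### Why inserted units inherit the donor's width

Winner-take-all between Gaussian units is nearest-neighbour competition in
$\sigma$-normalised distance. A broadly tuned unit
($\sigma \approx 6\text{--}10$) that covers many verbs accumulates the
highest local error and becomes the insertion site -- but a newcomer with a
small fixed width placed at that unit's own centre is at (essentially) the
same distance from every input as the donor while dividing that distance by
a smaller $\sigma$, so it can never win a single competition and is pruned
30,000 tokens later. In early versions with a fixed insertion width the
hidden layer oscillated between two and five units indefinitely and type
accuracy plateaued near 0.70. Inserted units therefore inherit the donor's
current width: the jittered copies then compete with the donor on equal
terms, partition its territory along Voronoi lines, and specialise as their
centres and widths adapt. The bootstrap insertion uses `sigma_init` (2.0)
since there is no donor. Typically two of each three inserted units are
later pruned, which is the intended selection dynamic, and the surviving
layer is quasi-localist: most units win 1--10 verbs, a few hubs win many.

### Other numerical choices

* The growth trigger additionally requires the recent window's mean error to
  be positive. Once the network is error-free there is nothing left to
  improve, and without the guard the comparison $0 \ge 0$ would insert
  units indefinitely.
* Ties in the winner competition are broken by the lowest unit index;
  equality in the pruning rule ("inactive for 30,000") removes the unit.
* The width update uses the pre-update distance (the same quantity that
  determined the response).
* Local error counters accumulate raw summed absolute error.
* Training order per token: learning step, growth check, pruning check.

## The phonological encoding

Each syllable fills an xCCCVCC template: one stress slot (0/1), three onset
consonant slots, one nucleus slot, two coda slots. Consonants are 7-feature
and vowels 6-feature binary vectors (entries ±1) from the inventory shipped
in `inst/extdata/phoneme_features.csv` (24 consonants, 13 vowels, ASCII
stand-ins for IPA). Empty slots are all-zero. Onsets are right-justified
against the vowel and codas left-justified after it, keeping phonologically
similar forms close in input space. A stem is two syllable frames (84
positions; monosyllables occupy the first frame), and a past-tense form
adds a 13-position VC suffix block: the /t/ and /d/ allomorphs fill only
the consonant slot, the syllabic allomorph (after alveolar stops) fills
both. The feature tables themselves are a package convention -- any
consistent ±1 inventory preserves the model's statistical logic, which
depends on overlap structure rather than on particular feature labels.

## The synthetic corpus

No licensed lexical database is redistributed; `generate_corpus()` builds
an artificial lexicon that emulates the statistical structure a realistic
English training set would provide:

* **Frequencies.** Zipf-Mandelbrot over type ranks,
  $w_r \propto (r + 2.7)^{-1}$.
* **Class structure.** Defaults of 8.73% irregular types carrying 46% of
  tokens. Irregular types are assigned to a stride-spread set of frequency
  ranks (always including rank 1), with the stride binary-searched so the
  realised token share hits the target; this reproduces the concentration
  of irregulars at high frequencies that drives the frequency-to-indirect-
  pathway result. Infeasible targets (token shares unreachable at the given
  type count) raise a configuration error.
* **Neighbourhoods.** Stems are drawn from rime families (about one family
  per six types, geometric family sizes). Friends share stem rime and
  past rime; enemies share only the stem rime. Irregular subtypes
  (15% no-change, 45% vowel change, 30% vowel change + dental suffix
  ("pseudo-regulars"), 10% suppletive) are assigned per family with a
  family-wide replacement vowel, so irregular friends exist; the realised
  subtype mixture therefore varies with family sizes.
* **Complexity.** Stem phoneme count. Regulars draw longer onsets and are
  bisyllabic more often (45% vs. 20%), making them phonologically more
  complex on average -- the property that produces the regular advantage in
  raw direct-pathway activation.
* **Homophone exclusion.** Stems are unique by construction (resampled on
  collision); encoding is injective over a corpus.

What the generator does *not* emulate: child-directed frequency
distributions, real English phonotactics beyond the template, orthography,
semantics, and the actual membership of English irregular families. Tests
passing on these corpora show that the mechanism produces the dissociation
structure whenever the input has this statistical shape; they cannot show
that any particular English verb would behave as in the original corpus.

## Synthetic brain imaging

For each verb, activation flowing into the output region is measured per
pathway as summed absolute input: direct
$\sum_o \sum_i |w_{oi} a_i|$, indirect $\sum_o |w_{oh} a_h|$ for the single
winning unit, total = direct + indirect. The *activation ratio* is
$\tilde d / (\tilde d + \tilde\imath)$ after scaling each pathway to a
maximum of 1 over the profiled set (subset analyses reuse full-set scale
factors via the `scale_direct`/`scale_indirect` arguments so ratios remain
comparable). Direct activation divided by the number of active input units
normalises away phonological complexity; stress slots count as active. A
verb with zero activation in both pathways would have an undefined ratio
and is reported as missing.

## The statistical battery

`run_experiment()` trains replicate networks and pools their SBI profiles:

* Group comparisons use the Mann-Whitney U test with tie-corrected normal
  approximation, two-sided, reporting U, z, and mean ranks.
* Correlations of verb statistics (frequency, friends, enemies, complexity)
  with the activation ratio are Pearson r.
* Pathway regressions are random-intercept linear mixed models (maximum
  likelihood, `lme4`), with verb and network intercepts and standardised
  predictors; R² is marginal (fixed-effect variance over total). The
  dual-mechanism analysis adds regularity as a predictor and compares
  nested models by likelihood ratio. With a single network the verb
  intercept is unidentifiable (one observation per verb) and the fit falls
  back to OLS.
* Typicality ranks verbs within class by activation ratio; the
  complexity-matched analysis greedily pairs each verb of the smaller class
  with the nearest unused verb of the other class and reruns the group
  tests on the matched subset.
* Lesion analysis compares per-class accuracy of the intact network, the
  network with all hidden units removed, and the network with half the
  direct weights zeroed.

No multiple-testing correction is applied, α = 0.05, all tests two-sided.

## Study sizes

The package's standard desk-scale conditions (`scaled_config()`) are 330
verb types (10% irregular types, ~45% irregular tokens), 2 million training
tokens per network, and three replicate networks -- a proportional scaling
of the full-size setting (1,271 types, 20 million tokens, five networks)
chosen so that a complete experiment, including the statistical battery,
runs in well under a minute on a single core while preserving the
token-per-type exposure needed for convergence. Under these conditions
every network reaches 100% type accuracy with a few dozen hidden units, and
all of the qualitative results hold: higher indirect activation for
irregulars, the Table-1-style sign pattern (frequency −, friends +,
enemies −, complexity + against the activation ratio), positive frequency
and negative regularity coefficients for the indirect pathway with
regularity adding no direct-pathway fit, disappearance of the regular
direct-pathway advantage under complexity matching, regular-like ratios for
pseudo-regulars, and selective irregular impairment after an indirect
lesion. Coefficient magnitudes are corpus-dependent and are not
reproduction targets.

## Known limitations

* The feature inventory and corpus generator are synthetic stand-ins; only
  sign and ordering structure of the statistical results is meaningful.
* Stress is a single 0/1 template slot per syllable, not a phonological
  feature bundle.
* The model contains no semantics, by design; homophones are excluded.
* Mixed-model R² conventions differ across the literature; the marginal
  definition used here is stated above.
* One inflectional paradigm only; no noun plurals or cross-linguistic
  inflection.
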