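---
title: "Quantifying connected speech in progressive aphasia: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying connected speech in progressive aphasia: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Connected speech elicited by picture description is one of the cheapest
assessments in the aphasia clinic, and one of the hardest to score
consistently. `connspeech` implements a complete quantitative workflow for
such samples across the three progressive aphasia variants (svPPA, lvPPA,
nfvPPA), progressive supranuclear palsy (PSP), corticobasal syndrome (CBS)
and controls: fluency quantification, psycholinguistic annotation, two
varimax-rotated principal component analyses, a quartile distribution
analysis, and the data-driven derivation and validation of a 15-word
diagnostic checklist. This vignette explains the model behind each stage,
the tunable parameters, and the design decisions taken where the methods
literature leaves the choice open.

## Transcript representation and parsing

A transcript is one participant's description of one picture. False speech
is excluded before any counting: spans written `{code material}` with codes
`fs` (false start), `gram` (grammatical error), `fill` (filler), `pause`,
`rep` (repetition), `unint` (unintelligible) and `neo` (neologism) are
removed entirely, and `//` (clause boundary) and `%%` (prosodic mark)
segment the retained speech without contributing tokens. What remains is an
ordered list of *runs*: maximal stretches of retained tokens uninterrupted
by any exclusion or boundary. Runs matter because n-grams are counted
within runs only — two words separated by an excluded disfluency or a
clause boundary never form a bigram, which prevents artefactual word
combinations from bridging removed material.

Tokenization is deterministic and deliberately simple: whitespace
splitting, lower-casing, stripping of leading/trailing punctuation, with
internal apostrophes and hyphens preserved (`it's` and `half-dried` are
single tokens). Malformed markup (unbalanced braces, unknown codes) is
rejected with the byte offset of the problem, because silently skipping
bad annotation corrupts counts.

Transcription reliability is quantified as per-cent agreement: the two
token sequences are aligned by longest common subsequence and the number
of aligned matching words is divided by the *reference* transcript's word
count. The denominator is intentionally asymmetric — reliability is judged
against the transcript used in the analysis — and the same computation can
be restricted to a word list (e.g. the 15-item checklist).

## The thirteen fluency measures

Per transcript: token and type counts for words, word bigrams and word
trigrams; the three type-to-token ratios; total description time in
seconds; words per minute; the proportion of function relative to content
words; and the combination ratio (trigram tokens divided by word tokens, an
index of connected multi-word output — 0 when no run reaches three words,
approaching 1 for long uninterrupted speech). A transcript of
`r` runs with lengths `L_i` contributes `sum(max(0, L_i - n + 1))` n-gram
tokens. Ratios with a zero denominator are reported as missing rather
than zero, so an empty transcript does not masquerade as maximally
repetitive.

The bundled function-word list covers the English closed classes
(articles, demonstratives, prepositions, pronouns, auxiliaries and
modals with common contractions, conjunctions, particles); any analysis
accepts a replacement list from file. Word counts include function words;
the function/content proportion is a separate measure.

## Psycholinguistic annotation

Each content *token* (not type) is annotated with eight properties from a
norms lexicon: length in letters, log corpus frequency, semantic
diversity, semantic neighbourhood density, concreteness, age of
acquisition (years), and orthographic and phonological Levenshtein
distance (OLD/PLD). Token-level annotation means a participant who says
"thing" five times is represented five times — participant averages weight
words by usage, which is what a production analysis needs. When a plural
surface form has no entry, the singular's ratings are used (`-s`, `-es`,
`-ies`→`-y`), flagged as a fallback; tokens with no entry at all are
dropped and counted in a coverage report, so the accounting
`function + annotated + dropped = total` always closes. Familiarity and
imageability are outside the property set; published ratings cover too
little of a spontaneous-speech vocabulary to survive listwise deletion.
The repository ships only a synthetic lexicon; real norm sets are supplied
by the user as CSV.

## The two principal component analyses

Both PCAs are correlation-matrix PCAs (features are z-scored first),
because the inputs mix scales — counts, ratios, minutes in one analysis;
letters, log units and rating scales in the other. Suitability is checked
with the Kaiser–Meyer–Olkin statistic, computed from the inverse
correlation matrix: the sum of squared off-diagonal correlations over that
sum plus the squared off-diagonal partial correlations. In the
two-variable case the partial correlation equals the correlation, so KMO
is exactly 0.5 — a useful analytic anchor that the test suite asserts.

The retained components are varimax-rotated with Kaiser normalization
(convergence tolerance 1e-12). Rotation is orthogonal: the test suite
checks `t(R) %*% R = I` to 1e-8 and that total explained variance is
unchanged by rotation. Row scores are the standardized data projected onto
the rotated basis; they have zero mean and unit variance on the fitted
data, which is what makes fixed score bins (below) meaningful. Two
conventions make refits bit-reproducible: components are ordered by
rotated explained variance, and each column's sign is set so its
largest-|loading| feature loads positively.

**Component count.** The scree elbow is operationalized as the position of
maximum acceleration of the scree profile — the forward second difference
of the *log* eigenvalues. The log scale is a deliberate choice: the raw
second difference is dominated by the absolute gaps among the largest
eigenvalues, so when two strong clusters differ in size it can place the
elbow before a third, smaller-but-real component. Relative flattening is
what a reader of a scree plot actually judges. On the textbook spectrum
`c(5, 3, 2, 0.3, 0.25, 0.2)` both scales put the elbow after the third
component. Eigenvalues below 1e-6 of the largest (exact collinearity) are
excluded as candidate positions. Because any elbow rule is a formalized
judgement call, `scree_select()` exposes its acceleration curve and takes
an `override`; the analysis drivers retain three components throughout.

**Labels.** Component labels ("speech quanta", "lexical richness",
"speech complexity" for the fluency PCA; "length", "semantic richness",
"acquisition age" for the word-properties PCA) are attached metadata.
`label_components()` assigns each component the label of its
largest-|loading| feature under a fixed feature-to-label map, because
varimax ordering does not guarantee a fixed positional order of the
clusters.

**Word scores per participant.** The word-properties PCA is fitted on the
pooled unique-word corpus of all participants and both pictures. Every
produced content token is then scored in that space and averaged per
participant and picture, so the participant score is a usage-weighted
centroid. Group differences are tested with standard fixed-effects ANOVA
(one-way on fluency components; two-way group × picture on averaged word
scores) with Tukey's HSD post hoc.

## Distribution analysis

Mean scores can hide where in the lexical space a group's usage shifts, so
scores are additionally binned into four fixed ranges on the standardized
PC scale: [-4, -2], (-2, 0], (0, 2], (2, 4]. These are fixed score ranges,
not data quantiles — the point is that the same bin means the same thing
for every participant and group. Unit-variance scores fall outside ±4 only
in the extreme tails; such scores are clipped into the end bins and
counted. Per participant, the 4×4 grid over two components holds the
proportion of their tokens in each cell (cells sum to 1); group maps are
unweighted means of participant maps; difference maps subtract the control
mean map and attach a cellwise Welch two-tailed t-test on the
participant-level proportions. Welch's form is used because group
variances differ by design. Cell p-values are reported uncorrected, as is
conventional for these exploratory maps; with 16 cells per map they are
descriptive, and the outputs say so. Finally, a group × quartile
mixed-design ANOVA (quartile within-subject, group between-subject, fitted
via an `aov` error stratum and checked against an independent
sums-of-squares oracle) tests whether the *shape* of the distribution
differs by group.

## Checklist derivation

The diagnostic checklist is derived per picture in five steps.

1. **Indicator coding.** Every unique content word becomes a binary
   column: 1 if the participant produced any form of it. Inflectional
   variants are merged by a light root-match (strip `-s`/`-es`/`-ies`,
   `-ing`, `-ed`, `-en`, undoing consonant doubling so "digging" matches
   "dig" while "falling" keeps "fall"); dialect synonyms are explicit
   equivalence classes ("boy" = "chap" = "lad" = "bloke") that take
   precedence over stemming. Indicator coding is monotone: adding speech
   can never un-produce a word.
2. **Pairwise selection.** For all 15 group pairs (5 control-vs-patient,
   10 patient-vs-patient), an L1-penalized logistic regression over all
   word columns is fitted by coordinate descent over a decreasing lambda
   path, with lambda chosen to minimize 4-fold cross-validated binomial
   deviance (stratified folds; ties resolve to the larger, more
   parsimonious lambda). Binary predictors are *not* standardized — they
   share the 0/1 scale, which keeps coefficients comparable across words —
   while any appended continuous covariates are z-scored. Contrasts that
   select zero words are recorded as findings, not errors: clinically
   similar pairs genuinely yield none, and on realistic synthetic cohorts
   the nfvPPA-vs-PSP and svPPA-vs-lvPPA contrasts regularly come back
   empty.
3. **Pooling and re-fitting.** The union of selected words is the pool;
   the pairwise fits are re-run on the pooled columns.
4. **Rank ordering.** Words are ordered lexicographically by (i) the
   number of pairwise contrasts selecting them, (ii) their maximum
   absolute coefficient across contrasts, (iii) the maximum between-group
   production-proportion difference (1 means all of one group and none of
   the other produced it), with an alphabetical final tie-break for full
   determinism. The combination rule is lexicographic because the three
   criteria are on incommensurable scales; absolute coefficients are used
   because a word can be diagnostic by presence or absence.
5. **Truncation.** The top 15 form the checklist; a smaller pool is
   reported as-is with a note.

## Validation

Validation is hierarchical, mirroring the clinical decision sequence:
patients vs controls; then the motor cluster (nfvPPA, PSP, CBS) vs the
lexico-semantic cluster (svPPA, lvPPA); then within-cluster pairs, with
PSP and CBS merged into one class where sample sizes demand it. Two
schemes exist. In k-fold validation the checklist columns are fixed and
only coefficients are re-estimated per training fold — the use case of a
fixed published checklist — with held-out predictions pooled into one
confusion matrix at a 0.5 probability threshold (class priors are not
adjusted). A stricter nested mode, in which word selection itself is
repeated inside each fold, is the right check when asking whether the
*derivation* overfits; the no-leakage null-control test instead fixes the
word set independently of the outcome labels, which achieves the same
guarantee without the cost. Out-of-sample validation refits on the full
training cohort and predicts a disjoint test cohort (shared participants
are an error). Cognitive sub-scores (ACE-R and MLSE subtests) can be
appended as z-scored columns; on synthetic cohorts this lifts the
word-insensitive svPPA-vs-lvPPA contrast from chance to near-perfect,
which is exactly the pattern that motivates supplementation.

Groups with fewer than three members cannot survive any cross-validation
split (each training fold needs two of each class); such stages are
skipped with a warning, and a penalized fit that cannot be
cross-validated falls back to a fixed lambda of 0.1 × lambda_max. These
policies exist for degenerate inputs and toy fixtures; the default study
layout's smallest group is 9.

## The synthetic cohort generator

No clinical transcripts ship with the package, so the generator provides
cohorts with the statistical structure the analyses assume, plus the
ground truth needed for recovery tests. Its defaults are the study
conditions, chosen once:

* **Layout**: 24 controls, 9 svPPA, 9 lvPPA, 9 nfvPPA, 10 PSP, 13 CBS,
  each describing both pictures; an optional second-site cohort shares
  the same lexicon (a real second site speaks the same language).
* **Norms lexicon**: per-word properties drawn from a correlated Gaussian
  with three clusters — word form {length, OLD, PLD} at r = 0.80; lexical
  semantics {log frequency, semantic diversity, neighbourhood density,
  −concreteness} at |r| = 0.65; age of acquisition cross-correlating at
  ±0.25 (positively with word form, negatively with frequency, the signs
  seen in published norm sets) — then mapped to realistic rating scales.
  At 500+ words the realized correlations sit within 0.1 of target and a
  PCA recovers the three clusters.
* **Production model**: token count is negative-binomial (output is
  overdispersed across patients: means 110 for controls and svPPA-like
  90–100 for the lexico-semantic groups against 40–55 for nfvPPA/PSP/CBS);
  lexical choice follows a softmax over standardized properties with
  group-specific tilts (svPPA/lvPPA toward high frequency and semantic
  diversity and away from length; nfvPPA/CBS toward earlier-acquired
  words); function words are interleaved at a group rate; disfluency
  spans are injected per-gap at group rates (highest in nfvPPA); duration
  is drawn near 65–70 s, as descriptions run past a one-minute mark.
* **Planted checklist words**: twelve per picture with production
  probability gaps of 0.6–0.8 on their discriminative contrasts (control
  markers, motor-cluster omissions, lexico-semantic omissions, and
  high-frequency substitution markers patients over-produce). No planted
  word separates svPPA from lvPPA or nfvPPA from PSP/CBS: those
  distinctions should require cognitive scores, and on generated cohorts
  they do.
* **Cognitive scores**: normal per-group sub-score profiles in which
  svPPA is marked by low MLSE semantics, lvPPA by low phonology and
  working memory, nfvPPA by low motor speech and syntax.

Everything is a pure function of (parameters, seed): per-participant
seeds derive from the master seed, and regenerating with the same seed is
byte-identical.

What the generator does *not* emulate is real syntax and discourse: word
order within a run is exchangeable, disfluencies are independent
insertions, and planted words are produced independently of the rest of
the description. Passing tests therefore demonstrate that the pipeline's
statistics recover the structure they are designed to detect — not that
any specific clinical accuracy will be achieved on real recordings, where
word co-occurrence, discourse structure and annotation noise all differ.

## Test design and problem sizes

The suite asserts, among others: exact equivalence of all n-gram and
ratio measures with a brute-force enumerator on 1000 random transcripts;
varimax agreement with an independently coded Jacobi-sweep rotation to
1e-6 on seeded 100×8 matrices; the bivariate KMO closed form and
agreement with a regression-residual KMO to 1e-10; three-cluster recovery
(scree k = 3 and one cluster per rotated component) in at least 95 of 100
lexicon draws at 500 words; conservation laws of the distribution stage;
recovery of at least 90% of planted checklist words across 50 cohorts at
25 per group, generated with identical group profiles so the planted
words are the only systematic signal; chance-level accuracy (mean in
[0.4, 0.6] over 100 seeds) on cohorts whose two groups are generated
identically, guarding against selection leakage; the analytic penalty
limits (null model as lambda → ∞, `glm` MLE at lambda = 0 to 1e-4); and
byte-identical artifacts across repeated pipeline runs. These problem
sizes are the package's chosen operating points: large enough for the
stochastic assertions to be stable, small enough to run routinely.

## Known limitations

* The root-matcher is a light inflectional stemmer; irregular forms must
  be listed as explicit variants (as "stolen" is for "steal").
* Cellwise difference-map p-values are uncorrected by design; treat them
  as descriptive under 16-cell multiplicity.
* The mixed-design ANOVA assumes complete quartile counts per participant
  and reports the standard split-plot F tests; it does not attempt
  sphericity corrections.
* Checklist derivation on cohorts with very small groups is limited by
  what penalized CV can support (see the degenerate-input policies
  above).
* Component labels are conveniences for reading output; nothing
  downstream depends on them.
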