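---
title: "Multilayer fraud detection for web-based surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer fraud detection for web-based surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveysieve)
```

## The problem

Compensated web-based surveys attract fraud: scripted bots submitting many
questionnaires, individuals re-submitting under altered identities to collect
multiple incentives, and ineligible actors (often routed through VPNs or data
centers) misrepresenting residence to pass eligibility screens. Fraudulent
records are not harmless noise — they can bias the distribution of key study
variables, so the *choice* of fraud-detection method becomes part of the
analysis. Survey platforms ship proprietary detectors (behavioral bot scores,
device-fingerprint duplicate scores), but their mechanics are opaque, which
makes it hard to know what they remove and whom they disproportionately
exclude.

surveysieve implements a transparent, rule-based alternative — a *multilayer*
classifier over the exported response table — alongside an adapter that
reproduces the platform-side classification from its exported scores, the
agreement statistics needed to compare the two systems, and a synthetic
cohort generator so the whole pipeline can be evaluated against known ground
truth.

## The multilayer classifier

### Stage 1: real-time exclusion rules

Each submission is checked against a **gazetteer** — reference tables of
known residential addresses with their neighborhoods, neighborhood adjacency,
nonstandard (PO box / unique) zip codes, the recruitment URLs actually
distributed, and IP intelligence. A response is labeled fraud if *any* of
these fires:

1. **Neighborhood mismatch** — the self-reported colloquial neighborhood
   name matches neither the neighborhood of the given address nor any
   adjacent neighborhood. Colloquial local knowledge is hard for a script to
   fake, which is why this check leads the list.
2. **Invalid address** — the address does not exist in the gazetteer index.
3. **Rapid submission** — start *and* stop times within ±1 minute of at
   least 2 other submissions. Timestamps are truncated to whole minutes
   before comparison, which makes the ±1-minute window well defined; the
   relation is evaluated pairwise per response, with no transitive chaining.
4. **Duplicate email** — the (lowercased, trimmed) email matches an earlier
   respondent's. The first user is kept; later users are flagged. We do not
   collapse plus-addressing: the rule is a literal re-use check, and
   anything cleverer would over-flag beyond what it claims to detect.
5. **Nonstandard zip** — the zip appears on the gazetteer's PO box / unique
   code list.
6. **Address overuse** — at least 2 *earlier* respondents already reported
   the same normalized address; the 3rd and later users are flagged. The
   first two users are never retro-flagged when a third appears: flags are
   assigned at the moment a response arrives, matching how the rule operates
   in deployment.
7. **Invalid referral URL** — the referring URL (compared scheme- and
   trailing-slash-insensitively) is not among the distributed links.

A **honeypot** check rides along: any non-blank answer to the hidden item
disqualifies the response. In deployment a honeypot ends the survey live; we
include it as a data rule so the exported table remains auditable.

For reporting, each fraud case is attributed to the *first* firing rule in
the order above, so per-rule counts are mutually exclusive and sum to the
stage's fraud count; every firing rule is still retained as evidence on the
flag table. The listed order is a deliberate tie-break — attribution needs
*some* precedence, and criterion order is the only one the protocol implies.

### Stage 2: post hoc k-strike rule

Responses surviving stage 1 are screened by three automated criteria. Each
only marks a response *suspicious* — a strike — because each can plausibly
hit genuine respondents:

* **Duplicate free text.** The free-text comment, normalized (lowercase,
  whitespace collapsed), is identical to other survivors' text at tiered
  thresholds: 1+ words repeated ≥ 100 times, 2+ words ≥ 10 times, 3+ words
  ≥ 3 times. Longer strings repeating verbatim are vastly less likely to be
  coincidence, hence the sliding scale. Matching is exact after
  normalization — no fuzzy matching, since the criterion targets *identical*
  submissions. All users of an over-threshold string are flagged, including
  its first submitter: unlike the duplicate-email rule this is evidence of
  scripting, not a first-come eligibility rule. Repeat counts are computed
  within the stage-1 survivor set, reproducing the pipeline topology in
  which the criterion was defined (the alternative — counting over the full
  batch — would let already-excluded bots push genuine survivors over a
  tier).
* **Bad IP origin.** Longest-prefix match in the IP-intelligence table says
  the IP belongs to a VPN or data center, or resolves outside the allowed
  country (default `"US"`). Unmatched IPs are *not* flagged: the criterion
  demands positive evidence, and an incomplete intelligence table should not
  manufacture strikes. Malformed IPs warn and pass. Only IPv4 CIDR prefixes
  are matched; other address forms are treated as unmatched.
* **Screener–main inconsistency.** A key item that should be stable (age,
  zip, household adult/minor counts, ethnicity, testing history, vaccination
  status) was answered differently in the eligibility screener and the main
  survey. Numeric-looking values compare numerically ("34" equals "34.0");
  items missing on either side are skipped.

A survivor is labeled fraud when it collects at least `k_strike` strikes
(default **2**). `k = 1` treats every suspicion as a verdict and is
aggressive; `k = 3` demands all three signals and misses almost everything;
`k = 2` balances the criteria's individual false-positive rates against the
need to remove strongly evidenced fraud. The package exposes `k` as a
configuration value precisely so this sensitivity can be re-run: fraud sets
are provably nested for k = 3 ⊆ 2 ⊆ 1 (a property the test suite checks).

### The platform adapter

The platform-side classifier is reproduced from the three scores the survey
platform exports per response: a reCAPTCHA v3 bot score in [0, 1] (fraud
when **strictly below 0.5**), a RelevantID fraud score in [0, 130] (fraud at
**≥ 30**) and a RelevantID duplicate score in [0, 100] (duplicate at
**≥ 75**). Boundary semantics are encoded exactly as documented — strict
`<` for reCAPTCHA, `≥` for both RelevantID scores — and one breached
threshold suffices. The underlying scoring models are proprietary; the
adapter deliberately models nothing beyond the exported scores and cutoffs.
Missing scores never flag (there is no documented rule for missingness, and
treating absence as guilt would be indefensible); a fully unscored response
is labeled valid and counted in an audit tally.

## Agreement statistics

Two classifiers over the same batch are compared through a 2×2
classification table (`build_confusion()`) and Cohen's κ:

$$\kappa = \frac{p_o - p_e}{1 - p_e},\qquad
p_o = \frac{a+d}{n},\qquad
p_e = \frac{(a+b)(a+c) + (c+d)(b+d)}{n^2}$$

with the standard error

$$\mathrm{SE}(\kappa) = \sqrt{\frac{p_o(1-p_o)}{n(1-p_e)^2}}$$

and a normal-quantile interval κ ± z·SE. This SE is the simplest of the
published variants; more elaborate formulas (e.g. Fleiss's) exist, but this
one reproduces the intervals of the classification tables the package is
tested against, and the package keeps exactly one formula rather than a
menu. κ is reported with both conventional qualitative scales — Landis–Koch
(cutpoints 0, 0.20, 0.40, 0.60, 0.80) and McHugh (0.20, 0.39, 0.59, 0.79,
0.90) — because the two scales can legitimately disagree about the same
number, and readers tend to anchor on whichever adjective they see first.

```{r kappa-example}
k <- cohen_kappa(confusion_2x2(2627, 934, 2095, 2294))
k
```

Supporting comparisons use the field-standard tests: Pearson chi-square for
categorical variables (no continuity correction by default, switchable in
the configuration), Welch's two-sided t for normal continuous variables, and
Mann–Whitney U otherwise. Subgroup means (e.g. vaccine confidence by racial
or ethnic group) carry normal-approximation intervals, mean ± 1.96·sd/√n at
95% — z, not t, matching how such tables are conventionally reported at
these group sizes.

**Mann–Whitney implementation note.** The U statistic is computed from rank
sums. For pooled sizes ≤ 10 the two-sided p-value is exact, by enumerating
all $\binom{n}{n_x}$ assignments of the pooled values (this handles ties,
which classical exact algorithms do not); beyond that, a tie-corrected
normal approximation with continuity correction is used. Exhaustive checks
in the test suite show the two paths agree within 0.02 at pooled size 10;
at the smallest exact size (4 + 4) the exact distribution itself moves in
steps of ≈ 0.03, so agreement there is bounded by 0.035 — a floor set by
discreteness, not by the approximation.

Fraud-proportion trends over the field period are summarized by a centered
moving-window proportion per method (`fraud_proportion_series()`, default
7-day window; empty windows yield `NA` so recruitment pauses appear as gaps).
A locally weighted smoother would serve the same purpose for display; the
windowed series was chosen because it is exactly reproducible and trivially
testable against a brute-force tally.

## The synthetic cohort generator

`generate_cohort()` draws a seeded response stream with ground-truth labels:
genuine respondents plus six fraud archetypes, each violating precisely the
rule(s) it is named for. It exists so that sensitivity and specificity —
which can never be computed on real survey data, where true fraud status is
unknowable — are measurable on data whose truth is known.

What the generator emulates:

* a ~110-day field period with three campaign windows; genuine arrivals
  concentrate inside the windows (weight 1 inside, 0.12 outside);
* genuine completion durations lognormal around a 23.5-minute median with
  sdlog 0.54 (chosen to match a typical interquartile ratio of ≈ 2 for a
  20-minute instrument);
* genuine free text drawn mostly empty or unique, with a small pool of short
  pleasantries whose repetition stays below the 1-word tier — though the
  2-word pool can occasionally cross its tier, deliberately: a genuine
  single-strike coincidence is exactly the false-positive mode the k-strike
  rule exists to absorb;
* two-person households (default 20% of genuine respondents) legitimately
  sharing an address — the substrate the address-overuse rule must *not*
  flag at two users;
* platform scores: genuine respondents concentrated near clean values
  (reCAPTCHA ~ 0.6 + 0.4·Beta(8, 1.5), RelevantID scores low), with a 5%
  contamination rate breaching a threshold to model platform false
  positives; archetype responses breach RelevantID thresholds with
  probability 0.7. These rates are declared assumptions — no quantitative
  description of genuine-respondent scores exists to calibrate against —
  and they are spec parameters, not constants.

Archetype design is **k-strike aware**: a single post hoc strike never
labels fraud under the default k = 2, so the two post-hoc-only archetypes
carry two strikes each — `vpn_actor` couples its VPN/offshore IP with
boilerplate duplicate text, `inconsistent_screener` couples its item
mismatch with boilerplate text. Likewise `duplicate_farm` reuses the email
of an *earlier genuine* respondent (so every farm response is a later
duplicate, and the genuine victim is not flagged), and `address_reuser`
reuses a genuine household's address (making every reuser the 3rd+
reporter). `bot_burst` submits in clusters of ≥ 3 sharing start/stop
minutes with low reCAPTCHA scores; `url_spoofer` arrives via an
undistributed URL. Under this design every archetype response is
deterministically detectable, and the pipeline's sensitivity/specificity on
default cohorts (760 responses: 500 genuine + 260 across archetypes) is
≥ 0.95 by construction, with residual error only from coincidental genuine
collisions — which is what the test suite asserts.

What the generator does **not** emulate: real city geography (the gazetteer
is a 12-district ring with synthetic addresses), adversarial bots that mimic
human behavior or vary their free text, respondents abandoning mid-survey,
or any correlation between demographics and fraud. Passing tests on
synthetic cohorts therefore demonstrates that the *rules are implemented
correctly and recover planted violations* — not that the rule set would
achieve comparable operating characteristics on real traffic.

`generate_planted_cohort()` is the deterministic counterpart: it plants
*exact* per-rule violation counts, an explicit strike-combination pattern
over the survivors, and explicit joint (survey type × multilayer × platform)
counts, then decorrelates the plants from time and stratum with seeded
shuffles. Feeding it the counts printed in a published flowchart or
classification table turns that publication into an executable data set:
running the pipeline over the planted stream must — and does — return the
published totals, percentages and κ values. Non-rapid submissions are
spaced ≥ 2 minutes apart so the rapid rule fires only on the planted
clusters; email and address donors are placed earliest in the stream so the
chronological rules flag only the planted reusers.

## Numerical and degenerate-input choices

* Timestamps are truncated to whole minutes before any comparison; the
  rapid-submission window is inclusive (|Δ| ≤ window).
* Text normalization is idempotent; the address variant strips punctuation
  before collapsing whitespace.
* Empty or missing addresses fail the invalid-address rule (they cannot
  match an existing address); empty zips and empty emails are never flagged
  (eligibility screening owns empty-field handling).
* Duplicate strike rows for the same (response, criterion) pair count once.
* κ is undefined when p_e = 1 (degenerate marginals, e.g. an all-valid
  batch); `cohen_kappa()` raises a typed error and `run_pipeline()` reports
  the stratum as not computable instead of failing.
* Adjacency is symmetrized on load with a logged note; conflicting
  address→neighborhood rows are an error, not a silent overwrite.
* Chi-square requires strictly positive expected counts and advises merging
  categories otherwise.

## Problem sizes

The test suite runs on cohorts of 40–760 responses plus one planted
7950-response stream, and completes in well under a minute; the acceptance
script re-runs the planted stream and a default 760-response synthetic
cohort in a few seconds. These sizes were chosen as the smallest that
exercise every rule interaction at realistic density; the implementation
itself is vectorized dplyr/base and handles batches of this order in
seconds.

## Known limitations

* The gazetteer is a static file interface; there is no live geocoding or
  proxy-detection service, and IP intelligence is only as good as the
  supplied table.
* IP matching supports IPv4 CIDR prefixes only; IPv6 addresses are treated
  as unmatched (hence never flagged).
* Free-text duplication is exact-match after normalization; paraphrasing
  bots evade it.
* The platform adapter reproduces documented thresholds over exported
  scores; if the platform applies additional unexported heuristics, the
  adapter cannot model them.
* Ground-truth evaluation is only as faithful as the synthetic archetypes;
  see the generator's non-goals above.
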