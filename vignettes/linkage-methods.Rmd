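---
title: "Deterministic registry linkage without a unique identifier: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic registry linkage without a unique identifier: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(registrylink)
```

## The problem

Two registries describe overlapping populations but share no person
identifier: a cancer registry (A) with one record per incident breast-cancer
diagnosis, and a primary-care registry (B) with one record per patient
enrolled at a participating GP practice. Analyses that need both — care
trajectories around a diagnosis, long-run adverse effects, case-control
designs with GP-registry controls — require person-level linkage that is
(i) accurate enough to trust, (ii) auditable, and (iii) achievable without
moving identifiable data between the registry holders.

`registrylink` implements one complete answer: deterministic linkage on the
quasi-identifier *(date of birth, 4-digit postal code)*, run on keyed
pseudonyms produced by a three-party chain, with a diagnosis-agreement
requirement to suppress false matches, plus the accounting and simulation
machinery needed to quantify what the procedure gets wrong.

## The linkage model

The key is $k = (\mathrm{dob}, \mathrm{pc4})$, where pc4 identifies a
neighbourhood of on average about 2,000 households. Two women born on the
same day in the same neighbourhood share $k$; the algorithm therefore never
guesses. Writing $n_A(k)$ and $n_B(k)$ for the number of A- and B-records
holding key $k$, and $d_B(k)$ for the number of those B-records with the
qualifying GP diagnosis, each female A-record is classified:

| condition | disposition |
|---|---|
| $n_A(k) > 1$ | excluded: correct linkage cannot be ascertained |
| $n_B(k) = 0$ | unmatched |
| $n_B(k) = 1$, $d_B(k) = 1$ | included (unique match, diagnosis confirmed) |
| $n_B(k) = 1$, $d_B(k) = 0$ | matched, not included (no GP diagnosis) |
| $n_B(k) > 1$, $d_B(k) = 1$ | included (resolved to the sole diagnosis-bearer) |
| $n_B(k) > 1$, $d_B(k) \ne 1$ | matched, not included (ambiguous or no diagnosis) |

Assumptions worth making explicit:

* **Exact matching only.** No phonetic or string-distance matching, no
  probabilistic (Fellegi–Sunter) scoring; a single-day error in a recorded
  date of birth loses the match. Registries with strict data-entry checks
  make this an acceptable trade for auditability.
* **Diagnosis agreement is a strong filter.** Requiring the diagnosis in
  both registries raises internal validity but removes women whose GP never
  recorded the code. The diagnosis years are deliberately *not* required to
  agree: the A-side code may carry any year, as may the B-side code, since a
  year constraint would compound GP recording noise.
* **The female restriction is applied inside the engine** and audited
  (`$audit` carries male and unknown-sex removals for both sides). Records
  with unknown sex are excluded rather than guessed; they appear in the
  audit, never silently in the cohort.
* Because A-records surviving the within-A uniqueness screen hold distinct
  keys, no B-record can be claimed by two included A-records; the engine
  asserts this rather than assuming it.

Diagnosis predicates: an A-record qualifies if any ICD-10 code has prefix
`C50` — registries code topography with subsites (`C50.4` etc.), so prefix
matching is the faithful reading of "code C50" — and a B-record qualifies
only on the exact ICPC-1 code `X76`, which has no subsite structure.

Within the non-unique-in-B branch the engine distinguishes *zero*
diagnosis-bearing candidates from *two or more* in its audit columns
(`n_b`, `n_b_dx`); the reporting merges them, since neither leads to
inclusion, but error analyses want the split (the two-or-more case is the
one that risks a false match when resolution *does* occur).

## The pseudonymization chain

Linkage must run at a party that holds neither registry's identifiers. The
chain separates knowledge across three parties:

1. **Sender** (each registry holder): validates record format (ISO-8601
   dates, `^\d{4}([A-Z]{2})?$` postal codes) and reports — never silently
   drops — failing rows; computes the *pre-pseudonym*
   $p_1 = \mathrm{HMAC}_{K_s}(\texttt{"YYYY-MM-DD|PPPP"})$ over the
   canonical key serialization; coarsens quasi-identifiers to (birth year,
   birth quarter, pc4). The fixed `|` delimiter makes the serialization
   prefix-free, so distinct (dob, pc4) pairs cannot alias.
2. **Trusted third party**: computes $p_2 = \mathrm{HMAC}_{K_t}(p_1)$. Its
   function signature accepts a bare character vector — it is *structurally*
   unable to receive quasi-identifiers. Without $K_s$ it cannot invert
   $p_1$; the receiver, not knowing $K_t$, cannot recompute $p_2$ from a
   dictionary of keys.
3. **Receiver**: re-attaches $p_2$ to the aggregated quasi-identifiers and
   clinical payload. Nothing downstream of this point contains a raw date
   of birth or 6-character postal code (asserted in code and scanned for in
   tests).

Since HMAC-SHA256 is deterministic and collision-free at any realistic
keyspace size, $p_2(r_1) = p_2(r_2) \iff k(r_1) = k(r_2)$: linkage on final
pseudonyms is identical to linkage on raw keys, which the test suite checks
end-to-end. Design choices made where the design was genuinely open:

* **The pre-pseudonym covers the 4-digit key only.** One could pseudonymize
  the full 6-character postal code and handle 4-digit matching differently;
  since the linkage is defined at pc4 granularity, hashing anything finer
  would only manufacture spurious non-matches. The 2-letter suffix is
  discarded before hashing.
* Secrets arrive as function arguments or key files; they are never written
  to outputs, logs or manifests. This simulates the data-flow contracts —
  it is not production key management, and a malicious TTP is out of scope.

## Flow accounting

`flow_report()` tallies nine nodes (total, excluded, remaining, matched,
unique/non-unique split, diagnosis-confirmed, resolved, included) and
carries *two* percentages per node: one against the node's natural local
denominator (matched among remaining; diagnosis-confirmed among unique
matches) and one against the overall cohort. Reports quote percentages with
their denominators labelled because the two conventions differ exactly where
the numbers are most quoted. Zero denominators yield flagged `NA`
percentages, never `NaN`. The arithmetic identities
(remaining = total − excluded; matched = unique + non-unique;
included = confirmed + resolved) are asserted on every construction.

## Inclusion bias and validation sampling

Selective linkage loss is the main threat to downstream validity: women who
moved after diagnosis cannot match, and the longer ago the diagnosis, the
more likely a move. `inclusion_table()` cross-tabulates the full cohort
against inclusion for each characteristic and applies a Pearson chi-square
test of independence — the standard test for such tables; no continuity
correction, $df = (r-1)(c-1)$. No multiple-testing adjustment is applied
across characteristics, matching how such tables are conventionally
presented; with half a dozen characteristics, a Bonferroni-minded reader
should mentally scale the p-values. Declared-but-empty categories are
excluded from the test and flagged rather than crashing it.

`gp_validation_sample()` operationalizes a pragmatic accuracy check:
practices are ranked by linked-patient count, drawn with probability
proportional to size from the top half (volunteer effort concentrates where
patients do), and whole practices are added until the target — default 44
patients, a feasible ask of 40–50 — is reached. "Top half with
size-proportional draws" is one defensible reading of "randomly selected
among relatively large practices"; it is configurable in effect because the
input table can be pre-filtered. Sheets carry year and quarter of birth,
registration date, both registries' diagnosis years and the last known
visit — enough for a GP to find the patient, never a date of birth or
postal code (schema-checked).

## The synthetic generator

`generate_population()` + `generate_registries()` emulate, with ground
truth:

* **Neighbourhood structure**: Poisson household counts around a mean of
  2,000 per pc4; one adult woman per household on average (configurable) —
  household microsimulation realism is not attempted.
* **Practice-based coverage**: practices nest in neighbourhoods; a fraction
  (default 0.10) is enrolled in B, so B membership is clustered by practice
  the way real GP databases are.
* **Incidence**: piecewise-constant per-woman-year hazard rising with age
  band (defaults 2·10⁻⁴ under 45 up to 3·10⁻³ at 60+ — deliberately round,
  arbitrary values; they set cohort size, not any tested quantity).
  Diagnosis year is drawn from the first-event distribution of the yearly
  hazards.
* **Imperfect GP recording**: a true diagnosis is recorded as X76 with
  probability `gp_recording_sensitivity` (default 0.80); a small background
  X76 rate (default 0.002) puts diagnosis codes on women whose disease
  predates the observation window, which is what makes false resolution of
  key collisions possible at all.
* **Mobility**: each woman moves to a uniformly random neighbourhood with
  per-year probability `move_prob` (default 0.02). Registry A records the
  pc4 *at diagnosis*; registry B the pc4 *at a snapshot year* (default
  2017). The diagnosis-to-snapshot lag is therefore the mechanism that makes
  older diagnoses less linkable — the qualitative inclusion-bias pattern the
  test suite checks. B's address semantics (one snapshot, rather than a
  full address history) is a deliberate simplification.
* Clinical attributes (stage, surgery, therapy flags) are sampled with
  realistic marginal frequencies but **independently of linkage success**,
  so the inclusion-bias tests have a clean null against which the
  chi-square calibration can be verified.

What the generator does *not* emulate: real incidence rates or geography,
households with correlated birth dates (twins, which inflate within-A
collisions), registration churn in B, coding drift over time, or
data-entry errors in the key itself (the generator's keys are always
recorded faithfully, so linkage misses come only from coverage, mobility,
recording and collisions). Passing tests therefore demonstrate internal
consistency of the machinery, not performance on any real registry pair.

`exact_flow_fixture()` is the complement: instead of sampling, it
*constructs* registries so the flow lands requested counts on every branch
exactly (colliding A-pairs, absent keys, unique matches with and without
the diagnosis, resolvable and ambiguous B-collisions), refusing
arithmetically inconsistent requests by naming the violated identity. By
construction the final inclusion count is additive in the two inclusion
branches. Ambiguous groups alternate between the two-diagnoses and
no-diagnosis flavour so both audit buckets occur. Only row order and
cosmetic attributes depend on the seed.

## Analytics

* `expected_collision_rate()`: under uniform occupancy of $C$ key cells by
  $N$ records, a record collides with probability $1-(1-1/C)^{N-1}$; a
  cell-probability vector generalizes this to non-uniform occupancy
  ($\sum_j q_j (1-(1-q_j)^{N-1})$). Tests verify it against placement
  simulation within Monte-Carlo error.
* `linkage_performance()`: pair-level sensitivity and PPV against ground
  truth. A reported pair is correct iff both records belong to one person.
  The sensitivity denominator counts persons truly present in both
  registries *with an intact key* (non-movers): exact-key linkage cannot
  recover a broken key, and folding movers into the denominator would
  conflate two different failure modes. Performance is pair-level, not
  cluster-level.
* `dilution_analysis()`: unlinked true cases sitting in B look like
  controls. With control exposure prevalence $p_0$, true odds ratio
  $\psi$, case prevalence $p_1 = \psi p_0 / (1 - p_0 + \psi p_0)$ and
  contamination fraction $f$, observed controls have prevalence
  $(1-f)p_0 + f p_1$ and the observed odds ratio attenuates monotonically
  toward — never past — the null, which is preserved exactly at $\psi = 1$.
  The mixture model is the simplest mechanism consistent with
  case-contaminated controls; `contamination_rate()` derives $f$ from a
  linkage result plus ground truth.

## Numerical and testing choices

Determinism: every stochastic function takes a seed and uses it through
`withr::with_seed`, leaving the caller's RNG state untouched; identical
seeds give byte-identical output. The linkage engine itself is
deterministic with no tie-breaks — ties are precisely what the disposition
taxonomy classifies instead of resolving.

Degenerate inputs have defined behaviour: empty registries link to empty
results; zero flow denominators flag rather than propagate `NaN`;
contingency tables with a zero row or column raise a named error; an empty
diagnosis set is `FALSE`, not an error; reading a registry aborts when more
than 1% of rows (configurable) fail validation.

Problem sizes in the test suite were chosen to make Monte-Carlo checks
sharp at interactive runtimes: the registry-scale worked example runs the
full pipeline on ~215,000 A-records; oracle-equivalence uses 200 randomized
instances of up to 60 records per side against an all-pairs reference
implementation; parameter recovery uses 50 replicates of a ~100,000-woman
population (50 neighbourhoods × ~2,000 households) with coverage 0.10 and
recording sensitivity 0.77, agreeing within three Monte-Carlo standard
errors; chi-square calibration uses 500 null replicates of a 400-woman
cohort. All statistical acceptance bands are expressed in Monte-Carlo
standard errors estimated from the replicates themselves, never as fixed
fudge factors.

## Known limitations

* Exact deterministic linkage only; no tolerance for key recording errors.
* The diagnosis-agreement rule conflates GP under-recording with genuine
  non-matches; the generator separates the two mechanisms (sensitivity vs
  collisions), but on real data their attribution is unidentifiable from
  the linked result alone.
* Male breast cancer is out of scope (the cohort definition is female-only).
* The inclusion table reports unadjusted p-values.
* The simulation is a mechanism testbed, not a calibrated model of any real
  population.
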