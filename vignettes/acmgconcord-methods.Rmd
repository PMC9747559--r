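---
title: "Methods: measuring automated-versus-manual interpretation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring automated-versus-manual interpretation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`acmgconcord` evaluates a fully automated ACMG/AMP variant-interpretation
engine against a high-confidence manual consensus, in the reporting frame
used by carrier screening: the five-level scale B < LB < VUS < LP < P is
binarized into *positive* (P, LP — actionable: partner testing, counseling)
and *negative* (VUS, LB, B — the carrier is assumed healthy and no action
follows). All concordance statements in the package are statements about
this binarization; sub-type disagreement (P versus LP, B versus LB) is
never counted as discordance.

The analysis operates on interpretations, not genomes. Inputs are
structured records — invoked criteria with evidence sources, submitter
assertions with dates, per-variant case counts — and the interchange format
is TSV throughout, because no stage touches alignments, genotypes or
coordinates.

## The evidence-combination engine

All 28 evidence codes are implemented, each at its guideline-fixed
direction and strength (PVS very strong, PS strong, PM moderate, PP
supporting; BA stand-alone, BS strong, BP supporting). Some published
descriptions of automated engines count 27 criteria; since no source states
which code would be omitted, the engine deliberately carries the full table
and never silently drops a code.

The combining rules are encoded as count thresholds. Pathogenic requires
PVS1 plus (one PS, two PM, one PM and one PP, or two PP), two PS, or one PS
plus (three PM, two PM and two PP, or one PM and four PP); likely
pathogenic, benign and likely benign follow the analogous lists. Every
threshold is implemented as *at least* (`>=`): with exact-count readings, a
set could fall out of a rule by acquiring extra supporting evidence, which
would break the monotonicity property the test suite verifies exhaustively
(adding pathogenic evidence never lowers the class; adding benign evidence
never raises it, over all 2^11 subsets of a representative panel).

**Conflicting evidence.** When a criteria set contains evidence in both
directions, the engine returns VUS regardless of which combining rules
would fire. This is deliberately stricter than a rule-level conflict test:
a single strong benign criterion fires no benign *rule*, yet automated
engines demote an otherwise-LP variant carrying BS1 to VUS, and two of the
nine discordance mechanisms (`high_frequency_pathogenic`,
`variable_penetrance`) exist precisely because one added BS code flips a
positive call. Evidence-level conflict reproduces that behaviour;
`combine_criteria(c("PS3","PM3","BS1"))` is VUS.

**PVS1 and NMD escape.** A truncating variant escapes nonsense-mediated
decay when it lies in the last exon or within the final 50 bases of the
penultimate exon. The 50-base boundary is inclusive (offset 50 escapes,
51 does not) — the standard reading of the heuristic, pinned by tests.
Single-exon transcripts always escape. PVS1 is withheld for escaping nulls
unless clinical LP/P cases 3′ of the variant establish that late truncation
is deleterious.

**In silico consensus.** For nonsynonymous variants, PP3/BP4 require a
strict majority of the missense tools *that made a call* (CADD, PolyPhen,
SIFT, MutationTaster); ties — including the 2–2 split — invoke nothing,
because only "majority" is defensible and a tie is not one. For synonymous
or intronic variants both splicing tools (MaxEntScan, GeneSplicer) must
agree; a single tool with a call is not concordance.

**BS1.** Whether the frequency compared against the disorder's maximum
credible frequency should come from the worst sub-population or the global
population is genuinely unresolved in practice (the phenotype prevalence
feeding the threshold may itself be population-specific), so both
behaviours are exposed as modes of `evaluate_bs1()` rather than resolved:
`subpopulation_max` models automated engines, `global` models manual
review. By construction the global mode can never fire when the
sub-population mode does not, a property the tests check on random
profiles. BA1 has no dedicated operation; it is supplied directly as an
assessment when wanted.

Strength modulation (e.g. upgrading PM3 to strong on multiple trans
observations) is not implemented: every code is used at its default
strength, which is how the discordance mechanisms are defined.

## Consensus building

A variant is high-confidence when, among *qualifying* submissions —
whitelisted submitter, assertion criteria met, dated strictly before the
cutoff ("prior to" read literally) — at least two exist and all agree at
the binary level. Two-or-more spanning both binary groups is `discordant`;
fewer than two is `insufficient`. The qualifying-submitter list is
configuration (the defaults name a synthetic pool `lab01`–`lab08`), and
assertion criteria are modelled per record rather than by the per-lab
majority heuristic a registry operator would apply; the whitelist
approximates that heuristic. High-confidence variants whose consensus
contradicts the internal laboratory's own manual call become
`lab_conflict` and are excluded from the analysis set; the funnel report
accounts for every variant exactly once
(`retained = high_confidence - lab_conflict`).

## Concordance tables and the discordance classifier

Per-variant tables weight each retained variant equally; per-case tables
weight by `case_count`, the number of tested individuals carrying the
variant. All printed percentages are per manual column, one decimal,
rounded half-up (base R's `round()` is half-to-even and produces visibly
different table entries). The two weightings bracket the clinical impact
question: a single misinterpreted common variant affects many cases, which
is why a 22.7% per-variant miss rate on positives can become a 63.4%
per-case miss rate.

The nine-mechanism classifier is a fixed priority cascade: flag-gated,
code-specific mechanisms first (automated-only PVS1 on a flagged late null;
missed-ClinVar PP5/BP6; phenotype-mismatched case criteria; sub-population
BS1 on a positive; healthy-in-population BS2 on a positive), then
manual-only literature case criteria (PM3/PP1/BS2/BP2 sourced from
literature), then manual-only functional criteria (PS3/BS3), then a
symmetric difference confined to computational codes (PM1/PP3/BP4), with
`expert_decision` as the fallback. One category per variant is a modelling
requirement; since no tie-breaking rule is otherwise defined, a fixed
priority makes the classifier deterministic and auditable, and the order
puts mechanisms with dedicated annotation evidence ahead of the generic
ones so a record never falls through to a vaguer category than its flags
support. Calling the classifier on a concordant record is an error, not a
silent "none".

Two published-count tensions are preserved, not reconciled: the per-variant
table implies 295 + 73 = 368 discordant variants while the mechanism
tabulation totals 359 (the package reports both, from separate fixtures,
and never forces them equal), and the per-case table's printed "(0.01)"
for 1,244/1,990,401 is arithmetically 0.06% — the package prints 0.1 under
its uniform one-decimal half-up rule and does not reproduce the 0.01.

The six-month currency rule for manual interpretations treats exactly six
months as expired (`re_review`), the conservative reading of a currency
window; month arithmetic clamps to the end of shorter months (31 August
plus six months is the last day of February).

## The synthetic cohort generator

The generator emulates the *statistical shape* of a year of carrier
screening so the pipeline is testable end to end without clinical data:

- a funnel with configurable high-confidence fraction (default preset
  5,548/116,721), internal-conflict rate (17/5,548) and positive fraction
  (1,299/5,531);
- submissions engineered per status: 2–5 concordant qualifying submissions
  with sub-type jitter for high-confidence variants, guaranteed
  binary-mixed sets for discordant ones, and single qualifying submissions
  (sometimes plus a record that fails exactly one qualifying filter) for
  insufficient ones — so the consensus builder reproduces the configured
  funnel exactly, a property the tests assert;
- discordance injected mechanism by mechanism. Each positive-stratum
  mechanism edits the automated view until the class genuinely flips
  (iterative removal, or addition of a conflicting benign code), because
  the combining rules are nonlinear and no single edit is guaranteed to
  flip; each edit is verified to round-trip through the classifier before
  the record is accepted. Manual criteria come from rejection sampling
  against the target class; when a sampled set cannot support the drawn
  mechanism the generator resamples, failing loudly after a bounded number
  of attempts rather than emitting a wrong record.

The mechanism-to-stratum assignment is a modelling decision: the
`atypical_phenotype` and `late_null_variant` definitions describe
automation *adding* pathogenic criteria, so they act on consensus-negative
variants (false positives); the other seven act on consensus-positive
variants (false negatives). Default rates scale the published mechanism
mix to per-stratum discordance rates of 295/1,299 and 73/4,232.

Case counts default to a log-normal (meanlog 4.77, sdlog 1.5: median ≈
120, mean ≈ 360 — the study's ≈ 362 observations per variant — and a 99th
percentile ≈ 30× the median). Only the qualitative heavy tail is
substantiated by the study, so the family is surfaced in configuration
with Zipf and point-mass alternatives; the log-normal is the default
because it is the only offered family that combines a mean near 360 with
finite variance. A truncated Zipf can reach that mean only with exponent
below 2, where the sample sum is dominated by single extreme draws and
case-weighted rates in a scaled-down cohort no longer concentrate — the
amplification direction below would then depend on the seed rather than on
the configured effect. Discordant positives receive an amplification
multiplier, default 6: with per-variant positive discordance d = 0.227, a
per-case rate of a·d/(a·d + (1−d)) ≈ 0.634 requires a ≈ 6. The preset runs
at 1/10 of the study size by default, which keeps a full
simulate–consensus–concord cycle in the low seconds while leaving every
empirical fraction estimable.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: criteria co-occurrence patterns are uniform
within classes rather than gene- or disease-structured; manual classes
within a binary stratum use fixed mixing weights (P:LP = 0.5:0.5,
VUS:LB:B = 0.6:0.2:0.2); case counts for negative variants are drawn from
the same family as positives, whereas in the study negative variants were
on average far more common than positives; and the ground-truth mechanism
is injected, so 100% classifier recovery is a round-trip contract on the
generator's edit templates, not an accuracy claim about classifying real
discordances.

## Numerical and degenerate-input choices

- Percentages: one decimal, half-up, at the table-rendering boundary only;
  all internal arithmetic is exact counts.
- Determinism: a cohort is a pure function of its configuration (the seed
  is mandatory); the generator saves and restores the session RNG state.
  Reports are byte-identical across runs on identical input.
- Rejection-sampling budgets (class sampler 1,000 draws, mechanism
  resampling 200 attempts) fail with explicit errors; no silent fallback
  ever substitutes a wrong class or mechanism.
- Empty inputs: empty submission lists are legal (`insufficient`); empty
  discordance sets tabulate to an empty table with total 0; confusion
  tables on zero records are an error, since a concordance rate of an
  empty cohort is meaningless.
- Validation failures across the TSV readers name the offending line and
  abort; the CLI converts them to nonzero exit codes.

## Known limitations

The package evaluates interpretation concordance only: no variant-effect
prediction, no annotation of real VCFs, no live ClinVar/population-database
queries, and no strength modulation of evidence codes. The discordance
classifier's priority order is one defensible linearization of overlapping
mechanism definitions; records engineered to satisfy several mechanisms at
once will be assigned the highest-priority one. Conclusions drawn from
synthetic cohorts inherit the generator's simplifications listed above.
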