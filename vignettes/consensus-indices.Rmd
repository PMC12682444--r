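---
title: "Consensus indices from use reports: conventions, reconstruction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus indices from use reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnotally)
```

## The data model and its one load-bearing convention

Everything in this package reduces to counting distinct elements of the
set of use reports: triples (informant, species, ailment category). The
single substantive convention is that a triple counts **once**, however
many preparations or phrasings an informant offered for it. This is not
cosmetic. The cultural importance index is defined as the sum over
ailment categories of the proportion of informants citing the species for
that category,

$$CI_s = \sum_c \frac{Np_{s,c}}{N},$$

which collapses to $UR_s/N$ — the use value — exactly when each informant
contributes at most one report per (species, category) cell. In the
packaged southern-Fars survey the printed UV and CI columns agree for all
31 species, which is what pins the convention down: under any
multiple-counting variant the two columns would drift apart.
`survey_dataset()` therefore deduplicates on construction (with a
warning), and `cultural_importance()` is literally `use_value()`.

The denominator $N$ is the number of informants *interviewed*, not the
number appearing in the records: interviewed informants who cited nothing
still dilute every relative index. $N$ is carried on the dataset object
and must come from the study design (here, 200), never inferred from the
records when that information exists.

## Index conventions and edge cases

The index formulas are stated in the README and the help pages; the
choices that needed making are at the edges:

* **ICF at $Nur \le 1$.** The formula $(Nur - Ntaxa)/(Nur - 1)$ is $0/0$
  for a category with a single report. We define it as 0: one report
  carries no information about agreement *among* informants. The fixture
  prints 0 for exactly these rows (fever, urinary retention, weaning),
  consistent with the convention.
* **Rounding.** Published tables round UV/RFC/CI/RI to 3 decimals and
  ICF/FL/CV to 2, with ties *up* (0.005 → 0.01). IEEE round-half-even
  would print 0.005 as 0.00 and fail to reproduce a third of the
  smallest-species rows, so emission goes through `round_half_up()`.
  Internally nothing is ever rounded; rounding happens only in
  `format_index_tables()` / `write_index_tables()`.
* **Ties in the RI maxima.** RI depends only on the maximum RFC and NU
  values, not on which species attain them, so ties need no breaking;
  RI = 1 if and only if one species holds both maxima.
* **Top choices.** The per-ailment "preferred species" table keeps all
  argmax ties rather than picking one.
* **Empty input.** An empty record set is valid (a survey before any
  interviews); all four index tables come back empty rather than erroring,
  while the scalar index functions reject genuinely undefined inputs
  (`use_value(x, n = 0)`, `choice_value(x, ntaxa = 0)`).

One property worth stating because it is easy to assume wrongly: cloning
every informant (fresh identifiers, same citations, $N \to 2N$) leaves
UV, RFC, CI, FL and RI unchanged, but **not** ICF and CV. Those are
report-count indices: doubling informants doubles $Nur$ and $Np$ while
$Ntaxa$ stays fixed, so CV doubles and ICF moves to
$(2Nur - Ntaxa)/(2Nur - 1)$, closer to 1. ICF comparisons across surveys
of different intensity are therefore not scale-free, a known property of
the index that the test suite asserts as an exact transformation law.

## Reconstructing the report matrix from printed margins

A published survey prints margins, not records: per-species FC and UR,
per-cell fidelity levels, per-ailment Nur and Ntaxa. Because
$FL_{s,c} = 100\,Np_{s,c}/FC_s$ was rounded to two decimals from an
integer ratio with $FC_s \le 58$, the rounding is injective and
half-up inversion

$$Np_{s,c} = \mathrm{round}(FL_{s,c} \cdot FC_s / 100)$$

recovers the integer cell counts exactly. The recovered matrix is then
over-determined by the other tables, which is what makes validation
possible: row sums must equal UR, column sums Nur, support sizes Ntaxa,
and the recomputed ICF and CV must equal the printed ones.

On the packaged fixture this audit passes everywhere except two places,
which `validate_margins()` reports as warnings rather than repairing:

* **urinary retention** — Crataegus aronia has FC = 2 and a single
  100%-fidelity cell, so the category must hold 2 reports, yet the
  printed Nur is 1. The same off-by-one shows up in the grand totals
  (Σ UR = 191 vs Σ Nur = 190) and in the printed ICF of 0 (2 reports on 1
  taxon give ICF = 1 — note the printed CV of 2 for this cell agrees with
  the *reconstructed* count, not the printed Nur).
* **animal bite** — only three taxa have fidelity rows (Tecomella,
  Teucrium, Periploca; 3 + 1 + 5 = 9 reports matching Nur = 9), but the
  printed Ntaxa is 5. The printed CV of 1.67 for Periploca equals 5/3,
  i.e. it too was computed with 3 taxa, so the package computes Ntaxa
  from data and flags the printed value. Whether the 5 reflects
  unprinted fidelity rows or a typo is not decidable from the tables;
  the validator reports, never repairs.

Downstream consequences of a flagged margin (the two ICF mismatches, the
grand total) are reported at `info` severity so the count of genuine
contradictions stays at two; a third `info` note marks the one printed
choice value (2/3 printed as 0.66) that appears to be rounded half-down.
Severity `failure` is reserved for structural impossibilities (a listed
fidelity cell reconstructing to zero informants, a cell exceeding its
species' FC), which a faithful transcription never triggers.

`realize_survey()` closes the loop: given feasible margins
($\max_c Np_{s,c} \le FC_s \le \sum_c Np_{s,c}$) it deals each category's
$Np$ citations to $FC_s$ per-species informant slots with a single
round-robin pointer that runs on across categories. Consecutive dealing
guarantees distinct slots within a category (since $Np \le FC$) and full
slot coverage once the pointer has wrapped (since $\sum Np \ge FC$), so
tallying the result returns the margins exactly — the round trip is
property-tested on random feasible margin sets. The construction is
deterministic and needs no randomness; its `seed` argument exists for
interface parity and is logged, not used. Informant identifiers are
namespaced per species because printed tables carry no information about
which informants were shared between species; see limitations.

## What the synthetic generator emulates

`simulate_survey()` produces datasets with the two features of real
consensus surveys that the indices lean on:

* **heavy-tailed species popularity** — weights $w_r \propto r^{-\alpha}$
  over species ranks, default $\alpha = 1.5$. The fixture's FC sequence
  (58, 14, 6, 5, 5, 5, 5, 4, …) is of this shape: one dominant cultural
  keystone, a short head, a long tail of once-cited species.
* **concentrated ailment profiles** — each species has one dominant
  category holding `dominant_share` = 0.8 of its profile mass. This
  mirrors the fixture, where 30 of 59 species-ailment cells sit at 100%
  fidelity.

Informants draw $1 + \mathrm{Pois}(0.5)$ distinct species
(popularity-weighted, without replacement; default mean 1.5) and, per
species, $1 + \mathrm{Pois}(0.35)$ categories from its profile. The
defaults are calibrated to the fixture's own totals: 140
informant–species pairs and 191 reports over $N = 200$ give roughly 1.4
species per citing informant and 1.36 categories per pair. Generation is
seeded and leaves the caller's RNG stream untouched.

`rank_recovery_experiment()` is the generator's sanity gauge: across
replicates, the Spearman correlation between true popularity weights and
observed FC. At the default survey-scale configuration the mean over 50
replicates is ≈ 0.84, and the test suite requires ≥ 0.8; with
exchangeable weights the correlation is reported as 0 by convention
(it is undefined when all weights tie).

What the generator does **not** emulate, deliberately: snowball-sampling
network structure, community or tribe covariates, informant-level
expertise heterogeneity, and correlation between a species' popularity
and the breadth of its ailment profile. Tests passing on synthetic data
therefore certify the accounting pipeline, not any sampling theory about
real surveys.

## Classifying uses against the literature

`classify_uses()` implements the three-way comparative scheme: a species
with no literature record is a *novel* use; literature present and
overlapping the local ailment categories (after both sides are normalised
through the term vocabulary) is *corroborated*; literature present but
disjoint is *divergent*. Two design points:

* The vocabulary is data (`fars_fixture("vocabulary")`), not code, and
  unmappable literature phrases are surfaced in `unmatched_terms` rather
  than dropped — an unmapped phrase can only have cost a corroboration,
  so the labels stay auditable.
* The published account names the label of only three species outright;
  the packaged per-species labels beyond those are marked
  `provisional = TRUE`, and the fixture's 9/9 divergent/corroborated
  split reflects the packaged vocabulary's matching judgments (e.g.
  grouping veterinary antiparasitic uses with the digestive category, and
  wound-infection phrases together). `fars_use_comparison()` returns the
  matcher-vs-fixture agreement column so any divergence between the two
  is a visible diff, not a silent overwrite. On the packaged tables the
  matcher reproduces the fixture exactly: 13 novel (42%), 9 divergent
  (29%), 9 corroborated (29%).

Two fixture rows are themselves synthetic and flagged as such: the
Ephedra pachyclada entry (the species appears only in the published
complex-remedy table, but is required for the 31-species / 21-family /
13 + 9 + 9 totals to close; its literature term is its widely documented
respiratory use) and the Ziziphus spina-christi literature cell, shared
with its congener in the source table's layout.

## Species synonymy

Printed tables name the same taxon inconsistently (abbreviated genus,
taxonomic synonyms, varying author strings). Resolution is table-driven
(`fars_fixture("synonyms")`) after a light normalisation, and one lumping
decision deserves its evidence: "Amygdalus lycioides" is keyed to
*Prunus eburnea* because the fidelity rows printed under the former
(40/20/40/20/80 % of FC = 5 → 2+1+2+1+4 reports) sum to exactly the UR
of 10 printed under the latter — the tables' own arithmetic confirms the
synonymy. The genus-level "Ziziphus sp." row is *not* resolvable (both
congeners have identical margins) and maps to an explicit ambiguity
(`NA` plus a flag), never a guess. Other name variants are carried
verbatim with their canonical spellings from the per-species index table.

## Problem sizes and determinism in the test suite

The suite (about 45 s end to end) uses: the full 31 × 15 fixture for all
exact reproduction checks; 200 random feasible margin sets (≤ 8 species,
≤ 6 categories) for the tally∘realize identity; 18 random small surveys
(≤ 20 informants) for brute-force oracle equality, where the oracle is an
independent base-R set-enumeration recount; and 50 generator replicates
at the default configuration for rank recovery. Every stochastic test
runs under a fixed seed; the acceptance script is deterministic from the
packaged tables.

## Known limitations

* Realized datasets model no informant overlap across species, so
  joint-citation statistics (e.g. informant-level species co-occurrence)
  are not recoverable — only the margins the indices use are guaranteed.
* ICF and CV are not informant-scale invariant (see above); cross-survey
  comparisons of these indices need comparable interview intensity.
* The divergent/corroborated boundary inherits the vocabulary's matching
  judgments; with a different vocabulary the 9/9 split can move, which is
  why provisional labels and the agreement diff are part of the API.
* The administration-route breakdown is descriptive only: its printed
  denominator is not recoverable from the tables, so the package reports
  percentages over route-tagged records and makes no reproduction claim.
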