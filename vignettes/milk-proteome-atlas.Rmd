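---
title: "Presence/absence mining of the bovine milk proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence mining of the bovine milk proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkatlas)
```

## The model

`milkatlas` treats a body of published milk-proteomics studies as a set of
binary detection experiments. Each dataset contributes a list of protein
identifications for one milk fraction at one lactation stage; nothing
about abundance is retained, because identification lists are the only
output comparable across labs, instruments and quantification schemes.
The atlas is therefore a long-format relation of (gene name, dataset)
presence pairs, and every downstream statement is a statement about set
membership.

The screening rule is *all-or-nothing identification*: a protein is a
candidate marker of a category (a lactation stage, say early lactation as
a proxy for negative energy balance, or a milk fraction) if it appears in
at least one dataset of that category and in no dataset of any other
category. Formally, with per-category union sets $S_1, \dots, S_k$, the
candidates for category $c$ are the Venn region with membership signature
$\{c\}$ — computed exactly, per element, for all $2^k - 1$ signatures.
This rule is deliberately conservative about *presence* and silent about
*absence*: a protein missing from a category may be undetectable there,
unidentified, or truly absent. The simulator (below) exists to quantify
exactly this asymmetry.

## Identifier harmonization

Source studies mix UniProt accessions, entry names and local database
IDs. Harmonization goes through a static mapping table; keys and gene
names are normalized (trimmed, internal whitespace collapsed, uppercased)
so matching is case-insensitive while symbols like `Bt.64131` survive
verbatim. Three policies govern multi-mapped identifiers: `first`
(default — one gene per identifier, which is how collapsed isoform
nomenclature behaves), `all`, and `drop_ambiguous`. Trailing isoform
suffixes (`-1`, `-2`) are stripped on a failed exact lookup, reflecting
the known loss of isoform resolution when converting protein IDs to gene
symbols. Unmapped identifiers never enter the atlas but are always
counted in per-dataset provenance; `keep_unmapped = TRUE` retains them
under a reserved `UNMAPPED:` prefix for audit.

## Classification rules

Lactation stages are intervals in days in milk (DIM): colostrum 0–5,
early 6–21, peak 22–80, mid ≥ 81, with drying-off as a separate class
keyed on days after milking cessation. Two boundary conventions were
genuinely open and are fixed as follows: DIM 81 belongs to mid (the
stage intervals must tile the non-negative integers, and the published
interval wording leaves 81 ambiguous), and a centrifugation force of
exactly 100,000 × g classifies as whey ("over" read as ≥, again for
totality). The constructor for a rule set rejects any gappy or
overlapping configuration, so totality is enforced, not assumed; users
can re-tile the axis (e.g. a 4-day colostrum window) without touching
code.

Milk fractions are defined operationally from the isolation protocol,
with precedence sucrose gradient (exosomes) > cream separation (MFGM) >
g-force split (whey at ≥ 100,000 × g, else skimmed). Precedence matters
because exosome protocols also centrifuge skimmed milk; acidification
and major-protein depletion flags are recorded but never change the
class.

## Over-representation analysis

Enrichment of a candidate list against an annotation table uses the
exact hypergeometric upper tail, accumulated in log space
(`lchoose` + log-sum-exp) so large backgrounds cannot underflow, followed
by Benjamini–Hochberg step-up adjustment implemented from its defining
formula. Both primitives are cross-checked in the test suite against
independent routes (exhaustive enumeration of all draws for every
universe of size ≤ 12, and `stats::phyper` / `stats::p.adjust` on random
instances) — the implementation never delegates to them.

Three analysis choices are configuration, because flat annotation
imports leave them open:

* **Universe.** The background for a namespace is the background genes
  carrying ≥ 1 annotation in that namespace, logged on every run.
  Unannotated genes carry no information about term membership and would
  only dilute p-values asymmetrically across namespaces.
* **Adjustment scope.** BH is applied within each GO namespace
  separately (top-50 reporting is namespace-wise); a flag switches to
  global adjustment.
* **Evidence codes.** The default whitelist is all codes; a curated
  whitelist (e.g. experimental codes only) is a parameter, not a
  hard-coded rule.

No GO-DAG propagation is applied: annotations are used as given, as in a
flat QuickGO-style import. Reported terms are those with adjusted
p < `alpha` (default 0.05), ranked by (p_adj, p_raw, term_id) — the
term_id tie-break makes report files byte-stable. Subcellular-location
flagging and protein-complex grouping run off the same annotation model
(`location` and `complex` namespaces); helpers can derive both from
curated protein-name text, where suffixes like ", mitochondrial" and
prefixes like "ATP synthase" encode the annotation.

## Biomarker selection

The final step is declarative on purpose. Upstream literature and
pathway-database mining are irreproducible web sessions, but their
per-protein outcome is transcribable, so the package consumes an
*evidence table* (tissue hits, pathway flags, literature support) and
applies an explicit rule: shortlist a candidate carrying ≥ 1 flag among
gluconeogenesis / ketone metabolism / oxidative phosphorylation / cell
proliferation *and* literature support. The rule is configurable and
monotone — adding evidence can only add candidates. On the packaged
fixtures this shortlists ACAT1, IVD, LRRC59, PCK2, SDHA and UQCRC1 from
the 59 early-lactation candidates.

## The synthetic-data generator

`synthetic_config()` describes a multi-study design: a protein universe
with a core present in every category, planted per-category exclusive
sets, and background proteins whose memberships are independent
Bernoulli(0.5) draws per category — the background exists to populate
intermediate Venn regions, which real designs produce but single-purpose
fixtures would not. Each dataset detects its category's proteins
independently with probability `p_detect`, and each emitted identifier
may be swapped for a mappable synonym (`synonym_prob`) or an unmappable
ID (`unmapped_prob`, emitted with unique `UNK_` labels so atlas
provenance reconciles exactly against generation counts).

Defaults emulate a five-stage, 35-dataset meta-analysis: 1000 proteins,
7 datasets per stage, a core of 100 (the order of the all-stages common
set), 50 planted exclusives per stage (the order of the per-stage
exclusive lists), `p_detect = 0.9`, 5% synonym and 2% unmappable
emissions. Detection dropout of ~10% per dataset and a few percent of
identifier loss are what one sees when shotgun-proteomics lists from
different labs are intersected; these values were fixed once as the
simulated study condition.

Ground truth for *exclusivity* is derived from the membership matrix: a
protein is truly exclusive to a category when its membership is exactly
that category — the planted set plus whatever background proteins landed
in a single category. Under perfect detection and zero identifier noise,
pipeline recovery of these sets is exact (this is the end-to-end oracle
in the test suite). Under dropout, a truly exclusive protein is
recovered iff it is detected in ≥ 1 of its category's $D$ datasets,
giving the closed form $P = 1 - (1 - p_{\text{detect}})^D$ for recall,
which the test suite and acceptance script verify by Monte Carlo (e.g.
$1 - 0.1^3 = 0.999$ for $D = 3$, $p = 0.9$). Precision is the quantity
dropout actually erodes: a multi-category protein detected in only one
category masquerades as exclusive. What the simulator does **not**
emulate: abundance-dependent detection (dropout is i.i.d., while real
missingness is intensity-correlated), correlated detection between
datasets of one lab, and peptide-level ambiguity. Passing tests
therefore demonstrate the correctness of the set logic and the
harmonization bookkeeping, not robustness to structured missingness in
real data.

## Numerical and reproducibility choices

* Hypergeometric tails are exact log-space sums; no normal or chi-square
  approximation is ever used.
* All randomness flows from a single integer seed per simulation; the
  same seed yields byte-identical outputs.
* Written reports sort rows and fix float formatting (6 significant
  digits), so repeated runs are byte-stable; the region signature
  canonicalization (lexicographic category order joined by `&`) is part
  of that contract.
* Venn decomposition is capped at 6 categories for named regions (the
  analysis needs at most 5); beyond that `membership_table()` produces
  the equivalent UpSet-style long form.
* Degenerate inputs are defined outcomes, not crashes: empty ID lists
  ingest to empty sets with a warning, declared-but-empty categories
  yield empty sets, an empty manifest yields a valid all-zero run, and
  precision/recall with empty denominators are 1 by convention.

Problem sizes in the test suite and acceptance script (universes of
150–300 proteins, 2–3 datasets per category, 20 exact-recovery seeds,
200 dropout replicates) were chosen so the Monte-Carlo standard error of
the checked means is far below the asserted tolerances.

## Known limitations

The atlas can only be as good as its inputs: detection lists inherit
each study's identification thresholds, and absence of a protein is
never evidence of absence in milk. Identifier conversion loses isoforms
by design. Reported category-exclusive lists are sensitive to the
category definitions — reclassifying one dataset can move every protein
unique to it — which is why the classification rules are explicit,
validated, and overridable rather than baked in. Finally, the
enrichment module deliberately reports flat-annotation results; with
DAG propagation the term counts would differ.
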