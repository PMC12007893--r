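---
title: "Cramer classification trees: models, rules and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cramer classification trees: models, rules and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cramertree)
```

## The problem

The Cramer classification scheme assigns chemicals - predominantly
food-relevant substances - to one of three ordinal hazard tiers: Class I
(lowest concern), Class II (intermediate) and Class III (highest concern).
The classes anchor threshold of toxicological concern (TTC) assessment,
where each tier carries a presumed-safe daily oral exposure limit, so a
disagreement of one class between two assessors translates directly into a
different exposure limit. The scheme exists in several forms: the original
33-question decision tree, an extended form with five additional rules, and
a revised tree that removes all reliance on expert look-up lists and screens
susceptible molecules as their hydrolysis or reduction products.

In practice, expert panels and automated implementations of these trees
disagree for identifiable families of chemicals. This package provides
three things:

1. an auditable **rule engine** in which each scheme is a data-defined
   binary decision graph over structural predicates, every classification
   returning a complete, replayable decision trace;
2. the **agreement statistics** used to quantify inter-source consistency
   (classification concordance, unweighted and linearly weighted Cohen
   kappa with confidence intervals, per-class TPR/TNR/PPV, intra-class
   concordance); and
3. a **fragment-enrichment** module that partitions jointly classified
   substances into discordance pools and ranks SMARTS fragments
   overrepresented among the disagreements, pointing the analyst to the
   rules responsible.

## The decision-tree model

A scheme is a rooted binary graph of question nodes. Each node holds a
predicate of one of five kinds:

* `smarts` - a substructure match;
* `smarts_boolean_expr` - a boolean combination (`!`, `&`, `|`) of named
  patterns from the tree's dictionary;
* `lookup_membership` - membership of an attached look-up list, decided by
  canonical structure key (stereo-aware or stereo-agnostic per list);
* `element_set` - presence of elements outside an allowed set (with `S2`
  denoting that sulphur is admitted only in divalent form);
* `computed` - a registered structural procedure (salt recognition,
  functional-group census, carbonyl wing-length measurement, aromatic
  substituent analysis, and similar conditions that are awkward as single
  SMARTS).

Yes/no edges lead to further nodes or to terminal classes. Edges may carry
transforms: the cyclic-ester rule hydrolyses a lactone on its "no" edge and
continues with the hydroxy-acid; the salt rules strip counter-ions on their
"yes" edge so the organic parent is evaluated. The revised tree
additionally applies global preprocessing transforms (acyclic ester
hydrolysis, acetal/1,3-dioxolane hydrolysis, disulphide reduction) before
traversal. When a transform fragments the structure, every organic product
is traversed separately and the terminal classes combine under the
`worst_case` policy (maximum severity). That policy is this package's
interpretation - the revised tool's combination rule is undocumented - and
it is conservative while matching the observed behaviour that ester
hydrolysis products reaching Class I yield a final Class I. Carbon-free
products (water, hydrogen sulphide, counter-ions) are skipped and noted in
the trace; a wholly inorganic input is classified as-is rather than
silently dropped.

Chemistry - SMILES parsing, canonicalisation, SMARTS matching - is
delegated to OpenBabel through ChemmineOB/ChemmineR. Canonical SMILES are
used purely as self-consistent join keys, never compared across toolkits.
Stereo-agnostic keys are derived by removing tetrahedral and cis/trans
descriptors before canonicalisation, which is what lets the
body-constituents rule accept the optical isomers its wording admits.
Transforms are implemented as graph edits on the atom/bond matrices (bond
deletions, plus one added oxygen per hydrolysed linkage), after which
connected components become the products; OpenBabel re-derives implicit
hydrogens on serialisation. One OpenBabel-specific quirk matters to rule
authors: 2-pyranones (coumarins, maltol) are perceived as aromatic, so the
shipped lactone and coumarin patterns use element-generic SMARTS with
unconstrained bond orders.

## Scheme encodings and their provenance

The three shipped schemes live as editable JSON rule graphs under
`inst/extdata/trees/`, regenerated by `data-raw/make_trees.R`. Every node
carries a `provenance` tag:

* `as_written` - the rule's behaviour is pinned by its published wording or
  by the concordance literature's rule-level analysis (the body-constituent
  rule R.1, salts at R.4, carbohydrates at R.5, heterocycle recognition at
  R.7, lactones at R.9, terpenes at R.16/R.17, the R.18 list question with
  its (a)-(h) features, the acyclic one-each census at R.20, food
  components at R.22, complex aromatic substituents at R.30, and the
  revised scheme's amended R.2/R.5/R.6/R.9/R.12/R.14/R.16/R.17/R.18 and
  R.25-R.27);
* `reconstructed` - connective topology whose exact wording is not
  available to this package; these nodes are deliberately conservative
  routers (for example "does the substance contain a ring of any kind?")
  and users can audit or replace them by editing the JSON;
* `fallback` - revised-tree nodes borrowed from the original topology with
  the list questions removed, covering regions of the revised scheme that
  its documentation does not describe.

Because the reconstructed nodes are routers rather than classifiers, the
fixture corpus - which exercises every documented rule family - classifies
correctly without tuning them; but classifications of chemistries far from
the documented families (polycyclic aromatics, polyfunctional acyclics)
lean on reconstructed routing and should be read with the trace in hand.
That is precisely what the trace is for.

Two readings of ambiguous rules are explicitly configurable:

* `ketoneChainReading` - whether the R.18 ketone condition requires a
  four-or-more-carbon chain on one carbonyl wing (`either_side`, the
  default, matching how agency experts and the major implementation read
  it) or on both (`both_sides`, available for sensitivity analysis). A
  wing qualifies only when it is a purely acyclic carbon chain - the
  "open-chained alkyl ketone" reading - so aryl and ring-bearing ketones do
  not trigger the chain rule.
* `followIntentOverBehavior` - the revised scheme follows the documented
  intent of its rules (L-amino acids recognised at R.2, salts at R.5, the
  one-each wording of R.16 applied to thiols and poly-thioethers).
  Reproducing the distributed tool's coding defects bit-for-bit is out of
  scope; instead, any traversal through a rule with a documented
  intent/behaviour conflict is recorded in the trace's divergence log
  (`revisedDivergences()`), so users can see where this implementation and
  the tool are expected to differ.

The four look-up lists (body constituents, common carbohydrates, common
terpenes, common food components) are plain-text, referenced and
user-replaceable; the shipped versions are deliberately compact and carry
the compounds the concordance literature names (the twenty proteinogenic
L-amino acids and core metabolites; common sugars; the documented terpene
alcohols; the five heterocyclics known to reach Class II by membership).
They are read stereo-agnostically. A fuller in-house list can be dropped in
via `originalSchemeConfig(lookupDir = ...)` without touching code - the
package treats the food-components list in particular as an evolving
document, not a constant.

## Agreement statistics

For two sources over their shared substances the package computes, from
the 3x3 confusion matrix:

* **classification concordance** - the diagonal fraction, as a percentage;
* **Cohen kappa**, unweighted and with linear weights
  `w_ij = 1 - |i - j| / 2` on the ordinal scale I < II < III. Linear
  weighting is fixed by verification: from the published inter-scheme
  confusion matrix the linear form reproduces the published weighted value
  (0.525) while quadratic weights do not (0.591) - the discriminating check
  is part of the test suite. The standard error is the asymptotic
  large-sample (non-null) form, and intervals are `estimate +/- z se`;
  published intervals are matched to within 0.005 since the originating
  CI formula is not stated;
* **intra-class concordance** - for each class, the intersection over
  union of the two sources' assignments, as a percentage;
* **per-class TPR/TNR/PPV** - one-vs-rest metrics treating either source
  as reference.

All of these are validated in the test suite against independent oracles
that expand the matrix into labelled rating pairs and count directly.
Report output rounds half-up to one decimal (percentages) and three
decimals (kappa).

## Fragment enrichment

Shared substances are divided into seven pools: concordant, plus the six
directional discordance pools I->II, I->III, II->I, II->III, III->I,
III->II. Each SMARTS feature of a fingerprint library is tested pool by
pool against the concordant pool (the alternative, pool versus all other
shared substances, is selectable) with a Pearson chi-square on the 2x2
presence/absence table, no continuity correction. Cells with expected
counts below five are flagged, not silently re-tested; the ranking that
guides manual review is by statistic, with Benjamini-Hochberg adjusted
p-values reported alongside the raw ones. The shipped library
(`inst/extdata/toxprint_mini.tsv`) is a compact set of fragments covering
the families most often implicated in disagreement; any library in the
same two-column format - including a full chemotype set - can be supplied.

## The fixture corpus and what passing it shows

`loadFixtures()` returns 53 named compounds spanning the documented
disagreement families (ketones, thiols/thioethers/polysulphides, lactones,
amino acids, salts, complex aromatics, ethers, terpenes, secondary and
tertiary alcohols, heterocycles, isothiocyanates, vicinal diketones,
alpha,beta-unsaturated carbonyls, allyl esters, carbohydrates,
1,3-dioxolanes). Each entry stores the documented expert class (where one
exists) separately from per-scheme expected classes - the two legitimately
disagree, and that disagreement is the corpus's subject matter, so no
single "truth" is forced. Expectations are recorded only where the
documentation pins them down.

`generateSeries()` supplies deterministic homologous series (linear methyl
ketones, alkyl thiols, 4-alkyl dioxolanes, allyl alkanoates, amino acids)
for property-style tests: totality and trace replay, the single I/II
boundary along the ketone series, transform atom bookkeeping (one oxygen
gained per hydrolysed linkage, exact conservation under reduction), and
enantiomer invariance at the body-constituent rule.

Passing the corpus shows that every rule behaviour the concordance
literature documents is encoded faithfully; it does not show that the
reconstructed connective topology matches the unpublished original in
regions no fixture exercises, nor does it predict agreement rates on the
full multi-thousand-compound inventories, which depend on list contents
and on chemistry outside the corpus.

## Numerical and degenerate-input choices

* Ties and traversal order are impossible by construction: the graph is
  binary, acyclic (validated) and predicates are pure, so classification
  is deterministic end to end; there is no randomness anywhere in the
  engine.
* Kappa with degenerate marginals (expected agreement 1) is an error, not
  an NA; intra-class concordance for a class absent from both sources is
  an error at the operation level and NA in the assembled report panel.
* Transform loops are bounded (a fixpoint guard and a per-path transform
  budget) so a pathological rule definition fails loudly instead of
  spinning.
* Substances without a defined structure (empty or unparseable SMILES,
  wildcard/polymer markers) are retained for expert-vs-expert statistics
  and emit NA from classification, with the skip reason reported.
* Problem sizes in the shipped tests are chosen to exercise every branch
  at small scale: tens of compounds per scheme, series of up to eight
  homologues, random 3x3 matrices with Poisson counts for the statistical
  oracles.

## Known limitations

* The original tree's verbatim question wordings beyond the documented
  rules are not redistributable here; connective nodes are reconstructions
  (tagged as such) and polyfunctional or polycyclic chemistries lean on
  them.
* The revised scheme is encoded intent-first; users comparing against the
  distributed tool should expect divergences exactly where the divergence
  log reports them.
* Look-up lists ship compact. Class II/III outcomes that hinge on food-
  component membership will follow the supplied list, and a substance
  missing from it lands one class higher than an expert who considers it a
  common food component would assign - the central subjectivity the
  agreement statistics are designed to expose, not a defect the package
  can remove.
* The acetal transform classifies all organic products including the
  liberated carbonyl unit; for small aldehydes this is inconsequential
  (they reach Class I), but the choice is a policy, selectable in
  principle by editing the preprocessor list.
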