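# cramertree

An auditable R implementation of the Cramer classification scheme - the
decision tree behind threshold of toxicological concern (TTC) chemical
categorisation - together with the statistics needed to quantify, and the
decision traces needed to localise, disagreement between classification
sources.

## Who this is for

Risk assessors and computational toxicologists who classify (mostly
food-relevant) chemicals into Cramer Class I/II/III, compare assignments
coming from different expert panels or software implementations, and need
to know *which rule* caused two sources to part ways - not just how often
they disagree.

## What it implements

**Three schemes as editable rule graphs.** The original 33-question Cramer
tree (with the four expert look-up lists: body constituents, common
carbohydrates, common terpenes, common food components), its five-rule
extension, and the revised Cramer decision tree, which uses no look-up
lists and instead screens susceptible molecules as breakdown products:
acyclic esters and acetals/1,3-dioxolanes are hydrolysed, disulphides
reduced, lactones hydrolysed at the cyclic-ester rule itself. Each scheme
is a JSON rule graph over SMARTS predicates, boolean pattern expressions,
look-up membership, element constraints and registered computed
conditions; chemistry runs on OpenBabel via ChemmineOB. Every
classification returns a `DecisionTrace`: the ordered (rule, answer) path
per fragment, replayable through the graph, with breakdown-product classes
combined worst-case. `locateDivergence()` compares two traces and names
the first rule answered differently.

**Agreement statistics.** For any two assignment sources over shared
substances: classification concordance; Cohen kappa, unweighted and with
linear weights on the ordinal scale (`w_ij = 1 - |i-j|/2`), with
asymptotic standard errors and confidence intervals; per-class TPR, TNR
and PPV; and intra-class concordance, the intersection-over-union of each
class's assignments.

**Fragment enrichment.** Shared substances are split into seven pools
(concordant plus six directional discordance pools, e.g. I->III); SMARTS
fingerprint features are chi-square-tested pool-by-pool against the
concordant pool to rank the fragments overrepresented among disagreements.

**A documented fixture corpus.** 53 compounds spanning the chemical
families known to drive inter-source inconsistency (alkyl ketones,
thiols/thioethers/polysulphides, lactones, amino acids, salts, complex
aromatics, ethers, terpenes, alcohols, heterocycles, isothiocyanates,
vicinal diketones, alpha,beta-unsaturated carbonyls, allyl esters,
dioxolanes), each with its documented expert class and per-scheme expected
classes, plus deterministic homologous-series generators for property
tests.

## Worked example

```r
library(cramertree)

## classify one substance under the revised scheme, with full audit trace
tr <- classifyRevised("CC(=O)OCC=C", substance = "allyl acetate")
tr
#> DecisionTrace [revised] allyl acetate -> Class III
#>   CC(=O)O  [R.2:yes] -> I
#>   OCC=C  [R.2:no R.3:no R.4:no R.6:no R.7:no R.23:no R.16:yes R.17:yes] -> III
```

The ester is hydrolysed during preprocessing; acetic acid reaches Class I
as a simple linear acid (R.2), while allyl alcohol answers "yes" at the
revised allyl-alcohol rule (R.17) and lands in Class III. The worst-case
combination makes the final verdict Class III - one class more severe than
the original scheme, which places allyl esters in Class II at its R.18
list question.

```r
## agreement statistics from a published inter-scheme confusion matrix
cm <- cramerConfusion(matrix(c(1570, 154, 164,
                               154,  40,  40,
                               208, 313, 612), 3, 3, byrow = TRUE),
                      "toxtree_original", "toxtree_revised")
overallConcordance(cm)        # 68.3 (% of 3255 shared substances agreeing)
cohenKappa(cm, "linear")
#> Cohen kappa (linear weights): 0.525  [0.500, 0.551] (95% CI), n = 3255
cohenKappa(cm, "none")
#> Cohen kappa (none weights): 0.431  [0.406, 0.455] (95% CI), n = 3255
round(intraClassConcordance(cm), 2)
#>     I    II   III
#> 69.78  5.71 45.77
```

The Class II row is the striking one: only 5.71% of the Class II
assignments issued by the two schemes coincide - Class II membership is
where the original and revised trees disagree most.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/cramer.R classify --scheme original --in substances.csv \
        --out classified.csv --trace traces.jsonl
Rscript inst/cli/cramer.R compare --in unified.csv --a FEMA --b JECFA \
        --out stats.json
Rscript inst/cli/cramer.R enrich --in unified.csv --a expert --b revised \
        --out enrichment.csv
Rscript inst/cli/cramer.R fixtures --schemes original,extended,revised
```

See `vignettes/cramer-classification.Rmd` for the model description, the
provenance of every encoded rule, the configurable ambiguous readings, and
known limitations.

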