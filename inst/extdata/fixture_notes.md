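# Fixture corpus notes

Each fixture entry's `citation` field keys into a section below. The notes
summarise, in this package's own words, why the documented expectation holds
for each compound family; they are the audit trail connecting the corpus to
the concordance literature on Cramer classification. Where an expert class
and a scheme expectation disagree, both are stored - the disagreement itself
is what the corpus documents.

## ketones

Open-chained alkyl ketones are decided by the chain-length condition of the
original scheme's R.18 list: a carbonyl wing of four or more carbons earns
Class II under the prevailing "either side" reading, which agency experts
and most tool users apply. Hex-5-en-2-one, 3-methylpentan-2-one and
hexan-2-one all bear a qualifying wing and are anticipated Class II under
the original rules. The revised scheme instead places linear alkyl ketones
in Class I irrespective of chain length; by its wording cis-5-octen-2-one
and 6-methylheptan-3-one also belong in Class I (the distributed tool's
Class III verdicts for gamma-substituted ketones appear unintended and are
logged as divergences, not reproduced).

## sulphur

Under the original R.20 a single thiol or a single thioether is compatible
with a "yes" answer and a Class I outcome (propane-1-thiol, methyl propyl
sulphide); duplicated groups fail the one-each condition and drift to Class
III (propane-1,3-dithiol, 2,4-dithiapentane), although experts placed the
di-forms in Class I. The revised R.16 treats thioethers as the original
does but admits thiols only alongside other functionality, so pure thiols
reach Class III while pure thioethers reach Class I. The extended scheme's
divalent-sulphur rule reassigns simple sulphides to Class III.

## polysulphides

The original R.20 list admits one polysulphide unit, so acyclic
disulphides as written reach Class I, agreeing with experts. The revised
scheme reduces disulphide bonds before classification; the resulting
multi-thiol products fail its stricter thiol condition and end in Class
III. Cyclic polysulphides (1,2,4-trithiolane,
3,6-dimethyl-1,2,4,5-tetrathiane) were judged Class II by experts, fall to
Class III through the original tree's heterocycle branch, and - following
the wording of revised 16(c) for their reduction products - also end in
Class III under the revised scheme (the distributed tool's Class I outcome
for them is a documented coding anomaly).

## lactones

The original R.9 sends alpha,beta-unsaturated or ring-fused lactones
straight to Class III and hydrolyses the rest for judgment at R.20; as
written, the saturated gamma-lactones here (with primary, secondary or
tertiary alcohol products) all reach Class I, matching expert judgment.
The revised R.9 is narrower: only phthalides and coumarins earn automatic
Class III, all other lactones being classified as their hydrolysis
products, almost always Class I.

## amino-acids

The original R.1 admits normal body constituents and their optical
isomers, so the proteinogenic L-amino acids classify Class I through the
body-constituents list; agency experts nonetheless preferred Class III for
several L-forms (reserving Class I for racemates), which is the stored
expert judgment. The revised R.2 is intended to recognise all L-amino
acids (and simple linear alkyl alcohols, acids and aldehydes) as Class I;
the distributed tool's failure to do so is a documented defect, so
intent-mode classifies L-alanine as Class I.

## salts

The original R.4 is meant to recognise common salt forms - metallic
carboxylates and sulphonates such as calcium lactate and sodium dodecyl
sulphate answer "yes" and continue as the parent acid - whereas an
un-ionised organo-sulphonic acid such as taurine answers "no" and is
assigned Class III.

## complex-aromatics

The original R.30 separates substituted benzenes by substituent
complexity: nitrogen or sulphur in any form, or carbon chains beyond five
carbons not reducible by ester hydrolysis, are complex.
1,4-Benzenediamine is therefore flagged and reaches Class III (the
inoperative rendering in distributed tools understates it); benzyl octyl
ether's long ether chain likewise keeps it out of Class I in both schemes.

## ethers

The original R.20 list does not admit ether linkages, so open-chain ethers
drift toward the food-component question and Class II/III. The revised
R.16 gives the group explicit consideration: methoxy and ethoxy units may
answer "yes" provided all other conditions hold, which carries prenyl
ethyl ether to Class I, while aromatic ethers are caught by the revised
aromatic-complexity rules.

## terpenes

Common terpenes answering R.16 "yes" and bearing only typical terpene
functionality reach Class I, matching the expert Class I judgments for
linalool and nerolidol (tertiary alcohols that distributed tools
mishandled); the shipped terpene list carries the compounds the
concordance literature names.

## alcohols

As written, R.18(b) does not fire on mere secondary alcohols, and tertiary
alcohols route onward through R.20/R.24 rather than defaulting to "no";
simple secondary and tertiary alkyl alcohols therefore classify Class I,
in line with expert judgment (the distributed tools' Class II/III verdicts
for them are documented faults, not reproduced).

## heterocycles

Simple heterocycles answer "no" to the structure questions of the original
heterocycle branch and survive only through the food-components list:
the five listed heterocyclics (2-methylpyrazine, 2,5-dimethylpyrazine,
nicotinic acid, maltol, ethyl maltol) reach Class II by membership, while
unlisted members such as furfural or 2-methyltetrahydrofuran fall to Class
III. The revised scheme, which has no lists, re-routes simple (especially
non-aromatic) heterocycles into Class II.

## isothiocyanates

Isothiocyanates match no list shipped with the tools and no revised-scheme
condition, so both schemes leave them in Class III, though experts treated
many as common food constituents (Class II).

## diketones

Saturated alkyl 1,2-diones exceed the one-ketone allowance of R.20 and,
absent from the food list, land in Class III under the original scheme;
the revised scheme reaches the same verdict through its vicinal-diacetyl
condition at R.18. Experts favoured Class II.

## ab-unsaturated

The original scheme flags only a short list of alpha,beta-unsaturated
carbonyls (acrolein-type aldehydes, acrylic acids, terminal vinyl
ketones) for Class II; cinnamaldehyde and the rose ketones fall outside it
and reach Class I. The revised R.18 broadens the condition to any
alpha,beta-unsaturated aldehyde or ketone with no or one beta-carbon
substituent, moving exactly these families to Class II.

## allyl

The original R.18 lists allyl alcohol and its acetal, ketal or ester
derivatives for Class II; the revised scheme regards allyl alcohol and its
esters as warranting Class III, reached after the global ester hydrolysis
liberates allyl alcohol itself.

## carbohydrates

Common carbohydrates answer R.5 (and the body-constituents rule) for Class
I; glucose is the canonical member.

## dioxolanes

The revised scheme hydrolyses the 1,3-dioxolane unit during preprocessing
and judges the 1,2-diol product: when both hydroxyls are secondary the
diol is oxidisable to a vicinal dione and triggers Class III; a diol with
at least one primary or tertiary hydroxyl escapes the condition and the
substance reaches Class I. Under the original scheme the intact dioxolane
is simply a non-aromatic heterocycle headed for Class III.
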