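---
title: "Dissecting chemokine-receptor selectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting chemokine-receptor selectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemodissect)
```

## The problem

Chemokines are small secreted proteins with a conserved fold (a
disulfide-stapled core, three β-strands, a C-terminal helix and a
disordered N-terminus) that signal through class A GPCRs. The family is
promiscuous in a structured way: CC chemokines activate CC receptors,
CXC chemokines CXC receptors, and within a subfamily some pairs are
exclusive while others share many partners. Understanding which residue
positions encode that selectivity requires comparing *structurally
equivalent* positions across paralogs, orthologs and complexes — which
is what this package mechanizes: a common numbering layer, conservation
and subfamily-discrimination scores per position, contact fingerprints
across complex structures, motif discovery in the disordered regions,
and variant/network summaries, all expressed against the common
numbering.

## Common numbering (CCN / CRN)

Chemokine columns are labeled `SSE.index` over the fixed SSE vocabulary
`NTc, CX, cxb1, B1, b1b2, B2, b2b3, B3, b3h, H, CT`. Loops are named by
the flanking strands in lowercase. A documented inconsistency exists in
the field's prose about whether the "30s loop" is `b1b2` or `b2b3`; we
take the label usage (`b1b2` connects β1 and β2) as authoritative and
note the conflict here rather than guessing intent.

Two conventions handle the regions where columns are not structurally
equivalent:

* **Cm stacking.** Disordered N-termini are indexed backwards from the
  first disulfide-bonding cysteine: the column immediately preceding
  the anchor is `NTc.Cm1` (receptors: `NTr.Cm1`). Stacking is gap-free
  by construction once the alignment is projected onto an
  insertion-free reference, so the k-th residue before the anchor is
  always `Cm k`. One human receptor (CXCR6) lacks the anchor cysteine;
  `assign_labels()` warns and proceeds rather than failing.
* **Cp indexing.** The receptor ECL2 alignment is only structurally
  meaningful at the conserved cysteine block `45x50-45x52`; columns
  after it are collapsed C-terminally and labeled `ECL2.Cp3, Cp4, ...`
  (starting at 3 because the block ends at x52). Pre-anchor ECL2
  columns are passed through as `ECL2.1-ECL2.13` and are excluded from
  conservation scoring; `extract_region()` never includes the anchor
  block in fragment enumeration.

Base GPCRdb numbers (`1x22`, `7x24`, ...) are consumed from the span
configuration rather than recomputed: reconstructing GPCRdb's
structure-based assignments is out of scope, and treating them as
configuration keeps the module testable. Coordinates are 1-based and
inclusive throughout, matching PDB author numbering; the gap symbol is
`-`, and `x` is reserved for gapped fragment patterns.

## Conservation: the trident score

Each column is scored
$(1-t)^a (1-r)^b (1-g)^c$
with $t$ the Shannon entropy of the residues (gaps excluded) normalized
by $\log\min(20, d)$ at column depth $d$ (so shallow ortholog sets stay
in $[0,1]$), $r$ the mean stereochemical distance of residues to the
column consensus, and $g$ the gap fraction. Distances derive from
BLOSUM62 normalized to unit self-similarity,
$d(a,b) = 1 - B(a,b)/\sqrt{B(a,a)B(b,b)}$, clipped to $[0,1]$.
Exponents default to $(a,b,c) = (1, 0.5, 3)$ and are recorded in the
profile's provenance attributes. The original trident software's exact
defaults are not restated anywhere we can consume, so absolute scores
here may differ slightly from other implementations; every analysis
that consumes conservation does so through thresholds (≥ 0.5 filters),
which is the surface the tests pin down. Ties for the consensus residue
break alphabetically for determinism; all-gap columns score 0 and are
flagged.

## Subfamily scores and prediction probabilities

For one position at a time, sequences are encoded by a single
categorical feature (one indicator per observed symbol; the gap is a
symbol) and a two-class logistic regression separates CC from CXC.
Because CC sequences outnumber CXC, the majority class is down-sampled
to the minority count before an 80/20 split; `floor(0.8 c)` per class
goes to training. With the family-scale class sizes of 421 and 226 this
yields 672/170 and 360/92 train/test sequences. Scoring requires the
training split to contain every residue that appears in test; when it
does not, the split seed is advanced deterministically (seed + 1, at
most 100 attempts, blind to accuracy) and a position whose residues
cannot be covered — e.g. a symbol private to one sequence that keeps
landing in test — is flagged `uncoverable` and excluded.

With indicator encoding the logistic coefficients decouple per symbol,
so the fit reduces to independent one-dimensional Newton solves with a
small ridge term ($\lambda = 10^{-4}$) that regularizes
quasi-separation. The reported metric is test accuracy, which is
insensitive to $\lambda$ (it only nudges probabilities toward 0.5, not
across it, for any sane magnitude). Predicted class is CXC iff
$p > 0.5$; exactly 0.5 resolves to CC for determinism. Replicate seeds
default to (1, 2, 3) and are recorded. The *subfamily score* of a
position is the mean accuracy over replicates; ≥ 0.75 flags it
subfamily-predictive.

The same per-position models evaluated on a query sequence give
*prediction probability scores* in $[0,1]$ (0 → CC-like). A query
residue unseen in training is reported as undefined, never imputed.
`classify_interface_character()` then summarizes a query's
contact-making, subfamily-predictive positions into %CC-like versus
%CXC-like (probabilities of exactly 0.5 counted in neither bucket).

## Contacts, fingerprints and filters

Two residues are in contact when any pair of their heavy atoms (any
non-hydrogen atom record — toy complexes are Cα-only) lies within a
cutoff, 5.0 Å by default. The study this design follows used a
third-party contact service with typed interaction rules that are not
restated; a plain distance cutoff is transparent, configurable and
equivalent for threshold-level analyses, but dataset-wide contact
totals from real structures are not comparable across the two
definitions and are not claimed here. Percentages in report output are
rounded half-up to integers.

The *contact fingerprint* is a boolean matrix of unique (CCN, CRN)
pairs × complexes. Near-redundant complexes of the same ligand-receptor
pair can be declared a *composite*: their columns OR together and count
once in consensus analyses. Filters implemented:

* conserved contacts: both sides' paralog conservation ≥ 0.5 (strict
  both-sides rule; a missing score counts as non-conserved and is
  logged);
* consensus subfamily contacts: present in a majority of one
  subfamily's complexes (`floor(n/2) + 1`, i.e. 3 of 5 CC and 2 of 3
  CXC at the study's column counts) and absent from the other's — the
  CC and CXC sets are disjoint by construction;
* preserved-but-variable contacts: present in strictly more than
  `min_complexes` columns with at least one side ≤ 0.5;
* diversification by region: contacts present in fewer than half the
  columns with both sides poorly conserved (the prose reading "composed
  of poorly conserved chemokine and GPCR residues" is taken as *both*
  sides; an either-side switch is provided), tabulated per SSE and SSE
  pair.

Pairwise complex comparison reports
$100 \cdot |A \cap B| / |A \cup B|$ over unique pairs and the mean of
ligand and receptor percent identity over *interface positions* — any
position contacting in any loaded complex, a universe computed once per
fingerprint. Gapped positions count as mismatches.

Structural variability uses receptor-anchored least-squares
superposition (bio3d's Kabsch-style fit) over shared-CRN Cα atoms,
then reports per-shared-CCN Cα deviations; ligand-anchored mode
measures the receptor side. At least three shared anchors are required.

## SLiMs

Fragments are all contiguous 2/3/4-mers of an unstructured region plus
gapped shapes (`x` at position 2 of 3-mers; positions 2, 3 or both of
4-mers), deduplicated per sequence. Ortholog conservation of a fragment
is the fraction of a protein's ortholog sequences containing it, each
sequence counted once — ECL2's pre- and post-anchor segments are pooled
per sequence before counting. A fragment at ≥ 0.5 ortholog conservation
is a *putative SLiM*. The reference (human) sequence counts in the
denominator like any other ortholog. Non-standard residue letters are
rejected at input rather than silently wildcard-matched. Fragment
fingerprints (presence across paralogs) summarize sharing: unique to
one paralog versus shared by ≥ 5.

## Variants, mutational scans, network

Variant rows map through per-gene residue→label tables into exactly one
of {labeled, unlabeled, error} buckets; reference-residue mismatches
against a supplied sequence are flagged and retained with the table's
residue as consensus. Interface variation is the per-gene sum of allele
counts (homozygotes pre-counted twice upstream) or frequencies at
interface positions — the two metrics are never mixed. Mutational-scan
substitutions average their replicates; a position's scalar for
structure painting is the absolute mean across substitutions and
replicates (depletion marks functional importance). Position
comparisons use the tie-corrected Kruskal–Wallis test with post-hoc
Dunn z tests, Bonferroni-corrected over all reported pairs; constant
data yields p = 1 with a flag. The phenotype-association threshold
defaults to p < 1e-8.

Network edges carry interaction strength 0–3 and evidence grade A–D;
the default filter keeps pairs with some edge of strength ≥ 2 and grade
C *or better* (the inclusive reading; exact-grade matching is a
switch). The subfamily-coupling test is a plain Pearson χ² (no
continuity correction) on like/unlike × interacting/not counts over
CC/CXC-tagged proteins.

## The synthetic system

The generator emulates the study conditions rather than realistic
evolution: 26 CC + 17 CXC paralogs with 22 orthologs each (≈ a thousand
sequences, matching the real master-alignment scale), a 51-column
chemokine-like layout with a 5-column stacked N-terminus and the anchor
cysteine at `CX.1`; conserved columns are invariant, discriminative
columns draw marker residue $r_1$ vs $r_2$ with class-conditional
probability $(1+d)/2$ at divergence $d$ (so $d$ equals the
class-conditional total variation), and neutral columns draw i.i.d.
from an eight-letter pool with a 2% gap rate. Motif regions plant each
paralog's 3-mer into exactly $\lceil \text{rate} \cdot n \rceil$
ortholog N-termini — deterministic planting, not Bernoulli sampling, so
threshold tests at the 0.5 boundary are exact — and draw motif and
background letters from disjoint alphabets, which excludes accidental
matches by construction (stronger than rejection sampling, and
checkable). Toy complexes place Cα chains on parallel lines 40 Å apart
with 10 Å spacing and move each planted receptor partner to
cutoff − 1 Å of its ligand residue, leaving all other cross-chain pairs
beyond cutoff + 2 Å; planted contact sets are therefore recovered
exactly. Tables (variants, scans, edges) carry their planned summaries
alongside.

What passing on this system does *not* show: robustness to alignment
error, phylogenetic correlation between orthologs (sequences here are
exchangeable within a class), realistic contact geometry, or the typed
interaction chemistry of real interfaces. Those caveats apply to any
claim transferred to real data.

## Problem sizes and determinism

Tests and the acceptance script run the classifier at class sizes of a
few hundred sequences (test sets of ≥ 80, where binomial noise on an
accuracy is below ±0.06) and property checks on dozens of regenerated
fixtures; these sizes make the whole suite complete in a few minutes on
one core while keeping every threshold test exact. All stochastic steps
take explicit seeds; the pipeline writes no timestamps, so two runs
from one configuration are byte-identical, which the suite asserts.

## Known limitations

* Absolute trident scores depend on the pinned exponents and matrix;
  only thresholded behavior is guaranteed against other
  implementations.
* The distance-cutoff contact definition is not the typed-interaction
  definition used by structure services; real-structure contact totals
  will differ.
* CRN base numbering is consumed, not derived; a wrong span
  configuration produces consistently wrong labels (validated only
  against the anchor-cysteine check).
* The classifiers are single-position by design and cannot see
  epistasis between columns; that is the intended granularity, not an
  oversight.
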