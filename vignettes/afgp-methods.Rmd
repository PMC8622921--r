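---
title: "Methods: annotating and simulating AFGP gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and simulating AFGP gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afgpkit)
```

## The biological model

Antifreeze glycoproteins (AFGPs) of codfishes are polymers of a single
glycosylated tripeptide, (Thr-Ala/Pro-Ala)~n~, carried on a galactosyl-N-
acetylgalactosamine disaccharide O-linked to each threonine.  The gene
encodes one long polyprotein: a signal/propeptide leader, then an imperfect
tandem array of 9-nt units each coding one tripeptide, then a short
characteristic C-terminus.  Occasional substitution of the unit's leading
Thr codon (predominantly ACA) by AGA (Arg) or AAA (Lys) plants trypsin-like
cleavage sites inside the array; post-translational cleavage at the carboxyl
side of these basic residues releases the individual size isoforms observed
in blood serum, from AFGP8 (four repeats) up to polypeptides of fifty or
more repeats.

`afgpkit` turns that gene architecture into a testable annotation pipeline:
locate and frame the repeat tract, decide whether a gene copy is intact,
enumerate cleavage sites, predict the mature isoform inventory and its
masses, quantify the codon usage of the repeat positions, and reconstruct
the family's duplication history from the non-repetitive flanks.  A
ground-truthed simulator generates families under the mechanisms believed to
drive the system — slipped-strand mispairing, point substitution, whole-gene
duplication, pseudogenization — so that every stage can be validated against
known truth without external data.

## Repeat-tract detection

The scanner (`find_repeat_region()`) tiles the CDS into 9-nt units at every
phase offset (0–8 nt) and classifies each unit from its translation:
Thr-led units with Ala/Pro at position 2 and Ala at position 3 are repeats
(`TAA`, `TPA`); Arg/Lys-Ala-Ala units are spacers (`RAA`, `KAA`); everything
else is `OTHER`.  It returns the run of consecutive units maximising the
number of classifiable units subject to

* at least `min_units` units (default 4, the smallest observed isoform),
* a fraction of `OTHER` units at most `max_other_frac` (default 0.1), and
* classifiable units at both ends (boundary `OTHER` units are trimmed).

Ties are resolved by leftmost start, then by longest run, making the result
deterministic.  Two design points deserve emphasis:

* **All nine phases, not only the annotated reading frame.**  A frameshift
  indel upstream of the repeats shifts the tract out of the annotated codon
  register while leaving the tract itself intact.  Scanning all nine phases
  lets the tract define its own register; whether that register agrees with
  an open reading frame is judged afterwards by the classifier.  This is
  what allows a 1-nt deletion upstream of the repeats to be recognised as a
  frameshift pseudogene rather than reported as a gene with no repeats.
* **The impurity tolerance is a modelling choice.**  Real tracts are
  "imperfect" but no purity threshold is measurable from a handful of loci;
  0.1 keeps recently degraded units inside the tract while refusing to
  bridge long non-repetitive interruptions.  It is a configurable parameter
  everywhere it matters.

The test suite holds the scanner to an exhaustive enumerator that scores
every (phase, start, end) triple independently, on a thousand random and
planted-tract sequences.

## Gene classification

`classify_gene()` calls a record functional when an uninterrupted reading
frame runs from a start codon through at least `min_leader_nt` (default
30 nt) of non-repetitive coding sequence, across the whole repeat region, to
a downstream in-frame stop.  Failures are named in a fixed order:

1. `coding_insertion` — after masking the main tract, a second qualifying
   tract at least `insertion_min_nt` away (default 500 nt) betrays a long
   interrupting insertion.  The default is far below the one observed
   6.5-kbp case on purpose: any tract long enough to disrupt the CDS
   qualifies.
2. `five_prime_truncated` — no start codon with a sufficient leader exists
   upstream of the repeats.
3. `frameshift_indel` — a start codon exists, but the repeats are out of
   register with it or a premature stop intervenes.

Records with no detectable tract are reported `non_AFGP` rather than
raising an error, so mixed inputs pass through cleanly.

## Cleavage, digestion, masses, bins

`find_cleavage_sites()` emits `single_Lys` for every Lys-Ala-Ala unit and,
for Arg-Ala-Ala units, `RAAR` when the following unit begins with Arg (the
four-residue Arg-Ala-Ala-Arg motif spans the unit boundary) or `single_Arg`
otherwise; overlapping RAAR motifs resolve leftmost-first.

`digest_polyprotein()` assumes exhaustive cleavage.  Spacer units are
treated as excised linkers: products are the maximal runs of non-spacer
units, and a product's repeat count is its number of Thr-led units.  This
excision convention is the only arithmetic consistent with the observed
isoforms — AFGP8 is four Thr-led repeats, and purified AFGPs contain almost
no Lys — but a `retain_linkers` flag provides the cut-only alternative.
Whether an RAAR site releases its internal Ala-Ala dipeptide is not
observable from the gene sequence; excising the whole spacer is the
modelling choice here.  Unit conservation (products + linkers + unreported
all-`OTHER` fragments = tract) is asserted on every call.  Fragments with
one to three repeats are reported and binned `sub_AFGP` instead of being
silently dropped.

`peptide_mass()` uses standard average residue masses (T 101.10, A 71.08,
P 97.12, R 156.19, K 128.17 Da), one water (18.02 Da), and one dehydrated
disaccharide (365.33 Da) per Thr:

```{r masses}
m <- mass_model()
sapply(c(4, 9, 33, 53), function(n) peptide_mass(strrep("TAA", n), m))
```

These sit within 10% of the historical "~2.6 kDa / ~5.4 kDa / ~20 kDa /
~32 kDa" figures; the residual discrepancy reflects rounding in those
figures and the two-to-four unmodelled C-terminal residues, which is why
comparisons against them use a ±10% band.  `assign_isoform_bin()` maps
products to the historical gel bins: repeat count decides AFGP8 (4) and
AFGP7 (5); larger products are binned by mass, with 9.2 kDa — the midpoint
of the gap between the AFGP6 group's upper edge (7.9 kDa) and the AFGP1–5
group's lower edge (10.5 kDa) — as the boundary.  Six-repeat products fall
slightly below the nominal 4.2 kDa edge of the AFGP6 gel range and are
assigned to the AFGP6 group, since the 6–8 repeat ladder is continuous on
gels.

## Codon usage

`position_codon_counts()` accumulates the codon observed at each of the
three tripeptide positions over all units of a tract, reporting
position-conditional frequencies.  `OTHER` units are excluded by default so
that degraded units in pseudogenes do not contaminate the repeat statistics;
`include_other = TRUE` restores raw counts (and is what a sampling check
against a generating distribution should use, since exclusion correlates
the positions).  `codon_bias_flags()` reports synonymous codons that are
absent (count zero while the amino acid is observed) or depleted (below a
2% synonymous share, configurable) — the pattern of missing ACG (Thr,
position 1) and CCC (Pro, position 2) characteristic of these tracts
surfaces as ordinary flags.

`usage_distance()` quantifies similarity between genes as the mean over
positions of the total-variation distance between their codon
distributions: symmetric, zero iff identical, 1 when the codon sets are
disjoint at every position.  A bounded, interpretable metric was needed
because the underlying observation ("similar usage in recent duplicates")
is qualitative.

## Family history from the flanks

The repeat tract itself cannot be aligned with confidence, so evolutionary
analysis uses the non-repetitive ends: the 5' flank plus leader, and the 3'
flank.  `pairwise_distance()` computes p or Jukes–Cantor distances under
pairwise deletion of gap/N columns, capping saturated JC distances (p ≥
0.75) at a configurable value with a warning.  `nj_tree()` is a standard
neighbor-joining implementation made fully deterministic: Q-criterion ties
break on the lexicographically smallest pair of clade labels, so a given
matrix always yields the same newick string regardless of input order.
Alignment itself is out of scope — inputs are pre-aligned or equal-length
(as simulator output is); `nj_bootstrap()` adds column-resampling support
values when wanted.

`assign_orthologs()` calls a cross-species pair orthologous when the two
genes form a cherry in at least one of the 5'/3' trees, are not placed in a
*different* cross-species cherry by the other tree, and share an identical
C-terminus residue signature.  Genes absent from one tree (e.g. truncated
pseudogenes excluded from the 5' tree, or dissimilar pseudogene 3' flanks,
operationalised as <60% identity to every other sequence) are judged on the
tree that contains them.

`expansion_order()` encodes the two deterministic rules available for
ordering duplications: pseudogene leaves whose terminal branch exceeds twice
the median of the others are basal candidates (release from selection lets
the oldest copies diverge fastest), and for each pair of gene clusters the
unique strictly-maximal shared-flank pair marks the seeding duplication.
The duplicon edge points out of the cluster containing a basal candidate
(the older cluster), falling back to lexicographic order; when the maximum
is not unique nothing is emitted, so a star-like family yields an empty
order rather than an arbitrary one.

## The simulator and what it does (not) emulate

`simulate_family()` grows one ancestral gene — 1140 nt of 5' flank, a start
codon plus a hydrophobic 60-nt leader, `n_initial_units` copies of
ACA-GCA-GCA, a 3-residue C-terminus, stop, 325 nt of 3' flank (flank
lengths match the segments used for real flank-based tree inference) — for
`generations` rounds of, in fixed order per gene: slippage (a contiguous
block of units, geometric mean 2, duplicated in place), coding substitution
(transition:transversion 2; a hit on the middle base of a position-1 ACA
yields AGA over AAA at 10:1 odds, reproducing the ~10:1 Arg:Lys ratio of
real repeat regions), flank substitution, whole-gene duplication
(bifurcating the recorded true tree), and pseudogenization (one of the
three lesion types at 0.4/0.4/0.2, the observed lesion spectrum).  An
optional speciation generation copies the whole family into a second
species and records the one-to-one ortholog pairs that remain single-copy.

Two rates exist where one might expect a single one: coding and flank
substitution are separate because they answer different questions — exact
repeat-count/cleavage-site recovery needs a quiet tract, while tree
reconstruction needs divergent flanks.  Defaults (both 1e-4/site/gen over
100 generations, duplication 0.02/gene/gen giving expected family sizes in
the observed 4–16 range, pseudogenization 0.002) describe a plausibly
recent family; they are conditions, not fitted estimates, since no
quantitative rates are measurable from the loci themselves.

Deliberate simplifications: no unequal crossing-over between paralogs (the
shared 5'/3' tree topology of real families argues it is not required to
generate the structure), no selection or population dynamics, no indels in
flanks outside the pseudogenization lesions, a fixed stop codon, and
insertion lesions only at unit boundaries leaving at least four units on
each side (a smaller remnant is, by the scanner's own definition, not a
second tract, so the lesion would be indistinguishable from a frameshift;
genes with fewer than eight units draw a frameshift instead).  Passing the
recovery tests therefore demonstrates correctness of the pipeline's logic
under this generative model, not robustness to everything real genomic data
contains (assembly errors, transposon insertions, alignment uncertainty).

`truth_compare()` scores any prediction set against the emitted truth:
exact-match rate of repeat counts, precision/recall of cleavage sites
matched by (gene, unit index, type), a status confusion matrix, and the
Robinson–Foulds distance between true and inferred trees.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; emitted GFF3 is 1-based
  inclusive.  Minus-strand records are normalised to coding orientation at
  CDS extraction.
* Letters outside A/C/G/T/N are rejected at input; N translates to X and
  can never be part of a classifiable unit.
* An empty FASTA yields a clean zero-gene report; a CDS with no tract is
  `non_AFGP`, not an error; fewer than three usable flank sequences simply
  skip tree building.
* NJ keeps negative branch lengths (they carry information about
  non-additivity) and resolves all ties deterministically.
* The simulator runs on an isolated RNG stream: the caller's `.Random.seed`
  is saved and restored, and the same (seed, config) is byte-identical.
* Problem sizes in the test suite — 1000 random sequences for the scanner
  oracle, additive matrices up to 8 leaves, 20 simulation replicates for
  recovery statistics, 500 units for frequency recovery — were chosen as
  the smallest sizes at which the checks are statistically meaningful.

## Known limitations

* Exhaustive cleavage is assumed; real processing is incomplete for at
  least one species, and which Arg sites go uncleaved is unknown.  Partial
  cleavage is a view the package does not model.
* Mass prediction ignores the C-terminal residues' composition (unspecified
  per isoform) and any glycan heterogeneity; hence the ±10% comparison
  band.
* The ortholog rule is cherry-based and will under-call in families where
  post-speciation duplications break one-to-one correspondence — by design,
  those pairs are ambiguous.
* Under heavy tract divergence (more than roughly 10% of units degraded),
  the scanner's impurity tolerance fragments the tract and repeat counts
  are no longer recoverable; this is a property of the tract definition
  itself, not of any particular implementation.
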