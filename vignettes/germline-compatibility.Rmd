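---
title: "Scoring germline-encoded TCR-MHC compatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring germline-encoded TCR-MHC compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrmhc)
```

## The problem

The orientation a T cell receptor (TCR) adopts over a peptide-MHC complex is
remarkably conserved across solved structures even though the hypervariable
CDR3 loops and the presented peptide vary freely. The germline-encoded CDR1
and CDR2 loops — fixed by the TRAV/TRBV gene used — and the likewise
germline-encoded MHC α-helices are the only parts of the interface shared
across all receptor-ligand combinations, which makes them the natural place
to look for conserved compatibility. Direct structural coverage of this
space is tiny (tens of crystallized complexes against thousands of
gene-allele combinations), so `tcrmhc` takes a pseudo-structural route: it
quantifies sequence diversity, biophysical composition, and a simplified
residue-pair interaction potential over every V-gene × HLA-allele
combination, without assuming any binding orientation, and validates the
potential against atom-level contacts in solved complexes.

## Encoding

All analyses operate on an integer alignment matrix: each sequence family
(TRAV, TRBV, HLA class I, class II α/β) is reduced to its structurally
conserved regions — CDR loops for the TCR, TCR-exposed helix residues and
peptide-contacting residues for the MHC — and each residue becomes a code
1–20 (alphabetical one-letter order), 21 for nonstandard residues, 0 for
structural padding. Region positions are not inferred; they come from an
editable config (`inst/extdata/region_definitions.yaml`). The shipped helix
position lists follow a solvent-exposure convention and are defaults to be
reviewed against the alignment in use, not authoritative annotations.

Within a region block, shorter segments are padded centrally: the first
⌈L/2⌉ residues anchor left, the rest anchor right, zeros fill the apex.
Loop termini are structurally conserved while apex length varies, so this
keeps homologous positions aligned; a `left` mode exists for testing.
Encoding is lossless (`decode_repertoire()` restores every segment), and
uniqueness filtering is judged on the extracted segments, because only
those enter any downstream statistic.

## Diversity: entropy and mutual information

Per-column diversity is the Shannon entropy $H = -\sum_x p(x)\log_2 p(x)$
over the amino acids observed at that position, in bits; 0 means full
conservation and $\log_2 20 = 4.32$ is the 20-letter maximum. Pad cells are
excluded from the distribution — they mark the absence of a residue, and
counting them would make entropy depend on block width. A column with at
most one effective observation has entropy 0.

Because the families differ greatly in size (tens of V genes versus
hundreds of alleles), profiles are compared after subsampling: draw
`n_subsample` sequences without replacement, compute the profile, repeat
(1000 repetitions by default) and report mean ± standard deviation. The
default subsample size for an MHC set paired with a TCR set is the TCR set
size, exposed as a parameter since no single choice is canonical.

Covariation between a TCR column and an MHC column is the mutual
information $I(X;Y) = H(X) - H(X|Y)$ computed from joint counts on a
*paired* sample: every TCR sequence (the channel input) is paired with one
HLA allele (the output) drawn uniformly with replacement, and the
calculation is repeated (1000 pairings by default) to average over the
arbitrary pairing. Identity pairing (row *i* with row *i*) is available for
planted-truth data, and grouped pairing restricts partners to the same
organismal source for cross-species analyses. Raw averages are reported, to
keep magnitudes comparable across set sizes; a Miller–Madow bias correction
is available behind a flag, default off. For judging whether an observed MI
exceeds finite-sample noise, `mi_bias_bound()` uses the asymptotic null
relation $2N\ln 2 \cdot I \sim \chi^2_{(K-1)(L-1)}$ and returns its 0.999
quantile in bits.

## Biophysical profiles

Position profiles average a per-residue property over sequences at each
column. Charge uses K, R = +1, D, E = −1, H = +0.1 (histidine is partially
protonated at physiological pH; the value is a config knob since no single
convention exists), hydropathy uses the Kyte–Doolittle index; both are
z-normalized over the 20 values (mean 0, sd 1) before profiling. Pads and
nonstandard residues never enter the statistics; an all-pad column is
reported missing rather than zero. The shaded-band statistic is the
per-sequence standard deviation at the column (not the standard error of
the mean) — the spread across molecules is the quantity of interest.

## The interaction potential

Residues fall into five classes: positive {K, R, H}, negative {D, E},
hydrophilic {S, T, N, Q, Y, C, W}, hydrophobic {F, L, I, M, V},
noninteracting {G, A, P}. Unordered class pairs carry integer scores:
salt bridges (positive × negative) +2; hydrogen-bond-capable pairings
(hydrophilic × hydrophilic, hydrophilic × charged) +1; hydrophobic packing
+1; like-charge clashes −2; hydrophobic-hydrophilic and
hydrophobic-charged mismatches −1; anything involving a noninteracting
residue 0. The class map and rules are config-overridable; any configured
matrix must reproduce two anchored worked cases (`NNK` vs `EDQ` scores
(+1, +1, +1) and is accepted; `KEL` vs `RKA` scores (−2, +2, 0) and is
rejected), enforced by a self-check at build time so a bad override fails
immediately.

A single complementary residue pair on a protein interface is not evidence
of a productive interaction, so scoring requires a *triad*: a window of
three consecutive loop residues against three consecutive helix residues,
valid only if all three pairwise scores are at least +1 (an alternative
"no clashing pair" rule is selectable; both reproduce the anchored cases).
The potential between a loop and a helix enumerates all
$(L_t-2)(L_m-2)$ trigram pairs — deliberately orientation-free — and sums
the totals of valid triads, so it is nonnegative and monotone in sequence
length. A per-trigram-pair normalization (divide by the pair count) is
available for cross-length comparison, default off, matching the raw
unitless score used in the gene × allele tables.

Per-residue attribution credits each helix position with its own pairwise
score inside every valid triad (not a third of the triad total): the
position's own chemistry is what creates or blocks the contact, and the
rule makes attribution sum exactly to the potential. Averaging attributions
over genes and loops yields the per-helix-position breakdown used to locate
permissive and obstructive bands on the MHC surface; a position conserved
as G/A/P attributes exactly zero.

## Structural validation

`find_contacts()` scans CDR-residue × helix-residue heavy-atom pairs in a
PDB structure: a van der Waals contact at ≤ 4.5 Å, an electrostatic contact
at ≤ 6.0 Å for nitrogen-oxygen pairs — with O–O admitted only when
Ser/Thr/Tyr is involved and N–N only when His is involved (hydroxyl and
imidazole donors). Electrostatic typing uses the element symbols of the two
atoms, not assigned charges, which is exactly what the O–O/N–N exception
rules require; the 6 Å rule is applied to all heavy atoms, with the contact
class recorded, rather than restricted to sidechains. Contacts are classed
SC-SC / SC-Back / Back-SC / Back-Back by whether each side's atom is
backbone ({N, CA, C, O, OXT}) or sidechain, deduplicated to one record per
(residue pair, class, bond type) keeping the closest atom pair — counting
every atom pair would weight large residues by atom count. Altlocs resolve
to the highest-occupancy conformer; insertion codes stay in the residue
key.

Counts are tabulated into a 20 × 20 (MHC aa, TCR aa) matrix; the
symmetrized variant is $M + M^\top$ (not an average), so its total is
exactly twice the record count. For comparison with the potential — which
cannot be negative-valued in contact space — `relu_normalize()` maps
negative potentials to zero. Per-gene potentials are binned into
weak/moderate/strong by tertiles (the natural three-way split when no
external thresholds exist), and bin differences in contact counts are
tested with a two-sided label-shuffling permutation test,
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(1 + n_{perm})$,
seeded, $n_{perm} = 10{,}000$ by default.

## Synthetic data and what passing tests mean

The generators produce every input with known ground truth: repertoires
with per-column distributions (fixed residue, uniform-within-class, or an
explicit probability vector), optional length variation realized as apex
deletions, and planted TCR↔MHC covariation (a bijection obeyed with a given
probability — at obedience 1 a uniform 4-symbol column carries exactly
2 bits of MI; at obedience 0 the truth is zero up to the documented bias
bound). Toy complexes place planted atom pairs at exact distances on a
scaffold whose residues sit 40 Å apart with remaining backbone atoms parked
away from the interface, so the qualifying contact list is known by
construction; coordinates land on the PDB's 3-decimal grid, so distances
reproduce to ±0.001 Å under rigid motion. The generators emulate controlled
marginal distributions and planted dependencies — not phylogenetic
correlation between alleles, realistic loop conformations, or database
biases — so green tests certify the machinery (encoding, estimators,
scoring, contact rules), not any claim about real repertoires.

## Sizes, determinism, degenerate inputs

Test-suite simulations use deliberately small problem sizes — 6-row
exhaustive subset enumeration against the subsampled entropy, 200 random
loop/helix pairs against a brute-force potential oracle, n = 5000 for MI
recovery, 1000 null datasets at 2000 permutations for the type-I
calibration of the permutation test — chosen so the full suite completes in
about a minute on one core while leaving Monte-Carlo error well inside the
asserted tolerances. All stochastic stages take a mandatory seed and run on
an isolated RNG stream, so results are reproducible and independent of the
caller's RNG state; the pipeline manifest records md5 hashes per output and
reruns reproduce them. Degenerate inputs resolve conservatively: loops
shorter than a trigram score 0 with a warning, all-pad columns have zero
entropy and missing property values, bins with fewer than two members are
skipped with a warning, empty FASTA or missing chains are errors.

## Limitations

The potential scores sidechain chemistry only; backbone-mediated contacts,
known to stabilize real interfaces, are visible to the contact quantifier
but not to the score. There is no geometry: all trigram pairs count
equally, so the score is a compatibility propensity, not a binding-energy
estimate, and length normalization is left off by default to match the raw
tables. Helix position lists ship as editable defaults. Cross-species
analysis is supported only through the grouped pairing scheme; no
phylogenetic correction is attempted.
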