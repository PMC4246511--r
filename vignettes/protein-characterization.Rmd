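---
title: "Characterizing protein sequences for machine learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protein sequences for machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protchar)
```

## The problem

Sequence-based protein prediction tools — secondary structure, solvent
accessibility, contact maps, disorder, model quality assessment — are almost
always machine-learning models over a numerical feature space derived from
the protein's primary sequence and its evolutionary profile. The learning
itself is well served by existing toolkits; the recurring engineering burden
is everything before it: parsing half a dozen legacy text formats, turning
symbols into numbers without imposing artificial orderings, and writing the
result in whatever line grammar the chosen learner expects. `protchar`
packages that pre-processing layer: parsers, characterizers/encoders and
feature writers, with a thin CLI over the top. It deliberately excludes
model training and PDB structure parsing.

## Data model and conventions

All residue positions exposed to the user are 1-based, the native R
convention; file formats keep their own indexing only inside the parsers.
Sequences are strings over the 20 standard one-letter codes plus `X`;
the ambiguity and rare codes B, Z, U, O, J normalize to `X` on input.
The package-wide conventions for `X` are:

* one-hot encoding: the all-zero length-20 vector (the feature space stays
  20-dimensional, and the zero vector is the natural "no evidence" point);
* Atchley factors: five zeros;
* hydrophobicity and contact potentials: the mean of the respective table,
  an uninformative central value;
* compositions: excluded from numerator and denominator.

The canonical amino-acid feature order is alphabetical one-letter order
(`A C D E ... Y`) in every encoding, composition and frequency vector. It is
self-documenting; nothing downstream depends on the choice. PSI-BLAST PSSM
files use their own historical column order, which `pssm_profile` objects
preserve (in matrix column names) and characterizers remap at their
boundary. The secondary-structure one-hot order is (H, E, C) — fixed by the
convention that helix is `100` and coil `001` — and solvent accessibility is
(b, e).

## Parsers

Six dialects are read: FASTA; query-anchored MSAs (defined here as
plain-text, one aligned row per line, equal lengths, gapless query first —
the simplest layout in which alignment columns map one-to-one onto query
residues); PSI-BLAST ASCII PSSMs (the 44-token row layout: index, residue,
20 log-odds, 20 weighted observed percentages, information, relative weight;
footer statistics ignored); classic fixed-column DSSP output (residue letter
at column 14, 8-state symbol at column 17, absolute accessibility at columns
35–38; chain-break lines skipped); SSpro/ACCpro two-line flat output; and
PSIPRED `.ss2` (the machine-readable vertical format carrying class
probabilities — the `.horiz` format is presentation output and is not
parsed). SSpro's historical output layouts vary; the two-line dialect here
is a defined stand-in, and the parser decides between secondary structure
and accessibility from the observed alphabet, requiring an explicit `kind`
when that is ambiguous.

Two derived annotations follow the field's dominant conventions, stated here
because DSSP itself defines neither:

* 8→3 state collapse: H, G, I → helix; E, B → strand; T, S, blank → coil
  (the EVA/CASP evaluation convention).
* Buried/exposed: relative accessibility = absolute accessibility divided by
  the residue's maximum accessible surface area (Rost & Sander normalization
  constants, embedded), exposed at ≥ 0.25 — the threshold used by the
  ACCpro/SSpro predictor family. The threshold is an argument of
  `dssp_sa2()`.

## Characterizers

**Lookup tables** ship as auditable tab-separated files with citation and
checksum headers (`lookup_table()`), loaded once per session and verified
against the checksum. The Atchley five-factor table and the hydrophobicity
scale (a pH-7 side-chain scale from the hydrophobicity/helical-propensity
literature) are verbatim transcriptions of the published values, frozen by
spot-value tests. The two pairwise contact-potential tables (interface
contacts; cross-strand beta pairing) are deterministic *synthetic
stand-ins*: symmetric 210-entry tables built from hydrophobicity and
strand-propensity products with a fixed perturbation, labelled `SYNTHETIC`
in their headers and filenames. They carry the documented statistical shape
(favourable hydrophobic–hydrophobic interface contacts, favourable
strand-former pairings) and satisfy every interface contract — symmetry,
min–max scaling, `X` → table mean — but their digits are not literature
values; replacing the TSV with a transcribed published table changes nothing
else in the package.

**Scaling.** Most characterizers take `scaled = TRUE` to emit values in
[0, 1], which several learners require. For finite tables min–max over the
table's own entries is exact, so that is used everywhere a table exists; for
the unbounded PSSM log-odds the logistic squash 1/(1 + e^{−x}) is used, the
standard treatment in secondary-structure prediction pipelines; profile
information divides by its log₂ 20 maximum.

**Profiles and information.** `column_profiles()` computes per-column
residue frequencies over non-gap rows of an anchored MSA, the gap fraction,
and the information content I = log₂ 20 − H(f) with H the Shannon entropy in
bits (0·log 0 ≡ 0). `X` residues in alignment rows count toward the non-gap
total and are spread uniformly over the 20 frequencies. A PSSM yields the
same structure from its percentage rows (renormalized; an all-zero row falls
back to uniform with a warning) with the information column taken from the
file. By construction MSA-derived information satisfies the definition
exactly — the test suite asserts it to 1e-12 — while PSSM-derived
information is whatever PSI-BLAST printed.

**Ordered means.** The "n-th ordered mean" of a sequence is implemented as
the generalized power mean Mₙ = ((1/L) Σ vᵢⁿ)^{1/n} over per-symbol values
scaled to [0, 1] (hydrophobicity or one Atchley dimension for residues;
class indices rescaled to [0, 1] for annotation strings). An alternative
reading — the n-th order statistic — was considered and rejected: order
statistics of a scaled string are a weaker, non-smooth summary, and the
power-mean family nests the arithmetic mean (n = 1) and is monotone in n,
which makes several orders jointly informative as features. The function
name `scaled_ordered_mean()` records the interpretation.

**Vector statistics.** `calculate_entropy()` validates that its input is a
probability distribution (non-negative, sum within 1e-6 of 1). Pearson
correlation is undefined for a constant vector, so zero variance raises a
typed error rather than returning 0 or NaN silently; cosine similarity
likewise rejects zero-norm inputs.

## Feature assembly and the file format

Per-residue feature vectors concatenate the selected blocks over an odd
sliding window centred on the target residue. Window slots falling outside
the sequence contribute zeros for the block plus a boundary indicator bit
(1 = outside), one bit per block per slot, so the feature length is constant
at `window × Σ(block width + 1)` and the learner can distinguish "terminal
residue" from "zero-valued features" — the standard alternative, truncating
windows at the termini, changes the feature length and was rejected. Labels
default to 0; 3-state secondary structure labels map H/E/C to 1/2/3.

Two output dialects are fixed (accommodating every learner's format is a
non-goal): the SVM^light numbered grammar — label, then `index:value` tokens
with 1-based strictly ascending indices — and an unnumbered dense dialect.
In sparse mode zero-valued features are omitted, except the final feature,
which is always written so the vector dimension survives a round trip.
Values print at 6 decimal places by default: lossless enough for
[0, 1]-scaled features while keeping files diffable. `parse_feature_file()`
reads both dialects back (missing sparse indices fill with zero up to the
line maximum), and write → parse → write is byte-identical, which the tests
assert.

## The synthetic-data generator

`make_fixture()` fabricates a coherent bundle from one seed: a uniformly
random sequence; an MSA mutated from it at a fixed per-position substitution
rate of 0.2 and gap rate of 0.05 in non-query rows (values typical of the
mid-range sequence identity — roughly 80% — at which profile methods
operate; they are constants of the generator, not tuning knobs); a PSSM
derived from the MSA columns (percentages by largest-remainder apportionment
so every row sums to exactly 100; log-odds `round(log2(freq/0.05))`, floored
at −9 where the frequency is zero, since log₂ 0 is undefined and PSI-BLAST's
own printed scores saturate near there; information = log₂ 20 − column
entropy at the file's 2-decimal precision); a DSSP file with
helix/strand/loop segments of length 5 and accessibilities uniform in
[0, max_acc(aa)]; and PSIPRED/SSpro predictions consistent with the DSSP
3-state string (true-class probability 0.8). Ground truth is stored at file
precision, so parser outputs are expected to equal it *exactly*, and the
same seed reproduces byte-identical files; the generator saves and restores
the caller's RNG state.

What the generator does **not** emulate: realistic residue composition or
neighbour correlation, phylogenetic structure in the alignment (rows are
independent), realistic secondary-structure segment statistics, or
correlation between structure and sequence. Passing round-trip and pipeline
tests therefore demonstrates format and bookkeeping correctness, not
biological validity of any downstream model.

## Numerical choices and problem sizes

Entropy uses base-2 logarithms throughout (information in bits, the sequence
-analysis convention). Composition and frequency vectors are asserted to sum
to 1 within 1e-9; entropy closed forms and the correlation/cosine oracles
are checked to 1e-12. The test suite and the acceptance script run on small
synthetic problems — sequences of 25–100 residues, alignments of up to 12
rows, 20 fixture seeds for round-trip checks, 1,000 random vector pairs for
the statistics oracles — sizes at which every expected value is computable
by an independent brute-force oracle in the tests themselves.

## Limitations

* The contact-potential digits are synthetic stand-ins (see above); users
  who need literature values must supply the transcribed table.
* One SSpro layout is supported; other historical layouts need conversion.
* PSIPRED `.horiz` output is not parsed.
* The anchored-MSA dialect excludes insertions relative to the query by
  construction; alignments with query gaps must be re-anchored upstream.
* `run_cli()` processes one protein per invocation; batch feature generation
  is a loop in the caller's hands.
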