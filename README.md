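# protchar

Machine-learning methods dominate sequence-based protein structure
prediction — secondary structure, solvent accessibility, residue contacts,
disorder, model quality — and all of them start the same way: the protein's
sequence and its evolutionary profile have to be read from a zoo of text
formats and converted into numerical feature vectors. `protchar` is a small
R package for exactly that pre-processing step. It parses the standard
inputs of the field, characterizes residues and whole proteins numerically,
and writes labeled feature files that off-the-shelf learners (SVM^light and
friends) consume directly. It deliberately does **no** training or
prediction, and it does not parse PDB structures.

## What it computes

**Parsers** for six text formats: FASTA (`read_fasta()`), query-anchored
multiple sequence alignments (`read_anchored_msa()`), PSI-BLAST ASCII PSSMs
(`read_pssm()`), classic DSSP output (`read_dssp()`), SSpro/ACCpro flat
predictions (`read_sspro()`) and PSIPRED `.ss2` files (`read_psipred()`).

**Encoders and characterizers.** One-hot (orthogonal) encodings of residue,
secondary-structure and accessibility symbols, with lengths 20 / 3 / 2 and
fixed orders — helix encodes as `1 0 0`, coil as `0 0 1`; compositions
(fraction of each symbol type); the five Atchley physicochemical factors per
residue; a hydrophobicity scale; symmetric pairwise contact potentials
(interface and cross-strand beta); Pearson correlation and cosine similarity
of feature vectors; Shannon entropy of a probability vector,

&nbsp;&nbsp;&nbsp;&nbsp;H(p) = −Σᵢ pᵢ log₂ pᵢ  (bits);

per-column profiles from an MSA or PSSM, with information content

&nbsp;&nbsp;&nbsp;&nbsp;I(column) = log₂ 20 − H(f)  where f are the column's residue frequencies;

and the generalized (power) mean of order n of a scaled sequence,
Mₙ = ((1/L) Σᵢ vᵢⁿ)^{1/n}, which is non-decreasing in n.

**Feature writers.** Labeled examples serialize to the SVM^light sparse
grammar (`<label> <index>:<value> …`, 1-based ascending indices) or a dense
whitespace dialect, with a reader (`parse_feature_file()`) for round trips.

**Windowed assembly + CLI.** `build_feature_table()` concatenates chosen
feature blocks over an odd sliding window per residue (out-of-sequence slots
zero-filled, flagged by a boundary bit), and `run_cli()` exposes the whole
pipeline as a shell program (`features`, `describe`, `fixture` subcommands).

**Fixture generator.** `make_fixture()` fabricates mutually consistent
synthetic inputs in all six formats from one seed, returning the in-memory
ground truth alongside the files, so every parser is testable offline.

Note on the lookup tables: the Atchley factors and the hydrophobicity scale
are verbatim transcriptions of the published scales (citations in the file
headers, `lookup_table("atchley")`). The two contact-potential tables are
deterministic **synthetic stand-ins** — symmetric, with the documented
statistical shape — shipped as auditable TSV files that a transcribed
published table can replace.

## Worked example

```r
library(protchar)

fx <- make_fixture(seed = 7, length = 40, msa_rows = 8, dir = tempfile())
read_fasta(fx$file_paths[["fasta"]])
#> # A tibble: 1 × 2
#>   id          sequence
#>   <chr>       <chr>
#> 1 synthetic_7 LWHCRIDIRINWYIVRGSEMGCEGMITQEDPKIPRKCNIL

glance(read_pssm(fx$file_paths[["pssm"]]))
#> # A tibble: 1 × 3
#>   length mean_information max_information
#>    <int>            <dbl>           <dbl>
#> 1     40             3.76            4.32

head(column_profiles(fx$msa)[, c("position", "residue", "gap_fraction", "information")], 4)
#> # A tibble: 4 × 4
#>   position residue gap_fraction information
#>      <int> <chr>          <dbl>       <dbl>
#> 1        1 L              0            4.32
#> 2        2 W              0            4.32
#> 3        3 H              0.125        4.32
#> 4        4 C              0            4.32

hot_encode_ss("H")        # helix over (H, E, C)
#> H E C
#> 1 0 0
atchley_factors("A")
#>     f1     f2     f3     f4     f5
#> -0.591 -1.302 -0.733  1.570 -0.146
```

An eight-row alignment of a 40-residue query gives a mean information of
3.76 bits per column: most columns are strongly conserved (the maximum,
log₂ 20 ≈ 4.32 bits, is a fully conserved column), as expected at the
fixture's 20% substitution rate. `autoplot()` methods plot compositions,
per-position conservation and PSSM heatmaps.

The same pipeline from the shell (the wrapper script is installed at
`system.file("cli", "protchar.R", package = "protchar")`):

```sh
Rscript inst/cli/protchar.R features \
  --fasta query.fasta --pssm query.pssm \
  --recipe hot_aa,pssm_logodds --window 15 --scaled --out query.feat
# protchar: fasta 'synthetic_7', 40 residues
# protchar: pssm 40 positions
# protchar: wrote 40 examples x 630 features to query.feat
```

Each of the 40 lines is one residue's example: 15 window slots × (20
one-hot values + boundary bit + 20 logistic-squashed log-odds + boundary
bit) = 630 features in SVM^light numbered form, ready for an external
learner.

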