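---
title: "Retro-biosynthetic analysis of modular PKS assembly lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retro-biosynthetic analysis of modular PKS assembly lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksretro)
```

## The problem

Modular type I polyketide synthases (PKSs) build aliphatic polyketides as
an assembly line: a loading module primes a starter unit (here always
acetate), and each extension module condenses one extender unit — malonyl-CoA
(C~2~), methylmalonyl-CoA (C~3~) or a rarer alkylmalonyl-CoA (C~2+n~) — onto
the growing thioester-bound chain. Each condensation creates a new
β-ketone; the module's reductive domains then decide how far it is
processed. Two independent kinds of evidence constrain what a cluster
makes:

* **Forward (genes → product).** The acyltransferase (AT) signature
  residues of each module predict the extender substrate; the complement
  of ketoreductase (KR), dehydratase (DH) and enoylreductase (ER) domains
  fixes the oxidation level of each β-carbon; KR sequence fingerprints
  (A/B types, subtypes 1/2) predict β-hydroxyl and α-substituent
  configuration and downstream double-bond geometry; ER classes predict
  the α-methyl configuration after full reduction.
* **Backward (isotopes → skeleton).** Feeding ^13^C-labeled precursors
  ([1-^13^C]- and [2-^13^C]acetate, [1-^13^C]propionate) and measuring
  per-carbon enrichment ratios reveals which skeleton carbons derive from
  which precursor carbon, which reconstructs the tiling of the carbon
  skeleton by starter/extender units and the direction of chain growth.

`pksretro` implements both directions plus the reconciliation between
them. A carbon–carbon bond that the inferred head-to-tail tiling cannot
explain is flagged *anomalous*: it must have been formed by post-assembly
(tailoring) chemistry, such as an aldol ring closure.

## The forward model

`assemble()` lays the backbone out starter-first: chain position 1 is the
starter methyl, each unit contributes its α-carbon (C2) then its
carboxyl-derived carbon (C1), and the final C1 is released as the
carboxylic acid (thioester hydrolysis; lactonization and all cyclizations
are considered tailoring and are out of scope). Extension module *i*
processes the β-carbon present at its condensation — C1 of the previous
unit — according to its *active* domains:

| active domains | β-carbon outcome | stereo/geometry source |
|---|---|---|
| none (no KR) | ketone | — |
| KR | hydroxyl | KR fingerprint β-descriptor; α-descriptor to its own unit's C2 if branched |
| KR + DH | enoyl pair with the next unit's C2 | geometry by KR letter (B → E, A → Z) |
| KR + DH + ER | methylene | ER class sets the α-substituent descriptor |

Domains annotated but marked `active: false` are treated as absent, which
is how clusters whose product retains β-hydroxyls despite annotated DH
domains are represented. A KR-less module yields a ketone regardless of
other annotations, since DH and ER act downstream of ketoreduction.

Stereo descriptors are recorded as raw R/S labels attached to chain
positions, not re-derived CIP assignments — CIP priorities can flip with
molecular context, and the labels are meant to carry the domain verdicts,
not to name the final molecule. For the same reason `to_smiles()` writes
tetrahedral marks (`[C@H]`/`[C@@H]`) under a fixed local atom order as an
encoding of the labels; the default output omits stereo entirely.
Hydrogen counts in `molecular_formula()` assume standard valences and no
ring closure.

Where a DH-containing module's KR has no fingerprint, geometry defaults to
E (trans), the overwhelmingly common outcome; the shipped fixtures always
carry fingerprints, so the default matters only for hand-built inputs.

## Rule content is data

The source annotations for AT substrate signatures and KR/ER fingerprints
are literature motif tables that the package treats as configuration, not
code. `default_rules()` ships canonical tokens (`HAFH` → malonyl, `YASH` →
methylmalonyl, both standard motif letters in the AT-specificity
literature, and a stand-in token `TAGH` for alkylmalonyl selectors, which
have no single canonical motif), the KR table with B1 → (β-S, α-R) and the
A-types mirrored, geometry B → E / A → Z, and the ER tyrosine rule (class
`Y` → S). Every table can be overridden from a JSON file via
`read_rules()` or the CLI `--rules` flag. An alkylmalonyl AT cannot reveal
its side-chain length from the signature alone, so cluster files carry an
explicit `side_carbons` attribute on such ATs; assembly refuses to guess.

## The enrichment model

Published feeding tables report, per carbon, the ^13^C signal intensity of
the labeled compound divided by that of the unlabeled compound, normalized
to a reference carbon known to incorporate no precursor. That footnote is
ambiguous between one- and two-spectrum readings; `compute_enrichment()`
implements the two-spectrum form

$$r_c = \frac{L_c / U_c}{L_{\mathrm{ref}} / U_{\mathrm{ref}}}$$

because it reproduces the printed reference value of exactly 1.00 and is
invariant to overall spectrum scaling (both properties are tested). When a
table supplies ratios instead of raw intensities — the published tables
print only ratios — they pass through renormalized by the reference row.
A carbon is called enriched when its ratio reaches the threshold; the
default threshold of 3.0 cleanly separates the smallest published bold
(enriched) entry, 3.77, from the largest unbold one, 2.11. Overlapping
signals (two carbons sharing a chemical shift) are distinct records with
equal shift; ascribing the shared ratio to the right carbon is the
fixture's documented responsibility, mirroring how the original argument
disambiguates the overlap using an orthogonal feeding experiment.

## The backward model: tiling

`tile()` searches for decompositions of the carbon graph into units. The
backbone grows from a candidate starter methyl — the graph's
`terminal_hint` when present, otherwise every degree-1 carbon — two nodes
per unit; after the backbone is laid, each remaining connected component
must hang off exactly one extender α-carbon, and its size types the unit
(0 side carbons → malonyl, 1 → methylmalonyl, ≥ 2 → alkylmalonyl). The
starter itself may carry no branch. The hint matters when tailoring has
closed a ring through the starter methyl, leaving it with degree 2.

Label calls enter as *consistency evidence*, not as the typing signal.
Each precursor rule predicts which carbon of which unit types an
experiment labels; concordance is the fraction of experiment × carbon
observations (enriched or not) matching the prediction. Rankings are by
concordance, then fewest anomalous bonds, then the lexicographic
unit-token sequence, with all rank-one ties returned. Any bond not used as
an intra-unit, inter-unit or side-attachment bond is anomalous.

One refinement over a naive "role C1/C2" rule was forced by the data: in
an alkylmalonyl unit built from a propionyl primer elongated with acetate
and then carboxylated, the propionate carboxyl carbon ends up at the
branch attachment, while the unit's own C1/C2 derive from acetate. The
default rules therefore give the propionate rule `alkyl_role =
"side_proximal"` and include alkylmalonyl among the acetate-labeled
types. With that reading, the full published label sets of both reference
compounds are reproduced at concordance 1.0, including the C5 unit whose
attachment carbon is propionate-labeled while its backbone carbons are
acetate-labeled.

A dicarboxylate feeding experiment (succinate) has no incorporation rule:
it is represented, when present, as an all-unenriched experiment and
contributes nothing to concordance — which is exactly its published role
as negative evidence.

`brute_force_tile()` is the test oracle: it enumerates candidate backbones
exhaustively via `igraph::all_simple_paths()` instead of the incremental
walk, refuses graphs over 14 carbons, and must agree with `tile()`
exactly on everything up to 12 carbons (property-tested). The two share
the unit-typing/scoring helpers — the oracle targets the search, while the
scoring itself is pinned by fixture-value tests.

## Reconciliation

`compare_prediction()` matches the gene-predicted and label-inferred unit
sequences position by position. Alkylmalonyl units match strictly by side
size (a C5 unit is not a C3 unit). The verdict is `consistent` when every
position matches and no bond is anomalous, `consistent_with_post_pks_bonds`
when the sequences match but the skeleton needs extra bond(s), and
`inconsistent` otherwise; overhanging positions of the longer sequence
count as mismatches.

## What the synthetic generator emulates — and what it does not

`generate_cluster()` draws module substrates and reductive profiles from
weighted tables, silences DH domains with probability `p_inactive_dh`, and
records the ground-truth unit sequence directly from the draws (never via
the assembly code under test). `simulate_labeling()` builds the product's
carbon graph, optionally injects one extra α–α bond as a synthetic
post-assembly bond, and emits ratio-mode enrichment tables: truly labeled
carbons at `base_enrichment · exp(N(0, σ_log))`, everything else at
`max(ε, N(1, σ))`.

Defaults are the stated world of the reference data and are not tuning
knobs: 7 extension modules (the length of both reference clusters);
`base_enrichment = 5` (the magnitude of the published acetate
enrichments, 3.8–5.0); `noise_sd_unlabeled = 0.1` (the scatter of the
published unenriched entries around 1); `p_inactive_dh = 0.2` (a handful
of silent domains across the two reference clusters); substrate weights
0.5/0.35/0.15 favouring malonyl, as in the reference clusters. The
generator simulates ratios directly because that is the form the
published tables take; an intensity mode (`U_c ~ N(1, 0.05)`,
`L_c = r_c·U_c`) exercises the two-spectrum normalization path.

The generator does **not** emulate realistic chemical shifts, spectral
overlap, tautomerization artifacts, or metabolic scrambling of label
through central metabolism. A green recovery test therefore establishes
that the inference chain is self-consistent and noise-robust in the
stated regime — not that it would survive every pathology of real NMR
data. One structural corner is intrinsic: a product built entirely from
acetate units has no never-labeled carbon to serve as reference, and the
generator raises an error rather than fabricate one; pipeline tests count
only generable replicates.

## Numerical and degenerate-input choices

* Thresholds compare with `>=`; classification is monotone in the
  threshold by construction.
* Tie-breaking in tiling is fully deterministic (concordance ↓, anomalous
  count ↑, token sequence, canonical backbone key); all rank-one ties are
  returned rather than hidden.
* A loading-only cluster assembles to the two-carbon acetate chain
  (C2H4O2); a single-unit tiling is just the starter.
* Empty call lists make concordance vacuously 1; experiments present in
  the calls but lacking a rule are ignored.
* Side-branch assignment enumerates at most 32 attachment combinations
  per backbone before falling back to the first choice per component —
  beyond anything a PKS skeleton produces.

## Known limitations

* Only C, H, O chemistry: no halogens, nitrogen or phosphorus; formulas
  assume acyclic products.
* The tiling search assumes one linear backbone; branched (convergent)
  assembly lines and trans-AT PKSs are out of scope.
* Geometry/stereo predictions are carried labels, not validated 3-D
  assignments.
* Domain detection from protein sequence (HMM/BLAST annotation) is out of
  scope; cluster files start from already-annotated domain organizations.
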