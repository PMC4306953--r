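# pksretro

Retro-biosynthetic analysis of modular type I polyketide synthase (PKS)
assembly lines in R.

## What problem does this solve, and for whom?

Natural-product chemists and genome miners routinely face two half-answers
about a polyketide's biosynthesis:

1. **From the genes:** a type I PKS gene cluster, annotated module by
   module — acyltransferase (AT) substrate signatures, the
   ketoreductase/dehydratase/enoylreductase (KR/DH/ER) complement, KR
   stereochemistry fingerprints — predicts a linear product: how many
   carbons, which extender units in which order, the oxidation level,
   configuration and double-bond geometry at each position.
2. **From the isotopes:** feeding ¹³C-labeled precursors
   ([1-¹³C]/[2-¹³C]acetate, [1-¹³C]propionate) and reading per-carbon NMR
   enrichment ratios reveals which skeleton carbons come from which
   precursor carbon, i.e. how the final compound's carbon skeleton tiles
   into starter and extender units.

`pksretro` computes both, checks them against each other, and flags every
carbon–carbon bond that head-to-tail chain extension cannot explain —
those bonds must be formed by post-assembly (tailoring) chemistry such as
an aldol ring closure.

At its core are three computations:

* **Assembly.** The β-carbon laid down before extension module *i* ends up
  as a ketone (no KR), hydroxyl (KR), enoyl double bond (KR+DH, geometry E
  for B-type KRs, Z for A-type) or methylene (KR+DH+ER); the last unit's C1
  is released as the carboxyl terminus.
* **Enrichment.** For carbon *c*, the ratio
  `r_c = (L_c/U_c) / (L_ref/U_ref)` of labeled-to-unlabeled ¹³C signal
  intensities, normalized to an unincorporated reference carbon; `r_c ≥ 3`
  calls the carbon enriched.
* **Tiling.** A backtracking search over decompositions of the carbon graph
  into a starter plus two-backbone-carbon extender units with typed side
  branches, ranked by concordance with the labeling calls and by fewest
  anomalous bonds (with an exhaustive brute-force oracle for testing).

Seeded generators of synthetic clusters, products, graphs and noisy
enrichment tables make the whole chain testable end to end.

## Worked example

The packaged fixtures describe a marine *Streptomyces* assembly line for a
C17 polyolefinic acid (one acetate starter + six malonates + one
methylmalonate) together with its published feeding-experiment table:

```r
library(pksretro)

lorn <- read_cluster(pks_extdata("lorneic_cluster.txt"))
prod <- assemble(lorn)
prod
#> <linear_product> lorneic_bgc: 17 carbons (16 backbone), C17H26O2
#>   units: acetyl_starter malonyl malonyl malonyl methylmalonyl malonyl malonyl malonyl
#>   double bonds: 4  smiles: CCCCCC=CCC(C)C=CC=CC=CC(=O)O

tabs <- read_enrichment_csv(pks_extdata("feeding_lorneic_acid_a.csv"),
                            compound = "lorneic acid A", reference = "16")
calls <- lapply(tabs, function(t) classify_enriched(compute_enrichment(t, 3), 3))
# acetate_1_13C: carbons 1,3,5,9,11,13,15   propionate_1_13C: carbon 7

g <- read_carbon_graph(pks_extdata("lorneic_acid_a_graph.txt"))
best <- tile(g, calls)[[1]]
best
#> <unit_tiling> 8 units, concordance 1.000, 0 anomalous bond(s)
#>   unit 1 acetyl_starter   C2=16 C1=15
#>   unit 2 malonyl          C2=14 C1=13
#>   unit 3 malonyl          C2=12 C1=11
#>   unit 4 malonyl          C2=10 C1=9
#>   unit 5 methylmalonyl    C2=8 C1=7 side={17}
#>   unit 6 malonyl          C2=6 C1=5
#>   unit 7 malonyl          C2=4 C1=3
#>   unit 8 malonyl          C2=2 C1=1

compare_prediction(prod, best)
#> <consistency_report> lorneic_bgc: verdict: consistent
```

Reading: the cluster predicts a 17-carbon chain whose single C3 unit sits
at position 5, and the labeling data independently tile the skeleton the
same way at concordance 1.0 — the gene-based and isotope-based accounts
agree completely.

The companion 22-carbon fixture (`akaeolide_cluster.txt`,
`akaeolide_graph.txt`, `feeding_chloroakaeolide.csv`) shows the other
outcome: the best tiling matches the predicted unit sequence but flags the
ring-closing bond C16–C17 as `anomalous`, giving the verdict
`consistent_with_post_pks_bonds` — that bond was formed after chain
assembly.

A command-line wrapper covers the same stages
(`predict`, `enrich`, `tile`, `check`, `simulate`); see
`system.file("scripts", "pksretro", package = "pksretro")` and `?pks_cli`.

## Further reading

`vignette("retrobiosynthesis")` documents the model and its assumptions,
the rule configuration, the noise model of the synthetic generator, and
known limitations.
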