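akae <- read_cluster(fixture("akaeolide_cluster.txt"))
lorn <- read_cluster(fixture("lorneic_cluster.txt"))

test_that("fixture products have the published carbon counts and unit sequences", {
  pa <- assemble(akae)
  expect_equal(pa$n_carbons, 22L)  # C2+C3+C3+C2+C3+C2+C5+C2
  expect_equal(unit_tokens(pa$units),
               c("acetyl_starter", "methylmalonyl", "methylmalonyl", "malonyl",
                 "methylmalonyl", "malonyl", "alkylmalonyl:3", "malonyl"))

  pl <- assemble(lorn)
  expect_equal(pl$n_carbons, 17L)  # C2 starter + 6 C2 + 1 C3 extenders
  expect_equal(pl$units$type[5], "methylmalonyl")
  expect_equal(sum(pl$units$type == "methylmalonyl"), 1L)

  # a lone loading module yields the acetate-level two-carbon chain
  ps <- assemble(loading_only_cluster())
  expect_equal(ps$n_carbons, 2L)
  expect_equal(formula_string(ps$formula), "C2H4O2")
  expect_equal(ps$smiles, "CC(=O)O")
})

test_that("double-bond counts follow DH activity", {
  expect_equal(count_double_bonds(assemble(lorn)), 4L)
  expect_equal(count_double_bonds(assemble(akae)), 2L)  # m3/m6 DH silent
  all_active <- set_domain_active(set_domain_active(akae, 4L, "DH", TRUE),
                                  7L, "DH", TRUE)
  expect_equal(count_double_bonds(assemble(all_active)), 4L)
})

test_that("molecular formulas are valence-consistent", {
  # silencing the m4 ER gives the fully olefinic C17 intermediate
  lornA <- set_domain_active(lorn, 5L, "ER", FALSE)
  pA <- assemble(lornA)
  expect_equal(formula_string(pA$formula), "C17H24O2")
  expect_equal(count_double_bonds(pA), 5L)

  # default lorneic product keeps the saturated methylene at that position
  expect_equal(formula_string(assemble(lorn)$formula), "C17H26O2")

  # every product carries at least the carboxyl oxygens
  for (seed in 1:10) {
    cl <- generate_cluster(simulation_config(seed = seed,
                                             n_extension_modules = 4L))$cluster
    expect_gte(assemble(cl)$formula[["O"]], 2L)
  }
})

test_that("stereo descriptors land on the carbons the domain verdicts name", {
  pa <- assemble(akae)
  cb <- pa$carbons
  # KR-only (silent DH) modules m3/m6 leave S-configured beta-hydroxyls
  hydroxyls <- cb[cb$oxidation == "hydroxyl", ]
  expect_equal(hydroxyls$chain_index, c(6L, 12L))
  expect_equal(hydroxyls$stereo, c("S", "S"))
  # the propylmalonyl alpha carbon takes R from its module's B1 KR
  expect_equal(cb$stereo[cb$chain_index == 13L], "R")
  # the m2 ER fixes the adjacent methylmalonyl alpha-methyl as S
  expect_equal(cb$stereo[cb$chain_index == 5L], "S")
  # ketones sit where modules carry no KR
  expect_equal(cb$chain_index[cb$oxidation == "ketone"], c(10L, 14L))
})

test_that("carbon conservation and profile->feature equivalence hold on generated clusters", {
  set.seed(42)
  for (seed in 1:20) {
    sim <- generate_cluster(simulation_config(seed = seed,
                                              n_extension_modules = sample(1:7, 1)))
    prod <- assemble(sim$cluster)
    # carbon conservation: sum of unit sizes equals total carbon count
    expect_equal(prod$n_carbons, sum(2L + sim$truth_units$side_carbons))
    expect_equal(prod$formula[["C"]], prod$n_carbons)

    # enoyl pairs = modules with active DH+KR, no active ER;
    # hydroxyls = modules with active KR but no active DH
    profiles <- count_reductive_profiles(sim$cluster)
    expect_equal(count_double_bonds(prod), profiles[["DH+KR"]])
    expect_equal(sum(prod$carbons$oxidation == "hydroxyl"), profiles[["KR"]])
    expect_equal(sum(prod$carbons$oxidation == "ketone"), profiles[["none"]])
  }
})

test_that("SMILES re-parse agrees with molecular_formula on generated products", {
  set.seed(43)
  for (seed in 1:15) {
    prod <- assemble(generate_cluster(simulation_config(
      seed = 100L + seed, n_extension_modules = sample(1:6, 1)))$cluster)
    expect_equal(smiles_formula(prod$smiles), prod$formula)
    expect_equal(smiles_formula(to_smiles(prod, include_stereo = TRUE)),
                 prod$formula)
  }
})

test_that("an independent cheminformatics parser accepts the fixture SMILES", {
  pa <- assemble(akae)
  pl <- assemble(lorn)
  smis <- c(pa$smiles, pl$smiles,
            to_smiles(pa, include_stereo = TRUE),
            to_smiles(pl, include_stereo = TRUE))
  parsed <- rdkit_parse(smis)
  expect_equal(parsed$n_carbons, c(22L, 17L, 22L, 17L))
  expect_equal(parsed$formula[1:2],
               c(formula_string(pa$formula), formula_string(pl$formula)))
})

test_that("assembly is deterministic and rejects unresolvable ATs", {
  expect_equal(assemble(akae), assemble(akae))
  bad <- akae
  bad$modules[[2]]$domains[[2]]$signature <- "ZZZZ"
  expect_error(assemble(bad), class = "pks_classification_error")
  # alkylmalonyl without a resolved side-chain length cannot be assembled
  noside <- akae
  noside$modules[[7]]$domains[[2]]$side_carbons <- NULL
  expect_error(assemble(noside), class = "pks_validation_error")
})
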