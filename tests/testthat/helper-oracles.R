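# Independent oracles and small builders shared across the test files.

fixture <- function(name) pks_extdata(name)

# --- independent SMILES formula oracle -------------------------------------
# Minimal parser for the SMILES subset this package emits (C/O atoms,
# branches, double bonds, slash geometry, [C@H]/[C@@H]). Counts element
# totals with hydrogens filled by standard valence (C=4, O=2); bracket
# atoms carry their explicit hydrogen only. Written independently of
# to_smiles(): it never consults the product model.
smiles_formula <- function(smi) {
  atoms <- list()
  add_atom <- function(el, bracket_h = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(el = el, bh = bracket_h, deg = 0L)
    length(atoms)
  }
  bond_to <- function(a, b, order) {
    atoms[[a]]$deg <<- atoms[[a]]$deg + order
    atoms[[b]]$deg <<- atoms[[b]]$deg + order
  }
  prev <- NA_integer_
  stack <- integer(0)
  pending <- 1L
  i <- 1L
  n <- nchar(smi)
  while (i <= n) {
    ch <- substr(smi, i, i)
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2L; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      i <- i + 1L
    } else if (ch == "[") {
      close <- regexpr("]", substr(smi, i, n), fixed = TRUE)
      stopifnot(close > 0)
      tok <- substr(smi, i + 1L, i + close - 2L)
      id <- add_atom("C", bracket_h = if (grepl("H", tok, fixed = TRUE)) 1L else 0L)
      if (!is.na(prev)) bond_to(prev, id, pending)
      pending <- 1L; prev <- id; i <- i + close
    } else if (ch %in% c("C", "O")) {
      id <- add_atom(ch)
      if (!is.na(prev)) bond_to(prev, id, pending)
      pending <- 1L; prev <- id; i <- i + 1L
    } else {
      stop("smiles_formula: unsupported character '", ch, "'")
    }
  }
  valence <- c(C = 4L, O = 2L)
  h <- vapply(atoms, function(a) {
    if (!is.na(a$bh)) a$bh else max(0L, valence[[a$el]] - a$deg)
  }, integer(1))
  els <- vapply(atoms, `[[`, character(1), "el")
  c(C = sum(els == "C"), H = sum(h), O = sum(els == "O"))
}

# --- RDKit oracle ----------------------------------------------------------
# Parses SMILES with the independent cheminformatics toolkit available in
# the environment's Python; returns data frame of carbon counts and Hill
# formulas (NA row on parse failure).
rdkit_parse <- function(smiles) {
  smi_file <- tempfile(fileext = ".smi")
  writeLines(smiles, smi_file)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    sprintf("lines = open(%s).read().split()", deparse(smi_file)),
    "for s in lines:",
    "    m = Chem.MolFromSmiles(s)",
    "    if m is None:",
    "        print('NA NA')",
    "    else:",
    "        nc = sum(1 for a in m.GetAtoms() if a.GetSymbol() == 'C')",
    "        print(nc, CalcMolFormula(m))"
  ), script)
  out <- system2("python", script, stdout = TRUE, stderr = FALSE)
  parts <- strsplit(out, " ", fixed = TRUE)
  data.frame(n_carbons = suppressWarnings(as.integer(vapply(parts, `[`, "", 1L))),
             formula = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# --- small builders --------------------------------------------------------
make_chain_graph <- function(n, hint = NULL) {
  ids <- as.character(seq_len(n))
  carbon_graph(data.frame(a = ids[-n], b = ids[-1L]), terminal_hint = hint)
}

loading_only_cluster <- function() {
  cluster_spec("solo", list(module_spec(
    0L, list(domain_spec("AT", signature = "HAFH"), domain_spec("ACP")),
    loading = TRUE)))
}

# Set the active flag of one domain kind in one module (1-based module
# position within the cluster list), returning the modified cluster.
set_domain_active <- function(cluster, module_pos, kind, active) {
  cluster$modules[[module_pos]]$domains <-
    lapply(cluster$modules[[module_pos]]$domains, function(d) {
      if (d$kind == kind) d$active <- active
      d
    })
  cluster
}

# Run the full synthetic pipeline for one seed; returns NULL when the drawn
# cluster admits no never-labeled reference carbon (an all-acetate product),
# otherwise a list with the truth and the best tiling.
run_pipeline <- function(seed, n_modules = 7L, inject = FALSE,
                         noise_unlabeled = 0, noise_enriched = 0) {
  cfg <- simulation_config(seed = seed, n_extension_modules = n_modules,
                           noise_sd_unlabeled = noise_unlabeled,
                           noise_sd_enriched_log = noise_enriched,
                           inject_post_pks_bond = inject)
  sim <- generate_cluster(cfg)
  product <- assemble(sim$cluster)
  lab <- tryCatch(simulate_labeling(product, config = cfg),
                  pks_data_error = function(e) NULL)
  if (is.null(lab)) return(NULL)
  calls <- lapply(lab$tables, function(t) classify_enriched(compute_enrichment(t)))
  tilings <- tile(lab$graph, calls)
  list(config = cfg, product = product, lab = lab, truth = lab$truth,
       best = tilings[[1L]], tilings = tilings,
       report = compare_prediction(product, tilings[[1L]]))
}

# Collect n generable pipeline replicates starting from seed_start.
collect_replicates <- function(n, seed_start, ...) {
  out <- list()
  seed <- seed_start
  while (length(out) < n) {
    r <- run_pipeline(seed, ...)
    if (!is.null(r)) out[[length(out) + 1L]] <- r
    seed <- seed + 1L
  }
  out
}

tiling_keys <- function(tilings) sort(vapply(tilings, `[[`, character(1), "key"))

# Enriched-call sets for the akaeolide skeleton with the overlapped
# 34.7 ppm signal (printed on the C-12 row) ascribed to C-15, as the
# propionate-derived C-21/C-12/C-11 fragment requires.
akaeolide_graph_calls <- function(threshold = 3) {
  tabs <- read_enrichment_csv(fixture("feeding_chloroakaeolide.csv"),
                              compound = "17-chloroakaeolide", reference = "2")
  calls <- lapply(tabs, function(t)
    classify_enriched(compute_enrichment(t, threshold = threshold), threshold))
  calls$acetate_1_13C[calls$acetate_1_13C == "12"] <- "15"
  calls
}

lorneic_graph_calls <- function(threshold = 3) {
  tabs <- read_enrichment_csv(fixture("feeding_lorneic_acid_a.csv"),
                              compound = "lorneic acid A", reference = "16")
  lapply(tabs, function(t)
    classify_enriched(compute_enrichment(t, threshold = threshold), threshold))
}
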