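#' @title Linear product assembly
#' @description Deterministic assembly of the predicted linear polyketide
#'   from a cluster description plus a rule configuration. Chain carbons are
#'   laid out starter-first (chain index 1 is the starter methyl terminus);
#'   each unit contributes its alpha carbon (C2) then its carboxyl-derived
#'   carbon (C1). The reductive domains of extension module i set the final
#'   oxidation level of the beta carbon present at module i's condensation,
#'   i.e. C1 of the previous unit: no KR leaves a ketone, KR alone a
#'   beta-hydroxyl, KR+DH an enoyl double bond paired with the new unit's
#'   C2, and KR+DH+ER a fully reduced methylene. The final unit's C1 is
#'   released as the carboxyl terminus (thioester hydrolysis); cyclizations
#'   are downstream tailoring and not modeled.
#' @name chain_assembly
NULL

OXIDATION_LEVELS <- c("methyl", "methylene", "methine", "hydroxyl",
                      "ketone", "enoyl", "carboxyl")

# Resolve each module of a cluster to its extender unit via the AT signature
# table. The loading module is always resolved to the acetate starter.
resolve_units <- function(cluster, config = default_rules()) {
  units <- vector("list", length(cluster$modules))
  for (i in seq_along(cluster$modules)) {
    m <- cluster$modules[[i]]
    at <- module_domain(m, "AT")
    if (m$loading) {
      units[[i]] <- extender_type("acetyl_starter", 0L)
      next
    }
    sub <- predict_substrate(at$signature, config)
    side <- at$side_carbons %||% sub$side_chain_carbons
    if (sub$name == "alkylmalonyl" && is.na(side)) {
      abort_validation(sprintf(
        "module %d: alkylmalonyl AT needs side_carbons to resolve the unit size",
        m$index))
    }
    units[[i]] <- extender_type(sub$name, side)
  }
  units
}

#' Assemble the predicted linear polyketide product of a cluster
#'
#' @param cluster A [cluster_spec()] object.
#' @param config A `rule_config`; defaults to [default_rules()].
#' @return An object of class `linear_product` with components:
#'   \describe{
#'     \item{carbons}{data frame of backbone carbons: `chain_index`, `unit`,
#'       `role` (`C2`/`C1`), `oxidation`, `stereo`, `geometry`.}
#'     \item{side_chains}{named list keyed by backbone `chain_index`, each a
#'       data frame of side carbons (`offset`, `oxidation`).}
#'     \item{units}{data frame of units: `unit`, `type`, `side_carbons`,
#'       `c2_index`, `c1_index`.}
#'     \item{n_carbons}{total carbon count (backbone + side chains).}
#'     \item{formula}{element counts, see [molecular_formula()].}
#'     \item{smiles}{SMILES string without stereo markers, see [to_smiles()].}
#'   }
#' @examples
#' lorn <- read_cluster(pks_extdata("lorneic_cluster.txt"))
#' prod <- assemble(lorn)
#' prod$n_carbons          # 17
#' count_double_bonds(prod)
#' @export
assemble <- function(cluster, config = default_rules()) {
  stopifnot(inherits(cluster, "pks_cluster"))
  units <- resolve_units(cluster, config)
  n_units <- length(units)
  L <- 2L * n_units

  oxidation <- rep("methylene", L)
  stereo <- rep("unspecified", L)
  geometry <- rep("none", L)
  oxidation[1L] <- "methyl"
  oxidation[L] <- "carboxyl"

  side_counts <- vapply(units, `[[`, integer(1), "side_chain_carbons")

  ext <- extension_modules(cluster)
  # extension module i processes the beta carbon C1 of unit i (the unit laid
  # down by the previous module); its own unit is unit i + 1
  for (i in seq_len(n_units - 1L)) {
    m <- ext[[i]]
    beta <- 2L * i
    alpha <- 2L * i + 1L
    kr <- has_domain(m, "KR")
    dh <- has_domain(m, "DH")
    er <- has_domain(m, "ER")
    krd <- if (kr) {
      fp <- module_domain(m, "KR")$kr_fingerprint
      if (!is.null(fp)) classify_kr(fp, config)
      else list(beta = "unspecified", alpha = "unspecified", geometry = "E")
    }
    if (!kr) {
      oxidation[beta] <- "ketone"
    } else if (dh && er) {
      oxidation[beta] <- "methylene"
      if (side_counts[i + 1L] > 0L) {
        cls <- module_domain(m, "ER")$er_class
        stereo[alpha] <- if (!is.null(cls)) classify_er(cls, config) else "unspecified"
      }
    } else if (dh) {
      oxidation[beta] <- "enoyl"
      oxidation[alpha] <- "enoyl"
      geometry[beta] <- geometry[alpha] <- krd$geometry
    } else {
      oxidation[beta] <- "hydroxyl"
      stereo[beta] <- krd$beta
      if (side_counts[i + 1L] > 0L) stereo[alpha] <- krd$alpha
    }
  }

  # saturated alpha carbons bearing a side chain are methines
  for (u in seq_len(n_units)) {
    a <- 2L * u - 1L
    if (side_counts[u] > 0L && oxidation[a] == "methylene") oxidation[a] <- "methine"
  }

  carbons <- data.frame(
    chain_index = seq_len(L),
    unit = rep(seq_len(n_units), each = 2L),
    role = rep(c("C2", "C1"), n_units),
    oxidation = oxidation,
    stereo = stereo,
    geometry = geometry,
    stringsAsFactors = FALSE
  )

  side_chains <- list()
  for (u in seq_len(n_units)) {
    s <- side_counts[u]
    if (s > 0L) {
      side_chains[[as.character(2L * u - 1L)]] <- data.frame(
        offset = seq_len(s),
        oxidation = c(rep("methylene", s - 1L), "methyl"),
        stringsAsFactors = FALSE
      )
    }
  }

  product <- structure(list(
    cluster_id = cluster$id,
    carbons = carbons,
    side_chains = side_chains,
    units = data.frame(
      unit = seq_len(n_units),
      type = vapply(units, `[[`, character(1), "name"),
      side_carbons = side_counts,
      c2_index = 2L * seq_len(n_units) - 1L,
      c1_index = 2L * seq_len(n_units),
      stringsAsFactors = FALSE
    ),
    n_carbons = L + sum(side_counts)
  ), class = "linear_product")
  product$formula <- molecular_formula(product)
  product$smiles <- to_smiles(product)
  product
}

#' @export
print.linear_product <- function(x, ...) {
  cat(sprintf("<linear_product> %s: %d carbons (%d backbone), %s\n",
              x$cluster_id %||% "?", x$n_carbons, nrow(x$carbons),
              formula_string(x$formula)))
  cat(sprintf("  units: %s\n", paste(unit_tokens(x$units), collapse = " ")))
  cat(sprintf("  double bonds: %d  smiles: %s\n", count_double_bonds(x), x$smiles))
  invisible(x)
}

# compact unit labels, alkylmalonyl carrying its side size (C5 != C3)
unit_tokens <- function(units_df) {
  ifelse(units_df$type == "alkylmalonyl",
         paste0(units_df$type, ":", units_df$side_carbons),
         units_df$type)
}

#' Count carbon-carbon double bonds in a linear product
#'
#' @param product A `linear_product`.
#' @return Number of enoyl pairs (each pair is one C=C).
#' @export
count_double_bonds <- function(product) {
  stopifnot(inherits(product, "linear_product"))
  sum(product$carbons$oxidation == "enoyl") %/% 2L
}

#' Molecular formula of a linear product
#'
#' Hydrogens are counted by valence completion of the acyclic chain model;
#' oxygens come from the carboxyl terminus (2), hydroxyls (1 each) and
#' ketones (1 each).
#'
#' @param product A `linear_product`.
#' @return Named integer vector with elements `C`, `H`, `O`.
#' @seealso [formula_string()] for Hill-order rendering.
#' @export
molecular_formula <- function(product) {
  stopifnot(inherits(product, "linear_product"))
  cb <- product$carbons
  has_side <- cb$chain_index %in% as.integer(names(product$side_chains))
  h <- integer(nrow(cb))
  o <- integer(nrow(cb))
  for (i in seq_len(nrow(cb))) {
    ox <- cb$oxidation[i]
    h[i] <- switch(ox,
      methyl = 3L, methylene = 2L, methine = 1L,
      hydroxyl = 2L,  # CH + OH
      ketone = 0L, carboxyl = 1L,
      enoyl = if (has_side[i]) 0L else 1L)
    o[i] <- switch(ox, hydroxyl = 1L, ketone = 1L, carboxyl = 2L, 0L)
  }
  side_h <- 0L
  for (sc in product$side_chains) {
    side_h <- side_h + sum(ifelse(sc$oxidation == "methyl", 3L, 2L))
  }
  c(C = product$n_carbons, H = sum(h) + side_h, O = sum(o))
}

#' Render an element-count vector as a Hill-order formula string
#'
#' @param formula Named counts as returned by [molecular_formula()].
#' @return A string such as `"C17H24O2"`.
#' @export
formula_string <- function(formula) {
  part <- function(el) {
    n <- formula[[el]] %||% 0L
    if (is.na(n) || n == 0L) "" else paste0(el, if (n > 1L) n else "")
  }
  paste0(part("C"), part("H"), part("O"))
}

#' Serialize a linear product as SMILES
#'
#' Writes the acyclic chain left to right from the starter methyl. By
#' default no stereocenters are emitted; with `include_stereo = TRUE`,
#' enoyl pairs receive `/`/`\` geometry markers and tetrahedral centers with
#' an `R`/`S` descriptor are written as `[C@@H]`/`[C@H]`. The tetrahedral
#' marks encode the recorded descriptor labels under a fixed local atom
#' order; they are not re-derived CIP assignments (descriptors are raw
#' chain-position labels, and CIP priorities can flip with molecular
#' context). Carbons whose descriptor is `unspecified` are silently written
#' without a mark.
#'
#' @param product A `linear_product`.
#' @param include_stereo Emit geometry and tetrahedral markers?
#' @return A SMILES string whose atom count equals `product$n_carbons` plus
#'   oxygens.
#' @export
to_smiles <- function(product, include_stereo = FALSE) {
  stopifnot(inherits(product, "linear_product"))
  cb <- product$carbons
  L <- nrow(cb)
  # double bond between positions p, p+1 iff p is a C1 position and both enoyl
  dbl_after <- vapply(seq_len(L - 1L), function(p) {
    p %% 2L == 0L && cb$oxidation[p] == "enoyl" && cb$oxidation[p + 1L] == "enoyl"
  }, logical(1))

  bond <- rep("", L)  # bond[p] precedes atom p (bond between p-1 and p)
  if (any(dbl_after)) bond[which(dbl_after) + 1L] <- "="
  if (include_stereo) {
    # walk conjugation-aware slash assignment: entry and exit single-bond
    # markers are equal for E, opposite for Z
    flip <- c("/" = "\\", "\\" = "/")
    for (p in which(dbl_after)) {
      geom <- cb$geometry[p]
      if (!geom %in% c("E", "Z")) next
      if (p >= 2L && bond[p] == "") bond[p] <- "/"
      m_in <- bond[p]
      if (m_in %in% c("/", "\\") && p + 2L <= L) {
        bond[p + 2L] <- if (geom == "E") m_in else flip[[m_in]]
      }
    }
  }

  atom <- character(L)
  for (p in seq_len(L)) {
    ox <- cb$oxidation[p]
    st <- cb$stereo[p]
    core <- if (include_stereo && st %in% c("R", "S") &&
                ox %in% c("methine", "hydroxyl")) {
      if (st == "R") "[C@@H]" else "[C@H]"
    } else "C"
    deco <- switch(ox,
      hydroxyl = "(O)", ketone = "(=O)", carboxyl = "(=O)O", "")
    side <- ""
    sc <- product$side_chains[[as.character(p)]]
    if (!is.null(sc)) side <- paste0("(", strrep("C", nrow(sc)), ")")
    atom[p] <- paste0(core, side, deco)
  }
  paste0(paste0(bond, atom), collapse = "")
}
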