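# Physicochemical space description (seven descriptors, Z-factor overlap
# statistic) and the two molecular scaffold definitions.

#' Seven physicochemical descriptors per compound
#'
#' Computes, for each standardized structure: molecular weight (MW, g/mol),
#' Wildman-Crippen n-octanol/water partition coefficient (WLOGP), Ertl
#' topological polar surface area (TPSA, square angstrom), number of
#' rotatable bonds (acyclic single bonds between two non-terminal heavy
#' atoms), fraction of sp3 carbon atoms (fCsp3), and the numbers of H-bond
#' acceptors (HBA, N/O-based) and donors (HBD). MW, WLOGP, TPSA, HBA and
#' HBD come from the OpenBabel descriptor implementations of the cited
#' atomic-contribution methods.
#'
#' @param compounds A data frame with columns `compound_id`, `smiles`.
#' @return A tibble with columns `compound_id`, `MW`, `WLOGP`, `TPSA`,
#'   `n_rotatable_bonds`, `fCsp3`, `HBA`, `HBD`.
#' @export
physchem_profile <- function(compounds) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  mols <- ob_parse_smiles(compounds$smiles, compounds$compound_id)
  props <- purrr::map(mols, ChemmineOB::prop_OB) |> bind_rows()
  mol2 <- ob_run(paste(compounds$smiles, compounds$compound_id),
                 "smi", "mol2", "-h")
  parsed <- parse_mol2(mol2)
  if (length(parsed) != nrow(compounds)) {
    abort("property computation failed for some compounds.",
          class = "revscreen_parse_error")
  }
  graph_props <- purrr::map(parsed, function(m) {
    carbons <- m$atoms$sybyl[m$atoms$element == "C"]
    fcsp3 <- if (length(carbons) == 0) 0 else mean(carbons == "C.3")
    rb <- rotatable_bonds(m$atoms, m$bonds)
    tibble(n_rotatable_bonds = nrow(rb), fCsp3 = fcsp3)
  }) |> bind_rows()
  tibble(
    compound_id = compounds$compound_id,
    MW = props$MW,
    WLOGP = props$logP,
    TPSA = props$TPSA,
    n_rotatable_bonds = graph_props$n_rotatable_bonds,
    fCsp3 = graph_props$fCsp3,
    HBA = props$HBA1,
    HBD = props$HBD
  )
}

#' Z-factor overlap statistic of two descriptor distributions
#'
#' `Z = 1 - 3 * (sigma_tr + sigma_ts) / |mu_tr - mu_ts|`. The statistic is
#' at most 1 and becomes strongly negative when the two distributions
#' overlap heavily relative to the separation of their means.
#'
#' @param mu_tr,sigma_tr Mean and standard deviation of the first
#'   (training) distribution.
#' @param mu_ts,sigma_ts Mean and standard deviation of the second (test)
#'   distribution.
#' @return Numeric vector of Z-factors.
#' @examples
#' z_factor(93.83, 46.259, 97.72, 41.506)  # about -66.7
#' @export
z_factor <- function(mu_tr, sigma_tr, mu_ts, sigma_ts) {
  if (any(sigma_tr < 0) || any(sigma_ts < 0)) {
    abort("standard deviations must be non-negative.",
          class = "revscreen_input_error")
  }
  if (any(mu_tr == mu_ts)) {
    abort("Z-factor is undefined for equal means.",
          class = "revscreen_undefined_statistic")
  }
  1 - 3 * (sigma_tr + sigma_ts) / abs(mu_tr - mu_ts)
}

#' Compare the physicochemical spaces of two compound sets
#'
#' @param profile_tr,profile_ts [physchem_profile()] tibbles for the
#'   training and test sets.
#' @return A tibble with one row per descriptor: means, standard deviations
#'   (sample SD) and the Z-factor.
#' @export
compare_physchem_spaces <- function(profile_tr, profile_ts) {
  descriptors <- c("WLOGP", "fCsp3", "n_rotatable_bonds", "TPSA",
                   "HBA", "HBD", "MW")
  purrr::map(descriptors, function(d) {
    tibble(
      descriptor = d,
      mu_tr = mean(profile_tr[[d]]), sigma_tr = sd(profile_tr[[d]]),
      mu_ts = mean(profile_ts[[d]]), sigma_ts = sd(profile_ts[[d]])
    )
  }) |>
    list_rbind() |>
    mutate(z_factor = z_factor(.data$mu_tr, .data$sigma_tr,
                               .data$mu_ts, .data$sigma_ts))
}

# ---------------------------------------------------------------------------
# Scaffolds
# ---------------------------------------------------------------------------

# Murcko core of a heavy-atom graph: iteratively strip terminal atoms until
# only ring systems and linkers remain. Returns an igraph (possibly empty).
murcko_graph <- function(g) {
  repeat {
    deg <- igraph::degree(g)
    leaves <- which(deg <= 1)
    if (length(leaves) == 0 || igraph::vcount(g) == 0) break
    g <- igraph::delete_vertices(g, leaves)
  }
  g
}

# Oprea abstraction of a Murcko core: contract acyclic linker atoms of
# degree 2 so every linker becomes a single edge; collapse parallel edges.
oprea_graph <- function(g) {
  repeat {
    if (igraph::vcount(g) == 0) break
    br <- as.integer(igraph::bridges(g))
    non_bridge <- setdiff(seq_len(igraph::ecount(g)), br)
    on_cycle <- rep(FALSE, igraph::vcount(g))
    if (length(non_bridge) > 0) {
      ends <- igraph::ends(g, non_bridge, names = FALSE)
      on_cycle[unique(as.vector(ends))] <- TRUE
    }
    deg <- igraph::degree(g)
    v <- which(!on_cycle & deg == 2)[1]
    if (is.na(v)) break
    nb <- as.integer(igraph::neighbors(g, v))
    g <- igraph::delete_vertices(
      igraph::add_edges(g, nb), v)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

# Canonical SMILES strings of a list of anonymized scaffold graphs
# (all-carbon, all-single-bond wire frames), via OpenBabel. Empty graphs
# map to "".
canonical_scaffold_smiles <- function(graphs) {
  out <- rep("", length(graphs))
  nonempty <- which(vapply(graphs, function(g) as.integer(igraph::vcount(g)), integer(1)) > 0)
  if (length(nonempty) == 0) return(out)
  blocks <- vapply(seq_along(nonempty), function(i) {
    graph_to_molblock(graphs[[nonempty[i]]], title = paste0("scf", i))
  }, character(1))
  can <- ob_run(paste(blocks, collapse = "\n"), "sdf", "can", character())
  rows <- strsplit(strsplit(can, "\n")[[1]], "\t")
  smi <- setNames(vapply(rows, `[`, character(1), 1),
                  vapply(rows, `[`, character(1), 2))
  out[nonempty] <- unname(smi[paste0("scf", seq_along(nonempty))])
  out
}

#' Molecular scaffolds of a compound table
#'
#' Computes both scaffold definitions used by the package for every
#' compound. The Murcko scaffold is the wire-like framework: ring systems
#' plus the linkers connecting them, with side chains removed, all atoms
#' made equivalent and bond orders leveled. The Oprea scaffold abstracts
#' the Murcko framework further by contracting every acyclic linker chain
#' to a single edge, leaving the ring/linker connectivity graph. Both are
#' returned as canonical strings (canonical within this package); acyclic
#' molecules have the empty scaffold `""`.
#'
#' @param compounds A data frame with columns `compound_id`, `smiles`.
#' @return A tibble with columns `compound_id`, `murcko`, `oprea`.
#' @export
compute_scaffolds <- function(compounds) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  mol2 <- ob_run(paste(compounds$smiles, compounds$compound_id),
                 "smi", "mol2", "-h")
  parsed <- parse_mol2(mol2)
  if (length(parsed) != nrow(compounds)) {
    abort("scaffold computation failed for some compounds.",
          class = "revscreen_parse_error")
  }
  cores <- lapply(parsed, function(m) murcko_graph(mol_graph(m)))
  opreas <- lapply(cores, oprea_graph)
  tibble(
    compound_id = compounds$compound_id,
    murcko = canonical_scaffold_smiles(cores),
    oprea = canonical_scaffold_smiles(opreas)
  )
}

#' @rdname compute_scaffolds
#' @param smiles Character vector of standardized SMILES.
#' @return `murcko_scaffold()` and `oprea_scaffold()` return character
#'   vectors of canonical scaffold strings.
#' @export
murcko_scaffold <- function(smiles) {
  compute_scaffolds(tibble(compound_id = paste0("m", seq_along(smiles)),
                           smiles = smiles))$murcko
}

#' @rdname compute_scaffolds
#' @export
oprea_scaffold <- function(smiles) {
  compute_scaffolds(tibble(compound_id = paste0("m", seq_along(smiles)),
                           smiles = smiles))$oprea
}

#' Average number of molecules described by one scaffold
#'
#' @param n_molecules Total number of molecules in the set.
#' @param n_scaffolds Number of distinct (non-empty) scaffolds.
#' @return `n_molecules / n_scaffolds`.
#' @export
molecules_per_scaffold <- function(n_molecules, n_scaffolds) {
  n_molecules / n_scaffolds
}

#' Percentage helper for scaffold bookkeeping
#'
#' @param n Count of interest.
#' @param total Reference total.
#' @return `100 * n / total`.
#' @export
pct_of <- function(n, total) 100 * n / total

#' Scaffold overlap statistics between two compound sets
#'
#' Counts distinct non-empty scaffolds in each set, the scaffolds shared
#' between them (with percentage shares relative to each set's scaffold
#' count), the average number of molecules per scaffold, and the molecules
#' described only by set-exclusive scaffolds. Acyclic molecules (empty
#' scaffold) are excluded from scaffold counts but included in molecule
#' totals.
#'
#' @param scaffolds_a,scaffolds_b [compute_scaffolds()] tibbles.
#' @param kind `"murcko"` or `"oprea"`.
#' @return A one-row tibble of overlap statistics.
#' @export
scaffold_set_stats <- function(scaffolds_a, scaffolds_b,
                               kind = c("murcko", "oprea")) {
  kind <- match.arg(kind)
  sa <- scaffolds_a[[kind]]
  sb <- scaffolds_b[[kind]]
  ua <- setdiff(unique(sa), "")
  ub <- setdiff(unique(sb), "")
  shared <- intersect(ua, ub)
  excl_a <- setdiff(ua, ub)
  excl_b <- setdiff(ub, ua)
  tibble(
    kind = kind,
    n_molecules_a = length(sa), n_molecules_b = length(sb),
    n_scaffolds_a = length(ua), n_scaffolds_b = length(ub),
    n_shared = length(shared),
    pct_shared_a = pct_of(length(shared), length(ua)),
    pct_shared_b = pct_of(length(shared), length(ub)),
    mols_per_scaffold_a = molecules_per_scaffold(length(sa), length(ua)),
    mols_per_scaffold_b = molecules_per_scaffold(length(sb), length(ub)),
    n_molecules_exclusive_a = sum(sa %in% excl_a),
    n_molecules_exclusive_b = sum(sb %in% excl_b)
  )
}
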