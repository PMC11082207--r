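# ES5D shape descriptors, conformer generation and the featurization front
# end used by both the training and the screening sides of the engine.

# Coarse-grained Wildman-Crippen atomic lipophilicity contributions keyed on
# the SYBYL atom type assigned by OpenBabel. A type-averaged table is used
# rather than the full SMARTS-typed scheme; the ES5D lipophilicity dimension
# only requires a per-atom contribution on the log-unit scale.
SYBYL_LOGP <- c(
  "C.3" = 0.1441, "C.2" = 0.1551, "C.1" = 0.1551, "C.ar" = 0.2955,
  "C.cat" = 0.2955,
  "N.3" = -0.6000, "N.2" = -0.2000, "N.1" = -0.2000, "N.ar" = -0.2604,
  "N.am" = -0.6000, "N.pl3" = -0.4458, "N.4" = -0.6000,
  "O.3" = -0.2893, "O.2" = -0.0500, "O.co2" = -0.5600, "O.spc" = -0.2893,
  "S.3" = 0.6482, "S.2" = 0.6482, "S.o" = -0.0024, "S.o2" = -0.0024,
  "P.3" = 0.8612,
  "F" = 0.4202, "CL" = 0.6895, "BR" = 0.8456, "I" = 0.8857,
  "H" = 0.1230, "H.spc" = 0.1230
)

atom_logp <- function(sybyl) {
  v <- SYBYL_LOGP[sybyl]
  v[is.na(v)] <- 0
  unname(v)
}

#' ES5D descriptor of one conformer
#'
#' Embeds every atom of a conformer as a point in a 5-dimensional space --
#' the three Cartesian coordinates plus the Gasteiger partial charge and the
#' atomic lipophilicity contribution, each scaled to an angstrom-comparable
#' range -- then measures the distances between all atoms and six reference
#' centroids encompassing the structure. For each centroid the mean, the
#' standard deviation and the sign-preserving cube root of the third central
#' moment of the distances are stored, giving an 18-dimensional shape vector
#' that is invariant under rigid rotation and translation of the conformer.
#'
#' The six centroids are: the 5D barycentre; the atom furthest from the
#' barycentre; the atom furthest from that atom; and three extremal points
#' placed on the axis perpendicular to the plane of the first three
#' centroids, probing the maximum and minimum of the charge dimension and
#' the maximum of the lipophilicity dimension. Degenerate geometries
#' (fewer than three atoms, collinear structures) fall back to duplicating
#' the barycentre so that 18 values are always returned.
#'
#' @param conformer A data frame with one row per atom and columns `x`, `y`,
#'   `z` (coordinates in angstrom), `charge` (partial charge, e) and `lipo`
#'   (atomic lipophilicity contribution, log units).
#' @param charge_scale Scaling of the charge dimension, angstrom per e
#'   (default 25, the ElectroShape convention).
#' @param logp_scale Scaling of the lipophilicity dimension, angstrom per
#'   log unit (default 10, chosen so the per-atom range of this dimension is
#'   comparable to atomic coordinates).
#' @return A numeric vector of length 18, ordered as (mean, sd, cube-rooted
#'   third moment) for each of the six centroids.
#' @export
compute_es5d <- function(conformer, charge_scale = 25, logp_scale = 10) {
  conformer <- as.data.frame(conformer)
  need <- c("x", "y", "z", "charge", "lipo")
  if (!all(need %in% names(conformer))) {
    abort(paste("conformer must have columns", paste(need, collapse = ", ")),
          class = "revscreen_descriptor_error")
  }
  if (nrow(conformer) < 1 || anyNA(conformer[, need])) {
    abort("conformer atoms must have coordinates, charges and lipophilicity.",
          class = "revscreen_descriptor_error")
  }
  P <- cbind(conformer$x, conformer$y, conformer$z,
             charge_scale * conformer$charge, logp_scale * conformer$lipo)
  es5d_moments(P, es5d_centroids(P))
}

# Six 5D centroids for an atom-point matrix P (n x 5).
es5d_centroids <- function(P) {
  c1 <- colMeans(P)
  d1 <- sqrt(rowSums(sweep(P, 2, c1)^2))
  c2 <- P[which.max(d1), ]
  d2 <- sqrt(rowSums(sweep(P, 2, c2)^2))
  c3 <- P[which.max(d2), ]
  a <- (c2 - c1)[1:3]
  b <- (c3 - c2)[1:3]
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  nv <- sqrt(sum(v^2))
  if (nrow(P) < 3 || nv < 1e-8) {
    # degenerate geometry: duplicate the barycentre
    return(rbind(c1, c2, c3, c1, c1, c1, deparse.level = 0))
  }
  u <- v / nv
  r <- max(sqrt(rowSums(sweep(P[, 1:3, drop = FALSE], 2, c1[1:3])^2)))
  qmax <- max(P[, 4]); qmin <- min(P[, 4]); qbar <- mean(P[, 4])
  lmax <- max(P[, 5]); lbar <- mean(P[, 5])
  c4 <- c(c1[1:3] + r * u, qmax, lbar)
  c5 <- c(c1[1:3] + r * u, qmin, lbar)
  c6 <- c(c1[1:3] - r * u, qbar, lmax)
  rbind(c1, c2, c3, c4, c5, c6, deparse.level = 0)
}

es5d_moments <- function(P, centroids) {
  out <- numeric(18)
  for (p in seq_len(6)) {
    d <- sqrt(rowSums(sweep(P, 2, centroids[p, ])^2))
    mu <- mean(d)
    m2 <- mean((d - mu)^2)
    m3 <- mean((d - mu)^3)
    out[(p - 1) * 3 + 1:3] <- c(mu, sqrt(m2), sign(m3) * abs(m3)^(1 / 3))
  }
  out
}

# ---------------------------------------------------------------------------
# Conformer generation: deterministic rule-based 3D embedding via
# `obabel --gen3d fast` (with Gasteiger charges), followed by torsion driving
# of the rotatable bonds in 120-degree steps. Rotamers are ranked by a
# steric-clash score and the `n` least-clashing distinct rotamers are kept.
# The procedure is a pure function of (structure, seed).
# ---------------------------------------------------------------------------

#' Generate conformer sets for standardized structures
#'
#' @param compounds A data frame with columns `compound_id` and `smiles`
#'   (standardized SMILES).
#' @param conformers Maximum number of conformers to keep per compound
#'   (1 to 20).
#' @param seed Integer seed controlling rotamer subsampling for highly
#'   flexible molecules.
#' @return A named list (one element per compound) of conformer sets; each
#'   set is a list of atom tibbles with columns `element`, `x`, `y`, `z`,
#'   `charge`, `lipo`, `sybyl`.
#' @export
generate_conformers <- function(compounds, conformers = 20, seed = 1L) {
  stopifnot(conformers >= 1, conformers <= 20)
  lines <- paste(compounds$smiles, compounds$compound_id)
  mol2 <- ob_gen3d(lines)
  mols <- parse_mol2(mol2)
  if (length(mols) != nrow(compounds)) {
    abort("3D generation failed for one or more compounds.",
          class = "revscreen_parse_error")
  }
  names(mols) <- compounds$compound_id
  lapply(mols, function(m) {
    base <- m$atoms
    base$lipo <- atom_logp(base$sybyl)
    if (conformers == 1) return(list(base))
    rotamers(base, m$bonds, n = conformers, seed = seed)
  })
}

# Deterministic torsion-driven rotamer enumeration for one molecule.
rotamers <- function(atoms, bonds, n, seed, max_combos = 243L) {
  rot <- rotatable_bonds(atoms, bonds)
  if (nrow(rot) == 0) return(list(atoms))
  k <- nrow(rot)
  combos <- as.matrix(do.call(expand.grid, rep(list(c(0, 120, 240)), k)))
  if (nrow(combos) > max_combos) {
    set.seed(seed)
    keep <- sort(sample(seq_len(nrow(combos)) [-1], max_combos - 1L))
    combos <- combos[c(1L, keep), , drop = FALSE]
  }
  xyz0 <- as.matrix(atoms[, c("x", "y", "z")])
  nb <- nonbonded_pairs(nrow(atoms), bonds)
  scored <- lapply(seq_len(nrow(combos)), function(i) {
    xyz <- xyz0
    for (j in seq_len(k)) {
      ang <- combos[i, j]
      if (ang != 0) {
        xyz <- rotate_about_bond(xyz, rot$from[j], rot$to[j],
                                 rot$side[[j]], ang * pi / 180)
      }
    }
    list(xyz = xyz, clash = clash_score(xyz, nb))
  })
  ord <- order(vapply(scored, `[[`, numeric(1), "clash"))
  keep <- head(ord, n)
  lapply(scored[keep], function(s) {
    out <- atoms
    out$x <- s$xyz[, 1]; out$y <- s$xyz[, 2]; out$z <- s$xyz[, 3]
    out
  })
}

# Rotatable bonds: single, acyclic, both endpoints heavy with heavy degree
# >= 2. `side` holds the atom indices (including hydrogens) rotated with the
# `to` end of the bond.
rotatable_bonds <- function(atoms, bonds) {
  g <- igraph::graph_from_data_frame(bonds[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(nrow(atoms))))
  heavy <- atoms$element != "H"
  hdeg <- vapply(seq_len(nrow(atoms)), function(i) {
    nbrs <- as.integer(igraph::neighbors(g, i))
    sum(heavy[nbrs])
  }, numeric(1))
  bridges <- igraph::bridges(g)
  bridge_ids <- as.integer(bridges)
  out <- list()
  for (b in bridge_ids) {
    ends <- igraph::ends(g, b)
    i <- as.integer(ends[1]); j <- as.integer(ends[2])
    bi <- which((bonds$from == i & bonds$to == j) |
                  (bonds$from == j & bonds$to == i))[1]
    if (bonds$type[bi] != "1") next
    if (!heavy[i] || !heavy[j] || hdeg[i] < 2 || hdeg[j] < 2) next
    g2 <- igraph::delete_edges(g, b)
    comp <- igraph::components(g2)$membership
    side <- which(comp == comp[j] & seq_len(nrow(atoms)) != j)
    if (length(side) == 0 || length(side) == nrow(atoms) - 1) next
    # rotate the smaller fragment for numerical tidiness
    if (length(side) > nrow(atoms) / 2) {
      side <- which(comp == comp[i] & seq_len(nrow(atoms)) != i)
      tmp <- i; i <- j; j <- tmp
    }
    out[[length(out) + 1]] <- tibble(from = i, to = j, side = list(side))
  }
  if (length(out) == 0) {
    return(tibble(from = integer(), to = integer(), side = list()))
  }
  bind_rows(out)
}

# Rodrigues rotation of `side` atoms about the axis through atoms i -> j.
rotate_about_bond <- function(xyz, i, j, side, angle) {
  axis <- xyz[j, ] - xyz[i, ]
  axis <- axis / sqrt(sum(axis^2))
  p <- sweep(xyz[side, , drop = FALSE], 2, xyz[i, ])
  cosa <- cos(angle); sina <- sin(angle)
  dotp <- p %*% axis
  crossp <- cbind(axis[2] * p[, 3] - axis[3] * p[, 2],
                  axis[3] * p[, 1] - axis[1] * p[, 3],
                  axis[1] * p[, 2] - axis[2] * p[, 1])
  rot <- p * cosa + crossp * sina +
    outer(as.vector(dotp), axis) * (1 - cosa)
  xyz[side, ] <- sweep(rot, 2, xyz[i, ], "+")
  xyz
}

# Atom pairs separated by 3+ bonds, used for the steric-clash score.
nonbonded_pairs <- function(n_atoms, bonds) {
  g <- igraph::graph_from_data_frame(bonds[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(n_atoms)))
  D <- igraph::distances(g)
  which(upper.tri(D) & D >= 3, arr.ind = TRUE)
}

# Quadratic overlap penalty below a 2.2 angstrom contact distance.
clash_score <- function(xyz, pairs, r0 = 2.2) {
  if (nrow(pairs) == 0) return(0)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  sum(pmax(0, r0 - d)^2)
}

#' Path fingerprint of standardized structures
#'
#' Computes the 1024-bit path-based fingerprint (presence/absence of linear
#' fragments of 1 to 7 atoms, FP2 dialect) for each structure. Deterministic:
#' identical standardized structures give bitwise-identical fingerprints.
#'
#' @param smiles Character vector of standardized SMILES.
#' @return An integer 0/1 matrix with one row per structure and 1024 columns.
#' @export
compute_fingerprint <- function(smiles) {
  fp_matrix(ob_parse_smiles(smiles, paste0("m", seq_along(smiles))))
}

#' Write conformer sets as multi-MOL2 files
#'
#' Writes one multi-conformer MOL2 file per compound (atoms with Gasteiger
#' partial charges and SYBYL types, bonds shared across conformers), the
#' storage format of the conformer ensembles.
#'
#' @inheritParams generate_conformers
#' @param dir Output directory (one `<compound_id>.mol2` per compound).
#' @return Invisibly, the written file paths.
#' @export
write_conformers_mol2 <- function(compounds, dir, conformers = 20,
                                  seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol2 <- ob_gen3d(paste(compounds$smiles, compounds$compound_id))
  mols <- parse_mol2(mol2)
  names(mols) <- compounds$compound_id
  paths <- vapply(compounds$compound_id, function(id) {
    m <- mols[[id]]
    sets <- if (conformers == 1) list(m$atoms)
            else rotamers(m$atoms, m$bonds, n = conformers, seed = seed)
    blocks <- vapply(sets, function(at) mol2_block(id, at, m$bonds),
                     character(1))
    path <- file.path(dir, paste0(id, ".mol2"))
    writeLines(paste(blocks, collapse = "\n"), path)
    path
  }, character(1))
  invisible(paths)
}

# One MOL2 text block from an atom tibble and a bond tibble.
mol2_block <- function(name, atoms, bonds) {
  paste(c(
    "@<TRIPOS>MOLECULE",
    name,
    sprintf(" %d %d 0 0 0", nrow(atoms), nrow(bonds)),
    "SMALL",
    "GASTEIGER",
    "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-8s%10.4f%10.4f%10.4f %-8s%3d  %-8s%10.4f",
            seq_len(nrow(atoms)), atoms$element, atoms$x, atoms$y, atoms$z,
            atoms$sybyl, 1L, "UNL1", atoms$charge),
    "@<TRIPOS>BOND",
    sprintf("%6d%6d%6d %s", seq_len(nrow(bonds)), bonds$from, bonds$to,
            bonds$type)
  ), collapse = "\n")
}

# ---------------------------------------------------------------------------
# Featurization front end
# ---------------------------------------------------------------------------

#' Compute fingerprints and ES5D conformer descriptors for a compound table
#'
#' The one-stop featurizer of the engine: for every compound it computes the
#' path-based 1024-bit fingerprint (linear fragments of 1 to 7 atoms, FP2
#' dialect) of the standardized structure, generates a deterministic set of
#' 3D conformers with Gasteiger partial charges, and encodes each conformer
#' as an 18-dimensional ES5D vector.
#'
#' @param compounds A data frame with columns `compound_id` and `smiles`
#'   (standardized SMILES, see [standardize_structure()]).
#' @inheritParams generate_conformers
#' @inheritParams compute_es5d
#' @return An object of class `revscreen_descriptors` with elements
#'   `fp` (integer matrix, compounds x 1024 bits), `es5d` (named list of
#'   conformer x 18 matrices) and `heavy_atoms` (named integer vector).
#' @export
featurize <- function(compounds, conformers = 20, seed = 1L,
                      charge_scale = 25, logp_scale = 10) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id)) {
    abort("compound_id must be unique.", class = "revscreen_input_error")
  }
  ids <- compounds$compound_id
  mols <- ob_parse_smiles(compounds$smiles, ids)
  fp <- fp_matrix(mols)
  rownames(fp) <- ids

  confs <- generate_conformers(compounds, conformers = conformers, seed = seed)
  es5d <- lapply(confs, function(set) {
    do.call(rbind, lapply(set, compute_es5d,
                          charge_scale = charge_scale,
                          logp_scale = logp_scale))
  })
  heavy <- vapply(confs, function(set) sum(set[[1]]$element != "H"), integer(1))

  structure(
    list(fp = fp, es5d = es5d, heavy_atoms = heavy,
         params = list(conformers = conformers, seed = seed,
                       charge_scale = charge_scale, logp_scale = logp_scale)),
    class = "revscreen_descriptors"
  )
}

#' @export
print.revscreen_descriptors <- function(x, ...) {
  cat("<revscreen_descriptors>\n")
  cat("  compounds: ", nrow(x$fp), "\n", sep = "")
  cat("  fingerprint bits: ", ncol(x$fp), "\n", sep = "")
  cat("  conformers per compound: ",
      paste(range(vapply(x$es5d, nrow, integer(1))), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn featurize Tidy per-compound summary of a descriptor object.
#' @param x A `revscreen_descriptors` object.
#' @param ... Unused.
#' @method tidy revscreen_descriptors
#' @export
tidy.revscreen_descriptors <- function(x, ...) {
  tibble(
    compound_id = rownames(x$fp),
    heavy_atoms = unname(x$heavy_atoms[rownames(x$fp)]),
    n_conformers = vapply(x$es5d[rownames(x$fp)], nrow, integer(1)),
    fp_popcount = rowSums(x$fp)
  )
}

# ---------------------------------------------------------------------------
# Descriptor cache: plain-text, bit-exact round trip.
# ---------------------------------------------------------------------------

fp_to_hex <- function(bits) {
  stopifnot(length(bits) %% 4 == 0)
  nib <- matrix(bits, nrow = 4)
  vals <- as.integer(8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ])
  paste(strsplit("0123456789abcdef", "")[[1]][vals + 1], collapse = "")
}

hex_to_fp <- function(hex) {
  vals <- match(strsplit(tolower(hex), "")[[1]],
                strsplit("0123456789abcdef", "")[[1]]) - 1L
  as.integer(vapply(vals, function(v) {
    c(v %/% 8, (v %/% 4) %% 2, (v %/% 2) %% 2, v %% 2)
  }, numeric(4)))
}

#' Write / read a descriptor cache
#'
#' Serializes a [featurize()] result to two TSV files, `fingerprints.tsv`
#' (compound id, heavy atoms, 1024-bit fingerprint as 256 hex characters)
#' and `es5d.tsv` (compound id, conformer index, 18 descriptor values at
#' full double precision). The round trip is bit-exact.
#'
#' @param x A `revscreen_descriptors` object.
#' @param dir Directory for the cache files (created if needed).
#' @return `write_descriptors()` returns `dir` invisibly;
#'   `read_descriptors()` returns a `revscreen_descriptors` object.
#' @export
write_descriptors <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- rownames(x$fp)
  fp_tbl <- tibble(
    compound_id = ids,
    heavy_atoms = unname(x$heavy_atoms[ids]),
    fp_hex = vapply(ids, function(i) fp_to_hex(x$fp[i, ]), character(1))
  )
  readr::write_tsv(fp_tbl, file.path(dir, "fingerprints.tsv"))
  es_tbl <- purrr::imap(x$es5d, function(m, id) {
    tibble(compound_id = id, conformer = seq_len(nrow(m)),
           as_tibble(matrix(sprintf("%.17g", m), nrow(m), 18,
                            dimnames = list(NULL, sprintf("d%02d", 1:18)))))
  }) |> list_rbind()
  readr::write_tsv(es_tbl, file.path(dir, "es5d.tsv"))
  invisible(dir)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(dir) {
  fp_tbl <- readr::read_tsv(file.path(dir, "fingerprints.tsv"),
                            col_types = "cic", progress = FALSE)
  fp <- do.call(rbind, lapply(fp_tbl$fp_hex, hex_to_fp))
  rownames(fp) <- fp_tbl$compound_id
  es_tbl <- readr::read_tsv(file.path(dir, "es5d.tsv"),
                            col_types = readr::cols(
                              compound_id = "c", conformer = "i",
                              .default = "c"), progress = FALSE)
  es5d <- lapply(split(es_tbl, factor(es_tbl$compound_id,
                                      levels = unique(es_tbl$compound_id))),
                 function(d) {
                   m <- apply(as.matrix(d[, sprintf("d%02d", 1:18)]), c(1, 2),
                              as.numeric)
                   dimnames(m) <- NULL
                   matrix(m, nrow = nrow(d), ncol = 18)
                 })
  es5d <- es5d[fp_tbl$compound_id]
  structure(
    list(fp = fp, es5d = es5d,
         heavy_atoms = setNames(fp_tbl$heavy_atoms, fp_tbl$compound_id),
         params = list()),
    class = "revscreen_descriptors"
  )
}
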