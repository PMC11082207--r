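# Thin wrappers around the OpenBabel toolchain (obabel CLI + ChemmineOB).
# All chemistry I/O in the package funnels through these helpers so that the
# rest of the code manipulates plain tibbles, matrices and igraph objects.

ob_available <- function() nzchar(Sys.which("obabel"))

assert_obabel <- function() {
  if (!ob_available()) {
    abort("The `obabel` executable was not found on the PATH.",
          class = "revscreen_obabel_missing")
  }
}

# Run obabel on `input` text lines, return output file contents as a string.
ob_run <- function(input, in_fmt, out_fmt, args = character()) {
  assert_obabel()
  fin <- tempfile(fileext = paste0(".", in_fmt))
  fout <- tempfile(fileext = paste0(".", out_fmt))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  status <- suppressWarnings(system2(
    "obabel",
    c(paste0("-i", in_fmt), fin, paste0("-o", out_fmt), "-O", fout, args),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(fout)) {
    abort("obabel conversion failed.", class = "revscreen_parse_error")
  }
  paste(readLines(fout, warn = FALSE), collapse = "\n")
}

# Deterministic 3D embedding with Gasteiger charges. The coordinate builder
# draws its stochastic search moves from a clock-seeded generator, so the
# conversion runs in its own clean R subprocess with the package's
# interposer library (src/timeshim.c) preloaded, which pins the entropy
# source: identical input then always yields identical coordinates.
ob_gen3d <- function(input_lines) {
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input_lines, fin)
  rscript <- file.path(R.home("bin"), "Rscript")
  code <- sprintf(
    paste0("suppressMessages(ChemmineOB::convertFormatFile('SMI','MOL2',",
           "'%s','%s',options=data.frame(names=c('gen3d','partialcharge'),",
           "args=c('','gasteiger'))))"),
    fin, fout)
  shim <- system.file("libs", paste0("revscreen", .Platform$dynlib.ext),
                      package = "revscreen")
  env <- if (nzchar(shim)) paste0("LD_PRELOAD=", shim) else character(0)
  status <- suppressWarnings(
    system2(rscript, c("--vanilla", "-e", shQuote(code)),
            stdout = FALSE, stderr = FALSE, env = env))
  if (!identical(status, 0L) || !file.exists(fout)) {
    abort("3D structure generation failed.", class = "revscreen_parse_error")
  }
  paste(readLines(fout, warn = FALSE), collapse = "\n")
}

# SMILES text ("smiles<space>id" lines) -> named OBMol list, in input order.
ob_parse_smiles <- function(smiles, ids = names(smiles)) {
  stopifnot(length(smiles) > 0)
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  txt <- paste(paste(smiles, ids), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", txt, identity)
  if (length(mols) != length(smiles)) {
    abort("one or more SMILES could not be parsed.",
          class = "revscreen_parse_error")
  }
  names(mols) <- ids
  mols
}

# Elemental formula string -> heavy (non-hydrogen) atom count.
heavy_atoms_from_formula <- function(formula) {
  vapply(formula, function(f) {
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    el <- sub("[0-9]*$", "", toks)
    ct <- as.integer(sub("^[A-Z][a-z]?", "", toks))
    ct[is.na(ct)] <- 1L
    sum(ct[el != "H"])
  }, integer(1), USE.NAMES = FALSE)
}

# Count heavy atoms per SMILES (via OpenBabel formula).
count_heavy_atoms <- function(smiles) {
  mols <- ob_parse_smiles(smiles)
  fml <- vapply(mols, function(m) ChemmineOB::prop_OB(m)$formula, character(1))
  heavy_atoms_from_formula(fml)
}

# Parse a (multi-)MOL2 string into a list of molecule records:
# atoms tibble (element, x, y, z, charge, sybyl) and bonds tibble
# (from, to, type). Hydrogens retained.
parse_mol2 <- function(mol2_text) {
  f <- tempfile(fileext = ".mol2")
  on.exit(unlink(f), add = TRUE)
  writeLines(mol2_text, f)
  mols <- bio3d::read.mol2(f)
  if (inherits(mols, "mol2")) mols <- list(mols)
  out <- list()
  for (m in mols) {
    at <- m$atom
    bd <- m$bond
    bonds <- tibble(
      from = as.integer(bd$origin),
      to = as.integer(bd$target),
      type = as.character(bd$type)
    )
    # consecutive records of the same molecule (conformers) come back as
    # one object with an n_conf x 3*natoms coordinate matrix
    n_conf <- if (is.matrix(m$xyz)) nrow(m$xyz) else 1L
    for (k in seq_len(n_conf)) {
      xyz <- if (is.matrix(m$xyz)) {
        matrix(m$xyz[k, ], ncol = 3, byrow = TRUE)
      } else {
        cbind(at$x, at$y, at$z)
      }
      out[[length(out) + 1]] <- list(
        name = m$name,
        atoms = tibble(
          element = toupper(sub("\\..*$", "", at$elety)),
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          charge = at$charge,
          sybyl = at$elety
        ),
        bonds = bonds
      )
    }
  }
  out
}

# FP2 fingerprints of a list of parsed molecules as an integer matrix
# (a single molecule comes back as a bare vector).
fp_matrix <- function(mols) {
  fp <- ChemmineOB::fingerprint_OB(mols, "FP2")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  storage.mode(fp) <- "integer"
  rownames(fp) <- NULL
  fp
}

# Heavy-atom connectivity graph of a parsed mol2 molecule.
# Vertices keep element and sybyl type; edges keep the mol2 bond type.
mol_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  idx <- match(seq_len(nrow(mol$atoms)), heavy)
  bd <- mol$bonds
  keep <- !is.na(idx[bd$from]) & !is.na(idx[bd$to])
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[bd$from[keep]], to = idx[bd$to[keep]],
               type = bd$type[keep]),
    directed = FALSE,
    vertices = data.frame(
      name = seq_along(heavy),
      element = mol$atoms$element[heavy],
      sybyl = mol$atoms$sybyl[heavy]
    )
  )
  g
}

# Write an anonymized scaffold graph (all carbon, all single bonds) as a
# V2000 molblock so OpenBabel can canonicalize it.
graph_to_molblock <- function(g, title = "scaffold") {
  n <- igraph::vcount(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  header <- c(title, "  revscreen", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n, nrow(e)))
  atoms <- rep(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, "C"), n)
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", e[, 1], e[, 2], 1L)
  paste(c(header, atoms, bonds, "M  END", "$$$$"), collapse = "\n")
}
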