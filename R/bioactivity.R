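# Bioactivity data model: standardization contract, activity labelling,
# filtering, set-overlap removal and the flat-file layouts.

MEASURE_TYPES <- c("IC50", "EC50", "Ki", "KD", "Kic", "Km")
ASSAY_CLASSES <- c("binding", "enzymatic", "generic", "second_messenger",
                   "electrophysiology", "transactivation")
SPECIES <- c("human", "rat", "mouse")
ACTIVE_UM <- 10
INACTIVE_UM <- 100

#' Standardize raw structures to canonical SMILES
#'
#' Applies the standardization contract used throughout the package: the
#' largest organic fragment is kept (counter-ions and solvents removed), the
#' net charge is neutralized where chemically valid, the structure is
#' re-kekulized during normalization, and the canonical (aromatic-notation)
#' SMILES is returned. The operation is idempotent and
#' stereochemistry-preserving; structure identity elsewhere in the package
#' (overlap removal, held-out set construction) is canonical-SMILES equality
#' after this standardization.
#'
#' @param smiles Character vector of raw SMILES.
#' @param ids Optional record identifiers used in error messages.
#' @return Character vector of standardized SMILES, same length and order.
#' @examples
#' \dontrun{
#' standardize_structure(c("CC(=O)[O-].[Na+]", "CCO.O"))
#' }
#' @export
standardize_structure <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  if (is.null(ids)) ids <- paste0("s", seq_along(smiles))
  pass <- function(smi) {
    out <- tryCatch(
      ob_run(paste(smi, ids), "smi", "can", c("-r", "--neutralize")),
      error = function(e) abort("structure standardization failed.",
                                class = "revscreen_parse_error")
    )
    rows <- strsplit(strsplit(out, "\n")[[1]], "\t")
    got <- setNames(vapply(rows, `[`, character(1), 1),
                    vapply(rows, `[`, character(1), 2))
    if (!all(ids %in% names(got))) {
      bad <- ids[!ids %in% names(got)]
      abort(paste0("unparsable structure for record(s): ",
                   paste(bad, collapse = ", ")),
            class = "revscreen_parse_error")
    }
    unname(got[ids])
  }
  # iterate to the canonical fixed point (ring-closure notation can move
  # on a first re-canonicalization); two passes suffice in practice
  out <- pass(smiles)
  again <- pass(out)
  if (!identical(again, out)) out <- pass(again) else out <- again
  out
}

#' Label the activity of one compound-target pair
#'
#' A pair is `active` when any qualifying measurement is at or below
#' 10 uM, `inactive` when all measurements are at or above 100 uM, and
#' `gray` otherwise (the 10-100 uM gray area, excluded from both training
#' labels). When active and inactive evidence conflict, activity takes
#' precedence.
#'
#' @param value_uM Numeric vector of activity measurements in micromolar.
#' @return One of `"active"`, `"inactive"`, `"gray"`.
#' @examples
#' classify_activity(5)      # active
#' classify_activity(150)    # inactive
#' classify_activity(50)     # gray
#' @export
classify_activity <- function(value_uM) {
  if (length(value_uM) == 0 || anyNA(value_uM)) {
    abort("at least one non-missing measurement is required.",
          class = "revscreen_input_error")
  }
  if (any(value_uM <= 0)) {
    abort("activity values must be positive.", class = "revscreen_input_error")
  }
  if (any(value_uM <= ACTIVE_UM)) return("active")
  if (all(value_uM >= INACTIVE_UM)) return("inactive")
  "gray"
}

#' Label every compound-target pair of an activity table
#'
#' @param activities A data frame of activity records with columns
#'   `compound_id`, `target_id`, `value_uM`.
#' @return A tibble with one row per (compound, target) pair and a `label`
#'   column (`active` / `inactive` / `gray`).
#' @export
label_activities <- function(activities) {
  activities |>
    group_by(.data$compound_id, .data$target_id) |>
    summarise(label = classify_activity(.data$value_uM), .groups = "drop")
}

#' Bundle compounds and activity records into a bioactivity set
#'
#' A light container pairing a compound table with its activity records and
#' derived per-pair labels; most pipeline functions accept and return it.
#'
#' @param compounds Tibble with columns `compound_id`, `smiles` and
#'   optionally `heavy_atoms` (computed when absent).
#' @param activities Tibble of activity records (`compound_id`, `target_id`,
#'   `measure_type`, `value_uM`, `assay_class`, `species`).
#' @return An object of class `bioactivity_set`: a list with elements
#'   `compounds`, `activities`, `labels`.
#' @export
bioactivity_set <- function(compounds, activities) {
  compounds <- as_tibble(compounds)
  activities <- as_tibble(activities)
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)),
            all(c("compound_id", "target_id", "value_uM") %in% names(activities)))
  if (!all(activities$compound_id %in% compounds$compound_id)) {
    abort("every activity record must reference a known compound.",
          class = "revscreen_input_error")
  }
  if (!"heavy_atoms" %in% names(compounds)) {
    compounds$heavy_atoms <- count_heavy_atoms(compounds$smiles)
  }
  structure(
    list(compounds = compounds, activities = activities,
         labels = label_activities(activities)),
    class = "bioactivity_set"
  )
}

#' @export
print.bioactivity_set <- function(x, ...) {
  cat("<bioactivity_set>\n")
  cat("  compounds: ", nrow(x$compounds), "\n", sep = "")
  cat("  activity records: ", nrow(x$activities),
      " on ", dplyr::n_distinct(x$activities$target_id), " targets\n", sep = "")
  lb <- table(x$labels$label)
  cat("  pair labels: ", paste(names(lb), lb, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Apply the extraction filters to a bioactivity set
#'
#' Retains compounds with 5 to 80 heavy atoms (inclusive) and activity
#' records with a permitted measure type, assay class and species, and
#' reports how many records each criterion removed.
#'
#' @param set A [bioactivity_set()].
#' @param heavy_range Inclusive heavy-atom bounds, default `c(5, 80)`.
#' @param assay_classes,species,measure_types Permitted enum values.
#' @return A filtered `bioactivity_set`; the removal counts are attached as
#'   attribute `removed` (a tibble criterion / n) and reported via a message.
#' @export
filter_compounds <- function(set,
                             heavy_range = c(5, 80),
                             assay_classes = ASSAY_CLASSES,
                             species = SPECIES,
                             measure_types = MEASURE_TYPES) {
  stopifnot(inherits(set, "bioactivity_set"))
  cmp <- set$compounds
  act <- set$activities
  bad_size <- cmp$compound_id[cmp$heavy_atoms < heavy_range[1] |
                                cmp$heavy_atoms > heavy_range[2]]
  n_size <- sum(act$compound_id %in% bad_size)
  act1 <- act[!act$compound_id %in% bad_size, , drop = FALSE]
  ok_measure <- if ("measure_type" %in% names(act1))
    act1$measure_type %in% measure_types else TRUE
  n_measure <- sum(!ok_measure)
  act2 <- act1[ok_measure, , drop = FALSE]
  ok_assay <- if ("assay_class" %in% names(act2))
    act2$assay_class %in% assay_classes else TRUE
  n_assay <- sum(!ok_assay)
  act3 <- act2[ok_assay, , drop = FALSE]
  ok_species <- if ("species" %in% names(act3))
    act3$species %in% species else TRUE
  n_species <- sum(!ok_species)
  act4 <- act3[ok_species, , drop = FALSE]

  removed <- tibble(
    criterion = c("heavy_atoms", "measure_type", "assay_class", "species"),
    n = c(n_size, n_measure, n_assay, n_species)
  )
  inform(paste0("filter_compounds removed ", sum(removed$n), " record(s): ",
                paste(removed$criterion, removed$n, sep = "=", collapse = ", ")))
  keep_cmp <- cmp[!cmp$compound_id %in% bad_size, , drop = FALSE]
  out <- bioactivity_set(keep_cmp, act4)
  attr(out, "removed") <- removed
  out
}

#' Remove training-set overlap from an external test set
#'
#' Enforces the externality of a test set: any test compound whose
#' standardized canonical structure occurs in the training set is dropped,
#' and test activity records are restricted to targets present in the
#' training set (external targets are not findable by screening).
#'
#' @param test_set,training_set [bioactivity_set()] objects standardized by
#'   the same procedure.
#' @return The filtered test `bioactivity_set`, with attribute `removed`
#'   holding the counts of dropped compounds and targets.
#' @export
remove_overlap <- function(test_set, training_set) {
  stopifnot(inherits(test_set, "bioactivity_set"),
            inherits(training_set, "bioactivity_set"))
  dup <- test_set$compounds$smiles %in% training_set$compounds$smiles
  keep_cmp <- test_set$compounds[!dup, , drop = FALSE]
  train_targets <- unique(training_set$activities$target_id)
  act <- test_set$activities
  act <- act[act$compound_id %in% keep_cmp$compound_id, , drop = FALSE]
  ext_target <- !act$target_id %in% train_targets
  act <- act[!ext_target, , drop = FALSE]
  keep_cmp <- keep_cmp[keep_cmp$compound_id %in% act$compound_id, , drop = FALSE]
  out <- if (nrow(keep_cmp) == 0) {
    structure(list(compounds = keep_cmp,
                   activities = act,
                   labels = tibble(compound_id = character(),
                                   target_id = character(),
                                   label = character())),
              class = "bioactivity_set")
  } else {
    bioactivity_set(keep_cmp, act)
  }
  attr(out, "removed") <- tibble(
    criterion = c("structure_overlap", "external_target"),
    n = c(sum(dup), sum(ext_target))
  )
  out
}

#' Build the screening set from a labeled training set
#'
#' The screening set is the active part of a training set organized by known
#' actives per target, restricted to targets of the requested species.
#'
#' @param training_set A [bioactivity_set()].
#' @param species Species filter for targets, default `"human"`. A target
#'   passes when it has at least one activity record of that species.
#' @return A tibble with columns `target_id`, `compound_id`, one row per
#'   (target, known active), deduplicated.
#' @export
build_screening_set <- function(training_set, species = "human") {
  stopifnot(inherits(training_set, "bioactivity_set"))
  act <- training_set$activities
  ok_targets <- if ("species" %in% names(act)) {
    unique(act$target_id[act$species %in% species])
  } else unique(act$target_id)
  training_set$labels |>
    filter(.data$label == "active", .data$target_id %in% ok_targets) |>
    select("target_id", "compound_id") |>
    distinct() |>
    arrange(.data$target_id, .data$compound_id)
}

# ---------------------------------------------------------------------------
# Flat-file layouts
# ---------------------------------------------------------------------------

#' Read / write the compound flat file
#'
#' The deposit-style layout: one compound per line with the standardized
#' SMILES, the compound identifier, the number of experimental targets and
#' the semicolon-separated UniProt-style target identifiers.
#'
#' @param set A [bioactivity_set()] (write) or a file path (read).
#' @param path Output file path.
#' @return `write_set_tsv()` returns `path` invisibly; `read_set_tsv()`
#'   returns a tibble with columns `smiles`, `compound_id`, `n_targets`,
#'   `target_ids` (list column).
#' @export
write_set_tsv <- function(set, path) {
  stopifnot(inherits(set, "bioactivity_set"))
  per_cmp <- set$labels |>
    filter(.data$label == "active") |>
    group_by(.data$compound_id) |>
    summarise(n_targets = dplyr::n_distinct(.data$target_id),
              uniprot = paste(sort(unique(.data$target_id)), collapse = ";"),
              .groups = "drop")
  out <- set$compounds |>
    left_join(per_cmp, by = "compound_id") |>
    mutate(n_targets = ifelse(is.na(.data$n_targets), 0L, .data$n_targets),
           uniprot = ifelse(is.na(.data$uniprot), "", .data$uniprot)) |>
    select("smiles", "compound_id", "n_targets", "uniprot")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_set_tsv
#' @export
read_set_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccic", progress = FALSE,
                       col_names = c("smiles", "compound_id", "n_targets",
                                     "uniprot"), skip = 1)
  d |>
    mutate(target_ids = strsplit(ifelse(is.na(.data$uniprot), "",
                                        .data$uniprot), ";")) |>
    select("smiles", "compound_id", "n_targets", "target_ids")
}

#' Read raw structures from an SDF file
#'
#' Converts an SDF of raw structures to a compound table; the molecule
#' titles become compound identifiers (falling back to positional
#' identifiers when absent). Structures are returned as written SMILES and
#' still need [standardize_structure()].
#'
#' @param path SDF file path.
#' @return A tibble with columns `compound_id`, `smiles`.
#' @export
read_structures_sdf <- function(path) {
  out <- ob_run(readLines(path, warn = FALSE), "sdf", "smi", character())
  rows <- strsplit(strsplit(out, "\n")[[1]], "\t")
  smiles <- vapply(rows, `[`, character(1), 1)
  ids <- vapply(rows, function(r) if (length(r) > 1) r[2] else NA_character_,
                character(1))
  ids[is.na(ids) | ids == ""] <- paste0("sdf", which(is.na(ids) | ids == ""))
  tibble(compound_id = ids, smiles = smiles)
}

#' Read an activity record CSV
#'
#' Documented columns: `compound_id`, `target_id`, `measure_type`,
#' `value`, `unit` (`uM` or `nM`; nanomolar values are converted to
#' micromolar on read), `assay_class`, `species`.
#'
#' @param path CSV file path.
#' @return A tibble of activity records with `value_uM` in micromolar.
#' @export
read_activities_csv <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("compound_id", "target_id", "value", "unit") %in% names(d)))
  d |>
    mutate(value_uM = ifelse(.data$unit == "nM", .data$value / 1000,
                             .data$value)) |>
    select(-"value", -"unit")
}
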