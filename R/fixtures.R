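# Seeded synthetic bioactivity universes with planted similarity structure.
# Each target owns a distinct ring-system core and an enumerated analog
# series (core + substituent grid); decoys come from separate cores. The
# generator embodies the similarity principle the engine relies on: actives
# of one target are structural analogs, so a held-out analog is closer to
# its own target's actives than to any other target's.

# Core templates: `{1}` / `{2}` mark substitution positions; an empty
# substituent removes the branch. Target cores were curated so that the
# full substituent grid keeps every analog strictly closer (FP2 Tanimoto)
# to its own series than to any other series.
TARGET_CORES <- c(
  naphthalene       = "c1cc{1}c2ccc{2}cc2c1",
  quinoline         = "c1cc{1}c2ncc{2}cc2c1",
  quinoxaline       = "c1c{1}cc2nc{2}cnc2c1",
  benzofuran        = "c1cc{1}c2oc{2}cc2c1",
  benzothiophene    = "c1cc{1}c2sc{2}cc2c1",
  benzimidazole     = "c1cc{1}c2[nH]c{2}nc2c1",
  benzoxazole       = "c1cc{1}c2oc{2}nc2c1",
  benzothiazole     = "c1cc{1}c2sc{2}nc2c1",
  biphenyl          = "c1cc{1}c(cc1{2})-c1ccccc1",
  diphenylmethane   = "C(c1cc{1}ccc1{2})c1ccccc1",
  phenylpiperidine  = "C1CC{1}N(CC1)c1ccc{2}cc1",
  phenylmorpholine  = "C1CN(c2ccc{2}cc2)CC{1}O1",
  cyclohexylbenzene = "C1CC{1}CCC1c1ccc{2}cc1",
  phenylpiperazine  = "C1CN(CCN1{1})c1ccc{2}cc1",
  tetralin          = "C1Cc2cc{2}ccc2CC1{1}",
  indane            = "C1Cc2cc{2}ccc2C1{1}",
  chromane          = "C1Oc2cc{2}ccc2CC1{1}",
  pyridylbenzene    = "c1cc{1}ccc1-c1ccnc{2}c1",
  furylbenzene      = "c1cc{1}ccc1-c1oc{2}cc1",
  thienylbenzene    = "c1cc{1}ccc1-c1sc{2}cc1"
)

DECOY_CORES <- c(
  benzodioxole       = "C1Oc2cc{1}c{2}cc2O1",
  quinazoline        = "c1cc{1}c2ncnc{2}c2c1",
  naphthyridine      = "c1cc2ncc{2}cc2nc1{1}",
  indazole           = "c1cc{1}c2cn[nH]c2c1{2}",
  benzotriazole      = "c1cc{1}c2[nH]nnc2c1{2}",
  pyrazolylbenzene   = "c1cc{1}ccc1-n1nc{2}cc1",
  thiazolylbenzene   = "c1cc{1}ccc1-c1nc{2}cs1",
  oxazolylbenzene    = "c1cc{1}ccc1-c1nc{2}co1",
  imidazolylbenzene  = "c1cc{1}ccc1-n1cc{2}nc1",
  pyrimidinylbenzene = "c1cc{1}ccc1-c1ncnc{2}c1"
)

SUBSTITUENTS <- c("", "F", "Cl", "C", "OC", "N", "CC", "O", "Br", "C#N",
                  "C(F)(F)F", "OCC")

render_analog <- function(template, s1, s2) {
  r <- gsub("{1}", if (nzchar(s1)) paste0("(", s1, ")") else "",
            template, fixed = TRUE)
  gsub("{2}", if (nzchar(s2)) paste0("(", s2, ")") else "", r, fixed = TRUE)
}

#' Specification of a synthetic bioactivity universe
#'
#' The defaults define the reference study conditions used throughout the
#' package's end-to-end validation: 20 targets with a planted analog series
#' of 30 actives each, 5 held-out analogs per target forming the external
#' test set, and 120 decoy compounds from unrelated cores serving as
#' measured inactives, gray-area records and alleged inactives.
#'
#' @param n_targets Number of targets (each gets a distinct core; at most
#'   `length(TARGET_CORES)` = 20).
#' @param actives_per_target Planted actives per target.
#' @param n_decoys Decoy compounds drawn from decoy cores.
#' @param analog_depth Substituent-grid side length (analog series size is
#'   `analog_depth^2`, which must cover actives + held-out).
#' @param heldout_per_target Held-out analogs per target (external test set).
#' @param fraction_measured_inactive Fraction of decoys given a measured
#'   inactive record on a random target.
#' @param fraction_gray Fraction of decoys given a gray-area record on a
#'   random target.
#' @param poor_targets Number of targets degraded to "poor knowledge":
#'   their training actives are replaced by 2 mutually dissimilar compounds
#'   from alternate cores (their held-out analogs stay, making target
#'   recovery hard). Used to probe the knowledge stratification.
#' @param seed Integer seed fixing the universe bit-exactly.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_targets = 20, actives_per_target = 30,
                         n_decoys = 120, analog_depth = 6,
                         heldout_per_target = 5,
                         fraction_measured_inactive = 0.25,
                         fraction_gray = 0.05,
                         poor_targets = 0, seed = 1L) {
  stopifnot(n_targets >= 1, n_targets <= length(TARGET_CORES),
            analog_depth >= 1, analog_depth <= length(SUBSTITUENTS),
            actives_per_target >= 0, heldout_per_target >= 0,
            n_decoys >= 0, poor_targets >= 0, poor_targets <= n_targets,
            fraction_gray >= 0, fraction_measured_inactive >= 0)
  if (actives_per_target + heldout_per_target > analog_depth^2) {
    abort("analog grid too small for actives + held-out compounds.",
          class = "revscreen_generation_error")
  }
  structure(list(
    n_targets = n_targets, actives_per_target = actives_per_target,
    n_decoys = n_decoys, analog_depth = analog_depth,
    heldout_per_target = heldout_per_target,
    fraction_measured_inactive = fraction_measured_inactive,
    fraction_gray = fraction_gray,
    poor_targets = poor_targets, seed = as.integer(seed)
  ), class = "fixture_spec")
}

log_uniform <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))

#' Generate a synthetic bioactivity universe
#'
#' Builds a seeded toy universe: per target a planted analog series labeled
#' active (measurements at or below 10 uM), decoys from unrelated cores with
#' measured inactive (at or above 100 uM) and gray-area records in the
#' specified fractions, and a held-out external test set of analogs absent
#' (by canonical structure) from the training set. Generation asserts the
#' planted truth: every held-out analog's highest fingerprint similarity
#' within its true target's actives exceeds its highest cross-target
#' similarity (skipped for degraded "poor" targets, whose planted actives
#' are deliberately dissimilar).
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `training` (a [bioactivity_set()]), `test`
#'   (tibble `compound_id`, `smiles`, `heavy_atoms`), `truth` (tibble
#'   `query_id`, `target_id`) and `spec`.
#' @export
generate_universe <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  subs <- SUBSTITUENTS[seq_len(spec$analog_depth)]
  grid <- expand.grid(s1 = subs, s2 = subs, stringsAsFactors = FALSE)
  targets <- sprintf("P%05d", seq_len(spec$n_targets))
  core_names <- names(TARGET_CORES)[seq_len(spec$n_targets)]
  poor <- if (spec$poor_targets > 0) targets[seq_len(spec$poor_targets)]
          else character(0)

  # Canonical analog pool per core: substituent cells that are equivalent
  # under ring symmetry collapse to one canonical structure after
  # standardization, so sampling happens on the deduplicated pool.
  pools <- analog_pools(c(TARGET_CORES, DECOY_CORES), grid)
  pool_fp <- pool_fingerprints(pools)

  compounds <- list(); activities <- list(); test <- list(); truth <- list()
  cid <- 0L
  next_id <- function() {
    cid <<- cid + 1L
    sprintf("CPD%05d", cid)
  }
  n_series <- spec$actives_per_target + spec$heldout_per_target
  for (i in seq_len(spec$n_targets)) {
    pool <- pools[[core_names[i]]]
    if (length(pool) < n_series) {
      abort(paste0("core ", core_names[i], " offers ", length(pool),
                   " distinct analogs for a series of ", n_series, "."),
            class = "revscreen_generation_error")
    }
    take <- sample(seq_along(pool), n_series)
    smiles <- pool[take]
    # the held-out analogs are chosen so that each keeps a training
    # neighbour within its own series closer than any cross-core analog:
    # the planted truth holds by construction, not by luck of the split
    if (spec$heldout_per_target > 0 && spec$actives_per_target > 0) {
      series_fp <- pool_fp$fp[pool_fp$offset[[core_names[i]]][take], ,
                              drop = FALSE]
      cross_cols <- pool_fp$core != core_names[i]
      crossmax <- apply(tanimoto_cross(series_fp,
                                       pool_fp$fp[cross_cols, , drop = FALSE]),
                        1, max)
      held <- select_heldout(tanimoto_cross(series_fp, series_fp),
                             crossmax, spec$heldout_per_target)
      smiles <- smiles[c(setdiff(seq_len(n_series), held), held)]
    }
    ids <- vapply(seq_len(n_series), function(k) next_id(), character(1))
    is_heldout <- seq_len(n_series) > spec$actives_per_target
    train_ids <- ids[!is_heldout]
    compounds[[i]] <- tibble(compound_id = train_ids,
                             smiles = smiles[!is_heldout],
                             core = core_names[i])
    if (!targets[i] %in% poor) {
      activities[[i]] <- tibble(
        compound_id = train_ids, target_id = targets[i],
        measure_type = sample(c("IC50", "EC50", "Ki", "KD"),
                              length(train_ids), replace = TRUE),
        value_uM = log_uniform(length(train_ids), 0.01, 10),
        assay_class = "binding", species = "human"
      )
    }
    test[[i]] <- tibble(compound_id = ids[is_heldout],
                        smiles = smiles[is_heldout])
    truth[[i]] <- tibble(query_id = ids[is_heldout], target_id = targets[i])
  }

  # poor targets: two mutually dissimilar actives from alternate cores
  poor_cmp <- list(); poor_act <- list()
  if (length(poor) > 0) {
    decoy_pool <- names(DECOY_CORES)
    for (j in seq_along(poor)) {
      cores2 <- decoy_pool[(2 * j - 2 + seq_len(2) - 1) %% length(decoy_pool) + 1]
      ids <- c(next_id(), next_id())
      smiles <- vapply(seq_len(2), function(k) {
        sample(pools[[cores2[k]]], 1)
      }, character(1))
      poor_cmp[[j]] <- tibble(compound_id = ids, smiles = smiles,
                              core = cores2)
      poor_act[[j]] <- tibble(
        compound_id = ids, target_id = poor[j],
        measure_type = sample(c("IC50", "Ki"), 2, replace = TRUE),
        value_uM = log_uniform(2, 0.01, 10),
        assay_class = "binding", species = "human"
      )
    }
  }

  # decoys: unrelated cores; some get measured inactive / gray records
  decoys <- list(); decoy_act <- list()
  if (spec$n_decoys > 0) {
    for (k in seq_len(spec$n_decoys)) {
      core <- names(DECOY_CORES)[(k - 1) %% length(DECOY_CORES) + 1]
      id <- next_id()
      decoys[[k]] <- tibble(
        compound_id = id,
        smiles = sample(pools[[core]], 1),
        core = core
      )
      u <- runif(1)
      if (u < spec$fraction_measured_inactive) {
        decoy_act[[k]] <- tibble(
          compound_id = id, target_id = sample(targets, 1),
          measure_type = sample(c("IC50", "Ki"), 1),
          value_uM = log_uniform(1, 100, 10000),
          assay_class = "binding", species = "human")
      } else if (u < spec$fraction_measured_inactive + spec$fraction_gray) {
        decoy_act[[k]] <- tibble(
          compound_id = id, target_id = sample(targets, 1),
          measure_type = sample(c("IC50", "Ki"), 1),
          value_uM = log_uniform(1, 10 * 1.0001, 100 * 0.9999),
          assay_class = "binding", species = "human")
      }
    }
  }

  cmp <- bind_rows(c(compounds, poor_cmp, decoys))
  act <- bind_rows(c(activities, poor_act, decoy_act))
  test_tbl <- bind_rows(test)
  truth_tbl <- bind_rows(truth)

  # pools are pre-standardized; verify externality and attach sizes
  cmp$heavy_atoms <- count_heavy_atoms(cmp$smiles)
  if (nrow(test_tbl) > 0) {
    if (any(test_tbl$smiles %in% cmp$smiles)) {
      abort("held-out analogs overlap the training set.",
            class = "revscreen_generation_error")
    }
    test_tbl$heavy_atoms <- count_heavy_atoms(test_tbl$smiles)
  } else {
    test_tbl$heavy_atoms <- integer(0)
  }

  training <- bioactivity_set(cmp, act)
  assert_planted_truth(training, test_tbl, truth_tbl, poor)
  list(training = training, test = test_tbl, truth = truth_tbl, spec = spec)
}

# Render the full substituent grid for each core template, standardize
# every analog once, and return the distinct canonical structures per core.
analog_pools <- function(cores, grid) {
  rendered <- lapply(cores, function(tpl) {
    vapply(seq_len(nrow(grid)), function(k)
      render_analog(tpl, grid$s1[k], grid$s2[k]), character(1))
  })
  flat <- unlist(rendered, use.names = FALSE)
  std <- standardize_structure(flat)
  idx <- rep(seq_along(rendered),
             times = vapply(rendered, length, integer(1)))
  out <- lapply(split(std, idx), unique)
  names(out) <- names(cores)
  out
}

# Fingerprints of every pooled analog, stacked with core bookkeeping.
pool_fingerprints <- function(pools) {
  smiles <- unlist(pools, use.names = FALSE)
  core <- rep(names(pools), times = vapply(pools, length, integer(1)))
  fp <- fp_matrix(ob_parse_smiles(smiles, paste0("p", seq_along(smiles))))
  offset <- split(seq_along(smiles), factor(core, levels = names(pools)))
  list(fp = fp, core = core, offset = offset)
}

# Greedy held-out selection: repeatedly pick the series member whose best
# remaining own-series neighbour beats its best cross-core similarity by
# the widest margin. Deterministic; ties resolve to the lowest index.
select_heldout <- function(tc_own, crossmax, n_held) {
  n <- nrow(tc_own)
  diag(tc_own) <- NA
  held <- integer(0)
  for (k in seq_len(n_held)) {
    candidates <- setdiff(seq_len(n), held)
    margins <- vapply(candidates, function(h) {
      train <- setdiff(candidates, h)
      max(tc_own[h, train]) - crossmax[h]
    }, numeric(1))
    held <- c(held, candidates[which.max(margins)])
  }
  held
}

# Planted-truth invariant: held-out analogs are closest (FP2 Tanimoto) to
# their own target's actives.
assert_planted_truth <- function(training, test_tbl, truth_tbl, poor) {
  if (nrow(test_tbl) == 0) return(invisible(TRUE))
  actives <- training$labels |>
    filter(.data$label == "active",
           !.data$target_id %in% poor)
  if (nrow(actives) == 0) return(invisible(TRUE))
  qok <- truth_tbl$query_id[!truth_tbl$target_id %in% poor]
  if (length(qok) == 0) return(invisible(TRUE))
  all_smiles <- c(setNames(training$compounds$smiles,
                           training$compounds$compound_id),
                  setNames(test_tbl$smiles, test_tbl$compound_id))
  ids <- unique(c(actives$compound_id, qok))
  fp <- fp_matrix(ob_parse_smiles(all_smiles[ids], ids))
  rownames(fp) <- ids
  tc <- tanimoto_cross(fp[qok, , drop = FALSE],
                       fp[unique(actives$compound_id), , drop = FALSE])
  by_target <- split(actives$compound_id, actives$target_id)
  for (q in qok) {
    tg <- truth_tbl$target_id[truth_tbl$query_id == q]
    own <- max(tc[q, by_target[[tg]]])
    other <- max(tc[q, setdiff(colnames(tc), by_target[[tg]])])
    if (own <= other) {
      abort(paste0("planted-truth violation for ", q,
                   ": own ", round(own, 3), " <= cross ", round(other, 3)),
            class = "revscreen_generation_error")
    }
  }
  invisible(TRUE)
}

#' Write a synthetic universe to flat files
#'
#' Writes the deposit-layout training TSV, the external test TSV and the
#' truth file (`query_id<TAB>target_id`).
#'
#' @param universe A [generate_universe()] result.
#' @param dir Output directory.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_set_tsv(universe$training, file.path(dir, "training_set.tsv"))
  readr::write_tsv(universe$test, file.path(dir, "test_set.tsv"))
  readr::write_tsv(universe$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Paired Gaussian descriptor samples for Z-factor exercises
#'
#' Draws two Gaussian samples per descriptor with configurable means and
#' standard deviations, emulating the physicochemical summary comparison of
#' a training and a test set across overlap regimes.
#'
#' @param params A tibble with columns `descriptor`, `mu_tr`, `sigma_tr`,
#'   `mu_ts`, `sigma_ts`; defaults to three regimes (heavy overlap,
#'   moderate, well separated).
#' @param n Sample size per set and descriptor.
#' @param seed Integer seed.
#' @return A tibble with columns `descriptor`, `set` (`tr`/`ts`), `value`.
#' @export
generate_table1_fixture <- function(params = NULL, n = 10000, seed = 1L) {
  if (is.null(params)) {
    params <- tibble(
      descriptor = c("overlapping", "moderate", "separated"),
      mu_tr = c(0, 0, 0), sigma_tr = c(1, 1, 0.05),
      mu_ts = c(0.1, 3, 10), sigma_ts = c(1, 1, 0.05)
    )
  }
  set.seed(seed)
  purrr::pmap(params, function(descriptor, mu_tr, sigma_tr, mu_ts, sigma_ts) {
    bind_rows(
      tibble(descriptor = descriptor, set = "tr",
             value = rnorm(n, mu_tr, sigma_tr)),
      tibble(descriptor = descriptor, set = "ts",
             value = rnorm(n, mu_ts, sigma_ts))
    )
  }) |> list_rbind()
}
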