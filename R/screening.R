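# Reverse screening: score a query against every target's known actives,
# turn the two scores into a probability, and rank the targets.

#' Score one query against a target's known actives
#'
#' The 3D score is the highest best-pair ES5D similarity between the query
#' and any known active of the target; the 2D score is the highest Tanimoto
#' coefficient. The two argmax actives are reported and may differ.
#'
#' @param descriptors A [featurize()] result.
#' @param query_id Compound identifier of the query.
#' @param active_ids Identifiers of the target's known actives (length >= 1).
#' @return A one-row tibble with `score3d`, `score2d`, `best_3d_active_id`,
#'   `best_2d_active_id`.
#' @export
score_against_target <- function(descriptors, query_id, active_ids) {
  if (length(active_ids) == 0) {
    abort("target has no actives.", class = "revscreen_input_error")
  }
  s3 <- sim3d_matrix(descriptors, query_id, active_ids)[1, ]
  s2 <- sim2d_matrix(descriptors, query_id, active_ids)[1, ]
  tibble(
    score3d = max(s3), score2d = max(s2),
    best_3d_active_id = active_ids[which.max(s3)],
    best_2d_active_id = active_ids[which.max(s2)]
  )
}

#' Probability of activity from the two similarity scores
#'
#' Evaluates the logistic equation
#' `1 / (1 + exp(-c1 * score3d - c2 * score2d - C))` with the smoothed
#' coefficients of the query's heavy-atom class.
#'
#' @param score3d,score2d Similarity scores in `[0, 1]` (vectorized).
#' @param model A smoothed `revscreen_model`.
#' @param n_heavy Heavy-atom count of the query molecule.
#' @return Probability strictly in `(0, 1)`.
#' @examples
#' \dontrun{
#' predict_probability(1, 1, model, n_heavy = 25)
#' }
#' @export
predict_probability <- function(score3d, score2d, model, n_heavy) {
  stopifnot(inherits(model, "revscreen_model"))
  if (is.null(model$smoothed)) {
    abort("model has no smoothed coefficients; run smooth_coefficients().",
          class = "revscreen_configuration_error")
  }
  cls <- heavy_atom_class(n_heavy)
  row <- model$smoothed[match(cls, model$smoothed$class_id), ]
  if (anyNA(row$c1)) {
    abort("no coefficients for the requested size class.",
          class = "revscreen_configuration_error")
  }
  plogis(row$c1 * score3d + row$c2 * score2d + row$C)
}

#' Reverse screen queries against a screening set
#'
#' For every query compound, every target of the screening set is scored
#' against its known actives, the per-target probability is computed with
#' the query's size-class coefficients, and the targets are ranked by
#' decreasing probability. Ties are broken deterministically by descending
#' 2D score, then descending 3D score, then target identifier.
#'
#' @param queries A data frame with columns `compound_id` (and optionally
#'   `smiles`, unused here; descriptors must cover all queries).
#' @param screening_set A tibble `target_id` / `compound_id` from
#'   [build_screening_set()].
#' @param descriptors A [featurize()] result covering queries and actives.
#' @param model A smoothed `revscreen_model`.
#' @param min_2d,min_3d Optional similarity floors (performance knob):
#'   actives below the floor are treated as dissimilar for that metric and
#'   contribute a score of 0 when no active passes. Defaults 0 (off).
#' @return A `revscreen_prediction` tibble with columns `query_id`, `rank`,
#'   `target_id`, `probability`, `score3d`, `score2d`,
#'   `best_3d_active_id`, `best_2d_active_id`. Queries that could not be
#'   screened are recorded in attribute `errors`.
#' @export
reverse_screen <- function(queries, screening_set, descriptors, model,
                           min_2d = 0, min_3d = 0) {
  stopifnot(inherits(descriptors, "revscreen_descriptors"),
            inherits(model, "revscreen_model"))
  if (nrow(screening_set) == 0) {
    abort("screening set is empty.", class = "revscreen_input_error")
  }
  qids <- unique(queries$compound_id)
  known <- qids %in% rownames(descriptors$fp)
  errors <- tibble(query_id = qids[!known],
                   error = "missing descriptors")
  if (any(!known)) {
    warn(paste0(sum(!known), " query(ies) skipped: missing descriptors."))
  }
  qids <- qids[known]
  targets <- sort(unique(screening_set$target_id))
  actives_by_target <- split(screening_set$compound_id,
                             screening_set$target_id)
  all_actives <- sort(unique(screening_set$compound_id))
  s3 <- sim3d_matrix(descriptors, qids, all_actives)
  s2 <- sim2d_matrix(descriptors, qids, all_actives)
  res <- lapply(qids, function(q) {
    per_target <- lapply(targets, function(tg) {
      act <- actives_by_target[[tg]]
      v3 <- s3[q, act]; v2 <- s2[q, act]
      p3 <- v3 >= min_3d; p2 <- v2 >= min_2d
      sc3 <- if (any(p3)) max(v3[p3]) else 0
      sc2 <- if (any(p2)) max(v2[p2]) else 0
      tibble(
        target_id = tg, score3d = sc3, score2d = sc2,
        best_3d_active_id = if (any(p3)) act[p3][which.max(v3[p3])] else NA_character_,
        best_2d_active_id = if (any(p2)) act[p2][which.max(v2[p2])] else NA_character_
      )
    }) |> bind_rows()
    nh <- descriptors$heavy_atoms[[q]]
    per_target$probability <- predict_probability(
      per_target$score3d, per_target$score2d, model, rep(nh, nrow(per_target)))
    per_target |>
      arrange(dplyr::desc(.data$probability), dplyr::desc(.data$score2d),
              dplyr::desc(.data$score3d), .data$target_id) |>
      mutate(query_id = q, rank = row_number())
  }) |> bind_rows()
  out <- res |>
    select("query_id", "rank", "target_id", "probability",
           "score3d", "score2d", "best_3d_active_id", "best_2d_active_id")
  class(out) <- c("revscreen_prediction", class(out))
  attr(out, "errors") <- errors
  out
}

#' Rank of a given target in a prediction
#'
#' @param prediction A [reverse_screen()] result.
#' @param query_id,target_id Identifiers to look up.
#' @return Integer rank (1-based), or `NA` if the pair was not screened.
#' @export
target_rank <- function(prediction, query_id, target_id) {
  i <- prediction$query_id == query_id & prediction$target_id == target_id
  if (!any(i)) return(NA_integer_)
  prediction$rank[i][1]
}

#' Write screening results as TSV
#'
#' @param prediction A [reverse_screen()] result.
#' @param path Output path.
#' @param top Optional cutoff: keep only ranks up to `top`.
#' @export
write_predictions <- function(prediction, path, top = NULL) {
  out <- prediction
  if (!is.null(top) && !is.na(top)) out <- out |> filter(.data$rank <= top)
  readr::write_tsv(out, path)
  invisible(path)
}
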