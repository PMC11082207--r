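# Predictive-ability assessment: success@rank curves, stratification by
# molecular size, target knowledge and scaffold diversity, the distinct test
# set, and enrichment factors.

#' Per-query evaluation records from predictions and truth
#'
#' Reduces a screening result to one row per query: the best (minimum) rank
#' over the query's experimentally known targets, restricted to targets that
#' were actually screened.
#'
#' @param prediction A [reverse_screen()] result.
#' @param truth A data frame with columns `query_id`, `target_id` listing
#'   the experimentally known targets of each query.
#' @return A tibble with columns `query_id`, `best_rank`, `best_target`
#'   (the best-ranked known target), `n_known`.
#' @export
evaluation_records <- function(prediction, truth) {
  stopifnot(all(c("query_id", "target_id") %in% names(truth)))
  hits <- prediction |>
    inner_join(distinct(as_tibble(truth)[, c("query_id", "target_id")]),
               by = c("query_id", "target_id"))
  if (nrow(hits) == 0) {
    abort("no known target of any query was screened.",
          class = "revscreen_input_error")
  }
  dropped <- setdiff(unique(truth$query_id), unique(hits$query_id))
  if (length(dropped) > 0) {
    warn(paste0(length(dropped),
                " query(ies) had no screened known target and were dropped."))
  }
  hits |>
    group_by(.data$query_id) |>
    summarise(best_rank = min(.data$rank),
              best_target = .data$target_id[which.min(.data$rank)],
              n_known = dplyr::n(), .groups = "drop")
}

#' Success-at-rank curve
#'
#' The percentage of queries whose best-ranked known target lies within each
#' rank cutoff.
#'
#' @param records An [evaluation_records()] tibble (columns `query_id`,
#'   `best_rank`).
#' @param cutoffs Integer rank cutoffs, default `c(1, 5, 15, 100)`.
#' @return A tibble of class `revscreen_success` with columns `cutoff`,
#'   `success` (percent in `[0, 100]`) and `n` (number of records).
#' @examples
#' records <- tibble::tibble(query_id = letters[1:4],
#'                           best_rank = c(1, 3, 20, 2))
#' success_at_rank(records, c(1, 5, 100))
#' @export
success_at_rank <- function(records, cutoffs = c(1, 5, 15, 100)) {
  if (nrow(records) == 0) {
    abort("no evaluation records.", class = "revscreen_input_error")
  }
  out <- tibble(
    cutoff = as.integer(cutoffs),
    success = vapply(cutoffs, function(cc)
      100 * mean(records$best_rank <= cc), numeric(1)),
    n = nrow(records)
  )
  class(out) <- c("revscreen_success", class(out))
  out
}

#' Success curves stratified by molecular size class
#'
#' @inheritParams success_at_rank
#' @param sizes A data frame `compound_id` / `heavy_atoms` covering all
#'   queries.
#' @return A tibble with one row per (class, cutoff): columns `class_id`,
#'   `cutoff`, `success`, `n`. Classes without records are omitted.
#' @export
success_by_size_class <- function(records, sizes, cutoffs = c(1, 5, 15, 100)) {
  d <- records |>
    inner_join(as_tibble(sizes)[, c("compound_id", "heavy_atoms")],
               by = c(query_id = "compound_id"))
  if (nrow(d) < nrow(records)) {
    abort("sizes missing for some queries.", class = "revscreen_input_error")
  }
  d |>
    mutate(class_id = heavy_atom_class(.data$heavy_atoms)) |>
    group_by(.data$class_id) |>
    dplyr::group_modify(~ success_at_rank(.x, cutoffs)) |>
    ungroup()
}

check_breaks <- function(breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("bins must be given as strictly increasing break points.",
          class = "revscreen_configuration_error")
  }
}

#' Success curves stratified by target bioactivity knowledge
#'
#' Groups queries by the number of known actives of their (best-ranked)
#' known target and computes a success curve per bin. The default bins
#' mirror the knowledge strata of the engine's validation: 10 or fewer
#' actives, 11-100, 101-1000, more than 1000.
#'
#' @inheritParams success_at_rank
#' @param screening_set The `target_id` / `compound_id` actives table that
#'   was screened.
#' @param breaks Strictly increasing upper break points defining the bins
#'   `(breaks[i], breaks[i+1]]`, default `c(0, 10, 100, 1000, Inf)`.
#' @return A tibble with columns `bin`, `cutoff`, `success`, `n`.
#' @export
stratify_by_target_knowledge <- function(records, screening_set,
                                         breaks = c(0, 10, 100, 1000, Inf),
                                         cutoffs = c(1, 5, 15, 100)) {
  check_breaks(breaks)
  counts <- screening_set |>
    group_by(.data$target_id) |>
    summarise(n_actives = dplyr::n_distinct(.data$compound_id),
              .groups = "drop")
  d <- records |>
    inner_join(counts, by = c(best_target = "target_id")) |>
    mutate(bin = cut(.data$n_actives, breaks = breaks))
  d |>
    group_by(.data$bin) |>
    dplyr::group_modify(~ success_at_rank(.x, cutoffs)) |>
    ungroup()
}

#' Success curves stratified by scaffold diversity of the target's actives
#'
#' Groups queries by the number of distinct molecular scaffolds (Murcko or
#' Oprea) among the known actives of their best-ranked known target.
#' Acyclic actives (empty scaffold) do not contribute to the scaffold count.
#'
#' @inheritParams stratify_by_target_knowledge
#' @param scaffolds A [compute_scaffolds()] tibble covering the screening
#'   actives.
#' @param kind `"murcko"` or `"oprea"`.
#' @param breaks Default `c(0, 10, 50, 500, Inf)`.
#' @return A tibble with columns `bin`, `cutoff`, `success`, `n`.
#' @export
stratify_by_scaffold_diversity <- function(records, screening_set, scaffolds,
                                           kind = c("murcko", "oprea"),
                                           breaks = c(0, 10, 50, 500, Inf),
                                           cutoffs = c(1, 5, 15, 100)) {
  kind <- match.arg(kind)
  check_breaks(breaks)
  counts <- screening_set |>
    inner_join(as_tibble(scaffolds)[, c("compound_id", kind)],
               by = "compound_id") |>
    group_by(.data$target_id) |>
    summarise(n_scaffolds = dplyr::n_distinct(
      .data[[kind]][.data[[kind]] != ""]), .groups = "drop")
  d <- records |>
    inner_join(counts, by = c(best_target = "target_id")) |>
    mutate(bin = cut(.data$n_scaffolds, breaks = breaks))
  d |>
    group_by(.data$bin) |>
    dplyr::group_modify(~ success_at_rank(.x, cutoffs)) |>
    ungroup()
}

#' Extract the chemically distinct subset of a test set
#'
#' Keeps the test compounds whose Murcko scaffold and Oprea scaffold each
#' occur in no training compound (the conjunction of the two definitions:
#' sharing either scaffold with the training set excludes a compound).
#' Acyclic test compounds (empty scaffolds) are excluded whenever the
#' training set contains any acyclic molecule.
#'
#' @param test_scaffolds,training_scaffolds [compute_scaffolds()] tibbles
#'   (`compound_id`, `murcko`, `oprea`).
#' @return Character vector of distinct test compound identifiers.
#' @export
build_distinct_test_set <- function(test_scaffolds, training_scaffolds) {
  tr_murcko <- unique(training_scaffolds$murcko)
  tr_oprea <- unique(training_scaffolds$oprea)
  keep <- !(test_scaffolds$murcko %in% tr_murcko) &
    !(test_scaffolds$oprea %in% tr_oprea)
  test_scaffolds$compound_id[keep]
}

#' Enrichment factor of a success rate over random ranking
#'
#' `EF(c) = (success / 100) / (c / n_targets)`: how much more often a known
#' target is recovered within the top `c` ranks than expected from a uniform
#' random ranking of `n_targets` targets.
#'
#' @param success_pct Success percentage in `[0, 100]`.
#' @param cutoff Rank cutoff, `1 <= cutoff <= n_targets`.
#' @param n_targets Number of screened targets.
#' @return Numeric enrichment factor.
#' @examples
#' enrichment_factor(50, 1, 1000)  # 500
#' @export
enrichment_factor <- function(success_pct, cutoff, n_targets) {
  if (any(cutoff < 1) || any(cutoff > n_targets)) {
    abort("cutoff must lie in [1, n_targets].",
          class = "revscreen_input_error")
  }
  (success_pct / 100) / (cutoff / n_targets)
}

#' Plot a success-at-rank curve
#' @param object A `revscreen_success` tibble.
#' @param ... Unused.
#' @method autoplot revscreen_success
#' @export
autoplot.revscreen_success <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff, y = .data$success)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rank cutoff", y = "success (%)",
                  title = "Success at rank") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Bar plot of stratified success curves
#'
#' @param strata A stratified success tibble (`bin` or `class_id` column plus
#'   `cutoff` and `success`).
#' @return A ggplot object.
#' @export
plot_stratified_success <- function(strata) {
  group_col <- intersect(c("bin", "class_id"), names(strata))[1]
  ggplot2::ggplot(strata,
                  ggplot2::aes(x = factor(.data[[group_col]]),
                               y = .data$success,
                               fill = factor(.data$cutoff))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = group_col, y = "success (%)", fill = "rank cutoff") +
    ggplot2::theme_minimal()
}
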