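# Size-stratified training of the logistic engine: heavy-atom classes,
# training-pair construction, logistic fits, cross-validation and cubic
# smoothing of the coefficient curves.

#' Heavy-atom size class of a molecule
#'
#' The engine stratifies molecules into 51 size classes: a single class for
#' small molecules (10 or fewer heavy atoms), one class per heavy-atom count
#' from 11 to 59, and a single class for large molecules (60 or more).
#'
#' @param n Integer vector of heavy-atom counts (all >= 1).
#' @return Integer vector of class identifiers in `10:60`.
#' @examples
#' heavy_atom_class(c(8, 35, 66))
#' @export
heavy_atom_class <- function(n) {
  if (any(n < 1)) {
    abort("heavy-atom counts must be >= 1.", class = "revscreen_input_error")
  }
  as.integer(pmin(pmax(n, 10L), 60L))
}

SIZE_CLASSES <- 10:60

# Best-pair 3D similarity matrix between two sets of compounds, reducing over
# all conformer pairs. Chunked over reference compounds to bound memory.
sim3d_matrix <- function(desc, qids, rids, chunk_rows = 2000L) {
  qe <- desc$es5d[qids]
  re <- desc$es5d[rids]
  Q <- do.call(rbind, qe)
  gq <- rep(seq_along(qids), times = vapply(qe, nrow, integer(1)))
  sizes <- vapply(re, nrow, integer(1))
  out <- matrix(NA_real_, length(qids), length(rids),
                dimnames = list(qids, rids))
  chunks <- split(seq_along(rids), ceiling(cumsum(sizes) / chunk_rows))
  qsplit <- split(seq_len(nrow(Q)), gq)
  for (ch in chunks) {
    R <- do.call(rbind, re[ch])
    gr <- rep(seq_along(ch), times = sizes[ch])
    D <- l1_cross(Q, R)
    # min over the conformers of each query compound
    Dq <- do.call(rbind, lapply(qsplit, function(r) {
      if (length(r) == 1) D[r, , drop = TRUE]
      else apply(D[r, , drop = FALSE], 2, min)
    }))
    for (j in seq_along(ch)) {
      cols <- which(gr == j)
      block <- Dq[, cols, drop = FALSE]
      out[, ch[j]] <- do.call(pmin, as.data.frame(block))
    }
  }
  1 / (1 + out / 18)
}

# Tanimoto similarity matrix between two sets of compounds.
sim2d_matrix <- function(desc, qids, rids) {
  out <- tanimoto_cross(desc$fp[qids, , drop = FALSE],
                        desc$fp[rids, , drop = FALSE])
  dimnames(out) <- list(qids, rids)
  out
}

#' Build size-stratified training pairs
#'
#' For every target, each known active becomes a positive training pair: its
#' 3D and 2D scores are the maximum similarities to the target's other known
#' actives (the query is never compared to itself). Negative pairs are drawn
#' per target from the measured inactives plus the alleged inactives
#' (compounds never reported active on that target; gray-area pairs are
#' excluded from both sides) at a fixed ratio of negatives per active,
#' sampled uniformly without replacement under the given seed.
#'
#' @param set A labeled [bioactivity_set()].
#' @param descriptors A [featurize()] result covering all compounds of `set`.
#' @param ratio Negatives sampled per active (default 10).
#' @param seed Integer seed for the negative sampling.
#' @return A tibble with columns `query_id`, `target_id`, `score3d`,
#'   `score2d`, `label` (1/0) and `class_id` (heavy-atom class of the query).
#' @export
build_training_pairs <- function(set, descriptors, ratio = 10, seed = 1L) {
  stopifnot(inherits(set, "bioactivity_set"),
            inherits(descriptors, "revscreen_descriptors"))
  labels <- set$labels
  all_ids <- set$compounds$compound_id
  missing <- setdiff(all_ids, rownames(descriptors$fp))
  if (length(missing) > 0) {
    abort("descriptors missing for some compounds.",
          class = "revscreen_input_error")
  }
  targets <- sort(unique(labels$target_id[labels$label == "active"]))
  if (length(targets) == 0) {
    warn("no actives in the training set; returning an empty pair table.")
    return(tibble(query_id = character(), target_id = character(),
                  score3d = double(), score2d = double(),
                  label = integer(), class_id = integer()))
  }
  heavy <- setNames(set$compounds$heavy_atoms, set$compounds$compound_id)
  set.seed(seed)
  rows <- list()
  for (tg in targets) {
    actives <- sort(labels$compound_id[labels$target_id == tg &
                                         labels$label == "active"])
    if (length(actives) < 2) next  # no comparators for a lone active
    measured_in <- labels$compound_id[labels$target_id == tg &
                                        labels$label == "inactive"]
    gray <- labels$compound_id[labels$target_id == tg & labels$label == "gray"]
    alleged <- setdiff(all_ids, c(actives, gray))
    candidates <- sort(unique(c(measured_in, alleged)))
    n_neg <- ratio * length(actives)
    if (length(candidates) < n_neg) {
      warn(paste0("target ", tg, ": only ", length(candidates),
                  " inactive candidates for ", n_neg, " requested."))
      negs <- candidates
    } else {
      negs <- sort(sample(candidates, n_neg))
    }
    qids <- c(actives, negs)
    s3 <- sim3d_matrix(descriptors, qids, actives)
    s2 <- sim2d_matrix(descriptors, qids, actives)
    score_one <- function(q, is_active) {
      refs <- if (is_active) setdiff(actives, q) else actives
      c(max(s3[q, refs]), max(s2[q, refs]))
    }
    pos <- t(vapply(actives, score_one, numeric(2), is_active = TRUE))
    neg <- t(vapply(negs, score_one, numeric(2), is_active = FALSE))
    rows[[tg]] <- tibble(
      query_id = c(actives, negs),
      target_id = tg,
      score3d = unname(c(pos[, 1], neg[, 1])),
      score2d = unname(c(pos[, 2], neg[, 2])),
      label = c(rep(1L, length(actives)), rep(0L, length(negs)))
    )
  }
  bind_rows(rows) |>
    mutate(class_id = heavy_atom_class(heavy[.data$query_id]))
}

#' Fit the binary logistic model of one size class
#'
#' Fits `Probability = 1 / (1 + exp(-c1 * score3d - c2 * score2d - C))` on a
#' table of training pairs. The default fit carries the same L2 penalty as
#' the reference implementation the engine's training recipe is built on
#' (inverse regularization strength `reg_c = 1`, intercept unpenalized),
#' which keeps the coefficients finite when a size class is perfectly
#' separable; `reg_c = Inf` gives the penalty-free maximum-likelihood fit.
#'
#' @param pairs A tibble with columns `score3d`, `score2d`, `label`.
#' @param reg_c Inverse regularization strength (default 1); `Inf` disables
#'   the penalty.
#' @return A one-row tibble with `c1`, `c2`, `C` and `n_pairs`.
#' @export
fit_logistic <- function(pairs, reg_c = 1) {
  if (length(unique(pairs$label)) < 2) {
    abort("training pairs must contain both labels.",
          class = "revscreen_degenerate_fit")
  }
  if (is.infinite(reg_c)) {
    fit <- suppressWarnings(
      glm(label ~ score3d + score2d, data = pairs, family = binomial(),
          control = list(epsilon = 1e-8, maxit = 100))
    )
    cf <- coef(fit)
    cf[is.na(cf)] <- 0  # constant feature drops out of the fit
    return(tibble(c1 = unname(cf["score3d"]), c2 = unname(cf["score2d"]),
                  C = unname(cf["(Intercept)"]), n_pairs = nrow(pairs)))
  }
  x <- as.matrix(pairs[, c("score3d", "score2d")])
  cf <- unname(ridge_logistic(x, pairs$label, lambda = 1 / reg_c))
  tibble(c1 = cf[2], c2 = cf[3], C = cf[1], n_pairs = nrow(x))
}

# Penalized IRLS for binary logistic regression: minimizes the summed
# log-loss plus (lambda/2)||slopes||^2, intercept unpenalized — the same
# objective as the reference tool's default L2 fit. Works for any label
# counts (a lone positive is allowed).
ridge_logistic <- function(X, y, lambda, maxit = 200, tol = 1e-10) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  D <- diag(c(0, rep(lambda, p - 1)), p, p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / wt
    H <- crossprod(Xi, Xi * wt) + D
    bnew <- drop(solve(H, crossprod(Xi, wt * z)))
    if (max(abs(bnew - beta)) < tol) {
      beta <- bnew
      break
    }
    beta <- bnew
  }
  beta
}

#' Fit one logistic model per heavy-atom class
#'
#' @param pairs A training-pair tibble from [build_training_pairs()].
#' @param min_pairs Classes with fewer pairs are flagged `low_confidence`
#'   (default 50); they are still fitted.
#' @inheritParams fit_logistic
#' @return An object of class `revscreen_model` holding the raw per-class
#'   coefficients; apply [smooth_coefficients()] before prediction.
#' @export
fit_size_models <- function(pairs, min_pairs = 50, reg_c = 1) {
  stopifnot(all(c("score3d", "score2d", "label", "class_id") %in% names(pairs)))
  raw <- pairs |>
    group_by(.data$class_id) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$label)) < 2) {
        warn(paste0("class ", key$class_id,
                    ": single-label data, class skipped."))
        return(tibble())
      }
      fit_logistic(d, reg_c = reg_c)
    }) |>
    ungroup() |>
    mutate(low_confidence = .data$n_pairs < min_pairs)
  structure(list(raw = raw, smoothed = NULL, classes = SIZE_CLASSES),
            class = "revscreen_model")
}

#' Smooth coefficient curves with a cubic polynomial
#'
#' Replaces each of the three per-class coefficient curves (`c1`, `c2`, `C`
#' as functions of the class identifier) by its unweighted least-squares
#' polynomial of degree three, evaluated at every one of the 51 classes.
#' Classes missing from the raw fit are filled in by the polynomial (with a
#' warning), so the smoothed table always covers all classes.
#'
#' @param model A `revscreen_model` from [fit_size_models()].
#' @param degree Polynomial degree (default 3); reduced automatically when
#'   fewer distinct classes than `degree + 1` are available.
#' @return The model with a `smoothed` coefficient table added.
#' @export
smooth_coefficients <- function(model, degree = 3) {
  stopifnot(inherits(model, "revscreen_model"))
  raw <- model$raw
  if (nrow(raw) == 0) {
    abort("no fitted classes to smooth.", class = "revscreen_degenerate_fit")
  }
  if (!all(model$classes %in% raw$class_id)) {
    warn(paste0("coefficients fitted for ", nrow(raw), " of ",
                length(model$classes),
                " classes; the polynomial fills the rest."))
  }
  deg <- min(degree, dplyr::n_distinct(raw$class_id) - 1)
  grid <- tibble(class_id = model$classes)
  sm <- grid
  for (term in c("c1", "c2", "C")) {
    d <- tibble(x = raw$class_id, y = raw[[term]])
    fit <- if (deg >= 1) lm(y ~ poly(x, deg, raw = TRUE), data = d)
           else lm(y ~ 1, data = d)
    sm[[term]] <- unname(predict(fit, tibble(x = grid$class_id)))
  }
  model$smoothed <- sm
  model
}

#' @export
print.revscreen_model <- function(x, ...) {
  cat("<revscreen_model>\n")
  cat("  classes fitted (raw): ", nrow(x$raw), " of ", length(x$classes),
      "\n", sep = "")
  cat("  smoothed: ", !is.null(x$smoothed), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_size_models Long coefficient table (raw and smoothed).
#' @param x A `revscreen_model`.
#' @param ... Unused.
#' @method tidy revscreen_model
#' @export
tidy.revscreen_model <- function(x, ...) {
  out <- x$raw |>
    select("class_id", "c1", "c2", "C") |>
    tidyr::pivot_longer(c("c1", "c2", "C"), names_to = "term",
                        values_to = "estimate") |>
    mutate(provenance = "raw")
  if (!is.null(x$smoothed)) {
    out <- bind_rows(out, x$smoothed |>
                       tidyr::pivot_longer(c("c1", "c2", "C"),
                                           names_to = "term",
                                           values_to = "estimate") |>
                       mutate(provenance = "smoothed"))
  }
  out
}

#' @describeIn fit_size_models One-row model summary.
#' @method glance revscreen_model
#' @export
glance.revscreen_model <- function(x, ...) {
  tibble(
    n_classes_fitted = nrow(x$raw),
    n_classes = length(x$classes),
    n_pairs = sum(x$raw$n_pairs),
    n_low_confidence = sum(x$raw$low_confidence),
    smoothed = !is.null(x$smoothed)
  )
}

#' Serialize / reload a coefficient table
#'
#' Writes the raw and smoothed coefficient tables to JSON at full double
#' precision; the reload is bit-exact.
#'
#' @param model A `revscreen_model`.
#' @param path JSON file path.
#' @export
write_coefficients <- function(model, path) {
  stopifnot(inherits(model, "revscreen_model"))
  jsonlite::write_json(
    list(raw = model$raw, smoothed = model$smoothed,
         classes = model$classes),
    path, digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(raw = as_tibble(x$raw),
                 smoothed = if (!is.null(x$smoothed)) as_tibble(x$smoothed),
                 classes = as.integer(x$classes)),
            class = "revscreen_model")
}

# ---------------------------------------------------------------------------
# Classification metrics and cross-validation
# ---------------------------------------------------------------------------

#' Matthews correlation coefficient and companions
#'
#' Confusion-matrix metrics at the probability 0.5 threshold, in the
#' active/inactive vocabulary of the engine: `TA`/`TI` are true actives and
#' true inactives, `FA`/`FI` false actives and false inactives.
#' `MCC = (TA*TI - FA*FI) / sqrt((TA+FA)(TA+FI)(TI+FA)(TI+FI))`, defined as
#' 0 whenever a denominator factor vanishes.
#'
#' @param TA,TI,FA,FI Non-negative counts (vectorized).
#' @return Numeric vector.
#' @examples
#' mcc(6, 3, 2, 1)  # 16 / sqrt(1120)
#' @export
mcc <- function(TA, TI, FA, FI) {
  # double arithmetic: the four-way count product overflows integers
  TA <- as.numeric(TA); TI <- as.numeric(TI)
  FA <- as.numeric(FA); FI <- as.numeric(FI)
  den <- sqrt((TA + FA) * (TA + FI) * (TI + FA) * (TI + FI))
  num <- TA * TI - FA * FI
  ifelse(den == 0, 0, num / den)
}

#' @rdname mcc
#' @export
precision <- function(TA, FA) ifelse(TA + FA == 0, 0, TA / (TA + FA))

#' @rdname mcc
#' @export
recall <- function(TA, FI) ifelse(TA + FI == 0, 0, TA / (TA + FI))

# Confusion counts of predicted probabilities against 0/1 labels.
confusion_counts <- function(prob, label, threshold = 0.5) {
  pred <- prob > threshold
  tibble(
    TA = sum(pred & label == 1), TI = sum(!pred & label == 0),
    FA = sum(pred & label == 0), FI = sum(!pred & label == 1)
  )
}

#' k-fold cross-validation of the logistic fit
#'
#' Rows are shuffled into `k` random folds (no grouping by molecule or
#' target); each fold is scored at the 0.5 probability threshold by a model
#' fitted on the other folds, and the fold-level metrics are averaged.
#'
#' @param pairs A training-pair tibble (one size class, or pooled).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @inheritParams fit_logistic
#' @return A one-row tibble with `mcc_cv`, `mcc_sd`, `precision`, `recall`,
#'   `k` and `n`; the per-fold metrics are attached as attribute `folds`.
#' @export
cross_validate <- function(pairs, k = 10, seed = 1L, reg_c = 1) {
  n <- nrow(pairs)
  if (n < k) abort("need at least k pairs.", class = "revscreen_input_error")
  if (length(unique(pairs$label)) < 2) {
    abort("both labels must be present.", class = "revscreen_degenerate_fit")
  }
  make_folds <- function(s) {
    set.seed(s)
    sample(rep(seq_len(k), length.out = n))
  }
  folds <- make_folds(seed)
  ok <- function(f) all(vapply(split(pairs$label, f),
                               function(l) length(unique(l)) == 2, logical(1)))
  if (!ok(folds)) {
    folds <- make_folds(seed + 1L)  # resample once
    if (!ok(folds)) {
      abort("a cross-validation fold contains a single label.",
            class = "revscreen_degenerate_fit")
    }
  }
  per_fold <- lapply(seq_len(k), function(i) {
    train <- pairs[folds != i, , drop = FALSE]
    test <- pairs[folds == i, , drop = FALSE]
    cf <- fit_logistic(train, reg_c = reg_c)
    prob <- plogis(cf$c1 * test$score3d + cf$c2 * test$score2d + cf$C)
    cc <- confusion_counts(prob, test$label)
    tibble(fold = i, mcc = mcc(cc$TA, cc$TI, cc$FA, cc$FI),
           precision = precision(cc$TA, cc$FA), recall = recall(cc$TA, cc$FI))
  }) |> bind_rows()
  out <- tibble(
    mcc_cv = mean(per_fold$mcc), mcc_sd = sd(per_fold$mcc),
    precision = mean(per_fold$precision), recall = mean(per_fold$recall),
    k = k, n = n
  )
  attr(out, "folds") <- per_fold
  out
}
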