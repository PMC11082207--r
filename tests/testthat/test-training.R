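# Size classes, logistic fits, metrics, cross-validation, smoothing.

test_that("heavy-atom classes pool the extremes", {
  expect_equal(heavy_atom_class(8), 10L)
  expect_equal(heavy_atom_class(10), 10L)
  expect_equal(heavy_atom_class(11), 11L)
  expect_equal(heavy_atom_class(35), 35L)
  expect_equal(heavy_atom_class(59), 59L)
  expect_equal(heavy_atom_class(66), 60L)
  expect_equal(heavy_atom_class(c(1, 25, 200)), c(10L, 25L, 60L))
  expect_error(heavy_atom_class(0), class = "revscreen_input_error")
})

test_that("confusion metrics match their formulas", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(0, 0, 5, 5), -1)
  expect_equal(mcc(6, 3, 2, 1), 16 / sqrt(1120))
  expect_equal(mcc(0, 10, 0, 0), 0)  # degenerate denominator
  expect_equal(precision(6, 2), 0.75)
  expect_equal(recall(6, 1), 6 / 7)
})

test_that("metrics agree with an independent confusion computation on random counts", {
  set.seed(77)
  for (i in 1:100) {
    k <- sample(0:50, 4, replace = TRUE)
    ta <- k[1]; ti <- k[2]; fa <- k[3]; fi <- k[4]
    den <- (ta + fa) * (ta + fi) * (ti + fa) * (ti + fi)
    expected <- if (den == 0) 0 else (ta * ti - fa * fi) / sqrt(den)
    expect_equal(mcc(ta, ti, fa, fi), expected)
    expect_equal(precision(ta, fa), if (ta + fa == 0) 0 else ta / (ta + fa))
    expect_equal(recall(ta, fi), if (ta + fi == 0) 0 else ta / (ta + fi))
  }
})

test_that("logistic fit orders separable data and recovers the null intercept", {
  set.seed(21)
  n <- 400
  pairs <- tibble::tibble(
    score3d = runif(n), score2d = runif(n),
    label = as.integer(runif(n) > 0.5)
  )
  pairs$label <- as.integer(pairs$score2d > 0.5)  # perfectly separable
  # the unpenalized ML fit separates the labels completely
  cf <- fit_logistic(pairs, reg_c = Inf)
  prob <- plogis(cf$c1 * pairs$score3d + cf$c2 * pairs$score2d + cf$C)
  expect_gt(min(prob[pairs$label == 1]), max(prob[pairs$label == 0]))
  # the default penalized fit still ranks by the informative score
  cfr <- fit_logistic(pairs)
  expect_gt(cfr$c2, 0)
  expect_gt(cfr$c2, abs(cfr$c1))

  # constant scores: slopes drop out, intercept = log odds of prevalence
  const <- tibble::tibble(score3d = 0.5, score2d = 0.5,
                          label = rep(c(1L, 0L), times = c(30, 70)))
  cfc <- fit_logistic(const)
  expect_equal(cfc$c1, 0)
  expect_equal(cfc$c2, 0)
  p <- 0.3
  expect_equal(plogis(cfc$c1 * 0.5 + cfc$c2 * 0.5 + cfc$C), p,
               tolerance = 1e-6)

  expect_error(fit_logistic(tibble::tibble(score3d = 1, score2d = 1,
                                           label = 1L)),
               class = "revscreen_degenerate_fit")
})

test_that("label-balanced antisymmetric data put probability 0.5 at the centre", {
  s <- seq(0.1, 0.4, by = 0.05)
  pairs <- tibble::tibble(
    score3d = c(0.5 + s, 0.5 - s),
    score2d = c(0.5 + s, 0.5 - s),
    label = c(rep(1L, length(s)), rep(0L, length(s)))
  )
  cf <- fit_logistic(pairs)
  expect_equal(plogis(cf$c1 * 0.5 + cf$c2 * 0.5 + cf$C), 0.5,
               tolerance = 1e-6)
})

test_that("training pairs honour the 10:1 ratio and exclude self-comparison", {
  u <- small_universe()
  d <- small_descriptors()
  pairs <- suppressWarnings(build_training_pairs(u$training, d, ratio = 10,
                                                 seed = 7))
  expect_true(all(pairs$score3d >= 0 & pairs$score3d <= 1))
  expect_true(all(pairs$score2d >= 0 & pairs$score2d <= 1))
  per_target <- dplyr::count(pairs, target_id, label)
  pos <- per_target$n[per_target$label == 1]
  neg <- per_target$n[per_target$label == 0]
  # candidate supply caps negatives below 10x here; never above
  expect_true(all(neg <= 10 * pos))
  # positives come from actives only, never scored against themselves:
  # identical analogs do not exist within a series, so scores < 1
  expect_true(all(pairs$score2d[pairs$label == 1] < 1))
  # determinism under the seed
  pairs2 <- suppressWarnings(build_training_pairs(u$training, d, ratio = 10,
                                                  seed = 7))
  expect_identical(pairs, pairs2)
})

test_that("ample inactive supply yields exactly ratio-times-actives negatives", {
  # fabricated descriptors: 4 actives on one target, 60 unrelated compounds
  set.seed(55)
  ids <- c(paste0("a", 1:4), paste0("d", 1:60))
  fp <- t(vapply(ids, function(i) as.integer(runif(1024) < 0.1),
                 integer(1024)))
  rownames(fp) <- ids
  es <- lapply(setNames(ids, ids), function(i) matrix(runif(18), 1, 18))
  desc <- structure(list(fp = fp, es5d = es,
                         heavy_atoms = setNames(rep(20L, length(ids)), ids),
                         params = list()),
                    class = "revscreen_descriptors")
  cmp <- tibble::tibble(compound_id = ids, smiles = "c1ccccc1",
                        heavy_atoms = 20L)
  act <- tibble::tibble(compound_id = paste0("a", 1:4), target_id = "T",
                        measure_type = "Ki", value_uM = 1,
                        assay_class = "binding", species = "human")
  pairs <- build_training_pairs(bioactivity_set(cmp, act), desc,
                                ratio = 10, seed = 2)
  expect_equal(sum(pairs$label == 1), 4)
  expect_equal(sum(pairs$label == 0), 40)  # exactly 10 per active
})

test_that("a planted identical twin keeps the self-exclusion score at 1", {
  u <- small_universe()
  train <- u$training
  first_active <- train$labels$compound_id[train$labels$label == "active"][1]
  tgt <- train$labels$target_id[train$labels$label == "active"][1]
  twin_smiles <- train$compounds$smiles[
    train$compounds$compound_id == first_active]
  cmp <- rbind(train$compounds[, c("compound_id", "smiles", "heavy_atoms")],
               tibble::tibble(compound_id = "twin", smiles = twin_smiles,
                              heavy_atoms = train$compounds$heavy_atoms[
                                train$compounds$compound_id == first_active]))
  act <- rbind(train$activities,
               tibble::tibble(compound_id = "twin", target_id = tgt,
                              measure_type = "Ki", value_uM = 1,
                              assay_class = "binding", species = "human"))
  set2 <- bioactivity_set(cmp, act)
  d2 <- featurize(cmp[, c("compound_id", "smiles")], conformers = 1, seed = 7)
  pairs <- suppressWarnings(build_training_pairs(set2, d2, ratio = 5,
                                                 seed = 7))
  twin_row <- pairs[pairs$query_id == "twin" & pairs$target_id == tgt, ]
  expect_equal(unname(twin_row$score2d), 1)  # its twin is a distinct active
  expect_equal(unname(twin_row$label), 1L)
})

test_that("ten-fold cross-validation is seeded, fair and calibrated", {
  set.seed(13)
  n <- 600
  sep <- tibble::tibble(score3d = runif(n), score2d = runif(n))
  sep$label <- as.integer(sep$score2d + 0.3 * sep$score3d > 0.6)
  cv1 <- cross_validate(sep, k = 10, seed = 5)
  cv2 <- cross_validate(sep, k = 10, seed = 5)
  expect_identical(cv1, cv2)
  expect_gt(cv1$mcc_cv, 0.8)

  # perfectly separable (with a margin around the threshold) -> MCC_cv 1
  strict <- sep
  strict$score2d <- ifelse(strict$score2d > 0.5,
                           0.6 + 0.4 * (strict$score2d - 0.5) / 0.5,
                           0.4 * strict$score2d / 0.5)
  strict$label <- as.integer(strict$score2d > 0.5)
  for (s in c(1, 2, 3)) {
    expect_equal(cross_validate(strict, k = 10, seed = s)$mcc_cv, 1)
  }
  expect_error(cross_validate(sep[1:5, ], k = 10),
               class = "revscreen_input_error")
})

test_that("permuted labels give near-zero cross-validated MCC", {
  set.seed(99)
  n <- 5000
  null_pairs <- tibble::tibble(
    score3d = runif(n), score2d = runif(n),
    label = sample(rep(0:1, each = n / 2))
  )
  cv <- cross_validate(null_pairs, k = 10, seed = 3)
  expect_lt(abs(cv$mcc_cv), 0.1)
})

test_that("cubic smoothing reproduces exact cubics and beats a coarse grid", {
  classes <- 10:60
  # exact cubic is reproduced to 1e-9
  cub <- function(x) 0.02 * x^3 - 1.5 * x^2 + 4 * x - 7
  raw <- tibble::tibble(class_id = classes, c1 = cub(classes),
                        c2 = -cub(classes) / 2, C = 5, n_pairs = 100L,
                        low_confidence = FALSE)
  model <- structure(list(raw = raw, smoothed = NULL, classes = classes),
                     class = "revscreen_model")
  sm <- smooth_coefficients(model)$smoothed
  expect_equal(sm$c1, raw$c1, tolerance = 1e-9)
  expect_equal(sm$c2, raw$c2, tolerance = 1e-9)
  expect_equal(sm$C, rep(5, 51), tolerance = 1e-9)  # constants stay constant

  # least squares beats any cubic from a coarse coefficient grid
  set.seed(31)
  noisy <- raw
  noisy$c1 <- cub(classes) + rnorm(51, 0, 3)
  mod2 <- structure(list(raw = noisy, smoothed = NULL, classes = classes),
                    class = "revscreen_model")
  sm2 <- smooth_coefficients(mod2)$smoothed
  rss_fit <- sum((noisy$c1 - sm2$c1)^2)
  grid <- expand.grid(a = seq(-0.02, 0.06, by = 0.02),
                      b = seq(-3, 0, by = 0.5),
                      c = seq(0, 8, by = 2), d = seq(-20, 10, by = 5))
  rss_grid <- min(apply(grid, 1, function(g) {
    sum((noisy$c1 - (g[1] * classes^3 + g[2] * classes^2 +
                       g[3] * classes + g[4]))^2)
  }))
  expect_lte(rss_fit, rss_grid)
})

test_that("smoothing covers all 51 classes even from partial fits", {
  raw <- tibble::tibble(class_id = c(12L, 15L, 20L, 30L, 40L),
                        c1 = c(1, 2, 3, 4, 5), c2 = 1, C = -2,
                        n_pairs = 100L, low_confidence = FALSE)
  model <- structure(list(raw = raw, smoothed = NULL, classes = 10:60),
                     class = "revscreen_model")
  expect_warning(sm <- smooth_coefficients(model), "classes")
  expect_equal(nrow(sm$smoothed), 51)
  expect_true(all(is.finite(sm$smoothed$c1)))
})

test_that("coefficient tables survive a JSON round trip bit-exactly", {
  model <- small_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(model, path)
  back <- read_coefficients(path)
  expect_equal(back$raw$c1, model$raw$c1)
  expect_identical(back$smoothed$C, model$smoothed$C)
  expect_identical(back$classes, model$classes)
})

test_that("model tidy/glance expose coefficients and summary", {
  model <- small_model()
  td <- tidy(model)
  expect_setequal(unique(td$provenance), c("raw", "smoothed"))
  expect_setequal(unique(td$term), c("c1", "c2", "C"))
  gl <- glance(model)
  expect_true(gl$smoothed)
  expect_equal(gl$n_classes, 51)
})

test_that("the penalized fit matches an independent ridge implementation", {
  set.seed(8)
  n <- 500
  pairs <- tibble::tibble(score3d = runif(n), score2d = runif(n))
  pairs$label <- rbinom(n, 1, plogis(2 * pairs$score2d + pairs$score3d - 1.5))
  ours <- fit_logistic(pairs, reg_c = 1)
  g <- glmnet::glmnet(as.matrix(pairs[, c("score3d", "score2d")]),
                      pairs$label, family = "binomial", alpha = 0,
                      lambda = 1 / n, standardize = FALSE, thresh = 1e-14)
  cf <- as.numeric(coef(g))
  expect_equal(c(ours$C, ours$c1, ours$c2), cf, tolerance = 1e-3)
  # the penalty shrinks slopes relative to the unpenalized fit
  ml <- fit_logistic(pairs, reg_c = Inf)
  expect_lt(abs(ours$c2), abs(ml$c2) + 1e-8)
})

test_that("a lone positive in a size class still yields a finite fit", {
  set.seed(12)
  pairs <- tibble::tibble(score3d = runif(20), score2d = runif(20),
                          label = c(1L, rep(0L, 19)))
  cf <- fit_logistic(pairs)
  expect_true(all(is.finite(c(cf$c1, cf$c2, cf$C))))
})
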