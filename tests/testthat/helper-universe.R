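# Shared fixtures, built once per test run and memoised.

.cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

# A small planted universe: 5 targets x 8 actives, 2 held-out each.
small_universe <- function() {
  memo("small_universe", function() {
    generate_universe(fixture_spec(
      n_targets = 5, actives_per_target = 8, n_decoys = 30,
      heldout_per_target = 2, seed = 7
    ))
  })
}

small_descriptors <- function() {
  memo("small_descriptors", function() {
    u <- small_universe()
    featurize(
      rbind(u$training$compounds[, c("compound_id", "smiles")],
            u$test[, c("compound_id", "smiles")]),
      conformers = 1, seed = 7
    )
  })
}

small_model <- function() {
  memo("small_model", function() {
    u <- small_universe()
    pairs <- suppressWarnings(
      build_training_pairs(u$training, small_descriptors(),
                           ratio = 10, seed = 7))
    suppressWarnings(smooth_coefficients(fit_size_models(pairs)))
  })
}

# Random binary fingerprints for property tests.
random_fp <- function(n_bits = 64, density = 0.3) {
  as.integer(runif(n_bits) < density)
}

# Random ES5D-like vectors.
random_es5d <- function() runif(18, 0, 10)

# Brute-force Tanimoto on index sets, independent of the bit arithmetic.
tanimoto_brute <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  u <- union(A, B)
  if (length(u) == 0) return(0)
  length(intersect(A, B)) / length(u)
}
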