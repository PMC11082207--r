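#' Tanimoto coefficient between two binary fingerprints
#'
#' The 2D similarity score of the engine: \eqn{T_c = |A \cap B| / |A \cup B|}
#' over the set bits of two equal-length binary fingerprints. Two empty
#' fingerprints return 0 (no evidence of similarity).
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 1), c(1, 0, 0, 1))
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort("fingerprints must have equal bit length.",
          class = "revscreen_dimension_error")
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Manhattan-based similarity of two ES5D vectors
#'
#' The 3D similarity score of the engine,
#' \eqn{M_s = 1 / (1 + d / 18)} where \eqn{d} is the Manhattan (L1) distance
#' between two 18-dimensional ES5D descriptor vectors. The score lies in
#' `(0, 1]` and decreases monotonically with the distance.
#'
#' @param u,v Numeric vectors of length 18.
#' @return A number in `(0, 1]`.
#' @examples
#' manhattan_similarity(rep(0, 18), rep(1, 18))  # d = 18 -> 0.5
#' @export
manhattan_similarity <- function(u, v) {
  if (length(u) != 18 || length(v) != 18) {
    abort("ES5D vectors must have length 18.",
          class = "revscreen_dimension_error")
  }
  1 / (1 + sum(abs(u - v)) / 18)
}

#' Best-pair shape similarity of two conformer sets
#'
#' Compares every conformer of `a` to every conformer of `b` and returns the
#' highest Manhattan-based similarity, i.e. the similarity corresponding to
#' the smallest Manhattan distance over all conformer pairs.
#'
#' @param a,b Matrices with one 18-dimensional ES5D vector per row
#'   (one row per conformer).
#' @return A number in `(0, 1]`.
#' @export
best_pair_similarity <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("conformer sets must be non-empty.", class = "revscreen_input_error")
  }
  if (ncol(a) != 18 || ncol(b) != 18) {
    abort("ES5D vectors must have length 18.",
          class = "revscreen_dimension_error")
  }
  1 / (1 + min(l1_cross(a, b)) / 18)
}

# Cross L1 distance matrix between rows of X and rows of Y.
l1_cross <- function(X, Y) {
  D <- matrix(0, nrow(X), nrow(Y))
  for (k in seq_len(ncol(X))) {
    D <- D + abs(outer(X[, k], Y[, k], "-"))
  }
  D
}

# Tanimoto similarity matrix between rows of binary matrices A (n x bits)
# and B (m x bits).
tanimoto_cross <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  inter <- A %*% t(B)
  pa <- rowSums(A); pb <- rowSums(B)
  un <- outer(pa, pb, "+") - inter
  out <- ifelse(un == 0, 0, inter / un)
  out
}
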