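#' Asymmetric binary distance between two enrichment profiles
#'
#' Entries are binarized as nonzero/zero; with `a` = positions where both are
#' nonzero, `b` and `c` = positions where only one is, the distance is
#' `(b + c) / (a + b + c)`. Positions where both profiles are zero carry no
#' information and are ignored; if no position is nonzero in either profile
#' the distance is undefined (`NA`). The result is invariant to any positive
#' rescaling of the profile values.
#'
#' @param profile_a,profile_b numeric vectors of equal length in the same
#'   context order.
#' @return a number in `[0, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' binary_distance(c(1, 0, 1, 0), c(1, 1, 0, 0))  # 2/3
binary_distance <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  za <- profile_a != 0
  zb <- profile_b != 0
  denom <- sum(za | zb)
  if (denom == 0) return(NA_real_)
  sum(xor(za, zb)) / denom
}

#' Pairwise profile-distance matrix for all diseases
#'
#' @param profiles an `enrichment_profiles` object from [build_profiles()],
#'   or a numeric disease-by-context matrix.
#' @param binarize `"score"` (default): profiles are binarized on a nonzero
#'   enrichment score, i.e. any overlap; `"significant"`: on the Fisher-test
#'   significance flag instead (only meaningful for an `enrichment_profiles`
#'   input).
#' @return object of class `distance_matrix`: a symmetric disease-by-disease
#'   matrix of binary distances with zero diagonal where defined and `NA` for
#'   undefined entries.
#' @export
profile_distance_matrix <- function(profiles, binarize = c("score", "significant")) {
  binarize <- match.arg(binarize)
  if (inherits(profiles, "enrichment_profiles")) {
    mat <- if (binarize == "significant") profiles$significant * 1 else profiles$score
  } else {
    stopifnot(is.matrix(profiles), is.numeric(profiles))
    mat <- profiles
  }
  n <- nrow(mat)
  dz <- rownames(mat) %||% paste0("d", seq_len(n))
  out <- matrix(NA_real_, n, n, dimnames = list(dz, dz))
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- binary_distance(mat[i, ], mat[j, ])
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  structure(out, class = c("distance_matrix", "matrix"))
}

#' Rank disease pairs by profile distance
#'
#' @param dm a `distance_matrix` from [profile_distance_matrix()].
#' @return data frame of all defined off-diagonal pairs (`disease_a`,
#'   `disease_b`, `distance`, `rank`), ascending by distance with ties broken
#'   lexicographically by pair name. Undefined pairs are excluded; their
#'   count and identities are attached as attributes `n_undefined` and
#'   `undefined_pairs`.
#' @export
rank_pairs <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  dz <- rownames(dm)
  pairs <- enumerate_pairs(dz)
  pairs$distance <- dm[cbind(pairs$disease_a, pairs$disease_b)]
  undef <- is.na(pairs$distance)
  undefined_pairs <- pairs[undef, c("disease_a", "disease_b")]
  pairs <- pairs[!undef, , drop = FALSE]
  if (nrow(pairs) == 0) stop("all pairwise distances are undefined")
  ord <- order(pairs$distance, pairs$disease_a, pairs$disease_b)
  pairs <- pairs[ord, , drop = FALSE]
  pairs$rank <- seq_len(nrow(pairs))
  rownames(pairs) <- NULL
  attr(pairs, "n_undefined") <- nrow(undefined_pairs)
  attr(pairs, "undefined_pairs") <- undefined_pairs
  pairs
}
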