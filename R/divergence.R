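check_distribution <- function(p, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > tol)
    stop("input is not a probability distribution (non-negative, sum 1)",
         call. = FALSE)
  invisible(p)
}

# -sum p log2 p with the 0 * log 0 = 0 convention
shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence (base 2)
#'
#' Symmetric, bounded dissimilarity between two discrete probability
#' distributions: `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with
#' `m = (p + q) / 2` and Shannon entropy `H` in bits, so the result lies in
#' \[0, 1\]. Zero-probability entries are handled by the `0 log 0 = 0`
#' convention; no pseudocounts are needed because the midpoint keeps every
#' Kullback-Leibler term finite.
#'
#' @param p,q non-negative numeric vectors of equal length, each summing
#'   to 1 (within `1e-9`).
#' @return JSD in bits, in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length", call. = FALSE)
  check_distribution(p)
  check_distribution(q)
  m <- (p + q) / 2
  d <- shannon_bits(m) - (shannon_bits(p) + shannon_bits(q)) / 2
  min(max(d, 0), 1)  # clamp floating-point fuzz at the boundaries
}

#' Square-root Jensen-Shannon distance
#'
#' The square root of [jsd()] is a true metric on probability distributions
#' (symmetry, identity of indiscernibles, triangle inequality) and is the
#' dissimilarity used for the persistence analysis.
#'
#' @inheritParams jsd
#' @return `sqrt(jsd(p, q))`, in \[0, 1\].
#' @export
sqrt_jsd <- function(p, q) sqrt(jsd(p, q))

#' Euclidean (L2) distance between two patterns
#'
#' Alternative dissimilarity for the persistence analysis; unlike [sqrt_jsd()]
#' it does not require the inputs to be probability distributions.
#'
#' @param p,q numeric vectors of equal length.
#' @return Euclidean norm of `p - q`.
#' @export
l2_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length", call. = FALSE)
  sqrt(sum((p - q)^2))
}

pattern_distance <- function(p, q, metric = c("sqrt_jsd", "l2")) {
  metric <- match.arg(metric)
  switch(metric, sqrt_jsd = sqrt_jsd(p, q), l2 = l2_distance(p, q))
}
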