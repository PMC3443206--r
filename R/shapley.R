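#' Exact average attributable fractions over a factor set
#'
#' Combines subset attributable fractions with Shapley weights:
#' `AAF_i = sum over S not containing i of |S|!(k-|S|-1)!/k! *
#' (AF(S + i) - AF(S))` — the average AF increment from eliminating factor
#' i after a uniformly random set of the other factors has already been
#' eliminated. The evaluator is called once per subset (2^k calls).
#'
#' @param af_evaluator Function taking an integer vector of factor indices
#'   (possibly empty) and returning `AF(S)`.
#' @param k Number of factors (exact mode capped at 12).
#' @param factor_names Optional names for the result.
#' @return Named numeric vector of per-factor AAFs. Their sum equals
#'   `AF(1:k) - AF(empty)` exactly (efficiency).
#' @export
aaf_exact <- function(af_evaluator, k, factor_names = NULL) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k > 12) {
    stop("exact mode capped at k = 12; use aaf_montecarlo()", call. = FALSE)
  }
  masks <- 0:(2^k - 1)
  af <- vapply(masks, function(m) af_evaluator(mask_to_subset(m, k)),
               numeric(1))
  sizes <- mask_popcounts(k)
  fact <- factorial(0:k)
  # weight for a subset of size s (not containing i): s!(k-s-1)!/k!
  w_size <- fact[0:(k - 1) + 1] * fact[k - (0:(k - 1))] / fact[k + 1]
  aaf <- numeric(k)
  for (i in seq_len(k)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[without + 1L]
    aaf[i] <- sum(w_size[s + 1L] *
                    (af[bitwOr(without, bit) + 1L] - af[without + 1L]))
  }
  names(aaf) <- factor_names %||% paste0("f", seq_len(k))
  aaf
}

#' Brute-force AAF by permutation enumeration
#'
#' Direct implementation of the defining average: enumerate all `k!`
#' elimination orders, accumulate for each factor the sequential increment
#' `AF(first i factors) - AF(first i-1 factors)` of the order, and average.
#' Serves as the independent oracle for [aaf_exact()].
#'
#' @inheritParams aaf_exact
#' @return Named numeric vector of per-factor AAFs.
#' @export
aaf_permutation_oracle <- function(af_evaluator, k, factor_names = NULL) {
  if (k < 1 || k > 8) {
    stop("permutation oracle limited to 1 <= k <= 8", call. = FALSE)
  }
  ev <- memoise_af(af_evaluator, k)
  perms <- all_permutations(k)
  totals <- numeric(k)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    prev <- ev(integer(0))
    for (i in seq_len(k)) {
      cur <- ev(ord[seq_len(i)])
      totals[ord[i]] <- totals[ord[i]] + (cur - prev)
      prev <- cur
    }
  }
  aaf <- totals / nrow(perms)
  names(aaf) <- factor_names %||% paste0("f", seq_len(k))
  aaf
}

#' Monte Carlo AAF over sampled elimination orders
#'
#' Averages sequential AF increments over `n_perms` uniformly sampled
#' permutations; scales to factor sets too large for exact enumeration.
#'
#' @inheritParams aaf_exact
#' @param n_perms Number of sampled permutations (>= 100).
#' @param seed Integer seed for reproducibility.
#' @return Named numeric vector of per-factor AAFs with attributes
#'   `"mc_se"` (per-factor Monte Carlo standard error), `"n_perms"` and
#'   `"seed"`.
#' @export
aaf_montecarlo <- function(af_evaluator, k, n_perms = 1000, seed = NULL,
                           factor_names = NULL) {
  if (n_perms < 100) stop("`n_perms` must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ev <- if (k <= 20) memoise_af(af_evaluator, k) else af_evaluator
  sums <- numeric(k)
  sq <- numeric(k)
  for (r in seq_len(n_perms)) {
    ord <- sample.int(k)
    prev <- ev(integer(0))
    for (i in seq_len(k)) {
      cur <- ev(ord[seq_len(i)])
      inc <- cur - prev
      sums[ord[i]] <- sums[ord[i]] + inc
      sq[ord[i]] <- sq[ord[i]] + inc^2
      prev <- cur
    }
  }
  aaf <- sums / n_perms
  mc_var <- pmax(sq / n_perms - aaf^2, 0) / n_perms
  names(aaf) <- factor_names %||% paste0("f", seq_len(k))
  structure(aaf, mc_se = sqrt(mc_var), n_perms = n_perms, seed = seed)
}
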