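`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign broad age classes
#'
#' Maps age in years onto the three broad classes used throughout the
#' analysis: `"18-40"`, `"40-65"`, `">65"`. By default the intervals are
#' half-open (`[18,40)`, `[40,65)`, `[65,Inf)`); `inclusive_forty = TRUE`
#' switches the first boundary so that exactly 40 falls in the youngest
#' class.
#'
#' @param age Numeric vector of ages in years (>= 18).
#' @param inclusive_forty If `TRUE`, age 40 is classed as `"18-40"`.
#' @return Factor with levels `"18-40"`, `"40-65"`, `">65"`.
#' @export
assign_age_class <- function(age, inclusive_forty = FALSE) {
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("`age` must be finite and >= 18", call. = FALSE)
  }
  young_cut <- if (inclusive_forty) age <= 40 else age < 40
  out <- ifelse(young_cut, "18-40", ifelse(age < 65, "40-65", ">65"))
  factor(out, levels = age_class_levels())
}

age_class_levels <- function() c("18-40", "40-65", ">65")

# Deterministic per-stage child seeds from one master seed (kept < 2^31).
child_seed <- function(master, stage) {
  (as.numeric(master) * 48271 + 1000003 * stage) %% 2147483629
}

# Indices (1-based) of set bits of mask over k positions.
mask_to_subset <- function(mask, k) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L)
}

# Number of set bits for each mask 0..2^k-1.
mask_popcounts <- function(k) {
  masks <- 0:(2^k - 1)
  counts <- integer(length(masks))
  for (j in 0:(k - 1)) {
    counts <- counts + as.integer(bitwAnd(masks, bitwShiftL(1L, j)) != 0L)
  }
  counts
}

# All permutations of 1:k as a (k! x k) matrix.
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  row <- 1L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    block <- cbind(first, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Wrap an AF evaluator with a bitmask-keyed memo table.
memoise_af <- function(af_evaluator, k) {
  cache <- rep(NA_real_, 2^k)
  function(subset) {
    mask <- if (length(subset)) sum(bitwShiftL(1L, subset - 1L)) else 0L
    val <- cache[mask + 1L]
    if (is.na(val)) {
      val <- af_evaluator(subset)
      cache[mask + 1L] <<- val
    }
    val
  }
}

assert_probability <- function(x, name, open_low = TRUE, open_high = TRUE) {
  bad <- !is.finite(x) |
    (if (open_low) x <= 0 else x < 0) |
    (if (open_high) x >= 1 else x > 1)
  if (any(bad)) {
    stop(sprintf("`%s` must lie in %s0,1%s", name,
                 if (open_low) "(" else "[", if (open_high) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}
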