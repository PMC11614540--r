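DEFAULT_SEED <- 20242553L
DEFAULT_RESAMPLES <- 1e6

# normalize a weights argument (data.frame from isolation_weights() or a
# named numeric vector) and check that it matches the trait's societies
match_weights <- function(x, weights) {
  if (is.data.frame(weights)) {
    w <- setNames(weights$weight, weights$society_id)
  } else {
    w <- weights
  }
  if (is.null(names(w)) || is.null(names(x))) {
    stop("trait values and weights must both be named by society_id",
         call. = FALSE)
  }
  if (!setequal(names(x), names(w)) || length(x) != length(w)) {
    stop("weight set does not match trait set", call. = FALSE)
  }
  w <- w[names(x)]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  w
}

#' Exact isolation-weighted value of a trait
#'
#' The closed-form expectation of the weighted resampler: for a binary
#' trait, the weighted proportion `sum(w_i * x_i)`; for a categorical
#' trait, the weight mass per category (which sums to 1). This is the
#' analytic reference that Monte-Carlo corrected estimates converge to.
#'
#' @param x named binary (0/1 or logical) or categorical (character/factor)
#'   trait vector, names the society identifiers.
#' @param weights weights over exactly the same societies: a data.frame
#'   from [isolation_weights()] or a named numeric vector summing to 1.
#' @return for binary traits a single proportion; for categorical traits a
#'   named numeric vector of category masses.
#' @export
#' @examples
#' w <- c(A = 3/11, B = 3/11, C = 5/11)
#' analytic_weighted_value(c(A = 1, B = 1, C = 0), w)  # 6/11
analytic_weighted_value <- function(x, weights) {
  w <- match_weights(x, weights)
  if (is.logical(x)) x <- as.numeric(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("binary trait values must be 0/1 or logical", call. = FALSE)
    }
    return(sum(w * x))
  }
  x <- as.character(x)
  masses <- tapply(w, x, sum)
  out <- setNames(as.numeric(masses), names(masses))
  out[sort(names(out))]
}

#' Phylogenetically corrected proportion by weighted resampling
#'
#' Draws `n_resamples` societies independently with replacement, each with
#' probability equal to its isolation weight, and reports the fraction of
#' draws carrying the trait. The raw value is the unweighted proportion.
#' The Monte-Carlo standard error is the plug-in binomial formula
#' `sqrt(p*(1-p)/n_resamples)`. Identical inputs and seed give
#' bit-identical results; the caller's RNG state is left untouched.
#'
#' @inheritParams analytic_weighted_value
#' @param n_resamples number of resampling draws (default 1e6).
#' @param seed integer RNG seed (default 20242553), recorded in the output.
#' @param label optional statistic label.
#' @return a one-row data.frame: `label`, `raw_value`, `corrected_value`,
#'   `mc_se`, `n_resamples`, `seed`, `n_societies`.
#' @export
corrected_proportion <- function(x, weights, n_resamples = DEFAULT_RESAMPLES,
                                 seed = DEFAULT_SEED, label = NA_character_) {
  stopifnot(n_resamples >= 1)
  w <- match_weights(x, weights)
  if (is.logical(x)) x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) {
    stop("binary trait values must be 0/1 or logical", call. = FALSE)
  }
  draws <- with_preserved_seed(seed, {
    sample.int(length(x), n_resamples, replace = TRUE, prob = w)
  })
  p_hat <- mean(x[draws])
  data.frame(
    label = label,
    raw_value = mean(x),
    corrected_value = p_hat,
    mc_se = sqrt(p_hat * (1 - p_hat) / n_resamples),
    n_resamples = n_resamples,
    seed = as.integer(seed),
    n_societies = length(x),
    stringsAsFactors = FALSE
  )
}

#' Phylogenetically corrected categorical distribution
#'
#' As [corrected_proportion()], for a categorical trait: all category
#' shares are computed from a single vector of weighted draws, so they sum
#' to one exactly for any seed.
#'
#' @inheritParams corrected_proportion
#' @param x named categorical trait (character or factor); factor levels,
#'   when given, fix the category set and order.
#' @return a data.frame with one row per category: `label`, `category`,
#'   `raw_value`, `corrected_value`, `mc_se`, `n_resamples`, `seed`,
#'   `n_societies`.
#' @export
corrected_distribution <- function(x, weights,
                                   n_resamples = DEFAULT_RESAMPLES,
                                   seed = DEFAULT_SEED,
                                   label = NA_character_) {
  stopifnot(n_resamples >= 1)
  w <- match_weights(x, weights)
  f <- if (is.factor(x)) x else factor(as.character(x))
  draws <- with_preserved_seed(seed, {
    sample.int(length(f), n_resamples, replace = TRUE, prob = w)
  })
  shares <- as.numeric(table(f[draws])) / n_resamples
  raw <- as.numeric(table(f)) / length(f)
  data.frame(
    label = label,
    category = levels(f),
    raw_value = raw,
    corrected_value = shares,
    mc_se = sqrt(shares * (1 - shares) / n_resamples),
    n_resamples = n_resamples,
    seed = as.integer(seed),
    n_societies = length(f),
    stringsAsFactors = FALSE
  )
}
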