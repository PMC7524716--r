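#' Goodness-of-fit metrics for model-data comparison
#'
#' `r_squared()` is the coefficient of determination
#' `1 - SSE / SStot` (can be negative for poor fits); `mare()` is the mean
#' absolute relative error `mean(|sim - obs| / |obs|)`; `pearson_r()` is the
#' product-moment correlation. These are the building blocks of the weighted
#' multi-objective calibration.
#'
#' @param obs,sim numeric vectors of equal length (observations first).
#' @return a single numeric value.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' mare(c(1, 2), c(1.5, 1))           # 0.5
#' pearson_r(1:5, 2 * (1:5) + 3)      # 1
#' @export
r_squared <- function(obs, sim) {
  check_paired(obs, sim, min_n = 2)
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) abort("`obs` has zero variance; R2 undefined.")
  1 - sum((sim - obs)^2) / sstot
}

#' @rdname r_squared
#' @export
mare <- function(obs, sim) {
  check_paired(obs, sim, min_n = 1)
  if (any(obs == 0)) abort("`obs` contains zeros; MARE undefined.")
  mean(abs(sim - obs) / abs(obs))
}

#' @rdname r_squared
#' @export
pearson_r <- function(obs, sim) {
  check_paired(obs, sim, min_n = 2)
  if (sd(obs) == 0 || sd(sim) == 0)
    abort("constant series; Pearson correlation undefined.")
  as.numeric(cor(obs, sim))
}

check_paired <- function(obs, sim, min_n) {
  if (length(obs) != length(sim))
    abort("`obs` and `sim` must have equal length.")
  if (length(obs) < min_n)
    abort(paste0("need at least ", min_n, " paired values."))
  if (any(!is.finite(obs)) || any(!is.finite(sim)))
    abort("`obs` and `sim` must be finite.")
  invisible(TRUE)
}

#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = n log(SSE / n) + 2 k`, the least-squares convention used to
#' compare calibrated models with different parameter counts; lower is
#' better.
#'
#' @param n number of observations (> k).
#' @param sse residual sum of squares (> 0).
#' @param k number of fitted parameters.
#' @return AIC value.
#' @examples
#' aic_sse(10, 10, 2)  # 4
#' @export
aic_sse <- function(n, sse, k) {
  if (sse <= 0) abort("`sse` must be > 0.")
  if (n <= k) abort("`n` must exceed `k`.")
  n * log(sse / n) + 2 * k
}
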