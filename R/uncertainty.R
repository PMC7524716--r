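#' Critical objective function index (COFI) threshold
#'
#' Objective-function threshold defining the nonlinear-regression parameter
#' confidence region:
#' `J_cr = J_min * (1 + p / (n - p) * F(1 - alpha; p, n - p))`.
#' Parameter sets from the search archive whose objective falls below `J_cr`
#' form the uncertainty ensemble. The threshold tightens towards `J_min` as
#' the number of observations grows and always exceeds `J_min`.
#'
#' @param j_min best (minimum) objective value (> 0).
#' @param p number of calibrated parameters (>= 1).
#' @param n number of observations (> p).
#' @param alpha significance level (default 0.05 for a 95% region).
#' @return the critical objective value `J_cr`.
#' @examples
#' cofi_threshold(0.5, p = 11, n = 74, alpha = 0.05)
#' @export
cofi_threshold <- function(j_min, p, n, alpha = 0.05) {
  if (n <= p) abort("`n` must exceed `p`.")
  if (p < 1) abort("`p` must be >= 1.")
  if (j_min <= 0) abort("`j_min` must be > 0.")
  j_min * (1 + p / (n - p) * qf(1 - alpha, p, n - p))
}

#' Filter a search archive into a COFI parameter ensemble
#'
#' Keeps the archived parameter sets with `J < j_critical`, and summarises
#' each calibrated parameter by mean, SD, coefficient of variation and
#' 2.5/97.5 percentiles.
#'
#' @param archive tibble of archived evaluations (parameter columns plus a
#'   `j` column), e.g. `sce_fit$archive` or [mcmc_sample()] draws.
#' @param j_critical COFI threshold from [cofi_threshold()].
#' @param params optional character vector naming the parameter columns to
#'   summarise (default: all columns except `j` and `eval`).
#' @return object of class `parameter_ensemble`: list with `sets` (accepted
#'   rows), `summary` (tibble: `parameter`, `mean`, `sd`, `cv`, `q2.5`,
#'   `q97.5`), `j_critical`, `n_accepted`.
#' @export
cofi_ensemble <- function(archive, j_critical, params = NULL) {
  if (nrow(archive) == 0) abort("`archive` is empty.")
  if (is.null(params))
    params <- setdiff(names(archive), c("j", "eval"))
  keep <- archive$j < j_critical
  if (!any(keep))
    abort(paste0("no archived parameter set has J < ", signif(j_critical, 5),
                 "; enlarge the search budget or loosen alpha."))
  sets <- archive[keep, , drop = FALSE]
  summ <- purrr::map_dfr(params, function(pn) {
    v <- sets[[pn]]
    tibble::tibble(parameter = pn, mean = mean(v), sd = sd(v),
                   cv = sd(v) / abs(mean(v)),
                   q2.5 = quantile(v, 0.025, names = FALSE),
                   q97.5 = quantile(v, 0.975, names = FALSE))
  })
  structure(list(sets = sets, summary = summ, j_critical = j_critical,
                 n_accepted = sum(keep)),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat("<parameter_ensemble> ", x$n_accepted, " sets below J_cr = ",
      signif(x$j_critical, 5), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Metropolis random-walk sampling of a parameter box
#'
#' Probabilistic inversion under uniform priors on the bounds: a random-walk
#' Metropolis sampler with acceptance probability
#' `exp(-(J' - J) / temperature)`, so lower objective values are always
#' accepted and worse ones with Boltzmann probability. Proposals outside the
#' box are reflected back inside. Used for the TECO inversion; exposed
#' generically for any objective.
#'
#' @param fn objective function of the full parameter vector (finite).
#' @param lower,upper finite box bounds (equal entries are held fixed).
#' @param n_iter iterations after burn-in.
#' @param burn_in discarded initial iterations.
#' @param proposal_scale SD of the Gaussian proposal as a fraction of the
#'   box width per free dimension (default 0.1).
#' @param temperature calibration temperature of the acceptance rule. The
#'   default `NULL` uses `j0 / 10` where `j0` is the objective at the
#'   starting point, a scale that keeps acceptance in a usable range for
#'   J-type objectives; pass an explicit value for likelihood-calibrated
#'   runs (e.g. `(J_cr - J_min)` from COFI).
#' @param start optional starting vector; default the box midpoint.
#' @param seed integer seed.
#' @return object of class `mcmc_fit`: `draws` (tibble with parameter
#'   columns + `j`), `acceptance_rate`, `converged_diag` (absolute split-half
#'   mean difference in units of the chain SD, per free parameter),
#'   `temperature`.
#' @export
mcmc_sample <- function(fn, lower, upper, n_iter = 2000, burn_in = 500,
                        proposal_scale = 0.1, temperature = NULL,
                        start = NULL, seed = 1) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    abort("bounds must be finite.")
  nm <- names(lower) %||% paste0("p", seq_along(lower))
  free <- which(upper > lower)
  if (length(free) == 0) abort("all parameters fixed.")
  width <- upper - lower

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  x <- start %||% ((lower + upper) / 2)
  j <- fn(x)
  if (!is.finite(j)) abort("objective non-finite at the starting point.")
  if (is.null(temperature)) temperature <- max(j / 10, 1e-12)

  reflect <- function(v, lo, hi) {
    # fold proposals back into the box
    rng <- hi - lo
    v <- (v - lo) %% (2 * rng)
    ifelse(v > rng, 2 * rng - v, v) + lo
  }

  total <- burn_in + n_iter
  draws <- matrix(NA_real_, n_iter, length(lower))
  js <- numeric(n_iter)
  acc <- 0L
  for (it in seq_len(total)) {
    prop <- x
    step <- rnorm(length(free), 0, proposal_scale * width[free])
    prop[free] <- reflect(x[free] + step, lower[free], upper[free])
    jp <- fn(prop)
    if (is.finite(jp) && runif(1) < exp(-(jp - j) / temperature)) {
      x <- prop; j <- jp
      acc <- acc + 1L
    }
    if (it > burn_in) {
      draws[it - burn_in, ] <- x
      js[it - burn_in] <- j
    }
  }
  rate <- acc / total
  if (rate < 0.05 || rate > 0.7)
    warn(paste0("MCMC acceptance rate ", signif(rate, 3),
                " outside [0.05, 0.7]; adjust `proposal_scale` or ",
                "`temperature`."))

  half <- n_iter %/% 2
  diag <- vapply(free, function(k) {
    v <- draws[, k]
    s <- sd(v)
    if (s == 0) return(0)
    abs(mean(v[seq_len(half)]) - mean(v[(half + 1):n_iter])) / s
  }, numeric(1))

  out <- tibble::as_tibble(as.data.frame(draws))
  names(out) <- nm
  out$j <- js
  structure(list(draws = out, acceptance_rate = rate,
                 converged_diag = stats::setNames(diag, nm[free]),
                 temperature = temperature, seed = seed),
            class = "mcmc_fit")
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat("<mcmc_fit> ", nrow(x$draws), " draws, acceptance rate ",
      signif(x$acceptance_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Uniformly sample the COFI confidence region
#'
#' The search archive of a global optimizer over-represents the
#' neighbourhood of the incumbent optimum, so percentile intervals taken
#' from archived sets alone can understate parameter uncertainty. This
#' sampler explores the region `{theta : J(theta) < j_critical}` with a
#' random-walk Metropolis chain whose target is uniform over the region
#' (proposals are accepted iff their objective stays below the threshold),
#' giving region-representative draws to pool with the archive.
#'
#' @param fn objective function of the full parameter vector.
#' @param lower,upper box bounds (equal entries held fixed).
#' @param j_critical COFI threshold.
#' @param start a parameter vector inside the region (e.g. the best fit).
#' @param n_iter chain length.
#' @param proposal_scale Gaussian proposal SD as a fraction of box width.
#' @param seed integer seed.
#' @return tibble of accepted parameter vectors with their `j` values (one
#'   row per iteration; rejected proposals repeat the current state, as
#'   usual for Metropolis chains).
#' @export
cofi_region_sample <- function(fn, lower, upper, j_critical, start,
                               n_iter = 1000, proposal_scale = 0.05,
                               seed = 1) {
  nm <- names(lower) %||% paste0("p", seq_along(lower))
  free <- which(upper > lower)
  if (length(free) == 0) abort("all parameters fixed.")
  width <- upper - lower
  j0 <- fn(start)
  if (!(j0 < j_critical))
    abort("`start` must lie inside the confidence region.")

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  x <- start
  j <- j0
  out <- matrix(NA_real_, n_iter, length(lower))
  js <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    prop <- x
    step <- rnorm(length(free), 0, proposal_scale * width[free])
    v <- x[free] + step
    rng <- width[free]
    v <- (v - lower[free]) %% (2 * rng)
    prop[free] <- ifelse(v > rng, 2 * rng - v, v) + lower[free]
    jp <- fn(prop)
    if (is.finite(jp) && jp < j_critical) {
      x <- prop; j <- jp
    }
    out[it, ] <- x
    js[it] <- j
  }
  res <- tibble::as_tibble(as.data.frame(out))
  names(res) <- nm
  res$j <- js
  res
}
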