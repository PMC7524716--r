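#' Control settings for the SCE-UA optimizer
#'
#' @param n_complexes number of complexes (>= 1).
#' @param points_per_complex points per complex; default `2 p + 1`.
#' @param simplex_size points per evolved sub-simplex; default `p + 1`.
#' @param evolutions_per_shuffle competitive-evolution steps each complex
#'   takes between shuffles; default `points_per_complex`.
#' @param max_evals total objective-evaluation budget.
#' @param rel_tol stop when the best objective improves by less than this
#'   relative amount over `stall_shuffles` consecutive shuffles.
#' @param stall_shuffles see `rel_tol`.
#' @return list of class `sce_control`.
#' @export
sce_control <- function(n_complexes = 4, points_per_complex = NULL,
                        simplex_size = NULL, evolutions_per_shuffle = NULL,
                        max_evals = 3000, rel_tol = 1e-6,
                        stall_shuffles = 5) {
  structure(list(n_complexes = n_complexes,
                 points_per_complex = points_per_complex,
                 simplex_size = simplex_size,
                 evolutions_per_shuffle = evolutions_per_shuffle,
                 max_evals = max_evals, rel_tol = rel_tol,
                 stall_shuffles = stall_shuffles),
            class = "sce_control")
}

#' Shuffled Complex Evolution (SCE-UA) global optimization
#'
#' Minimizes an objective over a box by competitive evolution of complexes
#' of points (simplex reflection / contraction / random replacement within
#' each complex) with periodic shuffling of the complexes. Every objective
#' evaluation is archived, which is what the COFI uncertainty filtering
#' consumes afterwards. Fully seeded and reproducible.
#'
#' @param fn objective function taking a numeric parameter vector, returning
#'   a finite scalar to minimize.
#' @param lower,upper numeric bounds; entries with `lower == upper` are held
#'   fixed and not searched.
#' @param control an [sce_control()] list.
#' @param seed integer seed.
#' @return object of class `sce_fit`: `best_par`, `j_min`, `j_components`
#'   (attribute of the best evaluation when `fn` attaches one), `archive`
#'   (tibble: one row per evaluation, parameter columns + `j` + `eval`),
#'   `n_evals`, `converged`.
#' @examples
#' sph <- function(x) sum(x^2)
#' fit <- sce_optimize(sph, rep(-5, 2), rep(5, 2),
#'                     control = sce_control(max_evals = 500), seed = 1)
#' fit$j_min
#' @export
sce_optimize <- function(fn, lower, upper, control = sce_control(),
                         seed = 1) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    abort("bounds must be finite.")
  if (any(lower > upper)) abort("`lower` must be <= `upper`.")
  nm <- names(lower)
  if (is.null(nm)) nm <- paste0("p", seq_along(lower))

  free <- which(upper > lower)
  p <- length(free)
  if (p == 0) abort("all parameters fixed; nothing to optimize.")
  lo <- lower[free]; hi <- upper[free]

  full_par <- function(x) {
    out <- lower
    out[free] <- x
    out
  }

  ngs <- control$n_complexes
  npg <- control$points_per_complex %||% (2 * p + 1)
  nps <- control$simplex_size %||% (p + 1)
  nspl <- control$evolutions_per_shuffle %||% npg
  npt <- ngs * npg

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  arch_par <- matrix(NA_real_, 0, length(lower))
  arch_j <- numeric(0)
  n_evals <- 0L
  evalfn <- function(x) {
    fp <- full_par(x)
    j <- fn(fp)
    if (!is.finite(j)) abort("objective returned a non-finite value.")
    arch_par <<- rbind(arch_par, fp)
    arch_j <<- c(arch_j, j)
    n_evals <<- n_evals + 1L
    j
  }

  # initial sample: uniform over the box
  pop <- matrix(runif(npt * p, rep(lo, each = npt), rep(hi, each = npt)),
                npt, p)
  jval <- apply(pop, 1, evalfn)

  best_hist <- min(jval)
  converged <- FALSE
  tri_prob <- (2 * (npg + 1 - seq_len(npg))) / (npg * (npg + 1))

  while (n_evals < control$max_evals) {
    ord <- order(jval)
    pop <- pop[ord, , drop = FALSE]
    jval <- jval[ord]
    for (g in seq_len(ngs)) {
      cx_idx <- seq(g, npt, by = ngs)
      cx <- pop[cx_idx, , drop = FALSE]
      cj <- jval[cx_idx]
      for (l in seq_len(nspl)) {
        if (n_evals >= control$max_evals) break
        ord_c <- order(cj)
        cx <- cx[ord_c, , drop = FALSE]
        cj <- cj[ord_c]
        sel <- sort(sample.int(npg, nps, prob = tri_prob))
        sx <- cx[sel, , drop = FALSE]
        sj <- cj[sel]
        worst <- which.max(sj)
        centroid <- colMeans(sx[-worst, , drop = FALSE])
        refl <- 2 * centroid - sx[worst, ]
        if (any(refl < lo) || any(refl > hi))
          refl <- runif(p, lo, hi)
        jr <- evalfn(refl)
        if (jr < sj[worst]) {
          sx[worst, ] <- refl; sj[worst] <- jr
        } else if (n_evals < control$max_evals) {
          contr <- (centroid + sx[worst, ]) / 2
          jc <- evalfn(contr)
          if (jc < sj[worst]) {
            sx[worst, ] <- contr; sj[worst] <- jc
          } else if (n_evals < control$max_evals) {
            rnd <- runif(p, lo, hi)
            jn <- evalfn(rnd)
            sx[worst, ] <- rnd; sj[worst] <- jn
          }
        }
        cx[sel, ] <- sx
        cj[sel] <- sj
      }
      pop[cx_idx, ] <- cx
      jval[cx_idx] <- cj
    }
    best_hist <- c(best_hist, min(jval))
    h <- length(best_hist)
    if (h > control$stall_shuffles) {
      prev <- best_hist[h - control$stall_shuffles]
      if ((prev - best_hist[h]) <= control$rel_tol * max(abs(prev), 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }

  ibest <- which.min(arch_j)
  archive <- tibble::as_tibble(as.data.frame(arch_par))
  names(archive) <- nm
  archive$j <- arch_j
  archive$eval <- seq_along(arch_j)

  structure(list(
    best_par = stats::setNames(as.numeric(arch_par[ibest, ]), nm),
    j_min = arch_j[ibest],
    archive = archive,
    n_evals = n_evals,
    converged = converged,
    seed = seed,
    control = control,
    lower = stats::setNames(as.numeric(lower), nm),
    upper = stats::setNames(as.numeric(upper), nm)
  ), class = "sce_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sce_fit <- function(x, ...) {
  cat("<sce_fit> ", x$n_evals, " evaluations, J_min = ",
      signif(x$j_min, 5), if (x$converged) " (converged)" else "", "\n",
      sep = "")
  invisible(x)
}
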