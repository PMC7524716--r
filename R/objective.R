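#' Expected warming enzyme concentrations from gene ratios
#'
#' Under warming, the gene-informed calibration compares simulated annual
#' enzyme pools against an "expected" series: the simulated annual enzyme
#' concentrations under control multiplied, year by year, by the
#' warming-to-control ratio of the detected gene abundances.
#'
#' @param control_sim_enz annual mean simulated enzyme concentrations under
#'   control (numeric, one value per year).
#' @param gene_ratio_w_to_c warming/control gene-abundance ratio per year
#'   (> 0, same length).
#' @return numeric annual series, elementwise product.
#' @examples
#' expected_warming_enzymes(c(1, 2), c(1, 2))  # c(1, 4)
#' @export
expected_warming_enzymes <- function(control_sim_enz, gene_ratio_w_to_c) {
  if (length(control_sim_enz) != length(gene_ratio_w_to_c))
    abort("year coverage of the two series must match.")
  if (any(gene_ratio_w_to_c <= 0)) abort("gene ratios must be > 0.")
  control_sim_enz * gene_ratio_w_to_c
}

#' Specify a weighted multi-objective calibration target
#'
#' Three calibration modes are supported. `"tMEND"` uses respiration and
#' microbial biomass only (components `1 - R2(Rh)` and `MARE(MBC)`, default
#' weights 5/6 and 1/6). `"gMEND"` adds two functional-gene components with
#' weights 5/8, 1/8, 1/8, 1/8: under control these are `1 - r` between
#' simulated annual enzyme pools and annual gene-abundance indices; under
#' warming they are `MARE` against the expected enzyme series of
#' [expected_warming_enzymes()]. `"TECO"` uses the respiration component
#' only.
#'
#' @param mode `"tMEND"`, `"gMEND"` or `"TECO"`.
#' @param treatment `"control"` or `"warming"` (selects the gene-component
#'   metric for gMEND).
#' @param weights optional weight vector; must sum to 1 with entries in
#'   \[0, 1\]. Defaults depend on `mode` as described above.
#' @return a list of class `objective_spec`.
#' @export
objective_spec <- function(mode = c("gMEND", "tMEND", "TECO"),
                           treatment = c("control", "warming"),
                           weights = NULL) {
  mode <- match.arg(mode)
  treatment <- match.arg(treatment)
  m <- switch(mode, gMEND = 4L, tMEND = 2L, TECO = 1L)
  if (is.null(weights))
    weights <- switch(mode,
                      gMEND = c(5, 1, 1, 1) / 8,
                      tMEND = c(5, 1) / 6,
                      TECO = 1)
  if (length(weights) != m)
    abort(paste0("mode '", mode, "' needs ", m, " weights."))
  check_weights(weights)
  structure(list(mode = mode, treatment = treatment, weights = weights),
            class = "objective_spec")
}

check_weights <- function(w) {
  if (any(w < 0 | w > 1) || abs(sum(w) - 1) > 1e-10)
    abort("weights must lie in [0, 1] and sum to 1.")
  invisible(w)
}

#' Objective components for one simulation against an observation set
#'
#' Computes the per-variable objective values J_i: `1 - R2` for
#' heterotrophic respiration (matched by date, in g C m-2 d-1), `MARE` for
#' microbial biomass carbon, and for gMEND the gene components described in
#' [objective_spec()]. Annual enzyme means are matched to the years present
#' in both the simulation and the gene table.
#'
#' @param sim a `mend_sim` or `teco_sim` object.
#' @param obs an observation set (see [gen_observations()]): list with
#'   `rh_obs`, `mbc_obs` tibbles and a `genes` tibble (`year`, `gene_ox`,
#'   `gene_hyd`).
#' @param spec an [objective_spec()].
#' @param control_enzymes for warming-mode gMEND: the control simulation's
#'   `annual_enzymes` tibble (simulated under the control calibration).
#' @param control_genes for warming-mode gMEND: the control gene table used
#'   to form warming-to-control ratios.
#' @return named numeric vector of objective components (`rh`, `mbc`,
#'   `enz_ox`, `enz_hyd` as applicable).
#' @export
objective_components <- function(sim, obs, spec, control_enzymes = NULL,
                                 control_genes = NULL) {
  stopifnot(inherits(spec, "objective_spec"))
  daily <- sim$daily
  idx <- match(obs$rh_obs$date, daily$date)
  if (any(is.na(idx)))
    abort("simulation does not cover all Rh observation dates.")
  j <- c(rh = 1 - r_squared(obs$rh_obs$value, daily$rh_area[idx]))

  if (spec$mode %in% c("tMEND", "gMEND")) {
    if (is.null(obs$mbc_obs) || nrow(obs$mbc_obs) == 0)
      abort("MBC observations required for MEND objectives.")
    mi <- match(obs$mbc_obs$date, daily$date)
    if (any(is.na(mi)))
      abort("simulation does not cover all MBC observation dates.")
    j <- c(j, mbc = mare(obs$mbc_obs$value, daily$mbc[mi]))
  }

  if (spec$mode == "gMEND") {
    if (is.null(obs$genes)) abort("gene table required for gMEND.")
    ann <- sim$annual_enzymes
    years <- intersect(ann$year, obs$genes$year)
    if (length(years) < 2) abort("need >= 2 overlapping years of gene data.")
    ann <- ann[match(years, ann$year), ]
    gen <- obs$genes[match(years, obs$genes$year), ]
    if (spec$treatment == "control") {
      j <- c(j,
             enz_ox = 1 - pearson_r(gen$gene_ox, ann$enz_ox),
             enz_hyd = 1 - pearson_r(gen$gene_hyd, ann$enz_hyd))
    } else {
      if (is.null(control_enzymes) || is.null(control_genes))
        abort("warming gMEND needs `control_enzymes` and `control_genes`.")
      ce <- control_enzymes[match(years, control_enzymes$year), ]
      cg <- control_genes[match(years, control_genes$year), ]
      if (any(is.na(ce$year)) || any(is.na(cg$year)))
        abort("control enzyme/gene tables must cover the gene years.")
      exp_ox <- expected_warming_enzymes(ce$enz_ox, gen$gene_ox / cg$gene_ox)
      exp_hyd <- expected_warming_enzymes(ce$enz_hyd, gen$gene_hyd / cg$gene_hyd)
      j <- c(j,
             enz_ox = mare(exp_ox, ann$enz_ox),
             enz_hyd = mare(exp_hyd, ann$enz_hyd))
    }
  }
  j
}

#' Weighted overall objective
#'
#' `J = sum(w_i J_i)` with weights in \[0, 1\] summing to 1.
#'
#' @param j_components numeric vector of objective components.
#' @param weights matching weight vector.
#' @return single numeric J.
#' @examples
#' overall_objective(c(0.4, 0.8, 0.8, 0.8), c(5, 1, 1, 1) / 8)  # 0.55
#' @export
overall_objective <- function(j_components, weights) {
  if (length(j_components) != length(weights))
    abort("components and weights must have equal length.")
  check_weights(weights)
  sum(weights * j_components)
}
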