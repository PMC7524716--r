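#' Read and write the package's CSV dialects
#'
#' Forcing tables have one row per day with columns `treatment`,
#' `day_index`, `date` (ISO), `soil_temp`, `moisture`, `ph`, `c_input`.
#' Observation files have one row per dated observation (`date`, `value`)
#' and gene tables one row per year (`year`, `gene_ox`, `gene_hyd`).
#' Readers validate types and invariants and report offending rows;
#' `read_forcing()` additionally checks per-treatment date contiguity.
#'
#' @param forcing,path,file table / file path arguments.
#' @return readers return validated tibbles; writers return the path,
#'   invisibly.
#' @export
write_forcing <- function(forcing, path) {
  validate_forcing(forcing)
  readr::write_csv(forcing, path)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    treatment = readr::col_character(),
    day_index = readr::col_integer(),
    date = readr::col_date(),
    soil_temp = readr::col_double(),
    moisture = readr::col_double(),
    ph = readr::col_double(),
    c_input = readr::col_double()
  ))
  prob <- readr::problems(out)
  if (nrow(prob) > 0)
    abort(paste0("malformed forcing rows (first at line ", prob$row[1],
                 "): ", prob$expected[1]))
  validate_forcing(out)
  out
}

#' @rdname write_forcing
#' @param obs tibble with `date` and `value` columns.
#' @export
write_observation_table <- function(obs, path) {
  readr::write_csv(obs, path)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_observation_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), value = readr::col_double()))
  prob <- readr::problems(out)
  if (nrow(prob) > 0)
    abort(paste0("malformed observation rows (first at line ", prob$row[1],
                 ")."))
  if (any(!is.finite(out$value)))
    abort("observation values must be finite numbers.")
  out
}

#' @rdname write_forcing
#' @param genes tibble with `year`, `gene_ox`, `gene_hyd`.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_csv(genes, path)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_gene_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    gene_ox = readr::col_double(),
    gene_hyd = readr::col_double()))
  prob <- readr::problems(out)
  if (nrow(prob) > 0)
    abort(paste0("malformed gene-table rows (first at line ", prob$row[1],
                 ")."))
  dup <- out$year[duplicated(out$year)]
  if (length(dup) > 0)
    abort(paste0("duplicate year(s) in gene table: ", toString(unique(dup))))
  out
}

#' Write an observation set to a directory
#'
#' Writes `rh_obs.csv`, `mbc_obs.csv` and `genes.csv` plus a `meta.yml`
#' sidecar recording treatment and seed.
#'
#' @param obs an `observation_set`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_observations <- function(obs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_observation_table(obs$rh_obs, file.path(dir, "rh_obs.csv"))
  write_observation_table(obs$mbc_obs, file.path(dir, "mbc_obs.csv"))
  write_gene_table(obs$genes, file.path(dir, "genes.csv"))
  yaml::write_yaml(list(treatment = obs$treatment, seed = obs$seed),
                   file.path(dir, "meta.yml"))
  invisible(dir)
}

#' @rdname write_observations
#' @param dir directory written by `write_observations()`.
#' @export
read_observations <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yml"))
  obs <- structure(list(
    rh_obs = read_observation_table(file.path(dir, "rh_obs.csv")),
    mbc_obs = read_observation_table(file.path(dir, "mbc_obs.csv")),
    genes = read_gene_table(file.path(dir, "genes.csv")),
    treatment = meta$treatment,
    truth = NULL,
    seed = meta$seed
  ), class = "observation_set")
  validate_observations(obs)
  obs
}
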