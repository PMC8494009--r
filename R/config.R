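#' Reference run configuration per kinetics model
#'
#' The standard simulation and detection parameters associated with each
#' kinetics model: grid spacing `dx` and Euler step `dt`, diffusion
#' coefficient `P11`, phase thresholds `V_star` / `R_star`, the LAT frame
#' interval `dt_lat`, the conduction-block threshold `dt_c` (of order
#' `dx / c`), the arrival-phase defect threshold `dphi_arr_crit`, the
#' arrival-phase time constant `tau`, and the activation-phase defect
#' threshold `dphi_crit` (2.22 rad). Times are ms except for the
#' dimensionless AP model.
#'
#' @param model `"ap"`, `"fk"` or `"bocf"`.
#' @param dim 2 or 3 (selects the 2D/3D grid spacing and FK parameter set).
#' @return Named list of parameters (a run configuration).
#' @export
default_config <- function(model = c("ap", "fk", "bocf"), dim = 2) {
  model <- match.arg(tolower(model), c("ap", "fk", "bocf"))
  base <- switch(model,
    ap = list(model = "ap", set = "standard", P11 = 1, dx = 0.5, dt = 0.0029,
              V_star = 0.5, R_star = 1, dt_lat = 1, dt_c = 10,
              dphi_arr_crit = 0.7, tau = 20),
    fk = if (dim >= 3)
      list(model = "fk", set = "MBR", P11 = 0.1, dx = 0.31, dt = 0.1,
           V_star = 0.5, R_star = 0.8, dt_lat = 1.6, dt_c = 16,
           dphi_arr_crit = 2, tau = 70)
    else
      list(model = "fk", set = "MLR-I", P11 = 0.1, dx = 0.262, dt = 0.16,
           V_star = 0.5, R_star = 0.8, dt_lat = 1.6, dt_c = 16,
           dphi_arr_crit = 2, tau = 70),
    bocf = list(model = "bocf", set = "EPI", P11 = 0.11,
                dx = if (dim >= 3) 0.5 else 0.25, dt = 0.1,
                V_star = 0.5, R_star = 0.2, dt_lat = 5, dt_c = 45,
                dphi_arr_crit = 0.5, tau = 300)
  )
  base$dphi_crit <- 2.22
  base$ps_method <- "ring2x2_4x4"
  base$dim <- dim
  base
}

#' Read / write a run configuration
#'
#' Run configurations are stored as YAML key-value files; the load-save-load
#' round trip is idempotent.
#'
#' @param config Named list (e.g. from [default_config()]).
#' @param path File path.
#' @return `read_config()` returns the named list; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
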