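#' Cardiac reaction kinetics
#'
#' Constructors for the three excitable-media kinetics used by the monodomain
#' simulator: the two-variable Aliev-Panfilov (AP) model, the three-variable
#' Fenton-Karma (FK) model and the four-variable Bueno-Orovio-Cherry-Fenton
#' (BOCF) minimal ventricular model. Each constructor returns a `pd_kinetics`
#' object holding the resting state, the vectorised reaction function
#' \eqn{F(u)}, the diffusion coefficient of the first (voltage-like) state
#' variable, and the observable transforms used for phase analysis:
#' `V` is always the first state variable and `R` is a recovery observable
#' (the gate `v` for AP, `1 - v` for FK and BOCF).
#'
#' Only the first state variable diffuses; the diffusion matrix is
#' `diag(P11, 0, ..., 0)`.
#'
#' @param set For `kinetics_fk()`, which published parameter set to use:
#'   `"MLR-I"` (modified Luo-Rudy I, linear-core rotors, used in 2D) or
#'   `"MBR"` (modified Beeler-Reuter, used in 3D slabs).
#' @return An object of class `pd_kinetics`: a list with elements `name`,
#'   `set`, `m` (number of state variables), `rest_state`, `reaction`
#'   (maps a list of `m` arrays to the list of their time derivatives),
#'   `P11`, `v_star`, `r_star`, `r_obs` (function of the state list giving
#'   the R observable), `time_unit` and the full parameter list `params`.
#'
#' @details Default simulation parameters associated with each kinetics
#' (grid spacing, time step, LAT frame interval, detection thresholds) are
#' available from [default_config()].
#'
#' @examples
#' kin <- kinetics_ap()
#' # resting state is a fixed point of the reaction
#' d <- kin$reaction(as.list(kin$rest_state))
#' stopifnot(all(abs(unlist(d)) < 1e-12))
#' @name kinetics
NULL

new_kinetics <- function(name, set, rest_state, reaction, P11,
                         v_star, r_star, r_obs, time_unit, params) {
  structure(list(
    name = name, set = set, m = length(rest_state),
    rest_state = rest_state, reaction = reaction, P11 = P11,
    v_star = v_star, r_star = r_star, r_obs = r_obs,
    time_unit = time_unit, params = params
  ), class = "pd_kinetics")
}

#' @export
format.pd_kinetics <- function(x, ...) {
  sprintf("<pd_kinetics %s (%s), m = %d, P11 = %g [%s]>",
          x$name, x$set, x$m, x$P11, x$time_unit)
}

#' @export
print.pd_kinetics <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname kinetics
#' @export
kinetics_ap <- function() {
  p <- list(k = 8, a = 0.15, eps0 = 0.002, mu1 = 0.2, mu2 = 0.3)
  reaction <- function(s) {
    u <- s[[1]]; v <- s[[2]]
    du <- p$k * u * (u - p$a) * (1 - u) - u * v
    eps <- p$eps0 + p$mu1 * v / (u + p$mu2)
    dv <- eps * (-v - p$k * u * (u - p$a - 1))
    list(du, dv)
  }
  new_kinetics("AP", "standard", c(u = 0, v = 0), reaction, P11 = 1,
               v_star = 0.5, r_star = 1,
               r_obs = function(s) s[[2]],
               time_unit = "a.u.", params = p)
}

fk_param_sets <- list(
  # Fenton & Karma (1998), three-current model parameter sets.
  # tau_d = Cm / g_fi with Cm = 1 uF/cm^2.
  "MLR-I" = list(tau_d = 1 / 5.8, tau_r = 130, tau_si = 127, tau_0 = 12.5,
                 tau_vp = 10, tau_vm1 = 18.2, tau_vm2 = 18.2,
                 tau_wp = 1020, tau_wm = 80,
                 u_c = 0.13, u_v = 0, u_csi = 0.85, k = 10),
  "MBR"   = list(tau_d = 0.25, tau_r = 50, tau_si = 44.84, tau_0 = 8.3,
                 tau_vp = 3.33, tau_vm1 = 1000, tau_vm2 = 19.2,
                 tau_wp = 667, tau_wm = 11,
                 u_c = 0.13, u_v = 0.055, u_csi = 0.85, k = 10)
)

#' @rdname kinetics
#' @export
kinetics_fk <- function(set = c("MLR-I", "MBR")) {
  set <- match.arg(set)
  p <- fk_param_sets[[set]]
  reaction <- function(s) {
    u <- s[[1]]; v <- s[[2]]; w <- s[[3]]
    pg <- (u >= p$u_c) * 1       # fast-gate Heaviside
    qg <- (u >= p$u_v) * 1
    tau_vm <- qg * p$tau_vm1 + (1 - qg) * p$tau_vm2
    J_fi <- -v * pg * (1 - u) * (u - p$u_c) / p$tau_d
    J_so <- u * (1 - pg) / p$tau_0 + pg / p$tau_r
    J_si <- -w * (1 + tanh(p$k * (u - p$u_csi))) / (2 * p$tau_si)
    du <- -(J_fi + J_so + J_si)
    dv <- (1 - pg) * (1 - v) / tau_vm - pg * v / p$tau_vp
    dw <- (1 - pg) * (1 - w) / p$tau_wm - pg * w / p$tau_wp
    list(du, dv, dw)
  }
  new_kinetics("FK", set, c(u = 0, v = 1, w = 1), reaction, P11 = 0.1,
               v_star = 0.5, r_star = 0.8,
               r_obs = function(s) 1 - s[[2]],
               time_unit = "ms", params = p)
}

bocf_epi <- list(
  # Bueno-Orovio, Cherry & Fenton (2008), epicardial (EPI) parameter set.
  u_o = 0, u_u = 1.55, theta_v = 0.3, theta_w = 0.13,
  theta_vm = 0.006, theta_o = 0.006,
  tau_v1m = 60, tau_v2m = 1150, tau_vp = 1.4506,
  tau_w1m = 60, tau_w2m = 15, k_wm = 65, u_wm = 0.03, tau_wp = 200,
  tau_fi = 0.11, tau_o1 = 400, tau_o2 = 6,
  tau_so1 = 30.0181, tau_so2 = 0.9957, k_so = 2.0458, u_so = 0.65,
  tau_s1 = 2.7342, tau_s2 = 16, k_s = 2.0994, u_s = 0.9087,
  tau_si = 1.8875, tau_winf = 0.07, w_infstar = 0.94
)

#' @rdname kinetics
#' @export
kinetics_bocf <- function() {
  p <- bocf_epi
  # s at rest relaxes to its steady state at u = 0; use it exactly so the
  # resting state is a true fixed point.
  s_rest <- (1 + tanh(p$k_s * (0 - p$u_s))) / 2
  reaction <- function(s) {
    u <- s[[1]]; v <- s[[2]]; w <- s[[3]]; sg <- s[[4]]
    H_v  <- (u >= p$theta_v) * 1
    H_w  <- (u >= p$theta_w) * 1
    H_vm <- (u >= p$theta_vm) * 1
    H_o  <- (u >= p$theta_o) * 1
    tau_vm <- (1 - H_vm) * p$tau_v1m + H_vm * p$tau_v2m
    tau_wm <- p$tau_w1m +
      (p$tau_w2m - p$tau_w1m) * (1 + tanh(p$k_wm * (u - p$u_wm))) / 2
    tau_so <- p$tau_so1 +
      (p$tau_so2 - p$tau_so1) * (1 + tanh(p$k_so * (u - p$u_so))) / 2
    tau_s <- (1 - H_w) * p$tau_s1 + H_w * p$tau_s2
    tau_o <- (1 - H_o) * p$tau_o1 + H_o * p$tau_o2
    v_inf <- (u < p$theta_vm) * 1
    w_inf <- (1 - H_o) * (1 - u / p$tau_winf) + H_o * p$w_infstar
    J_fi <- -v * H_v * (u - p$theta_v) * (p$u_u - u) / p$tau_fi
    J_so <- (u - p$u_o) * (1 - H_w) / tau_o + H_w / tau_so
    J_si <- -H_w * w * sg / p$tau_si
    du <- -(J_fi + J_so + J_si)
    dv <- (1 - H_v) * (v_inf - v) / tau_vm - H_v * v / p$tau_vp
    dw <- (1 - H_w) * (w_inf - w) / tau_wm - H_w * w / p$tau_wp
    ds <- ((1 + tanh(p$k_s * (u - p$u_s))) / 2 - sg) / tau_s
    list(du, dv, dw, ds)
  }
  new_kinetics("BOCF", "EPI", c(u = 0, v = 1, w = 1, s = s_rest), reaction,
               P11 = 0.11, v_star = 0.5, r_star = 0.2,
               r_obs = function(s) 1 - s[[2]],
               time_unit = "ms", params = p)
}

#' Look up a kinetics constructor by model name
#'
#' @param model One of `"ap"`, `"fk"`, `"bocf"` (case-insensitive).
#' @param dim Spatial dimensionality; selects the FK parameter set
#'   (`MLR-I` in 2D, `MBR` in 3D) as used in the reference simulations.
#' @return A `pd_kinetics` object.
#' @export
kinetics_by_name <- function(model, dim = 2) {
  switch(tolower(model),
    ap = kinetics_ap(),
    fk = kinetics_fk(if (dim >= 3) "MBR" else "MLR-I"),
    bocf = kinetics_bocf(),
    stop("unknown kinetics model: ", model)
  )
}
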