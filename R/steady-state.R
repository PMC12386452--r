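#' @title Steady-state extraction
#' @description The per-cell-line readout of the model is the steady-state
#'   H2O2 concentration. It can be obtained two ways: by integrating the
#'   ODE until all derivatives vanish (numeric) or by solving the
#'   flux-balance equation for H2O2 after eliminating the couple states at
#'   their own equilibria (analytic). The two must agree; the analytic
#'   route is used in bulk runs because it is orders of magnitude faster.
#' @name steady_state
NULL

steady_result <- function(h2o2_ss, flux_cat, flux_gpx, flux_prdx,
                          converged, t_reached, method) {
  structure(list(h2o2_ss = h2o2_ss, flux_cat = flux_cat,
                 flux_gpx = flux_gpx, flux_prdx = flux_prdx,
                 converged = converged, t_reached = t_reached,
                 method = method),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("<steady_state_result>", if (x$converged) "(converged)" else
      "(NOT converged)", "\n")
  cat(sprintf("  H2O2_ss: %.6g mM  [method: %s]\n", x$h2o2_ss, x$method))
  cat(sprintf("  fluxes (mM/ms): CAT %.4g | GPX/GSH %.4g | PRDX/TXN %.4g\n",
              x$flux_cat, x$flux_gpx, x$flux_prdx))
  if (is.finite(x$t_reached)) cat(sprintf("  t reached: %g ms\n", x$t_reached))
  invisible(x)
}

# Equilibrium reduced-glutathione level at a given H2O2 concentration:
# the linear balance of GPX oxidation against GSR recycling.
gsh_equilibrium <- function(H, k, p) {
  denom <- k$kGPX * p$GPX * H + k$kGSR * p$GSR
  if (denom <= 0) return(p$GSH_total)
  k$kGSR * p$GSR * p$GSH_total / denom
}

# Equilibrium reduced-peroxiredoxin level at a given H2O2 concentration.
# Eliminating thioredoxin from the two couple equilibria gives a quadratic
# in PRDX_red; its smaller root lies in [0, PRDX_total] (the parabola is
# non-negative at 0 and non-positive at PRDX_total).
prdx_equilibrium <- function(H, k, p) {
  if (H <= 0 || k$kPRDX <= 0 || p$PRDX_total <= 0) return(p$PRDX_total)
  rec <- k$kTXNRD * p$TXNRD
  if (rec <= 0 || k$kTXN <= 0 || p$TXN_total <= 0) return(0)
  a <- k$kPRDX * H / rec
  A <- k$kTXN * a
  B <- -(k$kPRDX * H + k$kTXN * (p$TXN_total + a * p$PRDX_total))
  C <- k$kTXN * p$TXN_total * p$PRDX_total
  disc <- B^2 - 4 * A * C
  disc <- max(disc, 0)
  # smaller root in the numerically stable form (B < 0 always)
  2 * C / (-B + sqrt(disc))
}

# Supremum of total removal flux over H (mM/ms). Catalase is first-order
# and unbounded; the two recycling-limited pathways saturate at their
# reductase capacity.
scavenging_capacity <- function(spec) {
  k <- masked_rates(spec)
  p <- spec$pools
  if (k$kCAT * p$CAT > 0) return(Inf)
  cap_gpx <- if (k$kGPX * p$GPX > 0) k$kGSR * p$GSR * p$GSH_total else 0
  cap_prdx <- if (k$kPRDX * p$PRDX_total > 0) {
    rec <- k$kTXNRD * p$TXNRD
    if (k$kTXN * p$TXN_total > 0 && rec > 0)
      k$kTXN * p$PRDX_total * p$TXN_total * rec /
        (rec + k$kTXN * p$PRDX_total)
    else 0
  } else 0
  cap_gpx + cap_prdx
}

# Per-pathway removal fluxes at a state (uses masked rates).
pathway_fluxes <- function(H, GSH, PRDX_red, spec) {
  k <- masked_rates(spec)
  p <- spec$pools
  c(cat = k$kCAT * p$CAT * H,
    gpx = k$kGPX * p$GPX * H * GSH,
    prdx = k$kPRDX * H * PRDX_red)
}

#' Analytic steady state by flux balance
#'
#' At steady state every couple sits at its own equilibrium, which can be
#' expressed in closed form as a function of the H2O2 level `H`. The
#' remaining scalar residual
#' `R(H) = influx - v_CAT(H) - v_GPX(H) - v_PRDX(H)`
#' is strictly decreasing in `H`, so its root is unique; it is bracketed by
#' geometric expansion and solved with [stats::uniroot()].
#'
#' @param spec a [model_spec()].
#' @return A `steady_state_result` with `method = "analytic"`.
#' @export
find_steady_analytic <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  k <- masked_rates(spec)
  p <- spec$pools
  if (spec$h2o2_influx == 0)
    return(steady_result(0, 0, 0, 0, TRUE, NA_real_, "analytic"))

  slope0 <- k$kCAT * p$CAT + k$kGPX * p$GPX * p$GSH_total +
    k$kPRDX * p$PRDX_total
  if (slope0 <= 0)
    stop("no steady state: no active pathway can absorb the influx")
  if (spec$h2o2_influx >= scavenging_capacity(spec))
    stop("no steady state: influx exceeds scavenging capacity")

  residual <- function(H) {
    fl <- pathway_fluxes(H, gsh_equilibrium(H, k, p),
                         prdx_equilibrium(H, k, p), spec)
    spec$h2o2_influx - sum(fl)
  }
  hi <- spec$h2o2_influx / slope0
  it <- 0L
  while (residual(hi) > 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 500L) stop("failed to bracket the steady state")
  }
  H <- stats::uniroot(residual, c(0, hi), tol = hi * 1e-14)$root
  fl <- pathway_fluxes(H, gsh_equilibrium(H, k, p),
                       prdx_equilibrium(H, k, p), spec)
  steady_result(H, fl[["cat"]], fl[["gpx"]], fl[["prdx"]],
                TRUE, NA_real_, "analytic")
}

#' Numeric steady state by integration
#'
#' Integrates from the fully reduced pre-stress state in geometrically
#' growing time chunks and stops once the relative derivative norm
#' `max_i |dX_i/dt| / max(X_i, 1e-12)` drops below `rel_tol` (per ms), or
#' `t_max` is reached (then `converged = FALSE` with the last state
#' retained). An influx at or above the saturable scavenging capacity
#' (possible only with catalase inactive) has no steady state and is an
#' error.
#'
#' @param spec a [model_spec()].
#' @param rel_tol convergence threshold on the relative derivative norm
#'   (1/ms), default 1e-9.
#' @param t_max integration horizon (ms), default 1e6.
#' @param init optional initial [redox_state()].
#' @return A `steady_state_result` with `method = "numeric"`.
#' @export
find_steady_numeric <- function(spec, rel_tol = 1e-9, t_max = 1e6,
                                init = initial_state(spec)) {
  stopifnot(inherits(spec, "model_spec"))
  if (rel_tol <= 0) stop("'rel_tol' must be > 0")
  if (t_max <= 0) stop("'t_max' must be > 0")
  if (spec$h2o2_influx > 0 &&
      spec$h2o2_influx >= scavenging_capacity(spec))
    stop("no steady state: influx exceeds scavenging capacity")

  state <- init
  t_now <- 0
  t_next <- min(100, t_max)
  converged <- FALSE
  repeat {
    d <- derivatives(state, spec)
    crit <- max(abs(d) / pmax(unclass(state), 1e-12))
    if (crit < rel_tol) { converged <- TRUE; break }
    if (t_now >= t_max) break
    traj <- simulate_redox(spec, times = c(0, t_next - t_now),
                           init = state)
    last <- as.numeric(traj[nrow(traj), -1L])
    state <- redox_state(H2O2 = last[1L], GSH = last[2L], GSSG = last[3L],
                         PRDX_red = last[4L], PRDX_ox = last[5L],
                         TXN_red = last[6L], TXN_ox = last[7L])
    t_now <- t_next
    t_next <- min(t_next * 4, t_max)
  }
  fl <- pathway_fluxes(state[["H2O2"]], state[["GSH"]],
                       state[["PRDX_red"]], spec)
  steady_result(state[["H2O2"]], fl[["cat"]], fl[["gpx"]], fl[["prdx"]],
                converged, t_now, "numeric")
}
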