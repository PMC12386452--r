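#' Full redox state at one time point
#'
#' Concentrations (mM) of hydrogen peroxide and the three redox couples.
#' Each couple (glutathione, peroxiredoxin, thioredoxin) is conserved:
#' reduced + oxidized equals the corresponding total in the pools.
#'
#' @param H2O2 hydrogen peroxide (mM).
#' @param GSH,GSSG reduced and oxidized glutathione (mM).
#' @param PRDX_red,PRDX_ox reduced and oxidized peroxiredoxin (mM).
#' @param TXN_red,TXN_ox reduced and oxidized thioredoxin (mM).
#' @return An object of class `redox_state` (named numeric vector).
#' @export
redox_state <- function(H2O2 = 0, GSH = 3.0, GSSG = 0,
                        PRDX_red = 0.15, PRDX_ox = 0,
                        TXN_red = 0.025, TXN_ox = 0) {
  s <- c(H2O2 = H2O2, GSH = GSH, GSSG = GSSG,
         PRDX_red = PRDX_red, PRDX_ox = PRDX_ox,
         TXN_red = TXN_red, TXN_ox = TXN_ox)
  if (any(!is.finite(s))) stop("redox state contains non-finite values")
  neg <- names(s)[s < 0]
  if (length(neg))
    stop("negative concentration in state field(s): ",
         paste(neg, collapse = ", "))
  structure(s, class = c("redox_state", "numeric"))
}

#' Pre-stress initial condition
#'
#' No peroxide and every couple fully reduced: `H2O2 = 0`,
#' `GSH = GSH_total`, `PRDX_red = PRDX_total`, `TXN_red = TXN_total`,
#' all oxidized forms 0.
#'
#' @param spec a [model_spec()].
#' @return A `redox_state`.
#' @export
initial_state <- function(spec = default_spec()) {
  p <- spec$pools
  redox_state(H2O2 = 0, GSH = p$GSH_total, GSSG = 0,
              PRDX_red = p$PRDX_total, PRDX_ox = 0,
              TXN_red = p$TXN_total, TXN_ox = 0)
}

# Rate constants with inactive pathways' peroxidase constants zeroed.
masked_rates <- function(spec) {
  k <- spec$rates
  if (!spec$mask$cat)      k$kCAT  <- 0
  if (!spec$mask$gpx_gsh)  k$kGPX  <- 0
  if (!spec$mask$prdx_txn) k$kPRDX <- 0
  k
}

#' Time derivatives of the full redox state
#'
#' Mass-action right-hand side of the seven-species network. The peroxide
#' balance is influx minus the three scavenging terms; each couple's
#' reduced and oxidized derivatives are exact negatives, so the couple sums
#' are invariants of the flow. An inactive pathway contributes nothing: its
#' peroxidase rate constant is treated as zero.
#'
#' @param state a [redox_state()] (all fields non-negative).
#' @param spec a [model_spec()].
#' @return Named numeric vector of d/dt values (mM/ms), same fields as the
#'   state.
#' @export
derivatives <- function(state, spec) {
  s <- unclass(state)
  neg <- names(s)[s < 0]
  if (length(neg))
    stop("negative concentration in state field(s): ",
         paste(neg, collapse = ", "))
  k <- masked_rates(spec)
  p <- spec$pools
  v_cat  <- k$kCAT  * s[["H2O2"]] * p$CAT
  v_gpx  <- k$kGPX  * s[["H2O2"]] * s[["GSH"]] * p$GPX
  v_prdx <- k$kPRDX * s[["H2O2"]] * s[["PRDX_red"]]
  v_gsr  <- k$kGSR  * s[["GSSG"]] * p$GSR
  v_txn  <- k$kTXN  * s[["TXN_red"]] * s[["PRDX_ox"]]
  v_txnrd <- k$kTXNRD * s[["TXN_ox"]] * p$TXNRD
  c(H2O2 = spec$h2o2_influx - v_cat - v_gpx - v_prdx,
    GSH = -v_gpx + v_gsr,
    GSSG = v_gpx - v_gsr,
    PRDX_red = -v_prdx + v_txn,
    PRDX_ox = v_prdx - v_txn,
    TXN_red = -v_txn + v_txnrd,
    TXN_ox = v_txn - v_txnrd)
}

# Check reduced+oxidized == total for each couple, 1e-9 relative.
check_conservation <- function(state, pools, tol = 1e-9) {
  sums <- c(GSH = state[["GSH"]] + state[["GSSG"]],
            PRDX = state[["PRDX_red"]] + state[["PRDX_ox"]],
            TXN = state[["TXN_red"]] + state[["TXN_ox"]])
  tot <- c(GSH = pools$GSH_total, PRDX = pools$PRDX_total,
           TXN = pools$TXN_total)
  rel <- abs(sums - tot) / pmax(tot, 1e-300)
  bad <- names(rel)[rel > tol & tot > 0]
  # a zero total with a non-zero sum is also a violation
  bad <- c(bad, names(tot)[tot == 0 & sums != 0])
  if (length(bad))
    stop("initial state violates couple conservation (",
         paste(bad, collapse = ", "), ") beyond ", format(tol), " relative")
  invisible(TRUE)
}

# deSolve RHS on the reduced state (H2O2, GSSG, PRDX_ox, TXN_ox); reduced
# forms recovered from totals so conservation holds by construction.
reduced_rhs <- function(t, y, parms) {
  k <- parms$k; p <- parms$p
  GSH <- p$GSH_total - y[[2L]]
  PRDX_red <- p$PRDX_total - y[[3L]]
  TXN_red <- p$TXN_total - y[[4L]]
  v_cat  <- k$kCAT  * y[[1L]] * p$CAT
  v_gpx  <- k$kGPX  * y[[1L]] * GSH * p$GPX
  v_prdx <- k$kPRDX * y[[1L]] * PRDX_red
  v_gsr  <- k$kGSR  * y[[2L]] * p$GSR
  v_txn  <- k$kTXN  * TXN_red * y[[3L]]
  v_txnrd <- k$kTXNRD * y[[4L]] * p$TXNRD
  list(c(parms$influx - v_cat - v_gpx - v_prdx,
         v_gpx - v_gsr,
         v_prdx - v_txn,
         v_txn - v_txnrd))
}

expand_reduced <- function(y, pools) {
  data.frame(
    H2O2 = y[, 1L], GSH = pools$GSH_total - y[, 2L], GSSG = y[, 2L],
    PRDX_red = pools$PRDX_total - y[, 3L], PRDX_ox = y[, 3L],
    TXN_red = pools$TXN_total - y[, 4L], TXN_ox = y[, 4L])
}

#' Integrate the network over time
#'
#' Solves the stiff mass-action system on `[0, t_end]` with an implicit
#' (lsoda) integrator at relative tolerance 1e-8 and absolute tolerance
#' 1e-12 mM. Only the four free variables (H2O2 and the three oxidized
#' forms) are integrated; reduced forms are recovered from the conserved
#' totals, so the couple sums are exact by construction. Rounding-level
#' negatives (above -1e-12 mM) are clamped to zero on output.
#'
#' @param spec a [model_spec()].
#' @param t_end horizon (ms), > 0.
#' @param init a [redox_state()] consistent with `spec$pools`
#'   (conservation within 1e-9 relative); default [initial_state()].
#' @param n_output number of output samples (>= 2), evenly spaced.
#' @param times optional explicit output times (overrides `n_output`);
#'   must start at 0 and be strictly increasing.
#' @return A `redox_trajectory`: a data.frame with columns `time_ms`,
#'   `H2O2`, `GSH`, `GSSG`, `PRDX_red`, `PRDX_ox`, `TXN_red`, `TXN_ox`.
#' @export
simulate_redox <- function(spec, t_end = 1e6, init = initial_state(spec),
                           n_output = 201L, times = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(times)) {
    if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be > 0")
    if (n_output < 2L) stop("'n_output' must be at least 2")
    times <- seq(0, t_end, length.out = n_output)
  } else {
    if (times[1L] != 0 || any(diff(times) <= 0))
      stop("'times' must start at 0 and be strictly increasing")
  }
  if (any(unclass(init) < 0))
    stop("negative concentration in initial state")
  check_conservation(init, spec$pools)

  y0 <- c(H2O2 = init[["H2O2"]], GSSG = init[["GSSG"]],
          PRDX_ox = init[["PRDX_ox"]], TXN_ox = init[["TXN_ox"]])
  parms <- list(k = masked_rates(spec), p = spec$pools,
                influx = spec$h2o2_influx)
  out <- deSolve::ode(y = y0, times = times, func = reduced_rhs,
                      parms = parms, method = "lsoda",
                      rtol = 1e-8, atol = 1e-12, maxsteps = 50000L)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop(sprintf("integrator failed near t = %g ms (istate = %d)",
                 max(out[, 1L]), istate[1L]))
  if (nrow(out) < length(times))
    stop(sprintf("integrator stopped early at t = %g ms", max(out[, 1L])))

  df <- expand_reduced(out[, -1L, drop = FALSE], spec$pools)
  # clamp integration-noise negatives
  for (j in seq_along(df)) {
    v <- df[[j]]
    v[v < 0 & v > -1e-12] <- 0
    df[[j]] <- v
  }
  traj <- cbind(time_ms = out[, 1L], df)
  rownames(traj) <- NULL
  class(traj) <- c("redox_trajectory", "data.frame")
  traj
}

#' Write a trajectory to CSV
#'
#' Columns `time_ms,H2O2,GSH,GSSG,PRDX_red,PRDX_ox,TXN_red,TXN_ox`,
#' concentrations in mM.
#'
#' @param traj a `redox_trajectory` from [simulate_redox()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
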