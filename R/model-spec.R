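#' Rate constants of the peroxide-neutralization network
#'
#' Second-order mass-action rate constants (units mM^-1 ms^-1, except
#' `kGPX` which multiplies two concentrations and is mM^-2 ms^-1) for the
#' three scavenging pathways and their recycling reactions. Defaults are the
#' literature-derived reference parameterization used for every cell line;
#' only enzyme pools vary between lines.
#'
#' @param kCAT catalase turnover constant (mM^-1 ms^-1).
#' @param kPRDX peroxiredoxin oxidation by H2O2 (mM^-1 ms^-1).
#' @param kTXN reduction of oxidized peroxiredoxin by thioredoxin
#'   (mM^-1 ms^-1).
#' @param kTXNRD re-reduction of oxidized thioredoxin by thioredoxin
#'   reductase (mM^-1 ms^-1).
#' @param kGSR re-reduction of oxidized glutathione by glutathione
#'   reductase (mM^-1 ms^-1).
#' @param kGPX glutathione peroxidase trimolecular constant (mM^-2 ms^-1).
#' @return An object of class `rate_constants` (named list).
#' @export
rate_constants <- function(kCAT = 0.034, kPRDX = 0.26, kTXN = 0.23,
                           kTXNRD = 0.31, kGSR = 0.08, kGPX = 67) {
  k <- list(kCAT = kCAT, kPRDX = kPRDX, kTXN = kTXN,
            kTXNRD = kTXNRD, kGSR = kGSR, kGPX = kGPX)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("rate constant '%s' must be a single finite positive number", nm))
  }
  structure(k, class = "rate_constants")
}

#' Enzyme and redox-couple pools
#'
#' Concentrations (mM) of the catalytic enzymes, held constant during a
#' simulation, and the total sizes of the three redox couples
#' (reduced + oxidized is conserved). Defaults are the reference-line
#' values; expression scaling multiplies the six enzyme-derived entries
#' while the glutathione pool, a metabolite without a transcript, stays
#' fixed.
#'
#' @param CAT,GPX,GSR,TXNRD enzyme concentrations (mM).
#' @param PRDX_total,TXN_total,GSH_total total couple pools (mM).
#' @return An object of class `enzyme_pools` (named list).
#' @export
enzyme_pools <- function(CAT = 0.001, GPX = 0.05, GSR = 0.05, TXNRD = 0.025,
                         PRDX_total = 0.15, TXN_total = 0.025,
                         GSH_total = 3.0) {
  p <- list(CAT = CAT, GPX = GPX, GSR = GSR, TXNRD = TXNRD,
            PRDX_total = PRDX_total, TXN_total = TXN_total,
            GSH_total = GSH_total)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("pool '%s' must be a single finite non-negative number", nm))
  }
  structure(p, class = "enzyme_pools")
}

#' Pathway on/off mask
#'
#' Which of the three neutralization systems are active. Switching a
#' pathway off zeroes its peroxidase rate constant, removing both its
#' H2O2-consumption term and its couple turnover -- the in-silico analogue
#' of a loss-of-function mutation.
#'
#' @param prdx_txn peroxiredoxin/thioredoxin system active?
#' @param cat catalase active?
#' @param gpx_gsh glutathione peroxidase/glutathione system active?
#' @return An object of class `pathway_mask` (named logical list).
#' @export
pathway_mask <- function(prdx_txn = TRUE, cat = TRUE, gpx_gsh = TRUE) {
  m <- list(prdx_txn = prdx_txn, cat = cat, gpx_gsh = gpx_gsh)
  for (nm in names(m))
    if (!is.logical(m[[nm]]) || length(m[[nm]]) != 1L || is.na(m[[nm]]))
      stop(sprintf("mask entry '%s' must be TRUE or FALSE", nm))
  structure(m, class = "pathway_mask")
}

#' Fully parameterized model for one cell line
#'
#' Bundles rate constants, enzyme pools, the pathway mask and the constant
#' H2O2 influx into the object every simulation and steady-state routine
#' consumes.
#'
#' @param rates a [rate_constants()] object.
#' @param pools an [enzyme_pools()] object.
#' @param mask a [pathway_mask()] object.
#' @param h2o2_influx constant H2O2 supply (mM ms^-1), non-negative.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(rates = rate_constants(), pools = enzyme_pools(),
                       mask = pathway_mask(), h2o2_influx = 1e-5) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(pools, "enzyme_pools"),
            inherits(mask, "pathway_mask"))
  if (!is.numeric(h2o2_influx) || length(h2o2_influx) != 1L ||
      !is.finite(h2o2_influx) || h2o2_influx < 0)
    stop("'h2o2_influx' must be a single finite non-negative number")
  structure(list(rates = rates, pools = pools, mask = mask,
                 h2o2_influx = h2o2_influx),
            class = "model_spec")
}

#' Reference parameterization
#'
#' The default model: reference rate constants and pools, all three
#' pathways active, and an influx of 1e-5 mM/ms.
#'
#' @return A `model_spec`.
#' @export
default_spec <- function() model_spec()

#' @export
print.model_spec <- function(x, ...) {
  on <- names(x$mask)[unlist(x$mask)]
  cat("<model_spec>\n")
  cat("  active pathways:", if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  cat("  influx:", format(x$h2o2_influx), "mM/ms\n")
  cat("  rates: ", paste(sprintf("%s=%g", names(x$rates), unlist(x$rates)),
                         collapse = " "), "\n")
  cat("  pools: ", paste(sprintf("%s=%g", names(x$pools), unlist(x$pools)),
                         collapse = " "), "\n")
  invisible(x)
}

# Config keys use the compact symbols of the parameter tables; couple totals
# are keyed by their reduced species (PRDX, TXN, GSH).
.config_keys <- c("kCAT", "kPRDX", "kTXN", "kTXNRD", "kGSR", "kGPX",
                  "CAT", "PRDX", "TXN", "TXNRD", "GSH", "GPX", "GSR",
                  "H2O2_IN")

#' Build a model spec from a flat key-value configuration
#'
#' Accepts the symbols of the parameter tables (`kCAT`, `kPRDX`, `kTXN`,
#' `kTXNRD`, `kGSR`, `kGPX`, `CAT`, `PRDX`, `TXN`, `TXNRD`, `GSH`, `GPX`,
#' `GSR`, `H2O2_IN`); omitted keys take the defaults. `PRDX`, `TXN` and
#' `GSH` set the corresponding couple totals. Unknown keys are an error.
#'
#' @param config named list (e.g. parsed from YAML), or `NULL` for defaults.
#' @param mask optional [pathway_mask()].
#' @return A `model_spec`.
#' @export
spec_from_config <- function(config = NULL, mask = pathway_mask()) {
  config <- config %||% list()
  bad <- setdiff(names(config), .config_keys)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  g <- function(key, default) {
    v <- config[[key]] %||% default
    if (!is.numeric(v) || length(v) != 1L) stop("key '", key, "' must be a number")
    v
  }
  model_spec(
    rates = rate_constants(
      kCAT = g("kCAT", 0.034), kPRDX = g("kPRDX", 0.26),
      kTXN = g("kTXN", 0.23), kTXNRD = g("kTXNRD", 0.31),
      kGSR = g("kGSR", 0.08), kGPX = g("kGPX", 67)),
    pools = enzyme_pools(
      CAT = g("CAT", 0.001), GPX = g("GPX", 0.05), GSR = g("GSR", 0.05),
      TXNRD = g("TXNRD", 0.025), PRDX_total = g("PRDX", 0.15),
      TXN_total = g("TXN", 0.025), GSH_total = g("GSH", 3.0)),
    mask = mask,
    h2o2_influx = g("H2O2_IN", 1e-5))
}

#' Read a YAML parameter configuration
#'
#' @param path YAML file of flat `key: value` pairs (see
#'   [spec_from_config()] for accepted keys).
#' @param mask optional [pathway_mask()].
#' @return A `model_spec`.
#' @export
read_model_config <- function(path, mask = pathway_mask()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  spec_from_config(yaml::read_yaml(path), mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
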