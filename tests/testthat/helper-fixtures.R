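# Shared fixtures: literal equation transcription used as the derivative
# oracle, random spec generator for property tests, and tiny expression
# tables built in code.

# Literal, independently coded right-hand side of the seven balance
# equations (no masking logic shared with the implementation; masks are
# applied by zeroing the peroxidase constants before the call).
literal_rhs <- function(st, k, p, influx) {
  c(H2O2 = influx - k$kCAT * st[["H2O2"]] * p$CAT -
      k$kGPX * st[["H2O2"]] * st[["GSH"]] * p$GPX -
      k$kPRDX * st[["H2O2"]] * st[["PRDX_red"]],
    GSH = -k$kGPX * st[["H2O2"]] * st[["GSH"]] * p$GPX +
      k$kGSR * st[["GSSG"]] * p$GSR,
    GSSG = k$kGPX * st[["H2O2"]] * st[["GSH"]] * p$GPX -
      k$kGSR * st[["GSSG"]] * p$GSR,
    PRDX_red = -k$kPRDX * st[["H2O2"]] * st[["PRDX_red"]] +
      k$kTXN * st[["TXN_red"]] * st[["PRDX_ox"]],
    PRDX_ox = k$kPRDX * st[["H2O2"]] * st[["PRDX_red"]] -
      k$kTXN * st[["TXN_red"]] * st[["PRDX_ox"]],
    TXN_red = -k$kTXN * st[["TXN_red"]] * st[["PRDX_ox"]] +
      k$kTXNRD * st[["TXN_ox"]] * p$TXNRD,
    TXN_ox = k$kTXN * st[["TXN_red"]] * st[["PRDX_ox"]] -
      k$kTXNRD * st[["TXN_ox"]] * p$TXNRD)
}

# Random spec: pools and rates scaled by log-uniform factors in [0.2, 5],
# random mask with >= 1 active pathway, influx safely below the masked
# scavenging capacity.
random_spec <- function() {
  lu <- function(n) exp(runif(n, log(0.2), log(5)))
  f <- lu(6L)
  rates <- rate_constants(kCAT = 0.034 * f[1L], kPRDX = 0.26 * f[2L],
                          kTXN = 0.23 * f[3L], kTXNRD = 0.31 * f[4L],
                          kGSR = 0.08 * f[5L], kGPX = 67 * f[6L])
  g <- lu(7L)
  pools <- enzyme_pools(CAT = 0.001 * g[1L], GPX = 0.05 * g[2L],
                        GSR = 0.05 * g[3L], TXNRD = 0.025 * g[4L],
                        PRDX_total = 0.15 * g[5L],
                        TXN_total = 0.025 * g[6L],
                        GSH_total = 3.0 * g[7L])
  repeat {
    m <- runif(3L) > 0.5
    if (any(m)) break
  }
  mask <- pathway_mask(prdx_txn = m[1L], cat = m[2L], gpx_gsh = m[3L])
  spec <- model_spec(rates, pools, mask, h2o2_influx = 0)
  cap <- redoxsim:::scavenging_capacity(spec)
  influx <- 1e-5 * runif(1L, 0.1, 1)
  if (is.finite(cap)) influx <- min(influx, 0.3 * cap)
  spec$h2o2_influx <- influx
  spec
}

# Random non-negative state respecting the spec's couple totals.
random_state <- function(spec) {
  p <- spec$pools
  fr <- runif(3L)
  redox_state(H2O2 = runif(1L, 0, 0.5),
              GSH = p$GSH_total * fr[1L],
              GSSG = p$GSH_total * (1 - fr[1L]),
              PRDX_red = p$PRDX_total * fr[2L],
              PRDX_ox = p$PRDX_total * (1 - fr[2L]),
              TXN_red = p$TXN_total * fr[3L],
              TXN_ox = p$TXN_total * (1 - fr[3L]))
}

# 3-gene x 2-line toy expression fixture written to a temp file.
write_toy_expression <- function(sep = ",", path = tempfile()) {
  lines <- c(paste("gene", "L1", "L2", sep = sep),
             paste("CAT", "5", "10", sep = sep),
             paste("GPX1", "2", "4", sep = sep),
             paste("GSR", "1", "1", sep = sep))
  writeLines(lines, path)
  path
}

# Full-map expression matrix: reference at `ref`, each other line a
# multiple of it.
full_map_matrix <- function(line_factors = c(A = 2, B = 0.5),
                            ref = "HCT116") {
  genes <- unlist(lapply(default_gene_map(), `[[`, "genes"),
                  use.names = FALSE)
  base <- seq_along(genes) + 10
  vals <- cbind(base, sapply(line_factors, function(f) base * f))
  colnames(vals) <- c(ref, names(line_factors))
  rownames(vals) <- genes
  vals
}
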