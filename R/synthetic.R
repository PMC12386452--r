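#' Configuration for the synthetic expression generator
#'
#' Describes a CCLE-style expression matrix with controlled group
#' structure: per-gene log-normal baselines, multiplicative log-normal
#' line-to-line noise, a designated reference line generated exactly at
#' baseline (the scaling anchor), and an optional multiplicative effect on
#' chosen enzymes' genes in radioresistant (RR) lines.
#'
#' Within each tissue, `round(n_lines_per_tissue * rr_fraction)` lines are
#' labelled RR (deterministically, so group sizes are exact) and the rest
#' RS.
#'
#' @param n_lines_per_tissue lines per tissue (>= 1).
#' @param tissues tissue labels; one synthetic tissue by default.
#' @param gene_map gene map ([default_gene_map()]); its symbols are the
#'   generated genes.
#' @param baseline_log_mean,baseline_log_sd log-scale mean and SD of the
#'   per-gene baseline abundances (drawn once per gene from the seed).
#' @param rr_effect named multiplicative factors (> 0) applied pre-noise
#'   to RR lines' genes, keyed by enzyme (`CAT`, `GPX`, `GSR`, `TXNRD`,
#'   `PRDX`, `TXN`); enzymes not named get 1.
#' @param noise_log_sd log-scale SD of line-to-line noise.
#' @param rr_fraction fraction of lines labelled RR, in `[0, 1]`.
#' @param seed integer; fixes the full output bit-identically.
#' @param include_reference add the reference line `HCT116` at exact
#'   baseline (no noise, no effect)?
#' @param reference_name name of the reference line.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_lines_per_tissue = 40L,
                         tissues = "synthetic",
                         gene_map = default_gene_map(),
                         baseline_log_mean = log(100),
                         baseline_log_sd = 1,
                         rr_effect = NULL,
                         noise_log_sd = 0.2,
                         rr_fraction = 0.5,
                         seed = 1L,
                         include_reference = TRUE,
                         reference_name = "HCT116") {
  validate_gene_map(gene_map)
  genes <- unlist(lapply(gene_map, `[[`, "genes"), use.names = FALSE)
  if (!length(genes)) stop("gene map yields an empty gene list")
  if (anyDuplicated(genes))
    stop("gene map assigns a symbol to more than one enzyme")
  eff <- stats::setNames(rep(1, length(gene_map)), names(gene_map))
  if (!is.null(rr_effect)) {
    bad <- setdiff(names(rr_effect), names(gene_map))
    if (length(bad))
      stop("rr_effect names unknown enzyme(s): ", paste(bad, collapse = ", "))
    eff[names(rr_effect)] <- unlist(rr_effect)
  }
  if (any(eff <= 0)) stop("rr_effect factors must be > 0")
  if (rr_fraction < 0 || rr_fraction > 1)
    stop("'rr_fraction' must be in [0, 1]")
  if (n_lines_per_tissue < 1L) stop("'n_lines_per_tissue' must be >= 1")
  if (noise_log_sd < 0 || baseline_log_sd < 0)
    stop("log-scale SDs must be >= 0")
  structure(list(n_lines_per_tissue = as.integer(n_lines_per_tissue),
                 tissues = tissues, gene_map = gene_map, genes = genes,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 rr_effect = eff, noise_log_sd = noise_log_sd,
                 rr_fraction = rr_fraction, seed = as.integer(seed),
                 include_reference = isTRUE(include_reference),
                 reference_name = reference_name),
            class = "synth_config")
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Generate a synthetic expression table
#'
#' Per line and gene, `abundance = baseline_g * exp(N(0, noise_log_sd)) *
#' rr_effect[enzyme(g)]^(line is RR)`, with per-gene baselines
#' `baseline_g = exp(N(baseline_log_mean, baseline_log_sd))` drawn once
#' from the seed. The reference line sits exactly at baseline. Output is
#' bit-identical for a fixed seed (base R Mersenne-Twister generator).
#'
#' @param config a [synth_config()].
#' @return List: `table` (an [expression_table()] including the reference
#'   line when configured) and `metadata` (data.frame
#'   `line,tissue,label`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- config$genes
  enzyme_of <- rep(names(config$gene_map),
                   vapply(config$gene_map,
                          function(e) length(e$genes), integer(1L)))
  names(enzyme_of) <- genes

  with_local_seed(config$seed, {
    baseline <- exp(stats::rnorm(length(genes), config$baseline_log_mean,
                                 config$baseline_log_sd))
    names(baseline) <- genes

    n <- config$n_lines_per_tissue
    n_rr <- round(n * config$rr_fraction)
    lines <- character(0); tissue <- character(0); label <- character(0)
    for (tis in config$tissues) {
      nm <- sprintf("%s_%02d", tis, seq_len(n))
      lines <- c(lines, nm)
      tissue <- c(tissue, rep(tis, n))
      label <- c(label, c(rep("RR", n_rr), rep("RS", n - n_rr)))
    }
    effect_per_gene <- config$rr_effect[enzyme_of[genes]]
    vals <- matrix(NA_real_, length(genes), length(lines),
                   dimnames = list(genes, lines))
    for (j in seq_along(lines)) {
      noise <- exp(stats::rnorm(length(genes), 0, config$noise_log_sd))
      v <- baseline * noise
      if (label[j] == "RR") v <- v * effect_per_gene
      vals[, j] <- v
    }
    if (config$include_reference) {
      if (config$reference_name %in% lines)
        stop("reference name collides with a generated line")
      vals <- cbind(vals, baseline)
      colnames(vals)[ncol(vals)] <- config$reference_name
      lines <- c(lines, config$reference_name)
      tissue <- c(tissue, "reference")
      label <- c(label, "unknown")
    }
    md <- data.frame(line = lines, tissue = tissue, label = label,
                     stringsAsFactors = FALSE)
    list(table = expression_table(vals,
                                  tissue = stats::setNames(tissue, lines),
                                  label = stats::setNames(label, lines)),
         metadata = md)
  })
}

#' End-to-end effect recovery on synthetic data
#'
#' Runs the full pipeline -- generate, aggregate to enzymes, scale pools
#' against the reference line, solve the knockout grid, compare RR vs RS
#' -- and returns the group comparison for one tissue x condition. With a
#' > 1 multiplicative RR effect on scavenging enzymes the comparison must
#' recover `mean_rr < mean_rs` (better-scavenging lines keep less
#' peroxide).
#'
#' @param config a [synth_config()]; default applies a 2x RR effect on
#'   the GPX and GSR genes.
#' @param condition grid condition to compare, default `"gpx_only"`.
#' @param tissue tissue to compare, default the config's first.
#' @param test,alpha passed to [compare_rs_rr()].
#' @param rates,influx model parameters shared by all lines.
#' @return A `group_comparison`.
#' @export
end_to_end_effect_check <- function(config = synth_config(
                                      rr_effect = list(GPX = 2, GSR = 2)),
                                    condition = "gpx_only",
                                    tissue = config$tissues[[1L]],
                                    test = "welch", alpha = 0.05,
                                    rates = rate_constants(),
                                    influx = 1e-5) {
  if (!config$include_reference)
    stop("the pipeline needs the reference line; set include_reference")
  gen <- generate_expression(config)
  enz <- aggregate_genes(gen$table, config$gene_map)
  prof <- scale_pools(enz, config$reference_name,
                      tissue = gen$table$tissue, label = gen$table$label)
  grid <- condition_grid()
  if (!condition %in% names(grid))
    stop("unknown condition: ", condition)
  res <- run_grid(prof, grid = grid[condition], rates = rates,
                  influx = influx)
  compare_rs_rr(res, tissue = tissue, condition = condition,
                test = test, alpha = alpha)
}
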