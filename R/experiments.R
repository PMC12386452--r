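#' The knockout condition grid
#'
#' The seven conditions of the in-silico knockout experiment: all three
#' systems active, each system alone, and each pair. Names encode the
#' ACTIVE pathways.
#'
#' @return Named list of [pathway_mask()] objects, `all_active` first.
#' @export
condition_grid <- function() {
  list(
    all_active = pathway_mask(TRUE, TRUE, TRUE),
    prdx_only = pathway_mask(TRUE, FALSE, FALSE),
    cat_only = pathway_mask(FALSE, TRUE, FALSE),
    gpx_only = pathway_mask(FALSE, FALSE, TRUE),
    prdx_cat = pathway_mask(TRUE, TRUE, FALSE),
    cat_gpx = pathway_mask(FALSE, TRUE, TRUE),
    prdx_gpx = pathway_mask(TRUE, FALSE, TRUE))
}

#' Run the knockout grid over cell-line profiles
#'
#' For every profile x condition, builds a [model_spec()] with the
#' profile's scaled pools and the condition's mask, and records the
#' steady-state H2O2. The analytic flux-balance solver is used; if it
#' reports no steady state (influx above the saturable capacity of the
#' active pathways) the row is recorded as non-converged with `NA` rather
#' than failing the run.
#'
#' @param profiles a `cell_line_profiles` data.frame ([scale_pools()]).
#' @param grid named list of masks, default [condition_grid()].
#' @param rates shared [rate_constants()].
#' @param influx constant H2O2 influx (mM/ms).
#' @param base base [enzyme_pools()] for the scaling factors.
#' @return A data.frame (`line`, `tissue`, `label`, `condition`,
#'   `h2o2_ss`, `converged`), one row per line x condition.
#' @export
run_grid <- function(profiles, grid = condition_grid(),
                     rates = rate_constants(), influx = 1e-5,
                     base = NULL) {
  if (length(grid) && is.null(names(grid)))
    stop("'grid' must be a named list of pathway masks")
  base <- base %||% attr(profiles, "base_pools") %||% enzyme_pools()
  rows <- vector("list", nrow(profiles) * length(grid))
  k <- 0L
  for (i in seq_len(nrow(profiles))) {
    pools <- profile_pools(profiles[i, ], base = base)
    for (cond in names(grid)) {
      spec <- model_spec(rates = rates, pools = pools,
                         mask = grid[[cond]], h2o2_influx = influx)
      res <- tryCatch(find_steady_analytic(spec), error = function(e) NULL)
      if (is.null(res))
        res <- tryCatch(find_steady_numeric(spec), error = function(e) NULL)
      k <- k + 1L
      rows[[k]] <- data.frame(
        line = profiles$line[i], tissue = profiles$tissue[i],
        label = profiles$label[i], condition = cond,
        h2o2_ss = if (is.null(res) || !res$converged) NA_real_ else
          res$h2o2_ss,
        converged = !is.null(res) && res$converged,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(line = character(), tissue = character(),
               label = character(), condition = character(),
               h2o2_ss = numeric(), converged = logical())
  rownames(out) <- NULL
  out
}

#' Per-tissue summary of steady-state H2O2
#'
#' Arithmetic mean and sample SD (n-1 denominator) of converged
#' steady-state values per tissue x condition -- the aggregation behind
#' bar-chart style summaries. Groups of size 1 get SD 0 and a warning
#' flag.
#'
#' @param results a [run_grid()] table.
#' @return data.frame `tissue`, `condition`, `n`, `mean`, `sd`,
#'   `single_line` (TRUE when n = 1).
#' @export
aggregate_by_tissue <- function(results) {
  ok <- results[results$converged & !is.na(results$h2o2_ss), , drop = FALSE]
  if (!nrow(ok))
    return(data.frame(tissue = character(), condition = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      single_line = logical()))
  key <- interaction(ok$tissue, ok$condition, drop = TRUE, sep = "\r")
  parts <- split(ok, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    data.frame(tissue = g$tissue[1L], condition = g$condition[1L],
               n = nrow(g), mean = mean(g$h2o2_ss),
               sd = if (nrow(g) > 1L) stats::sd(g$h2o2_ss) else 0,
               single_line = nrow(g) == 1L, stringsAsFactors = FALSE)
  }))
  if (any(out$single_line))
    warning("group(s) of size 1: SD reported as 0 for ",
            paste(sprintf("%s/%s", out$tissue[out$single_line],
                          out$condition[out$single_line]), collapse = ", "))
  out <- out[order(out$tissue, out$condition), ]
  rownames(out) <- NULL
  out
}

#' Compare radiosensitive vs radioresistant groups
#'
#' Two-sided comparison of steady-state H2O2 between RR- and RS-labelled
#' lines within one tissue x condition cell. Default is Welch's
#' unequal-variance t test; `test = "wilcoxon"` switches to the
#' Mann-Whitney rank test. Significance is called at `p < alpha`.
#'
#' @param results a [run_grid()] table.
#' @param tissue,condition the cell to compare.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param alpha significance level, default 0.05.
#' @return A `group_comparison` list: `tissue`, `condition`, `n_rr`,
#'   `n_rs`, `mean_rr`, `mean_rs`, `sd_rr`, `sd_rs`, `p_value`,
#'   `significant`, `test`.
#' @export
compare_rs_rr <- function(results, tissue, condition,
                          test = c("welch", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  sub <- results[results$tissue == tissue &
                   results$condition == condition &
                   results$converged & !is.na(results$h2o2_ss), ,
                 drop = FALSE]
  rr <- sub$h2o2_ss[sub$label == "RR"]
  rs <- sub$h2o2_ss[sub$label == "RS"]
  if (length(rr) < 2L)
    stop("RR group has fewer than 2 converged lines for ",
         tissue, "/", condition)
  if (length(rs) < 2L)
    stop("RS group has fewer than 2 converged lines for ",
         tissue, "/", condition)
  p <- if (test == "welch") {
    if (stats::sd(rr) == 0 && stats::sd(rs) == 0) {
      # t test undefined for two constant samples; identical means are
      # maximally non-significant, differing constant means are minimal p
      if (isTRUE(all.equal(mean(rr), mean(rs)))) 1 else 0
    } else
      stats::t.test(rr, rs, var.equal = FALSE)$p.value
  } else
    stats::wilcox.test(rr, rs, exact = FALSE)$p.value
  structure(list(tissue = tissue, condition = condition,
                 n_rr = length(rr), n_rs = length(rs),
                 mean_rr = mean(rr), mean_rs = mean(rs),
                 sd_rr = stats::sd(rr), sd_rs = stats::sd(rs),
                 p_value = p, significant = p < alpha, test = test),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s / %s (%s test)\n",
              x$tissue, x$condition, x$test))
  cat(sprintf("  RR: n=%d mean=%.6g sd=%.3g | RS: n=%d mean=%.6g sd=%.3g\n",
              x$n_rr, x$mean_rr, x$sd_rr, x$n_rs, x$mean_rs, x$sd_rs))
  cat(sprintf("  p = %.4g %s\n", x$p_value,
              if (x$significant) "(*)" else ""))
  invisible(x)
}

#' Compare all tissue x condition cells
#'
#' Runs [compare_rs_rr()] over every tissue x condition with at least two
#' converged lines per label group; optional Benjamini-Hochberg adjustment
#' across the grid (off by default, mirroring per-panel significance
#' calls).
#'
#' @param results a [run_grid()] table.
#' @param test,alpha as in [compare_rs_rr()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per comparable cell.
#' @export
compare_all <- function(results, test = c("welch", "wilcoxon"),
                        alpha = 0.05, adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  cells <- unique(results[!is.na(results$tissue),
                          c("tissue", "condition")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cmp <- tryCatch(
      compare_rs_rr(results, cells$tissue[i], cells$condition[i],
                    test = test, alpha = alpha),
      error = function(e) NULL)
    if (!is.null(cmp))
      rows[[length(rows) + 1L]] <-
        data.frame(tissue = cmp$tissue, condition = cmp$condition,
                   n_rr = cmp$n_rr, n_rs = cmp$n_rs,
                   mean_rr = cmp$mean_rr, mean_rs = cmp$mean_rs,
                   sd_rr = cmp$sd_rr, sd_rs = cmp$sd_rs,
                   p_value = cmp$p_value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(tissue = character(), condition = character(),
                      n_rr = integer(), n_rs = integer(),
                      mean_rr = numeric(), mean_rs = numeric(),
                      sd_rr = numeric(), sd_rs = numeric(),
                      p_value = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}
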