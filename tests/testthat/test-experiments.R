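# A small profile table built directly (factors relative to the default
# pools), avoiding the expression layer.
make_profiles <- function(df) {
  out <- cbind(df[c("line", "tissue", "label")],
               f_CAT = df$f %||% 1, f_GPX = df$f %||% 1,
               f_GSR = df$f %||% 1, f_TXNRD = df$f %||% 1,
               f_PRDX = df$f %||% 1, f_TXN = df$f %||% 1)
  attr(out, "base_pools") <- enzyme_pools()
  class(out) <- c("cell_line_profiles", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the condition grid is the seven-knockout design", {
  grid <- condition_grid()
  expect_identical(names(grid)[1L], "all_active")
  expect_length(grid, 7L)
  expect_false(any(duplicated(names(grid))))
  n_active <- vapply(grid, function(m) sum(unlist(m)), integer(1L))
  expect_identical(unname(n_active), c(3L, 1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("run_grid reproduces the single-pathway closed form", {
  prof <- make_profiles(data.frame(line = "REF", tissue = "colorectal",
                                   label = "RS"))
  res <- run_grid(prof)
  expect_equal(nrow(res), 7L)
  expect_true(all(res$converged))
  expect_equal(res$h2o2_ss[res$condition == "cat_only"],
               1e-5 / (0.034 * 0.001), tolerance = 1e-9)
  # knockout monotonicity across the grid
  all_active <- res$h2o2_ss[res$condition == "all_active"]
  expect_true(all(all_active <= res$h2o2_ss + 1e-15))
})

test_that("run_grid on an empty grid returns an empty table", {
  prof <- make_profiles(data.frame(line = "REF", tissue = "x",
                                   label = "RS"))
  res <- run_grid(prof, grid = list())
  expect_equal(nrow(res), 0L)
  expect_identical(names(res), c("line", "tissue", "label", "condition",
                                 "h2o2_ss", "converged"))
})

test_that("a no-steady-state case is recorded, not fatal", {
  prof <- make_profiles(data.frame(line = c("REF", "DEAD"),
                                   tissue = "x", label = c("RS", "RR"),
                                   f = c(1, 1e-9)))
  # influx above the GPX-only capacity of the weak line
  res <- run_grid(prof, grid = condition_grid()["gpx_only"])
  expect_true(res$converged[res$line == "REF"])
  expect_false(res$converged[res$line == "DEAD"])
  expect_true(is.na(res$h2o2_ss[res$line == "DEAD"]))
})

test_that("tissue aggregation uses mean and n-1 SD", {
  res <- data.frame(line = c("a", "b", "c"), tissue = c("t", "t", "u"),
                    label = "RS", condition = "all_active",
                    h2o2_ss = c(1, 3, 5), converged = TRUE)
  expect_warning(agg <- aggregate_by_tissue(res), "size 1")
  t_row <- agg[agg$tissue == "t", ]
  expect_equal(t_row$mean, 2)
  expect_equal(t_row$sd, sqrt(2))
  u_row <- agg[agg$tissue == "u", ]
  expect_equal(u_row$sd, 0)
  expect_true(u_row$single_line)

  # identical values: SD exactly 0
  res2 <- data.frame(line = c("a", "b"), tissue = "t", label = "RS",
                     condition = "x", h2o2_ss = c(2, 2), converged = TRUE)
  expect_equal(aggregate_by_tissue(res2)$sd, 0)
})

test_that("tissue aggregation is order-free", {
  set.seed(9)
  res <- data.frame(line = paste0("l", 1:12),
                    tissue = rep(c("t", "u"), 6), label = "RS",
                    condition = rep(c("a", "b"), each = 6),
                    h2o2_ss = runif(12), converged = TRUE)
  a1 <- aggregate_by_tissue(res)
  a2 <- aggregate_by_tissue(res[sample(nrow(res)), ])
  expect_equal(a1, a2)
})

test_that("Welch comparison matches a textbook implementation", {
  rr <- c(1, 1.1, 0.9)
  rs <- c(5, 5.1, 4.9)
  res <- data.frame(line = paste0("l", 1:6), tissue = "t", label =
                      rep(c("RR", "RS"), each = 3), condition = "c",
                    h2o2_ss = c(rr, rs), converged = TRUE)
  cmp <- compare_rs_rr(res, "t", "c")
  # hand-coded Welch statistic and Welch-Satterthwaite df
  se2 <- var(rr) / 3 + var(rs) / 3
  tstat <- (mean(rr) - mean(rs)) / sqrt(se2)
  df <- se2^2 / ((var(rr) / 3)^2 / 2 + (var(rs) / 3)^2 / 2)
  p_want <- 2 * pt(-abs(tstat), df)
  expect_equal(cmp$p_value, p_want, tolerance = 1e-12)
  expect_true(cmp$significant)
  expect_equal(cmp$n_rr, 3L)
  expect_equal(cmp$mean_rr, 1)

  # identical samples, permuted: maximally non-significant
  res2 <- res
  res2$h2o2_ss <- c(1, 2, 3, 3, 1, 2)
  cmp2 <- compare_rs_rr(res2, "t", "c")
  expect_gt(cmp2$p_value, 0.999)
  expect_false(cmp2$significant)
})

test_that("comparison is symmetric under label swap", {
  set.seed(31)
  res <- data.frame(line = paste0("l", 1:10), tissue = "t",
                    label = rep(c("RR", "RS"), each = 5),
                    condition = "c", h2o2_ss = rnorm(10, 5), converged = TRUE)
  swapped <- res
  swapped$label <- ifelse(res$label == "RR", "RS", "RR")
  a <- compare_rs_rr(res, "t", "c")
  b <- compare_rs_rr(swapped, "t", "c")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$mean_rr, b$mean_rs)
  expect_equal(a$mean_rs, b$mean_rr)
})

test_that("undersized groups are an error naming the group", {
  res <- data.frame(line = paste0("l", 1:3), tissue = "t",
                    label = c("RR", "RS", "RS"), condition = "c",
                    h2o2_ss = 1:3, converged = TRUE)
  expect_error(compare_rs_rr(res, "t", "c"), "RR group")
})

test_that("Mann-Whitney alternative is available", {
  set.seed(17)
  res <- data.frame(line = paste0("l", 1:12), tissue = "t",
                    label = rep(c("RR", "RS"), each = 6),
                    condition = "c",
                    h2o2_ss = c(rnorm(6, 1, 0.1), rnorm(6, 5, 0.1)),
                    converged = TRUE)
  cmp <- compare_rs_rr(res, "t", "c", test = "wilcoxon")
  expect_identical(cmp$test, "wilcoxon")
  expect_true(cmp$significant)
})

test_that("the classification fixture has the documented structure", {
  cls <- load_classification()
  expect_equal(nrow(cls), 42L)
  counts <- table(cls$tissue)
  expect_equal(unname(counts[c("lung", "breast", "colorectal")]),
               c(14L, 16L, 12L), ignore_attr = TRUE)
  split_counts <- table(cls$tissue, cls$label)
  expect_equal(split_counts["lung", "RR"], 7L, ignore_attr = TRUE)
  expect_equal(split_counts["lung", "RS"], 7L, ignore_attr = TRUE)
  expect_equal(split_counts["breast", "RR"], 8L, ignore_attr = TRUE)
  expect_equal(split_counts["breast", "RS"], 8L, ignore_attr = TRUE)
  expect_equal(split_counts["colorectal", "RR"], 7L, ignore_attr = TRUE)
  expect_equal(split_counts["colorectal", "RS"], 5L, ignore_attr = TRUE)
  expect_false(any(duplicated(cls$line)))
  expect_identical(cls$label[cls$line == "A549"], "RR")
  expect_identical(cls$label[cls$line == "SW48"], "RS")
  expect_identical(cls$label[cls$line == "HCT116"], "RS")
})
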