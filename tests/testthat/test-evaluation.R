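# Metrics, rank statistics, aggregation and report building.

test_that("rmse matches its closed forms and a brute-force loop", {
  y <- c(1, 2, 3, 4)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 0.5), 0.5)
  set.seed(1)
  a <- rnorm(25); b <- rnorm(25)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(rmse(a, b), sqrt(acc / 25))
  expect_error(rmse(1:3, 1:4), "equal")
})

test_that("nrmse normalises by the reference range in percent", {
  expect_equal(nrmse(c(0, 4), c(0.5, 4.5), 4), 12.5)
  expect_equal(nrmse(1:5, 1:5, 10), 0)
  expect_equal(nrmse(c(0, 1), c(1, 2), 1), 100)
  expect_error(nrmse(1:3, 1:3, 0), "positive")
})

test_that("rpiq divides the type-7 IQR by the RMSE", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(rpiq(y, IQR(y))), 1)
  r2 <- rpiq(c(0, 1, 2, 4), 0.875)  # type-7 IQR = 1.75
  expect_equal(as.numeric(r2), 2)
  expect_true(attr(r2, "reliable"))
  y100 <- 1:100
  expect_equal(as.numeric(rpiq(y100, 10)),
               (quantile7_oracle(y100, 0.75) -
                  quantile7_oracle(y100, 0.25)) / 10)
  expect_true(is.infinite(rpiq(y, 0)))
  # homogeneity of degree zero under common rescaling
  expect_equal(as.numeric(rpiq(3 * y100, 3 * 10)),
               as.numeric(rpiq(y100, 10)))
})

test_that("location aggregation averages non-negative predictions", {
  expect_equal(aggregate_location_prediction(c(2, -1, 4)), 3)
  expect_equal(aggregate_location_prediction(5), 5)
  all_neg <- aggregate_location_prediction(c(-1, -2))
  expect_true(is.na(all_neg))
  expect_true(attr(all_neg, "all_negative"))
  expect_error(aggregate_location_prediction(numeric(0)), "no predictions")
  # constant predictions pass through unchanged
  expect_equal(aggregate_location_prediction(rep(3.3, 8)), 3.3)
})

test_that("Spearman correlation matches the brute-force rank formula", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$rho, -1)
  set.seed(2)
  for (k in 1:10) {
    x <- sample(1:8); y <- rnorm(8)
    expect_equal(spearman_cor(x, y)$rho, spearman_oracle(x, y))
  }
  # tied data use average ranks
  x <- c(1, 1, 2, 3, 3, 4); y <- c(2, 1, 1, 3, 4, 4)
  expect_equal(spearman_cor(x, y)$rho, spearman_oracle(x, y))
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
})

test_that("Spearman p-values agree with cor.test", {
  set.seed(3)
  x <- rnorm(30); y <- x + rnorm(30)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate))
  x8 <- rnorm(8); y8 <- rnorm(8)
  expect_equal(spearman_cor(x8, y8)$p,
               cor.test(x8, y8, method = "spearman", exact = TRUE)$p.value)
})

test_that("Mann-Whitney U matches exhaustive enumeration for small n", {
  out <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  orc <- mw_enumeration_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p, orc$p)
  set.seed(4)
  for (k in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    out <- mann_whitney_u(a, b)
    orc <- mw_enumeration_oracle(a, b)
    expect_equal(out$U, orc$U)
    expect_equal(out$p, orc$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney obeys the conservation identity and null case", {
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.7, 4.4, 2.9)
  expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
               length(a) * length(b))
  ident <- suppressWarnings(mann_whitney_u(c(1, 2, 3), c(1, 2, 3)))
  expect_gt(ident$p, 0.9)
})

test_that("the normality gate routes clean and skewed samples correctly", {
  par_hits <- 0; nonpar_hits <- 0
  set.seed(5)
  for (k in 1:100) {
    par_hits <- par_hits + (shapiro_wilk_gate(rnorm(500)) == "parametric")
    nonpar_hits <- nonpar_hits +
      (shapiro_wilk_gate(stats::rexp(500)) == "nonparametric")
  }
  expect_gte(par_hits, 90)
  expect_gte(nonpar_hits, 99)
  expect_error(shapiro_wilk_gate(c(1, 2)), "3 <= n")
})

test_that("reports have one row per parameter, variant and set", {
  results <- list()
  set.seed(6)
  for (p in c("E_eq", "SMI")) {
    for (v in c("Model1", "Model2")) {
      y <- runif(20, 1, 2)
      sets <- list(calval = list(y_true = y, y_pred = y + rnorm(20, 0, 0.1)),
                   test = list(y_true = y[1:6], y_pred = y[1:6] + 0.05))
      if (v == "Model1") {
        sets$arthroscopic <- list(y_true = y[1:5], y_pred = y[1:5] * 1.1)
      }
      results[[paste(p, v)]] <- list(parameter = p, variant = v,
                                     region = c(0.75, 1.90),
                                     n_variables = 3, sets = sets)
    }
  }
  rep_df <- build_report(results, list(E_eq = 1, SMI = 1))
  expect_equal(nrow(rep_df), 2 * 2 * 2 + 2)  # + arthro rows for Model1
  expect_equal(unique(rep_df$region_um), "0.75-1.90")
  expect_named(rep_df, c("parameter", "variant", "region_um", "n_variables",
                         "set", "n", "rho", "p", "nrmse_pct", "rpiq",
                         "reliable_flag"))
  expect_equal(nrow(build_report(list(), list())), 0)
  # CSV round trip preserves the report
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rep_df, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$nrmse_pct, rep_df$nrmse_pct, tolerance = 1e-12)
  expect_equal(back$set, rep_df$set)
})

test_that("group summaries report quartiles per class and group", {
  set.seed(7)
  vals <- c(rnorm(40, 10), rnorm(20, 12))
  grp <- c(rep("repair", 40), rep("control", 20))
  cls <- rep(1:4, 15)
  gs <- group_summary(vals, grp, cls, "E_eq")
  expect_equal(nrow(gs), 8)
  expect_true(all(gs$q25 <= gs$median & gs$median <= gs$q75))
  expect_equal(sum(gs$n), 60)
})
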