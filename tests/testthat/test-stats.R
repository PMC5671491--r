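ds <- load_table1_fixture()

test_that("gene ratio matches direct division and flags implausible values", {
  r <- gene_ratio(ds)
  names(r) <- ds$samples$sample_id
  expect_equal(unname(r["M_bott"]), 1.6e9 / 5.1e9, tolerance = 1e-12)
  expect_equal(unname(r["R1_bott"]), 1.2e3 / 3.6e8, tolerance = 1e-12)
  expect_true(all(is.na(r[ds$samples$water_type == "sediment"])))
  expect_equal(gene_ratio(data.frame(archaea_16s = 5, mgii_16s = 5)), 1)
  expect_warning(gene_ratio(data.frame(archaea_16s = 1, mgii_16s = 2)),
                 "exceed")
  expect_true(is.na(gene_ratio(data.frame(archaea_16s = 0, mgii_16s = 2))))
})

test_that("group summaries reproduce fixture means and handle small groups", {
  gs <- group_summary(ds, "ri2", pool = "CL")
  mix_cl <- gs[gs$water_type == "mixing" & gs$pool == "CL", ]
  expect_equal(mix_cl$n, 6)
  expect_equal(round(mix_cl$mean, 2), 0.39)
  gm <- group_summary(ds, "mgii_16s")
  river <- gm[gm$water_type == "river", ]
  expect_equal(river$n, 2)              # only R1_sur / R1_bott were assayed
  expect_equal(river$mean, 1.506e5, tolerance = 1e-6)
  # single-record group: mean is the value, sample sd undefined
  one <- gdgt_dataset(tibble::tibble(sample_id = "x", water_type = "sea",
                                     archaea_16s = 10, mgii_16s = 5))
  g1 <- group_summary(one, "mgii_16s")
  expect_equal(g1$mean, 5)
  expect_true(is.na(g1$sd))
  expect_equal(g1$sd_pop, 0)
  # order invariance of means
  shuffled <- ds
  set.seed(1)
  perm <- sample(nrow(shuffled$samples))
  shuffled$samples <- shuffled$samples[perm, ]
  gshuf <- group_summary(shuffled, "mgii_16s")
  expect_equal(gshuf[order(gshuf$water_type), ]$mean,
               gm[order(gm$water_type), ]$mean)
  expect_warning(
    group_summary(gdgt_dataset(tibble::tibble(sample_id = "x",
                                              water_type = "sea",
                                              mgii_16s = NA_real_,
                                              archaea_16s = NA_real_)),
                  "mgii_16s"),
    "no defined values")
})

test_that("welch test behaves at the degenerate limits and on the fixture groups", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  r <- gene_ratio(ds)
  mix <- r[ds$samples$water_type == "mixing"]
  sea <- r[ds$samples$water_type == "sea"]
  tw <- welch_t_test(mix, sea)
  expect_lt(tw$p_value, 0.05)
  expect_gt(tw$statistic, 0)
  # symmetry in (a, b)
  tw2 <- welch_t_test(sea, mix)
  expect_equal(tw2$p_value, tw$p_value)
  expect_equal(tw2$statistic, -tw$statistic)
  # zero-variance shortcut
  degen <- welch_t_test(c(0, 0, 0), c(1, 1, 1))
  expect_equal(degen$p_value, 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  # pooled variant agrees with stats::t.test(var.equal = TRUE)
  st <- welch_t_test(mix, sea, var_equal = TRUE)
  ref <- t.test(mix, sea, var.equal = TRUE)
  expect_equal(st$p_value, ref$p.value)
})

test_that("ols regression matches closed forms and rejects bad input", {
  x <- 1:5
  fit <- ols_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  sym <- ols_regression(c(0, 1, 2), c(0, 1, 0))
  expect_equal(sym$slope, 0, tolerance = 1e-12)
  expect_equal(sym$r_squared, 0, tolerance = 1e-12)
  expect_error(ols_regression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ols_regression(c(1, 2), c(1, 2)), "at least 3")
  # NA pairs are dropped pairwise
  fit2 <- ols_regression(c(x, NA), c(2 * x + 1, 5))
  expect_equal(fit2$n, 5)
})

test_that("ols agrees with a normal-equation oracle and the r = cor identity", {
  set.seed(99)
  for (k in 1:200) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    y <- rnorm(n, 0.5 * x)
    fit <- ols_regression(x, y)
    orc <- ols_oracle(x, y)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-9)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-9)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-9)
  }
})

test_that("regression screen reproduces the fixture ring-index row", {
  rs <- regression_screen(ds, "ri2")
  expect_equal(nrow(rs), 3)
  expect_equal(rs$n, rep(12L, 3))
  # frozen from an independent lm() oracle on the printed table values
  expect_equal(rs$r_squared[rs$pool == "CL"], 0.4851, tolerance = 1e-3)
  expect_equal(rs$r_squared[rs$pool == "total_IPL"], 0.5087, tolerance = 1e-3)
  expect_equal(rs$r_squared[rs$pool == "phospho_IPL"], 0.7184, tolerance = 1e-3)
  wide <- format_regression_screen(rs)
  expect_equal(wide$r_squared_phospho_IPL, 0.72)
  expect_equal(wide$p_value_phospho_IPL, 0)   # 0.0005 prints as 0.00
  expect_equal(nrow(regression_screen(ds, character(0))), 0)
  # unknown variable yields a not-computable cell, not an error
  rs2 <- regression_screen(ds, c("ri2", "methane_index"), pools = "CL")
  expect_true(is.na(rs2$r_squared[rs2$variable == "methane_index"]))
})

test_that("station pairing strategies give defined fits and fail below 3 stations", {
  for (strategy in c("station-mean", "surface-only", "per-sample")) {
    fit <- paired_station_correlation(ds, "tex86", "CL", strategy)
    expect_true(is.finite(fit$r_squared))
    expect_equal(fit$pairing, strategy)
    expect_equal(fit$n_stations, 8)
  }
  # identical SPM and sediment values force a perfect fit
  toy <- gdgt_dataset(
    tibble::tibble(sample_id = c("a", "b", "c", "sa", "sb", "sc"),
                   station = rep(c("S1", "S2", "S3"), 2),
                   water_type = rep(c("sea", "sediment"), each = 3),
                   depth_m = c(1, 1, 1, 10, 10, 10)),
    indices = tibble::tibble(sample_id = c("a", "b", "c", "sa", "sb", "sc"),
                             pool = "CL", tex86 = c(0.4, 0.5, 0.6,
                                                    0.4, 0.5, 0.6)))
  perfect <- paired_station_correlation(toy, "tex86", "CL", "station-mean")
  expect_equal(perfect$r_squared, 1, tolerance = 1e-9)
  two <- gdgt_dataset(toy$samples[c(1, 2, 4, 5), ],
                      indices = toy$indices[c(1, 2, 4, 5), ])
  expect_error(paired_station_correlation(two, "tex86", "CL"), "3 stations")
})
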