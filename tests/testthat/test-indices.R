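# Direct-arithmetic checks of every index, then property-style tests of
# their ranges and invariances over random valid profiles.

test_that("tex86 matches direct arithmetic and handles degenerate numerators", {
  expect_equal(tex86(gdgt_profile(g0 = 90, g1 = 10)), 0)
  expect_equal(tex86(gdgt_profile(g0 = 60, g2 = 20, g3 = 10, cren_iso = 10)), 1)
  expect_equal(tex86(gdgt_profile(g0 = 50, g1 = 10, g2 = 20, g3 = 10,
                                  cren_iso = 10)), 0.8, tolerance = 1e-12)
  expect_true(is.na(tex86(gdgt_profile(g0 = 100))))
})

test_that("ring indices match direct arithmetic", {
  expect_equal(ring_index_1(gdgt_profile(g0 = 100)), 0)
  expect_equal(ring_index_2(gdgt_profile(g0 = 100)), 0)
  expect_equal(ring_index_1(gdgt_profile(cren = 100)), 4)
  p1 <- gdgt_profile(g0 = 35, g1 = 10, g2 = 10, g3 = 10, cren = 30,
                     cren_iso = 5)
  expect_equal(ring_index_1(p1), 2.0, tolerance = 1e-12)
  p2 <- gdgt_profile(g0 = 50, g1 = 10, g2 = 10, g3 = 10, g4 = 10,
                     cren_iso = 10)
  expect_equal(ring_index_2(p2), 1.4, tolerance = 1e-12)
})

test_that("ri2 ignores crenarchaeol while ri1 does not", {
  p <- gdgt_profile(g0 = 30, g1 = 10, g2 = 10, g3 = 10, g4 = 5, cren = 30,
                    cren_iso = 5)
  # move all crenarchaeol mass into GDGT-0
  q <- gdgt_profile(g0 = 60, g1 = 10, g2 = 10, g3 = 10, g4 = 5, cren = 0,
                    cren_iso = 5)
  expect_equal(ring_index_2(p), ring_index_2(q), tolerance = 1e-12)
  expect_gt(ring_index_1(p), ring_index_1(q))
})

test_that("methane index, %GDGT-2 and the simple ratios match direct arithmetic", {
  expect_equal(methane_index(gdgt_profile(g0 = 70, g1 = 10, g2 = 10, g3 = 10)), 1)
  expect_equal(methane_index(gdgt_profile(g0 = 50, cren = 50)), 0)
  expect_equal(methane_index(gdgt_profile(g1 = 10, g2 = 10, g3 = 10,
                                          cren = 60, cren_iso = 10)),
               0.3, tolerance = 1e-12)
  expect_equal(pct_gdgt2(gdgt_profile(g0 = 80, g1 = 10, g3 = 10)), 0)
  expect_equal(pct_gdgt2(gdgt_profile(g0 = 80, g2 = 20)), 100)
  expect_equal(pct_gdgt2(gdgt_profile(g0 = 60, g1 = 10, g2 = 20, g3 = 10)),
               50, tolerance = 1e-12)
  expect_true(is.na(pct_gdgt2(gdgt_profile(g0 = 100))))
  r <- gdgt_ratios(gdgt_profile(g0 = 50, g2 = 8, g3 = 4, cren = 25,
                                cren_iso = 13))
  expect_equal(r$ratio_2_3, 2)
  expect_equal(r$ratio_0_cren, 2)
  expect_equal(r$ratio_2_cren, 8 / 25)
  r0 <- gdgt_ratios(gdgt_profile(g0 = 90, g2 = 10))
  expect_true(is.na(r0$ratio_0_cren) && is.na(r0$ratio_2_cren) &&
                is.na(r0$ratio_2_3))
})

test_that("BIT index matches direct arithmetic and degenerate cases", {
  p <- gdgt_profile(g0 = 60, cren = 40)
  expect_equal(bit_index(p, br_gdgt_profile(0, 0, 0)), 0)
  expect_equal(bit_index(gdgt_profile(g0 = 100), br_gdgt_profile(3, 4, 3)), 1)
  expect_equal(bit_index(p, br_gdgt_profile(5, 3, 2)), 0.2, tolerance = 1e-12)
})

test_that("compute_indices aggregates the per-index functions", {
  p <- gdgt_profile(g0 = 50, g1 = 10, g2 = 20, g3 = 10, cren_iso = 10)
  ix <- compute_indices(p)
  expect_equal(ix$tex86, tex86(p))
  expect_equal(ix$ri1, ring_index_1(p))
  expect_equal(ix$ri2, ring_index_2(p))
  expect_equal(ix$pct_gdgt2, 50, tolerance = 1e-12)
  expect_false("bit" %in% names(ix))
  ix0 <- compute_indices(gdgt_profile(g0 = 100))
  expect_equal(ix0$tex86, NA_real_)
  expect_equal(ix0$ri1, 0)
  expect_true(is.na(ix0$ratio_0_cren))
  ixb <- compute_indices(p, br_gdgt_profile(1, 1, 1))
  expect_true("bit" %in% names(ixb))
})

test_that("defined indices stay inside their ranges on random profiles", {
  p <- random_profiles(200, seed = 7, allow_zero_cren = TRUE)
  ix <- compute_indices(p, br_gdgt_profile(runif(200, 0, 5),
                                           runif(200, 0, 5),
                                           runif(200, 0, 5)))
  in_range <- function(v, lo, hi) all(is.na(v) | (v >= lo & v <= hi))
  expect_true(in_range(ix$tex86, 0, 1))
  expect_true(in_range(ix$methane_index, 0, 1))
  expect_true(in_range(ix$bit, 0, 1))
  expect_true(in_range(ix$ri1, 0, 4))
  expect_true(in_range(ix$ri2, 0, 4))
  expect_true(in_range(ix$pct_gdgt2, 0, 100))
  expect_true(all(is.na(ix$ratio_2_3) | ix$ratio_2_3 >= 0))
})

test_that("ratio indices are scale-invariant; ring indices agree after normalization", {
  p <- random_profiles(50, seed = 13)
  scaled <- as.data.frame(p) * 0.37   # arbitrary non-percent scale
  renorm <- normalize_profile(scaled)
  expect_equal(tex86(as_gdgt_profile(renorm)), tex86(p), tolerance = 1e-9)
  expect_equal(methane_index(as_gdgt_profile(renorm)), methane_index(p),
               tolerance = 1e-9)
  expect_equal(ring_index_1(renorm), ring_index_1(p), tolerance = 1e-9)
  expect_equal(ring_index_2(renorm), ring_index_2(p), tolerance = 1e-9)
})

test_that("enriching GDGT-1 at the expense of GDGT-0 lowers tex86 and raises ri2", {
  base <- gdgt_profile(g0 = 40, g1 = 10, g2 = 15, g3 = 10, g4 = 5,
                       cren = 15, cren_iso = 5)
  shifts <- seq(0, 30, by = 5)
  tex <- ri2 <- numeric(length(shifts))
  for (i in seq_along(shifts)) {
    p <- gdgt_profile(g0 = 40 - shifts[i], g1 = 10 + shifts[i], g2 = 15,
                      g3 = 10, g4 = 5, cren = 15, cren_iso = 5)
    tex[i] <- tex86(p)
    ri2[i] <- ring_index_2(p)
  }
  expect_true(all(diff(tex) < 0))
  expect_true(all(diff(ri2) > 0))
})
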