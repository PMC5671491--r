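# Random valid percent-scale profiles for property-style tests.
random_profiles <- function(n, seed = 42, allow_zero_cren = FALSE) {
  set.seed(seed)
  m <- matrix(rexp(7 * n), nrow = n)
  if (allow_zero_cren) m[sample(n, ceiling(n / 4)), 6] <- 0
  m <- 100 * m / rowSums(m)
  colnames(m) <- c("g0", "g1", "g2", "g3", "g4", "cren", "cren_iso")
  as_gdgt_profile(as.data.frame(m))
}

# Normal-equation OLS oracle, independent of stats::lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * syy)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept, r_squared = r2,
       p_value = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE))
}

write_demo_csv <- function(path, rows = 3) {
  header <- paste("id,g0,g1,g2,g3,g4,cren,cren_iso,arch,mgii", sep = "")
  lines <- c(header,
             "a,50,10,10,10,5,10,5,2.1E+09,3.0E+05",
             "b,40,15,15,10,5,10,5,5.7E+08,1.2E+03",
             "c,30,20,15,15,5,10,5,–,–")
  writeLines(lines[seq_len(rows + 1)], path)
  path
}

demo_schema <- function(...) {
  gdgt_schema(sample_id = "id", archaea_16s = "arch", mgii_16s = "mgii",
              profiles = list(CL = c(g0 = "g0", g1 = "g1", g2 = "g2",
                                     g3 = "g3", g4 = "g4", cren = "cren",
                                     cren_iso = "cren_iso")), ...)
}
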