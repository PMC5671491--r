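# Group summaries, two-group comparison, OLS regression and the
# regression screen of index values against the MG-II/archaea gene ratio.
# Model fits go through stats::lm / stats::t.test; this module owns the
# undefined-value bookkeeping and the screen layout.

#' MG-II to total-archaea 16S gene-copy ratio
#'
#' `mgii_16s / archaea_16s` per sample; the abundance covariate of the
#' regression screen. Undefined (`NA`) where either abundance is absent or
#' the archaeal count is zero. A ratio above 1 is biologically implausible
#' (MG-II is a subset of archaea) and raises a warning, not an error.
#'
#' @param x A [gdgt_dataset()] or a data frame with `archaea_16s` and
#'   `mgii_16s` columns.
#' @return Numeric vector, one value per sample.
#' @export
gene_ratio <- function(x) {
  s <- if (inherits(x, "gdgt_dataset")) x$samples else tibble::as_tibble(x)
  if (!all(c("archaea_16s", "mgii_16s") %in% names(s))) {
    stop("need 'archaea_16s' and 'mgii_16s' columns", call. = FALSE)
  }
  r <- ifelse(!is.na(s$archaea_16s) & s$archaea_16s > 0,
              s$mgii_16s / s$archaea_16s, NA_real_)
  if (any(!is.na(r) & r > 1)) {
    warning("gene ratio > 1 for ",
            sum(!is.na(r) & r > 1),
            " sample(s): MG-II counts exceed total archaea", call. = FALSE)
  }
  r
}

#' Grouped mean and spread of a sample- or index-level variable
#'
#' Records with an undefined (`NA`) value are excluded from their group's
#' `n`. Both the sample standard deviation (`sd`, n-1 denominator) and the
#' population form (`sd_pop`, n denominator) are reported; `sd` is `NA` for
#' single-record groups.
#'
#' @param ds A [gdgt_dataset()].
#' @param variable Name of the variable to summarise. Either a column of
#'   `ds$samples` (e.g. `"mgii_16s"`), a column of `ds$indices` (e.g.
#'   `"ri2"`; requires `pool`), or `"gene_ratio"` (computed on the fly).
#' @param by Grouping columns from `ds$samples` (default `"water_type"`).
#' @param pool Lipid pool(s) to keep when `variable` lives in the index
#'   table; `NULL` keeps all pools and adds `pool` to the grouping.
#' @return A tibble with the grouping columns, `variable`, (`pool`,) `n`,
#'   `mean`, `sd`, `sd_pop`.
#' @export
group_summary <- function(ds, variable, by = "water_type", pool = NULL) {
  stopifnot(inherits(ds, "gdgt_dataset"))
  s <- ds$samples
  missing_by <- setdiff(by, names(s))
  if (length(missing_by) > 0) {
    stop("unknown grouping column(s): ", paste(missing_by, collapse = ", "),
         call. = FALSE)
  }
  if (identical(variable, "gene_ratio")) {
    dat <- s[by]
    dat$value <- gene_ratio(ds)
  } else if (variable %in% names(s)) {
    dat <- s[by]
    dat$value <- s[[variable]]
  } else if (!is.null(ds$indices) && variable %in% names(ds$indices)) {
    dat <- dplyr::left_join(
      ds$indices[c("sample_id", "pool", variable)],
      s[c("sample_id", by)], by = "sample_id")
    if (!is.null(pool)) dat <- dat[dat$pool %in% pool, ]
    dat$value <- dat[[variable]]
    by <- c(by, "pool")
  } else {
    stop("variable '", variable, "' not found in samples or indices",
         call. = FALSE)
  }
  dat <- dat[!is.na(dat$value), ]
  if (nrow(dat) == 0) {
    warning("no defined values of '", variable, "' in any group",
            call. = FALSE)
    return(tibble::tibble())
  }
  out <- dplyr::summarise(
    dplyr::group_by(dat, dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = ifelse(dplyr::n() >= 2, stats::sd(.data$value), NA_real_),
    sd_pop = sqrt(mean((.data$value - mean(.data$value))^2)),
    .groups = "drop")
  out$variable <- variable
  out[c(setdiff(names(out), "variable")[1:length(by)], "variable",
        "n", "mean", "sd", "sd_pop")]
}

#' Two-group t test (Welch by default)
#'
#' Welch's unequal-variance two-sided t test with Welch-Satterthwaite
#' degrees of freedom; `var_equal = TRUE` gives Student's pooled variant
#' for sensitivity analyses. When both groups have zero variance the test
#' statistic is degenerate and an exact-difference shortcut is used:
#' identical means give `statistic = 0, p = 1`, different means
#' `statistic = +/-Inf, p = 0`.
#'
#' @param a,b Numeric vectors (NAs dropped; each needs n >= 2).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A list with class `ttest_result`: `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 defined values", call. = FALSE)
  }
  method <- if (var_equal) "Student pooled t" else "Welch t"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p_value = if (same) 1 else 0,
                method = paste(method, "(zero-variance shortcut)"))
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal,
                        alternative = "two.sided")
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, method = method)
  }
  structure(res, class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<%s> t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression via [stats::lm()]; pairs with an `NA` in either
#' variable are dropped. The p-value is the two-sided t test of the slope
#' against zero on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with class `ols_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("x is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; exact fits are legitimate inputs here
  sm <- suppressWarnings(summary(fit))
  p <- if (nrow(sm$coefficients) >= 2) sm$coefficients["x", "Pr(>|t|)"] else NA_real_
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 p_value = unname(p),
                 n = length(x)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> y = %.4g x + %.4g, R^2 = %.3f, p = %.4g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Regression screen of index variables against the gene ratio
#'
#' For each (variable, pool) cell, regresses the per-sample index values on
#' the MG-II/archaea 16S gene-copy ratio over the samples where both are
#' defined (pairwise deletion). Cells with fewer than 3 complete pairs are
#' marked not computable (`NA` fit columns). The output mirrors the
#' variables-by-pools layout of a published regression table; see
#' [format_regression_screen()] for the wide 2-decimal rendering.
#'
#' @param ds A [gdgt_dataset()] with gene abundances and an index table.
#' @param variables Index columns to screen (default `"ri2"`).
#' @param pools Lipid pools to include.
#' @return A long tibble: `variable`, `pool`, `r_squared`, `p_value`,
#'   `slope`, `intercept`, `n`.
#' @export
regression_screen <- function(ds, variables = "ri2",
                              pools = pool_levels) {
  stopifnot(inherits(ds, "gdgt_dataset"))
  if (length(variables) == 0) return(tibble::tibble())
  if (is.null(ds$indices)) stop("dataset has no index table", call. = FALSE)
  ratios <- tibble::tibble(sample_id = ds$samples$sample_id,
                           ratio = gene_ratio(ds))
  if (sum(!is.na(ratios$ratio)) < 3) {
    stop("need gene ratios for at least 3 records", call. = FALSE)
  }
  grid <- expand.grid(variable = variables, pool = pools,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$variable[i]
    pl <- grid$pool[i]
    cell <- tibble::tibble(variable = v, pool = pl, r_squared = NA_real_,
                           p_value = NA_real_, slope = NA_real_,
                           intercept = NA_real_, n = NA_integer_)
    if (!v %in% names(ds$indices)) return(cell)
    ix <- ds$indices[ds$indices$pool == pl, c("sample_id", v)]
    dat <- dplyr::inner_join(ix, ratios, by = "sample_id")
    ok <- !is.na(dat[[v]]) & !is.na(dat$ratio)
    if (sum(ok) < 3 || stats::var(dat$ratio[ok]) == 0) return(cell)
    fit <- ols_regression(dat$ratio, dat[[v]])
    cell$r_squared <- fit$r_squared
    cell$p_value <- fit$p_value
    cell$slope <- fit$slope
    cell$intercept <- fit$intercept
    cell$n <- fit$n
    cell
  })
  dplyr::bind_rows(rows)
}

#' Render a regression screen as a wide variables-by-pools table
#'
#' Rows are variables; each pool contributes an (R^2, P) column pair,
#' rounded to 2 decimals as in the published layout (so a p of 0.004 prints
#' as 0.00). Full precision stays in the long table from
#' [regression_screen()].
#'
#' @param screen Output of [regression_screen()].
#' @param digits Decimals for the rounded columns.
#' @return A wide tibble.
#' @export
format_regression_screen <- function(screen, digits = 2) {
  if (nrow(screen) == 0) return(tibble::tibble())
  long <- screen
  long$r_squared <- round(long$r_squared, digits)
  long$p_value <- round(long$p_value, digits)
  tidyr::pivot_wider(long[c("variable", "pool", "r_squared", "p_value")],
                     names_from = "pool",
                     values_from = c("r_squared", "p_value"),
                     names_vary = "slowest")
}

#' Correlation between water-column and sediment proxy values by station
#'
#' Pairs the suspended-particulate-matter (SPM) record of each station with
#' the sediment record of the same station and regresses the sediment
#' values on the SPM values. The pairing strategy is recorded in the
#' output because published station-level correlations rarely state it:
#' `"station-mean"` averages all SPM depths/tides per station,
#' `"surface-only"` keeps the shallowest SPM record, `"per-sample"` pairs
#' every SPM record with its station's sediment value.
#'
#' @param ds A [gdgt_dataset()] whose samples carry `station` and
#'   `water_type` and whose index table has `variable`.
#' @param variable Index column to correlate (e.g. `"tex86"`).
#' @param pool Lipid pool.
#' @param pairing Pairing strategy.
#' @return An `ols_fit` with extra fields `pairing` and `n_stations`.
#' @export
paired_station_correlation <- function(ds, variable = "tex86", pool = "CL",
                                       pairing = c("station-mean",
                                                   "surface-only",
                                                   "per-sample")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(ds, "gdgt_dataset"))
  s <- ds$samples
  if (!all(c("station", "water_type") %in% names(s))) {
    stop("samples need 'station' and 'water_type' columns", call. = FALSE)
  }
  ix <- ds$indices[ds$indices$pool == pool, c("sample_id", variable)]
  dat <- dplyr::inner_join(
    s[c("sample_id", "station", "water_type",
        intersect("depth_m", names(s)))], ix, by = "sample_id")
  dat <- dat[!is.na(dat[[variable]]), ]
  sed <- dat[dat$water_type == "sediment", ]
  spm <- dat[dat$water_type != "sediment", ]
  sed_vals <- stats::setNames(sed[[variable]], sed$station)
  spm_by_station <- split(spm, spm$station)
  pairs <- switch(pairing,
    "station-mean" = dplyr::bind_rows(lapply(spm_by_station, function(g) {
      tibble::tibble(station = g$station[1], spm = mean(g[[variable]]))
    })),
    "surface-only" = dplyr::bind_rows(lapply(spm_by_station, function(g) {
      g <- g[order(g$depth_m), ]
      tibble::tibble(station = g$station[1], spm = g[[variable]][1])
    })),
    "per-sample" = tibble::tibble(station = spm$station,
                                  spm = spm[[variable]]))
  pairs$sediment <- sed_vals[pairs$station]
  pairs <- pairs[!is.na(pairs$sediment), ]
  n_stations <- length(unique(pairs$station))
  if (n_stations < 3) {
    stop("need at least 3 stations with both SPM and sediment values",
         call. = FALSE)
  }
  fit <- ols_regression(pairs$spm, pairs$sediment)
  fit$pairing <- pairing
  fit$n_stations <- n_stations
  fit
}
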