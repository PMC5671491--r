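# Column order fixed throughout the package: GDGT-0..4, crenarchaeol,
# crenarchaeol regioisomer. All abundances are percent of the lipid pool.
gdgt_cols <- c("g0", "g1", "g2", "g3", "g4", "cren", "cren_iso")
br_cols <- c("br_Ia", "br_IIa", "br_IIIa")
pool_levels <- c("CL", "total_IPL", "phospho_IPL")
water_type_levels <- c("river", "mixing", "sea", "sediment")

#' Construct a GDGT fractional-abundance profile
#'
#' A profile holds the percent fractional abundances of the seven isoprenoid
#' GDGTs quantified in one lipid pool of one sample: GDGT-0 through GDGT-4
#' (0-4 cyclopentane rings), crenarchaeol and the crenarchaeol regioisomer.
#' Abundances are stored in percent (0-100); readers can convert
#' fraction-scale input on the way in (see [read_gdgt_table()]).
#'
#' @param g0,g1,g2,g3,g4 Percent abundance of GDGT-0..GDGT-4. Vectorised:
#'   equal-length vectors build a multi-row profile table.
#' @param cren,cren_iso Percent abundance of crenarchaeol and its regioisomer.
#' @param tol Allowed deviation of the row sum from 100 (percent units).
#' @param normalize If `TRUE`, rescale each row to sum to exactly 100 before
#'   validation (so any positive composition is accepted).
#' @return A tibble with class `gdgt_profile` and columns
#'   `g0, g1, g2, g3, g4, cren, cren_iso`.
#' @seealso [normalize_profile()], [compute_indices()]
#' @examples
#' gdgt_profile(g0 = 50, g1 = 10, g2 = 10, g3 = 10, g4 = 5,
#'              cren = 10, cren_iso = 5)
#' @export
gdgt_profile <- function(g0 = 0, g1 = 0, g2 = 0, g3 = 0, g4 = 0,
                         cren = 0, cren_iso = 0, tol = 0.5,
                         normalize = FALSE) {
  p <- tibble::tibble(g0 = as.numeric(g0), g1 = as.numeric(g1),
                      g2 = as.numeric(g2), g3 = as.numeric(g3),
                      g4 = as.numeric(g4), cren = as.numeric(cren),
                      cren_iso = as.numeric(cren_iso))
  class(p) <- c("gdgt_profile", class(p))
  if (normalize) p <- normalize_profile(p)
  validate_profiles(p, tol = tol)
  p
}

#' Coerce a data frame to a validated GDGT profile table
#'
#' @param x A data frame containing the seven GDGT columns (percent).
#' @inheritParams gdgt_profile
#' @return A `gdgt_profile` tibble.
#' @export
as_gdgt_profile <- function(x, tol = 0.5, normalize = FALSE) {
  missing_cols <- setdiff(gdgt_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("missing GDGT column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  p <- tibble::as_tibble(x)[gdgt_cols]
  class(p) <- c("gdgt_profile", class(p))
  if (normalize) p <- normalize_profile(p)
  validate_profiles(p, tol = tol)
  p
}

#' Validate GDGT profile rows
#'
#' Checks that every abundance is non-negative and finite and that each row
#' sums to 100 within `tol` percent. Errors name the offending row and field.
#'
#' @param x A data frame with the seven GDGT columns.
#' @param tol Allowed deviation of the row sum from 100.
#' @return `x`, invisibly.
#' @export
validate_profiles <- function(x, tol = 0.5) {
  m <- as.matrix(as.data.frame(x)[gdgt_cols])
  for (j in seq_along(gdgt_cols)) {
    bad <- which(!is.na(m[, j]) & m[, j] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative abundance in row %d, field '%s'",
                   bad[1], gdgt_cols[j]), call. = FALSE)
    }
  }
  sums <- rowSums(m)
  off <- which(!is.na(sums) & abs(sums - 100) > tol)
  if (length(off) > 0) {
    stop(sprintf(
      "profile row %d sums to %.4g percent (must be within %g of 100); %s",
      off[1], sums[off[1]], tol,
      "use normalize_profile() if the scale is arbitrary"), call. = FALSE)
  }
  invisible(x)
}

#' Rescale profiles to sum to exactly 100 percent
#'
#' Idempotent and scale-invariant: proportions are preserved.
#'
#' @param p A data frame with the seven GDGT columns (any positive scale).
#' @return The rescaled profile table.
#' @export
normalize_profile <- function(p) {
  m <- as.matrix(as.data.frame(p)[gdgt_cols])
  sums <- rowSums(m)
  zero <- which(!is.na(sums) & sums <= 0)
  if (length(zero) > 0) {
    stop(sprintf("profile row %d is all zero; cannot normalize", zero[1]),
         call. = FALSE)
  }
  m <- 100 * m / sums
  out <- tibble::as_tibble(as.data.frame(m))
  extra <- setdiff(names(p), gdgt_cols)
  if (length(extra) > 0) out <- dplyr::bind_cols(tibble::as_tibble(p)[extra], out)
  out <- out[c(extra, gdgt_cols)]
  class(out) <- unique(c("gdgt_profile", class(out)))
  out
}

#' Construct a branched-GDGT profile
#'
#' Holds the three major branched GDGTs (Ia, IIa, IIIa) used by the BIT
#' index. Branched and isoprenoid abundances must be on a common response
#' scale for [bit_index()] to be meaningful; that is the caller's
#' responsibility. 5/6-methyl isomers are out of scope.
#'
#' @param br_Ia,br_IIa,br_IIIa Percent-scale abundances, each >= 0.
#' @return A tibble with class `br_gdgt_profile`.
#' @export
br_gdgt_profile <- function(br_Ia = 0, br_IIa = 0, br_IIIa = 0) {
  b <- tibble::tibble(br_Ia = as.numeric(br_Ia),
                      br_IIa = as.numeric(br_IIa),
                      br_IIIa = as.numeric(br_IIIa))
  m <- as.matrix(b)
  for (j in seq_along(br_cols)) {
    bad <- which(!is.na(m[, j]) & m[, j] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative abundance in row %d, field '%s'",
                   bad[1], br_cols[j]), call. = FALSE)
    }
  }
  class(b) <- c("br_gdgt_profile", class(b))
  b
}
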