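# Proxy indices computed from a single GDGT profile. All functions are
# vectorised over profile rows and return NA_real_ where a denominator is
# zero ("undefined"): field datasets legitimately contain zero crenarchaeol,
# so undefinedness is data, not an error.

.profile_cols <- function(p) {
  x <- as.data.frame(p)
  missing_cols <- setdiff(gdgt_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("not a GDGT profile: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x[gdgt_cols]
}

.safe_ratio <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA_real_)

#' TEX86 tetraether index
#'
#' `(g2 + g3 + cren_iso) / (g1 + g2 + g3 + cren_iso)`, the classic
#' cyclopentyl-GDGT ratio used as a sea-surface-temperature proxy.
#'
#' @param p A GDGT profile table (see [gdgt_profile()]).
#' @return Numeric vector in `[0, 1]`; `NA` where the denominator is zero.
#' @export
tex86 <- function(p) {
  x <- .profile_cols(p)
  num <- x$g2 + x$g3 + x$cren_iso
  .safe_ratio(num, x$g1 + num)
}

#' Ring indices
#'
#' Abundance-weighted mean number of cyclopentane rings per GDGT.
#' `ring_index_1()` is the core-top calibration form, counting crenarchaeol
#' and its regioisomer with weight 4:
#' `(g1 + 2 g2 + 3 g3 + 4 cren + 4 cren_iso) / 100`.
#' `ring_index_2()` replaces crenarchaeol with GDGT-4, removing the
#' thaumarchaeotal biomarker's dominance so the index tracks variation in
#' cyclopentane-bearing GDGTs from other archaea:
#' `(g1 + 2 g2 + 3 g3 + 4 g4 + 4 cren_iso) / 100`.
#'
#' Both presume percent-scale input (the `/100`); normalize first if the
#' scale is arbitrary.
#'
#' @param p A GDGT profile table.
#' @return Numeric vector in ring units, `[0, 4]` for percent input.
#' @export
ring_index_1 <- function(p) {
  x <- .profile_cols(p)
  (x$g1 + 2 * x$g2 + 3 * x$g3 + 4 * x$cren + 4 * x$cren_iso) / 100
}

#' @rdname ring_index_1
#' @export
ring_index_2 <- function(p) {
  x <- .profile_cols(p)
  (x$g1 + 2 * x$g2 + 3 * x$g3 + 4 * x$g4 + 4 * x$cren_iso) / 100
}

#' Methane Index
#'
#' `(g1 + g2 + g3) / (g1 + g2 + g3 + cren + cren_iso)`; values above 0.5
#' indicate input from methanotrophic archaea.
#'
#' @param p A GDGT profile table.
#' @return Numeric vector in `[0, 1]`; `NA` where the denominator is zero.
#' @export
methane_index <- function(p) {
  x <- .profile_cols(p)
  num <- x$g1 + x$g2 + x$g3
  .safe_ratio(num, num + x$cren + x$cren_iso)
}

#' Percent GDGT-2 among ringed TEX86 GDGTs
#'
#' Implemented as `100 * g2 / (g1 + g2 + g3)`. The screening literature
#' states only the threshold (45), not the formula; the denominator choice
#' (crenarchaeol regioisomer excluded) is deliberately isolated here so it
#' can be swapped if a different convention is required.
#'
#' @param p A GDGT profile table.
#' @return Numeric percent in `[0, 100]`; `NA` where `g1 + g2 + g3 = 0`.
#' @export
pct_gdgt2 <- function(p) {
  x <- .profile_cols(p)
  .safe_ratio(100 * x$g2, x$g1 + x$g2 + x$g3)
}

#' Simple abundance ratios used in TEX86 quality screening
#'
#' @param p A GDGT profile table.
#' @return A tibble with columns `ratio_2_3` (GDGT-2/GDGT-3), `ratio_0_cren`
#'   (GDGT-0/crenarchaeol) and `ratio_2_cren` (GDGT-2/crenarchaeol); each
#'   `NA` where its denominator is zero.
#' @export
gdgt_ratios <- function(p) {
  x <- .profile_cols(p)
  tibble::tibble(
    ratio_2_3 = .safe_ratio(x$g2, x$g3),
    ratio_0_cren = .safe_ratio(x$g0, x$cren),
    ratio_2_cren = .safe_ratio(x$g2, x$cren)
  )
}

#' BIT index (branched vs isoprenoid tetraethers)
#'
#' `(Ia + IIa + IIIa) / (Ia + IIa + IIIa + cren)`; high values flag
#' terrestrial/soil GDGT input. Branched and isoprenoid abundances must be
#' on a common response scale.
#'
#' @param p A GDGT profile table (supplies crenarchaeol).
#' @param b A branched-GDGT profile table (see [br_gdgt_profile()]) with the
#'   same number of rows.
#' @return Numeric vector in `[0, 1]`; `NA` where the denominator is zero.
#' @export
bit_index <- function(p, b) {
  x <- .profile_cols(p)
  bb <- as.data.frame(b)
  missing_cols <- setdiff(br_cols, names(bb))
  if (length(missing_cols) > 0) {
    stop("not a branched-GDGT profile: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  br <- bb$br_Ia + bb$br_IIa + bb$br_IIIa
  .safe_ratio(br, br + x$cren)
}

#' Compute the full index set for each profile row
#'
#' Aggregates [tex86()], [ring_index_1()], [ring_index_2()],
#' [methane_index()], [pct_gdgt2()], [gdgt_ratios()] and, when a branched
#' profile is supplied, [bit_index()]. Undefined values propagate as `NA`.
#'
#' @param p A GDGT profile table.
#' @param b Optional branched-GDGT profile table; when omitted the `bit`
#'   column is absent from the result.
#' @return A tibble, one row per profile row, with the index columns.
#' @export
compute_indices <- function(p, b = NULL) {
  out <- tibble::tibble(
    tex86 = tex86(p),
    ri1 = ring_index_1(p),
    ri2 = ring_index_2(p),
    methane_index = methane_index(p),
    pct_gdgt2 = pct_gdgt2(p)
  )
  out <- dplyr::bind_cols(out, gdgt_ratios(p))
  if (!is.null(b)) out$bit <- bit_index(p, b)
  out
}
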