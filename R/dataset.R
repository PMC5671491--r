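# Dataset container: per-sample metadata + gene abundances ("samples"),
# optional long per-(sample, pool) fractional-abundance profiles
# ("profiles") and per-(sample, pool) index values ("indices"). Field
# datasets often carry only index values (profiles unpublished), synthetic
# datasets carry both.

.numeric_sample_cols <- c("depth_m", "conc_cl", "conc_total_ipl",
                          "conc_phospho_ipl", "archaea_16s", "mgii_16s")

#' Assemble a GDGT dataset
#'
#' @param samples Tibble with one row per sample. Recognised columns:
#'   `sample_id` (required, unique), `station`, `water_type` (one of
#'   `river`, `mixing`, `sea`, `sediment`), `depth_m`, `temperature_c`,
#'   `salinity`, `ph`, `conc_cl` / `conc_total_ipl` / `conc_phospho_ipl`
#'   (isoprenoid GDGT concentration, ng/L per pool), `archaea_16s`,
#'   `mgii_16s` (qPCR copies/L). Extra columns are carried along.
#' @param profiles Optional long tibble of fractional abundances:
#'   `sample_id`, `pool` (one of `CL`, `total_IPL`, `phospho_IPL`) plus the
#'   seven GDGT percent columns.
#' @param indices Optional long tibble of pre-computed index values:
#'   `sample_id`, `pool` plus index columns (`tex86`, `ri1`, `ri2`, ...).
#' @param provenance Free-text description of where the data came from.
#' @param tol Row-sum tolerance forwarded to [validate_profiles()].
#' @return A list with class `gdgt_dataset`.
#' @export
gdgt_dataset <- function(samples, profiles = NULL, indices = NULL,
                         provenance = "", tol = 0.5) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) stop("dataset has no records", call. = FALSE)
  if (!"sample_id" %in% names(samples)) {
    stop("samples must have a 'sample_id' column", call. = FALSE)
  }
  if (anyNA(samples$sample_id) || anyDuplicated(samples$sample_id) > 0) {
    stop("sample_id must be present and unique for every record",
         call. = FALSE)
  }
  if ("water_type" %in% names(samples)) {
    bad <- setdiff(unique(stats::na.omit(as.character(samples$water_type))),
                   water_type_levels)
    if (length(bad) > 0) {
      stop("unknown water_type value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    samples$water_type <- factor(samples$water_type,
                                 levels = water_type_levels)
  }
  for (nm in intersect(.numeric_sample_cols, names(samples))) {
    v <- samples[[nm]]
    if (any(!is.na(v) & v < 0)) {
      stop(sprintf("negative value in column '%s' (row %d)", nm,
                   which(!is.na(v) & v < 0)[1]), call. = FALSE)
    }
  }
  check_long <- function(x, what, validate = FALSE) {
    x <- tibble::as_tibble(x)
    if (!all(c("sample_id", "pool") %in% names(x))) {
      stop(what, " must have 'sample_id' and 'pool' columns", call. = FALSE)
    }
    orphan <- setdiff(unique(x$sample_id), samples$sample_id)
    if (length(orphan) > 0) {
      stop(what, " reference unknown sample_id: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    bad_pool <- setdiff(unique(as.character(x$pool)), pool_levels)
    if (length(bad_pool) > 0) {
      stop(what, " has unknown pool(s): ", paste(bad_pool, collapse = ", "),
           call. = FALSE)
    }
    x$pool <- factor(x$pool, levels = pool_levels)
    if (validate) validate_profiles(x, tol = tol)
    x
  }
  if (!is.null(profiles)) profiles <- check_long(profiles, "profiles", validate = TRUE)
  if (!is.null(indices)) indices <- check_long(indices, "indices")
  structure(list(samples = samples, profiles = profiles, indices = indices,
                 provenance = provenance),
            class = "gdgt_dataset")
}

#' @export
print.gdgt_dataset <- function(x, ...) {
  cat("<gdgt_dataset>", nrow(x$samples), "samples")
  if (!is.null(x$samples$water_type)) {
    tab <- table(x$samples$water_type)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        ")", sep = "")
  }
  cat("\n  profiles:",
      if (is.null(x$profiles)) "absent" else paste(nrow(x$profiles), "rows"),
      "| indices:",
      if (is.null(x$indices)) "absent" else paste(nrow(x$indices), "rows"),
      "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Column-mapping schema for tabular input
#'
#' Describes how the columns of a CSV/TSV map onto the dataset fields.
#' Every non-`NULL` mapped column must exist in the file header (a schema
#' error names the missing column otherwise). Cells matching a missing-value
#' token are treated as absent, not zero: absence of a measurement is not a
#' measurement of zero.
#'
#' @param sample_id,station,water_type,depth,temperature,salinity,ph,archaea_16s,mgii_16s
#'   File column names for the metadata fields; `NULL` skips a field
#'   (`sample_id` is mandatory).
#' @param conc Named character vector mapping pools to isoprenoid-GDGT
#'   concentration columns, e.g. `c(CL = "conc_cl")`.
#' @param profiles Named list, one entry per pool, each a named character
#'   vector mapping the seven GDGT fields to file columns, e.g.
#'   `list(CL = c(g0 = "cl_gdgt0", ...))`.
#' @param indices Named list, one entry per pool, mapping index names
#'   (`tex86`, `ri1`, `ri2`, ...) to file columns.
#' @param scale `"percent"` (default) or `"fraction"`; fraction-scale
#'   abundances (0-1) are multiplied by 100 on input.
#' @param missing_tokens Cell values treated as absent.
#' @param tol Profile row-sum tolerance, percent.
#' @return A list with class `gdgt_schema`.
#' @export
gdgt_schema <- function(sample_id = "sample_id", station = NULL,
                        water_type = NULL, depth = NULL, temperature = NULL,
                        salinity = NULL, ph = NULL, archaea_16s = NULL,
                        mgii_16s = NULL, conc = NULL, profiles = NULL,
                        indices = NULL, scale = c("percent", "fraction"),
                        missing_tokens = c("–", "-", "", "NA"),
                        tol = 0.5) {
  scale <- match.arg(scale)
  if (is.null(sample_id)) stop("schema must map 'sample_id'", call. = FALSE)
  bad_pools <- setdiff(c(names(conc), names(profiles), names(indices)),
                       pool_levels)
  if (length(bad_pools) > 0) {
    stop("unknown pool(s) in schema: ", paste(bad_pools, collapse = ", "),
         call. = FALSE)
  }
  structure(list(sample_id = sample_id, station = station,
                 water_type = water_type, depth = depth,
                 temperature = temperature, salinity = salinity, ph = ph,
                 archaea_16s = archaea_16s, mgii_16s = mgii_16s,
                 conc = conc, profiles = profiles, indices = indices,
                 scale = scale, missing_tokens = missing_tokens, tol = tol),
            class = "gdgt_schema")
}

#' Read a GDGT sample table
#'
#' Reads a delimited text file (comma- or tab-separated, chosen from the
#' file extension unless `delim` is given) into a [gdgt_dataset()] using a
#' [gdgt_schema()] column mapping. Scientific notation (`5.7E+08`) is
#' parsed; missing-value tokens map to absent fields.
#'
#' @param path Path to the CSV/TSV file.
#' @param schema A [gdgt_schema()].
#' @param delim Field delimiter override.
#' @return A [gdgt_dataset()].
#' @export
read_gdgt_table <- function(path, schema = gdgt_schema(), delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  want <- function(col, what) {
    if (is.null(col)) return(NULL)
    if (!col %in% names(raw)) {
      stop(sprintf("schema error: column '%s' (%s) not found in %s",
                   col, what, path), call. = FALSE)
    }
    col
  }
  to_num <- function(v) {
    v[v %in% schema$missing_tokens] <- NA_character_
    suppressWarnings(as.numeric(v))
  }
  to_chr <- function(v) {
    v[v %in% schema$missing_tokens] <- NA_character_
    v
  }
  samples <- tibble::tibble(
    sample_id = to_chr(raw[[want(schema$sample_id, "sample_id")]]))
  chr_fields <- c(station = "station", water_type = "water_type")
  num_fields <- c(depth = "depth_m", temperature = "temperature_c",
                  salinity = "salinity", ph = "ph",
                  archaea_16s = "archaea_16s", mgii_16s = "mgii_16s")
  for (f in names(chr_fields)) {
    col <- want(schema[[f]], f)
    if (!is.null(col)) samples[[chr_fields[[f]]]] <- to_chr(raw[[col]])
  }
  for (f in names(num_fields)) {
    col <- want(schema[[f]], f)
    if (!is.null(col)) samples[[num_fields[[f]]]] <- to_num(raw[[col]])
  }
  for (pool in names(schema$conc)) {
    col <- want(schema$conc[[pool]], paste0("conc ", pool))
    samples[[paste0("conc_", tolower(sub("_IPL", "_ipl", pool)))]] <-
      to_num(raw[[col]])
  }
  scale_f <- if (schema$scale == "fraction") 100 else 1
  profiles <- NULL
  if (!is.null(schema$profiles)) {
    profiles <- dplyr::bind_rows(lapply(names(schema$profiles), function(pool) {
      mp <- schema$profiles[[pool]]
      missing_g <- setdiff(gdgt_cols, names(mp))
      if (length(missing_g) > 0) {
        stop(sprintf("schema error: pool %s profile mapping lacks %s", pool,
                     paste(missing_g, collapse = ", ")), call. = FALSE)
      }
      out <- tibble::tibble(sample_id = samples$sample_id, pool = pool)
      for (g in gdgt_cols) {
        out[[g]] <- scale_f * to_num(raw[[want(mp[[g]], paste(pool, g))]])
      }
      # drop rows where the whole profile is absent
      out[rowSums(!is.na(as.matrix(out[gdgt_cols]))) > 0, ]
    }))
  }
  indices <- NULL
  if (!is.null(schema$indices)) {
    indices <- dplyr::bind_rows(lapply(names(schema$indices), function(pool) {
      mp <- schema$indices[[pool]]
      out <- tibble::tibble(sample_id = samples$sample_id, pool = pool)
      for (ix in names(mp)) {
        out[[ix]] <- to_num(raw[[want(mp[[ix]], paste(pool, ix))]])
      }
      out
    }))
  }
  gdgt_dataset(samples, profiles = profiles, indices = indices,
               provenance = path, tol = schema$tol)
}

#' Load the packaged Pearl River transect dataset
#'
#' A transcription of the published estuarine-transect table: 26 samples
#' (18 suspended-particulate-matter, 8 surface sediments) along the salinity
#' gradient from the lower Pearl River through its estuary to the coastal
#' South China Sea, with per-pool TEX86 and RI_2 values, isoprenoid GDGT
#' concentrations, station metadata, and archaeal / MG-II Euryarchaeota 16S
#' rRNA gene abundances for the 12 SPM samples of stations R1, M and S.
#' Fractional abundances were not published, so this dataset carries index
#' values only (no profiles).
#'
#' @return A [gdgt_dataset()].
#' @examples
#' ds <- load_table1_fixture()
#' table(ds$samples$water_type)
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "pearl_river_table1.csv",
                      package = "gdgtproxy", mustWork = TRUE)
  schema <- gdgt_schema(
    sample_id = "sample_id", station = "station", water_type = "water_type",
    depth = "depth_m", temperature = "temperature_c", salinity = "salinity",
    ph = "ph", archaea_16s = "archaea_16s", mgii_16s = "mgii_16s",
    conc = c(CL = "conc_cl", total_IPL = "conc_total_ipl",
             phospho_IPL = "conc_phospho_ipl"),
    indices = list(
      CL = c(tex86 = "tex86_cl", ri2 = "ri2_cl"),
      total_IPL = c(tex86 = "tex86_total_ipl", ri2 = "ri2_total_ipl"),
      phospho_IPL = c(tex86 = "tex86_phospho_ipl", ri2 = "ri2_phospho_ipl")))
  ds <- read_gdgt_table(path, schema)
  ds$provenance <- "packaged Pearl River estuary transect table"
  ds
}

#' Fill the index table of a dataset from its profiles
#'
#' Computes the full index set (see [compute_indices()]) for every
#' (sample, pool) profile row and stores it in `ds$indices`.
#'
#' @param ds A [gdgt_dataset()] with profiles.
#' @return The dataset with `indices` replaced by the computed values.
#' @export
compute_dataset_indices <- function(ds) {
  stopifnot(inherits(ds, "gdgt_dataset"))
  if (is.null(ds$profiles)) {
    stop("dataset has no profiles to compute indices from", call. = FALSE)
  }
  ix <- compute_indices(ds$profiles)
  ds$indices <- dplyr::bind_cols(
    ds$profiles[c("sample_id", "pool")], ix)
  ds
}

#' Write per-(sample, pool) results to a flat TSV
#'
#' One row per (sample, pool); sample metadata (`station`, `water_type`)
#' is joined in. Numeric output is full-precision, C-locale decimal-point
#' TSV, so a write/read cycle is lossless well beyond 6 significant digits.
#'
#' @param ds The source [gdgt_dataset()] (consistency check for ids).
#' @param results Tibble keyed by `sample_id` and `pool` carrying any index,
#'   delta-RI and flag columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(ds, results, path) {
  stopifnot(inherits(ds, "gdgt_dataset"))
  results <- tibble::as_tibble(results)
  if (!all(c("sample_id", "pool") %in% names(results))) {
    stop("results must be keyed by sample_id and pool", call. = FALSE)
  }
  orphan <- setdiff(unique(results$sample_id), ds$samples$sample_id)
  if (length(orphan) > 0) {
    stop("results reference unknown sample_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  meta_cols <- intersect(c("sample_id", "station", "water_type"),
                         names(ds$samples))
  out <- dplyr::left_join(results, ds$samples[meta_cols], by = "sample_id")
  out <- out[c(meta_cols, setdiff(names(results), "sample_id"))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
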