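#' Construct and validate a feature table
#'
#' A feature table is the package's central container: an integer matrix of
#' read counts with samples as rows and features (sOTUs, i.e. exact-sequence
#' denoised tags) as columns. Row and column names are the sample and feature
#' identifiers and must be unique; counts must be non-negative integers.
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows. A data.frame is coerced.
#' @param sample_ids,feature_ids optional identifier vectors overriding the
#'   dimnames of `counts`.
#' @return an integer matrix of class `feature_table`.
#' @export
feature_table <- function(counts, sample_ids = NULL, feature_ids = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop("`counts` must be a matrix or data.frame")
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(feature_ids)) colnames(counts) <- feature_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("feature table needs sample (row) and feature (column) identifiers")
  storage.mode(counts) <- "double"
  validate_feature_table(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Validate feature-table invariants
#'
#' Checks that counts are non-negative integers and that sample and feature
#' identifiers are unique; errors name the offending cell or identifier.
#'
#' @param x matrix-like feature table, samples in rows.
#' @return `x`, invisibly, if valid.
#' @export
validate_feature_table <- function(x) {
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing count at sample '%s', feature '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  if (any(x < 0) || any(x != floor(x))) {
    bad <- which(x < 0 | x != floor(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("negative or non-integer count %g at sample '%s', feature '%s'",
                 x[bad[1L], bad[2L]], rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop(sprintf("duplicate sample identifier '%s'", dup[1L]))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop(sprintf("duplicate feature identifier '%s'", dup[1L]))
  invisible(x)
}

#' Read a feature table from a tab-delimited file
#'
#' The file must have one header row and one identifier column. Both
#' orientations occur in the wild; the orientation is always stated
#' explicitly by the caller — silent transposition is a classic microbiome
#' bug, so there is no autodetection.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples"` if rows are samples (the package's internal
#'   convention) or `"features"` if rows are features (the common BIOM/QIIME
#'   text export layout).
#' @return a [feature_table()] with samples as rows.
#' @export
read_feature_table <- function(path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("non-numeric cells in feature table ", path)
  if (orientation == "features") m <- t(m)
  feature_table(m)
}

#' Write a feature table to a tab-delimited file
#'
#' @param table a [feature_table()] (samples in rows).
#' @param path output path.
#' @param orientation row orientation for the file, as in
#'   [read_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  if (orientation == "features") m <- t(m)
  id_col <- if (orientation == "samples") "sample_id" else "feature_id"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a feature table as dense BIOM-style JSON
#'
#' Writes a minimal dense BIOM v1 (JSON) document, interoperable with
#' biom-format readers, for tables small enough that density is harmless.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom_json <- function(table, path) {
  m <- unclass(table)
  doc <- list(
    id = "feature-table",
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = "mucodiv",
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    matrix_type = "dense",
    matrix_element_type = "int",
    shape = c(ncol(m), nrow(m)),
    rows = lapply(colnames(m), function(f) list(id = f, metadata = NULL)),
    columns = lapply(rownames(m), function(s) list(id = s, metadata = NULL)),
    data = lapply(seq_len(ncol(m)), function(j) as.integer(m[, j]))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

# --- sample metadata ---------------------------------------------------------

.sample_types <- c("gill", "skin", "digesta", "GI", "pyloric_ceca",
                   "seawater", "sediment", "control")
.fish_sites <- c("gill", "skin", "digesta", "GI", "pyloric_ceca")

#' Closed vocabulary of sample types
#'
#' Five fish mucosal body sites, the two environmental reference types, and
#' extraction controls.
#'
#' @return character vector of the valid `sample_type` values.
#' @export
sample_types <- function() .sample_types

#' Fish body-site sample types
#'
#' @return character vector of the five mucosal body sites.
#' @export
fish_body_sites <- function() .fish_sites

#' Read a sample-metadata table
#'
#' Expects a TSV with at least `sample_id` and `sample_type` columns.
#' Recognised columns: `event_index` (integer chronological sampling-event
#' key, the authoritative ordering — not the date), `collection_date`
#' (ISO-8601), the environmental covariates `temperature` (deg C),
#' `salinity` (PSU), `pressure` (dbar), `chlorophyll_a` (ug/liter), and the
#' fish biometrics `fork_length_mm` and `mass_kg`. Missing covariates are NA,
#' never 0; downstream models declare their complete-case policy.
#'
#' @param path path to a TSV file.
#' @return a data.frame, one row per sample, rownames set to `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_metadata(md)
}

#' Validate sample metadata
#'
#' Enforces the closed sample-type vocabulary, unique sample identifiers,
#' parseable ISO-8601 dates, and the rule that biometric fields are present
#' only for fish body-site samples.
#'
#' @param md data.frame with at least `sample_id` and `sample_type`.
#' @return the validated data.frame with rownames set to `sample_id`.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "sample_type")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup)) stop(sprintf("duplicate sample identifier '%s'", dup[1L]))
  bad <- setdiff(unique(md$sample_type), .sample_types)
  if (length(bad))
    stop(sprintf("unknown sample_type '%s'; must be one of {%s}", bad[1L],
                 paste(.sample_types, collapse = ", ")))
  if ("collection_date" %in% names(md) && !inherits(md$collection_date, "Date")) {
    parsed <- as.Date(as.character(md$collection_date), format = "%Y-%m-%d")
    if (any(is.na(parsed) & !is.na(md$collection_date)))
      stop("collection_date must be ISO-8601 (YYYY-MM-DD)")
    md$collection_date <- parsed
  }
  for (col in c("fork_length_mm", "mass_kg")) {
    if (col %in% names(md)) {
      stray <- !is.na(md[[col]]) & !(md$sample_type %in% .fish_sites)
      if (any(stray))
        stop(sprintf("biometric '%s' set on non-fish sample '%s'", col,
                     md$sample_id[which(stray)[1L]]))
    }
  }
  rownames(md) <- md$sample_id
  md
}

#' Write sample metadata
#'
#' @param md data.frame of sample metadata.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
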