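#' @name plate_io
#' @title Plate-format table input/output
#'
#' @description
#' Readers and writers for plate-reader exports and plate maps. Tables are
#' plain CSV/TSV; wells are identified by row letter(s) plus column number
#' and are normalized to a canonical zero-padded form (`"A1"` becomes
#' `"A01"`). Rows are lettered `A`..`Z`, `AA`..`AF` top to bottom; columns
#' are 1-based left to right, matching common plate-reader exports.
NULL

# Known measurement channels; anything else in a long-format `channel`
# column is rejected.
.CHANNELS <- c("L460", "F535", "venus_fi", "F620", "F665",
               "viability_signal", "confluence_pct")

.MAP_ROLES <- c("ppi", "ctrl_donor_only", "ctrl_acceptor_only",
                "compound", "dmso", "blank", "positive")

.CONDITIONS <- c("minus_pbmc", "plus_pbmc", "cancer_alone", "coculture")

.plate_dims <- function(geometry) {
  switch(as.character(geometry),
    "96"   = c(rows = 8L,  cols = 12L),
    "384"  = c(rows = 16L, cols = 24L),
    "1536" = c(rows = 32L, cols = 48L),
    .err("os_layout_error", "unsupported plate geometry: ", geometry)
  )
}

# Row letters for the first n rows: A..Z then AA..AF.
.row_letters <- function(n) c(LETTERS, paste0("A", LETTERS))[seq_len(n)]

.row_index <- function(r) {
  ifelse(nchar(r) == 1L, match(r, LETTERS),
         26L + match(substr(r, 2L, 2L), LETTERS))
}

#' Normalize well identifiers to canonical zero-padded form
#'
#' @param well character vector of well IDs such as `"A1"`, `"a01"`, `"AF48"`.
#' @return character vector of canonical IDs (`"A01"`, `"AF48"`).
#'   Normalization is idempotent.
#' @examples
#' normalize_well(c("A1", "b12", "AF48"))
#' @export
normalize_well <- function(well) {
  w <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-Z]{1,2}0*[0-9]+$", w)
  if (any(!ok)) {
    .err("os_layout_error", "malformed well ID(s): ",
         paste(unique(w[!ok]), collapse = ", "))
  }
  row <- sub("^([A-Z]{1,2})0*[0-9]+$", "\\1", w)
  col <- as.integer(sub("^[A-Z]{1,2}0*([0-9]+)$", "\\1", w))
  sprintf("%s%02d", row, col)
}

#' Validate well identifiers against a plate geometry
#'
#' @param well character vector of well IDs (any zero-padding).
#' @param geometry plate size: 96, 384 or 1536.
#' @return invisibly, the normalized well IDs; errors (class
#'   `os_layout_error`) if any well falls outside the geometry.
#' @export
validate_wells <- function(well, geometry) {
  dims <- .plate_dims(geometry)
  w <- normalize_well(well)
  row <- sub("^([A-Z]{1,2})[0-9]+$", "\\1", w)
  col <- as.integer(sub("^[A-Z]{1,2}([0-9]+)$", "\\1", w))
  ri <- .row_index(row)
  bad <- is.na(ri) | ri < 1L | ri > dims[["rows"]] |
    col < 1L | col > dims[["cols"]]
  if (any(bad)) {
    .err("os_layout_error", "well(s) outside ", geometry, "-well geometry: ",
         paste(unique(w[bad]), collapse = ", "))
  }
  invisible(w)
}

#' Build canonical well IDs from plate coordinates
#'
#' @param row,col 1-based row and column indices.
#' @return canonical well ID, e.g. `well_id(1, 1)` is `"A01"`.
#' @export
well_id <- function(row, col) {
  sprintf("%s%02d", .row_letters(max(row))[row], as.integer(col))
}

.sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    .err("os_format_error", what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read a plate-reader measurement table
#'
#' Accepts either a wide dialect (one row per well, one column per channel)
#' or a long dialect (one row per well per channel, with `channel`/`value`
#' columns). Known channels: `L460`, `F535`, `venus_fi`, `F620`, `F665`,
#' `viability_signal`, `confluence_pct`. Raw intensities must be
#' nonnegative and finite; negative signal values (e.g. net BRET) only arise
#' downstream of the raw channels.
#'
#' @param path CSV or TSV file; the separator is inferred from the extension
#'   unless `sep` is given.
#' @param geometry plate size: 96, 384 or 1536.
#' @param format `"wide"` (default) or `"long"`.
#' @param sep field separator override.
#' @return data.frame of well measurements with normalized well IDs and one
#'   column per populated channel.
#' @export
read_plate_table <- function(path, geometry = 384, format = c("wide", "long"),
                             sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .err("os_io_error", "file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path, sep),
                          stringsAsFactors = FALSE, check.names = FALSE)
  .require_columns(df, c("plate_id", "well"), "plate table")
  if (format == "long") {
    .require_columns(df, c("channel", "value"), "long-format plate table")
    unknown <- setdiff(unique(df$channel), .CHANNELS)
    if (length(unknown)) {
      .err("os_format_error", "unknown channel(s): ",
           paste(unknown, collapse = ", "))
    }
    df$well <- validate_wells(df$well, geometry)
    out <- unique(df[c("plate_id", "well")])
    key <- paste(out$plate_id, out$well)
    for (ch in intersect(.CHANNELS, unique(df$channel))) {
      sub <- df[df$channel == ch, ]
      out[[ch]] <- sub$value[match(key, paste(sub$plate_id, sub$well))]
    }
    df <- out
  } else {
    present <- intersect(.CHANNELS, names(df))
    if (!length(present)) {
      .err("os_format_error",
           "plate table has no recognized channel column; expected one of: ",
           paste(.CHANNELS, collapse = ", "))
    }
    df$well <- validate_wells(df$well, geometry)
    df <- df[c("plate_id", "well", present)]
  }
  chan <- intersect(.CHANNELS, names(df))
  vals <- as.matrix(df[chan])
  if (any(!is.finite(vals) & !is.na(vals))) {
    .err("os_value_error", "non-finite intensity values in plate table")
  }
  if (any(vals < 0, na.rm = TRUE)) {
    .err("os_value_error", "negative raw intensity values in plate table")
  }
  if (any(rowSums(!is.na(vals)) == 0)) {
    .err("os_value_error", "well(s) with no populated channel")
  }
  rownames(df) <- NULL
  df
}

#' Read and validate a plate map
#'
#' A plate map assigns each well a `role` (`ppi`, `ctrl_donor_only`,
#' `ctrl_acceptor_only`, `compound`, `dmso`, `blank`, `positive`), the
#' construct or compound it carries, an optional culture `condition`
#' (`minus_pbmc`, `plus_pbmc`, `cancer_alone`, `coculture`), a replicate
#' index, and an optional molar `dose`.
#'
#' @inheritParams read_plate_table
#' @return validated plate-map data.frame with normalized well IDs.
#' @export
read_plate_map <- function(path, geometry = 384, sep = NULL) {
  if (!file.exists(path)) .err("os_io_error", "file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path, sep),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if ("compound" %in% names(df) && !"construct" %in% names(df)) {
    names(df)[names(df) == "compound"] <- "construct"
  }
  .require_columns(df, c("plate_id", "well", "role", "construct", "replicate"),
                   "plate map")
  df$well <- validate_wells(df$well, geometry)
  validate_plate_map(df)
  df
}

#' Validate an in-memory plate map
#'
#' @param map plate-map data.frame (`plate_id`, `well`, `role`, `construct`,
#'   `replicate`, optional `condition` and `dose`).
#' @return invisibly, `map`.
#' @export
validate_plate_map <- function(map) {
  .require_columns(map, c("plate_id", "well", "role", "construct", "replicate"),
                   "plate map")
  bad_role <- setdiff(unique(map$role), .MAP_ROLES)
  if (length(bad_role)) {
    .err("os_format_error", "unknown plate-map role(s): ",
         paste(bad_role, collapse = ", "))
  }
  if ("condition" %in% names(map)) {
    bad_cond <- setdiff(unique(map$condition[!is.na(map$condition)]),
                        .CONDITIONS)
    if (length(bad_cond)) {
      .err("os_format_error", "unknown condition(s): ",
           paste(bad_cond, collapse = ", "))
    }
  }
  key <- paste(map$plate_id, map$well)
  if (anyDuplicated(key)) {
    .err("os_layout_error", "duplicate (plate_id, well) in plate map: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(!is.finite(map$replicate) | map$replicate < 1)) {
    .err("os_format_error", "replicate must be a positive integer")
  }
  invisible(map)
}

#' Annotate measurements with their plate-map assignments
#'
#' @param measurements data.frame from [read_plate_table()] (or compatible).
#' @param map plate map data.frame.
#' @return data.frame with the map's `role`, `construct`, `condition`,
#'   `replicate` and `dose` columns joined on. An empty measurement table
#'   returns an empty annotated table. Measurements whose (plate_id, well)
#'   is absent from the map raise an `os_join_error` naming the wells.
#' @export
join_plate_map <- function(measurements, map) {
  validate_plate_map(map)
  add <- intersect(c("role", "construct", "condition", "replicate", "dose"),
                   names(map))
  if (nrow(measurements) == 0L) {
    for (col in add) measurements[[col]] <- map[[col]][0]
    return(measurements)
  }
  mkey <- paste(map$plate_id, map$well)
  key <- paste(measurements$plate_id, measurements$well)
  idx <- match(key, mkey)
  if (anyNA(idx)) {
    .err("os_join_error", "well(s) not present in plate map: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  for (col in add) measurements[[col]] <- map[[col]][idx]
  measurements
}

#' Write a results table as delimited text
#'
#' Numeric columns are serialized at full double precision (`%.17g`) so a
#' write/read round trip is lossless, and output is byte-identical for
#' identical input.
#'
#' @param table data.frame to write.
#' @param path output file; separator inferred from extension unless `sep`
#'   is given.
#' @param sep field separator override.
#' @param allow_empty write a header-only file for an empty table instead of
#'   raising an error.
#' @return invisibly, `path`.
#' @export
write_results <- function(table, path, sep = NULL, allow_empty = FALSE) {
  if (nrow(table) == 0L && !allow_empty) {
    .err("os_value_error", "refusing to write empty results table ",
         "(set allow_empty = TRUE to override)")
  }
  out <- table
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "NA"
      out[[col]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = .sep_for(path, sep), quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) .err("os_io_error", "cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value file declaring, e.g., `format` (wide/long), `geometry`,
#' channel column names, and analysis cutoffs. Unknown keys are preserved.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_plate_config <- function(path) {
  if (!file.exists(path)) .err("os_io_error", "file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .err("os_config_error",
                                           "cannot parse config: ",
                                           conditionMessage(e)))
  if (!is.null(cfg$geometry)) .plate_dims(cfg$geometry)
  if (!is.null(cfg$format) && !cfg$format %in% c("wide", "long")) {
    .err("os_config_error", "format must be 'wide' or 'long'")
  }
  cfg
}
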