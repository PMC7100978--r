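#' Measurement tables
#'
#' A measurement table holds one record per segmented nucleus: an integer
#' `cell_id`, the centroid position `x`, `y` (0-based pixel coordinates,
#' x = column, y = row, origin top-left), one raw mean-intensity column per
#' fluorescence channel (named `ch0`, `ch1`, ...), and optionally
#' background-corrected intensities (`ch<k>_corrected`), an annotated gene
#' `dosage` in \{0, 1, 2\}, its `confidence` in \[0, 1\], and a logical
#' `border` flag marking clone-border cells. Unset optional fields are `NA`.
#'
#' Tables produced by any external segmentation tool are accepted as long as
#' the mandatory columns are present; extra columns are carried through
#' untouched.
#'
#' @param df A data.frame with at least `cell_id`, `x`, `y` and one channel
#'   column `ch<k>`.
#' @return A validated `measurement_table` (a data.frame subclass).
#' @export
measurement_table <- function(df) {
  df <- as.data.frame(df)
  required <- c("cell_id", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    qm_stop(sprintf("missing mandatory column(s): %s",
                    paste(missing, collapse = ", ")),
            "qmosaic_schema_error")
  }
  if (length(raw_channels(df)) == 0) {
    qm_stop("missing mandatory column(s): at least one channel column 'ch<k>'",
            "qmosaic_schema_error")
  }
  dup <- unique(df$cell_id[duplicated(df$cell_id)])
  if (length(dup) > 0) {
    qm_stop(sprintf("duplicate cell_id: %s",
                    paste(dup, collapse = ", ")),
            "qmosaic_integrity_error")
  }
  for (ch in raw_channels(df)) {
    v <- df[[ch]]
    if (any(!is.na(v) & v < 0)) {
      qm_stop(sprintf("negative raw intensity in column %s", ch),
              "qmosaic_integrity_error")
    }
  }
  if ("confidence" %in% names(df)) {
    v <- df$confidence
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      qm_stop("confidence outside [0, 1]", "qmosaic_integrity_error")
    }
  }
  if ("dosage" %in% names(df)) df$dosage <- as.integer(df$dosage)
  df$cell_id <- as.integer(df$cell_id)
  class(df) <- unique(c("measurement_table", class(df)))
  df
}

#' Names of the raw channel columns of a measurement table
#'
#' @param table A measurement table (or plain data.frame).
#' @return Character vector of raw channel column names (`ch0`, `ch1`, ...),
#'   in ascending channel order.
#' @export
raw_channels <- function(table) {
  nm <- grep("^ch[0-9]+$", names(table), value = TRUE)
  nm[order(as.integer(sub("^ch", "", nm)))]
}

corrected_name <- function(channel) paste0(channel, "_corrected")

# Preferred intensity column for analysis: corrected if present, else raw.
intensity_column <- function(table, channel) {
  cc <- corrected_name(channel)
  if (cc %in% names(table)) cc else channel
}

#' Read a measurement table from delimited text
#'
#' Files are comma-separated with a header, `.` decimal separator, UTF-8
#' encoding, and empty fields for unset optional values.
#'
#' @param path Path to a CSV file with at least the columns `cell_id`, `x`,
#'   `y` and one channel column.
#' @return A `measurement_table`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    qm_stop(sprintf("no such file: %s", path), "qmosaic_io_error")
  }
  df <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  if ("border" %in% names(df)) df$border <- as.logical(df$border)
  measurement_table(df)
}

#' Write a measurement table to delimited text
#'
#' Output is re-readable by [read_measurements()] with field-by-field
#' identity, and byte-identical for identical input.
#'
#' @param table A `measurement_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  table <- measurement_table(table)
  ok <- tryCatch({
    write.csv(table, path, row.names = FALSE, na = "", quote = FALSE,
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    qm_stop(sprintf("cannot write: %s", path), "qmosaic_io_error")
  }
  invisible(path)
}

#' Per-layer metadata
#'
#' Each image layer is described by a plain-text (YAML) metadata file
#' recording the disc and layer identifiers, the role of every channel
#' (exactly one `clonal_marker`, one `nuclear_stain`, any number of
#' `reporter`), an optional image path, an optional region-of-interest
#' polygon, and any model coefficients written by the correction or
#' annotation stages.
#'
#' @param disc_id,layer_id Identifiers.
#' @param channel_roles Named character vector or list mapping channel names
#'   (`ch0`, ...) to roles in `c("nuclear_stain", "clonal_marker",
#'   "reporter")`.
#' @param image_path Optional path of the source image.
#' @param roi Optional two-column matrix of polygon vertices (x, y); must be
#'   a simple (non-self-intersecting) polygon.
#' @return A `layer_record` list.
#' @export
layer_record <- function(disc_id, layer_id, channel_roles,
                         image_path = NULL, roi = NULL) {
  channel_roles <- unlist(channel_roles)
  if (sum(channel_roles == "clonal_marker") != 1) {
    qm_stop("exactly one channel must be designated clonal_marker",
            "qmosaic_schema_error")
  }
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (!polygon_is_simple(roi)) {
      qm_stop("roi polygon is self-intersecting", "qmosaic_geometry_error")
    }
  }
  structure(list(disc_id = disc_id, layer_id = layer_id,
                 channel_roles = as.list(channel_roles),
                 image_path = image_path, roi = roi),
            class = "layer_record")
}

#' @rdname layer_record
#' @param record A `layer_record`.
#' @param path Metadata file path (YAML).
#' @export
write_layer_metadata <- function(record, path) {
  x <- unclass(record)
  if (!is.null(x$roi)) {
    x$roi <- lapply(seq_len(nrow(x$roi)),
                    function(i) as.numeric(x$roi[i, 1:2]))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname layer_record
#' @export
read_layer_metadata <- function(path) {
  x <- yaml::read_yaml(path)
  roi <- if (!is.null(x$roi)) do.call(rbind, lapply(x$roi, as.numeric))
  rec <- layer_record(x$disc_id, x$layer_id, x$channel_roles,
                      image_path = x$image_path, roi = roi)
  extra <- setdiff(names(x), names(rec))
  rec[extra] <- x[extra]
  rec
}
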