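#' Write an image as plain text with a JSON sidecar
#'
#' Images are stored as uncompressed comma-separated matrices alongside a
#' `<path>.json` sidecar holding the pixel size (and any extra metadata),
#' so that all artifacts remain text and a read-back image carries its
#' physical calibration. Writes are atomic (temp file + rename).
#'
#' @param image an `exm_image`.
#' @param path output path (conventionally `.csv`).
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_txt <- function(image, path, metadata = list()) {
  ps <- pixel_size(image)
  tmp <- paste0(path, ".tmp")
  utils::write.table(unclass(image), tmp, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  file.rename(tmp, path)
  side <- c(list(pixel_size_nm = ps, nrow = nrow(image), ncol = ncol(image)),
            metadata)
  write_report(side, paste0(path, ".json"))
  invisible(path)
}

#' Read an image written by [write_image_txt()]
#'
#' @param path path to the text matrix; `<path>.json` must exist (or
#'   `pixel_size_nm` must be given, which overrides the sidecar with a
#'   warning).
#' @param pixel_size_nm optional explicit pixel size in nm.
#' @return an `exm_image`.
#' @export
read_image_txt <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  side_path <- paste0(path, ".json")
  side_ps <- NULL
  if (file.exists(side_path)) {
    side_ps <- jsonlite::read_json(side_path)$pixel_size_nm
  }
  if (is.null(pixel_size_nm)) {
    if (is.null(side_ps)) {
      stop("no pixel size available for ", path,
           " (missing sidecar and no pixel_size_nm argument)")
    }
    pixel_size_nm <- side_ps
  } else if (!is.null(side_ps) && !isTRUE(all.equal(side_ps, pixel_size_nm))) {
    warning("pixel_size_nm argument overrides sidecar value (",
            side_ps, " nm)")
  }
  exm_image(m, as.numeric(pixel_size_nm))
}

#' Atomic CSV writer for result tables
#'
#' @param records a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(records, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Atomic JSON report writer
#'
#' Every pipeline command funnels its numeric outputs, parameters and seed
#' through this writer so results stay reproducible from the report alone.
#'
#' @param x a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' @param path JSON file of parameters; returned as a plain named list.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
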