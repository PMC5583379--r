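# Map serialization. NIfTI carries pixel spacing in its header; CSV grids
# always need the JSON sidecar. Every write emits a sidecar with the map
# kind, units and grid so areas in mm^2 are never inferred.

sidecar_path <- function(path) paste0(path, ".json")

file_ext2 <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) "nii.gz" else tolower(tools::file_ext(path))
}

write_sidecar <- function(path, grid, kind) {
  meta <- list(kind = kind, units = unname(map_units[[kind]]),
               n_x = grid$n_x, n_y = grid$n_y,
               fov_mm = grid$fov_mm, pixel_mm = grid$pixel_mm)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a typed map to disk
#'
#' Supported formats: NIfTI (`.nii` / `.nii.gz`, float64, pixel spacing in
#' the header) and plain-text CSV. A JSON sidecar `<path>.json` carrying the
#' map kind, units and grid geometry is always written alongside.
#'
#' @param map An [ep_map()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  grid <- map_grid(map)
  kind <- map_kind(map)
  ext <- file_ext2(path)
  if (ext %in% c("nii", "nii.gz")) {
    data <- map_data(map)
    attr(data, "pixdim") <- c(grid$pixel_mm, grid$pixel_mm)
    RNifti::writeNifti(RNifti::asNifti(data), path, datatype = "double")
  } else if (ext == "csv") {
    lines <- apply(map_data(map), 1L, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(lines, path)
  } else {
    stop(sprintf("write_map: unsupported format '.%s' (use .nii, .nii.gz or .csv)", ext))
  }
  write_sidecar(path, grid, kind)
  invisible(path)
}

#' Read a typed map from disk
#'
#' Reads NIfTI or CSV maps written by [write_map()] (or by other tools, if a
#' JSON sidecar supplies the grid geometry). Pixel spacing comes from the
#' sidecar when present, otherwise from the NIfTI header; CSV without a
#' sidecar is refused, since mm^2 areas are the pipeline's endpoint and must
#' never rest on a guessed pixel size. Maps containing NaNs are rejected with
#' the offending pixel indices.
#'
#' @param path Input path.
#' @param expected_kind If given, the sidecar's kind tag must match.
#' @return An [ep_map()].
#' @export
read_map <- function(path, expected_kind = NULL) {
  if (!file.exists(path)) stop("read_map: no such file: ", path)
  ext <- file_ext2(path)
  meta <- read_sidecar(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    data <- matrix(as.numeric(img), dim(img)[1L], dim(img)[2L])
    px <- RNifti::pixdim(img)[1L]
    if (!is.null(meta)) px <- meta$pixel_mm
    if (!is.finite(px) || px <= 0)
      stop("read_map: missing or invalid pixel-size metadata")
    grid <- grid_spec(ncol(data), nrow(data), fov_mm = px * ncol(data))
  } else if (ext == "csv") {
    if (is.null(meta))
      stop("read_map: CSV maps require a JSON sidecar with grid metadata (", sidecar_path(path), ")")
    rows <- strsplit(readLines(path), ",", fixed = TRUE)
    # non-numeric tokens become NA here and are reported by the NaN check
    data <- do.call(rbind, lapply(rows, function(r) suppressWarnings(as.numeric(r))))
    grid <- grid_spec(meta$n_x, meta$n_y, fov_mm = meta$fov_mm)
  } else {
    stop(sprintf("read_map: unknown format '.%s'", ext))
  }
  if (anyNA(data)) {
    bad <- which(is.na(data), arr.ind = TRUE)
    show <- utils::head(bad, 10L)
    stop("read_map: map contains NaN pixels at (row, col): ",
         paste(sprintf("(%d, %d)", show[, 1], show[, 2]), collapse = " "),
         if (nrow(bad) > 10L) sprintf(" ... and %d more", nrow(bad) - 10L) else "")
  }
  kind <- if (!is.null(meta)) meta$kind else NULL
  if (!is.null(expected_kind)) {
    if (is.null(kind))
      stop("read_map: no kind metadata found but expected_kind = '", expected_kind, "'")
    if (!identical(kind, expected_kind))
      stop(sprintf("read_map: map is tagged '%s' but '%s' was expected", kind, expected_kind))
  }
  ep_map(data, grid, kind %||% expected_kind %||% "mask")
}
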