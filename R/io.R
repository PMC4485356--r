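# NIfTI + JSON sidecar + CSV readers/writers for every pipeline artifact.
# Images are written as uncompressed .nii so identical inputs give
# byte-identical files (the manifest checksums rely on this).

protocol_to_list <- function(p) unclass(p)

protocol_from_list <- function(l) {
  acquisition_protocol(tr = l$tr, te_list = unlist(l$te_list),
                       mt_offset_hz = l$mt_offset_hz,
                       matrix_size = unlist(l$matrix_size),
                       slice_thickness = l$slice_thickness,
                       pixel_spacing = l$pixel_spacing)
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Write / read a phantom (label map NIfTI + JSON sidecar)
#'
#' @param phantom a `tissue_phantom`.
#' @param dir output directory (created if missing).
#' @return `write_phantom()` the file paths invisibly; `read_phantom()` the
#'   phantom.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab_path <- file.path(dir, "label_map.nii")
  side_path <- file.path(dir, "phantom.json")
  RNifti::writeNifti(phantom$labels, lab_path, datatype = "int16")
  write_json_sidecar(list(pixel_spacing = phantom$pixel_spacing,
                          timepoint = phantom$timepoint,
                          geometry = phantom$geometry,
                          discs = phantom$discs,
                          params = phantom$params), side_path)
  invisible(c(lab_path, side_path))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  lab <- matrix(as.integer(RNifti::readNifti(file.path(dir, "label_map.nii"))),
                nrow = dim(RNifti::readNifti(file.path(dir, "label_map.nii")))[1])
  side <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  structure(list(labels = lab, pixel_spacing = side$pixel_spacing,
                 geometry = side$geometry, discs = side$discs,
                 params = side$params, timepoint = side$timepoint),
            class = "tissue_phantom")
}

#' Write / read a multi-echo series (3D NIfTI + protocol sidecar)
#'
#' @param series an `echo_series`.
#' @param dir output directory.
#' @export
write_echo_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- file.path(dir, "echo_series.nii")
  side <- file.path(dir, "echo_series.json")
  RNifti::writeNifti(series$data, img, datatype = "double")
  write_json_sidecar(protocol_to_list(series$protocol), side)
  invisible(c(img, side))
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(dir) {
  dat <- RNifti::readNifti(file.path(dir, "echo_series.nii"))
  proto <- protocol_from_list(jsonlite::read_json(
    file.path(dir, "echo_series.json"), simplifyVector = TRUE))
  structure(list(data = array(as.numeric(dat), dim = dim(dat)),
                 protocol = proto), class = "echo_series")
}

#' Write / read an MT pair (two NIfTIs + protocol sidecar)
#'
#' @param pair an `mt_pair`.
#' @param dir output directory.
#' @export
write_mt_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("mt_off.nii", "mt_on.nii", "mt_pair.json"))
  RNifti::writeNifti(pair$mo, paths[1], datatype = "double")
  RNifti::writeNifti(pair$ms, paths[2], datatype = "double")
  write_json_sidecar(protocol_to_list(pair$protocol), paths[3])
  invisible(paths)
}

#' @rdname write_mt_pair
#' @export
read_mt_pair <- function(dir) {
  as_mat <- function(p) {
    x <- RNifti::readNifti(p)
    matrix(as.numeric(x), nrow = dim(x)[1])
  }
  proto <- protocol_from_list(jsonlite::read_json(
    file.path(dir, "mt_pair.json"), simplifyVector = TRUE))
  structure(list(mo = as_mat(file.path(dir, "mt_off.nii")),
                 ms = as_mat(file.path(dir, "mt_on.nii")),
                 protocol = proto), class = "mt_pair")
}

#' Write / read a quantitative map (values + quality NIfTI + JSON)
#'
#' @param map a `quantitative_map`.
#' @param dir output directory.
#' @param prefix file name prefix (defaults to the lowercase kind).
#' @export
write_quantitative_map <- function(map, dir, prefix = tolower(map$kind)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_values.nii", "_quality.nii",
                                           "_map.json")))
  vals <- map$values; vals[!map$valid] <- NaN
  qual <- map$quality; qual[!map$valid] <- NaN
  RNifti::writeNifti(vals, paths[1], datatype = "double")
  RNifti::writeNifti(qual, paths[2], datatype = "double")
  write_json_sidecar(list(kind = map$kind, method = map$method,
                          noise_floor = map$noise_floor,
                          pixel_spacing = map$pixel_spacing), paths[3])
  invisible(paths)
}

#' @rdname write_quantitative_map
#' @export
read_quantitative_map <- function(dir, prefix) {
  as_mat <- function(p) {
    x <- RNifti::readNifti(p)
    m <- matrix(as.numeric(x), nrow = dim(x)[1])
    m[is.nan(m)] <- NA_real_
    m
  }
  vals <- as_mat(file.path(dir, paste0(prefix, "_values.nii")))
  qual <- as_mat(file.path(dir, paste0(prefix, "_quality.nii")))
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, "_map.json")),
                              simplifyVector = TRUE)
  quantitative_map(side$kind, vals, qual, !is.na(vals),
                   pixel_spacing = side$pixel_spacing,
                   method = side$method, noise_floor = side$noise_floor)
}

#' Write / read biochemistry records as CSV
#'
#' Header: tissue, timepoint, water_pct, uronic_acid, hydroxyproline,
#' endplate_score, t2_value, mtr_value.
#'
#' @param records data.frame from [simulate_biochem()].
#' @param path CSV file path.
#' @export
write_biochem <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biochem
#' @export
read_biochem <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "timepoint", "water_pct", "uronic_acid",
            "hydroxyproline", "endplate_score", "t2_value", "mtr_value")
  if (!all(need %in% names(df))) {
    stop("input error: biochemistry CSV must have columns ",
         paste(need, collapse = ", "))
  }
  df
}

#' Write a profile curve as CSV (position, value, label)
#'
#' @param profile a `profile_curve`.
#' @param path CSV file path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = profile$positions, value = profile$values)
  if (!is.null(profile$labels)) df$label <- profile$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# chain geometry echoed to JSON for audit
write_chain <- function(chain, path) {
  write_json_sidecar(list(kind = chain$kind,
                          pixel_spacing = chain$pixel_spacing,
                          rects = chain$rects), path)
  invisible(path)
}
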