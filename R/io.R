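# Readers/writers for the plain-text exchange formats used around the
# pipeline: TSV paths and beta tables, YAML geometry / model-space configs,
# and (optionally) NIfTI voxel maps via RNifti.

#' Read a trajectory config from YAML
#'
#' The YAML keys match the [trajectory_spec()] arguments exactly.
#'
#' @param path Path to a YAML file.
#' @return A `trajectory_spec`.
#' @export
read_trajectory_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(trajectory_spec, cfg)
}

#' Write a projected path as TSV
#'
#' Columns: `frame_time`, `ang_x_deg`, `ang_y_deg`, `ang_size_deg`.
#'
#' @param path_obj A `projected_path`.
#' @param file Output file path.
#' @export
write_projected_path <- function(path_obj, file) {
  stopifnot(inherits(path_obj, "projected_path"))
  df <- data.frame(frame_time = path_obj$frame_times,
                   ang_x_deg = path_obj$angular_x,
                   ang_y_deg = path_obj$angular_y,
                   ang_size_deg = path_obj$angular_size)
  utils::write.table(df, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Read a projected path from TSV
#'
#' @param file TSV written by [write_projected_path()].
#' @return A `projected_path` (centroid shift 0).
#' @export
read_projected_path <- function(file) {
  df <- utils::read.delim(file)
  structure(list(frame_times = df$frame_time, angular_x = df$ang_x_deg,
                 angular_y = df$ang_y_deg, angular_size = df$ang_size_deg,
                 centroid_shift = c(0, 0), quadrant = NULL),
            class = "projected_path")
}

#' Read a model-space spec from YAML
#'
#' Expected keys: `variables`, `common_edges`, `two_option_slots`,
#' `three_option_slots`, each edge/slot a 2-element list `[from, to]` /
#' `[a, b]`.
#'
#' @param path Path to a YAML file.
#' @return A `model_space_spec`.
#' @export
read_model_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pairs <- function(x) lapply(x, function(p) as.character(unlist(p)))
  model_space_spec(variables = as.character(cfg$variables),
                   common_edges = as_pairs(cfg$common_edges),
                   two_option_slots = as_pairs(cfg$two_option_slots),
                   three_option_slots = as_pairs(cfg$three_option_slots))
}

#' Read / write a voxel map as NIfTI
#'
#' Thin wrappers over RNifti (a suggested dependency) for exchanging beta
#' maps and ROI masks with neuroimaging tools.
#'
#' @param file NIfTI file path.
#' @return `read_voxel_map`: list with `data` (array) and `voxel_size_mm`.
#' @export
read_voxel_map <- function(file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_domain("RNifti is required for NIfTI input")
  }
  img <- RNifti::readNifti(file)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname read_voxel_map
#' @param data Numeric 3D array.
#' @param voxel_size_mm Voxel edge lengths in mm (length 3 or scalar).
#' @export
write_voxel_map <- function(data, file, voxel_size_mm = 1.5) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_domain("RNifti is required for NIfTI output")
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(voxel_size_mm, length.out = 3)
  RNifti::writeNifti(img, file)
  invisible(file)
}
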