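#' Read a 3-D NIfTI volume
#'
#' Reads one volume and returns the voxel array together with the spacing
#' from the image header. Inputs are assumed co-registered upstream, so the
#' affine orientation beyond the voxel spacing is deliberately ignored.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expected_grid optional [voxel_grid()]; if given, the image
#'   dimensions must match the grid's.
#' @return list with `data` (numeric or integer 3-D array) and `spacing`
#'   (mm triple).
#' @export
read_volume <- function(path, expected_grid = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop NIfTI attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s is not a 3-D image (dims: %s)", path,
                 paste(dim(arr), collapse = "x")), call. = FALSE)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (!is.null(expected_grid)) {
    if (!identical(as.integer(dim(arr)), as.integer(expected_grid$dims)))
      stop(sprintf(
        "dimension mismatch: %s is %s, expected %s",
        path, paste(dim(arr), collapse = "x"),
        paste(expected_grid$dims, collapse = "x")), call. = FALSE)
  }
  list(data = arr, spacing = as.numeric(spacing))
}

#' Write a 3-D volume as NIfTI
#'
#' Integer arrays are stored as 32-bit integers (bit-exact round trip);
#' numeric arrays as 64-bit floats. Spacing is written into the header
#' `pixdim`.
#'
#' @param data 3-D array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param spacing mm triple.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.logical(data)) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# read a plain-text key: value / key=value manifest into a named character
# vector; '#' starts a comment
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop(sprintf("malformed manifest line(s): %s",
                 paste(lines[bad], collapse = "; ")), call. = FALSE)
  vals <- vapply(m, `[`, character(1), 3L)
  names(vals) <- vapply(m, `[`, character(1), 2L)
  trimws(vals)
}

write_manifest <- function(entries, path) {
  writeLines(sprintf("%s: %s", names(entries), unlist(entries)), path)
  invisible(path)
}

#' Load one imaging study from NIfTI files
#'
#' Assembles and validates an [imaging_study()] from the per-time-point file
#' set produced by upstream preprocessing: the T1 post-contrast and T2/FLAIR
#' intensity volumes, the tissue-label volume, the enhancing-tumor and edema
#' segmentations, and optional necrotic-core and resection-cavity masks.
#'
#' @param paths named character vector or list with required entries `t1c`,
#'   `t2`, `labels`, `enhancing`, `edema` and optional `necrotic`, `cavity`.
#' @param day integer acquisition day.
#' @return a validated [imaging_study()].
#' @export
load_study <- function(paths, day = 0L) {
  paths <- unlist(paths)
  required <- c("t1c", "t2", "labels", "enhancing", "edema")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0)
    stop(sprintf("missing required study file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lab <- read_volume(paths[["labels"]])
  grid <- voxel_grid(lab$data, lab$spacing)
  vol <- function(key) read_volume(paths[[key]], expected_grid = grid)$data
  imaging_study(
    grid = grid,
    t1c = vol("t1c"),
    t2 = vol("t2"),
    enhancing = vol("enhancing"),
    edema = vol("edema"),
    necrotic = if ("necrotic" %in% names(paths)) vol("necrotic") else NULL,
    cavity = if ("cavity" %in% names(paths)) vol("cavity") else NULL,
    day = day
  )
}

#' Load a study described by a manifest file
#'
#' The manifest is a plain-text `key: value` file naming the NIfTI volumes
#' (paths relative to the manifest's directory) and the acquisition `day`.
#'
#' @param manifest_path path to the manifest file.
#' @return a validated [imaging_study()].
#' @export
load_study_manifest <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  day <- if ("day" %in% names(man)) as.integer(man[["day"]]) else 0L
  keys <- intersect(names(man),
                    c("t1c", "t2", "labels", "enhancing", "edema",
                      "necrotic", "cavity"))
  paths <- file.path(dir, man[keys])
  names(paths) <- keys
  load_study(paths, day = day)
}

#' Write simulated segmentation masks as NIfTI volumes
#'
#' Writes the virtual enhancing and edema segmentations of one scenario
#' result as binary NIfTI volumes with the grid spacing in the header,
#' suitable for overlay on the source images.
#'
#' @param result a `scenario_result` (see [run_ensemble()]).
#' @param grid the [voxel_grid()] the result was simulated on.
#' @param out_dir output directory (created if absent).
#' @param prefix filename prefix; defaults to `scenario<index>`.
#' @return named character vector of the written file paths.
#' @export
write_result_masks <- function(result, grid, out_dir,
                               prefix = sprintf("scenario%02d", result$index)) {
  stopifnot_same_dims(result$sim_enhancing, grid$labels,
                      "result masks vs grid")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", out_dir),
                  call. = FALSE)
  }
  paths <- c(
    enhancing = file.path(out_dir, paste0(prefix, "_enhancing.nii.gz")),
    edema = file.path(out_dir, paste0(prefix, "_edema.nii.gz"))
  )
  write_volume(result$sim_enhancing, paths[["enhancing"]], grid$spacing)
  write_volume(result$sim_edema, paths[["edema"]], grid$spacing)
  paths
}

#' Write a complete study file set (volumes + manifest)
#'
#' Inverse of [load_study_manifest()]: writes the study's volumes as NIfTI
#' files plus a plain-text manifest into a directory.
#'
#' @param study an [imaging_study()].
#' @param out_dir output directory (created if absent).
#' @param stem filename stem, e.g. `"baseline"`.
#' @return path of the written manifest.
#' @export
write_study <- function(study, out_dir, stem = "study") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", out_dir),
                  call. = FALSE)
  }
  sp <- study$grid$spacing
  files <- list(
    labels = study$grid$labels,
    t1c = study$t1c,
    t2 = study$t2,
    enhancing = study$enhancing,
    edema = study$edema
  )
  if (!is.null(study$necrotic)) files$necrotic <- study$necrotic
  if (!is.null(study$cavity)) files$cavity <- study$cavity
  entries <- list()
  for (key in names(files)) {
    fn <- sprintf("%s_%s.nii.gz", stem, key)
    write_volume(files[[key]], file.path(out_dir, fn), sp)
    entries[[key]] <- fn
  }
  entries$day <- study$day
  manifest <- file.path(out_dir, sprintf("%s_manifest.txt", stem))
  write_manifest(entries, manifest)
  manifest
}
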