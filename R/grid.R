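#' Tissue label codes
#'
#' Fixed integer encoding of the tissue classes on the computational domain.
#' The labeled brain volume produced by upstream preprocessing (skull
#' stripping + tissue segmentation) is expected to use these codes:
#' 0 = BACKGROUND (outside the brain / skull), 1 = CSF, 2 = GRAY matter,
#' 3 = WHITE matter.
#'
#' @return Named integer vector with elements `BACKGROUND`, `CSF`, `GRAY`,
#'   `WHITE`.
#' @export
#' @examples
#' label_codes()
label_codes <- function() {
  c(BACKGROUND = 0L, CSF = 1L, GRAY = 2L, WHITE = 3L)
}

#' Construct a labeled voxel grid
#'
#' A `voxel_grid` is the computational domain for all simulations: a 3-D
#' array of tissue labels together with the physical voxel spacing.
#' Clinical surveillance MRI is strongly anisotropic (roughly 0.9 mm
#' in-plane, 7 mm between axial slices), so the slice spacing may greatly
#' exceed the in-plane spacing.
#'
#' @param labels integer 3-D array of tissue codes (see [label_codes()]).
#' @param spacing numeric triple of positive voxel edge lengths in mm,
#'   ordered (in-plane x, in-plane y, slice).
#' @return An object of class `voxel_grid`: a list with elements `dims`
#'   (integer triple), `spacing` (numeric triple, mm) and `labels`
#'   (integer array).
#' @export
voxel_grid <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  storage.mode(labels) <- "integer"
  codes <- label_codes()
  bad <- !(labels %in% codes)
  if (any(bad))
    stop(sprintf(
      "invalid tissue label(s) %s: allowed codes are %s",
      paste(unique(labels[bad]), collapse = ", "),
      paste(sprintf("%d=%s", codes, names(codes)), collapse = ", ")
    ), call. = FALSE)
  if (!any(labels == codes[["WHITE"]] | labels == codes[["GRAY"]]))
    stop("degenerate domain: no WHITE or GRAY voxels", call. = FALSE)
  structure(
    list(dims = dim(labels), spacing = spacing, labels = labels),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  codes <- label_codes()
  counts <- vapply(codes, function(v) sum(x$labels == v), integer(1))
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    x$dims[1], x$dims[2], x$dims[3],
    x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat("  ", paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#' @param grid a [voxel_grid()].
#' @return scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

# logical array: voxels where tumor cells can live (white or gray matter)
tissue_mask <- function(grid) {
  codes <- label_codes()
  grid$labels == codes[["WHITE"]] | grid$labels == codes[["GRAY"]]
}

stopifnot_same_dims <- function(a, b, what) {
  if (!identical(as.integer(dim(a)), as.integer(dim(b))))
    stop(sprintf("dimension mismatch: %s", what), call. = FALSE)
  invisible(TRUE)
}

as_mask <- function(x, what = "mask") {
  if (is.logical(x)) return(x)
  v <- as.integer(x)
  if (any(!(v %in% c(0L, 1L))))
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  array(v == 1L, dim = dim(x))
}

#' Construct an imaging study
#'
#' Bundles the co-registered volumes describing one MRI time point: T1
#' post-contrast and T2/FLAIR intensities, the expert segmentations of
#' enhancing tumor and tumor-associated edema, and optionally a necrotic
#' core and a resection cavity, plus the acquisition day.
#'
#' Validation enforces the contracts the pipeline relies on: all volumes
#' share the grid dimensions; enhancing, edema and necrotic masks are
#' pairwise disjoint; masks only cover brain tissue (not background or
#' CSF); intensities are finite and nonnegative. Resection-cavity voxels
#' are relabeled CSF in the grid (fluid-filled: no cells, no flux), so the
#' returned study's grid may differ from the input grid.
#'
#' @param grid a [voxel_grid()].
#' @param t1c,t2 numeric 3-D arrays of nonnegative image intensities.
#' @param enhancing,edema logical/0-1 3-D arrays (required masks).
#' @param necrotic,cavity optional masks (`NULL` if absent).
#' @param day integer acquisition day.
#' @param truth optional numeric array carrying a known ground-truth cell
#'   density (phantom studies only; ignored by the pipeline).
#' @return An object of class `imaging_study`.
#' @export
imaging_study <- function(grid, t1c, t2, enhancing, edema,
                          necrotic = NULL, cavity = NULL, day = 0L,
                          truth = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  codes <- label_codes()
  for (nm in c("t1c", "t2")) {
    v <- get(nm)
    stopifnot_same_dims(v, grid$labels, sprintf("%s vs grid", nm))
    if (any(!is.finite(v)) || any(v < 0))
      stop(sprintf("%s intensities must be finite and >= 0", nm),
           call. = FALSE)
  }
  enhancing <- as_mask(enhancing, "enhancing mask")
  edema <- as_mask(edema, "edema mask")
  stopifnot_same_dims(enhancing, grid$labels, "enhancing mask vs grid")
  stopifnot_same_dims(edema, grid$labels, "edema mask vs grid")
  if (!is.null(necrotic)) {
    necrotic <- as_mask(necrotic, "necrotic mask")
    stopifnot_same_dims(necrotic, grid$labels, "necrotic mask vs grid")
  }
  if (!is.null(cavity)) {
    cavity <- as_mask(cavity, "cavity mask")
    stopifnot_same_dims(cavity, grid$labels, "cavity mask vs grid")
    # fluid-filled resection cavity: relabel as CSF so no cells live or
    # diffuse there
    labels <- grid$labels
    labels[cavity] <- codes[["CSF"]]
    grid <- voxel_grid(labels, grid$spacing)
  }
  n_overlap <- sum(enhancing & edema)
  if (n_overlap > 0)
    stop(sprintf("enhancing and edema masks overlap in %d voxel(s)",
                 n_overlap), call. = FALSE)
  if (!is.null(necrotic)) {
    n_ov <- sum(necrotic & (enhancing | edema))
    if (n_ov > 0)
      stop(sprintf("necrotic mask overlaps enhancing/edema in %d voxel(s)",
                   n_ov), call. = FALSE)
  }
  outside <- grid$labels == codes[["BACKGROUND"]] | grid$labels == codes[["CSF"]]
  all_masks <- enhancing | edema
  if (!is.null(necrotic)) all_masks <- all_masks | necrotic
  n_out <- sum(all_masks & outside)
  if (n_out > 0)
    stop(sprintf(
      "tumor masks cover %d voxel(s) outside brain tissue (BACKGROUND/CSF)",
      n_out), call. = FALSE)
  structure(
    list(grid = grid, t1c = t1c, t2 = t2,
         enhancing = enhancing, edema = edema,
         necrotic = necrotic, cavity = cavity,
         day = as.integer(day), truth = truth),
    class = "imaging_study"
  )
}

#' @export
print.imaging_study <- function(x, ...) {
  cat(sprintf(
    "<imaging_study> day %d, %d enhancing, %d edema, %s necrotic voxel(s)\n",
    x$day, sum(x$enhancing), sum(x$edema),
    if (is.null(x$necrotic)) "no" else format(sum(x$necrotic))
  ))
  invisible(x)
}

#' Pair a baseline and follow-up study
#'
#' @param baseline,followup [imaging_study()] objects on co-registered grids
#'   (same dimensions).
#' @return An object of class `study_pair` with the inter-scan interval in
#'   days.
#' @export
study_pair <- function(baseline, followup) {
  stopifnot(inherits(baseline, "imaging_study"),
            inherits(followup, "imaging_study"))
  stopifnot_same_dims(baseline$grid$labels, followup$grid$labels,
                      "baseline vs follow-up grid")
  interval <- followup$day - baseline$day
  if (interval <= 0)
    stop("follow-up day must be after baseline day", call. = FALSE)
  structure(
    list(baseline = baseline, followup = followup,
         interval_days = as.integer(interval)),
    class = "study_pair"
  )
}
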