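#' Virtually re-segment a simulated density field
#'
#' Converts a simulated cell-density state into virtual segmentations by
#' thresholding the total density `p + q` against the scenario's closed
#' density windows: voxels with `I_c[1] <= p + q <= I_c[2]` count as
#' enhancing, voxels with `I_e[1] <= p + q <= I_e[2]` as edematous. The
#' windows are disjoint by construction, so the masks are too. Voxels
#' denser than the `I_c` upper bound fall in neither mask (dense quiescent
#' tissue does not enhance).
#'
#' @param state a `state_fields`.
#' @param params a [model_parameters()].
#' @return list with logical arrays `enhancing` and `edema`.
#' @export
classify_state <- function(state, params) {
  total <- state$p + state$q
  list(
    enhancing = total >= params$I_c[1] & total <= params$I_c[2],
    edema = total >= params$I_e[1] & total <= params$I_e[2]
  )
}

#' Relative change in enhancing volume
#'
#' `(V_1 - V_0) / V_0` on enhancing voxel counts: -1 if the comparison
#' count is zero, +1 if it doubles, 0 if unchanged.
#'
#' @param V_1 comparison voxel count (>= 0).
#' @param V_0 reference voxel count (> 0; intervals with no enhancing tumor
#'   at baseline are excluded upstream).
#' @return the relative change.
#' @export
#' @examples
#' relative_change(2175, 1629) # ~0.335
relative_change <- function(V_1, V_0) {
  if (any(V_0 <= 0))
    stop("V_0 must be positive: relative change is undefined without baseline enhancing tumor",
         call. = FALSE)
  if (any(V_1 < 0)) stop("V_1 must be nonnegative", call. = FALSE)
  (V_1 - V_0) / V_0
}

#' Select the scenario closest to the observed volume
#'
#' Picks the ensemble member whose simulated enhancing voxel count is
#' closest to the observed one and returns its relative volume error
#' `R_best = (V* - V_obs) / V_obs`. Ties go to the lowest index
#' (deterministic, order-stable).
#'
#' @param V_sims numeric vector of simulated enhancing voxel counts,
#'   ordered by scenario index.
#' @param V_obs observed enhancing voxel count (> 0).
#' @return list with `index` and `R_best`.
#' @export
best_scenario <- function(V_sims, V_obs) {
  if (length(V_sims) == 0) stop("V_sims is empty", call. = FALSE)
  if (V_obs <= 0) stop("V_obs must be positive", call. = FALSE)
  idx <- which.min(abs(V_sims - V_obs))  # which.min takes the first minimum
  list(index = idx, R_best = (V_sims[idx] - V_obs) / V_obs)
}

#' Spatial overlap between a simulated and an observed segmentation
#'
#' Two complementary scores comparing the simulated mask `S` against the
#' observed mask `R`: the containment `C = |S n R| / |R|` (how much of the
#' real tumor the simulation covers) and the agreement
#' `A = |S n R| / |S u R|` (Jaccard-type; penalizes over-segmentation too).
#' A perfect, perfectly co-registered simulation gives `A = C = 1`.
#'
#' @param S simulated binary mask (logical or 0/1 array).
#' @param R observed binary mask, same dims, nonempty.
#' @return object of class `overlap_scores`: list with `agreement`,
#'   `containment` and the raw counts `size_S`, `size_R`, `intersection`,
#'   `union`.
#' @export
overlap_scores <- function(S, R) {
  S <- as_mask(S, "S"); R <- as_mask(R, "R")
  stopifnot_same_dims(S, R, "S vs R")
  nR <- sum(R)
  if (nR == 0L)
    stop("observed mask R is empty: containment is undefined", call. = FALSE)
  nS <- sum(S)
  n_int <- sum(S & R)
  n_uni <- nS + nR - n_int
  structure(
    list(agreement = n_int / n_uni, containment = n_int / nR,
         size_S = nS, size_R = nR, intersection = n_int, union = n_uni),
    class = "overlap_scores"
  )
}

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf(
    "<overlap_scores> A = %.4f, C = %.4f (|S| = %d, |R| = %d, |SnR| = %d, |SuR| = %d)\n",
    x$agreement, x$containment, x$size_S, x$size_R, x$intersection, x$union))
  invisible(x)
}

#' Default growth/shrinkage thresholds
#'
#' The signed fractional thresholds used to summarize the chance that a
#' tumor grows or shrinks by given amounts until the next scan.
#' @return numeric vector of signed fractions.
#' @export
default_thresholds <- function() {
  c(-0.50, -0.25, -0.20, -0.15, -0.10, 0.10, 0.15, 0.20, 0.25, 0.50, 1.00)
}

#' Tail fractions of relative volume changes
#'
#' For each negative threshold `tau`, the fraction of changes `<= tau`
#' (shrinkage by at least that much); for each nonnegative threshold, the
#' fraction `>= tau` (growth by at least that much); plus the overall
#' fractions `< 0` and `>= 0`. Fractions are exact; rounding is left to
#' display.
#'
#' @param deltas nonempty numeric vector of relative changes.
#' @param thresholds signed fractional thresholds.
#' @return data frame with columns `threshold`, `direction` (`"<="`, `">="`,
#'   `"<"`), and `fraction`.
#' @export
threshold_summary <- function(deltas, thresholds = default_thresholds()) {
  if (length(deltas) == 0) stop("deltas is empty", call. = FALSE)
  n <- length(deltas)
  rows <- lapply(sort(thresholds), function(tau) {
    if (tau < 0)
      data.frame(threshold = tau, direction = "<=",
                 fraction = sum(deltas <= tau) / n)
    else
      data.frame(threshold = tau, direction = ">=",
                 fraction = sum(deltas >= tau) / n)
  })
  neg <- data.frame(threshold = 0, direction = "<",
                    fraction = sum(deltas < 0) / n)
  pos <- data.frame(threshold = 0, direction = ">=",
                    fraction = sum(deltas >= 0) / n)
  out <- do.call(rbind, c(rows[vapply(rows, function(r) r$threshold < 0,
                                      logical(1))],
                          list(neg, pos),
                          rows[vapply(rows, function(r) r$threshold >= 0,
                                      logical(1))]))
  rownames(out) <- NULL
  out
}

#' Evaluate an ensemble against an observed imaging interval
#'
#' Assembles the full per-interval report: observed baseline and follow-up
#' enhancing voxel counts and their relative change, each scenario's
#' simulated count, relative change and overlap scores against the
#' follow-up enhancing segmentation, and the best-matching scenario with
#' its relative volume error.
#'
#' @param pair a [study_pair()].
#' @param results list of `scenario_result` from [run_ensemble()] on
#'   `pair$baseline`.
#' @return object of class `interval_report`.
#' @export
evaluate_interval <- function(pair, results) {
  stopifnot(inherits(pair, "study_pair"))
  V_0 <- sum(pair$baseline$enhancing)
  V_obs <- sum(pair$followup$enhancing)
  if (V_obs == 0L)
    stop("follow-up enhancing mask is empty: interval cannot be evaluated",
         call. = FALSE)
  R <- pair$followup$enhancing
  V_sims <- vapply(results, function(r) as.numeric(r$V_sim), numeric(1))
  overlaps <- lapply(results, function(r) overlap_scores(r$sim_enhancing, R))
  best <- best_scenario(V_sims, V_obs)
  scen <- data.frame(
    index = vapply(results, function(r) r$index, integer(1)),
    V_sim = V_sims,
    delta_sim = vapply(results, function(r) r$delta_sim, numeric(1)),
    agreement = vapply(overlaps, function(o) o$agreement, numeric(1)),
    containment = vapply(overlaps, function(o) o$containment, numeric(1))
  )
  structure(
    list(V_0 = V_0, V_obs = V_obs,
         delta_obs = relative_change(V_obs, V_0),
         scenarios = scen, overlaps = overlaps,
         best_index = best$index, R_best = best$R_best),
    class = "interval_report"
  )
}

#' @export
print.interval_report <- function(x, ...) {
  cat(sprintf(
    "<interval_report> V_0 = %d, V_obs = %d, delta_obs = %.4f\n",
    x$V_0, x$V_obs, x$delta_obs))
  cat(sprintf("  best scenario %d: R_best = %.4f, A = %.3f, C = %.3f\n",
              x$best_index, x$R_best,
              x$scenarios$agreement[x$best_index],
              x$scenarios$containment[x$best_index]))
  invisible(x)
}

#' Serialize an interval report to JSON
#'
#' Versioned schema; floating-point values are written at full precision
#' (display rounding is a consumer concern).
#'
#' @param report an `interval_report` or the list returned by
#'   [run_ensemble()] when no follow-up is available.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interval_report <- function(report, path) {
  payload <- unclass(report)
  payload$overlaps <- NULL
  out <- c(list(schema_version = 1L), payload)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
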