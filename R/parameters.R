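#' Convert a doubling or halving time to a rate
#'
#' Model growth and quiescence parameters are quoted as doubling and halving
#' times (days) because those are the quantities clinicians reason about;
#' the rates actually used in the equations are `log(2) / time`.
#'
#' @param that doubling or halving time in days (> 0); vectorized.
#' @return rate in 1/day.
#' @export
#' @examples
#' rate_from_time(14) # ~0.0495 per day
rate_from_time <- function(that) {
  if (any(!is.finite(that)) || any(that <= 0))
    stop("doubling/halving time must be positive and finite", call. = FALSE)
  log(2) / that
}

#' Construct one model parameter set (scenario)
#'
#' A scenario fixes the seven adjustable quantities of the growth model:
#' the edema-region halving and doubling times `khat0`, `rhohat0` (days),
#' the white-matter/tumor diffusivity `D_w` (mm^2/day), the density windows
#' `I_e` and `I_c` used both to impute initial densities from image
#' intensities and to re-segment simulated density fields, and the
#' enhancing-region halving and doubling times `khat1`, `rhohat1` (days).
#'
#' Densities are dimensionless fractions of the carrying capacity (1).
#' The windows must satisfy `0 < I_e lo < I_e hi < I_c lo < I_c hi <= 1`:
#' edema is a low-density state, contrast enhancement a high-density one,
#' and the two never overlap.
#'
#' @param khat0,rhohat0 edema-region halving/doubling times, days.
#' @param D_w diffusivity in white matter and tumor, mm^2/day.
#' @param I_e,I_c numeric length-2 closed density windows (lo, hi).
#' @param khat1,rhohat1 enhancing-region halving/doubling times, days.
#' @param index optional integer scenario index.
#' @return object of class `model_parameters`.
#' @export
model_parameters <- function(khat0, rhohat0, D_w, I_e, I_c, khat1, rhohat1,
                             index = NA_integer_) {
  times <- c(khat0 = khat0, rhohat0 = rhohat0, khat1 = khat1,
             rhohat1 = rhohat1)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("all halving/doubling times must be positive", call. = FALSE)
  if (!is.finite(D_w) || D_w <= 0)
    stop("D_w must be positive", call. = FALSE)
  I_e <- as.numeric(I_e); I_c <- as.numeric(I_c)
  if (length(I_e) != 2L || length(I_c) != 2L)
    stop("I_e and I_c must each have two endpoints", call. = FALSE)
  w <- c(I_e, I_c)
  if (any(!is.finite(w)) ||
      !(0 < I_e[1] && I_e[1] < I_e[2] && I_e[2] < I_c[1] &&
        I_c[1] < I_c[2] && I_c[2] <= 1))
    stop("density windows must satisfy 0 < I_e[1] < I_e[2] < I_c[1] < I_c[2] <= 1",
         call. = FALSE)
  structure(
    list(khat0 = khat0, rhohat0 = rhohat0, D_w = D_w,
         I_e = I_e, I_c = I_c, khat1 = khat1, rhohat1 = rhohat1,
         index = as.integer(index)),
    class = "model_parameters"
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf(
    paste0("<model_parameters>%s khat0=%g d, rhohat0=%g d, D_w=%g mm^2/d, ",
           "I_e=[%g, %g], I_c=[%g, %g], khat1=%g d, rhohat1=%g d\n"),
    if (is.na(x$index)) "" else sprintf(" scenario %d:", x$index),
    x$khat0, x$rhohat0, x$D_w, x$I_e[1], x$I_e[2], x$I_c[1], x$I_c[2],
    x$khat1, x$rhohat1))
  invisible(x)
}

scenario_columns <- c("index", "khat0_d", "rhohat0_d", "Dw_mm2_per_d",
                      "Ie_lo", "Ie_hi", "Ic_lo", "Ic_hi",
                      "khat1_d", "rhohat1_d")

#' Read a scenario table from CSV
#'
#' The CSV schema has header columns `index, khat0_d, rhohat0_d,
#' Dw_mm2_per_d, Ie_lo, Ie_hi, Ic_lo, Ic_hi, khat1_d, rhohat1_d`. Indices
#' must be unique and contiguous from 1.
#'
#' @param path CSV file path.
#' @return a `scenario_set`: list of [model_parameters()] ordered by index.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path))
    stop(sprintf("scenario table not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(scenario_columns, names(df))
  if (length(missing) > 0)
    stop(sprintf("scenario table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[order(df$index), , drop = FALSE]
  if (!identical(as.integer(df$index), seq_len(nrow(df))))
    stop("scenario indices must be unique and contiguous from 1",
         call. = FALSE)
  scenarios <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    model_parameters(
      khat0 = r$khat0_d, rhohat0 = r$rhohat0_d, D_w = r$Dw_mm2_per_d,
      I_e = c(r$Ie_lo, r$Ie_hi), I_c = c(r$Ic_lo, r$Ic_hi),
      khat1 = r$khat1_d, rhohat1 = r$rhohat1_d, index = r$index
    )
  })
  structure(scenarios, class = "scenario_set")
}

#' Write a scenario table to CSV
#' @param set a `scenario_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(set, path) {
  df <- as.data.frame(set)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.scenario_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    data.frame(index = p$index, khat0_d = p$khat0, rhohat0_d = p$rhohat0,
               Dw_mm2_per_d = p$D_w, Ie_lo = p$I_e[1], Ie_hi = p$I_e[2],
               Ic_lo = p$I_c[1], Ic_hi = p$I_c[2], khat1_d = p$khat1,
               rhohat1_d = p$rhohat1)
  }))
}

#' The default 18-scenario parameter ensemble
#'
#' Returns the fixed ensemble of 18 parameter sets used to simulate every
#' tumor: an orthogonal-array (Taguchi) design over the seven model
#' parameters at three levels each, prioritizing the two most sensitive
#' parameters (the edema-region halving and doubling times), whose nine
#' level pairs each occur exactly twice. The table ships with the package
#' as a machine-readable CSV; [validate_design()] checks its balance
#' properties.
#'
#' @return a `scenario_set` of 18 [model_parameters()].
#' @export
#' @examples
#' set <- default_scenarios()
#' length(set)
#' set[[1]]
default_scenarios <- function() {
  path <- system.file("extdata", "scenarios_default.csv",
                      package = "gliosim", mustWork = TRUE)
  read_scenarios(path)
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> %d scenario(s)\n", length(x)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Validate the balance properties of a scenario set
#'
#' Checks the structural properties the 18-run orthogonal-array design is
#' supposed to have: (a) each of the 9 level pairs of the two most
#' sensitive parameters (`khat0`, `rhohat0`) occurs exactly twice; (b)
#' every parameter takes exactly 3 distinct levels, each occurring 6 times
#' (the density windows `I_e`, `I_c` count as one parameter apiece); (c)
#' `I_e` and `I_c` never overlap within a scenario. For designs that are
#' not 18-run/3-level, the pair-balance and level-balance checks are
#' reported as not applicable rather than failed.
#'
#' @param set a `scenario_set`.
#' @return object of class `design_report`: list with logical `pass`, and a
#'   data frame `checks` with columns `check`, `status` ("pass", "fail",
#'   "not_applicable") and `detail`.
#' @export
validate_design <- function(set) {
  stopifnot(length(set) > 0)
  df <- as.data.frame(set)
  n <- nrow(df)
  checks <- list()
  add <- function(check, status, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }

  is_18_3lvl <- n == 18L
  param_levels <- list(
    khat0 = df$khat0_d, rhohat0 = df$rhohat0_d, D_w = df$Dw_mm2_per_d,
    I_e = paste(df$Ie_lo, df$Ie_hi), I_c = paste(df$Ic_lo, df$Ic_hi),
    khat1 = df$khat1_d, rhohat1 = df$rhohat1_d
  )
  if (is_18_3lvl && all(vapply(param_levels,
                               function(v) length(unique(v)) == 3L,
                               logical(1)))) {
    # (a) the 9 (khat0, rhohat0) pairs each occur exactly twice
    pair <- paste(df$khat0_d, df$rhohat0_d)
    tab <- table(pair)
    if (length(tab) == 9L && all(tab == 2L)) {
      add("pair_balance", "pass",
          "9 (khat0, rhohat0) level pairs, each twice")
    } else {
      bad <- tab[tab != 2L]
      add("pair_balance", "fail",
          sprintf("expected 9 pairs x 2; found %d distinct pair(s), deviating: %s",
                  length(tab),
                  paste(sprintf("(%s) x %d", names(bad), bad),
                        collapse = "; ")))
    }
    # (b) each parameter: 3 levels, each 6 times
    for (pn in names(param_levels)) {
      tabp <- table(param_levels[[pn]])
      if (length(tabp) == 3L && all(tabp == 6L)) {
        add(sprintf("level_balance_%s", pn), "pass", "3 levels x 6")
      } else {
        add(sprintf("level_balance_%s", pn), "fail",
            sprintf("levels: %s", paste(sprintf("%s x %d", names(tabp),
                                                tabp), collapse = "; ")))
      }
    }
  } else {
    add("pair_balance", "not_applicable",
        sprintf("design has %d run(s); pair balance is defined for the 18-run 3-level design", n))
    add("level_balance", "not_applicable",
        "level balance is defined for the 18-run 3-level design")
  }
  # (c) I_e / I_c disjoint in every scenario (also enforced per-row by
  # model_parameters; re-checked here so the report enumerates failures)
  overlap <- df$Ie_hi >= df$Ic_lo
  if (any(overlap)) {
    add("window_disjoint", "fail",
        sprintf("I_e/I_c overlap in scenario(s): %s",
                paste(df$index[overlap], collapse = ", ")))
  } else {
    add("window_disjoint", "pass", "I_e < I_c in all scenarios")
  }

  checks <- do.call(rbind, checks)
  structure(list(pass = !any(checks$status == "fail"), checks = checks),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %s: %s\n", x$checks$status[i], x$checks$check[i],
                x$checks$detail[i]))
  invisible(x)
}
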