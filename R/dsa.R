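# Deterministic sensitivity analyses: one-way sweeps, bisection threshold
# search on the net-monetary-benefit difference, two-way preference maps,
# and tornado diagrams.

# Map a parameter path onto the plain-number engine view.  Returns a list
# with the field name and which arm(s) it patches.
.NUM_FIELD <- c(
  procedure_cost = "pc", complication_prob = "cp", complication_cost = "cc",
  treatment_disutility = "td", complication_disutility = "cd",
  p_local_annual = "pL", p_distant_annual = "pD", p_mortality_annual = "pM",
  routine_cost_increment = "incr",
  routine_annual_cost = "cr", local_recurrence_cost = "clr",
  advanced_disease_cost = "cad", u_first_year = "u1", u_subsequent = "us",
  u_local = "ul", u_distant = "udr"
)

.path_target <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("bca", "bcs", "shared") ||
      is.na(.NUM_FIELD[parts[2]])) {
    rlang::abort(paste0("unknown parameter path: ", path))
  }
  list(block = parts[1], field = unname(.NUM_FIELD[parts[2]]))
}

# Closure evaluating both arms' NMBs with one or more parameters patched.
# values: named list path -> scalar.  Returns c(nmb_bca, nmb_bcs).
.nmb_evaluator <- function(scn, wtp = NULL) {
  validate_scenario(scn)
  wtp <- wtp %||% scn$econ$wtp
  base <- list(bca = .strategy_numbers(scn, "bca"),
               bcs = .strategy_numbers(scn, "bcs"))
  function(values = list()) {
    nums <- base
    for (path in names(values)) {
      tg <- .path_target(path)
      arms <- if (identical(tg$block, "shared")) c("bca", "bcs") else tg$block
      for (arm in arms) nums[[arm]][[tg$field]] <- values[[path]]
    }
    rb <- .cohort_totals(nums$bca)
    rs <- .cohort_totals(nums$bcs)
    c(nmb_bca = wtp * rb[["qaly"]] - rb[["cost"]],
      nmb_bcs = wtp * rs[["qaly"]] - rs[["cost"]])
  }
}

.check_sweep_range <- function(scn, param, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    rlang::abort("sweep range must satisfy lo < hi (finite)")
  }
  p <- get_param(scn, param)
  if (p$unit %in% c("probability", "probability_per_year", "utility") &&
      (lo < 0 || hi > 1)) {
    rlang::abort(paste0(param, ": sweep range [", lo, ", ", hi,
                        "] outside the valid range [0, 1]"))
  }
  if (identical(p$unit, "usd") && lo < 0) {
    rlang::abort(paste0(param, ": costs cannot be negative"))
  }
  invisible(TRUE)
}

#' One-way deterministic sensitivity sweep
#'
#' Varies a single parameter over `[lo, hi]` while holding every other
#' parameter at its base value, recomputing both cohorts at each point.
#'
#' @param scn A `cryo_scenario`.
#' @param param Dotted parameter path (see [param_paths()]).
#' @param lo,hi Sweep range, inside the parameter's valid range.
#' @param steps Number of grid points (default 25).
#' @param wtp Optional willingness-to-pay override.
#' @return An object of class `owsa_result`: a tibble with columns
#'   `param`, `value`, `nmb_bca`, `nmb_bcs`, `nmb_diff`, `preferred`.
#' @examples
#' scn <- paper_scenarios()$low_risk
#' one_way_sweep(scn, "bca.p_mortality_annual", 0, 0.10, steps = 11)
#' @export
one_way_sweep <- function(scn, param, lo, hi, steps = 25, wtp = NULL) {
  .check_sweep_range(scn, param, lo, hi)
  ev <- .nmb_evaluator(scn, wtp)
  values <- seq(lo, hi, length.out = steps)
  res <- vapply(values, function(v) ev(stats::setNames(list(v), param)),
                numeric(2))
  out <- tibble::tibble(
    param = param, value = values,
    nmb_bca = res[1, ], nmb_bcs = res[2, ],
    nmb_diff = res[1, ] - res[2, ],
    preferred = dplyr::case_when(res[1, ] > res[2, ] ~ "bca",
                                 res[1, ] < res[2, ] ~ "bcs",
                                 TRUE ~ "tie")
  )
  class(out) <- c("owsa_result", class(out))
  out
}

#' Threshold (break-even) search by bisection
#'
#' Finds the parameter value at which the two strategies' net monetary
#' benefits are equal, by bisection on the NMB difference.  The bracket is
#' first scanned on a coarse grid; the bisection runs on the first
#' sign-change interval from the lower end.  If the scan finds several
#' sign changes the first is reported and the status flags it.
#'
#' @param scn A `cryo_scenario`.
#' @param param Dotted parameter path.
#' @param bracket Length-2 numeric search interval.
#' @param tol Absolute tolerance on the parameter value (default
#'   `1e-6 * max(1, |hi|)`).
#' @param scan_steps Coarse-scan resolution (default 64 intervals).
#' @param wtp Optional willingness-to-pay override.
#' @return An object of class `threshold_result`: a list with `param`,
#'   `value`, `bracket`, `achieved_tolerance`, `status` (one of `"found"`,
#'   `"no_crossing"`, `"multiple_crossings_first_reported"`), and
#'   `nmb_gap` (the NMB difference at the reported value).
#' @examples
#' scn <- paper_scenarios()$low_risk
#' find_threshold(scn, "bca.procedure_cost", c(0, 60000))
#' @export
find_threshold <- function(scn, param, bracket, tol = NULL, scan_steps = 64,
                           wtp = NULL) {
  if (length(bracket) != 2L || !all(is.finite(bracket)) ||
      bracket[1] >= bracket[2]) {
    rlang::abort("bracket must be a finite, increasing length-2 vector")
  }
  .check_sweep_range(scn, param, bracket[1], bracket[2])
  tol <- tol %||% (1e-6 * max(1, abs(bracket[2])))
  ev <- .nmb_evaluator(scn, wtp)
  f <- function(x) {
    v <- ev(stats::setNames(list(x), param))
    v[[1]] - v[[2]]
  }
  xs <- seq(bracket[1], bracket[2], length.out = scan_steps + 1L)
  fs <- vapply(xs, f, numeric(1))
  sgn <- sign(fs)
  changes <- which(sgn[-1] * sgn[-length(sgn)] < 0 | sgn[-length(sgn)] == 0)
  result <- function(value, status, achieved) {
    structure(list(param = param, value = value, bracket = bracket,
                   achieved_tolerance = achieved, status = status,
                   n_crossings = length(changes),
                   nmb_gap = if (is.na(value)) NA_real_ else f(value)),
              class = "threshold_result")
  }
  if (length(changes) == 0L) {
    if (sgn[length(sgn)] == 0) {
      return(result(xs[length(xs)], "found", 0))
    }
    return(result(NA_real_, "no_crossing", NA_real_))
  }
  i <- changes[1]
  if (sgn[i] == 0) return(result(xs[i], "found", 0))
  lo <- xs[i]; hi <- xs[i + 1]
  flo <- fs[i]
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) { lo <- hi <- mid; break }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  status <- if (length(changes) > 1L) "multiple_crossings_first_reported" else "found"
  result((lo + hi) / 2, status, (hi - lo) / 2)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s: %s (status %s, bracket [%g, %g])\n",
              x$param,
              if (is.na(x$value)) "no crossing" else format(x$value),
              x$status, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble::tibble(param = x$param, value = x$value,
                 bracket_lo = x$bracket[1], bracket_hi = x$bracket[2],
                 achieved_tolerance = x$achieved_tolerance,
                 status = x$status, nmb_gap = x$nmb_gap)
}

#' Two-way preference map
#'
#' Evaluates the preferred strategy on the Cartesian grid of two parameter
#' sweeps, all other parameters at base values.
#'
#' @param scn A `cryo_scenario`.
#' @param param_a,param_b Dotted parameter paths.
#' @param grid_a,grid_b Numeric grids of values.
#' @param wtp Optional willingness-to-pay override.
#' @return An object of class `twsa_result`: a long tibble with columns
#'   `value_a`, `value_b`, `nmb_diff`, `preferred`.
#' @examples
#' scn <- paper_scenarios()$low_risk
#' two_way_map(scn, "bca.p_mortality_annual", "bcs.p_mortality_annual",
#'             seq(0, 0.05, 0.01), seq(0, 0.05, 0.01))
#' @export
two_way_map <- function(scn, param_a, param_b, grid_a, grid_b, wtp = NULL) {
  .check_sweep_range(scn, param_a, min(grid_a), max(grid_a) + 1e-15)
  .check_sweep_range(scn, param_b, min(grid_b), max(grid_b) + 1e-15)
  ev <- .nmb_evaluator(scn, wtp)
  out <- tidyr::expand_grid(value_a = grid_a, value_b = grid_b)
  diff <- purrr::map2_dbl(out$value_a, out$value_b, function(a, b) {
    v <- ev(stats::setNames(list(a, b), c(param_a, param_b)))
    v[[1]] - v[[2]]
  })
  out$nmb_diff <- diff
  out$preferred <- dplyr::case_when(diff > 0 ~ "bca", diff < 0 ~ "bcs",
                                    TRUE ~ "tie")
  attr(out, "params") <- c(param_a, param_b)
  class(out) <- c("twsa_result", class(out))
  out
}

#' Preference boundary of a two-way sweep
#'
#' For each value of the first parameter, locates (by [find_threshold()])
#' the value of the second parameter at which the preference flips, and
#' reports the difference along the boundary.
#'
#' @param scn A `cryo_scenario`.
#' @param param_a,param_b Dotted parameter paths; `param_b` is the one
#'   solved for.
#' @param a_values Values of `param_a` at which to trace the boundary.
#' @param bracket_b Search bracket for `param_b`.
#' @param wtp Optional willingness-to-pay override.
#' @return A tibble with columns `value_a`, `b_threshold`, `status`, and
#'   `boundary_diff` (`value_a - b_threshold`).
#' @export
two_way_boundary <- function(scn, param_a, param_b, a_values, bracket_b,
                             wtp = NULL) {
  purrr::map_dfr(a_values, function(a) {
    scn_a <- set_param(scn, param_a, a)
    thr <- find_threshold(scn_a, param_b, bracket_b, wtp = wtp)
    tibble::tibble(value_a = a, b_threshold = thr$value, status = thr$status,
                   boundary_diff = a - thr$value)
  })
}

#' Tornado diagram of parameter influence
#'
#' Evaluates the net-monetary-benefit difference (cryoablation minus
#' surgery) with each parameter set in turn to the lower and upper
#' quantiles of its sampling distribution (after [rescale_scenario()]),
#' all other parameters at base values.  Bars are sorted by width.  Point
#' parameters are skipped with a warning unless an explicit range override
#' is supplied.
#'
#' @param scn A `cryo_scenario`.
#' @param params Character vector of dotted paths (default: every
#'   parameter with a non-degenerate distribution).
#' @param quantiles Length-2 probabilities for the low/high values
#'   (default 2.5th and 97.5th percentiles).
#' @param overrides Optional named list `path -> c(lo, hi)` of explicit
#'   ranges (required for point parameters).
#' @param rescale Reconcile distribution means with base values first
#'   (default TRUE, matching the probabilistic analysis).
#' @param wtp Optional willingness-to-pay override.
#' @return An object of class `tornado_result`: a tibble with columns
#'   `param`, `low_value`, `high_value`, `nmb_diff_low`, `nmb_diff_high`,
#'   `width`, sorted by decreasing `width`.
#' @examples
#' tornado(paper_scenarios()$low_risk)
#' @export
tornado <- function(scn, params = NULL, quantiles = c(0.025, 0.975),
                    overrides = NULL, rescale = TRUE, wtp = NULL) {
  validate_scenario(scn)
  if (rescale) scn <- rescale_scenario(scn)
  params <- params %||% param_paths(scn, uncertain_only = TRUE)$path
  ev <- .nmb_evaluator(scn, wtp)
  base_diff <- {
    v <- ev()
    v[[1]] - v[[2]]
  }
  rows <- purrr::map_dfr(params, function(pp) {
    p <- get_param(scn, pp)
    rng <- if (!is.null(overrides) && pp %in% names(overrides)) {
      sort(overrides[[pp]])
    } else if (is_point_dist(p$dist)) {
      rlang::warn(paste0(pp, ": point distribution without an override; skipped"))
      return(NULL)
    } else {
      rng <- dist_quantile(p$dist, quantiles,
                           annualization = scn$econ$annualization)
      sapply(sort(rng), clamp_unit, unit = p$unit)
    }
    d <- vapply(rng, function(v) {
      r <- ev(stats::setNames(list(v), pp))
      r[[1]] - r[[2]]
    }, numeric(1))
    tibble::tibble(param = pp, low_value = rng[1], high_value = rng[2],
                   nmb_diff_low = d[1], nmb_diff_high = d[2],
                   width = abs(d[2] - d[1]))
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$width))
  attr(out, "base_nmb_diff") <- base_diff
  class(out) <- c("tornado_result", class(out))
  out
}
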