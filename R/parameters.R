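# Uncertain parameters: a published base value plus a distribution.

.PARAM_UNITS <- c("usd", "probability_per_year", "probability", "utility")

#' Define an uncertain model parameter
#'
#' Couples the published point estimate used in the base case with the
#' distribution sampled by the probabilistic sensitivity analysis.  The two
#' need not imply the same mean; [rescale_scenario()] reconciles them before
#' sampling.
#'
#' @param base_value The base-case value (annual probability, US dollars, or
#'   utility weight depending on `unit`).
#' @param dist A [dist_beta()]-family specification; defaults to a point
#'   mass at `base_value`.
#' @param unit One of `"usd"`, `"probability_per_year"`, `"probability"`
#'   (per-event), or `"utility"`.
#' @return An object of class `cryo_param`.
#' @examples
#' uparam(0.0086, dist_beta(8, 186, per_years = 5), "probability_per_year")
#' @export
uparam <- function(base_value, dist = dist_point(base_value),
                   unit = c("usd", "probability_per_year", "probability",
                            "utility")) {
  unit <- match.arg(unit)
  structure(list(base_value = base_value, dist = dist, unit = unit),
            class = "cryo_param")
}

#' @export
print.cryo_param <- function(x, ...) {
  cat(sprintf("<cryo_param> base %g (%s), ", x$base_value, x$unit))
  print(x$dist)
  invisible(x)
}

validate_uparam <- function(p, path) {
  if (!inherits(p, "cryo_param")) {
    rlang::abort(paste0(path, ": not an uncertain parameter"))
  }
  v <- p$base_value
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    rlang::abort(paste0(path, ": base_value must be a finite number"))
  }
  ok <- switch(p$unit,
    usd = v >= 0,
    probability_per_year = v >= 0 && v <= 1,
    probability = v >= 0 && v <= 1,
    utility = v >= -1 && v <= 1
  )
  if (is.null(ok) || !ok) {
    rlang::abort(paste0(path, ": base_value ", v, " out of range for unit '",
                        p$unit, "'"))
  }
  validate_dist(p$dist, paste0(path, ".dist"))
  invisible(p)
}

# Clamp a drawn value to the valid range for its unit.
clamp_unit <- function(x, unit) {
  switch(unit,
    usd = pmax(x, 0),
    probability_per_year = pmin(pmax(x, 0), 1),
    probability = pmin(pmax(x, 0), 1),
    utility = pmin(pmax(x, 0), 1)
  )
}

# ---- serialization helpers (YAML / JSON round trip) -------------------------

dist_to_list <- function(spec) {
  out <- list(kind = spec$kind)
  if (!identical(spec$kind, "sum")) {
    out$a <- spec$a
    if (!identical(spec$kind, "point")) out$b <- spec$b
  }
  if (spec$per_years != 1) out$per_years <- spec$per_years
  if (spec$frac != 1) out$frac <- spec$frac
  if (!is.na(spec$group)) out$group <- spec$group
  if (!is.na(spec$target)) out$target <- spec$target
  if (identical(spec$kind, "sum")) {
    out$components <- lapply(spec$components, dist_to_list)
  }
  out
}

dist_from_list <- function(x, path) {
  known <- c("kind", "a", "b", "per_years", "frac", "group", "target",
             "components")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    rlang::abort(paste0(path, ": unknown distribution field(s): ",
                        paste(extra, collapse = ", ")))
  }
  if (is.null(x$kind)) rlang::abort(paste0(path, ": missing field 'kind'"))
  comps <- if (!is.null(x$components)) {
    lapply(seq_along(x$components), function(i) {
      dist_from_list(x$components[[i]], paste0(path, ".components[", i, "]"))
    })
  }
  validate_dist(
    new_dist(
      kind = x$kind,
      a = x$a %||% NA_real_, b = x$b %||% NA_real_,
      per_years = x$per_years %||% 1, frac = x$frac %||% 1,
      group = x$group %||% NA_character_, components = comps,
      target = x$target %||% NA_real_
    ),
    path
  )
}

param_to_list <- function(p) {
  list(base_value = p$base_value, unit = p$unit, dist = dist_to_list(p$dist))
}

param_from_list <- function(x, path) {
  known <- c("base_value", "unit", "dist")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    rlang::abort(paste0(path, ": unknown parameter field(s): ",
                        paste(extra, collapse = ", ")))
  }
  if (is.null(x$base_value)) {
    rlang::abort(paste0(path, ": missing field 'base_value'"))
  }
  if (is.null(x$unit) || !x$unit %in% .PARAM_UNITS) {
    rlang::abort(paste0(path, ": missing or unknown unit"))
  }
  dist <- if (is.null(x$dist)) dist_point(x$base_value) else {
    dist_from_list(x$dist, paste0(path, ".dist"))
  }
  validate_uparam(uparam(x$base_value, dist, x$unit), path)
}
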