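# Distribution machinery for uncertain model parameters.
#
# Specifications are stored on the scale they were elicited on (often a
# cumulative risk over a follow-up window) together with the transform that
# maps a draw onto the model's annual scale: `per_years` divides a cumulative
# probability by the follow-up length (linear annualization) and `frac`
# apportions a composite risk (e.g. total recurrence split into local and
# distant components).  `group` marks specifications that must share one
# underlying random draw per probabilistic-sensitivity-analysis iteration.

.DIST_KINDS <- c("beta", "gamma", "normal", "point", "sum")

new_dist <- function(kind, a = NA_real_, b = NA_real_, per_years = 1,
                     frac = 1, group = NA_character_, components = NULL,
                     target = NA_real_) {
  structure(
    list(kind = kind, a = a, b = b, per_years = per_years, frac = frac,
         group = group, components = components, target = target),
    class = "cryo_dist"
  )
}

validate_dist <- function(spec, path = "dist") {
  if (!inherits(spec, "cryo_dist")) {
    rlang::abort(paste0(path, ": not a distribution specification"))
  }
  if (!spec$kind %in% .DIST_KINDS) {
    rlang::abort(paste0(path, ": unknown distribution kind '", spec$kind, "'"))
  }
  ok <- switch(spec$kind,
    beta   = is.finite(spec$a) && is.finite(spec$b) && spec$a > 0 && spec$b > 0,
    gamma  = is.finite(spec$a) && is.finite(spec$b) && spec$a > 0 && spec$b > 0,
    normal = is.finite(spec$a) && is.finite(spec$b) && spec$b >= 0,
    point  = is.finite(spec$a),
    sum    = length(spec$components) >= 1
  )
  if (!ok) {
    rlang::abort(paste0(path, ": invalid ", spec$kind, " parameters (a = ",
                        spec$a, ", b = ", spec$b, ")"))
  }
  if (!is.numeric(spec$per_years) || spec$per_years <= 0) {
    rlang::abort(paste0(path, ": per_years must be > 0"))
  }
  if (identical(spec$kind, "sum")) {
    for (i in seq_along(spec$components)) {
      validate_dist(spec$components[[i]], paste0(path, ".components[", i, "]"))
    }
  }
  invisible(spec)
}

#' Distribution specifications for uncertain parameters
#'
#' Constructors for the parameter distributions used by the probabilistic
#' sensitivity analysis and the tornado diagram.  Beta specifications may be
#' elicited on a cumulative scale: `per_years` divides draws by the follow-up
#' length (the linear annualization convention) and `frac` apportions a
#' composite risk between components.  Specifications sharing a `group` label
#' reuse a single underlying draw per iteration, inducing perfect correlation
#' (used e.g. to split one total-recurrence draw into local and distant
#' parts, and to share identical cost rows between treatment arms).
#'
#' @param shape1,shape2 Beta shape parameters (both > 0).
#' @param mean,sd Mean and standard deviation on the elicited scale.
#' @param value Fixed value for a point (degenerate) specification.
#' @param per_years Follow-up window in years over which the elicited
#'   probability is cumulative; draws are divided by it.
#' @param frac Fraction of the elicited quantity attributed to this
#'   parameter.
#' @param group Optional shared-draw group label.
#' @param target For components of `dist_sum()`: the published mean of the
#'   component, used by [rescale_scenario()].
#' @param ... Component specifications for `dist_sum()`.
#'
#' @return An object of class `cryo_dist`.
#' @seealso [dist_mean()], [dist_draw()], [gamma_from_mean_sd()]
#' @examples
#' dist_beta(8, 186, per_years = 5)   # cumulative 5-year risk, annualized
#' dist_gamma(2501, 500)              # cost with mean $2,501, SD $500
#' @export
dist_beta <- function(shape1, shape2, per_years = 1, frac = 1,
                      group = NA_character_, target = NA_real_) {
  validate_dist(new_dist("beta", shape1, shape2, per_years, frac, group,
                         target = target))
}

#' @rdname dist_beta
#' @export
dist_gamma <- function(mean, sd, group = NA_character_) {
  spec <- gamma_from_mean_sd(mean, sd)
  spec$group <- group
  spec
}

#' @rdname dist_beta
#' @export
dist_normal <- function(mean, sd, group = NA_character_) {
  validate_dist(new_dist("normal", mean, sd, group = group))
}

#' @rdname dist_beta
#' @export
dist_point <- function(value) {
  validate_dist(new_dist("point", value))
}

#' @rdname dist_beta
#' @export
dist_sum <- function(...) {
  validate_dist(new_dist("sum", components = list(...)))
}

#' @export
print.cryo_dist <- function(x, ...) {
  lab <- switch(x$kind,
    beta   = sprintf("Beta(%g, %g)", x$a, x$b),
    gamma  = sprintf("Gamma(shape = %g, scale = %g)", x$a, x$b),
    normal = sprintf("Normal(%g, sd = %g)", x$a, x$b),
    point  = sprintf("point at %g", x$a),
    sum    = paste0("sum of ", length(x$components), " components")
  )
  if (x$per_years != 1) lab <- paste0(lab, " over ", x$per_years, " years")
  if (x$frac != 1) lab <- paste0(lab, " x fraction ", x$frac)
  if (!is.na(x$group)) lab <- paste0(lab, " [shared draw: ", x$group, "]")
  cat("<cryo_dist> ", lab, "\n", sep = "")
  invisible(x)
}

#' Moment-matched Gamma specification from a mean and standard deviation
#'
#' Cost parameters are published as a mean with a standard deviation; the
#' Gamma distribution matching those first two moments has
#' `shape = (mean/sd)^2` and `scale = sd^2/mean`.
#'
#' @param mean,sd Positive mean and standard deviation (e.g. US dollars).
#' @return A `cryo_dist` of kind `"gamma"` with fields `a` (shape) and `b`
#'   (scale).
#' @examples
#' gamma_from_mean_sd(2501, 500)
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    rlang::abort("gamma_from_mean_sd(): mean and sd must both be positive")
  }
  validate_dist(new_dist("gamma", a = (mean / sd)^2, b = sd^2 / mean))
}

#' Mean of a Beta specification
#'
#' @param spec A `cryo_dist` of kind `"beta"`.
#' @return `a / (a + b)`, the mean on the elicited (possibly cumulative)
#'   scale, before any annualization.
#' @examples
#' beta_mean(dist_beta(2, 192))  # 0.0103
#' @export
beta_mean <- function(spec) {
  validate_dist(spec)
  if (!identical(spec$kind, "beta")) {
    rlang::abort("beta_mean(): spec is not a beta distribution")
  }
  spec$a / (spec$a + spec$b)
}

#' Convert a cumulative probability to an annual probability
#'
#' The linear convention divides the cumulative probability by the number of
#' years (the arithmetic used throughout the published parameter tables,
#' e.g. 4.3% over 5 years -> 0.86% per year); the exponential convention
#' assumes a constant hazard, `1 - (1 - p)^(1/years)`.  The two agree
#' closely for small risks; for windows longer than a year the constant-hazard
#' value is the larger of the two.
#'
#' @param p_cum Cumulative probability in `[0, 1]` (vectorized).
#' @param years Positive length of the window in years.
#' @param method `"linear"` (default) or `"exponential"`.
#' @return Annual probability.
#' @examples
#' cumulative_to_annual(0.043, 5)                  # 0.0086
#' cumulative_to_annual(0.043, 5, "exponential")
#' @export
cumulative_to_annual <- function(p_cum, years,
                                 method = c("linear", "exponential")) {
  method <- match.arg(method)
  if (any(!is.finite(p_cum)) || any(p_cum < 0) || any(p_cum > 1)) {
    rlang::abort("cumulative_to_annual(): p_cum must lie in [0, 1]")
  }
  if (!is.numeric(years) || any(years <= 0)) {
    rlang::abort("cumulative_to_annual(): years must be > 0")
  }
  switch(method,
    linear      = p_cum / years,
    exponential = 1 - (1 - p_cum)^(1 / years)
  )
}

.underlying_mean <- function(spec) {
  switch(spec$kind,
    beta   = spec$a / (spec$a + spec$b),
    gamma  = spec$a * spec$b,
    normal = spec$a,
    point  = spec$a,
    sum    = sum(vapply(spec$components, .underlying_mean, numeric(1)))
  )
}

.annualize <- function(x, spec, method = "linear") {
  if (identical(method, "exponential") && spec$per_years != 1) {
    (1 - (1 - x)^(1 / spec$per_years)) * spec$frac
  } else {
    x / spec$per_years * spec$frac
  }
}

#' Mean, quantiles and random draws of a distribution specification
#'
#' All three return values on the model scale, i.e. after annualization by
#' `per_years` and scaling by `frac`.  For `dist_sum()` specifications the
#' quantile is the sum of component quantiles (the comonotone bound, used
#' only to set tornado-diagram ranges), while draws sum independent
#' component draws.
#'
#' @param spec A `cryo_dist`.
#' @param p Probability (vectorized) for `dist_quantile()`.
#' @param n Number of draws for `dist_draw()`.
#' @param u Optional uniform variates to invert (length `n`); used to share
#'   draws across grouped specifications.
#' @param annualization `"linear"` or `"exponential"`.
#' @return Numeric vector.
#' @examples
#' dist_mean(dist_beta(8, 186, per_years = 5))
#' dist_quantile(dist_gamma(2501, 500), c(0.025, 0.975))
#' @export
dist_mean <- function(spec, annualization = "linear") {
  validate_dist(spec)
  if (identical(spec$kind, "sum")) {
    return(sum(vapply(spec$components, dist_mean, numeric(1),
                      annualization = annualization)))
  }
  .annualize(.underlying_mean(spec), spec, annualization)
}

#' @rdname dist_mean
#' @export
dist_quantile <- function(spec, p, annualization = "linear") {
  validate_dist(spec)
  q <- switch(spec$kind,
    beta   = stats::qbeta(p, spec$a, spec$b),
    gamma  = stats::qgamma(p, shape = spec$a, scale = spec$b),
    normal = stats::qnorm(p, spec$a, spec$b),
    point  = rep(spec$a, length(p)),
    sum    = {
      comp <- vapply(spec$components, dist_quantile, numeric(length(p)),
                     p = p, annualization = annualization)
      return(if (length(p) == 1L) sum(comp) else rowSums(comp))
    }
  )
  .annualize(q, spec, annualization)
}

#' @rdname dist_mean
#' @export
dist_draw <- function(spec, n = 1, u = NULL, annualization = "linear") {
  validate_dist(spec)
  if (identical(spec$kind, "sum")) {
    comp <- vapply(spec$components, dist_draw, numeric(n), n = n,
                   annualization = annualization)
    return(if (n == 1L) sum(comp) else rowSums(comp))
  }
  if (identical(spec$kind, "point")) {
    return(rep(.annualize(spec$a, spec, annualization), n))
  }
  if (is.null(u)) u <- stats::runif(n)
  dist_quantile(spec, u, annualization = annualization)
}

#' Is a specification degenerate (a point mass)?
#'
#' @param spec A `cryo_dist`.
#' @return Logical scalar.
#' @export
is_point_dist <- function(spec) {
  identical(spec$kind, "point") ||
    (identical(spec$kind, "normal") && spec$b == 0)
}

# Rescale one specification so that its implied model-scale mean matches the
# published base value, whenever the two disagree by more than rel_tol
# (default 10%) relative.  Beta keeps the effective sample size (a + b) and
# resets the mean; Gamma keeps the coefficient of variation (i.e. the
# shape) and resets the scale; Normal resets its mean.  Components of a sum
# are rescaled toward their own `target` means.
rescale_dist <- function(spec, base_value, rel_tol = 0.1) {
  validate_dist(spec)
  if (identical(spec$kind, "sum")) {
    spec$components <- lapply(spec$components, function(cs) {
      if (is.na(cs$target)) cs else rescale_dist(cs, cs$target, rel_tol)
    })
    return(spec)
  }
  if (is_point_dist(spec) || base_value == 0) return(spec)
  implied <- dist_mean(spec)
  if (abs(implied - base_value) / abs(base_value) <= rel_tol) return(spec)
  m <- base_value * spec$per_years / spec$frac  # target mean, elicited scale
  if (identical(spec$kind, "beta")) {
    n_eff <- spec$a + spec$b
    spec$a <- n_eff * m
    spec$b <- n_eff * (1 - m)
  } else if (identical(spec$kind, "gamma")) {
    spec$b <- m / spec$a   # shape (= 1/cv^2) kept, scale reset
  } else if (identical(spec$kind, "normal")) {
    spec$a <- m
  }
  validate_dist(spec)
}
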