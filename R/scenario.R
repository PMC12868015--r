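# Scenario objects: the complete parameter set for one BCA-vs-BCS
# comparison, with validation and YAML/JSON round-tripping.

.STRAT_FIELDS <- c(
  "procedure_cost", "complication_prob", "complication_cost",
  "treatment_disutility", "complication_disutility",
  "p_local_annual", "p_distant_annual", "p_mortality_annual",
  "routine_cost_increment"
)
.STRAT_UNITS <- c(
  procedure_cost = "usd", complication_prob = "probability",
  complication_cost = "usd", treatment_disutility = "utility",
  complication_disutility = "utility",
  p_local_annual = "probability_per_year",
  p_distant_annual = "probability_per_year",
  p_mortality_annual = "probability_per_year",
  routine_cost_increment = "usd"
)
.SHARED_FIELDS <- c(
  "routine_annual_cost", "local_recurrence_cost", "advanced_disease_cost",
  "u_first_year", "u_subsequent", "u_local", "u_distant"
)
.SHARED_UNITS <- c(
  routine_annual_cost = "usd", local_recurrence_cost = "usd",
  advanced_disease_cost = "usd", u_first_year = "utility",
  u_subsequent = "utility", u_local = "utility", u_distant = "utility"
)
.ECON_FIELDS <- c("discount_rate", "wtp", "horizon_cycles",
                  "cycle_length_years", "annualization")

#' Strategy-arm parameters
#'
#' The per-strategy block of a [scenario()]: one-time procedure and
#' complication costs and disutilities, plus the three annual transition
#' probabilities out of the disease-free state.  `routine_cost_increment`
#' is an additive per-cycle surveillance cost applied on top of the shared
#' routine cost (0 unless a sensitivity analysis varies it).
#'
#' @param name Strategy label.
#' @param procedure_cost,complication_prob,complication_cost One-time
#'   treatment cost, per-procedure complication probability, and cost per
#'   complication, as [uparam()] objects.
#' @param treatment_disutility,complication_disutility First-cycle utility
#'   decrements ([uparam()]); the complication decrement is weighted by
#'   `complication_prob`.
#' @param p_local_annual,p_distant_annual,p_mortality_annual Annual
#'   probabilities of local recurrence, distant recurrence, and
#'   breast-cancer death ([uparam()]); their base values must sum to at
#'   most 1.
#' @param routine_cost_increment Additive annual surveillance cost
#'   ([uparam()], default 0).
#' @return A list of class `cryo_strategy`.
#' @export
strategy_params <- function(name, procedure_cost, complication_prob,
                            complication_cost, treatment_disutility,
                            complication_disutility, p_local_annual,
                            p_distant_annual, p_mortality_annual,
                            routine_cost_increment = uparam(0, unit = "usd")) {
  structure(
    list(name = name, procedure_cost = procedure_cost,
         complication_prob = complication_prob,
         complication_cost = complication_cost,
         treatment_disutility = treatment_disutility,
         complication_disutility = complication_disutility,
         p_local_annual = p_local_annual,
         p_distant_annual = p_distant_annual,
         p_mortality_annual = p_mortality_annual,
         routine_cost_increment = routine_cost_increment),
    class = "cryo_strategy"
  )
}

#' Parameters shared between both strategies
#'
#' Annual routine (stage I surveillance) cost, local-recurrence and
#' advanced-disease costs, and the health-state utility weights.  The dead
#' state has utility 0 exactly and is not a parameter.
#'
#' @param routine_annual_cost,local_recurrence_cost,advanced_disease_cost
#'   Cost parameters ([uparam()], US dollars).
#' @param u_first_year,u_subsequent,u_local,u_distant Utility weights
#'   ([uparam()], in `[0, 1]`).
#' @return A list of class `cryo_shared`.
#' @export
shared_params <- function(routine_annual_cost, local_recurrence_cost,
                          advanced_disease_cost, u_first_year, u_subsequent,
                          u_local, u_distant) {
  structure(
    list(routine_annual_cost = routine_annual_cost,
         local_recurrence_cost = local_recurrence_cost,
         advanced_disease_cost = advanced_disease_cost,
         u_first_year = u_first_year, u_subsequent = u_subsequent,
         u_local = u_local, u_distant = u_distant),
    class = "cryo_shared"
  )
}

#' Economic settings
#'
#' @param discount_rate Annual discount rate (default 0.03).
#' @param wtp Willingness-to-pay in dollars per QALY (default 100,000).
#' @param horizon_cycles Number of one-year Markov cycles (default 5).
#' @param cycle_length_years Cycle length; fixed at 1 year.
#' @param annualization `"linear"` (default) or `"exponential"` conversion
#'   between cumulative and annual probabilities.
#' @return A list of class `cryo_econ`.
#' @export
econ_settings <- function(discount_rate = 0.03, wtp = 1e5,
                          horizon_cycles = 5L, cycle_length_years = 1,
                          annualization = c("linear", "exponential")) {
  annualization <- match.arg(annualization)
  structure(
    list(discount_rate = discount_rate, wtp = wtp,
         horizon_cycles = as.integer(horizon_cycles),
         cycle_length_years = cycle_length_years,
         annualization = annualization),
    class = "cryo_econ"
  )
}

#' Assemble and validate a scenario
#'
#' A scenario bundles the two strategy arms, the shared cost/utility
#' parameters, the economic settings and the structural [variant_flags()].
#' Every invariant (probabilities in range, costs nonnegative, utilities in
#' `[0, 1]`, annual risks summing to at most 1) is checked on construction.
#'
#' @param name Scenario label.
#' @param bca,bcs [strategy_params()] for cryoablation and surgery.
#' @param shared [shared_params()].
#' @param econ [econ_settings()].
#' @param variant [variant_flags()].
#' @return A validated list of class `cryo_scenario`.
#' @seealso [read_scenario()], [paper_scenarios()], [run_cohort()]
#' @export
scenario <- function(name, bca, bcs, shared, econ = econ_settings(),
                     variant = variant_flags()) {
  validate_scenario(structure(
    list(name = name, bca = bca, bcs = bcs, shared = shared, econ = econ,
         variant = variant),
    class = "cryo_scenario"
  ))
}

#' Validate a scenario
#'
#' @param scn A `cryo_scenario`.
#' @return The scenario, invisibly unchanged, or an error naming the
#'   offending parameter path.
#' @export
validate_scenario <- function(scn) {
  if (!inherits(scn, "cryo_scenario")) {
    rlang::abort("not a cryo_scenario object")
  }
  if (!is.character(scn$name) || length(scn$name) != 1L) {
    rlang::abort("name: must be a single string")
  }
  for (arm in c("bca", "bcs")) {
    st <- scn[[arm]]
    if (!inherits(st, "cryo_strategy")) {
      rlang::abort(paste0(arm, ": not a strategy_params block"))
    }
    for (f in .STRAT_FIELDS) {
      p <- st[[f]]
      if (is.null(p)) rlang::abort(paste0(arm, ".", f, ": missing"))
      validate_uparam(p, paste0(arm, ".", f))
      if (!identical(p$unit, unname(.STRAT_UNITS[f]))) {
        rlang::abort(paste0(arm, ".", f, ": unit must be '",
                            .STRAT_UNITS[f], "'"))
      }
    }
    psum <- st$p_local_annual$base_value + st$p_distant_annual$base_value +
      st$p_mortality_annual$base_value
    if (psum > 1 + 1e-12) {
      rlang::abort(paste0(arm, ": annual local + distant + mortality ",
                          "probabilities sum to ", signif(psum, 6), " > 1"))
    }
  }
  if (!inherits(scn$shared, "cryo_shared")) {
    rlang::abort("shared: not a shared_params block")
  }
  for (f in .SHARED_FIELDS) {
    p <- scn$shared[[f]]
    if (is.null(p)) rlang::abort(paste0("shared.", f, ": missing"))
    validate_uparam(p, paste0("shared.", f))
    if (!identical(p$unit, unname(.SHARED_UNITS[f]))) {
      rlang::abort(paste0("shared.", f, ": unit must be '",
                          .SHARED_UNITS[f], "'"))
    }
    if (startsWith(f, "u_") && p$base_value < 0) {
      rlang::abort(paste0("shared.", f, ": utilities must lie in [0, 1]"))
    }
  }
  ec <- scn$econ
  if (!inherits(ec, "cryo_econ")) rlang::abort("econ: not an econ_settings block")
  if (ec$discount_rate < 0) rlang::abort("econ.discount_rate: must be >= 0")
  if (ec$horizon_cycles < 1) rlang::abort("econ.horizon_cycles: must be >= 1")
  if (ec$wtp < 0) rlang::abort("econ.wtp: must be >= 0")
  validate_variant(scn$variant)
  invisible(scn)
}

#' @export
print.cryo_scenario <- function(x, ...) {
  cat("<cryo_scenario> ", x$name, "\n", sep = "")
  cat(sprintf("  horizon %d x %g-year cycles, discount %.1f%%, WTP $%s/QALY\n",
              x$econ$horizon_cycles, x$econ$cycle_length_years,
              100 * x$econ$discount_rate,
              format(x$econ$wtp, big.mark = ",", scientific = FALSE)))
  for (arm in c("bca", "bcs")) {
    st <- x[[arm]]
    cat(sprintf(
      "  %s: procedure $%s, annual local %.2f%% / distant %.2f%% / mortality %.2f%%\n",
      arm, format(st$procedure_cost$base_value, big.mark = ","),
      100 * st$p_local_annual$base_value,
      100 * st$p_distant_annual$base_value,
      100 * st$p_mortality_annual$base_value))
  }
  invisible(x)
}

# ---- parameter addressing ---------------------------------------------------

#' List, read, or replace uncertain parameters by dotted path
#'
#' Parameters are addressed as `"<block>.<field>"`, e.g.
#' `"bca.procedure_cost"` or `"shared.routine_annual_cost"`.
#' `param_paths()` tabulates every addressable parameter; `set_param()`
#' replaces only the base value (used by the deterministic sensitivity
#' analyses), returning a revalidated scenario.
#'
#' @param scn A `cryo_scenario`.
#' @param path Dotted parameter address.
#' @param value Replacement base value.
#' @param uncertain_only For `param_paths()`: keep only parameters with a
#'   non-degenerate distribution.
#' @return `get_param()` returns the [uparam()]; `set_param()` the modified
#'   scenario; `param_paths()` a tibble with columns `path`, `unit`,
#'   `kind`, `base_value`.
#' @export
get_param <- function(scn, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("bca", "bcs", "shared")) {
    rlang::abort(paste0("unknown parameter path: ", path))
  }
  p <- scn[[parts[1]]][[parts[2]]]
  if (is.null(p)) rlang::abort(paste0("unknown parameter path: ", path))
  p
}

#' @rdname get_param
#' @export
set_param <- function(scn, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  p <- get_param(scn, path)
  p$base_value <- value
  scn[[parts[1]]][[parts[2]]] <- p
  validate_scenario(scn)
  scn
}

#' @rdname get_param
#' @export
param_paths <- function(scn, uncertain_only = FALSE) {
  paths <- c(paste0("bca.", .STRAT_FIELDS), paste0("bcs.", .STRAT_FIELDS),
             paste0("shared.", .SHARED_FIELDS))
  out <- purrr::map_dfr(paths, function(pp) {
    p <- get_param(scn, pp)
    tibble::tibble(path = pp, unit = p$unit, kind = p$dist$kind,
                   base_value = p$base_value)
  })
  if (uncertain_only) out <- dplyr::filter(out, .data$kind != "point")
  out
}

#' @method as_tibble cryo_scenario
#' @export
as_tibble.cryo_scenario <- function(x, ...) {
  dplyr::mutate(param_paths(x),
                implied_mean = purrr::map_dbl(.data$path, function(pp) {
                  dist_mean(get_param(x, pp)$dist)
                }))
}

#' @method tidy cryo_scenario
#' @export
tidy.cryo_scenario <- function(x, ...) as_tibble.cryo_scenario(x)

# ---- file round trip --------------------------------------------------------

scenario_to_list <- function(scn) {
  strat_list <- function(st) {
    out <- lapply(st[.STRAT_FIELDS], param_to_list)
    c(list(name = st$name), out)
  }
  list(
    name = scn$name,
    econ = unclass(scn$econ),
    variant = unclass(scn$variant),
    bca = strat_list(scn$bca),
    bcs = strat_list(scn$bcs),
    shared = lapply(scn$shared[.SHARED_FIELDS], param_to_list)
  )
}

scenario_from_list <- function(x) {
  known <- c("name", "econ", "variant", "bca", "bcs", "shared")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    rlang::abort(paste0("unknown scenario field(s): ",
                        paste(extra, collapse = ", ")))
  }
  for (f in known) {
    if (is.null(x[[f]])) rlang::abort(paste0("missing scenario field: ", f))
  }
  parse_strat <- function(b, arm) {
    extra <- setdiff(names(b), c("name", .STRAT_FIELDS))
    if (length(extra)) {
      rlang::abort(paste0(arm, ": unknown field(s): ",
                          paste(extra, collapse = ", ")))
    }
    args <- lapply(.STRAT_FIELDS, function(f) {
      if (is.null(b[[f]])) rlang::abort(paste0(arm, ".", f, ": missing"))
      param_from_list(b[[f]], paste0(arm, ".", f))
    })
    names(args) <- .STRAT_FIELDS
    do.call(strategy_params, c(list(name = b$name %||% arm), args))
  }
  extra_sh <- setdiff(names(x$shared), .SHARED_FIELDS)
  if (length(extra_sh)) {
    rlang::abort(paste0("shared: unknown field(s): ",
                        paste(extra_sh, collapse = ", ")))
  }
  shared_args <- lapply(.SHARED_FIELDS, function(f) {
    if (is.null(x$shared[[f]])) rlang::abort(paste0("shared.", f, ": missing"))
    param_from_list(x$shared[[f]], paste0("shared.", f))
  })
  names(shared_args) <- .SHARED_FIELDS
  extra_ec <- setdiff(names(x$econ), .ECON_FIELDS)
  if (length(extra_ec)) {
    rlang::abort(paste0("econ: unknown field(s): ",
                        paste(extra_ec, collapse = ", ")))
  }
  scenario(
    name = x$name,
    bca = parse_strat(x$bca, "bca"),
    bcs = parse_strat(x$bcs, "bcs"),
    shared = do.call(shared_params, shared_args),
    econ = do.call(econ_settings, x$econ),
    variant = do.call(variant_flags, x$variant)
  )
}

#' Read and write scenario configuration files
#'
#' Scenarios serialize to YAML or JSON (chosen by file extension, or the
#' `format` argument).  All monetary values are US dollars, probabilities
#' are decimals, and one cycle is one year.  Reading validates every field
#' and rejects unknown keys, naming the offending path.
#'
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @param scn A `cryo_scenario`.
#' @param format Optional override of the extension-derived format.
#' @return `read_scenario()` returns a validated `cryo_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_scenario(paper_scenarios()$low_risk, f)
#' scn <- read_scenario(f)
#' @export
read_scenario <- function(path, format = NULL) {
  format <- format %||% .format_from_ext(path)
  x <- switch(format,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  )
  scenario_from_list(x)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scn, path, format = NULL) {
  validate_scenario(scn)
  format <- format %||% .format_from_ext(path)
  x <- scenario_to_list(scn)
  switch(format,
    yaml = yaml::write_yaml(x, path, precision = 15L),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null")
  )
  invisible(path)
}

.format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  rlang::abort(paste0("cannot infer scenario format from extension '.",
                      ext, "' (use .yaml or .json)"))
}

# ---- PSA mean reconciliation ------------------------------------------------

#' Reconcile sampling distributions with published base values
#'
#' The published parameter tables occasionally print a distribution whose
#' implied mean (after annualization) disagrees with the printed point
#' estimate that drives the base case.  Before probabilistic sampling,
#' every distribution whose implied mean is more than `rel_tol` (default
#' 10%) away from the base value is rescaled: Beta keeps its effective
#' sample size (alpha + beta) and resets its mean, Gamma keeps its
#' coefficient of variation, Normal resets its mean.  Point masses are
#' untouched.
#'
#' @param scn A `cryo_scenario`.
#' @param rel_tol Relative disagreement that triggers rescaling.
#' @return The scenario with adjusted distributions.
#' @export
rescale_scenario <- function(scn, rel_tol = 0.1) {
  validate_scenario(scn)
  for (arm in c("bca", "bcs")) {
    for (f in .STRAT_FIELDS) {
      p <- scn[[arm]][[f]]
      p$dist <- rescale_dist(p$dist, p$base_value, rel_tol)
      scn[[arm]][[f]] <- p
    }
  }
  for (f in .SHARED_FIELDS) {
    p <- scn$shared[[f]]
    p$dist <- rescale_dist(p$dist, p$base_value, rel_tol)
    scn$shared[[f]] <- p
  }
  scn
}
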