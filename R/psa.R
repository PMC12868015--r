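# Probabilistic sensitivity analysis: joint parameter sampling and
# decision-uncertainty summaries.

.ALL_PARAM_PATHS <- function() {
  c(paste0("bca.", .STRAT_FIELDS), paste0("bcs.", .STRAT_FIELDS),
    paste0("shared.", .SHARED_FIELDS))
}

# Draw n values for every parameter, in the fixed documented order
# (cryoablation arm fields, surgery arm fields, shared fields).  Grouped
# specifications reuse one uniform draw per iteration when shared_draws is
# TRUE; point parameters consume no randomness.  Returns a named list
# path -> numeric(n) on the model (annual) scale, clamped to each unit's
# valid range.
.psa_values <- function(scn, n, shared_draws = TRUE) {
  ann <- scn$econ$annualization
  group_u <- list()
  values <- list()
  for (path in .ALL_PARAM_PATHS()) {
    p <- get_param(scn, path)
    spec <- p$dist
    if (is_point_dist(spec)) {
      values[[path]] <- rep(p$base_value, n)
      next
    }
    if (identical(spec$kind, "sum")) {
      v <- dist_draw(spec, n, annualization = ann)
    } else if (!is.na(spec$group) && shared_draws) {
      if (is.null(group_u[[spec$group]])) {
        group_u[[spec$group]] <- stats::runif(n)
      }
      v <- dist_draw(spec, n, u = group_u[[spec$group]], annualization = ann)
    } else {
      v <- dist_draw(spec, n, annualization = ann)
    }
    values[[path]] <- clamp_unit(v, p$unit)
  }
  # keep each arm's annual risks jointly feasible
  for (arm in c("bca", "bcs")) {
    s <- values[[paste0(arm, ".p_local_annual")]] +
      values[[paste0(arm, ".p_distant_annual")]] +
      values[[paste0(arm, ".p_mortality_annual")]]
    bad <- s > 1
    if (any(bad)) {
      for (f in c("p_local_annual", "p_distant_annual", "p_mortality_annual")) {
        key <- paste0(arm, ".", f)
        values[[key]][bad] <- values[[key]][bad] / s[bad]
      }
    }
  }
  values
}

#' Draw one scenario from the parameter distributions
#'
#' Replaces every uncertain parameter's base value with one draw from its
#' distribution (point parameters unchanged), sharing draws within groups,
#' clamping probabilities and utilities to `[0, 1]`, and rescaling each
#' arm's annual risks onto the simplex in the rare case they exceed 1
#' jointly.  Uses the current RNG state; seed externally (e.g. with
#' [withr::with_seed()]) for reproducibility.
#'
#' @param base A `cryo_scenario`.
#' @param shared_draws Draw parameters shared between arms once (default
#'   TRUE).
#' @param rescale Apply [rescale_scenario()] first (default TRUE).
#' @return A `cryo_scenario` with drawn base values.
#' @export
draw_scenario <- function(base, shared_draws = TRUE, rescale = TRUE) {
  validate_scenario(base)
  scn <- if (rescale) rescale_scenario(base) else base
  vals <- .psa_values(scn, 1L, shared_draws)
  out <- base
  for (path in names(vals)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]]$base_value <- vals[[path]][1]
  }
  validate_scenario(out)
  out
}

#' Probabilistic sensitivity analysis
#'
#' Samples every uncertain parameter from its distribution `n` times
#' (parameters shared between arms drawn once per iteration), runs both
#' cohorts per iteration, and summarizes decision uncertainty: the
#' proportion of iterations preferring cryoablation at the scenario
#' willingness-to-pay, and the cost-effectiveness acceptability curve over
#' a willingness-to-pay grid.  Reruns with the same seed are identical.
#'
#' @param scn A `cryo_scenario`.
#' @param n Number of iterations (default 10,000).
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve
#'   (default $0-$200,000 in $10,000 steps).
#' @param rescale Reconcile distribution means with base values first
#'   (default TRUE).
#' @param shared_draws Draw between-arm shared parameters once per
#'   iteration (default TRUE); set FALSE for independent sampling.
#' @return An object of class `psa_result` with elements `draws`
#'   (per-iteration tibble), `proportion_bca_preferred`, `ceac` (tibble
#'   `wtp`, `p_bca`), `summary` (per-strategy means and SDs), `n`, `seed`,
#'   `wtp`.
#' @examples
#' psa <- run_psa(paper_scenarios()$low_risk, n = 200, seed = 1)
#' psa$proportion_bca_preferred
#' @export
run_psa <- function(scn, n = 10000, seed = 1L,
                    wtp_grid = seq(0, 2e5, by = 1e4), rescale = TRUE,
                    shared_draws = TRUE) {
  validate_scenario(scn)
  if (n < 1) rlang::abort("run_psa(): n must be >= 1")
  scn_s <- if (rescale) rescale_scenario(scn) else scn
  vals <- withr::with_seed(as.integer(seed),
                           .psa_values(scn_s, as.integer(n), shared_draws))
  tmpl <- list(bca = .strategy_numbers(scn_s, "bca"),
               bcs = .strategy_numbers(scn_s, "bcs"))
  short <- .NUM_FIELD
  cost <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("bca", "bcs")))
  qaly <- cost
  for (i in seq_len(n)) {
    for (arm in c("bca", "bcs")) {
      num <- tmpl[[arm]]
      for (f in .STRAT_FIELDS) {
        num[[short[[f]]]] <- vals[[paste0(arm, ".", f)]][i]
      }
      for (f in .SHARED_FIELDS) {
        num[[short[[f]]]] <- vals[[paste0("shared.", f)]][i]
      }
      r <- .cohort_totals(num)
      cost[i, arm] <- r[["cost"]]
      qaly[i, arm] <- r[["qaly"]]
    }
  }
  wtp <- scn$econ$wtp
  delta_cost <- cost[, "bca"] - cost[, "bcs"]
  delta_qaly <- qaly[, "bca"] - qaly[, "bcs"]
  nmb_diff <- wtp * delta_qaly - delta_cost
  draws <- tibble::tibble(
    iteration = seq_len(n),
    cost_bca = cost[, "bca"], qaly_bca = qaly[, "bca"],
    cost_bcs = cost[, "bcs"], qaly_bcs = qaly[, "bcs"],
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    preferred = dplyr::case_when(nmb_diff > 0 ~ "bca", nmb_diff < 0 ~ "bcs",
                                 TRUE ~ "tie")
  )
  ceac <- tibble::tibble(
    wtp = wtp_grid,
    p_bca = vapply(wtp_grid,
                   function(w) mean(w * delta_qaly - delta_cost > 0),
                   numeric(1))
  )
  summary <- tibble::tibble(
    strategy = c("bca", "bcs"),
    mean_cost = colMeans(cost), sd_cost = apply(cost, 2, stats::sd),
    mean_qaly = colMeans(qaly), sd_qaly = apply(qaly, 2, stats::sd)
  )
  structure(
    list(scenario_name = scn$name, n = as.integer(n),
         seed = as.integer(seed), wtp = wtp, draws = draws,
         proportion_bca_preferred = mean(nmb_diff > 0), ceac = ceac,
         summary = summary),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %s: %d iterations (seed %d), BCA preferred in %.1f%% at WTP $%s\n",
    x$scenario_name, x$n, x$seed, 100 * x$proportion_bca_preferred,
    format(x$wtp, big.mark = ",", scientific = FALSE)))
  print(x$summary)
  invisible(x)
}

#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "strategy",
                             values_from = c("mean_cost", "sd_cost",
                                             "mean_qaly", "sd_qaly"))
  dplyr::bind_cols(
    tibble::tibble(scenario = x$scenario_name, n = x$n, seed = x$seed,
                   wtp = x$wtp,
                   proportion_bca_preferred = x$proportion_bca_preferred),
    wide
  )
}
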