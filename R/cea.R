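# Incremental cost-effectiveness metrics: NMB, ICER, dominance.

#' Net monetary benefit
#'
#' `nmb = wtp * qaly - cost`.  The strategy with the higher net monetary
#' benefit at a given willingness-to-pay is preferred.
#'
#' @param cost Total discounted cost in dollars (vectorized).
#' @param qaly Total discounted QALYs.
#' @param wtp Willingness-to-pay in dollars per QALY (>= 0).
#' @return Dollars.
#' @examples
#' nmb(173766, 3.69, 1e5)
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) rlang::abort("nmb(): wtp must be >= 0")
  wtp * qaly - cost
}

.icer_case <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("tie")
  if (delta_cost < 0 && delta_qaly > 0) return("dominant")
  if (delta_cost > 0 && delta_qaly < 0) return("dominated")
  if (sign(delta_cost) == sign(delta_qaly) && delta_cost != 0) return("ratio")
  "undefined"
}

#' Compare two strategy results at a willingness-to-pay
#'
#' Differences are cryoablation minus surgery (BCA is the reference).  The
#' ICER (incremental cost over incremental effectiveness) is reported only
#' when both increments share a nonzero sign; otherwise the comparison is
#' classified as `dominant` (BCA cheaper and more effective), `dominated`
#' (the reverse), `tie`, or `undefined`.  Preference is the argmax of net
#' monetary benefit, with exact ties reported explicitly as `"tie"`.
#'
#' @param bca,bcs [run_cohort()] results for the two arms of one scenario.
#' @param wtp Willingness-to-pay in dollars per QALY.
#' @return An object of class `cea_comparison`; see [glance.cea_comparison()].
#' @examples
#' scn <- paper_scenarios()$low_risk
#' compare_strategies(run_cohort(scn, "bca"), run_cohort(scn, "bcs"), 1e5)
#' @export
compare_strategies <- function(bca, bcs, wtp) {
  stopifnot(inherits(bca, "strategy_result"), inherits(bcs, "strategy_result"))
  delta_cost <- bca$total_cost - bcs$total_cost
  delta_qaly <- bca$total_qaly - bcs$total_qaly
  icer_case <- .icer_case(delta_cost, delta_qaly)
  icer <- if (identical(icer_case, "ratio")) delta_cost / delta_qaly else NA_real_
  nmb_bca <- nmb(bca$total_cost, bca$total_qaly, wtp)
  nmb_bcs <- nmb(bcs$total_cost, bcs$total_qaly, wtp)
  preferred <- if (nmb_bca > nmb_bcs) "bca" else if (nmb_bca < nmb_bcs) "bcs" else "tie"
  structure(
    list(scenario_name = bca$scenario_name, wtp = wtp, bca = bca, bcs = bcs,
         delta_cost = delta_cost, delta_qaly = delta_qaly, icer = icer,
         icer_case = icer_case, nmb_bca = nmb_bca, nmb_bcs = nmb_bcs,
         preferred = preferred),
    class = "cea_comparison"
  )
}

#' Run the base case for a scenario
#'
#' Runs both arms at their base values and compares them at the scenario's
#' willingness-to-pay.
#'
#' @param scn A `cryo_scenario`.
#' @param wtp Optional willingness-to-pay override (dollars per QALY).
#' @return A `cea_comparison`.
#' @examples
#' glance(run_base_case(paper_scenarios()$low_risk))
#' @export
run_base_case <- function(scn, wtp = NULL) {
  validate_scenario(scn)
  compare_strategies(run_cohort(scn, "bca"), run_cohort(scn, "bcs"),
                     wtp %||% scn$econ$wtp)
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s at WTP $%s/QALY\n", x$scenario_name,
              format(x$wtp, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  bca: cost $%s, QALY %.4f   bcs: cost $%s, QALY %.4f\n",
              format(round(x$bca$total_cost), big.mark = ","),
              x$bca$total_qaly,
              format(round(x$bcs$total_cost), big.mark = ","),
              x$bcs$total_qaly))
  cat(sprintf("  delta cost $%s, delta QALY %.4f (%s); preferred: %s\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly,
              x$icer_case, x$preferred))
  invisible(x)
}

#' Tidy accessors for base-case comparisons
#'
#' `tidy()` returns one row per strategy (cost, QALY, NMB); `glance()` one
#' row with the increments, the ICER or dominance classification, and the
#' preferred strategy.
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cea_comparison
#' @export
tidy.cea_comparison <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario_name,
    strategy = c("bca", "bcs"),
    total_cost = c(x$bca$total_cost, x$bcs$total_cost),
    total_qaly = c(x$bca$total_qaly, x$bcs$total_qaly),
    nmb = c(x$nmb_bca, x$nmb_bcs)
  )
}

#' @rdname tidy.cea_comparison
#' @method glance cea_comparison
#' @export
glance.cea_comparison <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario_name, wtp = x$wtp,
    cost_bca = x$bca$total_cost, qaly_bca = x$bca$total_qaly,
    cost_bcs = x$bcs$total_cost, qaly_bcs = x$bcs$total_qaly,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, icer_case = x$icer_case,
    nmb_bca = x$nmb_bca, nmb_bcs = x$nmb_bcs, preferred = x$preferred
  )
}
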