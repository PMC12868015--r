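# The discounted four-state Markov cohort engine.
#
# States: disease_free, local_recurrence, distant_recurrence, dead.  The
# cohort starts fully disease-free; one-time treatment costs fall at cycle
# 0 (undiscounted) and state costs/utilities accrue per cycle, discounted
# at the annual rate.  No half-cycle correction is applied.

.STATES <- c("disease_free", "local_recurrence", "distant_recurrence", "dead")

#' Structural variant flags
#'
#' The published state diagram leaves several structural readings open;
#' these flags enumerate them.  The defaults are the combination selected
#' by [calibrate_variant()]: among the variants that reproduce the
#' qualitative structure of the published one-way analyses (a break-even
#' point exists for each of the three cryoablation risks), the one with
#' the smallest mean relative error against the published base-case cost
#' cells and the procedure-cost break-even point.  That combination --
#' local recurrence billed once on entry (salvage treatment, then routine
#' surveillance), distant recurrence billed per cycle occupied (ongoing
#' advanced care), destination states accruing from the entry cycle, no
#' accrual after death, mortality from every alive state -- is also the
#' clinically conventional reading.
#'
#' @param lr_cost_mode,dr_cost_mode How recurrence costs accrue:
#'   `"one_time_on_entry"` bills the recurrence cost once on entry (the
#'   state then continues to accrue routine cost), `"per_cycle"` bills it
#'   every cycle occupied, replacing routine cost.
#' @param event_timing Whether a transition's destination state accrues its
#'   cost and utility in the cycle during which the transition occurs
#'   (`"entry_cycle"`) or only from the following cycle (`"next_cycle"`).
#' @param dead_accrues_routine Should the dead state continue to accrue the
#'   routine annual cost (a cohort-level cost-accounting reading)?
#' @param mortality_source_states Whether annual breast-cancer mortality
#'   applies from every alive state (`"all_alive"`) or from the
#'   disease-free state only (`"disease_free_only"`).
#' @return A list of class `cryo_variant`.
#' @export
variant_flags <- function(
    lr_cost_mode = c("one_time_on_entry", "per_cycle"),
    dr_cost_mode = c("per_cycle", "one_time_on_entry"),
    event_timing = c("entry_cycle", "next_cycle"),
    dead_accrues_routine = FALSE,
    mortality_source_states = c("all_alive", "disease_free_only")) {
  structure(
    list(lr_cost_mode = match.arg(lr_cost_mode),
         dr_cost_mode = match.arg(dr_cost_mode),
         event_timing = match.arg(event_timing),
         dead_accrues_routine = isTRUE(dead_accrues_routine),
         mortality_source_states = match.arg(mortality_source_states)),
    class = "cryo_variant"
  )
}

validate_variant <- function(fl) {
  if (!inherits(fl, "cryo_variant")) {
    rlang::abort("variant: not a variant_flags block")
  }
  ok <- fl$lr_cost_mode %in% c("one_time_on_entry", "per_cycle") &&
    fl$dr_cost_mode %in% c("one_time_on_entry", "per_cycle") &&
    fl$event_timing %in% c("entry_cycle", "next_cycle") &&
    is.logical(fl$dead_accrues_routine) &&
    fl$mortality_source_states %in% c("all_alive", "disease_free_only")
  if (!ok) rlang::abort("variant: invalid flag value")
  invisible(fl)
}

#' Discount factor for a cycle
#'
#' Cycle 0 is undiscounted; cycle `k` is weighted by `(1 + rate)^-k`.
#'
#' @param cycle Nonnegative integer cycle index (vectorized).
#' @param rate Annual discount rate.
#' @return Numeric discount weight(s).
#' @examples
#' discount_factor(0:4, 0.03)
#' @export
discount_factor <- function(cycle, rate) {
  if (any(cycle < 0)) rlang::abort("discount_factor(): cycle must be >= 0")
  (1 + rate)^(-cycle)
}

.transition_matrix_num <- function(pL, pD, pM, mortality_source) {
  stay <- 1 - pL - pD - pM
  if (stay < -1e-9) {
    rlang::abort(paste0(
      "annual local + distant + mortality probabilities sum to ",
      signif(pL + pD + pM, 6), " > 1"))
  }
  stay <- max(stay, 0)
  pm_rec <- if (identical(mortality_source, "all_alive")) pM else 0
  matrix(c(stay, pL,          pD,          pM,
           0,    1 - pm_rec,  0,           pm_rec,
           0,    0,           1 - pm_rec,  pm_rec,
           0,    0,           0,           1),
         nrow = 4, byrow = TRUE, dimnames = list(.STATES, .STATES))
}

#' Annual transition matrix for one strategy arm
#'
#' Builds the row-stochastic matrix over the four health states.  The
#' disease-free row is `[1 - pL - pD - pM, pL, pD, pM]`; recurrence states
#' self-persist (no return to disease-free within the horizon, matching the
#' exclusion of de novo second primaries) and route mortality according to
#' `flags$mortality_source_states`; dead is absorbing.
#'
#' @param sp A [strategy_params()] block (or a scenario arm).
#' @param flags A [variant_flags()] block.
#' @return A 4x4 named matrix.
#' @examples
#' scn <- paper_scenarios()$low_risk
#' build_transition_matrix(scn$bca, scn$variant)
#' @export
build_transition_matrix <- function(sp, flags = variant_flags()) {
  validate_variant(flags)
  .transition_matrix_num(sp$p_local_annual$base_value,
                         sp$p_distant_annual$base_value,
                         sp$p_mortality_annual$base_value,
                         flags$mortality_source_states)
}

# Plain-number view of one strategy arm within a scenario; the engine and
# the sensitivity analyses work on this to avoid touching the full object
# in inner loops.
.strategy_numbers <- function(scn, strategy) {
  st <- scn[[strategy]]
  sh <- scn$shared
  ec <- scn$econ
  list(
    pc = st$procedure_cost$base_value,
    cp = st$complication_prob$base_value,
    cc = st$complication_cost$base_value,
    td = st$treatment_disutility$base_value,
    cd = st$complication_disutility$base_value,
    pL = st$p_local_annual$base_value,
    pD = st$p_distant_annual$base_value,
    pM = st$p_mortality_annual$base_value,
    incr = st$routine_cost_increment$base_value,
    cr = sh$routine_annual_cost$base_value,
    clr = sh$local_recurrence_cost$base_value,
    cad = sh$advanced_disease_cost$base_value,
    u1 = sh$u_first_year$base_value,
    us = sh$u_subsequent$base_value,
    ul = sh$u_local$base_value,
    udr = sh$u_distant$base_value,
    rate = ec$discount_rate,
    H = ec$horizon_cycles,
    fl = scn$variant
  )
}

# Core engine on plain numbers.  Returns occupancy (H x 4), discounted
# per-cycle cost/QALY vectors, the one-time cost, and totals.
.cohort_run <- function(n) {
  fl <- n$fl
  H <- n$H
  P <- .transition_matrix_num(n$pL, n$pD, n$pM, fl$mortality_source_states)
  path <- matrix(0, H + 1L, 4L)
  path[1L, 1L] <- 1
  for (t in seq_len(H)) path[t + 1L, ] <- path[t, ] %*% P
  entry <- identical(fl$event_timing, "entry_cycle")
  lr_percycle <- identical(fl$lr_cost_mode, "per_cycle")
  dr_percycle <- identical(fl$dr_cost_mode, "per_cycle")
  occ <- matrix(0, H, 4L, dimnames = list(NULL, .STATES))
  cycle_cost <- numeric(H)
  cycle_qaly <- numeric(H)
  disc <- (1 + n$rate)^(-(0:(H - 1L)))
  for (k in 0:(H - 1L)) {
    a <- if (entry) path[k + 2L, ] else path[k + 1L, ]
    pre_df <- if (entry) path[k + 1L, 1L] else if (k >= 1L) path[k, 1L] else 0
    cost <- a[1L] * (n$cr + n$incr)
    cost <- cost + if (lr_percycle) a[2L] * n$clr else
      pre_df * n$pL * n$clr + a[2L] * (n$cr + n$incr)
    cost <- cost + if (dr_percycle) a[3L] * n$cad else
      pre_df * n$pD * n$cad + a[3L] * n$cr
    if (fl$dead_accrues_routine) cost <- cost + a[4L] * n$cr
    u_df <- if (k == 0L) n$u1 - n$td - n$cp * n$cd else n$us
    q <- a[1L] * u_df + a[2L] * n$ul + a[3L] * n$udr
    occ[k + 1L, ] <- a
    cycle_cost[k + 1L] <- disc[k + 1L] * cost
    cycle_qaly[k + 1L] <- disc[k + 1L] * q
  }
  onetime <- n$pc + n$cp * n$cc
  list(onetime_cost = onetime, occupancy = occ, cycle_cost = cycle_cost,
       cycle_qaly = cycle_qaly, total_cost = onetime + sum(cycle_cost),
       total_qaly = sum(cycle_qaly))
}

.cohort_totals <- function(n) {
  r <- .cohort_run(n)
  c(cost = r$total_cost, qaly = r$total_qaly)
}

#' Run the discounted cohort simulation for one strategy
#'
#' Simulates the cohort (starting 100% disease-free) over the scenario
#' horizon, accruing discounted costs and QALYs per cycle.  One-time costs
#' at cycle 0 are `procedure_cost + complication_prob * complication_cost`;
#' the first disease-free cycle uses the first-year utility minus the
#' treatment disutility and the probability-weighted complication
#' disutility, later disease-free cycles the subsequent-year utility.
#' State costs follow the scenario's [variant_flags()].
#'
#' @param scn A `cryo_scenario`.
#' @param strategy `"bca"` or `"bcs"`.
#' @return An object of class `strategy_result` with elements
#'   `total_cost`, `total_qaly`, `onetime_cost`, and `trace` (a tibble with
#'   columns `cycle`, `state`, `occupancy`, `discounted_cost`,
#'   `discounted_qaly`; per-cycle amounts are repeated across the four
#'   state rows of a cycle).
#' @examples
#' res <- run_cohort(paper_scenarios()$low_risk, "bca")
#' res$total_cost
#' glance(res)
#' @export
run_cohort <- function(scn, strategy = c("bca", "bcs")) {
  strategy <- match.arg(strategy)
  validate_scenario(scn)
  r <- .cohort_run(.strategy_numbers(scn, strategy))
  H <- scn$econ$horizon_cycles
  trace <- tibble::tibble(
    cycle = rep(0:(H - 1L), each = 4L),
    state = rep(.STATES, times = H),
    occupancy = as.vector(t(r$occupancy)),
    discounted_cost = rep(r$cycle_cost, each = 4L),
    discounted_qaly = rep(r$cycle_qaly, each = 4L)
  )
  structure(
    list(strategy = strategy, scenario_name = scn$name,
         total_cost = r$total_cost, total_qaly = r$total_qaly,
         onetime_cost = r$onetime_cost, cycle_cost = r$cycle_cost,
         cycle_qaly = r$cycle_qaly, trace = trace),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf(
    "<strategy_result> %s (%s): total cost $%s, total QALY %.4f\n",
    x$strategy, x$scenario_name,
    format(round(x$total_cost), big.mark = ","), x$total_qaly))
  invisible(x)
}

#' @method tidy strategy_result
#' @export
tidy.strategy_result <- function(x, ...) x$trace

#' @method glance strategy_result
#' @export
glance.strategy_result <- function(x, ...) {
  tibble::tibble(scenario = x$scenario_name, strategy = x$strategy,
                 total_cost = x$total_cost, total_qaly = x$total_qaly,
                 onetime_cost = x$onetime_cost)
}

#' Export a cohort trace to CSV
#'
#' Writes the per-cycle state occupancy and discounted accruals with
#' columns `cycle`, `state`, `occupancy`, `discounted_cost`,
#' `discounted_qaly`.
#'
#' @param result A [run_cohort()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(result, path) {
  stopifnot(inherits(result, "strategy_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
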