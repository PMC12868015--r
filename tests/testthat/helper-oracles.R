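# Independent oracles and scenario builders used across the suite.

# Brute-force cohort expectation by enumerating all 4^H state paths and
# accumulating each path's discounted costs and QALYs explicitly.  Shares
# nothing with the matrix-based engine except the scenario object.
oracle_cohort <- function(scn, strategy) {
  st <- scn[[strategy]]
  sh <- scn$shared
  ec <- scn$econ
  fl <- scn$variant
  pL <- st$p_local_annual$base_value
  pD <- st$p_distant_annual$base_value
  pM <- st$p_mortality_annual$base_value
  pmr <- if (fl$mortality_source_states == "all_alive") pM else 0
  P <- rbind(c(1 - pL - pD - pM, pL, pD, pM),
             c(0, 1 - pmr, 0, pmr),
             c(0, 0, 1 - pmr, pmr),
             c(0, 0, 0, 1))
  H <- ec$horizon_cycles
  disc <- (1 + ec$discount_rate)^(-(0:(H - 1)))
  cp <- st$complication_prob$base_value
  cr <- sh$routine_annual_cost$base_value
  incr <- st$routine_cost_increment$base_value
  clr <- sh$local_recurrence_cost$base_value
  cad <- sh$advanced_disease_cost$base_value
  u1 <- sh$u_first_year$base_value - st$treatment_disutility$base_value -
    cp * st$complication_disutility$base_value
  us <- sh$u_subsequent$base_value
  ul <- sh$u_local$base_value
  ud <- sh$u_distant$base_value
  entry <- fl$event_timing == "entry_cycle"
  lr_lump <- fl$lr_cost_mode == "one_time_on_entry"
  dr_lump <- fl$dr_cost_mode == "one_time_on_entry"
  total_cost <- st$procedure_cost$base_value +
    cp * st$complication_cost$base_value
  total_qaly <- 0
  paths <- as.matrix(expand.grid(rep(list(1:4), H)))
  for (r in seq_len(nrow(paths))) {
    x <- c(1L, paths[r, ])  # x[t+1] = state after t transitions
    prob <- 1
    for (t in 1:H) prob <- prob * P[x[t], x[t + 1]]
    if (prob == 0) next
    cost <- 0
    qaly <- 0
    for (k in 0:(H - 1)) {
      s <- if (entry) x[k + 2] else x[k + 1]
      tstep <- if (entry) k + 1 else k  # transition billed in cycle k
      ccost <- 0
      if (tstep >= 1) {
        if (lr_lump && x[tstep] == 1 && x[tstep + 1] == 2) ccost <- ccost + clr
        if (dr_lump && x[tstep] == 1 && x[tstep + 1] == 3) ccost <- ccost + cad
      }
      if (s == 1) ccost <- ccost + cr + incr
      if (s == 2) ccost <- ccost + (if (lr_lump) cr + incr else clr)
      if (s == 3) ccost <- ccost + (if (dr_lump) cr else cad)
      if (s == 4 && fl$dead_accrues_routine) ccost <- ccost + cr
      uq <- if (s == 1) (if (k == 0) u1 else us) else
        if (s == 2) ul else if (s == 3) ud else 0
      cost <- cost + disc[k + 1] * ccost
      qaly <- qaly + disc[k + 1] * uq
    }
    total_cost <- total_cost + prob * cost
    total_qaly <- total_qaly + prob * qaly
  }
  c(cost = total_cost, qaly = total_qaly)
}

# A scenario with no events, unit utilities and a single routine cost:
# closed forms are exact (QALYs equal the discount-factor sum).
degenerate_scenario <- function(procedure_cost = 1000, routine_cost = 36351,
                                rate = 0.03, horizon = 5L,
                                variant = variant_flags()) {
  zerop <- function(unit) uparam(0, unit = unit)
  arm <- function(name) {
    strategy_params(
      name = name,
      procedure_cost = uparam(procedure_cost, unit = "usd"),
      complication_prob = zerop("probability"),
      complication_cost = zerop("usd"),
      treatment_disutility = zerop("utility"),
      complication_disutility = zerop("utility"),
      p_local_annual = zerop("probability_per_year"),
      p_distant_annual = zerop("probability_per_year"),
      p_mortality_annual = zerop("probability_per_year")
    )
  }
  sh <- shared_params(
    routine_annual_cost = uparam(routine_cost, unit = "usd"),
    local_recurrence_cost = uparam(routine_cost, unit = "usd"),
    advanced_disease_cost = uparam(routine_cost, unit = "usd"),
    u_first_year = uparam(1, unit = "utility"),
    u_subsequent = uparam(1, unit = "utility"),
    u_local = uparam(1, unit = "utility"),
    u_distant = uparam(1, unit = "utility")
  )
  scenario("degenerate", arm("bca"), arm("bcs"), sh,
           econ = econ_settings(discount_rate = rate,
                                horizon_cycles = horizon),
           variant = variant)
}

# Every variant-flag combination, as a list of variant_flags objects.
all_variants <- function() {
  g <- variant_grid()
  purrr::pmap(g, variant_flags)
}

# Minimal strategy_result stub for metric-level tests.
fake_result <- function(cost, qaly, strategy = "bca", name = "fake") {
  structure(list(strategy = strategy, scenario_name = name,
                 total_cost = cost, total_qaly = qaly),
            class = "strategy_result")
}
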