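#' CD4-stratified health states
#'
#' The model describes HIV disease severity with five health states defined
#' by CD4 count ranges (ascending: <50, 50-199, 200-349, 350-499, >=500
#' cells/mm3). Each state carries an annual non-antiretroviral care cost
#' (inpatient + outpatient + laboratory, 2012 USD per person-year) and a
#' health-state utility (dimensionless quality weight in \[0, 1\]). Sicker
#' states cost more and are valued less, so costs must be non-increasing and
#' utilities non-decreasing with ascending CD4.
#'
#' @param cd4_range Character vector of five CD4 range labels, ascending.
#' @param annual_care_cost Numeric, annual care cost per state (USD).
#' @param utility Numeric, utility weight per state.
#' @return A validated `health_state_table` (a tibble with five rows).
#' @seealso [validate_state_table()], [default_health_states()]
#' @export
#' @examples
#' health_state_table(
#'   cd4_range = c("<50", "50-199", "200-349", "350-499", ">=500"),
#'   annual_care_cost = c(33007, 14964, 8216, 5758, 4535),
#'   utility = c(0.853, 0.861, 0.889, 0.913, 0.934)
#' )
health_state_table <- function(cd4_range, annual_care_cost, utility) {
  tbl <- tibble::tibble(
    cd4_range = as.character(cd4_range),
    annual_care_cost = as.numeric(annual_care_cost),
    utility = as.numeric(utility)
  )
  class(tbl) <- c("health_state_table", class(tbl))
  validate_state_table(tbl)
}

#' Validate a health-state table
#'
#' Checks the structural invariants of the five-state model: exactly five
#' strata, utilities in \[0, 1\], non-negative care costs, costs
#' non-increasing and utilities non-decreasing with ascending CD4. Error
#' messages name the offending stratum.
#'
#' @param table A `health_state_table` or plain data frame with columns
#'   `cd4_range`, `annual_care_cost`, `utility`.
#' @return The table, invisibly unchanged, if all invariants hold.
#' @export
validate_state_table <- function(table) {
  need <- c("cd4_range", "annual_care_cost", "utility")
  if (!all(need %in% names(table))) {
    stop("health-state table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(table) != 5L) {
    stop("expected 5 states, got ", nrow(table))
  }
  bad_u <- which(table$utility < 0 | table$utility > 1)
  if (length(bad_u)) {
    stop("utility out of [0, 1] for stratum ", table$cd4_range[bad_u[1]],
         " (", table$utility[bad_u[1]], ")")
  }
  bad_c <- which(table$annual_care_cost < 0)
  if (length(bad_c)) {
    stop("negative annual care cost for stratum ", table$cd4_range[bad_c[1]])
  }
  dc <- diff(table$annual_care_cost)
  if (any(dc > 0)) {
    i <- which(dc > 0)[1]
    stop("annual care cost must be non-increasing with ascending CD4; ",
         "violated at stratum ", table$cd4_range[i + 1])
  }
  du <- diff(table$utility)
  if (any(du < 0)) {
    i <- which(du < 0)[1]
    stop("utility must be non-decreasing with ascending CD4; ",
         "violated at stratum ", table$cd4_range[i + 1])
  }
  if (!inherits(table, "health_state_table")) {
    class(table) <- c("health_state_table", class(table))
  }
  table
}

#' Effectiveness scenario: upward transition probabilities
#'
#' A scenario names the probability `p_i` that a patient in CD4 stratum `i`
#' moves up to stratum `i + 1` in response to the intervention (four
#' transitions among five states; the top stratum only receives). Downward
#' (worsening) transitions are not modelled. The scenario average
#' `avg_prob = mean(p)` is kept at full precision; published scenario tables
#' round it for display, but all computations here use the unrounded mean.
#'
#' @param name Scenario label (e.g. "minimally", "highly").
#' @param probs Numeric vector of four transition probabilities in \[0, 1\].
#' @return An `effect_scenario` object (list with `name`, `probs`,
#'   `avg_prob`).
#' @export
#' @examples
#' effect_scenario("minimally", c(0.05, 0, 0, 0))$avg_prob  # 0.0125
effect_scenario <- function(name, probs) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L) {
    stop("an effect scenario needs exactly 4 transition probabilities")
  }
  if (any(probs < 0 | probs > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  structure(
    list(name = as.character(name), probs = probs, avg_prob = mean(probs)),
    class = "effect_scenario"
  )
}

#' @export
print.effect_scenario <- function(x, ...) {
  cat("<effect_scenario> ", x$name, ": p = (",
      paste(format(x$probs), collapse = ", "),
      "), avg = ", format(x$avg_prob), "\n", sep = "")
  invisible(x)
}

as_effect_scenario <- function(scenario, scenarios = NULL) {
  if (inherits(scenario, "effect_scenario")) return(scenario)
  if (is.character(scenario) && !is.null(scenarios) &&
      scenario %in% names(scenarios)) {
    return(scenarios[[scenario]])
  }
  stop("unknown effectiveness scenario: ", scenario)
}

# per-transition cost drops and utility gains (length 4, ascending CD4)
transition_cost_drops <- function(table) {
  table$annual_care_cost[1:4] - table$annual_care_cost[2:5]
}

transition_utility_gains <- function(table) {
  table$utility[2:5] - table$utility[1:4]
}

#' Per-capita expected decrease in care costs under a scenario
#'
#' The intervention's effect on non-antiretroviral care costs is the
#' probability-weighted cost drop for each of the four upward transitions,
#' averaged across the CD4 groups. The averaging denominator is always 4
#' (the number of transitions), including zero-probability transitions:
#' `mean_i p_i (cost_i - cost_(i+1))`. This is the canonical averaging rule
#' of the model; zero-probability transitions contribute zero.
#'
#' @param table Validated [health_state_table()].
#' @param scenario An [effect_scenario()].
#' @return USD per person-year (non-negative, full precision).
#' @export
#' @examples
#' hs <- default_health_states()
#' sc <- effect_scenario("minimally", c(0.05, 0, 0, 0))
#' per_capita_cost_decrease(hs, sc)  # 0.05 * 18043 / 4 = 225.5375
per_capita_cost_decrease <- function(table, scenario) {
  validate_state_table(table)
  drops <- transition_cost_drops(table)
  sum(scenario$probs * drops) / length(scenario$probs)
}

#' Per-capita expected utility gain under a scenario
#'
#' In `faithful` mode the gain follows the same probability-weighted
#' averaging rule as the cost decrease: `mean_i p_i (u_(i+1) - u_i)`,
#' utility per person-year. In `replication` mode a fixed, scenario-
#' independent per-capita gain is returned verbatim; this mode exists
#' because the published results tables imply a constant QALY denominator
#' across all effectiveness scenarios (0.014 per person-year reproduces
#' them), which the probability-weighted rule cannot produce. `faithful`
#' is the default.
#'
#' @inheritParams per_capita_cost_decrease
#' @param mode `"faithful"` (probability-weighted) or `"replication"`
#'   (fixed gain).
#' @param fixed_gain Utility per person-year; required in replication mode.
#' @return Utility per person-year.
#' @export
per_capita_utility_gain <- function(table, scenario,
                                    mode = c("faithful", "replication"),
                                    fixed_gain = NULL) {
  mode <- match.arg(mode)
  if (mode == "replication") {
    if (is.null(fixed_gain) || is.na(fixed_gain)) {
      stop("replication mode requires a fixed per-capita utility gain ",
           "(fixed_gain)")
    }
    return(as.numeric(fixed_gain))
  }
  validate_state_table(table)
  gains <- transition_utility_gains(table)
  sum(scenario$probs * gains) / length(scenario$probs)
}

#' Apply an effectiveness scenario to stratum occupancy
#'
#' One-step upward mass movement: stratum `i` loses `p_i * occ_i` to stratum
#' `i + 1`; the top stratum only receives. No downward movement is modelled
#' and total occupancy mass is conserved.
#'
#' @param occupancy Numeric vector of five stratum fractions summing to 1.
#' @param scenario An [effect_scenario()].
#' @return New occupancy vector summing to 1.
#' @export
#' @examples
#' apply_scenario(c(1, 0, 0, 0, 0), effect_scenario("minimally", c(.05, 0, 0, 0)))
apply_scenario <- function(occupancy, scenario) {
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != 5L) {
    stop("occupancy must have 5 stratum fractions")
  }
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy must sum to 1 (got ", format(sum(occupancy)), ")")
  }
  moved <- scenario$probs * occupancy[1:4]
  out <- occupancy
  out[1:4] <- out[1:4] - moved
  out[2:5] <- out[2:5] + moved
  out
}
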