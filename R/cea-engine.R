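#' Total decrease in care costs across the exposed users
#'
#' @param n_users Users exposed.
#' @param per_capita_cost_decrease USD per person-year, from
#'   [per_capita_cost_decrease()].
#' @param duration_years Effect duration in years.
#' @return USD, full precision.
#' @export
#' @examples
#' care_cost_decrease_total(540, 225.5375, 0.5)  # 60895.125
care_cost_decrease_total <- function(n_users, per_capita_cost_decrease,
                                     duration_years) {
  stopifnot(n_users >= 0, per_capita_cost_decrease >= 0, duration_years >= 0)
  n_users * per_capita_cost_decrease * duration_years
}

#' Assemble the cost components of one analysis cell
#'
#' A light container naming every component entering the net cost. Missing
#' required components raise an error naming the component.
#'
#' @param development Development total (USD), after any multiplier.
#' @param deployment Deployment total (USD).
#' @param medication_increase Increase in medication consumption costs
#'   (USD).
#' @param care_decrease Decrease in care costs (USD).
#' @param return_to_work Return-to-work wage benefit (USD).
#' @param lost_wages_separate Participants' lost wages charged outside the
#'   deployment ledger (web mode); 0 for kiosk, where the component lives
#'   inside the deployment total.
#' @param rural_transport Rural travel cost add-on (USD).
#' @param n_users Users exposed.
#' @param duration_years Effect duration (years, > 0).
#' @return A `cea_inputs` list.
#' @export
cea_inputs <- function(development, deployment, medication_increase,
                       care_decrease, return_to_work,
                       lost_wages_separate = 0, rural_transport = 0,
                       n_users, duration_years) {
  required <- list(development = development, deployment = deployment,
                   medication_increase = medication_increase,
                   care_decrease = care_decrease,
                   return_to_work = return_to_work)
  for (nm in names(required)) {
    if (is.null(required[[nm]]) || is.na(required[[nm]])) {
      stop("missing cost component: ", nm)
    }
  }
  if (duration_years <= 0) stop("duration_years must be positive")
  if (n_users <= 0) stop("n_users must be positive")
  structure(
    c(required, list(lost_wages_separate = lost_wages_separate,
                     rural_transport = rural_transport, n_users = n_users,
                     duration_years = duration_years)),
    class = "cea_inputs"
  )
}

#' Net cost of the intervention
#'
#' Development + deployment + medication increase + separate lost wages +
#' rural transport, minus the care-cost decrease and the return-to-work
#' benefit. Negative values are net savings. Full precision; round for
#' display with [round_usd()] / [format_usd()].
#'
#' @param inputs A [cea_inputs()] object.
#' @return USD (signed), full precision.
#' @export
net_cost <- function(inputs) {
  stopifnot(inherits(inputs, "cea_inputs"))
  inputs$development + inputs$deployment + inputs$medication_increase +
    inputs$lost_wages_separate + inputs$rural_transport -
    inputs$care_decrease - inputs$return_to_work
}

#' QALYs gained by the exposed users
#'
#' `n_users * per-capita utility gain * duration`; the per-capita gain is
#' utility per person-year, so a 6-month effect contributes half a year.
#'
#' @param n_users Users exposed.
#' @param per_capita_utility_gain Utility per person-year.
#' @param duration_years Effect duration in years.
#' @return QALYs.
#' @export
#' @examples
#' qalys_gained(540, 0.014, 0.5)  # 3.78
qalys_gained <- function(n_users, per_capita_utility_gain, duration_years) {
  stopifnot(n_users >= 0, per_capita_utility_gain >= 0, duration_years >= 0)
  n_users * per_capita_utility_gain * duration_years
}

#' Cost per QALY with savings / undefined flags
#'
#' Net cost divided by QALYs gained. A negative ratio flags net savings
#' (rendered in parentheses by [format_usd()]). Zero QALYs make the ratio
#' undefined; this is reported as a flagged `NA`, never a division error.
#'
#' @param net Net cost (USD, signed).
#' @param qalys QALYs gained (>= 0).
#' @return List with `value` (USD/QALY or `NA`), `savings` (logical),
#'   `undefined` (logical).
#' @export
cost_per_qaly <- function(net, qalys) {
  if (qalys < 0) stop("qalys must be non-negative")
  if (qalys == 0) {
    return(list(value = NA_real_, savings = FALSE, undefined = TRUE))
  }
  v <- net / qalys
  list(value = v, savings = v < 0, undefined = FALSE)
}

#' Development-cost multiplier reaching a target cost per QALY
#'
#' Solves `(net + (k - 1) * dev_total) / qalys = target` for the multiplier
#' `k` on development costs (exact linear solution). `k < 1` means
#' development costs would have to shrink to reach the benchmark; `k > 1`
#' means they could grow.
#'
#' @param net Net cost (USD) at multiplier 1.
#' @param qalys QALYs gained (> 0 for a defined solution).
#' @param dev_total Development total (USD) included in `net`.
#' @param target Target cost per QALY (USD/QALY), default the $50,000
#'   willingness-to-pay benchmark.
#' @return Multiplier (numeric), or flagged `NA` when `qalys` is 0.
#' @export
threshold_dev_multiplier <- function(net, qalys, dev_total, target = 50000) {
  if (qalys <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  1 + (target * qalys - net) / dev_total
}

#' Run one cost-effectiveness analysis cell
#'
#' Orchestrates the full pipeline for a single (deployment, utilization,
#' scenario, duration) combination: builds the deployment plan, computes
#' every cost component, aggregates the net cost, QALYs, cost per user and
#' cost per QALY, and solves the development-cost threshold multiplier for
#' the willingness-to-pay benchmark.
#'
#' In `faithful` mode (default) the per-capita utility gain is probability
#' weighted from the health-state table; in `replication` mode the fixed
#' calibrated gain from the parameter bundle is used, which reproduces the
#' published results tables. `web_health_multiplier` scales the medication
#' and care rows for web delivery (the published web tables carry exactly
#' twice the kiosk health-state rows at equal user counts; the replication
#' bundle sets 2, the faithful default is 1).
#'
#' @param deployment `"kiosk"` or `"web"`.
#' @param utilization `"low"` (540 users/6 months) or `"high"` (1,620).
#' @param scenario Scenario name from the bundle, or an
#'   [effect_scenario()].
#' @param duration_months Duration of the intervention effect, months.
#' @param mode `"faithful"` or `"replication"`.
#' @param params Parameter bundle from [cea_defaults()] /
#'   [load_parameters()].
#' @param dev_cost_multiplier Sensitivity multiplier on development costs.
#' @param deployment_cost_multiplier Sensitivity multiplier on deployment
#'   costs.
#' @param rural Add rural automobile travel costs (kiosk only).
#' @param web_health_multiplier Multiplier on the web health-state rows;
#'   `NULL` picks 1 (faithful) or the bundle value (replication).
#' @param fixed_utility_gain Per-capita utility gain for replication mode;
#'   `NULL` picks the bundle value.
#' @return One-row tibble (class `cea_result`) with itemized components,
#'   `net_cost`, `cost_per_user`, `qalys`, `cost_per_qaly`, `savings`,
#'   `qaly_undefined` and `threshold_dev_multiplier`.
#' @export
#' @examples
#' \donttest{
#' cea_run("kiosk", "low", "moderately", mode = "replication")
#' }
cea_run <- function(deployment = c("kiosk", "web"),
                    utilization = c("low", "high"),
                    scenario = "moderately",
                    duration_months = 6,
                    mode = c("faithful", "replication"),
                    params = cea_defaults(),
                    dev_cost_multiplier = 1,
                    deployment_cost_multiplier = 1,
                    rural = FALSE,
                    web_health_multiplier = NULL,
                    fixed_utility_gain = NULL) {
  deployment <- match.arg(deployment)
  utilization <- match.arg(utilization)
  mode <- match.arg(mode)
  if (duration_months <= 0) stop("duration_months must be positive")
  sc <- as_effect_scenario(scenario, params$scenarios)
  dur <- duration_months / 12

  dev <- total_development_cost(params$dev_ledger)$total * dev_cost_multiplier
  if (deployment == "kiosk") {
    plan <- kiosk_plan(utilization, params)
    dep <- kiosk_deployment_cost(plan)
    lost_sep <- 0
    lost_display <- dep$components[["participant_lost_wages"]]
    hm <- 1
  } else {
    plan <- web_plan(utilization, params)
    dep <- web_deployment_cost(plan)
    lost_sep <- plan$components$participant_lost_wages
    lost_display <- lost_sep
    hm <- web_health_multiplier %||%
      (if (mode == "replication") {
        params$params$replication$web_health_multiplier %||% 1
      } else 1)
  }
  deploy_total <- dep$total * deployment_cost_multiplier
  n <- plan$n_users

  med <- hm * medication_cost_increase(n, params$medication, sc, dur)
  care_rate <- per_capita_cost_decrease(params$health_states, sc)
  care <- hm * care_cost_decrease_total(n, care_rate, dur)
  rtw <- return_to_work_benefit(n, params$wages, sc, dur)
  rural_cost <- if (rural && deployment == "kiosk") {
    rural_transport_cost(n, params$transport, mode = "kiosk")
  } else 0

  inputs <- cea_inputs(
    development = dev, deployment = deploy_total,
    medication_increase = med, care_decrease = care, return_to_work = rtw,
    lost_wages_separate = lost_sep, rural_transport = rural_cost,
    n_users = n, duration_years = dur
  )
  net <- net_cost(inputs)

  gain <- if (mode == "replication") {
    per_capita_utility_gain(
      params$health_states, sc, mode = "replication",
      fixed_gain = fixed_utility_gain %||%
        params$params$replication$fixed_utility_gain
    )
  } else {
    per_capita_utility_gain(params$health_states, sc, mode = "faithful")
  }
  q <- qalys_gained(n, gain, dur)
  cpq <- cost_per_qaly(net, q)
  thr <- threshold_dev_multiplier(net, q, dev,
                                  target = params$params$wtp_per_qaly %||% 50000)

  out <- tibble::tibble(
    deployment = deployment, utilization = utilization, scenario = sc$name,
    duration_months = duration_months, mode = mode,
    dev_cost_multiplier = dev_cost_multiplier, rural = rural,
    n_users = n, dev_cost = dev, deploy_cost = deploy_total,
    med_increase = med, care_decrease = care, rtw_benefit = rtw,
    lost_wages = lost_display, rural_transport = rural_cost,
    net_cost = net, cost_per_user = round_usd(net / n), qalys = q,
    cost_per_qaly = cpq$value, savings = cpq$savings,
    qaly_undefined = cpq$undefined,
    threshold_dev_multiplier = as.numeric(thr)
  )
  class(out) <- c("cea_result", class(out))
  out
}

#' Build a sensitivity-sweep grid
#'
#' @param scenarios Scenario names, ordered minimally -> highly.
#' @param deployments Delivery modes.
#' @param utilizations Utilization levels.
#' @param durations_months Effect durations (months); the published
#'   sensitivity set is 3, 6, 9, 12, extensible to 1-12.
#' @param dev_cost_multipliers Development-cost multipliers (published
#'   range 0.5-1.5).
#' @param rural Logical axis for the rural-transport add-on.
#' @return A `sweep_grid` tibble (one row per analysis cell).
#' @export
sweep_grid <- function(scenarios = c("minimally", "slightly", "moderately",
                                     "highly"),
                       deployments = c("kiosk", "web"),
                       utilizations = c("low", "high"),
                       durations_months = c(3, 6, 9, 12),
                       dev_cost_multipliers = 1,
                       rural = FALSE) {
  g <- expand.grid(
    deployment = deployments, utilization = utilizations,
    scenario = scenarios, duration_months = durations_months,
    dev_cost_multiplier = dev_cost_multipliers, rural = rural,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  out <- tibble::as_tibble(g)
  class(out) <- c("sweep_grid", class(out))
  out
}

#' Run a sensitivity sweep
#'
#' Evaluates [cea_run()] on every grid cell. The result is deterministic
#' and sorted by deployment, utilization, scenario (in the grid's scenario
#' order), duration and multiplier.
#'
#' @param grid A [sweep_grid()].
#' @param mode `"faithful"` or `"replication"`, passed to [cea_run()].
#' @param params Parameter bundle.
#' @param ... Further arguments passed to [cea_run()].
#' @return Tibble of `cea_result` rows.
#' @export
run_sweep <- function(grid = sweep_grid(), mode = c("faithful", "replication"),
                      params = cea_defaults(), ...) {
  mode <- match.arg(mode)
  if (!nrow(grid)) stop("sweep grid is empty")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cea_run(
      deployment = grid$deployment[i], utilization = grid$utilization[i],
      scenario = grid$scenario[i],
      duration_months = grid$duration_months[i], mode = mode,
      params = params, dev_cost_multiplier = grid$dev_cost_multiplier[i],
      rural = grid$rural[i], ...
    )
  })
  out <- do.call(rbind, rows)
  scen_levels <- unique(grid$scenario)
  ord <- order(out$deployment, out$utilization,
               match(out$scenario, scen_levels), out$duration_months,
               out$dev_cost_multiplier)
  out[ord, ]
}

#' Recompute a published-style results table
#'
#' Runs the default replication analysis (6-month effect, both utilization
#' levels, all four scenarios) for one delivery mode and lays the
#' components out as in the published semiannual tables: medication
#' increase, care-cost decrease, lost wages, return-to-work benefit, net
#' cost, cost per user, cost per QALY.
#'
#' @param deployment `"kiosk"` or `"web"`.
#' @param params Parameter bundle.
#' @param mode Analysis mode; the published layout corresponds to
#'   `"replication"`.
#' @return Tibble with one row per (utilization, scenario) cell.
#' @export
replicate_published_tables <- function(deployment = c("kiosk", "web"),
                                       params = cea_defaults(),
                                       mode = "replication") {
  deployment <- match.arg(deployment)
  run_sweep(
    sweep_grid(deployments = deployment, durations_months = 6),
    mode = mode, params = params
  )[, c("deployment", "utilization", "scenario", "med_increase",
        "care_decrease", "lost_wages", "rtw_benefit", "net_cost",
        "cost_per_user", "qalys", "cost_per_qaly", "savings")]
}
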