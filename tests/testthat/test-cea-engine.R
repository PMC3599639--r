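test_that("care-cost decrease totals scale the per-capita rate", {
  expect_equal(care_cost_decrease_total(540, 0.05 * DC1 / 4, 0.5), 60895.125)
  expect_equal(care_cost_decrease_total(540, 0, 0.5), 0)
  expect_equal(care_cost_decrease_total(1620, 0.05 * DC1 / 4, 0.5),
               3 * 60895.125)
})

test_that("net cost aggregates all components and names missing ones", {
  inp <- cea_inputs(development = 100, deployment = 50,
                    medication_increase = 10, care_decrease = 30,
                    return_to_work = 20, lost_wages_separate = 5,
                    n_users = 10, duration_years = 0.5)
  expect_equal(net_cost(inp), 100 + 50 + 10 + 5 - 30 - 20)
  expect_error(
    cea_inputs(development = 100, deployment = 50,
               medication_increase = 10, care_decrease = NA,
               return_to_work = 20, n_users = 10, duration_years = 0.5),
    "missing cost component: care_decrease"
  )
})

test_that("a zero-effect scenario costs exactly development plus deployment", {
  b <- cea_defaults()
  zero_params <- b
  zero_params$scenarios$none <- scenario_zero()
  r <- cea_run("kiosk", "low", "none", mode = "faithful",
               params = zero_params)
  dev <- total_development_cost(b$dev_ledger)$total
  dep <- kiosk_deployment_cost(kiosk_plan("low", b))$total
  expect_equal(r$net_cost, dev + dep)
  expect_equal(r$qalys, 0)
  expect_true(r$qaly_undefined)
  expect_true(is.na(r$cost_per_qaly))
})

test_that("QALY computation and the guarded cost-per-QALY ratio", {
  expect_equal(qalys_gained(540, 0.014, 0.5), 3.78)
  expect_equal(qalys_gained(1620, 0.014, 0.5), 11.34)
  expect_equal(qalys_gained(540, 0, 0.5), 0)

  cpq <- cost_per_qaly(124094, 3.78)
  expect_false(cpq$savings)
  expect_false(cpq$undefined)
  expect_equal(round_usd(cpq$value), 32829)

  expect_equal(cost_per_qaly(0, 3.78)$value, 0)
  sav <- cost_per_qaly(-59443, 3.78)
  expect_true(sav$savings)
  und <- cost_per_qaly(1000, 0)
  expect_true(und$undefined)
  expect_true(is.na(und$value))
  expect_error(cost_per_qaly(10, -1), "non-negative")
})

test_that("threshold multiplier solves the linear target equation and round-trips", {
  # fixed point: net already at the target
  expect_equal(threshold_dev_multiplier(net = 50000 * 2, qalys = 2,
                                        dev_total = 1000), 1)
  b <- cea_defaults()
  r <- cea_run("kiosk", "low", "moderately", mode = "replication", params = b)
  k <- r$threshold_dev_multiplier
  expect_equal(k, 1.22, tolerance = 0.01)
  # plugging the multiplier back reproduces the benchmark within $1/QALY
  r2 <- cea_run("kiosk", "low", "moderately", mode = "replication",
                params = b, dev_cost_multiplier = k)
  expect_equal(r2$cost_per_qaly, 50000, tolerance = 1 / 50000)
  expect_true(is.na(threshold_dev_multiplier(100, 0, 1000)))
})

test_that("sweeps enumerate the grid deterministically and sorted", {
  b <- cea_defaults()
  g <- sweep_grid()  # 4 scenarios x 2 deployments x 2 utilizations x 4 durations
  expect_equal(nrow(g), 4 * 2 * 2 * 4)
  sw <- run_sweep(g, mode = "replication", params = b)
  expect_equal(nrow(sw), 64)
  key <- paste(sw$deployment, sw$utilization,
               match(sw$scenario, c("minimally", "slightly", "moderately",
                                    "highly")),
               sprintf("%02d", sw$duration_months))
  expect_identical(key, sort(key))
  sw2 <- run_sweep(g, mode = "replication", params = b)
  expect_identical(sw, sw2)
  expect_error(run_sweep(sweep_grid(scenarios = character(0))), "empty")
})

test_that("net cost is non-increasing across the scenario ordering", {
  b <- cea_defaults()
  sw <- run_sweep(sweep_grid(durations_months = 6), mode = "replication",
                  params = b)
  for (dep in unique(sw$deployment)) {
    for (ut in unique(sw$utilization)) {
      nets <- sw$net_cost[sw$deployment == dep & sw$utilization == ut]
      expect_true(all(diff(nets) <= 1e-9),
                  info = paste("ordering violated for", dep, ut))
    }
  }
})

test_that("cost per QALY is non-increasing in effect duration", {
  b <- cea_defaults()
  sw <- run_sweep(sweep_grid(durations_months = c(1, 3, 6, 9, 12)),
                  mode = "replication", params = b)
  cells <- unique(sw[, c("deployment", "utilization", "scenario")])
  for (i in seq_len(nrow(cells))) {
    sel <- sw$deployment == cells$deployment[i] &
      sw$utilization == cells$utilization[i] &
      sw$scenario == cells$scenario[i]
    cpq <- sw$cost_per_qaly[sel][order(sw$duration_months[sel])]
    expect_true(all(diff(cpq) <= 1e-6))
  }
})

test_that("very short effect durations are dominated by fixed development costs", {
  b <- cea_defaults()
  r1 <- cea_run("kiosk", "low", "minimally", duration_months = 1,
                mode = "replication", params = b)
  r6 <- cea_run("kiosk", "low", "minimally", duration_months = 6,
                mode = "replication", params = b)
  expect_gt(r1$cost_per_qaly, 400000)        # far beyond the $50,000 benchmark
  expect_gt(r1$cost_per_qaly, 7 * r6$cost_per_qaly)
})

test_that("net savings, negative ratio and parentheses rendering coincide", {
  b <- cea_defaults()
  sw <- run_sweep(sweep_grid(durations_months = c(3, 6, 12)),
                  mode = "replication", params = b)
  expect_identical(sw$savings, sw$cost_per_qaly < 0)
  expect_identical(sw$net_cost < 0, sw$cost_per_qaly < 0)
  shown <- format_usd(sw$net_cost)
  expect_identical(startsWith(shown, "("), sw$net_cost < -0.5)
})

test_that("deployment and development sensitivity multipliers act on their own totals", {
  b <- cea_defaults()
  base <- cea_run("kiosk", "low", "moderately", mode = "replication",
                  params = b)
  up <- cea_run("kiosk", "low", "moderately", mode = "replication",
                params = b, dev_cost_multiplier = 1.5)
  expect_equal(up$net_cost - base$net_cost, 0.5 * base$dev_cost)
  dep_up <- cea_run("kiosk", "low", "moderately", mode = "replication",
                    params = b, deployment_cost_multiplier = 2)
  expect_equal(dep_up$net_cost - base$net_cost, base$deploy_cost)
  rural <- cea_run("kiosk", "low", "moderately", mode = "replication",
                   params = b, rural = TRUE)
  expect_equal(rural$net_cost - base$net_cost,
               rural_transport_cost(540, b$transport))
})
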