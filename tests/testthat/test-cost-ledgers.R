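test_that("development ledger totals apply the administrative rate to direct costs", {
  b <- cea_defaults()
  tc <- total_development_cost(b$dev_ledger)
  expect_equal(tc$direct, 204704)
  expect_equal(tc$admin, 0.448 * 204704)
  expect_equal(round_usd(tc$total), 296411)

  empty <- dev_cost_ledger(numeric(0))
  expect_equal(total_development_cost(empty),
               list(direct = 0, admin = 0, total = 0))
  flat <- dev_cost_ledger(c(a = 100, b = 50), admin_rate = 0)
  expect_equal(total_development_cost(flat)$total, 150)
  expect_error(dev_cost_ledger(c(a = -1)), "negative ledger line item: a")
})

test_that("per-participant and per-percent costs use whole-dollar rounding", {
  expect_equal(dev_cost_per_participant(296411, 124), 2390)
  expect_equal(dev_cost_per_participant(296411, 1), 296411)
  expect_equal(dev_cost_per_participant(100, 3), 33)
  expect_error(dev_cost_per_participant(100, 0), "positive")

  expect_equal(cost_per_percent_adherence(2390, 10), 239)
  expect_equal(cost_per_percent_adherence(60, 10), 6)
  expect_equal(cost_per_percent_adherence(0, 10), 0)
  expect_error(cost_per_percent_adherence(100, 0), "undefined")
})

test_that("kiosk deployment reproduces the semiannual ledger at both utilizations", {
  b <- cea_defaults()
  low <- kiosk_deployment_cost(kiosk_plan("low", b))
  expect_equal(round_usd(low$components),
               c(computer = 2200, licensing = 50, office_space = 8874,
                 staff_support = 3181, participant_lost_wages = 18202))
  expect_equal(low$total, sum(low$components))  # no hidden terms
  expect_equal(round_usd(low$total), 32507)
  expect_equal(low$per_user, 60)

  high <- kiosk_deployment_cost(kiosk_plan("high", b))
  expect_equal(round_usd(high$total), 97522)
  expect_equal(high$per_user, 60)
  # every component triples with three kiosks
  expect_equal(unname(high$components), unname(3 * low$components))

  expect_error(kiosk_deployment_cost(web_plan("low", b)), "kiosk plan")
})

test_that("web deployment sums its four components and costs fall per user at scale", {
  b <- cea_defaults()
  low <- web_deployment_cost(web_plan("low", b))
  expect_equal(low$total, 17160 + 150 + 510 + 10398)
  expect_equal(low$total, 28218)
  expect_equal(low$per_user, 52)

  high <- web_deployment_cost(web_plan("high", b))
  expect_equal(high$total, 17160 + 450 + 5100 + 20796)
  expect_equal(high$total, 43506)
  expect_equal(high$per_user, 27)

  zero <- deployment_plan("web", n_users = 10, components = list(
    project_coordinator = 0, server_hosting = 0, advertising = 0,
    tech_support = 0
  ))
  expect_equal(web_deployment_cost(zero)$total, 0)
  expect_error(web_deployment_cost(kiosk_plan("low", b)), "web plan")
  expect_error(deployment_plan("web", n_users = 0), "positive")
})

test_that("medication cost increase is linear in users, duration and effectiveness", {
  b <- cea_defaults()
  med <- b$medication
  slightly <- effect_scenario("slightly", c(.05, .01, 0, 0))
  expect_equal(round_usd(medication_cost_increase(540, med, slightly, 0.5)),
               9183)
  expect_equal(round_usd(medication_cost_increase(
    1620, med, scenario_minimally(), 0.5)), 22958)
  expect_equal(medication_cost_increase(540, med, scenario_zero(), 0.5), 0)

  base <- medication_cost_increase(540, med, slightly, 0.5)
  expect_equal(medication_cost_increase(1080, med, slightly, 0.5), 2 * base)
  expect_equal(medication_cost_increase(540, med, slightly, 1), 2 * base)
})

test_that("return-to-work benefit matches the published row and scales linearly", {
  b <- cea_defaults()
  moderately <- effect_scenario("moderately", c(.10, .05, .05, 0))
  expect_equal(round_usd(return_to_work_benefit(540, b$wages, moderately, 0.5)),
               82575)
  expect_equal(return_to_work_benefit(540, b$wages, scenario_zero(), 0.5), 0)
  one <- return_to_work_benefit(540, b$wages, moderately, 0.5)
  expect_equal(return_to_work_benefit(1080, b$wages, moderately, 0.5), 2 * one)
})

test_that("lost wages sum hourly pay over employed participants", {
  w <- wage_model()
  expect_equal(lost_wages(43264, w), 41.60)  # $20.80/h basis, 2 h
  expect_equal(lost_wages(numeric(0), w), 0)
  expect_equal(lost_wages(c(20800, 41600), w), 20 + 40)
})

test_that("rural transport multiplies distance, rate and trip legs, kiosk only", {
  tr <- transport_model(one_way_miles = 50, cost_per_mile = 0.596,
                        round_trip = TRUE)
  expect_equal(rural_transport_cost(540, tr), 32184)
  one_way <- transport_model(50, 0.596, round_trip = FALSE)
  expect_equal(rural_transport_cost(540, one_way), 32184 / 2)
  expect_equal(rural_transport_cost(540, transport_model(0)), 0)
  expect_error(rural_transport_cost(540, tr, mode = "web"), "kiosk")
})

test_that("cost operations are homogeneous of degree 1 in monetary inputs", {
  k <- 2.5
  led1 <- dev_cost_ledger(c(a = 100, b = 40), admin_rate = 0.448)
  led2 <- dev_cost_ledger(k * c(a = 100, b = 40), admin_rate = 0.448)
  expect_equal(total_development_cost(led2)$total,
               k * total_development_cost(led1)$total)

  med1 <- medication_cost_model(10000, 0.7, 0.1)
  med2 <- medication_cost_model(k * 10000, 0.7, 0.1)
  sc <- scenario_minimally()
  expect_equal(medication_cost_increase(100, med2, sc, 0.5),
               k * medication_cost_increase(100, med1, sc, 0.5))

  expect_equal(
    rural_transport_cost(10, transport_model(50, k * 0.596)),
    k * rural_transport_cost(10, transport_model(50, 0.596))
  )
})

test_that("display rounding never feeds back into downstream computation", {
  b <- cea_defaults()
  tc <- total_development_cost(b$dev_ledger)
  # chained full-precision pipeline
  chained <- cost_per_percent_adherence(tc$total / 124, 10)
  # rounding the intermediate per-participant figure first
  rounded_first <- cost_per_percent_adherence(
    dev_cost_per_participant(tc$total, 124), 10)
  expect_equal(chained, rounded_first)  # both display as $239
  # but the engine's internal values stay unrounded
  expect_false(isTRUE(all.equal(tc$total, round_usd(tc$total))))
  r <- cea_run("kiosk", "low", "moderately", mode = "replication", params = b)
  manual <- tc$total +
    kiosk_deployment_cost(kiosk_plan("low", b))$total +
    medication_cost_increase(540, b$medication,
                             b$scenarios$moderately, 0.5) -
    care_cost_decrease_total(
      540, per_capita_cost_decrease(b$health_states,
                                    b$scenarios$moderately), 0.5) -
    return_to_work_benefit(540, b$wages, b$scenarios$moderately, 0.5)
  expect_equal(r$net_cost, manual, tolerance = 1e-12)
})

test_that("staff support helper exposes the loading structure", {
  # multiplicative fringe-then-admin loading on the hourly wage
  expect_equal(staff_support_cost(10, 0.5, 0.5, 1, 100), 10 * 1.5 * 1.5 * 100)
  # the published $3,181 is a direct input; the helper's default
  # reconstruction lands near, not on, it (no day count reproduces it)
  expect_gt(abs(staff_support_cost() - 3181), 1)
})
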