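# shared fixtures: the shipped default table plus generators for random,
# invariant-satisfying tables and scenarios used by the property tests

fixture_states <- function() default_health_states()

rand_state_table <- function() {
  costs <- sort(stats::runif(5, 1000, 50000), decreasing = TRUE)
  utils <- sort(stats::runif(5, 0.3, 0.99))
  health_state_table(paste0("s", 1:5), costs, utils)
}

rand_scenario <- function(name = "rand") {
  effect_scenario(name, stats::runif(4, 0, 0.5))
}

scenario_minimally <- function() effect_scenario("minimally", c(0.05, 0, 0, 0))
scenario_zero <- function() effect_scenario("none", c(0, 0, 0, 0))

# printed per-transition cost drop between the two sickest strata
DC1 <- 33007 - 14964
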