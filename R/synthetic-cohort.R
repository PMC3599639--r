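#' Specification for a synthetic patient cohort
#'
#' Describes the statistical structure of a simulated cohort matching the
#' assumptions of the analysis: CD4 stratum occupancy over the five ranges,
#' a split between patients below and above the 85% adherence threshold
#' (only the low group responds, with a +10 percentage-point gain),
#' education-linked wages with a fixed employment rate, and log-normally
#' dispersed annual regimen costs. The development study's observable
#' margins (n = 124, 22 employed, mean baseline adherence 0.58 in the low
#' group, mean regimen cost $22,675/year) are the defaults; the CD4 and
#' education mixes are synthetic modelling choices, not published
#' statistics.
#'
#' @param n Cohort size (>= 1).
#' @param cd4_occupancy Five stratum fractions summing to 1 (default
#'   uniform; synthetic).
#' @param frac_below_85 Fraction of patients below the 0.85 adherence
#'   threshold (synthetic default 0.75).
#' @param mean_low_adherence Mean baseline adherence in the low group.
#' @param adherence_sd SD of the truncated-normal adherence draws.
#' @param adherence_effect Adherence gain applied below the threshold.
#' @param adherence_threshold Response threshold (0.85).
#' @param employment_rate Fraction employed (default 22/124).
#' @param employment_mode `"quota"` (deterministic count, default) or
#'   `"bernoulli"`.
#' @param education_probs Education mix (synthetic).
#' @param wage_by_education Annual wages by education (calibrated; see
#'   [default_wage_by_education()]).
#' @param mean_regimen_cost Mean annual regimen cost (USD).
#' @param regimen_cv Coefficient of variation of the log-normal regimen
#'   costs.
#' @param seed Default RNG seed for [generate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n = 124,
                        cd4_occupancy = rep(0.2, 5),
                        frac_below_85 = 0.75,
                        mean_low_adherence = 0.58,
                        adherence_sd = 0.15,
                        adherence_effect = 0.10,
                        adherence_threshold = 0.85,
                        employment_rate = 22 / 124,
                        employment_mode = c("quota", "bernoulli"),
                        education_probs = c(less_than_hs = 0.18,
                                            high_school = 0.36,
                                            some_college = 0.27,
                                            bachelor = 0.14,
                                            graduate = 0.05),
                        wage_by_education = default_wage_by_education(),
                        mean_regimen_cost = 22675,
                        regimen_cv = 0.35,
                        seed = 1L) {
  employment_mode <- match.arg(employment_mode)
  if (n < 1) stop("cohort size n must be >= 1")
  if (length(cd4_occupancy) != 5L || abs(sum(cd4_occupancy) - 1) > 1e-9 ||
      any(cd4_occupancy < 0)) {
    stop("cd4_occupancy must be 5 non-negative fractions summing to 1")
  }
  fracs <- c(frac_below_85, mean_low_adherence, adherence_effect,
             adherence_threshold, employment_rate)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (!setequal(names(education_probs), names(wage_by_education))) {
    stop("education_probs and wage_by_education must use the same levels")
  }
  structure(
    list(n = as.integer(n), cd4_occupancy = cd4_occupancy,
         frac_below_85 = frac_below_85,
         mean_low_adherence = mean_low_adherence,
         adherence_sd = adherence_sd, adherence_effect = adherence_effect,
         adherence_threshold = adherence_threshold,
         employment_rate = employment_rate,
         employment_mode = employment_mode,
         education_probs = education_probs / sum(education_probs),
         wage_by_education = wage_by_education,
         mean_regimen_cost = mean_regimen_cost, regimen_cv = regimen_cv,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a seeded synthetic cohort
#'
#' Samples `n` patients per the spec: CD4 stratum (categorical on the
#' occupancy), baseline adherence (truncated normal below the threshold for
#' the low group, a narrow truncated normal above it for the rest),
#' post-intervention adherence (`baseline + effect`, clipped to \[0, 1\],
#' only below the threshold), employment (deterministic quota by default so
#' small-cohort counts are exact, Bernoulli optionally), education
#' (deterministic quota within the employed and unemployed groups, which
#' makes the cohort's lost-wages figure seed-invariant), education-linked
#' annual wage, and a log-normal annual regimen cost with the specified
#' mean and coefficient of variation. The same seed yields an identical
#' cohort.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to the spec's seed.
#' @return Tibble (class `synthetic_cohort`) with one row per patient:
#'   `id`, `cd4_stratum`, `baseline_adherence`, `post_adherence`,
#'   `employed`, `education`, `annual_wage`, `annual_regimen_cost`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  set.seed(seed)

  cd4_stratum <- sample.int(5L, n, replace = TRUE, prob = spec$cd4_occupancy)

  n_low <- quota_counts(n, c(low = spec$frac_below_85,
                             high = 1 - spec$frac_below_85))[["low"]]
  low <- seq_len(n) %in% sample.int(n, n_low)
  baseline <- numeric(n)
  if (n_low > 0) {
    baseline[low] <- rtruncnorm(n_low, spec$mean_low_adherence,
                                spec$adherence_sd, 0,
                                spec$adherence_threshold - 1e-9)
  }
  if (n - n_low > 0) {
    baseline[!low] <- rtruncnorm(n - n_low, 0.93, 0.05,
                                 spec$adherence_threshold, 1)
  }
  post <- ifelse(baseline < spec$adherence_threshold,
                 pmin(1, baseline + spec$adherence_effect), baseline)

  if (spec$employment_mode == "quota") {
    n_emp <- round(n * spec$employment_rate)
    employed <- seq_len(n) %in% sample.int(n, n_emp)
  } else {
    employed <- stats::runif(n) < spec$employment_rate
    n_emp <- sum(employed)
  }

  levels <- names(spec$education_probs)
  education <- character(n)
  fill_quota <- function(k) {
    counts <- quota_counts(k, spec$education_probs)
    sample(rep(levels, counts))
  }
  if (n_emp > 0) education[employed] <- fill_quota(n_emp)
  if (n - n_emp > 0) education[!employed] <- fill_quota(n - n_emp)
  annual_wage <- unname(spec$wage_by_education[education])

  sdlog <- sqrt(log(1 + spec$regimen_cv^2))
  meanlog <- log(spec$mean_regimen_cost) - sdlog^2 / 2
  regimen <- stats::rlnorm(n, meanlog, sdlog)

  out <- tibble::tibble(
    id = seq_len(n), cd4_stratum = cd4_stratum,
    baseline_adherence = baseline, post_adherence = post,
    employed = employed, education = education, annual_wage = annual_wage,
    annual_regimen_cost = regimen
  )
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  class(out) <- c("synthetic_cohort", class(out))
  out
}

#' Summarize a cohort into model inputs
#'
#' Empirical stratum occupancy, mean regimen cost, employment counts and
#' the mean wage of the employed, in the shape the analysis engine
#' consumes.
#'
#' @param cohort A [generate_cohort()] result.
#' @return List with `n`, `occupancy` (five fractions summing to 1),
#'   `mean_regimen_cost`, `n_employed`, `mean_wage_employed`,
#'   `lost_wages` (for the visit, via [lost_wages()]).
#' @export
cohort_to_model_inputs <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!nrow(cohort)) stop("cohort is empty")
  occ <- tabulate(cohort$cd4_stratum, 5L) / nrow(cohort)
  emp_wages <- cohort$annual_wage[cohort$employed]
  list(
    n = nrow(cohort),
    occupancy = occ,
    mean_regimen_cost = mean(cohort$annual_regimen_cost),
    n_employed = sum(cohort$employed),
    mean_wage_employed = if (length(emp_wages)) mean(emp_wages) else NA_real_,
    lost_wages = lost_wages(emp_wages, wage_model())
  )
}

#' Monte-Carlo twin of the closed-form transition deltas
#'
#' Applies the effectiveness scenario at the individual level: each patient
#' in stratum `i < 5` moves up one stratum with probability `p_i`
#' (independent Bernoulli draws). Per-patient care-cost savings and utility
#' gains are the corresponding transition deltas for movers, zero
#' otherwise. Aggregates are the sampling counterpart of
#' [per_capita_cost_decrease()] / [per_capita_utility_gain()] (faithful
#' mode) when the occupancy weights match the closed form's equal weighting
#' of the four transition-eligible strata.
#'
#' @param cohort A [generate_cohort()] result.
#' @param table Validated [health_state_table()].
#' @param scenario An [effect_scenario()].
#' @param seed RNG seed for the transition draws.
#' @return List with `patients` (tibble: `id`, `cd4_stratum`, `moved`,
#'   `care_cost_saving`, `utility_gain`) and `totals` (named list:
#'   `n_moved`, `care_cost_saving`, `utility_gain`).
#' @export
simulate_patient_transitions <- function(cohort, table, scenario,
                                         seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  validate_state_table(table)
  set.seed(seed)
  strat <- cohort$cd4_stratum
  p <- c(scenario$probs, 0)[strat]
  moved <- stats::runif(nrow(cohort)) < p
  drops <- c(transition_cost_drops(table), 0)
  gains <- c(transition_utility_gains(table), 0)
  care <- ifelse(moved, drops[strat], 0)
  util <- ifelse(moved, gains[strat], 0)
  patients <- tibble::tibble(
    id = cohort$id, cd4_stratum = strat, moved = moved,
    care_cost_saving = care, utility_gain = util
  )
  list(
    patients = patients,
    totals = list(n_moved = sum(moved), care_cost_saving = sum(care),
                  utility_gain = sum(util))
  )
}
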