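#' Configuration for the synthetic patient cohort
#'
#' The generator emulates the marginal structure of a retrospective
#' pediatric asthma cohort: per subgroup, a number of patients, an
#' over-dispersed visit-count distribution (negative binomial, matched by
#' moments), a per-visit health-state share vector, right-skewed per-visit
#' cost-category amounts (independent Gammas per category), and a longest
#' symptom-free duration whose exceedance probabilities at the 3/6/12/24
#' month thresholds hit configured targets exactly in expectation
#' (piecewise-exponential between thresholds).
#'
#' @param subgroups Tibble with columns `strategy`, `n_patients`,
#'   `visit_mean`, `visit_sd`, `followup_mean`, `followup_sd`.
#' @param state_shares Tibble with columns `strategy`, `state`,
#'   `probability` (summing to 1 within strategy) -- or `visits` counts,
#'   which are converted to shares.
#' @param cost_moments Tibble with columns `strategy`, `state`, `category`
#'   (`ics`, `tcm`, `other`, `non_medication`), `mean`, `sd`. An sd of zero
#'   makes that category deterministic.
#' @param duration_targets Tibble with columns `strategy`,
#'   `threshold_months`, `exceedance` (probability in `[0, 1]`,
#'   non-increasing within strategy).
#' @param seed Root seed for [generate_cohort()].
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(subgroups, state_shares, cost_moments,
                          duration_targets, seed = 1) {
  stopifnot(
    all(c("strategy", "n_patients", "visit_mean", "visit_sd",
          "followup_mean", "followup_sd") %in% names(subgroups)),
    all(c("strategy", "state") %in% names(state_shares)),
    all(c("strategy", "state", "category", "mean", "sd") %in%
          names(cost_moments)),
    all(c("strategy", "threshold_months", "exceedance") %in%
          names(duration_targets))
  )
  if (any(subgroups$n_patients < 1)) {
    stop("`n_patients` must be >= 1", call. = FALSE)
  }
  if (any(subgroups$visit_mean <= 0) || any(subgroups$followup_mean <= 0)) {
    stop("visit and follow-up means must be positive", call. = FALSE)
  }
  if (!"probability" %in% names(state_shares)) {
    state_shares <- visit_share_probabilities(state_shares)
  }
  sums <- dplyr::summarise(dplyr::group_by(state_shares, .data$strategy),
                           s = sum(.data$probability), .groups = "drop")
  if (any(abs(sums$s - 1) > 5e-4)) {
    stop("state shares must sum to 1 within each subgroup", call. = FALSE)
  }
  if (any(cost_moments$mean < 0) || any(cost_moments$sd < 0)) {
    stop("cost moments must be non-negative", call. = FALSE)
  }
  bad <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(duration_targets, .data$threshold_months),
                    .data$strategy),
    ok = all(.data$exceedance >= 0 & .data$exceedance <= 1) &&
      !is.unsorted(rev(.data$exceedance)),
    .groups = "drop"
  )
  if (any(!bad$ok)) {
    stop("infeasible exceedance targets: must be non-increasing ",
         "probabilities for ", paste(bad$strategy[!bad$ok], collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(subgroups = tibble::as_tibble(subgroups),
         state_shares = tibble::as_tibble(state_shares),
         cost_moments = tibble::as_tibble(cost_moments),
         duration_targets = tibble::as_tibble(duration_targets),
         seed = seed),
    class = "cohort_config"
  )
}

#' Study-calibrated cohort configuration
#'
#' A [cohort_config()] pre-filled with the study conditions of the packaged
#' pediatric asthma cohort: subgroup sizes (A1 = 8, A2 = 22, B1 = 21,
#' B2 = 8), visit-count and follow-up moments, visit-share state vectors,
#' per-category cost moments and symptom-free exceedance targets, all from
#' the printed study tables (see [asthma_data]).
#'
#' @param n_patients Optional override of the per-subgroup patient counts: a
#'   single number (applied to every subgroup) or a vector named by
#'   subgroup. Used by the large-`n` parameter-recovery checks.
#' @param seed Root seed.
#' @return A `cohort_config`.
#' @export
#' @examples
#' cfg <- asthma_cohort_config(seed = 42)
#' cohort <- generate_cohort(cfg)
asthma_cohort_config <- function(n_patients = NULL, seed = 1) {
  subs <- c("A1", "A2", "B1", "B2")
  vm <- dplyr::filter(asthma_visit_moments(), .data$strategy %in% subs)
  if (!is.null(n_patients)) {
    if (is.null(names(n_patients))) {
      vm$n_patients <- n_patients
    } else {
      idx <- match(vm$strategy, names(n_patients))
      vm$n_patients <- ifelse(is.na(idx), vm$n_patients, n_patients[idx])
    }
  }
  eff <- dplyr::filter(asthma_effectiveness(), .data$strategy %in% subs)
  cohort_config(
    subgroups = vm,
    state_shares = visit_share_probabilities(
      dplyr::filter(asthma_visit_counts(), .data$strategy %in% subs)),
    cost_moments = dplyr::filter(asthma_cost_moments(),
                                 .data$strategy %in% subs),
    duration_targets = dplyr::transmute(
      eff, .data$strategy, .data$threshold_months,
      exceedance = .data$rate_percent / 100),
    seed = seed
  )
}

#' Sample longest symptom-free durations
#'
#' Inverse-CDF sampler for a survival curve that is piecewise-exponential
#' between the calibration thresholds: the survival function passes exactly
#' through `S(t_k) = exceedance_k`, so `P(duration >= t_k)` equals each
#' target in expectation. Beyond the last threshold the final segment's
#' hazard is carried forward.
#'
#' @param n Number of draws.
#' @param thresholds Increasing thresholds in months.
#' @param exceedance Target exceedance probabilities at the thresholds
#'   (non-increasing, in `[0, 1]`).
#' @return Numeric vector of durations (months).
#' @export
sample_sf_durations <- function(n, thresholds = c(3, 6, 12, 24), exceedance) {
  stopifnot(length(thresholds) == length(exceedance),
            all(diff(thresholds) > 0))
  if (any(exceedance < 0 | exceedance > 1) || is.unsorted(rev(exceedance))) {
    stop("infeasible exceedance targets: must be non-increasing in [0, 1]",
         call. = FALSE)
  }
  t <- c(0, thresholds)
  S <- c(1, exceedance)
  k <- length(t)
  logS <- log(pmax(S, 1e-300))
  h <- (logS[-k] - logS[-1]) / diff(t)
  h_tail <- h[k - 1]
  if (!is.finite(h_tail) || h_tail <= 0) {
    pos <- h[is.finite(h) & h > 0]
    h_tail <- if (length(pos)) pos[length(pos)] else 1 / max(t)
  }
  u <- stats::runif(n)
  d <- numeric(n)
  in_tail <- u <= S[k]
  d[in_tail] <- t[k] + (logS[k] - log(u[in_tail])) / h_tail
  for (j in seq_len(k - 1)) {
    idx <- !in_tail & u > S[j + 1] & u <= S[j]
    if (any(idx)) {
      d[idx] <- t[j] + (logS[j] - log(u[idx])) / h[j]
    }
  }
  d
}

# Negative binomial visit counts matched by moments, resampling zeros so
# every patient has at least one visit. Falls back to Poisson when the
# variance does not exceed the mean.
sample_visit_counts <- function(n, mean, sd) {
  var <- sd^2
  draw <- if (var > mean) {
    size <- mean^2 / (var - mean)
    function(m) stats::rnbinom(m, size = size, mu = mean)
  } else {
    function(m) stats::rpois(m, lambda = mean)
  }
  x <- draw(n)
  while (any(x == 0)) {
    x[x == 0] <- draw(sum(x == 0))
  }
  x
}

rgamma_moments <- function(n, mean, sd) {
  out <- numeric(n)
  fixed <- sd == 0 | mean == 0
  out[fixed] <- mean[fixed]
  if (any(!fixed)) {
    out[!fixed] <- stats::rgamma(sum(!fixed),
                                 shape = (mean[!fixed] / sd[!fixed])^2,
                                 scale = sd[!fixed]^2 / mean[!fixed])
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws patient-level records per subgroup according to the configuration:
#' a visit count per patient, a health state and four cost-category amounts
#' (ICS, traditional Chinese medicine, other medication, non-medication) per
#' visit, and a longest symptom-free duration and follow-up length per
#' patient. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `cohort` object: list with `patients` (tibble: `patient_id`,
#'   `strategy`, `n_visits`, `longest_symptom_free`, `followup_months`) and
#'   `visits` (tibble: `patient_id`, `strategy`, `visit`, `state`,
#'   `ics_cost`, `tcm_cost`, `other_cost`, `non_medication_cost`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  states <- health_states()
  patients <- list()
  visits <- list()
  offset <- 0L
  for (i in seq_len(nrow(config$subgroups))) {
    sub <- config$subgroups[i, ]
    n <- sub$n_patients
    ids <- offset + seq_len(n)
    offset <- offset + n

    n_visits <- sample_visit_counts(n, sub$visit_mean, sub$visit_sd)
    shares <- dplyr::filter(config$state_shares,
                            .data$strategy == sub$strategy)
    p <- shares$probability[match(states, shares$state)]
    p[is.na(p)] <- 0

    v <- tibble::tibble(
      patient_id = rep(ids, n_visits),
      strategy = sub$strategy,
      visit = sequence(n_visits),
      state = sample(states, sum(n_visits), replace = TRUE, prob = p)
    )
    mom <- dplyr::filter(config$cost_moments, .data$strategy == sub$strategy)
    for (cat in c("ics", "tcm", "other", "non_medication")) {
      mc <- dplyr::filter(mom, .data$category == cat)
      mu <- mc$mean[match(v$state, mc$state)]
      sd <- mc$sd[match(v$state, mc$state)]
      mu[is.na(mu)] <- 0
      sd[is.na(sd)] <- 0
      v[[paste0(cat, "_cost")]] <- rgamma_moments(nrow(v), mu, sd)
    }

    tg <- dplyr::arrange(
      dplyr::filter(config$duration_targets, .data$strategy == sub$strategy),
      .data$threshold_months)
    durations <- sample_sf_durations(n, tg$threshold_months, tg$exceedance)
    followup <- rgamma_moments(n, sub$followup_mean, sub$followup_sd)
    followup <- pmax(followup, durations)

    patients[[i]] <- tibble::tibble(
      patient_id = ids,
      strategy = sub$strategy,
      n_visits = n_visits,
      longest_symptom_free = durations,
      followup_months = followup
    )
    visits[[i]] <- v
  }
  structure(
    list(patients = dplyr::bind_rows(patients),
         visits = dplyr::bind_rows(visits),
         config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$patients), " patients, ", nrow(x$visits),
      " visits, ", dplyr::n_distinct(x$patients$strategy),
      " subgroups (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Aggregate a cohort back into model parameters
#'
#' Mirrors the study's own aggregation: per-state visit counts become branch
#' probabilities (visit shares), per-visit mean costs per state become
#' branch costs on both cost bases (ICS-only, and total medication = ICS +
#' TCM + other medication), longest symptom-free durations become
#' effectiveness rates, and per-category cost moments are summarised. The
#' resulting strategy tables feed [evaluate_strategy()] and friends
#' unchanged. A state with no visits gets probability 0; its (unobservable)
#' branch cost is reported as `NA` in the cost summary and set to 0 in the
#' strategy table, where it has no weight.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param model Utility model supplying the branch utilities.
#' @return A `cohort_summary`: list with `strategies_ics`,
#'   `strategies_medication` (both [strategy_params()]), `visit_counts`,
#'   `effectiveness`, `cost_summary`.
#' @export
aggregate_cohort <- function(cohort, model = utility_model()) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort$visits) == 0L) stop("empty cohort", call. = FALSE)
  states <- health_states()
  v <- dplyr::mutate(cohort$visits,
                     medication_cost = .data$ics_cost + .data$tcm_cost +
                       .data$other_cost)
  counts <- dplyr::count(v, .data$strategy, .data$state, name = "visits")
  counts <- tidyr::complete(
    counts, .data$strategy, state = !!states, fill = list(visits = 0L))
  counts <- dplyr::arrange(counts, .data$strategy,
                           factor(.data$state, levels = states))
  probs <- visit_share_probabilities(counts)

  mean_costs <- dplyr::summarise(
    dplyr::group_by(v, .data$strategy, .data$state),
    ics = mean(.data$ics_cost),
    medication = mean(.data$medication_cost),
    .groups = "drop"
  )
  tab <- dplyr::left_join(probs, mean_costs, by = c("strategy", "state"))
  tab <- dplyr::left_join(tab, state_utilities(model), by = "state")

  make_params <- function(basis) {
    x <- dplyr::transmute(
      tab, .data$strategy, .data$state,
      cost_cny = dplyr::coalesce(.data[[basis]], 0),
      .data$probability, .data$utility_qaly)
    strategy_params(x, cost_basis = basis, prob_tol = 1e-9)
  }

  eff <- effectiveness_rates(
    dplyr::transmute(cohort$patients, .data$strategy,
                     duration_months = .data$longest_symptom_free))

  cost_summary <- tidyr::pivot_longer(
    v, cols = c("ics_cost", "tcm_cost", "other_cost",
                "non_medication_cost"),
    names_to = "category", values_to = "amount")
  cost_summary <- dplyr::summarise(
    dplyr::group_by(cost_summary, .data$strategy, .data$state,
                    .data$category),
    mean = mean(.data$amount), sd = stats::sd(.data$amount),
    n_visits = dplyr::n(), .groups = "drop")

  structure(
    list(strategies_ics = make_params("ics"),
         strategies_medication = make_params("medication"),
         visit_counts = counts,
         effectiveness = eff,
         cost_summary = cost_summary),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", dplyr::n_distinct(x$visit_counts$strategy),
      " subgroups, ", sum(x$visit_counts$visits), " visits\n", sep = "")
  print(x$strategies_ics)
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed); writes
#'   `patients.csv` and `visits.csv`.
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"))
  invisible(dir)
}
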