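#' Fit a Gamma cost prior by the method of moments
#'
#' Cost parameters are given uncertainty through a Gamma distribution
#' matched to a (mean, sd) pair: `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`. The fitted distribution preserves the input moments
#' exactly.
#'
#' @param mean,sd Positive moments, in CNY (vectorised).
#' @return A tibble with columns `mean`, `sd`, `shape`, `scale`.
#' @export
#' @examples
#' fit_gamma_from_moments(100, 10)
fit_gamma_from_moments <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) {
    stop("gamma moments must be positive", call. = FALSE)
  }
  tibble::tibble(mean = mean, sd = sd,
                 shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Dirichlet prior over the three-state probability simplex
#'
#' Probability parameters are given joint uncertainty through a Dirichlet
#' distribution with the observed visit counts as concentration parameters.
#' Each marginal is then Beta(`count_i`, `total - count_i`), and every draw
#' sums to 1, so the three branch probabilities remain a valid probability
#' vector in every iteration.
#'
#' @param counts Positive per-state counts (named by state or in canonical
#'   state order).
#' @return A list of class `dirichlet_prior` with elements `alpha` and
#'   `mean`.
#' @export
#' @examples
#' dirichlet_from_counts(c(8, 8, 30))
dirichlet_from_counts <- function(counts) {
  if (any(counts <= 0)) {
    stop("zero count: every state needs a positive count ",
         "(add a small offset to empty states before calling)",
         call. = FALSE)
  }
  structure(list(alpha = counts, mean = counts / sum(counts)),
            class = "dirichlet_prior")
}

#' Sample from a Dirichlet distribution
#'
#' Standard Gamma-normalisation sampler: independent Gamma(`alpha_i`, 1)
#' draws scaled to sum to 1.
#'
#' @param n Number of draws.
#' @param alpha Concentration parameters (length k).
#' @return An `n x k` matrix; rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = k)
  g / rowSums(g)
}

# Deterministic sub-seed for a named parameter stream: a byte-rolling hash
# of the id folded into the root seed, kept below 2^31 - 1. Adding a new
# parameter leaves every other parameter's stream unchanged.
substream_seed <- function(root, id) {
  m <- 2^31 - 1
  s <- as.numeric(root) %% m
  for (b in utf8ToInt(id)) s <- (s * 31 + b) %% m
  as.integer(s) + 1L
}

#' Attach PSA priors to one strategy
#'
#' Builds the per-parameter uncertainty specification for a single strategy
#' column: a Gamma prior on each state cost (moment-matched to the supplied
#' sd, or to `cv * mean` when no sd is available; an sd of zero keeps the
#' cost fixed), a Dirichlet prior on the branch probability vector when
#' visit counts are given (fixed probabilities otherwise), and fixed
#' utilities -- the base model varies only costs and probabilities. Set
#' `vary_utilities = TRUE` to add a Beta prior on the base annual utility.
#'
#' @param params A [strategy_params()] table containing `label`.
#' @param label Strategy to extract.
#' @param cost_sd Optional data frame with columns `state`, `sd` (CNY)
#'   giving the prior sd of each state cost; defaults to `cv * mean`.
#' @param prob_counts Optional per-state visit counts (named vector or data
#'   frame with `state`, `visits`) for the Dirichlet prior.
#' @param cv Coefficient of variation used for costs with no supplied sd.
#' @param vary_utilities Give the base annual utility a Beta prior (moment
#'   matched at mean `utility_model()$base_utility` with `utility_cv`).
#' @param utility_cv Coefficient of variation for the utility prior.
#' @param model Utility model used when `vary_utilities = TRUE`.
#' @return A `psa_spec` object.
#' @export
#' @examples
#' counts <- dplyr::filter(asthma_visit_counts(), strategy == "A")
#' psa_spec(asthma_strategies("ics"), "A", prob_counts = counts)
psa_spec <- function(params, label, cost_sd = NULL, prob_counts = NULL,
                     cv = 0.3, vary_utilities = FALSE, utility_cv = 0.05,
                     model = utility_model()) {
  stopifnot(inherits(params, "strategy_params"))
  col <- dplyr::filter(tibble::as_tibble(params), .data$strategy == label)
  if (nrow(col) != 3L) stop("unknown strategy label: ", label, call. = FALSE)
  costs <- tibble::tibble(state = col$state, mean = col$cost_cny)
  if (!is.null(cost_sd)) {
    if (is.numeric(cost_sd)) {
      cost_sd <- tibble::tibble(state = names(cost_sd), sd = unname(cost_sd))
    }
    costs <- dplyr::left_join(costs, cost_sd[c("state", "sd")], by = "state")
  } else {
    costs$sd <- NA_real_
  }
  costs$sd <- ifelse(is.na(costs$sd), cv * costs$mean, costs$sd)
  costs$kind <- ifelse(costs$sd == 0 | costs$mean == 0, "fixed", "gamma")
  fit <- costs$kind == "gamma"
  costs$shape <- costs$scale <- NA_real_
  if (any(fit)) {
    g <- fit_gamma_from_moments(costs$mean[fit], costs$sd[fit])
    costs$shape[fit] <- g$shape
    costs$scale[fit] <- g$scale
  }

  probs <- list(kind = "fixed", p = stats::setNames(col$probability, col$state))
  if (!is.null(prob_counts)) {
    if (is.data.frame(prob_counts)) {
      prob_counts <- stats::setNames(prob_counts$visits, prob_counts$state)
    }
    if (!is.null(names(prob_counts))) {
      prob_counts <- prob_counts[col$state]
    }
    probs <- list(kind = "dirichlet",
                  prior = dirichlet_from_counts(unname(prob_counts)))
  }

  utilities <- list(kind = "fixed",
                    u = stats::setNames(col$utility_qaly, col$state))
  if (vary_utilities) {
    mu <- model$base_utility
    sd <- utility_cv * mu
    # Beta moments: a = mu * (mu(1-mu)/sd^2 - 1), b = (1-mu) * (...)
    nu <- mu * (1 - mu) / sd^2 - 1
    utilities <- list(kind = "beta_base", a = mu * nu, b = (1 - mu) * nu,
                      model = model)
  }

  structure(
    list(label = label, cost_basis = cost_basis(params),
         costs = costs, probs = probs, utilities = utilities),
    class = "psa_spec"
  )
}

draw_spec <- function(spec, n, root_seed, arm) {
  states <- health_states()
  cost_draws <- matrix(NA_real_, nrow = n, ncol = 3L,
                       dimnames = list(NULL, states))
  for (i in seq_len(3L)) {
    row <- spec$costs[i, ]
    if (row$kind == "fixed") {
      cost_draws[, i] <- rep(row$mean, n)
    } else {
      set.seed(substream_seed(root_seed, paste(arm, "cost", row$state,
                                               sep = "/")))
      cost_draws[, i] <- stats::rgamma(n, shape = row$shape,
                                       scale = row$scale)
    }
  }
  if (spec$probs$kind == "fixed") {
    prob_draws <- matrix(rep(spec$probs$p[states], each = n), nrow = n)
  } else {
    set.seed(substream_seed(root_seed, paste(arm, "probs", sep = "/")))
    prob_draws <- rdirichlet(n, spec$probs$prior$alpha)
  }
  if (spec$utilities$kind == "fixed") {
    util_draws <- matrix(rep(spec$utilities$u[states], each = n), nrow = n)
  } else {
    set.seed(substream_seed(root_seed, paste(arm, "utility", sep = "/")))
    base <- stats::rbeta(n, spec$utilities$a, spec$utilities$b)
    model <- spec$utilities$model
    hf <- horizon_factor(model$horizon_years, model$discount_rate)
    util_draws <- outer(base, rep(1, 3L)) + # base per draw
      matrix(rep(model$decrements[states], each = n), nrow = n)
    util_draws <- pmax(util_draws, 0) * hf
  }
  list(cost = rowSums(prob_draws * cost_draws),
       utility = rowSums(prob_draws * util_draws))
}

spec_base_case <- function(spec) {
  states <- health_states()
  p <- if (spec$probs$kind == "fixed") spec$probs$p[states] else
    spec$probs$prior$mean
  u <- if (spec$utilities$kind == "fixed") spec$utilities$u[states] else {
    model <- spec$utilities$model
    (model$base_utility + model$decrements[states]) *
      horizon_factor(model$horizon_years, model$discount_rate)
  }
  c(cost = sum(p * spec$costs$mean), utility = sum(p * u))
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty through the decision
#' tree: in each iteration every uncertain cost is drawn from its Gamma
#' prior, every probability vector from its Dirichlet prior (utilities per
#' the spec), the two strategies' expected values are recomputed, and the
#' incremental pair `(delta cost, delta utility)` is stored. Each parameter
#' has its own random substream derived from the root seed (see
#' [psa_spec()]), so runs are bit-reproducible and adding a parameter does
#' not reshuffle the others.
#'
#' @param ref,alt `psa_spec` objects for the reference and alternative
#'   strategies; must share a cost basis.
#' @param n Number of iterations (>= 1); the worked examples use 1000.
#' @param seed Root seed.
#' @param wtp A [wtp_threshold()] or positive number, recorded for plots.
#' @return A `psa_result`: list with `draws` (tibble: `iteration`,
#'   `ref_cost`, `ref_utility`, `alt_cost`, `alt_utility`, `delta_cost`,
#'   `delta_utility`), `base` (deterministic base-case deltas), `n`, `seed`,
#'   `wtp`, `cost_basis`, `labels`.
#' @export
#' @examples
#' params <- asthma_strategies("ics")
#' counts <- asthma_visit_counts()
#' ref <- psa_spec(params, "A",
#'                 prob_counts = dplyr::filter(counts, strategy == "A"))
#' alt <- psa_spec(params, "B",
#'                 prob_counts = dplyr::filter(counts, strategy == "B"))
#' psa <- run_psa(ref, alt, n = 200, seed = 1)
run_psa <- function(ref, alt, n = 1000, seed = 1, wtp = wtp_threshold()) {
  stopifnot(inherits(ref, "psa_spec"), inherits(alt, "psa_spec"))
  if (!identical(ref$cost_basis, alt$cost_basis)) {
    stop("cost basis mismatch between the two strategies", call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  r <- draw_spec(ref, n, seed, arm = paste0("ref:", ref$label))
  a <- draw_spec(alt, n, seed, arm = paste0("alt:", alt$label))
  draws <- tibble::tibble(
    iteration = seq_len(n),
    ref_cost = r$cost, ref_utility = r$utility,
    alt_cost = a$cost, alt_utility = a$utility,
    delta_cost = a$cost - r$cost,
    delta_utility = a$utility - r$utility
  )
  base_r <- spec_base_case(ref)
  base_a <- spec_base_case(alt)
  structure(
    list(draws = draws,
         base = tibble::tibble(
           delta_cost = unname(base_a["cost"] - base_r["cost"]),
           delta_utility = unname(base_a["utility"] - base_r["utility"])),
         n = n, seed = seed, wtp = as_wtp(wtp),
         cost_basis = ref$cost_basis,
         labels = c(ref = ref$label, alt = alt$label)),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$labels[["alt"]], " vs ", x$labels[["ref"]],
      " (", x$cost_basis, " costs), n = ", x$n, ", seed = ", x$seed, "\n",
      sep = "")
  cat("  mean delta cost: ", round(mean(x$draws$delta_cost), 2),
      " CNY; mean delta utility: ", round(mean(x$draws$delta_utility), 4),
      " QALYs\n", sep = "")
  cat("  base case: ", round(x$base$delta_cost, 2), " CNY / ",
      round(x$base$delta_utility, 4), " QALYs\n", sep = "")
  invisible(x)
}

#' Tidy PSA draws
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return The draw tibble.
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' Glance at a PSA
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return One-row tibble with iteration count, seed, mean deltas, base-case
#'   deltas and the probability of cost-effectiveness at the recorded WTP.
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n,
    seed = x$seed,
    cost_basis = x$cost_basis,
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_utility = mean(x$draws$delta_utility),
    base_delta_cost = x$base$delta_cost,
    base_delta_utility = x$base$delta_utility,
    prob_cost_effective_at_wtp =
      mean(x$wtp * x$draws$delta_utility - x$draws$delta_cost > 0)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' that the alternative is cost-effective is the fraction of draws with a
#' positive incremental net monetary benefit,
#' `lambda * delta_utility - delta_cost > 0`. At `lambda = 0` this is the
#' fraction of cost-saving draws; as `lambda` grows it approaches the
#' fraction of utility-gaining draws.
#'
#' @param result A `psa_result` (or a data frame with `delta_cost`,
#'   `delta_utility`).
#' @param wtp_grid Non-empty numeric grid of WTP values (CNY/QALY).
#' @return A `ceac` tibble with columns `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 600000, by = 10000)) {
  draws <- if (inherits(result, "psa_result")) result$draws else result
  stopifnot(is.data.frame(draws),
            all(c("delta_cost", "delta_utility") %in% names(draws)))
  if (nrow(draws) == 0L) stop("no draws", call. = FALSE)
  if (length(wtp_grid) == 0L) stop("empty WTP grid", call. = FALSE)
  out <- tibble::tibble(
    wtp = wtp_grid,
    prob_cost_effective = vapply(
      wtp_grid,
      function(l) mean(l * draws$delta_utility - draws$delta_cost > 0),
      numeric(1))
  )
  class(out) <- c("ceac", class(out))
  out
}

#' Cost-effectiveness plane summary
#'
#' Normal-theory summary of the incremental cloud: the bivariate mean and
#' covariance of `(delta_cost, delta_utility)` define a confidence ellipse
#' (Mahalanobis radius `sqrt(qchisq(level, 2))`), and the draws are
#' apportioned among the four quadrants of the plane.
#'
#' @param result A `psa_result` (>= 3 draws).
#' @param level Confidence level of the ellipse.
#' @return A list of class `ce_plane_summary`: `center`, `cov`, `level`,
#'   `axes` (half-axis lengths), `angle` (radians, major axis), `ellipse`
#'   (tibble of boundary points), `inside_fraction`, and `quadrants` (tibble
#'   of quadrant shares summing to 1).
#' @export
ce_plane_summary <- function(result, level = 0.95) {
  draws <- if (inherits(result, "psa_result")) result$draws else result
  stopifnot(is.data.frame(draws), nrow(draws) >= 3L)
  m <- cbind(draws$delta_cost, draws$delta_utility)
  center <- colMeans(m)
  S <- stats::cov(m)
  degenerate <- any(diag(S) == 0)
  r2 <- stats::qchisq(level, df = 2)
  theta <- seq(0, 2 * pi, length.out = 181L)
  if (degenerate) {
    warning("zero-variance draws: ellipse degenerates to a point")
    inside <- 1
    ell <- tibble::tibble(delta_cost = center[1], delta_utility = center[2])
    axes <- c(0, 0); angle <- 0
  } else {
    md <- stats::mahalanobis(m, center, S)
    inside <- mean(md <= r2)
    eig <- eigen(S, symmetric = TRUE)
    axes <- sqrt(eig$values * r2)
    angle <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
    circ <- rbind(cos(theta) * axes[1], sin(theta) * axes[2])
    pts <- t(eig$vectors %*% circ + center)
    ell <- tibble::tibble(delta_cost = pts[, 1], delta_utility = pts[, 2])
  }
  quad <- tibble::tibble(
    quadrant = c("costlier_more_effective", "cheaper_more_effective",
                 "cheaper_less_effective", "costlier_less_effective"),
    share = c(
      mean(draws$delta_cost >= 0 & draws$delta_utility > 0),
      mean(draws$delta_cost < 0 & draws$delta_utility > 0),
      mean(draws$delta_cost < 0 & draws$delta_utility <= 0),
      mean(draws$delta_cost >= 0 & draws$delta_utility <= 0))
  )
  structure(
    list(center = stats::setNames(center, c("delta_cost", "delta_utility")),
         cov = S, level = level, axes = axes, angle = angle,
         ellipse = ell, inside_fraction = inside, quadrants = quad),
    class = "ce_plane_summary"
  )
}

#' @export
print.ce_plane_summary <- function(x, ...) {
  cat("<ce_plane_summary> ", x$level * 100, "% ellipse; ",
      round(x$inside_fraction * 100, 1), "% of draws inside\n", sep = "")
  cat("  center: ", round(x$center[1], 2), " CNY / ",
      round(x$center[2], 4), " QALYs\n", sep = "")
  print(x$quadrants)
  invisible(x)
}
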