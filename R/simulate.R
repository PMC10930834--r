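#' Simulate realistic integrated-farm DMU tables
#'
#' Generates batches with the statistical structure of the reference
#' dataset: log-normal housing (mean ~513,000 birds, CV ~56%), slaughter
#' age normal(42, 1) truncated to [40, 45] days, mortality a scaled
#' Beta(2, 4) on (3%, 9.2%) (mean ~5.1%), per-bird daily gain normal(72, 3)
#' g/day, feed conversion normal(1.55, 0.05) and unit cost normal(4.33,
#' 0.10) linked negatively to the batch's production efficiency factor.
#' Outputs are built structurally, which reproduces the near-collinearity of
#' feed, housing and total weight seen in real integration data:
#' `total_weight = housing (1 - mortality) dwg age / scale` and
#' `feed = fcr * total_weight`.
#'
#' @param n_dmus number of batches (>= 2).
#' @param seed integer seed; all draws are governed by it and the global
#'   RNG state is left untouched.
#' @param housing_mean,housing_cv log-normal law of housed birds.
#' @param age_mean,age_sd,age_range truncated-normal law of slaughter age
#'   (days).
#' @param mortality_range,mortality_shape bounds (as fractions) and Beta
#'   shape parameters of the mortality law.
#' @param dwg_mean,dwg_sd normal law of per-bird daily gain (g/day).
#' @param fcr_mean,fcr_sd normal law of feed conversion.
#' @param cost_mean,cost_sd cost law (currency/kg).
#' @param cost_pef_rho strength of the negative cost-PEF link in [0, 1);
#'   0 makes cost independent noise.
#' @param mass_unit_to_grams weight unit, as in [zootech_indicators()].
#' @return a [dmu_table()] with attribute `truth`: the generating dwg and
#'   fcr per batch (recoverable exactly via [zootech_indicators()]).
#' @export
#' @examples
#' tab <- simulate_farms(31, seed = 1)
#' descriptive_stats(tab)["mean", ]
simulate_farms <- function(n_dmus, seed,
                           housing_mean = 513000, housing_cv = 0.56,
                           age_mean = 42, age_sd = 1, age_range = c(40, 45),
                           mortality_range = c(0.03, 0.092),
                           mortality_shape = c(2, 4),
                           dwg_mean = 72, dwg_sd = 3,
                           fcr_mean = 1.55, fcr_sd = 0.05,
                           cost_mean = 4.33, cost_sd = 0.10,
                           cost_pef_rho = 0.4,
                           mass_unit_to_grams = 1e6) {
  if (!is.numeric(n_dmus) || n_dmus < 2)
    stop("n_dmus must be at least 2", call. = FALSE)
  stopifnot(housing_mean > 0, housing_cv > 0, age_sd > 0,
            mortality_range[1] > 0, mortality_range[2] < 1,
            mortality_range[1] < mortality_range[2],
            all(mortality_shape > 0), dwg_mean > 0, fcr_mean > 0,
            cost_mean > 0, cost_pef_rho >= 0, cost_pef_rho < 1)
  withr::with_seed(as.integer(seed), {
    sdlog <- sqrt(log(1 + housing_cv^2))
    meanlog <- log(housing_mean) - sdlog^2 / 2
    housing <- round(exp(rnorm(n_dmus, meanlog, sdlog)))
    # truncated normal by inverse-cdf sampling
    lo <- pnorm(age_range[1], age_mean, age_sd)
    hi <- pnorm(age_range[2], age_mean, age_sd)
    age <- qnorm(runif(n_dmus, lo, hi), age_mean, age_sd)
    mortality <- mortality_range[1] + diff(mortality_range) *
      rbeta(n_dmus, mortality_shape[1], mortality_shape[2])
    dwg <- pmax(rnorm(n_dmus, dwg_mean, dwg_sd), 1)
    fcr <- pmax(rnorm(n_dmus, fcr_mean, fcr_sd), 0.6)
    total_weight <- housing * (1 - mortality) * dwg * age / mass_unit_to_grams
    feed <- fcr * total_weight
    pef <- (100 * (1 - mortality)) * dwg / (10 * fcr)
    z_pef <- if (sd(pef) > 0) (pef - mean(pef)) / sd(pef) else numeric(n_dmus)
    cost <- cost_mean + cost_sd * (-cost_pef_rho * z_pef +
                                     sqrt(1 - cost_pef_rho^2) * rnorm(n_dmus))
    cost <- pmax(cost, 0.1)
    tab <- dmu_table(data.frame(dmu = seq_len(n_dmus), housing = housing,
                                age = age, feed = feed,
                                mortality = mortality, cost = cost,
                                total_weight = total_weight))
    attr(tab, "truth") <- data.frame(dmu = seq_len(n_dmus),
                                     dwg = dwg, fcr = fcr)
    tab
  })
}

#' Generate a frontier with planted, analytically known efficiencies
#'
#' Builds a validation instance for the envelopment solver. Efficient units
#' are drawn on a common supporting hyperplane of a randomly weighted
#' technology (`u'y = v'x` under constant returns, `u'y = v'x + w` under
#' variable returns, with strictly positive u, v), so every one of them --
#' and every convex (CRS: conic) combination of them -- attains radial
#' score exactly 1. Each inefficient unit takes such a combination and
#' inflates its inputs by `1/theta`; a duality argument (any feasible
#' contraction below `theta` would contradict `u'y <= v'x (+ w)` holding on
#' the whole table) makes `theta` its exact input-oriented score under the
#' chosen returns-to-scale assumption.
#'
#' @param n_efficient number of frontier-defining units (>= 1; >= 2
#'   recommended under VRS so the frontier has extent).
#' @param n_inefficient number of dominated units.
#' @param n_inputs number of inputs (single output).
#' @param rts `"crs"` or `"vrs"`.
#' @param theta_range planted scores are drawn uniformly from this interval.
#' @param seed integer seed.
#' @return list with `table` (a [dmu_table()] whose input columns are named
#'   `x1..xk`, output `y`) and `truth` (data.frame of dmu and the planted
#'   input-oriented score, 1 for frontier units).
#' @export
#' @examples
#' inst <- planted_frontier(3, 5, seed = 7)
#' all.equal(unname(dea(inst$table)$scores), inst$truth$score, tolerance = 1e-6)
planted_frontier <- function(n_efficient, n_inefficient, n_inputs = 3,
                             rts = c("crs", "vrs"),
                             theta_range = c(0.5, 0.99), seed = 1) {
  rts <- match.arg(rts)
  stopifnot(n_efficient >= 1, n_inefficient >= 0, n_inputs >= 1)
  withr::with_seed(as.integer(seed), {
    v <- runif(n_inputs, 0.5, 2)          # input prices
    u <- runif(1, 0.5, 2)                 # output price
    w <- if (rts == "vrs") runif(1, 0.1, 1) else 0
    Xe <- matrix(runif(n_efficient * n_inputs, 1, 10), n_efficient)
    ye <- (Xe %*% v + w) / u              # on the hyperplane u y = v'x + w
    Xi <- NULL; yi <- NULL; theta <- numeric(0)
    if (n_inefficient > 0) {
      theta <- runif(n_inefficient, theta_range[1], theta_range[2])
      lam <- matrix(runif(n_inefficient * n_efficient), n_inefficient)
      lam <- lam / rowSums(lam)           # convex weights
      if (rts == "crs") lam <- lam * runif(n_inefficient, 0.5, 2)
      Xi <- (lam %*% Xe) / theta          # inflate inputs
      yi <- lam %*% ye
    }
    d <- data.frame(dmu = seq_len(n_efficient + n_inefficient),
                    rbind(cbind(Xe, ye), cbind(Xi, yi)))
    names(d) <- c("dmu", paste0("x", seq_len(n_inputs)), "y")
    tab <- dmu_table(d, input_names = paste0("x", seq_len(n_inputs)),
                     output_names = "y")
    list(table = tab,
         truth = data.frame(dmu = d$dmu,
                            score = c(rep(1, n_efficient), theta)))
  })
}
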