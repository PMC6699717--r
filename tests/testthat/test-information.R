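test_that("per-observation information is the reciprocal count variance", {
  expect_equal(unit_info_mean(4, count_model("poisson")), 0.25)
  expect_equal(unit_info_mean(4, count_model("nb", k = 12)), 0.1875)
  # Poisson limit of the NB
  expect_equal(unit_info_mean(4, count_model("nb", k = 1e12)), 0.25,
               tolerance = 1e-9)
  expect_error(unit_info_mean(0, count_model("poisson")), "positive")
})

test_that("NB log-likelihood curvature matches the information kernel", {
  # Monte-Carlo oracle: -E[d^2 logL / dm^2] estimated from draws
  set.seed(101)
  for (i in 1:10) {
    m <- exp(stats::runif(1, log(2), log(500)))
    k <- exp(stats::runif(1, log(1), log(200)))
    x <- stats::rnbinom(1e5, size = k, mu = m)
    h <- m * 1e-4
    d2 <- (stats::dnbinom(x, size = k, mu = m + h, log = TRUE) -
             2 * stats::dnbinom(x, size = k, mu = m, log = TRUE) +
             stats::dnbinom(x, size = k, mu = m - h, log = TRUE)) / h^2
    se <- stats::sd(d2) / sqrt(length(d2))
    expect_lt(abs(-mean(d2) - unit_info_mean(m, count_model("nb", k = k))),
              3 * se)
  }
})

test_that("SLAMseq Poisson FIM is diagonal with the known inverse term", {
  g <- gene_kinetics(delta = 1, mu = 100)
  f <- fim(slam_design_points(1), g, count_model("poisson"))
  expect_equal(f$matrix["delta", "mu"], 0, tolerance = 1e-12)
  v <- variance_of_estimates(f)
  expect_equal(v$variances[["delta"]], 0.0171828, tolerance = 1e-5)
  expect_equal(v$variances[["delta"]], closed_form_slamseq_poisson(1, 100, 1),
               tolerance = 1e-10)
  # diagonal FIM: the bound is attained exactly
  expect_equal(v$variances[["delta"]], v$bound_delta, tolerance = 1e-12)
  # replicates scale the matrix exactly
  f3 <- fim(slam_design_points(1), g, count_model("poisson"), n_reps = 3)
  expect_equal(f3$matrix, 3 * f$matrix)
})

test_that("generic FIM assembly reproduces the closed forms", {
  set.seed(7)
  for (i in 1:100) {
    delta <- exp(stats::runif(1, log(0.05), log(5)))
    mu <- exp(stats::runif(1, log(20), log(1e5)))
    t <- stats::runif(1, 0.05, 6)
    k <- exp(stats::runif(1, log(1), log(1e3)))
    g <- gene_kinetics(delta, mu)
    pts <- slam_design_points(t)
    vp <- variance_of_estimates(fim(pts, g, count_model("poisson")))
    expect_equal(vp$variances[["delta"]],
                 closed_form_slamseq_poisson(delta, mu, t),
                 tolerance = 1e-8)
    vn <- variance_of_estimates(fim(pts, g, count_model("nb", k = k)))
    expect_equal(vn$variances[["delta"]],
                 closed_form_slamseq_nb(delta, mu, t, k),
                 tolerance = 1e-8)
    # dimensionless forms at alpha = delta * t
    terms <- normalized_fim_terms(delta * t, mu)
    f <- fim(pts, g, count_model("poisson"))
    expect_equal(f$matrix["delta", "delta"] * delta^2, terms$combined,
                 tolerance = 1e-8)
  }
  # small-delta series of the Poisson closed form
  expect_equal(closed_form_slamseq_poisson(1e-3, 100, 1),
               (1e-3 / 100) * (1 + 1e-3 / 2), tolerance = 1e-6)
  # doubling the depth halves the variance
  expect_equal(closed_form_slamseq_poisson(1, 200, 1),
               closed_form_slamseq_poisson(1, 100, 1) / 2)
  # NB reduces to Poisson as k grows
  expect_equal(closed_form_slamseq_nb(1, 100, 1, 1e12),
               closed_form_slamseq_poisson(1, 100, 1), tolerance = 1e-9)
})

test_that("normalized information terms are additive with known shapes", {
  alpha <- exp(seq(log(0.05), log(10), length.out = 40))
  terms <- normalized_fim_terms(alpha, mu = 1)
  expect_equal(terms$combined, terms$labeled + terms$unlabeled,
               tolerance = 1e-12)
  expect_equal(normalized_fim_terms(1.5936, 1)$combined, 0.6476,
               tolerance = 1e-4)
  # power-law growth at short times: slopes on a log-log grid
  a_small <- exp(seq(log(1e-4), log(1e-3), length.out = 20))
  ts <- normalized_fim_terms(a_small, 1)
  slope <- function(y) {
    unname(stats::coef(stats::lm(log(y) ~ log(a_small)))[2])
  }
  expect_equal(slope(ts$combined), 1, tolerance = 1e-3)
  expect_equal(slope(ts$labeled), 1, tolerance = 1e-3)
  expect_equal(slope(ts$unlabeled), 2, tolerance = 1e-3)
  # exponential decay at long times: after removing the alpha^2 prefactor,
  # log(term) is asymptotically linear in alpha
  a_big <- seq(12, 16, length.out = 20)
  tb <- normalized_fim_terms(a_big, 1)
  eslope <- function(y) {
    unname(stats::coef(stats::lm(I(log(y) - 2 * log(a_big)) ~ a_big))[2])
  }
  expect_equal(eslope(tb$labeled), -2, tolerance = 0.02)
  expect_equal(eslope(tb$combined), -1, tolerance = 0.02)
  expect_equal(eslope(tb$unlabeled), -1, tolerance = 0.02)
})

test_that("overdispersion limits match their closed forms", {
  m <- count_model("nb", k = 100)
  lims <- asymptotic_limits(m, delta = 1, t = 1e-9)
  expect_equal(lims$slam_depth_floor, 0.02, tolerance = 1e-6)
  expect_equal(lims$slam_t0_floor, 0.02)
  expect_equal(asymptotic_limits(count_model("nb", k = 10), 1, 2,
                                 "unlabeled_ceiling"), 40)
  lab <- asymptotic_limits(count_model("nb", k = 10), 1, 0.01,
                           "labeled_ceiling")
  expect_equal(lab, 9.90, tolerance = 1e-2)
  expect_lt(lab, 10)  # k / delta^2 supremum, approached from below
  expect_error(asymptotic_limits(count_model("poisson"), 1, 1), "NB")
})

test_that("assembled information matrices are symmetric, PSD and bounded", {
  set.seed(11)
  for (i in 1:25) {
    g <- random_gene()
    k <- exp(stats::runif(1, log(1), log(500)))
    times <- sort(stats::runif(3, 0.1, 8))
    pts <- unlist(lapply(times, slam_design_points), recursive = FALSE)
    f <- fim(pts, g, count_model("nb", k = k),
             n_reps = sample(1:3, 1))
    expect_equal(f$matrix, t(f$matrix))
    ev <- eigen(f$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10 * max(ev)))
    v <- variance_of_estimates(f)
    expect_gte(v$variances[["delta"]] * (1 + 1e-10), v$bound_delta)
  }
})

test_that("conditional fraction split is binomial with rate exp(-delta t)", {
  expect_equal(conditional_binomial_rate(1, 0)[["unlabeled"]], 1)
  expect_equal(conditional_binomial_rate(1, 1)[["unlabeled"]], 0.367879,
               tolerance = 1e-5)
  expect_equal(sum(conditional_binomial_rate(0.4, 2)), 1)
  # the conditional-binomial rate estimator equals the joint Poisson MLE
  set.seed(5)
  g <- gene_kinetics(delta = 0.8, mu = 2000)
  t <- 1.5
  for (i in 1:5) {
    xL <- stats::rpois(1, mean_count(design_point(t, "labeled", "pulse"), g))
    xU <- stats::rpois(1, mean_count(design_point(t, "unlabeled", "pulse"),
                                     g))
    counts <- matrix(c(xL, xU), 1, 2,
                     dimnames = list("g1", c("L", "U")))
    ss <- data.frame(sample = c("L", "U"), time = t,
                     fraction = c("labeled", "unlabeled"), replicate = 1)
    fit <- fit_kinetics(counts, ss, phase = "pulse", family = "poisson")
    expect_equal(fit$estimates$delta, -log(xU / (xU + xL)) / t,
                 tolerance = 1e-5)
  }
})

test_that("designs with no information are flagged", {
  g <- gene_kinetics(1, 100)
  expect_warning(
    f <- fim(design_point(0, "labeled", "pulse"), g, count_model("poisson")),
    "zero information")
  expect_true(f$singular)
  v <- variance_of_estimates(f)
  expect_true(v$bound_only)
})
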