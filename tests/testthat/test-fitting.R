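test_that("noiseless counts recover the generating rates", {
  deltas <- c(0.3, 1, 3)
  panel <- lapply(deltas, gene_kinetics, mu = 10000)
  des <- slam_pulse_design(1, n_reps = 1, t0_total = TRUE)
  nz <- noiseless_counts(panel, des)
  fit <- fit_kinetics(nz$counts, nz$samples, phase = "pulse",
                      family = "poisson")
  expect_true(all(fit$estimates$converged))
  expect_equal(fit$estimates$delta, deltas, tolerance = 0.01)
  expect_equal(fit$estimates$mu, rep(10000, 3), tolerance = 0.01)
})

test_that("the fitted likelihood dominates the truth", {
  set.seed(31)
  panel <- lapply(exp(stats::runif(6, log(0.1), log(2))),
                  gene_kinetics, mu = 800)
  des <- slam_pulse_design(c(1, 3), n_reps = 2)
  sim <- simulate_counts(panel, des, seed = 99)
  fit <- fit_kinetics(sim$counts, sim$samples)
  nz <- noiseless_counts(panel, des)  # to reuse the sample sheet layout
  # log-likelihood at the true parameters, same normalization
  ll_truth <- 0
  for (g in seq_along(panel)) {
    truth <- panel[[g]]
    m <- vapply(seq_len(nrow(sim$samples)), function(s) {
      mean_count(design_point(sim$samples$time[s], sim$samples$fraction[s],
                              "pulse"), truth)
    }, numeric(1))
    ll_truth <- ll_truth + sum(stats::dpois(sim$counts[g, ], pmax(m, 1e-10),
                                            log = TRUE))
  }
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("Wald and profile intervals agree at high counts", {
  set.seed(17)
  panel <- list(gene_kinetics(0.8, 10000))
  des <- slam_pulse_design(2, n_reps = 2)
  sim <- simulate_counts(panel, des, seed = 3)
  fit <- fit_kinetics(sim$counts, sim$samples)
  wa <- wald_ci(fit, "gene1")
  pr <- profile_ci(fit, "gene1")
  expect_equal(pr[["lower"]], wa[["lower"]], tolerance = 0.05)
  expect_equal(pr[["upper"]], wa[["upper"]], tolerance = 0.05)
  # both contain the estimate, and the Wald width halves with 4x replicates
  d_hat <- fit$estimates$delta
  expect_true(wa[["lower"]] < d_hat && d_hat < wa[["upper"]])
  expect_true(pr[["lower"]] < d_hat && d_hat < pr[["upper"]])
  des4 <- slam_pulse_design(2, n_reps = 8)
  sim4 <- simulate_counts(panel, des4, seed = 3)
  fit4 <- fit_kinetics(sim4$counts, sim4$samples)
  wa4 <- wald_ci(fit4, "gene1")
  expect_equal((wa4[["upper"]] - wa4[["lower"]]) /
                 (wa[["upper"]] - wa[["lower"]]),
               0.5, tolerance = 0.15)
})

test_that("nearly fully labeled genes have an open upper profile bound", {
  # delta * t = 8: the unlabeled fraction is essentially gone
  panel <- list(gene_kinetics(8, 100))
  des <- slam_pulse_design(1, n_reps = 2, t0_total = TRUE)
  sim <- simulate_counts(panel, des, seed = 21)
  # unlabeled counts are zero in this draw
  expect_true(all(sim$counts[, sim$samples$fraction == "unlabeled"] == 0))
  fit <- fit_kinetics(sim$counts, sim$samples)
  pr <- profile_ci(fit, "gene1")
  expect_true(is.infinite(pr[["upper"]]))
  expect_true(attr(pr, "open")[["upper"]])
  expect_true(is.finite(pr[["lower"]]) && pr[["lower"]] > 0)
})

test_that("t = 0 chase samples identify levels but not rates", {
  g <- gene_kinetics(0.5, mu1 = 200, mu2 = 100)
  des <- labeling_design("pulse_chase_incomplete", 0,
                         c("labeled", "unlabeled"), n_reps = 4)
  sim <- simulate_counts(list(g), des, seed = 11)
  expect_warning(
    fit <- fit_kinetics(sim$counts, sim$samples,
                        phase = "pulse_chase_incomplete"),
    "unidentifiable")
  expect_true(fit$estimates$unidentifiable[1])
  expect_true(is.na(fit$estimates$delta[1]))
  expect_equal(fit$estimates$mu1[1], 200, tolerance = 0.15)
  expect_equal(fit$estimates$mu2[1], 100, tolerance = 0.15)
})

test_that("incomplete-labeling chase fits recover all three parameters", {
  set.seed(77)
  panel <- lapply(1:8, function(i) {
    gene_kinetics(exp(stats::runif(1, log(0.1), log(1))),
                  mu1 = 2510, mu2 = 890)
  })
  des <- labeling_design("pulse_chase_incomplete", c(0, 1, 3, 6),
                         c("labeled", "unlabeled"), n_reps = 2)
  sim <- simulate_counts(panel, des, seed = 13)
  fit <- fit_kinetics(sim$counts, sim$samples,
                      phase = "pulse_chase_incomplete")
  truth <- vapply(panel, function(g) g$delta, numeric(1))
  expect_true(all(fit$estimates$converged))
  expect_equal(fit$estimates$delta, truth, tolerance = 0.25)
  expect_equal(stats::median(fit$estimates$mu1), 2510, tolerance = 0.1)
  expect_equal(stats::median(fit$estimates$mu2), 890, tolerance = 0.1)
})

test_that("Wald intervals attain nominal coverage on Poisson data", {
  des <- slam_pulse_design(1, n_reps = 2, t0_total = TRUE)
  spec <- simulation_spec(300, delta = c(0.5, 3), mu = c(log(10000), 0),
                          design = des, seed = 8)
  panel <- simulate_panel(spec)
  sim <- simulate_counts(panel, des, seed = 8)
  fit <- fit_kinetics(sim$counts, sim$samples)
  ci <- confint(fit, method = "wald")
  truth <- sim$truth$delta[match(rownames(ci), sim$truth$gene)]
  cov <- mean(ci[, "lower"] <= truth & truth <= ci[, "upper"],
              na.rm = TRUE)
  expect_gte(cov, 0.93)
})

test_that("gene filtering keeps genes above the mean total-count cutoff", {
  counts <- rbind(gene1 = c(10, 10, 5), gene2 = c(50, 50, 1),
                  gene3 = c(50, 51, 2), gene4 = c(100, 100, 3),
                  gene5 = c(0, 0, 0))
  colnames(counts) <- c("T1", "T2", "L1")
  ss <- data.frame(sample = c("T1", "T2", "L1"), time = c(0, 0, 2),
                   fraction = c("total", "total", "labeled"),
                   replicate = c(1, 2, 1))
  kept <- filter_genes(counts, ss, 50)
  expect_equal(rownames(kept), c("gene3", "gene4"))  # strict inequality
  expect_equal(nrow(filter_genes(counts, ss, 0)), 4)
  expect_warning(empty <- filter_genes(counts, ss, 1e6), "no genes")
  expect_equal(nrow(empty), 0)
  ss_no_total <- transform(ss, fraction = "labeled")
  expect_error(filter_genes(counts, ss_no_total, 50), "total")
})

test_that("shared normalization coefficients are recovered from data", {
  set.seed(19)
  panel <- lapply(exp(stats::runif(40, log(0.2), log(1.5))),
                  gene_kinetics, mu = 5000)
  des <- labeling_design("pulse", c(0, 1, 3),
                         fractions = list("total", c("labeled", "unlabeled"),
                                          c("labeled", "unlabeled")),
                         n_reps = 2,
                         norm_coeffs = data.frame(
                           time = c(1, 1, 3, 3),
                           fraction = c("labeled", "unlabeled",
                                        "labeled", "unlabeled"),
                           coeff = c(0.5, 2, 1.5, 0.8)))
  sim <- simulate_counts(panel, des, seed = 23)
  fit <- fit_kinetics(sim$counts, sim$samples, norm_coeffs = "estimate")
  got <- fit$norm_coeffs
  truth <- c("1.labeled" = 0.5, "1.unlabeled" = 2,
             "3.labeled" = 1.5, "3.unlabeled" = 0.8)
  key <- paste(got$time, got$fraction, sep = ".")
  est <- got$coeff[match(names(truth), key)]
  expect_equal(stats::median(abs(est / truth - 1)), 0, tolerance = 0.05)
  expect_equal(got$coeff[got$fraction == "total"], 1)
})

test_that("shared NB overdispersion is estimated by profiling", {
  set.seed(29)
  panel <- lapply(exp(stats::runif(60, log(0.2), log(1.5))),
                  gene_kinetics, mu = 2000)
  des <- slam_pulse_design(c(2, 4), n_reps = 2,
                           model = count_model("nb", k = 20))
  sim <- simulate_counts(panel, des, seed = 41)
  fit <- fit_kinetics(sim$counts, sim$samples, family = "nb")
  expect_true(fit$k_estimated)
  expect_equal(fit$k, 20, tolerance = 0.35)
})

test_that("information contributions at the fit obey the NB ceilings", {
  set.seed(43)
  panel <- lapply(c(0.15, 0.5, 1.5), gene_kinetics, mu = 3000)
  des <- slam_pulse_design(c(2, 6), n_reps = 2,
                           model = count_model("nb", k = 50))
  sim <- simulate_counts(panel, des, seed = 47)
  fit <- fit_kinetics(sim$counts, sim$samples, family = "nb", k = 50)
  tab <- fim_at_fit(fit)
  lab <- tab[tab$fraction == "labeled", ]
  unl <- tab[tab$fraction == "unlabeled", ]
  expect_true(all(lab$info_dd_times_delta2 <= lab$ceiling_times_delta2))
  expect_true(all(unl$info_dd_times_delta2 <= unl$ceiling_times_delta2))
  # short times favor the labeled fraction, long times the unlabeled one
  g_noiseless <- noiseless_counts(list(gene_kinetics(1, 10000)),
                                  slam_pulse_design(c(0.3, 3), n_reps = 1))
  fit2 <- fit_kinetics(g_noiseless$counts, g_noiseless$samples)
  tab2 <- fim_at_fit(fit2)
  pick <- function(t, fr) {
    tab2$info_dd_times_delta2[tab2$time == t & tab2$fraction == fr]
  }
  expect_gt(pick(0.3, "labeled"), pick(0.3, "unlabeled"))
  expect_lt(pick(3, "labeled"), pick(3, "unlabeled"))
  # fast genes vanish from the unlabeled fraction at long times
  fast <- gene_kinetics(2, 10000)
  m1 <- mean_count(design_point(2, "unlabeled", "pulse"), fast)
  m2 <- mean_count(design_point(8, "unlabeled", "pulse"), fast)
  i1 <- mean_gradient(design_point(2, "unlabeled", "pulse"),
                      fast)[["delta"]]^2 *
    unit_info_mean(m1, count_model("poisson"))
  i2 <- mean_gradient(design_point(8, "unlabeled", "pulse"),
                      fast)[["delta"]]^2 *
    unit_info_mean(m2, count_model("poisson"))
  expect_lt(i2, i1 * 1e-3)
})

test_that("sample sheets and counts must agree", {
  counts <- matrix(1:4, 2, 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  ss <- data.frame(sample = "a", time = 1, fraction = "labeled",
                   replicate = 1)
  expect_error(fit_kinetics(counts, ss), "b")
  ss2 <- data.frame(sample = c("a", "b"), time = 1, fraction = "labeled")
  expect_error(fit_kinetics(counts, ss2), "replicate")
  ss3 <- data.frame(sample = c("a", "b"), time = 1,
                    fraction = c("labeled", "enriched"), replicate = 1)
  expect_error(fit_kinetics(counts, ss3), "fraction")
})
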