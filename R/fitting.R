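# Maximum-likelihood estimation of per-gene kinetics from count matrices,
# with shared NB overdispersion and shared fraction normalization
# coefficients (one per time x fraction group), in the style of pulseR.
#
# Parametrization: gene parameters are optimized on the log scale with box
# bounds log delta in [-12, 6]; shared parameters are updated by coordinate
# ascent (alternating maximization) until the total log-likelihood changes
# by less than `tol`.

LOG_DELTA_MIN <- -12
LOG_DELTA_MAX <- 6

# per-sample unit means (mean / (norm_coeff * depth-free part)): base mean
# for parameter vector th (natural scale, named) at sample table `ss`
# (columns time, fraction), phase. Returns vector of means WITHOUT coeff.
base_means <- function(th, ss, phase) {
  t <- ss$time
  e <- exp(-th[["delta"]] * t)
  lf <- -expm1(-th[["delta"]] * t)
  if (phase == "pulse_chase_incomplete") {
    m <- ifelse(ss$fraction == "labeled", th[["mu2"]] * e,
                th[["mu1"]] + th[["mu2"]] * lf)
  } else {
    up <- if (phase == "pulse") e else lf      # unlabeled part
    lp <- if (phase == "pulse") lf else e      # labeled part
    m <- ifelse(ss$fraction == "total", th[["mu"]],
                ifelse(ss$fraction == "labeled", th[["mu"]] * lp,
                       th[["mu"]] * up))
  }
  m
}

cell_loglik <- function(x, m, family, k) {
  m <- pmax(m, 1e-10)
  if (family == "poisson") stats::dpois(x, m, log = TRUE)
  else stats::dnbinom(x, size = k, mu = m, log = TRUE)
}

gene_negll <- function(logth, pnames, x, ss, coeff, phase, family, k) {
  th <- exp(logth)
  names(th) <- pnames
  m <- coeff * base_means(th, ss, phase)
  -sum(cell_loglik(x, m, family, k))
}

# Method-of-moments starting values for one gene.
mom_init <- function(x, ss, coeff, phase) {
  if (phase == "pulse_chase_incomplete") {
    at0 <- ss$time == 0
    mu1 <- mean(x[at0 & ss$fraction == "unlabeled"] /
                  coeff[at0 & ss$fraction == "unlabeled"])
    mu2 <- mean(x[at0 & ss$fraction == "labeled"] /
                  coeff[at0 & ss$fraction == "labeled"])
    if (!is.finite(mu1) || mu1 <= 0) mu1 <- max(1, mean(x) / 2)
    if (!is.finite(mu2) || mu2 <= 0) mu2 <- max(1, mean(x) / 2)
    # decay of the labeled fraction: log m_L linear in t with slope -delta
    lab <- ss$fraction == "labeled" & x > 0
    delta <- if (sum(lab) >= 2 && length(unique(ss$time[lab])) >= 2) {
      fitl <- stats::lm.fit(cbind(1, ss$time[lab]),
                            log(x[lab] / coeff[lab]))
      max(min(-fitl$coefficients[2], 50), 1e-3)
    } else {
      0.1
    }
    c(delta = delta, mu1 = mu1, mu2 = mu2)
  } else {
    tot <- ss$fraction == "total"
    mu <- if (any(tot)) mean(x[tot]) else NA_real_
    # conditional split labeled/unlabeled at each positive time
    dts <- c()
    for (tt in unique(ss$time[ss$time > 0])) {
      il <- ss$fraction == "labeled" & ss$time == tt
      iu <- ss$fraction == "unlabeled" & ss$time == tt
      if (any(il) && any(iu)) {
        sl <- sum(x[il] / coeff[il])
        su <- sum(x[iu] / coeff[iu])
        if (sl + su > 0) {
          p_u <- min(max(su / (sl + su), 1e-6), 1 - 1e-6)
          surv <- if (phase == "pulse") p_u else 1 - p_u
          dts <- c(dts, -log(surv) / tt)
        }
        if (!is.finite(mu)) mu <- (sl + su) / (sum(il) + sum(iu)) * 2
      }
    }
    delta <- if (length(dts)) stats::median(dts) else 0.1
    delta <- max(min(delta, 50), 1e-3)
    if (!is.finite(mu) || mu <= 0) mu <- max(mean(x), 1)
    c(delta = delta, mu = mu)
  }
}

fit_one_gene <- function(x, ss, coeff, phase, family, k, start = NULL,
                         multi_start = TRUE) {
  pnames <- kinetic_params(phase)
  init <- if (is.null(start)) mom_init(x, ss, coeff, phase) else start
  starts <- list(init)
  if (multi_start) {
    s2 <- init; s2[["delta"]] <- init[["delta"]] * 0.1
    s3 <- init; s3[["delta"]] <- init[["delta"]] * 10
    starts <- c(starts, list(s2, s3))
  }
  best <- NULL
  for (s in starts) {
    lp <- log(pmax(s[pnames], 1e-8))
    lp[1] <- min(max(lp[1], LOG_DELTA_MIN), LOG_DELTA_MAX)
    opt <- tryCatch(
      stats::optim(lp, gene_negll, pnames = pnames, x = x, ss = ss,
                   coeff = coeff, phase = phase, family = family, k = k,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    return(list(par = init, loglik = NA_real_, converged = FALSE))
  }
  par <- exp(best$par)
  names(par) <- pnames
  par[["delta"]] <- min(max(par[["delta"]], exp(LOG_DELTA_MIN)),
                        exp(LOG_DELTA_MAX))
  list(par = par, loglik = -best$value, converged = best$convergence == 0)
}

validate_samples <- function(counts, samples) {
  need <- c("sample", "time", "fraction", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  samples$fraction <- ifelse(samples$fraction == "flowthrough", "unlabeled",
                             samples$fraction)
  if (!all(samples$fraction %in% .fractions)) {
    stop("unknown fraction in sample sheet; use total/labeled/unlabeled")
  }
  if (any(samples$time < 0)) stop("sample times must be >= 0")
  extra <- setdiff(colnames(counts), samples$sample)
  if (length(extra)) {
    stop("count columns absent from the sample sheet: ",
         paste(extra, collapse = ", "))
  }
  extra2 <- setdiff(samples$sample, colnames(counts))
  if (length(extra2)) {
    stop("sample sheet rows without count columns: ",
         paste(extra2, collapse = ", "))
  }
  samples[match(colnames(counts), samples$sample), , drop = FALSE]
}

#' Fit the kinetic model to a gene panel
#'
#' Maximum-likelihood estimation of per-gene kinetic parameters
#' (\eqn{\delta, \mu} for pulse/chase; \eqn{\delta, \mu_1, \mu_2} for the
#' incomplete-labeling pulse-chase model) from a genes-by-samples count
#' matrix, with optionally estimated shared parameters: the NB overdispersion
#' `k` and per-(time, fraction) normalization coefficients (the total
#' fraction is the reference with coefficient 1). Fitting alternates
#' (a) per-gene parameters given the shared ones, (b) shared coefficients,
#' (c) shared `k`, until the total log-likelihood improves by less than
#' `tol`. Gene parameters are optimized on the log scale with three starting
#' points (a method-of-moments start from the conditional labeled/unlabeled
#' split, and the same with the rate scaled by 0.1 and 10).
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param samples data.frame with columns `sample`, `time` (hours),
#'   `fraction` (`total`/`labeled`/`unlabeled`, alias `flowthrough`),
#'   `replicate`.
#' @param phase `"pulse"`, `"chase"` or `"pulse_chase_incomplete"`.
#' @param family `"poisson"` or `"nb"`.
#' @param k NB overdispersion: a number to hold it fixed, or `NULL` to
#'   estimate it by profile likelihood (NB only).
#' @param norm_coeffs `NULL` (all coefficients known and equal to 1), a
#'   data.frame `time`/`fraction`/`coeff` of known values, or `"estimate"`.
#' @param max_iter maximum outer iterations.
#' @param tol log-likelihood convergence tolerance.
#' @return An object of class `"kinetics_fit"`; see [coef.kinetics_fit()],
#'   [confint.kinetics_fit()], [profile_ci()], [wald_ci()], [fim_at_fit()].
#' @examples
#' panel <- list(gene_kinetics(0.5, 500), gene_kinetics(2, 300))
#' des <- slam_pulse_design(c(2, 4), n_reps = 2, t0_total = TRUE)
#' sim <- simulate_counts(panel, des, seed = 1)
#' fit <- fit_kinetics(sim$counts, sim$samples)
#' coef(fit)
#' @export
fit_kinetics <- function(counts, samples, phase = c("pulse", "chase",
                                                    "pulse_chase_incomplete"),
                         family = c("poisson", "nb"), k = NULL,
                         norm_coeffs = NULL, max_iter = 200L, tol = 1e-6) {
  phase <- match.arg(phase)
  family <- match.arg(family)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  samples <- validate_samples(counts, samples)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  estimate_k <- family == "nb" && is.null(k)
  if (family == "nb" && !estimate_k && (!is.numeric(k) || k <= 0)) {
    stop("'k' must be positive")
  }
  if (family == "poisson") k <- Inf

  # normalization coefficient bookkeeping: one group per (time, fraction),
  # total fixed at 1
  grp <- interaction(samples$time, samples$fraction, drop = TRUE)
  coeff_tab <- unique(data.frame(time = samples$time,
                                 fraction = samples$fraction,
                                 stringsAsFactors = FALSE))
  coeff_tab <- coeff_tab[order(coeff_tab$time, coeff_tab$fraction), ]
  coeff_tab$coeff <- 1
  estimate_x <- identical(norm_coeffs, "estimate")
  coeff_tab$estimated <- estimate_x & coeff_tab$fraction != "total"
  if (!is.null(norm_coeffs) && !estimate_x) {
    stopifnot(is.data.frame(norm_coeffs),
              all(c("time", "fraction", "coeff") %in% names(norm_coeffs)))
    for (j in seq_len(nrow(norm_coeffs))) {
      hit <- coeff_tab$time == norm_coeffs$time[j] &
        coeff_tab$fraction == norm_coeffs$fraction[j]
      coeff_tab$coeff[hit] <- norm_coeffs$coeff[j]
    }
    if (any(coeff_tab$fraction == "total" & coeff_tab$coeff != 1)) {
      stop("the total fraction is the reference: its coefficient must be 1")
    }
  }
  sample_coeff <- function() {
    coeff_tab$coeff[match(paste(samples$time, samples$fraction),
                          paste(coeff_tab$time, coeff_tab$fraction))]
  }

  ng <- nrow(counts)
  all_zero <- rowSums(counts) == 0
  rate_info <- any(samples$time > 0 & samples$fraction != "total")
  if (!rate_info) {
    warning("no sample carries rate information (all times are 0 or ",
            "total fraction): rates flagged unidentifiable")
  }
  if (phase == "pulse_chase_incomplete" &&
      length(unique(samples$time)) < 2L) {
    rate_info <- FALSE
  }

  if (estimate_k) k <- 10  # neutral overdispersion start
  pnames <- kinetic_params(phase)
  pars <- matrix(NA_real_, ng, length(pnames),
                 dimnames = list(rownames(counts), pnames))
  gene_ll <- rep(NA_real_, ng)
  gene_conv <- rep(FALSE, ng)
  total_ll <- -Inf
  iters <- 0L
  converged_outer <- FALSE

  for (iter in seq_len(max_iter)) {
    iters <- iter
    cf <- sample_coeff()
    # (a) per-gene parameters
    for (g in which(!all_zero)) {
      start <- if (iter > 1L) pars[g, ] else NULL
      if (!rate_info) {
        # no decay information: fix delta at a nominal value, fit levels
        res <- fit_levels_only(counts[g, ], samples, cf, phase, family, k)
      } else {
        res <- fit_one_gene(counts[g, ], samples, cf, phase, family, k,
                            start = start, multi_start = (iter == 1L))
      }
      pars[g, ] <- res$par[pnames]
      gene_ll[g] <- res$loglik
      gene_conv[g] <- res$converged
    }
    # (b) shared normalization coefficients
    if (estimate_x) {
      for (j in which(coeff_tab$estimated)) {
        sel <- samples$time == coeff_tab$time[j] &
          samples$fraction == coeff_tab$fraction[j]
        if (!any(sel)) next
        B <- matrix(0, ng, sum(sel))  # base means of group samples
        for (g in which(!all_zero)) {
          B[g, ] <- base_means(pars[g, ], samples[sel, , drop = FALSE],
                               phase)
        }
        X <- counts[, sel, drop = FALSE]
        if (sum(B) < 1e-9) next  # e.g. labeled at t = 0: x unidentifiable
        if (family == "poisson") {
          coeff_tab$coeff[j] <- sum(X) / sum(B)
        } else {
          f <- function(lx) {
            -sum(cell_loglik(X, exp(lx) * B, family, k))
          }
          coeff_tab$coeff[j] <-
            exp(stats::optimize(f, c(-10, 10), tol = 1e-9)$minimum)
        }
      }
    }
    # (c) shared overdispersion by profile likelihood
    if (estimate_k) {
      cf <- sample_coeff()
      M <- t(vapply(seq_len(ng), function(g) {
        if (all_zero[g]) rep(1e-10, nrow(samples))
        else cf * base_means(pars[g, ], samples, phase)
      }, numeric(nrow(samples))))
      prof <- function(logk) {
        -sum(stats::dnbinom(counts[!all_zero, , drop = FALSE],
                            size = exp(logk),
                            mu = pmax(M[!all_zero, , drop = FALSE], 1e-10),
                            log = TRUE))
      }
      grid <- seq(log(0.05), log(1e4), length.out = 25)
      vals <- vapply(grid, prof, numeric(1))
      i0 <- which.min(vals)
      lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
      k <- exp(stats::optimize(prof, c(lo, hi), tol = 1e-8)$minimum)
    }
    # convergence on the total log-likelihood
    cf <- sample_coeff()
    new_ll <- 0
    for (g in which(!all_zero)) {
      m <- cf * base_means(pars[g, ], samples, phase)
      new_ll <- new_ll + sum(cell_loglik(counts[g, ], m, family, k))
    }
    nothing_shared <- !estimate_x && !estimate_k
    if (is.finite(total_ll) && abs(new_ll - total_ll) < tol) {
      total_ll <- new_ll
      converged_outer <- TRUE
      break
    }
    total_ll <- new_ll
    if (nothing_shared) { converged_outer <- TRUE; break }
  }

  est <- data.frame(gene = rownames(counts), stringsAsFactors = FALSE)
  for (p in pnames) est[[p]] <- pars[, p]
  est$loglik <- gene_ll
  est$converged <- gene_conv & converged_outer
  est$unidentifiable <- all_zero | !rate_info
  if (!rate_info) est$delta <- NA_real_

  structure(list(estimates = est, phase = phase, family = family,
                 k = if (family == "poisson") NULL else k,
                 k_estimated = estimate_k,
                 norm_coeffs = coeff_tab[, c("time", "fraction", "coeff",
                                             "estimated")],
                 counts = counts, samples = samples, iterations = iters,
                 converged = converged_outer, loglik = total_ll),
            class = "kinetics_fit")
}

# delta carries no information: estimate levels only (delta fixed nominal)
fit_levels_only <- function(x, ss, coeff, phase, family, k) {
  if (phase == "pulse_chase_incomplete") {
    init <- mom_init(x, ss, coeff, phase)
    par <- c(delta = NA_real_, mu1 = init[["mu1"]], mu2 = init[["mu2"]])
    th <- c(delta = 1e-6, mu1 = init[["mu1"]], mu2 = init[["mu2"]])
  } else {
    mu <- max(mean(x / coeff), 1e-8)
    par <- c(delta = NA_real_, mu = mu)
    th <- c(delta = 1e-6, mu = mu)
  }
  m <- coeff * base_means(th, ss, phase)
  list(par = par, loglik = sum(cell_loglik(x, m, family, k)),
       converged = TRUE)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  ok <- !x$estimates$unidentifiable
  cat("Kinetic model fit (", x$phase, ", ", x$family, " counts)\n",
      sep = "")
  cat("  genes:", nrow(x$estimates), "(", sum(!ok), "unidentifiable )\n")
  if (!is.null(x$k)) {
    cat("  overdispersion k =", format(x$k, digits = 4),
        if (x$k_estimated) "(estimated)" else "(fixed)", "\n")
  }
  cat("  log-likelihood:", format(x$loglik, digits = 8), "in",
      x$iterations, "outer iteration(s)\n")
  if (ok[1] || any(ok)) {
    cat("  median delta:",
        format(stats::median(x$estimates$delta[ok], na.rm = TRUE),
               digits = 4), "per hour\n")
  }
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) {
  est <- object$estimates
  ok <- !est$unidentifiable & is.finite(est$delta)
  out <- list(
    phase = object$phase, family = object$family, k = object$k,
    n_genes = nrow(est), n_unidentifiable = sum(est$unidentifiable),
    n_nonconverged = sum(!est$converged & !est$unidentifiable),
    delta_quantiles = if (any(ok)) {
      stats::quantile(est$delta[ok], c(0.05, 0.25, 0.5, 0.75, 0.95))
    },
    half_life_median = if (any(ok)) {
      log(2) / stats::median(est$delta[ok])
    },
    norm_coeffs = object$norm_coeffs,
    loglik = object$loglik)
  class(out) <- "summary.kinetics_fit"
  out
}

#' @export
print.summary.kinetics_fit <- function(x, ...) {
  cat("Kinetic model fit summary (", x$phase, ", ", x$family, ")\n",
      sep = "")
  cat("  genes:", x$n_genes, "| unidentifiable:", x$n_unidentifiable,
      "| non-converged:", x$n_nonconverged, "\n")
  if (!is.null(x$k)) cat("  overdispersion k =", format(x$k, digits = 4),
                         "\n")
  if (!is.null(x$delta_quantiles)) {
    cat("  delta quantiles (1/h):\n")
    print(signif(x$delta_quantiles, 4))
    cat("  median half-life:", format(x$half_life_median, digits = 4),
        "h\n")
  }
  cat("  normalization coefficients:\n")
  print(x$norm_coeffs, row.names = FALSE)
  invisible(x)
}

#' Per-gene coefficient matrix of a kinetics fit
#'
#' @param object a [fit_kinetics()] result.
#' @param ... unused.
#' @return numeric matrix, genes x kinetic parameters.
#' @export
coef.kinetics_fit <- function(object, ...) {
  pn <- kinetic_params(object$phase)
  as.matrix(object$estimates[, pn, drop = FALSE])
}

#' @export
logLik.kinetics_fit <- function(object, ...) {
  pn <- kinetic_params(object$phase)
  n_shared <- sum(object$norm_coeffs$estimated) + object$k_estimated
  ok <- !object$estimates$unidentifiable
  val <- object$loglik
  attr(val, "df") <- sum(ok) * length(pn) + n_shared
  attr(val, "nobs") <- length(object$counts)
  class(val) <- "logLik"
  val
}

#' Fitted mean counts
#'
#' @param object a [fit_kinetics()] result.
#' @param ... unused.
#' @return matrix of fitted means, genes x samples.
#' @export
fitted.kinetics_fit <- function(object, ...) {
  cf <- object$norm_coeffs$coeff[
    match(paste(object$samples$time, object$samples$fraction),
          paste(object$norm_coeffs$time, object$norm_coeffs$fraction))]
  pn <- kinetic_params(object$phase)
  M <- t(vapply(seq_len(nrow(object$counts)), function(g) {
    th <- unlist(object$estimates[g, pn])
    if (any(!is.finite(th))) return(rep(NA_real_, nrow(object$samples)))
    cf * base_means(th, object$samples, object$phase)
  }, numeric(nrow(object$samples))))
  dimnames(M) <- dimnames(object$counts)
  M
}

#' Pearson residuals of a kinetics fit
#'
#' \eqn{(x - m)/\sqrt{\mathrm{var}(m)}} with the variance of the fitted
#' count model (`m` for Poisson, `m + m^2/k` for NB).
#'
#' @param object a [fit_kinetics()] result.
#' @param ... unused.
#' @return matrix of Pearson residuals.
#' @export
residuals.kinetics_fit <- function(object, ...) {
  M <- fitted(object)
  V <- if (object$family == "poisson") M else M + M^2 / object$k
  (object$counts - M) / sqrt(pmax(V, 1e-10))
}

#' Simulate count matrices from a fitted model
#'
#' Draws new count matrices from the fitted means under the fitted count
#' model, preserving the sample layout.
#'
#' @param object a [fit_kinetics()] result.
#' @param nsim number of simulated matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` count matrices.
#' @export
simulate.kinetics_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- fitted(object)
  ok <- is.finite(M)
  lapply(seq_len(nsim), function(i) {
    out <- M
    out[ok] <- if (object$family == "poisson") {
      stats::rpois(sum(ok), M[ok])
    } else {
      stats::rnbinom(sum(ok), size = object$k, mu = M[ok])
    }
    out
  })
}

#' Confidence intervals for fitted degradation rates
#'
#' @param object a [fit_kinetics()] result.
#' @param parm gene ids (default: all identifiable genes).
#' @param level confidence level.
#' @param method `"wald"` (normal approximation from the inverse FIM at the
#'   estimate) or `"profile"` (profile likelihood).
#' @param ... unused.
#' @return matrix with columns `lower`, `upper`, rows named by gene.
#' @export
confint.kinetics_fit <- function(object, parm = NULL, level = 0.95,
                                 method = c("wald", "profile"), ...) {
  method <- match.arg(method)
  est <- object$estimates
  if (is.null(parm)) parm <- est$gene[!est$unidentifiable]
  out <- t(vapply(parm, function(g) {
    ci <- tryCatch(
      if (method == "wald") wald_ci(object, g, level)
      else profile_ci(object, g, level),
      error = function(e) c(lower = NA_real_, upper = NA_real_))
    c(ci[["lower"]], ci[["upper"]])
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  rownames(out) <- parm
  out
}

fit_gene_row <- function(fit, gene) {
  i <- match(gene, fit$estimates$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  i
}

fit_gene_kinetics <- function(fit, i) {
  e <- fit$estimates[i, ]
  if (fit$phase == "pulse_chase_incomplete") {
    gene_kinetics(delta = e$delta, mu1 = e$mu1, mu2 = e$mu2)
  } else {
    gene_kinetics(delta = e$delta, mu = e$mu)
  }
}

fit_design_points <- function(fit) {
  cf <- fit$norm_coeffs$coeff[
    match(paste(fit$samples$time, fit$samples$fraction),
          paste(fit$norm_coeffs$time, fit$norm_coeffs$fraction))]
  lapply(seq_len(nrow(fit$samples)), function(j) {
    design_point(fit$samples$time[j], fit$samples$fraction[j], fit$phase,
                 if (fit$samples$fraction[j] == "total") 1 else cf[j])
  })
}

fit_count_model <- function(fit) {
  if (fit$family == "poisson") count_model("poisson")
  else count_model("nb", k = fit$k)
}

#' Wald confidence interval for a fitted rate
#'
#' \eqn{\hat\delta \pm z_{level}\sqrt{(I^{-1})_{\delta\delta}}} with the
#' Fisher information matrix evaluated at the fitted parameter values over
#' all samples of the fit (overdispersion and normalization coefficients
#' treated as known).
#'
#' @param fit a [fit_kinetics()] result.
#' @param gene gene id.
#' @param level confidence level.
#' @return named vector `c(lower, upper)`.
#' @export
wald_ci <- function(fit, gene, level = 0.95) {
  stopifnot(inherits(fit, "kinetics_fit"))
  i <- fit_gene_row(fit, gene)
  e <- fit$estimates[i, ]
  if (e$unidentifiable || !is.finite(e$delta)) {
    stop("gene '", gene, "' has no identifiable rate")
  }
  g <- fit_gene_kinetics(fit, i)
  f <- fim(fit_design_points(fit), g, fit_count_model(fit))
  v <- variance_of_estimates(f)
  if (v$bound_only) stop("singular information matrix for gene '", gene, "'")
  z <- stats::qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(v$variances[["delta"]])
  c(lower = e$delta - hw, upper = e$delta + hw)
}

#' Profile-likelihood confidence interval for a fitted rate
#'
#' Endpoints of \eqn{\{\delta: 2[\ell(\hat\delta) - \ell_{prof}(\delta)]
#' \le \chi^2_1(level)\}}, where \eqn{\ell_{prof}} re-optimizes the nuisance
#' level parameters at each fixed \eqn{\delta}. Endpoints are located by
#' stepping outward from the estimate until the deviance crosses the
#' threshold, then root-finding; if the threshold is never crossed within
#' \eqn{\delta \in [e^{-12}, e^{6}]} the endpoint is reported open (`0` or
#' `Inf`) with attribute `"open"`.
#'
#' @param fit a [fit_kinetics()] result.
#' @param gene gene id.
#' @param level confidence level.
#' @return named vector `c(lower, upper)`, attribute `"open"` flagging open
#'   sides.
#' @export
profile_ci <- function(fit, gene, level = 0.95) {
  stopifnot(inherits(fit, "kinetics_fit"))
  i <- fit_gene_row(fit, gene)
  e <- fit$estimates[i, ]
  if (e$unidentifiable || !is.finite(e$delta) || !e$converged) {
    stop("gene '", gene, "' has no converged identifiable fit")
  }
  x <- fit$counts[i, ]
  ss <- fit$samples
  cf <- fit$norm_coeffs$coeff[
    match(paste(ss$time, ss$fraction),
          paste(fit$norm_coeffs$time, fit$norm_coeffs$fraction))]
  phase <- fit$phase
  family <- fit$family
  k <- if (family == "poisson") Inf else fit$k
  pn <- kinetic_params(phase)
  th_hat <- unlist(e[pn])

  prof_ll <- function(delta) {
    if (family == "poisson" && phase != "pulse_chase_incomplete") {
      # closed-form nuisance: means are mu * c_s(delta); Poisson MLE of mu
      th1 <- c(delta = delta, mu = 1)
      cvec <- cf * base_means(th1, ss, phase)
      mu_hat <- sum(x) / max(sum(cvec), 1e-12)
      sum(cell_loglik(x, mu_hat * cvec, family, k))
    } else {
      nuis <- setdiff(pn, "delta")
      f <- function(lnu) {
        th <- c(delta, exp(lnu))
        names(th) <- c("delta", nuis)
        -sum(cell_loglik(x, cf * base_means(th, ss, phase), family, k))
      }
      start <- log(pmax(th_hat[nuis], 1e-8))
      if (length(nuis) == 1L) {
        -stats::optimize(function(v) f(v), start + c(-8, 8),
                         tol = 1e-9)$objective
      } else {
        -stats::optim(start, f, method = "Nelder-Mead",
                      control = list(maxit = 1000,
                                     reltol = 1e-12))$value
      }
    }
  }

  ll_hat <- prof_ll(e$delta)
  if (ll_hat < e$loglik - 1e-6) ll_hat <- e$loglik
  q <- stats::qchisq(level, df = 1)
  dev <- function(delta) 2 * (ll_hat - prof_ll(delta)) - q

  find_end <- function(direction) {
    bound <- if (direction < 0) exp(LOG_DELTA_MIN) else exp(LOG_DELTA_MAX)
    s <- 0.25
    prev <- e$delta
    repeat {
      cand <- e$delta * exp(direction * s)
      if ((direction < 0 && cand <= bound) ||
          (direction > 0 && cand >= bound)) {
        if (dev(bound) < 0) {
          return(structure(if (direction < 0) 0 else Inf, open = TRUE))
        }
        cand <- bound
      }
      if (dev(cand) >= 0) {
        r <- stats::uniroot(function(ld) dev(exp(ld)),
                            sort(c(log(prev), log(cand))), tol = 1e-8)
        return(structure(exp(r$root), open = FALSE))
      }
      if (cand == bound) {
        return(structure(if (direction < 0) 0 else Inf, open = TRUE))
      }
      prev <- cand
      s <- s * 2
    }
  }

  lo <- find_end(-1)
  hi <- find_end(1)
  out <- c(lower = as.numeric(lo), upper = as.numeric(hi))
  attr(out, "open") <- c(lower = attr(lo, "open"), upper = attr(hi, "open"))
  out
}

#' Filter genes by mean total-fraction count
#'
#' Retains genes whose mean read count across total-fraction samples is
#' strictly greater than `min_mean_total` (default 50, a common expression
#' filter before rate fitting).
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet (see [fit_kinetics()]).
#' @param min_mean_total threshold; strict inequality.
#' @return the filtered count matrix (possibly with 0 rows, with a warning).
#' @export
filter_genes <- function(counts, samples, min_mean_total = 50) {
  counts <- as.matrix(counts)
  samples <- validate_samples(counts, samples)
  tot <- samples$fraction == "total"
  if (!any(tot)) stop("no total-fraction samples to filter on")
  keep <- rowMeans(counts[, tot, drop = FALSE]) > min_mean_total
  if (!any(keep)) warning("no genes pass the total-count filter")
  counts[keep, , drop = FALSE]
}

#' Per-sample-group information contributions at the fitted values
#'
#' For each gene and each (time, fraction) group of the fit, computes the
#' delta-delta Fisher information contribution multiplied by
#' \eqn{\hat\delta^2} (a dimensionless information gain, comparable across
#' genes), together with the NB overdispersion ceilings (labeled
#' \eqn{\le k/\hat\delta^2} scaled by \eqn{\hat\delta^2} to `k`; unlabeled
#' \eqn{t^2 k \hat\delta^2}) for reference.
#'
#' @param fit a converged [fit_kinetics()] result.
#' @return data.frame with columns `gene`, `time`, `fraction`,
#'   `info_dd_times_delta2` and, for NB fits, `ceiling_times_delta2`.
#' @export
fim_at_fit <- function(fit) {
  stopifnot(inherits(fit, "kinetics_fit"))
  model <- fit_count_model(fit)
  groups <- unique(fit$samples[, c("time", "fraction")])
  est <- fit$estimates
  rows <- list()
  for (i in which(!est$unidentifiable)) {
    g <- fit_gene_kinetics(fit, i)
    d2 <- est$delta[i]^2
    for (j in seq_len(nrow(groups))) {
      sel <- fit$samples$time == groups$time[j] &
        fit$samples$fraction == groups$fraction[j]
      cf <- fit$norm_coeffs$coeff[
        match(paste(groups$time[j], groups$fraction[j]),
              paste(fit$norm_coeffs$time, fit$norm_coeffs$fraction))]
      pt <- design_point(groups$time[j], groups$fraction[j], fit$phase,
                         if (groups$fraction[j] == "total") 1 else cf)
      m <- mean_count(pt, g)
      info <- if (m < 1e-12) 0 else {
        mean_gradient(pt, g)[["delta"]]^2 * unit_info_mean(m, model)
      }
      row <- data.frame(gene = est$gene[i], time = groups$time[j],
                        fraction = groups$fraction[j],
                        info_dd_times_delta2 = sum(sel) * info * d2)
      if (fit$family == "nb") {
        row$ceiling_times_delta2 <- sum(sel) * switch(groups$fraction[j],
          labeled = fit$k,
          unlabeled = groups$time[j]^2 * fit$k * d2,
          total = NA_real_)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
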