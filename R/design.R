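# Optimal-time solvers and design evaluation over gene panels.

#' A labeling experiment design
#'
#' Describes which samples an experiment sequences: the phase, the time
#' points, which fractions are taken at each time, the number of replicates,
#' per-(time, fraction) normalization coefficients and the count model.
#'
#' @param phase `"pulse"`, `"chase"` or `"pulse_chase_incomplete"`.
#' @param time_points numeric vector of times in hours, >= 0.
#' @param fractions either a character vector applied at every time point, or
#'   a list (one character vector per time point) of fractions among
#'   `"total"`, `"labeled"`, `"unlabeled"`.
#' @param n_reps replicates per sample, integer >= 1.
#' @param norm_coeffs optional data.frame with columns `time`, `fraction`,
#'   `coeff`; missing entries default to 1 (the total fraction is always 1).
#' @param model a [count_model()].
#' @return An object of class `"labeling_design"`.
#' @examples
#' labeling_design("pulse", c(0, 2, 4, 8),
#'                 fractions = list("total", c("labeled", "unlabeled"),
#'                                  c("labeled", "unlabeled"),
#'                                  c("labeled", "unlabeled")),
#'                 n_reps = 2)
#' @export
labeling_design <- function(phase = c("pulse", "chase",
                                      "pulse_chase_incomplete"),
                            time_points, fractions, n_reps = 1L,
                            norm_coeffs = NULL,
                            model = count_model("poisson")) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(time_points), length(time_points) >= 1L,
            all(time_points >= 0), inherits(model, "count_model"))
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
    stop("'n_reps' must be an integer >= 1")
  }
  if (!is.list(fractions)) {
    fractions <- rep(list(fractions), length(time_points))
  }
  if (length(fractions) != length(time_points)) {
    stop("'fractions' must have one entry per time point")
  }
  tab <- do.call(rbind, lapply(seq_along(time_points), function(i) {
    fr <- fractions[[i]]
    fr[fr == "flowthrough"] <- "unlabeled"
    if (!all(fr %in% .fractions)) stop("unknown fraction name")
    data.frame(time = time_points[i], fraction = fr,
               stringsAsFactors = FALSE)
  }))
  tab$coeff <- 1
  if (!is.null(norm_coeffs)) {
    stopifnot(all(c("time", "fraction", "coeff") %in% names(norm_coeffs)))
    for (j in seq_len(nrow(norm_coeffs))) {
      hit <- tab$time == norm_coeffs$time[j] &
        tab$fraction == norm_coeffs$fraction[j]
      tab$coeff[hit] <- norm_coeffs$coeff[j]
    }
    if (any(tab$fraction == "total" & tab$coeff != 1)) {
      stop("the total fraction is the reference: its coefficient must be 1")
    }
  }
  if (nrow(tab) == 0L) stop("design must sequence at least one sample")
  structure(list(phase = phase, points = tab, n_reps = as.integer(n_reps),
                 model = model),
            class = "labeling_design")
}

#' @export
print.labeling_design <- function(x, ...) {
  cat("Labeling design (", x$phase, "), ", x$n_reps, " replicate(s)\n",
      sep = "")
  print(x$points, row.names = FALSE)
  print(x$model)
  invisible(x)
}

# Expand a labeling_design into a list of design_point objects.
as_design_points <- function(design) {
  stopifnot(inherits(design, "labeling_design"))
  lapply(seq_len(nrow(design$points)), function(i) {
    design_point(design$points$time[i], design$points$fraction[i],
                 design$phase, design$points$coeff[i])
  })
}

# Bounded scalar maximization on [lo, hi]; optimize() uses golden-section
# search with parabolic interpolation, tolerance on the argument.
maximize_scalar <- function(f, lo = 1e-3, hi = 20, tol = 1e-8) {
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  # stationarity check via central difference
  h <- 1e-5 * max(1, abs(opt$maximum))
  d <- (f(opt$maximum + h) - f(opt$maximum - h)) / (2 * h)
  list(argmax = opt$maximum, value = opt$objective, derivative = d)
}

#' Asymptotically optimal dimensionless labeling time
#'
#' Finds the maximizer \eqn{\alpha^* = (t/\tau)^*} of the delta-delta
#' information term for a single sample. For the Poisson model the objectives
#' are the dimensionless terms of [normalized_fim_terms()], giving
#' \eqn{\alpha^* \approx 1.59} for a combined (SLAMseq) sample, exactly 2 for
#' the unlabeled fraction alone, and \eqn{\approx 0.64} for the labeled
#' fraction alone. For the NB model the optimum depends on depth and
#' overdispersion, so `mu` (and `k` inside the model) must be supplied;
#' overdispersion shifts the combined optimum to larger \eqn{\alpha}. For the
#' combined design the NB objective is the reciprocal of the inverse-FIM
#' delta term (minimum asymptotic variance); for single fractions it is the
#' diagonal information term.
#'
#' @param design_kind `"slam_combined"`, `"unlabeled_only"` or
#'   `"labeled_only"`.
#' @param model a [count_model()].
#' @param mu expression level; required for the NB model.
#' @return \eqn{\alpha^*}, the optimal time in units of \eqn{\tau}.
#' @examples
#' optimal_alpha("slam_combined")   # 1.5936
#' optimal_alpha("unlabeled_only")  # 2
#' optimal_alpha("labeled_only")    # 0.6438
#' @export
optimal_alpha <- function(design_kind = c("slam_combined", "unlabeled_only",
                                          "labeled_only"),
                          model = count_model("poisson"), mu = NULL) {
  design_kind <- match.arg(design_kind)
  stopifnot(inherits(model, "count_model"))
  if (model$family == "poisson") {
    obj <- switch(design_kind,
      slam_combined = function(a) a^2 / expm1(a),
      unlabeled_only = function(a) a^2 * exp(-a),
      labeled_only = function(a) a^2 / (exp(2 * a) - exp(a)))
  } else {
    if (is.null(mu)) stop("the NB optimum depends on depth: supply 'mu'")
    k <- model$k
    obj <- switch(design_kind,
      # minimize relative variance <=> maximize its reciprocal
      slam_combined = function(a) {
        1 / (expm1(a) / (mu * a^2) + 2 * (-expm1(-a))^2 / (k * a^2))
      },
      unlabeled_only = function(a) {
        m <- mu * exp(-a)
        mu^2 * a^2 * exp(-2 * a) * k / (m * (m + k))
      },
      labeled_only = function(a) {
        m <- mu * (-expm1(-a))
        mu^2 * a^2 * exp(-2 * a) * k / (m * (m + k))
      })
  }
  sol <- maximize_scalar(obj)
  if (abs(sol$derivative) > 1e-4 * max(1, abs(sol$value))) {
    warning("optimum is not an interior stationary point")
  }
  sol$argmax
}

#' Asymptotically optimal labeling time in hours
#'
#' \eqn{t^* = \alpha^* \tau}. A transcript with a 1 h half-life
#' (\eqn{\tau \approx 1.44} h) is best measured with a SLAMseq pulse of about
#' 2.3 h.
#'
#' @param gene a [gene_kinetics()] object; alternatively supply `half_life`
#'   or `delta`.
#' @param design_kind,model passed to [optimal_alpha()].
#' @param half_life half-life in hours (alternative input).
#' @param delta degradation rate in 1/h (alternative input).
#' @return optimal time in hours.
#' @examples
#' optimal_time(half_life = 1)  # 2.299
#' optimal_time(delta = 1, design_kind = "unlabeled_only")  # 2
#' @export
optimal_time <- function(gene = NULL, design_kind = "slam_combined",
                         model = count_model("poisson"), half_life = NULL,
                         delta = NULL) {
  tau_val <- if (!is.null(gene)) {
    tau(gene)
  } else if (!is.null(half_life)) {
    half_life_to_tau(half_life)
  } else if (!is.null(delta)) {
    stopifnot(delta > 0)
    1 / delta
  } else {
    stop("supply 'gene', 'half_life' or 'delta'")
  }
  mu <- if (!is.null(gene)) gene$mu else NULL
  optimal_alpha(design_kind, model, mu = mu) * tau_val
}

#' Optimal chase time under incomplete labeling
#'
#' For the incomplete-labeling pulse-chase model (background \eqn{\mu_1},
#' labelable pool \eqn{\mu_2}) with NB counts, maximizes the dimensionless
#' objective \eqn{I_{\delta\delta}(\alpha)\,\delta^2} of a single
#' labeled+unlabeled sample over \eqn{\alpha = t/\tau}. The objective
#' \deqn{\mu_2^2 \alpha^2 e^{-2\alpha}\left[u(m_U) + u(m_L)\right], \quad
#'   m_U = \mu_1 + \mu_2(1-e^{-\alpha}),\ m_L = \mu_2 e^{-\alpha},}
#' depends on \eqn{\delta} only through \eqn{\alpha}, so the result is a pure
#' number. The default uses the diagonal information term; set
#' `use_inverse = TRUE` to maximize the reciprocal of the inverse-FIM
#' delta-delta entry of the full three-parameter matrix instead.
#'
#' @param mu1 background level, > 0.
#' @param mu2 labelable level, > 0.
#' @param k NB overdispersion, > 0.
#' @param use_inverse use the inverse-FIM-based objective (default FALSE).
#' @param delta internal rate used to build the dimensionless objective; the
#'   result is invariant to it (exposed for testing that claim).
#' @return \eqn{\alpha^*}, optimal chase time in units of \eqn{\tau}.
#' @examples
#' optimal_chase_time_incomplete(251, 89, 10.4)  # about 2.9
#' @export
optimal_chase_time_incomplete <- function(mu1, mu2, k, use_inverse = FALSE,
                                          delta = 1) {
  stopifnot(mu1 > 0, mu2 > 0, k > 0, delta > 0)
  model <- count_model("nb", k = k)
  gene <- gene_kinetics(delta = delta, mu1 = mu1, mu2 = mu2)
  obj <- function(a) {
    t <- a / delta
    pts <- slam_design_points(t, phase = "pulse_chase_incomplete")
    f <- fim(pts, gene, model)
    if (use_inverse) {
      v <- variance_of_estimates(f)
      if (v$bound_only) return(0)
      delta^2 / v$variances[["delta"]]
    } else {
      f$matrix["delta", "delta"] * delta^2
    }
  }
  sol <- maximize_scalar(Vectorize(obj))
  sol$argmax
}

#' Evaluate a design over a panel of genes
#'
#' For each gene, assembles the full Fisher information matrix over all
#' sequenced samples of the design, inverts it and reports the relative
#' standard deviation \eqn{sd(\hat\delta)/\delta} of the asymptotic rate
#' estimator and the relative width of the Wald 95% confidence interval,
#' \eqn{2 \cdot 1.96 \cdot sd(\hat\delta)/\delta}. Genes whose information
#' matrix is singular are flagged unidentifiable.
#'
#' @param design a [labeling_design()].
#' @param panel a list of [gene_kinetics()] objects.
#' @param conf_mult normal quantile for the interval width (1.96 for 95%).
#' @return An object of class `"design_evaluation"`: a data.frame with one
#'   row per gene (`delta`, `mu`, `rel_sd`, `ci_rel_width`,
#'   `unidentifiable`), with summary quantiles of `ci_rel_width` in
#'   attribute `"summary"`.
#' @export
evaluate_design <- function(design, panel, conf_mult = 1.96) {
  stopifnot(inherits(design, "labeling_design"), length(panel) >= 1L)
  pts <- as_design_points(design)
  rows <- lapply(panel, function(gene) {
    f <- suppressWarnings(fim(pts, gene, design$model,
                              n_reps = design$n_reps))
    v <- variance_of_estimates(f)
    if (v$bound_only) {
      data.frame(delta = gene$delta, mu = gene$mu, rel_sd = NA_real_,
                 ci_rel_width = NA_real_, unidentifiable = TRUE)
    } else {
      rel_sd <- sqrt(v$rel_var_delta)
      data.frame(delta = gene$delta, mu = gene$mu, rel_sd = rel_sd,
                 ci_rel_width = 2 * conf_mult * rel_sd,
                 unidentifiable = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ok <- !out$unidentifiable
  attr(out, "summary") <- if (any(ok)) {
    stats::quantile(out$ci_rel_width[ok], c(0.25, 0.5, 0.75))
  } else {
    NULL
  }
  class(out) <- c("design_evaluation", class(out))
  out
}

#' Sequencing depth versus replicate number
#'
#' Computes the asymptotic variance \eqn{\mathrm{var}(\hat\delta)} of a
#' design over a grid of depth scalings (multiplying \eqn{\mu}) and replicate
#' counts. Under the Poisson model doubling the depth and doubling the
#' replicates are exactly equivalent; under the NB model depth saturates at
#' the overdispersion floor \eqn{2(1-e^{-\delta t})^2/(k t^2)} (reported for
#' single-time SLAMseq designs), while replication always scales the
#' variance as \eqn{1/n}.
#'
#' @param design a [labeling_design()].
#' @param gene a [gene_kinetics()] object (its `mu` is the unscaled depth).
#' @param depth_grid multiplicative depth factors, > 0.
#' @param rep_grid replicate counts, integers >= 1.
#' @return list with `surface` (matrix, rows = depth factors, cols =
#'   replicate counts) and `depth_asymptote` (NB single-time designs, else
#'   NA).
#' @export
depth_vs_replicates <- function(design, gene, depth_grid = c(1, 2, 4, 8),
                                rep_grid = c(1L, 2L, 4L)) {
  stopifnot(inherits(design, "labeling_design"),
            inherits(gene, "gene_kinetics"),
            all(depth_grid > 0), all(rep_grid >= 1))
  surface <- matrix(NA_real_, length(depth_grid), length(rep_grid),
                    dimnames = list(paste0("depth_x", depth_grid),
                                    paste0("n", rep_grid)))
  for (i in seq_along(depth_grid)) {
    g <- gene_kinetics(delta = gene$delta, mu = gene$mu * depth_grid[i])
    pts <- as_design_points(design)
    for (j in seq_along(rep_grid)) {
      f <- fim(pts, g, design$model, n_reps = rep_grid[j])
      v <- variance_of_estimates(f)
      surface[i, j] <- if (v$bound_only) NA_real_ else
        v$variances[["delta"]]
    }
  }
  times <- unique(design$points$time[design$points$fraction != "total"])
  asym <- if (design$model$family == "nb" && length(times) == 1L) {
    asymptotic_limits(design$model, gene$delta, times,
                      "slam_depth_floor") / design$n_reps
  } else {
    NA_real_
  }
  list(surface = surface, depth_asymptote = asym)
}

#' Effective-depth ("zooming") normalization coefficient
#'
#' When labeled and unlabeled molecules are biochemically separated and each
#' fraction is sequenced to the depth of the total sample, the fraction-level
#' normalization coefficient acts as an effective depth amplifier. Summing
#' over a panel of genes,
#' \deqn{x_L = \frac{\sum_i \mu_i}{\sum_i \mu_i (1 - e^{-\delta_i t})},
#' \qquad x_U = \frac{\sum_i \mu_i}{\sum_i \mu_i e^{-\delta_i t}}.}
#' At short times the labeled fraction is dominated by fast genes and
#' \eqn{x_L} can be large ("zooming in" on them).
#'
#' @param panel a list of [gene_kinetics()] objects.
#' @param t labeling time, hours, > 0 for the labeled fraction.
#' @param target_fraction `"labeled"` or `"unlabeled"`.
#' @return the normalization coefficient (scalar >= 1 for a single gene).
#' @examples
#' panel <- list(gene_kinetics(1, 100), gene_kinetics(0.01, 100))
#' zooming_factor(panel, t = 0.1, "labeled")  # 20.8
#' @export
zooming_factor <- function(panel, t, target_fraction = c("labeled",
                                                         "unlabeled")) {
  target_fraction <- match.arg(target_fraction)
  stopifnot(length(panel) >= 1L, t >= 0)
  mu <- vapply(panel, function(g) g$mu, numeric(1))
  delta <- vapply(panel, function(g) g$delta, numeric(1))
  denom <- if (target_fraction == "labeled") {
    if (t == 0) stop("labeled fraction is empty at t = 0")
    sum(mu * (-expm1(-delta * t)))
  } else {
    sum(mu * exp(-delta * t))
  }
  sum(mu) / denom
}
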