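# Fisher information machinery for Poisson and negative-binomial read counts.
# The NB is parametrized by its mean m and size k, var(X) = m + m^2/k; k is a
# shared constant of the count model, never an inference target here.

#' Count distribution model
#'
#' @param family `"poisson"` or `"nb"` (negative binomial).
#' @param k NB overdispersion (size) parameter, > 0; low `k` means strong
#'   overdispersion, `k -> Inf` recovers the Poisson. Ignored for
#'   `family = "poisson"`.
#' @return An object of class `"count_model"`.
#' @examples
#' count_model("nb", k = 100)
#' @export
count_model <- function(family = c("poisson", "nb"), k = NULL) {
  family <- match.arg(family)
  if (family == "nb") {
    if (is.null(k) || !is.numeric(k) || length(k) != 1L || !is.finite(k) ||
        k <= 0) {
      stop("the NB family requires a positive overdispersion parameter 'k'")
    }
  } else {
    k <- NULL
  }
  structure(list(family = family, k = k), class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  if (x$family == "poisson") cat("Count model: Poisson\n")
  else cat("Count model: negative binomial, k =", format(x$k), "\n")
  invisible(x)
}

#' Per-observation Fisher information with respect to the mean
#'
#' The scalar kernel from which all information matrices here are assembled:
#' for a count with mean `m`, the information about `m` itself is `1/m` for
#' the Poisson and `k/(m (m + k))` for the NB (the reciprocal of the variance
#' `m (m + k)/k`).
#'
#' @param m expected count(s), > 0 (vectorized).
#' @param model a [count_model()].
#' @return numeric vector of per-observation informations.
#' @examples
#' unit_info_mean(4, count_model("poisson"))       # 0.25
#' unit_info_mean(4, count_model("nb", k = 12))    # 0.1875
#' @export
unit_info_mean <- function(m, model) {
  stopifnot(inherits(model, "count_model"))
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0)) {
    stop("'m' must be positive; zero-mean samples carry no information")
  }
  if (model$family == "poisson") 1 / m else model$k / (m * (m + model$k))
}

#' Fisher information matrix of a design for one gene
#'
#' Assembles the expected information about the free kinetic parameters from
#' a set of sequenced samples. For independent counts with means
#' \eqn{m_p(\theta)} the information matrix is
#' \deqn{I_{ab} = n \sum_p \frac{\partial m_p}{\partial \theta_a}
#'   \frac{\partial m_p}{\partial \theta_b}\, u(m_p),}
#' where \eqn{u(m)} is [unit_info_mean()] and \eqn{n} the number of
#' replicates. Information is additive over samples and replicates. Samples
#' whose mean is numerically zero (below 1e-12, e.g. the labeled fraction at
#' t = 0) contribute zero information; their gradients vanish at least as
#' fast, so this is the continuity limit.
#'
#' @param design a list of [design_point()]s (or a single point); all points
#'   must share a phase.
#' @param gene a [gene_kinetics()] object.
#' @param model a [count_model()].
#' @param n_reps replicate multiplier, integer >= 1.
#' @return An object of class `"fim_result"`: list with `params` (parameter
#'   names), `matrix` (the information matrix), `n_reps`, `gene`, `model` and
#'   `singular` (TRUE when every design mean is numerically zero or the
#'   matrix is ill-conditioned).
#' @examples
#' g <- gene_kinetics(delta = 1, mu = 100)
#' d <- slam_design_points(1)
#' fim(d, g, count_model("poisson"))
#' @export
fim <- function(design, gene, model, n_reps = 1L) {
  if (inherits(design, "design_point")) design <- list(design)
  stopifnot(length(design) >= 1L, inherits(gene, "gene_kinetics"),
            inherits(model, "count_model"))
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 ||
      n_reps != round(n_reps)) {
    stop("'n_reps' must be an integer >= 1")
  }
  phases <- vapply(design, function(p) p$phase, character(1))
  if (length(unique(phases)) != 1L) {
    stop("all design points must share the same phase")
  }
  params <- kinetic_params(phases[[1L]])
  np <- length(params)
  info <- matrix(0, np, np, dimnames = list(params, params))
  any_info <- FALSE
  for (p in design) {
    m <- mean_count(p, gene)
    if (m < 1e-12) next  # zero-mean sample: no information (continuity)
    g <- mean_gradient(p, gene)[params]
    info <- info + tcrossprod(g) * unit_info_mean(m, model)
    any_info <- TRUE
  }
  info <- info * n_reps
  # conditioning is judged on the correlation-scaled matrix so that
  # parameters with very different units do not masquerade as singularity
  singular <- !any_info || !all(diag(info) > 0)
  if (!singular) {
    s <- sqrt(diag(info))
    singular <- rcond_sym(info / tcrossprod(s)) < 1e-12
  }
  if (!any_info) {
    warning("design has zero information: all means are numerically zero")
  }
  structure(list(params = params, matrix = info, n_reps = as.integer(n_reps),
                 gene = gene, model = model, singular = singular),
            class = "fim_result")
}

# reciprocal condition number of a symmetric matrix, 0 if not computable
rcond_sym <- function(A) {
  ev <- tryCatch(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @export
print.fim_result <- function(x, ...) {
  cat("Fisher information matrix (", x$n_reps, "replicate(s) )\n")
  print(x$matrix)
  if (x$singular) cat("  [flagged singular]\n")
  invisible(x)
}

#' Asymptotic variances of the kinetic-parameter estimators
#'
#' Inverts an assembled information matrix and reads off the asymptotic
#' variances \eqn{\mathrm{var}(\hat\theta_i) = (I^{-1})_{ii}}, the relative
#' variance \eqn{\mathrm{var}(\hat\delta)/\delta^2}, and the single-parameter
#' lower bound \eqn{1/I_{\delta\delta} \le (I^{-1})_{\delta\delta}} (equality
#' when \eqn{\delta} is information-orthogonal to the other parameters). For
#' a singular matrix only the bound is returned, with `bound_only = TRUE`.
#'
#' @param fim_result a [fim()] result.
#' @return list with `variances` (named, or NULL when singular),
#'   `rel_var_delta`, `bound_delta` (= 1/I_dd), `bound_only`.
#' @export
variance_of_estimates <- function(fim_result) {
  stopifnot(inherits(fim_result, "fim_result"))
  I <- fim_result$matrix
  idd <- I["delta", "delta"]
  bound <- if (idd > 0) 1 / idd else Inf
  if (fim_result$singular) {
    return(list(variances = NULL, rel_var_delta = NA_real_,
                bound_delta = bound, bound_only = TRUE))
  }
  # invert on the correlation scale for numerical stability across
  # parameters with very different units
  s <- sqrt(diag(I))
  Iinv <- solve(I / tcrossprod(s)) / tcrossprod(s)
  v <- diag(Iinv)
  names(v) <- fim_result$params
  list(variances = v,
       rel_var_delta = v[["delta"]] / fim_result$gene$delta^2,
       bound_delta = bound,
       bound_only = FALSE)
}

#' Closed-form asymptotic variance of the rate estimator, SLAMseq designs
#'
#' For a fraction-ratio-preserving (SLAMseq-style) pulse sample sequenced at
#' time `t` with both labeled and unlabeled reads and unit normalization, the
#' inverse information term for \eqn{\delta} has closed forms
#' \deqn{\textrm{Poisson:}\quad (I^{-1})_{\delta\delta} =
#'   \frac{e^{\delta t}-1}{\mu t^2}, \qquad
#'   \textrm{NB:}\quad \frac{e^{\delta t}-1}{\mu t^2} +
#'   \frac{2 (1-e^{-\delta t})^2}{k t^2}.}
#' In the Poisson case \eqn{\delta} and \eqn{\mu} are information orthogonal;
#' the NB adds an overdispersion penalty that no sequencing depth removes.
#'
#' @param delta degradation rate, 1/h, > 0.
#' @param mu expression level, counts, > 0.
#' @param t labeling time, hours, > 0 (at t = 0 the information vanishes).
#' @param k NB overdispersion, > 0.
#' @return asymptotic variance of \eqn{\hat\delta} (scalar).
#' @examples
#' closed_form_slamseq_poisson(1, 100, 1)      # 0.01718
#' closed_form_slamseq_nb(1, 100, 1, k = 100)  # 0.02517
#' @export
closed_form_slamseq_poisson <- function(delta, mu, t) {
  stopifnot(delta > 0, mu > 0)
  if (any(t <= 0)) stop("'t' must be > 0: information vanishes at t = 0")
  expm1(delta * t) / (mu * t^2)
}

#' @rdname closed_form_slamseq_poisson
#' @export
closed_form_slamseq_nb <- function(delta, mu, t, k) {
  stopifnot(delta > 0, mu > 0, k > 0)
  if (any(t <= 0)) stop("'t' must be > 0: information vanishes at t = 0")
  expm1(delta * t) / (mu * t^2) + 2 * (-expm1(-delta * t))^2 / (k * t^2)
}

#' Dimensionless information terms of the Poisson SLAMseq model
#'
#' With \eqn{\alpha = t/\tau = \delta t}, the delta-delta information terms
#' scaled by \eqn{\delta^2} become functions of \eqn{\alpha} alone (times the
#' depth \eqn{\mu}):
#' \deqn{(I_L)_{\delta\delta}\delta^2 = \frac{\alpha^2 \mu}{e^{2\alpha} -
#'   e^{\alpha}},\quad (I_U)_{\delta\delta}\delta^2 = \alpha^2 e^{-\alpha}
#'   \mu,\quad (I_{slam})_{\delta\delta}\delta^2 =
#'   \frac{\alpha^2 \mu}{e^{\alpha}-1}.}
#' The combined term is the sum of the two fraction terms. For
#' \eqn{\alpha \ll 1} the combined and labeled terms grow linearly and the
#' unlabeled one quadratically; for \eqn{\alpha \gg 1} all decay
#' exponentially.
#'
#' @param alpha dimensionless time(s) t/tau, > 0 (vectorized).
#' @param mu expression level, > 0.
#' @return data.frame with columns `alpha`, `labeled`, `unlabeled`,
#'   `combined`.
#' @export
normalized_fim_terms <- function(alpha, mu) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("'alpha' must be positive")
  }
  stopifnot(mu > 0)
  labeled <- alpha^2 * mu / (exp(2 * alpha) - exp(alpha))
  unlabeled <- alpha^2 * exp(-alpha) * mu
  combined <- alpha^2 * mu / expm1(alpha)
  data.frame(alpha = alpha, labeled = labeled, unlabeled = unlabeled,
             combined = combined)
}

#' Overdispersion-imposed limits of the information terms
#'
#' Under the NB model, neither sequencing depth nor labeling time can push
#' the information about \eqn{\delta} past overdispersion-set limits:
#' \itemize{
#'   \item SLAMseq variance floor at infinite depth:
#'     \eqn{2(1-e^{-\delta t})^2/(k t^2)}, approaching \eqn{2\delta^2/k} as
#'     \eqn{t \to 0};
#'   \item separated labeled fraction information ceiling
#'     \eqn{t^2 e^{-2\delta t} k/(1-e^{-\delta t})^2}, with supremum
#'     \eqn{k/\delta^2} at \eqn{t \to 0};
#'   \item separated unlabeled fraction ceiling \eqn{t^2 k} (grows with
#'     longer labeling, given unlimited depth).
#' }
#'
#' @param model a [count_model()] with family `"nb"`.
#' @param delta degradation rate, > 0.
#' @param t labeling time, > 0.
#' @param scenario which limit(s) to return: `"all"` (default, a list) or one
#'   of `"slam_depth_floor"`, `"slam_t0_floor"`, `"labeled_ceiling"`,
#'   `"labeled_sup"`, `"unlabeled_ceiling"`.
#' @return a scalar, or a named list for `scenario = "all"`.
#' @export
asymptotic_limits <- function(model, delta, t,
                              scenario = c("all", "slam_depth_floor",
                                           "slam_t0_floor",
                                           "labeled_ceiling", "labeled_sup",
                                           "unlabeled_ceiling")) {
  stopifnot(inherits(model, "count_model"))
  if (model$family != "nb") {
    stop("asymptotic limits are finite only for the NB family")
  }
  stopifnot(delta > 0, t > 0)
  scenario <- match.arg(scenario)
  k <- model$k
  lf <- -expm1(-delta * t)
  lims <- list(
    slam_depth_floor = 2 * lf^2 / (k * t^2),
    slam_t0_floor = 2 * delta^2 / k,
    labeled_ceiling = t^2 * exp(-2 * delta * t) * k / lf^2,
    labeled_sup = k / delta^2,
    unlabeled_ceiling = t^2 * k
  )
  if (scenario == "all") lims else lims[[scenario]]
}

#' Conditional binomial rates of a SLAMseq sample
#'
#' Conditionally on the total number of reads, the split between unlabeled
#' and labeled reads of a Poisson SLAMseq sample is binomial with unlabeled
#' proportion \eqn{e^{-\delta t}} (labeled \eqn{1 - e^{-\delta t}}),
#' independent of \eqn{\mu}. This is the basis of method-of-moments starting
#' values and explains the information orthogonality of \eqn{\delta} and
#' \eqn{\mu}.
#'
#' @param delta degradation rate, >= 0.
#' @param t labeling time, >= 0.
#' @return named vector `c(unlabeled = , labeled = )`.
#' @export
conditional_binomial_rate <- function(delta, t) {
  stopifnot(delta >= 0, t >= 0)
  e <- exp(-delta * t)
  c(unlabeled = e, labeled = -expm1(-delta * t))
}

#' Design points of one SLAMseq sample
#'
#' Convenience constructor for the pair of labeled + unlabeled design points
#' that a single fraction-ratio-preserving sample yields.
#'
#' @param time labeling (or chase) time, hours.
#' @param phase experiment phase.
#' @param norm_coeff shared normalization coefficient (x_L = x_U for
#'   ratio-preserving protocols).
#' @return list of two [design_point()]s.
#' @export
slam_design_points <- function(time, phase = "pulse", norm_coeff = 1) {
  list(design_point(time, "labeled", phase, norm_coeff),
       design_point(time, "unlabeled", phase, norm_coeff))
}
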