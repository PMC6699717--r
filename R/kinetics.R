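#' Per-gene kinetic parameters
#'
#' Bundles the parameters of the first-order synthesis/degradation model for
#' one gene. Under steady state the expected total read count is
#' \eqn{\mu = s/\delta} where \eqn{s} is the synthesis rate, so the model is
#' parametrized by the degradation rate \eqn{\delta} (per hour) and the
#' expression level \eqn{\mu} (read counts). For incomplete-labeling
#' pulse-chase experiments the level splits into a never-labeled background
#' \eqn{\mu_1} and a labelable pool \eqn{\mu_2} with
#' \eqn{\mu = \mu_1 + \mu_2}.
#'
#' @param delta degradation rate, 1/hour, > 0.
#' @param mu steady-state expression level in expected read counts, > 0.
#'   May be omitted when both `mu1` and `mu2` are given.
#' @param mu1 never-labeled background level, >= 0 (optional).
#' @param mu2 labelable level, >= 0 (optional).
#' @return An object of class `"gene_kinetics"`.
#' @examples
#' g <- gene_kinetics(delta = 1, mu = 100)
#' tau(g)        # characteristic time 1/delta
#' half_life(g)  # tau * log(2)
#' @export
gene_kinetics <- function(delta, mu = NULL, mu1 = NULL, mu2 = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0) {
    stop("'delta' must be a single positive number (rate, 1/hour)")
  }
  has_split <- !is.null(mu1) || !is.null(mu2)
  if (has_split) {
    if (is.null(mu1) || is.null(mu2)) {
      stop("'mu1' and 'mu2' must be supplied together")
    }
    if (mu1 < 0 || mu2 < 0) stop("'mu1' and 'mu2' must be >= 0")
    if (is.null(mu)) {
      mu <- mu1 + mu2
    } else if (abs(mu1 + mu2 - mu) > 1e-9 * max(1, abs(mu))) {
      stop("'mu1' + 'mu2' must equal 'mu'")
    }
  }
  if (is.null(mu)) stop("'mu' is required when 'mu1'/'mu2' are not given")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("'mu' must be a single positive number (read counts)")
  }
  structure(
    list(delta = delta, mu = mu,
         mu1 = if (has_split) mu1 else NULL,
         mu2 = if (has_split) mu2 else NULL),
    class = "gene_kinetics"
  )
}

#' @export
print.gene_kinetics <- function(x, ...) {
  cat("Gene kinetics: delta =", format(x$delta), "per hour, mu =",
      format(x$mu), "counts\n")
  if (!is.null(x$mu1)) {
    cat("  background mu1 =", format(x$mu1), ", labelable mu2 =",
        format(x$mu2), "\n")
  }
  cat("  tau =", format(1 / x$delta), "h, half-life =",
      format(log(2) / x$delta), "h\n")
  invisible(x)
}

#' Characteristic time and half-life
#'
#' `tau()` returns the characteristic degradation time \eqn{\tau = 1/\delta};
#' `half_life()` returns \eqn{\lambda = \tau \log 2}.
#'
#' @param gene a [gene_kinetics()] object.
#' @return time in hours.
#' @export
tau <- function(gene) {
  stopifnot(inherits(gene, "gene_kinetics"))
  1 / gene$delta
}

#' @rdname tau
#' @export
half_life <- function(gene) {
  stopifnot(inherits(gene, "gene_kinetics"))
  log(2) / gene$delta
}

#' Convert a half-life to the characteristic degradation time
#'
#' \eqn{\tau = \lambda / \log 2}: a transcript with a 1 h half-life has a
#' characteristic time of about 1.44 h.
#'
#' @param lambda half-life, hours, > 0.
#' @return characteristic time \eqn{\tau} in hours.
#' @examples
#' half_life_to_tau(1)  # 1.4427
#' @export
half_life_to_tau <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("'lambda' must be positive (half-life, hours)")
  }
  lambda / log(2)
}

.fractions <- c("total", "labeled", "unlabeled")
.phases <- c("pulse", "chase", "pulse_chase_incomplete")

#' A single sequenced sample in a labeling design
#'
#' Describes one observation: the labeling (or chase) time, which fraction
#' was sequenced, the experiment phase, and the fraction normalization
#' coefficient relating its sequencing depth to the total-sample reference
#' (which is fixed at 1). `"flowthrough"` is accepted as an alias for
#' `"unlabeled"`, matching separation protocols where the unlabeled material
#' is the streptavidin flow-through.
#'
#' @param time labeling or chase time in hours, >= 0.
#' @param fraction one of `"total"`, `"labeled"`, `"unlabeled"`
#'   (alias `"flowthrough"`).
#' @param phase one of `"pulse"`, `"chase"`, `"pulse_chase_incomplete"`.
#' @param norm_coeff normalization coefficient \eqn{x_i}, > 0; must be 1 for
#'   the total fraction.
#' @return An object of class `"design_point"`.
#' @export
design_point <- function(time, fraction = c("total", "labeled", "unlabeled",
                                            "flowthrough"),
                         phase = c("pulse", "chase",
                                   "pulse_chase_incomplete"),
                         norm_coeff = 1) {
  if (!is.numeric(time) || length(time) != 1L || !is.finite(time) ||
      time < 0) {
    stop("'time' must be a single non-negative number of hours")
  }
  fraction <- match.arg(fraction)
  if (fraction == "flowthrough") fraction <- "unlabeled"
  phase <- match.arg(phase)
  if (!is.numeric(norm_coeff) || length(norm_coeff) != 1L ||
      !is.finite(norm_coeff) || norm_coeff <= 0) {
    stop("'norm_coeff' must be a single positive number")
  }
  if (fraction == "total" && norm_coeff != 1) {
    stop("the total fraction is the reference: 'norm_coeff' must be 1")
  }
  if (phase == "pulse_chase_incomplete" && fraction == "total") {
    stop("the incomplete-labeling chase model has no total-fraction mean; ",
         "sequence labeled and unlabeled fractions instead")
  }
  structure(list(time = time, fraction = fraction, phase = phase,
                 norm_coeff = norm_coeff),
            class = "design_point")
}

# Free kinetic parameters implied by the phase.
kinetic_params <- function(phase) {
  if (phase == "pulse_chase_incomplete") c("delta", "mu1", "mu2")
  else c("delta", "mu")
}

#' Expected read count for one sample
#'
#' Evaluates the first-order kinetic mean model. For a pulse experiment with
#' normalization coefficients \eqn{x_L, x_U}:
#' \deqn{m_T = \mu,\quad m_L(t) = x_L \mu (1 - e^{-\delta t}),\quad
#'   m_U(t) = x_U \mu e^{-\delta t}.}
#' In a chase experiment the labeled fraction decays while the unlabeled one
#' accumulates, so the two expressions swap roles. The incomplete-labeling
#' pulse-chase model tracks a never-labeled background:
#' \deqn{m_U(t) = \mu_1 + \mu_2 (1 - e^{-\delta t}),\quad
#'   m_L(t) = \mu_2 e^{-\delta t}.}
#' `expm1` is used so that \eqn{1 - e^{-\delta t}} stays accurate for small
#' \eqn{\delta t}.
#'
#' @param point a [design_point()].
#' @param gene a [gene_kinetics()] object; for phase
#'   `"pulse_chase_incomplete"` it must carry `mu1` and `mu2`.
#' @return the expected read count (non-negative scalar).
#' @examples
#' g <- gene_kinetics(delta = 1, mu = 100)
#' mean_count(design_point(1, "labeled", "pulse"), g)    # 63.21
#' mean_count(design_point(1, "unlabeled", "pulse"), g)  # 36.79
#' @export
mean_count <- function(point, gene) {
  stopifnot(inherits(point, "design_point"), inherits(gene, "gene_kinetics"))
  t <- point$time
  labeled_frac <- -expm1(-gene$delta * t)    # 1 - exp(-delta t)
  unlabeled_frac <- exp(-gene$delta * t)
  switch(point$phase,
    pulse = switch(point$fraction,
      total = gene$mu,
      labeled = point$norm_coeff * gene$mu * labeled_frac,
      unlabeled = point$norm_coeff * gene$mu * unlabeled_frac),
    chase = switch(point$fraction,
      total = gene$mu,
      labeled = point$norm_coeff * gene$mu * unlabeled_frac,
      unlabeled = point$norm_coeff * gene$mu * labeled_frac),
    pulse_chase_incomplete = {
      if (is.null(gene$mu1)) {
        stop("phase 'pulse_chase_incomplete' requires 'mu1' and 'mu2'")
      }
      switch(point$fraction,
        labeled = point$norm_coeff * gene$mu2 * unlabeled_frac,
        unlabeled = point$norm_coeff *
          (gene$mu1 + gene$mu2 * labeled_frac))
    }
  )
}

#' Gradient of the mean read count in the free kinetic parameters
#'
#' Analytic partial derivatives of [mean_count()] with respect to the free
#' parameters of the phase: \eqn{(\delta, \mu)} for pulse/chase,
#' \eqn{(\delta, \mu_1, \mu_2)} for the incomplete-labeling model. These are
#' the building blocks of the Fisher information matrix.
#'
#' @inheritParams mean_count
#' @return named numeric vector of partial derivatives.
#' @export
mean_gradient <- function(point, gene) {
  stopifnot(inherits(point, "design_point"), inherits(gene, "gene_kinetics"))
  t <- point$time
  x <- point$norm_coeff
  e <- exp(-gene$delta * t)
  lf <- -expm1(-gene$delta * t)
  switch(point$phase,
    pulse = switch(point$fraction,
      total = c(delta = 0, mu = 1),
      labeled = c(delta = x * gene$mu * t * e, mu = x * lf),
      unlabeled = c(delta = -x * gene$mu * t * e, mu = x * e)),
    chase = switch(point$fraction,
      total = c(delta = 0, mu = 1),
      labeled = c(delta = -x * gene$mu * t * e, mu = x * e),
      unlabeled = c(delta = x * gene$mu * t * e, mu = x * lf)),
    pulse_chase_incomplete = {
      if (is.null(gene$mu1)) {
        stop("phase 'pulse_chase_incomplete' requires 'mu1' and 'mu2'")
      }
      switch(point$fraction,
        labeled = c(delta = -x * gene$mu2 * t * e, mu1 = 0, mu2 = x * e),
        unlabeled = c(delta = x * gene$mu2 * t * e, mu1 = x, mu2 = x * lf))
    }
  )
}
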