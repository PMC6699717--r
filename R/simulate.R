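# Reproducible synthetic count generator with the statistical structure the
# asymptotic theory assumes: NB (or Poisson) counts around kinetic means,
# shared overdispersion, fraction normalization coefficients, optional
# cross-contamination and incomplete labeling.
#
# Reproducibility scheme: one global seed drives a deterministic substream
# per (gene, sample) cell, so extending a panel leaves earlier draws
# untouched.

cell_seed <- function(seed, g, s) {
  # deterministic per-cell substream seed, kept inside 32-bit integer range
  (as.numeric(seed) + 1000003 * g + 10007 * s) %% 2147483629
}

#' Specification of a simulated labeling experiment
#'
#' @param n_genes number of genes to draw.
#' @param delta either `c(min, max)` bounds of a log-uniform rate
#'   distribution (1/h) or, when `delta_explicit = TRUE` or the vector is
#'   longer than 2, an explicit per-gene rate vector.
#' @param mu either `c(meanlog, sdlog)` of a log-normal level distribution
#'   (counts) or an explicit per-gene vector (see `mu_explicit`).
#' @param design a [labeling_design()].
#' @param contamination fraction-swap proportion in `[0, 1)`: each labeled
#'   mean becomes `(1 - c) m_L + c m_U` and symmetrically, before drawing.
#' @param incomplete_share per-gene background share `mu1/mu` in `[0, 1)`;
#'   positive values generate (mu1, mu2) splits for the incomplete-labeling
#'   model.
#' @param seed integer seed; the same spec and seed reproduce the counts
#'   exactly.
#' @param delta_explicit,mu_explicit force explicit-vector interpretation.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_genes, delta = c(0.05, 2), mu = c(log(500), 1),
                            design, contamination = 0, incomplete_share = 0,
                            seed = 1L, delta_explicit = length(delta) > 2,
                            mu_explicit = length(mu) > 2) {
  stopifnot(n_genes >= 1, inherits(design, "labeling_design"),
            contamination >= 0, contamination < 1,
            incomplete_share >= 0, incomplete_share < 1)
  if (!delta_explicit) {
    if (length(delta) != 2 || delta[1] <= 0 || delta[2] <= delta[1]) {
      stop("'delta' bounds must be positive and increasing")
    }
  } else if (any(delta <= 0)) {
    stop("explicit rates must be positive")
  }
  if (mu_explicit && any(mu <= 0)) stop("explicit levels must be positive")
  structure(list(n_genes = as.integer(n_genes), delta = delta, mu = mu,
                 design = design, contamination = contamination,
                 incomplete_share = incomplete_share,
                 seed = as.integer(seed),
                 delta_explicit = delta_explicit, mu_explicit = mu_explicit),
            class = "simulation_spec")
}

#' Draw a panel of gene kinetics
#'
#' Rates are drawn log-uniformly between the stated bounds (or passed
#' through when explicit); levels log-normally (or passed through, recycled
#' to `n_genes`). With `incomplete_share > 0`, the level is split into
#' `mu1 = share * mu` and `mu2 = (1 - share) * mu`.
#'
#' @param spec a [simulation_spec()].
#' @return list of [gene_kinetics()] objects of length `n_genes`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  delta <- if (spec$delta_explicit) {
    rep_len(spec$delta, n)
  } else {
    exp(stats::runif(n, log(spec$delta[1]), log(spec$delta[2])))
  }
  mu <- if (spec$mu_explicit) {
    rep_len(spec$mu, n)
  } else {
    stats::rlnorm(n, spec$mu[1], spec$mu[2])
  }
  lapply(seq_len(n), function(i) {
    if (spec$incomplete_share > 0) {
      gene_kinetics(delta = delta[i],
                    mu1 = spec$incomplete_share * mu[i],
                    mu2 = (1 - spec$incomplete_share) * mu[i])
    } else {
      gene_kinetics(delta = delta[i], mu = mu[i])
    }
  })
}

#' Simulate a count matrix for a gene panel under a design
#'
#' For every gene and sequenced sample, forms the kinetic mean (scaled by
#' the design's normalization coefficient), optionally mixes labeled and
#' unlabeled means at the same time point to emulate cross-contamination,
#' and draws a Poisson or NB count. Each (gene, sample) cell uses its own
#' deterministic substream of the seed, so adding genes or samples does not
#' perturb existing draws.
#'
#' @param panel list of [gene_kinetics()] objects (or a single one).
#' @param design a [labeling_design()]; its `model` supplies the count
#'   family unless `model` is given.
#' @param model optional [count_model()] overriding the design's.
#' @param contamination fraction-swap proportion in `[0, 0.5]`&nbsp;typical;
#'   `c = 0.5` makes the two fraction means identical.
#' @param seed integer seed.
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (sample sheet with columns sample/time/fraction/replicate) and `truth`
#'   (data.frame of generating parameters).
#' @examples
#' panel <- list(gene_kinetics(1, 100))
#' des <- slam_pulse_design(1, n_reps = 3)
#' simulate_counts(panel, des, seed = 7)$counts
#' @export
simulate_counts <- function(panel, design, model = NULL, contamination = 0,
                            seed = 1L) {
  if (inherits(panel, "gene_kinetics")) panel <- list(panel)
  stopifnot(inherits(design, "labeling_design"),
            contamination >= 0, contamination < 1)
  if (is.null(model)) model <- design$model
  stopifnot(inherits(model, "count_model"))
  pts <- as_design_points(design)
  n_pts <- length(pts)
  reps <- design$n_reps
  samples <- do.call(rbind, lapply(seq_len(n_pts), function(i) {
    data.frame(sample = paste0(pts[[i]]$fraction, "_t",
                               format(pts[[i]]$time), "_r", seq_len(reps)),
               time = pts[[i]]$time, fraction = pts[[i]]$fraction,
               replicate = seq_len(reps), stringsAsFactors = FALSE)
  }))
  samples$sample <- make.unique(gsub(" ", "", samples$sample))
  ns <- nrow(samples)
  ng <- length(panel)

  # per-gene mean for each design point, with contamination mixing between
  # labeled and unlabeled points at the same time
  mean_for <- function(gene) {
    m <- vapply(pts, mean_count, numeric(1), gene = gene)
    if (contamination > 0) {
      for (i in seq_len(n_pts)) {
        if (pts[[i]]$fraction == "labeled") {
          j <- which(vapply(pts, function(p) {
            p$fraction == "unlabeled" && p$time == pts[[i]]$time
          }, logical(1)))
          if (length(j) == 1L) {
            mL <- m[i]; mU <- m[j]
            m[i] <- (1 - contamination) * mL + contamination * mU
            m[j] <- (1 - contamination) * mU + contamination * mL
          }
        }
      }
    }
    m
  }

  counts <- matrix(0L, ng, ns,
                   dimnames = list(paste0("gene", seq_len(ng)),
                                   samples$sample))
  truth <- do.call(rbind, lapply(seq_along(panel), function(g) {
    gene <- panel[[g]]
    data.frame(gene = paste0("gene", g), delta = gene$delta, mu = gene$mu,
               mu1 = if (is.null(gene$mu1)) NA_real_ else gene$mu1,
               mu2 = if (is.null(gene$mu2)) NA_real_ else gene$mu2)
  }))
  point_of_sample <- rep(seq_len(n_pts), each = reps)
  for (g in seq_len(ng)) {
    m_pts <- mean_for(panel[[g]])
    if (any(m_pts > 1e12)) stop("simulated mean exceeds 1e12; check units")
    for (s in seq_len(ns)) {
      m <- m_pts[point_of_sample[s]]
      if (m < 1e-12) next
      set.seed(cell_seed(seed, g, s))
      counts[g, s] <- if (model$family == "poisson") {
        stats::rpois(1L, m)
      } else {
        stats::rnbinom(1L, size = model$k, mu = m)
      }
    }
  }
  list(counts = counts, samples = samples, truth = truth)
}

#' Standard SLAMseq pulse design
#'
#' Convenience constructor mirroring a common simulation layout: labeled and
#' unlabeled fractions at the given times, optionally total samples at
#' t = 0, unit normalization coefficients.
#'
#' @param times positive labeling times, hours.
#' @param n_reps replicates per sample.
#' @param t0_total include total-fraction samples at t = 0.
#' @param model a [count_model()].
#' @param phase experiment phase for the timed fractions.
#' @return a [labeling_design()].
#' @export
slam_pulse_design <- function(times, n_reps = 2L, t0_total = TRUE,
                              model = count_model("poisson"),
                              phase = "pulse") {
  times <- sort(unique(times))
  stopifnot(all(times > 0))
  tp <- c(if (t0_total) 0, times)
  fr <- c(if (t0_total) list("total"),
          rep(list(c("labeled", "unlabeled")), length(times)))
  labeling_design(phase, tp, fr, n_reps = n_reps, model = model)
}

#' Confidence-interval width study over a rate grid
#'
#' Emulates the classic simulation: for each candidate time set, simulate
#' SLAMseq counts for a panel of genes spanning a rate grid (defaults:
#' Poisson counts, depth `mu` = 10000, total samples at t = 0, unit
#' normalization, 2 replicates), fit the kinetic model with the
#' normalization treated as known, compute per-gene 95% profile-likelihood
#' CIs for the rate, and average the relative width (upper - lower)/estimate
#' over runs.
#'
#' @param rate_grid rates delta (1/h) to place on the panel.
#' @param time_sets list of numeric vectors of labeling times (hours).
#' @param depth expression level mu of every gene.
#' @param n_runs simulation runs averaged per condition.
#' @param seed integer seed (run r uses `seed + r`).
#' @param n_reps replicates per sample.
#' @param model a [count_model()].
#' @param ci `"profile"` or `"wald"`.
#' @param smooth window of an optional rolling-median smoother applied along
#'   the rate grid (odd integer; 1 = no smoothing).
#' @return data.frame with columns `delta`, `time_set`, `rel_width` (mean
#'   over runs) and `rel_width_smooth`.
#' @export
ci_width_study <- function(rate_grid, time_sets, depth = 10000, n_runs = 10,
                           seed = 1L, n_reps = 2L,
                           model = count_model("poisson"),
                           ci = c("profile", "wald"), smooth = 1L) {
  ci <- match.arg(ci)
  stopifnot(n_runs >= 1, all(rate_grid > 0))
  if (!is.list(time_sets)) time_sets <- list(time_sets)
  panel <- lapply(rate_grid, function(d) gene_kinetics(d, depth))
  out <- list()
  for (ts in time_sets) {
    label <- paste(ts, collapse = ",")
    des <- slam_pulse_design(ts, n_reps = n_reps, t0_total = TRUE,
                             model = model)
    W <- matrix(NA_real_, length(rate_grid), n_runs)
    for (r in seq_len(n_runs)) {
      sim <- simulate_counts(panel, des, model = model,
                             seed = seed + r)
      fit <- fit_kinetics(sim$counts, sim$samples, phase = "pulse",
                          family = model$family, k = model$k)
      for (i in seq_len(length(rate_grid))) {
        g <- fit$estimates$gene[i]
        if (fit$estimates$unidentifiable[i] || !fit$estimates$converged[i]) {
          next
        }
        ival <- tryCatch(
          if (ci == "profile") profile_ci(fit, g) else wald_ci(fit, g),
          error = function(e) NULL)
        if (is.null(ival) || any(!is.finite(ival))) next
        W[i, r] <- (ival[["upper"]] - ival[["lower"]]) /
          fit$estimates$delta[i]
      }
    }
    rw <- rowMeans(W, na.rm = TRUE)
    out[[label]] <- data.frame(delta = rate_grid, time_set = label,
                               rel_width = rw,
                               rel_width_smooth = roll_median(rw, smooth),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

roll_median <- function(x, window = 1L) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  h <- window %/% 2L
  vapply(seq_along(x), function(i) {
    stats::median(x[max(1, i - h):min(length(x), i + h)], na.rm = TRUE)
  }, numeric(1))
}

#' Rate-estimation bias under ignored cross-contamination
#'
#' Simulates counts with a fraction-swap contamination `c`, fits the model
#' assuming none, and reports the median relative bias of the rate estimate
#' per true rate. Slow genes (\eqn{\delta t \ll 1}) are biased fast
#' (positive) and fast genes (\eqn{\delta t \gg 1}) biased slow (negative).
#'
#' @param delta_grid true rates (1/h).
#' @param c contamination proportion, in (0, 0.5).
#' @param design a [labeling_design()]; defaults to a single-time SLAMseq
#'   pulse at t = 1 h with 4 replicates.
#' @param seed integer seed.
#' @param depth expression level of the simulated genes.
#' @param n_genes_per_rate genes simulated per grid rate (bias is the
#'   median over them).
#' @return data.frame with columns `delta`, `median_bias` (relative).
#' @export
contamination_bias_study <- function(delta_grid, c = 0.05, design = NULL,
                                     seed = 1L, depth = 10000,
                                     n_genes_per_rate = 20L) {
  stopifnot(c > 0, c < 0.5, all(delta_grid > 0))
  if (is.null(design)) {
    design <- slam_pulse_design(1, n_reps = 4L, t0_total = TRUE)
  }
  panel <- lapply(rep(delta_grid, each = n_genes_per_rate),
                  function(d) gene_kinetics(d, depth))
  sim <- simulate_counts(panel, design, contamination = c, seed = seed)
  fit <- fit_kinetics(sim$counts, sim$samples, phase = design$phase,
                      family = design$model$family, k = design$model$k)
  truth <- rep(delta_grid, each = n_genes_per_rate)
  rel_bias <- (fit$estimates$delta - truth) / truth
  data.frame(delta = delta_grid,
             median_bias = vapply(delta_grid, function(d) {
               stats::median(rel_bias[truth == d], na.rm = TRUE)
             }, numeric(1)))
}
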