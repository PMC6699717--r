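# Shared fixtures: random parameter draws and tiny simulated experiments.

random_gene <- function() {
  gene_kinetics(delta = exp(stats::runif(1, log(0.05), log(5))),
                mu = exp(stats::runif(1, log(10), log(1e5))))
}

# central finite difference of mean_count in one kinetic parameter
fd_gradient <- function(point, gene, h = 1e-6) {
  pn <- kinetic_params(point$phase)
  vapply(pn, function(p) {
    bump <- function(sign) {
      g <- unclass(gene)
      g[[p]] <- g[[p]] * (1 + sign * h)
      if (!is.null(g$mu1)) {
        gene_kinetics(g$delta, mu1 = g$mu1, mu2 = g$mu2)
      } else {
        gene_kinetics(g$delta, g$mu)
      }
    }
    (mean_count(point, bump(1)) - mean_count(point, bump(-1))) /
      (2 * h * unclass(gene)[[p]])
  }, numeric(1))
}

# one noiseless "experiment": rounded model means as counts
noiseless_counts <- function(panel, design) {
  pts <- as_design_points(design)
  samples <- do.call(rbind, lapply(seq_along(pts), function(i) {
    data.frame(sample = paste0("s", i, "_", seq_len(design$n_reps)),
               time = pts[[i]]$time, fraction = pts[[i]]$fraction,
               replicate = seq_len(design$n_reps))
  }))
  counts <- t(vapply(panel, function(g) {
    rep(vapply(pts, mean_count, numeric(1), gene = g),
        each = design$n_reps)
  }, numeric(nrow(samples))))
  counts <- round(counts)
  rownames(counts) <- paste0("gene", seq_along(panel))
  colnames(counts) <- samples$sample
  list(counts = counts, samples = samples)
}
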