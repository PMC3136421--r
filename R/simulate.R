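#' Draw a kinetic parameter set for a signed network
#'
#' Samples one set of Hill-kinetics parameters: per edge an interaction
#' strength (uniform on \\[0.5, 2]) and a cooperativity/Hill coefficient
#' (uniform on \\[1, 3]), and per gene a basal expression level (uniform on
#' \\[0.05, 0.2]). The Hill threshold of an edge is derived from its
#' strength at simulation time, as the `1 / (1 + strength)` quantile of the
#' regulator's operating range, so stronger interactions respond at lower
#' regulator levels. Resampling the kinetics between datasets is what turns
#' repeated simulation into an ensemble mimicking biological variability
#' across a population of similar organisms.
#'
#' @param net a fully signed [grn] object.
#' @param noise_sd standard deviation of the lognormal noise on the log
#'   scale. Default 0.1.
#' @param seed integer seed.
#' @return An object of class `"kinetics"`: list with named numeric vectors
#'   `strength` and `cooperativity` (one entry per edge, named
#'   `"from\tto"`), `basal` (one per gene) and scalar `noise_sd`.
#' @export
draw_kinetics <- function(net, noise_sd = 0.1, seed = NULL) {
  stopifnot(inherits(net, "grn"))
  if (nrow(net$edges) > 0L && anyNA(net$edges$sign)) {
    stop("network has unsigned edges; run assign_edge_signs() first")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  check_seed(seed)
  ne <- nrow(net$edges)
  ek <- edge_keys(net$edges$from, net$edges$to)
  kin <- list(
    strength = stats::setNames(stats::runif(ne, 0.5, 2), ek),
    cooperativity = stats::setNames(stats::runif(ne, 1, 3), ek),
    basal = stats::setNames(stats::runif(length(net$nodes), 0.05, 0.2),
                            net$nodes),
    noise_sd = noise_sd
  )
  class(kin) <- "kinetics"
  kin
}

#' @export
print.kinetics <- function(x, ...) {
  cat(sprintf(
    "Kinetic model: %d edge parameters, %d basal levels, noise_sd = %g\n",
    length(x$strength), length(x$basal), x$noise_sd))
  invisible(x)
}

#' Simulate steady-state expression data from a signed network
#'
#' Generates `n_samples` independent steady states. Per sample, input genes
#' (in-degree zero) draw independent activation levels uniform on (0, 1);
#' every regulated gene takes the value
#' `basal + (1 - basal) * prod_act h(x) * prod_rep (1 - h(x))`
#' with the Hill response `h(x) = x^c / (x^c + K^c)`, so activators increase
#' and repressors decrease the target. Acyclic networks are evaluated
#' exactly in topological order; networks with directed cycles are solved by
#' damped fixed-point iteration (damping 0.5, tolerance 1e-8, at most 500
#' sweeps). Multiplicative lognormal noise is applied to every gene's value
#' as its steady state is formed, so intrinsic fluctuations propagate to
#' downstream targets the way biological noise does; positivity is
#' preserved throughout.
#'
#' @param net a fully signed [grn] object.
#' @param kin a `"kinetics"` object from [draw_kinetics()]; drawn fresh with
#'   `seed` when omitted.
#' @param n_samples number of samples (columns), at least 2.
#' @param seed integer seed.
#' @param noise logical; set `FALSE` to return the noise-free steady states.
#' @return A numeric genes-by-samples matrix with `dimnames` set to gene and
#'   sample identifiers. All entries are strictly positive.
#' @examples
#' net <- assign_edge_signs(generate_dag(10, 0.15, seed = 1), seed = 2)
#' x <- simulate_steady_state(net, n_samples = 50, seed = 3)
#' dim(x)
#' @export
simulate_steady_state <- function(net, kin = NULL, n_samples, seed = NULL,
                                  noise = TRUE) {
  stopifnot(inherits(net, "grn"))
  if (nrow(net$edges) > 0L && anyNA(net$edges$sign)) {
    stop("network has unsigned edges; run assign_edge_signs() first")
  }
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be at least 2")
  }
  n_samples <- as.integer(n_samples)
  check_seed(seed)
  if (is.null(kin)) kin <- draw_kinetics(net)
  stopifnot(inherits(kin, "kinetics"))

  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  indeg <- in_degree(net)
  x <- matrix(0, n, n_samples, dimnames = list(net$nodes, sample_names(n_samples)))

  # intrinsic lognormal noise, one factor per gene and sample, applied as
  # each gene's steady state is formed so fluctuations propagate to targets
  E <- if (noise) {
    matrix(exp(stats::rnorm(n * n_samples, 0, kin$noise_sd)), n, n_samples)
  } else {
    matrix(1, n, n_samples)
  }

  # input genes: independent uniform activation per sample
  inputs <- indeg == 0L
  x[inputs, ] <- stats::runif(sum(inputs) * n_samples) * E[inputs, ]

  # per-target regulator bookkeeping
  regs <- split(seq_len(nrow(net$edges)), net$edges$to)

  hill_input <- function(k, xs) {
    # xs: regulator values (vector over samples) for edge row k.
    # The Hill threshold K sits at a strength-dependent quantile of the
    # regulator's own operating range (stronger edges respond at lower
    # levels), so interactions stay responsive at any network depth.
    K <- stats::quantile(xs, 1 / (1 + kin$strength[k]), names = FALSE)
    K <- max(K, .Machine$double.eps)
    c_ <- kin$cooperativity[k]
    h <- xs^c_ / (xs^c_ + K^c_)
    if (net$edges$sign[k] == "+") h else 1 - h
  }

  regulated_value <- function(gene, state) {
    ks <- regs[[gene]]
    prod <- rep(1, n_samples)
    for (k in ks) prod <- prod * hill_input(k, state[idx[[net$edges$from[k]]], ])
    b <- kin$basal[[gene]]
    b + (1 - b) * prod
  }

  topo <- topological_order(net)
  if (!is.null(topo)) {
    for (gene in topo) {
      g <- idx[[gene]]
      if (!inputs[g]) x[g, ] <- regulated_value(gene, x) * E[g, ]
    }
  } else {
    # cyclic: damped fixed-point iteration from basal levels; the noise
    # factors are frozen per gene and sample, so the iteration converges
    # to a noisy steady state
    reg_genes <- net$nodes[!inputs]
    for (gene in reg_genes) x[idx[[gene]], ] <- kin$basal[[gene]]
    converged <- FALSE
    for (it in seq_len(500L)) {
      delta <- 0
      for (gene in reg_genes) {
        g <- idx[[gene]]
        new <- 0.5 * x[g, ] + 0.5 * regulated_value(gene, x) * E[g, ]
        delta <- max(delta, max(abs(new - x[g, ])))
        x[g, ] <- new
      }
      if (delta < 1e-8) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("steady-state fixed-point iteration did not converge in 500 sweeps")
    }
  }
  x
}

#' Apply multiplicative lognormal noise
#'
#' Returns `values * exp(e)` with `e ~ Normal(0, noise_sd^2)` drawn
#' independently per entry — the biological noise model of lognormally
#' distributed expression variation. Positivity of the input is preserved.
#'
#' @param values numeric vector or matrix of strictly positive values.
#' @param noise_sd standard deviation on the log scale (> 0).
#' @param seed integer seed.
#' @return Object of the same shape with noise applied.
#' @export
add_lognormal_noise <- function(values, noise_sd, seed = NULL) {
  if (!is.numeric(values) || any(values <= 0) || any(!is.finite(values))) {
    stop("values must be finite and strictly positive")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  check_seed(seed)
  values * exp(stats::rnorm(length(values), 0, noise_sd))
}

#' Generate an ensemble of simulated expression datasets
#'
#' Repeats steady-state simulation `n_datasets` times, drawing a fresh
#' kinetic parameter set for every dataset, so the ensemble imitates the
#' biological variability of a population of similar organisms sharing one
#' regulatory network. The default ensemble size of 300 matches the scale
#' at which edge-level true-positive rates are customarily estimated.
#' Per-dataset seeds are spawned from `master_seed` (the master seed seeds a
#' draw of `n_datasets` independent stream seeds), so the whole ensemble is
#' reproducible from one integer.
#'
#' @param net a fully signed [grn] object.
#' @param n_datasets ensemble size. Default 300.
#' @param n_samples samples per dataset.
#' @param master_seed integer seed governing the whole ensemble.
#' @param noise_sd lognormal noise level passed to [draw_kinetics()].
#' @return An object of class `"ensemble"`: list with `datasets` (list of
#'   matrices), `network`, `seeds` and `kinetics`.
#' @export
generate_ensemble <- function(net, n_datasets = 300, n_samples,
                              master_seed = NULL, noise_sd = 0.1) {
  stopifnot(inherits(net, "grn"))
  if (nrow(net$edges) > 0L && anyNA(net$edges$sign)) {
    stop("network has unsigned edges; run assign_edge_signs() first")
  }
  if (!is.numeric(n_datasets) || n_datasets < 1) {
    stop("n_datasets must be at least 1")
  }
  n_datasets <- as.integer(n_datasets)
  check_seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_datasets)
  datasets <- vector("list", n_datasets)
  kinetics <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    kin <- draw_kinetics(net, noise_sd = noise_sd, seed = seeds[i])
    kinetics[[i]] <- kin
    datasets[[i]] <- simulate_steady_state(net, kin, n_samples)
  }
  structure(list(datasets = datasets, network = net, seeds = seeds,
                 kinetics = kinetics),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$datasets[[1L]])
  cat(sprintf("Expression ensemble: %d datasets of %d genes x %d samples\n",
              length(x$datasets), d[1L], d[2L]))
  invisible(x)
}

sample_names <- function(m) sprintf("S%d", seq_len(m))
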