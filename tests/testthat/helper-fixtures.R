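# Shared fixtures, built once per test session and cached.

.fx <- new.env(parent = emptyenv())

tiny_cfg <- function(seed = 3L, ...)
  synth_config(n_households = 300, n_waves = 2, n_clusters = 20, seed = seed, ...)

# small panel + prep + fit used across files
get_tiny <- function() {
  if (is.null(.fx$tiny)) {
    cfg <- tiny_cfg()
    prefs <- generate_preferences(cfg)
    pan <- generate_panel(cfg, prefs)
    prep <- prepare_observations(pan)
    fit <- easi_fit(prep, degree = 2)
    .fx$tiny <- list(cfg = cfg, prefs = prefs, pan = pan, prep = prep, fit = fit)
  }
  .fx$tiny
}

# hand-built preferences whose latent shares never cross zero over the
# sample: exercises the censoring-free identities and exact recovery
noiseless_prefs <- function(cfg, sigma_e = 0) {
  J <- cfg$n_groups
  R <- cfg$poly_degree_true
  c0 <- easidemand:::typical_y(cfg)
  s1 <- seq(-0.012, 0.012, length.out = J)
  s2 <- rep_len(c(0.002, -0.002), J)
  slopes <- cbind(s1, s2)[, seq_len(R), drop = FALSE]
  b <- t(vapply(seq_len(J),
                function(j) easidemand:::raw_from_centered(0.55 / J, slopes[j, ], c0),
                numeric(R + 1L)))
  A <- matrix(0, J, J)
  A[upper.tri(A)] <- seq(0.002, 0.008, length.out = J * (J - 1) / 2)
  A <- A + t(A); diag(A) <- -rowSums(A)
  D <- matrix(0, J, J)
  D[upper.tri(D)] <- rep_len(c(0.001, -0.001), J * (J - 1) / 2)
  D <- D + t(D); diag(D) <- -rowSums(D)
  G <- matrix(seq(-0.002, 0.002, length.out = J * 4), J, 4)
  p <- easi_params(b = b, A = A, D = D, G = G, utility = "exact")
  p$Sigma_e <- diag(sigma_e^2, J)
  p
}

noiseless_cfg <- function(seed = 2L, ...)
  synth_config(n_households = 400, n_waves = 2, n_clusters = 25, seed = seed,
               expenditure_lognormal = c(mu = log(2.4), sigma = 0.4),
               share_error_scale = 0, quality_loading = 0,
               search_loading = 0, price_noise = 0, ...)

# random admissible parameter draws for oracle loops
rand_params <- function(J = 4, R = 2, seed = 1, utility = "exact") {
  set.seed(seed)
  c0 <- 3
  b <- t(sapply(seq_len(J), function(j)
    easidemand:::raw_from_centered(0.5 / J, stats::rnorm(R, 0, 0.02), c0)))
  A <- matrix(0, J, J)
  A[upper.tri(A)] <- stats::rnorm(J * (J - 1) / 2, 0.004, 0.004)
  A <- A + t(A); diag(A) <- -rowSums(A)
  D <- matrix(0, J, J)
  D[upper.tri(D)] <- stats::rnorm(J * (J - 1) / 2, 0, 0.002)
  D <- D + t(D); diag(D) <- -rowSums(D)
  easi_params(b = b, A = A, D = D, utility = utility)
}

cobb_douglas_params <- function(w0) {
  J <- length(w0)
  easi_params(b = cbind(w0, 0, 0), A = matrix(0, J, J), D = matrix(0, J, J))
}
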