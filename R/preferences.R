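## Ground-truth preference generator for the synthetic data-generating process.
##
## Engel-curve coefficients are drawn on powers of (y - y0), where y0 is the
## implicit utility of the median household at base prices, and then expanded
## into raw polynomial coefficients; this keeps budget shares near their
## baseline values over the realised range of y.

## expand w0 + sum_r s_r (y - c0)^r into raw coefficients on y^0..y^R
raw_from_centered <- function(w0, slopes, c0) {
  R <- length(slopes)
  out <- numeric(R + 1L); out[1] <- w0
  for (r in seq_len(R)) {
    ## (y - c0)^r coefficients via binomial theorem
    m <- 0:r
    out[m + 1L] <- out[m + 1L] + slopes[r] * choose(r, m) * (-c0)^(r - m)
  }
  out
}

## typical implicit utility at the generator's median household:
## log(median per-AE daily spend * typical AE * 7 days), base prices = 1
typical_y <- function(config) {
  unname(config$expenditure_lognormal["mu"]) + log(2.8 * 7)
}

#' Draw admissible ground-truth EASI preferences
#'
#' Samples a restriction-satisfying parameter set (symmetric `A` and `D` with
#' zero row sums, negative own-price coefficients) for the synthetic
#' data-generating process, by rejection: candidate draws are kept only if
#' the implied latent budget shares at the median household (median
#' expenditures, unit prices, reference shifters) lie in (0.01, 0.6) for
#' every food group, the numeraire share at the median exceeds 0.15, and
#' shares remain in (-0.05, 0.75) at median utility +/- 1.5.
#'
#' @param config a [synth_config] object.
#' @param max_tries bound on rejection resampling.
#' @return an object of classes `true_preferences` and [easi_params], with
#'   the latent-share error covariance in `$Sigma_e` and the centering point
#'   of the Engel polynomial in `$y_center`.
#' @export
generate_preferences <- function(config, max_tries = 500L) {
  stopifnot(inherits(config, "synth_config"))
  J <- config$n_groups
  R <- config$poly_degree_true
  c0 <- typical_y(config)
  prefs <- NULL
  with_seed(sub_seed(config$seed, 0L), {
    last_violation <- "no draw attempted"
    for (try in seq_len(max_tries)) {
      food_total <- stats::runif(1, 0.50, 0.60)
      wts <- stats::rgamma(J, shape = 0.8) + 0.06
      w0 <- food_total * wts / sum(wts)
      if (any(w0 <= 0.012 | w0 >= 0.6)) { last_violation <- "median share outside (0.01, 0.6)"; next }

      slopes <- matrix(stats::rnorm(J * R, 0, 0.03 / seq_len(R)^1.5),
                       nrow = J, byrow = TRUE)
      b <- t(vapply(seq_len(J),
                    function(j) raw_from_centered(w0[j], slopes[j, ], c0),
                    numeric(R + 1L)))

      A <- matrix(0, J, J)
      A[upper.tri(A)] <- stats::rnorm(J * (J - 1) / 2, 0.004, 0.005)
      A <- A + t(A); diag(A) <- -rowSums(A)
      if (any(diag(A) >= -0.002)) { last_violation <- "own-price coefficient not negative"; next }

      D <- matrix(0, J, J)
      D[upper.tri(D)] <- stats::rnorm(J * (J - 1) / 2, 0, 0.0015)
      D <- D + t(D); diag(D) <- -rowSums(D)

      G <- matrix(stats::rnorm(J * 4L, 0, 0.012), J, 4L,
                  dimnames = list(NULL, c("log_hhsize_c", "urban_c",
                                          "head_age_z", "head_female_c")))

      ## shares along the realised range of utility must stay near-admissible
      yy <- c0 + c(-1.5, 0, 1.5)
      Wchk <- poly_matrix(yy, R) %*% t(b)
      if (any(Wchk < -0.05 | Wchk > 0.75)) { last_violation <- "share outside (-0.05, 0.75) over utility range"; next }
      if (any(1 - rowSums(Wchk) < 0.15)) { last_violation <- "numeraire share below 0.15"; next }

      ## latent-share error covariance: near-uniform dispersion across
      ## groups with modest cross-group correlation; zero consumption then
      ## concentrates in the small-share groups, as in survey data
      s <- config$share_error_scale * stats::runif(J, 0.85, 1.15)
      L <- matrix(stats::rnorm(J * 2L), J, 2L)
      C <- stats::cov2cor(tcrossprod(L) + diag(2.5, J))
      Sigma_e <- diag(s) %*% C %*% diag(s)

      p <- easi_params(b = b, A = A, D = D, G = G, utility = "exact")
      p$Sigma_e <- Sigma_e
      p$w0 <- w0
      p$y_center <- c0
      class(p) <- c("true_preferences", class(p))
      prefs <- p
      break
    }
    if (is.null(prefs))
      stop_ed("no admissible preference draw in %d resamples (last violated bound: %s)",
              max_tries, last_violation)
  })
  prefs
}
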