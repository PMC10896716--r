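#' EASI demand-system parameter set
#'
#' Container for the parameters of an incomplete Exact Affine Stone Index
#' (EASI) demand system over `J` food groups plus a non-food numeraire whose
#' log price is normalised to zero.  The latent budget share of food group
#' `j` at implicit utility `y` is
#'
#' \deqn{w_j = \sum_{r=0}^{R} b_{jr} y^r + \sum_k a_{jk} \ln p_k
#'       + y \sum_k d_{jk} \ln p_k + g_j' z + m_j' \bar c}
#'
#' where `z` are demand shifters and `\bar c` optional cluster-mean
#' (correlated random effects) regressors.  The numeraire share is implied
#' by adding-up.  `A` and `D` must be symmetric with zero row sums
#' (Slutsky symmetry and homogeneity; with the numeraire price normalised to
#' zero its implied column is zero as well).
#'
#' @param b `J x (R+1)` matrix of polynomial coefficients on powers
#'   `y^0 .. y^R` of implicit utility.
#' @param A `J x J` symmetric log-price coefficient matrix, zero row sums.
#' @param D `J x J` symmetric price-utility interaction matrix, zero row sums.
#' @param G optional `J x Z` demand-shifter coefficient matrix.
#' @param M optional `J x C` correlated-random-effects coefficient matrix on
#'   cluster means.
#' @param theta optional length-`J` censoring-correction loadings (the
#'   coefficients on the probit density term in the two-step censored system).
#' @param censor optional censoring model as returned by
#'   [fit_censoring_stage()]; used by [predict_shares()] when
#'   `adjust = "censored"`.
#' @param Sigma optional residual covariance (`J x J`).
#' @param utility `"exact"` (default) for the exact-affine implicit utility
#'   transformation, `"stone"` for the Stone-deflated approximation.
#' @param groups optional character vector of food-group names.
#' @return an object of class `easi_params`.
#' @export
easi_params <- function(b, A, D, G = NULL, M = NULL, theta = NULL,
                        censor = NULL, Sigma = NULL,
                        utility = c("exact", "stone"), groups = NULL) {
  utility <- match.arg(utility)
  b <- as.matrix(b); A <- as.matrix(A); D <- as.matrix(D)
  J <- nrow(b)
  if (!all(dim(A) == c(J, J)) || !all(dim(D) == c(J, J)))
    stop_ed("A and D must be %d x %d", J, J)
  if (max(abs(A - t(A))) > 1e-8) stop_ed("A must be symmetric")
  if (max(abs(D - t(D))) > 1e-8) stop_ed("D must be symmetric")
  if (max(abs(rowSums(A))) > 1e-8) stop_ed("rows of A must sum to 0 (homogeneity)")
  if (max(abs(rowSums(D))) > 1e-8) stop_ed("rows of D must sum to 0 (homogeneity)")
  if (!is.null(G)) { G <- as.matrix(G); stopifnot(nrow(G) == J) }
  if (!is.null(M)) { M <- as.matrix(M); stopifnot(nrow(M) == J) }
  if (!is.null(theta)) stopifnot(length(theta) == J)
  structure(list(
    b = b, A = A, D = D, G = G, M = M, theta = theta, censor = censor,
    Sigma = Sigma, degree = ncol(b) - 1L, J = J, utility = utility,
    groups = groups %||% paste0("g", seq_len(J))
  ), class = "easi_params")
}

#' @export
print.easi_params <- function(x, ...) {
  cat(sprintf("EASI demand-system parameters: %d food groups + numeraire, degree %d (%s utility)\n",
              x$J, x$degree, x$utility))
  cat(sprintf("  shifters: %s, cluster means: %s, censoring loadings: %s\n",
              ncol(x$G %||% matrix(0, 1, 0)), ncol(x$M %||% matrix(0, 1, 0)),
              if (is.null(x$theta)) "none" else "yes"))
  invisible(x)
}

## powers y^0..y^R as an n x (R+1) matrix
poly_matrix <- function(y, R) {
  out <- matrix(1, length(y), R + 1L)
  for (r in seq_len(R)) out[, r + 1L] <- out[, r] * y
  out
}

#' Implicit utility of the EASI system
#'
#' Computes implicit utility `y` from observed budget shares.  With the
#' default Stone form (no `A`/`D`), `y` is log nominal expenditure deflated
#' by the Stone price index, `y = ln x - sum_k w_k ln p_k`.  When `A` and
#' `D` are supplied the exact-affine transformation is used:
#' `y = (ln x - w'ln p + 0.5 ln p'A ln p) / (1 - 0.5 ln p'D ln p)`.
#'
#' @param ln_x log total expenditures (vector of length n).
#' @param w `n x K` matrix (or length-K vector) of budget shares summing to 1
#'   across each row, numeraire included.
#' @param ln_p `n x K` matrix (or length-K vector) of log prices aligned with
#'   `w`; the numeraire entry is conventionally 0.
#' @param A,D optional symmetric food-price coefficient matrices (over the
#'   first `J` columns) activating the exact-affine form.
#' @return numeric vector `y` of length n.
#' @export
implicit_utility <- function(ln_x, w, ln_p, A = NULL, D = NULL) {
  if (is.null(dim(w))) w <- matrix(w, nrow = length(ln_x), ncol = length(w), byrow = TRUE)
  if (is.null(dim(ln_p))) ln_p <- matrix(ln_p, nrow = length(ln_x), ncol = length(ln_p), byrow = TRUE)
  stone <- rowSums(w * ln_p)
  if (is.null(A)) return(ln_x - stone)
  J <- nrow(A)
  lp <- ln_p[, seq_len(J), drop = FALSE]
  qA <- rowSums((lp %*% A) * lp)
  qD <- rowSums((lp %*% D) * lp)
  (ln_x - stone + 0.5 * qA) / (1 - 0.5 * qD)
}

## evaluate the participation probit of a fitted censoring stage at given
## covariates (model-implied utility and actual prices at prediction time)
censor_probabilities <- function(censor, ln_p, y, z, cm) {
  n <- length(y); J <- ncol(ln_p)
  X <- cens_design(y - (censor$y_center %||% 0), ln_p,
                   z %||% matrix(0, n, 0L), cm %||% matrix(0, n, 0L),
                   censor$degree)
  Phi <- matrix(1, n, J); phi <- matrix(0, n, J)
  for (j in seq_len(J)) {
    if (is.null(censor$coef[[j]])) next
    xb <- pmin(pmax(drop(X %*% censor$coef[[j]]), -8), 8)
    Phi[, j] <- stats::pnorm(xb)
    phi[, j] <- stats::dnorm(xb)
  }
  list(Phi = Phi, phi = phi)
}

#' Predict budget shares from an EASI parameter set
#'
#' Solves the joint fixed point between implicit utility `y` and the latent
#' share equations by damped iteration, then (optionally) applies the
#' two-step censoring adjustment `w*_j = Phi_j w_j + theta_j phi_j`.
#'
#' @param params an [easi_params] object.
#' @param ln_p `n x J` matrix of log food-group price indices.
#' @param ln_x length-n vector of log total (food + non-food) expenditures.
#' @param z optional `n x Z` shifter matrix (must match `params$G`).
#' @param cm optional `n x C` cluster-mean matrix (must match `params$M`).
#' @param offset optional `n x J` additive disturbance on the latent shares
#'   (used by the synthetic-data generator to inject preference errors).
#' @param adjust `"latent"` returns the latent system prediction;
#'   `"censored"` additionally applies the participation-probability
#'   adjustment when a censoring model is attached.
#' @param tol,max_iter,damp fixed-point controls.
#' @return list with elements `w` (`n x J` latent food shares), `w_num`
#'   (latent numeraire share), `y` (implicit utility), `iterations`, and --
#'   when adjusted -- `w_adj`, `w_num_adj`, `Phi`, `phi`, `renorm` (count of
#'   renormalised rows).
#' @export
predict_shares <- function(params, ln_p, ln_x, z = NULL, cm = NULL,
                           offset = NULL,
                           adjust = c("latent", "censored"),
                           tol = 1e-10, max_iter = 100L, damp = 0.5) {
  adjust <- match.arg(adjust)
  J <- params$J; R <- params$degree
  ln_p <- as.matrix(ln_p); n <- length(ln_x)
  stopifnot(nrow(ln_p) == n, ncol(ln_p) == J)
  base <- matrix(0, n, J)
  if (!is.null(params$G)) {
    if (is.null(z)) stop_ed("params include shifter coefficients; `z` is required")
    base <- base + as.matrix(z) %*% t(params$G)
  }
  if (!is.null(params$M)) {
    if (is.null(cm)) stop_ed("params include cluster-mean coefficients; `cm` is required")
    base <- base + as.matrix(cm) %*% t(params$M)
  }
  if (!is.null(offset)) base <- base + offset
  Alp <- ln_p %*% params$A
  Dlp <- ln_p %*% params$D
  qA <- rowSums(Alp * ln_p)
  qD <- rowSums(Dlp * ln_p)
  denomD <- if (params$utility == "exact") 1 - 0.5 * qD else rep(1, n)
  if (any(abs(denomD) < 0.1))
    stop_ed("exact-affine denominator 1 - 0.5 lnp'D lnp close to zero; prices outside supported range")
  numA <- if (params$utility == "exact") 0.5 * qA else 0
  shares_at <- function(y)
    poly_matrix(y, R) %*% t(params$b) + Alp + (y * ln_p) %*% params$D + base
  y <- ln_x
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    W <- shares_at(y)
    y_target <- (ln_x - rowSums(W * ln_p) + numA) / denomD
    delta <- max(abs(y_target - y))
    trace <- c(trace, delta)
    y <- y + damp * (y_target - y)
    if (delta < tol) break
  }
  if (trace[length(trace)] >= tol * 10)
    stop_ed("implicit-utility fixed point did not converge in %d iterations (last deltas: %s)",
            max_iter, paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  W <- shares_at(y)
  out <- list(w = W, w_num = 1 - rowSums(W), y = y, iterations = length(trace))
  if (adjust == "censored" && !is.null(params$censor)) {
    cp <- censor_probabilities(params$censor, ln_p, y, z, cm)
    theta <- params$theta %||% rep(0, J)
    W_adj <- cp$Phi * W + matrix(theta, n, J, byrow = TRUE) * cp$phi
    w_num_adj <- 1 - rowSums(W_adj)
    bad <- w_num_adj < 0.005
    if (any(bad)) {  # keep adding-up with a positive numeraire floor
      scale <- (1 - 0.005) / rowSums(W_adj[bad, , drop = FALSE])
      W_adj[bad, ] <- W_adj[bad, , drop = FALSE] * scale
      w_num_adj[bad] <- 0.005
    }
    out$w_adj <- W_adj; out$w_num_adj <- w_num_adj
    out$Phi <- cp$Phi; out$phi <- cp$phi; out$renorm <- sum(bad)
  }
  out
}
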