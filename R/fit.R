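## Censored EASI system estimation.
##
## J share equations (numeraire dropped, recovered by adding-up), linear in
## parameters given implicit utility y.  Cross-equation symmetry and
## homogeneity are imposed through a restriction matrix mapping a free
## parameter vector to all equation coefficients; endogeneity of real
## expenditures (own-share Stone index) and of unit-value price indices is
## handled by 2SLS with the average-share Stone index and leave-one-out
## neighbour prices as instruments; censoring by the two-step
## probit-corrected system (participation probit, then Phi-scaled share
## equations with a phi term); cluster-level means enter as correlated
## random effects.  y and the parameters are iterated to a joint fixed
## point.

## wave dummy columns (reference = first wave)
wave_dummies <- function(wave) {
  lv <- sort(unique(wave))
  if (length(lv) < 2L) return(matrix(0, length(wave), 0L))
  m <- sapply(lv[-1], function(l) as.numeric(wave == l))
  colnames(m) <- paste0("wave", lv[-1])
  m
}

## covariate block shared by the participation probit and its prediction
cens_design <- function(y, lnp, z, cm, R) {
  cbind(1, poly_matrix(y, R)[, -1, drop = FALSE], lnp, y * lnp, z, cm)
}

## restriction matrices R_j (one per equation) mapping the free parameter
## vector to equation-j coefficients; returns list plus index bookkeeping
build_restrictions <- function(J, R, Zz, C, cens_groups) {
  ## pair order must match upper.tri() extraction (column-major)
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  dimnames(pairs) <- NULL
  np <- nrow(pairs)
  ix <- list()
  q0 <- 0L
  ix$b <- matrix(seq_len(J * (R + 1L)), J, R + 1L); q0 <- q0 + J * (R + 1L)
  ix$a <- q0 + seq_len(np); q0 <- q0 + np
  ix$d <- q0 + seq_len(np); q0 <- q0 + np
  ix$g <- if (Zz > 0) matrix(q0 + seq_len(J * Zz), J, Zz) else matrix(0L, J, 0L)
  q0 <- q0 + J * Zz
  ix$m <- if (C > 0) matrix(q0 + seq_len(J * C), J, C) else matrix(0L, J, 0L)
  q0 <- q0 + J * C
  ix$theta <- rep(NA_integer_, J)
  ix$theta[cens_groups] <- q0 + seq_len(sum(cens_groups))
  q <- q0 + sum(cens_groups)

  ## equation-j column layout: 1, y..y^R, lnp (J), y*lnp (J), z, cm [, phi]
  K <- 1L + R + 2L * J + Zz + C
  Rmats <- vector("list", J)
  for (j in seq_len(J)) {
    Kj <- K + as.integer(cens_groups[j])
    Rj <- matrix(0, Kj, q)
    for (r in 0:R) Rj[1L + r, ix$b[j, r + 1L]] <- 1
    col_lnp <- 1L + R + seq_len(J)
    col_ylnp <- 1L + R + J + seq_len(J)
    for (p in seq_len(np)) {
      jj <- pairs[p, 1]; kk <- pairs[p, 2]
      if (j == jj) {  # a_jk free: +1 on lnp_k, -1 on lnp_j (zero row sum)
        Rj[col_lnp[kk], ix$a[p]] <- Rj[col_lnp[kk], ix$a[p]] + 1
        Rj[col_lnp[jj], ix$a[p]] <- Rj[col_lnp[jj], ix$a[p]] - 1
        Rj[col_ylnp[kk], ix$d[p]] <- Rj[col_ylnp[kk], ix$d[p]] + 1
        Rj[col_ylnp[jj], ix$d[p]] <- Rj[col_ylnp[jj], ix$d[p]] - 1
      }
      if (j == kk) {  # symmetry: same free parameter enters equation k
        Rj[col_lnp[jj], ix$a[p]] <- Rj[col_lnp[jj], ix$a[p]] + 1
        Rj[col_lnp[kk], ix$a[p]] <- Rj[col_lnp[kk], ix$a[p]] - 1
        Rj[col_ylnp[jj], ix$d[p]] <- Rj[col_ylnp[jj], ix$d[p]] + 1
        Rj[col_ylnp[kk], ix$d[p]] <- Rj[col_ylnp[kk], ix$d[p]] - 1
      }
    }
    if (Zz > 0) for (s in seq_len(Zz)) Rj[1L + R + 2L * J + s, ix$g[j, s]] <- 1
    if (C > 0) for (s in seq_len(C)) Rj[1L + R + 2L * J + Zz + s, ix$m[j, s]] <- 1
    if (cens_groups[j]) Rj[Kj, ix$theta[j]] <- 1
    Rmats[[j]] <- Rj
  }
  list(Rmats = Rmats, index = ix, q = q, pairs = pairs, K = K)
}

## rebuild structured parameter matrices from the free vector
params_from_free <- function(theta, index, J, R, Zz, C) {
  b <- matrix(theta[index$b], J, R + 1L)
  A <- matrix(0, J, J); D <- matrix(0, J, J)
  if (nrow(index$pairs %||% matrix(0, 0, 2)) > 0) NULL
  A[upper.tri(A)] <- theta[index$a]
  A <- A + t(A); diag(A) <- -rowSums(A)
  D[upper.tri(D)] <- theta[index$d]
  D <- D + t(D); diag(D) <- -rowSums(D)
  G <- if (Zz > 0) matrix(theta[index$g], J, Zz) else NULL
  M <- if (C > 0) matrix(theta[index$m], J, C) else NULL
  th <- ifelse(is.na(index$theta), 0, theta[ifelse(is.na(index$theta), 1L, index$theta)])
  list(b = b, A = A, D = D, G = G, M = M, theta = th)
}

## convert centred-polynomial estimates (powers of y - y_c, interactions on
## y - y_c) to the raw parameterisation stored in `easi_params`
centered_to_raw <- function(b_c, A_c, D, y_c) {
  R <- ncol(b_c) - 1L
  b <- t(vapply(seq_len(nrow(b_c)),
                function(j) raw_from_centered(b_c[j, 1], b_c[j, -1], y_c),
                numeric(R + 1L)))
  if (R == 0L) b <- b_c
  list(b = b, A = A_c - y_c * D, D = D)
}

#' Participation (censoring) stage of the two-step censored system
#'
#' Fits, per food group, a probit of the consumption indicator on all
#' exogenous regressors and instruments, and returns the participation
#' probabilities `Phi` and densities `phi` entering the corrected share
#' equations.  Groups consumed by every household get `Phi = 1`, `phi = 0`
#' (the corrected equation collapses to the latent one) with a note; a
#' group never consumed is an error.
#'
#' @param prep a `prepared_observations` table.
#' @param degree polynomial degree used for the utility proxy columns.
#' @param min_rate groups with a zero-consumption rate below this are
#'   treated as uncensored: a nearly-always-consumed group yields an almost
#'   constant probit density column that is collinear with the intercept.
#' @param min_zeros minimum number of zero observations needed to estimate
#'   a participation equation (guards against quasi-separation in small
#'   samples).
#' @return list with `Phi`, `phi` (`n x J`), `coef` (coefficients per
#'   group), `censored` (logical per group), `rates` (zero-consumption
#'   rate per group), `accuracy` (in-sample classification accuracy),
#'   `base_rate` (majority-class share) and `notes`.
#' @export
fit_censoring_stage <- function(prep, degree = 2, min_rate = 0.01,
                                min_zeros = 30L) {
  J <- attr(prep, "J")
  W <- prep_matrix(prep, "w")
  iv <- prep_matrix(prep, "iv")
  wbar <- attr(prep, "wbar")
  yhat <- prep$lnx - avg_share_stone_index(wbar[seq_len(J)], iv)
  y_center <- mean(yhat)
  Zfull <- cbind(prep_z(prep), wave_dummies(prep$wave))
  X <- cens_design(yhat - y_center, iv, Zfull, prep_cm(prep), degree)
  n <- nrow(X)
  Phi <- matrix(1, n, J); phi <- matrix(0, n, J)
  coefs <- vector("list", J); notes <- character(0)
  rates <- colMeans(W == 0)
  acc <- base <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    d <- as.numeric(W[, j] > 0)
    if (all(d == 0)) stop_ed("food group %d is never consumed; cannot estimate its demand", j)
    if (mean(d == 0) < min_rate || sum(d == 0) < min_zeros) {
      notes <- c(notes, sprintf("group %d: too little censoring (%d zeros), no correction applied",
                                j, sum(d == 0)))
      next
    }
    fit <- suppressWarnings(stats::glm.fit(X, d, family = stats::binomial("probit"),
                                           control = list(maxit = 50)))
    xb <- pmin(pmax(drop(X %*% fit$coefficients), -8), 8)
    Phi[, j] <- stats::pnorm(xb)
    phi[, j] <- stats::dnorm(xb)
    coefs[[j]] <- fit$coefficients
    acc[j] <- mean((Phi[, j] > 0.5) == (d > 0.5))
    base[j] <- max(mean(d), 1 - mean(d))
  }
  list(Phi = Phi, phi = phi, coef = coefs,
       censored = !vapply(coefs, is.null, logical(1)), rates = rates,
       accuracy = acc, base_rate = base, notes = notes, degree = degree,
       y_center = y_center)
}

#' Estimate a censored EASI demand system
#'
#' Iterated restricted system instrumental-variables estimation of the `J`
#' food-group share equations (the numeraire equation is implied by
#' adding-up).  See the package vignette for the estimator's anatomy.
#'
#' @param prep a `prepared_observations` table from [prepare_observations()].
#' @param degree polynomial degree R of the Engel curves (see
#'   [select_degree()] for data-driven choice).
#' @param use_iv instrument the utility polynomial and price terms
#'   (average-share Stone index, neighbour prices)?  Disabling gives the
#'   naive least-squares system (useful to quantify endogeneity bias).
#' @param censor apply the two-step censoring correction?
#' @param utility `"exact"` (exact-affine implicit utility) or `"stone"`.
#' @param weighting `"sur"` (default) weights the stacked system by the
#'   inverse residual covariance across equations (feasible GLS / 3SLS
#'   flavour, updated each iteration); `"identity"` uses unweighted
#'   stacking.  With (near-)singular residual covariance -- noiseless data
#'   -- the identity weighting is used automatically.
#' @param max_iter,tol iteration control for the y-parameter fixed point
#'   (`tol` on the maximum absolute parameter change).
#' @param damp damping of the A/D update used in recomputing y.
#' @return object of classes `easi_fit` and `easi_params`: the restricted
#'   parameter estimates plus `Cov_free` (household-clustered sandwich
#'   covariance of the free parameters), `free` (free-parameter vector),
#'   `free_index`, the censoring stage, and a `report` with iteration path,
#'   first-stage instrument strength and censoring rates.
#' @export
easi_fit <- function(prep, degree = 2, use_iv = TRUE, censor = TRUE,
                     utility = c("exact", "stone"),
                     weighting = c("sur", "identity"),
                     max_iter = 100L, tol = 1e-8, damp = 0.5) {
  utility <- match.arg(utility)
  weighting <- match.arg(weighting)
  J <- attr(prep, "J")
  n <- nrow(prep)
  W <- prep_matrix(prep, "w")
  lnp <- prep_matrix(prep, "lnp")
  iv <- prep_matrix(prep, "iv")
  Zfull <- cbind(prep_z(prep), wave_dummies(prep$wave))
  CM <- prep_cm(prep)
  Zz <- ncol(Zfull); C <- ncol(CM)
  wbar <- attr(prep, "wbar")
  lnx <- prep$lnx
  R <- check_count(degree, "degree")

  cs <- if (censor) fit_censoring_stage(prep, degree = R) else
    list(Phi = matrix(1, n, J), phi = matrix(0, n, J),
         censored = rep(FALSE, J), rates = colMeans(W == 0),
         coef = vector("list", J), notes = "censoring correction disabled")
  rs <- build_restrictions(J, R, Zz, C, cs$censored)

  w_all <- cbind(W, 1 - rowSums(W))
  lnp_all <- cbind(lnp, 0)
  A_use <- matrix(0, J, J); D_use <- matrix(0, J, J)
  theta_free <- rep(0, rs$q)
  deltas <- numeric(0)
  first_stage <- NULL
  y_c <- NA_real_
  relax <- 1

  for (it in seq_len(max_iter)) {
    if (utility == "exact") {
      y <- implicit_utility(lnx, w_all, lnp_all, A_use, D_use)
      qA_iv <- rowSums((iv %*% A_use) * iv)
      qD_iv <- rowSums((iv %*% D_use) * iv)
      yhat <- (lnx - avg_share_stone_index(wbar[seq_len(J)], iv) + 0.5 * qA_iv) /
        (1 - 0.5 * qD_iv)
    } else {
      y <- implicit_utility(lnx, w_all, lnp_all)
      yhat <- lnx - avg_share_stone_index(wbar[seq_len(J)], iv)
    }
    ## centre the utility polynomial (pure reparameterisation, converted
    ## back to raw coefficients on exit) to keep the system well conditioned
    if (it == 1L) y_c <- mean(y)
    ycd <- y - y_c; yhd <- yhat - y_c

    Py <- poly_matrix(ycd, R)
    X_end <- cbind(Py[, -1, drop = FALSE], lnp, ycd * lnp)
    if (use_iv) {
      Zi <- cbind(1, poly_matrix(yhd, R)[, -1, drop = FALSE], iv, yhd * iv,
                  Zfull, CM)
      qz <- qr(Zi)
      if (qz$rank < ncol(Zi))
        stop_ed("instrument matrix is rank deficient (collinear instrument columns)")
      Xhat <- qr.fitted(qz, X_end)
      if (it == 1L) {
        r2 <- 1 - colSums((X_end - Xhat)^2) / colSums(scale(X_end, scale = FALSE)^2)
        k <- ncol(Zi)
        first_stage <- data.frame(
          regressor = c(paste0("y^", seq_len(R)), paste0("lnp_g", seq_len(J)),
                        paste0("y*lnp_g", seq_len(J))),
          r_squared = r2,
          F_stat = (r2 / (1 - r2)) * (n - k) / (k - 1))
      }
    } else Xhat <- X_end

    Xbase <- cbind(1, Xhat, Zfull, CM)
    Xt_list <- vector("list", J)
    for (j in seq_len(J)) {
      Xj <- Xbase * cs$Phi[, j]
      if (cs$censored[j]) Xj <- cbind(Xj, cs$phi[, j])
      Xt_list[[j]] <- Xj %*% rs$Rmats[[j]]
    }
    ## cross-equation weighting: mix equations by the Cholesky factor of
    ## the residual precision (identity on the first pass / fallback)
    Tm <- if (it > 1L && weighting == "sur") {
      Sig <- stats::cov(U_prev)
      if (is.finite(rcond(Sig)) && rcond(Sig) > 1e-10)
        chol(solve(Sig)) else diag(J)
    } else diag(J)
    XtX <- matrix(0, rs$q, rs$q); Xty <- numeric(rs$q)
    for (j in seq_len(J)) {
      ks <- which(Tm[j, ] != 0)
      Xs <- Xt_list[[ks[1]]] * Tm[j, ks[1]]
      ws <- W[, ks[1]] * Tm[j, ks[1]]
      for (k in ks[-1]) {
        Xs <- Xs + Xt_list[[k]] * Tm[j, k]
        ws <- ws + W[, k] * Tm[j, k]
      }
      XtX <- XtX + crossprod(Xs)
      Xty <- Xty + crossprod(Xs, ws)[, 1]
    }
    ch <- tryCatch(chol(XtX), error = function(e) NULL)
    if (is.null(ch))
      stop_ed("restricted system is rank deficient; check instruments and regressors")
    theta_ls <- backsolve(ch, forwardsolve(t(ch), Xty))
    ## full-step distance decides convergence; the applied update is
    ## relaxed when the fixed point oscillates (small samples)
    delta <- max(abs(theta_ls - theta_free))
    if (it > 2L && delta > deltas[it - 1L]) relax <- max(relax * 0.6, 0.05)
    deltas <- c(deltas, delta)
    theta_free <- theta_free + relax * (theta_ls - theta_free)
    ## residuals for next iteration's weighting
    U_prev <- W
    for (j in seq_len(J)) {
      Xj <- Xbase * cs$Phi[, j]
      if (cs$censored[j]) Xj <- cbind(Xj, cs$phi[, j])
      U_prev[, j] <- W[, j] - drop(Xj %*% (rs$Rmats[[j]] %*% theta_free))
    }
    pm <- params_from_free(theta_free, rs$index, J, R, Zz, C)
    raw <- centered_to_raw(pm$b, pm$A, pm$D, y_c)
    A_use <- A_use + damp * (raw$A - A_use)
    D_use <- D_use + damp * (raw$D - D_use)
    if (delta < tol) break
  }
  if (deltas[length(deltas)] > sqrt(tol))
    warning(sprintf("parameter fixed point not fully converged (last delta %.2e)",
                    deltas[length(deltas)]), call. = FALSE)

  pm <- params_from_free(theta_free, rs$index, J, R, Zz, C)
  raw <- centered_to_raw(pm$b, pm$A, pm$D, y_c)
  ## household-clustered sandwich covariance on the weighted moments
  U <- U_prev
  Ustar <- U %*% t(Tm)
  S <- matrix(0, n, rs$q)
  for (j in seq_len(J)) {
    Xs <- Xt_list[[1]] * Tm[j, 1]
    for (k in seq_len(J)[-1]) if (Tm[j, k] != 0) Xs <- Xs + Xt_list[[k]] * Tm[j, k]
    S <- S + Xs * Ustar[, j]
  }
  Sh <- rowsum(S, prep$hh)
  bread <- chol2inv(chol(XtX))
  Cov_free <- bread %*% crossprod(Sh) %*% bread

  ## latent-error covariance: residuals of the uncorrected latent equation,
  ## per pair over observations where both groups are interior (used by the
  ## policy module to simulate intake distributions with truncation)
  U_lat <- matrix(0, n, J)
  for (j in seq_len(J)) {
    beta_j <- drop(rs$Rmats[[j]] %*% theta_free)
    K0 <- ncol(Xbase)
    U_lat[, j] <- W[, j] - drop(Xbase %*% beta_j[seq_len(K0)])
  }
  Sigma_latent <- matrix(0, J, J)
  for (j in seq_len(J)) for (k in j:J) {
    ok <- W[, j] > 0 & W[, k] > 0
    Sigma_latent[j, k] <- Sigma_latent[k, j] <-
      stats::cov(U_lat[ok, j], U_lat[ok, k])
  }
  ## interior residuals understate the latent noise when censoring is
  ## material; refit each group's error location and scale by censored
  ## (Tobit) maximum likelihood around the fitted latent mean, keeping the
  ## interior correlation structure
  sd_cal <- sqrt(diag(Sigma_latent))
  delta_cal <- rep(0, J)
  for (j in seq_len(J)) {
    zero_j <- W[, j] == 0
    if (mean(zero_j) < 0.02) next
    m_j <- W[, j] - U_lat[, j]
    r_int <- U_lat[!zero_j, j]
    m_cen <- m_j[zero_j]
    nll <- function(par) {
      s <- exp(par[2])
      -(sum(stats::dnorm(r_int, par[1], s, log = TRUE)) +
          sum(stats::pnorm(-(m_cen + par[1]) / s, log.p = TRUE)))
    }
    opt <- tryCatch(stats::optim(c(0, log(sd_cal[j])), nll, method = "BFGS"),
                    error = function(e) NULL)
    if (!is.null(opt) && opt$convergence == 0) {
      delta_cal[j] <- opt$par[1]
      sd_cal[j] <- exp(opt$par[2])
    }
  }
  Cor <- suppressWarnings(stats::cov2cor(Sigma_latent))
  Cor[!is.finite(Cor)] <- 0; diag(Cor) <- 1
  Sigma_latent <- diag(sd_cal) %*% Cor %*% diag(sd_cal)
  ee <- eigen(Sigma_latent, symmetric = TRUE)  # pairwise cov need not be PSD
  Sigma_latent <- ee$vectors %*% (pmax(ee$values, 0) * t(ee$vectors))

  censor_model <- if (censor) list(coef = cs$coef, censored = cs$censored,
                                   degree = R, y_center = cs$y_center,
                                   notes = cs$notes) else NULL
  fit <- easi_params(b = raw$b, A = raw$A, D = raw$D, G = pm$G, M = pm$M,
                     theta = pm$theta, censor = censor_model,
                     Sigma = stats::cov(U), utility = utility)
  fit$Cov_free <- Cov_free
  fit$free <- theta_free
  fit$free_index <- rs$index
  fit$Sigma_latent <- Sigma_latent
  fit$latent_shift <- delta_cal
  fit$y_center <- y_c
  fit$dims <- list(J = J, R = R, Zz = Zz, C = C)
  fit$wbar <- wbar
  fit$z_cols <- attr(prep, "z_cols")
  fit$cm_cols <- attr(prep, "cm_cols")
  fit$report <- list(iterations = length(deltas), deltas = deltas,
                     first_stage = first_stage, censor_rates = cs$rates,
                     censor_accuracy = cs$accuracy %||% NULL,
                     use_iv = use_iv, censor = censor, degree = R,
                     n = n, n_households = length(unique(prep$hh)))
  class(fit) <- c("easi_fit", class(fit))
  fit
}

#' @export
print.easi_fit <- function(x, ...) {
  cat(sprintf("Censored EASI system fit: %d groups + numeraire, degree %d, n = %d (%d households)\n",
              x$J, x$degree, x$report$n, x$report$n_households))
  cat(sprintf("  IV: %s | censoring correction: %s | converged in %d iterations (last delta %.1e)\n",
              x$report$use_iv, x$report$censor, x$report$iterations,
              x$report$deltas[length(x$report$deltas)]))
  cat("  own-price coefficients a_jj:", paste(signif(diag(x$A), 3), collapse = ", "), "\n")
  invisible(x)
}

## rebuild an easi_params object from a free-parameter vector drawn around a
## fitted model (used by the standard-error simulation; restrictions hold by
## construction of the free parameterisation)
free_to_params <- function(model, theta) {
  d <- model$dims
  pm <- params_from_free(theta, model$free_index, d$J, d$R, d$Zz, d$C)
  raw <- centered_to_raw(pm$b, pm$A, pm$D, model$y_center)
  p <- easi_params(b = raw$b, A = raw$A, D = raw$D, G = pm$G, M = pm$M,
                   theta = pm$theta, censor = model$censor,
                   utility = model$utility)
  p$Sigma <- model$Sigma
  p$Sigma_latent <- model$Sigma_latent
  p$latent_shift <- model$latent_shift
  p$y_center <- model$y_center
  p$dims <- model$dims
  class(p) <- c("easi_fit", class(p))  # draws use the fit's design recipe
  p
}

## rebuild the full shifter matrix (z + wave dummies) a fit expects
model_design_z <- function(model, prep) {
  cbind(prep_z(prep), wave_dummies(prep$wave))
}

#' Select the Engel-curve polynomial degree
#'
#' Fits the system for each candidate degree and picks the one minimising
#' the Bayesian information criterion computed on the stacked system
#' residuals, `n J log(RSS / (nJ)) + q log(nJ)` with `q` free parameters.
#'
#' @param prep prepared observations.
#' @param degrees candidate degrees.
#' @param ... passed to [easi_fit()].
#' @return list with `degree` (selected), `criterion` (data.frame of BIC and
#'   RSS per candidate) and `fit` (the refitted winner).
#' @export
select_degree <- function(prep, degrees = 1:5, ...) {
  J <- attr(prep, "J")
  n <- nrow(prep)
  rows <- lapply(degrees, function(d) {
    f <- easi_fit(prep, degree = d, ...)
    rss <- sum(residual_matrix(f, prep)^2)
    q <- length(f$free)
    data.frame(degree = d, rss = rss,
               bic = n * J * log(rss / (n * J)) + q * log(n * J))
  })
  tab <- do.call(rbind, rows)
  sel <- tab$degree[which.min(tab$bic)]
  list(degree = sel, criterion = tab, fit = easi_fit(prep, degree = sel, ...))
}

## in-sample residuals of the (censoring-adjusted) share equations
residual_matrix <- function(model, prep) {
  J <- model$J
  pred <- predict_shares(model, prep_matrix(prep, "lnp"), prep$lnx,
                         z = model_design_z(model, prep), cm = prep_cm(prep),
                         adjust = "censored")
  Wfit <- if (!is.null(pred$w_adj)) pred$w_adj else pred$w
  prep_matrix(prep, "w") - Wfit
}
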