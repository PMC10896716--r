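## Expenditure and price elasticities of the fitted demand system, and their
## mapping into nutrient-intake elasticities.
##
## All derivatives are total derivatives through the implicit-utility fixed
## point.  With the exact-affine utility the envelope result
## dy/dlnp_k = -w_k dy/dlnx makes the Marshallian matrix satisfy Slutsky
## symmetry exactly; the Stone-approximate flavour carries the extra direct
## price terms of its deflator instead.

#' Household-level demand elasticities
#'
#' Computes, at every observation, expenditure elasticities and full
#' (J+1) x (J+1) Marshallian and Hicksian price-elasticity matrices of the
#' demand system (food groups plus numeraire), by analytic differentiation
#' through the implicit-utility fixed point.  The numeraire price column is
#' implied by homogeneity (its log price is the normalisation).
#'
#' @param params an [easi_params] or [easi_fit] object.
#' @param prep a `prepared_observations` table (or supply `ln_p`, `ln_x`,
#'   `z`, `cm` directly).
#' @param ln_p,ln_x,z,cm observation matrices when `prep` is not given.
#' @param demand `"latent"` (default) evaluates the preference-consistent
#'   latent demand, under which all aggregation and symmetry identities are
#'   exact; `"adjusted"` scales derivatives by the participation
#'   probabilities of the censoring model (Slutsky symmetry then holds only
#'   approximately).
#' @param share_floor observations with a predicted share below this are
#'   flagged unstable (`flag` matrix) and excluded from median summaries.
#' @return object of class `elasticity_set`: list with `w` (shares used,
#'   `n x (J+1)`), `eta` (expenditure elasticities, `n x (J+1)`),
#'   `marshallian` and `hicksian` (`n x (J+1) x (J+1)` arrays, `[i, j, k]` =
#'   elasticity of good j with respect to price k), `flag`, `y`, and the
#'   `quartile` labels when `prep` carries them.
#' @export
elasticities <- function(params, prep = NULL, ln_p = NULL, ln_x = NULL,
                         z = NULL, cm = NULL,
                         demand = c("latent", "adjusted"),
                         share_floor = 1e-4) {
  demand <- match.arg(demand)
  quartile <- NULL
  if (!is.null(prep)) {
    stopifnot(inherits(prep, "prepared_observations"))
    ln_p <- prep_matrix(prep, "lnp"); ln_x <- prep$lnx
    z <- if (inherits(params, "easi_fit")) model_design_z(params, prep) else prep_z(prep)
    cm <- if (!is.null(params$M)) prep_cm(prep) else NULL
    quartile <- prep$quartile
  }
  J <- params$J; R <- params$degree
  n <- length(ln_x)
  ln_p <- as.matrix(ln_p)
  adj <- demand == "adjusted" && !is.null(params$censor)
  pred <- predict_shares(params, ln_p, ln_x, z = z, cm = cm,
                         adjust = if (adj) "censored" else "latent")
  W <- pred$w; y <- pred$y
  ## dw_j/dy: polynomial slope plus price interaction
  beta <- matrix(0, n, J)
  if (R >= 1)
    for (r in seq_len(R)) beta <- beta + r * (y^(r - 1L)) %o% params$b[, r + 1L]
  Dlp <- ln_p %*% params$D
  Alp <- ln_p %*% params$A
  wprime <- beta + Dlp
  Sp <- rowSums(wprime * ln_p)
  if (params$utility == "exact") {
    denom <- (1 - 0.5 * rowSums(Dlp * ln_p)) + Sp
    dydp <- -W / denom
  } else {
    denom <- 1 + Sp
    dydp <- -(W + Alp + y * Dlp) / denom
  }
  dWdx <- wprime / denom

  dWdp <- array(0, dim = c(n, J, J))
  for (j in seq_len(J)) for (k in seq_len(J))
    dWdp[, j, k] <- params$A[j, k] + y * params$D[j, k] + wprime[, j] * dydp[, k]

  if (adj) {
    Phi <- pred$Phi
    dWdx <- dWdx * Phi
    for (k in seq_len(J)) dWdp[, , k] <- dWdp[, , k] * Phi
    W <- pred$w_adj
  }
  w_num <- 1 - rowSums(W)
  w_all <- cbind(W, w_num)
  Jp1 <- J + 1L
  dWdx_all <- cbind(dWdx, -rowSums(dWdx))
  eta <- 1 + dWdx_all / w_all

  E <- array(NA_real_, dim = c(n, Jp1, Jp1))
  for (k in seq_len(J)) {
    dnum <- -rowSums(dWdp[, , k, drop = FALSE][, , 1])
    for (j in seq_len(J))
      E[, j, k] <- -(j == k) + dWdp[, j, k] / W[, j]
    E[, Jp1, k] <- dnum / w_num
  }
  ## numeraire price column from homogeneity of degree zero
  for (j in seq_len(Jp1))
    E[, j, Jp1] <- -eta[, j] - rowSums(E[, j, seq_len(J), drop = FALSE][, 1, ])
  H <- E
  for (k in seq_len(Jp1)) H[, , k] <- E[, , k] + eta * w_all[, k]

  flag <- w_all < share_floor
  structure(list(w = w_all, eta = eta, marshallian = E, hicksian = H,
                 y = y, flag = flag, quartile = quartile, demand = demand,
                 J = J), class = "elasticity_set")
}

#' Expenditure elasticities at each observation
#'
#' Convenience wrapper around [elasticities()] returning the `eta` matrix.
#'
#' @inheritParams elasticities
#' @return `n x (J+1)` matrix of expenditure elasticities.
#' @export
expenditure_elasticities <- function(params, prep = NULL, ...) {
  elasticities(params, prep = prep, ...)$eta
}

#' Marshallian and Hicksian price elasticities at each observation
#'
#' @inheritParams elasticities
#' @return list with `marshallian` and `hicksian` arrays.
#' @export
price_elasticities <- function(params, prep = NULL, ...) {
  es <- elasticities(params, prep = prep, ...)
  list(marshallian = es$marshallian, hicksian = es$hicksian)
}

#' Median elasticities by expenditure quartile
#'
#' The package's reporting convention: per expenditure group, the median
#' over household-observations of each elasticity, with unstable cells
#' (below the share floor) excluded.
#'
#' @param es an `elasticity_set` with quartile labels.
#' @return list with `eta` (quartile x good matrix), `own_price` (quartile x
#'   good Marshallian own-price medians) and `marshallian` (quartile x good
#'   x price array).
#' @export
median_elasticity_table <- function(es) {
  stopifnot(inherits(es, "elasticity_set"), !is.null(es$quartile))
  qs <- levels(es$quartile)
  Jp1 <- ncol(es$eta)
  eta <- matrix(NA_real_, length(qs), Jp1, dimnames = list(qs, NULL))
  own <- eta
  Em <- array(NA_real_, dim = c(length(qs), Jp1, Jp1))
  for (qi in seq_along(qs)) {
    rows <- which(es$quartile == qs[qi])
    for (j in seq_len(Jp1)) {
      ok <- rows[!es$flag[rows, j]]
      if (!length(ok)) next
      eta[qi, j] <- med(es$eta[ok, j])
      own[qi, j] <- med(es$marshallian[ok, j, j])
      for (k in seq_len(Jp1)) Em[qi, j, k] <- med(es$marshallian[ok, j, k])
    }
  }
  list(eta = eta, own_price = own, marshallian = Em)
}

#' Draw parameter vectors from the estimated sampling distribution
#'
#' Multivariate normal draws centred at the estimated free parameter vector
#' with its cluster-robust covariance; demand-theory restrictions hold for
#' every draw because the free parameterisation embeds them.  A covariance
#' that is not positive semi-definite is repaired by clipping negative
#' eigenvalues at zero (noted in the result).
#'
#' @param model an [easi_fit].
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return matrix `n_draws x q` of free-parameter draws, with the repair
#'   flag in `attr(, "psd_repaired")`.
#' @export
draw_parameters <- function(model, n_draws, seed = 1L) {
  q <- length(model$free)
  V <- (model$Cov_free + t(model$Cov_free)) / 2
  e <- eigen(V, symmetric = TRUE)
  repaired <- any(e$values < -1e-12 * max(abs(e$values)))
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  with_seed(seed, {
    Zm <- matrix(stats::rnorm(n_draws * q), n_draws, q)
  })
  draws <- sweep(Zm %*% rt, 2, model$free, "+")
  attr(draws, "psd_repaired") <- repaired
  draws
}

#' Simulation-based standard errors for elasticity summaries
#'
#' Re-evaluates the median-by-quartile elasticity tables under parameter
#' draws from the estimated sampling distribution and reports the standard
#' deviation (and quantile bands) across draws, following the parametric
#' simulation approach to inference on nonlinear functionals.
#'
#' @param model an [easi_fit].
#' @param prep prepared observations.
#' @param n_draws number of parameter draws (default 200; increase for
#'   publication-grade bands).
#' @param seed integer seed, recorded in the output.
#' @param subsample number of observations (stratified by quartile) used to
#'   evaluate elasticities per draw; `Inf` uses all.
#' @param demand passed to [elasticities()].
#' @return list with point tables (`eta`, `own_price`), their simulated
#'   standard errors (`eta_se`, `own_price_se`), 95% bands, `n_draws`,
#'   `seed`, and `psd_repaired`.
#' @export
simulate_standard_errors <- function(model, prep, n_draws = 200, seed = 1L,
                                     subsample = 400, demand = "latent") {
  stopifnot(inherits(model, "easi_fit"))
  rows <- seq_len(nrow(prep))
  if (is.finite(subsample) && subsample < nrow(prep)) {
    with_seed(sub_seed(seed, 1L), {
      parts <- split(rows, prep$quartile)
      take <- lapply(parts, function(ix)
        if (length(ix) > 0) sample(ix, min(length(ix), ceiling(subsample / length(parts)))) else ix)
      rows <- sort(unlist(take))
    })
  }
  sub <- prep[rows, ]
  attributes(sub)[c("J", "wbar", "composition", "z_cols", "cm_cols")] <-
    attributes(prep)[c("J", "wbar", "composition", "z_cols", "cm_cols")]
  class(sub) <- class(prep)

  point <- median_elasticity_table(elasticities(model, sub, demand = demand))
  draws <- draw_parameters(model, n_draws, seed = seed)
  eta_d <- array(NA_real_, dim = c(n_draws, dim(point$eta)))
  own_d <- eta_d
  for (d in seq_len(n_draws)) {
    pd <- free_to_params(model, draws[d, ])
    td <- median_elasticity_table(elasticities(pd, sub, demand = demand))
    eta_d[d, , ] <- td$eta
    own_d[d, , ] <- td$own_price
  }
  sdev <- function(a) apply(a, c(2, 3), stats::sd)
  qlo <- function(a) apply(a, c(2, 3), stats::quantile, 0.025, na.rm = TRUE)
  qhi <- function(a) apply(a, c(2, 3), stats::quantile, 0.975, na.rm = TRUE)
  list(eta = point$eta, own_price = point$own_price,
       eta_se = sdev(eta_d), own_price_se = sdev(own_d),
       eta_lo = qlo(eta_d), eta_hi = qhi(eta_d),
       own_price_lo = qlo(own_d), own_price_hi = qhi(own_d),
       n_draws = n_draws, seed = seed, n_obs_used = nrow(sub),
       psd_repaired = attr(draws, "psd_repaired"))
}

#' Nutrient source shares
#'
#' Share of each nutrient's household intake contributed by each food
#' group, `s_nj = q_j c_nj / sum_m q_m c_nm` with quantities in kg and
#' composition per 100 g.
#'
#' @param q `n x J` matrix (or length-J vector) of group quantities, kg.
#' @param composition composition table (`J x nutrients`, per 100 g).
#' @return list with `shares` (`n x J x nutrient` array), `intake`
#'   (`n x nutrient`, in composition units), and `zero_intake` flag matrix
#'   (`TRUE` where total intake of the nutrient is zero and shares are
#'   undefined).
#' @export
nutrient_source_shares <- function(q, composition) {
  if (is.null(dim(q))) q <- matrix(q, 1)
  comp <- unclass(composition)
  J <- nrow(comp)
  stopifnot(ncol(q) == J)
  if (any(q < 0)) stop_ed("negative quantities")
  nn <- colnames(comp)
  contrib <- array(0, dim = c(nrow(q), J, length(nn)),
                   dimnames = list(NULL, NULL, nn))
  for (u in seq_along(nn)) contrib[, , u] <- 10 * q * rep(comp[, u], each = nrow(q))
  intake <- apply(contrib, c(1, 3), sum)
  shares <- contrib / ifelse(array(intake[, rep(seq_along(nn), each = J)],
                                   dim(contrib)) > 0,
                             array(intake[, rep(seq_along(nn), each = J)], dim(contrib)), NA)
  list(shares = shares, intake = intake, zero_intake = intake == 0)
}

#' Nutrient-intake elasticities
#'
#' Weighted sums of food demand elasticities with nutrient source shares:
#' expenditure elasticity of nutrient intake `e_nx = sum_j s_nj eta_j` and
#' price elasticities `e_np[k] = sum_j s_nj eps_jk`.
#'
#' @param s `J`-vector (or `n x J` matrix) of source shares of one nutrient.
#' @param eta expenditure elasticities of the J food groups (vector or
#'   `n x J`).
#' @param E Marshallian matrix `J x J` (or `n x J x J`) over food groups.
#' @return list with `e_x` and `e_p` (length J, or `n x J`).
#' @export
nutrient_elasticities <- function(s, eta, E) {
  if (is.null(dim(s))) {
    stopifnot(length(s) == length(eta))
    e_x <- sum(s * eta)
    e_p <- as.numeric(s %*% E)
    return(list(e_x = e_x, e_p = e_p))
  }
  stopifnot(all(dim(s) == dim(eta)), dim(E)[2] == ncol(s))
  e_x <- rowSums(s * eta)
  J <- ncol(s)
  e_p <- matrix(0, nrow(s), J)
  for (k in seq_len(J)) e_p[, k] <- rowSums(s * E[, , k])
  list(e_x = e_x, e_p = e_p)
}

#' Own- versus cross-price decomposition of a nutrient-price elasticity
#'
#' Splits the elasticity of nutrient intake with respect to the price of
#' food group `k` (typically a staple) into the part flowing through
#' changed intake of group `k` itself (`own = s_nk eps_kk`) and the part
#' flowing through all other foods (`cross = sum_{j != k} s_nj eps_jk`).
#'
#' @param s source-share vector over the J food groups.
#' @param E Marshallian `J x J` matrix over food groups.
#' @param k index of the price whose effect is decomposed.
#' @return list with `own`, `cross` and `total` (their sum).
#' @export
decompose_price_effect <- function(s, E, k) {
  stopifnot(length(s) == nrow(E), k >= 1, k <= nrow(E))
  own <- s[k] * E[k, k]
  cross <- sum(s[-k] * E[-k, k])
  list(own = own, cross = cross, total = own + cross)
}
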