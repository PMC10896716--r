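#' Configuration of the synthetic household-panel generator
#'
#' Defines the study conditions the generator emulates: a multi-wave
#' LSMS-style consumption panel with 7-day recall over `n_groups` food groups
#' plus a non-food numeraire, cluster-by-wave price variation, zero
#' consumption (censoring) of some food groups, and household-level
#' quality/price-search premia that make unit values endogenous.
#'
#' Quantities are weekly kilograms, prices US$ PPP per kg, expenditures
#' weekly US$ PPP; daily values are weekly values divided by 7.
#'
#' @param n_households number of households.
#' @param n_waves number of survey waves (each household observed each wave).
#' @param n_clusters number of enumeration clusters (grouped into strata of
#'   five clusters for the imputation/instrument fall-backs).
#' @param n_groups number of food groups J (the numeraire is group J+1).
#' @param n_items_per_group food items per group.
#' @param poly_degree_true true polynomial degree R of the Engel curves.
#' @param expenditure_lognormal `c(mu, sigma)` of log expenditures per adult
#'   equivalent per day, US$ PPP.  The default centres median spending near
#'   US$2.4/AE/day so the international poverty lines at 1.90/3.20/5.50
#'   partition the sample into populated expenditure groups.
#' @param price_dispersion s.d. of cluster-by-wave log base prices.
#' @param quality_loading coefficient linking log item price to the
#'   household's log-expenditure z-score (quality choice within groups).
#' @param search_loading coefficient linking log item price to the
#'   household's standardised preference error (price search).
#' @param price_noise s.d. of idiosyncratic log item-price noise.
#' @param share_error_scale s.d. scale of the latent budget-share errors;
#'   drives the censoring rate.
#' @param own_production_fraction probability a consumption record is
#'   self-provisioned rather than purchased (plus a small gift share).
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_households = 2000, n_waves = 3, n_clusters = 100,
                         n_groups = 6, n_items_per_group = 3,
                         poly_degree_true = 2,
                         expenditure_lognormal = c(mu = log(2.4), sigma = 0.7),
                         price_dispersion = 0.15,
                         quality_loading = 0.1, search_loading = 0.1,
                         price_noise = 0.05,
                         share_error_scale = 0.05,
                         own_production_fraction = 0.25,
                         seed = 1L) {
  cfg <- list(
    n_households = check_count(n_households, "n_households"),
    n_waves = check_count(n_waves, "n_waves"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    n_groups = check_count(n_groups, "n_groups", min = 2L),
    n_items_per_group = check_count(n_items_per_group, "n_items_per_group"),
    poly_degree_true = check_count(poly_degree_true, "poly_degree_true"),
    expenditure_lognormal = c(mu = unname(expenditure_lognormal[1]),
                              sigma = check_number(unname(expenditure_lognormal[2]),
                                                   "sigma", lower = 0)),
    price_dispersion = check_number(price_dispersion, "price_dispersion", lower = 0),
    quality_loading = check_number(quality_loading, "quality_loading"),
    search_loading = check_number(search_loading, "search_loading"),
    price_noise = check_number(price_noise, "price_noise", lower = 0),
    share_error_scale = check_number(share_error_scale, "share_error_scale", lower = 0),
    own_production_fraction = check_number(own_production_fraction,
                                           "own_production_fraction", 0, 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic panel configuration: %d households x %d waves, ",
                     "%d clusters, %d food groups x %d items, true degree %d, seed %d\n"),
              x$n_households, x$n_waves, x$n_clusters, x$n_groups,
              x$n_items_per_group, x$poly_degree_true, x$seed))
  invisible(x)
}
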