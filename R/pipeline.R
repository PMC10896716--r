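## End-to-end orchestration: simulate -> prepare -> fit -> elasticities ->
## diet quality -> policy simulations, with per-stage outputs, caching and a
## run manifest.

#' Pipeline configuration
#'
#' @param synth a [synth_config] (its `seed` drives every stage unless
#'   `seed` is given here).
#' @param degrees candidate Engel-curve degrees; a single value skips
#'   data-driven selection.
#' @param se_draws parameter draws for elasticity standard errors (0 skips).
#' @param scenarios policy scenarios: `"ct"` and/or price-discount category
#'   codes.
#' @param discount price-discount depth.
#' @param kappa spent fraction of the cash transfer.
#' @param figures write PNG figures alongside the tables?
#' @param seed overrides the synthetic seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), degrees = 2,
                            se_draws = 200,
                            scenarios = c("ct", "SG", "SS", "PN", "FFV", "ASF"),
                            discount = 0.25, kappa = 1,
                            figures = TRUE, seed = NULL) {
  if (!is.null(seed)) synth$seed <- check_count(seed, "seed", min = 0L)
  structure(list(synth = synth, degrees = degrees, se_draws = se_draws,
                 scenarios = scenarios, discount = discount, kappa = kappa,
                 figures = figures),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `synth`
#' block holds [synth_config()] fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) {
    y$synth$expenditure_lognormal <- unlist(y$synth$expenditure_lognormal)
    do.call(synth_config, y$synth)
  } else synth_config()
  do.call(pipeline_config,
          c(list(synth = synth), y[setdiff(names(y), "synth")]))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full demand-to-nutrition pipeline
#'
#' Simulates a panel, prepares observations, fits the censored demand
#' system (with optional degree selection and cached refits), computes
#' elasticity summaries with simulated standard errors, scores baseline
#' diet quality, and runs the configured cash-transfer and price-discount
#' scenarios with cost accounting.  Every output lands under `out_dir` and
#' is listed, with its digest, in `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param refit force refitting even when a cached model with the same
#'   configuration hash exists.
#' @return invisibly, a list with the manifest and all in-memory stage
#'   objects (`panel`, `prep`, `model`, `elasticities`, `se`,
#'   `diet_quality`, `policies`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, refit = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  hash <- config_hash(config)
  stage_log <- list()
  tick <- function(stage, t0) {
    stage_log[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    message(sprintf("[pipeline] %-12s %6.1fs", stage, stage_log[[stage]]))
  }

  t0 <- Sys.time()
  prefs <- generate_preferences(config$synth)
  panel <- generate_panel(config$synth, prefs)
  write_panel(panel, file.path(out_dir, "panel"))
  tick("simulate", t0)

  t0 <- Sys.time()
  prep <- prepare_observations(panel)
  write_prepared(prep, file.path(out_dir, "prepared.csv"))
  tick("prepare", t0)

  t0 <- Sys.time()
  model_dir <- file.path(out_dir, "model")
  hash_file <- file.path(model_dir, "config_hash.txt")
  cached <- !refit && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE)[1], hash)
  if (cached) {
    model <- read_model(model_dir)
    sel_tab <- NULL
  } else {
    if (length(config$degrees) > 1L) {
      sel <- select_degree(prep, degrees = config$degrees)
      model <- sel$fit; sel_tab <- sel$criterion
    } else {
      model <- easi_fit(prep, degree = config$degrees)
      sel_tab <- NULL
    }
    write_model(model, model_dir)
    if (!is.null(sel_tab))
      utils::write.csv(sel_tab, file.path(model_dir, "degree_selection.csv"),
                       row.names = FALSE)
    writeLines(hash, hash_file)
  }
  tick("fit", t0)

  t0 <- Sys.time()
  es <- elasticities(model, prep)
  tab <- median_elasticity_table(es)
  el_dir <- file.path(out_dir, "elasticities")
  dir.create(el_dir, showWarnings = FALSE)
  utils::write.csv(as.data.frame(tab$eta), file.path(el_dir, "eta_median.csv"))
  utils::write.csv(as.data.frame(tab$own_price),
                   file.path(el_dir, "own_price_median.csv"))
  se <- NULL
  if (config$se_draws > 0) {
    se <- simulate_standard_errors(model, prep, n_draws = config$se_draws,
                                   seed = sub_seed(config$synth$seed, 77L))
    utils::write.csv(as.data.frame(se$eta_se), file.path(el_dir, "eta_se.csv"))
    utils::write.csv(as.data.frame(se$own_price_se),
                     file.path(el_dir, "own_price_se.csv"))
  }
  ## nutrient elasticities at quartile medians
  ns <- nutrient_source_shares(prep_matrix(prep, "q"), panel$composition)
  nut_tab <- nutrient_median_table(ns, es)
  utils::write.csv(nut_tab$e_x, file.path(el_dir, "nutrient_expenditure.csv"))
  tick("elasticities", t0)

  t0 <- Sys.time()
  dq <- diet_quality(prep_matrix(prep, "q"), prep$hh, panel$roster,
                     panel$composition)
  dq_dir <- file.path(out_dir, "dietquality")
  dir.create(dq_dir, showWarnings = FALSE)
  utils::write.csv(cbind(wave = prep$wave, quartile = prep$quartile,
                         as.data.frame(dq)),
                   file.path(dq_dir, "baseline.csv"), row.names = FALSE)
  tick("dietquality", t0)

  t0 <- Sys.time()
  pol_dir <- file.path(out_dir, "policy")
  dir.create(pol_dir, showWarnings = FALSE)
  policies <- list()
  cost_rows <- list()
  for (sc in config$scenarios) {
    po <- if (sc == "ct")
      simulate_cash_transfer(model, prep, panel$roster,
                             composition = panel$composition,
                             kappa = config$kappa)
    else
      simulate_price_discount(model, prep, panel$roster, sc,
                              discount = config$discount,
                              composition = panel$composition)
    policies[[sc]] <- po
    utils::write.csv(
      data.frame(quartile = rownames(po$summary$sufficiency_post),
                 round(po$summary$sufficiency_post, 4)),
      file.path(pol_dir, paste0("sufficiency_post_", sc, ".csv")),
      row.names = FALSE)
    cost_rows[[sc]] <- if (sc == "ct")
      data.frame(scenario = "ct", quartile = names(po$summary$mpc_food_median),
                 mpc_food = as.numeric(po$summary$mpc_food_median),
                 monthly_cost = po$ct_monthly)
    else
      data.frame(scenario = sc, quartile = names(po$cost$quartile_median),
                 mpc_food = NA, monthly_cost = as.numeric(po$cost$quartile_median))
    if (config$figures && sc == "ct")
      plot_sufficiency_curve(po, file.path(pol_dir, "sufficiency_curve_ct.png"))
  }
  if (length(policies)) {
    baseline <- data.frame(quartile = rownames(policies[[1]]$summary$sufficiency_pre),
                           round(policies[[1]]$summary$sufficiency_pre, 4))
    utils::write.csv(baseline, file.path(pol_dir, "sufficiency_pre.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, cost_rows),
                     file.path(pol_dir, "costs.csv"), row.names = FALSE)
  }
  tick("policy", t0)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    config_hash = hash,
    seed = config$synth$seed,
    package_version = tryCatch(as.character(utils::packageVersion("easidemand")),
                               error = function(e) "dev"),
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 1),
    stage_seconds = stage_log,
    model_cached = cached,
    files = lapply(stats::setNames(files, sub(paste0("^", out_dir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, panel = panel, prep = prep,
                 model = model, elasticities = tab, se = se,
                 diet_quality = dq, policies = policies))
}

## quartile-median nutrient elasticities (expenditure and per-price)
nutrient_median_table <- function(ns, es) {
  J <- es$J
  nut <- dimnames(ns$shares)[[3]]
  qs <- levels(es$quartile)
  ex <- matrix(NA_real_, length(qs), length(nut), dimnames = list(qs, nut))
  for (u in seq_along(nut)) {
    s_u <- ns$shares[, , u]
    e_obs <- rowSums(s_u * es$eta[, seq_len(J)])
    for (qi in seq_along(qs))
      ex[qi, u] <- med(e_obs[es$quartile == qs[qi]])
  }
  list(e_x = as.data.frame(ex))
}

## Fig-1-style curve: smoothed DE sufficiency vs log expenditures, pre/post
plot_sufficiency_curve <- function(outcome, path) {
  if (!capabilities("png")) return(invisible(NULL))
  sc <- sufficiency_curve(outcome)
  grDevices::png(path, width = 900, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  plot(sc$log_x_ae_day, sc$pre, type = "l", lwd = 2, ylim = c(0, 1),
       xlab = "log expenditures per AE per day (US$ PPP)",
       ylab = "P(dietary energy sufficient)")
  graphics::lines(sc$log_x_ae_day, sc$post, lwd = 2, lty = 2)
  graphics::abline(v = attr(sc, "cutoffs"), col = "grey60", lty = 3)
  graphics::legend("bottomright", c("baseline", "post-transfer"),
                   lwd = 2, lty = c(1, 2), bty = "n")
  invisible(path)
}
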