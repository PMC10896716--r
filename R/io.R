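## CSV/JSON persistence for panels, prepared tables and fitted models.

#' Write a household panel to CSV
#'
#' Writes `households.csv`, `roster.csv`, `records.csv`, `composition.csv`,
#' `config.yaml` and a column data dictionary to a directory.  The ground
#' truth slot of synthetic panels is not serialised; round-tripping through
#' CSV mimics ingesting a real survey extract.
#'
#' @param panel a `household_panel`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- as.data.frame(unclass(panel$composition))
  comp <- cbind(group = seq_len(nrow(comp)),
                archetype = attr(panel$composition, "archetype") %||% NA, comp)
  files <- c(households = "households.csv", roster = "roster.csv",
             records = "records.csv", composition = "composition.csv")
  utils::write.csv(panel$households, file.path(dir, files["households"]), row.names = FALSE)
  utils::write.csv(panel$roster, file.path(dir, files["roster"]), row.names = FALSE)
  utils::write.csv(panel$records, file.path(dir, files["records"]), row.names = FALSE)
  utils::write.csv(comp, file.path(dir, files["composition"]), row.names = FALSE)
  yaml::write_yaml(unclass(panel$config), file.path(dir, "config.yaml"))
  writeLines(panel_dictionary(), file.path(dir, "data_dictionary.md"))
  invisible(file.path(dir, c(files, "config.yaml", "data_dictionary.md")))
}

panel_dictionary <- function() c(
  "# Data dictionary",
  "",
  "## households.csv (one row per household-wave)",
  "- hh: household id; wave: survey wave; cluster: enumeration cluster;",
  "  stratum: group of clusters; urban: 0/1; weight: sampling weight;",
  "  nonfood_value: weekly non-food expenditures, US$ PPP.",
  "",
  "## roster.csv (one row per member)",
  "- hh, member, age (years), female (0/1).",
  "",
  "## records.csv (one row per consumed item per household-wave)",
  "- hh, wave, group (food group id), item (item id), quantity (kg/week),",
  "  value (US$ PPP/week), source (purchase | own | gift).",
  "",
  "## composition.csv",
  "- group, archetype, nutrient contents per 100 g (column units in names)."
)

#' Read a household panel from CSV
#'
#' @param dir directory written by [write_panel()].
#' @return a `household_panel` (without the synthetic ground-truth slot).
#' @export
read_panel <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  comp_df <- rd("composition.csv")
  arch <- comp_df$archetype
  comp <- as.matrix(comp_df[, setdiff(names(comp_df), c("group", "archetype"))])
  rownames(comp) <- paste0("g", comp_df$group)
  attr(comp, "archetype") <- arch
  class(comp) <- c("composition_table", class(comp))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$expenditure_lognormal <- unlist(cfg$expenditure_lognormal)
  cfg <- do.call(synth_config, cfg)
  structure(list(households = rd("households.csv"), roster = rd("roster.csv"),
                 records = rd("records.csv"), composition = comp,
                 config = cfg, truth = NULL),
            class = "household_panel")
}

#' Write / read a prepared-observations table
#'
#' The table goes to CSV with its estimation metadata (group count, average
#' shares, column roles) in a JSON sidecar.
#'
#' @param prep a `prepared_observations` table.
#' @param path CSV path; the sidecar is `<path>.meta.json`.
#' @return invisibly, `path`.
#' @export
write_prepared <- function(prep, path) {
  utils::write.csv(as.data.frame(prep), path, row.names = FALSE)
  meta <- list(J = attr(prep, "J"), wbar = as.list(attr(prep, "wbar")),
               z_cols = attr(prep, "z_cols"), cm_cols = attr(prep, "cm_cols"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_prepared
#' @export
read_prepared <- function(path) {
  out <- utils::read.csv(path)
  out$quartile <- factor(out$quartile, levels = quartile_scheme()$labels)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  attr(out, "J") <- meta$J
  attr(out, "wbar") <- unlist(meta$wbar)
  attr(out, "z_cols") <- meta$z_cols
  attr(out, "cm_cols") <- meta$cm_cols
  class(out) <- c("prepared_observations", class(out))
  out
}

#' Write / read a fitted demand system
#'
#' Parameters, censoring stage, residual covariances and fit report go to a
#' structured JSON file; the free-parameter covariance goes to CSV.
#'
#' @param model an [easi_fit].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    b = model$b, A = model$A, D = model$D, G = model$G, M = model$M,
    theta = model$theta, Sigma = model$Sigma,
    Sigma_latent = model$Sigma_latent, latent_shift = model$latent_shift,
    free = model$free, y_center = model$y_center, dims = model$dims,
    wbar = as.list(model$wbar), z_cols = model$z_cols, cm_cols = model$cm_cols,
    utility = model$utility, degree = model$degree, groups = model$groups,
    free_index = lapply(model$free_index, function(x) {
      if (is.matrix(x)) list(dim = dim(x), values = as.integer(x)) else
        list(dim = NULL, values = as.integer(x))
    }),
    censor = if (!is.null(model$censor)) list(
      coef = model$censor$coef, censored = model$censor$censored,
      degree = model$censor$degree, y_center = model$censor$y_center,
      notes = model$censor$notes) else NULL,
    report = model$report[c("iterations", "censor_rates", "use_iv",
                            "censor", "degree", "n", "n_households")]
  )
  jsonlite::write_json(js, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  utils::write.csv(model$Cov_free, file.path(dir, "covariance.csv"),
                   row.names = FALSE)
  if (!is.null(model$report$first_stage))
    utils::write.csv(model$report$first_stage,
                     file.path(dir, "first_stage.csv"), row.names = FALSE)
  ## exact binary copy so cached refits reproduce downstream results
  ## bit-identically (JSON/CSV round-trips lose the last float digit)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  rds <- file.path(dir, "model.rds")
  if (file.exists(rds)) return(readRDS(rds))
  js <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  mat <- function(x) if (is.null(x)) NULL else as.matrix(x)
  cens <- NULL
  if (!is.null(js$censor)) {
    coefs <- lapply(js$censor$coef, function(cf) if (length(cf)) unlist(cf) else NULL)
    cens <- list(coef = coefs, censored = js$censor$censored,
                 degree = js$censor$degree, y_center = js$censor$y_center,
                 notes = js$censor$notes)
  }
  fit <- easi_params(b = mat(js$b), A = mat(js$A), D = mat(js$D),
                     G = mat(js$G), M = mat(js$M), theta = js$theta,
                     censor = cens, Sigma = mat(js$Sigma),
                     utility = js$utility, groups = js$groups)
  fit$Sigma_latent <- mat(js$Sigma_latent)
  fit$latent_shift <- js$latent_shift
  fit$free <- js$free
  fit$y_center <- js$y_center
  fit$dims <- js$dims
  fit$wbar <- unlist(js$wbar)
  fit$z_cols <- js$z_cols
  fit$cm_cols <- js$cm_cols
  fit$free_index <- lapply(js$free_index, function(x) {
    v <- as.integer(x$values)
    if (!is.null(x$dim) && length(x$dim)) array(v, dim = unlist(x$dim)) else v
  })
  fit$Cov_free <- as.matrix(utils::read.csv(file.path(dir, "covariance.csv")))
  dimnames(fit$Cov_free) <- NULL
  fit$report <- as.list(js$report)
  class(fit) <- c("easi_fit", class(fit))
  fit
}
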