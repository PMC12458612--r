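#' Default run configuration
#'
#' The configuration document is hierarchical: one section per pipeline
#' stage (`simulate`, `select`, `architecture`, `train`, `explain`,
#' `correlate`). [load_config()] fills every omitted key from these
#' defaults and rejects keys it does not know, so a run's resolved
#' configuration is always complete and explicit.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  sim <- unclass(simulation_params())
  sim$noise_sd <- as.list(sim$noise_sd)   # YAML mapping keeps the names
  list(
    config_version = 1L,
    simulate = sim,
    select = unclass(qc_thresholds()),
    architecture = unclass(architecture_config()),
    train = unclass(train_config()),
    explain = list(
      reference = "train_mean",   # or "zeros"
      top_k = 10L
    ),
    correlate = list(
      alpha = 0.05,
      adjust = "BH",
      flag_on = "raw"             # mirror reporting on raw p; or "adjusted"
    )
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration document, merges it over
#' [default_config()], validates ranges, and rejects unknown keys. The
#' fully resolved configuration is echoed to the log via `message()` as a
#' one-line JSON document.
#'
#' @param path file path to a YAML/JSON config, or `NULL` for pure defaults.
#' @param quiet suppress the resolved-config echo.
#' @return The resolved configuration list (class `hinn_config`).
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  defaults <- default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(user)) stop("config document must be a key-value mapping")
  cfg <- merge_config(defaults, user, path = "")
  validate_config(cfg)
  if (!quiet)
    message("resolved config: ",
            jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  structure(cfg, class = c("hinn_config", "list"))
}

merge_config <- function(def, usr, path) {
  unknown <- setdiff(names(usr), names(def))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(usr)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      if (!is.list(usr[[k]]))
        stop("config key ", sub("^\\.", "", paste0(path, ".", k)),
             " must be a mapping")
      def[[k]] <- merge_config(def[[k]], usr[[k]], paste0(path, ".", k))
    } else {
      def[[k]] <- usr[[k]]
    }
  }
  def
}

validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  a <- cfg$architecture
  chk(a$dropout >= 0 && a$dropout < 1, "architecture.dropout")
  chk(a$bypass_width >= 1, "architecture.bypass_width")
  chk(a$denominator_epsilon > 0, "architecture.denominator_epsilon")
  s <- cfg$select
  chk(s$min_maf > 0 && s$min_maf < 1, "select.min_maf")
  chk(s$max_missing_rate > 0 && s$max_missing_rate < 1,
      "select.max_missing_rate")
  chk(s$hwe_alpha > 0 && s$hwe_alpha < 1, "select.hwe_alpha")
  chk(s$gwas_adjusted_alpha > 0 && s$gwas_adjusted_alpha <= 1,
      "select.gwas_adjusted_alpha")
  chk(s$window_bp > 0, "select.window_bp")
  chk(s$enrichment_alpha > 0 && s$enrichment_alpha <= 1,
      "select.enrichment_alpha")
  t <- cfg$train
  chk(t$test_fraction > 0 && t$test_fraction < 1, "train.test_fraction")
  chk(t$validation_fraction > 0 && t$validation_fraction < 1,
      "train.validation_fraction")
  chk(t$n_repeats >= 1, "train.n_repeats")
  sim <- cfg$simulate
  chk(sim$score_heritability >= 0 && sim$score_heritability <= 1,
      "simulate.score_heritability")
  chk(all(sim$maf_range > 0) && all(sim$maf_range <= 0.5),
      "simulate.maf_range")
  chk(cfg$explain$top_k >= 1, "explain.top_k")
  chk(cfg$correlate$alpha > 0 && cfg$correlate$alpha <= 1, "correlate.alpha")
  if (length(bad))
    stop("config values out of range: ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Write a configuration document
#'
#' @param cfg configuration list (as from [load_config()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_deep)
  x
}
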