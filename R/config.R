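#' Pipeline configuration
#'
#' Bundles every tunable of the ranking / IFS / selection / rule stages.
#' All randomness in a run flows from `seed` through [derive_seed()], so two
#' runs with an equal config are identical.
#'
#' @param top_n number of top-ranked genes swept by IFS (default 200).
#' @param step IFS prefix spacing (default 5).
#' @param cv_folds cross-validation folds (default 10).
#' @param rankers subset of [ranker_names()] to run (default all eight).
#' @param classifiers subset of c("DT", "RF") (default both).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param relative_delta tolerated weighted-F1 drop for relatively high
#'   points (default 0.015).
#' @param relative_k_threshold minimum max-point size before a relatively
#'   high point is sought (default 100).
#' @param selection_classifier classifier whose curves define essential
#'   subsets (default "RF").
#' @param seed integer master seed (default 1).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(top_n = 200L, step = 5L, cv_folds = 10L,
                            rankers = ranker_names(),
                            classifiers = c("DT", "RF"),
                            smote_k = 5L, relative_delta = 0.015,
                            relative_k_threshold = 100L,
                            selection_classifier = "RF", seed = 1L) {
  cfg <- structure(list(
    top_n = as.integer(top_n), step = as.integer(step),
    cv_folds = as.integer(cv_folds),
    rankers = as.character(rankers), classifiers = as.character(classifiers),
    smote_k = as.integer(smote_k), relative_delta = relative_delta,
    relative_k_threshold = as.integer(relative_k_threshold),
    selection_classifier = selection_classifier, seed = as.integer(seed),
    schema_version = 1L
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$top_n < 1L || cfg$step < 1L) stop("top_n and step must be positive")
  if (cfg$step > cfg$top_n) stop("step must not exceed top_n")
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2")
  if (cfg$smote_k < 1L) stop("smote_k must be >= 1")
  if (cfg$relative_delta < 0 || cfg$relative_delta >= 1) {
    stop("relative_delta must lie in [0, 1)")
  }
  bad <- setdiff(cfg$rankers, ranker_names())
  if (length(bad)) stop("unknown ranker(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$classifiers, c("DT", "RF"))
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  if (!cfg$selection_classifier %in% cfg$classifiers) {
    stop("selection_classifier must be one of the configured classifiers")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unset fields take their [pipeline_config()] defaults; `overrides` (e.g.
#' parsed command-line values) take precedence over the file.
#'
#' @param path YAML file path.
#' @param overrides named list of field overrides.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(vals$schema_version) && vals$schema_version != 1L) {
    stop("unsupported config schema_version: ", vals$schema_version)
  }
  vals$schema_version <- NULL
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
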