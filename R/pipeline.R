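# Configuration, orchestration and result serialization for the full
# multistage analysis.

#' Pipeline configuration
#'
#' Collects every stage's configuration with desk-scale defaults. Stage
#' seeds are derived from the master seed by fixed offsets so that any stage
#' can be rerun in isolation and toggling one stage never changes another's
#' random stream.
#'
#' @param sim A [sim_config()] (the synthetic-cohort stage).
#' @param cohort_type `"profile"` (fast path, default) or `"timeseries"`
#'   (full spectral + coupling estimation).
#' @param k Components per (mode, frequency).
#' @param bag_size,n_draw,n_perm,percentile,q,classifier,cv,lambda Selection
#'   stage, see [fcbag()].
#' @param nested_n_draw,nested_n_perm Reduced scales used inside each nested
#'   cross-validation fold.
#' @param run_connstats,run_confidence,run_nested Stage toggles.
#' @param split_hz Frequency split for band summaries and mode/frequency
#'   restricted accuracies.
#' @param seed Master seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), cohort_type = c("profile",
                                                                "timeseries"),
                            k = 30, bag_size = 10, n_draw = 2e4, n_perm = 200,
                            percentile = 75, q = 0.05, classifier = "ridge",
                            cv = "loo", lambda = 1, nested_n_draw = 2000,
                            nested_n_perm = 50, run_connstats = TRUE,
                            run_confidence = TRUE, run_nested = FALSE,
                            split_hz = 35, seed = 1) {
  cohort_type <- match.arg(cohort_type)
  structure(list(sim = sim, cohort_type = cohort_type, k = k,
                 bag_size = bag_size, n_draw = n_draw, n_perm = n_perm,
                 percentile = percentile, q = q, classifier = classifier,
                 cv = cv, lambda = lambda, nested_n_draw = nested_n_draw,
                 nested_n_perm = nested_n_perm,
                 run_connstats = run_connstats,
                 run_confidence = run_confidence, run_nested = run_nested,
                 split_hz = split_hz, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the defaults of [pipeline_config()] /
#' [sim_config()]; matrix-valued simulation fields must be set
#' programmatically.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$planted_effect)) {
    sim_args$planted_effect <- as.data.frame(sim_args$planted_effect)
  }
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), y))
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)) %%
            .Machine$integer.max)
}

#' Run the complete multistage pipeline
#'
#' Executes simulate -> (spectral -> coupling) -> connection statistics ->
#' component reduction -> feature-bagged selection -> confidence/accuracy in
#' order, honoring the stage toggles, and optionally writes all result
#' tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, result tables are written
#'   via [write_run()].
#' @return A `"coupling_run"` list: `cohort`, `tests`, `asymmetry`,
#'   `features`, `fit` (the [fcbag()] object), `bands`, `confidence`,
#'   `severity`, `accuracy`, `record` (config snapshot, package version,
#'   stage wall-times, warnings).
#' @export
run_coupling_pipeline <- function(config = pipeline_config(),
                                  out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  times <- c()
  warns <- character(0)
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  tick <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    times[nm] <<- t1 - t0
    t0 <<- t1
  }

  sim <- config$sim
  sim$seed <- config$seed
  cohort <- if (config$cohort_type == "profile") {
    simulate_profile_cohort(sim)
  } else {
    coupling_profiles(simulate_timeseries_cohort(sim))
  }
  tick("simulate")

  man <- cohort$manifest
  is_pat <- man$group == "patient"
  is_con <- man$group == "control"

  tests <- NULL
  asym <- NULL
  if (config$run_connstats) {
    tests <- list()
    for (m in names(cohort$profiles)) {
      tests[[m]] <- lapply(names(cohort$profiles[[m]]), function(fl) {
        P <- cohort$profiles[[m]][[fl]]
        connection_tests(P[is_pat, , drop = FALSE],
                         P[is_con, , drop = FALSE],
                         mode = m, frequency = as.numeric(sub("^f", "", fl)))
      })
    }
    asym <- do.call(rbind, lapply(tests, sign_asymmetry))
    tick("connstats")
  }

  features <- wcollect(build_feature_matrix(cohort, k = config$k))
  tick("components")

  set.seed(config$seed + 1000L)
  fit <- wcollect(fcbag(features, attr(features, "labels"),
                        bag_size = config$bag_size, n_draw = config$n_draw,
                        n_perm = config$n_perm,
                        percentile = config$percentile, q = config$q,
                        classifier = config$classifier, cv = config$cv,
                        lambda = config$lambda))
  tick("selection")

  aligned <- align_component_signs(features)
  bands <- if (any(fit$selection$significant)) {
    band_average_components(aligned, fit$selection$significant,
                            split_hz = config$split_hz)
  } else {
    NULL
  }

  confidence <- NULL
  severity <- NULL
  if (config$run_confidence) {
    sig_cols <- which(fit$selection$significant)
    if (length(sig_cols) == 0) {
      sig_cols <- order(fit$selection$score,
                        decreasing = TRUE)[seq_len(config$bag_size)]
    }
    confidence <- wcollect(
      mahalanobis_confidence(unclass(features)[, sig_cols, drop = FALSE],
                             attr(features, "labels")))
    sev <- man[is_pat, c("edss_like", "msfc_like")]
    if (any(is.finite(sev$edss_like)) || any(is.finite(sev$msfc_like))) {
      severity <- wcollect(severity_correlation(confidence, sev))
    }
    tick("confidence")
  }

  accuracy <- NULL
  if (config$run_nested) {
    accuracy <- nested_loo_accuracy(
      features, attr(features, "labels"), bag_size = config$bag_size,
      n_draw = config$nested_n_draw, n_perm = config$nested_n_perm,
      percentile = config$percentile, q = config$q,
      classifier = config$classifier, cv = config$cv,
      lambda = config$lambda, seed = config$seed + 2000L)
    tick("accuracy")
  }

  run <- structure(list(
    cohort = cohort, tests = tests, asymmetry = asym, features = features,
    fit = fit, bands = bands, confidence = confidence, severity = severity,
    accuracy = accuracy,
    record = list(config = config, hash = config_hash(config),
                  version = as.character(utils::packageVersion("fcbag")),
                  times = times, warnings = warns)
  ), class = "coupling_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.coupling_run <- function(x, ...) {
  cat("<coupling_run>\n")
  print(x$fit)
  if (!is.null(x$accuracy)) print(x$accuracy)
  invisible(x)
}
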