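#' Configuration of a full verification experiment
#'
#' Bundles the cohort definition and the experiment grid: which band
#' sets, hidden-neuron counts and train/test scenarios to run, how many
#' training restarts per network, and the master seed from which every
#' other seed is derived.
#'
#' Two profiles are provided. `"desk"` (the default) is a reduced grid
#' that runs on a laptop in minutes: 8 subjects x 8 sessions, 6
#' external impostors, one hidden neuron, 3 restarts, and the five
#' single bands plus the all-band set. `"full"` is the complete study
#' grid: 29 subjects x 20 sessions, 23 external impostors, all 10 band
#' sets, 1--10 hidden neurons, 10 restarts.
#'
#' @param profile `"desk"` or `"full"`.
#' @param cohort a [cohort_config()]; overrides the profile cohort.
#' @param band_sets named list of band-name vectors (see
#'   [canonical_band_sets()]).
#' @param n_hidden integer vector of hidden-neuron counts.
#' @param scenarios subset of `c(1, 2)`.
#' @param n_restarts training restarts per network.
#' @param seed master seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "full"),
                              cohort = NULL, band_sets = NULL,
                              n_hidden = NULL, scenarios = c(1, 2),
                              n_restarts = NULL, seed = 1) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") {
    list(cohort = cohort_config(n_subjects = 8, n_sessions = 8,
                                n_external = 6, seed = seed),
         band_sets = canonical_band_sets()[c("delta", "theta", "alpha",
                                             "beta", "gamma", "all")],
         n_hidden = 1L, n_restarts = 3L)
  } else {
    list(cohort = cohort_config(seed = seed),
         band_sets = canonical_band_sets(),
         n_hidden = 1:10, n_restarts = 10L)
  }
  cfg <- list(
    profile = profile,
    cohort = if (is.null(cohort)) defaults$cohort else cohort,
    band_sets = if (is.null(band_sets)) defaults$band_sets else band_sets,
    n_hidden = if (is.null(n_hidden)) defaults$n_hidden else n_hidden,
    scenarios = scenarios,
    n_restarts = if (is.null(n_restarts)) defaults$n_restarts else
      n_restarts,
    seed = as.integer(seed)
  )
  bad <- setdiff(unlist(cfg$band_sets), eeg_bands()$name)
  if (length(bad) > 0) stop("unknown bands in band_sets: ",
                            paste(bad, collapse = ", "))
  structure(cfg, class = "experiment_config")
}

# Build the split plans of every (scenario, subject) pair once; they do
# not depend on band set or hidden-neuron count.
build_plans <- function(prov, scenarios, seed) {
  genuine <- prov[prov$role == "genuine", ]
  subjects <- unique(genuine$subject_id)
  plans <- list()
  for (sc in scenarios) {
    for (s in subjects) {
      mine <- genuine[genuine$subject_id == s,
                      c("subject_id", "session_id", "segment_index")]
      pool <- genuine[genuine$subject_id != s,
                      c("subject_id", "session_id", "segment_index")]
      plans[[paste(sc, s, sep = "|")]] <- if (sc == 1) {
        scenario1_folds(mine, pool, derive_seed(seed, "plan", sc, s))
      } else {
        scenario2_folds(mine, pool, derive_seed(seed, "plan", sc, s))
      }
    }
  }
  plans
}

plan_matrix <- function(ft, refs, cols) {
  ft$features[prov_key(refs$subject_id, refs$session_id,
                       refs$segment_index), cols, drop = FALSE]
}

#' Run a verification experiment end to end
#'
#' Simulates the cohort, extracts features, builds the split plans of
#' both scenarios, trains one best-of-n network per (scenario, band
#' set, hidden-neuron count, subject, fold), evaluates confusion counts
#' and metrics, and runs the external-impostor attack against the
#' fold-0 model bank of every grid cell. Fully deterministic given the
#' config (all sub-seeds are derived from the master seed and the grid
#' coordinates, so any subset of the grid can be recomputed
#' independently).
#'
#' @param config an [experiment_config()].
#' @param feature_table optionally, a precomputed [cohort_features()]
#'   table for this config's cohort (skips simulation + extraction).
#' @param verbose log per-stage progress to stderr.
#' @return List of class `experiment_result`:
#'   \describe{
#'     \item{`metrics`}{data.frame, one row per (scenario, band_set,
#'       n_hidden, subject, fold) with TP/FN/TN/FP and
#'       ACC/SEN/SPEC/PREC.}
#'     \item{`attack`}{data.frame, one row per (scenario, band_set,
#'       n_hidden) with attempts, successes and success percentage
#'       (NULL when the cohort has no external impostors).}
#'     \item{`manifest`}{config, package version and cohort manifest —
#'       enough to replay the run exactly.}
#'   }
#' @export
run_experiment <- function(config = experiment_config(),
                           feature_table = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  cohort <- make_cohort(config$cohort)
  if (is.null(feature_table)) {
    say("extracting features for %d recordings ...", nrow(cohort$manifest))
    feature_table <- cohort_features(cohort, verbose = verbose)
  }
  ft <- feature_table
  prov <- ft$provenance
  say("features ready (%.1f s)", as.numeric(Sys.time() - t0, units = "secs"))

  plans <- build_plans(prov, config$scenarios, config$seed)
  subjects <- unique(prov$subject_id[prov$role == "genuine"])
  ext_idx <- prov$role == "external"

  metrics_rows <- list()
  attack_rows <- list()
  for (sc in config$scenarios) {
    for (bi in seq_along(config$band_sets)) {
      bs_name <- names(config$band_sets)[bi]
      cols <- band_set_columns(config$band_sets[[bi]], ft$montage)
      for (h in config$n_hidden) {
        bank <- list()
        for (s in subjects) {
          folds <- plans[[paste(sc, s, sep = "|")]]
          for (p in folds) {
            Xtr <- rbind(plan_matrix(ft, p$genuine_train, cols),
                         plan_matrix(ft, p$impostor_train, cols))
            ytr <- rep(c("genuine", "impostor"),
                       c(nrow(p$genuine_train), nrow(p$impostor_train)))
            model <- train_best_of(
              Xtr, ytr, n_hidden = h, n_restarts = config$n_restarts,
              seed = derive_seed(config$seed, "train", sc, bs_name, h, s,
                                 p$fold_index))
            cts <- confusion(model,
                             plan_matrix(ft, p$genuine_test, cols),
                             plan_matrix(ft, p$impostor_test, cols))
            met <- verification_metrics(cts)
            metrics_rows[[length(metrics_rows) + 1]] <- data.frame(
              scenario = sc, band_set = bs_name, n_hidden = h,
              subject = s, fold = p$fold_index,
              TP = cts[["TP"]], FN = cts[["FN"]],
              TN = cts[["TN"]], FP = cts[["FP"]],
              ACC = met[["ACC"]], SEN = met[["SEN"]],
              SPEC = met[["SPEC"]], PREC = met[["PREC"]],
              stringsAsFactors = FALSE
            )
            if (p$fold_index == 0L) bank[[s]] <- model
          }
        }
        if (any(ext_idx)) {
          rep_ <- external_attack(
            bank, ft$features[ext_idx, cols, drop = FALSE],
            prov[ext_idx, , drop = FALSE],
            plans = unlist(lapply(subjects, function(s) {
              plans[paste(sc, s, sep = "|")]
            }), recursive = FALSE))
          attack_rows[[length(attack_rows) + 1]] <- data.frame(
            scenario = sc, band_set = bs_name, n_hidden = h,
            attempts = rep_$total$attempts,
            successes = rep_$total$successes,
            success_pct = rep_$total$success_pct,
            attempts_per_model = rep_$per_model$attempts[1],
            stringsAsFactors = FALSE
          )
        }
        say("scenario %d, band set %s, h=%d done (%.1f s)", sc, bs_name,
            h, as.numeric(Sys.time() - t0, units = "secs"))
      }
    }
  }

  structure(list(
    metrics = do.call(rbind, metrics_rows),
    attack = if (length(attack_rows) > 0) do.call(rbind, attack_rows),
    manifest = list(config = config,
                    package_version =
                      as.character(utils::packageVersion("eegverify")),
                    cohort_manifest = cohort$manifest)
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<experiment_result> %d metric rows (%d scenarios x %d band sets x %d hidden x %d subjects x folds)\n",
    nrow(m), length(unique(m$scenario)), length(unique(m$band_set)),
    length(unique(m$n_hidden)), length(unique(m$subject))))
  invisible(x)
}

#' Aggregate experiment metrics to the reporting level
#'
#' Fold-level metrics are averaged per subject (undefined precision
#' cells dropped), then summarized as mean and standard deviation over
#' subjects — the reporting unit of the study tables.
#'
#' @param result an `experiment_result` (or its `metrics` data.frame).
#' @return data.frame with one row per (scenario, band_set, n_hidden)
#'   and columns `<metric>_mean`, `<metric>_sd`.
#' @export
aggregate_metrics <- function(result) {
  m <- if (inherits(result, "experiment_result")) result$metrics else result
  sm <- subject_means(m, by = c("subject", "scenario", "band_set",
                                "n_hidden"))
  agg_mean <- stats::aggregate(
    sm[c("ACC", "SEN", "SPEC", "PREC")],
    sm[c("scenario", "band_set", "n_hidden")], mean)
  agg_sd <- stats::aggregate(
    sm[c("ACC", "SEN", "SPEC", "PREC")],
    sm[c("scenario", "band_set", "n_hidden")], stats::sd)
  names(agg_mean)[4:7] <- paste0(c("ACC", "SEN", "SPEC", "PREC"), "_mean")
  names(agg_sd)[4:7] <- paste0(c("ACC", "SEN", "SPEC", "PREC"), "_sd")
  merge(agg_mean, agg_sd,
        by = c("scenario", "band_set", "n_hidden"), sort = TRUE)
}
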