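# Verification metrics, the external-impostor attack, and the
# statistical comparisons of the experiment grid.

#' Confusion counts of a verifier on labelled test sets
#'
#' Applies the model to genuine and impostor test vectors and tallies
#' the four outcomes: TP (genuine recognized as genuine), FN (genuine
#' rejected), TN (impostor rejected), FP (impostor accepted).
#'
#' @param model a `verifier_model`.
#' @param genuine_test,impostor_test numeric matrices of raw feature
#'   vectors (nonempty).
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @export
confusion <- function(model, genuine_test, impostor_test) {
  if (NROW(genuine_test) == 0 || NROW(impostor_test) == 0) {
    stop("confusion() requires nonempty genuine and impostor test sets")
  }
  pg <- predict(model, genuine_test)$label
  pi_ <- predict(model, impostor_test)$label
  c(TP = sum(pg == "genuine"), FN = sum(pg == "impostor"),
    TN = sum(pi_ == "impostor"), FP = sum(pi_ == "genuine"))
}

#' Verification metrics from confusion counts
#'
#' The four classification measures of a verification system:
#' \deqn{ACC = (TP + TN) / (TP + FN + FP + TN)}
#' \deqn{SEN = TP / (TP + FN)}   (ability to detect the genuine person)
#' \deqn{SPEC = TN / (FP + TN)}  (ability to detect an impostor)
#' \deqn{PREC = TP / (TP + FP)}
#' PREC is undefined (returned as `NA`) when no vector was accepted as
#' genuine; such cells are excluded from aggregation rather than set to
#' zero, since sensitivity already captures the degenerate fold.
#'
#' @param counts named vector with elements `TP`, `FN`, `TN`, `FP`
#'   (e.g. from [confusion()]).
#' @return Named numeric vector `c(ACC, SEN, SPEC, PREC)`.
#' @export
verification_metrics <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be nonnegative")
  if (tp + fn == 0) stop("no genuine test vectors (TP + FN = 0)")
  if (tn + fp == 0) stop("no impostor test vectors (TN + FP = 0)")
  c(ACC = (tp + tn) / (tp + fn + fp + tn),
    SEN = tp / (tp + fn),
    SPEC = tn / (fp + tn),
    PREC = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' External impostor attack
#'
#' Presents every feature vector of the external impostors — subjects
#' whose recordings appear in no training or testing split — to every
#' trained verifier. An attack attempt succeeds when the model labels
#' the foreign vector genuine. With the full study design (23 external
#' impostors x 24 segments, 29 verifiers) this is 552 attempts per
#' model and 16,008 in total.
#'
#' @param models named list of `verifier_model`s, one per verified
#'   subject.
#' @param external_features matrix of external-impostor feature vectors
#'   (columns already restricted to the models' band set).
#' @param external_prov provenance data.frame aligned with
#'   `external_features` rows.
#' @param plans optional list of `split_plan`s used to train/test the
#'   models; if given, any external subject found in any plan aborts
#'   (contamination guard).
#' @return List of class `attack_report`: `per_model` data.frame
#'   (`subject`, `attempts`, `successes`, `success_pct`) and `total`
#'   (`attempts`, `successes`, `success_pct`).
#' @export
external_attack <- function(models, external_features, external_prov,
                            plans = NULL) {
  ext_subjects <- unique(external_prov$subject_id)
  if (!is.null(plans)) {
    seen <- unique(unlist(lapply(plans, function(p) {
      c(p$genuine_train$subject_id, p$genuine_test$subject_id,
        p$impostor_train$subject_id, p$impostor_test$subject_id)
    })))
    bad <- intersect(ext_subjects, seen)
    if (length(bad) > 0) {
      stop("external impostor(s) contaminate the train/test splits: ",
           paste(bad, collapse = ", "))
    }
  }
  per_model <- do.call(rbind, lapply(names(models), function(nm) {
    lab <- predict(models[[nm]], external_features)$label
    data.frame(subject = nm, attempts = length(lab),
               successes = sum(lab == "genuine"),
               stringsAsFactors = FALSE)
  }))
  per_model$success_pct <- 100 * per_model$successes / per_model$attempts
  structure(list(
    per_model = per_model,
    total = data.frame(attempts = sum(per_model$attempts),
                       successes = sum(per_model$successes),
                       success_pct = 100 * sum(per_model$successes) /
                         sum(per_model$attempts))
  ), class = "attack_report")
}

#' @export
print.attack_report <- function(x, ...) {
  cat(sprintf("<attack_report> %d models, %d attempts, %.2f%% successful\n",
              nrow(x$per_model), x$total$attempts, x$total$success_pct))
  invisible(x)
}

# Aggregate a long metrics table (one row per subject x fold with ACC,
# SEN, SPEC, PREC columns) to subject-level means; NA cells (undefined
# precision) are dropped from the fold average.
subject_means <- function(metrics_df, by = c("subject")) {
  vars <- c("ACC", "SEN", "SPEC", "PREC")
  stats::aggregate(metrics_df[vars], metrics_df[by],
                   function(v) mean(v, na.rm = TRUE))
}

#' Compare the two scenarios per band set and metric
#'
#' One-way fixed-effects ANOVA between scenarios for each (band set,
#' metric) pair, on subject-level values (each subject's metric averaged
#' over folds), i.e. with 1 and `2 n - 2` degrees of freedom for `n`
#' subjects per scenario.
#'
#' @param metrics_df long metrics data.frame with columns `scenario`,
#'   `band_set`, `subject`, `fold`, `ACC`, `SEN`, `SPEC`, `PREC`.
#' @return data.frame with one row per (band_set, metric): `F`, `p`,
#'   `df1`, `df2`, and the two scenario means.
#' @export
compare_scenarios <- function(metrics_df) {
  stopifnot(all(c(1, 2) %in% metrics_df$scenario))
  subj1 <- unique(metrics_df$subject[metrics_df$scenario == 1])
  subj2 <- unique(metrics_df$subject[metrics_df$scenario == 2])
  if (!setequal(subj1, subj2)) {
    stop("both scenarios must cover the same subjects")
  }
  out <- list()
  for (bs in unique(metrics_df$band_set)) {
    sub <- metrics_df[metrics_df$band_set == bs, ]
    sm <- subject_means(sub, by = c("subject", "scenario"))
    for (metric in c("ACC", "SEN", "SPEC", "PREC")) {
      v <- sm[[metric]]; g <- factor(sm$scenario)
      keep <- is.finite(v)
      fit <- stats::anova(stats::lm(v[keep] ~ g[keep]))
      out[[length(out) + 1]] <- data.frame(
        band_set = bs, metric = metric,
        F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1],
        df1 = fit$Df[1], df2 = fit$Df[2],
        mean_scenario1 = mean(v[keep][g[keep] == 1]),
        mean_scenario2 = mean(v[keep][g[keep] == 2]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' One-way ANOVA across band sets with Tukey HSD post hoc
#'
#' Tests whether subject-level accuracy differs across band sets, then
#' computes all pairwise Tukey honestly-significant-difference adjusted
#' p-values (45 pairs for the 10 canonical band sets).
#'
#' @param metrics_df long metrics data.frame (single scenario) with
#'   columns `band_set`, `subject`, `fold` and the metric column.
#' @param metric which metric to compare (default `"ACC"`).
#' @return List: `anova` (data.frame with F, p, dfs), `tukey`
#'   (data.frame `pair`, `diff`, `p_adj`), `p_matrix` (upper-triangular
#'   matrix of adjusted p-values).
#' @export
band_anova_tukey <- function(metrics_df, metric = "ACC") {
  sm <- subject_means(metrics_df, by = c("subject", "band_set"))
  counts <- table(sm$band_set)
  if (length(unique(counts)) != 1) {
    stop("every band set needs the same subjects (missing cells)")
  }
  g <- factor(sm$band_set, levels = unique(metrics_df$band_set))
  v <- sm[[metric]]
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  lv <- levels(g)
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pm[b, a] <- tk[i, "p adj"]
  }
  list(
    anova = data.frame(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                       df1 = an$Df[1], df2 = an$Df[2]),
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL),
    p_matrix = pm
  )
}

#' Two-way ANOVA of accuracy over band set and hidden-neuron count
#'
#' Fixed-effects two-way ANOVA with interaction on subject-level
#' accuracy (fold-averaged), crossed over band set and number of hidden
#' neurons. With 29 subjects and a 10 x 10 grid the error degrees of
#' freedom are 2800.
#'
#' @param metrics_df long metrics data.frame with columns `band_set`,
#'   `n_hidden`, `subject`, `fold` and the metric column.
#' @param metric metric column to analyse (default `"ACC"`).
#' @return data.frame with rows `band_set`, `n_hidden`, `interaction`:
#'   `F`, `p`, `df1`, `df2`.
#' @export
two_way_anova <- function(metrics_df, metric = "ACC") {
  sm <- subject_means(metrics_df, by = c("subject", "band_set", "n_hidden"))
  ok <- table(sm$band_set, sm$n_hidden)
  if (any(ok == 0)) stop("incomplete band_set x n_hidden design")
  v <- sm[[metric]]
  if (stats::var(v) == 0) stop("zero-variance response: ANOVA degenerate")
  a <- factor(sm$band_set); b <- factor(sm$n_hidden)
  an <- summary(stats::aov(v ~ a * b))[[1]]
  data.frame(
    effect = c("band_set", "n_hidden", "interaction"),
    F = an[["F value"]][1:3], p = an[["Pr(>F)"]][1:3],
    df1 = an$Df[1:3], df2 = an$Df[4],
    stringsAsFactors = FALSE
  )
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample Kolmogorov-Smirnov test of normality with estimated mean
#' and standard deviation (Lilliefors correction, so the p-value
#' accounts for the estimated moments).
#'
#' @param values numeric vector, at least 5 non-constant values.
#' @return The p-value.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values")
  if (stats::sd(values) == 0) stop("constant input: normality undefined")
  nortest::lillie.test(values)$p.value
}
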