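# Confusion counts, metrics, attack, and the statistical machinery.

test_that("verification metrics reproduce the defining arithmetic", {
  m <- verification_metrics(c(TP = 90, FN = 10, TN = 80, FP = 20))
  expect_equal(m[["SEN"]], 0.90)
  expect_equal(m[["SPEC"]], 0.80)
  expect_equal(m[["ACC"]], 0.85)
  expect_equal(m[["PREC"]], 90 / 110)
  all_right <- verification_metrics(c(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unname(all_right), c(1, 1, 1, 1))
  # degenerate: nothing accepted as genuine -> precision undefined
  d <- verification_metrics(c(TP = 0, FN = 10, TN = 10, FP = 0))
  expect_equal(d[["SEN"]], 0)
  expect_equal(d[["SPEC"]], 1)
  expect_true(is.na(d[["PREC"]]))
  expect_error(verification_metrics(c(TP = 0, FN = 0, TN = 1, FP = 0)),
               "genuine")
  expect_error(verification_metrics(c(TP = 1, FN = 0, TN = 0, FP = 0)),
               "impostor")
  expect_error(verification_metrics(c(TP = -1, FN = 1, TN = 1, FP = 1)),
               "nonnegative")
})

test_that("accuracy decomposes as the prevalence-weighted mean of SEN and SPEC", {
  set.seed(8)
  for (i in 1:25) {
    cts <- c(TP = rpois(1, 40), FN = rpois(1, 10) + 1,
             TN = rpois(1, 40) + 1, FP = rpois(1, 10))
    m <- verification_metrics(cts)
    P <- cts[["TP"]] + cts[["FN"]]; N <- cts[["TN"]] + cts[["FP"]]
    expect_equal(m[["ACC"]], (m[["SEN"]] * P + m[["SPEC"]] * N) / (P + N))
  }
})

test_that("confusion counts partition the test sets", {
  toy <- separable_toy()
  m <- train_lm(toy$X, toy$labels, n_hidden = 1, seed = 2)
  gen <- toy$X[toy$labels == "genuine", ]
  imp <- toy$X[toy$labels == "impostor", ]
  cts <- confusion(m, gen, imp)
  expect_equal(cts[["TP"]] + cts[["FN"]], nrow(gen))
  expect_equal(cts[["TN"]] + cts[["FP"]], nrow(imp))
  # a perfect model on its separable training data
  expect_equal(cts[["FN"]], 0)
  expect_equal(cts[["FP"]], 0)
  # constant-impostor model: TP = FP = 0
  z <- m; z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  cz <- confusion(z, gen, imp)
  expect_equal(cz[["TP"]], 0)
  expect_equal(cz[["FP"]], 0)
  expect_error(confusion(m, gen[0, ], imp), "nonempty")
})

test_that("attack success rate is one minus specificity on the same vectors", {
  toy <- separable_toy()
  m <- train_lm(toy$X, toy$labels, n_hidden = 1, seed = 2)
  set.seed(3)
  foreign <- matrix(rnorm(40 * 2, 0, 3), 40, 2)
  prov <- data.frame(subject_id = rep(c("X01", "X02"), each = 20),
                     session_id = 1L, segment_index = rep(0:19, 2))
  rep_ <- external_attack(list(S01 = m), foreign, prov)
  cts <- confusion(m, toy$X[toy$labels == "genuine", ], foreign)
  spec <- verification_metrics(cts)[["SPEC"]]
  expect_equal(rep_$total$success_pct / 100, 1 - spec)
  expect_equal(rep_$total$attempts, 40)
  # rejecting model -> 0% success
  z <- m; z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  expect_equal(external_attack(list(S01 = z), foreign,
                               prov)$total$success_pct, 0)
})

test_that("the attack contamination guard fires", {
  toy <- separable_toy()
  m <- train_lm(toy$X, toy$labels, n_hidden = 1, seed = 2)
  prov <- data.frame(subject_id = "X01", session_id = 1L,
                     segment_index = 0:4)
  plan <- scenario2_folds(fake_prov("S01", 4),
                          rbind(fake_prov("X01", 4), fake_prov("P2", 4)),
                          seed = 1)
  expect_error(
    external_attack(list(S01 = m), matrix(0, 5, 2), prov, plans = plan),
    "contaminate")
})

test_that("scenario comparison reduces to the two-group F = t^2 identity", {
  # 3 subjects per scenario, hand-checkable toy values
  df <- data.frame(
    scenario = rep(c(1, 2), each = 3),
    band_set = "beta", subject = rep(c("a", "b", "c"), 2), fold = 0,
    ACC = c(0.90, 0.92, 0.94, 0.80, 0.82, 0.84),
    SEN = c(0.90, 0.92, 0.94, 0.80, 0.82, 0.84),
    SPEC = c(0.90, 0.92, 0.94, 0.80, 0.82, 0.84),
    PREC = c(0.90, 0.92, 0.94, 0.80, 0.82, 0.84)
  )
  out <- compare_scenarios(df)
  tt <- t.test(c(0.90, 0.92, 0.94), c(0.80, 0.82, 0.84),
               var.equal = TRUE)
  expect_equal(out$F[out$metric == "ACC"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(out$p[out$metric == "ACC"], tt$p.value, tolerance = 1e-10)
  expect_equal(out$df1[1], 1)
  expect_equal(out$df2[1], 4) # 2n - 2
  # identical groups -> F ~ 0, p ~ 1
  df2 <- df; df2$ACC <- 0.9; df2$SEN <- 0.9
  df2$SPEC <- 0.9; df2$PREC <- 0.9
  # add tiny jitter so variance is nonzero but groups identical in mean
  df2[c("ACC", "SEN", "SPEC", "PREC")] <-
    df2[c("ACC", "SEN", "SPEC", "PREC")] +
    rep(c(-0.001, 0, 0.001), 2)
  out2 <- compare_scenarios(df2)
  expect_lt(max(out2$F), 1e-10)
  expect_true(all(out2$p > 0.999))
  expect_error(compare_scenarios(df[df$subject != "a" |
                                    df$scenario != 2, ]),
               "same subjects")
})

test_that("band ANOVA with Tukey HSD yields 45 pairs for 10 band sets", {
  set.seed(14)
  bs <- names(canonical_band_sets())
  df <- expand.grid(subject = paste0("S", 1:12), band_set = bs,
                    stringsAsFactors = FALSE)
  df$fold <- 0
  df$ACC <- 0.9 + rnorm(nrow(df), 0, 0.02)
  df$SEN <- df$SPEC <- df$PREC <- df$ACC
  out <- band_anova_tukey(df)
  expect_equal(nrow(out$tukey), choose(10, 2))
  expect_equal(dim(out$p_matrix), c(10, 10))
  expect_equal(sum(!is.na(out$p_matrix)), 45)
  # null data: no pair significant at a generous threshold most times
  expect_gt(min(out$tukey$p_adj), 0.001)
})

test_that("a far-shifted band set is flagged by every one of its Tukey pairs", {
  bs <- names(canonical_band_sets())
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    df <- expand.grid(subject = paste0("S", 1:10), band_set = bs,
                      stringsAsFactors = FALSE)
    df$fold <- 0
    df$ACC <- 0.85 + rnorm(nrow(df), 0, 0.02)
    df$ACC[df$band_set == "theta"] <- df$ACC[df$band_set == "theta"] - 0.2
    df$SEN <- df$SPEC <- df$PREC <- df$ACC
    out <- band_anova_tukey(df)
    theta_pairs <- grepl("(^theta-)|(-theta$)", out$tukey$pair)
    all(out$tukey$p_adj[theta_pairs] < 0.05)
  }, logical(1))
  expect_true(all(hits))
})

test_that("two-way ANOVA detects a strong band effect and reports the design dfs", {
  set.seed(4)
  df <- expand.grid(subject = paste0("S", 1:29),
                    band_set = names(canonical_band_sets()),
                    n_hidden = 1:10, stringsAsFactors = FALSE)
  df$fold <- 0
  band_fx <- stats::setNames(seq(0, 0.27, length.out = 10) - 0.135,
                             names(canonical_band_sets()))
  df$ACC <- 0.8 + band_fx[df$band_set] + rnorm(nrow(df), 0, 0.045)
  df$SEN <- df$SPEC <- df$PREC <- df$ACC
  out <- two_way_anova(df)
  expect_equal(out$df1, c(9, 9, 81))
  expect_equal(out$df2[1], 2800) # 2900 cells - 100 parameters
  expect_lt(out$p[out$effect == "band_set"], 1e-6)
  expect_gt(out$p[out$effect == "n_hidden"], 0.001)
  # degenerate input
  dfz <- df; dfz$ACC <- 0.5; dfz$SEN <- dfz$SPEC <- dfz$PREC <- 0.5
  expect_error(two_way_anova(dfz), "zero-variance")
  expect_error(two_way_anova(df[df$band_set != "beta" |
                                df$n_hidden != 3, ]),
               "incomplete")
})

test_that("the hidden-neuron null keeps its nominal type-I error rate", {
  # 200 null simulations: no hidden-neuron effect injected; the
  # fraction of p < 0.05 should sit near 0.05 (binomial 3-sigma band)
  bs <- names(canonical_band_sets())[1:5]
  rejections <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    df <- expand.grid(subject = paste0("S", 1:8), band_set = bs,
                      n_hidden = 1:4, stringsAsFactors = FALSE)
    df$fold <- 0
    band_fx <- stats::setNames(c(-0.04, -0.02, 0, 0.02, 0.04), bs)
    df$ACC <- 0.85 + band_fx[df$band_set] + rnorm(nrow(df), 0, 0.03)
    df$SEN <- df$SPEC <- df$PREC <- df$ACC
    out <- two_way_anova(df)
    out$p[out$effect == "n_hidden"] < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.05 - 3 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("KS normality check is calibrated on normal and bimodal samples", {
  passes <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(500)) > 0.05
  }, logical(1))
  expect_gte(mean(passes), 0.9)
  set.seed(2)
  bimodal <- c(rnorm(100, -10), rnorm(100, 10))
  expect_lt(ks_normality(bimodal), 0.05)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})
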