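# Parametric metrics-table generator for statistics-stage tests: a balanced
# cohort layout with a known linear-mixed-model data-generating process,
# independent of the trajectory simulator.
null_metrics_table <- function(n_subjects = 12, n_trials = 10,
                               drift = 0, re_sd = 0.05, noise_sd = 0.1) {
  d <- expand.grid(subject = seq_len(n_subjects), trial = seq_len(n_trials))
  d$condition <- ifelse(d$subject <= n_subjects / 2, "individual", "social")
  d$door_location <- ifelse(d$subject %% 2 == 0, "preferred",
                            "nonpreferred")
  re <- rnorm(n_subjects, 0, re_sd)
  d$PI <- 0.5 + re[d$subject] + drift * d$trial + rnorm(nrow(d), 0, noise_sd)
  d
}

test_that("corrected alpha reproduces the conservative 0.050/3 level", {
  expect_equal(corrected_alpha(0.050, 3), 0.050 / 3)
  expect_equal(round(corrected_alpha(0.050, 3), 3), 0.017)
  expect_equal(corrected_alpha(0.050, 1), 0.050)
  expect_equal(corrected_alpha(0.050, 2), 0.025)
  expect_error(corrected_alpha(0.050, 0), "at least 1")
})

test_that("Levene/Brown-Forsythe matches a hand-computed one-way ANOVA", {
  d <- data.frame(y = c(0, 2, -5, 5), g = c("a", "a", "b", "b"))
  out <- levene_variability(d, "y", "g")
  # |y - median| per group: {1, 1} and {5, 5}; ANOVA on these deviations
  dev <- c(1, 1, 5, 5)
  ssb <- 2 * (1 - 3)^2 + 2 * (5 - 3)^2
  ssw <- 0
  expect_equal(out$df1, 1)
  expect_equal(out$df2, 2)
  expect_true(is.infinite(out$F))       # zero within-group variation
  # identical deviation patterns in every group give F = 0
  d2 <- data.frame(y = c(0, 2, 10, 12), g = c("a", "a", "b", "b"))
  out2 <- levene_variability(d2, "y", "g")
  expect_equal(out2$F, 0)
  # a non-degenerate hand-checkable case
  d3 <- data.frame(y = c(0, 1, 4, 0, 2, 10), g = rep(c("a", "b"), each = 3))
  dev3 <- abs(d3$y - rep(tapply(d3$y, d3$g, median), each = 3))
  expect_equal(levene_variability(d3, "y", "g")$F,
               summary(stats::aov(dev3 ~ d3$g))[[1]]$`F value`[1],
               tolerance = 1e-9)
  expect_error(levene_variability(
    data.frame(y = c(1, 2, 3), g = c("a", "a", "b")), "y", "g"),
    "fewer than 2")
})

test_that("null Levene p-values are approximately uniform", {
  set.seed(512)
  ps <- replicate(300, {
    d <- null_metrics_table(n_subjects = 24, n_trials = 1, re_sd = 0)
    d$test <- sample(c(0, 10, 20), nrow(d), replace = TRUE)
    levene_variability(d, "PI", c("condition", "door_location"))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.06)
})

test_that("type II table is invariant to factor level order", {
  set.seed(21)
  d <- null_metrics_table(drift = 0.01)
  a1 <- fit_lmm_type2(d, "PI",
                      predictors = c("condition", "trial", "door_location"))
  d2 <- d
  d2$condition <- factor(d2$condition, levels = c("social", "individual"))
  d2$door_location <- factor(d2$door_location,
                             levels = c("preferred", "nonpreferred"))
  a2 <- fit_lmm_type2(d2, "PI",
                      predictors = c("condition", "trial", "door_location"))
  expect_equal(a1$full$chisq, a2$full$chisq, tolerance = 1e-6)
  expect_equal(a1$full$term, a2$full$term)
})

test_that("additive-model type II equals direct Wald tests (type III limit)", {
  set.seed(33)
  d <- null_metrics_table(n_subjects = 16, n_trials = 6, drift = 0.015)
  a <- fit_lmm_type2(d, "PI",
                     predictors = c("condition", "trial", "door_location"),
                     max_order = 1)
  # direct single-fit Wald chi-squares from the additive model
  d$condition <- factor(d$condition)
  d$door_location <- factor(d$door_location)
  contrasts(d$condition) <- contr.sum(2)
  contrasts(d$door_location) <- contr.sum(2)
  fit <- lme4::lmer(PI ~ condition + trial + door_location + (1 | subject),
                    data = d, REML = TRUE)
  b <- lme4::fixef(fit)[-1]
  V <- as.matrix(vcov(fit))[-1, -1]
  direct <- vapply(seq_along(b), function(j) b[j]^2 / V[j, j], 0)
  expect_equal(a$full$chisq, unname(direct), tolerance = 1e-6)
})

test_that("a perfect linear trial effect yields p ~ 0", {
  set.seed(9)
  d <- null_metrics_table()
  d$PI <- 0.3 + 0.01 * d$trial
  a <- suppressWarnings(fit_lmm_type2(
    d, "PI", predictors = c("condition", "trial", "door_location")))
  expect_lt(a$full$p[a$full$term == "trial"], 1e-10)
})

test_that("interaction pruning respects marginality and reports both tables", {
  set.seed(77)
  d <- null_metrics_table(n_subjects = 20, n_trials = 10)
  a <- fit_lmm_type2(d, "PI",
                     predictors = c("condition", "trial", "door_location"))
  expect_named(a[c("full", "pruned")], c("full", "pruned"))
  expect_equal(nrow(a$full), 7)         # 3 mains + 3 two-way + 1 three-way
  # every dropped term is an interaction with p >= 0.05 whose parents are
  # also dropped
  for (u in a$dropped) {
    expect_gt(length(strsplit(u, ":")[[1]]), 1)
    expect_gte(a$full$p[a$full$term == u], 0.05)
  }
  # retained interactions keep their main effects in the pruned model
  expect_true(all(c("condition", "trial", "door_location") %in%
                    a$pruned$term))
  # report row order matches the full factorial term order
  expect_equal(a$full$term,
               c("condition", "trial", "door_location", "condition:trial",
                 "condition:door_location", "trial:door_location",
                 "condition:trial:door_location"))
})

test_that("empty design cells are reported by name", {
  set.seed(3)
  d <- null_metrics_table()
  d <- d[!(d$condition == "social" & d$door_location == "preferred"), ]
  d$test <- 0
  expect_error(fit_lmm_type2(d, "PI",
                             predictors = c("condition", "door_location")),
               "empty design cell")
})

test_that("summarize_study mirrors the published table layout", {
  set.seed(101)
  tr <- null_metrics_table(n_subjects = 16, n_trials = 8, drift = 0.02)
  tr$theta_C <- 90 - 2 * tr$trial + rnorm(nrow(tr), 0, 15)
  tr$T <- pmax(10, 900 - 20 * tr$trial + rnorm(nrow(tr), 0, 150))
  te <- do.call(rbind, lapply(c(0, 10, 20), function(k) {
    d <- null_metrics_table(n_subjects = 16, n_trials = 1, drift = 0)
    d$trial <- NULL
    d$test <- k
    d$PI <- 0.5 + 0.006 * k + rnorm(nrow(d), 0, 0.08)
    d$theta_C <- 90 - 1.2 * k + rnorm(nrow(d), 0, 12)
    d
  }))
  rep <- summarize_study(tr, te)
  expect_equal(rep$alpha, 0.050 / 3)
  expect_named(rep$tables, c("test_PI", "test_theta_C", "training_T",
                             "training_PI", "training_theta_C"))
  expect_equal(rep$tables$test_PI$full$term,
               c("condition", "door_location", "test",
                 "condition:door_location", "condition:test",
                 "door_location:test",
                 "condition:door_location:test"))
  # injected test-session improvement is detected for PI on test data
  expect_true("test" %in% rep$significant$test_PI)
  expect_true("trial" %in% rep$significant$training_PI)
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$alpha, 0.050 / 3, tolerance = 1e-12)
  expect_equal(parsed$tables$test_PI$full$term[3], "test")
  unlink(f)
})
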