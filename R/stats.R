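#' Mixed model with type II Wald chi-square table
#'
#' Fits a linear mixed model of a per-trial metric on the design factors
#' with a random intercept per subject, and produces a type II Wald
#' chi-square table: each term is tested, respecting marginality, in the
#' model containing that term and every term that does not contain it (so a
#' main effect is adjusted for the other main effects and their
#' interactions, but not for interactions involving itself).  Unordered
#' factors use sum-to-zero contrasts and the ordered `Test` factor uses
#' polynomial contrasts, as required for meaningful type II tests.  After
#' the full-model table, non-significant interaction terms (p >= `prune_p`
#' on the full table, highest order first, keeping marginality) are
#' discarded and the reduced model's table is reported as well.
#'
#' @param data Per-trial metrics data frame (see [trial_metrics()]), with
#'   columns for the response, the predictors, and `subject`.
#' @param response Response column name (e.g. `"PI"`, `"theta_C"`, `"T"`).
#' @param predictors Fixed-factor column names; the full model is their
#'   full factorial crossing.  Columns named `test` are coded as ordered
#'   factors, `trial` stays numeric, everything else becomes an unordered
#'   factor with sum contrasts.
#' @param random Grouping column for the random intercept (default
#'   `"subject"`).
#' @param prune_p Threshold for discarding interaction terms (default 0.05).
#' @param max_order Highest interaction order entering the full model
#'   (default: all interactions; 1 fits main effects only).
#' @param terms Optional subset of term labels to test (default: every
#'   term of the full model).  Restricting the set changes nothing about
#'   each computed row — each term is still tested in its own
#'   marginality-respecting refit — and skips interaction pruning; it is
#'   a cost control for simulation studies.
#' @return A `bc_anova` object: list with `full` and `pruned` tables (data
#'   frames `term`, `chisq`, `df`, `p`), `dropped` (labels of pruned
#'   terms), `singular` (TRUE if any fit was singular), `response`, and
#'   `formula`.
#' @export
fit_lmm_type2 <- function(data, response,
                          predictors = c("condition", "door_location",
                                         "test"),
                          random = "subject", prune_p = 0.05,
                          max_order = length(predictors), terms = NULL) {
  d <- data[stats::complete.cases(data[, c(response, predictors, random)]),
            , drop = FALSE]
  if (!nrow(d)) stop("no complete cases for response ", response)
  for (p in predictors) {
    if (p %in% c("test", "Test")) {
      d[[p]] <- factor(d[[p]], ordered = TRUE)  # polynomial contrasts
    } else if (!(p %in% c("trial", "Trial")) && !is.numeric(d[[p]])) {
      d[[p]] <- factor(d[[p]])
      stats::contrasts(d[[p]]) <- stats::contr.sum(nlevels(d[[p]]))
    }
  }
  d[[random]] <- factor(d[[random]])
  # check for empty design cells among the factor predictors
  fac <- predictors[vapply(predictors, function(p) is.factor(d[[p]]), TRUE)]
  if (length(fac) > 1) {
    tab <- table(d[, fac])
    if (any(tab == 0)) {
      cell <- which(tab == 0, arr.ind = TRUE)[1, ]
      stop("empty design cell: ",
           paste(fac, dimnames(tab)[[1]][cell], sep = "=",
                 collapse = ", "))
    }
  }
  full_rhs <- if (max_order >= length(predictors))
    paste(predictors, collapse = " * ")
  else if (max_order == 1) paste(predictors, collapse = " + ")
  else sprintf("(%s)^%d", paste(predictors, collapse = " + "), max_order)
  full_terms <- attr(stats::terms(
    stats::reformulate(full_rhs)), "term.labels")
  test_set <- if (is.null(terms)) full_terms else {
    missing <- setdiff(terms, full_terms)
    if (length(missing))
      stop("not terms of the full model: ", paste(missing, collapse = ", "))
    full_terms[full_terms %in% terms]
  }
  tab_full <- type2_table(d, response, full_terms, test_set, random)
  if (!is.null(terms)) {
    return(structure(list(full = tab_full$table, pruned = tab_full$table,
                          dropped = character(0),
                          singular = tab_full$singular,
                          response = response,
                          formula = sprintf("%s ~ %s + (1 | %s)", response,
                                            full_rhs, random)),
                     class = "bc_anova"))
  }

  keep <- prune_terms(full_terms, tab_full, prune_p)
  dropped <- setdiff(full_terms, keep)
  tab_pruned <- if (length(dropped))
    type2_table(d, response, keep, keep, random) else tab_full

  structure(list(full = tab_full$table, pruned = tab_pruned$table,
                 dropped = dropped,
                 singular = tab_full$singular || tab_pruned$singular,
                 response = response,
                 formula = sprintf("%s ~ %s + (1 | %s)", response, full_rhs,
                                   random)),
            class = "bc_anova")
}

# Variables of a term label ("a:b" -> c("a", "b")).
term_vars <- function(label) strsplit(label, ":", fixed = TRUE)[[1]]

# Does term v strictly contain term u?
term_contains <- function(u, v) {
  uv <- term_vars(u); vv <- term_vars(v)
  length(vv) > length(uv) && all(uv %in% vv)
}

# Type II Wald table for `test_terms` within the scope `model_terms`.
type2_table <- function(d, response, model_terms, test_terms, random) {
  singular <- FALSE
  rows <- lapply(test_terms, function(u) {
    keep <- model_terms[!vapply(model_terms, function(v)
      term_contains(u, v), TRUE)]
    fml <- stats::as.formula(sprintf(
      "%s ~ %s + (1 | %s)", response, paste(keep, collapse = " + "), random))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = d, REML = TRUE)))
    if (lme4::isSingular(fit)) singular <<- TRUE
    X <- lme4::getME(fit, "X")
    asgn <- attr(X, "assign")
    labels <- attr(stats::terms(stats::reformulate(keep)), "term.labels")
    j <- match(u, labels)
    idx <- which(asgn == j)
    b <- lme4::fixef(fit)[idx]
    V <- as.matrix(stats::vcov(fit))[idx, idx, drop = FALSE]
    chisq <- as.numeric(t(b) %*% solve(V, b))
    df <- length(idx)
    data.frame(term = u, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, singular = singular)
}

# Discard non-significant interactions from the full table, highest order
# first, never dropping a term contained in a retained higher-order term.
prune_terms <- function(terms, tab_full, prune_p) {
  p <- setNames(tab_full$table$p, tab_full$table$term)
  ord <- vapply(terms, function(t) length(term_vars(t)), 0L)
  keep <- terms
  for (o in sort(unique(ord[ord > 1]), decreasing = TRUE)) {
    for (u in terms[ord == o]) {
      retained_parent <- any(vapply(keep, function(v)
        term_contains(u, v), TRUE))
      if (!retained_parent && p[[u]] >= prune_p)
        keep <- setdiff(keep, u)
    }
  }
  keep
}

#' @export
print.bc_anova <- function(x, ...) {
  cat("Type II Wald chi-square tests:", x$formula,
      if (x$singular) " [singular fit]" else "", "\n")
  fmt <- function(tab) {
    tab$chisq <- sprintf("%.2f", tab$chisq)
    tab$p <- ifelse(tab$p < 0.001, "<0.001", sprintf("%.3f", tab$p))
    print(tab, row.names = FALSE)
  }
  cat("Full model:\n"); fmt(x$full)
  if (length(x$dropped)) {
    cat("After discarding non-significant interactions (",
        paste(x$dropped, collapse = ", "), "):\n", sep = "")
    fmt(x$pruned)
  }
  invisible(x)
}

#' Multiplicity-corrected alpha level
#'
#' Bonferroni division of the nominal level by the number of tests each
#' independent variable enters; with the study's three training-data tests,
#' `0.050 / 3 = 0.0167`.
#'
#' @param nominal Nominal alpha (e.g. 0.050).
#' @param n_tests Number of tests (>= 1).
#' @return Corrected alpha.
#' @examples
#' corrected_alpha(0.050, 3)
#' @export
corrected_alpha <- function(nominal, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  if (nominal <= 0 || nominal >= 1) stop("nominal must be in (0, 1)")
  nominal / n_tests
}

#' Levene's (Brown-Forsythe) test of variability
#'
#' One-way ANOVA on the absolute deviations of the response from its group
#' median — the median-centred (Brown-Forsythe) variant of Levene's test,
#' robust to non-normality.  Groups are the cells of the interaction of the
#' `grouping` columns.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param grouping Character vector of grouping column names.
#' @return List with `F`, `df1` (k - 1), `df2` (N - k), `p`, and `k`.
#' @export
levene_variability <- function(data, response, grouping) {
  d <- data[stats::complete.cases(data[, c(response, grouping)]), ,
            drop = FALSE]
  g <- interaction(d[, grouping, drop = FALSE], drop = TRUE)
  sizes <- table(g)
  if (any(sizes < 2))
    stop("group with fewer than 2 observations: ",
         names(sizes)[sizes < 2][1])
  y <- d[[response]]
  dev <- abs(y - stats::ave(y, g, FUN = median))
  k <- nlevels(g)
  N <- length(y)
  gm <- mean(dev)
  means <- tapply(dev, g, mean)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((dev - stats::ave(dev, g, FUN = mean))^2)
  df1 <- k - 1
  df2 <- N - k
  Fst <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  list(F = Fst, df1 = df1, df2 = df2,
       p = stats::pf(Fst, df1, df2, lower.tail = FALSE), k = k)
}

#' Run the full statistical stage of the study
#'
#' Reproduces the analysis layout: type II mixed-model tables for the
#' preference index and heading error on test data (factors condition x
#' correct-door location x test) and for triggering time, preference index,
#' and heading error on training data (condition x trial x correct-door
#' location), a single conservatively corrected alpha of
#' `nominal / n_tests` (default 0.050/3), and Levene's variability test of
#' the preference index across the 12 condition x location x test groups.
#'
#' @param training_metrics,test_metrics Metrics data frames (training /
#'   test sessions) sharing the design label columns.
#' @param responses_test,responses_training Response columns analyzed on
#'   each data set.
#' @param nominal,n_tests Passed to [corrected_alpha()].
#' @param prune_p Interaction-pruning threshold.
#' @return A `bc_report`: list with `alpha`, `tables` (named list of
#'   `bc_anova`, names like `test_PI`, `training_T`), `levene`, and
#'   `significant` (full-model terms with p below the corrected alpha).
#' @export
summarize_study <- function(training_metrics, test_metrics,
                            responses_test = c("PI", "theta_C"),
                            responses_training = c("T", "PI", "theta_C"),
                            nominal = 0.050, n_tests = 3, prune_p = 0.05) {
  alpha <- corrected_alpha(nominal, n_tests)
  tables <- list()
  safe_fit <- function(...) tryCatch(fit_lmm_type2(...), error = function(e)
    structure(list(error = conditionMessage(e)), class = "bc_anova_error"))
  for (r in responses_test)
    tables[[paste0("test_", r)]] <- safe_fit(
      test_metrics, r, predictors = c("condition", "door_location", "test"),
      prune_p = prune_p)
  for (r in responses_training)
    tables[[paste0("training_", r)]] <- safe_fit(
      training_metrics, r,
      predictors = c("condition", "trial", "door_location"),
      prune_p = prune_p)
  lev <- tryCatch(
    levene_variability(test_metrics, "PI",
                       c("condition", "door_location", "test")),
    error = function(e) list(error = conditionMessage(e)))
  signif <- lapply(tables, function(tb)
    if (inherits(tb, "bc_anova_error")) character(0) else
      tb$full$term[tb$full$p < alpha])
  structure(list(alpha = alpha, tables = tables, levene = lev,
                 significant = signif),
            class = "bc_report")
}

#' @export
print.bc_report <- function(x, ...) {
  cat(sprintf("Study report (corrected alpha = %.4f)\n", x$alpha))
  for (nm in names(x$tables)) {
    cat("\n==", nm, "==\n")
    tb <- x$tables[[nm]]
    if (inherits(tb, "bc_anova_error"))
      cat("  model not fitted:", tb$error, "\n")
    else print(tb)
  }
  if (is.null(x$levene$error))
    cat(sprintf(
      "\nLevene (Brown-Forsythe) on PI: F(%d, %d) = %.2f, p = %.3f\n",
      x$levene$df1, x$levene$df2, x$levene$F, x$levene$p))
  invisible(x)
}

#' Write a study report as JSON
#'
#' Machine-readable mirror of the report's tables, mirroring the chi^2 /
#' Df / p layout.
#'
#' @param report A `bc_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    alpha = report$alpha,
    tables = lapply(report$tables, function(tb) {
      if (inherits(tb, "bc_anova_error")) return(list(error = tb$error))
      list(response = tb$response, formula = tb$formula,
           singular = tb$singular, full = tb$full, pruned = tb$pruned,
           dropped = tb$dropped)
    }),
    levene = report$levene,
    significant = report$significant)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
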