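# Inline gaussian generator for targeted mixed-model tests: two 2-level
# factors in sliding-difference codes, crossed subject/item effects.
gen_lmm_data <- function(n_subj = 12, n_item = 4, n_rep = 8,
                         b0 = 400, b_pc = -30, b_dp = 0, b_pcdp = 0,
                         subj_int_sd = 50, subj_pc_sd = 0,
                         item_int_sd = 15, item_pc_sd = 0,
                         resid_sd = 90, seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    participant_id = sprintf("S%02d", seq_len(n_subj)),
    item_id = sprintf("I%02d", seq_len(n_item)),
    pc = factor(c("blurred", "intact"), c("blurred", "intact")),
    dp = factor(c("left", "right"), c("left", "right")),
    rep = seq_len(n_rep))
  pcc <- ifelse(grid$pc == "intact", 0.5, -0.5)
  dpc <- ifelse(grid$dp == "right", 0.5, -0.5)
  si <- rnorm(n_subj, 0, subj_int_sd)[match(grid$participant_id,
                                            sprintf("S%02d", seq_len(n_subj)))]
  ss <- rnorm(n_subj, 0, subj_pc_sd)[match(grid$participant_id,
                                           sprintf("S%02d", seq_len(n_subj)))]
  ii <- rnorm(n_item, 0, item_int_sd)[match(grid$item_id,
                                            sprintf("I%02d", seq_len(n_item)))]
  is <- rnorm(n_item, 0, item_pc_sd)[match(grid$item_id,
                                           sprintf("I%02d", seq_len(n_item)))]
  grid$y <- b0 + b_pc * pcc + b_dp * dpc + b_pcdp * pcc * dpc +
    si + ss * pcc + ii + is * pcc + rnorm(nrow(grid), 0, resid_sd)
  grid
}

test_that("sliding-difference contrasts encode successive level differences", {
  expect_equal(unname(sliding_difference_contrasts(2)[, 1]), c(-0.5, 0.5))
  for (k in 2:5)
    expect_equal(colSums(sliding_difference_contrasts(k)),
                 rep(0, k - 1), ignore_attr = TRUE)
  expect_error(sliding_difference_contrasts(1), ">= 2")

  # on balanced cell means the coefficients are exactly the successive
  # differences and the intercept the grand mean
  mu <- c(a = 2, b = 5, c = 11)
  df <- tibble::tibble(g = factor(rep(names(mu), each = 4),
                                  levels = names(mu)),
                       y = rep(mu, each = 4))
  contrasts(df$g) <- sliding_difference_contrasts(3)
  cf <- coef(lm(y ~ g, df))
  expect_equal(unname(cf), c(mean(mu), 5 - 2, 11 - 5))
})

test_that("with balanced data and no group variance the fit reduces to OLS", {
  d <- gen_lmm_data(n_subj = 6, n_item = 3, n_rep = 4,
                    b_pc = -20, b_dp = 8, subj_int_sd = 0, item_int_sd = 0,
                    resid_sd = 10, seed = 2)
  fit <- fit_trial_model(y ~ pc * dp + (1 | participant_id) + (1 | item_id), d)
  ols <- fit_trial_model(y ~ pc * dp, d)
  expect_equal(tidy(fit)$estimate, tidy(ols)$estimate, tolerance = 1e-6)
  expect_true(glance(fit)$singular)
})

test_that("fixed effects are recovered within 3 SE at realistic magnitudes", {
  ok <- 0
  for (s in 1:3) {
    d <- gen_lmm_data(n_subj = 16, n_item = 4, n_rep = 6, b_pc = -30,
                      subj_int_sd = 50, subj_pc_sd = 15, item_int_sd = 15,
                      resid_sd = 90, seed = 100 + s)
    fit <- fit_trial_model(
      y ~ pc + (1 + pc | participant_id) + (1 | item_id), d)
    td <- tidy(fit)
    row <- td[grepl("^pc", td$term), ]
    ok <- ok + (abs(row$estimate - (-30)) <= 3 * row$std.error)
  }
  expect_gte(ok, 2)
})

test_that("a constant response yields zero effects and zero residual SD", {
  d <- gen_lmm_data(n_subj = 4, n_item = 2, n_rep = 2, seed = 3)
  d$y <- 5
  fit <- fit_trial_model(y ~ pc, d)
  # summary.lm warns about the perfect fit; the contract is the numbers
  td <- suppressWarnings(tidy(fit))
  expect_equal(unname(td$estimate[td$term != "(Intercept)"]), 0)
  expect_equal(suppressWarnings(glance(fit))$sigma, 0, tolerance = 1e-10)
})

test_that("binomial fits report z statistics and recover logit effects", {
  set.seed(4)
  d <- gen_lmm_data(n_subj = 24, n_item = 4, n_rep = 12, subj_int_sd = 0.8,
                    item_int_sd = 0, resid_sd = 1, b0 = 0, b_pc = 0)
  eta <- 1.5 + 1 * ifelse(d$pc == "intact", 0.5, -0.5) +
    rnorm(24, 0, 0.8)[match(d$participant_id, sprintf("S%02d", 1:24))]
  d$hit <- rbinom(nrow(d), 1, plogis(eta))
  fit <- fit_trial_model(hit ~ pc + (1 | participant_id), d,
                         family = "binomial")
  td <- tidy(fit)
  expect_true(all(c("statistic", "p.value") %in% names(td)))
  row <- td[grepl("^pc", td$term), ]
  expect_lt(abs(row$estimate - 1), 3 * row$std.error)
})

test_that("singular random terms are pruned slopes-first, deterministically", {
  removed_item_slope <- 0
  kept_subj_slope <- 0
  for (s in 1:5) {
    d <- gen_lmm_data(n_subj = 16, n_item = 4, n_rep = 8,
                      subj_int_sd = 50, subj_pc_sd = 20,
                      item_int_sd = 10, item_pc_sd = 0,
                      resid_sd = 60, seed = 200 + s)
    pr <- prune_singular_random_terms(
      y ~ pc + (1 + pc | participant_id) + (1 + pc | item_id), d)
    bars <- vapply(lme4::findbars(pr$formula), deparse, character(1))
    item_bar <- bars[grepl("item_id", bars)]
    subj_bar <- bars[grepl("participant_id", bars)]
    removed_item_slope <- removed_item_slope +
      (length(item_bar) == 0 || !grepl("pc", item_bar))
    kept_subj_slope <- kept_subj_slope +
      (length(subj_bar) == 1 && grepl("pc", subj_bar))
  }
  expect_gte(removed_item_slope, 3)
  expect_gte(kept_subj_slope, 3)

  # well-supported structures are left untouched
  d <- gen_lmm_data(n_subj = 20, n_item = 6, n_rep = 8, subj_int_sd = 60,
                    subj_pc_sd = 25, item_int_sd = 20, resid_sd = 40,
                    seed = 300)
  pr2 <- prune_singular_random_terms(
    y ~ pc + (1 + pc | participant_id) + (1 | item_id), d)
  expect_equal(nrow(pr2$log), 0L)
  # determinism: same data, same removals in the same order
  d3 <- gen_lmm_data(seed = 301, item_pc_sd = 0)
  f3 <- y ~ pc + (1 + pc | participant_id) + (1 + pc | item_id)
  expect_identical(prune_singular_random_terms(f3, d3)$log,
                   prune_singular_random_terms(f3, d3)$log)
})

test_that("stepwise reduction drops weak terms, keeps strong ones, and its LRT is the logLik identity", {
  d <- gen_lmm_data(n_subj = 16, n_item = 4, n_rep = 8, b_pc = -40,
                    b_dp = 0, b_pcdp = 0, subj_int_sd = 40, item_int_sd = 10,
                    resid_sd = 60, seed = 400)
  red <- reduce_fixed_effects(
    y ~ pc * dp + (1 | participant_id) + (1 | item_id), d)
  final_terms <- attr(terms(lme4::nobars(red$formula)), "term.labels")
  expect_true("pc" %in% final_terms)
  expect_false("pc:dp" %in% final_terms)
  expect_true(all(red$trail$dropped[1] == "pc:dp"))

  # the recorded chi-square equals twice the ML log-likelihood difference
  step1 <- red$trail[1, ]
  big <- fit_trial_model(y ~ pc * dp + (1 | participant_id) + (1 | item_id),
                         d, REML = FALSE)
  small <- fit_trial_model(y ~ pc + dp + (1 | participant_id) + (1 | item_id),
                           d, REML = FALSE)
  expect_equal(step1$statistic,
               2 * (glance(big)$logLik - glance(small)$logLik),
               tolerance = 1e-8)
  expect_equal(step1$dAIC, glance(small)$AIC - glance(big)$AIC,
               tolerance = 1e-6)

  # strongly supported terms produce an immediate stop
  d2 <- gen_lmm_data(n_subj = 16, n_item = 4, n_rep = 8, b_pc = -80,
                     b_dp = 60, b_pcdp = 50, subj_int_sd = 20,
                     item_int_sd = 5, resid_sd = 30, seed = 401)
  red2 <- reduce_fixed_effects(
    y ~ pc * dp + (1 | participant_id) + (1 | item_id), d2)
  expect_equal(sum(!red2$trail$kept), 0L)
  final2 <- attr(terms(lme4::nobars(red2$formula)), "term.labels")
  expect_setequal(final2, c("pc", "dp", "pc:dp"))
})

test_that("nested follow-ups recover per-level effects and average to the main effect", {
  # pc effect +20 for left, 0 for right deviants:
  # effect(left) = b_pc - b_pcdp/2, effect(right) = b_pc + b_pcdp/2
  f <- y ~ pc * dp + (1 | participant_id) + (1 | item_id)
  covered <- 0L
  for (s in 1:3) {
    d <- gen_lmm_data(n_subj = 16, n_item = 4, n_rep = 8, b_pc = 10,
                      b_pcdp = -20, subj_int_sd = 30, item_int_sd = 5,
                      resid_sd = 40, seed = 500 + s)
    nf <- nested_followup(f, d, inner = "pc", outer = "dp")
    est <- nf$estimates
    left <- est[est$outer_level == "left", ]
    right <- est[est$outer_level == "right", ]
    covered <- covered + (abs(left$estimate - 20) <= 3 * left$std.error &&
                            abs(right$estimate - 0) <= 3 * right$std.error)
  }
  expect_gte(covered, 2)

  # balanced design: the mean of the nested estimates is the main effect
  d <- gen_lmm_data(n_subj = 16, n_item = 4, n_rep = 8, b_pc = 10,
                    b_pcdp = -20, subj_int_sd = 30, item_int_sd = 5,
                    resid_sd = 40, seed = 500)
  nf <- nested_followup(f, d, inner = "pc", outer = "dp")
  est <- nf$estimates
  main <- tidy(fit_trial_model(f, d))
  b_main <- main$estimate[grepl("^pc", main$term) & !grepl(":", main$term)]
  expect_equal(unname(mean(est$estimate)), unname(b_main), tolerance = 1e-6)
  expect_error(nested_followup(f, d, inner = "pc", outer = "nope"), "nope")
})

test_that("partial effects remove exactly the requested contributions", {
  d <- gen_lmm_data(n_subj = 12, n_item = 4, n_rep = 6, b_pc = -30,
                    b_dp = 25, subj_int_sd = 40, item_int_sd = 10,
                    resid_sd = 30, seed = 600)
  fit <- fit_trial_model(y ~ pc + dp + (1 | participant_id) + (1 | item_id), d)
  expect_equal(partial_effects(fit), fit$data$y)
  all_terms <- c("(Intercept)",
                 attr(terms(lme4::nobars(fit$formula)), "term.labels"))
  expect_equal(unname(partial_effects(fit, all_terms, remove_random = TRUE)),
               unname(residuals(fit$model)), tolerance = 1e-8)
  expect_error(partial_effects(fit, "bogus"), "bogus")

  # partialing out the nuisance factor recovers the other slope by OLS
  adj <- partial_effects(fit, remove_fixed = "dp", remove_random = TRUE)
  pcc <- ifelse(d$pc == "intact", 0.5, -0.5)
  slope <- coef(lm(adj ~ pcc))[2]
  se <- summary(lm(adj ~ pcc))$coefficients[2, 2]
  expect_lt(abs(slope - (-30)), 3 * se)
})

test_that("amplitude rescaling divides columns and scales slopes inversely", {
  d <- tibble::tibble(x = c(15, -5, 30), y = c(1, 2, 3))
  expect_equal(rescale_amplitudes(d, "x")$x, c(1.5, -0.5, 3))
  expect_equal(rescale_amplitudes(d, "x", factor = 1)$x, d$x)
  set.seed(7)
  d2 <- tibble::tibble(x = rnorm(50), e = rnorm(50))
  d2$y <- 3 * d2$x + d2$e
  d2r <- rescale_amplitudes(d2, "x")
  expect_equal(unname(coef(lm(y ~ x, d2r))[2]),
               10 * unname(coef(lm(y ~ x, d2))[2]), tolerance = 1e-8)
  expect_error(rescale_amplitudes(d, "zz"), "zz")
})
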