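# Single-trial mixed-model stage.
#
# The models are fit by lme4 (lmerTest supplies Satterthwaite degrees of
# freedom for gaussian fits); this module owns everything around the
# solver: sliding-difference contrast coding, singular random-term pruning,
# stepwise fixed-effect reduction by likelihood-ratio tests, nested
# follow-up models, and remef-style partial effects.

#' Sliding-difference (successive differences) contrast matrix
#'
#' Each contrast estimates the difference between consecutive factor levels
#' (level 2 minus level 1, level 3 minus level 2, ...), and the intercept
#' estimates the unweighted grand mean of the cell means — not the mean of
#' a baseline cell as under treatment coding. Columns sum to zero.
#'
#' @param n_levels Number of factor levels (>= 2).
#' @return `n_levels` x `(n_levels - 1)` contrast matrix.
#' @export
sliding_difference_contrasts <- function(n_levels) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 2)
    abort("`n_levels` must be a single integer >= 2.")
  MASS::contr.sdif(as.integer(n_levels))
}

# Coerce character predictors to factors and install sliding-difference
# contrasts on every factor the formula uses.
prepare_model_data <- function(formula, data) {
  data <- as_tibble(data)
  vars <- intersect(all.vars(formula), names(data))
  for (v in vars) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]])) {
      data[[v]] <- droplevels(data[[v]])
      if (nlevels(data[[v]]) >= 2)
        contrasts(data[[v]]) <- sliding_difference_contrasts(nlevels(data[[v]]))
    }
  }
  data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
}

#' Fit a (generalized) linear mixed model on single-trial data
#'
#' Thin, contract-preserving wrapper around `lmerTest::lmer` /
#' `lme4::glmer`: sliding-difference contrasts are installed on all factor
#' predictors, rows with missing values in model variables are dropped
#' listwise, gaussian fits report Satterthwaite-approximated p values,
#' binomial fits report Wald z tests. Crossed random effects (e.g.
#' `(1 + pc | participant_id) + (1 | item_id)`) are supported throughout.
#'
#' A singular fit (a random term estimated at the boundary) is returned,
#' not errored, with the singularity recorded — see
#' [prune_singular_random_terms()] for the repair strategy.
#'
#' @param formula lme4-style model formula with fixed and random terms.
#' @param data Long-format data (one row per trial).
#' @param family `"gaussian"` (identity link, REML by default) or
#'   `"binomial"` (logit).
#' @param REML Use REML for gaussian variance estimation (default `TRUE`;
#'   likelihood-ratio model comparisons refit with ML automatically).
#' @return Object of class `trial_fit` wrapping the backend fit; use
#'   [tidy()], [glance()], [variance_components()], [blups()].
#' @export
fit_trial_model <- function(formula, data, family = c("gaussian", "binomial"),
                            REML = TRUE) {
  family <- match.arg(family)
  data <- prepare_model_data(formula, data)
  if (nrow(data) == 0L) abort("no complete rows left to fit.")
  has_ranef <- length(lme4::findbars(formula)) > 0
  model <- if (family == "gaussian") {
    if (has_ranef) {
      lmerTest::lmer(formula, data = data, REML = REML,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      stats::lm(formula, data = data)
    }
  } else {
    if (has_ranef) {
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(check.conv.singular = "ignore"))
    } else {
      stats::glm(formula, data = data, family = stats::binomial())
    }
  }
  structure(list(model = model, formula = formula, family = family,
                 data = data, REML = REML && family == "gaussian"),
            class = "trial_fit")
}

is_mermod <- function(fit) methods::is(fit$model, "merMod")

#' @export
print.trial_fit <- function(x, ...) {
  cat(sprintf("<trial_fit> %s %s | n = %d%s\n", x$family,
              if (is_mermod(x)) "mixed model" else "fixed-effects model",
              nrow(x$data),
              if (is_mermod(x) && lme4::isSingular(x$model)) " | SINGULAR" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy fixed-effect estimates of a trial-level model fit
#'
#' @param x A [fit_trial_model()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (b), `std.error` (SE),
#'   `statistic` (t for gaussian, z for binomial), `df` (Satterthwaite, where
#'   available) and `p.value`.
#' @method tidy trial_fit
#' @export
tidy.trial_fit <- function(x, ...) {
  cf <- coef(summary(x$model))
  out <- tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                std.error = cf[, "Std. Error"])
  if (x$family == "gaussian") {
    out$statistic <- cf[, "t value"]
    if ("df" %in% colnames(cf)) {         # lmerTest Satterthwaite
      out$df <- cf[, "df"]
      out$p.value <- cf[, "Pr(>|t|)"]
    } else if ("Pr(>|t|)" %in% colnames(cf)) {
      out$p.value <- cf[, "Pr(>|t|)"]
    } else {
      inform("backend provided no t-distribution df; using normal approximation for p values.")
      out$p.value <- 2 * pnorm(-abs(out$statistic))
    }
  } else {
    out$statistic <- cf[, "z value"]
    out$p.value <- cf[, "Pr(>|z|)"]
  }
  out
}

#' One-line model summary
#'
#' @param x A [fit_trial_model()] result.
#' @param ... Unused.
#' @return Tibble with `logLik`, `REML_deviance` (gaussian REML fits, else
#'   `NA`), `AIC`, `BIC`, `nobs`, `sigma` (residual SD), `singular`.
#' @method glance trial_fit
#' @export
glance.trial_fit <- function(x, ...) {
  singular <- if (is_mermod(x)) lme4::isSingular(x$model) else FALSE
  tibble(
    logLik = as.numeric(logLik(x$model)),
    REML_deviance = if (x$REML && is_mermod(x)) lme4::REMLcrit(x$model) else NA_real_,
    AIC = AIC(x$model), BIC = BIC(x$model),
    nobs = nrow(x$data),
    sigma = if (x$family == "gaussian") stats::sigma(x$model) else NA_real_,
    singular = singular)
}

#' Random-effect standard deviations
#'
#' @param fit A [fit_trial_model()] result with random effects.
#' @return Tibble `group`, `term`, `sd` (one row per variance component,
#'   residual included for gaussian fits).
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "trial_fit"))
  if (!is_mermod(fit))
    return(tibble(group = "Residual", term = "sd",
                  sd = if (fit$family == "gaussian") stats::sigma(fit$model) else NA_real_))
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  vc <- vc[is.na(vc$var2), , drop = FALSE]       # drop correlations
  tibble(group = vc$grp,
         term = ifelse(is.na(vc$var1), "sd", vc$var1),
         sd = vc$sdcor)
}

#' Per-group deviations (BLUPs)
#'
#' @param fit A [fit_trial_model()] result.
#' @return Tibble `group`, `level`, `term`, `blup`.
#' @export
blups <- function(fit) {
  stopifnot(inherits(fit, "trial_fit"))
  if (!is_mermod(fit)) return(tibble(group = character(), level = character(),
                                     term = character(), blup = numeric()))
  re <- lme4::ranef(fit$model)
  purrr::imap(re, function(df, grp) {
    tidyr::pivot_longer(
      dplyr::mutate(as_tibble(df, rownames = "level"), group = grp),
      cols = -c("level", "group"), names_to = "term", values_to = "blup")
  }) |> dplyr::bind_rows()
}

# ---- random-effect formula surgery ----------------------------------------

# Decompose the random part of an lme4 formula into a list of
# list(group = "participant_id", terms = c("1", "pc")).
random_structure <- function(formula) {
  bars <- lme4::findbars(formula)
  lapply(bars, function(b) {
    lhs <- b[[2]]; grp <- deparse(b[[3]])
    tt <- terms(reformulate(deparse(lhs)))
    labs <- attr(tt, "term.labels")
    has_int <- attr(tt, "intercept") == 1
    list(group = grp, terms = c(if (has_int) "1", labs))
  })
}

# Rebuild a full lme4 formula from fixed terms + random structure.
assemble_formula <- function(response, fixed_terms, rand) {
  fixed <- if (length(fixed_terms) == 0) "1" else paste(fixed_terms, collapse = " + ")
  rparts <- vapply(rand, function(r) {
    inner <- if (length(r$terms) == 0) "0" else {
      slopes <- setdiff(r$terms, "1")
      paste(c(if ("1" %in% r$terms) "1" else "0", slopes), collapse = " + ")
    }
    sprintf("(%s | %s)", inner, r$group)
  }, character(1))
  as.formula(paste(response, "~", paste(c(fixed, rparts), collapse = " + ")),
             env = globalenv())
}

fixed_terms_of <- function(formula) {
  attr(terms(lme4::nobars(formula)), "term.labels")
}

response_of <- function(formula) deparse(formula[[2]])

#' Drop random terms that explain (numerically) zero variance
#'
#' Refits the model, and while the fit is singular — any random-effect
#' standard deviation below `tol` times the residual SD (or below `tol` for
#' binomial models), or a degenerate random-effect covariance — removes the
#' offending term with the smallest SD and refits. Random slopes are always
#' removed before their group's intercept, and the last remaining intercept
#' is never removed, so the worst case is an intercept-only random
#' structure. The removal order is deterministic and returned as a log.
#'
#' @param formula lme4-style formula.
#' @param data Long-format data.
#' @param family `"gaussian"` or `"binomial"`.
#' @param tol Singularity tolerance relative to the residual SD (default
#'   `1e-6`).
#' @return List: `fit` (final [fit_trial_model()] result), `formula` (the
#'   reduced formula), `log` (tibble `step`, `group`, `term`, `sd`).
#' @export
prune_singular_random_terms <- function(formula, data,
                                        family = c("gaussian", "binomial"),
                                        tol = 1e-6) {
  family <- match.arg(family)
  rand <- random_structure(formula)
  if (length(rand) == 0) abort("formula has no random terms to prune.")
  fixed <- fixed_terms_of(formula)
  response <- response_of(formula)
  log <- tibble(step = integer(), group = character(), term = character(),
                sd = numeric())
  repeat {
    f <- assemble_formula(response, fixed, rand)
    fit <- fit_trial_model(f, data, family = family)
    vc <- variance_components(fit)
    resid_sd <- if (family == "gaussian")
      vc$sd[vc$group == "Residual"][1] else 1
    comp <- vc[vc$group != "Residual", , drop = FALSE]
    # VarCorr reports model-matrix column names (e.g. "pc2-1" for a factor
    # slope); fold them back onto the formula terms they encode and keep
    # each term's largest component SD as its effective size
    col_map <- c("(Intercept)" = "1")
    all_rand_terms <- unique(unlist(lapply(rand, `[[`, "terms")))
    for (lb in setdiff(all_rand_terms, "1")) {
      mm <- colnames(model.matrix(reformulate(lb), fit$data))
      col_map[setdiff(mm, "(Intercept)")] <- lb
    }
    comp$term <- unname(col_map[comp$term])
    comp <- comp |>
      dplyr::group_by(.data$group, .data$term) |>
      dplyr::summarise(sd = max(.data$sd), .groups = "drop")
    comp$is_slope <- comp$term != "1"
    thresh <- tol * max(resid_sd, .Machine$double.eps)
    degenerate <- comp$sd < thresh
    singular <- is_mermod(fit) && lme4::isSingular(fit$model, tol = 1e-5)
    if (!any(degenerate) && !singular) break
    cand <- comp[if (any(degenerate)) degenerate else rep(TRUE, nrow(comp)), ,
                 drop = FALSE]
    # slopes first; among equals the smallest SD goes
    cand <- cand[order(-cand$is_slope, cand$sd), , drop = FALSE]
    # never remove the very last random term
    n_terms_total <- sum(vapply(rand, function(r) length(r$terms), integer(1)))
    removed <- FALSE
    for (i in seq_len(nrow(cand))) {
      gi <- which(vapply(rand, function(r) r$group == cand$group[i], logical(1)))
      r <- rand[[gi]]
      # an intercept may only go once its group's slopes are gone
      if (cand$term[i] == "1" && length(setdiff(r$terms, "1")) > 0) next
      if (n_terms_total <= 1L) break
      rand[[gi]]$terms <- setdiff(r$terms, cand$term[i])
      if (length(rand[[gi]]$terms) == 0) rand[[gi]] <- NULL
      log <- dplyr::bind_rows(log, tibble(step = nrow(log) + 1L,
                                          group = cand$group[i],
                                          term = cand$term[i],
                                          sd = cand$sd[i]))
      removed <- TRUE
      break
    }
    if (!removed) break
  }
  list(fit = fit, formula = assemble_formula(response, fixed, rand), log = log)
}

# ---- fixed-effect reduction ------------------------------------------------

# Terms that may be dropped: those not marginal to a retained higher-order
# interaction.
removable_terms <- function(term_labels) {
  varsets <- lapply(strsplit(term_labels, ":", fixed = TRUE), sort)
  keep <- vapply(seq_along(varsets), function(i) {
    !any(vapply(seq_along(varsets), function(j) {
      i != j && all(varsets[[i]] %in% varsets[[j]])
    }, logical(1)))
  }, logical(1))
  term_labels[keep]
}

term_order <- function(label) length(strsplit(label, ":", fixed = TRUE)[[1]])

# Worst (largest) coefficient p value per fixed term, used only to order
# candidates; the decision itself is a likelihood-ratio test.
term_pvalues <- function(fit) {
  td <- tidy(fit)
  X <- model.matrix(fit$model)
  assign <- attr(X, "assign")
  labels <- fixed_terms_of(fit$formula)
  vapply(labels, function(lb) {
    cols <- which(assign == match(lb, labels))
    max(td$p.value[match(colnames(X)[cols], td$term)], na.rm = TRUE)
  }, numeric(1))
}

#' Likelihood-ratio comparison of two nested fits
#'
#' Both models are refit with ML when needed (gaussian REML fits cannot be
#' compared across fixed-effect structures).
#'
#' @param big,small Nested [fit_trial_model()] results (same data).
#' @return Tibble `statistic` (chi-square), `df`, `p.value`, `dAIC`, `dBIC`
#'   (small minus big; negative favors the smaller model), `preferred`
#'   (`"small"` if the test does not reject at 0.05).
#' @export
lrt_compare <- function(big, small) {
  stopifnot(inherits(big, "trial_fit"), inherits(small, "trial_fit"))
  if (is_mermod(big) || is_mermod(small)) {
    a <- suppressMessages(anova(big$model, small$model, refit = TRUE))
  } else {
    a <- anova(small$model, big$model, test = "LRT")
  }
  if (is_mermod(big) || is_mermod(small)) {
    # anova() orders the models by complexity: row 1 = smaller model
    stat <- a$Chisq[2]; df <- a$Df[2]; p <- a$`Pr(>Chisq)`[2]
    daic <- a$AIC[1] - a$AIC[2]; dbic <- a$BIC[1] - a$BIC[2]
  } else {
    stat <- a$Deviance[2]; df <- a$Df[2]; p <- a$`Pr(>Chi)`[2]
    daic <- AIC(small$model) - AIC(big$model)
    dbic <- BIC(small$model) - BIC(big$model)
  }
  tibble(statistic = stat, df = df, p.value = p, dAIC = daic, dBIC = dbic,
         preferred = if (!is.na(p) && p < 0.05) "big" else "small")
}

#' Stepwise reduction of the fixed-effect structure
#'
#' Starting from the full model, repeatedly drops the least significant
#' removable fixed term (interactions before the main effects they contain;
#' candidates ordered by their worst coefficient p value, ties broken in
#' favor of higher-order terms) and tests the smaller against the larger
#' model with a likelihood-ratio test. Reduction stops when the smaller
#' model explains the data significantly worse (LRT p < `alpha`). Each step
#' reports the chi-square statistic, AIC and BIC differences.
#'
#' @param formula Full lme4-style formula.
#' @param data Long-format data.
#' @param family `"gaussian"` or `"binomial"`.
#' @param alpha LRT stopping level (default 0.05).
#' @return List: `fit` (final [fit_trial_model()], REML for gaussian),
#'   `formula`, `trail` (tibble: `step`, `dropped`, `statistic`, `df`,
#'   `p.value`, `dAIC`, `dBIC`, `kept` — `TRUE` when the drop was rejected
#'   and the term retained).
#' @export
reduce_fixed_effects <- function(formula, data,
                                 family = c("gaussian", "binomial"),
                                 alpha = 0.05) {
  family <- match.arg(family)
  response <- response_of(formula)
  rand <- random_structure(formula)
  fixed <- fixed_terms_of(formula)
  trail <- tibble(step = integer(), dropped = character(),
                  statistic = numeric(), df = numeric(), p.value = numeric(),
                  dAIC = numeric(), dBIC = numeric(), kept = logical())
  current <- fit_trial_model(assemble_formula(response, fixed, rand), data,
                             family = family)
  repeat {
    cand_labels <- removable_terms(fixed)
    if (length(cand_labels) == 0) break
    pvals <- term_pvalues(current)[cand_labels]
    ord <- order(-pvals, -vapply(cand_labels, term_order, numeric(1)))
    candidate <- cand_labels[ord[1]]
    smaller_fixed <- setdiff(fixed, candidate)
    smaller <- fit_trial_model(assemble_formula(response, smaller_fixed, rand),
                               data, family = family)
    cmp <- lrt_compare(current, smaller)
    accepted <- is.na(cmp$p.value) || cmp$p.value >= alpha
    trail <- dplyr::bind_rows(trail, tibble(
      step = nrow(trail) + 1L, dropped = candidate,
      statistic = cmp$statistic, df = cmp$df, p.value = cmp$p.value,
      dAIC = cmp$dAIC, dBIC = cmp$dBIC, kept = !accepted))
    if (!accepted) break
    fixed <- smaller_fixed
    current <- smaller
  }
  list(fit = current,
       formula = assemble_formula(response, fixed, rand),
       trail = trail)
}

#' Nested follow-up of an interaction
#'
#' Refits the model with `inner` nested within the levels of `outer`
#' (fixed part `outer + outer:inner` replacing `inner` and the
#' `inner:outer` interaction; everything else, including the random
#' structure, is kept identical) and returns the estimate of the `inner`
#' sliding-difference effect at each level of `outer`.
#'
#' @param formula Original lme4-style formula containing both factors.
#' @param data Long-format data.
#' @param inner,outer Factor column names: the effect of `inner` is
#'   estimated within each level of `outer`.
#' @param family `"gaussian"` or `"binomial"`.
#' @return List: `estimates` (tibble `outer_level`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`), `fit` (the nested
#'   [fit_trial_model()]).
#' @export
nested_followup <- function(formula, data, inner, outer,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  fixed <- fixed_terms_of(formula)
  absent <- setdiff(c(inner, outer), all.vars(lme4::nobars(formula)))
  if (length(absent) > 0)
    abort(sprintf("factor(s) not in the fixed part of the formula: %s",
                  paste(absent, collapse = ", ")))
  data2 <- as_tibble(data)
  if (is.character(data2[[outer]])) data2[[outer]] <- factor(data2[[outer]])
  # unused factor levels have no trials by construction and are dropped;
  # the error below names levels that are present but unusable
  data2[[outer]] <- droplevels(data2[[outer]])
  lvls <- levels(data2[[outer]]) %||% unique(data2[[outer]])
  empty <- lvls[!lvls %in% unique(as.character(
    data2[[outer]][complete.cases(data2[, c(inner, outer)])]))]
  if (length(empty) > 0)
    abort(sprintf("level(s) of `%s` with no data: %s", outer,
                  paste(empty, collapse = ", ")))
  is_pair <- function(lb) {
    vs <- sort(strsplit(lb, ":", fixed = TRUE)[[1]])
    identical(vs, sort(c(inner, outer)))
  }
  fixed2 <- fixed[!(fixed == inner | vapply(fixed, is_pair, logical(1)))]
  fixed2 <- union(union(fixed2, outer), paste0(outer, ":", inner))
  f2 <- assemble_formula(response_of(formula), fixed2,
                         random_structure(formula))
  fit <- fit_trial_model(f2, data2, family = family)
  td <- tidy(fit)
  X <- model.matrix(fit$model)
  assign <- attr(X, "assign")
  labels <- fixed_terms_of(f2)
  nest_lab <- paste0(outer, ":", inner)
  cols <- which(assign == match(nest_lab, labels))
  rows <- td[match(colnames(X)[cols], td$term), , drop = FALSE]
  lev_of <- vapply(rows$term, function(nm) {
    hit <- lvls[vapply(lvls, function(l) grepl(paste0(outer, l), nm, fixed = TRUE),
                       logical(1))]
    if (length(hit) >= 1) hit[which.max(nchar(hit))] else NA_character_
  }, character(1))
  list(estimates = dplyr::bind_cols(tibble(outer_level = lev_of), rows),
       fit = fit)
}

#' Remef-style partial effects
#'
#' Removes the contribution of chosen fixed terms (and optionally all
#' random effects) from the observed response, leaving the effects of
#' interest plus residual: `y_partial = y - X_removed b_removed - Z u`.
#' Removing nothing returns the observed response; removing every term
#' (intercept included) and the random effects returns the residuals.
#' Gaussian fits only.
#'
#' @param fit A gaussian [fit_trial_model()] result.
#' @param remove_fixed Character vector of fixed terms to remove
#'   (`"(Intercept)"` allowed).
#' @param remove_random Remove the BLUP-weighted random-effect
#'   contributions as well (default `FALSE`).
#' @return Numeric vector, one adjusted response per fitted observation.
#' @export
partial_effects <- function(fit, remove_fixed = character(),
                            remove_random = FALSE) {
  stopifnot(inherits(fit, "trial_fit"))
  if (fit$family != "gaussian")
    abort("partial effects are defined here for gaussian fits only.")
  X <- model.matrix(fit$model)
  assign <- attr(X, "assign")
  labels <- fixed_terms_of(fit$formula)
  known <- c("(Intercept)", labels)
  unknown <- setdiff(remove_fixed, known)
  if (length(unknown) > 0)
    abort(sprintf("unknown term(s): %s (model terms: %s)",
                  paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  y <- fit$data[[response_of(fit$formula)]]
  adj <- y
  if (length(remove_fixed) > 0) {
    target <- c(if ("(Intercept)" %in% remove_fixed) 0L,
                match(setdiff(remove_fixed, "(Intercept)"), labels))
    cols <- which(assign %in% target)
    b <- if (is_mermod(fit)) lme4::fixef(fit$model) else coef(fit$model)
    adj <- adj - as.vector(X[, cols, drop = FALSE] %*% b[cols])
  }
  if (remove_random && is_mermod(fit)) {
    ran_part <- fitted(fit$model) -
      as.vector(X %*% (if (is_mermod(fit)) lme4::fixef(fit$model) else coef(fit$model)))
    adj <- adj - ran_part
  }
  adj
}

#' Divide amplitude columns by a constant scale factor
#'
#' Rescaling single-trial amplitudes (conventionally by 10) keeps mixed-
#' model optimization well conditioned when microvolt covariates sit next
#' to millisecond responses; downstream slopes then read "per 10 uV". A
#' linear rescaling changes slopes exactly inversely, nothing else.
#'
#' @param data A data frame.
#' @param cols Character vector of numeric columns to rescale.
#' @param factor Divisor (default 10).
#' @return `data` with the columns divided by `factor`.
#' @export
rescale_amplitudes <- function(data, cols, factor = 10) {
  stopifnot_scalar_number(factor, "factor")
  for (cc in cols) {
    if (!cc %in% names(data)) abort(sprintf("unknown column `%s`.", cc))
    if (!is.numeric(data[[cc]])) abort(sprintf("column `%s` is not numeric.", cc))
    data[[cc]] <- data[[cc]] / factor
  }
  data
}
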