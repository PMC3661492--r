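# Maximum-likelihood binomial GLM (IRLS via stats::glm) and greedy
# bidirectional stepwise covariate selection driven by AIC, with the
# deviance-reduction stopping rule that keeps weak covariates out.

#' Fit a binomial (logit) GLM by maximum likelihood
#'
#' Thin wrapper over IRLS (`stats::glm.fit`) that returns the quantities the
#' step search consumes and screens for separation (coefficients running
#' away) and singular designs.
#'
#' @param X numeric design matrix, no intercept column (one is added).
#' @param y binary response vector.
#' @param max_iter,tol IRLS control.
#' @return object of class `glm_fit`: coefficients, log-likelihood,
#'   deviance, AIC, parameter count, convergence flag, iteration count,
#'   separation flag.
#' @export
fit_binomial_glm <- function(X, y, max_iter = 100, tol = 1e-9) {
  if (!is.matrix(X)) X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= ncol(X) + 1)
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) {
    stopf("fit_binomial_glm(): singular design; check columns [%s] for collinearity",
          paste(colnames(Xi)[-1], collapse = ", "))
  }
  fit <- stats::glm.fit(Xi, y, family = binomial(),
                        control = list(maxit = max_iter, epsilon = tol))
  k <- ncol(Xi)
  ll <- -fit$deviance / 2   # Bernoulli saturated log-likelihood is 0
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(Xi)),
    loglik = ll,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    aic = fit$deviance + 2 * k,
    k = k,
    converged = fit$converged,
    iter = fit$iter,
    separation = any(abs(fit$coefficients) > 30)
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("<glm_fit> k =", x$k, " deviance =", format(x$deviance, digits = 6),
      " AIC =", format(x$aic, digits = 6),
      if (x$separation) " [separation suspected]" else "", "\n")
  invisible(x)
}

fit_candidate_model <- function(cov, y, specs, selected) {
  if (!length(selected)) {
    return(fit_binomial_glm(matrix(numeric(0), length(y), 0), y))
  }
  dm <- build_design_matrix_terms(cov, specs[selected])
  fit_binomial_glm(dm, y)
}

# design columns for a set of candidate terms, over observed rows only
build_design_matrix_terms <- function(cov, specs) {
  cols <- list()
  for (spec in specs) {
    x <- cov[[spec$source]]
    if (!is.null(spec$levels)) {
      f <- factor(x, levels = c(spec$reference,
                                setdiff(spec$levels, spec$reference)))
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste(spec$name, levels(f)[-1], sep = "_")
      for (cn in colnames(mm)) cols[[cn]] <- mm[, cn]
    } else {
      cols[[spec$name]] <- transform_column(x, spec)
    }
  }
  do.call(cbind, cols)
}

#' Greedy stepwise covariate selection with a deviance stopping rule
#'
#' Bidirectional search from the intercept-only model over whole candidate
#' terms (a factor enters or leaves with all its contrasts). At each step
#' every single addition and removal is fitted; the move with the greatest
#' AIC reduction wins. An addition is only applied if it also cuts the
#' current model's residual deviance by more than `stop_frac` (default 1%);
#' an addition failing that rule, or no AIC-reducing move, ends the search.
#' A variable and its log transform are never in the model together.
#'
#' @param cov covariate table ([derive_covariates()]) restricted to rows
#'   with a defined response.
#' @param y binary capture-event response aligned with `cov`.
#' @param candidates named list of [covariate_spec()]s.
#' @param stop_frac minimum relative residual-deviance reduction an accepted
#'   addition must achieve.
#' @return list with `selected` (names, in order of entry), `trace`
#'   (tibble: step, action, term, AIC and deviance before/after, relative
#'   deviance reduction), and `fit` (the final `glm_fit`).
#' @export
step_select <- function(cov, y, candidates = default_covariate_specs(),
                        stop_frac = 0.01) {
  stopifnot(length(candidates) > 0, all(y %in% c(0, 1)))
  cand_names <- sort(names(candidates))   # deterministic under permutation
  selected <- character()
  current <- fit_candidate_model(cov, y, candidates, selected)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- list()
    excluded <- unlist(lapply(candidates[selected], `[[`, "excludes"))
    mutual <- names(Filter(function(s) any(s$excludes %in% selected), candidates))
    for (nm in setdiff(cand_names, union(selected, union(excluded, mutual)))) {
      fit <- try(fit_candidate_model(cov, y, candidates, c(selected, nm)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        stopf("step_select(): candidate '%s' failed to fit: %s", nm,
              attr(fit, "condition")$message)
      }
      moves[[paste0("+", nm)]] <- fit
    }
    for (nm in selected) {
      moves[[paste0("-", nm)]] <-
        fit_candidate_model(cov, y, candidates, setdiff(selected, nm))
    }
    if (!length(moves)) break
    aics <- vapply(moves, `[[`, 0, "aic")
    best <- names(moves)[order(aics, names(moves))][1]
    if (aics[best] >= current$aic) break
    fit <- moves[[best]]
    action <- substr(best, 1, 1)
    term <- substring(best, 2)
    rel_red <- (current$deviance - fit$deviance) / current$deviance
    if (action == "+" && rel_red <= stop_frac) break   # too weak: not applied
    trace[[step]] <- tibble::tibble(
      step = step, action = if (action == "+") "add" else "remove",
      term = term, aic_before = current$aic, aic_after = fit$aic,
      deviance_before = current$deviance, deviance_after = fit$deviance,
      rel_deviance_reduction = rel_red)
    selected <- if (action == "+") c(selected, term) else setdiff(selected, term)
    current <- fit
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         tibble::tibble(step = integer(), action = character(),
                        term = character(), aic_before = numeric(),
                        aic_after = numeric(), deviance_before = numeric(),
                        deviance_after = numeric(),
                        rel_deviance_reduction = numeric()),
       fit = current)
}
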