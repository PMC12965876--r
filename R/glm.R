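#' Fit a Gaussian log-link GLM with survey-style diagnostics
#'
#' The workhorse model of the pipeline: a Gaussian-family GLM with log link,
#' i.e. `E[y] = exp(X beta)` with additive Gaussian error. The log link
#' captures the multiplicative, outlier-prone behaviour of biodiversity
#' metrics while keeping the response untransformed. Responses containing
#' zeros or occasional negative values are handled by flooring the IRLS
#' starting means at a small positive value; no offset is added to the
#' response itself.
#'
#' @param response name of the response column in `data`.
#' @param terms character vector of predictor term names (may be empty for an
#'   intercept-only model); a factor column enters as a single term.
#' @param data data.frame containing response and predictors.
#' @param link `"log"` (the pipeline default) or `"identity"` (ordinary least
#'   squares within the same machinery, used for cross-checks).
#' @param maxit,epsilon IRLS control passed to [stats::glm.control()].
#' @return object of class `driver_glm`: list with the `stats::glm` fit,
#'   `response`, `terms`, `converged`, and `diagnostics` (`r2` the squared
#'   Pearson correlation of predicted vs observed, plus `mae`, `mse`, `rmse`).
#' @export
fit_driver_glm <- function(response, terms, data, link = c("log", "identity"),
                           maxit = 100L, epsilon = 1e-8) {
  link <- match.arg(link)
  stopifnot(is.character(response), length(response) == 1L,
            response %in% names(data))
  terms <- as.character(terms)
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms))
    stop_config("terms not found in data: %s", paste(missing_terms, collapse = ", "))
  y <- data[[response]]
  if (!is.numeric(y)) stop_config("response '%s' must be numeric", response)
  n <- length(y)
  if (n <= length(terms) + 1L)
    stop_config("need n > number of terms + 1 (n = %d, terms = %d)", n, length(terms))
  fml <- stats::reformulate(if (length(terms)) terms else "1", response = response)
  # log link needs positive starting means even when y has zeros/negatives
  pos <- y[y > 0]
  floor_mu <- if (length(pos)) max(1e-6, 0.05 * mean(pos)) else 1e-3
  fit <- tryCatch(
    if (link == "log") {
      stats::glm(fml, data = data, family = stats::gaussian(link = "log"),
                 mustart = pmax(y, floor_mu),
                 control = stats::glm.control(maxit = maxit, epsilon = epsilon))
    } else {
      stats::glm(fml, data = data, family = stats::gaussian(),
                 control = stats::glm.control(maxit = maxit, epsilon = epsilon))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(fit = NULL, response = response, terms = terms,
                converged = FALSE, error = conditionMessage(fit),
                diagnostics = NULL)
    class(out) <- "driver_glm"
    return(out)
  }
  out <- list(fit = fit, response = response, terms = terms,
              converged = isTRUE(fit$converged),
              diagnostics = glm_diagnostics(fit, y))
  class(out) <- "driver_glm"
  out
}

glm_diagnostics <- function(fit, y) {
  mu <- stats::fitted(fit)
  r2 <- if (stats::sd(mu) == 0 || stats::sd(y) == 0) 0 else stats::cor(mu, y)^2
  err <- y - mu
  list(r2 = r2, mae = mean(abs(err)), mse = mean(err^2), rmse = sqrt(mean(err^2)),
       aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)))
}

#' @export
print.driver_glm <- function(x, ...) {
  cat("Gaussian log-link GLM (driver_glm)\n")
  cat("  response:", x$response, "\n")
  cat("  terms:   ", if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)", "\n")
  if (!is.null(x$groups)) {
    gl <- vapply(names(x$groups), function(g)
      sprintf("%s[%d]", g, length(x$groups[[g]])), character(1))
    cat("  groups:  ", paste(gl, collapse = "  "), "\n")
  }
  if (!x$converged) {
    cat("  ** fit did not converge **\n")
  } else {
    d <- x$diagnostics
    cat(sprintf("  AIC %.2f   r2 %.3f   RMSE %.4g\n", d$aic, d$r2, d$rmse))
  }
  invisible(x)
}

#' @export
summary.driver_glm <- function(object, ...) {
  out <- list(model = object,
              coef_table = if (!is.null(object$fit)) stats::coef(summary(object$fit)),
              diagnostics = object$diagnostics,
              path = object$path)
  class(out) <- "summary.driver_glm"
  out
}

#' @export
print.summary.driver_glm <- function(x, ...) {
  print(x$model)
  if (!is.null(x$coef_table)) {
    cat("\nCoefficients:\n")
    stats::printCoefmat(x$coef_table, signif.stars = FALSE)
  }
  d <- x$diagnostics
  if (!is.null(d))
    cat(sprintf("\nr2 = %.4f  MAE = %.4g  MSE = %.4g  RMSE = %.4g\n",
                d$r2, d$mae, d$mse, d$rmse))
  if (!is.null(x$path) && nrow(x$path)) {
    cat("\nSelection path:\n")
    print(x$path, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.driver_glm <- function(object, ...) stats::coef(object$fit)

#' @export
predict.driver_glm <- function(object, newdata = NULL, type = "response", ...) {
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.driver_glm <- function(object, type = "response", ...) {
  stats::residuals(object$fit, type = type, ...)
}

#' @export
fitted.driver_glm <- function(object, ...) stats::fitted(object$fit)

#' @export
AIC.driver_glm <- function(object, ..., k = 2) stats::AIC(object$fit, k = k)

#' @export
plot.driver_glm <- function(x, ...) {
  r <- stats::residuals(x$fit, type = "response")
  stats::qqnorm(r, main = paste("Normal QQ,", x$response), ...)
  stats::qqline(r)
  invisible(x)
}

#' Scope-constrained bidirectional AIC stepwise selection
#'
#' Starting from `start_terms`, repeatedly evaluates every single-term
#' addition from `scope_upper` and every single-term deletion not protected by
#' `scope_lower`, accepting the move with the largest AIC decrease; stops when
#' no move lowers the AIC. AIC counts the estimated Gaussian dispersion as a
#' parameter. Exact AIC ties between candidate moves are broken by preferring
#' deletion over addition, then lexicographic term name, so the selected set
#' is deterministic. Candidate fits that fail or do not converge are skipped
#' with a warning.
#'
#' @param response response column name.
#' @param data data.frame of response and candidate predictors.
#' @param start_terms terms of the start model (default: `scope_lower`).
#' @param scope_lower terms that must stay in the model.
#' @param scope_upper terms allowed to enter (must contain `scope_lower`).
#' @param link link function passed to [fit_driver_glm()].
#' @param trace print accepted moves.
#' @return a `driver_glm` for the final model, with `$path` recording every
#'   accepted move and its AIC (strictly decreasing).
#' @export
stepwise_aic <- function(response, data, scope_lower = character(0),
                         scope_upper, start_terms = scope_lower,
                         link = "log", trace = FALSE) {
  scope_lower <- as.character(scope_lower)
  scope_upper <- as.character(scope_upper)
  start_terms <- as.character(start_terms)
  if (!all(scope_lower %in% scope_upper))
    stop_config("scope_lower must be a subset of scope_upper")
  if (!all(start_terms %in% scope_upper) || !all(scope_lower %in% start_terms))
    stop_config("start model must satisfy scope_lower <= start <= scope_upper")

  current <- fit_driver_glm(response, start_terms, data, link = link)
  if (!current$converged)
    stop_config("start model failed to converge")
  path <- data.frame(step = 0L, action = "start", term = "",
                     aic = current$diagnostics$aic, stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    cur_terms <- current$terms
    adds <- sort(setdiff(scope_upper, cur_terms))
    drops <- sort(setdiff(cur_terms, scope_lower))
    cand <- rbind(
      if (length(drops)) data.frame(action = "drop", term = drops, stringsAsFactors = FALSE),
      if (length(adds)) data.frame(action = "add", term = adds, stringsAsFactors = FALSE)
    )
    if (is.null(cand) || !nrow(cand)) break
    fits <- vector("list", nrow(cand))
    aics <- rep(NA_real_, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      trms <- if (cand$action[i] == "add") c(cur_terms, cand$term[i])
              else setdiff(cur_terms, cand$term[i])
      f <- fit_driver_glm(response, trms, data, link = link)
      if (!f$converged) {
        warning(sprintf("candidate model (%s %s) failed to converge; skipped",
                        cand$action[i], cand$term[i]), call. = FALSE)
        next
      }
      fits[[i]] <- f
      aics[i] <- f$diagnostics$aic
    }
    cur_aic <- current$diagnostics$aic
    ok <- which(!is.na(aics) & aics < cur_aic - 1e-8)
    if (!length(ok)) break
    best_aic <- min(aics[ok])
    # ties: candidates within 1e-8 of the best; drop before add, then by name
    tied <- ok[aics[ok] <= best_aic + 1e-8]
    tied <- tied[order(cand$action[tied] != "drop", cand$term[tied])]
    pick <- tied[1L]
    current <- fits[[pick]]
    step_i <- step_i + 1L
    path <- rbind(path, data.frame(step = step_i, action = cand$action[pick],
                                   term = cand$term[pick],
                                   aic = current$diagnostics$aic,
                                   stringsAsFactors = FALSE))
    if (trace)
      message(sprintf("step %d: %s %s  (AIC %.3f)", step_i, cand$action[pick],
                      cand$term[pick], current$diagnostics$aic))
  }
  current$path <- path
  current
}

#' Two-stage driver selection: environment first, pesticides second
#'
#' Stage 1 runs bidirectional AIC stepwise selection over soil, climate and
#' ecosystem terms (intercept-only start by default). Stage 2 re-runs the
#' selection with the stage-1 terms locked in (`scope_lower`) and the
#' pesticide concentrations as the only new candidates, so a pesticide enters
#' only if it lowers the AIC beyond what the retained environment already
#' achieves. This ordering prevents pesticides from standing in for the
#' environmental conditions they co-occur with. Only the stage-2 model is
#' meant for downstream attribution.
#'
#' @param response response column name.
#' @param data data.frame holding response, environment and pesticide columns.
#' @param soil_terms,climate_terms continuous environmental candidate terms.
#' @param ecosystem_term name of the ecosystem factor column, or `NULL` to
#'   omit it.
#' @param pesticide_terms pesticide concentration candidate terms (already
#'   near-zero-variance filtered).
#' @param start stage-1 start model: `"intercept"` (default) or `"full"`.
#' @param trace print accepted moves.
#' @return a `driver_glm` with `$groups` (selected terms by driver group),
#'   `$stage1` (the stage-1 model) and `$path` (stage-2 selection path).
#' @export
two_stage_selection <- function(response, data, soil_terms, climate_terms,
                                ecosystem_term = "ecosystem", pesticide_terms,
                                start = c("intercept", "full"), trace = FALSE) {
  start <- match.arg(start)
  env_terms <- c(as.character(soil_terms), as.character(climate_terms),
                 if (!is.null(ecosystem_term)) ecosystem_term)
  s1 <- stepwise_aic(response, data,
                     scope_lower = character(0), scope_upper = env_terms,
                     start_terms = if (start == "intercept") character(0) else env_terms,
                     trace = trace)
  s2 <- stepwise_aic(response, data,
                     scope_lower = s1$terms,
                     scope_upper = c(s1$terms, as.character(pesticide_terms)),
                     start_terms = s1$terms, trace = trace)
  s2$stage1 <- s1
  s2$groups <- list(
    pesticides = intersect(s2$terms, pesticide_terms),
    soil = intersect(s2$terms, soil_terms),
    climate = intersect(s2$terms, climate_terms),
    ecosystem = intersect(s2$terms, ecosystem_term %||% character(0))
  )
  s2
}

#' Variance inflation factors for a fitted driver model
#'
#' Computes per-term VIFs from the model's design matrix: for a single-column
#' term, `VIF = 1 / (1 - R2)` where `R2` comes from regressing that column on
#' all other design columns; a multi-column factor term gets the generalized
#' VIF (Fox-Monette determinant formula on the design-column correlation
#' matrix), reported on both the GVIF and `GVIF^(1/(2 df))` scales. Exactly
#' collinear (aliased) terms are reported as infinite and flagged.
#'
#' @param model a converged `driver_glm` with at least 2 non-intercept terms.
#' @param threshold VIF above which a term is flagged.
#' @return data.frame with columns term, vif (GVIF; equals the ordinary VIF
#'   for single-column terms), gvif_scaled (`GVIF^(1/(2 df))`), df, flagged.
#' @export
vif_check <- function(model, threshold = 10) {
  stopifnot(inherits(model, "driver_glm"))
  if (!model$converged) stop_config("vif_check needs a converged model")
  if (length(model$terms) < 2L)
    stop_config("vif_check needs at least 2 non-intercept terms")
  X <- stats::model.matrix(model$fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(model$fit), "term.labels")
  X <- X[, asgn > 0L, drop = FALSE]
  asgn <- asgn[asgn > 0L]
  aliased <- is.na(stats::coef(model$fit))
  if (any(aliased) || qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    return(data.frame(term = labels, vif = Inf, gvif_scaled = Inf,
                      df = as.integer(table(asgn)[as.character(seq_along(labels))]),
                      flagged = TRUE, stringsAsFactors = FALSE))
  }
  R <- stats::cor(X)
  detR <- det(R)
  out <- do.call(rbind, lapply(seq_along(labels), function(j) {
    cols <- which(asgn == j)
    gvif <- det(R[cols, cols, drop = FALSE]) *
      det(R[-cols, -cols, drop = FALSE]) / detR
    data.frame(term = labels[j], vif = gvif,
               gvif_scaled = gvif^(1 / (2 * length(cols))),
               df = length(cols), stringsAsFactors = FALSE)
  }))
  out$flagged <- out$vif > threshold
  rownames(out) <- NULL
  out
}

#' Residual normality diagnostics
#'
#' Summarizes response-scale residuals with their normal QQ correlation (the
#' correlation between sorted residuals and standard normal quantiles) and the
#' Shapiro-Wilk statistic, as a compact stand-in for a visual QQ inspection.
#'
#' @param model a converged `driver_glm`.
#' @return list with `residuals`, `qq_cor`, `shapiro_w`, `shapiro_p`,
#'   `perfect_fit` (all residuals zero).
#' @export
residual_diagnostics <- function(model) {
  stopifnot(inherits(model, "driver_glm"))
  if (!model$converged) stop_config("residual_diagnostics needs a converged model")
  r <- stats::residuals(model$fit, type = "response")
  n <- length(r)
  if (all(abs(r) < 1e-12))
    return(list(residuals = r, qq_cor = 1, shapiro_w = NA_real_,
                shapiro_p = NA_real_, perfect_fit = TRUE))
  qq_cor <- stats::cor(sort(r), stats::qnorm(stats::ppoints(n)))
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(r) else NULL
  list(residuals = r, qq_cor = qq_cor,
       shapiro_w = if (!is.null(sw)) unname(sw$statistic) else NA_real_,
       shapiro_p = if (!is.null(sw)) sw$p.value else NA_real_,
       perfect_fit = FALSE)
}
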