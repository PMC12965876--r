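#' Variable importance with coefficient sign
#'
#' Ranks the retained terms of a fitted driver model by the absolute
#' t-statistic of their coefficient (|estimate / SE|), annotated with the
#' coefficient's sign so the direction of the association is kept. A
#' multi-level factor term is summarized by its largest-|t| level (sign taken
#' from that level, relative to the reference).
#'
#' @param model a converged `driver_glm` with at least one non-intercept term.
#' @return data.frame of class `vip_table`: term, group (if the model carries
#'   driver-group labels), importance, sign (`"+"` / `"-"`), rank; sorted by
#'   rank. Terms with zero standard error get infinite importance.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "driver_glm"))
  if (!model$converged) stop_config("vip needs a converged model")
  if (!length(model$terms)) stop_config("vip needs at least one non-intercept term")
  ct <- stats::coef(summary(model$fit))
  # map coefficient rows to model terms via the design matrix 'assign'
  asgn <- attr(stats::model.matrix(model$fit), "assign")
  labels <- attr(stats::terms(model$fit), "term.labels")
  rows <- which(asgn > 0L)
  row_term <- labels[asgn[rows]]
  est <- ct[rows, "Estimate"]
  se <- ct[rows, "Std. Error"]
  tval <- ifelse(se == 0, Inf * sign(est), est / se)
  out <- do.call(rbind, lapply(unique(row_term), function(trm) {
    i <- which(row_term == trm)
    j <- i[which.max(abs(tval[i]))]
    data.frame(term = trm, importance = abs(tval[j]),
               sign = if (est[j] >= 0) "+" else "-",
               stringsAsFactors = FALSE)
  }))
  if (!is.null(model$groups)) {
    g2t <- stack_groups(model$groups)
    out$group <- g2t[out$term]
  }
  out <- out[order(-out$importance, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("vip_table", "data.frame")
  out
}

stack_groups <- function(groups) {
  trm <- unlist(groups, use.names = FALSE)
  stats::setNames(rep(names(groups), lengths(groups)), trm)
}

subset_masks <- function(k) seq_len(2^k - 1L)

mask_members <- function(mask, k) which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) > 0L)

#' Variation partitioning of GLM explained variance across driver groups
#'
#' Decomposes the explained variance of a Gaussian log-link GLM into the
#' unique and shared fractions attributable to up to four predictor groups,
#' in the spirit of `vegan::varpart` but using the pipeline's own performance
#' metric: r-squared is the squared Pearson correlation between predicted and
#' observed values (not adjusted R-squared). One sub-model is fitted per
#' non-empty subset of groups — the union of their terms, with no
#' re-selection — and the Venn-region fractions are obtained by Moebius
#' (inclusion-exclusion) inversion of the subset r-squared values. Shared
#' fractions may be negative and are reported as computed, never clipped.
#' Groups with no terms contribute exactly 0 and are reported as dropped.
#'
#' @param response response column name.
#' @param groups named list (at most 4 entries) mapping driver-group name to
#'   the character vector of its model terms (typically the selected terms of
#'   the final model, partitioned by group).
#' @param data data.frame with the response and all terms.
#' @param link link function for the sub-model fits.
#' @return object of class `varpart_glm`: list with `fractions` (data.frame:
#'   one row per Venn region, with the groups it covers and its fraction),
#'   `unique` (named vector, including 0 for dropped groups), `residual`
#'   (`1 - r2(full)`), `r2` (named vector of sub-model r-squared values keyed
#'   by group subset), `dropped` (empty groups).
#' @export
variation_partition <- function(response, groups, data, link = "log") {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (length(groups) > 4L) stop_config("at most 4 driver groups are supported")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_config("groups must be a named list")
  dropped <- names(groups)[lengths(groups) == 0L]
  groups <- groups[lengths(groups) > 0L]
  if (!length(groups)) stop_config("all driver groups are empty")
  k <- length(groups)
  gnames <- names(groups)

  # r2 per non-empty subset of groups
  r2 <- numeric(2^k - 1L)
  names(r2) <- vapply(subset_masks(k), function(m)
    paste(gnames[mask_members(m, k)], collapse = "+"), character(1))
  for (m in subset_masks(k)) {
    terms_m <- unique(unlist(groups[mask_members(m, k)], use.names = FALSE))
    f <- fit_driver_glm(response, terms_m, data, link = link)
    if (!f$converged)
      stop_config("sub-model for group subset {%s} failed to converge",
                  names(r2)[m])
    r2[m] <- f$diagnostics$r2
  }
  full_mask <- 2^k - 1L
  g_of <- function(mask) if (mask == 0L) 0 else r2[mask]

  # Moebius inversion: fraction of the Venn region 'exactly the groups in T'
  #   f_T = sum_{W subset T} (-1)^(|T| - |W| + 1) * r2(U \ W)
  fractions <- vapply(subset_masks(k), function(Tm) {
    tot <- 0
    members <- mask_members(Tm, k)
    sz_T <- length(members)
    for (Wm in 0:Tm) {
      if (bitwAnd(Wm, Tm) != Wm) next  # W must be a subset of T
      sz_W <- length(mask_members(Wm, k))
      tot <- tot + (-1)^(sz_T - sz_W + 1) * g_of(bitwAnd(full_mask, bitwNot(Wm)))
    }
    tot
  }, numeric(1))

  frac_df <- data.frame(
    subset = names(r2),
    n_groups = vapply(subset_masks(k), function(m) length(mask_members(m, k)), integer(1)),
    fraction = fractions,
    stringsAsFactors = FALSE
  )
  uniq <- stats::setNames(rep(0, length(dropped) + k),
                          c(gnames, dropped))
  for (i in seq_len(k))
    uniq[gnames[i]] <- r2[full_mask] - g_of(bitwAnd(full_mask, bitwNot(bitwShiftL(1L, i - 1L))))
  out <- list(fractions = frac_df, unique = uniq,
              residual = 1 - r2[[full_mask]], r2 = r2, dropped = dropped,
              response = response)
  class(out) <- "varpart_glm"
  out
}

#' @export
print.varpart_glm <- function(x, digits = 4, ...) {
  cat("Variation partitioning of GLM explained variance\n")
  cat("  response:", x$response, "\n")
  df <- x$fractions
  df$fraction <- round(df$fraction, digits)
  print(df, row.names = FALSE)
  cat(sprintf("  residual: %.*f   (fractions + residual sum to %.6f)\n",
              digits, x$residual, sum(x$fractions$fraction) + x$residual))
  if (length(x$dropped))
    cat("  groups with no terms (fraction 0):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Stack attribution results across biodiversity metrics
#'
#' Applies [vip()] and [variation_partition()] to each final model of a
#' metric collection and stacks the results into tidy long-format tables —
#' the data behind importance-network and stacked-bar style summaries.
#'
#' @param models named list of `driver_glm` objects (one per biodiversity
#'   metric) carrying `$groups` driver-group labels, as returned by
#'   [two_stage_selection()].
#' @param data data.frame used to refit the partition sub-models.
#' @return list with `vip` (metric, term, group, importance, sign, rank),
#'   `partition` (metric, subset, n_groups, fraction, plus residual rows),
#'   `unique` (metric, group, fraction — zero rows kept for groups whose
#'   terms were never selected).
#' @export
attribute_all <- function(models, data) {
  stopifnot(is.list(models), !is.null(names(models)))
  vips <- list(); parts <- list(); uniqs <- list()
  for (metric in names(models)) {
    m <- models[[metric]]
    stopifnot(inherits(m, "driver_glm"))
    if (is.null(m$groups))
      stop_config("model for '%s' carries no driver-group labels", metric)
    if (length(m$terms)) {
      v <- vip(m)
      vips[[metric]] <- cbind(metric = metric, as.data.frame(v))
    }
    vp <- variation_partition(m$response, m$groups, data)
    pf <- rbind(
      cbind(metric = metric, vp$fractions),
      data.frame(metric = metric, subset = "residual", n_groups = 0L,
                 fraction = vp$residual, stringsAsFactors = FALSE)
    )
    parts[[metric]] <- pf
    uniqs[[metric]] <- data.frame(metric = metric, group = names(vp$unique),
                                  fraction = unname(vp$unique),
                                  stringsAsFactors = FALSE)
  }
  list(vip = do.call(rbind, c(vips, list(make.row.names = FALSE))),
       partition = do.call(rbind, c(parts, list(make.row.names = FALSE))),
       unique = do.call(rbind, c(uniqs, list(make.row.names = FALSE))))
}
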