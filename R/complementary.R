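# Kruskal-Wallis with the degenerate all-tied case defined: no separation at
# all means H = 0, p = 1 (stats::kruskal.test returns NaN there because the
# tie correction divides by zero).
kw_test <- function(x, g) {
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  kw <- stats::kruskal.test(x, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value)
}

#' Environmental conditions associated with pesticide presence
#'
#' For every pesticide retained in a final model, tests whether each
#' environmental variable selected in the same model differs between sites
#' where the pesticide was detected (concentration > 0 after censoring) and
#' sites where it was not, using a Kruskal-Wallis test (for two groups this
#' is equivalent to a Wilcoxon rank-sum test). Raw and Benjamini-Hochberg
#' adjusted p-values are reported side by side.
#'
#' @param models named list of `driver_glm` objects carrying `$groups`.
#' @param conc censored site x pesticide concentration matrix, rows aligned
#'   with `env`.
#' @param env site environment data.frame.
#' @return data.frame with metric, pesticide, env_var, n_present, n_absent,
#'   H, df, p, q (BH across the whole table). Pairs with an empty presence
#'   group are listed with `NA` statistics and a reason.
#' @export
presence_env_tests <- function(models, conc, env) {
  stopifnot(is.list(models), !is.null(names(models)))
  conc <- as.matrix(conc)
  stopifnot(nrow(conc) == nrow(env))
  rows <- list()
  for (metric in names(models)) {
    m <- models[[metric]]
    pests <- m$groups$pesticides
    env_vars <- c(m$groups$soil, m$groups$climate)
    if (!length(pests) || !length(env_vars)) next
    for (p in pests) {
      present <- conc[, p] > 0
      for (v in env_vars) {
        if (!any(present) || all(present)) {
          rows[[length(rows) + 1L]] <- data.frame(
            metric = metric, pesticide = p, env_var = v,
            n_present = sum(present), n_absent = sum(!present),
            H = NA_real_, df = NA_integer_, p = NA_real_,
            skipped = "empty presence group", stringsAsFactors = FALSE)
          next
        }
        kw <- kw_test(env[[v]], factor(present))
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, pesticide = p, env_var = v,
          n_present = sum(present), n_absent = sum(!present),
          H = kw$H, df = kw$df, p = kw$p, skipped = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(metric = character(0), pesticide = character(0),
               env_var = character(0), n_present = integer(0),
               n_absent = integer(0), H = numeric(0), df = integer(0),
               p = numeric(0), skipped = character(0))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Spearman correlation screen: biodiversity vs aggregated pesticide metrics
#'
#' Rank correlations (average-rank tie handling) between every biodiversity
#' metric and every aggregated pesticide metric (occurrence counts per type,
#' cumulative risks), capturing monotone but nonlinear association.
#' Benjamini-Hochberg adjustment is applied across the whole screen.
#'
#' @param biodiv data.frame keyed by `site_id` with biodiversity metric
#'   columns.
#' @param aggregates data.frame keyed by `site_id` with aggregate columns
#'   (e.g. from [aggregate_occurrence()] / [risk_quotients()]).
#' @param min_pairs minimum number of complete pairs per cell (default 4).
#' @return data.frame with metric, aggregate, n, rho, p, q. Constant columns
#'   yield `NA` with a reason.
#' @export
spearman_screen <- function(biodiv, aggregates, min_pairs = 4L) {
  stopifnot("site_id" %in% names(biodiv), "site_id" %in% names(aggregates))
  merged <- merge(biodiv, aggregates, by = "site_id")
  metrics <- setdiff(names(biodiv), "site_id")
  aggs <- setdiff(names(aggregates), "site_id")
  rows <- list()
  for (mt in metrics) for (ag in aggs) {
    x <- merged[[mt]]; y <- merged[[ag]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < min_pairs) {
      rows[[length(rows) + 1L]] <- data.frame(metric = mt, aggregate = ag, n = n,
                                              rho = NA_real_, p = NA_real_,
                                              note = "too few pairs",
                                              stringsAsFactors = FALSE)
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(metric = mt, aggregate = ag, n = n,
                                              rho = NA_real_, p = NA_real_,
                                              note = "constant column",
                                              stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(metric = mt, aggregate = ag, n = n,
                                            rho = unname(ct$estimate),
                                            p = ct$p.value, note = NA_character_,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Compare per-site residue counts between ecosystem types
#'
#' Counts detected residues per site and compares every pair of ecosystem
#' types with a two-sided Wilcoxon rank-sum test, Benjamini-Hochberg adjusted
#' across pairs; a compact letter display assigns shared letters to pairs
#' that do not differ at `alpha`.
#'
#' @param conc censored site x pesticide concentration matrix.
#' @param env site environment data.frame with an `ecosystem` column aligned
#'   row-wise with `conc`.
#' @param alpha significance level for the letter display.
#' @return list with `pairs` (group1, group2, p, q), `letters` (named
#'   character vector per ecosystem), `counts` (per-site residue counts).
#' @export
ecosystem_residue_comparison <- function(conc, env, alpha = 0.05) {
  conc <- as.matrix(conc)
  stopifnot(nrow(conc) == nrow(env), "ecosystem" %in% names(env))
  eco <- droplevels(factor(env$ecosystem))
  sizes <- table(eco)
  if (length(sizes) < 2L) stop_config("need >= 2 ecosystem types")
  if (any(sizes < 2L))
    stop_config("every ecosystem needs >= 2 sites (violated by: %s)",
                paste(names(sizes)[sizes < 2L], collapse = ", "))
  counts <- rowSums(conc > 0)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(counts, eco, p.adjust.method = "none",
                                exact = FALSE))
  pm <- pw$p.value
  pairs <- do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
    js <- which(!is.na(pm[i, ]))
    if (!length(js)) return(NULL)
    data.frame(group1 = colnames(pm)[js], group2 = rownames(pm)[i],
               p = pm[i, js], stringsAsFactors = FALSE)
  }))
  pairs$q <- stats::p.adjust(pairs$p, method = "BH")
  letters_out <- compact_letter_display(levels(eco), pairs$group1, pairs$group2,
                                        pairs$q < alpha)
  list(pairs = pairs, letters = letters_out, counts = counts)
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb algorithm: groups share a letter if and only if they are
#' not significantly different in any pairwise comparison connecting them.
#'
#' @param groups character vector of group labels.
#' @param g1,g2 pairwise comparison endpoints.
#' @param significant logical vector: is the pair significantly different?
#' @return named character vector of letter codes per group.
#' @export
compact_letter_display <- function(groups, g1, g2, significant) {
  stopifnot(length(g1) == length(g2), length(g1) == length(significant))
  # start with one column containing every group; split on each significant pair
  cols <- list(groups)
  for (i in which(significant)) {
    a <- g1[i]; b <- g2[i]
    new_cols <- list()
    for (cl in cols) {
      if (a %in% cl && b %in% cl) {
        new_cols <- c(new_cols, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else new_cols <- c(new_cols, list(cl))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (u in seq_along(new_cols)) for (v in seq_along(new_cols)) {
      if (u != v && keep[u] && keep[v] &&
          all(new_cols[[u]] %in% new_cols[[v]]) &&
          !(all(new_cols[[v]] %in% new_cols[[u]]) && u < v))
        keep[u] <- FALSE
    }
    cols <- new_cols[keep]
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols))
    out[cols[[j]]] <- paste0(out[cols[[j]]], letters[j])
  out
}
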