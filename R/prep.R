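check_catalog <- function(catalog, pesticides = NULL) {
  need <- c("pesticide", "type", "noec_min", "loq")
  missing_cols <- setdiff(need, names(catalog))
  if (length(missing_cols))
    stop_config("catalog lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (any(!is.na(catalog$noec_min) & catalog$noec_min <= 0))
    stop_config("catalog noec_min must be > 0 when present")
  if (!is.null(pesticides)) {
    unmatched <- setdiff(pesticides, catalog$pesticide)
    if (length(unmatched))
      stop_config("pesticide(s) missing from catalog: %s",
                  paste(utils::head(unmatched, 5), collapse = ", "))
  }
  invisible(catalog)
}

#' Censor concentrations below the limit of quantification
#'
#' Residue surveys report concentrations below the per-compound limit of
#' quantification (LOQ) as zero; this applies that rule: values strictly
#' below the LOQ become exact zeros, values equal to the LOQ are kept.
#' Censoring is idempotent, and detection is thereafter `value > 0`.
#'
#' @param raw site x pesticide matrix of non-negative concentrations (mg/kg).
#' @param catalog pesticide catalog with `pesticide` and `loq` columns.
#' @return censored matrix with no value strictly between 0 and its LOQ.
#' @export
censor_loq <- function(raw, catalog) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop_config("negative concentrations are invalid")
  check_catalog(catalog, colnames(raw))
  loq <- catalog$loq[match(colnames(raw), catalog$pesticide)]
  out <- raw
  for (j in seq_len(ncol(out))) out[out[, j] < loq[j], j] <- 0
  out
}

#' Near-zero-variance filtering of pesticide columns
#'
#' Removes pesticide columns with little to no variation across sites, the
#' screen applied before any pesticide enters a model. Following the
#' near-zero-variance convention, a column is removed when the ratio of the
#' most common value's frequency to the second most common value's frequency
#' exceeds `freq_ratio_max` (default 95/5 = 19, strict inequality) **and**
#' the percentage of distinct values out of the number of sites falls below
#' `unique_pct_min` (default 5) — the joint condition distinguishes
#' rarely-detected residues (mostly zeros, a handful of distinct values) from
#' widely-detected ones whose many distinct concentrations are worth keeping
#' even though zero remains the single most common value. Set
#' `combine = "or"` for the stricter either-rule variant. Constant
#' (zero-variance) columns are always removed. Applying the filter to its own
#' kept set removes nothing.
#'
#' @param conc site x pesticide concentration matrix (>= 2 sites).
#' @param freq_ratio_max maximum allowed most-common / second-most-common
#'   frequency ratio.
#' @param unique_pct_min minimum allowed percentage of distinct values.
#' @param combine how the two rules combine to remove a column.
#' @return list with `kept` (column names), `removed` (data.frame: column,
#'   reason, freq_ratio, unique_pct).
#' @export
near_zero_variance_filter <- function(conc, freq_ratio_max = 19,
                                      unique_pct_min = 5,
                                      combine = c("and", "or")) {
  combine <- match.arg(combine)
  conc <- as.matrix(conc)
  if (!nrow(conc) || !ncol(conc)) stop_config("empty concentration matrix")
  if (nrow(conc) < 2L) stop_config("near-zero-variance filter needs >= 2 sites")
  n <- nrow(conc)
  res <- lapply(colnames(conc) %||% as.character(seq_len(ncol(conc))), function(nm) {
    x <- conc[, nm]
    tab <- sort(table(x), decreasing = TRUE)
    distinct <- length(tab)
    unique_pct <- 100 * distinct / n
    if (distinct == 1L)
      return(data.frame(column = nm, reason = "zero_variance",
                        freq_ratio = Inf, unique_pct = unique_pct,
                        stringsAsFactors = FALSE))
    freq_ratio <- as.numeric(tab[1] / tab[2])
    reason <- c(if (freq_ratio > freq_ratio_max) "freq_ratio",
                if (unique_pct < unique_pct_min) "low_unique_pct")
    hit <- if (combine == "and") length(reason) == 2L else length(reason) >= 1L
    if (!hit) return(NULL)
    data.frame(column = nm, reason = paste(reason, collapse = "+"),
               freq_ratio = freq_ratio, unique_pct = unique_pct,
               stringsAsFactors = FALSE)
  })
  removed <- do.call(rbind, res)
  removed_names <- if (is.null(removed)) character(0) else removed$column
  list(kept = setdiff(colnames(conc), removed_names),
       removed = removed %||% data.frame(column = character(0),
                                         reason = character(0),
                                         freq_ratio = numeric(0),
                                         unique_pct = numeric(0)))
}

#' Transform environmental covariates for modelling
#'
#' Applies the survey's covariate transforms: pH is negatively exponentially
#' transformed (`exp(-pH)`) and electrical conductivity is natural-log
#' transformed; all other columns are untouched. The transforms applied are
#' recorded in `attr(, "transforms")`.
#'
#' @param env data.frame of site environment.
#' @param ph_col,cond_col column names holding pH and conductivity (set to
#'   `NULL` to skip either transform).
#' @return transformed data.frame.
#' @export
transform_environment <- function(env, ph_col = "ph", cond_col = "conductivity") {
  applied <- character(0)
  if (!is.null(ph_col)) {
    if (!ph_col %in% names(env)) stop_config("pH column '%s' not found", ph_col)
    env[[ph_col]] <- exp(-env[[ph_col]])
    applied <- c(applied, sprintf("%s -> exp(-%s)", ph_col, ph_col))
  }
  if (!is.null(cond_col)) {
    if (!cond_col %in% names(env)) stop_config("conductivity column '%s' not found", cond_col)
    bad <- env[[cond_col]] <= 0
    if (any(bad))
      stop_config("non-positive conductivity at site(s): %s",
                  paste(utils::head(env$site_id[bad] %||% which(bad), 5), collapse = ", "))
    env[[cond_col]] <- log(env[[cond_col]])
    applied <- c(applied, sprintf("%s -> log(%s)", cond_col, cond_col))
  }
  attr(env, "transforms") <- applied
  env
}

#' Per-site pesticide occurrence counts
#'
#' Counts detected residues (concentration > 0 after censoring) per site,
#' overall and split by pesticide type; `n_detected` always equals the sum of
#' the three per-type counts.
#'
#' @param conc censored site x pesticide concentration matrix.
#' @param catalog pesticide catalog covering every column, with `type` in
#'   fungicide / herbicide / insecticide.
#' @return data.frame with site_id, n_detected, n_fungicides, n_herbicides,
#'   n_insecticides.
#' @export
aggregate_occurrence <- function(conc, catalog) {
  conc <- as.matrix(conc)
  check_catalog(catalog, colnames(conc))
  type <- catalog$type[match(colnames(conc), catalog$pesticide)]
  bad <- setdiff(unique(type), c("fungicide", "herbicide", "insecticide"))
  if (length(bad)) stop_config("unknown pesticide type(s): %s", paste(bad, collapse = ", "))
  det <- conc > 0
  data.frame(
    site_id = rownames(conc) %||% as.character(seq_len(nrow(conc))),
    n_detected = as.integer(rowSums(det)),
    n_fungicides = as.integer(rowSums(det[, type == "fungicide", drop = FALSE])),
    n_herbicides = as.integer(rowSums(det[, type == "herbicide", drop = FALSE])),
    n_insecticides = as.integer(rowSums(det[, type == "insecticide", drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' NOEC-based ecotoxicological risk quotients
#'
#' Per pesticide and site, the risk quotient is the concentration divided by
#' the compound's minimum no-observed-effect concentration (NOEC_min),
#' multiplied by a regulatory assessment factor (default 5). Cumulative risk
#' per site sums the quotients of detected pesticides, overall and per type.
#' Pesticides without a NOEC are excluded from all sums and listed in
#' `excluded` (mirroring surveys in which a NOEC is unavailable for a few
#' compounds).
#'
#' @param conc censored site x pesticide concentration matrix.
#' @param catalog pesticide catalog (`noec_min` > 0 where present).
#' @param assessment_factor regulatory assessment factor.
#' @return list with `rq` (site x pesticide quotient matrix for compounds
#'   with a NOEC), `site_table` (site_id, cumulative_risk, per-type
#'   cumulative risks, occurrence counts), `excluded` (pesticides without a
#'   NOEC).
#' @export
risk_quotients <- function(conc, catalog, assessment_factor = 5) {
  conc <- as.matrix(conc)
  check_catalog(catalog, colnames(conc))
  if (assessment_factor <= 0) stop_config("assessment_factor must be > 0")
  noec <- catalog$noec_min[match(colnames(conc), catalog$pesticide)]
  excluded <- colnames(conc)[is.na(noec)]
  if (length(excluded))
    message("excluded from risk sums (no NOEC): ", paste(excluded, collapse = ", "))
  keep <- !is.na(noec)
  rq <- sweep(conc[, keep, drop = FALSE], 2, noec[keep], "/") * assessment_factor
  type <- catalog$type[match(colnames(rq), catalog$pesticide)]
  occ <- aggregate_occurrence(conc, catalog)
  site_table <- data.frame(
    site_id = occ$site_id,
    cumulative_risk = rowSums(rq),
    cumulative_risk_fungicide = rowSums(rq[, type == "fungicide", drop = FALSE]),
    cumulative_risk_herbicide = rowSums(rq[, type == "herbicide", drop = FALSE]),
    cumulative_risk_insecticide = rowSums(rq[, type == "insecticide", drop = FALSE]),
    stringsAsFactors = FALSE
  )
  site_table <- merge(site_table, occ, by = "site_id", sort = FALSE)
  list(rq = rq, site_table = site_table, excluded = excluded)
}
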