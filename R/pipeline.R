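# polynomial rolling hash over the serialized config; cheap provenance tag
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full driver-attribution pipeline
#'
#' Orchestrates the analysis end to end on a dataset (real or simulated):
#' per analysis scope, subsets sites, censors concentrations, applies the
#' near-zero-variance filter, transforms the environment, runs the two-stage
#' scope-constrained selection per biodiversity metric, computes variable
#' importance and variation partitioning, and the complementary analyses
#' (presence/absence Kruskal-Wallis, Spearman screen against occurrence and
#' risk aggregates, pairwise ecosystem comparison). Scope subsetting happens
#' before filtering, so the cropland scope can legitimately retain a
#' different pesticide set than the all-ecosystem scope.
#'
#' @param dataset a `soildriver_sim` (or a list with the same named elements:
#'   `concentrations`, `catalog`, `environment`, `responses`).
#' @param scope `"croplands_only"`, `"all_ecosystems"` or `"both"`.
#' @param metrics response metric names (default: every non-key column of
#'   `dataset$responses`).
#' @param freq_ratio_max,unique_pct_min near-zero-variance filter thresholds.
#' @param transform_env apply the pH / conductivity transforms first.
#' @param start stage-1 stepwise start model.
#' @param assessment_factor risk-quotient assessment factor.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV (tagged with the config hash).
#' @return object of class `soildriver_report`: per scope a list with
#'   `filter`, `models`, `vip`, `partition`, `unique`, `presence_tests`,
#'   `spearman`, `ecosystem_comparison` (all-ecosystem scope only), plus
#'   `provenance`.
#' @export
run_soildriver <- function(dataset,
                           scope = c("both", "croplands_only", "all_ecosystems"),
                           metrics = NULL,
                           freq_ratio_max = 19, unique_pct_min = 5,
                           transform_env = TRUE,
                           start = "intercept",
                           assessment_factor = 5,
                           out_dir = NULL) {
  scope <- match.arg(scope)
  need <- c("concentrations", "catalog", "environment", "responses")
  missing_el <- setdiff(need, names(dataset))
  if (length(missing_el))
    stop_config("dataset lacks element(s): %s", paste(missing_el, collapse = ", "))
  env <- dataset$environment
  metrics <- metrics %||% setdiff(names(dataset$responses), "site_id")
  vg <- attr(env, "var_groups")
  if (is.null(vg))
    stop_config("dataset$environment must carry attr 'var_groups' (soil/climate membership)")

  scopes <- switch(scope, both = c("croplands_only", "all_ecosystems"), scope)
  report <- list()
  for (sc in scopes) {
    in_scope <- if (sc == "croplands_only")
      env$ecosystem %in% cropland_levels() else rep(TRUE, nrow(env))
    if (sum(in_scope) < 20L)
      stop_config("scope '%s' leaves too few sites (%d)", sc, sum(in_scope))
    env_s <- env[in_scope, , drop = FALSE]
    conc_s <- censor_loq(dataset$concentrations[in_scope, , drop = FALSE],
                         dataset$catalog)
    resp_s <- dataset$responses[in_scope, , drop = FALSE]
    # ecosystem is a driver only when the scope retains >1 level with >=2 sites
    eco_tab <- table(droplevels(factor(env_s$ecosystem)))
    use_eco <- length(eco_tab[eco_tab >= 2L]) > 1L
    env_s$ecosystem <- droplevels(factor(env_s$ecosystem))

    filt <- near_zero_variance_filter(conc_s, freq_ratio_max, unique_pct_min)
    if (transform_env) env_s <- transform_environment(env_s)
    data_s <- cbind(env_s, as.data.frame(conc_s), resp_s[setdiff(names(resp_s), "site_id")])

    models <- list()
    for (mt in metrics) {
      models[[mt]] <- two_stage_selection(
        mt, data_s,
        soil_terms = intersect(vg$soil, names(env_s)),
        climate_terms = intersect(vg$climate, names(env_s)),
        ecosystem_term = if (use_eco) "ecosystem" else NULL,
        pesticide_terms = filt$kept, start = start)
    }
    attr_res <- attribute_all(models, data_s)
    pres <- presence_env_tests(models, conc_s, env_s)
    rq <- risk_quotients(conc_s, dataset$catalog, assessment_factor)
    biodiv <- cbind(site_id = resp_s$site_id, resp_s[metrics])
    spear <- spearman_screen(biodiv, rq$site_table)
    eco_cmp <- if (sc == "all_ecosystems" && use_eco)
      ecosystem_residue_comparison(conc_s, env_s) else NULL
    report[[sc]] <- list(filter = filt, models = models, vip = attr_res$vip,
                         partition = attr_res$partition, unique = attr_res$unique,
                         presence_tests = pres, spearman = spear,
                         risk = rq$site_table, ecosystem_comparison = eco_cmp,
                         n_sites = sum(in_scope))
  }
  cfg <- list(scope = scope, metrics = metrics, freq_ratio_max = freq_ratio_max,
              unique_pct_min = unique_pct_min, transform_env = transform_env,
              start = start, assessment_factor = assessment_factor)
  report$provenance <- list(
    config = cfg, config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("soildriver")),
    r_version = R.version.string)
  class(report) <- "soildriver_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report to disk as TSV + JSON
#'
#' Every table carries the run's config hash so downstream joins can verify
#' provenance.
#'
#' @param report a `soildriver_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- report$provenance$config_hash
  for (sc in setdiff(names(report), "provenance")) {
    br <- report[[sc]]
    for (nm in c("vip", "partition", "unique", "presence_tests", "spearman", "risk")) {
      df <- br[[nm]]
      if (is.null(df) || !nrow(df)) next
      df$config_hash <- hash
      utils::write.table(df, file.path(out_dir, sprintf("%s_%s.tsv", sc, nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(br$filter$removed) && nrow(br$filter$removed)) {
      fr <- br$filter$removed; fr$config_hash <- hash
      utils::write.table(fr, file.path(out_dir, sprintf("%s_filter_removed.tsv", sc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.soildriver_report <- function(x, ...) {
  cat("soildriver run report\n")
  for (sc in setdiff(names(x), "provenance")) {
    br <- x[[sc]]
    cat(sprintf("  scope %-15s  %d sites, %d pesticides kept, %d metrics\n",
                sc, br$n_sites, length(br$filter$kept), length(br$models)))
  }
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Contrast the cropland-only and all-ecosystem scopes
#'
#' Per biodiversity metric, puts the pesticide unique explained-variance
#' fractions of the two scopes side by side, reports their ratio, and flags
#' pesticide terms selected in only one scope.
#'
#' @param report a `soildriver_report` containing both scopes.
#' @return list with `fractions` (metric, cropland and all-ecosystem
#'   pesticide unique fractions, ratio) and `terms` (metric, term, scope
#'   flags).
#' @export
compare_scopes <- function(report) {
  stopifnot(inherits(report, "soildriver_report"))
  scopes <- c("croplands_only", "all_ecosystems")
  if (!all(scopes %in% names(report)))
    stop_config("compare_scopes needs both scopes in the report")
  u_crop <- report$croplands_only$unique
  u_all <- report$all_ecosystems$unique
  pc <- u_crop[u_crop$group == "pesticides", c("metric", "fraction")]
  pa <- u_all[u_all$group == "pesticides", c("metric", "fraction")]
  names(pc)[2] <- "croplands_only"; names(pa)[2] <- "all_ecosystems"
  fr <- merge(pc, pa, by = "metric")
  fr$ratio <- ifelse(fr$croplands_only > 0 & fr$all_ecosystems > 0,
                     fr$croplands_only / fr$all_ecosystems, NA_real_)
  term_rows <- list()
  for (mt in unique(fr$metric)) {
    tc <- report$croplands_only$models[[mt]]$groups$pesticides
    ta <- report$all_ecosystems$models[[mt]]$groups$pesticides
    all_terms <- union(tc, ta)
    if (!length(all_terms)) next
    term_rows[[mt]] <- data.frame(
      metric = mt, term = all_terms,
      in_croplands = all_terms %in% tc, in_all_ecosystems = all_terms %in% ta,
      scope_specific = ifelse(all_terms %in% tc & !(all_terms %in% ta), "croplands_only",
                       ifelse(!(all_terms %in% tc) & all_terms %in% ta, "all_ecosystems", "shared")),
      stringsAsFactors = FALSE)
  }
  list(fractions = fr, terms = do.call(rbind, c(term_rows, list(make.row.names = FALSE))))
}
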