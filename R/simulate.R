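#' Simulation configuration for a synthetic soil survey
#'
#' Builds and validates the configuration driving [simulate_soildriver()].
#' Defaults emulate the design of a continental soil survey: 373 sites across
#' five ecosystem types with proportions 210/34/19/97/13, eleven soil
#' properties, seven climatic variables, zero-inflated LOQ-censored pesticide
#' residue concentrations, and biodiversity responses drawn from a Gaussian
#' log-link GLM whose per-driver-group unique explained-variance fractions are
#' controlled ground truth.
#'
#' @param n_sites number of sites.
#' @param n_pesticides number of pesticide residue columns.
#' @param detect_prob probability that a pesticide is present at a site.
#' @param conc_log_mean,conc_log_sd lognormal parameters (log mg/kg) for
#'   detected concentrations.
#' @param loq limit of quantification (mg/kg); generated values below it are
#'   recorded as exact zeros.
#' @param round_digits reporting precision of concentrations in decimal
#'   digits of mg/kg (default 3, matching LOQs of 0.001); rounding creates
#'   the repeated values real residue tables show.
#' @param n_soil_vars,n_climate_vars number of soil and climate covariates.
#' @param ecosystem_levels ecosystem type labels (default: the five survey
#'   types).
#' @param ecosystem_props sampling proportions per ecosystem level.
#' @param env_correlation exchangeable correlation among continuous
#'   environmental covariates, or a full positive-definite correlation matrix.
#' @param group_r2 named numeric vector of target unique explained-variance
#'   fractions per driver group (`pesticides`, `soil`, `climate`, optionally
#'   `ecosystem`); must sum to < 1.
#' @param noise_sd standard deviation of additive Gaussian response noise, in
#'   response units.
#' @param baseline baseline response level; the response is
#'   `exp(log(baseline) + signal) + noise`.
#' @param n_true named integer vector: number of true predictors used per
#'   driver group.
#' @param response_metrics names of the response metrics to generate.
#' @param orthogonalize orthogonalize the per-group signals against each other
#'   so planted unique fractions have no shared component.
#' @param cropland_only_effect restrict the pesticide signal to cropland sites
#'   (annual + permanent croplands); used to study scope contrasts.
#' @param plant_rare_column plant one nearly-always-zero pesticide column to
#'   exercise the near-zero-variance filter.
#' @param organism_groups labels for the taxon count tables.
#' @param n_taxa taxa per organism group.
#' @param dirichlet_conc Dirichlet concentration for taxon base probabilities.
#' @param lib_size_range integer range of per-site library sizes.
#' @param gene_groups labels for functional gene groups.
#' @param seed integer seed; all sub-generators derive child seeds from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 373L,
                       n_pesticides = 30L,
                       detect_prob = 0.3,
                       conc_log_mean = log(0.02),
                       conc_log_sd = 1,
                       loq = 0.001,
                       round_digits = 3L,
                       n_soil_vars = 11L,
                       n_climate_vars = 7L,
                       ecosystem_levels = c("annual_cropland", "permanent_cropland",
                                            "former_cropland", "extensive_grassland",
                                            "woodland"),
                       ecosystem_props = c(210, 34, 19, 97, 13) / 373,
                       env_correlation = 0.2,
                       group_r2 = c(pesticides = 0.30, soil = 0.20, climate = 0.10),
                       noise_sd = 25,
                       baseline = 100,
                       n_true = c(pesticides = 3L, soil = 3L, climate = 2L),
                       response_metrics = c("richness_bacteria", "shannon_fungi",
                                            "functional_gene_diversity"),
                       orthogonalize = TRUE,
                       cropland_only_effect = FALSE,
                       plant_rare_column = TRUE,
                       organism_groups = c("archaea", "bacteria", "fungi",
                                           "protists", "nematodes", "arthropods"),
                       n_taxa = 120L,
                       dirichlet_conc = 0.5,
                       lib_size_range = c(5000L, 50000L),
                       gene_groups = c("cellulose_degradation", "lignin_degradation",
                                       "nitrogen_fixation", "nitrification",
                                       "phosphatase"),
                       seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_pesticides = as.integer(n_pesticides),
              detect_prob = detect_prob, conc_log_mean = conc_log_mean,
              conc_log_sd = conc_log_sd, loq = loq,
              round_digits = as.integer(round_digits),
              n_soil_vars = as.integer(n_soil_vars),
              n_climate_vars = as.integer(n_climate_vars),
              ecosystem_levels = ecosystem_levels, ecosystem_props = ecosystem_props,
              env_correlation = env_correlation, group_r2 = group_r2,
              noise_sd = noise_sd, baseline = baseline, n_true = n_true,
              response_metrics = response_metrics, orthogonalize = orthogonalize,
              cropland_only_effect = cropland_only_effect,
              plant_rare_column = plant_rare_column,
              organism_groups = organism_groups, n_taxa = as.integer(n_taxa),
              dirichlet_conc = dirichlet_conc,
              lib_size_range = as.integer(lib_size_range),
              gene_groups = gene_groups, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_sites)) stop_config("n_sites must be a positive integer")
  if (!is_count(cfg$n_pesticides)) stop_config("n_pesticides must be a positive integer")
  if (!is.numeric(cfg$detect_prob) || cfg$detect_prob < 0 || cfg$detect_prob > 1)
    stop_config("detect_prob must lie in [0, 1]")
  if (cfg$loq < 0) stop_config("loq must be >= 0")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$baseline <= 0) stop_config("baseline must be > 0")
  if (length(cfg$ecosystem_props) != length(cfg$ecosystem_levels))
    stop_config("ecosystem_props must match ecosystem_levels in length")
  if (any(cfg$ecosystem_props < 0) || abs(sum(cfg$ecosystem_props) - 1) > 1e-6)
    stop_config("ecosystem_props must be non-negative and sum to 1")
  if (any(cfg$group_r2 < 0)) stop_config("group_r2 fractions must be non-negative")
  if (sum(cfg$group_r2) >= 1) stop_config("group_r2 fractions must sum to < 1")
  bad <- setdiff(names(cfg$group_r2), c("pesticides", "soil", "climate", "ecosystem"))
  if (length(bad)) stop_config("unknown driver group(s): %s", paste(bad, collapse = ", "))
  if (cfg$lib_size_range[1] <= 0 || diff(cfg$lib_size_range) < 0)
    stop_config("lib_size_range must be a positive, non-decreasing pair")
  invisible(cfg)
}

site_ids <- function(n) sprintf("site_%04d", seq_len(n))

#' Generate a zero-inflated, LOQ-censored pesticide concentration matrix
#'
#' Each entry is 0 with probability `1 - detect_prob`, otherwise a lognormal
#' draw; draws below the limit of quantification are recorded as exact zeros,
#' emulating the reporting convention of residue surveys. Unless disabled, one
#' nearly-always-zero column is planted so downstream near-zero-variance
#' filtering has something to remove.
#'
#' @param cfg a [sim_config()].
#' @return site x pesticide numeric matrix (mg/kg) with site ids as rownames.
#' @export
generate_concentrations <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, 1L))
  n <- cfg$n_sites; p <- cfg$n_pesticides
  detected <- matrix(stats::rbinom(n * p, 1L, cfg$detect_prob), n, p)
  conc <- matrix(0, n, p)
  k <- sum(detected == 1L)
  conc[detected == 1L] <- stats::rlnorm(k, cfg$conc_log_mean, cfg$conc_log_sd)
  if (!is.null(cfg$round_digits)) conc <- round(conc, cfg$round_digits)
  conc[conc < cfg$loq] <- 0
  dimnames(conc) <- list(site_ids(n), sprintf("pest_%02d", seq_len(p)))
  if (isTRUE(cfg$plant_rare_column) && p >= 2L && n >= 4L) {
    rare <- rep(0, n)
    idx <- sample.int(n, max(2L, min(3L, n)))[1:2]
    rare[idx] <- pmax(round(stats::rlnorm(2L, cfg$conc_log_mean, cfg$conc_log_sd),
                            cfg$round_digits %||% 3L), cfg$loq)
    conc[, p] <- rare
  }
  conc
}

#' Generate a pesticide catalog
#'
#' Assigns each pesticide a type (fungicide / herbicide / insecticide), a
#' chemical group, a mode of action, a per-compound LOQ drawn within the
#' survey's reported 0.001-0.025 mg/kg range, and a minimum no-observed-effect
#' concentration (NOEC_min). Two compounds are left without a NOEC to mirror
#' catalogs in which risk quotients cannot be computed for every residue.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns pesticide, type, chemical_group,
#'   mode_of_action, noec_min, loq.
#' @export
generate_catalog <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, 2L))
  p <- cfg$n_pesticides
  types <- rep_len(c("fungicide", "herbicide", "insecticide"), p)
  noec <- stats::rlnorm(p, log(0.05), 1)
  missing_noec <- if (p >= 5L) utils::tail(seq_len(p), 2L) else integer(0)
  noec[missing_noec] <- NA_real_
  data.frame(
    pesticide = sprintf("pest_%02d", seq_len(p)),
    type = types,
    chemical_group = sprintf("chem_group_%02d", rep_len(1:6, p)),
    mode_of_action = sprintf("moa_%02d", rep_len(1:8, p)),
    noec_min = noec,
    loq = stats::runif(p, 0.001, 0.025),
    stringsAsFactors = FALSE
  )
}

soil_var_names <- function(k) {
  base <- c("water_content", "coarse_fragments", "sand", "clay", "ph",
            "conductivity", "corg_n_ratio", "phosphorus", "bulk_density",
            "potassium", "organic_carbon")
  if (k <= length(base)) base[seq_len(k)] else c(base, sprintf("soil_%02d", seq_len(k - length(base))))
}

climate_var_names <- function(k) {
  base <- c("mat", "diurnal_range", "precip_seasonality", "temp_seasonality",
            "precip_month", "temp_month", "aridity")
  if (k <= length(base)) base[seq_len(k)] else c(base, sprintf("climate_%02d", seq_len(k - length(base))))
}

#' Generate correlated site-level environmental covariates
#'
#' Soil and climate covariates are drawn from a multivariate normal with an
#' exchangeable (or user-supplied) correlation structure; pH and electrical
#' conductivity are placed on realistic scales (conductivity strictly
#' positive, ready for log transformation). The ecosystem type is a 5-level
#' factor drawn with configurable proportions.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `site_id`, soil and climate columns, and an
#'   `ecosystem` factor; soil/climate membership is recorded in
#'   `attr(, "var_groups")`.
#' @export
generate_environment <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, 3L))
  n <- cfg$n_sites
  k <- cfg$n_soil_vars + cfg$n_climate_vars
  if (is.matrix(cfg$env_correlation)) {
    R <- cfg$env_correlation
    if (nrow(R) != k || ncol(R) != k)
      stop_config("env_correlation matrix must be %d x %d", k, k)
  } else {
    R <- matrix(cfg$env_correlation, k, k)
    diag(R) <- 1
  }
  ch <- tryCatch(chol(R), error = function(e)
    stop_config("env_correlation is not positive definite"))
  z <- matrix(stats::rnorm(n * k), n, k) %*% ch
  vars <- c(soil_var_names(cfg$n_soil_vars), climate_var_names(cfg$n_climate_vars))
  colnames(z) <- vars
  env <- as.data.frame(z)
  if ("ph" %in% vars) env$ph <- pmin(pmax(6.5 + 0.8 * env$ph, 3.5), 9.5)
  if ("conductivity" %in% vars) env$conductivity <- exp(-2 + 0.8 * env$conductivity)
  env$ecosystem <- factor(
    sample(cfg$ecosystem_levels, n, replace = TRUE, prob = cfg$ecosystem_props),
    levels = cfg$ecosystem_levels
  )
  env <- cbind(site_id = site_ids(n), env, stringsAsFactors = FALSE)
  rownames(env) <- env$site_id
  attr(env, "var_groups") <- list(soil = soil_var_names(cfg$n_soil_vars),
                                  climate = climate_var_names(cfg$n_climate_vars))
  env
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc, rate = 1)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}

#' Generate taxon count tables and functional-gene summaries
#'
#' Per organism group, per-site taxon counts are multinomial draws over
#' Dirichlet-distributed taxon probabilities with heterogeneous library sizes.
#' Gene summaries give per site and functional gene group an orthologous-group
#' count and a functionally annotated read total.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (named list of site x taxon integer matrices)
#'   and `gene_summaries` (long data.frame: site_id, gene_group, og_count,
#'   functional_reads).
#' @export
generate_counts <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, 4L))
  n <- cfg$n_sites
  counts <- lapply(cfg$organism_groups, function(g) {
    p <- rdirichlet1(cfg$n_taxa, cfg$dirichlet_conc)
    libs <- sample(cfg$lib_size_range[1]:cfg$lib_size_range[2], n, replace = TRUE)
    m <- t(vapply(libs, function(L) stats::rmultinom(1L, L, p)[, 1L],
                  integer(cfg$n_taxa)))
    dimnames(m) <- list(site_ids(n), sprintf("%s_taxon_%03d", g, seq_len(cfg$n_taxa)))
    m
  })
  names(counts) <- cfg$organism_groups
  gs <- expand.grid(site_id = site_ids(n), gene_group = cfg$gene_groups,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gs$functional_reads <- sample(100000:2000000, nrow(gs), replace = TRUE)
  gs$og_count <- stats::rpois(nrow(gs), gs$functional_reads / 4000)
  list(counts = counts, gene_summaries = gs)
}

cropland_levels <- function() c("annual_cropland", "permanent_cropland")

# Composite unit-variance signal for one driver group; beta alternates sign.
group_signal <- function(X) {
  X <- scale(X)
  X[is.nan(X)] <- 0
  beta <- rep_len(c(1, -1), ncol(X))
  s <- drop(X %*% beta)
  if (stats::sd(s) == 0) stop_config("degenerate (constant) driver-group signal")
  list(signal = drop(scale(s)), beta = beta)
}

# Unique explained-variance fractions of each group, computed exactly the way
# the attribution module does: full-model r2 minus leave-one-group-out r2,
# with r2 the squared predicted-observed correlation of a Gaussian log-link GLM.
realized_unique <- function(y, data, groups) {
  full_terms <- unlist(groups, use.names = FALSE)
  r2_of <- function(terms) {
    f <- fit_driver_glm("..y..", terms, cbind(data, `..y..` = y))
    if (is.null(f$diagnostics))
      stop_config("calibration failure: sub-model fit failed (%s)",
                  f$error %||% "no diagnostics")
    f$diagnostics$r2
  }
  r2_full <- r2_of(full_terms)
  u <- vapply(names(groups), function(g) {
    rest <- unlist(groups[setdiff(names(groups), g)], use.names = FALSE)
    r2_full - (if (length(rest)) r2_of(rest) else 0)
  }, numeric(1))
  list(unique = u, r2_full = r2_full)
}

#' Generate biodiversity responses from a Gaussian log-link GLM with
#' controlled driver-group contributions
#'
#' For each requested metric, the response is `y = exp(eta) + noise` where
#' `eta` is a linear combination of unit-variance composite signals built from
#' true predictors in each driver group (optionally orthogonalized across
#' groups). Per-group coefficient scales are calibrated by a deterministic
#' damped fixed-point search on the realized design so that each group's
#' unique explained-variance fraction — recomputed exactly as the attribution
#' module computes it — matches `cfg$group_r2`.
#'
#' @param env output of [generate_environment()].
#' @param conc output of [generate_concentrations()].
#' @param cfg a [sim_config()].
#' @return list with `responses` (data.frame, site_id + one column per metric)
#'   and `truth` (per metric: true terms per group, calibrated scales,
#'   realized unique fractions, noise sd, baseline).
#' @export
generate_response <- function(env, conc, cfg) {
  validate_sim_config(cfg)
  stopifnot(identical(env$site_id, rownames(conc)))
  set.seed(child_seed(cfg$seed, 5L))
  n <- cfg$n_sites
  vg <- attr(env, "var_groups") %||%
    list(soil = intersect(soil_var_names(cfg$n_soil_vars), names(env)),
         climate = intersect(climate_var_names(cfg$n_climate_vars), names(env)))

  active <- names(cfg$group_r2)[cfg$group_r2 > 0]
  pick_terms <- function(group) {
    k <- cfg$n_true[[group]] %||% 2L
    pool <- switch(group,
      pesticides = {
        det <- colSums(conc > 0)
        usable <- colnames(conc)[det >= max(3L, ceiling(0.05 * n))]
        if (!length(usable)) {
          ord <- names(det)[order(-det)]
          usable <- ord[det[ord] > 0]
        }
        if (!length(usable)) stop_config("no pesticide column has any detections for a planted effect")
        usable
      },
      soil = vg$soil, climate = vg$climate,
      ecosystem = "ecosystem")
    pool[seq_len(min(k, length(pool)))]
  }
  true_terms <- lapply(stats::setNames(active, active), pick_terms)

  data <- cbind(env, as.data.frame(conc))
  signals <- matrix(0, n, length(active), dimnames = list(NULL, active))
  betas <- list()
  for (g in active) {
    if (g == "ecosystem") {
      mm <- stats::model.matrix(~ ecosystem, data = env)[, -1, drop = FALSE]
      gsig <- group_signal(mm)
    } else {
      gsig <- group_signal(data[, true_terms[[g]], drop = FALSE])
    }
    signals[, g] <- gsig$signal
    betas[[g]] <- gsig$beta
  }
  if (isTRUE(cfg$cropland_only_effect) && "pesticides" %in% active) {
    crop <- env$ecosystem %in% cropland_levels()
    s <- signals[, "pesticides"] * as.numeric(crop)
    if (stats::sd(s) == 0) stop_config("cropland_only_effect requires cropland sites")
    signals[, "pesticides"] <- drop(scale(s))
  }
  if (isTRUE(cfg$orthogonalize) && ncol(signals) > 1L) {
    q <- qr.Q(qr(cbind(1, signals)))[, -1, drop = FALSE]
    signals <- apply(q, 2, function(x) drop(scale(x)))
    colnames(signals) <- active
  }

  targets <- cfg$group_r2[active]
  eta0 <- log(cfg$baseline)
  # with a cropland-restricted pesticide effect, group_r2 is defined on the
  # scope where the effect exists; the all-ecosystem fraction is its dilution
  cal_rows <- if (isTRUE(cfg$cropland_only_effect) && "pesticides" %in% active)
    which(env$ecosystem %in% cropland_levels()) else seq_len(n)
  responses <- data.frame(site_id = env$site_id, stringsAsFactors = FALSE)
  truth <- list()
  for (metric in cfg$response_metrics) {
    eps <- stats::rnorm(n, 0, cfg$noise_sd)
    if (!length(active)) {
      y <- cfg$baseline + eps
      responses[[metric]] <- y
      truth[[metric]] <- list(true_terms = list(), scales = numeric(0),
                              realized_unique = numeric(0), group_r2 = cfg$group_r2,
                              noise_sd = cfg$noise_sd, baseline = cfg$baseline)
      next
    }
    if (cfg$noise_sd == 0) {
      # noiseless limit: the full model explains everything, so group_r2 can
      # only set the relative signal weights, not absolute fractions
      scales <- sqrt(targets / sum(targets)) * 0.3
      y <- drop(exp(eta0 + signals %*% scales)) + eps
      cal <- realized_unique(y[cal_rows], data[cal_rows, , drop = FALSE], true_terms)
    } else {
      # linear-scale initial guess: var(exp(eta)) ~ baseline^2 * sum(c^2)
      tot <- sum(targets)
      scales <- sqrt(targets / (1 - tot)) * cfg$noise_sd / cfg$baseline
      cal <- NULL
      for (it in 1:30) {
        y <- drop(exp(eta0 + signals %*% scales)) + eps
        cal <- realized_unique(y[cal_rows], data[cal_rows, , drop = FALSE], true_terms)
        err <- cal$unique - targets
        if (max(abs(err)) < 0.008) break
        adj <- sqrt(targets / pmax(cal$unique, 1e-4))
        scales <- scales * adj^0.7
        scales <- pmin(scales, 3)  # guard against runaway exp
      }
      if (max(abs(cal$unique - targets)) > 0.05)
        stop_config("calibration failure for metric '%s': unattainable group_r2 given noise_sd (worst gap %.3f)",
                    metric, max(abs(cal$unique - targets)))
    }
    responses[[metric]] <- drop(exp(eta0 + signals %*% scales)) + eps
    truth[[metric]] <- list(true_terms = true_terms, betas = betas,
                            scales = stats::setNames(as.numeric(scales), active),
                            realized_unique = cal$unique, r2_full = cal$r2_full,
                            group_r2 = cfg$group_r2, noise_sd = cfg$noise_sd,
                            baseline = cfg$baseline)
  }
  rownames(responses) <- responses$site_id
  list(responses = responses, truth = truth)
}

#' Simulate a complete synthetic soil-survey dataset
#'
#' Runs every sub-generator under child seeds derived from `cfg$seed` and
#' returns all pipeline inputs with aligned site identifiers plus the ground
#' truth of the response-generating model.
#'
#' @param cfg a [sim_config()].
#' @return object of class `soildriver_sim`: list with `concentrations`,
#'   `catalog`, `environment`, `counts`, `gene_summaries`, `responses`,
#'   `truth`, `config`.
#' @export
simulate_soildriver <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  conc <- generate_concentrations(cfg)
  catalog <- generate_catalog(cfg)
  env <- generate_environment(cfg)
  cg <- generate_counts(cfg)
  resp <- generate_response(env, conc, cfg)
  out <- list(concentrations = conc, catalog = catalog, environment = env,
              counts = cg$counts, gene_summaries = cg$gene_summaries,
              responses = resp$responses, truth = resp$truth, config = cfg)
  class(out) <- "soildriver_sim"
  out
}

#' @export
print.soildriver_sim <- function(x, ...) {
  cat("Synthetic soil-survey dataset\n")
  cat(sprintf("  sites: %d   pesticides: %d   responses: %s\n",
              x$config$n_sites, x$config$n_pesticides,
              paste(setdiff(names(x$responses), "site_id"), collapse = ", ")))
  cat(sprintf("  planted unique fractions: %s\n",
              paste(sprintf("%s=%.2f", names(x$config$group_r2), x$config$group_r2),
                    collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to disk as plain-text tables
#'
#' All tables are TSV keyed by `site_id`; the ground-truth record is JSON.
#'
#' @param sim a `soildriver_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "soildriver_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  wt(data.frame(site_id = rownames(sim$concentrations), sim$concentrations,
                check.names = FALSE), "concentrations")
  wt(sim$catalog, "catalog")
  wt(sim$environment, "environment")
  for (g in names(sim$counts))
    wt(data.frame(site_id = rownames(sim$counts[[g]]), sim$counts[[g]],
                  check.names = FALSE), paste0("counts_", g))
  wt(sim$gene_summaries, "gene_summaries")
  wt(sim$responses, "responses")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
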