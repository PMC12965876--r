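#' Normalize a count table by scaling with ranked subsampling (SRS)
#'
#' Scales each site's counts to a common total `c_min`: counts are multiplied
#' by `c_min / total`, integer parts are kept, and the remaining deficit is
#' distributed one unit each to the taxa ranked by descending fractional
#' part. Ties among equal fractional parts are broken by descending original
#' abundance, then stable input order; passing `seed` randomizes the
#' tie-breaking instead. Every normalized site total equals `c_min` exactly,
#' and subsampling can never create a taxon that was absent.
#'
#' @param table site x taxon matrix of non-negative integer counts (sites as
#'   rows).
#' @param c_min target library size; defaults to the minimum site total.
#' @param seed optional integer; if supplied, ties are broken at random
#'   (reproducibly) instead of by abundance/input order.
#' @return integer matrix with the retained sites, every row summing to
#'   `c_min`. Sites with fewer than `c_min` reads are dropped with a warning.
#' @export
srs_normalize <- function(table, c_min = NULL, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table)))
    stop_config("counts must be non-negative integers")
  totals <- rowSums(table)
  c_min <- c_min %||% min(totals)
  if (!is_count(c_min)) stop_config("c_min must be a positive integer")
  keep <- totals >= c_min
  if (!any(keep)) stop_config("all sites fall below c_min = %d", c_min)
  if (!all(keep))
    warning(sprintf("dropping %d site(s) below c_min = %d: %s", sum(!keep),
                    c_min, paste(rownames(table)[!keep], collapse = ", ")),
            call. = FALSE)
  table <- table[keep, , drop = FALSE]
  totals <- totals[keep]
  if (!is.null(seed)) set.seed(seed)
  out <- t(vapply(seq_len(nrow(table)), function(i) {
    x <- table[i, ]
    scaled <- x * c_min / totals[i]
    fl <- floor(scaled)
    deficit <- c_min - sum(fl)
    if (deficit > 0) {
      frac <- scaled - fl
      tie_key <- if (is.null(seed)) -x else sample.int(length(x))
      ord <- order(-frac, tie_key, seq_along(x))
      fl[ord[seq_len(deficit)]] <- fl[ord[seq_len(deficit)]] + 1
    }
    as.integer(fl)
  }, integer(ncol(table))))
  dimnames(out) <- dimnames(table)
  out
}

#' Per-site richness and Shannon diversity
#'
#' Richness is the number of taxa with positive counts; Shannon diversity is
#' `-sum(p * log(p))` over positive counts, in nats.
#'
#' @param table site x taxon count matrix (raw or SRS-normalized — the choice
#'   is the caller's).
#' @return data.frame with site_id, richness, shannon. An all-zero site gets
#'   richness 0 and shannon 0, with a warning.
#' @export
richness_shannon <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop_config("counts must be non-negative")
  totals <- rowSums(table)
  if (any(totals == 0))
    warning(sprintf("%d site(s) have zero total counts; richness and Shannon set to 0",
                    sum(totals == 0)), call. = FALSE)
  rich <- rowSums(table > 0)
  shan <- vapply(seq_len(nrow(table)), function(i) {
    x <- table[i, ]
    x <- x[x > 0]
    if (!length(x)) return(0)
    p <- x / sum(x)
    -sum(p * log(p))
  }, numeric(1))
  data.frame(site_id = rownames(table) %||% as.character(seq_len(nrow(table))),
             richness = as.numeric(rich), shannon = shan,
             stringsAsFactors = FALSE)
}

#' Multidiversity index
#'
#' The mean of per-group min-max standardized richness: for each organism
#' group, richness is rescaled across the analyzed site set to
#' `z = (r - min) / (max - min)`, and the index is the mean of the `z` values
#' (equal 1/6 weighting for the default six groups). A site maximal in every
#' group scores 1 and one minimal in every group scores 0. Standardization is
#' computed over exactly the sites supplied, so analysis subsets (e.g.
#' croplands only) get their own scaling.
#'
#' @param richness_by_group site x group matrix or data.frame of richness
#'   values (>= 2 sites).
#' @return data.frame with site_id, one `z_<group>` column per group, and
#'   `multidiversity`. A group with zero range across sites gets `z = 0.5`
#'   everywhere, with a warning, to keep the equal weighting meaningful.
#' @export
multidiversity <- function(richness_by_group) {
  m <- as.matrix(richness_by_group)
  if (nrow(m) < 2L) stop_config("multidiversity needs >= 2 sites")
  z <- apply(m, 2, function(r) {
    rng <- range(r)
    if (diff(rng) == 0) return(rep(0.5, length(r)))
    (r - rng[1]) / diff(rng)
  })
  flat <- apply(m, 2, function(r) diff(range(r)) == 0)
  if (any(flat))
    warning(sprintf("group(s) with zero richness range set to z = 0.5: %s",
                    paste(colnames(m)[flat], collapse = ", ")), call. = FALSE)
  out <- data.frame(site_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    z, multidiversity = rowMeans(z), stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[1 + seq_len(ncol(m))] <- paste0("z_", colnames(m))
  out
}

#' Relative abundance of functional groups
#'
#' Per site and functional group: the summed read counts of taxa assigned to
#' the group, divided by the site's total read count (assigned plus
#' unassigned taxa), as a percentage.
#'
#' @param table site x taxon count matrix.
#' @param assignment named character vector mapping taxon identifier to
#'   functional-group label; taxa absent from it count as unassigned and
#'   contribute to the denominator only.
#' @return data.frame with site_id and one percent column per functional
#'   group in `assignment`. Sites with zero total reads get `NA` with a
#'   warning.
#' @export
functional_abundance <- function(table, assignment) {
  table <- as.matrix(table)
  stopifnot(!is.null(colnames(table)), !is.null(names(assignment)))
  unknown <- setdiff(names(assignment), colnames(table))
  if (length(unknown))
    stop_config("assignment references unknown taxa: %s",
                paste(utils::head(unknown, 5), collapse = ", "))
  totals <- rowSums(table)
  if (any(totals == 0))
    warning(sprintf("%d site(s) with zero total reads reported as NA",
                    sum(totals == 0)), call. = FALSE)
  groups <- sort(unique(assignment))
  pct <- vapply(groups, function(g) {
    taxa <- names(assignment)[assignment == g]
    num <- rowSums(table[, taxa, drop = FALSE])
    ifelse(totals == 0, NA_real_, 100 * num / totals)
  }, numeric(nrow(table)))
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = nrow(table),
                                       dimnames = list(NULL, groups))
  data.frame(site_id = rownames(table) %||% as.character(seq_len(nrow(table))),
             pct, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Functional-gene diversity in pmOG
#'
#' Number of gene orthologous groups per million functionally annotated
#' reads: `og_count / functional_reads * 1e6`. Scale-invariant in the sense
#' that doubling both counts leaves the value unchanged.
#'
#' @param og_count non-negative orthologous-group counts.
#' @param functional_reads positive functionally-annotated read totals.
#' @return numeric vector of pmOG values; entries with zero reads are `NA`
#'   with a warning.
#' @export
pmog <- function(og_count, functional_reads) {
  if (any(og_count < 0)) stop_config("og_count must be >= 0")
  if (any(functional_reads < 0)) stop_config("functional_reads must be >= 0")
  if (any(functional_reads == 0))
    warning("functional_reads of 0 reported as NA", call. = FALSE)
  ifelse(functional_reads == 0, NA_real_, og_count / functional_reads * 1e6)
}

#' Assemble a per-site biodiversity table from counts and gene summaries
#'
#' Convenience constructor: SRS-normalizes each organism group's counts
#' (optional), computes per-group richness and Shannon diversity, the
#' multidiversity index over the groups, and pmOG per functional gene group.
#'
#' @param counts named list of site x taxon count matrices (one per organism
#'   group).
#' @param gene_summaries data.frame with site_id, gene_group, og_count,
#'   functional_reads (optional).
#' @param normalize SRS-normalize each group's counts first (default TRUE).
#' @param c_min optional common target library size passed to
#'   [srs_normalize()]; default is each group's minimum site total.
#' @return data.frame keyed by site_id with richness_/shannon_ columns per
#'   group, multidiversity, and pmog_ columns per gene group.
#' @export
biodiversity_table <- function(counts, gene_summaries = NULL, normalize = TRUE,
                               c_min = NULL) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  per_group <- lapply(names(counts), function(g) {
    tab <- counts[[g]]
    if (normalize) tab <- srs_normalize(tab, c_min = c_min)
    rs <- richness_shannon(tab)
    names(rs)[2:3] <- paste0(c("richness_", "shannon_"), g)
    rs
  })
  out <- Reduce(function(a, b) merge(a, b, by = "site_id"), per_group)
  rich <- as.matrix(out[, paste0("richness_", names(counts)), drop = FALSE])
  rownames(rich) <- out$site_id
  colnames(rich) <- names(counts)
  md <- multidiversity(rich)
  out$multidiversity <- md$multidiversity[match(out$site_id, md$site_id)]
  if (!is.null(gene_summaries)) {
    gs <- gene_summaries
    gs$pmog <- pmog(gs$og_count, gs$functional_reads)
    wide <- stats::reshape(gs[, c("site_id", "gene_group", "pmog")],
                           idvar = "site_id", timevar = "gene_group",
                           direction = "wide")
    names(wide) <- sub("^pmog\\.", "pmog_", names(wide))
    out <- merge(out, wide, by = "site_id", all.x = TRUE)
  }
  out
}
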