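#' Clade-by-sample abundance table at a fixed rank
#'
#' Counts assigned reads per clade and sample at the requested rank. Reads
#' whose assignment is shallower than the rank are excluded from the counts;
#' the proportion denominator depends on `denominator`:
#' \describe{
#'   \item{`rank_assigned`}{reads counted in the table (after any domain
#'     restriction) — the default;}
#'   \item{`domain`}{all reads assigned at least to `domain`;}
#'   \item{`total`}{all assigned reads in the sample, including reads only
#'     reaching the unclassified root.}
#' }
#' When `domain` is given, only reads in that domain are counted.
#'
#' @param assignments Per-read assignment tibble from [lca_assign()] /
#'   [assign_reads()]; a `sample` column is used if present.
#' @param rank Target rank name (default `"family"`).
#' @param denominator Denominator mode, see Details.
#' @param domain Optional domain name restricting the table (required for
#'   `denominator = "domain"`).
#' @param ranks Rank names in lineage order (default domain through genus).
#' @return A `clade_table` tibble with columns `sample`, `clade`, `count`,
#'   `proportion`, complete over all sample x clade pairs; the rank and
#'   denominator mode are recorded as attributes.
#' @export
clade_table <- function(assignments,
                        rank = "family",
                        denominator = c("rank_assigned", "domain", "total"),
                        domain = NULL,
                        ranks = c("domain", "phylum", "class", "order",
                                  "family", "genus")) {
  denominator <- match.arg(denominator)
  check_cols(assignments, c("lineage", "depth"), "assignment table")
  depth_needed <- match(rank, ranks)
  if (is.na(depth_needed)) {
    abort(sprintf("unknown rank '%s'; expected one of: %s",
                  rank, paste(ranks, collapse = ", ")))
  }
  if (denominator == "domain" && is.null(domain)) {
    abort("`domain` must be given for the domain denominator")
  }
  a <- tibble::as_tibble(assignments)
  if (!"sample" %in% names(a)) a$sample <- "sample_1"
  parts <- strsplit(ifelse(is.na(a$lineage), "", a$lineage), ";", fixed = TRUE)
  a$.domain <- vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_,
                      character(1))
  a$.clade <- vapply(parts, function(p) {
    if (length(p) >= depth_needed) p[depth_needed] else NA_character_
  }, character(1))

  denom_pool <- switch(denominator,
    total = a,
    domain = a[!is.na(a$.domain) & a$.domain == domain, , drop = FALSE],
    rank_assigned = NULL # computed from the counted reads below
  )
  counted <- a[!is.na(a$.clade), , drop = FALSE]
  if (!is.null(domain)) {
    counted <- counted[counted$.domain == domain, , drop = FALSE]
  }
  if (is.null(denom_pool)) denom_pool <- counted
  denom <- dplyr::count(denom_pool, .data$sample, name = ".denom")

  out <- dplyr::count(counted, .data$sample, clade = .data$.clade,
                      name = "count")
  out <- tidyr::complete(out,
                         sample = unique(a$sample),
                         clade = unique(counted$.clade),
                         fill = list(count = 0L))
  out <- dplyr::left_join(out, denom, by = "sample")
  out$.denom[is.na(out$.denom)] <- 0L
  out$proportion <- ifelse(out$.denom > 0, out$count / out$.denom, 0)
  out$.denom <- NULL
  out <- dplyr::arrange(out, .data$sample, .data$clade)
  attr(out, "rank") <- rank
  attr(out, "denominator") <- denominator
  attr(out, "domain") <- domain
  class(out) <- c("clade_table", class(out))
  out
}

#' Round proportions to a fixed decimal resolution
#'
#' Rounds each proportion half away from zero to `decimals` places. This
#' plays the role of rarefying: it equalizes the effective resolution across
#' libraries of different depth (values below half the resolution become 0)
#' without adding resampling noise. Typical choices are 3 decimals for
#' eukaryotic and 2 for bacterial SSU tables, and 5 for KO tables.
#'
#' @param table A table with a `proportion` column (e.g. from
#'   [clade_table()] or [ko_proportions()]).
#' @param decimals Number of decimal places (>= 1).
#' @return The table with rounded proportions; the resolution
#'   `10^-decimals` is recorded in the `resolution` attribute.
#' @export
round_normalize <- function(table, decimals) {
  if (!is.numeric(decimals) || length(decimals) != 1 || decimals < 1) {
    abort("`decimals` must be a single integer >= 1")
  }
  check_cols(table, "proportion", "abundance table")
  table$proportion <- round_half_away(table$proportion, decimals)
  attr(table, "decimals") <- decimals
  attr(table, "resolution") <- 10^-decimals
  table
}

#' Sample-by-clade community matrix
#'
#' Widens a long clade (or KO) table into the samples x taxa numeric matrix
#' used by distance and ordination functions.
#'
#' @param table Long table with `sample`, a taxon column (`clade` or `ko`)
#'   and the value column.
#' @param value `"proportion"` (default, falling back to `"count"` when no
#'   proportions are present) or `"count"`.
#' @return Numeric matrix, samples in rows.
#' @export
community_matrix <- function(table, value = c("proportion", "count")) {
  value <- match.arg(value)
  taxon <- intersect(c("clade", "ko"), names(table))[1]
  if (is.na(taxon)) abort("table must have a `clade` or `ko` column")
  if (value == "proportion" && !"proportion" %in% names(table)) value <- "count"
  check_cols(table, c("sample", value), "abundance table")
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(table),
                  dplyr::all_of(c("sample", taxon, value))),
    names_from = dplyr::all_of(taxon), values_from = dplyr::all_of(value),
    values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  m
}

#' NMDS ordination of square-root transformed Bray-Curtis distances
#'
#' Square-root transforms the abundance table, computes pairwise Bray-Curtis
#' dissimilarities and embeds the samples by non-metric multidimensional
#' scaling (via [vegan::metaMDS()] with several random restarts). The random
#' seed is fixed and recorded so the embedding is reproducible.
#'
#' @param table Long abundance table (see [community_matrix()]), at least 3
#'   samples.
#' @param k Number of ordination dimensions (default 2).
#' @param seed Integer seed for the random restarts (default 1).
#' @param trymax Maximum number of random starts (default 20).
#' @param sqrt_transform Apply the square-root transform (default TRUE).
#' @return An `nmds_ordination` object: `points` (tibble of sample
#'   coordinates), `stress`, `k`, `seed`, `converged`, and the underlying
#'   `engine` fit.
#' @export
sqrt_bray_nmds <- function(table, k = 2, seed = 1, trymax = 20,
                           sqrt_transform = TRUE) {
  m <- community_matrix(table)
  if (nrow(m) < 3) abort("NMDS needs at least 3 samples")
  if (sqrt_transform) m <- sqrt(m)
  fit <- withr::with_seed(seed,
    vegan::metaMDS(m, distance = "bray", k = k, trymax = trymax,
                   autotransform = FALSE, trace = 0))
  pts <- tibble::as_tibble(vegan::scores(fit, display = "sites"),
                           rownames = "sample")
  structure(
    list(points = pts, stress = fit$stress, k = k, seed = seed,
         converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0),
         engine = fit),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, k = %d, stress = %.4f (seed %d)\n",
              nrow(x$points), x$k, x$stress, x$seed))
  invisible(x)
}

#' Per-sample clade richness above an abundance threshold
#'
#' Counts, per sample, the clades whose proportion exceeds `threshold`
#' (default 1%), the operational definition of presence used for family
#' richness comparisons. Two-group richness comparisons use Welch's t test
#' (see [welch_test()]).
#'
#' @param table Long abundance table with proportions.
#' @param threshold Presence threshold on the proportion (default 0.01);
#'   presence is strict (`> threshold`).
#' @return Tibble with `sample` and `richness`.
#' @export
family_richness <- function(table, threshold = 0.01) {
  check_cols(table, c("sample", "proportion"), "abundance table")
  out <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(table), .data$sample),
                          richness = sum(.data$proportion > threshold),
                          .groups = "drop")
  out
}

#' Per-clade differential abundance between two sample groups
#'
#' Two-sided Mann-Whitney U test per clade on (rounded) proportions, with
#' Benjamini-Hochberg adjustment across clades and flagging at an FDR
#' threshold. Clades constant across all samples get p = 1 and are never
#' flagged.
#'
#' @param table Long clade table with proportions (round first with
#'   [round_normalize()] to mimic rarefying).
#' @param groups Data frame (`sample`, `group`) or named vector mapping each
#'   sample to one of two groups, each with at least 2 samples.
#' @param fdr Adjusted-p threshold for flagging (default 0.005).
#' @return Tibble with one row per clade: mean proportion per group, `p.value`,
#'   `p.adjusted`, and `enriched` (the group with the higher mean when
#'   flagged, else `NA`). Group levels are recorded in the `groups`
#'   attribute.
#' @export
clade_group_test <- function(table, groups, fdr = 0.005) {
  m <- t(community_matrix(table)) # clades x samples
  g <- resolve_groups(groups, colnames(m))
  lev <- attr(g, "levels")
  if (length(lev) != 2) abort("`groups` must define exactly 2 groups")
  ia <- which(g == lev[1]); ib <- which(g == lev[2])
  if (length(ia) < 2 || length(ib) < 2) abort("need at least 2 samples per group")
  p <- row_mann_whitney(m, ia, ib)
  out <- tibble::tibble(
    clade = rownames(m),
    mean_a = rowMeans(m[, ia, drop = FALSE]),
    mean_b = rowMeans(m[, ib, drop = FALSE]),
    p.value = p,
    p.adjusted = p.adjust(p, method = "BH")
  )
  out$enriched <- dplyr::case_when(
    out$p.adjusted < fdr & out$mean_a > out$mean_b ~ lev[1],
    out$p.adjusted < fdr & out$mean_b > out$mean_a ~ lev[2],
    TRUE ~ NA_character_
  )
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2])
  attr(out, "groups") <- lev
  attr(out, "fdr") <- fdr
  out
}

#' Mean top-hit percent identity per clade and sample
#'
#' Averages, within each sample and clade at the given rank, the percent
#' identity of each read's top-scoring hit — a guide to how closely the
#' reads match known reference sequences.
#'
#' @inheritParams clade_table
#' @return Tibble with `sample`, `clade`, `mean_identity`, `n_reads`.
#' @export
mean_top_identity <- function(assignments, rank = "family",
                              ranks = c("domain", "phylum", "class", "order",
                                        "family", "genus")) {
  check_cols(assignments, c("lineage", "top_pident"), "assignment table")
  depth_needed <- match(rank, ranks)
  if (is.na(depth_needed)) abort(sprintf("unknown rank '%s'", rank))
  a <- tibble::as_tibble(assignments)
  if (!"sample" %in% names(a)) a$sample <- "sample_1"
  parts <- strsplit(ifelse(is.na(a$lineage), "", a$lineage), ";", fixed = TRUE)
  a$.clade <- vapply(parts, function(p) {
    if (length(p) >= depth_needed) p[depth_needed] else NA_character_
  }, character(1))
  a <- a[!is.na(a$.clade), , drop = FALSE]
  dplyr::summarise(dplyr::group_by(a, .data$sample, clade = .data$.clade),
                   mean_identity = mean(.data$top_pident),
                   n_reads = dplyr::n(), .groups = "drop")
}
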