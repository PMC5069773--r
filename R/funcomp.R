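#' Reads of unambiguously bacterial origin
#'
#' A read is considered bacterial when all of its best-scoring protein hits
#' with an alignment length of at least `min_len` amino acids are to
#' bacterial subjects. Reads with a best-score tie between a bacterial and a
#' non-bacterial subject, or with no qualifying hits, are excluded.
#'
#' @param hits Protein hit table with columns `read_id`, `align_length`
#'   (amino acids), `bit_score`, and either a `subject_domain` column or a
#'   `domain_map`.
#' @param domain_map Optional data frame (`subject_id`, `domain`) labelling
#'   subjects when `hits` lacks `subject_domain`.
#' @param min_len Minimum alignment length in amino acids (default 50).
#' @param domain Domain label counted as bacterial (default `"Bacteria"`).
#' @return Character vector of read ids that pass.
#' @export
bacterial_read_filter <- function(hits, domain_map = NULL, min_len = 50,
                                  domain = "Bacteria") {
  check_cols(hits, c("read_id", "align_length", "bit_score"), "protein hit table")
  hits <- tibble::as_tibble(hits)
  if (!"subject_domain" %in% names(hits)) {
    if (is.null(domain_map)) {
      abort("hits need a `subject_domain` column or a `domain_map`")
    }
    check_cols(hits, "subject_id", "protein hit table")
    check_cols(domain_map, c("subject_id", "domain"), "domain map")
    hits$subject_domain <- domain_map$domain[
      match(hits$subject_id, domain_map$subject_id)]
    if (anyNA(hits$subject_domain)) {
      abort("some subjects are missing from `domain_map`")
    }
  }
  q <- dplyr::filter(hits, .data$align_length >= min_len)
  if (nrow(q) == 0) return(character())
  best <- dplyr::filter(dplyr::group_by(q, .data$read_id),
                        .data$bit_score == max(.data$bit_score))
  ok <- dplyr::summarise(best,
                         pass = all(.data$subject_domain == domain),
                         .groups = "drop")
  ok$read_id[ok$pass]
}

#' Assign reads to the KEGG ortholog of their top hit
#'
#' Each read takes the KO annotation of its single top-scoring hit; if the
#' top hit has no KO annotation the read is unassigned, even when a
#' lower-scoring hit is annotated. Score ties between subjects carrying the
#' same KO are harmless; ties with conflicting KOs are broken
#' deterministically toward the lexicographically lowest KO id, with a
#' warning.
#'
#' @param hits Protein hit table with columns `read_id`, `subject_id`,
#'   `bit_score` (a `sample` column is carried along).
#' @param ko_map Data frame (`subject_id`, `ko`); subjects absent from the
#'   map count as unannotated.
#' @param read_ids Optional read ids to restrict to (e.g. the output of
#'   [bacterial_read_filter()]).
#' @return Tibble with `read_id` (and `sample`) and `ko` for assigned reads;
#'   unassigned reads are absent.
#' @export
ko_assign <- function(hits, ko_map, read_ids = NULL) {
  check_cols(hits, c("read_id", "subject_id", "bit_score"), "protein hit table")
  check_cols(ko_map, c("subject_id", "ko"), "KO map")
  hits <- tibble::as_tibble(hits)
  if (!is.null(read_ids)) hits <- dplyr::filter(hits, .data$read_id %in% read_ids)
  hits$.ko <- ko_map$ko[match(hits$subject_id, ko_map$subject_id)]
  keys <- intersect(c("sample", "read_id"), names(hits))
  top <- dplyr::filter(dplyr::group_by(hits, dplyr::across(dplyr::all_of(keys))),
                       .data$bit_score == max(.data$bit_score))
  out <- dplyr::summarise(top, {
    kos <- unique(.data$.ko[!is.na(.data$.ko)])
    all_na <- all(is.na(.data$.ko))
    tibble::tibble(
      ko = if (all_na || length(kos) == 0) NA_character_ else sort(kos)[1],
      .conflict = length(kos) > 1
    )
  }, .groups = "drop")
  if (any(out$.conflict)) {
    warn(sprintf(
      "%d read(s) had top-score ties with conflicting KOs; lowest KO id used",
      sum(out$.conflict)))
  }
  out$.conflict <- NULL
  out[!is.na(out$ko), , drop = FALSE]
}

#' Count KO assignments per sample
#'
#' @param assignments Tibble from [ko_assign()] with `sample` and `ko`.
#' @return Long tibble (`ko`, `sample`, `count`), complete over all
#'   KO x sample pairs.
#' @export
ko_count_table <- function(assignments) {
  check_cols(assignments, "ko", "KO assignment table")
  a <- tibble::as_tibble(assignments)
  if (!"sample" %in% names(a)) a$sample <- "sample_1"
  out <- dplyr::count(a, .data$ko, .data$sample, name = "count")
  tidyr::complete(out, ko = unique(a$ko), sample = unique(a$sample),
                  fill = list(count = 0L))
}

#' Per-sample KO proportions at fixed decimal resolution
#'
#' Converts KO counts to proportions of the total KO-assigned reads in each
#' sample and rounds them half away from zero to `decimals` places. Rounding
#' to 5 decimals approximates rarefying every library to ~1e5 reads without
#' adding resampling noise.
#'
#' @param table Long KO count table (`ko`, `sample`, `count`).
#' @param decimals Decimal places for rounding (default 5).
#' @return The table with a rounded `proportion` column; resolution recorded
#'   as attribute.
#' @export
ko_proportions <- function(table, decimals = 5) {
  check_cols(table, c("ko", "sample", "count"), "KO count table")
  table <- tibble::as_tibble(table)
  totals <- tapply(table$count, table$sample, sum)
  if (any(totals <= 0)) {
    abort(sprintf("sample(s) with zero assigned reads: %s",
                  paste(names(totals)[totals <= 0], collapse = ", ")))
  }
  table$proportion <- table$count / unname(totals[table$sample])
  round_normalize(table, decimals)
}

#' Differential KO abundance between two metagenome groups
#'
#' Per-KO two-sided Mann-Whitney U tests on rounded proportions with
#' Benjamini-Hochberg adjustment across all tested KOs, plus a log2 fold
#' change of group mean proportions with a symmetric pseudocount. A KO is
#' flagged as enriched in a group when its adjusted p-value is below `fdr`
#' and |log2 fold change| exceeds `lfc_threshold`. KOs absent from every
#' sample are excluded from testing.
#'
#' The fold change is `log2((mean_1 + pc) / (mean_2 + pc))` where group 1 is
#' the first group level encountered in `groups` (positive values mean
#' enrichment in group 1) and `pc` defaults to half the smallest nonzero
#' proportion in the table.
#'
#' An alternative per-KO test (e.g. a negative-binomial model) can be plugged
#' in via `p_fun`, a function `(matrix, idx_a, idx_b) -> p-value vector`
#' replacing the Mann-Whitney step; everything else (BH, fold change,
#' flagging) is unchanged.
#'
#' @param table KO proportion table from [ko_proportions()].
#' @param groups Data frame (`sample`, `group`) or named vector; two groups
#'   with at least 2 samples each.
#' @param fdr Adjusted-p threshold (default 0.005).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 2).
#' @param pseudocount Symmetric pseudocount for the fold change (default:
#'   half the smallest nonzero proportion).
#' @param p_fun Optional replacement test, see Details.
#' @return A `ko_diff` tibble: `ko`, group mean proportions, `log2fc`,
#'   `p.value`, `p.adjusted`, `enriched` (group name or `NA`).
#' @export
ko_diff_test <- function(table, groups, fdr = 0.005, lfc_threshold = 2,
                         pseudocount = NULL, p_fun = NULL) {
  m <- t(community_matrix(table)) # KOs x samples
  g <- resolve_groups(groups, colnames(m))
  lev <- attr(g, "levels")
  if (length(lev) != 2) abort("`groups` must define exactly 2 groups")
  ia <- which(g == lev[1]); ib <- which(g == lev[2])
  if (length(ia) < 2 || length(ib) < 2) abort("need at least 2 samples per group")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) abort("no KO present in any sample")
  if (is.null(pseudocount)) pseudocount <- min(m[m > 0]) / 2
  p <- if (is.null(p_fun)) row_mann_whitney(m, ia, ib) else p_fun(m, ia, ib)
  mean_a <- rowMeans(m[, ia, drop = FALSE])
  mean_b <- rowMeans(m[, ib, drop = FALSE])
  out <- tibble::tibble(
    ko = rownames(m),
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount)),
    p.value = p,
    p.adjusted = p.adjust(p, method = "BH")
  )
  out$enriched <- dplyr::case_when(
    out$p.adjusted < fdr & out$log2fc > lfc_threshold ~ lev[1],
    out$p.adjusted < fdr & out$log2fc < -lfc_threshold ~ lev[2],
    TRUE ~ NA_character_
  )
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2])
  attr(out, "groups") <- lev
  attr(out, "fdr") <- fdr
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("ko_diff", class(out))
  out
}

#' Summarize enrichment directions of a differential-abundance result
#'
#' Counts tested and flagged KOs per direction and expresses each direction
#' as an integer percentage of the KOs tested (rounded half away from zero
#' for display).
#'
#' @param result A `ko_diff` tibble (or any data frame with an `enriched`
#'   column whose non-`NA` values name the enriched group).
#' @return One-row tibble: `n_tested`, `n_up`, `n_down`, `pct_up`,
#'   `pct_down`, `group_up`, `group_down`. "Up" is the first group level.
#' @export
enrichment_summary <- function(result) {
  check_cols(result, "enriched", "differential-abundance result")
  lev <- attr(result, "groups")
  if (is.null(lev)) {
    lev <- sort(unique(result$enriched[!is.na(result$enriched)]))
    if (length(lev) == 0) lev <- c("up", "down")
    if (length(lev) == 1) lev <- c(lev, ".none")
  }
  n <- nrow(result)
  n_up <- sum(result$enriched == lev[1], na.rm = TRUE)
  n_down <- sum(result$enriched == lev[2], na.rm = TRUE)
  tibble::tibble(
    n_tested = n,
    n_up = n_up,
    n_down = n_down,
    pct_up = if (n > 0) round_half_away(100 * n_up / n) else 0,
    pct_down = if (n > 0) round_half_away(100 * n_down / n) else 0,
    group_up = lev[1],
    group_down = lev[2]
  )
}
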