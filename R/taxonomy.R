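#' Reference taxonomy with lineage map, blacklist and masked regions
#'
#' Bundles the information needed to place alignment hits on a taxonomy: a
#' lineage per database subject (an ordered rank path, SILVA-style
#' semicolon-delimited), an optional blacklist of flagged subjects (e.g.
#' probable chimeras) whose hits are discarded, and optional masked
#' coordinate intervals per subject (e.g. contaminant non-SSU tails) such
#' that hits overlapping a masked interval are discarded.
#'
#' @param lineages Data frame with columns `accession` and `lineage`
#'   (semicolon-delimited rank path), or a named character vector of lineages.
#' @param blacklist Character vector of blacklisted accessions.
#' @param masks Data frame with columns `accession`, `start`, `end`
#'   (1-based inclusive subject coordinates).
#' @param ranks Rank names corresponding to lineage path positions (default
#'   domain through genus).
#' @return A `taxonomy` object.
#' @export
#' @examples
#' taxonomy(c(A1 = "Bacteria;Proteobacteria", A2 = "Eukaryota;Bryozoa"))
taxonomy <- function(lineages, blacklist = NULL, masks = NULL,
                     ranks = c("domain", "phylum", "class", "order",
                               "family", "genus")) {
  if (!is.data.frame(lineages)) {
    if (is.null(names(lineages))) {
      abort("`lineages` must be a data frame or a named character vector")
    }
    lineages <- tibble::tibble(accession = names(lineages),
                               lineage = unname(lineages))
  }
  check_cols(lineages, c("accession", "lineage"), "lineage map")
  if (anyDuplicated(lineages$accession)) {
    abort("duplicated accessions in lineage map")
  }
  path <- lapply(strsplit(lineages$lineage, ";", fixed = TRUE), trimws)
  if (any(lengths(path) == 0) || any(vapply(path, function(p) any(p == ""), logical(1)))) {
    abort("every lineage must be a non-empty semicolon-delimited path")
  }
  if (!is.null(masks)) {
    check_cols(masks, c("accession", "start", "end"), "mask table")
    masks <- tibble::as_tibble(masks)
  }
  structure(
    list(
      lineages = tibble::tibble(accession = lineages$accession,
                                lineage = lineages$lineage,
                                path = path),
      blacklist = as.character(blacklist %||% character()),
      masks = masks,
      ranks = ranks
    ),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("Taxonomy: %d subjects, %d blacklisted, %d masked intervals\n",
              nrow(x$lineages), length(x$blacklist),
              if (is.null(x$masks)) 0L else nrow(x$masks)))
  cat(sprintf("  ranks: %s\n", paste(x$ranks, collapse = ", ")))
  invisible(x)
}

#' Remove hits to blacklisted subjects and masked subject regions
#'
#' Drops alignment hits whose subject is blacklisted in the taxonomy, and
#' hits whose subject coordinates overlap a masked interval (any overlap;
#' coordinates 1-based inclusive, with reversed minus-strand coordinates
#' handled). Hits without subject coordinates are screened against the
#' blacklist only.
#'
#' @param hits Hit table with columns `read_id`, `subject_id`, and optionally
#'   `sstart`, `send`.
#' @param taxonomy A [taxonomy()] object.
#' @return The filtered hit tibble.
#' @export
blacklist_filter <- function(hits, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  check_cols(hits, c("read_id", "subject_id"), "hit table")
  hits <- tibble::as_tibble(hits)
  if (length(taxonomy$blacklist) > 0) {
    hits <- dplyr::filter(hits, !.data$subject_id %in% taxonomy$blacklist)
  }
  masks <- taxonomy$masks
  if (!is.null(masks) && nrow(masks) > 0 &&
      all(c("sstart", "send") %in% names(hits))) {
    lo <- pmin(hits$sstart, hits$send)
    hi <- pmax(hits$sstart, hits$send)
    drop <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(masks))) {
      sel <- hits$subject_id == masks$accession[i]
      drop[sel] <- drop[sel] |
        (lo[sel] <= masks$end[i] & hi[sel] >= masks$start[i])
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  hits
}

#' Retain high-scoring hits within the bit-score window
#'
#' Per read, keeps the hits that pass the alignment-length and bit-score
#' floors and whose bit score lies within a fractional window of the best
#' floor-qualifying hit: `bit_score >= (1 - window) * best`. The best
#' qualifying hit itself is always retained, and the result does not depend
#' on input order. Reads with no qualifying hits yield no rows (and stay
#' unassigned).
#'
#' @param hits Hit table with columns `read_id`, `align_length`, `bit_score`
#'   (a `sample` column, if present, is carried along and reads are treated
#'   per sample).
#' @param min_len Minimum alignment length (default 100, bp for nucleotide
#'   hits).
#' @param min_bit Minimum bit score (default 50).
#' @param window Fractional bit-score window below the best hit (default
#'   0.01).
#' @return The retained hit tibble.
#' @export
retain_hits <- function(hits, min_len = 100, min_bit = 50, window = 0.01) {
  check_cols(hits, c("read_id", "align_length", "bit_score"), "hit table")
  if (window < 0 || window >= 1) abort("`window` must be in [0, 1)")
  hits <- dplyr::filter(tibble::as_tibble(hits),
                        .data$align_length >= min_len,
                        .data$bit_score >= min_bit)
  if (nrow(hits) == 0) return(hits)
  keys <- intersect(c("sample", "read_id"), names(hits))
  hits <- dplyr::group_by(hits, dplyr::across(dplyr::all_of(keys)))
  hits <- dplyr::filter(hits, .data$bit_score >= (1 - window) * max(.data$bit_score))
  dplyr::ungroup(hits)
}

#' Assign reads to the lowest common ancestor of their retained hits
#'
#' Each read is assigned the longest common rank-prefix of the lineages of
#' its retained hits: a read whose retained hits agree down to the family but
#' diverge at the genus is assigned the family and no genus. Reads whose
#' retained hits share no ranks at all (e.g. one bacterial and one eukaryotic
#' hit) are assigned to the unclassified root (`lineage = NA`, depth 0). The
#' percent identity of the top-scoring hit is carried along.
#'
#' @param hits Retained hit table (see [retain_hits()]) with columns
#'   `read_id`, `subject_id`, `bit_score`, `pident`, optionally `sample`.
#' @param taxonomy A [taxonomy()] object covering the hit subjects.
#' @param on_missing `"fail"` (default) to error when a subject is absent
#'   from the taxonomy, `"skip"` to drop such hits.
#' @return Tibble with one row per read: `read_id` (and `sample`),
#'   `lineage` (semicolon-joined LCA path, `NA` at root), `depth` (ranks
#'   achieved), `rank` (name of the deepest rank achieved, `"root"` if none),
#'   `top_pident`, `n_hits`.
#' @export
lca_assign <- function(hits, taxonomy, on_missing = c("fail", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(taxonomy, "taxonomy"))
  check_cols(hits, c("read_id", "subject_id", "bit_score", "pident"), "hit table")
  hits <- tibble::as_tibble(hits)
  idx <- match(hits$subject_id, taxonomy$lineages$accession)
  if (anyNA(idx)) {
    if (on_missing == "fail") {
      abort(sprintf(
        "subject(s) missing from taxonomy: %s",
        paste(unique(hits$subject_id[is.na(idx)]), collapse = ", ")
      ))
    }
    hits <- hits[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(hits) == 0) {
    return(tibble::tibble(read_id = character(), lineage = character(),
                          depth = integer(), rank = character(),
                          top_pident = numeric(), n_hits = integer()))
  }
  hits$.path <- taxonomy$lineages$path[idx]
  keys <- intersect(c("sample", "read_id"), names(hits))
  grouped <- dplyr::group_by(hits, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(grouped, {
    paths <- .data$.path
    lca <- paths[[1]]
    for (p in paths[-1]) {
      n <- min(length(lca), length(p))
      agree <- if (n == 0) 0L else {
        d <- which(lca[seq_len(n)] != p[seq_len(n)])
        if (length(d) == 0) n else d[1] - 1L
      }
      lca <- lca[seq_len(agree)]
      if (length(lca) == 0) break
    }
    depth <- length(lca)
    top <- order(-.data$bit_score, .data$subject_id)[1]
    top_pident <- .data$pident[top]
    tibble::tibble(
      lineage = if (depth == 0) NA_character_ else paste(lca, collapse = ";"),
      depth = as.integer(depth),
      rank = if (depth == 0) "root" else
        if (depth <= length(taxonomy$ranks)) taxonomy$ranks[depth] else
          paste0("rank_", depth),
      top_pident = top_pident,
      n_hits = length(paths)
    )
  }, .groups = "drop")
  out
}

#' Full read-assignment pipeline
#'
#' Convenience wrapper chaining [blacklist_filter()], [retain_hits()] and
#' [lca_assign()]. Reads left with no qualifying hits are absent from the
#' output (unassigned).
#'
#' @inheritParams retain_hits
#' @inheritParams lca_assign
#' @return Per-read assignment tibble (see [lca_assign()]).
#' @export
assign_reads <- function(hits, taxonomy, min_len = 100, min_bit = 50,
                         window = 0.01, on_missing = c("fail", "skip")) {
  hits <- blacklist_filter(hits, taxonomy)
  hits <- retain_hits(hits, min_len = min_len, min_bit = min_bit, window = window)
  lca_assign(hits, taxonomy, on_missing = on_missing)
}
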