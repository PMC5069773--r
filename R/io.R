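#' Read a tabular alignment hit file
#'
#' Reads BLAST/LAST tabular output. Headerless files must have the 12
#' standard outfmt-6 columns (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`) or the 5-column minimal form
#' (`qseqid sseqid pident length bitscore`). Files with a header line may
#' carry any subset of columns under either the outfmt-6 names or the
#' canonical names used throughout this package (`read_id`, `subject_id`,
#' `pident`, `align_length`, `bit_score`, `sstart`, `send`, ...). Hit tables
#' are assumed to be pre-filtered at the aligner's E-value cutoff.
#'
#' @param path Path to the TSV file.
#' @param sample Optional sample identifier stamped on every row.
#' @return Hit tibble with canonical column names.
#' @export
read_hit_table <- function(path, sample = NULL) {
  canon <- c(qseqid = "read_id", sseqid = "subject_id", pident = "pident",
             length = "align_length", mismatch = "mismatch",
             gapopen = "gapopen", qstart = "qstart", qend = "qend",
             sstart = "sstart", send = "send", evalue = "evalue",
             bitscore = "bit_score")
  first <- readLines(path, n = 1)
  has_header <- any(strsplit(first, "\t", fixed = TRUE)[[1]] %in%
                      c(names(canon), unname(canon)))
  if (has_header) {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    hit <- names(out) %in% names(canon)
    names(out)[hit] <- canon[names(out)[hit]]
  } else {
    out <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(out) == 12) {
      names(out) <- unname(canon)
    } else if (ncol(out) == 5) {
      names(out) <- c("read_id", "subject_id", "pident", "align_length",
                      "bit_score")
    } else {
      abort("headerless hit tables must have 12 (full outfmt 6) or 5 columns")
    }
  }
  check_cols(out, c("read_id", "subject_id", "pident", "align_length",
                    "bit_score"), "hit table")
  if (!is.null(sample)) out$sample <- sample
  tibble::as_tibble(out)
}

#' Write a hit table in 12-column outfmt-6 layout
#'
#' Optional columns absent from the input are filled with neutral defaults
#' so the written file is a valid headerless outfmt-6 table that
#' [read_hit_table()] reads back losslessly (for the columns present).
#'
#' @param hits Hit tibble with canonical column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  check_cols(hits, c("read_id", "subject_id", "pident", "align_length",
                     "bit_score"), "hit table")
  n <- nrow(hits)
  defaults <- list(mismatch = 0L, gapopen = 0L, qstart = 1L,
                   qend = hits$align_length, sstart = 1L,
                   send = hits$align_length, evalue = 0)
  for (col in names(defaults)) {
    if (!col %in% names(hits)) hits[[col]] <- defaults[[col]]
  }
  out <- hits[, c("read_id", "subject_id", "pident", "align_length",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bit_score")]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a lineage map, with optional blacklist and mask files
#'
#' The lineage file is a 2-column TSV (`accession`, semicolon-delimited
#' `lineage`), with or without a header. The blacklist file is one accession
#' per line; the mask file a 3-column TSV (`accession`, `start`, `end`,
#' 1-based inclusive).
#'
#' @param path Lineage TSV path.
#' @param blacklist_path,mask_path Optional companion files.
#' @param ranks Rank names for the lineage paths.
#' @return A [taxonomy()] object.
#' @export
read_taxonomy <- function(path, blacklist_path = NULL, mask_path = NULL,
                          ranks = c("domain", "phylum", "class", "order",
                                    "family", "genus")) {
  lin <- readr::read_tsv(path, col_names = c("accession", "lineage"),
                         col_types = "cc", progress = FALSE)
  if (nrow(lin) > 0 && lin$accession[1] == "accession") lin <- lin[-1, ]
  blacklist <- if (!is.null(blacklist_path)) {
    bl <- readLines(blacklist_path)
    bl[bl != "" & bl != "accession"]
  }
  masks <- if (!is.null(mask_path)) {
    m <- readr::read_tsv(mask_path, col_names = c("accession", "start", "end"),
                         col_types = "cdd", progress = FALSE)
    if (nrow(m) > 0 && m$accession[1] == "accession") m <- m[-1, ]
    m
  }
  taxonomy(lin, blacklist = blacklist, masks = masks, ranks = ranks)
}

#' Read a particle measurement table
#'
#' @param path TSV with columns `particle_id`, `station`, `size_class`,
#'   `diameter_mm` and optionally `surface_area_m2`.
#' @return Tibble of particle records.
#' @export
read_particle_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(out, c("station", "size_class", "diameter_mm"), "particle table")
  if (any(out$diameter_mm <= 0)) abort("diameters must be positive")
  out
}

#' Read a trawl count table
#'
#' @param path TSV with columns `station`, `size_class`, `count`,
#'   `volume_m3`.
#' @return Tibble of trawl records.
#' @export
read_trawl_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(out, c("station", "size_class", "count", "volume_m3"),
             "trawl table")
  out
}

#' Read a bottle incubation table
#'
#' @param path TSV with columns `experiment_id`, `station`, `treatment`,
#'   `o2_umol_per_L` and optionally `size_class`, `bottle_volume_L`,
#'   `particle_volume_L`, `duration_h`.
#' @return Tibble of bottle measurements.
#' @export
read_bottle_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(out, c("treatment", "o2_umol_per_L"), "bottle table")
  out
}

#' Read a wide KO count table
#'
#' @param path TSV with a `ko` column and one column of counts per sample.
#' @return Long tibble (`ko`, `sample`, `count`).
#' @export
read_ko_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(wide, "ko", "KO table")
  tidyr::pivot_longer(wide, -"ko", names_to = "sample", values_to = "count")
}

#' Write a long KO count table in wide layout
#'
#' @param table Long tibble (`ko`, `sample`, `count`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ko_table <- function(table, path) {
  check_cols(table, c("ko", "sample", "count"), "KO table")
  wide <- tidyr::pivot_wider(table, names_from = "sample",
                             values_from = "count", values_fill = 0)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a sample-to-group map
#'
#' @param path 2-column TSV (`sample`, `group`), header optional.
#' @return Tibble with `sample` and `group`.
#' @export
read_group_map <- function(path) {
  out <- readr::read_tsv(path, col_names = c("sample", "group"),
                         col_types = "cc", progress = FALSE)
  if (nrow(out) > 0 && out$sample[1] == "sample") out <- out[-1, ]
  out
}
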