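#' Round half away from zero
#'
#' Base `round()` rounds half to even; clade and KO proportion tables are
#' instead rounded half away from zero so that results are bit-reproducible
#' under the documented rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(c(0.0004, 0.4567, 0.455), 3)
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# stop unless all needed columns are present
check_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# resolve a sample -> group mapping given as data frame or named vector;
# returns a named character vector ordered like `samples`, with a "levels"
# attribute preserving the level order of the mapping itself (factor levels,
# or order of first appearance) so callers can fix the reference group
resolve_groups <- function(groups, samples) {
  raw <- if (is.data.frame(groups)) {
    check_cols(groups, c("sample", "group"), "group map")
    setNames(groups$group, as.character(groups$sample))
  } else {
    if (is.null(names(groups))) {
      abort("`groups` must be a data frame with columns sample/group or a named vector")
    }
    groups
  }
  lev <- if (is.factor(raw)) levels(raw) else unique(as.character(raw))
  g <- setNames(as.character(raw), names(raw))
  missing <- setdiff(samples, names(g))
  if (length(missing) > 0) {
    abort(sprintf("no group given for sample(s): %s", paste(missing, collapse = ", ")))
  }
  out <- g[samples]
  attr(out, "levels") <- intersect(lev, out)
  out
}
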