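#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return One-row tibble with `exponent`, `intercept`, `r_squared`,
#'   `fit_min_diameter`, `method`, `n_bins`.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent, intercept = x$intercept,
    r_squared = x$r_squared, fit_min_diameter = x$fit_min_diameter,
    method = x$method, n_bins = x$n_bins
  )
}

#' @rdname tidy.power_law_fit
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) tidy(x, ...)

#' Tidy a size-class test
#'
#' `tidy()` returns the pairwise Dunn contrasts; `glance()` the
#' Kruskal-Wallis omnibus row.
#'
#' @param x A `size_class_test`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy size_class_test
#' @export
tidy.size_class_test <- function(x, ...) x$pairwise

#' @rdname tidy.size_class_test
#' @method glance size_class_test
#' @export
glance.size_class_test <- function(x, ...) x$omnibus

#' Tidy an NMDS ordination
#'
#' `tidy()` returns the sample coordinates; `glance()` the stress, number of
#' dimensions and seed.
#'
#' @param x An `nmds_ordination`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nmds_ordination
#' @export
tidy.nmds_ordination <- function(x, ...) x$points

#' @rdname tidy.nmds_ordination
#' @method glance nmds_ordination
#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, seed = x$seed,
                 converged = x$converged, n_samples = nrow(x$points))
}
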