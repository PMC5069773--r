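#' Bin particle diameters into logarithmic size classes
#'
#' Assigns each particle diameter to a logarithmic size bin. Bin edges are
#' anchored at integer multiples of `log_width` in log10(mm), i.e. at
#' `10^(k * log_width)`, so edges do not depend on the data. A diameter `d`
#' falls in the bin `(lower, upper]` whose upper edge is the smallest anchored
#' edge at or above `d`. All bins between the first and last occupied bin are
#' returned, including empty ones.
#'
#' @param particles A data frame of per-particle records, or a bare numeric
#'   vector of diameters in mm.
#' @param log_width Bin width in log10 units (default 0.1, i.e. ten bins per
#'   decade).
#' @param diameter Column holding diameters in mm when `particles` is a data
#'   frame (default `diameter_mm`).
#' @return A `size_spectrum` tibble with columns `bin_lower`, `bin_upper`
#'   (mm), `midpoint` (geometric midpoint, mm) and `count`, and a `log_width`
#'   attribute.
#' @seealso [normalize_to_bin_width()], [fit_power_law()]
#' @export
#' @examples
#' assign_log_bins(c(1, 2, 4, 8), log_width = log10(2))
assign_log_bins <- function(particles, log_width = 0.1, diameter = diameter_mm) {
  if (is.data.frame(particles)) {
    d <- dplyr::pull(particles, {{ diameter }})
  } else {
    d <- as.numeric(particles)
  }
  if (length(d) == 0) abort("no diameters supplied")
  if (any(!is.finite(d)) || any(d <= 0)) {
    abort("all diameters must be positive and finite")
  }
  if (!is.numeric(log_width) || length(log_width) != 1 || log_width <= 0) {
    abort("`log_width` must be a single positive number")
  }
  k <- ceiling(log10(d) / log_width)
  ks <- seq(min(k), max(k))
  counts <- tabulate(k - min(k) + 1L, nbins = length(ks))
  out <- tibble::tibble(
    bin_lower = 10^((ks - 1) * log_width),
    bin_upper = 10^(ks * log_width),
    midpoint = 10^((ks - 0.5) * log_width),
    count = as.integer(counts)
  )
  attr(out, "log_width") <- log_width
  class(out) <- c("size_spectrum", class(out))
  out
}

#' Normalize bin counts to linear bin width
#'
#' Divides each bin count by the linear (mm) width of the bin, giving the
#' abundance density `a_n` in counts per mm. This is the ordinate of a
#' particle size spectrum: it makes abundances comparable across
#' logarithmically spaced bins of unequal linear width.
#'
#' @param spectrum A `size_spectrum` tibble from [assign_log_bins()].
#' @return The spectrum with an added `a_n` column (per mm).
#' @export
normalize_to_bin_width <- function(spectrum) {
  check_cols(spectrum, c("bin_lower", "bin_upper", "count"), "size spectrum")
  width <- spectrum$bin_upper - spectrum$bin_lower
  if (any(width <= 0)) abort("all bins must have positive linear width")
  spectrum$a_n <- spectrum$count / width
  spectrum
}

#' Fit the power-law scaling exponent of a particle size spectrum
#'
#' Fits `a_n ~ C * d^-exponent` over the bins whose upper edge exceeds
#' `min_diameter`, with `d` the geometric bin midpoint. Floating plastic
#' fragmentation theory predicts an exponent of 3 at steady state; observed
#' spectra typically follow the power law only above ~3 mm, below which
#' particles are lost or under-sampled.
#'
#' Two estimators are available. `"poisson"` (the default) is a Poisson
#' log-link regression of the bin counts on `log(midpoint)` with the linear
#' bin width as offset; zero-count bins stay in the fit, and no log of a small
#' count is ever taken, so the estimator remains accurate when the qualifying
#' bins hold few particles. `"ols"` is unweighted least squares of
#' `log10(a_n)` on `log10(midpoint)` over occupied bins only; it is exact on
#' noiseless spectra but biased low when tail bins hold 0-2 particles, so it
#' is kept for closed-form checks and comparison.
#'
#' @param spectrum A `size_spectrum`; `a_n` is computed if absent.
#' @param min_diameter Only bins with `bin_upper > min_diameter` (mm) enter
#'   the fit (default 3).
#' @param method `"poisson"` (default) or `"ols"`; see Details.
#' @return A `power_law_fit` object with elements `exponent`, `intercept`
#'   (log10 `a_n` at d = 1 mm), `r_squared` (OLS R^2, or 1 - residual/null
#'   deviance for Poisson), `fit_min_diameter`, `method`, `n_bins`, the bin
#'   subset used (`data`) and the underlying model fit (`fit`).
#' @export
#' @examples
#' d <- sim_particle_sizes(5000, exponent = 3, d_min = 0.3, d_max = 30, seed = 1)
#' fit_power_law(assign_log_bins(d))
fit_power_law <- function(spectrum, min_diameter = 3,
                          method = c("poisson", "ols")) {
  method <- match.arg(method)
  check_cols(spectrum, c("bin_lower", "bin_upper", "midpoint", "count"),
             "size spectrum")
  if (!"a_n" %in% names(spectrum)) spectrum <- normalize_to_bin_width(spectrum)
  above <- spectrum$bin_upper > min_diameter
  occupied <- above & spectrum$count > 0
  if (sum(occupied) < 2) {
    abort("power-law fit needs at least 2 occupied bins above `min_diameter`")
  }
  if (method == "ols") {
    sub <- spectrum[occupied, , drop = FALSE]
    fit <- lm(log10(a_n) ~ log10(midpoint), data = sub)
    exponent <- -unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    # summary.lm warns on exactly collinear (noiseless) spectra; R^2 is still valid
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    sub <- spectrum[above, , drop = FALSE]
    fit <- glm(count ~ log(midpoint),
               family = poisson(),
               offset = log(bin_upper - bin_lower),
               data = sub)
    exponent <- -unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1]) / log(10)
    r2 <- 1 - fit$deviance / fit$null.deviance
  }
  structure(
    list(
      exponent = exponent,
      intercept = intercept,
      r_squared = r2,
      fit_min_diameter = min_diameter,
      method = method,
      n_bins = nrow(sub),
      data = tibble::as_tibble(sub),
      fit = fit
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Particle size-spectrum power-law fit\n")
  cat(sprintf("  exponent: %.4f  (method: %s)\n", x$exponent, x$method))
  cat(sprintf("  fit range: bins with upper edge > %g mm (%d bins)\n",
              x$fit_min_diameter, x$n_bins))
  cat(sprintf("  r_squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Volumetric concentration of trawl-collected fragments
#'
#' Converts fragment counts from a surface net tow into concentrations per
#' cubic metre of water filtered, per row (typically one row per station and
#' size class).
#'
#' @param trawl Data frame with columns `count` and `volume_m3`.
#' @return The input tibble with an added `fragments_m3` column.
#' @export
volumetric_concentration <- function(trawl) {
  check_cols(trawl, c("count", "volume_m3"), "trawl table")
  if (any(trawl$volume_m3 <= 0)) abort("`volume_m3` must be positive")
  if (any(trawl$count < 0)) abort("`count` must be non-negative")
  dplyr::mutate(tibble::as_tibble(trawl),
                fragments_m3 = .data$count / .data$volume_m3)
}

#' Areal concentration of neustonic fragments
#'
#' Integrates a volumetric surface concentration over the depth of the
#' neuston layer sampled by the net, giving fragments per square kilometre of
#' sea surface: `conc * layer_depth * 1e6`.
#'
#' @param conc Volumetric concentration(s), fragments per m^3.
#' @param layer_depth Depth of the sampled surface layer in m (default 0.15,
#'   the submerged height of a manta-trawl mouth).
#' @return Fragments per km^2.
#' @export
#' @examples
#' areal_concentration(3.71) # 556,500 fragments/km^2
areal_concentration <- function(conc, layer_depth = 0.15) {
  if (any(conc < 0)) abort("concentration must be non-negative")
  if (length(layer_depth) != 1 || layer_depth <= 0) {
    abort("`layer_depth` must be a single positive number")
  }
  conc * layer_depth * 1e6
}
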