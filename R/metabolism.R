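#' Adjust bottle oxygen for particle displacement
#'
#' Plastic pieces incubated in a bottle displace part of the water volume, so
#' equal concentrations in amended and unamended bottles do not represent
#' equal amounts of oxygen. This converts measured concentrations into total
#' oxygen amounts over the effective water volume
#' `bottle_volume_L - particle_volume_L`, the basis on which rates are
#' compared. With no particle the adjustment is the identity
#' (amount = concentration x bottle volume).
#'
#' @param bottles Data frame with column `o2_umol_per_L`; optional columns
#'   `bottle_volume_L` (default 0.125) and `particle_volume_L` (default 0)
#'   are filled when absent.
#' @return The input tibble with added `water_volume_L` and `o2_umol`
#'   columns.
#' @export
displacement_adjust <- function(bottles) {
  check_cols(bottles, "o2_umol_per_L", "bottle table")
  bottles <- tibble::as_tibble(bottles)
  if (!"bottle_volume_L" %in% names(bottles)) bottles$bottle_volume_L <- 0.125
  if (!"particle_volume_L" %in% names(bottles)) bottles$particle_volume_L <- 0
  if (any(bottles$o2_umol_per_L < 0)) abort("oxygen concentrations must be non-negative")
  if (any(bottles$particle_volume_L < 0)) abort("particle volumes must be non-negative")
  if (any(bottles$particle_volume_L >= bottles$bottle_volume_L)) {
    abort("particle volume must be smaller than bottle volume")
  }
  dplyr::mutate(
    bottles,
    water_volume_L = .data$bottle_volume_L - .data$particle_volume_L,
    o2_umol = .data$o2_umol_per_L * .data$water_volume_L
  )
}

#' Community metabolic rates from light/dark bottle incubations
#'
#' Computes net community production (NCP), community respiration (R) and
#' gross primary production (GPP) from grouped light, dark and time-zero
#' oxygen measurements:
#' NCP = (mean light - mean t0) x 24/duration,
#' R = (mean t0 - mean dark) x 24/duration, and GPP = NCP + R (computed as
#' that sum, so the identity holds bit-exactly). Standard errors are
#' propagated from the within-treatment variances.
#'
#' Measurements are displacement-adjusted first (see
#' [displacement_adjust()]); `per = "liter"` expresses rates per litre of
#' incubated water (the natural unit for unamended seawater), `per = "bottle"`
#' per bottle (the natural basis for subtracting background rates from
#' particle-amended bottles).
#'
#' @param bottles Data frame with columns `treatment` (values `light`,
#'   `dark`, `t0`) and `o2_umol_per_L`, plus optional `experiment_id`,
#'   `station`, `duration_h` (default 24), `bottle_volume_L`,
#'   `particle_volume_L`.
#' @param per `"liter"` (default) or `"bottle"`; see Details.
#' @return A `rate_estimate` tibble, one row per experiment, with columns
#'   `ncp`, `r`, `gpp` (umol O2 per day, on the chosen basis), their standard
#'   errors, and per-treatment bottle counts. The unit basis is recorded in
#'   the `units` attribute.
#' @export
bottle_rates <- function(bottles, per = c("liter", "bottle")) {
  per <- match.arg(per)
  check_cols(bottles, c("treatment", "o2_umol_per_L"), "bottle table")
  bottles <- displacement_adjust(bottles)
  if (!"duration_h" %in% names(bottles)) bottles$duration_h <- 24
  if (any(bottles$duration_h <= 0)) abort("`duration_h` must be positive")
  bad <- setdiff(unique(bottles$treatment), c("light", "dark", "t0"))
  if (length(bad) > 0) {
    abort(sprintf("unknown treatment value(s): %s", paste(bad, collapse = ", ")))
  }
  bottles$.value <- if (per == "liter") {
    bottles$o2_umol / bottles$water_volume_L
  } else {
    bottles$o2_umol
  }

  keys <- intersect(c("experiment_id", "station"), names(bottles))
  grouped <- dplyr::group_by(bottles, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(grouped, .rates = list({
    v <- .data$.value
    trt <- .data$treatment
    dur <- unique(.data$duration_h)
    if (length(dur) != 1) abort("`duration_h` must be constant within an experiment")
    miss <- setdiff(c("light", "dark", "t0"), trt)
    if (length(miss) > 0) {
      abort(sprintf("missing treatment group(s): %s", paste(miss, collapse = ", ")))
    }
    f <- 24 / dur
    st <- function(w) {
      x <- v[trt == w]
      list(m = mean(x), se2 = if (length(x) > 1) var(x) / length(x) else 0,
           n = length(x))
    }
    l <- st("light"); d <- st("dark"); z <- st("t0")
    ncp <- (l$m - z$m) * f
    r <- (z$m - d$m) * f
    tibble::tibble(
      ncp = ncp, r = r, gpp = ncp + r,
      se_ncp = sqrt(l$se2 + z$se2) * f,
      se_r = sqrt(z$se2 + d$se2) * f,
      se_gpp = sqrt(l$se2 + d$se2) * f,
      n_light = l$n, n_dark = d$n, n_t0 = z$n,
      duration_h = dur
    )
  }), .groups = "drop")
  out <- tidyr::unnest(out, ".rates")
  attr(out, "units") <- sprintf("umol_O2_per_%s_per_day",
                                if (per == "liter") "L" else "bottle")
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Subtract background seawater rates to get per-particle rates
#'
#' Rates measured in particle-amended bottles include the activity of the
#' surrounding seawater community; subtracting the rates of unamended control
#' bottles (component-wise) isolates the contribution of the particle(s), and
#' dividing by the number of particles per bottle expresses it per particle.
#' GPP is recomputed as NCP + R, which equals the direct subtraction because
#' the identity is linear.
#'
#' @param amended `rate_estimate` from particle-amended bottles.
#' @param control `rate_estimate` from unamended bottles, either a single row
#'   or joinable to `amended` by shared `experiment_id`/`station` columns.
#' @param n_particles Particles per amended bottle (default 1, matching
#'   incubations where pieces are placed individually into bottles).
#' @return A `rate_estimate` tibble of per-particle rates with propagated
#'   standard errors; units attribute becomes per-particle.
#' @export
background_subtract <- function(amended, control, n_particles = 1) {
  ua <- attr(amended, "units")
  uc <- attr(control, "units")
  if (!identical(ua, uc)) {
    abort(sprintf("unit mismatch between amended (%s) and control (%s) rates", ua, uc))
  }
  if (n_particles < 1) abort("`n_particles` must be at least 1")
  rate_cols <- c("ncp", "r", "gpp", "se_ncp", "se_r", "se_gpp")
  check_cols(amended, rate_cols, "amended rates")
  check_cols(control, rate_cols, "control rates")

  keys <- intersect(intersect(c("experiment_id", "station"), names(amended)),
                    names(control))
  ctl <- dplyr::select(tibble::as_tibble(control),
                       dplyr::all_of(c(keys, rate_cols)))
  ctl <- dplyr::rename_with(ctl, ~ paste0(".ctl_", .x), dplyr::all_of(rate_cols))
  if (nrow(control) == 1) {
    joined <- dplyr::bind_cols(tibble::as_tibble(amended),
                               ctl[rep(1, nrow(amended)),
                                   setdiff(names(ctl), keys), drop = FALSE])
  } else if (length(keys) > 0) {
    joined <- dplyr::inner_join(tibble::as_tibble(amended), ctl, by = keys)
    if (nrow(joined) != nrow(amended)) {
      abort("could not match every amended experiment to a control")
    }
  } else {
    abort("control has several rows but no shared key columns to join on")
  }
  out <- dplyr::mutate(
    joined,
    ncp = (.data$ncp - .data$.ctl_ncp) / n_particles,
    r = (.data$r - .data$.ctl_r) / n_particles,
    gpp = .data$ncp + .data$r,
    se_ncp = sqrt(.data$se_ncp^2 + .data$.ctl_se_ncp^2) / n_particles,
    se_r = sqrt(.data$se_r^2 + .data$.ctl_se_r^2) / n_particles,
    se_gpp = sqrt(.data$se_gpp^2 + .data$.ctl_se_gpp^2) / n_particles
  )
  out <- dplyr::select(out, -dplyr::starts_with(".ctl_"))
  attr(out, "units") <- "umol_O2_per_particle_per_day"
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Surface area of a spherical particle
#'
#' @param diameter_mm Particle diameter in mm.
#' @return Surface area `pi * d^2` in m^2.
#' @export
#' @examples
#' sphere_surface_area(5) # 7.854e-5 m^2
sphere_surface_area <- function(diameter_mm) {
  if (any(diameter_mm < 0)) abort("diameter must be non-negative")
  pi * (diameter_mm / 1000)^2
}

#' Chlorophyll a per unit particle surface area
#'
#' @param chl_mass_mg Chl a mass on the particle, mg.
#' @param surface_area_m2 Particle surface area, m^2.
#' @return Areal Chl a density in mg/m^2.
#' @export
chl_per_area <- function(chl_mass_mg, surface_area_m2) {
  if (any(surface_area_m2 <= 0)) abort("surface area must be positive")
  if (any(chl_mass_mg < 0)) abort("Chl mass must be non-negative")
  chl_mass_mg / surface_area_m2
}

#' Seawater volume holding as much chlorophyll as a particle
#'
#' Expresses the Chl a standing stock on a plastic particle as the volume of
#' surrounding seawater containing the same amount of Chl:
#' `chl_areal * surface_area / chl_water`, converted from m^3 to mL.
#'
#' @param chl_areal Chl a density on the particle, mg/m^2.
#' @param surface_area_m2 Particle surface area, m^2.
#' @param chl_water Chl a concentration of the surrounding water, mg/m^3.
#' @return Equivalent seawater volume in mL.
#' @export
#' @examples
#' seawater_equiv_volume(0.42, sphere_surface_area(5), 0.1) # ~330 mL
seawater_equiv_volume <- function(chl_areal, surface_area_m2, chl_water) {
  if (any(chl_water <= 0)) abort("seawater Chl concentration must be positive")
  if (any(chl_areal < 0)) abort("areal Chl must be non-negative")
  chl_areal * surface_area_m2 / chl_water * 1e6
}

#' Compare a measurement across particle size classes
#'
#' Kruskal-Wallis omnibus rank test across groups, followed by Dunn's
#' post hoc pairwise z-tests with multiplicity adjustment
#' (Benjamini-Hochberg by default). Used for e.g. areal Chl a densities on
#' the three debris size classes.
#'
#' @param data Data frame of measurements.
#' @param value Column holding the measured values.
#' @param group Column holding the group labels.
#' @param p_adjust Adjustment method for the pairwise p-values (default
#'   `"BH"`).
#' @param alpha Significance level for flagging pairwise contrasts (default
#'   0.05).
#' @return A `size_class_test` list with `omnibus` (one-row tibble) and
#'   `pairwise` (one row per contrast) tibbles; `tidy()` returns the pairwise
#'   table, `glance()` the omnibus row.
#' @export
size_class_test <- function(data, value, group, p_adjust = "BH", alpha = 0.05) {
  x <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("need at least 2 values per group")
  if (length(unique(x)) == 1) {
    warn("all values tied; reporting non-significant results")
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    out <- list(
      omnibus = tibble::tibble(statistic = 0, df = nlevels(g) - 1, p.value = 1,
                               method = "Kruskal-Wallis rank sum test"),
      pairwise = tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                                z = 0, p.value = 1, p.adjusted = 1,
                                significant = FALSE)
    )
    class(out) <- "size_class_test"
    return(out)
  }
  kw <- kruskal.test(x, g)
  pw <- dunn_test(x, g, p_adjust = p_adjust)
  pw$significant <- pw$p.adjusted < alpha
  out <- list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p.value = kw$p.value,
                             method = "Kruskal-Wallis rank sum test"),
    pairwise = pw
  )
  class(out) <- "size_class_test"
  out
}

#' @export
print.size_class_test <- function(x, ...) {
  cat("Omnibus:\n"); print(x$omnibus)
  cat("Pairwise (Dunn):\n"); print(x$pairwise)
  invisible(x)
}

#' Two-group test of metabolic rates
#'
#' Compares two groups of rate measurements with either a two-sided
#' Mann-Whitney U test or a one-way ANOVA F test. The Mann-Whitney p-value is
#' computed by exact enumeration when both groups have at most 8 untied
#' values, and by the normal approximation with tie correction and continuity
#' correction otherwise. Degenerate all-tied inputs return p = 1 with a
#' warning.
#'
#' @param a,b Numeric vectors of measurements, at least 2 values each.
#' @param method `"mann_whitney"` (default) or `"anova"`.
#' @return One-row tibble with `method`, `statistic` and `p.value`.
#' @export
two_group_rate_test <- function(a, b, method = c("mann_whitney", "anova")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group")
  if (method == "mann_whitney") {
    use_exact <- length(a) <= 8 && length(b) <= 8 && !any(duplicated(c(a, b)))
    ht <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = TRUE))
    p <- ht$p.value
    if (is.nan(p) || is.na(p)) {
      warn("degenerate (all-tied) data; returning p = 1")
      p <- 1
    }
    tibble::tibble(method = "mann_whitney",
                   statistic = unname(ht$statistic), p.value = p)
  } else {
    x <- c(a, b)
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    ht <- oneway.test(x ~ g, var.equal = TRUE)
    p <- ht$p.value
    stat <- unname(ht$statistic)
    if (is.nan(p) || is.na(p)) {
      warn("degenerate (all-tied) data; returning p = 1")
      p <- 1
      stat <- 0
    }
    tibble::tibble(method = "anova", statistic = stat, p.value = p)
  }
}
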