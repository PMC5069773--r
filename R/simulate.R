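#' Sample particle diameters from a bounded power law
#'
#' Draws i.i.d. diameters from the density proportional to `d^-exponent` on
#' `[d_min, d_max]` by inverse-CDF sampling. `exponent = 1` uses the
#' log-uniform closed form. The steady-state fragmentation prediction for
#' floating plastic corresponds to `exponent = 3`.
#'
#' @param n Number of particles.
#' @param exponent Power-law exponent (> 0).
#' @param d_min,d_max Diameter bounds in mm, `0 < d_min <= d_max`.
#' @param seed Optional integer seed; when given, the draw is a pure
#'   function of the arguments.
#' @return Numeric vector of diameters in mm.
#' @export
sim_particle_sizes <- function(n, exponent = 3, d_min = 0.3, d_max = 30,
                               seed = NULL) {
  if (d_min <= 0 || d_max < d_min) abort("need 0 < d_min <= d_max")
  draw <- function() {
    if (d_min == d_max) return(rep(d_min, n))
    u <- runif(n)
    if (abs(exponent - 1) < 1e-12) {
      d_min * (d_max / d_min)^u
    } else {
      a <- 1 - exponent
      (d_min^a + u * (d_max^a - d_min^a))^(1 / a)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a per-particle measurement table
#'
#' Generates a particle table in the on-disk layout (`particle_id`,
#' `station`, `size_class`, `diameter_mm`, `surface_area_m2`) with diameters
#' from [sim_particle_sizes()], stations assigned uniformly, size classes cut
#' at 2 and 5 mm, and spherical surface areas.
#'
#' @inheritParams sim_particle_sizes
#' @param stations Station identifiers to sample from.
#' @return Tibble of per-particle records.
#' @export
sim_particle_table <- function(n = 554, exponent = 3, d_min = 0.2, d_max = 30,
                               stations = paste0("S", 1:14), seed = NULL) {
  run <- function() {
    d <- sim_particle_sizes(n, exponent, d_min, d_max)
    tibble::tibble(
      particle_id = sprintf("P%04d", seq_len(n)),
      station = sample(stations, n, replace = TRUE),
      size_class = cut(d, breaks = c(0, 2, 5, Inf),
                       labels = c("0.2-2 mm", ">2-5 mm", ">5 mm")),
      diameter_mm = d,
      surface_area_m2 = sphere_surface_area(d)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate light/dark/time-zero bottle oxygen measurements
#'
#' Emulates a bottle incubation with known true rates: time-zero bottles at
#' the baseline concentration, light bottles at
#' `baseline + ncp * duration/24`, dark bottles at
#' `baseline - r * duration/24`, each with additive Gaussian noise. With
#' `noise_sd = 0`, [bottle_rates()] recovers the configured rates exactly.
#' Negative generated concentrations are clipped at 0 with a warning.
#'
#' @param ncp,r True net community production and respiration, umol O2/L/day.
#' @param baseline_o2 Time-zero oxygen concentration, umol/L (default 210,
#'   near air saturation for warm surface seawater).
#' @param n_per_treatment Bottles per treatment (default 8).
#' @param noise_sd Gaussian measurement noise sd, umol/L (default 0.5).
#' @param duration_h Incubation duration, h (default 24).
#' @param bottle_volume_L,particle_volume_L Bottle and particle volumes, L.
#' @param experiment_id,station Identifiers stamped on the rows.
#' @param seed Optional integer seed.
#' @return Tibble of bottle measurements in the on-disk layout.
#' @export
sim_bottles <- function(ncp = 10, r = 5, baseline_o2 = 210,
                        n_per_treatment = 8, noise_sd = 0.5, duration_h = 24,
                        bottle_volume_L = 0.125, particle_volume_L = 0,
                        experiment_id = "exp1", station = "S1", seed = NULL) {
  if (n_per_treatment < 1) abort("`n_per_treatment` must be at least 1")
  run <- function() {
    f <- duration_h / 24
    means <- c(t0 = baseline_o2,
               light = baseline_o2 + ncp * f,
               dark = baseline_o2 - r * f)
    out <- tibble::tibble(
      experiment_id = experiment_id,
      station = station,
      treatment = rep(names(means), each = n_per_treatment),
      o2_umol_per_L = rep(unname(means), each = n_per_treatment) +
        rnorm(3 * n_per_treatment, sd = noise_sd),
      bottle_volume_L = bottle_volume_L,
      particle_volume_L = particle_volume_L,
      duration_h = duration_h
    )
    if (any(out$o2_umol_per_L < 0)) {
      warn("negative generated oxygen concentration(s) clipped at 0")
      out$o2_umol_per_L <- pmax(out$o2_umol_per_L, 0)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default synthetic community profile
#'
#' A small cross-domain community resembling the biofouling assemblage on
#' open-ocean plastic: encrusting bryozoans and diatoms among the eukaryotes,
#' and Rhodobacteraceae, Flavobacteriaceae and filamentous cyanobacteria
#' among the bacteria. Lineages are 6-rank paths (domain through genus).
#'
#' @return Tibble with `accession`, `lineage` and `proportion` (summing
#'   to 1).
#' @export
sim_community_profile <- function() {
  tibble::tribble(
    ~accession, ~lineage, ~proportion,
    "ACC001", "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Roseovarius", 0.18,
    "ACC002", "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Tenacibaculum", 0.12,
    "ACC003", "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Muricauda", 0.08,
    "ACC004", "Bacteria;Cyanobacteria;Cyanophyceae;Oscillatoriales;Microcoleaceae;Phormidium", 0.12,
    "ACC005", "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodospirillales;Rhodospirillaceae;Thalassospira", 0.05,
    "ACC006", "Eukaryota;Bryozoa;Gymnolaemata;Cheilostomatida;Membraniporidae;Membranipora", 0.25,
    "ACC007", "Eukaryota;Arthropoda;Hexanauplia;Harpacticoida;Harpacticidae;Harpacticus", 0.08,
    "ACC008", "Eukaryota;Ochrophyta;Bacillariophyceae;Naviculales;Naviculaceae;Navicula", 0.12
  )
}

#' Simulate an alignment hit table with known true lineages
#'
#' Emulates the tabular output of aligning shotgun SSU rRNA reads against a
#' reference database. Each read is drawn from a clade of the community
#' profile and receives a top-scoring hit to its true subject. With
#' probability `p_confounder` it also receives a hit to a sister subject
#' whose lineage differs at `confounder_rank`, with a bit score inside the
#' retention window by construction — such reads can only be resolved to the
#' parent rank, and the truth table says so. With probability `p_decoy` it
#' receives a hit 2-5% below the best score (outside a 1% window), which
#' correct retention must ignore.
#'
#' @param profile Community profile (see [sim_community_profile()]).
#' @param n_reads Reads per sample.
#' @param samples Sample identifiers.
#' @param p_confounder Probability of an in-window sister-lineage hit.
#' @param confounder_rank Rank at which the confounder's lineage differs
#'   (default `"genus"`).
#' @param p_decoy Probability of an out-of-window decoy hit.
#' @param identity_mean,identity_sd Percent-identity model for the top hit.
#' @param window Bit-score window the generator is exercising (default 0.01).
#' @param seed Optional integer seed.
#' @param ranks Rank names of the lineage paths.
#' @return List with `hits` (tabular hit tibble), `taxonomy` (a [taxonomy()]
#'   covering true, sister and decoy subjects) and `truth` (per-read tibble
#'   with the deepest unambiguously recoverable `lineage`, `depth` and
#'   `rank`).
#' @export
sim_hit_table <- function(profile = sim_community_profile(), n_reads = 300,
                          samples = "plastic_1", p_confounder = 0.3,
                          confounder_rank = "genus", p_decoy = 0.2,
                          identity_mean = 97, identity_sd = 1.5,
                          window = 0.01, seed = NULL,
                          ranks = c("domain", "phylum", "class", "order",
                                    "family", "genus")) {
  check_cols(profile, c("accession", "lineage", "proportion"), "community profile")
  k <- match(confounder_rank, ranks)
  if (is.na(k)) abort(sprintf("unknown confounder rank '%s'", confounder_rank))
  run <- function() {
    paths <- strsplit(profile$lineage, ";", fixed = TRUE)
    if (any(lengths(paths) < k)) {
      abort("every profile lineage must reach the confounder rank")
    }
    sib_path <- vapply(paths, function(p) {
      p[k] <- paste0(p[k], "_sister"); paste(p, collapse = ";")
    }, character(1))
    decoy_path <- vapply(paths, function(p) {
      p[-1] <- paste0(p[-1], "_decoy"); paste(p, collapse = ";")
    }, character(1))
    tax <- taxonomy(
      tibble::tibble(
        accession = c(profile$accession,
                      paste0(profile$accession, "_sib"),
                      paste0(profile$accession, "_dec")),
        lineage = c(profile$lineage, sib_path, decoy_path)
      ),
      ranks = ranks
    )
    all_hits <- list(); all_truth <- list()
    for (s in samples) {
      clade <- sample(nrow(profile), n_reads, replace = TRUE,
                      prob = profile$proportion)
      read_id <- sprintf("%s_read%05d", s, seq_len(n_reads))
      best_bit <- round(runif(n_reads, 300, 800), 1)
      pident <- pmin(100, rnorm(n_reads, identity_mean, identity_sd))
      len <- sample(120:400, n_reads, replace = TRUE)
      has_conf <- runif(n_reads) < p_confounder
      has_decoy <- runif(n_reads) < p_decoy
      base <- tibble::tibble(
        sample = s, read_id = read_id,
        subject_id = profile$accession[clade],
        pident = round(pident, 1), align_length = len,
        bit_score = best_bit
      )
      conf <- base[has_conf, , drop = FALSE]
      conf$subject_id <- paste0(conf$subject_id, "_sib")
      conf$bit_score <- round(conf$bit_score *
                                (1 - runif(nrow(conf), 0, 0.9 * window)), 1)
      conf$pident <- pmax(80, conf$pident - round(runif(nrow(conf), 0.1, 1), 1))
      dec <- base[has_decoy, , drop = FALSE]
      dec$subject_id <- paste0(dec$subject_id, "_dec")
      dec$bit_score <- round(dec$bit_score *
                               (1 - runif(nrow(dec), 2 * window, 5 * window)), 1)
      dec$pident <- pmax(75, dec$pident - round(runif(nrow(dec), 2, 8), 1))
      hits <- dplyr::bind_rows(base, conf, dec)
      hits <- hits[sample(nrow(hits)), , drop = FALSE]
      truth_depth <- ifelse(has_conf, k - 1L, lengths(paths)[clade])
      all_truth[[s]] <- tibble::tibble(
        sample = s, read_id = read_id,
        lineage = vapply(seq_len(n_reads), function(i) {
          d <- truth_depth[i]
          if (d == 0) NA_character_ else
            paste(paths[[clade[i]]][seq_len(d)], collapse = ";")
        }, character(1)),
        depth = as.integer(truth_depth),
        rank = ifelse(truth_depth == 0, "root", ranks[pmax(truth_depth, 1)])
      )
      all_hits[[s]] <- hits
    }
    list(hits = dplyr::bind_rows(all_hits), taxonomy = tax,
         truth = dplyr::bind_rows(all_truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a KO count table with planted fold changes
#'
#' Generates a KO x sample count table from negative-binomial draws whose
#' expected proportions follow a lognormal baseline shared by both groups,
#' except for a planted fraction of KOs whose group means differ by
#' `2^planted_log2fc` (half enriched in each group). Per-sample library
#' sizes vary to emulate uneven sequencing depth. `dispersion = 0` gives
#' Poisson counts.
#'
#' @param n_kos Number of KOs (default 2000).
#' @param n_per_group Named integer vector of group sizes (default 12
#'   plastic, 17 picoplankton samples).
#' @param planted_fraction Fraction of KOs with a planted effect (default
#'   0.1).
#' @param planted_log2fc Planted log2 fold change (default 4).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; default 0.3).
#' @param library_sizes Optional per-sample totals; default: drawn uniformly
#'   between 216,000 and 1,000,000 reads.
#' @param abundance_sdlog Lognormal sd of baseline KO abundances (default 1).
#' @param seed Optional integer seed.
#' @return List with `counts` (long tibble `ko`, `sample`, `count`),
#'   `groups` (tibble `sample`, `group`) and `truth` (tibble `ko`,
#'   `planted`, `direction` — the group the KO is enriched in, or `NA`).
#' @export
sim_ko_table <- function(n_kos = 2000,
                         n_per_group = c(plastic = 12, picoplankton = 17),
                         planted_fraction = 0.1, planted_log2fc = 4,
                         dispersion = 0.3, library_sizes = NULL,
                         abundance_sdlog = 1, seed = NULL) {
  if (length(n_per_group) != 2 || any(n_per_group < 2)) {
    abort("`n_per_group` must give two group sizes of at least 2")
  }
  if (planted_fraction < 0 || planted_fraction > 1) {
    abort("`planted_fraction` must be in [0, 1]")
  }
  grp <- names(n_per_group) %||% c("group1", "group2")
  run <- function() {
    base <- rlnorm(n_kos, sdlog = abundance_sdlog)
    base <- base / sum(base)
    n_planted <- round(planted_fraction * n_kos)
    planted <- if (n_planted > 0) sample(n_kos, n_planted) else integer()
    up <- planted[seq_len(ceiling(n_planted / 2))]
    down <- setdiff(planted, up)
    pa <- base; pb <- base
    pa[up] <- pa[up] * 2^planted_log2fc
    pa[down] <- pa[down] / 2^planted_log2fc
    pa <- pa / sum(pa); pb <- pb / sum(pb)
    n_samples <- sum(n_per_group)
    libs <- library_sizes %||% round(runif(n_samples, 216e3, 1e6))
    if (length(libs) != n_samples) {
      abort("`library_sizes` must have one value per sample")
    }
    group <- rep(grp, n_per_group)
    sample_id <- paste0(group, "_", unlist(lapply(n_per_group, seq_len)))
    ko <- sprintf("K%05d", seq_len(n_kos))
    counts <- lapply(seq_len(n_samples), function(s) {
      mu <- libs[s] * (if (group[s] == grp[1]) pa else pb)
      cnt <- if (dispersion <= 0) rpois(n_kos, mu) else
        rnbinom(n_kos, mu = mu, size = 1 / dispersion)
      tibble::tibble(ko = ko, sample = sample_id[s], count = cnt)
    })
    direction <- rep(NA_character_, n_kos)
    direction[up] <- grp[1]; direction[down] <- grp[2]
    list(
      counts = dplyr::bind_rows(counts),
      groups = tibble::tibble(sample = sample_id, group = group),
      truth = tibble::tibble(ko = ko,
                             planted = seq_len(n_kos) %in% planted,
                             direction = direction)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write a complete set of synthetic fixtures to disk
#'
#' Runs every generator with sub-seeds derived deterministically from one
#' master seed and writes all tables (particles, bottles, SSU hit table with
#' taxonomy and truth, KO counts with groups and truth) as TSV files, plus a
#' `manifest.tsv` recording the master seed and a hash of the configuration.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; each generator gets `seed * 100 + offset`.
#' @param ... Overrides passed on to the individual generators as
#'   `particles`, `bottles`, `hits`, `kos` argument lists.
#' @return Invisibly, the manifest tibble.
#' @export
sim_write_all <- function(dir, seed = 1, ...) {
  dots <- list(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  particles <- do.call(sim_particle_table,
                       c(list(seed = seed * 100 + 1), dots$particles))
  bottles <- do.call(sim_bottles, c(list(seed = seed * 100 + 2), dots$bottles))
  hit_sim <- do.call(sim_hit_table, c(list(seed = seed * 100 + 3), dots$hits))
  ko_sim <- do.call(sim_ko_table, c(list(seed = seed * 100 + 4), dots$kos))

  readr::write_tsv(particles, file.path(dir, "particles.tsv"))
  readr::write_tsv(bottles, file.path(dir, "bottles.tsv"))
  write_hit_table(hit_sim$hits, file.path(dir, "ssu_hits.tsv"))
  readr::write_tsv(hit_sim$taxonomy$lineages[, c("accession", "lineage")],
                   file.path(dir, "taxonomy.tsv"), col_names = FALSE)
  readr::write_tsv(hit_sim$truth, file.path(dir, "ssu_truth.tsv"))
  write_ko_table(ko_sim$counts, file.path(dir, "ko_counts.tsv"))
  readr::write_tsv(ko_sim$groups, file.path(dir, "ko_groups.tsv"))
  readr::write_tsv(ko_sim$truth, file.path(dir, "ko_truth.tsv"))

  manifest <- tibble::tibble(
    key = c("seed", "config_hash", "n_particles", "n_reads", "n_kos"),
    value = c(seed, rlang::hash(dots), nrow(particles),
              nrow(hit_sim$truth), length(unique(ko_sim$counts$ko)))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
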