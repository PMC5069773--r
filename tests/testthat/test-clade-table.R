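# assignments fixture: a sample's reads distributed over known families
toy_assignments <- function() {
  rb <- "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae"
  fl <- "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae"
  cl <- "Bacteria;Proteobacteria;Alphaproteobacteria" # class-level only
  tibble::tibble(
    sample = "s1",
    read_id = sprintf("r%02d", 1:12),
    lineage = c(rep(rb, 6), rep(fl, 4), cl, NA),
    depth = c(rep(5L, 10), 3L, 0L),
    rank = c(rep("family", 10), "class", "root"),
    top_pident = 95
  )
}

test_that("clade tables count rank-assigned reads under each denominator", {
  a <- toy_assignments()
  ct <- clade_table(a, rank = "family")
  expect_setequal(ct$clade, c("Rhodobacteraceae", "Flavobacteriaceae"))
  expect_equal(sort(ct$count), c(4L, 6L))
  expect_equal(sort(ct$proportion), c(0.4, 0.6))
  # class-level read excluded from a family table, included at class rank
  cc <- clade_table(a, rank = "class")
  expect_equal(sum(cc$count), 11)
  # total denominator includes root and class-only reads
  ct_tot <- clade_table(a, rank = "family", denominator = "total")
  expect_equal(sort(ct_tot$proportion), c(4, 6) / 12)
  # domain denominator counts reads assigned at least to the domain
  ct_dom <- clade_table(a, rank = "family", denominator = "domain",
                        domain = "Bacteria")
  expect_equal(sort(ct_dom$proportion), c(4, 6) / 11)
  expect_error(clade_table(a, rank = "species"), "unknown rank")
  expect_error(clade_table(a, denominator = "domain"), "domain")
})

test_that("single-clade sample yields proportion 1", {
  a <- toy_assignments()[1:6, ]
  ct <- clade_table(a, rank = "family")
  expect_equal(ct$count, 6L)
  expect_equal(ct$proportion, 1)
})

test_that("rounding is half-away-from-zero at the requested resolution", {
  expect_equal(round_half_away(0.0004, 3), 0)
  expect_equal(round_half_away(0.4567, 2), 0.46)
  expect_equal(round_half_away(0.455, 2), 0.46) # half rounds away, not to even
  expect_equal(round_half_away(-0.455, 2), -0.46)
  tab <- tibble::tibble(sample = "s", clade = c("a", "b"),
                        proportion = c(0.0004, 0.4567))
  out <- round_normalize(tab, 3)
  expect_equal(out$proportion, c(0, 0.457))
  expect_equal(attr(out, "resolution"), 1e-3)
  expect_error(round_normalize(tab, 0), "integer >= 1")
})

test_that("rounded proportion columns sum to 1 within the rounding budget", {
  sim <- sim_hit_table(n_reads = 400, samples = c("s1", "s2"), seed = 17)
  asn <- assign_reads(sim$hits, sim$taxonomy)
  for (decimals in c(2, 3)) {
    ct <- round_normalize(clade_table(asn, rank = "family"), decimals)
    sums <- tapply(ct$proportion, ct$sample, sum)
    n_clades <- length(unique(ct$clade))
    expect_true(all(abs(sums - 1) <= n_clades * 0.5 * 10^-decimals))
  }
})

test_that("Bray-Curtis distances behave on hand-computed cases", {
  m <- matrix(c(4, 0, 0, 4, 4, 0), nrow = 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  tab <- long_table(m)
  cm <- community_matrix(tab)
  d <- as.matrix(vegan::vegdist(sqrt(cm), method = "bray"))
  expect_equal(d["s1", "s2"], 1) # no shared taxa
  expect_equal(d["s1", "s3"], 0) # duplicates
  # BC({1,1},{1,0}) = 1 - 2*min-sum/total = 1/3, untransformed
  m2 <- rbind(a = c(1, 1), b = c(1, 0))
  d2 <- as.matrix(vegan::vegdist(m2, method = "bray"))
  expect_equal(d2["a", "b"], 1 / 3)
})

test_that("NMDS embeds samples reproducibly with recorded stress and seed", {
  withr::with_seed(3, {
    m <- matrix(rpois(8 * 12, 5), nrow = 12,
                dimnames = list(paste0("cl", 1:12), paste0("s", 1:8)))
  })
  tab <- long_table(m / rep(colSums(m), each = 12))
  ord1 <- sqrt_bray_nmds(tab, seed = 7)
  ord2 <- sqrt_bray_nmds(tab, seed = 7)
  expect_equal(tidy(ord1), tidy(ord2))
  expect_gte(glance(ord1)$stress, 0)
  expect_equal(nrow(tidy(ord1)), 8)
  expect_error(sqrt_bray_nmds(tab[tab$sample %in% c("s1", "s2"), ]),
               "at least 3")
})

test_that("richness counts clades strictly above the presence threshold", {
  tab <- tibble::tibble(sample = "s1", clade = letters[1:4],
                        proportion = c(0.60, 0.30, 0.05, 0.009))
  expect_equal(family_richness(tab)$richness, 3)
  zero <- tibble::tibble(sample = "z", clade = letters[1:3], proportion = 0)
  expect_equal(family_richness(zero)$richness, 0)
  # exactly at threshold is absent (strict >)
  at <- tibble::tibble(sample = "s", clade = "a", proportion = 0.01)
  expect_equal(family_richness(at)$richness, 0)
})

test_that("planted richness difference is detected by the Welch comparison", {
  n_a <- 12; n_b <- 17
  build_group <- function(n_samples, n_above, prefix) {
    purrr::map_dfr(seq_len(n_samples), function(i) {
      k <- n_above + (i %% 3) - 1 # mild sample-to-sample variation
      above <- withr::with_seed(5000 + 31 * i + nchar(prefix),
                                runif(k, 0.02, 0.06))
      props <- c(above, rep(0.001, 30 - k))
      tibble::tibble(sample = paste0(prefix, i), clade = paste0("f", 1:30),
                     proportion = props / sum(props) * 0.9)
    })
  }
  tab <- dplyr::bind_rows(build_group(n_a, 20, "plastic"),
                          build_group(n_b, 8, "plankton"))
  rich <- family_richness(tab)
  rich$group <- ifelse(grepl("^plastic", rich$sample), "plastic", "plankton")
  res <- welch_test(rich, richness, group)
  expect_lt(res$p.value, 0.001)
})

test_that("per-clade group test flags separated clades and spares null ones", {
  n_a <- 12; n_b <- 17
  samples <- c(paste0("a", 1:n_a), paste0("b", 1:n_b))
  groups <- setNames(rep(c("plastic", "plankton"), c(n_a, n_b)), samples)
  sep <- withr::with_seed(11, round(runif(n_a, 0.10, 0.30), 2))
  m <- rbind(
    separated = c(sep, rep(0, n_b)),
    constant = rep(0.5, n_a + n_b),
    nullish = round(rep(0.2, n_a + n_b) + rep(c(0.01, -0.01), length.out = n_a + n_b), 2)
  )
  colnames(m) <- samples
  res <- clade_group_test(long_table(m), groups, fdr = 0.005)
  expect_equal(res$enriched[res$clade == "separated"], "plastic")
  expect_true(is.na(res$enriched[res$clade == "constant"]))
  expect_equal(res$p.value[res$clade == "constant"], 1)
  expect_true(is.na(res$enriched[res$clade == "nullish"]))
})

test_that("full-null clade tables are almost never flagged at FDR 0.005", {
  n_flagged <- withr::with_seed(21, {
    vapply(1:20, function(i) {
      m <- matrix(round(runif(50 * 12, 0, 0.2), 2), nrow = 50,
                  dimnames = list(paste0("c", 1:50), paste0("s", 1:12)))
      g <- setNames(rep(c("x", "y"), each = 6), colnames(m))
      sum(!is.na(clade_group_test(long_table(m), g)$enriched))
    }, numeric(1))
  })
  expect_lte(mean(n_flagged) / 50, 0.005)
})

test_that("mean top-hit identity averages within sample and clade", {
  a <- toy_assignments()
  a$top_pident <- c(90, 100, rep(95, 4), rep(97, 4), 80, 70)
  mi <- mean_top_identity(a, rank = "family")
  expect_equal(mi$mean_identity[mi$clade == "Rhodobacteraceae"], 95)
  expect_equal(mi$mean_identity[mi$clade == "Flavobacteriaceae"], 97)
  expect_equal(sort(mi$n_reads), c(4L, 6L))
  # constant identities survive any partition
  a2 <- toy_assignments()
  mi2 <- mean_top_identity(a2, rank = "class")
  expect_true(all(mi2$mean_identity == 95))
})
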