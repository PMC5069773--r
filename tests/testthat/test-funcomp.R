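phit <- function(read, subject, bit, len = 60, domain = "Bacteria") {
  tibble::tibble(read_id = read, subject_id = subject, align_length = len,
                 bit_score = bit, subject_domain = domain)
}

test_that("bacterial filter demands all best-scoring qualifying hits bacterial", {
  hits <- dplyr::bind_rows(
    phit("r1", "b1", bit = 300),                       # clean bacterial
    phit("r2", "b2", bit = 300),                       # tie: one bacterial...
    phit("r2", "e1", bit = 300, domain = "Eukaryota"), # ...one eukaryotic
    phit("r3", "b3", bit = 300, len = 49),             # too short to qualify
    phit("r4", "b4", bit = 300),                       # best is bacterial,
    phit("r4", "e2", bit = 200, domain = "Eukaryota")  # weaker hit ignored
  )
  expect_setequal(bacterial_read_filter(hits), c("r1", "r4"))
  # domain map variant
  hits2 <- dplyr::select(hits, -subject_domain)
  dm <- tibble::tibble(subject_id = c("b1", "b2", "b3", "b4", "e1", "e2"),
                       domain = c(rep("Bacteria", 4), rep("Eukaryota", 2)))
  expect_setequal(bacterial_read_filter(hits2, domain_map = dm), c("r1", "r4"))
})

test_that("KO assignment follows the single top hit", {
  komap <- tibble::tibble(subject_id = c("s1", "s2", "s3", "s4"),
                          ko = c("K02014", "K00001", NA, "K00002"))
  # single annotated top hit
  a <- ko_assign(phit("r1", "s1", bit = 500), komap)
  expect_equal(a$ko, "K02014")
  # unannotated top hit wins over annotated runner-up -> read unassigned
  b <- ko_assign(dplyr::bind_rows(phit("r2", "s3", bit = 500),
                                  phit("r2", "s1", bit = 400)), komap)
  expect_equal(nrow(b), 0)
  # equal-score duplicates with the same KO: no warning
  expect_no_warning(
    cc <- ko_assign(dplyr::bind_rows(phit("r3", "s1", bit = 500),
                                     phit("r3", "s1", bit = 500)), komap))
  expect_equal(cc$ko, "K02014")
  # conflicting tie breaks to the lowest KO id, with a warning
  expect_warning(
    d <- ko_assign(dplyr::bind_rows(phit("r4", "s1", bit = 500),
                                    phit("r4", "s2", bit = 500)), komap),
    "conflicting")
  expect_equal(d$ko, "K00001")
})

test_that("KO proportions divide by per-sample totals and round", {
  tab <- tibble::tibble(
    ko = rep(c("K1", "K2"), 2),
    sample = rep(c("s1", "s2"), each = 2),
    count = c(216, 216000 - 216, 5, 995)
  )
  pr <- ko_proportions(tab, decimals = 5)
  expect_equal(pr$proportion[pr$ko == "K1" & pr$sample == "s1"], 0.001)
  # all counts in one KO -> exactly 1
  one <- ko_proportions(tibble::tibble(ko = "K1", sample = "s", count = 7))
  expect_equal(one$proportion, 1)
  # below half-resolution of the total -> 0
  tiny <- ko_proportions(tibble::tibble(ko = c("K1", "K2"), sample = "s",
                                        count = c(1, 1e6)), decimals = 5)
  expect_equal(tiny$proportion[tiny$ko == "K1"], 0)
  expect_error(ko_proportions(tibble::tibble(ko = "K1", sample = "s",
                                             count = 0)), "zero")
  # per-sample sums stay within the rounding budget
  sim <- sim_ko_table(n_kos = 300, seed = 4)
  pr2 <- ko_proportions(sim$counts)
  sums <- tapply(pr2$proportion, pr2$sample, sum)
  expect_true(all(abs(sums - 1) <= 300 * 0.5e-5))
})

test_that("separated KOs are flagged with the right direction", {
  n_a <- 12; n_b <- 17
  samples <- c(paste0("p", 1:n_a), paste0("w", 1:n_b))
  groups <- tibble::tibble(sample = samples,
                           group = rep(c("plastic", "picoplankton"),
                                       c(n_a, n_b)))
  sepvals <- withr::with_seed(2, round(runif(n_a, 0.10, 0.30), 5))
  m <- rbind(
    K00010 = c(sepvals, rep(0.01, n_b)),        # 16-fold-ish, separated
    K00020 = rep(0.05, n_a + n_b),              # identical
    K00030 = c(rep(0.001, n_a), sepvals[seq_len(n_b) %% n_a + 1]) # down
  )
  colnames(m) <- samples
  tab <- long_table(m, taxon = "ko")
  res <- ko_diff_test(tab, groups)
  expect_equal(res$enriched[res$ko == "K00010"], "plastic")
  expect_equal(res$enriched[res$ko == "K00030"], "picoplankton")
  expect_true(is.na(res$enriched[res$ko == "K00020"]))
  expect_true(all(res$p.adjusted >= res$p.value))
  # antisymmetry: making the other group the reference flips fold changes
  # but leaves the enrichment calls untouched
  res_rev <- ko_diff_test(tab, groups[rev(seq_len(nrow(groups))), ])
  expect_equal(res_rev$log2fc, -res$log2fc)
  expect_equal(res_rev$enriched, res$enriched)
  expect_equal(res_rev$p.value, res$p.value)
})

test_that("planted KO effects are recovered with controlled error", {
  sim <- sim_ko_table(seed = 12)
  res <- ko_diff_test(ko_proportions(sim$counts), sim$groups)
  joined <- dplyr::inner_join(res, sim$truth, by = "ko")
  sens <- mean(!is.na(joined$enriched[joined$planted]))
  flagged <- sum(!is.na(joined$enriched))
  fdp <- sum(!is.na(joined$enriched) & !joined$planted) / max(flagged, 1)
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.01)
  # flagged direction matches the planted direction
  hitdir <- joined[joined$planted & !is.na(joined$enriched), ]
  expect_equal(hitdir$enriched, hitdir$direction)
})

test_that("sensitivity grows with planted effect size and with depth", {
  sens_at <- function(lfc, lib_scale = 1) {
    sim <- sim_ko_table(n_kos = 500, planted_log2fc = lfc,
                        library_sizes = round(lib_scale *
                                                rep(250e3, 29)), seed = 33)
    res <- ko_diff_test(ko_proportions(sim$counts), sim$groups)
    j <- dplyr::inner_join(res, sim$truth, by = "ko")
    mean(!is.na(j$enriched[j$planted]))
  }
  by_effect <- c(sens_at(1), sens_at(3), sens_at(5))
  expect_true(all(diff(by_effect) >= 0))
  expect_lt(by_effect[1], by_effect[3])
  by_depth <- c(sens_at(3, 0.002), sens_at(3, 0.05), sens_at(3, 1))
  expect_true(all(diff(by_depth) >= 0))
})

test_that("enrichment summary turns counts into display percentages", {
  fake <- tibble::tibble(
    ko = sprintf("K%05d", 1:5912),
    enriched = c(rep("plastic", 1064), rep("picoplankton", 129),
                 rep(NA, 5912 - 1064 - 129))
  )
  attr(fake, "groups") <- c("plastic", "picoplankton")
  s <- enrichment_summary(fake)
  expect_equal(s$n_tested, 5912)
  expect_equal(s$pct_up, 18)
  expect_equal(s$pct_down, 2)
  none <- enrichment_summary(tibble::tibble(ko = "K1", enriched = NA_character_))
  expect_equal(none$pct_up, 0)
  expect_equal(none$pct_down, 0)
})

test_that("KO tables and group maps round-trip through TSV", {
  sim <- sim_ko_table(n_kos = 25, seed = 9)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "ko.tsv"); p2 <- file.path(dir, "groups.tsv")
  write_ko_table(sim$counts, p1)
  readr::write_tsv(sim$groups, p2, col_names = FALSE)
  back <- dplyr::arrange(read_ko_table(p1), ko, sample)
  orig <- dplyr::arrange(sim$counts, ko, sample)
  expect_equal(back$count, orig$count)
  expect_equal(read_group_map(p2), sim$groups)
})
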