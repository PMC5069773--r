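test_that("hit retention applies floors and the 1% bit-score window", {
  hits <- dplyr::bind_rows(
    hit("r1", "G1", bit = 500),
    hit("r1", "G2", bit = 496),
    hit("r1", "F2", bit = 495),
    hit("r1", "EU", bit = 494)
  )
  kept <- retain_hits(hits)
  expect_setequal(kept$subject_id, c("G1", "G2", "F2")) # >= 0.99 * 500
  # length floor beats any score
  long_score <- dplyr::bind_rows(hit("r2", "G1", bit = 600, len = 99),
                                 hit("r2", "G2", bit = 100, len = 150))
  expect_equal(retain_hits(long_score)$subject_id, "G2")
  # single qualifying hit is its own best
  expect_equal(nrow(retain_hits(hit("r3", "G1", bit = 51))), 1)
  # below floors -> empty result, not an error
  expect_equal(nrow(retain_hits(hit("r4", "G1", bit = 40))), 0)
})

test_that("hit retention is order-invariant and idempotent", {
  withr::with_seed(42, {
    hits <- dplyr::bind_rows(lapply(1:30, function(i) {
      hit(paste0("r", sample(5, 1)), sample(c("G1", "G2", "F2", "EU"), 1),
          bit = runif(1, 40, 600), len = sample(80:300, 1))
    }))
  })
  ordered <- dplyr::arrange(retain_hits(hits), read_id, subject_id, bit_score)
  shuffled <- dplyr::arrange(retain_hits(hits[sample(nrow(hits)), ]),
                             read_id, subject_id, bit_score)
  expect_equal(ordered, shuffled)
  twice <- dplyr::arrange(retain_hits(retain_hits(hits)),
                          read_id, subject_id, bit_score)
  expect_equal(ordered, twice)
  # a maximal-score qualifying hit survives for every read
  best <- dplyr::summarise(dplyr::group_by(retain_hits(hits), read_id),
                           has_best = any(bit_score == max(bit_score)))
  expect_true(all(best$has_best))
})

test_that("LCA truncates at the deepest shared rank", {
  tax <- toy_taxonomy()
  # same family, different genera -> family, no genus
  two <- dplyr::bind_rows(hit("r1", "G1", bit = 500),
                          hit("r1", "G2", bit = 498))
  a <- lca_assign(two, tax)
  expect_equal(a$lineage,
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae")
  expect_equal(a$rank, "family")
  expect_equal(a$depth, 5L)
  # single hit keeps the full lineage
  one <- lca_assign(hit("r2", "F2", bit = 300, pident = 97.2), tax)
  expect_equal(one$depth, 6L)
  expect_equal(one$rank, "genus")
  expect_equal(one$top_pident, 97.2)
  # cross-domain hits share nothing -> unclassified root
  cross <- dplyr::bind_rows(hit("r3", "G1", bit = 400),
                            hit("r3", "EU", bit = 399))
  root <- lca_assign(cross, tax)
  expect_true(is.na(root$lineage))
  expect_equal(root$rank, "root")
  expect_equal(root$depth, 0L)
})

test_that("LCA is invariant to hit order and duplication, never deeper than shallowest", {
  tax <- toy_taxonomy()
  hits <- dplyr::bind_rows(hit("r1", "G1", bit = 500),
                           hit("r1", "G2", bit = 499))
  a1 <- lca_assign(hits, tax)
  a2 <- lca_assign(hits[2:1, ], tax)
  a3 <- lca_assign(dplyr::bind_rows(hits, hits), tax)
  expect_equal(a1$lineage, a2$lineage)
  expect_equal(a1$lineage, a3$lineage)
  expect_equal(a3$n_hits, 4L)
  # depth never exceeds the shallowest retained lineage
  shallow <- taxonomy(c(S1 = "Bacteria;Proteobacteria", S2 = paste(
    "Bacteria", "Proteobacteria", "Alphaproteobacteria", sep = ";")))
  mix <- dplyr::bind_rows(hit("r2", "S1", bit = 100), hit("r2", "S2", bit = 100))
  expect_equal(lca_assign(mix, shallow)$depth, 2L)
})

test_that("missing subjects fail or are skipped as configured", {
  tax <- toy_taxonomy()
  hits <- dplyr::bind_rows(hit("r1", "G1", bit = 500),
                           hit("r1", "NOPE", bit = 499))
  expect_error(lca_assign(hits, tax), "missing from taxonomy")
  skipped <- lca_assign(hits, tax, on_missing = "skip")
  expect_equal(skipped$depth, 6L)
})

test_that("blacklist and masked intervals remove the right hits", {
  tax <- toy_taxonomy(blacklist = "G2",
                      masks = tibble::tibble(accession = "G1",
                                             start = 100, end = 200))
  hits <- dplyr::bind_rows(
    hit("r1", "G2", bit = 500, sstart = 1, send = 120),    # blacklisted
    hit("r2", "G1", bit = 500, sstart = 10, send = 120),   # overlaps mask
    hit("r3", "G1", bit = 500, sstart = 210, send = 300),  # clear of mask
    hit("r4", "G1", bit = 500, sstart = 120, send = 10),   # reversed coords
    hit("r5", "F2", bit = 500, sstart = 100, send = 200)   # other subject
  )
  kept <- blacklist_filter(hits, tax)
  expect_setequal(kept$read_id, c("r3", "r5"))
  # empty blacklist and no masks: identity
  expect_equal(blacklist_filter(hits, toy_taxonomy()), hits)
})

test_that("pipeline assignments equal generated truth on ambiguous reads", {
  sim <- sim_hit_table(n_reads = 250, samples = c("p1", "p2"),
                       p_confounder = 0.4, p_decoy = 0.3, seed = 31)
  asn <- assign_reads(sim$hits, sim$taxonomy)
  expect_equal(nrow(asn), nrow(sim$truth)) # every read assigned
  cmp <- dplyr::inner_join(asn, sim$truth, by = c("sample", "read_id"),
                           suffix = c("", ".truth"))
  expect_equal(cmp$lineage, cmp$lineage.truth)
  expect_equal(cmp$depth, cmp$depth.truth)
})

test_that("hit tables round-trip losslessly through outfmt-6 files", {
  sim <- sim_hit_table(n_reads = 40, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(sim$hits, path)
  back <- read_hit_table(path, sample = "plastic_1")
  cols <- c("read_id", "subject_id", "pident", "align_length", "bit_score")
  expect_equal(back[cols], sim$hits[cols])
  # headered subset tables also load
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim$hits[cols], path2)
  expect_equal(read_hit_table(path2)[cols], sim$hits[cols])
})

test_that("taxonomy files round-trip with blacklist and masks", {
  dir <- withr::local_tempdir()
  lin <- file.path(dir, "tax.tsv")
  writeLines(c("A1\tBacteria;Proteobacteria", "A2\tEukaryota;Bryozoa"), lin)
  bl <- file.path(dir, "bl.txt"); writeLines("A2", bl)
  mk <- file.path(dir, "mask.tsv"); writeLines("A1\t1\t50", mk)
  tax <- read_taxonomy(lin, blacklist_path = bl, mask_path = mk)
  expect_equal(nrow(tax$lineages), 2)
  expect_equal(tax$blacklist, "A2")
  expect_equal(tax$masks$end, 50)
  expect_error(taxonomy(c(A1 = "Bacteria", A1 = "Bacteria")), "duplicated")
  expect_error(taxonomy(c(A1 = "")), "non-empty")
})
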