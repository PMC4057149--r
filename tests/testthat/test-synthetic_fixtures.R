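test_that("miRNA panels are reproducible with pairwise-distinct seeds", {
  p1 <- make_mirna_panel(10, rng_seed = 1)
  p2 <- make_mirna_panel(10, rng_seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_mirna_panel(10, rng_seed = 2)))
  seeds <- substr(p1$sequence, 2, 7)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(nchar(p1$sequence) == 22L))

  expect_error(make_mirna_panel(0), ">= 1")
  expect_error(make_mirna_panel(5000), "4\\^6")
})

test_that("planted transcripts carry exactly their truth sites", {
  panel <- make_mirna_panel(5, rng_seed = 17)
  pl <- data.frame(
    mirna_id = panel$id[c(1, 2, 3, 4, 5)],
    site_class = c("8mer", "7mer-m8", "7mer-A1", "6mer",
                   "mismatch-compensatory"),
    position = c(20, 65, 110, 155, 215), stringsAsFactors = FALSE)
  fx <- make_transcript_with_planted_sites(plant_spec(280, pl, rng_seed = 31),
                                           panel)
  sites <- predict_all(fx$record, panel, mismatch_mode = "all")
  expect_equal(nrow(sites), 5L)
  expect_equal(sites$t_start, sort(fx$truth$t_start))
  got <- sites[order(sites$t_start), ]
  want <- fx$truth[order(fx$truth$t_start), ]
  expect_equal(got$site_class, want$site_class)
  expect_equal(got$t_end, want$t_end)
  expect_equal(got$mirna_id, want$mirna_id)
})

test_that("plant specifications are validated", {
  panel <- make_mirna_panel(2, rng_seed = 5)
  overlapping <- data.frame(mirna_id = panel$id,
                            site_class = c("8mer", "8mer"),
                            position = c(50, 53))
  expect_error(make_transcript_with_planted_sites(
    plant_spec(200, overlapping, rng_seed = 1), panel), "overlap")

  outside <- data.frame(mirna_id = panel$id[1], site_class = "8mer",
                        position = 199)
  expect_error(make_transcript_with_planted_sites(
    plant_spec(200, outside, rng_seed = 1), panel), "fit")

  early_mm <- data.frame(mirna_id = panel$id[1],
                         site_class = "mismatch-compensatory", position = 5)
  expect_error(make_transcript_with_planted_sites(
    plant_spec(200, early_mm, rng_seed = 1), panel), "position >= 12")
})

test_that("fixture generation is deterministic under its seed", {
  panel <- make_mirna_panel(3, rng_seed = 2)
  pl <- data.frame(mirna_id = panel$id[1], site_class = "8mer", position = 30)
  a <- make_transcript_with_planted_sites(plant_spec(150, pl, rng_seed = 9),
                                          panel)
  b <- make_transcript_with_planted_sites(plant_spec(150, pl, rng_seed = 9),
                                          panel)
  expect_identical(a, b)
})

test_that("universe records designated-pair statistics consistently", {
  u <- make_cerna_universe(universe_spec(n_mirnas = 50, n_lncrnas = 10,
                                         n_mrnas = 10, n_designated = 10,
                                         p_target = 0.3, p_both = 0.15,
                                         rng_seed = 41))
  d <- u$designated_pairs
  expect_equal(nrow(d), 10L)
  expect_true(all(d$m_c <= pmin(d$m_p, d$m_n)))
  expect_true(all(d$shared_MREs <= d$total_MREs_lnc))
  expect_equal(d$ceRNA_score, d$shared_MREs / d$total_MREs_lnc)
  # membership sets agree with the recorded margins
  for (i in 1:10) {
    expect_length(u$lnc_sets[[d$lnc_id[i]]], d$m_n[i])
    expect_length(u$mrna_sets[[d$mrna_id[i]]], d$m_p[i])
    expect_length(intersect(u$lnc_sets[[d$lnc_id[i]]],
                            u$mrna_sets[[d$mrna_id[i]]]), d$m_c[i])
  }
})

test_that("a sequence-backed universe survives the full pipeline exactly", {
  u <- make_cerna_universe(universe_spec(n_mirnas = 12, n_lncrnas = 3,
                                         n_mrnas = 3, p_target = 0.4,
                                         sequences = TRUE, rng_seed = 5))
  sites <- predict_all(u$transcripts, u$mirnas, mismatch_mode = "none")
  # every planted site is recovered at its exact coordinates
  key <- function(df, s, e) paste(df$transcript_id, df$mirna_id, df[[s]],
                                  df[[e]], df$site_class)
  expect_setequal(key(sites, "t_start", "t_end"),
                  key(u$site_truth, "t_start", "t_end"))

  lnc_idx <- aggregate_mres(sites[sites$biotype == "lncRNA", ])
  mrna_idx <- aggregate_mres(sites[sites$biotype == "protein_coding", ])
  pairs <- build_pairs(lnc_idx, mrna_idx, cerna_params(M_T = u$M_T),
                       pairs = u$designated_pairs[, c("lnc_id", "mrna_id")])
  mg <- merge(pairs, u$designated_pairs, by = c("lnc_id", "mrna_id"))
  expect_equal(nrow(pairs), sum(u$designated_pairs$m_c >= 1))
  expect_equal(mg$n_shared_miRNAs, mg$m_c)
  expect_equal(mg$shared_MREs.x, mg$shared_MREs.y)
  expect_equal(mg$total_MREs_lnc.x, mg$total_MREs_lnc.y)
  expect_equal(mg$ceRNA_score.x, mg$ceRNA_score.y, tolerance = 1e-12)
  expect_equal(mg$p_value.x, mg$p_value.y, tolerance = 1e-12)
})

test_that("universe generation is deterministic and writes a full bundle", {
  spec <- universe_spec(n_mirnas = 12, n_lncrnas = 2, n_mrnas = 2,
                        p_target = 0.4, sequences = TRUE, rng_seed = 77)
  u1 <- make_cerna_universe(spec)
  u2 <- make_cerna_universe(spec)
  expect_identical(u1$transcripts, u2$transcripts)
  expect_identical(u1$gene_expr, u2$gene_expr)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_universe_bundle(u1, d1)
  write_universe_bundle(u2, d2)
  files <- list.files(d1)
  expect_true(all(c("mirnas.fa", "lncrna.fa", "mrna.fa", "sites_truth.tsv",
                    "gene_expression.tsv", "mirna_expression.tsv",
                    "expected_pairs.tsv", "conserved_regions.tsv",
                    "ago_regions.tsv", "manifest.txt") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})
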