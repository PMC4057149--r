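test_that("MRE aggregation sums per-miRNA counts and deduplicates", {
  st <- data.frame(transcript_id = "t1",
                   mirna_id = c("miR-a", "miR-a", "miR-b", "miR-b", "miR-b"),
                   t_start = c(10L, 50L, 90L, 130L, 170L),
                   t_end = c(17L, 57L, 97L, 137L, 177L),
                   site_class = "7mer-m8", stringsAsFactors = FALSE)
  idx <- aggregate_mres(st)
  expect_equal(unname(idx$totals["t1"]), 5L)
  expect_equal(idx$mirna_sets[["t1"]], c("miR-a", "miR-b"))
  expect_equal(idx$counts$n[idx$counts$mirna_id == "miR-b"], 3L)

  # exact duplicate rows count once
  idx2 <- aggregate_mres(rbind(st, st[1, ]))
  expect_equal(unname(idx2$totals["t1"]), 5L)

  empty <- aggregate_mres(st[0, ])
  expect_length(empty$mirna_sets, 0L)
})

test_that("ceRNA score is the shared/total MRE ratio with its bounds", {
  expect_equal(cerna_score(3, 10), 0.3)
  expect_equal(cerna_score(10, 10), 1)
  expect_error(cerna_score(1, 0), "total_mre_lnc > 0")
})

test_that("hypergeometric p-value matches the spot enumeration", {
  # 66/252 by exhaustive enumeration of all C(10,5) draws
  expect_equal(oracle_hyper(10, 4, 5, 3), 66 / 252)
  expect_equal(hypergeom_pvalue(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  # m_c = 0 covers the whole support
  expect_identical(hypergeom_pvalue(10, 4, 5, 0), 1)
  # degenerate margin: every draw overlaps fully when m_p = M_T
  expect_equal(hypergeom_pvalue(8, 8, 3, 3), 1, tolerance = 1e-12)
  # invalid arguments
  expect_error(hypergeom_pvalue(10, 4, 5, 6), "m_c")
  expect_error(hypergeom_pvalue(10, 12, 5, 2), "M_T")
})

test_that("p-value is non-increasing in the shared count at fixed margins", {
  set.seed(7)
  for (i in 1:50) {
    M_T <- sample(5:60, 1)
    m_p <- sample.int(M_T, 1)
    m_n <- sample.int(M_T, 1)
    p <- hypergeom_pvalue(M_T, m_p, m_n, 0:min(m_p, m_n))
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("pairs carry the shared-set statistics and sort order", {
  lnc_idx <- aggregate_mres(data.frame(
    transcript_id = "lnc1", mirna_id = c("a", "b", "c"),
    t_start = c(0L, 10L, 20L), t_end = c(7L, 17L, 27L),
    site_class = "7mer-m8", stringsAsFactors = FALSE))
  mrna_idx <- aggregate_mres(data.frame(
    transcript_id = "m1", mirna_id = c("b", "c", "d"),
    t_start = c(0L, 10L, 20L), t_end = c(7L, 17L, 27L),
    site_class = "7mer-m8", stringsAsFactors = FALSE))
  pairs <- build_pairs(lnc_idx, mrna_idx, cerna_params(M_T = 10))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$n_shared_miRNAs, 2L)
  expect_equal(pairs$shared_miRNA_list, "b,c")
  expect_equal(pairs$shared_MREs, 2L)
  expect_equal(pairs$total_MREs_lnc, 3L)
  expect_equal(pairs$ceRNA_score, 2 / 3)
  expect_equal(pairs$p_value, hypergeom_pvalue(10, 3, 3, 2))

  # disjoint sets form no pair
  mrna_idx2 <- aggregate_mres(data.frame(
    transcript_id = "m2", mirna_id = c("x", "y"),
    t_start = c(0L, 10L), t_end = c(7L, 17L),
    site_class = "7mer-m8", stringsAsFactors = FALSE))
  expect_equal(nrow(build_pairs(lnc_idx, mrna_idx2, cerna_params(M_T = 10))),
               0L)

  # M_T below an observed margin is an error
  expect_error(build_pairs(lnc_idx, mrna_idx, cerna_params(M_T = 2)),
               "margin")
})

test_that("pair tables sort by shared count, then p-value, then ids", {
  u <- make_cerna_universe(universe_spec(n_mirnas = 40, n_lncrnas = 8,
                                         n_mrnas = 8, n_designated = 0,
                                         p_target = 0.35, rng_seed = 19))
  pairs <- build_pairs(u$lnc_index, u$mrna_index, cerna_params(M_T = 40))
  expect_gt(nrow(pairs), 2L)
  expect_true(all(diff(pairs$n_shared_miRNAs) <= 0))
  ties <- split(seq_len(nrow(pairs)), pairs$n_shared_miRNAs)
  for (idx in ties) {
    expect_true(all(diff(pairs$p_value[idx]) >= 0))
  }
})

test_that("swapping the candidate changes the score but not m_c or p", {
  u <- make_cerna_universe(universe_spec(n_mirnas = 30, n_lncrnas = 5,
                                         n_mrnas = 5, n_designated = 0,
                                         p_target = 0.4, rng_seed = 23))
  fwd <- build_pairs(u$lnc_index, u$mrna_index, cerna_params(M_T = 30))
  rev <- build_pairs(u$mrna_index, u$lnc_index, cerna_params(M_T = 30))
  expect_gt(nrow(fwd), 0L)
  key_f <- paste(fwd$lnc_id, fwd$mrna_id)
  key_r <- paste(rev$mrna_id, rev$lnc_id)
  common <- intersect(key_f, key_r)
  expect_equal(sort(key_f), sort(key_r))
  for (k in common) {
    i <- match(k, key_f); j <- match(k, key_r)
    expect_equal(fwd$n_shared_miRNAs[i], rev$n_shared_miRNAs[j])
    expect_equal(fwd$p_value[i], rev$p_value[j], tolerance = 1e-12)
  }
})

test_that("BH q-values follow the hand-computed step-up", {
  single <- data.frame(p_value = 0.05)
  expect_equal(adjust_fdr(single)$q_value, 0.05)

  three <- data.frame(p_value = c(0.01, 0.02, 0.03))
  # step-up by hand: q_(3) = 0.03, q_(2) = min(0.03, 0.02*3/2) = 0.03,
  # q_(1) = min(0.03, 0.01*3) = 0.03
  expect_equal(adjust_fdr(three)$q_value, c(0.03, 0.03, 0.03))

  ones <- data.frame(p_value = rep(1, 4))
  expect_equal(adjust_fdr(ones)$q_value, rep(1, 4))
})

test_that("conserved-only filtering recomputes numerator and denominator", {
  st <- data.frame(transcript_id = "lnc1",
                   mirna_id = c("a", "a", "b"),
                   t_start = c(0L, 10L, 20L), t_end = c(7L, 17L, 27L),
                   site_class = "7mer-m8",
                   conserved = c(TRUE, FALSE, TRUE),
                   ago_supported = c(NA, NA, TRUE),
                   stringsAsFactors = FALSE)
  full <- aggregate_mres(st)
  expect_equal(unname(full$totals["lnc1"]), 3L)
  cons <- aggregate_mres(filter_sites(st, conserved_only = TRUE))
  expect_equal(unname(cons$totals["lnc1"]), 2L)
  ago <- aggregate_mres(filter_sites(st, ago_only = TRUE))
  expect_equal(ago$mirna_sets[["lnc1"]], "b")
})
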