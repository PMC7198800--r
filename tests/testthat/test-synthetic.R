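test_that("elemental-N dosing divides by nitrogen atoms per molecule", {
  expect_equal(n_source_concentration(5, 2), 2.5)  # urea, lysine
  expect_equal(n_source_concentration(5, 1), 5)    # ammonium et al.
  expect_equal(n_source_concentration(0, 3), 0)
  expect_error(n_source_concentration(5, 0), "integer >= 1")
  expect_error(n_source_concentration(5, 1.5), "integer >= 1")
  expect_error(n_source_concentration(-1, 1), ">= 0")
})

test_that("universe generation is a pure function of its seed", {
  u1 <- generate_universe(n_metabolites = 25, n_db_reactions = 50,
                          n_strains = 2, n_sources = 6, seed = 5)
  u2 <- generate_universe(n_metabolites = 25, n_db_reactions = 50,
                          n_strains = 2, n_sources = 6, seed = 5)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network_json(u1$db, f1); write_network_json(u2$db, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(u1$truth, u2$truth)
  expect_identical(names(u1$strains$strain1$draft$reactions),
                   names(u2$strains$strain1$draft$reactions))
  u3 <- generate_universe(n_metabolites = 25, n_db_reactions = 50,
                          n_strains = 2, n_sources = 6, seed = 6)
  expect_false(identical(u1$truth, u3$truth))
})

test_that("universe invariants hold: coverage, truth, draft nesting", {
  u <- generate_universe(n_metabolites = 30, n_db_reactions = 60,
                         n_strains = 2, n_sources = 8, seed = 12)
  for (sn in names(u$strains)) {
    s <- u$strains[[sn]]
    expect_true(check_db_coverage(s$true, u$db))
    # draft is a subset of the true network
    expect_true(all(names(s$draft$reactions) %in%
                      names(s$true$reactions)))
    # truth row is reproducible by direct FBA on the true network
    for (cid in colnames(u$truth))
      expect_identical(predicts_growth(s$true, u$media[[cid]]),
                       u$truth[sn, cid])
    # at least one growth-positive and one negative source
    expect_gte(sum(u$truth[sn, ]), 2)
    expect_gte(sum(!u$truth[sn, ]), 1)
    expect_true(u$truth[sn, "ammonium"])
    # drafts still grow on ammonium (deletions were non-essential)
    expect_true(predicts_growth(s$draft, u$media$ammonium))
  }
})

test_that("zero deletion gives drafts identical to true networks", {
  u <- generate_universe(n_metabolites = 25, n_db_reactions = 50,
                         n_strains = 1, n_sources = 5,
                         deletion_fraction = 0, seed = 9)
  expect_identical(names(u$strains$strain1$draft$reactions),
                   names(u$strains$strain1$true$reactions))
  gf <- gapfill_positive(u$strains$strain1$draft, u$db,
                         u$media$ammonium)
  expect_identical(gf$added, character(0))
})

test_that("noiseless plates reproduce the truth row exactly", {
  u <- generate_universe(n_metabolites = 25, n_db_reactions = 50,
                         n_strains = 1, n_sources = 10, seed = 31)
  run <- simulate_plate(u$truth[1, ], strain = "strain1",
                        noise_sd = 0, seed = 2,
                        high_background_substrate = NULL)
  sc <- score_plate_run(run)
  expect_identical(stats::setNames(sc$growth_matrix$call,
                                   sc$growth_matrix$substrate)[
                                     colnames(u$truth)],
                   u$truth[1, ])
})

test_that("plate simulation is seeded and carries the planted features", {
  truth_row <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
                               paste0("s", 1:6))
  r1 <- simulate_plate(truth_row, seed = 4)
  r2 <- simulate_plate(truth_row, seed = 4)
  expect_identical(r1, r2)
  expect_true("control" %in% r1$substrate_id)       # A1 well present
  expect_identical(attr(r1, "high_background_substrate"), "s6")
  # the high-background well reads far above a normal non-growth well
  hb <- r1$value[r1$substrate_id == "s6" & r1$replicate == 1]
  nb <- r1$value[r1$substrate_id == "s4" & r1$replicate == 1]
  expect_gt(max(hb), 3 * max(nb))
  expect_true(all(abs(diff(r1$time_h[r1$substrate_id == "control" &
                                       r1$replicate == 1]) -
                        1 / 6) < 1e-9))
})

test_that("growth-call recovery stays high at realistic plate noise", {
  hits <- 0; total <- 0
  for (seed in 1:4) {
    truth_row <- withr::with_seed(100 + seed, stats::setNames(
      stats::runif(25) < 0.6, paste0("s", 1:25)))
    run <- simulate_plate(truth_row, noise_sd = 0.01,
                          seed = 200 + seed,
                          high_background_substrate = NULL)
    sc <- score_plate_run(run)
    calls <- stats::setNames(sc$growth_matrix$call,
                             sc$growth_matrix$substrate)
    hits <- hits + sum(calls == truth_row[names(calls)])
    total <- total + length(calls)
  }
  expect_gte(hits / total, 0.95)
})

test_that("proteomics simulation is seeded and respects planted structure", {
  pt <- make_proteome_truth(strains = "s1", n_proteins = 50, n_dep = 5,
                            n_pii_pos = 3, n_pii_neg = 2,
                            n_absence = 2, seed = 3)
  m1 <- simulate_proteomics(pt, seed = 10)$s1
  m2 <- simulate_proteomics(pt, seed = 10)$s1
  expect_equal(m1$lfq, m2$lfq)
  # zero noise, zero effects -> all tested log2FCs are zero
  pt0 <- make_proteome_truth(strains = "s1", n_proteins = 30,
                             n_dep = 0, n_pii_pos = 0, n_pii_neg = 0,
                             n_absence = 0, seed = 3)
  m0 <- simulate_proteomics(pt0, noise_sd_log2 = 0, seed = 1)$s1
  cmp <- differential_abundance(m0, "ammonium", "lysine")
  tested <- cmp$class == "tested" & cmp$protein != pt0$pii_id
  expect_equal(cmp$log2fc[tested], rep(0, sum(tested)))
  # planted absence proteins fall below the detection limit
  ab <- pt$per_strain$s1$absence
  tr <- m1$metadata$treatment
  for (i in seq_len(nrow(ab)))
    expect_true(all(is.na(
      m1$lfq[ab$protein[i], tr == ab$treatment[i]])))
})
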