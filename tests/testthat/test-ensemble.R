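u_small <- generate_universe(n_metabolites = 25, n_db_reactions = 50,
                             n_strains = 1, n_sources = 6, seed = 7)
pos_small <- u_small$media[colnames(u_small$truth)[u_small$truth[1, ]]]
neg_small <- u_small$media[colnames(u_small$truth)[!u_small$truth[1, ]]]

test_that("identical inputs and seed give byte-identical ensembles", {
  args <- list(u_small$strains$strain1$draft, u_small$db, pos_small,
               neg_small, size = 2, n_pos = 3, n_neg = 1, seed = 42)
  e1 <- do.call(build_ensemble, args)
  e2 <- do.call(build_ensemble, args)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_ensemble(e1, d1); write_ensemble(e2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  e3 <- do.call(build_ensemble, utils::modifyList(args,
                                                  list(seed = 43)))
  expect_false(identical(e1$records, e3$records))
})

test_that("ensemble serialization round trips", {
  ens <- build_ensemble(u_small$strains$strain1$draft, u_small$db,
                        pos_small, neg_small, size = 2, n_pos = 3,
                        n_neg = 1, seed = 9)
  d <- withr::local_tempdir()
  write_ensemble(ens, d)
  back <- read_ensemble(d)
  expect_equal(back$size, ens$size)
  expect_identical(lapply(back$records, unclass),
                   lapply(ens$records, unclass))
  expect_identical(names(back$networks[[1]]$reactions),
                   names(ens$networks[[1]]$reactions))
})

test_that("every member satisfies its training conditions", {
  ens <- build_ensemble(u_small$strains$strain1$draft, u_small$db,
                        pos_small, neg_small, size = 3,
                        n_pos = length(pos_small),
                        n_neg = length(neg_small), seed = 11)
  for (i in seq_len(ens$size)) {
    rec <- ens$records[[i]]
    for (cid in rec$positives_used)
      expect_true(predicts_growth(ens$networks[[i]],
                                  u_small$media[[cid]]))
    for (cid in setdiff(rec$negatives_used, rec$unresolved_negatives))
      expect_false(predicts_growth(ens$networks[[i]],
                                   u_small$media[[cid]]))
  }
})

test_that("ensemble prediction follows the weighted-activity formula", {
  ens <- build_ensemble(u_small$strains$strain1$draft, u_small$db,
                        pos_small, neg_small, size = 3, n_pos = 3,
                        n_neg = 1, seed = 13)
  for (cid in names(u_small$media)) {
    pr <- ensemble_predict(ens, u_small$media[[cid]])
    growing <- pr$growth_rates > 1e-3
    expect_equal(pr$fraction_growing, mean(growing))
    expect_equal(pr$activity,
                 mean(ifelse(growing, pr$growth_rates, 0)))
    expect_gte(pr$activity, 0)
    expect_lte(pr$activity, max(pr$growth_rates))
    expect_identical(pr$activity == 0, pr$fraction_growing == 0)
    expect_identical(pr$binary_call, pr$fraction_growing >= 0.5)
  }
})

test_that("ensemble flux weighting follows the occurrence-fraction formula", {
  toyA <- toy_branched()        # uses R2 only at optimum
  # hand-assembled two-member ensemble with identical networks
  ens <- structure(list(networks = list(toyA$net, toyA$net),
                        records = list(gapfill_record(),
                                       gapfill_record()),
                        size = 2L), class = "model_ensemble")
  wf <- ensemble_flux(ens, toyA$medium)
  expect_equal(unname(wf["R2"]), 5)      # active in both members
  expect_equal(unname(wf["R1"]), 0)      # zero flux everywhere
  # member without the reaction counts in the denominator only
  netB <- remove_reactions(toyA$net, "R1")
  ens2 <- structure(list(networks = list(toyA$net, netB),
                         records = list(gapfill_record(),
                                        gapfill_record()),
                         size = 2L), class = "model_ensemble")
  wf2 <- ensemble_flux(ens2, toyA$medium)
  expect_equal(unname(wf2["R2"]), 5)
  expect_equal(unname(wf2["BIO"]), 10)
})

test_that("flux fold changes are floored, thresholded and sorted", {
  a <- c(r1 = 8, r2 = 3, r3 = 1, r4 = 0, r5 = 2)
  b <- c(r1 = 2, r2 = 2, r3 = 1, r4 = 1, r5 = 64)
  fc <- flux_fold_changes(a, b, threshold = 1)
  expect_identical(fc$reaction_id, c("r4", "r5", "r1"))
  expect_equal(fc$log2fc[fc$reaction_id == "r1"], 2)
  expect_equal(fc$log2fc[fc$reaction_id == "r5"], -5)
  expect_equal(fc$log2fc[fc$reaction_id == "r4"], log2(1e-6 / 1))
  # |log2FC| below threshold excluded; identical maps give nothing
  expect_false("r2" %in% fc$reaction_id)
  expect_equal(nrow(flux_fold_changes(a, a)), 0)
  # reversible reactions compare by magnitude
  expect_equal(nrow(flux_fold_changes(c(r = -4), c(r = 4))), 0)
})

test_that("the study-scale ensemble configuration is the default", {
  cfg <- default_config()
  expect_equal(cfg$ensemble$size, 50L)
  expect_equal(cfg$ensemble$n_pos, 26L)
  expect_equal(cfg$ensemble$n_neg, 11L)
  expect_identical(formals(build_ensemble)$size, 50L)
})
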