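make_pm <- function(lfq_log2, treatments, strain = "st1") {
  n_rep <- ncol(lfq_log2) / length(treatments)
  meta <- data.frame(
    sample = colnames(lfq_log2),
    treatment = rep(treatments, each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(treatments)))
  proteomics_matrix(strain, 2^lfq_log2, meta)
}

test_that("differential abundance computes log2FC, Welch p and DEP calls", {
  lg <- rbind(
    same  = rep(8, 8),
    shift = c(8, 8, 8, 8, 4, 4, 4, 4) +
      withr::with_seed(1, stats::rnorm(8, 0, 1e-6)),
    small = c(8.3, 8.1, 8.2, 8.25, 8, 8.1, 7.9, 8.05))
  colnames(lg) <- paste0("s", 1:8)
  pm <- make_pm(lg, c("A", "B"))
  res <- differential_abundance(pm, "A", "B", min_reps = 3)
  expect_equal(res$log2fc[res$protein == "same"], 0)
  expect_equal(res$p[res$protein == "same"], 1)
  expect_false(res$dep[res$protein == "same"])
  expect_equal(res$log2fc[res$protein == "shift"], 4,
               tolerance = 1e-4)
  expect_true(res$dep[res$protein == "shift"])
  expect_false(res$dep[res$protein == "small"])   # |log2FC| < 1
})

test_that("swapping the comparison negates log2FC and keeps p and DEPs", {
  lg <- withr::with_seed(3, matrix(stats::rnorm(80, 10, 1), 10, 8,
                                   dimnames = list(paste0("p", 1:10),
                                                   paste0("s", 1:8))))
  lg[1:3, 1:4] <- lg[1:3, 1:4] + 2.5
  pm <- make_pm(lg, c("A", "B"))
  ab <- differential_abundance(pm, "A", "B")
  ba <- differential_abundance(pm, "B", "A")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
  expect_identical(ab$dep, ba$dep)
})

test_that("detection-count rules route proteins to test or presence class", {
  lg <- matrix(10, 4, 8, dimnames = list(paste0("p", 1:4),
                                         paste0("s", 1:8)))
  lfq <- 2^lg
  lfq[2, 5:8] <- 0          # detected in A only -> presence class
  lfq[3, 1:4] <- 0          # detected in B only
  lfq[4, c(1, 2, 5)] <- 0   # 2 reps in A, 3 in B -> insufficient
  meta <- data.frame(sample = paste0("s", 1:8),
                     treatment = rep(c("A", "B"), each = 4),
                     replicate = rep(1:4, 2))
  pm <- proteomics_matrix("st1", lfq, meta)
  res <- differential_abundance(pm, "A", "B", min_reps = 3)
  expect_identical(res$class,
                   c("tested", "present_a_only", "present_b_only",
                     "insufficient"))
  expect_true(all(is.na(res$p[2:4])))
  expect_error(differential_abundance(pm, "A", "Z"), "absent")
})

test_that("BH adjustment matches the step-up definition", {
  # fixed vector: all four adjust to 0.04
  p_fix <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(oracle_bh(p_fix), rep(0.04, 4))
  lg <- withr::with_seed(9, matrix(stats::rnorm(240, 12, 0.8), 30, 8,
                                   dimnames = list(sprintf("p%02d", 1:30),
                                                   paste0("s", 1:8))))
  lg[1:5, 1:4] <- lg[1:5, 1:4] + 3
  pm <- make_pm(lg, c("A", "B"))
  res <- differential_abundance(pm, "A", "B")
  expect_equal(res$p_adj, oracle_bh(res$p))
  # monotone in raw-p rank and bounded by raw p and 1
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj <= 1 & res$p_adj >= res$p))
})

test_that("Fisher's combined probability matches the closed form", {
  expect_equal(fisher_combined_p(0.2), 0.2, tolerance = 1e-12)
  x <- -2 * 3 * log(0.5)
  expect_equal(x, 4.1589, tolerance = 1e-4)
  expect_equal(fisher_combined_p(rep(0.5, 3)),
               oracle_chisq_upper_even_df(x, 6), tolerance = 1e-12)
  expect_equal(fisher_combined_p(rep(0.5, 3)), 0.65519,
               tolerance = 1e-4)
  p <- c(0.01, 0.2, 0.6, 0.9)
  expect_equal(fisher_combined_p(p),
               oracle_chisq_upper_even_df(-2 * sum(log(p)), 8),
               tolerance = 1e-12)
})

test_that("pairwise comparison enumeration covers C(n,2) pairs", {
  five <- enumerate_comparisons(c("ammonium", "glutamate", "lysine",
                                  "serine", "urea"))
  expect_equal(nrow(five), 10)
  expect_equal(anyDuplicated(paste(five$a, five$b)), 0)
  expect_false(any(five$a == five$b))
  expect_equal(nrow(enumerate_comparisons(c("A", "B"))), 1)
  expect_error(enumerate_comparisons("A"))
})

test_that("KO matching filters, picks representatives and derives views", {
  treatments <- c("ammonium", "urea")
  mk <- function(vals, strain) {
    lg <- matrix(vals, nrow = length(vals) / 6, ncol = 6, byrow = TRUE,
                 dimnames = list(paste0(strain, "_p",
                                        seq_len(length(vals) / 6)),
                                 paste0(strain, "_s", 1:6)))
    make_pm(lg, treatments, strain)
  }
  # strain1: p1/p2 share KO1 (p2 has higher grand mean), p3 is KO2
  m1 <- mk(c(rep(10, 6), rep(12, 6), rep(9, 6)), "a")
  # strain2: q1 = KO1; q2 = KO2 but undetected under urea -> KO2 drops
  lg2 <- matrix(rep(c(11, 8), each = 6), 2, 6, byrow = TRUE,
                dimnames = list(c("b_p1", "b_p2"), paste0("b_s", 1:6)))
  m2raw <- 2^lg2
  m2raw[2, 4:6] <- 0
  m2 <- proteomics_matrix("b", m2raw,
                          data.frame(sample = paste0("b_s", 1:6),
                                     treatment = rep(treatments,
                                                     each = 3),
                                     replicate = rep(1:3, 2)))
  ko_map <- data.frame(protein_id = c("a_p1", "a_p2", "a_p3", "b_p1",
                                      "b_p2"),
                       ko = c("KO1", "KO1", "KO2", "KO1", "KO2"))
  kt <- match_kos(list(a = m1, b = m2), ko_map, min_reps = 3)
  expect_identical(kt$kos, "KO1")     # KO2 fails the all-strain filter
  reps <- kt$representatives
  expect_identical(reps$protein[reps$strain == "a"], "a_p2")
  # z view has mean 0 per (ko, strain); ratio view is log2 vs ammonium
  z1 <- kt$z[kt$z$strain == "a", ]
  expect_equal(mean(z1$z), 0, tolerance = 1e-9)
  expect_equal(kt$ratio$log2_ratio,
               rep(0, nrow(kt$ratio)), tolerance = 1e-9)
  expect_true(all(kt$ratio$treatment != "ammonium"))
})

test_that("z-scored KO views have unit spread across treatments", {
  pt <- make_proteome_truth(strains = c("s1", "s2"), n_proteins = 40,
                            n_dep = 5, n_pii_pos = 3, n_pii_neg = 2,
                            n_absence = 2, seed = 6)
  pms <- simulate_proteomics(pt, seed = 6)
  kt <- match_kos(pms, pt$ko_map)
  for (d in split(kt$z, list(kt$z$ko, kt$z$strain), drop = TRUE)) {
    expect_equal(mean(d$z), 0, tolerance = 1e-9)
    if (stats::sd(d$mean_lfq) > 1e-12)
      expect_equal(stats::sd(d$z), 1, tolerance = 1e-9)
  }
})

test_that("pathway statistics combine member p-values and apply filters", {
  lg <- withr::with_seed(11, matrix(stats::rnorm(160, 12, 0.5), 20, 8,
                                    dimnames = list(sprintf("p%02d", 1:20),
                                                    paste0("s", 1:8))))
  lg[1:4, 1:4] <- lg[1:4, 1:4] + 3
  pm <- make_pm(lg, c("A", "B"))
  cmp <- differential_abundance(pm, "A", "B")
  ko_map <- data.frame(protein_id = sprintf("p%02d", 1:20),
                       ko = sprintf("K%02d", 1:20))
  pathway_map <- data.frame(
    ko = sprintf("K%02d", 1:20),
    pathway_id = c(rep("up", 4), rep("null", 14), rep("tiny", 2)))
  pt <- pathway_test(cmp, ko_map, pathway_map)
  expect_false("tiny" %in% pt$pathway_id)    # < 3 proteins excluded
  # combined p equals Fisher's method on the member BH p-values
  members <- cmp$p_adj[match(sprintf("p%02d", 1:4), cmp$protein)]
  expect_equal(pt$p[pt$pathway_id == "up"],
               fisher_combined_p(members), tolerance = 1e-12)
  expect_lt(pt$p[pt$pathway_id == "up"],
            pt$p[pt$pathway_id == "null"])
  # blacklist removal and the enrichment variant
  pt2 <- pathway_test(cmp, ko_map, pathway_map, blacklist = "null")
  expect_identical(pt2$pathway_id, "up")
  pt3 <- pathway_test(cmp, ko_map, pathway_map, method = "enrichment")
  expect_true(all(c("up", "null") %in% pt3$pathway_id))
  expect_lt(pt3$p[pt3$pathway_id == "up"], 0.05)
})

test_that("PII screen classifies by correlation and OLS slope", {
  treatments <- paste0("t", 1:5)
  pii <- c(-1.2, -0.5, 0.1, 0.6, 1.0)
  prof <- rbind(
    PII = 20 + pii,
    ident = 20 + pii,                    # slope 1 -> none
    strong = 18 + 3 * pii,               # slope 3, corr 1 -> positive
    anti = 22 - 3 * pii,                 # slope -3 -> negative
    weak = withr::with_seed(2, 20 + 0.8 * pii +
                              stats::rnorm(5, 0, 0.05)),
    flat = rep(20, 5))
  colnames(prof) <- treatments
  sc <- pii_screen(prof, "PII")
  cls <- stats::setNames(sc$class, sc$protein)
  expect_identical(unname(cls[c("ident", "strong", "anti", "weak",
                                "flat")]),
                   c("none", "positive", "negative", "none", "none"))
  expect_equal(sc$slope[sc$protein == "ident"], 1, tolerance = 1e-9)
  expect_equal(sc$correlation[sc$protein == "ident"], 1,
               tolerance = 1e-9)
  expect_equal(sc$slope[sc$protein == "strong"], 3, tolerance = 1e-9)
  expect_true(is.na(sc$correlation[sc$protein == "flat"]))
  # a high-correlation, sub-threshold-slope profile stays unclassified
  expect_gt(sc$correlation[sc$protein == "weak"], 0.75)
  expect_lt(sc$slope[sc$protein == "weak"], 2)
  expect_error(pii_screen(prof, "missing"))
})

test_that("the PII screen recovers the planted coupled block", {
  pt <- make_proteome_truth(seed = 2)
  pms <- simulate_proteomics(pt, seed = 4)
  for (st in pt$strains) {
    prof <- treatment_profiles(pms[[st]])
    sc <- pii_screen(prof, pt$pii_id)
    pos_called <- sc$protein[sc$class == "positive"]
    neg_called <- sc$protein[sc$class == "negative"]
    expect_gte(mean(pt$pii_positive %in% pos_called), 0.9)
    # anti-coupled proteins are never classified positive
    expect_length(intersect(pt$pii_negative, pos_called), 0)
    expect_gte(mean(pt$pii_negative %in% neg_called), 0.9)
  }
})

test_that("proteomics TSV round trip preserves values and metadata", {
  pt <- make_proteome_truth(strains = "s1", n_proteins = 30, n_dep = 4,
                            n_pii_pos = 2, n_pii_neg = 1,
                            n_absence = 2, seed = 8)
  pm <- simulate_proteomics(pt, seed = 8)$s1
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_proteomics_tsv(pm, f1, f2)
  back <- read_proteomics_tsv(f1, f2, "s1")
  expect_equal(back$lfq, pm$lfq, tolerance = 1e-9)
  expect_identical(back$metadata$treatment, pm$metadata$treatment)
})
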