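# Synthetic ground-truth generators: toy metabolic universes (universal
# database, per-strain true and draft networks, media panel, truth
# growth matrix), plate-reader kinetics, and LFQ proteomics matrices
# with planted effects. All generators are pure functions of
# (parameters, seed).

.N_SOURCE_POOL <- c(
  glutamate = 1, lysine = 2, serine = 1, urea = 2, glycine = 1,
  alanine = 1, arginine = 4, histidine = 3, proline = 1,
  glutamine = 2, asparagine = 2, ornithine = 2, putrescine = 2,
  citrulline = 3, nitrate = 1, nitrite = 1)

#' Nitrogen source concentration for an elemental-N dose
#'
#' Media are dosed so total nitrogen atoms, not molecules, are equimolar
#' across substrates: a two-nitrogen molecule (urea, lysine) at a 5 mM
#' elemental-N target is supplied at 2.5 mM.
#'
#' @param target_elemental_n Target elemental nitrogen concentration
#'   (mM, >= 0).
#' @param n_atoms_per_molecule Nitrogen atoms per substrate molecule
#'   (integer >= 1).
#' @return Substrate concentration in mM.
#' @examples
#' n_source_concentration(5, 2)  # urea, lysine -> 2.5
#' n_source_concentration(5, 1)  # ammonium, glutamate, serine -> 5
#' @export
n_source_concentration <- function(target_elemental_n,
                                   n_atoms_per_molecule) {
  if (length(n_atoms_per_molecule) != 1L ||
      n_atoms_per_molecule < 1 ||
      n_atoms_per_molecule != round(n_atoms_per_molecule))
    stop("n_atoms_per_molecule must be an integer >= 1")
  if (target_elemental_n < 0) stop("target must be >= 0")
  target_elemental_n / n_atoms_per_molecule
}

#' Generate a synthetic metabolic universe
#'
#' Builds a universal reaction database from layered pathways: a shared
#' carbon/ammonium core (glucose uptake, glycolysis, ammonium
#' assimilation into an amino-acid pool feeding biomass) plus one
#' degradation pathway per organic nitrogen source (transport, then 1-2
#' enzymatic steps releasing ammonium), plus inert distractor reactions
#' among dead-end metabolites to fill the database. Each strain's true
#' network carries the core and the pathways for its own growth-positive
#' sources; drafts arise by seeded deletion of reactions non-essential
#' for growth on ammonium. The truth growth matrix is computed by FBA on
#' the true networks, and every strain is guaranteed at least one
#' growth-positive and one growth-negative source.
#'
#' @param n_metabolites Approximate metabolite count for the database
#'   (dead-end distractor metabolites fill up to it).
#' @param n_db_reactions Approximate database reaction count
#'   (distractors fill up to it).
#' @param n_strains Number of strains.
#' @param n_sources Number of nitrogen-source conditions (including
#'   ammonium).
#' @param deletion_fraction Fraction of true-network reactions deleted
#'   to form the draft (0-0.5).
#' @param seed Master integer seed.
#' @param p_positive Probability a strain can use an organic source.
#' @return A `synthetic_universe`: `db`, `strains` (per strain: `true`,
#'   `draft`, `positive_sources`), `media` (named list), `truth`
#'   (strains x conditions logical matrix), `seed`, `params`.
#' @export
generate_universe <- function(n_metabolites = 40L,
                              n_db_reactions = 120L, n_strains = 3L,
                              n_sources = 12L, deletion_fraction = 0.15,
                              seed = 1L, p_positive = 0.65) {
  stopifnot(n_metabolites > 0, n_db_reactions > 0, n_strains >= 1,
            n_sources >= 2, deletion_fraction >= 0,
            deletion_fraction <= 0.5)
  if (n_sources - 1L > length(.N_SOURCE_POOL))
    stop("at most ", length(.N_SOURCE_POOL) + 1L, " sources supported")
  for (attempt in 1:10) {
    u <- withr::with_seed(.child_seed(seed, 1000L + attempt),
                          .try_universe(n_metabolites, n_db_reactions,
                                        n_strains, n_sources,
                                        deletion_fraction, p_positive))
    if (!is.null(u)) {
      u$seed <- as.integer(seed)
      u$params <- list(n_metabolites = n_metabolites,
                       n_db_reactions = n_db_reactions,
                       n_strains = n_strains, n_sources = n_sources,
                       deletion_fraction = deletion_fraction,
                       p_positive = p_positive)
      return(u)
    }
  }
  stop("universe constraints unsatisfiable after bounded retries")
}

.try_universe <- function(n_metabolites, n_db_reactions, n_strains,
                          n_sources, deletion_fraction, p_positive) {
  sources <- c("ammonium",
               names(.N_SOURCE_POOL)[seq_len(n_sources - 1L)])

  ## ---- metabolites -------------------------------------------------
  core_mets <- list(
    metabolite("glc_e", "glucose", "e"),
    metabolite("glc_c", "glucose"),
    metabolite("pyr_c", "pyruvate"),
    metabolite("nh4_e", "ammonium", "e"),
    metabolite("nh4_c", "ammonium"),
    metabolite("aa_c", "amino acid pool"))
  ## organic sources either carry a private one-step deaminase or feed
  ## a family-shared intermediate whose downstream deaminase is common
  ## to the family -- mirroring how catabolic routes converge on shared
  ## intermediates, so training on one substrate informs its relatives
  organic <- setdiff(sources, "ammonium")
  n_fam <- max(2L, ceiling(length(organic) / 4))
  family <- stats::setNames(sample(n_fam, length(organic),
                                   replace = TRUE), organic)
  private <- stats::setNames(stats::runif(length(organic)) < 0.5,
                             organic)
  src_mets <- list()
  for (s in organic)
    src_mets <- c(src_mets, list(
      metabolite(paste0(s, "_e"), s, "e"),
      metabolite(paste0(s, "_c"), s)))
  fam_used <- sort(unique(family[!private]))
  for (f in fam_used)
    src_mets <- c(src_mets,
                  list(metabolite(paste0("fam", f, "_c"),
                                  paste0("family ", f,
                                         " intermediate"))))
  n_dead <- max(4L, n_metabolites - length(core_mets) - length(src_mets))
  dead_mets <- lapply(seq_len(n_dead), function(i)
    metabolite(paste0("dead", i, "_c"), paste0("distractor ", i)))
  mets <- c(core_mets, src_mets, dead_mets)

  ## ---- reactions ---------------------------------------------------
  core_rxns <- list(
    reaction("EX_glc", c(glc_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("T_glc", c(glc_e = -1, glc_c = 1)),
    reaction("GLYC", c(glc_c = -1, pyr_c = 2)),
    reaction("ASSIM", c(pyr_c = -1, nh4_c = -1, aa_c = 1)),
    reaction("EX_nh4", c(nh4_e = -1), 0, 1000, is_exchange = TRUE),
    reaction("T_nh4", c(nh4_e = -1, nh4_c = 1)))
  biomass <- reaction("BIOMASS", c(aa_c = -1, pyr_c = -1),
                      is_biomass = TRUE)
  path_rxns <- list()   # per source: source-specific reactions
  fam_rxns <- list()    # per family: the shared downstream deaminase
  for (f in fam_used)
    fam_rxns[[as.character(f)]] <- reaction(
      paste0("DEGF_", f),
      stats::setNames(c(-1, 1, 1),
                      c(paste0("fam", f, "_c"), "nh4_c", "pyr_c")))
  for (s in organic) {
    ## two independent uptake systems per source (specific permease
    ## plus a second importer), as bacterial amino-acid uptake is
    ## typically redundant
    rs <- list(
      reaction(paste0("EX_", s), stats::setNames(-1, paste0(s, "_e")),
               0, 1000, is_exchange = TRUE),
      reaction(paste0("T_", s),
               stats::setNames(c(-1, 1),
                               c(paste0(s, "_e"), paste0(s, "_c")))),
      reaction(paste0("T2_", s),
               stats::setNames(c(-1, 1),
                               c(paste0(s, "_e"), paste0(s, "_c")))))
    if (private[[s]]) {
      rs <- c(rs, list(reaction(
        paste0("DEG_", s, "_1"),
        stats::setNames(c(-1, 1, 1),
                        c(paste0(s, "_c"), "nh4_c", "pyr_c")))))
    } else {
      rs <- c(rs, list(reaction(
        paste0("DEG_", s, "_1"),
        stats::setNames(c(-1, 1),
                        c(paste0(s, "_c"),
                          paste0("fam", family[[s]], "_c"))))))
    }
    path_rxns[[s]] <- rs
  }
  n_core <- length(core_rxns) + sum(lengths(path_rxns)) +
    length(fam_rxns)
  n_distract <- max(0L, n_db_reactions - n_core)
  dead_ids <- vapply(dead_mets, `[[`, character(1), "id")
  distract <- list()
  for (i in seq_len(n_distract)) {
    # inert conversions: consume pyruvate or a dead metabolite, make
    # dead metabolites; cannot create nitrogen, so cannot enable growth
    from <- sample(c("pyr_c", dead_ids), 1L)
    to <- sample(setdiff(dead_ids, from), 1L)
    distract[[i]] <- reaction(sprintf("DIS_%03d", i),
                              stats::setNames(c(-1, 1), c(from, to)))
  }
  db <- universal_db("synthetic_db", mets,
                     c(core_rxns, unname(fam_rxns),
                       unlist(path_rxns, recursive = FALSE),
                       distract))

  ## ---- media panel -------------------------------------------------
  media <- list()
  for (s in sources) {
    ex <- if (s == "ammonium") "EX_nh4" else paste0("EX_", s)
    ub <- stats::setNames(c(10, 10), c("EX_glc", ex))
    media[[s]] <- medium_condition(s, ub, ex)
  }

  ## ---- strains -----------------------------------------------------
  strains <- list()
  truth <- matrix(NA, n_strains, length(sources),
                  dimnames = list(paste0("strain", seq_len(n_strains)),
                                  sources))
  for (k in seq_len(n_strains)) {
    pos <- organic[stats::runif(length(organic)) < p_positive]
    if (length(pos) == length(organic))
      pos <- pos[-sample(length(pos), 1L)]
    if (!length(pos)) pos <- sample(organic, 1L)
    fams <- sort(unique(family[pos[!private[pos]]]))
    own_rxns <- c(core_rxns,
                  unname(fam_rxns[as.character(fams)]),
                  unlist(path_rxns[pos], recursive = FALSE),
                  lapply(setdiff(organic, pos), function(s)
                    db$reactions[[paste0("EX_", s)]]),
                  distract[stats::runif(length(distract)) < 0.3],
                  list(biomass))
    true_net <- metabolic_network(paste0("strain", k, "_true"), mets,
                                  own_rxns)
    for (s in sources)
      truth[k, s] <- predicts_growth(true_net, media[[s]])
    ## keep realized utilization rates in the generalist regime
    ## (around three in five substrates supporting growth)
    n_src <- length(sources)
    if (!truth[k, "ammonium"] ||
        sum(truth[k, ]) < max(2L, ceiling(0.35 * n_src)) ||
        sum(truth[k, ]) > floor(0.8 * n_src))
      return(NULL)
    draft <- .delete_nonessential(true_net, media[["ammonium"]],
                                  deletion_fraction)
    strains[[rownames(truth)[k]]] <-
      list(true = true_net, draft = draft,
           positive_sources = c("ammonium", pos))
  }
  structure(list(db = db, strains = strains, media = media,
                 truth = truth), class = "synthetic_universe")
}

# delete up to fraction * n reactions, shuffled, each kept out only if
# growth on the reference medium survives the (cumulative) deletion.
# Exchange reactions are never deleted: they encode boundary
# conditions, not gene-associated functions, so draft reconstructions
# retain them.
.delete_nonessential <- function(net, medium, fraction) {
  ids <- names(net$reactions)[!vapply(net$reactions, function(r)
    r$is_biomass || r$is_exchange, logical(1))]
  target <- floor(fraction * length(net$reactions))
  if (target == 0L) return(net)
  ord <- sample(ids)
  deleted <- character(0)
  cur <- net
  for (id in ord) {
    if (length(deleted) >= target) break
    trial <- remove_reactions(cur, id)
    ok <- tryCatch(predicts_growth(trial, medium),
                   error = function(e) FALSE)
    if (ok) {
      cur <- trial
      deleted <- c(deleted, id)
    }
  }
  cur$id <- sub("_true$", "_draft", net$id)
  cur
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat("<synthetic_universe> ", length(x$strains), " strains, ",
      ncol(x$truth), " nitrogen sources, db of ",
      length(x$db$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Simulate phenotype-microarray kinetics for one strain
#'
#' Generates 10-minute-interval absorbance series over 72 h for one
#' plate: a negative-control well (A1), one well per substrate, three
#' replicates. Growth-positive substrates follow logistic curves with
#' carrying capacities drawn from `k_growth_range`; negative wells stay
#' at a small baseline. All wells share a slowly saturating background
#' drift (captured by the control well and removed by background
#' subtraction), replicates get small multiplicative jitter on K and r,
#' and Gaussian noise of sd `noise_sd` is added. One planted
#' high-background well exercises the exclusion rule for wells with
#' unusable background.
#'
#' @param truth_row Named logical vector: substrate -> grows.
#' @param strain Strain id used as `plate_id`.
#' @param noise_sd Gaussian noise sd (absorbance units).
#' @param seed Integer seed.
#' @param n_replicates Replicates (default 3).
#' @param hours Duration (default 72).
#' @param dt_min Sampling interval in minutes (default 10).
#' @param k_growth_range,k_flat Carrying-capacity prior for growth
#'   wells, and the flat baseline of non-growth wells.
#' @param high_background_substrate Substrate given an 8x background
#'   (NULL to disable). Defaults to the last substrate.
#' @return Long-form plate data.frame; attributes `truth` and
#'   `high_background_substrate`.
#' @export
simulate_plate <- function(truth_row, strain = "strain1",
                           noise_sd = 0.01, seed = 1L,
                           n_replicates = 3L, hours = 72, dt_min = 10,
                           k_growth_range = c(0.15, 0.6),
                           k_flat = 0.02,
                           high_background_substrate =
                             names(truth_row)[length(truth_row)]) {
  stopifnot(is.logical(truth_row), !is.null(names(truth_row)))
  tt <- seq(0, hours, by = dt_min / 60)
  wells <- .well_ids(length(truth_row) + 1L)
  withr::with_seed(seed, {
    drift <- 0.03 * (1 - exp(-tt / 24))
    pars <- lapply(names(truth_row), function(s) {
      if (truth_row[[s]])
        list(K = stats::runif(1, k_growth_range[1], k_growth_range[2]),
             r = stats::runif(1, 0.1, 0.5),
             N0 = stats::runif(1, 0.01, 0.03))
      else list(K = 0, r = 0, N0 = k_flat)
    })
    names(pars) <- names(truth_row)
    out <- list()
    for (rep_i in seq_len(n_replicates)) {
      ## control well A1: background only
      out[[length(out) + 1L]] <- data.frame(
        plate_id = strain, well = wells[1L], replicate = rep_i,
        substrate_id = "control", time_h = tt,
        value = drift + stats::rnorm(length(tt), 0, noise_sd))
      for (j in seq_along(truth_row)) {
        s <- names(truth_row)[j]
        p <- pars[[s]]
        signal <- if (p$K > 0)
          .logistic_curve(tt, p$K * stats::runif(1, 0.9, 1.1),
                          p$r * stats::runif(1, 0.9, 1.1), p$N0)
        else rep(p$N0, length(tt))
        bg <- if (!is.null(high_background_substrate) &&
                  identical(s, high_background_substrate))
          8 * drift else drift
        out[[length(out) + 1L]] <- data.frame(
          plate_id = strain, well = wells[j + 1L], replicate = rep_i,
          substrate_id = s, time_h = tt,
          value = pmax(signal + bg +
                         stats::rnorm(length(tt), 0, noise_sd), 0))
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "truth") <- truth_row
    attr(res, "high_background_substrate") <- high_background_substrate
    res
  })
}

.well_ids <- function(n) {
  grid <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  if (n > length(grid)) stop("at most 96 wells per plate")
  grid[seq_len(n)]
}

#' Define ground truth for a synthetic proteomics experiment
#'
#' Plans strain-specific baselines, planted differential-abundance
#' effects (one treatment shifted by +/- `effect_log2` for a set of DEP
#' proteins), a PII-coupled block (proteins whose profiles follow the
#' PII protein's treatment profile with slopes +/- `coupling_slope`),
#' planted presence/absence proteins (shifted below the detection limit
#' in one treatment), and shared KO / pathway annotation maps.
#'
#' @param strains Character vector of strain ids.
#' @param treatments Treatment labels; the first is the reference
#'   (default the five-source panel with ammonium first).
#' @param n_proteins Proteins per strain.
#' @param n_dep Planted DEP proteins per strain.
#' @param effect_log2 Planted |log2 fold change| (default 3).
#' @param n_pii_pos,n_pii_neg Sizes of the positively and negatively
#'   PII-coupled blocks.
#' @param coupling_slope Coupling slope magnitude (default 3).
#' @param n_absence Planted presence/absence proteins per strain.
#' @param detection_limit_log2 Left-censoring limit on the log2 scale.
#' @param seed Integer seed.
#' @return A `proteome_truth` object used by [simulate_proteomics()].
#' @export
make_proteome_truth <- function(strains = c("strain1", "strain2",
                                            "strain3"),
                                treatments = c("ammonium", "glutamate",
                                               "lysine", "serine",
                                               "urea"),
                                n_proteins = 200L, n_dep = 20L,
                                effect_log2 = 3, n_pii_pos = 15L,
                                n_pii_neg = 5L, coupling_slope = 3,
                                n_absence = 8L,
                                detection_limit_log2 = 13,
                                seed = 1L) {
  stopifnot(n_dep + n_pii_pos + n_pii_neg + n_absence + 1L <=
              n_proteins, length(treatments) >= 3L)
  withr::with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    pii_id <- "P0001"
    ## PII treatment profile in log2 units, sd-1 scaled; the reference
    ## (ammonium) has the lowest nitrogen-stress signal
    raw <- c(0, sort(stats::runif(length(treatments) - 1L, 0.5, 3)))
    pii_profile <- stats::setNames((raw - mean(raw)) / stats::sd(raw),
                                   treatments)
    pool <- setdiff(proteins, pii_id)
    pick <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    pii_pos <- pick(n_pii_pos)
    pii_neg <- pick(n_pii_neg)
    per_strain <- lapply(strains, function(st) {
      dep <- sample(pool, n_dep)
      abs_p <- sample(setdiff(pool, dep), n_absence)
      dep_tab <- data.frame(
        protein = dep,
        treatment = sample(treatments[-1L], n_dep, replace = TRUE),
        effect = sample(c(-1, 1), n_dep, replace = TRUE) * effect_log2,
        stringsAsFactors = FALSE)
      abs_tab <- data.frame(
        protein = abs_p,
        treatment = sample(treatments[-1L], n_absence,
                           replace = TRUE),
        stringsAsFactors = FALSE)
      list(dep = dep_tab, absence = abs_tab)
    })
    names(per_strain) <- strains
    ko_map <- data.frame(protein_id = proteins,
                         ko = sprintf("K%05d", seq_len(n_proteins)),
                         stringsAsFactors = FALSE)
    n_pw <- max(3L, n_proteins %/% 20L)
    pathway_map <- data.frame(
      ko = ko_map$ko,
      pathway_id = sprintf("path%02d",
                           rep(seq_len(n_pw),
                               length.out = n_proteins)),
      stringsAsFactors = FALSE)
    pathway_map$pathway_name <- paste("pathway",
                                      pathway_map$pathway_id)
    structure(list(strains = strains, treatments = treatments,
                   proteins = proteins, pii_id = pii_id,
                   pii_profile = pii_profile,
                   pii_positive = pii_pos, pii_negative = pii_neg,
                   coupling_slope = coupling_slope,
                   per_strain = per_strain,
                   effect_log2 = effect_log2,
                   detection_limit_log2 = detection_limit_log2,
                   ko_map = ko_map, pathway_map = pathway_map,
                   seed = as.integer(seed)),
              class = "proteome_truth")
  })
}

#' Simulate LFQ proteomics matrices from a planned truth
#'
#' Per (strain, protein): a log-normal baseline (log2 ~ N(20, 2)),
#' planted DEP effects added in their treatment, PII-coupled abundances
#' equal to baseline + slope x (PII profile) + noise, replicate noise
#' i.i.d. N(0, `noise_sd_log2`), and left-censoring of values below the
#' detection limit (returned as missing). Intensities are returned on
#' the linear LFQ scale.
#'
#' @param truth A [make_proteome_truth()] object.
#' @param n_replicates Replicates per (strain, treatment) (>= 3).
#' @param noise_sd_log2 Replicate noise sd on the log2 scale (default
#'   0.25).
#' @param seed Integer seed.
#' @return Named list of [proteomics_matrix()] objects, one per strain.
#' @export
simulate_proteomics <- function(truth, n_replicates = 4L,
                                noise_sd_log2 = 0.25, seed = 1L) {
  stopifnot(inherits(truth, "proteome_truth"), n_replicates >= 3L)
  treatments <- truth$treatments
  withr::with_seed(seed, {
    out <- lapply(truth$strains, function(st) {
      plan <- truth$per_strain[[st]]
      base <- stats::setNames(stats::rnorm(length(truth$proteins), 20,
                                           2), truth$proteins)
      base[truth$pii_id] <- 20
      ## mean log2 abundance per protein x treatment
      mu <- matrix(base, length(truth$proteins), length(treatments),
                   dimnames = list(truth$proteins, treatments))
      mu[truth$pii_id, ] <- base[truth$pii_id] + truth$pii_profile
      for (i in seq_len(nrow(plan$dep)))
        mu[plan$dep$protein[i], plan$dep$treatment[i]] <-
          mu[plan$dep$protein[i], plan$dep$treatment[i]] +
          plan$dep$effect[i]
      for (p in truth$pii_positive)
        mu[p, ] <- base[p] + truth$coupling_slope * truth$pii_profile
      for (p in truth$pii_negative)
        mu[p, ] <- base[p] - truth$coupling_slope * truth$pii_profile
      for (i in seq_len(nrow(plan$absence)))
        mu[plan$absence$protein[i], plan$absence$treatment[i]] <-
          truth$detection_limit_log2 - 4
      samples <- as.vector(t(outer(treatments,
                                   seq_len(n_replicates),
                                   function(t1, r)
                                     paste0(st, "_", t1, "_", r))))
      meta <- data.frame(
        sample = samples,
        treatment = rep(treatments, each = n_replicates),
        replicate = rep(seq_len(n_replicates),
                        times = length(treatments)),
        stringsAsFactors = FALSE)
      lg <- matrix(NA_real_, length(truth$proteins), length(samples),
                   dimnames = list(truth$proteins, samples))
      for (j in seq_along(samples)) {
        t1 <- meta$treatment[j]
        lg[, j] <- mu[, t1] + stats::rnorm(nrow(lg), 0, noise_sd_log2)
      }
      lg[lg < truth$detection_limit_log2] <- NA_real_
      lfq <- 2^lg
      lfq[is.na(lfq)] <- 0
      proteomics_matrix(st, lfq, meta)
    })
    names(out) <- truth$strains
    out
  })
}
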