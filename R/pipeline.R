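# Pipeline orchestration: run the synthetic benchmark end-to-end with a
# single configuration object and a reproducible run manifest.

#' Default pipeline configuration
#'
#' All tunables in one nested list. The ensemble block encodes the
#' study-scale defaults (50 members, 26 positive and 11 negative
#' training conditions); training sizes are capped at panel size at run
#' time. Override any element by passing replacements through `...`
#' (top-level names replace whole sub-lists unless given as lists,
#' which are merged).
#'
#' @param ... Named overrides merged into the defaults.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    ensemble = list(size = 50L, n_pos = 26L, n_neg = 11L),
    thresholds = list(epsilon = 1e-3, vote = 0.5, k_growth = 0.1,
                      min_replicates = 2L, fc = 1, alpha = 0.05,
                      corr = 0.75, slope = 2),
    universe = list(n_metabolites = 40L, n_db_reactions = 120L,
                    n_strains = 3L, n_sources = 12L,
                    deletion_fraction = 0.15),
    plate = list(noise_sd = 0.01, n_replicates = 3L),
    proteomics = list(n_proteins = 200L, n_replicates = 4L,
                      noise_sd_log2 = 0.25, min_reps = 3L),
    baseline = list(n_draws = 1000L),
    exclude_substrates = character(0))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

.PIPELINE_STAGES <- c("simulate", "score-growth", "build-ensemble",
                      "predict", "evaluate", "dea", "ko", "pathways",
                      "pii", "report")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (write
#' the synthetic universe, plates and LFQ matrices), `score-growth`
#' (plate scoring to a growth matrix), `build-ensemble` (per-strain
#' ensembles trained on the scored calls), `predict` (ensemble growth
#' and activity per condition), `evaluate` (masked metrics, random
#' baseline, rank r-squared), `dea` (all pairwise differential
#' abundance), `ko` (cross-strain KO table), `pathways` (combined
#' pathway p-values), `pii` (PII-correlation screen) and `report`
#' (summary JSON). Later stages read the files earlier stages wrote, so
#' partial reruns resume from cached outputs. A manifest records
#' parameters, seeds, outputs and their checksums.
#'
#' @param config A [default_config()] list.
#' @param outdir Output directory.
#' @param stages Subset of stages to run (default: all).
#' @return The manifest, invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = .PIPELINE_STAGES) {
  stopifnot(all(stages %in% .PIPELINE_STAGES))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("nitrofill")),
                   seed = config$seed, config = unclass(config),
                   stages_run = stages, outputs = list())
  add_out <- function(stage, path) {
    manifest$outputs[[stage]] <<-
      c(manifest$outputs[[stage]],
        stats::setNames(unname(tools::md5sum(path)),
                        basename(path)))
  }
  pth <- function(...) file.path(outdir, ...)
  th <- config$thresholds

  if ("simulate" %in% stages) {
    uni <- do.call(generate_universe,
                   c(config$universe, list(seed = config$seed)))
    write_network_json(uni$db, pth("db.json"))
    write_media_tsv(uni$media, pth("media.tsv"))
    truth_df <- data.frame(strain = rep(rownames(uni$truth),
                                        ncol(uni$truth)),
                           condition = rep(colnames(uni$truth),
                                           each = nrow(uni$truth)),
                           grows = as.vector(uni$truth))
    utils::write.table(truth_df, pth("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_out("simulate", pth("truth.tsv"))
    plates <- list()
    for (sn in names(uni$strains)) {
      write_network_json(uni$strains[[sn]]$true,
                         pth(paste0(sn, "_true.json")))
      write_network_json(uni$strains[[sn]]$draft,
                         pth(paste0(sn, "_draft.json")))
      plates[[sn]] <- simulate_plate(
        uni$truth[sn, ], strain = sn,
        noise_sd = config$plate$noise_sd,
        n_replicates = config$plate$n_replicates,
        seed = .child_seed(config$seed, match(sn, names(uni$strains))),
        high_background_substrate = NULL)
    }
    run <- do.call(rbind, plates)
    write_plate_csv(run, pth("plates.csv"))
    add_out("simulate", pth("plates.csv"))
    ptruth <- make_proteome_truth(
      strains = names(uni$strains),
      n_proteins = config$proteomics$n_proteins,
      seed = .child_seed(config$seed, 77L))
    pms <- simulate_proteomics(
      ptruth, n_replicates = config$proteomics$n_replicates,
      noise_sd_log2 = config$proteomics$noise_sd_log2,
      seed = .child_seed(config$seed, 78L))
    for (sn in names(pms))
      write_proteomics_tsv(pms[[sn]], pth(paste0(sn, "_lfq.tsv")),
                           pth(paste0(sn, "_meta.tsv")))
    utils::write.table(ptruth$ko_map, pth("ko_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ptruth$pathway_map, pth("pathway_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pii_id = ptruth$pii_id,
           treatments = ptruth$treatments,
           strains = names(uni$strains)),
      pth("proteome_design.json"), auto_unbox = TRUE)
    add_out("simulate", pth("ko_map.tsv"))
  }

  strains <- unique(utils::read.delim(pth("truth.tsv"))$strain)

  if ("score-growth" %in% stages) {
    run <- read_plate_csv(pth("plates.csv"))
    scored <- score_plate_run(run, exclude = config$exclude_substrates,
                              k_threshold = th$k_growth,
                              min_replicates = th$min_replicates)
    write_growth_matrix_tsv(scored$growth_matrix,
                            pth("growth_matrix.tsv"))
    add_out("score-growth", pth("growth_matrix.tsv"))
  }

  if ("build-ensemble" %in% stages) {
    db <- read_network_json(pth("db.json"))
    media <- read_media_tsv(pth("media.tsv"))
    gm <- read_growth_matrix_tsv(pth("growth_matrix.tsv"))
    for (sn in strains) {
      draft <- read_network_json(pth(paste0(sn, "_draft.json")))
      g <- gm[gm$strain == sn, ]
      pos <- media[g$substrate[g$call]]
      neg <- media[g$substrate[!g$call]]
      ens <- build_ensemble(
        draft, db, pos, neg, size = config$ensemble$size,
        n_pos = min(config$ensemble$n_pos, length(pos)),
        n_neg = min(config$ensemble$n_neg, length(neg)),
        seed = .child_seed(config$seed, 100L + match(sn, strains)),
        epsilon = th$epsilon)
      write_ensemble(ens, pth(paste0("ensemble_", sn)))
    }
  }

  if ("predict" %in% stages) {
    media <- read_media_tsv(pth("media.tsv"))
    rows <- list()
    for (sn in strains) {
      ens <- read_ensemble(pth(paste0("ensemble_", sn)))
      for (cid in names(media)) {
        pr <- ensemble_predict(ens, media[[cid]],
                               epsilon = th$epsilon,
                               vote_threshold = th$vote)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = sn, condition = cid,
          fraction = pr$fraction_growing, activity = pr$activity,
          call = pr$binary_call)
      }
    }
    utils::write.table(do.call(rbind, rows), pth("predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_out("predict", pth("predictions.tsv"))
  }

  if ("evaluate" %in% stages) {
    media <- read_media_tsv(pth("media.tsv"))
    gm <- read_growth_matrix_tsv(pth("growth_matrix.tsv"))
    reports <- list()
    for (sn in strains) {
      ens <- read_ensemble(pth(paste0("ensemble_", sn)))
      g <- gm[gm$strain == sn, ]
      truth <- stats::setNames(g$call, g$substrate)
      rep1 <- evaluate_ensemble(ens, media, truth,
                                epsilon = th$epsilon,
                                vote_threshold = th$vote)
      bl <- random_baseline(truth,
                            n_draws = config$baseline$n_draws,
                            seed = .child_seed(config$seed,
                                               200L + match(sn,
                                                            strains)))
      ## activity for the rank comparison uses all members (the masked
      ## activities cover too few conditions on small training panels)
      act <- vapply(names(truth), function(cid)
        ensemble_predict(ens, media[[cid]], epsilon = th$epsilon,
                         vote_threshold = th$vote)$activity,
        numeric(1))
      expz <- stats::setNames(ifelse(g$call, g$mean_z, -1),
                              g$substrate)
      rr2 <- tryCatch(rank_r2(act, expz), error = function(e) NA_real_)
      reports[[sn]] <- list(
        confusion = as.list(rep1$confusion),
        accuracy = rep1$accuracy, precision = rep1$precision,
        recall = rep1$recall,
        baseline = bl$summary,
        rank_r2 = rr2)
    }
    jsonlite::write_json(reports, pth("evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_out("evaluate", pth("evaluation.json"))
  }

  needs_prot <- any(c("dea", "ko", "pathways", "pii") %in% stages)
  if (needs_prot) {
    design <- jsonlite::read_json(pth("proteome_design.json"),
                                  simplifyVector = TRUE)
    pms <- lapply(design$strains, function(sn)
      read_proteomics_tsv(pth(paste0(sn, "_lfq.tsv")),
                          pth(paste0(sn, "_meta.tsv")), sn))
    names(pms) <- design$strains
    ko_map <- utils::read.delim(pth("ko_map.tsv"),
                                stringsAsFactors = FALSE)
  }

  if ("dea" %in% stages) {
    pairs <- enumerate_comparisons(design$treatments)
    for (sn in design$strains) {
      for (i in seq_len(nrow(pairs))) {
        cmp <- differential_abundance(
          pms[[sn]], pairs$a[i], pairs$b[i],
          min_reps = config$proteomics$min_reps,
          fc_threshold = th$fc, alpha = th$alpha)
        write_comparison_tsv(cmp, pth(sprintf("dea_%s_%s_vs_%s.tsv",
                                              sn, pairs$a[i],
                                              pairs$b[i])))
      }
    }
    add_out("dea", pth(sprintf("dea_%s_%s_vs_%s.tsv", design$strains[1],
                               pairs$a[1], pairs$b[1])))
  }

  if ("ko" %in% stages) {
    kt <- match_kos(pms, ko_map,
                    min_reps = config$proteomics$min_reps)
    utils::write.table(kt$abundance, pth("ko_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(kt$z, pth("ko_z.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_out("ko", pth("ko_abundance.tsv"))
  }

  if ("pathways" %in% stages) {
    pathway_map <- utils::read.delim(pth("pathway_map.tsv"),
                                     stringsAsFactors = FALSE)
    rows <- list()
    pairs <- enumerate_comparisons(design$treatments)
    for (sn in design$strains) {
      for (i in seq_len(nrow(pairs))) {
        cmp <- differential_abundance(
          pms[[sn]], pairs$a[i], pairs$b[i],
          min_reps = config$proteomics$min_reps,
          fc_threshold = th$fc, alpha = th$alpha)
        pt <- pathway_test(cmp, ko_map, pathway_map)
        if (nrow(pt)) {
          pt$strain <- sn
          pt$comparison <- paste0(pairs$a[i], "_vs_", pairs$b[i])
          rows[[length(rows) + 1L]] <- pt
        }
      }
    }
    utils::write.table(do.call(rbind, rows), pth("pathways.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_out("pathways", pth("pathways.tsv"))
  }

  if ("pii" %in% stages) {
    rows <- list()
    for (sn in design$strains) {
      prof <- treatment_profiles(pms[[sn]],
                                 min_reps = config$proteomics$min_reps)
      if (design$pii_id %in% rownames(prof)) {
        sc <- pii_screen(prof, design$pii_id,
                         corr_threshold = th$corr,
                         slope_threshold = th$slope)
        sc$strain <- sn
        rows[[length(rows) + 1L]] <- sc
      }
    }
    utils::write.table(do.call(rbind, rows), pth("pii_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_out("pii", pth("pii_screen.tsv"))
  }

  if ("report" %in% stages) {
    summary <- list(seed = config$seed, stages = stages)
    if (file.exists(pth("evaluation.json")))
      summary$evaluation <- jsonlite::read_json(pth("evaluation.json"))
    if (file.exists(pth("growth_matrix.tsv"))) {
      gm <- read_growth_matrix_tsv(pth("growth_matrix.tsv"))
      summary$n_growth_positive <-
        as.list(tapply(gm$call, gm$strain, sum))
    }
    jsonlite::write_json(summary, pth("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_out("report", pth("report.json"))
  }

  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
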