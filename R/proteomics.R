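# Label-free proteomics statistics: differential abundance with BH
# control, cross-strain KEGG-ortholog matching, combined pathway
# p-values, and the PII-correlation screen.

#' Create a proteomics matrix
#'
#' Wraps a proteins x samples LFQ intensity matrix with its sample
#' metadata. Zero intensities are treated as missing (not detected), the
#' usual LFQ convention.
#'
#' @param strain Strain identifier.
#' @param lfq Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids); NA or 0 = not detected.
#' @param metadata data.frame with columns `sample`, `treatment`,
#'   `replicate` covering every column of `lfq`.
#' @return A `proteomics_matrix`.
#' @export
proteomics_matrix <- function(strain, lfq, metadata) {
  stopifnot(is.matrix(lfq), !is.null(rownames(lfq)),
            !is.null(colnames(lfq)),
            all(c("sample", "treatment", "replicate") %in%
                  names(metadata)))
  if (!all(colnames(lfq) %in% metadata$sample))
    stop("metadata must describe every sample column")
  metadata <- metadata[match(colnames(lfq), metadata$sample), ]
  if (length(unique(metadata$treatment)) < 2L)
    stop("at least two treatments required")
  if (any(lfq < 0, na.rm = TRUE)) stop("LFQ intensities must be >= 0")
  lfq[!is.na(lfq) & lfq == 0] <- NA_real_
  structure(list(strain = strain, lfq = lfq, metadata = metadata),
            class = "proteomics_matrix")
}

#' @export
print.proteomics_matrix <- function(x, ...) {
  cat("<proteomics_matrix> ", x$strain, ": ", nrow(x$lfq),
      " proteins x ", ncol(x$lfq), " samples (",
      length(unique(x$metadata$treatment)), " treatments)\n", sep = "")
  invisible(x)
}

#' Differential protein abundance between two treatments
#'
#' Proteins detected in at least `min_reps` replicates of both
#' treatments are tested: log2 fold change is the difference of group
#' means on the log2 scale, the p-value comes from a two-sample t-test
#' (Welch by default), and Benjamini-Hochberg adjustment is applied
#' across all tested proteins within this comparison. A protein is a
#' differentially expressed protein (DEP) when |log2FC| exceeds
#' `fc_threshold` and the BH-adjusted p is below `alpha`. Proteins with
#' >= `min_reps` detections in one treatment and none in the other are
#' classified presence/absence and excluded from the test.
#'
#' @param pm A [proteomics_matrix()].
#' @param treat_a,treat_b Treatment labels (log2FC is A minus B).
#' @param min_reps Minimum detected replicates per group (default 3).
#' @param fc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param var_equal Use Student's pooled-variance t instead of Welch.
#' @return A `comparison_result` data.frame with one row per protein:
#'   `protein`, `n_a`, `n_b`, `log2fc`, `p`, `p_adj`, `dep`, `class`
#'   (`tested`, `present_a_only`, `present_b_only`, `insufficient`).
#' @export
differential_abundance <- function(pm, treat_a, treat_b, min_reps = 3L,
                                   fc_threshold = 1, alpha = 0.05,
                                   var_equal = FALSE) {
  stopifnot(inherits(pm, "proteomics_matrix"))
  tr <- pm$metadata$treatment
  if (!all(c(treat_a, treat_b) %in% tr))
    stop("treatment(s) absent from matrix: ",
         paste(setdiff(c(treat_a, treat_b), tr), collapse = ", "))
  A <- pm$lfq[, tr == treat_a, drop = FALSE]
  B <- pm$lfq[, tr == treat_b, drop = FALSE]
  prot <- rownames(pm$lfq)
  n_a <- rowSums(!is.na(A))
  n_b <- rowSums(!is.na(B))

  res <- data.frame(protein = prot, n_a = n_a, n_b = n_b,
                    log2fc = NA_real_, p = NA_real_, p_adj = NA_real_,
                    dep = FALSE, class = "insufficient",
                    stringsAsFactors = FALSE, row.names = NULL)
  res$class[n_a >= min_reps & n_b == 0L] <- "present_a_only"
  res$class[n_b >= min_reps & n_a == 0L] <- "present_b_only"
  testable <- which(n_a >= min_reps & n_b >= min_reps)
  for (i in testable) {
    xa <- log2(A[i, !is.na(A[i, ])])
    xb <- log2(B[i, !is.na(B[i, ])])
    res$log2fc[i] <- mean(xa) - mean(xb)
    res$p[i] <- .t_p(xa, xb, var_equal)
    res$class[i] <- "tested"
  }
  res$p_adj[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  res$dep <- res$class == "tested" &
    abs(res$log2fc) > fc_threshold & res$p_adj < alpha
  attr(res, "treat_a") <- treat_a
  attr(res, "treat_b") <- treat_b
  attr(res, "strain") <- pm$strain
  class(res) <- c("comparison_result", "data.frame")
  res
}

# two-sample t p-value with a guard for (near-)constant groups, where
# t.test() errors: identical means -> p = 1, else effectively certain.
.t_p <- function(xa, xb, var_equal) {
  if (stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12)
    return(if (abs(mean(xa) - mean(xb)) < 1e-12) 1 else 2.2e-16)
  stats::t.test(xa, xb, var.equal = var_equal)$p.value
}

#' Enumerate pairwise treatment comparisons
#'
#' All unordered treatment pairs in canonical (input) order; five
#' treatments yield the 10 pairwise comparisons shown per strain in
#' volcano-plot panels.
#'
#' @param treatments Character vector of treatment labels (>= 2).
#' @return data.frame with columns `a` and `b`, one row per pair.
#' @export
enumerate_comparisons <- function(treatments) {
  treatments <- unique(treatments)
  if (length(treatments) < 2L) stop("need at least two treatments")
  pairs <- utils::combn(treatments, 2L)
  data.frame(a = pairs[1L, ], b = pairs[2L, ], stringsAsFactors = FALSE)
}

#' Match KEGG orthologs across strains
#'
#' Keeps the KOs observed (>= `min_reps` detected replicates) in every
#' treatment of every strain. When several proteins of one strain map
#' to the same KO, the protein with the highest average LFQ across all
#' samples (missing counted as zero, the LFQ convention) is taken as
#' the representative. Produces the treatment-mean abundance table plus
#' two derived views: within-strain z-scores and log2 ratios to the
#' ammonium reference.
#'
#' @param matrices Named list of [proteomics_matrix()] (one per strain).
#' @param ko_map data.frame with columns `protein_id`, `ko`.
#' @param min_reps Detection filter (default 3).
#' @param reference Reference treatment for the ratio view (default
#'   `"ammonium"`).
#' @return A `ko_table` list: `abundance` (long data.frame: ko, strain,
#'   treatment, mean_lfq), `z` (same, z-scored within strain x ko),
#'   `ratio` (log2 mean/reference), `representatives` (ko, strain,
#'   protein), `n_unmapped` (proteins without KO annotation).
#' @export
match_kos <- function(matrices, ko_map, min_reps = 3L,
                      reference = "ammonium") {
  stopifnot(length(matrices) >= 1L,
            all(c("protein_id", "ko") %in% names(ko_map)))
  komap <- stats::setNames(ko_map$ko, ko_map$protein_id)

  per_strain <- lapply(matrices, function(pm) {
    tr <- pm$metadata$treatment
    prot <- rownames(pm$lfq)
    mapped <- prot[prot %in% names(komap)]
    det <- sapply(unique(tr), function(t1)
      rowSums(!is.na(pm$lfq[, tr == t1, drop = FALSE])))
    grand <- rowMeans(ifelse(is.na(pm$lfq), 0, pm$lfq))
    list(pm = pm, mapped = mapped, det = det, grand = grand,
         treatments = unique(tr),
         n_unmapped = length(setdiff(prot, names(komap))))
  })

  ## a KO is observed in (strain, treatment) if some mapped protein
  ## passes the detection filter there
  ko_ok <- lapply(per_strain, function(s) {
    kos <- unique(komap[s$mapped])
    ok <- vapply(kos, function(k) {
      prots <- s$mapped[komap[s$mapped] == k]
      all(apply(s$det[prots, , drop = FALSE] >= min_reps, 2, any))
    }, logical(1))
    kos[ok]
  })
  keep <- Reduce(intersect, ko_ok)
  if (!length(keep))
    stop("no KO passes the detection filter in all strains")

  reps <- list(); abund <- list()
  for (sn in names(per_strain)) {
    s <- per_strain[[sn]]
    tr <- s$pm$metadata$treatment
    for (k in keep) {
      prots <- s$mapped[komap[s$mapped] == k]
      rep_prot <- prots[which.max(s$grand[prots])]
      reps[[length(reps) + 1L]] <- data.frame(
        ko = k, strain = sn, protein = rep_prot,
        stringsAsFactors = FALSE)
      means <- vapply(s$treatments, function(t1)
        mean(s$pm$lfq[rep_prot, tr == t1], na.rm = TRUE), numeric(1))
      abund[[length(abund) + 1L]] <- data.frame(
        ko = k, strain = sn, treatment = s$treatments,
        mean_lfq = unname(means), stringsAsFactors = FALSE)
    }
  }
  abund <- do.call(rbind, abund)
  reps <- do.call(rbind, reps)

  z <- do.call(rbind, lapply(
    split(abund, list(abund$ko, abund$strain), drop = TRUE),
    function(d) {
      s <- stats::sd(d$mean_lfq)
      d$z <- if (is.na(s) || s < 1e-12) rep(0, nrow(d)) else
        (d$mean_lfq - mean(d$mean_lfq)) / s
      d
    }))
  rownames(z) <- NULL

  ratio <- NULL
  if (reference %in% abund$treatment) {
    ratio <- do.call(rbind, lapply(
      split(abund, list(abund$ko, abund$strain), drop = TRUE),
      function(d) {
        ref <- d$mean_lfq[d$treatment == reference]
        d$log2_ratio <- log2(d$mean_lfq / ref)
        d[d$treatment != reference, ]
      }))
    rownames(ratio) <- NULL
  } else {
    warning("reference treatment '", reference,
            "' absent; ratio view not computed")
  }

  structure(list(abundance = abund, z = z, ratio = ratio,
                 representatives = reps,
                 n_unmapped = vapply(per_strain, `[[`, integer(1),
                                     "n_unmapped"),
                 kos = sort(keep)),
            class = "ko_table")
}

#' @export
print.ko_table <- function(x, ...) {
  cat("<ko_table> ", length(x$kos), " KOs x ",
      length(unique(x$abundance$strain)), " strains x ",
      length(unique(x$abundance$treatment)), " treatments\n", sep = "")
  invisible(x)
}

#' Combine per-protein p-values into pathway p-values
#'
#' For each pathway with at least `min_proteins` tested member proteins,
#' combines their BH-adjusted p-values with Fisher's combined
#' probability method: X = -2 * sum(log p_i) referred to a chi-square
#' with 2k degrees of freedom. Zero p-values are floored at 1e-300 with
#' a warning. A 2x2 enrichment alternative (DEP membership x pathway
#' membership, Fisher's exact test) is available via
#' `method = "enrichment"`.
#'
#' @param comparison A [differential_abundance()] result.
#' @param ko_map data.frame `protein_id`, `ko`.
#' @param pathway_map data.frame `ko`, `pathway_id`, and optionally
#'   `pathway_name`.
#' @param min_proteins Minimum tested proteins per pathway (default 3).
#' @param blacklist Pathway ids to discard (e.g. non-bacterial
#'   processes).
#' @param method `"fisher_combined"` (default) or `"enrichment"`.
#' @return data.frame: `pathway_id`, `pathway_name`, `n_proteins`,
#'   `statistic`, `p`.
#' @export
pathway_test <- function(comparison, ko_map, pathway_map,
                         min_proteins = 3L, blacklist = character(0),
                         method = c("fisher_combined", "enrichment")) {
  method <- match.arg(method)
  stopifnot(inherits(comparison, "comparison_result"),
            all(c("protein_id", "ko") %in% names(ko_map)),
            all(c("ko", "pathway_id") %in% names(pathway_map)))
  tested <- comparison[comparison$class == "tested", ]
  komap <- stats::setNames(ko_map$ko, ko_map$protein_id)
  tested$ko <- komap[tested$protein]
  tested <- tested[!is.na(tested$ko), ]
  pw <- pathway_map[!pathway_map$pathway_id %in% blacklist, ]
  if (!"pathway_name" %in% names(pw)) pw$pathway_name <- pw$pathway_id

  out <- lapply(split(pw, pw$pathway_id), function(d) {
    members <- tested[tested$ko %in% d$ko, ]
    k <- nrow(members)
    if (k < min_proteins) return(NULL)
    if (method == "fisher_combined") {
      p_i <- members$p_adj
      if (any(p_i == 0)) {
        warning("pathway '", d$pathway_id[1L],
                "': zero p-value floored at 1e-300")
        p_i <- pmax(p_i, 1e-300)
      }
      X <- -2 * sum(log(p_i))
      p <- stats::pchisq(X, df = 2 * k, lower.tail = FALSE)
    } else {
      in_path <- tested$ko %in% d$ko
      tab <- table(factor(tested$dep, c(FALSE, TRUE)),
                   factor(in_path, c(FALSE, TRUE)))
      ft <- stats::fisher.test(tab, alternative = "greater")
      X <- unname(ft$estimate)
      p <- ft$p.value
    }
    data.frame(pathway_id = d$pathway_id[1L],
               pathway_name = d$pathway_name[1L], n_proteins = k,
               statistic = X, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(pathway_id = character(0),
                      pathway_name = character(0),
                      n_proteins = integer(0), statistic = numeric(0),
                      p = numeric(0)))
  rownames(res) <- NULL
  res[order(res$p), , drop = FALSE]
}

#' Fisher's combined probability method
#'
#' X = -2 * sum(log(p)) compared to a chi-square distribution with 2k
#' degrees of freedom.
#'
#' @param p Vector of p-values.
#' @return Combined p-value.
#' @export
fisher_combined_p <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0), all(p <= 1))
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p),
                lower.tail = FALSE)
}

#' Screen for proteins tracking the PII nitrogen-stress protein
#'
#' Each protein's treatment-mean abundance profile is compared to the
#' PII (GlnK) profile: the Pearson correlation, and the ordinary
#' least-squares slope of the protein profile on the PII profile. The
#' slope is the plain OLS slope cor * sd(protein) / sd(PII), which is
#' invariant under any common within-strain normalization of the
#' abundance matrix and equals 1 when a protein's profile coincides
#' with PII's. Classification: positive when correlation >
#' `corr_threshold` and slope > `slope_threshold`; negative when
#' correlation < -`corr_threshold` and slope < -`slope_threshold`;
#' otherwise none. Constant profiles have undefined correlation and
#' class none.
#'
#' @param profiles Numeric matrix of treatment-mean abundances (log2
#'   scale recommended): proteins in rows, treatments in columns.
#' @param pii_id Row name of the PII protein.
#' @param corr_threshold Correlation threshold (default 0.75).
#' @param slope_threshold Slope threshold (default 2).
#' @return A `pii_screen` data.frame: `protein`, `correlation`,
#'   `slope`, `class`.
#' @export
pii_screen <- function(profiles, pii_id, corr_threshold = 0.75,
                       slope_threshold = 2) {
  stopifnot(is.matrix(profiles), pii_id %in% rownames(profiles),
            ncol(profiles) >= 3L)
  pii <- profiles[pii_id, ]
  if (any(is.na(pii)) || stats::sd(pii) < 1e-12)
    stop("PII profile must be complete and non-constant across ",
         "treatments")
  res <- data.frame(protein = rownames(profiles),
                    correlation = NA_real_, slope = NA_real_,
                    class = "none", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    if (any(is.na(p)) || stats::sd(p) < 1e-12) next
    r <- stats::cor(p, pii)
    res$correlation[i] <- r
    res$slope[i] <- r * stats::sd(p) / stats::sd(pii)
  }
  pos <- !is.na(res$correlation) & res$correlation > corr_threshold &
    res$slope > slope_threshold
  neg <- !is.na(res$correlation) & res$correlation < -corr_threshold &
    res$slope < -slope_threshold
  res$class[pos] <- "positive"
  res$class[neg] <- "negative"
  res$class[res$protein == pii_id] <- "none"   # PII itself is the anchor
  class(res) <- c("pii_screen", "data.frame")
  res
}

#' Treatment-mean abundance profiles from a proteomics matrix
#'
#' Per-protein mean of detected log2 intensities per treatment;
#' proteins must be detected at least `min_reps` times in every
#' treatment to receive a profile (others are dropped).
#'
#' @param pm A [proteomics_matrix()].
#' @param min_reps Detection filter per treatment.
#' @return Numeric matrix proteins x treatments (log2 scale).
#' @export
treatment_profiles <- function(pm, min_reps = 3L) {
  stopifnot(inherits(pm, "proteomics_matrix"))
  tr <- pm$metadata$treatment
  treats <- unique(tr)
  det <- sapply(treats, function(t1)
    rowSums(!is.na(pm$lfq[, tr == t1, drop = FALSE])))
  keep <- rowSums(det >= min_reps) == length(treats)
  prof <- sapply(treats, function(t1)
    rowMeans(log2(pm$lfq[keep, tr == t1, drop = FALSE]), na.rm = TRUE))
  rownames(prof) <- rownames(pm$lfq)[keep]
  prof
}

#' Write a comparison result to TSV
#' @param x A `comparison_result`.
#' @param path Output TSV path.
#' @export
write_comparison_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an LFQ matrix and metadata into a proteomics matrix
#'
#' @param lfq_path TSV with `protein_id` column then one column per
#'   sample.
#' @param meta_path TSV with `sample`, `treatment`, `replicate`.
#' @param strain Strain id.
#' @return A [proteomics_matrix()].
#' @export
read_proteomics_tsv <- function(lfq_path, meta_path, strain) {
  df <- utils::read.delim(lfq_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  rownames(m) <- df$protein_id
  proteomics_matrix(strain, m, meta)
}

#' Write an LFQ matrix and metadata
#' @param pm A [proteomics_matrix()].
#' @param lfq_path,meta_path Output TSV paths.
#' @export
write_proteomics_tsv <- function(pm, lfq_path, meta_path) {
  df <- data.frame(protein_id = rownames(pm$lfq), pm$lfq,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, lfq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pm$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(lfq_path)
}
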