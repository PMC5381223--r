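#' Match detected DMRs against planted truth
#'
#' A planted DMR counts as recovered when some detected DMR on the
#' same chromosome has reciprocal overlap of at least
#' `min_reciprocal` (overlap length relative to BOTH spans) and, if
#' directions are available, the matching direction. Detected DMRs
#' overlapping no planted span at all are false calls.
#'
#' @param dmrs Detected DMR tibble from [call_dmrs()].
#' @param planted Planted-DMR tibble (`chrom`, `start`, `end`,
#'   `direction`).
#' @param min_reciprocal Reciprocal-overlap threshold (default 0.5).
#' @return A list: `planted` (the truth tibble with `recovered` and
#'   `direction_ok` flags), `n_recovered`, `recall`, `n_false_calls`.
#' @export
evaluate_dmr_recovery <- function(dmrs, planted, min_reciprocal = 0.5) {
  recovered <- logical(nrow(planted))
  direction_ok <- logical(nrow(planted))
  touched <- logical(nrow(dmrs))
  for (i in seq_len(nrow(planted))) {
    dsel <- which(dmrs$chrom == planted$chrom[i])
    for (j in dsel) {
      ov <- min(dmrs$end[j], planted$end[i]) -
        max(dmrs$start[j], planted$start[i])
      if (ov <= 0) next
      touched[j] <- TRUE
      rec <- ov / (dmrs$end[j] - dmrs$start[j]) >= min_reciprocal &&
        ov / (planted$end[i] - planted$start[i]) >= min_reciprocal
      if (rec) {
        recovered[i] <- TRUE
        if (!is.null(planted[["direction"]]) &&
            dmrs$direction[j] == planted$direction[i]) {
          direction_ok[i] <- TRUE
        }
      }
    }
  }
  planted$recovered <- recovered
  planted$direction_ok <- direction_ok
  list(
    planted = planted,
    n_recovered = sum(recovered),
    recall = if (nrow(planted) > 0) mean(recovered) else NA_real_,
    n_false_calls = sum(!touched)
  )
}

#' Run the full simulated pipeline
#'
#' Chains every stage on synthetic data: simulate a genome, plant
#' hypermethylated DMRs over gene promoters (unless the config
#' already carries planted DMRs), simulate the two group reports and
#' spike-in, estimate the non-conversion rate, call sites, profile
#' methylation, scan for DMRs, map them to genes, join with the
#' simulated expression table, and apply the promoter-hypermethylation
#' candidate filter. Returns every intermediate product plus an
#' evaluation against the planted truth.
#'
#' @param config A [sim_config()].
#' @param dmr_cfg A [dmr_config()].
#' @param n_promoter_dmrs Number of genes given a planted promoter
#'   hyper-DMR when `config$planted_dmrs` is `NULL` (default 8).
#' @param delta_ml Methylation difference of those planted DMRs.
#' @return A list of class `methage_pipeline` with elements
#'   `config`, `genome_sim`, `reports`, `conversion`, `calls_g1`,
#'   `calls_g2`, `elements`, `profiles`, `scan`, `dmrs`, `dmgs`,
#'   `expression`, `traits`, `joint`, `candidates`, `evaluation`.
#' @export
run_pipeline <- function(config = sim_config(), dmr_cfg = dmr_config(),
                         n_promoter_dmrs = 8, delta_ml = 0.3) {
  genome_sim <- simulate_genome(config)
  planted_genes <- character(0)
  if (is.null(config$planted_dmrs) && n_promoter_dmrs > 0) {
    pd <- plant_promoter_dmrs(config, genome_sim, n_promoter_dmrs,
                              delta_ml = delta_ml)
    config$planted_dmrs <- pd
    planted_genes <- pd$gene_id
  } else if (!is.null(config$planted_dmrs)) {
    planted_genes <- config$planted_dmrs[["gene_id"]] %||% character(0)
  }
  reports <- simulate_cytosine_reports(config, genome_sim)
  conversion <- estimate_nonconversion_rate(reports$spikein)
  calls_g1 <- call_sites(reports$group1, conversion)
  calls_g2 <- call_sites(reports$group2, conversion)
  elements <- gene_elements(genome_sim$genes,
                            chrom_sizes = config$chrom_sizes)
  profiles <- list(
    composition_g1 = context_composition(calls_g1),
    composition_g2 = context_composition(calls_g2),
    chromosome_g1 = chromosome_levels(calls_g1),
    chromosome_g2 = chromosome_levels(calls_g2),
    features_g1 = feature_levels(calls_g1, elements,
                                 cgi = genome_sim$cgi,
                                 repeats = genome_sim$repeats),
    features_g2 = feature_levels(calls_g2, elements,
                                 cgi = genome_sim$cgi,
                                 repeats = genome_sim$repeats)
  )
  scan <- scan_dmr(calls_g1, calls_g2, config$chrom_sizes, dmr_cfg)
  expr <- simulate_expression(config, genome_sim)
  dmgs <- map_dmrs_to_genes(scan$dmrs, elements)
  joint <- overlap_dmg_deg(dmgs, expr$expression)
  candidates <- select_candidates(joint)
  truth <- reports$truth
  eval_dmr <- if (!is.null(truth$planted)) {
    evaluate_dmr_recovery(scan$dmrs, truth$planted)
  }
  planted_down <- expr$expression$gene_id[
    expr$expression$planted & expr$expression$de_flag %in% TRUE &
      expr$expression$direction %in% "Down"
  ]
  candidate_recall <- if (length(planted_genes) > 0) {
    mean(planted_genes %in% candidates$gene_id)
  } else {
    NA_real_
  }
  structure(
    list(
      config = config, genome_sim = genome_sim, reports = reports,
      conversion = conversion, calls_g1 = calls_g1, calls_g2 = calls_g2,
      elements = elements, profiles = profiles, scan = scan,
      dmrs = scan$dmrs, dmgs = dmgs, expression = expr$expression,
      traits = expr$traits, joint = joint, candidates = candidates,
      evaluation = list(
        dmr = eval_dmr,
        planted_genes = planted_genes,
        planted_down_genes = planted_down,
        candidate_recall = candidate_recall
      )
    ),
    class = "methage_pipeline"
  )
}

#' @export
print.methage_pipeline <- function(x, ...) {
  cat(sprintf(
    paste0("<methage_pipeline> %d genes, %s bp genome\n",
           "  non-conversion rate: %.4f (true %.4f)\n",
           "  %d DMRs, %d DMGs, %d joint DMG x DEG, %d candidates\n"),
    nrow(x$genome_sim$genes), format(sum(x$config$chrom_sizes),
                                     big.mark = ","),
    x$conversion$r, x$reports$truth$r_true,
    nrow(x$dmrs), nrow(x$dmgs), nrow(x$joint), nrow(x$candidates)
  ))
  if (!is.null(x$evaluation$dmr)) {
    cat(sprintf("  planted-DMR recall: %d/%d, false calls: %d\n",
                x$evaluation$dmr$n_recovered,
                nrow(x$evaluation$dmr$planted),
                x$evaluation$dmr$n_false_calls))
  }
  invisible(x)
}
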