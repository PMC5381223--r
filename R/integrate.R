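ELEMENT_ORDER <- c("promoter", "utr5", "exon", "intron", "utr3")

#' Map DMRs to genes (DMG records)
#'
#' A gene becomes a differentially methylated gene (DMG) when any of
#' its functional elements (promoter, 5'UTR, exon, intron, 3'UTR)
#' overlaps a DMR. Per gene, the overlapped element set is
#' deduplicated and ordered promoter, utr5, exon, intron, utr3; the
#' methylation direction is the majority direction of the supporting
#' DMRs, with ties reported as `"Hypo/hyper"`.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param elements Element tibble from [gene_elements()].
#' @return Tibble `gene_id`, `elements` (comma-separated),
#'   `methylation` (`Hyper`/`Hypo`/`Hypo/hyper`), `n_dmrs`,
#'   `dmr_ids` (semicolon-separated).
#' @export
map_dmrs_to_genes <- function(dmrs, elements) {
  empty <- tibble::tibble(gene_id = character(), elements = character(),
                          methylation = character(), n_dmrs = integer(),
                          dmr_ids = character())
  if (nrow(dmrs) == 0 || nrow(elements) == 0) return(empty)
  el <- elements[elements$element %in% ELEMENT_ORDER, ]
  pairs <- purrr::map(unique(el$chrom), function(cr) {
    dsel <- which(dmrs$chrom == cr)
    esel <- which(el$chrom == cr)
    if (length(dsel) == 0 || length(esel) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      as_iranges0(dmrs$start[dsel], dmrs$end[dsel]),
      as_iranges0(el$start[esel], el$end[esel])
    )
    if (length(hits) == 0) return(NULL)
    di <- dsel[S4Vectors::queryHits(hits)]
    ei <- esel[S4Vectors::subjectHits(hits)]
    tibble::tibble(
      gene_id = el$gene_id[ei], element = el$element[ei],
      dmr_id = dmrs$dmr_id[di], direction = dmrs$direction[di]
    )
  }) |> dplyr::bind_rows()
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      elements = paste(
        ELEMENT_ORDER[ELEMENT_ORDER %in% unique(.data$element)],
        collapse = ", "
      ),
      methylation = majority_direction(
        .data$direction[!duplicated(.data$dmr_id)]
      ),
      n_dmrs = dplyr::n_distinct(.data$dmr_id),
      dmr_ids = paste(unique(.data$dmr_id), collapse = ";"),
      .groups = "drop"
    )
}

#' @keywords internal
#' @noRd
majority_direction <- function(dirs) {
  n_hyper <- sum(dirs == "hyper")
  n_hypo <- sum(dirs == "hypo")
  if (n_hyper > n_hypo) "Hyper" else if (n_hypo > n_hyper) "Hypo"
  else "Hypo/hyper"
}

#' Join DMGs with differentially expressed genes
#'
#' Rows are the genes that are both differentially methylated and
#' differentially expressed; columns follow the standard joint-table
#' schema (gene, overlapped DMR elements, methylation direction,
#' expression regulation, group 2 vs group 1). DMG gene ids absent
#' from the expression table altogether are reported with a message
#' and excluded.
#'
#' @param dmgs DMG tibble from [map_dmrs_to_genes()].
#' @param expression Expression tibble with `gene_id`, `de_flag`,
#'   `direction` (see [read_expression_table()]).
#' @return Tibble `gene_id`, `elements`, `methylation`, `regulation`.
#' @export
overlap_dmg_deg <- function(dmgs, expression) {
  check_columns(expression, c("gene_id", "de_flag", "direction"),
                "expression table")
  missing <- setdiff(dmgs$gene_id, expression$gene_id)
  if (length(missing) > 0) {
    inform(sprintf(
      "%d DMG id(s) absent from the expression table, excluded: %s",
      length(missing), paste(head(missing, 5), collapse = ", ")
    ))
  }
  deg <- expression[expression$de_flag %in% TRUE,
                    c("gene_id", "direction")]
  dmgs |>
    dplyr::inner_join(deg, by = "gene_id") |>
    dplyr::rename(regulation = "direction") |>
    dplyr::select("gene_id", dplyr::any_of("gene_name"), "elements",
                  "methylation", "regulation")
}

#' Select promoter-methylation candidate genes
#'
#' Filters a joint DMG-by-DEG table down to candidate genes:
#' optionally requiring a promoter-overlapping DMR, a methylation
#' direction, and an expression regulation direction. The default
#' (`"Hyper"` + `"Down"`) selects genes whose promoter gained
#' methylation in group 2 with a concordant expression loss - the
#' classic promoter-silencing candidate. Filters are conjunctive, so
#' adding one can never enlarge the set; pass `NULL` to skip a
#' filter.
#'
#' @param joint Joint tibble from [overlap_dmg_deg()] (columns
#'   `gene_id`, `elements`, `methylation`, `regulation`).
#' @param require_promoter Keep only genes with a promoter element
#'   overlap (default `TRUE`).
#' @param methylation Required methylation direction (default
#'   `"Hyper"`; `NULL` to skip). The mixed label `"Hypo/hyper"` never
#'   matches a pure direction.
#' @param regulation Required expression direction (default
#'   `"Down"`; `NULL` to skip).
#' @return The filtered tibble.
#' @examples
#' example_dmg_deg_table() |>
#'   select_candidates(methylation = NULL, regulation = NULL)
#' @export
select_candidates <- function(joint, require_promoter = TRUE,
                              methylation = "Hyper",
                              regulation = "Down") {
  check_columns(joint, c("gene_id", "elements", "methylation",
                         "regulation"), "joint table")
  out <- joint
  if (require_promoter) {
    has_prom <- purrr::map_lgl(
      strsplit(out$elements, ",\\s*"), ~ "promoter" %in% .x
    )
    out <- out[has_prom, ]
  }
  if (!is.null(methylation)) out <- out[out$methylation %in% methylation, ]
  if (!is.null(regulation)) out <- out[out$regulation %in% regulation, ]
  out
}

#' Split genes into low/high expression classes per sample
#'
#' Within each sample, genes with positive FPKM are split at the
#' median positive FPKM: strictly above the median is `"high"`, at or
#' below (and all zero-FPKM genes) is `"low"`. The split is rank
#' based, hence invariant under monotone rescaling.
#'
#' @param expression Long tibble `gene_id`, `sample`, `fpkm`.
#' @return The input with an added `class` column.
#' @export
expression_class_split <- function(expression) {
  check_columns(expression, c("gene_id", "sample", "fpkm"),
                "expression table")
  if (all(expression$fpkm == 0)) {
    warn("all FPKM values are zero: every gene labelled 'low'")
  }
  expression |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(class = {
      pos <- .data$fpkm[.data$fpkm > 0]
      if (length(pos) == 0) {
        rep("low", dplyr::n())
      } else {
        ifelse(.data$fpkm > median(pos), "high", "low")
      }
    }) |>
    dplyr::ungroup()
}

#' Methylation level by expression class and gene element
#'
#' Computes each gene's mean corrected methylation level within each
#' of its five functional elements and context, then averages those
#' gene-level values within expression class. Elements with no
#' covered sites are absent (missing, not zero).
#'
#' @param calls Call tibble from [call_sites()].
#' @param elements Element tibble from [gene_elements()].
#' @param classes Tibble `gene_id`, `class` (from
#'   [expression_class_split()], one sample's labels).
#' @return Tibble `class`, `element`, `context`, `mean_ml`,
#'   `n_genes`.
#' @export
methylation_by_expression_class <- function(calls, elements, classes) {
  check_columns(classes, c("gene_id", "class"), "class table")
  el <- elements[elements$element %in% ELEMENT_ORDER, ]
  per_gene <- purrr::map(unique(el$chrom), function(cr) {
    esel <- which(el$chrom == cr)
    csel <- which(calls$chrom == cr)
    if (length(csel) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      as_iranges_pos(calls$pos[csel]),
      as_iranges0(el$start[esel], el$end[esel])
    )
    if (length(hits) == 0) return(NULL)
    si <- csel[S4Vectors::queryHits(hits)]
    ei <- esel[S4Vectors::subjectHits(hits)]
    tibble::tibble(
      gene_id = el$gene_id[ei], element = el$element[ei],
      context = calls$context[si], ml = calls$ml_corrected[si]
    )
  }) |>
    dplyr::bind_rows()
  if (nrow(per_gene) == 0) {
    return(tibble::tibble(class = character(), element = character(),
                          context = character(), mean_ml = numeric(),
                          n_genes = integer()))
  }
  per_gene |>
    dplyr::group_by(.data$gene_id, .data$element, .data$context) |>
    dplyr::summarise(ml = mean(.data$ml), .groups = "drop") |>
    dplyr::inner_join(classes[, c("gene_id", "class")], by = "gene_id") |>
    dplyr::group_by(.data$class, .data$element, .data$context) |>
    dplyr::summarise(mean_ml = mean(.data$ml),
                     n_genes = dplyr::n(), .groups = "drop")
}

#' Pearson correlation of gene expression with traits
#'
#' Correlates each gene's expression vector across samples (or
#' groups) with each trait's vector across the same samples. Cells
#' with fewer than 2 complete pairs or zero variance in either vector
#' are `NA`; the number of pairs is reported per cell so users can
#' judge power (a pooled two-group design gives only n = 2). A
#' warning is raised when any cell has fewer than 3 pairs.
#'
#' @param expression Long tibble `gene_id`, `sample`, `fpkm`.
#' @param traits Long tibble `sample`, `trait`, `value`.
#' @return Tibble `gene_id`, `trait`, `r`, `n`.
#' @export
trait_correlation <- function(expression, traits) {
  check_columns(expression, c("gene_id", "sample", "fpkm"),
                "expression table")
  check_columns(traits, c("sample", "trait", "value"), "trait table")
  grid <- tidyr::expand_grid(gene_id = unique(expression$gene_id),
                             trait = unique(traits$trait))
  out <- purrr::pmap(grid, function(gene_id, trait) {
    e <- expression[expression$gene_id == gene_id, c("sample", "fpkm")]
    t <- traits[traits$trait == trait, c("sample", "value")]
    m <- dplyr::inner_join(e, t, by = "sample")
    m <- m[complete.cases(m), ]
    n <- nrow(m)
    r <- if (n >= 2 && sd(m$fpkm) > 0 && sd(m$value) > 0) {
      cor(m$fpkm, m$value)
    } else {
      NA_real_
    }
    tibble::tibble(gene_id = gene_id, trait = trait, r = r, n = n)
  }) |> dplyr::bind_rows()
  if (any(out$n < 3)) {
    warn("some gene-trait cells have fewer than 3 paired observations")
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per condition, `dCt = Ct_target - Ct_ref`; relative to the
#' calibrator condition, `ddCt = dCt - dCt_calibrator` and the fold
#' change is `2^-ddCt`.
#'
#' @param ct_table Tibble `condition`, `ct_target`, `ct_ref` (one row
#'   per condition).
#' @param calibrator Condition used as the calibrator (default: the
#'   first row).
#' @return The input with added `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' relative_expression(
#'   tibble::tibble(condition = c("g1", "g2"),
#'                  ct_target = c(24, 27), ct_ref = c(18, 19))
#' )
#' @export
relative_expression <- function(ct_table, calibrator = NULL) {
  check_columns(ct_table, c("condition", "ct_target", "ct_ref"),
                "Ct table")
  if (any(is.na(ct_table$ct_ref))) {
    abort("missing reference Ct: cannot compute delta Ct")
  }
  calibrator <- calibrator %||% ct_table$condition[1]
  if (!calibrator %in% ct_table$condition) {
    abort(sprintf("calibrator '%s' not among conditions", calibrator))
  }
  dct <- ct_table$ct_target - ct_table$ct_ref
  ddct <- dct - dct[ct_table$condition == calibrator][1]
  ct_table |>
    dplyr::mutate(delta_ct = dct, delta_delta_ct = ddct,
                  fold = 2^(-ddct))
}
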