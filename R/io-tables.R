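#' Read a per-gene expression table
#'
#' Expects a tab-separated table with a header and columns `gene_id`,
#' `fpkm_g1`, `fpkm_g2`, `de_flag` (logical), `direction`
#' (`Up`/`Down` for group 2 vs group 1, `NA` for non-DE genes).
#' Extra columns are kept.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_expression_table <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols())
  check_columns(df, c("gene_id", "fpkm_g1", "fpkm_g2", "de_flag"),
                "expression table")
  if (any(df$fpkm_g1 < 0, na.rm = TRUE) || any(df$fpkm_g2 < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative")
  }
  df$de_flag <- as.logical(df$de_flag)
  df
}

#' Read a trait table
#'
#' Long format with header: `sample` (or group), `trait`, `value`.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_trait_table <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols())
  check_columns(df, c("sample", "trait", "value"), "trait table")
  df
}

#' Example joint table of differentially methylated and expressed genes
#'
#' Loads the bundled example joint DMG-by-DEG table (18 genes from a
#' published hen breast-muscle methylation study at two age stages),
#' in the schema produced by [overlap_dmg_deg()]: `gene_id`,
#' `gene_name`, `elements` (comma-separated overlapped gene elements),
#' `methylation` (`Hyper`/`Hypo`/`Hypo/hyper`, group 2 vs group 1) and
#' `regulation` (`Up`/`Down`).
#'
#' @return A tibble with 18 rows.
#' @examples
#' example_dmg_deg_table() |> select_candidates()
#' @export
example_dmg_deg_table <- function() {
  path <- system.file("extdata", "dmg_deg_joint.tsv", package = "methage",
                      mustWork = TRUE)
  readr::read_tsv(path, progress = FALSE, col_types = "ccccc")
}
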