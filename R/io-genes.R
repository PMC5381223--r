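#' Read BED12 gene models
#'
#' Reads a BED12 table (0-based half-open coordinates) into one row per
#' gene, with exon blocks as a list-column of two-column tibbles
#' (`start`, `end`). `thickStart`/`thickEnd` are taken as the CDS span;
#' a zero-width thick region marks a non-coding transcript.
#'
#' @param path Path to a BED12 file (tab-separated, no header).
#' @return A tibble with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end` and list-column
#'   `exons`.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "thickStart", "thickEnd", "itemRgb", "blockCount",
                  "blockSizes", "blockStarts"),
    col_types = "ciiciciicicc",
    progress = FALSE
  )
  parse_gene_models(df)
}

#' @keywords internal
#' @noRd
parse_gene_models <- function(df) {
  check_columns(df, c("chrom", "start", "end", "name", "strand",
                      "thickStart", "thickEnd", "blockCount",
                      "blockSizes", "blockStarts"),
                "gene model table")
  if (any(!(df$strand %in% c("+", "-")))) {
    abort("gene model with unknown strand (must be '+' or '-')")
  }
  exons <- purrr::pmap(
    list(df$start, df$blockSizes, df$blockStarts, df$name),
    function(start, sizes, offsets, name) {
      sz <- as.integer(strsplit(sub(",$", "", sizes), ",")[[1]])
      of <- as.integer(strsplit(sub(",$", "", offsets), ",")[[1]])
      if (length(sz) != length(of)) {
        abort(sprintf("gene '%s': blockSizes/blockStarts length mismatch", name))
      }
      ex_start <- start + of
      ex <- tibble::tibble(start = ex_start, end = ex_start + sz)
      ex <- ex[order(ex$start), ]
      if (any(ex$start[-1] < ex$end[-nrow(ex)])) {
        abort(sprintf("gene '%s': overlapping exon blocks", name))
      }
      ex
    }
  )
  tibble::tibble(
    gene_id = df$name,
    chrom = df$chrom,
    strand = df$strand,
    tx_start = df$start,
    tx_end = df$end,
    cds_start = df$thickStart,
    cds_end = df$thickEnd,
    exons = exons
  )
}

#' Write gene models as BED12
#'
#' @param genes Gene tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  bed <- tibble::tibble(
    chrom = genes$chrom,
    start = genes$tx_start,
    end = genes$tx_end,
    name = genes$gene_id,
    score = 0L,
    strand = genes$strand,
    thickStart = genes$cds_start,
    thickEnd = genes$cds_end,
    itemRgb = "0",
    blockCount = purrr::map_int(genes$exons, nrow),
    blockSizes = purrr::map_chr(
      genes$exons, ~ paste0(paste(.x$end - .x$start, collapse = ","), ",")
    ),
    blockStarts = purrr::map2_chr(
      genes$exons, genes$tx_start,
      ~ paste0(paste(.x$start - .y, collapse = ","), ",")
    )
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Intersect sorted exon intervals with a [s, e) span.
#' @keywords internal
#' @noRd
intersect_span <- function(iv, s, e) {
  out <- tibble::tibble(start = pmax(iv$start, s), end = pmin(iv$end, e))
  out[out$end > out$start, , drop = FALSE]
}

#' Derive functional elements from gene models
#'
#' Decomposes each gene into promoter, 5'UTR, exon, intron and 3'UTR
#' intervals (0-based half-open). The promoter is the
#' `promoter_width` bp immediately upstream of the transcription start
#' site, strand-aware and clipped at the chromosome boundary. UTRs are
#' the exonic portions outside the CDS span; introns are the gaps
#' between consecutive exons. Non-coding genes (zero-width CDS) get no
#' UTR intervals.
#'
#' @param genes Gene tibble from [read_gene_models()].
#' @param promoter_width Promoter size in bp upstream of the TSS
#'   (default 2000).
#' @param chrom_sizes Optional named vector of chromosome lengths, used
#'   to clip promoters of minus-strand genes at the chromosome end.
#' @return Tibble with columns `gene_id`, `element` (one of `promoter`,
#'   `utr5`, `exon`, `intron`, `utr3`), `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' g <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", strand = "+",
#'   tx_start = 5000L, tx_end = 8000L, cds_start = 5500L, cds_end = 7500L,
#'   exons = list(tibble::tibble(start = c(5000L, 6000L, 7000L),
#'                               end = c(5600L, 6400L, 8000L)))
#' )
#' gene_elements(g)
#' @export
gene_elements <- function(genes, promoter_width = 2000, chrom_sizes = NULL) {
  check_columns(genes, c("gene_id", "chrom", "strand", "tx_start", "tx_end",
                         "cds_start", "cds_end", "exons"),
                "gene table")
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$strand, genes$tx_start,
         genes$tx_end, genes$cds_start, genes$cds_end, genes$exons),
    function(id, chrom, strand, txs, txe, cdss, cdse, ex) {
      pieces <- list()
      if (strand == "+") {
        prom <- c(max(0, txs - promoter_width), txs)
      } else {
        pe <- txe + promoter_width
        if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
          pe <- min(pe, unname(chrom_sizes[chrom]))
        }
        prom <- c(txe, pe)
      }
      if (prom[2] > prom[1]) {
        pieces$promoter <- tibble::tibble(start = prom[1], end = prom[2])
      }
      pieces$exon <- ex
      if (nrow(ex) > 1) {
        pieces$intron <- tibble::tibble(
          start = ex$end[-nrow(ex)], end = ex$start[-1]
        )
      }
      coding <- cdse > cdss
      if (coding) {
        left <- intersect_span(ex, txs, cdss)
        right <- intersect_span(ex, cdse, txe)
        if (strand == "+") {
          pieces$utr5 <- left
          pieces$utr3 <- right
        } else {
          pieces$utr5 <- right
          pieces$utr3 <- left
        }
      }
      pieces <- pieces[purrr::map_int(pieces, nrow) > 0]
      dplyr::bind_rows(pieces, .id = "element") |>
        dplyr::mutate(gene_id = id, chrom = chrom, strand = strand)
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_id = character(), element = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  out |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    dplyr::select("gene_id", "element", "chrom", "start", "end", "strand")
}

#' Intergenic complement of gene spans and promoters
#'
#' @param elements Element tibble from [gene_elements()].
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Tibble `chrom`, `start`, `end` of intervals covered by no
#'   gene span or promoter (0-based half-open).
#' @export
intergenic_track <- function(elements, chrom_sizes) {
  purrr::imap(as.list(chrom_sizes), function(size, chrom) {
    iv <- elements[elements$chrom == chrom, ]
    complement_intervals(iv$start, iv$end, size) |>
      dplyr::mutate(chrom = chrom, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Read a BED3 interval track (e.g. CpG islands or repeats)
#'
#' @param path Path to a 3+ column BED file (no header).
#' @return Tibble `chrom`, `start`, `end`, per-chromosome sorted and
#'   merged.
#' @export
read_bed3 <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        col_types = readr::cols())
  if (ncol(df) < 3) abort(sprintf("'%s' has fewer than 3 columns", path))
  df <- tibble::tibble(chrom = as.character(df[[1]]),
                       start = as.integer(df[[2]]),
                       end = as.integer(df[[3]]))
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(merge_intervals(.data$start, .data$end))
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (`-log10(fdr)` capped at
#' 1000), strand (`.`), then `ml_g1`, `ml_g2`, `fold_change`,
#' `p_value`, `fdr`, `direction`. Coordinates are 0-based half-open. A
#' header line prefixed with `#` names the columns.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  header <- paste0("#", paste(
    c("chrom", "start", "end", "name", "score", "strand",
      "ml_g1", "ml_g2", "fold_change", "p_value", "fdr", "direction"),
    collapse = "\t"
  ))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dmrs) == 0) return(invisible(path))
  check_columns(dmrs, c("chrom", "start", "end", "ml_g1", "ml_g2",
                        "fold_change", "p_value", "fdr", "direction"),
                "DMR table")
  name <- dmrs$dmr_id %||% sprintf("dmr_%04d", seq_len(nrow(dmrs)))
  score <- round(pmin(1000, -log10(pmax(dmrs$fdr, 1e-300))), 3)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t.\t%s\t%s\t%s\t%s\t%s\t%s",
    dmrs$chrom, dmrs$start, dmrs$end, name,
    format(score, trim = TRUE),
    format(dmrs$ml_g1, digits = 15, trim = TRUE, scientific = FALSE),
    format(dmrs$ml_g2, digits = 15, trim = TRUE, scientific = FALSE),
    format(dmrs$fold_change, digits = 15, trim = TRUE, scientific = FALSE),
    format(dmrs$p_value, digits = 15, trim = TRUE),
    format(dmrs$fdr, digits = 15, trim = TRUE),
    dmrs$direction
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED6+ DMR file written by [write_dmr_bed()]
#'
#' @param path Path to the file.
#' @return Tibble with the DMR columns (`chrom`, `start`, `end`,
#'   `dmr_id`, `ml_g1`, `ml_g2`, `fold_change`, `p_value`, `fdr`,
#'   `direction`).
#' @export
read_dmr_bed <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_names = c("chrom", "start", "end", "dmr_id", "score", "strand",
                  "ml_g1", "ml_g2", "fold_change", "p_value", "fdr",
                  "direction"),
    col_types = "ciicdcdddddc"
  )
  df |>
    dplyr::select("chrom", "start", "end", "dmr_id", "ml_g1", "ml_g2",
                  "fold_change", "p_value", "fdr", "direction")
}
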