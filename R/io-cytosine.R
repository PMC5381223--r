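#' Read a Bismark-style per-cytosine report
#'
#' Parses a 7-column tab-separated cytosine report in the dialect of the
#' Bismark CX report: chromosome, 1-based position, strand (`+`/`-`),
#' methylated read count, unmethylated read count, context
#' (`CG`/`CHG`/`CHH`), trinucleotide. One row per strand-specific
#' cytosine; no header line.
#'
#' @param path Path to the report file.
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`,
#'   `n_meth`, `n_unmeth`, `context`, `trinucleotide`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("chr1\t101\t+\t5\t5\tCG\tCGT", tf)
#' read_cytosine_report(tf)
#' @export
read_cytosine_report <- function(path) {
  # parse issues are collected via readr::problems() and re-raised as
  # one error naming the first offending line
  df <- suppressWarnings(readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                  "context", "trinucleotide"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      n_meth = readr::col_integer(),
      n_unmeth = readr::col_integer(),
      context = readr::col_character(),
      trinucleotide = readr::col_character()
    ),
    progress = FALSE
  ))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "malformed cytosine report '%s': %d bad field(s), first at line %d (%s)",
      path, nrow(prob), prob$row[1], prob$expected[1]
    ))
  }
  bad <- which(!(df$context %in% c("CG", "CHG", "CHH")))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown context token '%s' at line %d of '%s'",
      df$context[bad[1]], bad[1], path
    ))
  }
  bad <- which(df$n_meth < 0 | df$n_unmeth < 0 | df$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("negative count or position at line %d of '%s'", bad[1], path))
  }
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown strand '%s' at line %d of '%s'", df$strand[bad[1]], bad[1], path
    ))
  }
  df
}

#' Write a per-cytosine report
#'
#' Inverse of [read_cytosine_report()]: writes the 7-column
#' tab-separated dialect with 1-based positions and no header.
#'
#' @param records Tibble with the columns returned by
#'   [read_cytosine_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  check_columns(records, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                           "context", "trinucleotide"),
                "cytosine record table")
  readr::write_tsv(
    records[, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                "context", "trinucleotide")],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}
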