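#' @keywords internal
#' @noRd
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Merge 0-based half-open intervals on one chromosome; `gap` joins
# intervals separated by at most `gap` bp (gap = 0 merges abutting only
# when they touch or overlap).
#' @keywords internal
#' @noRd
merge_intervals <- function(start, end, gap = 0) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Complement of merged 0-based half-open intervals within [0, size).
#' @keywords internal
#' @noRd
complement_intervals <- function(start, end, size) {
  m <- merge_intervals(pmax(start, 0), pmin(end, size))
  keep <- m$end > m$start
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble::tibble(start = 0L, end = as.integer(size)))
  }
  gaps_s <- c(0, m$end)
  gaps_e <- c(m$start, size)
  keep <- gaps_e > gaps_s
  tibble::tibble(start = as.integer(gaps_s[keep]), end = as.integer(gaps_e[keep]))
}

# IRanges view of a 0-based half-open interval table (columns start, end).
#' @keywords internal
#' @noRd
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# IRanges view of 1-based point positions.
#' @keywords internal
#' @noRd
as_iranges_pos <- function(pos) {
  IRanges::IRanges(start = pos, width = 1L)
}

#' @keywords internal
#' @noRd
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' @keywords internal
#' @noRd
reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
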