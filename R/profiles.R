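#' Context composition of methylcytosines
#'
#' Two normalisations, reported side by side: `fraction_of_mc`, the
#' share of each sequence context among called methylcytosines (the
#' composition of the methylome), and `meth_rate`, the fraction of
#' covered cytosines of that context that are called methylated
#' (e.g. mCG / CG).
#'
#' @param calls Call tibble from [call_sites()].
#' @return Tibble `context`, `n_sites`, `n_methylated`,
#'   `fraction_of_mc`, `meth_rate`.
#' @export
context_composition <- function(calls) {
  check_columns(calls, c("context", "is_methylated"), "call table")
  out <- calls |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_methylated = sum(.data$is_methylated),
      .groups = "drop"
    )
  total_mc <- sum(out$n_methylated)
  if (total_mc == 0) {
    warn("no methylated sites: composition fractions are undefined (NA)")
    out$fraction_of_mc <- NA_real_
  } else {
    out$fraction_of_mc <- out$n_methylated / total_mc
  }
  out$meth_rate <- out$n_methylated / out$n_sites
  out
}

#' Mean methylation level per chromosome and context
#'
#' Chromosomes with no covered sites are simply absent from the
#' output (missing, not zero).
#'
#' @param calls Call tibble from [call_sites()].
#' @return Tibble `chrom`, `context`, `mean_ml`, `n_sites`.
#' @export
chromosome_levels <- function(calls) {
  check_columns(calls, c("chrom", "context", "ml_corrected"), "call table")
  calls |>
    dplyr::group_by(.data$chrom, .data$context) |>
    dplyr::summarise(
      mean_ml = mean(.data$ml_corrected),
      n_sites = dplyr::n(), .groups = "drop"
    )
}

# Single-label class per site under the precedence
# promoter > utr5 > utr3 > exon > intron > CGI > repeat > intergenic.
#' @keywords internal
#' @noRd
assign_site_class <- function(calls, elements, cgi = NULL, repeats = NULL) {
  cls <- rep(NA_character_, nrow(calls))
  tracks <- list()
  for (el in c("promoter", "utr5", "utr3", "exon", "intron")) {
    tracks[[el]] <- elements[elements$element == el,
                             c("chrom", "start", "end")]
  }
  if (!is.null(cgi)) tracks[["CGI"]] <- cgi[, c("chrom", "start", "end")]
  if (!is.null(repeats)) {
    tracks[["repeat"]] <- repeats[, c("chrom", "start", "end")]
  }
  for (name in names(tracks)) {
    iv <- tracks[[name]]
    if (nrow(iv) == 0) next
    open <- is.na(cls)
    if (!any(open)) break
    hit <- point_in_track(calls$chrom[open], calls$pos[open], iv)
    cls[open][hit] <- name
  }
  cls[is.na(cls)] <- "intergenic"
  cls
}

#' Mean methylation level per functional element class
#'
#' With `disjoint = TRUE` (default) each covered site is counted
#' exactly once under the highest-precedence class covering it
#' (promoter > 5'UTR > 3'UTR > exon > intron > CGI > repeat >
#' intergenic), so class counts partition the call set. With
#' `disjoint = FALSE` every class is summarised over its full site
#' set, so a site may contribute to several classes (the usual way
#' CGI and repeat tracks are plotted alongside gene elements).
#'
#' @param calls Call tibble from [call_sites()].
#' @param elements Element tibble from [gene_elements()].
#' @param cgi,repeats Optional BED3-like tibbles (`chrom`, `start`,
#'   `end`).
#' @param disjoint Single-label precedence assignment (default) or
#'   multi-label.
#' @return Tibble `class`, `context`, `mean_ml`, `n_sites`.
#' @export
feature_levels <- function(calls, elements, cgi = NULL, repeats = NULL,
                           disjoint = TRUE) {
  check_columns(calls, c("chrom", "pos", "context", "ml_corrected"),
                "call table")
  if (disjoint) {
    calls$class <- assign_site_class(calls, elements, cgi, repeats)
    return(
      calls |>
        dplyr::group_by(.data$class, .data$context) |>
        dplyr::summarise(mean_ml = mean(.data$ml_corrected),
                         n_sites = dplyr::n(), .groups = "drop")
    )
  }
  tracks <- purrr::map(
    setNames(c("promoter", "utr5", "utr3", "exon", "intron"),
             c("promoter", "utr5", "utr3", "exon", "intron")),
    ~ elements[elements$element == .x, c("chrom", "start", "end")]
  )
  if (!is.null(cgi)) tracks[["CGI"]] <- cgi
  if (!is.null(repeats)) tracks[["repeat"]] <- repeats
  purrr::imap(tracks, function(iv, name) {
    if (nrow(iv) == 0) return(NULL)
    sel <- point_in_track(calls$chrom, calls$pos, iv)
    if (!any(sel)) return(NULL)
    calls[sel, ] |>
      dplyr::group_by(.data$context) |>
      dplyr::summarise(mean_ml = mean(.data$ml_corrected),
                       n_sites = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(class = name, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Metagene methylation profile around gene bodies
#'
#' Bins each gene's upstream flank, length-normalised body, and
#' downstream flank into `flank_bins + body_bins + flank_bins`
#' positions (5' to 3'; minus-strand genes are flipped) and averages
#' corrected methylation levels per bin and context over all genes.
#'
#' @param calls Call tibble from [call_sites()].
#' @param genes Gene tibble from [read_gene_models()].
#' @param flank Flank size in bp (default 2000).
#' @param flank_bins,body_bins Bin counts for each flank and for the
#'   gene body (defaults 20 and 60).
#' @return Tibble `context`, `bin` (1-based, 5' to 3'), `zone`
#'   (`upstream`/`body`/`downstream`), `mean_ml`, `n_sites`.
#' @export
metagene_profile <- function(calls, genes, flank = 2000, flank_bins = 20,
                             body_bins = 60) {
  check_columns(calls, c("chrom", "pos", "context", "ml_corrected"),
                "call table")
  short <- (genes$tx_end - genes$tx_start) < body_bins
  if (any(short)) {
    warn(sprintf("%d gene(s) shorter than body_bins excluded", sum(short)))
    genes <- genes[!short, ]
  }
  n_bins <- 2 * flank_bins + body_bins
  pieces <- purrr::pmap(
    list(genes$chrom, genes$strand, genes$tx_start, genes$tx_end),
    function(chrom, strand, txs, txe) {
      sel <- calls$chrom == chrom & calls$pos > txs - flank &
        calls$pos <= txe + flank
      if (!any(sel)) return(NULL)
      pos0 <- calls$pos[sel] - 1L
      len <- txe - txs
      if (strand == "+") {
        bin <- dplyr::case_when(
          pos0 < txs ~ floor((pos0 - (txs - flank)) / flank * flank_bins),
          pos0 >= txe ~ flank_bins + body_bins +
            floor((pos0 - txe) / flank * flank_bins),
          TRUE ~ flank_bins + pmin(body_bins - 1,
                                   floor((pos0 - txs) / len * body_bins))
        )
      } else {
        bin <- dplyr::case_when(
          pos0 >= txe ~ flank_bins - 1 -
            floor((pos0 - txe) / flank * flank_bins),
          pos0 < txs ~ flank_bins + body_bins +
            floor((txs - 1 - pos0) / flank * flank_bins),
          TRUE ~ flank_bins + pmin(body_bins - 1,
                                   floor((txe - 1 - pos0) / len * body_bins))
        )
      }
      tibble::tibble(context = calls$context[sel],
                     ml = calls$ml_corrected[sel],
                     bin = as.integer(bin) + 1L)
    }
  )
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble::tibble(context = character(), bin = integer(),
                          zone = character(), mean_ml = numeric(),
                          n_sites = integer()))
  }
  out |>
    dplyr::filter(.data$bin >= 1, .data$bin <= n_bins) |>
    dplyr::group_by(.data$context, .data$bin) |>
    dplyr::summarise(mean_ml = mean(.data$ml), n_sites = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(zone = dplyr::case_when(
      .data$bin <= flank_bins ~ "upstream",
      .data$bin <= flank_bins + body_bins ~ "body",
      TRUE ~ "downstream"
    ), .after = "bin")
}

#' Base composition around methylcytosines
#'
#' Tabulates the bases at offsets `-k .. +k` around every called
#' methylcytosine (9 positions for the default `k = 4`), reading the
#' reverse complement for minus-strand sites. Sites within `k` bp of a
#' chromosome edge are skipped.
#'
#' @param calls Call tibble from [call_sites()] (only rows with
#'   `is_methylated` are used).
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param k Window half-width (default 4).
#' @return Tibble `context`, `offset`, `base`, `count`, `freq` (the
#'   frequency within each context and offset).
#' @export
neighbor_base_context <- function(calls, genome, k = 4) {
  check_columns(calls, c("chrom", "pos", "strand", "context",
                         "is_methylated"), "call table")
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  mc <- calls[calls$is_methylated, ]
  pieces <- purrr::map(unique(mc$chrom), function(chrom) {
    if (!chrom %in% names(genome)) return(NULL)
    seq_chr <- as.character(genome[[chrom]])
    len <- nchar(seq_chr)
    sub <- mc[mc$chrom == chrom, ]
    sub <- sub[sub$pos - k >= 1 & sub$pos + k <= len, ]
    if (nrow(sub) == 0) return(NULL)
    win <- substring(seq_chr, sub$pos - k, sub$pos + k)
    neg <- sub$strand == "-"
    if (any(neg)) win[neg] <- reverse_complement_chr(win[neg])
    mat <- matrix(unlist(strsplit(win, "")), ncol = 2 * k + 1, byrow = TRUE)
    purrr::map(seq_len(2 * k + 1), function(j) {
      tibble::tibble(context = sub$context, offset = j - k - 1L,
                     base = mat[, j])
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble::tibble(context = character(), offset = integer(),
                          base = character(), count = integer(),
                          freq = numeric()))
  }
  out |>
    dplyr::count(.data$context, .data$offset, .data$base, name = "count") |>
    dplyr::group_by(.data$context, .data$offset) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}
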