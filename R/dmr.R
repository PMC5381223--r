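#' DMR scan configuration
#'
#' Defaults follow the standard pooled-WGBS sliding-window scan:
#' 1000 bp windows advanced in 100 bp steps; windows are kept as
#' significant when the two-sided Fisher p-value is below `p_max`,
#' the Benjamini-Hochberg FDR across all tested windows is below
#' `fdr_max`, the corrected-level fold change exceeds
#' `min_fold_change`, and mean depth per covered cytosine exceeds
#' `min_coverage` in both groups.
#'
#' @param window Window size in bp.
#' @param step Step length in bp (must not exceed `window`).
#' @param p_max Raw p-value threshold.
#' @param min_coverage Minimum mean depth per covered site, per group.
#' @param min_fold_change Minimum fold change between group levels.
#' @param fdr_max BH FDR threshold.
#' @param epsilon Pseudocount added to both levels before the ratio.
#' @return A list of class `dmr_config`.
#' @export
dmr_config <- function(window = 1000L, step = 100L, p_max = 0.05,
                       min_coverage = 5, min_fold_change = 2,
                       fdr_max = 0.05, epsilon = 1e-6) {
  if (step <= 0 || window <= 0) abort("window and step must be positive")
  if (step > window) {
    abort("step must not exceed window (gaps would break the scan)")
  }
  structure(
    list(window = as.integer(window), step = as.integer(step),
         p_max = p_max, min_coverage = min_coverage,
         min_fold_change = min_fold_change, fdr_max = fdr_max,
         epsilon = epsilon),
    class = "dmr_config"
  )
}

#' Enumerate sliding windows over chromosomes
#'
#' Window starts are `0, step, 2 * step, ...` with
#' `start + window <= length`; a chromosome shorter than `window`
#' yields a single window covering it entirely.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Window size in bp (default 1000).
#' @param step Step length in bp (default 100).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' generate_windows(c(chr1 = 1200), 1000, 100)
#' @export
generate_windows <- function(chrom_sizes, window = 1000L, step = 100L) {
  if (step <= 0 || window <= 0) abort("window and step must be positive")
  if (step > window) {
    abort("step must not exceed window (gaps would break the scan)")
  }
  purrr::imap(as.list(chrom_sizes), function(size, chrom) {
    if (size < window) {
      return(tibble::tibble(chrom = chrom, start = 0L,
                            end = as.integer(size)))
    }
    starts <- seq.int(0L, as.integer(size - window), by = as.integer(step))
    tibble::tibble(chrom = chrom, start = starts,
                   end = starts + as.integer(window))
  }) |> dplyr::bind_rows()
}

#' Two-group test of one window's pooled counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of pooled
#' methylated/unmethylated counts, plus the direction-free fold
#' change of the pooled methylation levels
#' (`(ml2 + eps) / (ml1 + eps)` or its reciprocal, whichever is
#' >= 1).
#'
#' @param m1,u1 Pooled methylated/unmethylated counts, group 1.
#' @param m2,u2 Pooled methylated/unmethylated counts, group 2.
#' @param epsilon Pseudocount for the level ratio.
#' @return One-row tibble `p_value`, `fold_change`.
#' @examples
#' test_window(50, 50, 50, 50) # p = 1, fold_change = 1
#' @export
test_window <- function(m1, u1, m2, u2, epsilon = 1e-6) {
  if (min(m1, u1, m2, u2) < 0) abort("counts must be non-negative")
  if (m1 + u1 + m2 + u2 == 0) {
    abort("both groups have zero depth: window cannot be tested")
  }
  p <- fisher.test(matrix(c(m1, u1, m2, u2), nrow = 2, byrow = TRUE))$p.value
  ml1 <- if (m1 + u1 > 0) m1 / (m1 + u1) else 0
  ml2 <- if (m2 + u2 > 0) m2 / (m2 + u2) else 0
  ratio <- (ml2 + epsilon) / (ml1 + epsilon)
  tibble::tibble(p_value = p, fold_change = max(ratio, 1 / ratio))
}

# Aggregate one group's calls into windows. Returns one row per
# window index with pooled counts, covered-site count, mean corrected
# level and mean depth per covered site.
#' @keywords internal
#' @noRd
window_group_stats <- function(calls, windows) {
  out <- tibble::tibble(
    win = seq_len(nrow(windows)),
    n_meth = 0, n_unmeth = 0, n_sites = 0L, mean_ml = NA_real_,
    mean_depth = 0
  )
  for (cr in unique(windows$chrom)) {
    wsel <- which(windows$chrom == cr)
    csel <- which(calls$chrom == cr)
    if (length(csel) == 0) next
    hits <- IRanges::findOverlaps(
      as_iranges_pos(calls$pos[csel]),
      as_iranges0(windows$start[wsel], windows$end[wsel])
    )
    if (length(hits) == 0) next
    si <- csel[S4Vectors::queryHits(hits)]
    wi <- wsel[S4Vectors::subjectHits(hits)]
    agg <- tibble::tibble(
      win = wi,
      n_meth = calls$n_meth[si], n_unmeth = calls$n_unmeth[si],
      ml = calls$ml_corrected[si]
    ) |>
      dplyr::group_by(.data$win) |>
      dplyr::summarise(
        n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
        n_sites = dplyr::n(), mean_ml = mean(.data$ml), .groups = "drop"
      )
    out$n_meth[agg$win] <- agg$n_meth
    out$n_unmeth[agg$win] <- agg$n_unmeth
    out$n_sites[agg$win] <- agg$n_sites
    out$mean_ml[agg$win] <- agg$mean_ml
  }
  out$mean_depth <- ifelse(out$n_sites > 0,
                           (out$n_meth + out$n_unmeth) / out$n_sites, 0)
  out
}

#' Sliding-window differential methylation scan
#'
#' Pools per-site counts of each group within every sliding window,
#' tests each covered window with a two-sided Fisher's exact test,
#' adjusts p-values with Benjamini-Hochberg across all tested
#' windows, computes the corrected-level fold change, and merges
#' significant windows into DMRs (see [call_dmrs()]). The scan runs
#' within one sequence context (CG by default) so sparse CHG/CHH
#' signal cannot be diluted by CG sites.
#'
#' @param calls_g1,calls_g2 Call tibbles from [call_sites()] for the
#'   two groups.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param config A [dmr_config()].
#' @param context Sequence context to scan (default `"CG"`).
#' @return An object of class `dmr_scan`: a list with `windows` (all
#'   tested windows with counts, levels, `p_value`, `fdr`,
#'   `fold_change`, `significant`), `dmrs` (merged DMR tibble),
#'   `config`, `context` and `chrom_sizes`.
#' @export
scan_dmr <- function(calls_g1, calls_g2, chrom_sizes,
                     config = dmr_config(), context = "CG") {
  stopifnot(inherits(config, "dmr_config"))
  g1 <- calls_g1[calls_g1$context == context, ]
  g2 <- calls_g2[calls_g2$context == context, ]
  windows <- generate_windows(chrom_sizes, config$window, config$step)
  s1 <- window_group_stats(g1, windows)
  s2 <- window_group_stats(g2, windows)
  tested <- which(s1$n_meth + s1$n_unmeth + s2$n_meth + s2$n_unmeth > 0)
  w <- windows[tested, ]
  w$n_meth_g1 <- s1$n_meth[tested]
  w$n_unmeth_g1 <- s1$n_unmeth[tested]
  w$n_meth_g2 <- s2$n_meth[tested]
  w$n_unmeth_g2 <- s2$n_unmeth[tested]
  w$n_sites_g1 <- s1$n_sites[tested]
  w$n_sites_g2 <- s2$n_sites[tested]
  w$ml_g1 <- s1$mean_ml[tested]
  w$ml_g2 <- s2$mean_ml[tested]
  w$mean_depth_g1 <- s1$mean_depth[tested]
  w$mean_depth_g2 <- s2$mean_depth[tested]
  if (nrow(w) > 0) {
    w$p_value <- mapply(
      function(m1, u1, m2, u2) {
        fisher.test(matrix(c(m1, u1, m2, u2), nrow = 2,
                           byrow = TRUE))$p.value
      },
      w$n_meth_g1, w$n_unmeth_g1, w$n_meth_g2, w$n_unmeth_g2
    )
    w$fdr <- p.adjust(w$p_value, method = "BH")
    eps <- config$epsilon
    ml1 <- ifelse(is.na(w$ml_g1), 0, w$ml_g1)
    ml2 <- ifelse(is.na(w$ml_g2), 0, w$ml_g2)
    ratio <- (ml2 + eps) / (ml1 + eps)
    w$fold_change <- pmax(ratio, 1 / ratio)
    w$significant <- w$p_value < config$p_max &
      w$fdr < config$fdr_max &
      w$fold_change > config$min_fold_change &
      w$mean_depth_g1 > config$min_coverage &
      w$mean_depth_g2 > config$min_coverage
  } else {
    w$p_value <- numeric(0)
    w$fdr <- numeric(0)
    w$fold_change <- numeric(0)
    w$significant <- logical(0)
  }
  scan <- structure(
    list(windows = w, dmrs = NULL, config = config, context = context,
         chrom_sizes = chrom_sizes),
    class = "dmr_scan"
  )
  scan$dmrs <- call_dmrs(w, config)
  scan
}

#' Merge significant windows into DMRs
#'
#' Significant windows whose spans overlap or lie within one step of
#' each other are merged; each DMR reports the union span, the mean
#' of its windows' group levels, the maximum window fold change, the
#' minimum p/FDR, and the hyper/hypo direction of group 2 relative to
#' group 1.
#'
#' @param windows Tested-window tibble (from a [scan_dmr()] object's
#'   `windows`, or any tibble with the same columns), or a `dmr_scan`
#'   object.
#' @param config A [dmr_config()].
#' @return Tibble `dmr_id`, `chrom`, `start`, `end`, `n_windows`,
#'   `ml_g1`, `ml_g2`, `fold_change`, `p_value`, `fdr`, `direction`.
#' @export
call_dmrs <- function(windows, config = dmr_config()) {
  if (inherits(windows, "dmr_scan")) {
    config <- windows$config
    windows <- windows$windows
  }
  empty <- tibble::tibble(
    dmr_id = character(), chrom = character(), start = integer(),
    end = integer(), n_windows = integer(), ml_g1 = numeric(),
    ml_g2 = numeric(), fold_change = numeric(), p_value = numeric(),
    fdr = numeric(), direction = character()
  )
  sig <- windows[windows$significant %||% logical(nrow(windows)), ]
  if (nrow(sig) == 0) return(empty)
  sig <- sig[order(sig$chrom, sig$start), ]
  grp <- integer(nrow(sig))
  gid <- 1L
  grp[1] <- gid
  cur_end <- sig$end[1]
  for (i in seq_len(nrow(sig))[-1]) {
    same <- sig$chrom[i] == sig$chrom[i - 1]
    if (same && sig$start[i] <= cur_end + config$step) {
      grp[i] <- gid
      cur_end <- max(cur_end, sig$end[i])
    } else {
      gid <- gid + 1L
      grp[i] <- gid
      cur_end <- sig$end[i]
    }
  }
  sig$grp <- grp
  out <- sig |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(),
      ml_g1 = mean(.data$ml_g1), ml_g2 = mean(.data$ml_g2),
      fold_change = max(.data$fold_change),
      p_value = min(.data$p_value), fdr = min(.data$fdr),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(
      dmr_id = sprintf("dmr_%04d", dplyr::row_number()),
      direction = dmr_direction(.data$ml_g1, .data$ml_g2),
      .before = 1
    ) |>
    dplyr::select(-"grp")
  out
}

#' Hyper/hypo direction of a DMR
#'
#' `"hyper"` when the group-2 level exceeds the group-1 level,
#' `"hypo"` when it is lower, `"ambiguous"` when equal (unreachable
#' after the fold-change filter). Vectorised.
#'
#' @param ml_g1,ml_g2 Per-group methylation levels.
#' @return Character vector.
#' @export
dmr_direction <- function(ml_g1, ml_g2) {
  dplyr::case_when(
    ml_g2 > ml_g1 ~ "hyper",
    ml_g2 < ml_g1 ~ "hypo",
    TRUE ~ "ambiguous"
  )
}

#' Distribution of DMRs across functional element classes
#'
#' Each DMR is assigned to every element class its span overlaps
#' (multi-assignment); fractions are computed over assignments, so
#' they sum to 1 across classes. DMRs overlapping no class are
#' counted as `intergenic`.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param elements Element tibble from [gene_elements()].
#' @param cgi,repeats Optional BED3-like tracks.
#' @return Tibble `class`, `n_dmrs`, `fraction`.
#' @export
dmr_feature_distribution <- function(dmrs, elements, cgi = NULL,
                                     repeats = NULL) {
  empty <- tibble::tibble(class = character(), n_dmrs = integer(),
                          fraction = numeric())
  if (nrow(dmrs) == 0) return(empty)
  tracks <- purrr::map(
    setNames(c("promoter", "utr5", "exon", "intron", "utr3"),
             c("promoter", "utr5", "exon", "intron", "utr3")),
    ~ elements[elements$element == .x, c("chrom", "start", "end")]
  )
  if (!is.null(cgi)) tracks[["CGI"]] <- cgi
  if (!is.null(repeats)) tracks[["repeat"]] <- repeats
  hit_any <- logical(nrow(dmrs))
  rows <- purrr::imap(tracks, function(iv, name) {
    if (nrow(iv) == 0) return(NULL)
    hits <- interval_overlaps_any(dmrs, iv)
    hit_any <<- hit_any | hits
    if (!any(hits)) return(NULL)
    tibble::tibble(class = name, n_dmrs = sum(hits))
  })
  out <- dplyr::bind_rows(rows)
  if (any(!hit_any)) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(class = "intergenic", n_dmrs = sum(!hit_any))
    )
  }
  out$fraction <- out$n_dmrs / sum(out$n_dmrs)
  out
}

# TRUE per row of `a` (chrom/start/end, 0-based half-open) that
# overlaps any interval of `b`.
#' @keywords internal
#' @noRd
interval_overlaps_any <- function(a, b) {
  out <- logical(nrow(a))
  for (cr in unique(a$chrom)) {
    asel <- a$chrom == cr
    iv <- b[b$chrom == cr, ]
    if (nrow(iv) == 0) next
    out[asel] <- IRanges::overlapsAny(
      as_iranges0(a$start[asel], a$end[asel]),
      as_iranges0(iv$start, iv$end)
    )
  }
  out
}

#' @export
print.dmr_scan <- function(x, ...) {
  cat(sprintf(
    "<dmr_scan> context %s: %d tested windows, %d significant, %d DMRs\n",
    x$context, nrow(x$windows), sum(x$windows$significant),
    nrow(x$dmrs)
  ))
  invisible(x)
}

#' Tidy a DMR scan
#'
#' @param x A `dmr_scan` object.
#' @param type `"dmrs"` (default) or `"windows"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.dmr_scan <- function(x, type = c("dmrs", "windows"), ...) {
  type <- match.arg(type)
  if (type == "dmrs") x$dmrs else x$windows
}

#' One-row summary of a DMR scan
#'
#' @param x A `dmr_scan` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.dmr_scan <- function(x, ...) {
  tibble::tibble(
    context = x$context,
    window = x$config$window, step = x$config$step,
    n_windows_tested = nrow(x$windows),
    n_significant = sum(x$windows$significant),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    total_dmr_bp = sum(x$dmrs$end - x$dmrs$start)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
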