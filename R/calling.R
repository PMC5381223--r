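#' Estimate the bisulfite non-conversion rate from a spike-in
#'
#' The spike-in (unmethylated lambda DNA by construction) is fully
#' unmethylated, so every methylated read observed on it is a
#' conversion failure. The non-conversion rate `r` is the pooled
#' fraction of methylated reads over all spike-in cytosines; it serves
#' as the null success probability of the site-calling binomial test
#' and as the correction constant of [corrected_ml()].
#'
#' @param spike_records Cytosine-record tibble for the spike-in
#'   (columns `n_meth`, `n_unmeth` at minimum).
#' @return A one-row tibble: `r`, `n_meth_spike`, `n_total_spike`.
#' @examples
#' estimate_nonconversion_rate(
#'   tibble::tibble(n_meth = c(2, 3), n_unmeth = c(1000, 995))
#' )
#' @export
estimate_nonconversion_rate <- function(spike_records) {
  check_columns(spike_records, c("n_meth", "n_unmeth"), "spike-in table")
  n_meth <- sum(as.numeric(spike_records$n_meth))
  n_total <- n_meth + sum(as.numeric(spike_records$n_unmeth))
  if (n_total <= 0) {
    abort("cannot estimate conversion rate: spike-in has zero total depth")
  }
  tibble::tibble(r = n_meth / n_total,
                 n_meth_spike = n_meth, n_total_spike = n_total)
}

#' Exact binomial upper-tail p-value for a methylation site
#'
#' Probability of observing at least `n_meth` methylated reads out of
#' `depth` if the site is truly unmethylated and each read
#' independently fails conversion with probability `r`:
#' `P(X >= n_meth)` for `X ~ Binomial(depth, r)`. Vectorised.
#'
#' @param n_meth Methylated read count(s).
#' @param depth Total read count(s).
#' @param r Non-conversion rate in `[0, 1]`.
#' @return Upper-tail probability, same length as the inputs.
#' @examples
#' binomial_site_pvalue(0, 10, 0.01) # 1
#' binomial_site_pvalue(5, 5, 0.01)  # 1e-10
#' @export
binomial_site_pvalue <- function(n_meth, depth, r) {
  if (any(n_meth > depth)) abort("n_meth cannot exceed depth")
  if (any(n_meth < 0) || any(depth < 0)) abort("counts must be non-negative")
  if (any(r < 0) || any(r > 1)) abort("r must be in [0, 1]")
  pbinom(n_meth - 1, depth, r, lower.tail = FALSE)
}

#' Conversion-corrected methylation level
#'
#' The raw level `ML = n_meth / (n_meth + n_unmeth)` has expectation
#' `ml + (1 - ml) * r` when a fraction `r` of unmethylated cytosines
#' escapes conversion; inverting that relationship gives
#' `ML_corrected = (ML - r) / (1 - r)`, clipped to `[0, 1]`. With
#' `r = 0` the raw level is returned unchanged. Vectorised.
#'
#' @param n_meth Methylated read count(s).
#' @param n_unmeth Unmethylated read count(s).
#' @param r Non-conversion rate in `[0, 1)`.
#' @return Corrected methylation level(s) in `[0, 1]`; `NA` where depth
#'   is zero (no coverage).
#' @examples
#' corrected_ml(50, 50, 0)    # 0.5
#' corrected_ml(1, 99, 0.01)  # 0: raw level equals the noise floor
#' corrected_ml(50, 50, 0.01) # (0.5 - 0.01) / 0.99
#' @export
corrected_ml <- function(n_meth, n_unmeth, r) {
  if (any(r < 0) || any(r >= 1)) abort("r must be in [0, 1)")
  depth <- n_meth + n_unmeth
  ml <- ifelse(depth > 0, n_meth / depth, NA_real_)
  clamp01((ml - r) / (1 - r))
}

#' Call methylation sites against the non-conversion null
#'
#' Sites with depth below `min_depth` are excluded from testing (and
#' from the output). For the remaining sites an exact binomial
#' upper-tail p-value against `Binomial(depth, r)` is computed and
#' Benjamini-Hochberg q-values are derived separately within each
#' sequence context (CG/CHG/CHH base rates differ by orders of
#' magnitude, so a joint adjustment would let CG dominate). A site is
#' called methylated when `q_value <= q_max`. Sub-threshold sites are
#' retained as unmethylated covered sites: their corrected level still
#' feeds the profile statistics.
#'
#' @param records Cytosine-record tibble
#'   (see [read_cytosine_report()]).
#' @param conversion One-row tibble from
#'   [estimate_nonconversion_rate()], or a bare rate in `[0, 1)`.
#' @param min_depth Minimum read depth for a site to be tested
#'   (default 5).
#' @param q_max Benjamini-Hochberg q-value threshold (default 0.05).
#' @return The tested records with added columns `depth`, `ml_raw`,
#'   `ml_corrected`, `p_value`, `q_value`, `is_methylated`. The
#'   estimated rate is attached as attribute `nonconversion_rate`.
#' @export
call_sites <- function(records, conversion, min_depth = 5, q_max = 0.05) {
  check_columns(records, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                           "context"), "cytosine record table")
  r <- if (is.data.frame(conversion)) conversion$r[1] else conversion
  if (r < 0 || r >= 1) abort("non-conversion rate must be in [0, 1)")
  out <- records |>
    dplyr::mutate(depth = .data$n_meth + .data$n_unmeth) |>
    dplyr::filter(.data$depth >= min_depth)
  if (nrow(out) == 0) {
    out <- dplyr::mutate(out, ml_raw = numeric(0), ml_corrected = numeric(0),
                         p_value = numeric(0), q_value = numeric(0),
                         is_methylated = logical(0))
    attr(out, "nonconversion_rate") <- r
    return(out)
  }
  out <- out |>
    dplyr::mutate(
      ml_raw = .data$n_meth / .data$depth,
      ml_corrected = corrected_ml(.data$n_meth, .data$n_unmeth, r),
      p_value = binomial_site_pvalue(.data$n_meth, .data$depth, r)
    ) |>
    dplyr::group_by(.data$context) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(is_methylated = .data$q_value <= q_max)
  attr(out, "nonconversion_rate") <- r
  out
}
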