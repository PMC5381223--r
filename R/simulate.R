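#' Simulation configuration
#'
#' Bundles every knob of the two-group bisulfite simulator. The
#' defaults emulate the pooled two-library design of a vertebrate WGBS
#' ageing study: one pooled report per group, a CG baseline near 0.65
#' with sparse CHG/CHH methylation, Poisson sequencing depth around
#' 30x, a small bisulfite non-conversion rate estimated from a fully
#' unmethylated spike-in, and optional planted DMRs with known
#' location, magnitude and direction.
#'
#' Planted DMRs sit on an intermediate-methylation background: within
#' a planted span the lower group level is `base_ml` (default 0.25)
#' and the higher group level is `base_ml + delta_ml`, applied to
#' CG-context sites. Differential regions in real vertebrate data
#' arise in such partially methylated domains; a shift on top of the
#' 0.65 genome-wide baseline could never clear the standard
#' fold-change > 2 DMR filter, so it would be an untestable truth.
#'
#' @param seed Integer RNG seed; every simulator output is a pure
#'   function of `(config, seed)`.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param n_genes Number of genes to place (non-overlapping, >= 2
#'   exons each).
#' @param baseline_ml Named vector of per-context true methylation
#'   probabilities (`CG`, `CHG`, `CHH`).
#' @param cgi_ml True CG methylation level inside CpG islands
#'   (hypomethylated, default 0.1).
#' @param depth_mean Mean per-site sequencing depth per group.
#' @param nonconversion_rate True probability that an unmethylated
#'   cytosine reads as methylated (`r_true`).
#' @param overdispersion `NULL` for Poisson depth; a positive number
#'   switches to negative-binomial depth with that `size` parameter.
#' @param planted_dmrs `NULL` or a tibble with columns `chrom`,
#'   `start`, `end` (0-based half-open), `direction`
#'   (`"hyper"`/`"hypo"`, group 2 vs group 1), `delta_ml`, and
#'   optionally `base_ml`.
#' @param dmr_base_ml Default lower group level inside planted DMRs.
#' @param expression_coupling Slope linking promoter methylation to
#'   log-FPKM (`log FPKM = intercept - coupling * promoter_ML + noise`).
#' @param expression_intercept Intercept of the expression model on the
#'   natural-log scale.
#' @param expression_noise_sd Standard deviation of the per-group
#'   log-FPKM noise.
#' @param de_log2fc_cutoff Absolute observed log2 fold-change above
#'   which a simulated gene is labelled differentially expressed.
#' @param spikein_sites Number of fully unmethylated spike-in control
#'   cytosines.
#' @param cgi_fraction_of_genes Fraction of genes whose TSS is wrapped
#'   in a CpG island.
#' @param cgi_halfwidth Half-width (bp) of TSS CpG islands.
#' @param repeat_density One repeat interval per this many bp.
#' @param traits Tibble `trait`, `mean_g1`, `mean_g2`, `sd` of
#'   per-individual phenotypic traits generated for each group.
#' @param n_per_group Individuals per group in the trait table.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 500000L),
                       n_genes = 40L,
                       baseline_ml = c(CG = 0.65, CHG = 0.006, CHH = 0.006),
                       cgi_ml = 0.1,
                       depth_mean = 30,
                       nonconversion_rate = 0.005,
                       overdispersion = NULL,
                       planted_dmrs = NULL,
                       dmr_base_ml = 0.25,
                       expression_coupling = 4,
                       expression_intercept = 3,
                       expression_noise_sd = 0.2,
                       de_log2fc_cutoff = 1,
                       spikein_sites = 2000L,
                       cgi_fraction_of_genes = 0.5,
                       cgi_halfwidth = 300L,
                       repeat_density = 25000L,
                       traits = default_trait_config(),
                       n_per_group = 6L) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)))
  if (any(baseline_ml < 0) || any(baseline_ml > 1)) {
    abort("baseline_ml values must lie in [0, 1]")
  }
  if (nonconversion_rate < 0 || nonconversion_rate > 1) {
    abort("nonconversion_rate must lie in [0, 1]")
  }
  if (depth_mean < 0) abort("depth_mean must be non-negative")
  if (!all(c("CG", "CHG", "CHH") %in% names(baseline_ml))) {
    abort("baseline_ml must name CG, CHG and CHH")
  }
  if (!is.null(planted_dmrs)) {
    check_columns(planted_dmrs, c("chrom", "start", "end", "direction",
                                  "delta_ml"), "planted_dmrs")
    if (!all(planted_dmrs$direction %in% c("hyper", "hypo"))) {
      abort("planted DMR direction must be 'hyper' or 'hypo'")
    }
  }
  structure(
    list(
      seed = as.integer(seed), chrom_sizes = chrom_sizes,
      n_genes = as.integer(n_genes), baseline_ml = baseline_ml,
      cgi_ml = cgi_ml, depth_mean = depth_mean,
      nonconversion_rate = nonconversion_rate,
      overdispersion = overdispersion, planted_dmrs = planted_dmrs,
      dmr_base_ml = dmr_base_ml,
      expression_coupling = expression_coupling,
      expression_intercept = expression_intercept,
      expression_noise_sd = expression_noise_sd,
      de_log2fc_cutoff = de_log2fc_cutoff,
      spikein_sites = as.integer(spikein_sites),
      cgi_fraction_of_genes = cgi_fraction_of_genes,
      cgi_halfwidth = as.integer(cgi_halfwidth),
      repeat_density = as.integer(repeat_density),
      traits = traits, n_per_group = as.integer(n_per_group)
    ),
    class = "sim_config"
  )
}

#' @keywords internal
#' @noRd
default_trait_config <- function() {
  tibble::tribble(
    ~trait,        ~mean_g1, ~mean_g2, ~sd,
    "IMF",              1.2,      2.3, 0.3,
    "IFW",              2.0,      3.1, 0.4,
    "shear_force",      2.4,      3.5, 0.4,
    "drip_loss",        4.6,      3.1, 0.5,
    "TG",               0.4,      5.9, 0.8
  )
}

#' Simulate a genome with gene models, CpG islands and repeats
#'
#' Generates random chromosome sequences with CG density elevated
#' inside CpG islands (placed around a fraction of TSSs plus random
#' background islands), places `n_genes` non-overlapping multi-exon
#' genes with coding spans (so 5'/3'UTRs exist), and scatters repeat
#' intervals. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (a
#'   [Biostrings::DNAStringSet]), `genes` (gene tibble as from
#'   [read_gene_models()]), `cgi` and `repeats` (BED3-like tibbles)
#'   and `chrom_sizes`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    sizes <- config$chrom_sizes
    # allocate genes to chromosomes proportionally to length
    alloc <- floor(config$n_genes * sizes / sum(sizes))
    rem <- config$n_genes - sum(alloc)
    if (rem > 0) {
      o <- order(sizes, decreasing = TRUE)
      alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1
    }
    genes <- purrr::imap(as.list(sizes), function(size, chrom) {
      place_genes(chrom, size, alloc[chrom])
    }) |> dplyr::bind_rows()
    if (config$n_genes > 0) {
      genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
    }
    # CpG islands: around a fraction of TSSs, plus sparse background
    cgi <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
    if (nrow(genes) > 0 && config$cgi_fraction_of_genes > 0) {
      n_cgi <- round(config$cgi_fraction_of_genes * nrow(genes))
      pick <- sort(sample.int(nrow(genes), n_cgi))
      tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)[pick]
      cgi <- tibble::tibble(
        chrom = genes$chrom[pick],
        start = pmax(0L, as.integer(tss - config$cgi_halfwidth)),
        end = as.integer(tss + config$cgi_halfwidth)
      )
    }
    bg <- purrr::imap(as.list(sizes), function(size, chrom) {
      n <- max(0, floor(size / (config$repeat_density * 4)))
      if (n == 0) return(NULL)
      s <- sort(sample.int(size - 1000L, n))
      tibble::tibble(chrom = chrom, start = s, end = s + 600L)
    }) |> dplyr::bind_rows()
    cgi <- dplyr::bind_rows(cgi, bg) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::reframe(merge_intervals(.data$start, pmin(.data$end,
                                                       sizes[.data$chrom[1]])))
    reps <- purrr::imap(as.list(sizes), function(size, chrom) {
      n <- max(0, floor(size / config$repeat_density))
      if (n == 0) return(NULL)
      s <- sort(sample.int(max(1L, size - 1200L), n))
      w <- sample(200:1000, n, replace = TRUE)
      tibble::tibble(chrom = chrom, start = s, end = pmin(s + w, size))
    }) |> dplyr::bind_rows()
    if (nrow(reps) > 0) {
      reps <- reps |>
        dplyr::group_by(.data$chrom) |>
        dplyr::reframe(merge_intervals(.data$start, .data$end))
    }
    # sequence: background base mix ~42% GC; CGI intervals C/G-enriched
    seqs <- purrr::imap_chr(as.list(sizes), function(size, chrom) {
      bases <- sample(c("A", "C", "G", "T"), size, replace = TRUE,
                      prob = c(0.29, 0.21, 0.21, 0.29))
      iv <- cgi[cgi$chrom == chrom, ]
      for (i in seq_len(nrow(iv))) {
        idx <- (iv$start[i] + 1):iv$end[i]
        bases[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                             replace = TRUE, prob = c(0.15, 0.35, 0.35, 0.15))
      }
      paste(bases, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(sizes)
    list(genome = genome, genes = genes, cgi = cgi, repeats = reps,
         chrom_sizes = sizes)
  })
}

# Place n non-overlapping genes with >= 2 exons and a coding span on
# one chromosome. 0-based half-open coordinates.
#' @keywords internal
#' @noRd
place_genes <- function(chrom, size, n) {
  empty <- tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), tx_start = integer(),
                          tx_end = integer(), cds_start = integer(),
                          cds_end = integer(), exons = list())
  if (n == 0) return(empty)
  pos <- 2500L # leave room for a clipped-free promoter of the first gene
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(3000:8000, 1)
    if (pos + len > size - 500) {
      abort(sprintf(
        "chromosome '%s' (%d bp) too small to host its %d gene(s)",
        chrom, size, n
      ))
    }
    n_ex <- sample(2:6, 1)
    # split the span into alternating exon/intron segments (>= 80 bp)
    n_seg <- 2L * n_ex - 1L
    w <- stats::rgamma(n_seg, shape = 2)
    seg <- 80L + floor(w / sum(w) * (len - 80L * n_seg))
    seg[n_seg] <- len - sum(seg[-n_seg])
    bounds <- pos + cumsum(c(0L, seg))
    ex <- tibble::tibble(
      start = as.integer(bounds[seq(1, n_seg, by = 2)]),
      end = as.integer(bounds[seq(2, n_seg + 1, by = 2)])
    )
    cds_start <- as.integer(ex$start[1] + floor((ex$end[1] - ex$start[1]) / 2))
    nr <- nrow(ex)
    cds_end <- as.integer(ex$end[nr] - floor((ex$end[nr] - ex$start[nr]) / 2))
    rows[[i]] <- tibble::tibble(
      gene_id = NA_character_, chrom = chrom,
      strand = sample(c("+", "-"), 1),
      tx_start = as.integer(pos), tx_end = as.integer(pos + len),
      cds_start = cds_start, cds_end = cds_end, exons = list(ex)
    )
    pos <- as.integer(pos + len + sample(2500:6000, 1))
  }
  dplyr::bind_rows(rows)
}

# True per-site methylation table for both groups: deterministic given
# the genome and config (no RNG). CG sites in CpG islands are
# hypomethylated; planted DMRs override CG levels within their span.
#' @keywords internal
#' @noRd
site_truth <- function(config, genome_sim) {
  planted <- config$planted_dmrs
  if (!is.null(planted)) {
    sz <- config$chrom_sizes
    bad <- !(planted$chrom %in% names(sz)) |
      planted$start < 0 | planted$end > sz[planted$chrom]
    if (any(bad)) {
      abort(sprintf("planted DMR outside any chromosome (row %d)",
                    which(bad)[1]))
    }
  }
  per_chrom <- purrr::imap(as.list(as.character(genome_sim$genome)),
                           function(seq, chrom) {
    s <- strsplit(seq, "")[[1]]
    len <- length(s)
    # plus strand: C at i, context read rightwards
    ip <- which(s == "C")
    ip <- ip[ip <= len - 2]
    ctx_p <- ifelse(s[ip + 1] == "G", "CG",
                    ifelse(s[ip + 2] == "G", "CHG", "CHH"))
    tri_p <- paste0(s[ip], s[ip + 1], s[ip + 2])
    # minus strand: G at i pairs with a C; context read leftwards,
    # reported as the reverse complement
    im <- which(s == "G")
    im <- im[im >= 3]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ctx_m <- ifelse(s[im - 1] == "C", "CG",
                    ifelse(s[im - 2] == "C", "CHG", "CHH"))
    tri_m <- paste0("C", comp[s[im - 1]], comp[s[im - 2]])
    tibble::tibble(
      chrom = chrom,
      pos = c(ip, im),
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(ctx_p, ctx_m),
      trinucleotide = c(tri_p, tri_m)
    ) |> dplyr::arrange(.data$pos)
  })
  sites <- dplyr::bind_rows(per_chrom)
  ml <- unname(config$baseline_ml[sites$context])
  is_cg <- sites$context == "CG"
  # CpG island hypomethylation (CG context)
  cgi <- genome_sim$cgi
  if (!is.null(cgi) && nrow(cgi) > 0) {
    in_cgi <- point_in_track(sites$chrom, sites$pos, cgi)
    ml[in_cgi & is_cg] <- config$cgi_ml
  }
  ml_g1 <- ml
  ml_g2 <- ml
  if (!is.null(planted) && nrow(planted) > 0) {
    base <- planted[["base_ml"]] %||% rep(config$dmr_base_ml, nrow(planted))
    if (is.null(planted[["base_ml"]])) planted$base_ml <- base
    for (i in seq_len(nrow(planted))) {
      hit <- is_cg & sites$chrom == planted$chrom[i] &
        sites$pos > planted$start[i] & sites$pos <= planted$end[i]
      lo <- planted$base_ml[i]
      hi <- min(1, lo + planted$delta_ml[i])
      if (planted$direction[i] == "hyper") {
        ml_g1[hit] <- lo
        ml_g2[hit] <- hi
      } else {
        ml_g1[hit] <- hi
        ml_g2[hit] <- lo
      }
    }
  }
  sites$ml_g1 <- ml_g1
  sites$ml_g2 <- ml_g2
  sites
}

# TRUE where 1-based position pos falls in a BED3-like 0-based
# half-open track.
#' @keywords internal
#' @noRd
point_in_track <- function(chrom, pos, track) {
  out <- logical(length(pos))
  for (cr in unique(track$chrom)) {
    sel <- chrom == cr
    if (!any(sel)) next
    iv <- track[track$chrom == cr, ]
    hits <- IRanges::overlapsAny(as_iranges_pos(pos[sel]),
                                 as_iranges0(iv$start, iv$end))
    out[sel] <- hits
  }
  out
}

#' Simulate two-group per-cytosine reports with a spike-in and truth
#'
#' For every cytosine of the simulated genome (both strands), the true
#' methylation level is the context baseline, lowered inside CpG
#' islands and overridden inside planted DMRs for the designated
#' group. Depth is Poisson (or negative-binomial when
#' `overdispersion` is set); the observed methylated count is
#' `Binomial(depth, ml + (1 - ml) * r)`, folding bisulfite
#' non-conversion into the success probability. The spike-in report
#' holds fully unmethylated control cytosines on a `lambda` contig.
#'
#' @param config A [sim_config()].
#' @param genome_sim Output of [simulate_genome()].
#' @return A list: `group1`, `group2`, `spikein` (cytosine-record
#'   tibbles as from [read_cytosine_report()]) and `truth` (a list
#'   with `planted` per-group true levels, `r_true`, and the full
#'   per-site truth table `sites`).
#' @export
simulate_cytosine_reports <- function(config, genome_sim) {
  stopifnot(inherits(config, "sim_config"))
  sites <- site_truth(config, genome_sim)
  r <- config$nonconversion_rate
  n <- nrow(sites)
  draw_depth <- function(n) {
    if (is.null(config$overdispersion)) {
      rpois(n, config$depth_mean)
    } else {
      rnbinom(n, size = config$overdispersion, mu = config$depth_mean)
    }
  }
  withr::with_seed(config$seed + 1L, {
    reports <- purrr::map(c(g1 = "ml_g1", g2 = "ml_g2"), function(col) {
      depth <- draw_depth(n)
      p <- sites[[col]] + (1 - sites[[col]]) * r
      n_meth <- rbinom(n, depth, p)
      tibble::tibble(
        chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
        n_meth = as.integer(n_meth),
        n_unmeth = as.integer(depth - n_meth),
        context = sites$context, trinucleotide = sites$trinucleotide
      )
    })
    ns <- config$spikein_sites
    depth_s <- draw_depth(ns)
    meth_s <- rbinom(ns, depth_s, r)
    ctx_s <- sample(c("CG", "CHG", "CHH"), ns, replace = TRUE,
                    prob = c(0.2, 0.3, 0.5))
    spike <- tibble::tibble(
      chrom = "lambda",
      pos = seq(1L, by = 10L, length.out = ns),
      strand = "+",
      n_meth = as.integer(meth_s),
      n_unmeth = as.integer(depth_s - meth_s),
      context = ctx_s,
      trinucleotide = c(CG = "CGA", CHG = "CAG", CHH = "CAT")[ctx_s]
    )
    planted <- config$planted_dmrs
    if (!is.null(planted) && nrow(planted) > 0) {
      base <- planted[["base_ml"]] %||% rep(config$dmr_base_ml, nrow(planted))
      hi <- pmin(1, base + planted$delta_ml)
      planted <- planted |>
        dplyr::mutate(
          ml_g1 = ifelse(.data$direction == "hyper", base, hi),
          ml_g2 = ifelse(.data$direction == "hyper", hi, base)
        )
    }
    list(
      group1 = reports$g1, group2 = reports$g2, spikein = spike,
      truth = list(planted = planted, r_true = r, sites = sites)
    )
  })
}

#' Plant hyper- or hypomethylated DMRs over gene promoters
#'
#' Selects `n` simulated genes (seeded) and returns a planted-DMR
#' tibble covering each gene's promoter span, suitable for
#' `sim_config(planted_dmrs = ...)`. Used to create ground truth for
#' the promoter-methylation candidate filter.
#'
#' @param config A [sim_config()].
#' @param genome_sim Output of [simulate_genome()].
#' @param n Number of genes to affect.
#' @param delta_ml Methylation difference between groups.
#' @param direction `"hyper"` (group 2 higher, default) or `"hypo"`.
#' @param promoter_width Promoter size in bp (default 2000).
#' @return Tibble `chrom`, `start`, `end`, `direction`, `delta_ml`,
#'   `gene_id`.
#' @export
plant_promoter_dmrs <- function(config, genome_sim, n, delta_ml = 0.3,
                                direction = "hyper",
                                promoter_width = 2000) {
  genes <- genome_sim$genes
  if (n > nrow(genes)) abort("fewer simulated genes than requested DMRs")
  withr::with_seed(config$seed + 2L, {
    pick <- sort(sample.int(nrow(genes), n))
  })
  g <- genes[pick, ]
  prom <- gene_elements(g, promoter_width = promoter_width,
                        chrom_sizes = config$chrom_sizes) |>
    dplyr::filter(.data$element == "promoter")
  tibble::tibble(
    chrom = prom$chrom, start = prom$start, end = prom$end,
    direction = direction, delta_ml = delta_ml, gene_id = prom$gene_id
  )
}

#' Simulate an expression table and trait table coupled to promoter
#' methylation
#'
#' Per gene and group, `log FPKM = intercept - coupling * promoter_ML
#' + noise`, where promoter ML is the true mean CG-context level over
#' the promoter for that group. Genes whose promoter carries a planted
#' hyper-DMR in group 2 therefore lose expression in group 2. Observed
#' DE labels are set where `|log2 FC|` exceeds the configured cutoff.
#' Traits are drawn per individual around configured group means.
#'
#' @param config A [sim_config()].
#' @param genome_sim Output of [simulate_genome()].
#' @return A list: `expression` (tibble `gene_id`, `fpkm_g1`,
#'   `fpkm_g2`, `log2_fc`, `de_flag`, `direction`, `promoter_ml_g1`,
#'   `promoter_ml_g2`, `planted`) and `traits` (long tibble `sample`,
#'   `group`, `trait`, `value`).
#' @export
simulate_expression <- function(config, genome_sim) {
  stopifnot(inherits(config, "sim_config"))
  genes <- genome_sim$genes
  if (nrow(genes) == 0) {
    return(list(expression = tibble::tibble(), traits = tibble::tibble()))
  }
  sites <- site_truth(config, genome_sim) |>
    dplyr::filter(.data$context == "CG")
  prom <- gene_elements(genes, chrom_sizes = config$chrom_sizes) |>
    dplyr::filter(.data$element == "promoter")
  pm <- purrr::map(seq_len(nrow(prom)), function(i) {
    sel <- sites$chrom == prom$chrom[i] &
      sites$pos > prom$start[i] & sites$pos <= prom$end[i]
    c(mean(sites$ml_g1[sel]), mean(sites$ml_g2[sel]))
  })
  prom_ml <- do.call(rbind, pm)
  planted_genes <- character(0)
  if (!is.null(config$planted_dmrs) && nrow(config$planted_dmrs) > 0) {
    pd <- config$planted_dmrs
    for (i in seq_len(nrow(prom))) {
      ov <- pd$chrom == prom$chrom[i] &
        pd$start < prom$end[i] & pd$end > prom$start[i]
      if (any(ov)) planted_genes <- c(planted_genes, prom$gene_id[i])
    }
  }
  withr::with_seed(config$seed + 3L, {
    gn <- rnorm(nrow(prom), 0, config$expression_noise_sd)
    e1 <- rnorm(nrow(prom), 0, config$expression_noise_sd)
    e2 <- rnorm(nrow(prom), 0, config$expression_noise_sd)
    log_f1 <- config$expression_intercept -
      config$expression_coupling * prom_ml[, 1] + gn + e1
    log_f2 <- config$expression_intercept -
      config$expression_coupling * prom_ml[, 2] + gn + e2
    fpkm_g1 <- exp(log_f1)
    fpkm_g2 <- exp(log_f2)
    log2_fc <- log2(fpkm_g2 / fpkm_g1)
    expression <- tibble::tibble(
      gene_id = prom$gene_id,
      fpkm_g1 = fpkm_g1, fpkm_g2 = fpkm_g2, log2_fc = log2_fc,
      de_flag = abs(log2_fc) >= config$de_log2fc_cutoff,
      direction = ifelse(log2_fc < 0, "Down", "Up"),
      promoter_ml_g1 = prom_ml[, 1], promoter_ml_g2 = prom_ml[, 2],
      planted = prom$gene_id %in% planted_genes
    )
    expression$direction[!expression$de_flag] <- NA_character_
    tr <- config$traits
    traits <- purrr::pmap(
      list(tr$trait, tr$mean_g1, tr$mean_g2, tr$sd),
      function(trait, m1, m2, sd) {
        tibble::tibble(
          sample = c(sprintf("g1_%d", seq_len(config$n_per_group)),
                     sprintf("g2_%d", seq_len(config$n_per_group))),
          group = rep(c("g1", "g2"), each = config$n_per_group),
          trait = trait,
          value = c(rnorm(config$n_per_group, m1, sd),
                    rnorm(config$n_per_group, m2, sd))
        )
      }
    ) |> dplyr::bind_rows()
    list(expression = expression, traits = traits)
  })
}
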