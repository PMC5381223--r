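# Small in-code fixtures shared across the suite.

# A minimal cytosine-record tibble.
make_records <- function(n = 10, chrom = "chr1", seed = 1,
                         depth_mean = 20, ml = 0.5, context = "CG") {
  withr::with_seed(seed, {
    depth <- rpois(n, depth_mean)
    n_meth <- rbinom(n, depth, ml)
    tibble::tibble(
      chrom = chrom,
      pos = sort(sample.int(n * 50, n)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      n_meth = as.integer(n_meth),
      n_unmeth = as.integer(depth - n_meth),
      context = context,
      trinucleotide = "CGA"
    )
  })
}

# A two-exon plus-strand coding gene and its minus-strand mirror.
make_genes <- function() {
  tibble::tibble(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    tx_start = c(5000L, 20000L),
    tx_end = c(9000L, 24000L),
    cds_start = c(5600L, 20600L),
    cds_end = c(8400L, 23400L),
    exons = list(
      tibble::tibble(start = c(5000L, 7000L), end = c(6000L, 9000L)),
      tibble::tibble(start = c(20000L, 22000L), end = c(21000L, 24000L))
    )
  )
}

# Calls table built directly (bypassing call_sites) for profile tests.
make_calls <- function(pos, ml, chrom = "chr1", context = "CG",
                       strand = "+", depth = 20L, methylated = TRUE) {
  n_meth <- as.integer(round(ml * depth))
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    n_meth = n_meth, n_unmeth = depth - n_meth,
    context = context, trinucleotide = "CGA",
    depth = depth, ml_raw = n_meth / depth, ml_corrected = ml,
    p_value = 0, q_value = 0, is_methylated = methylated
  )
}

# Brute-force Benjamini-Hochberg: sort, scale by m/rank, cumulative
# minimum from the largest p, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  stepped <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- pmin(stepped, 1)
  out
}

# Brute-force two-sided Fisher p: enumerate all 2x2 tables with the
# observed margins via the hypergeometric mass, sum those no more
# probable than the observed table (with fisher.test's tolerance).
fisher_oracle <- function(m1, u1, m2, u2) {
  row1 <- m1 + u1
  k <- m1 + m2
  n <- m1 + u1 + m2 + u2
  support <- max(0, k - (n - row1)):min(k, row1)
  dens <- dhyper(support, row1, n - row1, k)
  p_obs <- dhyper(m1, row1, n - row1, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}
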