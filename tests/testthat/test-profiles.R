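test_that("context composition reports both normalisations", {
  calls <- dplyr::bind_rows(
    make_calls(1:947 * 10, 0.8, context = "CG"),
    make_calls(1:11 * 10 + 30000, 0.5, context = "CHG"),
    make_calls(1:42 * 10 + 40000, 0.5, context = "CHH"),
    make_calls(1:37 * 10 + 50000, 0.1, context = "CG", methylated = FALSE)
  )
  comp <- context_composition(calls)
  expect_equal(sum(comp$fraction_of_mc), 1, tolerance = 1e-9)
  expect_equal(comp$fraction_of_mc[comp$context == "CG"], 0.947)
  expect_equal(comp$fraction_of_mc[comp$context == "CHG"], 0.011)
  expect_equal(comp$meth_rate[comp$context == "CG"], 947 / 984)
  expect_true(all(comp$meth_rate >= 0 & comp$meth_rate <= 1))

  one_ctx <- make_calls(1:10 * 10, 0.9, context = "CG")
  expect_equal(context_composition(one_ctx)$fraction_of_mc, 1)

  none <- make_calls(1:10 * 10, 0.1, methylated = FALSE)
  expect_warning(comp0 <- context_composition(none), "undefined")
  expect_true(all(is.na(comp0$fraction_of_mc)))
})

test_that("63 methylated of 100 CG sites gives an mCG level of 0.63", {
  calls <- dplyr::bind_rows(
    make_calls(1:63 * 10, 0.9, methylated = TRUE),
    make_calls(64:100 * 10, 0.1, methylated = FALSE)
  )
  comp <- context_composition(calls)
  expect_equal(comp$meth_rate, 0.63)
})

test_that("chromosome levels equal a brute-force group-by mean", {
  calls <- dplyr::bind_rows(
    make_calls(1:400 * 7, withr::with_seed(8, runif(400)), chrom = "chr1"),
    make_calls(1:600 * 5, withr::with_seed(9, runif(600)), chrom = "chr2")
  )
  lv <- chromosome_levels(calls)
  brute <- tapply(calls$ml_corrected, calls$chrom, mean)
  expect_equal(lv$mean_ml[lv$chrom == "chr1"], unname(brute["chr1"]))
  expect_equal(lv$mean_ml[lv$chrom == "chr2"], unname(brute["chr2"]))
  expect_false("chr3" %in% lv$chrom) # uncovered chromosome absent

  single <- make_calls(1:50 * 10, 0.5)
  expect_equal(chromosome_levels(single)$mean_ml, 0.5)
})

test_that("feature levels follow the precedence partition", {
  g <- make_genes()
  el <- gene_elements(g, chrom_sizes = c(chr1 = 30000L))
  calls <- dplyr::bind_rows(
    make_calls(4500, 0.2),   # promoter of gplus ([3000,5000))
    make_calls(5100, 0.3),   # utr5/exon of gplus
    make_calls(6500, 0.6),   # intron of gplus
    make_calls(15000, 0.9)   # between genes -> intergenic
  )
  ft <- feature_levels(calls, el)
  expect_equal(sum(ft$n_sites), nrow(calls)) # partition conservation
  expect_equal(ft$mean_ml[ft$class == "promoter"], 0.2)
  expect_equal(ft$mean_ml[ft$class == "utr5"], 0.3)
  expect_equal(ft$mean_ml[ft$class == "intron"], 0.6)
  expect_equal(ft$mean_ml[ft$class == "intergenic"], 0.9)
  expect_false("exon" %in% ft$class) # utr5 outranks exon for site 5100
})

test_that("feature class means equal brute-force membership on a toy genome", {
  g <- make_genes()
  el <- gene_elements(g, chrom_sizes = c(chr1 = 30000L))
  cgi <- tibble::tibble(chrom = "chr1", start = 12000L, end = 12500L)
  withr::with_seed(31, {
    calls <- make_calls(sort(sample.int(29000, 800)), runif(800))
  })
  ft <- feature_levels(calls, el, cgi = cgi)
  # O(n * m) membership with the same precedence
  classes <- c("promoter", "utr5", "utr3", "exon", "intron", "CGI")
  tracks <- c(
    purrr::map(c("promoter", "utr5", "utr3", "exon", "intron"),
               ~ el[el$element == .x, ]),
    list(cgi)
  )
  label <- purrr::map_chr(calls$pos, function(p) {
    for (k in seq_along(classes)) {
      iv <- tracks[[k]]
      if (any(p > iv$start & p <= iv$end)) return(classes[k])
    }
    "intergenic"
  })
  brute <- tapply(calls$ml_corrected, label, mean)
  for (cl in names(brute)) {
    expect_equal(ft$mean_ml[ft$class == cl], unname(brute[cl]),
                 info = cl)
  }
})

test_that("multi-label feature levels count CGI sites in both classes", {
  g <- make_genes()
  el <- gene_elements(g, chrom_sizes = c(chr1 = 30000L))
  cgi <- tibble::tibble(chrom = "chr1", start = 4400L, end = 4600L)
  calls <- make_calls(4500, 0.2) # promoter AND CGI
  ft <- feature_levels(calls, el, cgi = cgi, disjoint = FALSE)
  expect_setequal(ft$class, c("promoter", "CGI"))
})

test_that("metagene profile is flat under uniform methylation", {
  g <- make_genes()
  calls <- make_calls(seq(2000, 27000, by = 20), 0.4)
  prof <- metagene_profile(calls, g, flank = 2000, flank_bins = 5,
                           body_bins = 10)
  expect_true(all(abs(prof$mean_ml - 0.4) < 1e-12))
  expect_true(all(prof$bin %in% 1:20))
})

test_that("minus-strand genes mirror plus-strand genes", {
  gp <- make_genes()[1, ]
  gm <- make_genes()[2, ]
  pos <- seq(3001, 11000, by = 7) # covers flank+body+flank of gplus
  ml <- withr::with_seed(4, runif(length(pos)))
  calls_p <- make_calls(pos, ml)
  # reflect the sites around the gminus span: x' = 29000 - x + 1 maps
  # [gplus span 5000,9000) onto [20000,24000) given tx mirror
  calls_m <- make_calls(29000 - pos + 1, ml)
  pp <- metagene_profile(calls_p, gp, flank_bins = 4, body_bins = 8)
  pm <- metagene_profile(calls_m, gm, flank_bins = 4, body_bins = 8)
  merged <- dplyr::inner_join(pp, pm, by = c("context", "bin"))
  expect_equal(nrow(merged), nrow(pp))
  expect_equal(merged$mean_ml.x, merged$mean_ml.y, tolerance = 1e-12)
})

test_that("metagene profile is translation invariant and warns on short genes", {
  g <- make_genes()[1, ]
  pos <- seq(3001, 11000, by = 13)
  ml <- withr::with_seed(6, runif(length(pos)))
  p1 <- metagene_profile(make_calls(pos, ml), g,
                         flank_bins = 4, body_bins = 8)
  shift <- 1000L
  g2 <- g
  g2$tx_start <- g$tx_start + shift
  g2$tx_end <- g$tx_end + shift
  g2$cds_start <- g$cds_start + shift
  g2$cds_end <- g$cds_end + shift
  g2$exons <- list(g$exons[[1]] + shift)
  p2 <- metagene_profile(make_calls(pos + shift, ml), g2,
                         flank_bins = 4, body_bins = 8)
  expect_equal(p1$mean_ml, p2$mean_ml)

  short <- g
  short$tx_end <- short$tx_start + 5L
  expect_warning(metagene_profile(make_calls(pos, ml), short,
                                  body_bins = 8), "excluded")
})

test_that("promoter-hypomethylated genes dip upstream of the TSS", {
  cfg <- sim_config(seed = 23, chrom_sizes = c(chr1 = 300000L),
                    n_genes = 25, cgi_fraction_of_genes = 1)
  gs <- simulate_genome(cfg)
  rep <- simulate_cytosine_reports(cfg, gs)
  calls <- call_sites(rep$group1, 0.005)
  prof <- metagene_profile(calls[calls$context == "CG", ], gs$genes)
  up <- prof[prof$zone == "upstream" & prof$bin > 15, ]
  body <- prof[prof$zone == "body" & prof$bin > 40, ]
  expect_lt(min(up$mean_ml), mean(body$mean_ml) - 0.2)
})

test_that("neighbor base context extracts the right windows", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTTAAAACAAAATTTT"))
  calls <- make_calls(8, 0.9) # C at position 8, window AAAACAAAA
  nb <- neighbor_base_context(calls, genome, k = 4)
  expect_equal(nb$base[nb$offset == 0], "C")
  expect_true(all(nb$base[nb$offset != 0] == "A"))
  expect_true(all(nb$freq == 1))

  # minus-strand site reports the reverse complement window
  genome2 <- Biostrings::DNAStringSet(c(chr1 = "TTTTGTTTTAAATTTT"))
  calls2 <- make_calls(5, 0.9, strand = "-")
  nb2 <- neighbor_base_context(calls2, genome2, k = 4)
  expect_equal(nb2$base[nb2$offset == 0], "C")
  expect_true(all(nb2$base[nb2$offset != 0] == "A"))

  # edge sites are skipped
  calls3 <- make_calls(2, 0.9)
  expect_equal(nrow(neighbor_base_context(calls3, genome, k = 4)), 0)
})

test_that("neighbor frequencies match brute-force substring extraction", {
  cfg <- sim_config(seed = 29, chrom_sizes = c(chr1 = 50000L), n_genes = 3)
  gs <- simulate_genome(cfg)
  rep <- simulate_cytosine_reports(cfg, gs)
  calls <- call_sites(rep$group1, 0.005)
  mc <- calls[calls$is_methylated, ][1:500, ]
  nb <- neighbor_base_context(mc, gs$genome, k = 2)
  s <- as.character(gs$genome[["chr1"]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wins <- purrr::map_chr(seq_len(nrow(mc)), function(i) {
    w <- substring(s, mc$pos[i] - 2, mc$pos[i] + 2)
    if (mc$strand[i] == "-") {
      w <- paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
    }
    w
  })
  keep <- mc$pos - 2 >= 1 & mc$pos + 2 <= nchar(s)
  for (off in -2:2) {
    bases <- substring(wins[keep], off + 3, off + 3)
    brute <- table(factor(bases, c("A", "C", "G", "T")),
                   mc$context[keep])
    for (ctx in colnames(brute)) {
      for (b in rownames(brute)) {
        got <- nb$count[nb$context == ctx & nb$offset == off &
                          nb$base == b]
        expect_equal(if (length(got) == 0) 0L else got,
                     unname(brute[b, ctx]))
      }
    }
  }
})
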