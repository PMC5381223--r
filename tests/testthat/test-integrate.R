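toy_elements <- function() {
  gene_elements(make_genes(), chrom_sizes = c(chr1 = 30000L))
}

toy_dmr <- function(start, end, direction = "hyper",
                    id = "dmr_0001") {
  tibble::tibble(
    dmr_id = id, chrom = "chr1", start = as.integer(start),
    end = as.integer(end), ml_g1 = 0.2, ml_g2 = 0.6, fold_change = 3,
    p_value = 1e-10, fdr = 1e-8, direction = direction
  )
}

test_that("DMR-gene mapping respects element overlap", {
  el <- toy_elements()
  in_promoter <- map_dmrs_to_genes(toy_dmr(3500, 4500), el)
  expect_equal(in_promoter$gene_id, "gplus")
  expect_equal(in_promoter$elements, "promoter")
  expect_equal(in_promoter$methylation, "Hyper")

  intergenic <- map_dmrs_to_genes(toy_dmr(12000, 13000), el)
  expect_equal(nrow(intergenic), 0)

  spanning <- map_dmrs_to_genes(toy_dmr(4500, 6500), el)
  expect_equal(spanning$elements, "promoter, utr5, exon, intron")
})

test_that("DMG mapping equals brute-force all-pairs intersection", {
  withr::with_seed(61, {
    genes <- purrr::map(1:20, function(i) {
      s <- 3000L + (i - 1L) * 12000L
      tibble::tibble(
        gene_id = sprintf("g%02d", i), chrom = "chr1",
        strand = sample(c("+", "-"), 1),
        tx_start = s, tx_end = s + 6000L,
        cds_start = s + 500L, cds_end = s + 5500L,
        exons = list(tibble::tibble(start = c(s, s + 4000L),
                                    end = c(s + 2000L, s + 6000L)))
      )
    }) |> dplyr::bind_rows()
    el <- gene_elements(genes)
    dmrs <- dplyr::bind_rows(purrr::map(1:15, function(i) {
      s <- sample.int(240000L, 1)
      toy_dmr(s, s + sample(500:3000, 1),
              direction = sample(c("hyper", "hypo"), 1),
              id = sprintf("dmr_%04d", i))
    }))
  })
  got <- map_dmrs_to_genes(dmrs, el)
  brute <- list()
  for (g in unique(el$gene_id)) {
    sub <- el[el$gene_id == g, ]
    hit <- character(0)
    for (j in seq_len(nrow(dmrs))) {
      if (any(sub$start < dmrs$end[j] & sub$end > dmrs$start[j])) {
        hit <- c(hit, dmrs$dmr_id[j])
      }
    }
    if (length(hit) > 0) brute[[g]] <- sort(hit)
  }
  expect_setequal(got$gene_id, names(brute))
  for (g in got$gene_id) {
    expect_equal(sort(strsplit(got$dmr_ids[got$gene_id == g],
                               ";")[[1]]),
                 brute[[g]])
  }
})

test_that("mixed DMR directions produce the combined label", {
  el <- toy_elements()
  dmrs <- dplyr::bind_rows(
    toy_dmr(5100, 5400, "hyper", "dmr_0001"),
    toy_dmr(6200, 6600, "hypo", "dmr_0002")
  )
  dmg <- map_dmrs_to_genes(dmrs, el)
  expect_equal(dmg$methylation, "Hypo/hyper")
})

test_that("DMG x DEG join is a set intersection", {
  dmgs <- tibble::tibble(
    gene_id = c("a", "b", "c"), elements = "promoter",
    methylation = "Hyper", n_dmrs = 1L, dmr_ids = "dmr_0001"
  )
  expr <- tibble::tibble(
    gene_id = c("b", "c", "d"),
    fpkm_g1 = 1, fpkm_g2 = 2,
    de_flag = c(TRUE, FALSE, TRUE),
    direction = c("Down", NA, "Up")
  )
  expect_message(joint <- overlap_dmg_deg(dmgs, expr), "absent")
  expect_equal(joint$gene_id, "b")
  expect_equal(joint$regulation, "Down")
  expect_lte(nrow(joint), min(nrow(dmgs), sum(expr$de_flag)))

  disjoint <- overlap_dmg_deg(
    dmgs[dmgs$gene_id == "c", ],
    expr[expr$gene_id == "d", ]
  )
  expect_equal(nrow(disjoint), 0)

  # randomized ids: row set equals the plain intersection
  withr::with_seed(67, {
    ids <- replicate(30, paste(sample(letters, 6), collapse = ""))
    dm <- tibble::tibble(gene_id = sample(ids, 12), elements = "intron",
                         methylation = "Hyper", n_dmrs = 1L,
                         dmr_ids = "dmr_0001")
    ex <- tibble::tibble(gene_id = sample(ids, 15), fpkm_g1 = 1,
                         fpkm_g2 = 1, de_flag = TRUE, direction = "Up")
  })
  j <- suppressMessages(overlap_dmg_deg(dm, ex))
  expect_setequal(j$gene_id, intersect(dm$gene_id, ex$gene_id))
})

test_that("candidate filters are conjunctive and monotone", {
  joint <- example_dmg_deg_table()
  all_prom <- select_candidates(joint, methylation = NULL,
                                regulation = NULL)
  hyper <- select_candidates(joint, regulation = NULL)
  hyper_down <- select_candidates(joint)
  expect_lte(nrow(hyper), nrow(all_prom))
  expect_lte(nrow(hyper_down), nrow(hyper))
  expect_true(all(hyper_down$gene_id %in% hyper$gene_id))
  expect_equal(nrow(select_candidates(joint[0, ])), 0)
})

test_that("expression classes split at the median positive FPKM", {
  expr <- tibble::tibble(gene_id = letters[1:4], sample = "s1",
                         fpkm = c(1, 2, 3, 4))
  cl <- expression_class_split(expr)
  expect_equal(cl$class, c("low", "low", "high", "high"))

  ties <- tibble::tibble(gene_id = letters[1:4], sample = "s1", fpkm = 5)
  expect_equal(unique(expression_class_split(ties)$class), "low")

  zeros <- tibble::tibble(gene_id = letters[1:3], sample = "s1", fpkm = 0)
  expect_warning(cl0 <- expression_class_split(zeros), "zero")
  expect_equal(unique(cl0$class), "low")

  # invariant under monotone rescaling
  withr::with_seed(71, {
    f <- runif(50, 0, 100)
  })
  base <- tibble::tibble(gene_id = as.character(1:50), sample = "s1",
                         fpkm = f)
  scaled <- dplyr::mutate(base, fpkm = log1p(.data$fpkm) * 7)
  expect_equal(expression_class_split(base)$class,
               expression_class_split(scaled)$class)
})

test_that("methylation by expression class recovers constructed levels", {
  el <- toy_elements()
  calls <- dplyr::bind_rows(
    make_calls(4500, 0.8),  # gplus promoter
    make_calls(25000, 0.1)  # gminus promoter ([24000, 26000))
  )
  classes <- tibble::tibble(gene_id = c("gplus", "gminus"),
                            class = c("low", "high"))
  tab <- methylation_by_expression_class(calls, el, classes)
  expect_equal(
    tab$mean_ml[tab$class == "low" & tab$element == "promoter"], 0.8
  )
  expect_equal(
    tab$mean_ml[tab$class == "high" & tab$element == "promoter"], 0.1
  )
  # no spurious cells for uncovered elements
  expect_false("utr3" %in% tab$element)
})

test_that("class permutation nulls out the promoter difference", {
  cfg <- sim_config(seed = 73, chrom_sizes = c(chr1 = 400000L),
                    n_genes = 30)
  gs <- simulate_genome(cfg)
  rep <- simulate_cytosine_reports(cfg, gs)
  calls <- call_sites(rep$group1, 0.005)
  el <- gene_elements(gs$genes, chrom_sizes = cfg$chrom_sizes)
  ml_prom <- methylation_by_expression_class(
    calls, el,
    tibble::tibble(gene_id = gs$genes$gene_id,
                   class = rep(c("low", "high"), length.out = 30))
  )
  perm_diffs <- purrr::map_dbl(1:20, function(i) {
    withr::with_seed(i, {
      cl <- tibble::tibble(gene_id = gs$genes$gene_id,
                           class = sample(rep(c("low", "high"), 15)))
    })
    t <- methylation_by_expression_class(calls, el, cl)
    p <- t[t$element == "promoter" & t$context == "CG", ]
    p$mean_ml[p$class == "high"] - p$mean_ml[p$class == "low"]
  })
  expect_lt(abs(mean(perm_diffs)), 0.05)
})

test_that("coupled simulation puts lower promoter methylation on high expressers", {
  cfg <- sim_config(seed = 79, chrom_sizes = c(chr1 = 400000L),
                    n_genes = 30, expression_coupling = 4)
  gs <- simulate_genome(cfg)
  rep <- simulate_cytosine_reports(cfg, gs)
  calls <- call_sites(rep$group1, 0.005)
  el <- gene_elements(gs$genes, chrom_sizes = cfg$chrom_sizes)
  expr <- simulate_expression(cfg, gs)$expression
  cl <- expression_class_split(
    tibble::tibble(gene_id = expr$gene_id, sample = "g1",
                   fpkm = expr$fpkm_g1)
  )
  tab <- methylation_by_expression_class(calls, el, cl)
  p <- tab[tab$element == "promoter" & tab$context == "CG", ]
  expect_lt(p$mean_ml[p$class == "high"], p$mean_ml[p$class == "low"])
})

test_that("trait correlation matches the direct covariance formula", {
  expr <- tibble::tibble(
    gene_id = "g", sample = sprintf("s%d", 1:6),
    fpkm = c(1, 2, 3, 4, 5, 6)
  )
  tr_lin <- tibble::tibble(sample = sprintf("s%d", 1:6), trait = "t",
                           value = 2 * (1:6))
  expect_equal(trait_correlation(expr, tr_lin)$r, 1)
  tr_neg <- dplyr::mutate(tr_lin, value = -(1:6) + 5)
  expect_equal(trait_correlation(expr, tr_neg)$r, -1)

  withr::with_seed(83, {
    x <- rnorm(10)
    y <- rnorm(10)
  })
  ex <- tibble::tibble(gene_id = "g", sample = sprintf("s%d", 1:10),
                       fpkm = x)
  ty <- tibble::tibble(sample = sprintf("s%d", 1:10), trait = "t",
                       value = y)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- trait_correlation(ex, ty)
  expect_equal(out$r, direct, tolerance = 1e-12)
  expect_equal(out$n, 10L)

  flat <- dplyr::mutate(ty, value = 1)
  expect_true(is.na(trait_correlation(ex, flat)$r))

  expect_warning(two <- trait_correlation(ex[1:2, ], ty[1:2, ]),
                 "fewer than 3")
  expect_equal(two$n, 2L)
})

test_that("2^-ddCt folds follow the power identities", {
  ct <- tibble::tibble(condition = c("cal", "b", "c"),
                       ct_target = c(24, 25, 22),
                       ct_ref = c(18, 18, 18))
  out <- relative_expression(ct)
  expect_equal(out$fold, c(1, 0.5, 4))
  expect_true(all(out$fold > 0))

  missing_ref <- tibble::tibble(condition = "x", ct_target = 20,
                                ct_ref = NA_real_)
  expect_error(relative_expression(missing_ref), "reference")
})
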