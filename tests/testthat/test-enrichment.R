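test_that("two-sided Fisher p matches closed-form enumerations", {
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact_two_sided(0, 5, 5, 0), 2 / 252)
  expect_equal(fisher_exact_two_sided(2, 2, 2, 2), 1)
  expect_error(fisher_exact_two_sided(0, 0, 3, 4), "degenerate")
})

test_that("Fisher p agrees with the enumeration oracle and fisher.test", {
  set.seed(101)
  for (i in 1:60) {
    cells <- as.integer(rmultinom(1, sample(6:28, 1), rep(1, 4)))
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0 ||
        cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
    p <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
    ft <- fisher.test(matrix(cells, nrow = 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
    # symmetry: swapping the two genomes (rows) leaves p unchanged
    expect_equal(p, fisher_exact_two_sided(cells[3], cells[4],
                                           cells[1], cells[2]))
  }
})

test_that("chi-squared 2x2 reproduces the Pearson statistic", {
  res <- chi_squared_2x2(17, 3, 45, 60)
  expect_equal(res$p_value, 0.00055, tolerance = 0.02)
  ref <- suppressWarnings(
    chisq.test(matrix(c(17, 45, 3, 60), 2), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  flat <- chi_squared_2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_equal(chi_squared_2x2(20, 0, 0, 20)$statistic, 40)
  expect_error(chi_squared_2x2(0, 0, 5, 5), "degenerate")

  # continuity correction matches chisq.test(correct = TRUE)
  cc <- chi_squared_2x2(17, 3, 45, 60, continuity_correction = TRUE)
  refc <- chisq.test(matrix(c(17, 45, 3, 60), 2), correct = TRUE)
  expect_equal(cc$statistic, unname(refc$statistic))
})

test_that("fold versus median handles direction, ties and zeros", {
  bdfae <- c(EMU = 1, EMA = 2, ZRA = 3, CCO = 23, NTH = 25, PFO = 20,
             SCA = 23)
  fv <- fold_vs_median(bdfae, "EMU")
  expect_equal(fv$median, 20)
  expect_equal(fv$fold, 20)
  expect_equal(fv$direction, "down")

  up <- fold_vs_median(c(a = 348, b = 66, c = 66, d = 66, e = 66), "a")
  expect_equal(up$fold, 348 / 66)
  expect_equal(up$direction, "up")

  tie <- fold_vs_median(c(a = 5, b = 5, c = 5), "b")
  expect_equal(tie$fold, 1)
  expect_equal(tie$direction, "at_median")

  zero <- fold_vs_median(c(a = 0, b = 4, c = 6), "a")
  expect_equal(zero$fold, Inf)
  expect_equal(zero$direction, "down")
  expect_error(fold_vs_median(c(a = 1, b = 2), "z"), "key error")
})

test_that("pairwise enrichment flags planted signal and skips rare domains", {
  totals <- setNames(rep(10000, 7), paste0("g", 1:7))
  counts <- matrix(30L, nrow = 7, ncol = 3,
                   dimnames = list(names(totals), c("dA", "dB", "dC")))
  counts["g1", "dA"] <- 300L
  counts[, "dB"] <- 25L
  counts[2:7, "dC"] <- 0L  # present in one genome only
  m <- structure(list(counts = counts, totals = totals,
                      domain_db = setNames(rep("Pfam", 3),
                                           colnames(counts))),
                 class = "domain_count_matrix")
  res <- pairwise_domain_enrichment(m, enrichment_params())

  focal <- res[res$domain == "dA" & res$genome == "g1", ]
  expect_equal(focal$n_significant_pairs, 6L)
  expect_equal(focal$direction, "up")
  expect_equal(focal$fold, 10)

  flatrows <- res[res$domain == "dB", ]
  expect_true(all(flatrows$n_significant_pairs == 0L))
  expect_true(all(flatrows$direction == "at_median"))

  rare <- res[res$domain == "dC", ]
  expect_true(all(rare$skipped))
  expect_true(all(is.na(rare$n_significant_pairs)))
  pw <- attr(res, "pairwise")
  expect_false("dC" %in% pw$domain)
  # Bonferroni factor is the number of pairs per domain
  expect_equal(pw$adjusted_p, pmin(1, pw$p * choose(7, 2)))
})

test_that("representation calls need direction and a significant pair", {
  totals <- setNames(rep(5000, 3), paste0("g", 1:3))
  counts <- matrix(c(100L, 10L, 10L), nrow = 3, ncol = 1,
                   dimnames = list(names(totals), "d"))
  m <- structure(list(counts = counts, totals = totals,
                      domain_db = c(d = "Pfam")),
                 class = "domain_count_matrix")
  calls <- representation_calls(
    pairwise_domain_enrichment(m, enrichment_params()))
  expect_equal(calls$call[calls$genome == "g1"], "overrepresented")
  expect_true(all(calls$call[calls$genome != "g1"] != "overrepresented"))
})

test_that("gene-set Pfam enrichment computes the documented 2x2 and OR", {
  # universe of 1000 genes, domain in 100, set of 100 containing 50
  universe <- sprintf("u%04d", 1:1000)
  with_dom <- universe[1:100]
  set <- c(with_dom[1:50], universe[101:150])
  ann <- data.frame(genome_id = "g1", protein_id = with_dom,
                    domain_accession = "PF11111", domain_db = "Pfam",
                    n_instances = 1L, stringsAsFactors = FALSE)
  res <- gene_set_domain_enrichment(set, ann, enrichment_params(),
                                    universe_genes = universe)
  row <- res[res$pfam == "PF11111", ]
  expect_equal(row$in_set_with, 50L)
  expect_equal(row$odds_ratio, (50 * 850) / (50 * 50))
  expect_true(row$significant)
  # genes without any Pfam get the NO_PFAM pseudo-domain
  nop <- res[res$pfam == "NO_PFAM", ]
  expect_equal(nop$in_set_with, 50L)
  expect_equal(nop$out_set_with, 850L)

  # set == universe: degenerate margins, OR 1, nothing significant
  degen <- gene_set_domain_enrichment(universe, ann, enrichment_params(),
                                      universe_genes = universe)
  expect_true(all(degen$degenerate))
  expect_true(all(degen$odds_ratio == 1))
  expect_false(any(degen$significant))

  expect_error(
    gene_set_domain_enrichment("missing", ann, enrichment_params(),
                               universe_genes = universe),
    "not in universe")
})

test_that("planted 8-fold enrichments are recovered on simulated tables", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    sim <- simulate_domain_annotations(sim_annotation_params(
      n_domains = 50L,
      planted_enrichments = data.frame(domain = 1L, genome = "g1",
                                       fold = 8),
      seed = 5000L + r))
    m <- build_domain_count_matrix(sim$records, sim$totals)
    res <- pairwise_domain_enrichment(m, enrichment_params())
    focal <- res[res$domain == sim$truth$planted_enrichments$domain[1] &
                   res$genome == "g1", ]
    if (!is.na(focal$n_significant_pairs) &&
        focal$n_significant_pairs >= 1L && focal$direction == "up") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.95)
})
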