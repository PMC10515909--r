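make_ogs <- function(..., species) {
  ogs <- list(...)
  structure(ogs, species = species, class = "orthogroup_table")
}

four <- c("EMU", "EMA", "ZRA", "CTH")

test_that("orthogroups classify by exact species occupancy", {
  ogs <- make_ogs(
    OG0 = list(EMU = "e1", EMA = "m1", ZRA = "z1", CTH = "c1"),
    OG1 = list(EMU = c("e2", "e3"), EMA = character(0),
               ZRA = character(0), CTH = character(0)),
    OG2 = list(EMU = "e4", EMA = "m2", ZRA = character(0),
               CTH = character(0)),
    species = four)
  cls <- classify_orthogroups(ogs, four)
  expect_equal(cls$class, c("core", "species_specific", "shared_subset"))
  expect_equal(cls$species_subset[2], "EMU")
  expect_equal(cls$species_subset[3], "EMU,EMA")

  bad <- make_ogs(OG0 = list(XXX = "x1"), species = "XXX")
  expect_error(classify_orthogroups(bad, four), "not in universe")
})

test_that("occupancy summary percentages partition to 100", {
  ogs <- make_ogs(
    OG0 = list(A = "a1", B = "b1"), OG1 = list(A = "a2", B = character(0)),
    OG2 = list(A = "a3", B = character(0)), OG3 = list(A = character(0), B = "b2"),
    OG4 = list(A = "a4", B = "b3"),
    species = c("A", "B"))
  s <- occupancy_summary(classify_orthogroups(ogs, c("A", "B")), c("A", "B"))
  expect_equal(s$n_ogs, 5L)
  expect_equal(sum(s$class_pct), 100)
  expect_equal(unname(s$class_counts["core"]), 2L)
  expect_equal(
    s$per_species$pct_species_specific[s$per_species$species == "A"], 40)
  expect_equal(
    s$per_species$pct_ogs_with_gene[s$per_species$species == "B"], 60)
  expect_error(occupancy_summary(data.frame()), "nrow")
})

test_that("gene status partitions genes and flags potential specificity", {
  ogs <- make_ogs(
    OGcore = list(EMU = "e1", EMA = "m1", ZRA = "z1", CTH = "c1"),
    OGspec = list(EMU = c("e2", "e3"), EMA = character(0),
                  ZRA = character(0), CTH = character(0)),
    species = four)
  universe <- list(EMU = c("e1", "e2", "e3", "e9"), EMA = c("m1", "m9"),
                   ZRA = "z1", CTH = "c1")
  st <- classify_genes(ogs, universe)
  expect_equal(st$status[st$gene_id == "e1"], "assigned_shared")
  expect_equal(st$status[st$gene_id == "e2"], "assigned_species_specific")
  expect_equal(st$status[st$gene_id == "e9"], "unassigned")
  expect_identical(st$potentially_species_specific,
                   st$status != "assigned_shared")
  # per-species percentages partition to 100
  summ <- attr(st, "summary")
  expect_equal(summ$pct_assigned_shared + summ$pct_assigned_species_specific +
                 summ$pct_unassigned, rep(100, 4), tolerance = 1e-9)

  bad_universe <- list(EMU = "e1", EMA = "m1", ZRA = "z1", CTH = "c1")
  expect_error(classify_genes(ogs, bad_universe), "absent from")
})

test_that("species-specific OG counts match single-species exclusive sets", {
  set.seed(61)
  sim <- simulate_orthogroups(sim_og_params(seed = 8L))
  cls <- classify_orthogroups(sim$ogs, attr(sim$ogs, "species"))
  presence <- lapply(setNames(nm = attr(sim$ogs, "species")), function(sp) {
    names(sim$ogs)[vapply(sim$ogs, function(m) length(m[[sp]]) > 0L,
                          logical(1))]
  })
  inter <- exclusive_intersections(presence)
  for (sp in attr(sim$ogs, "species")) {
    expect_equal(inter$n_domains[inter$subset == sp],
                 sum(cls$class == "species_specific" &
                       cls$species_subset == sp))
  }
})

test_that("expression filter drops genes below 5 pooled counts", {
  statuses <- data.frame(
    gene_id = c("e1", "e2", "e3", "e4"), species = "EMU",
    og_id = NA_character_,
    status = c("unassigned", "unassigned", "assigned_species_specific",
               "assigned_shared"),
    potentially_species_specific = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  expression <- data.frame(
    gene_id = c("e1", "e2", "e3", "e3", "e3"),
    sample_id = c("s1", "s1", "s1", "s2", "s3"),
    est_counts = c(4.9, 5.0, 2, 2, 2))
  res <- apply_expression_filter(statuses, expression,
                                 occupancy_params("EMU"))
  expect_setequal(res$retained$gene_id, c("e2", "e3"))  # 5.0 and 2+2+2
  expect_identical(res$removed$gene_id, "e1")           # 4.9 < 5
  expect_equal(res$summary$pct_before, 75)
  expect_equal(res$summary$pct_after, 50)

  # genes absent from the expression table count as zero
  empty <- apply_expression_filter(statuses, expression[0, ],
                                   occupancy_params("EMU"))
  expect_equal(nrow(empty$retained), 0L)
})

test_that("planted occupancy structure is recovered exactly", {
  sim <- simulate_orthogroups(sim_og_params(seed = 99L))
  species <- attr(sim$ogs, "species")
  cls <- classify_orthogroups(sim$ogs, species)
  expect_identical(
    setNames(cls$class, cls$og_id),
    setNames(sim$truth$orthogroups$class, sim$truth$orthogroups$og_id))
  st <- classify_genes(sim$ogs, sim$gene_universe)
  truth <- sim$truth$genes
  expect_identical(st$status[match(truth$gene_id, st$gene_id)], truth$status)
  # expression filter agrees with the simulator's expressed flag
  filt <- apply_expression_filter(st, sim$expression,
                                  occupancy_params(species))
  spec_truth <- truth[truth$status != "assigned_shared", ]
  expect_setequal(filt$retained$gene_id,
                  spec_truth$gene_id[spec_truth$expressed])
})
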