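small_genome_params <- function(rate = 0.2, seed = 5L) {
  sim_genome_params(
    length_bp = 50000L,
    repeat_families = data.frame(family_id = c("famA", "famB"),
                                 unit_length = 1500L, n_copies = 4L),
    rip_rate = rate, seed = seed)
}

test_that("genome simulation is seed-deterministic with exact repeat copies", {
  a <- simulate_genome(small_genome_params())
  b <- simulate_genome(small_genome_params())
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$repeats, b$repeats)

  # rate 0: every copy is an exact duplicate of its family master
  sim0 <- simulate_genome(small_genome_params(rate = 0))
  expect_equal(nrow(sim0$mutations), 0L)
  for (fam in unique(sim0$repeats$family_id)) {
    reg <- sim0$repeats[sim0$repeats$family_id == fam, ]
    copies <- substring(sim0$sequences[reg$seq_id], reg$start + 1, reg$end)
    expect_length(unique(copies), 1L)
  }

  # repeat placements never overlap
  reg <- a$repeats[order(a$repeats$start), ]
  expect_true(all(reg$end[-nrow(reg)] <= reg$start[-1]))
})

test_that("background GC lands within binomial sampling error", {
  sim <- simulate_genome(sim_genome_params(
    length_bp = 100000L, gc_fraction = 0.5,
    repeat_families = data.frame(family_id = character(),
                                 unit_length = integer(),
                                 n_copies = integer()),
    seed = 12L))
  bases <- strsplit(sim$sequences[[1]], "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  se <- sqrt(0.5 * 0.5 / 100000)
  expect_lt(abs(gc - 0.5), 3 * se)
})

test_that("RIP mutation hits exactly the CpA/TpG contexts at rate 1", {
  full <- data.frame(start = 0, end = 4)
  expect_identical(apply_rip_mutations("CACA", full, 1, 1)$sequence, "TATA")
  expect_identical(apply_rip_mutations("TGTG", full, 1, 1)$sequence, "TATA")
  expect_identical(apply_rip_mutations("CACA", full, 0, 1)$sequence, "CACA")

  # sites outside the region are untouched; truth lists each mutation
  res <- apply_rip_mutations("CACACACA", data.frame(start = 0, end = 4), 1, 1)
  expect_identical(res$sequence, "TATACACA")
  expect_equal(res$mutations$pos, c(0, 2))
  expect_true(all(res$mutations$from == "C" & res$mutations$to == "T"))

  expect_error(
    apply_rip_mutations("CACA", data.frame(start = c(0, 1), end = c(3, 4)),
                        1, 1),
    "overlapping")

  # capacity: repeats that cannot fit are rejected up front
  expect_error(sim_genome_params(
    length_bp = 1000L,
    repeat_families = data.frame(family_id = "f", unit_length = 600L,
                                 n_copies = 2L)),
    "capacity")
})

test_that("RIP mutations raise TpA and deplete CpA/TpG as the index assumes", {
  sim0 <- simulate_genome(small_genome_params(rate = 0))
  sim2 <- simulate_genome(small_genome_params(rate = 0.2))
  d0 <- count_dinucleotides(sim0$sequences[[1]])
  d2 <- count_dinucleotides(sim2$sequences[[1]])
  expect_gt(d2[["TA"]], d0[["TA"]])
  expect_lt(d2[["CA"]] + d2[["TG"]], d0[["CA"]] + d0[["TG"]])
})

test_that("simulated annotation tables parse through the readers unchanged", {
  sim <- simulate_domain_annotations(sim_annotation_params(
    n_genomes = 3L, n_domains = 20L, baseline_lambda = 4, totals = 300L,
    planted_architectures = data.frame(genome = "g1", label = "AGO",
                                       n_proteins = 1L),
    seed = 21L))
  path <- tempfile(fileext = ".tsv")
  write_domain_annotations(sim$records, path)
  back <- read_domain_annotations(path)
  expect_equal(back, sim$records)

  same <- simulate_domain_annotations(sim_annotation_params(
    n_genomes = 3L, n_domains = 20L, baseline_lambda = 4, totals = 300L,
    planted_architectures = data.frame(genome = "g1", label = "AGO",
                                       n_proteins = 1L),
    seed = 21L))
  expect_identical(sim$records, same$records)
})

test_that("simulated genomes and orthogroups round-trip through files", {
  gsim <- simulate_genome(small_genome_params())
  fa <- tempfile(fileext = ".fasta")
  write_fasta(gsim$sequences, fa)
  expect_identical(read_fasta(fa), gsim$sequences)

  osim <- simulate_orthogroups(sim_og_params(seed = 31L))
  og <- tempfile(fileext = ".tsv")
  write_orthogroups(osim$ogs, og)
  back <- read_orthogroups(og)
  expect_identical(lapply(back, identity), lapply(osim$ogs, identity))

  ex <- tempfile(fileext = ".tsv")
  write_expression(osim$expression, ex)
  expect_equal(read_expression(ex)$est_counts, osim$expression$est_counts,
               tolerance = 1e-6)
})

test_that("degenerate simulator settings produce the expected limits", {
  allcore <- simulate_orthogroups(sim_og_params(
    n_core = 30L,
    shared_counts = setNames(integer(0), character(0)),
    specific_counts = c(EMU = 0L, EMA = 0L, ZRA = 0L, CTH = 0L),
    unassigned_counts = c(EMU = 0L, EMA = 0L, ZRA = 0L, CTH = 0L),
    seed = 3L))
  cls <- classify_orthogroups(allcore$ogs, attr(allcore$ogs, "species"))
  expect_true(all(cls$class == "core"))

  nothing_expressed <- simulate_orthogroups(sim_og_params(p0 = 1, seed = 3L))
  st <- classify_genes(nothing_expressed$ogs,
                       nothing_expressed$gene_universe)
  filt <- apply_expression_filter(
    st, nothing_expressed$expression,
    occupancy_params(attr(nothing_expressed$ogs, "species")))
  expect_equal(nrow(filt$retained), 0L)
})
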