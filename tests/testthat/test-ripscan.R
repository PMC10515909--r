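test_that("dinucleotide counts match hand enumeration and mask N pairs", {
  counts <- count_dinucleotides("CATG")
  expect_equal(counts[["CA"]], 1L)
  expect_equal(counts[["AT"]], 1L)
  expect_equal(counts[["TG"]], 1L)
  expect_equal(sum(counts), 3L)

  expect_equal(sum(count_dinucleotides("")), 0L)
  expect_equal(sum(count_dinucleotides("A")), 0L)

  masked <- count_dinucleotides("ANAT")
  expect_equal(masked[["AT"]], 1L)
  expect_equal(sum(masked), 1L)

  expect_error(count_dinucleotides("ACXT"), "alphabet")

  set.seed(41)
  for (i in 1:25) {
    s <- random_dna(sample(2:80, 1), c("A", "C", "G", "T", "N"))
    expect_equal(unname(count_dinucleotides(s)), unname(oracle_dinuc(s)))
  }
})

test_that("RIP indices follow the product/substrate/composite definitions", {
  idx <- compute_rip_indices(count_dinucleotides("TATAGT"))
  expect_equal(idx$product_index, 2)
  expect_equal(idx$substrate_index, 0)
  expect_equal(idx$composite_index, 2)
  expect_true(idx$evaluable)

  idx2 <- compute_rip_indices(count_dinucleotides("ATCATGGT"))
  expect_equal(idx2$product_index, 0)
  expect_equal(idx2$substrate_index, 2)
  expect_equal(idx2$composite_index, -2)

  degenerate <- compute_rip_indices(count_dinucleotides("TATATA"))
  expect_false(degenerate$evaluable)
  expect_true(is.na(degenerate$composite_index))
})

test_that("window layout obeys the step/short-window rules", {
  g <- function(n) c(s = random_dna(n))
  set.seed(7)
  w2000 <- scan_windows(g(2000))
  expect_equal(nrow(w2000), 3L)
  expect_equal(w2000$start, c(0L, 500L, 1000L))
  expect_equal(w2000$end, c(1000L, 1500L, 2000L))

  expect_equal(nrow(scan_windows(g(999))), 1L)
  expect_equal(scan_windows(g(999))$end, 999L)
  expect_equal(nrow(scan_windows(g(400))), 0L)

  # terminal short window extending past the last full window is kept
  w1800 <- scan_windows(g(1800))
  expect_equal(w1800$end[nrow(w1800)], 1800L)
  expect_equal(w1800$start[nrow(w1800)], 1000L)

  # closed form for full windows
  for (L in c(1000, 1500, 5000, 12345)) {
    w <- scan_windows(g(L))
    n_full <- sum(w$end - w$start == 1000L)
    expect_equal(n_full, floor((L - 1000) / 500) + 1)
  }

  # windows never cross sequence boundaries
  multi <- c(a = random_dna(1250), b = random_dna(990))
  w <- scan_windows(multi)
  expect_true(all(w$end[w$seq_id == "a"] <= 1250))
  expect_true(all(w$end[w$seq_id == "b"] <= 990))
})

test_that("scanned indices agree exactly with a naive window recount", {
  set.seed(13)
  params <- rip_scan_params(window_bp = 50L, step_bp = 20L)
  for (i in 1:20) {
    s <- random_dna(sample(40:200, 1), c("A", "C", "G", "T", "N"))
    w <- scan_windows(c(x = s), params)
    for (j in seq_len(nrow(w))) {
      frag <- substr(s, w$start[j] + 1L, w$end[j])
      expect_equal(w$composite_index[j], oracle_rip_composite(frag))
    }
  }
})

test_that("the composite index is strand-invariant", {
  set.seed(17)
  for (i in 1:200) {
    s <- random_dna(sample(20:120, 1))
    fwd <- compute_rip_indices(count_dinucleotides(s))
    rev <- compute_rip_indices(count_dinucleotides(revcomp(s)))
    expect_equal(fwd$evaluable, rev$evaluable)
    if (fwd$evaluable) {
      expect_equal(fwd$composite_index, rev$composite_index)
    }
  }
})

test_that("percent RIPped counts strictly positive evaluable windows", {
  w <- data.frame(composite_index = c(2, -1, 0), evaluable = TRUE)
  s <- summarize_rip(w, rip_scan_params())
  expect_equal(s$n_rip_positive, 1L)
  expect_equal(s$pct_ripped, 100 / 3)

  w2 <- data.frame(composite_index = rep(1, 10), evaluable = TRUE)
  expect_equal(summarize_rip(w2, rip_scan_params())$pct_ripped, 100)

  w3 <- data.frame(composite_index = NA_real_, evaluable = FALSE)
  expect_warning(s3 <- summarize_rip(w3, rip_scan_params()), "evaluable")
  expect_true(is.na(s3$pct_ripped))
})

test_that("mean composite over RIPped repeats is non-decreasing in rate", {
  rates <- c(0, 0.05, 0.1, 0.2)
  means <- pcts <- numeric(length(rates))
  for (k in seq_along(rates)) {
    sim <- simulate_genome(sim_genome_params(
      length_bp = 100000L,
      repeat_families = data.frame(family_id = paste0("fam", 1:3),
                                   unit_length = 2000L, n_copies = 5L),
      rip_rate = rates[k], seed = 2024L))
    w <- scan_windows(sim$sequences)
    rip <- sim$repeats[sim$repeats$ripped, , drop = FALSE]
    inside <- mapply(function(st, en) {
      any(rip$start <= st & rip$end >= en)
    }, w$start, w$end)
    means[k] <- mean(w$composite_index[inside & w$evaluable])
    pcts[k] <- summarize_rip(w, rip_scan_params())$pct_ripped
  }
  expect_true(all(diff(means) >= 0))
  expect_gt(pcts[length(pcts)], pcts[1])
})

test_that("bedGraph output is half-open and omits non-evaluable windows", {
  w <- scan_windows(c(s = paste0(strrep("TTTT", 125), random_dna(1000))),
                    rip_scan_params())
  path <- tempfile(fileext = ".bedgraph")
  write_rip_bedgraph(w, path)
  lines <- readLines(path)
  expect_match(lines[1], "^track type=bedGraph")
  body <- read.delim(text = lines[-1], header = FALSE)
  expect_equal(nrow(body), sum(w$evaluable))
  expect_true(all(body$V3 > body$V2))
})
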