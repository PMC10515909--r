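# Independent brute-force oracles used to validate the fast implementations.
# These share no code with the package internals.

# dinucleotide counting by explicit character-pair enumeration
oracle_dinuc <- function(sequence) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  counts <- setNames(integer(16L),
                     as.vector(t(outer(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T"), paste0))))
  if (length(bases) >= 2L) {
    for (i in seq_len(length(bases) - 1L)) {
      pair <- paste0(bases[i], bases[i + 1L])
      if (pair %in% names(counts)) counts[pair] <- counts[pair] + 1L
    }
  }
  counts
}

# composite RIP index recomputed from first principles on one window
oracle_rip_composite <- function(sequence) {
  n <- oracle_dinuc(sequence)
  if (n[["AT"]] == 0L || n[["AC"]] + n[["GT"]] == 0L) return(NA_real_)
  n[["TA"]] / n[["AT"]] - (n[["CA"]] + n[["TG"]]) / (n[["AC"]] + n[["GT"]])
}

# two-sided Fisher exact p by exhaustive enumeration of all tables with the
# observed margins, using closed-form binomial products (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  support <- max(0L, c1 - r2):min(c1, r1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1L))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

revcomp <- function(sequence) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(sequence, "", fixed = TRUE)[[1L]]),
               collapse = ""))
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
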