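#' Parameters for a windowed RIP scan
#'
#' Defaults reproduce the standard scan: 1 kb windows advanced in 500 bp
#' steps, terminal short windows kept when at least half a window long, and
#' a window called RIP-positive when its composite index is strictly greater
#' than 0.
#'
#' @param window_bp Window length in bp.
#' @param step_bp Step (offset) between window starts in bp; must not exceed
#'   `window_bp`.
#' @param min_window_fraction Minimum length of a terminal short window,
#'   as a fraction of `window_bp`, for it to be emitted.
#' @param rip_threshold Composite-index threshold; windows with composite
#'   strictly above it count as RIP-positive.
#' @return An object of class `rip_scan_params`.
#' @export
rip_scan_params <- function(window_bp = 1000L, step_bp = 500L,
                            min_window_fraction = 0.5, rip_threshold = 0) {
  window_bp <- as.integer(window_bp)
  step_bp <- as.integer(step_bp)
  stopifnot(window_bp >= 1L, step_bp >= 1L, step_bp <= window_bp,
            min_window_fraction > 0, min_window_fraction <= 1,
            is.numeric(rip_threshold), length(rip_threshold) == 1L)
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 min_window_fraction = min_window_fraction,
                 rip_threshold = rip_threshold),
            class = "rip_scan_params")
}

.check_alphabet <- function(sequence) {
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("alphabet error: illegal character '",
         substr(sequence, bad, bad), "' at position ", bad)
  }
  invisible(TRUE)
}

#' Count overlapping dinucleotides in a sequence
#'
#' Counts all 16 dinucleotides over `{A,C,G,T}` left-to-right on the given
#' strand. Pairs containing `N` contribute nothing, so hard-masked input is
#' handled transparently.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`.
#' @return Named integer vector of length 16 (names `AA`, `AC`, ..., `TT`).
#' @examples
#' count_dinucleotides("CATG")
#' @export
count_dinucleotides <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  .check_alphabet(sequence)
  if (nchar(sequence) < 2L) {
    counts <- integer(16L)
    names(counts) <- .dinuc_names
    return(counts)
  }
  Biostrings::dinucleotideFrequency(Biostrings::DNAString(sequence))
}

# canonical Biostrings column order: AA AC AG AT CA ... TT
.dinuc_names <- as.vector(t(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)))

#' Compute RIP indices from dinucleotide counts
#'
#' The product index is TpA/ApT (RIP products raise TpA); the substrate
#' index is (CpA+TpG)/(ApC+GpT) (RIP depletes its CpA/TpG substrate pool);
#' the composite index is their difference, positive values indicating
#' RIP-altered sequence. A window is evaluable only when both denominators
#' (ApT and ApC+GpT) are positive; otherwise all three indices are `NA`.
#'
#' @param counts Named dinucleotide count vector as returned by
#'   [count_dinucleotides()].
#' @return List with `product_index`, `substrate_index`, `composite_index`
#'   (all `NA` when not evaluable) and logical `evaluable`.
#' @examples
#' compute_rip_indices(count_dinucleotides("TATAGT"))
#' @export
compute_rip_indices <- function(counts) {
  stopifnot(all(.dinuc_names %in% names(counts)))
  tpa <- as.numeric(counts[["TA"]])
  apt <- as.numeric(counts[["AT"]])
  cpa_tpg <- as.numeric(counts[["CA"]]) + as.numeric(counts[["TG"]])
  apc_gpt <- as.numeric(counts[["AC"]]) + as.numeric(counts[["GT"]])
  if (apt == 0 || apc_gpt == 0) {
    return(list(product_index = NA_real_, substrate_index = NA_real_,
                composite_index = NA_real_, evaluable = FALSE))
  }
  product <- tpa / apt
  substrate <- cpa_tpg / apc_gpt
  list(product_index = product, substrate_index = substrate,
       composite_index = product - substrate, evaluable = TRUE)
}

# window layout for one sequence length; returns 0-based starts and ends
.window_layout <- function(len, params) {
  w <- params$window_bp
  s <- params$step_bp
  minlen <- params$min_window_fraction * w
  if (len >= w) {
    full_starts <- seq.int(0L, by = s, length.out = (len - w) %/% s + 1L)
    starts <- full_starts
    ends <- starts + w
    # terminal short window: only when the last full window does not already
    # end at the sequence end (it would otherwise be a strict suffix of it)
    tail_start <- full_starts[length(full_starts)] + s
    tail_len <- len - tail_start
    if (ends[length(ends)] < len && tail_len >= minlen) {
      starts <- c(starts, tail_start)
      ends <- c(ends, len)
    }
  } else if (len >= minlen) {
    starts <- 0L
    ends <- len
  } else {
    starts <- integer(0L)
    ends <- integer(0L)
  }
  list(start = as.integer(starts), end = as.integer(ends))
}

#' Scan genome sequences in sliding windows and compute RIP indices
#'
#' Tiles every sequence with windows of `window_bp` bases advanced by
#' `step_bp` (windows never cross sequence boundaries) and computes the
#' product, substrate and composite RIP indices in each window. A terminal
#' short window is emitted only when it is at least
#' `min_window_fraction * window_bp` long and is not already covered by a
#' full window ending at the sequence end.
#'
#' @param genome Named character vector of sequences (as from
#'   [read_fasta()]).
#' @param params A [rip_scan_params()] object.
#' @return `data.frame` of class `rip_windows` with columns `seq_id`,
#'   `start` (0-based inclusive), `end` (exclusive), the four dinucleotide
#'   sums entering the indices (`tpa`, `apt`, `cpa_tpg`, `apc_gpt`),
#'   `product_index`, `substrate_index`, `composite_index` and `evaluable`;
#'   ordered by sequence, then start. The scan parameters are stored in
#'   `attr(, "params")`.
#' @export
scan_windows <- function(genome, params = rip_scan_params()) {
  stopifnot(inherits(params, "rip_scan_params"),
            is.character(genome), length(genome) > 0L,
            !is.null(names(genome)))
  pieces <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    seq_i <- toupper(genome[[i]])
    .check_alphabet(seq_i)
    lay <- .window_layout(nchar(seq_i), params)
    if (length(lay$start) == 0L) {
      pieces[[i]] <- NULL
      next
    }
    frags <- substring(seq_i, lay$start + 1L, lay$end)
    counts <- Biostrings::dinucleotideFrequency(Biostrings::DNAStringSet(frags))
    tpa <- counts[, "TA"]
    apt <- counts[, "AT"]
    cpa_tpg <- counts[, "CA"] + counts[, "TG"]
    apc_gpt <- counts[, "AC"] + counts[, "GT"]
    evaluable <- apt > 0 & apc_gpt > 0
    product <- ifelse(evaluable, tpa / apt, NA_real_)
    substrate <- ifelse(evaluable, cpa_tpg / apc_gpt, NA_real_)
    pieces[[i]] <- data.frame(
      seq_id = names(genome)[i], start = lay$start, end = lay$end,
      tpa = tpa, apt = apt, cpa_tpg = cpa_tpg, apc_gpt = apc_gpt,
      product_index = product, substrate_index = substrate,
      composite_index = product - substrate, evaluable = evaluable,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), tpa = integer(), apt = integer(),
                      cpa_tpg = integer(), apc_gpt = integer(),
                      product_index = numeric(), substrate_index = numeric(),
                      composite_index = numeric(), evaluable = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("rip_windows", "data.frame")
  out
}

#' Summarize a RIP window scan into the percent-RIPped statistic
#'
#' A window is RIP-positive when it is evaluable and its composite index is
#' strictly greater than `rip_threshold`. The percent-RIPped statistic is
#' 100 * n_rip_positive / n_evaluable; non-evaluable windows (zero
#' denominators) carry no signal and are excluded from the denominator. All
#' counts are reported so the all-windows convention remains recoverable.
#'
#' @param windows A `rip_windows` data frame from [scan_windows()].
#' @param params A [rip_scan_params()] object (supplies `rip_threshold`).
#' @return List of class `rip_summary`: `n_windows`, `n_evaluable`,
#'   `n_rip_positive`, `pct_ripped` (`NA` when no window is evaluable),
#'   plus the scan parameters.
#' @export
summarize_rip <- function(windows, params = attr(windows, "params")) {
  if (is.null(params)) params <- rip_scan_params()
  stopifnot(inherits(params, "rip_scan_params"),
            all(c("composite_index", "evaluable") %in% names(windows)))
  n_windows <- nrow(windows)
  n_evaluable <- sum(windows$evaluable)
  n_pos <- sum(windows$evaluable &
                 windows$composite_index > params$rip_threshold)
  if (n_evaluable > 0L) {
    pct <- 100 * n_pos / n_evaluable
  } else {
    warning("no evaluable windows; pct_ripped is undefined")
    pct <- NA_real_
  }
  structure(list(n_windows = n_windows, n_evaluable = n_evaluable,
                 n_rip_positive = n_pos, pct_ripped = pct,
                 window_bp = params$window_bp, step_bp = params$step_bp,
                 min_window_fraction = params$min_window_fraction,
                 rip_threshold = params$rip_threshold),
            class = "rip_summary")
}

#' @export
print.rip_summary <- function(x, ...) {
  cat("RIP scan summary (", x$window_bp, " bp windows, ", x$step_bp,
      " bp steps)\n", sep = "")
  cat("  windows:      ", x$n_windows, "\n", sep = "")
  cat("  evaluable:    ", x$n_evaluable, "\n", sep = "")
  cat("  RIP-positive: ", x$n_rip_positive, " (composite > ",
      x$rip_threshold, ")\n", sep = "")
  cat("  % RIPped:     ",
      if (is.na(x$pct_ripped)) "undefined" else
        sprintf("%.2f%%", x$pct_ripped), "\n", sep = "")
  invisible(x)
}

#' Write the composite RIP index per window as a bedGraph track
#'
#' Emits 0-based half-open intervals; non-evaluable windows are omitted.
#'
#' @param windows A `rip_windows` data frame.
#' @param path Output path.
#' @param track_name Track name for the bedGraph header line.
#' @return Invisibly, `path`.
#' @export
write_rip_bedgraph <- function(windows, path,
                               track_name = "composite_rip_index") {
  keep <- windows[windows$evaluable, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  if (nrow(keep) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", keep$seq_id, keep$start, keep$end,
                       keep$composite_index), con)
  }
  invisible(path)
}

#' Write all RIP windows (indices and evaluability) as TSV
#' @param windows A `rip_windows` data frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rip_windows <- function(windows, path) {
  utils::write.table(as.data.frame(windows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a RIP summary as JSON
#' @param summary A `rip_summary` object.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_rip_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
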