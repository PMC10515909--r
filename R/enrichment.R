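#' Parameters for domain enrichment analyses
#'
#' @param alpha Significance threshold on the Bonferroni-corrected p-value
#'   of a pairwise comparison (strict `<`).
#' @param correction Multiple-testing correction; only `"bonferroni"` (over
#'   the pairwise comparisons of one domain) reproduces the standard
#'   per-domain pairwise-test semantics. `"BH"` is available as an
#'   alternative.
#' @param min_genomes_present Minimum number of genomes a domain must be
#'   present in (count >= 1) to be tested pairwise.
#' @param gene_set_alpha Threshold for gene-set (subset vs universe) tests
#'   (inclusive `<=`).
#' @return Object of class `enrichment_params`.
#' @export
enrichment_params <- function(alpha = 0.01, correction = "bonferroni",
                              min_genomes_present = 2L,
                              gene_set_alpha = 0.001) {
  stopifnot(alpha > 0, alpha < 1, gene_set_alpha > 0, gene_set_alpha < 1,
            min_genomes_present >= 1L,
            correction %in% c("bonferroni", "BH"))
  structure(list(alpha = alpha, correction = correction,
                 min_genomes_present = as.integer(min_genomes_present),
                 gene_set_alpha = gene_set_alpha),
            class = "enrichment_params")
}

# vectorized two-sided Fisher p for tables given as columns a,b,c,d;
# assumes margins already validated
.fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]           # row 1 total
    m2 <- c[i] + d[i]           # row 2 total
    k <- a[i] + c[i]            # column 1 total
    lo <- max(0L, k - m2)
    hi <- min(k, m1)
    support <- lo:hi
    dens <- stats::dhyper(support, m1, m2, k)
    p_obs <- dens[support == a[i]]
    p[i] <- min(1, sum(dens[dens <= p_obs * (1 + rel_tol)]))
  }
  p
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test: with all margins fixed, the two-sided p-value is
#' the sum of hypergeometric probabilities of all tables as or less probable
#' than the observed one (a relative tolerance of 1e-7 on the comparison
#' absorbs floating-point error).
#'
#' @param a,b,c,d Non-negative integer cells of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)))
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("degenerate-table error: a margin of the 2x2 table is zero")
  }
  .fisher_p(a, b, c, d)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' @param a,b,c,d Non-negative cells of the table `rbind(c(a, b), c(c, d))`.
#' @param continuity_correction Apply the Yates continuity correction
#'   (default `FALSE`).
#' @return List with `statistic` (1 df) and `p_value` (upper tail).
#' @examples
#' chi_squared_2x2(17, 3, 45, 60)
#' @export
chi_squared_2x2 <- function(a, b, c, d, continuity_correction = FALSE) {
  obs <- matrix(c(a, c, b, d), nrow = 2L)
  stopifnot(all(obs >= 0))
  n <- sum(obs)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  if (any(expected == 0)) {
    stop("degenerate-table error: zero expected cell")
  }
  dev <- abs(obs - expected)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE))
}

#' Fold change of a focal genome's domain count versus the cross-genome median
#'
#' The median is taken over all genomes including the focal one. The fold is
#' always >= 1 (`max(count, median) / min(count, median)`) with the
#' direction reported separately: `"up"` when the focal count exceeds the
#' median, `"down"` when below, `"at_median"` when equal. When the smaller
#' of the two is zero and they differ the fold is infinite (`Inf`).
#'
#' @param counts Named vector of per-genome protein counts for one domain.
#' @param focal Genome id.
#' @return List with `fold`, `direction` and `median`.
#' @examples
#' fold_vs_median(c(EMU = 1, EMA = 2, ZRA = 3, CCO = 23, NTH = 25,
#'                  PFO = 20, SCA = 23), "EMU")
#' @export
fold_vs_median <- function(counts, focal) {
  stopifnot(length(counts) >= 2L, !is.null(names(counts)))
  if (!focal %in% names(counts)) {
    stop("key error: unknown focal genome '", focal, "'")
  }
  med <- stats::median(counts)
  cf <- as.numeric(counts[[focal]])
  if (cf == med) {
    fold <- 1
    direction <- "at_median"
  } else {
    direction <- if (cf > med) "up" else "down"
    lo <- min(cf, med)
    fold <- if (lo == 0) Inf else max(cf, med) / lo
  }
  list(fold = fold, direction = direction, median = med)
}

#' Pairwise Fisher exact enrichment of domain counts across genomes
#'
#' For every domain present in at least `min_genomes_present` genomes, each
#' unordered genome pair (i, j) is tested with a two-sided Fisher exact test
#' on the table `[[c_i, T_i - c_i], [c_j, T_j - c_j]]`, where `c` is the
#' number of proteins bearing the domain and `T` the genome's total
#' annotated proteins. P-values are Bonferroni-corrected within each domain
#' (factor = number of pairs, `choose(G, 2)`); a pair is significant when
#' the corrected p is strictly below `alpha`. Per (domain, genome) the
#' number of significant pairs involving that genome is reported together
#' with the fold and direction versus the cross-genome median count.
#' Domains failing the presence filter are emitted with `skipped = TRUE`
#' and no test results.
#'
#' @param matrix A `domain_count_matrix` (see [build_domain_count_matrix()]).
#' @param params An [enrichment_params()] object.
#' @return `data.frame` with columns `domain`, `domain_db`, `genome`,
#'   `count`, `median_count`, `fold`, `direction`, `n_significant_pairs`,
#'   `min_adjusted_p`, `skipped`. The full pairwise test table
#'   (`domain`, `genome_i`, `genome_j`, `p`, `adjusted_p`, `significant`)
#'   is attached as `attr(, "pairwise")`.
#' @export
pairwise_domain_enrichment <- function(matrix,
                                       params = enrichment_params()) {
  stopifnot(inherits(matrix, "domain_count_matrix"),
            inherits(params, "enrichment_params"))
  counts <- matrix$counts
  totals <- matrix$totals[rownames(counts)]
  if (anyNA(totals)) stop("validation error: totals missing for a genome")
  genomes <- rownames(counts)
  G <- length(genomes)
  if (G < 2L) stop("validation error: need >= 2 genomes")
  pairs <- utils::combn(G, 2L)
  n_pairs <- ncol(pairs)
  tested <- colSums(counts >= 1L) >= params$min_genomes_present
  doms <- colnames(counts)

  pw <- NULL
  nsig_mat <- matrix(NA_integer_, nrow = G, ncol = length(doms),
                     dimnames = list(genomes, doms))
  minp_mat <- matrix(NA_real_, nrow = G, ncol = length(doms),
                     dimnames = list(genomes, doms))
  if (any(tested)) {
    td <- doms[tested]
    ci <- as.vector(counts[pairs[1L, ], td, drop = FALSE])
    cj <- as.vector(counts[pairs[2L, ], td, drop = FALSE])
    ti <- rep(totals[pairs[1L, ]], times = length(td))
    tj <- rep(totals[pairs[2L, ]], times = length(td))
    # identical tables recur constantly across domains; test each once
    keys <- paste(ci, ti, cj, tj, sep = "/")
    ukeys <- !duplicated(keys)
    p_unique <- .fisher_p(ci[ukeys], ti[ukeys] - ci[ukeys],
                          cj[ukeys], tj[ukeys] - cj[ukeys])
    p <- p_unique[match(keys, keys[ukeys])]
    adj <- if (params$correction == "bonferroni") {
      pmin(1, p * n_pairs)
    } else {
      as.vector(apply(matrix(p, nrow = n_pairs), 2L,
                      stats::p.adjust, method = "BH"))
    }
    sig <- adj < params$alpha
    pw <- data.frame(
      domain = rep(td, each = n_pairs),
      genome_i = rep(genomes[pairs[1L, ]], times = length(td)),
      genome_j = rep(genomes[pairs[2L, ]], times = length(td)),
      p = p, adjusted_p = adj, significant = sig,
      stringsAsFactors = FALSE
    )
    # genome x pair incidence folds the pairwise columns onto genomes
    incidence <- matrix(0L, nrow = G, ncol = n_pairs)
    incidence[cbind(pairs[1L, ], seq_len(n_pairs))] <- 1L
    incidence[cbind(pairs[2L, ], seq_len(n_pairs))] <- 1L
    sig_m <- matrix(as.integer(sig), nrow = n_pairs)
    adj_m <- matrix(adj, nrow = n_pairs)
    nsig_mat[, td] <- incidence %*% sig_m
    big <- adj_m
    for (g in seq_len(G)) {
      involved <- incidence[g, ] == 1L
      minp_mat[g, td] <- apply(big[involved, , drop = FALSE], 2L, min)
    }
  }

  meds <- apply(counts, 2L, stats::median)
  med_mat <- matrix(meds, nrow = G, ncol = length(doms), byrow = TRUE)
  lo <- pmin(counts, med_mat)
  hi <- pmax(counts, med_mat)
  fold_mat <- ifelse(counts == med_mat, 1, ifelse(lo == 0, Inf, hi / lo))
  dir_mat <- ifelse(counts > med_mat, "up",
                    ifelse(counts < med_mat, "down", "at_median"))

  out <- data.frame(
    domain = rep(doms, each = G),
    domain_db = rep(unname(matrix$domain_db[doms]), each = G),
    genome = rep(genomes, times = length(doms)),
    count = as.vector(counts),
    median_count = rep(meds, each = G),
    fold = as.vector(fold_mat),
    direction = as.vector(dir_mat),
    n_significant_pairs = as.vector(nsig_mat),
    min_adjusted_p = as.vector(minp_mat),
    skipped = rep(!tested, each = G),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "pairwise") <- pw
  attr(out, "params") <- params
  out
}

#' Over/under-representation calls from a pairwise enrichment table
#'
#' Minimal call rule: a domain is overrepresented in a genome when its
#' direction versus the median is `"up"` and at least `min_pairs` pairwise
#' comparisons involving that genome are significant; underrepresented
#' symmetrically.
#'
#' @param enrichment Result of [pairwise_domain_enrichment()].
#' @param min_pairs Minimum number of significant pairwise comparisons.
#' @return The input `data.frame` with an added `call` column
#'   (`"overrepresented"`, `"underrepresented"` or `"none"`).
#' @export
representation_calls <- function(enrichment, min_pairs = 1L) {
  stopifnot(all(c("direction", "n_significant_pairs") %in% names(enrichment)))
  sig <- !is.na(enrichment$n_significant_pairs) &
    enrichment$n_significant_pairs >= min_pairs
  enrichment$call <- ifelse(sig & enrichment$direction == "up",
                            "overrepresented",
                     ifelse(sig & enrichment$direction == "down",
                            "underrepresented", "none"))
  enrichment
}

#' Pfam enrichment of a gene set against its universe
#'
#' For each Pfam domain (plus a `NO_PFAM` pseudo-domain collecting genes
#' with no Pfam annotation at all), builds the 2x2 table of set membership
#' by domain presence over the gene universe and applies the two-sided
#' Fisher exact test. The odds ratio is `(a * d) / (b * c)`, reported as
#' `Inf` when `b * c = 0`; when the table is degenerate (e.g. the set
#' equals the universe) the odds ratio is 1, p is 1 and the row is flagged.
#'
#' @param set_genes Character vector of gene/protein ids (must be a subset
#'   of the universe).
#' @param universe_annotations Annotation `data.frame`; its Pfam records
#'   define domain presence.
#' @param params An [enrichment_params()] object (`gene_set_alpha` is the
#'   significance threshold, inclusive).
#' @param universe_genes Optional character vector of all gene ids in the
#'   universe; defaults to every protein id in `universe_annotations`
#'   (any database).
#' @return `data.frame` with columns `pfam`, `in_set_with`,
#'   `in_set_without`, `out_set_with`, `out_set_without`, `odds_ratio`, `p`,
#'   `significant`, `degenerate`, sorted by p.
#' @export
gene_set_domain_enrichment <- function(set_genes, universe_annotations,
                                       params = enrichment_params(),
                                       universe_genes = NULL) {
  stopifnot(inherits(params, "enrichment_params"))
  if (is.null(universe_genes)) {
    universe_genes <- unique(universe_annotations$protein_id)
  }
  universe_genes <- unique(universe_genes)
  set_genes <- unique(set_genes)
  outside <- setdiff(set_genes, universe_genes)
  if (length(outside) > 0L) {
    stop("validation error: set gene(s) not in universe: ",
         paste(utils::head(outside, 3L), collapse = ", "))
  }
  pf <- universe_annotations[universe_annotations$domain_db == "Pfam", ,
                             drop = FALSE]
  genes_by_pfam <- split(pf$protein_id, pf$domain_accession)
  genes_by_pfam <- lapply(genes_by_pfam, unique)
  no_pfam <- setdiff(universe_genes, unique(pf$protein_id))
  if (length(no_pfam) > 0L) genes_by_pfam[["NO_PFAM"]] <- no_pfam
  n_univ <- length(universe_genes)
  n_set <- length(set_genes)
  rows <- lapply(names(genes_by_pfam), function(dom) {
    with_dom <- intersect(genes_by_pfam[[dom]], universe_genes)
    a <- length(intersect(with_dom, set_genes))
    b <- n_set - a
    cc <- length(with_dom) - a
    d <- n_univ - n_set - cc
    degenerate <- (a + cc == 0) || (b + d == 0) || (a + b == 0) ||
      (cc + d == 0)
    if (degenerate) {
      or <- 1
      p <- 1
    } else {
      or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
      p <- .fisher_p(a, b, cc, d)
    }
    data.frame(pfam = dom, in_set_with = a, in_set_without = b,
               out_set_with = cc, out_set_without = d, odds_ratio = or,
               p = p, significant = !degenerate & p <= params$gene_set_alpha,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$pfam), , drop = FALSE]
  rownames(out) <- NULL
  out
}
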