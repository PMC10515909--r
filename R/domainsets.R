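#' Build a genomes-by-domains protein count matrix
#'
#' Each cell counts the number of distinct proteins in a genome carrying at
#' least one instance of a domain ("accessions containing the domain"), not
#' the number of domain instances. Callers are expected to supply one record
#' per gene's representative protein (typically the longest peptide); the
#' builder does not deduplicate isoforms. Domains absent from every genome
#' are dropped.
#'
#' @param records Annotation `data.frame` (see [read_domain_annotations()]).
#' @param totals Named vector mapping every `genome_id` present in `records`
#'   to its total number of annotated proteins (the enrichment background).
#' @param db_filter Optional single database name (`"Pfam"`, `"CAZy"` or
#'   `"MEROPS"`) restricting the matrix to one database.
#' @return Object of class `domain_count_matrix`: a list with integer matrix
#'   `counts` (rows = genomes, columns = domain accessions), named vector
#'   `totals` and named character vector `domain_db` (database per column).
#' @export
build_domain_count_matrix <- function(records, totals, db_filter = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(db_filter)) {
    stopifnot(length(db_filter) == 1L, db_filter %in% .domain_dbs)
    records <- records[records$domain_db == db_filter, , drop = FALSE]
  }
  genomes <- names(totals)
  if (is.null(genomes) || anyNA(totals) || any(totals < 0)) {
    stop("validation error: totals must be a named non-negative vector")
  }
  extra <- setdiff(unique(records$genome_id), genomes)
  if (length(extra) > 0L) {
    stop("validation error: genome(s) missing from totals: ",
         paste(extra, collapse = ", "))
  }
  if (nrow(records) == 0L) {
    counts <- matrix(0L, nrow = length(genomes), ncol = 0L,
                     dimnames = list(genomes, character(0L)))
    return(structure(list(counts = counts, totals = totals,
                          domain_db = character(0L)),
                     class = "domain_count_matrix"))
  }
  # records are unique per (genome, protein, accession) after aggregation,
  # so each row is one protein bearing the domain
  domains <- sort(unique(records$domain_accession))
  tab <- table(factor(records$genome_id, levels = genomes),
               factor(records$domain_accession, levels = domains))
  counts <- matrix(as.integer(tab), nrow = length(genomes),
                   dimnames = list(genomes, domains))
  keep <- colSums(counts) > 0L
  counts <- counts[, keep, drop = FALSE]
  db_map <- records$domain_db[!duplicated(records$domain_accession)]
  names(db_map) <- records$domain_accession[!duplicated(records$domain_accession)]
  db <- db_map[colnames(counts)]
  over <- which(counts > matrix(totals[genomes], nrow = length(genomes),
                                ncol = ncol(counts)), arr.ind = TRUE)
  if (nrow(over) > 0L) {
    stop("validation error: domain protein count exceeds genome total for ",
         genomes[over[1L, 1L]])
  }
  structure(list(counts = counts, totals = totals, domain_db = db),
            class = "domain_count_matrix")
}

#' @export
print.domain_count_matrix <- function(x, ...) {
  cat("domain count matrix: ", nrow(x$counts), " genomes x ",
      ncol(x$counts), " domains\n", sep = "")
  dbs <- table(x$domain_db)
  if (length(dbs) > 0L) {
    cat("  databases: ",
        paste(names(dbs), dbs, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-genome domain presence sets
#'
#' @param matrix A `domain_count_matrix`.
#' @return Named list mapping each genome to the character vector of domains
#'   present (count >= 1) in it.
#' @export
domain_presence_sets <- function(matrix) {
  stopifnot(inherits(matrix, "domain_count_matrix"))
  counts <- matrix$counts
  sets <- lapply(rownames(counts),
                 function(g) colnames(counts)[counts[g, ] >= 1L])
  names(sets) <- rownames(counts)
  sets
}

#' Exclusive intersections of domain presence sets
#'
#' Assigns every domain to exactly one subset of genomes — the exact set of
#' genomes that contain it — yielding the exclusive (UpSet-style)
#' intersection counts. The counts over all subsets partition the union of
#' all domains.
#'
#' @param sets Named list of domain sets as from [domain_presence_sets()].
#' @return Object of class `intersection_report`: a `data.frame` with
#'   columns `subset` (genome ids joined by `&`), `n_genomes` and
#'   `n_domains`, sorted by `n_domains` descending; the member domains per
#'   subset are in `attr(, "domains")` and per-genome unique-domain lists in
#'   `attr(, "unique_domains")`. When there are at most 10 genomes, all
#'   2^G - 1 non-empty subsets are reported (including empty intersections);
#'   beyond that only observed subsets appear.
#' @export
exclusive_intersections <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  genomes <- names(sets)
  domains <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) domains %in% s,
                       logical(length(domains)))
  if (length(domains) == 0L) {
    membership <- matrix(FALSE, nrow = 0L, ncol = length(genomes),
                         dimnames = list(NULL, genomes))
  }
  if (length(domains) == 1L) membership <- matrix(membership, nrow = 1L,
                                                  dimnames = list(NULL, genomes))
  key <- apply(membership, 1L, function(m) paste(genomes[m], collapse = "&"))
  by_subset <- split(domains, key)
  if (length(genomes) <= 10L) {
    all_keys <- unlist(lapply(seq_along(genomes), function(k) {
      utils::combn(genomes, k, paste, collapse = "&")
    }))
    missing <- setdiff(all_keys, names(by_subset))
    by_subset <- c(by_subset, stats::setNames(
      replicate(length(missing), character(0L), simplify = FALSE), missing))
  }
  n_genomes <- lengths(strsplit(names(by_subset), "&", fixed = TRUE))
  report <- data.frame(subset = names(by_subset), n_genomes = n_genomes,
                       n_domains = lengths(by_subset),
                       stringsAsFactors = FALSE)
  ord <- order(-report$n_domains, report$subset)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  uniq <- lapply(genomes, function(g) {
    m <- by_subset[[g]]
    if (is.null(m)) character(0L) else m
  })
  names(uniq) <- genomes
  structure(report, domains = by_subset[report$subset],
            unique_domains = uniq,
            class = c("intersection_report", "data.frame"))
}

#' Domains unique to, and missing from, a focal genome
#'
#' @param matrix A `domain_count_matrix`.
#' @param focal Genome id of the focal genome.
#' @return List with `unique` (domains present only in the focal genome)
#'   and `missing` (domains absent from the focal genome but present in at
#'   least one other).
#' @export
unique_and_missing_domains <- function(matrix, focal) {
  stopifnot(inherits(matrix, "domain_count_matrix"))
  counts <- matrix$counts
  if (!focal %in% rownames(counts)) {
    stop("key error: unknown focal genome '", focal, "'")
  }
  present <- counts >= 1L
  in_focal <- present[focal, ]
  n_others <- colSums(present[setdiff(rownames(counts), focal), ,
                              drop = FALSE])
  list(unique = colnames(counts)[in_focal & n_others == 0L],
       missing = colnames(counts)[!in_focal & n_others > 0L])
}
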