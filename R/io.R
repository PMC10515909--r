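#' Read genome sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a named
#' character vector of uppercase nucleotide strings over the alphabet
#' `{A, C, G, T, N}`. The sequence identifier is the header token before the
#' first whitespace character; lowercase (soft-masked) residues are folded to
#' uppercase.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record in file order.
#'   Names are the sequence identifiers.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1 demo", "acgtACGT", ">chr2", "NNAC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA format error: file is empty: ", path)
  }
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop("FASTA format error at line ", nonblank[1L],
         ": expected a '>' header before sequence data")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA format error: no records in ", path)
  }
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA format error: record ", which(!nzchar(ids))[1L],
         " has an empty identifier")
  }
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      stop("FASTA format error: record '", ids[i], "' has an empty sequence")
    }
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0L) {
      stop("alphabet error in record '", ids[i], "': illegal character '",
           substr(seqs[i], bad, bad), "' at position ", bad)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write genome sequences to a FASTA file
#'
#' @param sequences Named character vector of nucleotide strings.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  stopifnot(is.character(sequences), length(sequences) > 0L,
            !is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.domain_dbs <- c("Pfam", "CAZy", "MEROPS")

#' Read a protein domain annotation table
#'
#' Reads the tab-separated annotation dialect used throughout the package:
#' mandatory header columns `genome_id`, `protein_id`, `domain_accession`,
#' `domain_db` (one of `Pfam`, `CAZy`, `MEROPS`) and `n_instances`
#' (positive integer count of domain instances on that protein), plus an
#' optional logical `secreted` column. Duplicate rows for the same
#' (genome, protein, accession) key are aggregated by summing `n_instances`
#' (a secreted flag is OR-ed across duplicates).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with one row per (genome, protein, accession).
#' @export
read_domain_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("genome_id", "protein_id", "domain_accession", "domain_db",
                "n_instances")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("annotation format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_db <- setdiff(unique(df$domain_db), .domain_dbs)
  if (length(bad_db) > 0L) {
    stop("annotation format error: unknown domain_db value(s): ",
         paste(bad_db, collapse = ", "), " (expected ",
         paste(.domain_dbs, collapse = "/"), ")")
  }
  n <- suppressWarnings(as.numeric(df$n_instances))
  if (anyNA(n) || any(n < 1) || any(n != round(n))) {
    stop("annotation validation error: n_instances must be integers >= 1")
  }
  df$n_instances <- as.integer(n)
  has_secreted <- "secreted" %in% names(df)
  if (has_secreted) df$secreted <- as.logical(df$secreted)
  key <- paste(df$genome_id, df$protein_id, df$domain_accession, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- !duplicated(key)
    sums <- rowsum(df$n_instances, key)
    agg <- df[ord, , drop = FALSE]
    agg$n_instances <- as.integer(sums[paste(agg$genome_id, agg$protein_id,
                                             agg$domain_accession,
                                             sep = "\r"), 1L])
    if (has_secreted) {
      sec <- tapply(df$secreted, key, function(x) any(x, na.rm = TRUE))
      agg$secreted <- as.logical(sec[paste(agg$genome_id, agg$protein_id,
                                           agg$domain_accession, sep = "\r")])
    }
    df <- agg
  }
  rownames(df) <- NULL
  df
}

#' Write a protein domain annotation table
#' @param records Annotation `data.frame` (see [read_domain_annotations()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_domain_annotations <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' Reads the de facto `Orthogroups.tsv` layout: first column is the
#' orthogroup id, remaining columns are species; each cell holds a
#' comma-separated list of gene ids (empty cell = no members in that
#' species). Whitespace around gene ids is stripped.
#'
#' @param path Path to a TSV file with a header row naming the species.
#' @return A named list (one element per orthogroup, in file order); each
#'   element is a named list mapping species to a character vector of gene
#'   ids. The species order is stored in `attr(, "species")`. Class
#'   `"orthogroup_table"`.
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || !nzchar(lines[1L])) {
    stop("orthogroup format error: missing header row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1L]])
  if (ncol < 2L) {
    stop("orthogroup format error: header must name at least one species")
  }
  species <- fields[[1L]][-1L]
  ogs <- vector("list", length(lines) - 1L)
  ids <- character(length(ogs))
  for (i in seq_along(ogs)) {
    f <- fields[[i + 1L]]
    # strsplit drops trailing empty fields; pad them back before the
    # ragged-row check
    if (length(f) < ncol) {
      raw <- lines[i + 1L]
      ntab <- nchar(raw) - nchar(gsub("\t", "", raw, fixed = TRUE))
      if (ntab + 1L == ncol) f <- c(f, rep("", ncol - length(f)))
    }
    if (length(f) != ncol) {
      stop("orthogroup format error: ragged row at line ", i + 1L,
           " (expected ", ncol, " fields, found ", length(f), ")")
    }
    ids[i] <- f[1L]
    members <- lapply(f[-1L], function(cell) {
      g <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
      g[nzchar(g)]
    })
    names(members) <- species
    ogs[[i]] <- members
  }
  if (anyDuplicated(ids)) {
    stop("orthogroup format error: duplicate orthogroup id '",
         ids[duplicated(ids)][1L], "'")
  }
  names(ogs) <- ids
  structure(ogs, species = species, class = "orthogroup_table")
}

#' Write an orthogroup membership table
#' @param ogs An `orthogroup_table` (see [read_orthogroups()]).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_orthogroups <- function(ogs, path) {
  species <- attr(ogs, "species")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Orthogroup", species), collapse = "\t"), con)
  for (id in names(ogs)) {
    cells <- vapply(species, function(sp) paste(ogs[[id]][[sp]],
                                                collapse = ", "), "")
    writeLines(paste(c(id, cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an expression count table
#'
#' Accepts either long form (columns `gene_id`, `sample_id`, `est_counts`)
#' or wide form (first column gene ids, remaining columns one per sample),
#' auto-detected from the header; wide tables are unpivoted.
#'
#' @param path Path to a TSV file.
#' @return Long-form `data.frame` with columns `gene_id`, `sample_id`,
#'   `est_counts`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  long_cols <- c("gene_id", "sample_id", "est_counts")
  if (all(long_cols %in% names(df))) {
    out <- df[long_cols]
  } else {
    if (ncol(df) < 2L) {
      stop("expression format error: need gene column plus >= 1 sample")
    }
    samples <- names(df)[-1L]
    out <- data.frame(
      gene_id = rep(df[[1L]], times = length(samples)),
      sample_id = rep(samples, each = nrow(df)),
      est_counts = as.numeric(unlist(df[-1L], use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  }
  out$est_counts <- as.numeric(out$est_counts)
  if (anyNA(out$est_counts) || any(out$est_counts < 0)) {
    stop("expression validation error: est_counts must be >= 0")
  }
  if (anyDuplicated(paste(out$gene_id, out$sample_id, sep = "\r"))) {
    stop("expression validation error: duplicate (gene_id, sample_id) pair")
  }
  rownames(out) <- NULL
  out
}

#' Write an expression count table (long form)
#' @param expression Long-form expression `data.frame`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genome catalog table
#'
#' @param path TSV with columns `species`, `assembly_size` (bp),
#'   `gene_count` and optionally `phylum`.
#' @return A `data.frame`.
#' @export
read_genome_catalog <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("species", "assembly_size", "gene_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("catalog format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(df$assembly_size <= 0) || any(df$gene_count <= 0)) {
    stop("catalog validation error: assembly_size and gene_count must be > 0")
  }
  df
}

#' Summarize a genome catalog
#'
#' Computes median assembly size and median gene count over catalog entries
#' at or below a size cutoff, the convention used when summarizing public
#' fungal genome compilations where a handful of repeat-bloated assemblies
#' would otherwise dominate. Medians of even-sized samples are the midpoint
#' of the two central order statistics.
#'
#' @param catalog `data.frame` with columns `species`, `assembly_size` (bp)
#'   and `gene_count`.
#' @param size_cutoff Entries with `assembly_size` strictly greater than this
#'   value (bp) are excluded. Default 500 Mb. Use `Inf` for no exclusion.
#' @return List with `median_assembly_size`, `median_gene_count`,
#'   `n_included`, `n_excluded`.
#' @examples
#' cat <- data.frame(species = c("a", "b", "c"),
#'                   assembly_size = c(10e6, 20e6, 30e6),
#'                   gene_count = c(1000, 2000, 3000))
#' summarize_genome_catalog(cat, size_cutoff = 500e6)
#' @export
summarize_genome_catalog <- function(catalog, size_cutoff = 500e6) {
  stopifnot(is.data.frame(catalog), nrow(catalog) > 0L)
  keep <- catalog$assembly_size <= size_cutoff
  if (!any(keep)) {
    stop("empty-catalog error: all ", nrow(catalog),
         " entries exceed the size cutoff")
  }
  inc <- catalog[keep, , drop = FALSE]
  list(
    median_assembly_size = stats::median(inc$assembly_size),
    median_gene_count = stats::median(inc$gene_count),
    n_included = sum(keep),
    n_excluded = sum(!keep)
  )
}
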