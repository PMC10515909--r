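#' Parameters for orthogroup occupancy analysis
#'
#' @param species_universe Character vector of species ids defining the
#'   analysis set.
#' @param min_total_counts Minimum summed estimated counts across the pooled
#'   expression samples for a gene to pass the expression-support filter.
#' @return Object of class `occupancy_params`.
#' @export
occupancy_params <- function(species_universe, min_total_counts = 5) {
  stopifnot(is.character(species_universe), length(species_universe) >= 1L,
            min_total_counts >= 0)
  structure(list(species_universe = species_universe,
                 min_total_counts = min_total_counts),
            class = "occupancy_params")
}

#' Classify orthogroups by species occupancy
#'
#' Each orthogroup is classified by the exact set of species with at least
#' one member gene: `core` (every species of the universe represented),
#' `species_specific` (exactly one species) or `shared_subset` (a proper
#' subset of two or more species). The classes partition the orthogroups.
#'
#' @param ogs An `orthogroup_table` (see [read_orthogroups()]).
#' @param species_universe Character vector of species ids; every species
#'   with members in `ogs` must belong to it.
#' @return `data.frame` with columns `og_id`, `class`, `species_subset`
#'   (comma-joined, in universe order) and `n_species`.
#' @export
classify_orthogroups <- function(ogs, species_universe) {
  stopifnot(length(ogs) >= 1L)
  present_mat <- vapply(ogs, function(members) {
    vapply(species_universe,
           function(sp) length(members[[sp]]) > 0L, logical(1L))
  }, logical(length(species_universe)))
  if (length(species_universe) == 1L) {
    present_mat <- matrix(present_mat, nrow = 1L)
  }
  member_species <- unique(unlist(lapply(ogs, function(m) {
    names(m)[lengths(m) > 0L]
  })))
  unknown <- setdiff(member_species, species_universe)
  if (length(unknown) > 0L) {
    stop("validation error: species not in universe: ",
         paste(unknown, collapse = ", "))
  }
  n_species <- colSums(present_mat)
  if (any(n_species == 0L)) {
    stop("validation error: orthogroup with no members: ",
         names(ogs)[which(n_species == 0L)[1L]])
  }
  cls <- ifelse(n_species == length(species_universe), "core",
                ifelse(n_species == 1L, "species_specific", "shared_subset"))
  subset <- apply(present_mat, 2L, function(p) {
    paste(species_universe[p], collapse = ",")
  })
  data.frame(og_id = names(ogs), class = unname(cls),
             species_subset = unname(subset),
             n_species = unname(as.integer(n_species)),
             stringsAsFactors = FALSE)
}

#' Summarize orthogroup occupancy
#'
#' @param classified Output of [classify_orthogroups()].
#' @param species_universe Optional species ids (defaults to the species
#'   observed in `classified`).
#' @return Object of class `occupancy_summary`: `n_ogs`; `class_counts` and
#'   `class_pct` (named by `core`, `shared_subset`, `species_specific`,
#'   percentages over all orthogroups, summing to 100); `subset_counts`
#'   (exact-subset occupancy); and a per-species `data.frame` with the
#'   percentage of orthogroups containing at least one gene of that species
#'   and the percentage that are specific to it.
#' @export
occupancy_summary <- function(classified, species_universe = NULL) {
  stopifnot(is.data.frame(classified), nrow(classified) > 0L)
  n <- nrow(classified)
  lv <- c("core", "shared_subset", "species_specific")
  cc <- table(factor(classified$class, levels = lv))
  class_counts <- stats::setNames(as.integer(cc), lv)
  if (is.null(species_universe)) {
    species_universe <- unique(unlist(strsplit(classified$species_subset,
                                               ",", fixed = TRUE)))
  }
  subsets <- strsplit(classified$species_subset, ",", fixed = TRUE)
  per_species <- data.frame(
    species = species_universe,
    pct_ogs_with_gene = vapply(species_universe, function(sp) {
      100 * sum(vapply(subsets, function(s) sp %in% s, logical(1L))) / n
    }, numeric(1L)),
    pct_species_specific = vapply(species_universe, function(sp) {
      100 * sum(classified$class == "species_specific" &
                  classified$species_subset == sp) / n
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(per_species) <- NULL
  structure(list(
    n_ogs = n,
    class_counts = class_counts,
    class_pct = 100 * class_counts / n,
    subset_counts = table(classified$species_subset),
    per_species = per_species
  ), class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("orthogroup occupancy: ", x$n_ogs, " orthogroups\n", sep = "")
  for (cl in names(x$class_counts)) {
    cat(sprintf("  %-17s %6d (%.1f%%)\n", cl, x$class_counts[[cl]],
                x$class_pct[[cl]]))
  }
  invisible(x)
}

#' Classify genes by orthogroup status
#'
#' Genes belonging to no orthogroup are `unassigned`; genes in an
#' orthogroup populated by a single species are `assigned_species_specific`;
#' all others are `assigned_shared`. Unassigned and species-specific genes
#' together form the potentially species-specific set.
#'
#' @param ogs An `orthogroup_table`.
#' @param gene_universe Named list mapping each species to the character
#'   vector of all its gene ids; every orthogroup member must appear in it.
#' @return `data.frame` with columns `gene_id`, `species`, `og_id` (`NA`
#'   for unassigned genes), `status` and logical
#'   `potentially_species_specific`; a per-species percentage summary is in
#'   `attr(, "summary")`.
#' @export
classify_genes <- function(ogs, gene_universe) {
  stopifnot(is.list(gene_universe), !is.null(names(gene_universe)))
  species <- names(gene_universe)
  cls <- classify_orthogroups(ogs, species)
  og_class <- stats::setNames(cls$class, cls$og_id)
  pieces <- vector("list", length(species))
  for (si in seq_along(species)) {
    sp <- species[si]
    genes <- gene_universe[[sp]]
    gene_og <- rep(NA_character_, length(genes))
    names(gene_og) <- genes
    for (og in names(ogs)) {
      members <- ogs[[og]][[sp]]
      if (length(members) == 0L) next
      missing <- setdiff(members, genes)
      if (length(missing) > 0L) {
        stop("validation error: orthogroup gene(s) absent from the ", sp,
             " universe: ", paste(utils::head(missing, 3L), collapse = ", "))
      }
      gene_og[members] <- og
    }
    status <- ifelse(is.na(gene_og), "unassigned",
                     ifelse(og_class[gene_og] == "species_specific",
                            "assigned_species_specific", "assigned_shared"))
    pieces[[si]] <- data.frame(
      gene_id = genes, species = sp, og_id = unname(gene_og),
      status = unname(status),
      potentially_species_specific = unname(status != "assigned_shared"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  lv <- c("assigned_shared", "assigned_species_specific", "unassigned")
  summ <- do.call(rbind, lapply(species, function(sp) {
    sub <- out[out$species == sp, , drop = FALSE]
    n <- nrow(sub)
    pct <- 100 * as.integer(table(factor(sub$status, levels = lv))) / n
    data.frame(species = sp, n_genes = n,
               pct_assigned_shared = pct[1L],
               pct_assigned_species_specific = pct[2L],
               pct_unassigned = pct[3L],
               pct_potentially_specific =
                 100 * sum(sub$potentially_species_specific) / n,
               stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- summ
  out
}

#' Filter the potentially species-specific gene set by expression support
#'
#' A potentially species-specific gene is retained only when the sum of its
#' estimated counts across all pooled samples reaches `min_total_counts`
#' (strictly fewer are filtered out). Genes absent from the expression
#' table are treated as zero-count (quantifiers routinely omit zero-count
#' genes) and are removed.
#'
#' @param statuses Output of [classify_genes()].
#' @param expression Long-form expression `data.frame` (see
#'   [read_expression()]).
#' @param params An [occupancy_params()] object.
#' @return List of class `expression_filter_result`: `retained` and
#'   `removed` (subsets of the potentially species-specific rows of
#'   `statuses`, with a `total_counts` column) and `summary`, a per-species
#'   `data.frame` with the percentage of genes that are potentially
#'   species-specific before and after filtering.
#' @export
apply_expression_filter <- function(statuses, expression, params) {
  stopifnot(inherits(params, "occupancy_params"),
            all(c("gene_id", "species", "potentially_species_specific") %in%
                  names(statuses)))
  totals <- if (nrow(expression) > 0L) {
    tapply(expression$est_counts, expression$gene_id, sum)
  } else {
    numeric(0L)
  }
  cand <- statuses[statuses$potentially_species_specific, , drop = FALSE]
  tot <- as.numeric(totals[cand$gene_id])
  tot[is.na(tot)] <- 0
  cand$total_counts <- tot
  keep <- tot >= params$min_total_counts
  summ <- do.call(rbind, lapply(unique(statuses$species), function(sp) {
    n_sp <- sum(statuses$species == sp)
    before <- sum(cand$species == sp)
    after <- sum(keep & cand$species == sp)
    data.frame(species = sp, n_genes = n_sp,
               n_potentially_specific = before,
               n_potentially_specific_expressed = after,
               pct_before = 100 * before / n_sp,
               pct_after = 100 * after / n_sp,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(retained = cand[keep, , drop = FALSE],
                 removed = cand[!keep, , drop = FALSE],
                 summary = summ,
                 min_total_counts = params$min_total_counts),
            class = "expression_filter_result")
}

#' @export
print.expression_filter_result <- function(x, ...) {
  cat("expression-support filter (total counts >= ", x$min_total_counts,
      " across pooled samples)\n", sep = "")
  print(x$summary)
  invisible(x)
}
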