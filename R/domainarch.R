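#' Construct a domain architecture rule
#'
#' A rule is a label plus one or more conjunctive clauses; a protein matches
#' the rule when all constraints of at least one clause are satisfied
#' (disjunctive normal form). Each constraint bounds the instance count of
#' one domain accession on the protein (`min <= n <= max`), so "absent"
#' constraints are expressed as `min = 0, max = 0`.
#'
#' @param label Rule label.
#' @param ... One or more clauses, each a `data.frame` with columns
#'   `accession`, `min`, `max` (use `Inf` for unbounded).
#' @return Object of class `architecture_rule`.
#' @export
architecture_rule <- function(label, ...) {
  clauses <- list(...)
  stopifnot(length(clauses) >= 1L)
  for (cl in clauses) {
    stopifnot(is.data.frame(cl),
              all(c("accession", "min", "max") %in% names(cl)),
              all(cl$min <= cl$max), all(cl$min >= 0),
              any(cl$min >= 1))
  }
  structure(list(label = label, clauses = clauses),
            class = "architecture_rule")
}

.constraint <- function(accession, min, max = Inf) {
  data.frame(accession = accession, min = min, max = max,
             stringsAsFactors = FALSE)
}

#' Pfam accessions used by the built-in rule sets and surveys
#'
#' @return Named character vector mapping domain names to Pfam accessions.
#' @export
pfam_accessions <- function() {
  c(`7tm_1` = "PF00001", Bac_rhodopsin = "PF01036",
    DNA_photolyase = "PF00875", FAD_binding_7 = "PF03441", PHY = "PF00360",
    GpcrRhopsn4 = "PF10192", GAF = "PF01590", PAS = "PF00989",
    PAS_3 = "PF08447", PAS_9 = "PF13426", GATA = "PF00320",
    FRQ = "PF09421", RdRP = "PF05183", Dicer_dimer = "PF03368",
    PAZ = "PF02170", Piwi = "PF02171", Ribonuclease_3 = "PF00636",
    DEAD = "PF00270", DNA_methylase = "PF00145")
}

#' Built-in circadian clock architecture rules
#'
#' Candidates of the fungal circadian machinery by expected Pfam pattern:
#' `FRQ` (a frequency domain), `WC1` (GATA zinc finger with both PAS_3 and
#' PAS_9, the white-collar-1 photoreceptor signature), `WC2` (GATA and
#' PAS_3 but no PAS_9) and `RHODOPSIN` (a 7tm_1 domain). Instance
#' requirements are "at least one" (Pfam frequently reports tandem repeats
#' of a domain), except the explicit absence of PAS_9 in WC2.
#'
#' @return List of [architecture_rule()] objects.
#' @export
circadian_rules <- function() {
  acc <- pfam_accessions()
  list(
    architecture_rule("FRQ", .constraint(acc[["FRQ"]], 1)),
    architecture_rule("WC1", rbind(.constraint(acc[["GATA"]], 1),
                                   .constraint(acc[["PAS_3"]], 1),
                                   .constraint(acc[["PAS_9"]], 1))),
    architecture_rule("WC2", rbind(.constraint(acc[["GATA"]], 1),
                                   .constraint(acc[["PAS_3"]], 1),
                                   .constraint(acc[["PAS_9"]], 0, 0))),
    architecture_rule("RHODOPSIN", .constraint(acc[["7tm_1"]], 1))
  )
}

#' Built-in RNAi machinery architecture rules
#'
#' `RDRP` (RNA-dependent RNA polymerase domain), `DICER` (Dicer
#' dimerization domain), `AGO` (Argonaute: both PAZ and Piwi) and
#' `DICER_ALT` (Ribonuclease_3 together with either a DEAD helicase or a
#' PAZ domain).
#'
#' @return List of [architecture_rule()] objects.
#' @export
rnai_rules <- function() {
  acc <- pfam_accessions()
  list(
    architecture_rule("RDRP", .constraint(acc[["RdRP"]], 1)),
    architecture_rule("DICER", .constraint(acc[["Dicer_dimer"]], 1)),
    architecture_rule("AGO", rbind(.constraint(acc[["PAZ"]], 1),
                                   .constraint(acc[["Piwi"]], 1))),
    architecture_rule("DICER_ALT",
                      rbind(.constraint(acc[["Ribonuclease_3"]], 1),
                            .constraint(acc[["DEAD"]], 1)),
                      rbind(.constraint(acc[["Ribonuclease_3"]], 1),
                            .constraint(acc[["PAZ"]], 1)))
  )
}

#' Built-in RID methyltransferase candidate rule
#'
#' RID (the cytosine DNA methyltransferase required for RIP) carries a
#' tandem DNA_methylase signature: candidates are proteins with more than
#' one DNA_methylase (PF00145) instance. Adjacency of the instances is not
#' checked because annotation tables carry no domain coordinates.
#'
#' @return List with one [architecture_rule()].
#' @export
rid_rules <- function() {
  acc <- pfam_accessions()
  list(architecture_rule("RID_CANDIDATE",
                         .constraint(acc[["DNA_methylase"]], 2)))
}

#' All built-in architecture rules
#' @return List of [architecture_rule()] objects (circadian + RNAi + RID).
#' @export
all_rules <- function() {
  c(circadian_rules(), rnai_rules(), rid_rules())
}

#' Light-sensing Pfam domains surveyed for circadian candidates
#' @return Named character vector (domain name -> Pfam accession).
#' @export
light_sensing_domains <- function() {
  acc <- pfam_accessions()
  acc[c("7tm_1", "Bac_rhodopsin", "DNA_photolyase", "FAD_binding_7", "PHY",
        "GpcrRhopsn4", "GAF", "PAS", "PAS_3", "PAS_9", "GATA", "FRQ")]
}

#' Load architecture rules from a JSON file
#'
#' Expected layout: an object mapping labels to an array of clauses, each
#' clause an array of `[accession, min, max]` triples (`max` may be `null`
#' for unbounded). A single flat array of triples is accepted as a
#' one-clause rule.
#'
#' @param path JSON file path.
#' @return List of [architecture_rule()] objects.
#' @export
read_architecture_rules <- function(path) {
  spec <- jsonlite::read_json(path)
  lapply(names(spec), function(label) {
    clauses <- spec[[label]]
    stopifnot(length(clauses) >= 1L)
    # a flat array of [accession, min, max] triples is a one-clause rule
    if (is.character(clauses[[1L]][[1L]])) clauses <- list(clauses)
    dfs <- lapply(clauses, function(cl) {
      do.call(rbind, lapply(cl, function(tr) {
        .constraint(tr[[1L]], as.numeric(tr[[2L]]),
                    if (length(tr) < 3L || is.null(tr[[3L]])) Inf
                    else as.numeric(tr[[3L]]))
      }))
    })
    do.call(architecture_rule, c(list(label), dfs))
  })
}

#' Classify one protein's domain architecture against a rule set
#'
#' @param protein_domains Named numeric vector mapping domain accessions to
#'   instance counts on the protein (domains not named count as zero).
#' @param ruleset List of [architecture_rule()] objects.
#' @return Character vector of matching labels, in rule-set order (a
#'   protein may match several rules).
#' @examples
#' classify_protein_architecture(
#'   c(PF00320 = 1, PF08447 = 1, PF13426 = 1), circadian_rules())
#' @export
classify_protein_architecture <- function(protein_domains, ruleset) {
  stopifnot(all(protein_domains >= 0))
  get_count <- function(acc) {
    if (acc %in% names(protein_domains)) protein_domains[[acc]] else 0
  }
  labels <- character(0L)
  for (rule in ruleset) {
    ok <- any(vapply(rule$clauses, function(cl) {
      all(vapply(seq_len(nrow(cl)), function(i) {
        n <- get_count(cl$accession[i])
        n >= cl$min[i] && n <= cl$max[i]
      }, logical(1L)))
    }, logical(1L)))
    if (ok) labels <- c(labels, rule$label)
  }
  labels
}

#' Survey single domains across genomes
#'
#' Counts, per genome, the number of distinct proteins carrying at least
#' one instance of each listed domain. Domains absent everywhere are
#' retained with zero counts (surveys report absences).
#'
#' @param records Annotation `data.frame`.
#' @param domain_list Character vector of domain accessions.
#' @return Integer matrix, genomes x accessions.
#' @export
survey_domains <- function(records, domain_list) {
  if (length(domain_list) == 0L) {
    stop("validation error: empty domain list")
  }
  genomes <- sort(unique(records$genome_id))
  sub <- records[records$domain_accession %in% domain_list, , drop = FALSE]
  tab <- table(factor(sub$genome_id, levels = genomes),
               factor(sub$domain_accession, levels = domain_list))
  matrix(as.integer(tab), nrow = length(genomes),
         dimnames = list(genomes, domain_list))
}

#' Classify all proteins of every genome against a rule set
#'
#' @param records Annotation `data.frame`.
#' @param ruleset List of [architecture_rule()] objects.
#' @return `data.frame` with one row per (genome, label): columns
#'   `genome_id`, `label`, `n` and `protein_ids` (comma-separated, sorted);
#'   labels with no candidates are retained with `n = 0`.
#' @export
classify_genome_candidates <- function(records, ruleset) {
  genomes <- sort(unique(records$genome_id))
  labels <- vapply(ruleset, function(r) r$label, "")
  key <- paste(records$genome_id, records$protein_id, sep = "\r")
  by_protein <- split(seq_len(nrow(records)), key)
  hits <- list()
  for (prot in names(by_protein)) {
    idx <- by_protein[[prot]]
    counts <- stats::setNames(records$n_instances[idx],
                              records$domain_accession[idx])
    matched <- classify_protein_architecture(counts, ruleset)
    if (length(matched) > 0L) {
      parts <- strsplit(prot, "\r", fixed = TRUE)[[1L]]
      hits[[prot]] <- data.frame(genome_id = parts[1L],
                                 protein_id = parts[2L], label = matched,
                                 stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(genome_id = character(), protein_id = character(),
               label = character(), stringsAsFactors = FALSE)
  out <- expand.grid(genome_id = genomes, label = labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, match(out$label, labels)), , drop = FALSE]
  out$n <- 0L
  out$protein_ids <- ""
  for (i in seq_len(nrow(out))) {
    members <- sort(hits$protein_id[hits$genome_id == out$genome_id[i] &
                                      hits$label == out$label[i]])
    out$n[i] <- length(members)
    out$protein_ids[i] <- paste(members, collapse = ",")
  }
  rownames(out) <- NULL
  out
}
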