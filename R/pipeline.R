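.pipeline_stages <- c("simulate_genome", "ripscan", "simulate_annotations",
                      "enrichment", "architecture", "simulate_orthogroups",
                      "occupancy")

.default_config <- function() {
  list(
    out_dir = NULL,
    seed = 1L,
    stages = .pipeline_stages,
    genome = list(length_bp = 100000L, n_families = 3L, unit_length = 2000L,
                  n_copies = 5L, gc_fraction = 0.5, rip_rate = 0.2,
                  rip_target_fraction = 1),
    ripscan = list(window_bp = 1000L, step_bp = 500L,
                   min_window_fraction = 0.5, rip_threshold = 0),
    annotations = list(n_genomes = 4L, n_domains = 60L, baseline_lambda = 10,
                       totals = 1000L, planted_folds = 8,
                       n_planted = 3L),
    enrichment = list(alpha = 0.01, min_genomes_present = 2L,
                      gene_set_alpha = 0.001),
    rules = "all",
    occupancy = list(min_total_counts = 5)
  )
}

# merge user config into defaults, rejecting unknown keys at both levels
.merge_config <- function(config) {
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("config validation error: unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  for (key in names(config)) {
    val <- config[[key]]
    if (is.list(val) && is.list(defaults[[key]])) {
      bad <- setdiff(names(val), names(defaults[[key]]))
      if (length(bad) > 0L) {
        stop("config validation error: unknown key(s) in '", key, "': ",
             paste(bad, collapse = ", "))
      }
      defaults[[key]][names(val)] <- val
    } else {
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Run the full analysis pipeline on simulated data
#'
#' Wires the stages together through files in the package's interchange
#' formats (FASTA, annotation/orthogroup/expression TSV, bedGraph, JSON):
#' simulate a genome, scan it for RIP, simulate annotation tables, run the
#' pairwise enrichment and architecture classification, simulate
#' orthogroups and run the occupancy analysis with the expression filter.
#' Every output file is recorded in a manifest with its MD5 checksum, so a
#' rerun with the same config and seed is verifiably identical. On stage
#' failure the manifest is still written, with the failing stage marked
#' `FAILED`, before the error is re-signalled.
#'
#' @param config A configuration list, or the path to a JSON file holding
#'   one. Top-level keys: `out_dir` (required), `seed`, `stages` and
#'   per-stage parameter blocks `genome`, `ripscan`, `annotations`,
#'   `enrichment`, `rules`, `occupancy`; unknown keys are rejected.
#' @return The run manifest (invisibly): per-stage parameters, output files
#'   with checksums, record counts and status. Also written to
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config validation error: no such config file: ", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- .merge_config(config)
  if (is.null(cfg$out_dir)) {
    stop("config validation error: out_dir is required")
  }
  bad_stage <- setdiff(cfg$stages, .pipeline_stages)
  if (length(bad_stage) > 0L) {
    stop("config validation error: unknown stage(s): ",
         paste(bad_stage, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "entorip",
                   version = as.character(utils::packageVersion("entorip")),
                   seed = seed, stages = list())
  path_of <- function(f) file.path(cfg$out_dir, f)
  record <- function(name, params, files, n_records, status = "OK") {
    manifest$stages[[name]] <<- list(
      status = status, params = params, n_records = n_records,
      outputs = lapply(files, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      })
    )
  }
  finish <- function() {
    jsonlite::write_json(manifest, path_of("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    message("[entorip] stage ", name)
    tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "FAILED",
                                       error = conditionMessage(e))
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("simulate_genome", function() {
    g <- cfg$genome
    sim <- simulate_genome(sim_genome_params(
      length_bp = g$length_bp,
      gc_fraction = g$gc_fraction,
      repeat_families = data.frame(
        family_id = sprintf("fam%d", seq_len(g$n_families)),
        unit_length = g$unit_length, n_copies = g$n_copies),
      rip_rate = g$rip_rate, rip_target_fraction = g$rip_target_fraction,
      seed = seed))
    fa <- path_of("genome.fasta")
    write_fasta(sim$sequences, fa)
    tr <- path_of("genome_repeats_truth.tsv")
    utils::write.table(sim$repeats, tr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("simulate_genome", g, c(fa, tr), length(sim$sequences))
  })

  run_stage("ripscan", function() {
    r <- cfg$ripscan
    genome <- read_fasta(path_of("genome.fasta"))
    params <- rip_scan_params(r$window_bp, r$step_bp,
                              r$min_window_fraction, r$rip_threshold)
    windows <- scan_windows(genome, params)
    summ <- summarize_rip(windows, params)
    bg <- path_of("rip_composite.bedgraph")
    tsv <- path_of("rip_windows.tsv")
    js <- path_of("rip_summary.json")
    write_rip_bedgraph(windows, bg)
    write_rip_windows(windows, tsv)
    write_rip_summary(summ, js)
    record("ripscan", r, c(bg, tsv, js), nrow(windows))
  })

  run_stage("simulate_annotations", function() {
    a <- cfg$annotations
    planted <- if (a$n_planted > 0L) {
      data.frame(domain = seq_len(a$n_planted), genome = "g1",
                 fold = a$planted_folds)
    } else {
      NULL
    }
    arch <- data.frame(genome = "g1",
                       label = c("WC1", "AGO", "RID_CANDIDATE"),
                       n_proteins = 1L)
    sim <- simulate_domain_annotations(sim_annotation_params(
      n_genomes = a$n_genomes, n_domains = a$n_domains,
      baseline_lambda = a$baseline_lambda, totals = a$totals,
      planted_enrichments = planted, planted_architectures = arch,
      seed = seed + 1L))
    ann <- path_of("annotations.tsv")
    write_domain_annotations(sim$records, ann)
    tot <- path_of("protein_totals.tsv")
    utils::write.table(data.frame(genome_id = names(sim$totals),
                                  n_proteins = as.integer(sim$totals)),
                       tot, sep = "\t", quote = FALSE, row.names = FALSE)
    record("simulate_annotations", a, c(ann, tot), nrow(sim$records))
  })

  run_stage("enrichment", function() {
    e <- cfg$enrichment
    records <- read_domain_annotations(path_of("annotations.tsv"))
    tot_df <- utils::read.delim(path_of("protein_totals.tsv"))
    totals <- stats::setNames(tot_df$n_proteins, tot_df$genome_id)
    mat <- build_domain_count_matrix(records, totals)
    res <- pairwise_domain_enrichment(mat, enrichment_params(
      alpha = e$alpha, min_genomes_present = e$min_genomes_present,
      gene_set_alpha = e$gene_set_alpha))
    out <- path_of("enrichment.tsv")
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    inter <- exclusive_intersections(domain_presence_sets(mat))
    out2 <- path_of("intersections.tsv")
    utils::write.table(as.data.frame(inter), out2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("enrichment", e, c(out, out2), nrow(res))
  })

  run_stage("architecture", function() {
    records <- read_domain_annotations(path_of("annotations.tsv"))
    ruleset <- switch(cfg$rules,
                      circadian = circadian_rules(),
                      rnai = rnai_rules(),
                      rid = rid_rules(),
                      all = all_rules(),
                      stop("config validation error: unknown rules '",
                           cfg$rules, "'"))
    res <- classify_genome_candidates(records, ruleset)
    out <- path_of("architectures.tsv")
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("architecture", list(rules = cfg$rules), out, nrow(res))
  })

  run_stage("simulate_orthogroups", function() {
    sim <- simulate_orthogroups(sim_og_params(seed = seed + 2L))
    og <- path_of("orthogroups.tsv")
    write_orthogroups(sim$ogs, og)
    expr <- path_of("expression.tsv")
    write_expression(sim$expression, expr)
    uni <- path_of("gene_universe.tsv")
    utils::write.table(
      data.frame(species = rep(names(sim$gene_universe),
                               times = lengths(sim$gene_universe)),
                 gene_id = unlist(sim$gene_universe, use.names = FALSE)),
      uni, sep = "\t", quote = FALSE, row.names = FALSE)
    record("simulate_orthogroups", list(), c(og, expr, uni),
           length(sim$ogs))
  })

  run_stage("occupancy", function() {
    o <- cfg$occupancy
    ogs <- read_orthogroups(path_of("orthogroups.tsv"))
    uni_df <- utils::read.delim(path_of("gene_universe.tsv"))
    gene_universe <- split(uni_df$gene_id, uni_df$species)
    gene_universe <- gene_universe[unique(uni_df$species)]
    expression <- read_expression(path_of("expression.tsv"))
    species <- attr(ogs, "species")
    cls <- classify_orthogroups(ogs, species)
    summ <- occupancy_summary(cls, species)
    statuses <- classify_genes(ogs, gene_universe)
    filt <- apply_expression_filter(statuses, expression,
                                    occupancy_params(species,
                                                     o$min_total_counts))
    out1 <- path_of("orthogroup_classes.tsv")
    utils::write.table(cls, out1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out2 <- path_of("gene_statuses.tsv")
    utils::write.table(statuses, out2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out3 <- path_of("occupancy_summary.json")
    jsonlite::write_json(list(
      n_ogs = summ$n_ogs,
      class_counts = as.list(summ$class_counts),
      class_pct = as.list(summ$class_pct),
      per_species = summ$per_species,
      expression_filter = filt$summary
    ), out3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("occupancy", o, c(out1, out2, out3), nrow(cls))
  })

  finish()
  invisible(manifest)
}
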