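# run expr with a private RNG stream seeded from `seed`, restoring any
# pre-existing RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Parameters for the genome simulator
#'
#' Defaults emulate a compact slice of a repeat-rich entomophthoralean
#' genome: a 500 kb sequence at 50% GC of which 30% is repeat-family copies
#' (five families of 2 kb units, 15 copies each), all copies subjected to
#' RIP-context mutation at a per-site rate of 0.2.
#'
#' @param n_sequences Number of sequences.
#' @param length_bp Length of each sequence in bp.
#' @param gc_fraction GC content of the background (and repeat masters).
#' @param repeat_families `data.frame` with columns `family_id`,
#'   `unit_length`, `n_copies`.
#' @param rip_rate Per-eligible-site mutation probability in RIPped copies.
#' @param rip_target_fraction Fraction of each family's copies subjected to
#'   RIP.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `sim_genome_params`.
#' @export
sim_genome_params <- function(n_sequences = 1L, length_bp = 500000L,
                              gc_fraction = 0.5,
                              repeat_families = data.frame(
                                family_id = paste0("fam", 1:5),
                                unit_length = 2000L, n_copies = 15L),
                              rip_rate = 0.2, rip_target_fraction = 1,
                              seed = 1L) {
  stopifnot(n_sequences >= 1L, length_bp >= 1L,
            gc_fraction > 0, gc_fraction < 1,
            rip_rate >= 0, rip_rate <= 1,
            rip_target_fraction >= 0, rip_target_fraction <= 1,
            is.data.frame(repeat_families),
            all(c("family_id", "unit_length", "n_copies") %in%
                  names(repeat_families)))
  if (sum(repeat_families$unit_length * repeat_families$n_copies) >
      n_sequences * length_bp) {
    stop("capacity error: total repeat length exceeds sequence length")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 length_bp = as.integer(length_bp),
                 gc_fraction = gc_fraction,
                 repeat_families = repeat_families,
                 rip_rate = rip_rate,
                 rip_target_fraction = rip_target_fraction,
                 seed = as.integer(seed)),
            class = "sim_genome_params")
}

.random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Apply RIP-context mutations to regions of a sequence
#'
#' Within each region, the cytosine of every CpA dinucleotide is replaced
#' by thymine with probability `rate`, and the guanine of every TpG
#' dinucleotide (the CpA context read on the reverse strand) is replaced by
#' adenine with probability `rate`. Eligible sites are determined on the
#' input sequence, then mutated simultaneously; sequence outside the
#' regions is untouched.
#'
#' @param sequence Nucleotide string.
#' @param regions `data.frame` with 0-based half-open `start`/`end`
#'   columns; regions must not overlap.
#' @param rate Per-site mutation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `sequence` (mutated string) and `mutations`, a
#'   `data.frame` of 0-based positions with `from`/`to` bases.
#' @examples
#' apply_rip_mutations("CACA", data.frame(start = 0, end = 4),
#'                     rate = 1, seed = 1)$sequence  # "TATA"
#' @export
apply_rip_mutations <- function(sequence, regions, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1, is.data.frame(regions),
            all(c("start", "end") %in% names(regions)))
  len <- nchar(sequence)
  if (nrow(regions) > 0L) {
    stopifnot(all(regions$start >= 0), all(regions$end <= len),
              all(regions$start < regions$end))
    ord <- order(regions$start)
    if (any(regions$end[ord][-nrow(regions)] >
            regions$start[ord][-1L])) {
      stop("validation error: overlapping regions")
    }
  }
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  in_region <- logical(len)
  for (i in seq_len(nrow(regions))) {
    in_region[(regions$start[i] + 1L):regions$end[i]] <- TRUE
  }
  # a dinucleotide site is eligible only when fully inside one region
  ca_c <- which(bases == "C" & c(bases[-1L], "") == "A" &
                  in_region & c(in_region[-1L], FALSE))
  tg_g <- which(bases == "G" & c("", bases[-len]) == "T" &
                  in_region & c(FALSE, in_region[-len]))
  .with_seed(seed, {
    ca_hit <- ca_c[stats::runif(length(ca_c)) < rate]
    tg_hit <- tg_g[stats::runif(length(tg_g)) < rate]
  })
  from <- c(rep("C", length(ca_hit)), rep("G", length(tg_hit)))
  to <- c(rep("T", length(ca_hit)), rep("A", length(tg_hit)))
  pos <- c(ca_hit, tg_hit)
  bases[ca_hit] <- "T"
  bases[tg_hit] <- "A"
  ord <- order(pos)
  list(sequence = paste(bases, collapse = ""),
       mutations = data.frame(pos = pos[ord] - 1L, from = from[ord],
                              to = to[ord], stringsAsFactors = FALSE))
}

#' Simulate genome sequences with repeat families and RIP mutation
#'
#' Background bases are drawn i.i.d. at the requested GC fraction; each
#' repeat family has one randomly drawn master unit whose copies are placed
#' non-overlapping at random positions (rejection sampling, 1000 attempts
#' per copy). A fraction of each family's copies is then subjected to
#' RIP-context mutation ([apply_rip_mutations()]).
#'
#' @param params A [sim_genome_params()] object.
#' @return List with `sequences` (named character vector), `repeats` (truth
#'   table: `seq_id`, `family_id`, `copy`, 0-based half-open
#'   `start`/`end`, logical `ripped`) and `mutations` (per-site truth:
#'   `seq_id`, 0-based `pos`, `from`, `to`).
#' @export
simulate_genome <- function(params = sim_genome_params()) {
  stopifnot(inherits(params, "sim_genome_params"))
  .with_seed(params$seed, {
    fams <- params$repeat_families
    masters <- lapply(seq_len(nrow(fams)), function(i) {
      paste(.random_bases(fams$unit_length[i], params$gc_fraction),
            collapse = "")
    })
    seq_ids <- sprintf("sim_seq%d", seq_len(params$n_sequences))
    sequences <- character(params$n_sequences)
    names(sequences) <- seq_ids
    truth <- list()
    mut_truth <- list()
    # assign every copy of every family to a sequence round-robin, then
    # place within the sequence by rejection sampling
    copy_tab <- do.call(rbind, c(list(
      data.frame(family = integer(0), copy = integer(0),
                 unit_length = integer(0))),
      lapply(seq_len(nrow(fams)), function(i) {
        data.frame(family = i, copy = seq_len(fams$n_copies[i]),
                   unit_length = fams$unit_length[i])
      })))
    copy_tab$seq <- rep_len(seq_len(params$n_sequences), nrow(copy_tab))
    for (s in seq_len(params$n_sequences)) {
      bases <- .random_bases(params$length_bp, params$gc_fraction)
      placed <- copy_tab[copy_tab$seq == s, , drop = FALSE]
      occupied <- matrix(numeric(0L), ncol = 2L)
      rows <- list()
      for (r in seq_len(nrow(placed))) {
        ulen <- placed$unit_length[r]
        ok <- FALSE
        for (attempt in seq_len(1000L)) {
          start <- sample.int(params$length_bp - ulen + 1L, 1L) - 1L
          end <- start + ulen
          if (nrow(occupied) == 0L ||
              all(end <= occupied[, 1L] | start >= occupied[, 2L])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop("capacity error: could not place repeat copy ",
               placed$copy[r], " of ", fams$family_id[placed$family[r]])
        }
        occupied <- rbind(occupied, c(start, end))
        master <- masters[[placed$family[r]]]
        bases[(start + 1L):end] <- strsplit(master, "", fixed = TRUE)[[1L]]
        rows[[r]] <- data.frame(seq_id = seq_ids[s],
                                family_id = fams$family_id[placed$family[r]],
                                copy = placed$copy[r], start = start,
                                end = end, stringsAsFactors = FALSE)
      }
      reg <- if (length(rows) > 0L) do.call(rbind, rows) else
        data.frame(seq_id = character(), family_id = character(),
                   copy = integer(), start = integer(), end = integer())
      # choose which copies are RIPped, per family
      reg$ripped <- logical(nrow(reg))
      for (i in seq_len(nrow(fams))) {
        idx <- which(reg$family_id == fams$family_id[i])
        n_rip <- round(params$rip_target_fraction * length(idx))
        if (n_rip > 0L) {
          reg$ripped[sample(idx, n_rip)] <- TRUE
        }
      }
      seq_s <- paste(bases, collapse = "")
      rip_regions <- reg[reg$ripped, c("start", "end"), drop = FALSE]
      mut_seed <- sample.int(.Machine$integer.max, 1L)
      ripped <- apply_rip_mutations(seq_s, rip_regions, params$rip_rate,
                                    seed = mut_seed)
      sequences[s] <- ripped$sequence
      truth[[s]] <- reg
      if (nrow(ripped$mutations) > 0L) {
        mut_truth[[s]] <- cbind(data.frame(seq_id = seq_ids[s],
                                           stringsAsFactors = FALSE),
                                ripped$mutations)
      }
    }
    repeats <- do.call(rbind, truth)
    rownames(repeats) <- NULL
    mutations <- if (length(mut_truth) > 0L) do.call(rbind, mut_truth) else
      data.frame(seq_id = character(), pos = integer(), from = character(),
                 to = character(), stringsAsFactors = FALSE)
    rownames(mutations) <- NULL
    list(sequences = sequences, repeats = repeats, mutations = mutations)
  })
}

#' Parameters for the domain annotation simulator
#'
#' Defaults mirror the null-calibration conditions used throughout the
#' package's tests: seven genomes of 5,000 annotated proteins each and 500
#' Pfam-style domains with per-genome protein counts drawn
#' Poisson(`baseline_lambda` = 20).
#'
#' @param n_genomes Number of genomes (ids `g1`, `g2`, ...).
#' @param n_domains Number of background domains (synthetic accessions).
#' @param baseline_lambda Poisson mean protein count per (genome, domain).
#' @param totals Total annotated proteins per genome (scalar or vector).
#' @param planted_enrichments `data.frame` with columns `domain` (index or
#'   accession), `genome`, `fold`: those cells are drawn
#'   Poisson(`fold * baseline_lambda`).
#' @param planted_architectures `data.frame` with columns `genome`, `label`
#'   (a built-in rule label from [all_rules()]), `n_proteins`.
#' @param decoys Plant one near-miss decoy protein per planted architecture
#'   label (e.g. GATA + PAS_3 without the PAS_9 that WC1 requires).
#' @param seed Integer seed.
#' @return Object of class `sim_annotation_params`.
#' @export
sim_annotation_params <- function(n_genomes = 7L, n_domains = 500L,
                                  baseline_lambda = 20,
                                  totals = 5000L,
                                  planted_enrichments = NULL,
                                  planted_architectures = NULL,
                                  decoys = TRUE, seed = 1L) {
  stopifnot(n_genomes >= 2L, n_domains >= 1L, baseline_lambda > 0)
  genomes <- sprintf("g%d", seq_len(n_genomes))
  if (length(totals) == 1L) totals <- rep(totals, n_genomes)
  stopifnot(length(totals) == n_genomes, all(totals > 0))
  names(totals) <- genomes
  structure(list(n_genomes = as.integer(n_genomes),
                 n_domains = as.integer(n_domains),
                 baseline_lambda = baseline_lambda,
                 totals = totals, genomes = genomes,
                 planted_enrichments = planted_enrichments,
                 planted_architectures = planted_architectures,
                 decoys = isTRUE(decoys),
                 seed = as.integer(seed)),
            class = "sim_annotation_params")
}

# one exemplar protein domain-content per built-in rule label, plus a
# near-miss decoy that must NOT match the label
.arch_exemplars <- function() {
  acc <- pfam_accessions()
  list(
    FRQ = list(hit = c(FRQ = 1), decoy = c(PAS = 1)),
    WC1 = list(hit = c(GATA = 1, PAS_3 = 1, PAS_9 = 1),
               decoy = c(GATA = 1, PAS_9 = 1)),
    WC2 = list(hit = c(GATA = 1, PAS_3 = 2),
               decoy = c(GATA = 1, PAS_3 = 1, PAS_9 = 1)),
    RHODOPSIN = list(hit = c(`7tm_1` = 1), decoy = c(GpcrRhopsn4 = 1)),
    RDRP = list(hit = c(RdRP = 1), decoy = c(DEAD = 1)),
    DICER = list(hit = c(Dicer_dimer = 1), decoy = c(Ribonuclease_3 = 1)),
    AGO = list(hit = c(PAZ = 1, Piwi = 1), decoy = c(Piwi = 1)),
    DICER_ALT = list(hit = c(Ribonuclease_3 = 1, DEAD = 1),
                     decoy = c(DEAD = 1, PAZ = 1)),
    RID_CANDIDATE = list(hit = c(DNA_methylase = 2),
                         decoy = c(DNA_methylase = 1))
  )
}

#' Simulate multi-genome domain annotation tables
#'
#' Background per-(genome, domain) protein counts are Poisson with mean
#' `baseline_lambda`, replaced by Poisson(`fold * baseline_lambda`) for
#' planted enrichments; every counted protein is a distinct protein id with
#' one domain instance. Planted architecture proteins (exact
#' rule-satisfying Pfam combinations) and, optionally, near-miss decoys are
#' appended. Note the decoy for WC1 (GATA + PAS_9, no PAS_3) and the decoy
#' for DICER_ALT (DEAD + PAZ, no Ribonuclease_3) match no built-in label;
#' the WC2 decoy intentionally matches WC1 instead of WC2.
#'
#' @param params A [sim_annotation_params()] object.
#' @return List with `records` (annotation `data.frame`), `totals` (named
#'   vector) and `truth` (list with `planted_enrichments`,
#'   `planted_architectures`, `decoys`).
#' @export
simulate_domain_annotations <- function(params = sim_annotation_params()) {
  stopifnot(inherits(params, "sim_annotation_params"))
  .with_seed(params$seed, {
    genomes <- params$genomes
    domains <- sprintf("PF9%04d", seq_len(params$n_domains))
    lam <- matrix(params$baseline_lambda, nrow = params$n_genomes,
                  ncol = params$n_domains,
                  dimnames = list(genomes, domains))
    pe <- params$planted_enrichments
    if (!is.null(pe)) {
      for (i in seq_len(nrow(pe))) {
        d <- pe$domain[i]
        if (is.numeric(d)) d <- domains[d]
        lam[pe$genome[i], d] <- pe$fold[i] * params$baseline_lambda
      }
    }
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = dimnames(lam))
    if (any(counts > params$totals[genomes])) {
      stop("capacity error: a domain's protein count exceeds genome totals")
    }
    # proteins carry multiple domains: each (genome, domain) count claims
    # that many distinct proteins sampled from the genome's protein pool
    recs <- list()
    for (g in genomes) {
      pool <- params$totals[[g]]
      carriers <- unlist(lapply(seq_along(domains), function(d) {
        sample.int(pool, counts[g, d])
      }), use.names = FALSE)
      if (length(carriers) == 0L) next
      recs[[g]] <- data.frame(
        genome_id = g,
        protein_id = sprintf("%s_p%05d", g, carriers),
        domain_accession = rep(domains, times = counts[g, ]),
        domain_db = "Pfam",
        n_instances = 1L,
        stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, recs)
    exemplars <- .arch_exemplars()
    acc <- pfam_accessions()
    arch_truth <- NULL
    decoy_truth <- NULL
    pa <- params$planted_architectures
    if (!is.null(pa)) {
      extra <- list()
      k <- 0L
      for (i in seq_len(nrow(pa))) {
        ex <- exemplars[[pa$label[i]]]
        if (is.null(ex)) {
          stop("validation error: unknown architecture label '",
               pa$label[i], "'")
        }
        for (j in seq_len(pa$n_proteins[i])) {
          k <- k + 1L
          pid <- sprintf("%s_arch%04d", pa$genome[i], k)
          extra[[length(extra) + 1L]] <- data.frame(
            genome_id = pa$genome[i], protein_id = pid,
            domain_accession = unname(acc[names(ex$hit)]),
            domain_db = "Pfam", n_instances = as.integer(ex$hit),
            stringsAsFactors = FALSE
          )
          arch_truth <- rbind(arch_truth, data.frame(
            genome_id = pa$genome[i], label = pa$label[i], protein_id = pid,
            stringsAsFactors = FALSE))
        }
        if (params$decoys) {
          k <- k + 1L
          pid <- sprintf("%s_decoy%04d", pa$genome[i], k)
          extra[[length(extra) + 1L]] <- data.frame(
            genome_id = pa$genome[i], protein_id = pid,
            domain_accession = unname(acc[names(ex$decoy)]),
            domain_db = "Pfam", n_instances = as.integer(ex$decoy),
            stringsAsFactors = FALSE
          )
          decoy_truth <- rbind(decoy_truth, data.frame(
            genome_id = pa$genome[i], label = pa$label[i], protein_id = pid,
            stringsAsFactors = FALSE))
        }
      }
      records <- rbind(records, do.call(rbind, extra))
    }
    rownames(records) <- NULL
    truth_pe <- pe
    if (!is.null(truth_pe) && is.numeric(truth_pe$domain)) {
      truth_pe$domain <- domains[truth_pe$domain]
    }
    list(records = records, totals = params$totals,
         truth = list(planted_enrichments = truth_pe,
                      planted_architectures = arch_truth,
                      decoys = decoy_truth))
  })
}

#' Parameters for the orthogroup and expression simulator
#'
#' Defaults generate a four-species analysis set with a core / shared /
#' species-specific occupancy mix and a pooled 27-sample expression table
#' whose per-gene totals follow a zero-inflated log-normal: a fraction `p0`
#' of genes has zero counts, the rest draw totals from
#' `Lognormal(meanlog, sdlog)` split across the samples at random
#' proportions.
#'
#' @param species Character vector of species ids.
#' @param n_core Number of core orthogroups.
#' @param shared_counts Named integer vector: names are comma-joined proper
#'   species subsets (in `species` order), values the number of orthogroups
#'   with exactly that occupancy.
#' @param specific_counts Named integer vector of species-specific
#'   orthogroup counts per species.
#' @param unassigned_counts Named integer vector of orthogroup-less gene
#'   counts per species.
#' @param genes_per_og_lambda Extra genes per occupied species beyond the
#'   mandatory one, Poisson mean.
#' @param p0 Zero-expression probability.
#' @param meanlog,sdlog Log-normal parameters of non-zero per-gene totals.
#' @param n_samples Number of pooled expression samples.
#' @param seed Integer seed.
#' @return Object of class `sim_og_params`.
#' @export
sim_og_params <- function(species = c("EMU", "EMA", "ZRA", "CTH"),
                          n_core = 200L,
                          shared_counts = c("EMU,EMA" = 40L,
                                            "EMU,EMA,ZRA" = 60L,
                                            "ZRA,CTH" = 30L,
                                            "EMA,ZRA,CTH" = 20L),
                          specific_counts = c(EMU = 80L, EMA = 40L,
                                              ZRA = 30L, CTH = 20L),
                          unassigned_counts = c(EMU = 150L, EMA = 100L,
                                                ZRA = 80L, CTH = 60L),
                          genes_per_og_lambda = 0.3,
                          p0 = 0.3, meanlog = log(50), sdlog = 1.5,
                          n_samples = 27L, seed = 1L) {
  stopifnot(length(species) >= 2L, n_core >= 0L,
            p0 >= 0, p0 <= 1, sdlog > 0, n_samples >= 1L,
            all(names(specific_counts) %in% species),
            all(names(unassigned_counts) %in% species))
  for (sub in names(shared_counts)) {
    members <- strsplit(sub, ",", fixed = TRUE)[[1L]]
    stopifnot(all(members %in% species), length(members) >= 2L,
              length(members) < length(species))
  }
  structure(list(species = species, n_core = as.integer(n_core),
                 shared_counts = shared_counts,
                 specific_counts = specific_counts,
                 unassigned_counts = unassigned_counts,
                 genes_per_og_lambda = genes_per_og_lambda,
                 p0 = p0, meanlog = meanlog, sdlog = sdlog,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sim_og_params")
}

#' Simulate orthogroup tables with planted occupancy structure
#'
#' Orthogroups are generated with exactly the requested occupancy classes;
#' each occupied species receives one mandatory gene plus
#' Poisson(`genes_per_og_lambda`) extras. Unassigned genes are appended to
#' the gene universe without any orthogroup. Per-gene expression totals are
#' drawn from the zero-inflated log-normal and split across the pooled
#' samples at uniform-random proportions.
#'
#' @param params A [sim_og_params()] object.
#' @return List with `ogs` (an `orthogroup_table`), `gene_universe` (named
#'   list species -> gene ids), `expression` (long-form `data.frame`) and
#'   `truth` (per-OG class table and per-gene `data.frame` with `status`
#'   and `expressed`, i.e. total counts >= 5).
#' @export
simulate_orthogroups <- function(params = sim_og_params()) {
  stopifnot(inherits(params, "sim_og_params"))
  .with_seed(params$seed, {
    species <- params$species
    subsets <- c(
      list(rep(paste(species, collapse = ","), params$n_core)),
      lapply(names(params$shared_counts), function(s) {
        rep(s, params$shared_counts[[s]])
      }),
      lapply(names(params$specific_counts), function(s) {
        rep(s, params$specific_counts[[s]])
      })
    )
    subsets <- unlist(subsets)
    n_ogs <- length(subsets)
    og_ids <- sprintf("OG%06d", seq_len(n_ogs))
    counter <- stats::setNames(integer(length(species)), species)
    ogs <- vector("list", n_ogs)
    for (i in seq_len(n_ogs)) {
      present <- strsplit(subsets[i], ",", fixed = TRUE)[[1L]]
      members <- stats::setNames(
        replicate(length(species), character(0L), simplify = FALSE), species)
      for (sp in present) {
        n_genes <- 1L + stats::rpois(1L, params$genes_per_og_lambda)
        ids <- sprintf("%s_gene%05d", sp, counter[[sp]] + seq_len(n_genes))
        counter[[sp]] <- counter[[sp]] + n_genes
        members[[sp]] <- ids
      }
      ogs[[i]] <- members
    }
    names(ogs) <- og_ids
    ogs <- structure(ogs, species = species, class = "orthogroup_table")
    gene_universe <- stats::setNames(vector("list", length(species)), species)
    for (sp in species) {
      assigned <- unlist(lapply(ogs, function(m) m[[sp]]), use.names = FALSE)
      n_un <- params$unassigned_counts[[sp]]
      if (is.null(n_un) || is.na(n_un)) n_un <- 0L
      unassigned <- if (n_un > 0L) {
        sprintf("%s_orphan%05d", sp, seq_len(n_un))
      } else {
        character(0L)
      }
      gene_universe[[sp]] <- c(assigned, unassigned)
    }
    all_genes <- unlist(gene_universe, use.names = FALSE)
    zero <- stats::runif(length(all_genes)) < params$p0
    tot <- ifelse(zero, 0,
                  stats::rlnorm(length(all_genes), params$meanlog,
                                params$sdlog))
    props <- matrix(stats::runif(length(all_genes) * params$n_samples),
                    nrow = length(all_genes))
    props <- props / rowSums(props)
    expression <- data.frame(
      gene_id = rep(all_genes, times = params$n_samples),
      sample_id = rep(sprintf("invivo_s%02d", seq_len(params$n_samples)),
                      each = length(all_genes)),
      est_counts = as.vector(props * tot),
      stringsAsFactors = FALSE
    )
    og_truth <- data.frame(og_id = og_ids, species_subset = subsets,
                           class = ifelse(
                             subsets == paste(species, collapse = ","),
                             "core",
                             ifelse(grepl(",", subsets, fixed = TRUE),
                                    "shared_subset", "species_specific")),
                           stringsAsFactors = FALSE)
    gene_class <- rep("unassigned", length(all_genes))
    names(gene_class) <- all_genes
    for (i in seq_len(n_ogs)) {
      cls <- if (og_truth$class[i] == "species_specific")
        "assigned_species_specific" else "assigned_shared"
      gene_class[unlist(ogs[[i]], use.names = FALSE)] <- cls
    }
    gene_truth <- data.frame(
      gene_id = all_genes,
      species = rep(names(gene_universe), times = lengths(gene_universe)),
      status = unname(gene_class[all_genes]),
      total_counts = tot,
      expressed = tot >= 5,
      stringsAsFactors = FALSE
    )
    list(ogs = ogs, gene_universe = gene_universe, expression = expression,
         truth = list(orthogroups = og_truth, genes = gene_truth))
  })
}
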