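# End-to-end orchestration: simulate -> amplicon -> haplotype -> genotype ->
# parentage -> traits, with config validation, logging and artifact writing.

#' Pipeline configuration
#'
#' Validates stage parameters for [run_pipeline()].
#'
#' @param mode `"fixture"`, `"simulated"` or `"files"`.
#' @param out_dir output directory.
#' @param seed integer seed (mandatory for `mode = "simulated"`).
#' @param n_parents,n_diploid_events,n_triploid_events simulated-world sizes
#'   (defaults mirror the motivating system: 7 parental taxa).
#' @param depth,error_rate read-simulation parameters.
#' @param min_reads,identity_threshold amplicon retention/clustering
#'   parameters.
#' @param min_samples rare-allele filter threshold.
#' @param group_threshold p-distance cut for lineage grouping.
#' @param samples_per_parent parental samples taken per taxon.
#' @param sample_table,allele_calls paths (for `mode = "files"`).
#' @return a validated `"pipeline_config"` list.
#' @export
pipeline_config <- function(mode = c("fixture", "simulated", "files"),
                            out_dir = tempfile("reticulator_run_"),
                            seed = NULL, n_parents = 7L,
                            n_diploid_events = 10L, n_triploid_events = 10L,
                            depth = 300, error_rate = 0, min_reads = 100L,
                            identity_threshold = 0.99, min_samples = 2L,
                            group_threshold = 0.05, samples_per_parent = 2L,
                            sample_table = NULL, allele_calls = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulated" && is.null(seed)) {
    stop("seed is mandatory when mode = 'simulated'")
  }
  if (min_reads < 0L) stop("min_reads must be >= 0")
  if (identity_threshold <= 0.5 || identity_threshold > 1) {
    stop("identity_threshold must be in (0.5, 1]")
  }
  if (min_samples < 1L) stop("min_samples must be >= 1")
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (group_threshold < 0 || group_threshold > 1) {
    stop("group_threshold must be in [0, 1]")
  }
  if (mode == "files" && (is.null(sample_table) || is.null(allele_calls))) {
    stop("mode = 'files' needs sample_table and allele_calls paths")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys are
#'   [pipeline_config()] arguments.
#' @return a validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, vals)
}

#' Call per-sample alleles from barcoded amplicon reads
#'
#' Demultiplexes by barcode, assigns each read to a locus by its primer pair
#' (reads matching no primer pair are discarded and counted), trims, then
#' clusters and applies the ploidy-aware retention rules per sample and
#' locus.
#'
#' @param reads character vector of read sequences.
#' @param barcode_map named character vector sample -> barcode.
#' @param samples sample table (`sample_id`, `ploidy`).
#' @param primers named list locus -> c(forward=, reverse=).
#' @param identity_threshold,min_reads see [cluster_reads()],
#'   [retain_clusters()].
#' @param max_primer_mismatches allowed mismatches per primer.
#' @return `data.frame` of retained consensus alleles: `sample_id`,
#'   `locus_id`, `rank`, `read_count`, `sequence`.
#' @export
process_amplicon_reads <- function(reads, barcode_map, samples,
                                   primers = default_primers(),
                                   identity_threshold = 0.99,
                                   min_reads = 100L,
                                   max_primer_mismatches = 0L) {
  dm <- demultiplex(reads, barcode_map)
  ploidy_of <- stats::setNames(samples$ploidy, samples$sample_id)
  out <- list()
  for (sid in names(dm$assigned)) {
    rs <- dm$assigned[[sid]]
    if (length(rs) == 0L) next
    for (loc in names(primers)) {
      pr <- primers[[loc]]
      trimmed <- trim_primers(rs, pr[["forward"]], pr[["reverse"]],
                              max_mismatches = max_primer_mismatches)
      if (length(trimmed) == 0L) next
      kept <- call_alleles(trimmed, ploidy = ploidy_of[[sid]],
                           identity_threshold = identity_threshold,
                           min_reads = min_reads)
      if (nrow(kept) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, locus_id = loc, rank = seq_len(nrow(kept)),
        read_count = kept$read_count, sequence = kept$consensus,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(sample_id = character(), locus_id = character(),
               rank = integer(), read_count = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  attr(res, "unassigned") <- length(dm$unassigned)
  res
}

#' Label allele sequences and assign lineage groups
#'
#' Collapses identical sequences per locus into haplotypes, clusters them
#' into lineage groups by p-distance, and relabels alleles in the
#' `<group><k>` convention so genotype strings read like published ones
#' (`A1`, `B2`, ...). Chloroplast haplotypes get `c<k>` labels and map to
#' themselves as groups.
#'
#' @param allele_seqs `data.frame` with `sample_id`, `locus_id`, `sequence`
#'   and optionally `read_count`.
#' @param cp_locus chloroplast locus id (its sequences are collapsed but not
#'   distance-grouped).
#' @param group_threshold p-distance cut (default 0.05).
#' @return allele-call `data.frame` (`sample_id`, `locus_id`,
#'   `allele_label`, `group_label`, `read_support`, `source`).
#' @export
label_alleles <- function(allele_seqs, cp_locus = "cpDNA",
                          group_threshold = 0.05) {
  out <- list()
  for (loc in unique(allele_seqs$locus_id)) {
    sub <- allele_seqs[allele_seqs$locus_id == loc, ]
    ht <- collapse_haplotypes(
      stats::setNames(sub$sequence, paste0("r", seq_len(nrow(sub)))),
      prefix = if (loc == cp_locus) "c" else "h")
    if (loc == cp_locus) {
      lab <- unname(ht$assignment)
      grp <- lab
    } else {
      reps <- ht$haplotypes
      groups <- assign_groups(reps, method = "distance_cluster",
                              threshold = group_threshold)
      # rename haplotype labels to <group letter><k>; group size-rank maps
      # onto letters (G1 -> A, G2 -> B, ...)
      grp_letters <- stats::setNames(
        LETTERS[as.integer(sub("^G", "", groups))], names(groups))
      relabel <- character(length(reps))
      names(relabel) <- names(reps)
      for (gl in unique(grp_letters)) {
        members <- names(grp_letters)[grp_letters == gl]
        relabel[members] <- paste0(gl, seq_along(members))
      }
      lab <- unname(relabel[ht$assignment])
      grp <- unname(grp_letters[ht$assignment])
    }
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sub$sample_id, locus_id = loc, allele_label = lab,
      group_label = grp,
      read_support = if ("read_count" %in% names(sub)) sub$read_count else
        NA_integer_,
      source = "ngs", stringsAsFactors = FALSE)
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Simulate a complete reticulate-evolution dataset
#'
#' Composes the simulator stages: parental panel, parental samples, a set of
#' hybridization events (diploid from two reduced gametes; triploid via an
#' unreduced gamete from the maternal or paternal side at random), barcoded
#' amplicon reads for the nuclear loci, and Sanger-style chloroplast
#' sequences.
#'
#' @param config a `"pipeline_config"` with `mode = "simulated"`.
#' @return list with `panel`, `samples`, `alleles`, `reads`, `barcodes`,
#'   `truth`.
#' @export
simulate_reticulate_dataset <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(config$seed)
  panel <- simulate_parental_panel(config$n_parents, seed = seed)
  events <- with_seed(seed + 1L, {
    n_total <- config$n_diploid_events + config$n_triploid_events
    lapply(seq_len(n_total), function(i) {
      pair <- sample(panel$taxa, 2L)
      triploid <- i > config$n_diploid_events
      unreduced_side <- if (triploid) sample(c("maternal", "paternal"), 1L)
        else "none"
      hybrid_event(
        maternal_taxon = pair[1L], paternal_taxon = pair[2L],
        maternal_gamete = if (unreduced_side == "maternal") "unreduced"
          else "reduced",
        paternal_gamete = if (unreduced_side == "paternal") "unreduced"
          else "reduced",
        child_mode = "apogamous")
    })
  })
  par_part <- panel_samples(panel, n_per_taxon = config$samples_per_parent)
  hyb <- simulate_hybridization(panel, events, seed = seed + 2L)
  samples <- rbind(par_part$samples, hyb$samples)
  alleles <- rbind(par_part$alleles, hyb$alleles)
  barcodes <- generate_barcodes(samples$sample_id, seed = seed + 3L)
  cp_locus <- .maternal_locus(panel)
  nuclear <- alleles[alleles$locus_id != cp_locus, ]
  reads <- simulate_reads(nuclear, depth = config$depth,
                          error_rate = config$error_rate,
                          barcode_map = barcodes, seed = seed + 4L)
  list(panel = panel, samples = samples, alleles = alleles, reads = reads,
       barcodes = barcodes, truth = hyb$truth)
}

#' Evaluate parent-pair and maternal-group recovery against simulation truth
#'
#' @param fit a fitted `"reticulogram"` on simulated data.
#' @param truth the `"simulation_truth"` record.
#' @return list with `parent_pair_recovery` and `maternal_group_recovery`
#'   (fractions in \[0, 1\]) plus a per-hybrid `detail` data frame.
#' @export
evaluate_recovery <- function(fit, truth) {
  ev <- truth$events
  reg <- fit$registry$alleles
  group_of_taxon <- function(tx) unique(reg$group[reg$taxon == tx])
  detail <- lapply(seq_len(nrow(ev)), function(i) {
    sid <- ev$sample_id[i]
    row <- fit$formulas[fit$formulas$sample_id == sid, ]
    if (nrow(row) != 1L) {
      return(data.frame(sample_id = sid, pair_ok = FALSE, group_ok = FALSE))
    }
    m_ok <- identical(row$maternal, ev$maternal_taxon[i])
    p_ok <- identical(row$paternal, ev$paternal_taxon[i])
    cp <- row$cp_haplotype
    g_ok <- FALSE
    if (!is.na(cp) && cp %in% names(fit$maternal)) {
      mg <- fit$maternal[[cp]]
      g_ok <- !mg$ambiguous &&
        identical(mg$groups, group_of_taxon(ev$maternal_taxon[i]))
    }
    data.frame(sample_id = sid, pair_ok = m_ok && p_ok, group_ok = g_ok,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  list(parent_pair_recovery = mean(detail$pair_ok),
       maternal_group_recovery = mean(detail$group_ok),
       detail = detail)
}

#' Run the full pipeline
#'
#' Runs the configured stages in order, writing one artifact per stage plus a
#' `run.log` and a `MANIFEST` to the output directory. Identical config and
#' seed produce identical outputs (timestamps appear only in the log).
#'
#' @param config a [pipeline_config()].
#' @return a run report (list): summary counts, file paths and, for simulated
#'   runs, recovery fractions.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  manifest <- character(0L)
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  # artifacts are recorded relative to out_dir so identical runs in
  # different directories produce identical reports
  note_artifact <- function(p) manifest <<- c(manifest, basename(p))
  stage <- "config"
  report <- tryCatch({
    if (config$mode == "fixture") {
      stage <- "fixture"
      fx <- load_fixture()
      logline("fixture: ", nrow(fx$samples), " samples, ",
              nrow(fx$calls), " allele calls")
      samples <- fx$samples; genotypes <- fx$genotypes
      characters <- fx$characters
    } else if (config$mode == "simulated") {
      stage <- "simulate"
      sim <- simulate_reticulate_dataset(config)
      logline("simulated: ", nrow(sim$samples), " samples, ",
              nrow(sim$reads), " reads")
      stage <- "amplicon"
      called <- process_amplicon_reads(
        sim$reads$sequence, sim$barcodes, sim$samples,
        identity_threshold = config$identity_threshold,
        min_reads = config$min_reads)
      logline("amplicon: ", nrow(called), " retained clusters, ",
              attr(called, "unassigned"), " unassigned reads")
      stage <- "haplotype"
      cp_locus <- .maternal_locus(sim$panel)
      cp_seqs <- sim$alleles[sim$alleles$locus_id == cp_locus,
                             c("sample_id", "locus_id", "sequence")]
      cp_seqs$read_count <- NA_integer_
      calls <- label_alleles(rbind(
        called[, c("sample_id", "locus_id", "sequence", "read_count")],
        cp_seqs), cp_locus = cp_locus,
        group_threshold = config$group_threshold)
      nuclear_calls <- calls[calls$locus_id != cp_locus, ]
      nuclear_calls <- filter_rare_alleles(nuclear_calls,
                                           min_samples = config$min_samples)
      calls <- rbind(nuclear_calls, calls[calls$locus_id == cp_locus, ])
      logline("haplotype: ", nrow(calls), " calls after rare-allele filter (",
              nrow(attr(nuclear_calls, "dropped")), " dropped)")
      samples <- sim$samples
      stage <- "genotype"
      genotypes <- genotype_table(samples, calls, haploid_loci = cp_locus)
      characters <- NULL
    } else {
      stage <- "files"
      samples <- read_sample_table(config$sample_table)
      calls <- read_allele_calls(config$allele_calls)
      if (!"mode" %in% names(samples)) samples$mode <- NA_character_
      genotypes <- genotype_table(samples, calls)
      characters <- NULL
      logline("files: ", nrow(samples), " samples, ", nrow(calls), " calls")
    }

    stage <- "infer"
    fit <- infer_reticulation(genotypes, samples)
    s <- summary(fit)
    logline("infer: ", s$total_genotypes, " genotypes, ",
            s$parental_genotypes, " parental, ", s$hybrid_genotypes,
            " hybrid")
    formulas_path <- file.path(config$out_dir, "formulas.tsv")
    write_tsv(fit$formulas[, setdiff(names(fit$formulas), "parent_set")],
              formulas_path); note_artifact(formulas_path)
    gml_path <- file.path(config$out_dir, "reticulogram.gml")
    dot_path <- file.path(config$out_dir, "reticulogram.dot")
    write_reticulogram(fit, gml_path, "gml"); note_artifact(gml_path)
    write_reticulogram(fit, dot_path, "dot"); note_artifact(dot_path)

    report <- list(mode = config$mode,
                   summary = list(
                     total_genotypes = s$total_genotypes,
                     parental_genotypes = s$parental_genotypes,
                     hybrid_genotypes = s$hybrid_genotypes,
                     parental_taxa = s$parental_taxa),
                   lineage_counts = s$lineage_counts,
                   artifacts = manifest)

    if (!is.null(characters)) {
      stage <- "traits"
      assoc_a <- associate_states(characters, genotypes,
                                  granularity = "allele")
      assoc_g <- associate_states(characters, genotypes,
                                  granularity = "group")
      traits_path <- file.path(config$out_dir, "trait_associations.tsv")
      write_tsv(rbind(cbind(granularity = "allele", assoc_a),
                      cbind(granularity = "group", assoc_g)), traits_path)
      note_artifact(traits_path)
      logline("traits: ", nrow(assoc_a), " state associations")
      report$trait_associations <- traits_path
    }
    if (config$mode == "simulated") {
      stage <- "recovery"
      rec <- evaluate_recovery(fit, sim$truth)
      logline("recovery: parent pairs ", rec$parent_pair_recovery,
              ", maternal groups ", rec$maternal_group_recovery)
      report$recovery <- rec[c("parent_pair_recovery",
                               "maternal_group_recovery")]
    }
    report_path <- file.path(config$out_dir, "report.json")
    write_json(report[setdiff(names(report), "lineage_counts")], report_path)
    note_artifact(report_path)
    report$artifacts <- manifest
    writeLines(c("status: complete", manifest),
               file.path(config$out_dir, "MANIFEST"))
    report
  }, error = function(e) {
    writeLines(c(paste0("status: incomplete (failed at stage '", stage, "')"),
                 manifest), file.path(config$out_dir, "MANIFEST"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  report
}
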