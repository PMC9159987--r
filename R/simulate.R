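# Forward simulator of reticulate evolution with apogamy: parental panel ->
# hybridization events -> barcoded amplicon reads, with a ground-truth record
# so the whole pipeline is testable without external data.

#' Locus configuration
#'
#' @param locus_id locus label.
#' @param inheritance `"maternal"` (chloroplast) or `"biparental"` (nuclear).
#' @param length sequence length in bp (> 0).
#' @param mutation_rate substitutions per site per lineage branch, in
#'   \[0, 1\].
#' @return a `"locus_config"` list.
#' @export
locus_config <- function(locus_id, inheritance = c("biparental", "maternal"),
                         length, mutation_rate = 0.05) {
  inheritance <- match.arg(inheritance)
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("locus length must be > 0")
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  structure(list(locus_id = locus_id, inheritance = inheritance,
                 length = length, mutation_rate = mutation_rate),
            class = "locus_config")
}

#' Default three-locus panel
#'
#' One maternally inherited chloroplast locus standing in for the
#' concatenated *rbcL*+*matK* markers (2184 bp) and two biparental nuclear
#' loci modelled on *Knox3* (493 bp) and *IBR3* (397 bp). The default
#' per-lineage divergence (5\% of sites) makes parental lineages roughly 10\%
#' divergent pairwise, comfortably separable by the default 5\% grouping
#' threshold.
#'
#' @param mutation_rate per-lineage substitution rate (default 0.05).
#' @return list of [locus_config()] objects.
#' @export
default_locus_panel <- function(mutation_rate = 0.05) {
  list(locus_config("cpDNA", "maternal", 2184L, mutation_rate),
       locus_config("Knox3", "biparental", 493L, mutation_rate),
       locus_config("IBR3", "biparental", 397L, mutation_rate))
}

#' Simulate a panel of diploid parental taxa
#'
#' Parental taxa diverge from a shared random ancestral sequence on a star
#' phylogeny: each taxon receives its own binomially-many private
#' substitutions per locus (Jukes-Cantor style uniform base choice). Every
#' parental taxon is diploid and homozygous at nuclear loci unless
#' `alleles_per_taxon = 2`, in which case the second allele diverges from the
#' first by `within_divergence` of sites (same-group heterozygote). Nuclear
#' allele sequences are guaranteed pairwise distinct across taxa, as are
#' chloroplast haplotypes; deterministic for a given seed.
#'
#' @param n_taxa number of parental taxa (>= 2, <= 26).
#' @param loci list of [locus_config()]; exactly one maternal locus.
#' @param seed integer seed.
#' @param alleles_per_taxon 1 (homozygous) or 2.
#' @param within_divergence per-site divergence between a taxon's two alleles
#'   (default 0.005).
#' @return a `"parental_panel"`: list with `taxa`, `loci`, `alleles`
#'   (`data.frame`: `taxon`, `locus_id`, `allele_label`, `sequence`),
#'   `group_map` (named character allele -> group) and `cp` (named character
#'   taxon -> haplotype label).
#' @export
simulate_parental_panel <- function(n_taxa, loci = default_locus_panel(),
                                    seed = 1L, alleles_per_taxon = 1L,
                                    within_divergence = 0.005) {
  if (n_taxa < 2L) stop("need at least two parents")
  if (n_taxa > 26L) stop("at most 26 parental taxa supported")
  inh <- vapply(loci, `[[`, character(1L), "inheritance")
  if (sum(inh == "maternal") != 1L) {
    stop("the locus panel must contain exactly one maternal locus")
  }
  stopifnot(alleles_per_taxon %in% c(1L, 2L))
  with_seed(seed, {
    taxa <- sprintf("parent_%s", LETTERS[seq_len(n_taxa)])
    rows <- list()
    group_map <- character(0L)
    cp <- character(0L)
    for (lc in loci) {
      ancestral <- random_sequence(lc$length)
      seen <- character(0L)
      for (t in seq_len(n_taxa)) {
        n_mut <- stats::rbinom(1L, lc$length, lc$mutation_rate)
        seq1 <- mutate_sequence(ancestral, max(n_mut, 1L))
        while (seq1 %in% seen) seq1 <- mutate_sequence(seq1, 1L)
        seen <- c(seen, seq1)
        if (lc$inheritance == "maternal") {
          hap <- paste0("c", letters[t])
          cp[taxa[t]] <- hap
          rows[[length(rows) + 1L]] <- data.frame(
            taxon = taxa[t], locus_id = lc$locus_id, allele_label = hap,
            sequence = seq1, stringsAsFactors = FALSE)
        } else {
          n_all <- alleles_per_taxon
          seqs <- seq1
          if (n_all == 2L) {
            n_within <- stats::rbinom(1L, lc$length, within_divergence)
            seq2 <- mutate_sequence(seq1, max(n_within, 1L))
            while (seq2 %in% seen) seq2 <- mutate_sequence(seq2, 1L)
            seen <- c(seen, seq2)
            seqs <- c(seqs, seq2)
          }
          for (k in seq_along(seqs)) {
            lab <- paste0(LETTERS[t], k)
            group_map[lab] <- LETTERS[t]
            rows[[length(rows) + 1L]] <- data.frame(
              taxon = taxa[t], locus_id = lc$locus_id, allele_label = lab,
              sequence = seqs[k], stringsAsFactors = FALSE)
          }
        }
      }
    }
    structure(list(taxa = taxa, loci = loci,
                   alleles = do.call(rbind, rows),
                   group_map = group_map, cp = cp),
              class = "parental_panel")
  })
}

#' @export
print.parental_panel <- function(x, ...) {
  cat("<parental_panel> ", length(x$taxa), " taxa, ",
      length(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Construct a hybridization event
#'
#' @param maternal_taxon,paternal_taxon parental taxon labels.
#' @param maternal_gamete,paternal_gamete `"reduced"` (one allele) or
#'   `"unreduced"` (the parent's full diploid complement). The resulting
#'   child ploidy must be 2 or 3: two unreduced gametes are rejected.
#' @param child_mode `"sexual"` (64 spores per sporangium) or `"apogamous"`
#'   (32).
#' @return a `"hybrid_event"` list.
#' @export
hybrid_event <- function(maternal_taxon, paternal_taxon,
                         maternal_gamete = c("reduced", "unreduced"),
                         paternal_gamete = c("reduced", "unreduced"),
                         child_mode = c("apogamous", "sexual")) {
  maternal_gamete <- match.arg(maternal_gamete)
  paternal_gamete <- match.arg(paternal_gamete)
  child_mode <- match.arg(child_mode)
  ploidy <- (maternal_gamete == "unreduced") + (paternal_gamete == "unreduced") + 2L
  if (!ploidy %in% c(2L, 3L)) {
    stop("gamete combination yields ploidy ", ploidy, ", must be 2 or 3")
  }
  structure(list(maternal_taxon = maternal_taxon,
                 paternal_taxon = paternal_taxon,
                 maternal_gamete = maternal_gamete,
                 paternal_gamete = paternal_gamete,
                 child_mode = child_mode, child_ploidy = ploidy),
            class = "hybrid_event")
}

#' Simulate hybridization events on a parental panel
#'
#' Each event yields one child sample carrying the union of the contributed
#' nuclear alleles (reduced gamete: one allele drawn at random from the
#' parent; unreduced: both chromosome sets), the maternal parent's
#' chloroplast haplotype (strict maternal inheritance), ploidy equal to the
#' number of contributed chromosome sets, and a spore count of 64 (sexual) or
#' 32 (apogamous). A ground-truth record maps every child allele to its
#' source parent.
#'
#' @param panel a [simulate_parental_panel()] result.
#' @param events list of [hybrid_event()]s.
#' @param seed integer seed (used for reduced-gamete allele draws from
#'   heterozygous parents).
#' @return list with `samples` (metadata `data.frame`), `alleles`
#'   (`data.frame`: `sample_id`, `locus_id`, `allele_label`, `sequence`,
#'   `dose`) and `truth` (class `"simulation_truth"`: `events` `data.frame`
#'   plus `allele_origin`).
#' @export
simulate_hybridization <- function(panel, events, seed = 1L) {
  stopifnot(inherits(panel, "parental_panel"))
  events <- lapply(events, function(e) {
    if (!inherits(e, "hybrid_event")) stop("events must be hybrid_event objects")
    if (!e$maternal_taxon %in% panel$taxa) {
      stop("unknown taxon: ", e$maternal_taxon)
    }
    if (!e$paternal_taxon %in% panel$taxa) {
      stop("unknown taxon: ", e$paternal_taxon)
    }
    e
  })
  nuclear <- panel$alleles[panel$alleles$locus_id != .maternal_locus(panel), ]
  cp_locus <- .maternal_locus(panel)
  with_seed(seed, {
    samples <- list()
    alleles <- list()
    origin <- list()
    ev_rows <- list()
    for (i in seq_along(events)) {
      e <- events[[i]]
      sid <- sprintf("hybrid_%02d", i)
      spores <- if (e$child_mode == "sexual") 64L else 32L
      samples[[i]] <- data.frame(
        sample_id = sid, taxon_name = sid, matches_type = FALSE,
        ploidy = e$child_ploidy, spore_count = spores,
        mode = if (e$child_mode == "sexual") "sexual" else "apogamous",
        stringsAsFactors = FALSE)
      # strict maternal chloroplast inheritance
      cp_row <- panel$alleles[panel$alleles$taxon == e$maternal_taxon &
                                panel$alleles$locus_id == cp_locus, ]
      alleles[[length(alleles) + 1L]] <- data.frame(
        sample_id = sid, locus_id = cp_locus,
        allele_label = cp_row$allele_label, sequence = cp_row$sequence,
        dose = 1L, stringsAsFactors = FALSE)
      for (loc in unique(nuclear$locus_id)) {
        contribute <- function(taxon, gamete) {
          own <- nuclear[nuclear$taxon == taxon & nuclear$locus_id == loc, ]
          if (gamete == "unreduced") {
            # full somatic complement: both chromosome sets (a homozygote
            # contributes its allele twice)
            if (nrow(own) == 1L) own <- own[c(1L, 1L), ] else own
          } else {
            own[sample.int(nrow(own), 1L), , drop = FALSE]
          }
          own
        }
        m <- contribute(e$maternal_taxon, e$maternal_gamete)
        p <- contribute(e$paternal_taxon, e$paternal_gamete)
        contributed <- rbind(m, p)
        tab <- table(contributed$allele_label)
        for (lab in names(tab)) {
          alleles[[length(alleles) + 1L]] <- data.frame(
            sample_id = sid, locus_id = loc, allele_label = lab,
            sequence = contributed$sequence[contributed$allele_label == lab][1L],
            dose = as.integer(tab[[lab]]), stringsAsFactors = FALSE)
        }
        for (k in seq_len(nrow(contributed))) {
          origin[[length(origin) + 1L]] <- data.frame(
            sample_id = sid, locus_id = loc,
            allele_label = contributed$allele_label[k],
            source_taxon = contributed$taxon[k], stringsAsFactors = FALSE)
        }
      }
      ev_rows[[i]] <- data.frame(
        sample_id = sid, maternal_taxon = e$maternal_taxon,
        paternal_taxon = e$paternal_taxon,
        maternal_gamete = e$maternal_gamete,
        paternal_gamete = e$paternal_gamete, child_mode = e$child_mode,
        child_ploidy = e$child_ploidy,
        cp_haplotype = cp_row$allele_label, stringsAsFactors = FALSE)
    }
    truth <- structure(list(events = do.call(rbind, ev_rows),
                            allele_origin = unique(do.call(rbind, origin))),
                       class = "simulation_truth")
    list(samples = do.call(rbind, samples),
         alleles = do.call(rbind, alleles), truth = truth)
  })
}

.maternal_locus <- function(panel) {
  inh <- vapply(panel$loci, `[[`, character(1L), "inheritance")
  panel$loci[[which(inh == "maternal")]]$locus_id
}

#' Parental taxa as samples
#'
#' Emits sample records and allele tables for the parental taxa themselves
#' (each taxon sampled `n_per_taxon` times), so parents go through the same
#' genotyping pipeline as their hybrids and private alleles pass the
#' rare-allele filter.
#'
#' @param panel a [simulate_parental_panel()] result.
#' @param n_per_taxon samples per parental taxon (default 2).
#' @param mode reproductive mode recorded for parents (default
#'   `"apogamous"`; five of the seven parental taxa of the motivating system
#'   are apogamous).
#' @return list with `samples` and `alleles` shaped like
#'   [simulate_hybridization()] output.
#' @export
panel_samples <- function(panel, n_per_taxon = 2L, mode = "apogamous") {
  samples <- list()
  alleles <- list()
  spores <- if (mode == "sexual") 64L else 32L
  for (t in panel$taxa) {
    for (k in seq_len(n_per_taxon)) {
      sid <- sprintf("%s_s%d", t, k)
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = sid, taxon_name = t, matches_type = TRUE, ploidy = 2L,
        spore_count = spores, mode = mode, stringsAsFactors = FALSE)
      own <- panel$alleles[panel$alleles$taxon == t, ]
      dose <- ifelse(own$locus_id == .maternal_locus(panel), 1L,
                     ifelse(duplicated(own$locus_id) |
                              duplicated(own$locus_id, fromLast = TRUE),
                            1L, 2L))
      alleles[[length(alleles) + 1L]] <- data.frame(
        sample_id = sid, locus_id = own$locus_id,
        allele_label = own$allele_label, sequence = own$sequence,
        dose = dose, stringsAsFactors = FALSE)
    }
  }
  list(samples = do.call(rbind, samples), alleles = do.call(rbind, alleles))
}

#' Generate sample barcodes
#'
#' Unique 8-base barcodes with pairwise Hamming distance >= 3.
#'
#' @param sample_ids character vector.
#' @param seed integer seed.
#' @return named character vector sample -> barcode.
#' @export
generate_barcodes <- function(sample_ids, seed = 1L) {
  with_seed(seed, {
    out <- character(0L)
    while (length(out) < length(sample_ids)) {
      cand <- random_sequence(8L)
      if (all(vapply(out, function(b) hamming(b, cand) >= 3L, logical(1L)))) {
        out <- c(out, cand)
      }
    }
    stats::setNames(out, sample_ids)
  })
}

# default amplification primer pairs per locus (forward, reverse as
# synthesised)
default_primers <- function() {
  list(Knox3 = c(forward = "CTTCAGCAGCATGTACGGGTTCA",
                 reverse = "CATCCTCATCGTCCGACATGGT"),
       IBR3 = c(forward = "CGCATATTCACAGACCCT",
                reverse = "GCCAGATATTGTTTAGCCCACC"))
}

#' Simulate barcoded amplicon reads
#'
#' Every allele of every sample yields a Poisson(`depth` x dose) number of
#' merged reads of the form `barcode + forward primer + allele +
#' revcomp(reverse primer)`, with independent per-base substitution errors at
#' `error_rate`. Deterministic for a given seed.
#'
#' @param alleles allele table (`sample_id`, `locus_id`, `allele_label`,
#'   `sequence`, optional `dose`), typically nuclear loci only.
#' @param depth mean reads per allele copy (> 0).
#' @param error_rate per-base substitution probability.
#' @param barcode_map named character vector sample -> 8-base barcode,
#'   unique.
#' @param seed integer seed.
#' @param primers named list locus -> c(forward=, reverse=); loci without an
#'   entry get no primer (barcode only).
#' @return `data.frame` with `read_id`, `sample_id` (truth only), `locus_id`,
#'   `sequence`.
#' @export
simulate_reads <- function(alleles, depth = 300, error_rate = 0,
                           barcode_map, seed = 1L,
                           primers = default_primers()) {
  if (depth <= 0) stop("depth must be > 0")
  if (anyDuplicated(barcode_map)) stop("duplicate barcodes in barcode map")
  if (any(nchar(barcode_map) != 8L)) stop("all barcodes must be 8 bases")
  missing <- setdiff(unique(alleles$sample_id), names(barcode_map))
  if (length(missing) > 0L) {
    stop("sample(s) without barcode: ", paste(missing, collapse = ", "))
  }
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(alleles))) {
      sid <- alleles$sample_id[i]
      loc <- alleles$locus_id[i]
      dose <- if ("dose" %in% names(alleles)) alleles$dose[i] else 1L
      pr <- primers[[loc]]
      body <- if (is.null(pr)) alleles$sequence[i] else
        paste0(pr[["forward"]], alleles$sequence[i],
               revcomp(pr[["reverse"]]))
      n_reads <- stats::rpois(1L, depth * dose)
      if (n_reads == 0L) next
      template <- paste0(barcode_map[[sid]], body)
      reads <- rep(template, n_reads)
      if (error_rate > 0) {
        len <- nchar(template)
        reads <- vapply(reads, function(r) {
          n_err <- stats::rbinom(1L, len, error_rate)
          mutate_sequence(r, n_err)
        }, character(1L), USE.NAMES = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        read_id = sprintf("%s|%s|%s|%04d", sid, loc,
                          alleles$allele_label[i], seq_len(n_reads)),
        sample_id = sid, locus_id = loc, sequence = reads,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Write simulator outputs to standard formats
#'
#' Samples to a metadata TSV, allele sequences to FASTA (record ids
#' `sample|locus|allele`), reads to FASTQ (barcode as the first 8 bases) and
#' the truth record to JSON.
#'
#' @param sim a [simulate_hybridization()]-shaped list (optionally with
#'   `reads`).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             alleles = file.path(dir, "alleles.fasta"),
             truth = file.path(dir, "truth.json"))
  write_tsv(sim$samples, paths[["samples"]])
  seqs <- stats::setNames(sim$alleles$sequence,
                          paste(sim$alleles$sample_id, sim$alleles$locus_id,
                                sim$alleles$allele_label, sep = "|"))
  write_fasta(seqs, paths[["alleles"]])
  if (!is.null(sim$reads)) {
    paths[["reads"]] <- file.path(dir, "reads.fastq")
    write_fastq(stats::setNames(sim$reads$sequence, sim$reads$read_id),
                paths[["reads"]])
  }
  if (!is.null(sim$truth)) {
    write_json(list(events = sim$truth$events,
                    allele_origin = sim$truth$allele_origin),
               paths[["truth"]])
  }
  invisible(paths)
}
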