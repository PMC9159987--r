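# Parental/hybrid classification, maternal lineage inference from
# chloroplast-nuclear co-occurrence, hybrid formula assignment and the
# reticulogram. infer_reticulation() is the model-fitting entry point.

#' Classify genotypes as putative parental or hybrid
#'
#' A genotype entry is classified parental when its nuclear genotype at the
#' primary locus has a single distinct allele (homozygous, regardless of
#' reproductive mode), or when the sample is a sexual diploid whose alleles
#' all belong to one lineage group. When the primary locus has no data the
#' fallback locus is used. Everything else — including entries with no
#' nuclear data at all, which cannot be shown homozygous — is classified
#' hybrid (with an explanatory note).
#'
#' @param genotypes long genotype `data.frame` (as from [load_fixture()] or
#'   [genotype_table()]).
#' @param samples sample table with `sample_id`, `mode`, `ploidy`.
#' @param group_of named character vector allele -> group.
#' @param primary_locus,fallback_locus locus ids (defaults `"Knox3"`,
#'   `"IBR3"`).
#' @return `data.frame` with `sample_id`, `status` (`"parental"`/`"hybrid"`),
#'   `basis_locus` and `note`.
#' @export
identify_parental_genotypes <- function(genotypes, samples, group_of,
                                        primary_locus = "Knox3",
                                        fallback_locus = "IBR3") {
  mode_of <- stats::setNames(samples$mode, samples$sample_id)
  ploidy_of <- stats::setNames(samples$ploidy, samples$sample_id)
  res <- lapply(samples$sample_id, function(sid) {
    g <- genotypes[genotypes$sample_id == sid &
                     genotypes$locus_id == primary_locus, ]
    basis <- primary_locus
    if (nrow(g) == 0L) {
      g <- genotypes[genotypes$sample_id == sid &
                       genotypes$locus_id == fallback_locus, ]
      basis <- fallback_locus
    }
    if (nrow(g) == 0L) {
      return(data.frame(sample_id = sid, status = "hybrid",
                        basis_locus = NA_character_,
                        note = "no nuclear data; homozygosity not assessable",
                        stringsAsFactors = FALSE))
    }
    alleles <- unique(g$alleles[[1L]])
    homozygous <- length(alleles) == 1L
    groups <- unique(allele_group(alleles))
    sexual_one_group <- identical(mode_of[[sid]], "sexual") &&
      identical(ploidy_of[[sid]], 2L) && length(groups) == 1L
    status <- if (homozygous || sexual_one_group) "parental" else "hybrid"
    note <- if (homozygous) "homozygous" else if (sexual_one_group)
      "sexual diploid, single lineage group" else ""
    data.frame(sample_id = sid, status = status, basis_locus = basis,
               note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Registry of parental taxa: which taxa are homozygous for which alleles,
# and which cpDNA haplotypes each parental taxon carries.
.parental_registry <- function(genotypes, samples, statuses,
                               primary_locus, cp_locus) {
  parental_ids <- statuses$sample_id[statuses$status == "parental"]
  taxon_of <- stats::setNames(samples$taxon_name, samples$sample_id)
  rows <- list()
  cp_sets <- list()
  for (sid in parental_ids) {
    g <- genotypes[genotypes$sample_id == sid &
                     genotypes$locus_id == primary_locus, ]
    cp <- genotypes[genotypes$sample_id == sid &
                      genotypes$locus_id == cp_locus, ]
    taxon <- taxon_of[[sid]]
    if (nrow(cp) == 1L) {
      cp_sets[[taxon]] <- union(cp_sets[[taxon]] %||% character(0L),
                                cp$canonical)
    }
    if (nrow(g) == 0L) next
    for (al in unique(g$alleles[[1L]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, allele = al, group = allele_group(al),
        stringsAsFactors = FALSE)
    }
  }
  alleles <- if (length(rows) > 0L) unique(do.call(rbind, rows)) else
    data.frame(taxon = character(), allele = character(), group = character())
  rownames(alleles) <- NULL
  list(alleles = alleles, cp = cp_sets)
}

#' Chloroplast-by-nuclear-group co-occurrence matrix
#'
#' Counts, per chloroplast haplotype and nuclear lineage group, the number of
#' samples in which they co-occur (one increment per sample and distinct
#' group in its nuclear genotype); a parallel matrix restricted to
#' parental-status samples drives the maternal-lineage cascade. Samples
#' without a chloroplast haplotype are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @inheritParams identify_parental_genotypes
#' @param statuses output of [identify_parental_genotypes()].
#' @param cp_locus chloroplast locus id (default `"cpDNA"`).
#' @return list of class `"cooccurrence_matrix"` with `counts`,
#'   `parental_counts` (haplotype x group matrices) and `carriers` (named
#'   integer, samples per haplotype).
#' @export
build_cooccurrence <- function(genotypes, samples, statuses,
                               primary_locus = "Knox3", cp_locus = "cpDNA") {
  status_of <- stats::setNames(statuses$status, statuses$sample_id)
  incid <- list()
  excluded <- character(0L)
  carriers <- list()
  for (sid in samples$sample_id) {
    cp <- genotypes[genotypes$sample_id == sid &
                      genotypes$locus_id == cp_locus, ]
    if (nrow(cp) == 0L) { excluded <- c(excluded, sid); next }
    hap <- cp$canonical
    carriers[[hap]] <- c(carriers[[hap]] %||% character(0L), sid)
    g <- genotypes[genotypes$sample_id == sid &
                     genotypes$locus_id == primary_locus, ]
    if (nrow(g) == 0L) next
    for (grp in unique(allele_group(unique(g$alleles[[1L]])))) {
      incid[[length(incid) + 1L]] <- data.frame(
        hap = hap, group = grp, parental = identical(status_of[[sid]],
                                                     "parental"),
        stringsAsFactors = FALSE)
    }
  }
  haps <- unique(vapply(names(carriers), identity, character(1L)))
  if (length(incid) > 0L) {
    df <- do.call(rbind, incid)
    groups <- sort(unique(df$group))
    counts <- matrix(0L, length(haps), length(groups),
                     dimnames = list(haps, groups))
    parental_counts <- counts
    for (i in seq_len(nrow(df))) {
      counts[df$hap[i], df$group[i]] <- counts[df$hap[i], df$group[i]] + 1L
      if (df$parental[i]) {
        parental_counts[df$hap[i], df$group[i]] <-
          parental_counts[df$hap[i], df$group[i]] + 1L
      }
    }
  } else {
    counts <- parental_counts <- matrix(0L, length(haps), 0L,
                                        dimnames = list(haps, character(0L)))
  }
  structure(list(counts = counts, parental_counts = parental_counts,
                 carriers = vapply(carriers, length, integer(1L)),
                 carrier_ids = carriers, excluded = excluded),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat("<cooccurrence_matrix> ", nrow(x$counts), " haplotype(s) x ",
      ncol(x$counts), " group(s)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Infer the maternal nuclear lineage group of a chloroplast haplotype
#'
#' Decision cascade: (1) if exactly one nuclear group co-occurs with the
#' haplotype among parental-status samples, that group is the maternal
#' lineage; (2) otherwise the set of groups present in *every* sample
#' carrying the haplotype (universal co-occurrence); (3) otherwise the
#' ambiguity set of all co-occurring groups, flagged.
#'
#' @param cp_haplotype haplotype label.
#' @param matrix a [build_cooccurrence()] result.
#' @return list with `groups` (character set), `basis` (`"parental"`,
#'   `"universal"` or `"ambiguous"`) and `ambiguous` (logical: not a
#'   confident singleton).
#' @export
infer_maternal_group <- function(cp_haplotype, matrix) {
  if (!cp_haplotype %in% rownames(matrix$counts)) {
    stop("haplotype not present in co-occurrence matrix: ", cp_haplotype)
  }
  pc <- matrix$parental_counts[cp_haplotype, ]
  parental_groups <- names(pc)[pc > 0L]
  if (length(parental_groups) == 1L) {
    return(list(groups = parental_groups, basis = "parental",
                ambiguous = FALSE))
  }
  cc <- matrix$counts[cp_haplotype, ]
  n_carr <- matrix$carriers[[cp_haplotype]]
  universal <- names(cc)[cc == n_carr & cc > 0L]
  if (length(universal) > 0L) {
    return(list(groups = universal, basis = "universal",
                ambiguous = length(universal) != 1L))
  }
  list(groups = names(cc)[cc > 0L], basis = "ambiguous", ambiguous = TRUE)
}

# Assign a hybrid formula to one hybrid genotype entry.
# registry: .parental_registry() output; maternal: infer_maternal_group()
# result for the entry's haplotype (NULL when it has no haplotype).
.assign_parentage_one <- function(alleles, cp, maternal, registry) {
  alleles <- unique(alleles)
  groups <- allele_group(alleles)
  reg <- registry$alleles
  taxon_cp_ok <- function(taxon) {
    !is.null(cp) && cp %in% (registry$cp[[taxon]] %||% character(0L))
  }
  # exact-allele parent set, role-agnostic (drives the per-lineage counts)
  exact_tax <- lapply(alleles, function(a) unique(reg$taxon[reg$allele == a]))
  names(exact_tax) <- alleles
  parent_set <- unique(unlist(exact_tax))

  out <- list(status = "hybrid", maternal_taxa = character(0L),
              paternal_taxa = character(0L), maternal_alleles = character(0L),
              maternal_ambiguous = NA, paternal_unknown_groups = character(0L),
              parent_set = parent_set %||% character(0L), notes = character(0L))

  mg <- character(0L)
  if (!is.null(maternal)) {
    mg <- intersect(maternal$groups, groups)
  }
  if (length(mg) != 1L) {
    out$status <- "unresolved"
    out$notes <- c(out$notes, if (is.null(maternal))
      "no chloroplast haplotype" else if (length(mg) == 0L)
        "maternal lineage group not represented in genotype" else
          paste0("ambiguous maternal group {", fmt_set(mg), "}"))
    return(out)
  }

  m_alleles <- alleles[groups == mg]
  # (a) parental taxa homozygous for an exact maternal allele, preferring
  # taxa whose own cp haplotype set contains the hybrid's haplotype
  cand <- unique(reg$taxon[reg$allele %in% m_alleles])
  basis <- "exact"
  if (length(cand) > 1L) {
    consistent <- cand[vapply(cand, taxon_cp_ok, logical(1L))]
    if (length(consistent) >= 1L) cand <- consistent
  }
  if (length(cand) == 0L) {
    # (b) same-group parental taxa carrying the hybrid's haplotype
    grp_tax <- unique(reg$taxon[reg$group == mg])
    consistent <- grp_tax[vapply(grp_tax, taxon_cp_ok, logical(1L))]
    if (length(consistent) >= 1L) {
      cand <- consistent; basis <- "group_cp"
    } else if (length(grp_tax) >= 1L) {
      cand <- grp_tax; basis <- "group"
    }
  }
  if (length(cand) == 0L) {
    out$maternal_taxa <- "unknown"
    out$maternal_ambiguous <- FALSE
    out$notes <- c(out$notes,
                   paste0("no parental taxon registered for maternal group ",
                          mg))
  } else {
    out$maternal_taxa <- sort(cand)
    out$maternal_ambiguous <- length(cand) > 1L || basis == "group"
    if (basis != "exact") {
      out$notes <- c(out$notes, paste0("maternal taxon by ", basis,
                                       " fallback"))
    }
  }
  # maternal alleles: those matching the chosen taxa exactly, else all
  # same-group alleles
  matched <- m_alleles[vapply(m_alleles, function(a)
    any(reg$taxon[reg$allele == a] %in% out$maternal_taxa), logical(1L))]
  out$maternal_alleles <- if (length(matched) > 0L) sort_alleles(matched) else
    sort_alleles(m_alleles)

  # paternal side: remaining alleles, exact match else group fallback
  paternal_alleles <- setdiff(alleles, out$maternal_alleles)
  pat <- character(0L)
  for (a in paternal_alleles) {
    t_exact <- exact_tax[[a]]
    if (length(t_exact) > 0L) {
      pat <- union(pat, t_exact)
    } else {
      grp_tax <- unique(reg$taxon[reg$group == allele_group(a)])
      grp_tax <- setdiff(grp_tax, out$maternal_taxa)
      if (length(grp_tax) > 0L) {
        pat <- union(pat, paste0(sort(grp_tax), "?"))
        out$notes <- c(out$notes, paste0("allele ", a,
                                         ": group-level paternal candidates"))
      } else {
        out$paternal_unknown_groups <- union(out$paternal_unknown_groups,
                                             allele_group(a))
      }
    }
  }
  if (length(out$paternal_unknown_groups) > 0L) {
    pat <- union(pat, "unknown")
  }
  if (length(paternal_alleles) == 0L) {
    # all alleles fall in the maternal group (intra-group hybrid); the
    # paternal parent is a same-group lineage
    pat <- if (length(out$maternal_taxa) > 0L &&
               !identical(out$maternal_taxa, "unknown"))
      out$maternal_taxa else "unknown"
    out$notes <- c(out$notes, "intra-group hybrid")
  }
  out$paternal_taxa <- sort(unique(pat))
  out
}

#' Fit a reticulate-evolution model to genotype data
#'
#' The model-fitting entry point of the package. From per-sample nuclear
#' genotypes and chloroplast haplotypes it (i) classifies genotype entries as
#' putative parental vs hybrid ([identify_parental_genotypes()]); (ii) builds
#' the chloroplast-by-nuclear-group co-occurrence matrix
#' ([build_cooccurrence()]) and infers the maternal lineage group of every
#' haplotype ([infer_maternal_group()]); (iii) assigns each hybrid a hybrid
#' formula (maternal and paternal parental taxa, exact allele matches
#' preferred, chloroplast-consistent taxa preferred among ties, group-level
#' fallbacks flagged as ambiguous); and (iv) assembles the reticulogram — a
#' directed network with maternal and paternal parent-to-hybrid edges.
#'
#' @param genotypes long genotype `data.frame`: columns `sample_id`,
#'   `locus_id`, `canonical`, `unassorted`, `ploidy` and list column
#'   `alleles` (as returned by [load_fixture()] or built via
#'   [genotype_table()]); the chloroplast locus carries the haplotype label
#'   as its single "allele".
#' @param samples sample table (`sample_id`, `taxon_name`, `ploidy`, `mode`,
#'   optionally `habitat`, `elevation_class`).
#' @param primary_locus nuclear locus driving the inference (default
#'   `"Knox3"`).
#' @param fallback_locus secondary nuclear locus used when the primary has no
#'   data (default `"IBR3"`).
#' @param cp_locus chloroplast locus id (default `"cpDNA"`).
#' @return an object of class `"reticulogram"`; see [summary.reticulogram()],
#'   [plot.reticulogram()], [write_reticulogram()].
#' @export
infer_reticulation <- function(genotypes, samples, primary_locus = "Knox3",
                               fallback_locus = "IBR3", cp_locus = "cpDNA") {
  stopifnot(is.data.frame(genotypes), is.data.frame(samples))
  statuses <- identify_parental_genotypes(genotypes, samples,
                                          primary_locus = primary_locus,
                                          fallback_locus = fallback_locus)
  registry <- .parental_registry(genotypes, samples, statuses,
                                 primary_locus, cp_locus)
  coocc <- build_cooccurrence(genotypes, samples, statuses,
                              primary_locus, cp_locus)
  maternal_by_hap <- lapply(rownames(coocc$counts), infer_maternal_group,
                            matrix = coocc)
  names(maternal_by_hap) <- rownames(coocc$counts)

  taxon_of <- stats::setNames(samples$taxon_name, samples$sample_id)
  formulas <- list()
  for (i in seq_len(nrow(statuses))) {
    sid <- statuses$sample_id[i]
    g <- genotypes[genotypes$sample_id == sid &
                     genotypes$locus_id == primary_locus, ]
    cp <- genotypes[genotypes$sample_id == sid &
                      genotypes$locus_id == cp_locus, ]
    cp_hap <- if (nrow(cp) == 1L) cp$canonical else NULL
    canonical <- if (nrow(g) == 1L) g$canonical else NA_character_
    base <- data.frame(sample_id = sid, taxon = taxon_of[[sid]],
                       genotype = canonical,
                       cp_haplotype = cp_hap %||% NA_character_,
                       status = statuses$status[i],
                       stringsAsFactors = FALSE)
    if (statuses$status[i] == "parental") {
      row <- cbind(base, data.frame(maternal = "", paternal = "",
                                    maternal_alleles = "",
                                    ambiguous = FALSE,
                                    note = statuses$note[i],
                                    stringsAsFactors = FALSE))
      row$parent_set <- list(character(0L))
    } else if (nrow(g) == 0L) {
      row <- cbind(base, data.frame(maternal = "", paternal = "",
                                    maternal_alleles = "",
                                    ambiguous = NA,
                                    note = statuses$note[i],
                                    stringsAsFactors = FALSE))
      row$status <- "unresolved"
      row$parent_set <- list(character(0L))
    } else {
      maternal <- if (!is.null(cp_hap)) maternal_by_hap[[cp_hap]] else NULL
      pr <- .assign_parentage_one(g$alleles[[1L]], cp_hap, maternal, registry)
      row <- cbind(base, data.frame(
        maternal = fmt_set(pr$maternal_taxa),
        paternal = fmt_set(pr$paternal_taxa),
        maternal_alleles = fmt_set(pr$maternal_alleles),
        ambiguous = isTRUE(pr$maternal_ambiguous),
        note = paste(unique(pr$notes), collapse = "; "),
        stringsAsFactors = FALSE))
      row$status <- pr$status
      row$parent_set <- list(pr$parent_set)
    }
    formulas[[length(formulas) + 1L]] <- row
  }
  formulas <- do.call(rbind, formulas)
  rownames(formulas) <- NULL

  obj <- structure(list(formulas = formulas, statuses = statuses,
                        registry = registry, cooccurrence = coocc,
                        maternal = maternal_by_hap,
                        primary_locus = primary_locus,
                        cp_locus = cp_locus,
                        samples = samples, genotypes = genotypes),
                   class = "reticulogram")
  obj$network <- build_reticulogram(obj)
  obj
}

#' Assign a hybrid formula to a single hybrid genotype
#'
#' Lower-level access to the formula-assignment step of
#' [infer_reticulation()] for one genotype.
#'
#' @param alleles character vector of nuclear allele labels.
#' @param cp_haplotype chloroplast haplotype label (or `NULL`).
#' @param fit a fitted `"reticulogram"` (supplies the parental registry and
#'   maternal lineage calls).
#' @return list with `status`, `maternal_taxa`, `paternal_taxa`,
#'   `maternal_alleles`, `maternal_ambiguous`, `parent_set` and `notes`.
#' @export
assign_parentage <- function(alleles, cp_haplotype, fit) {
  stopifnot(inherits(fit, "reticulogram"))
  maternal <- if (!is.null(cp_haplotype) &&
                  cp_haplotype %in% names(fit$maternal))
    fit$maternal[[cp_haplotype]] else NULL
  .assign_parentage_one(alleles, cp_haplotype, maternal, fit$registry)
}
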