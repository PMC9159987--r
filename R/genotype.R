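#' Classify reproductive mode from spore counts
#'
#' Sexual plants of this group produce 64 spores per sporangium; apogamous
#' plants produce 32 or fewer. Counts strictly between 32 and 64, or above
#' 64, do not match either syndrome and are returned as `"unknown"` with a
#' warning.
#'
#' @param spore_count integer vector of spores per sporangium (`NA` allowed).
#' @return character vector: `"sexual"`, `"apogamous"` or `"unknown"`.
#' @export
infer_reproductive_mode <- function(spore_count) {
  if (any(!is.na(spore_count) & spore_count <= 0)) {
    stop("spore_count must be a positive integer")
  }
  out <- rep("unknown", length(spore_count))
  out[!is.na(spore_count) & spore_count == 64] <- "sexual"
  out[!is.na(spore_count) & spore_count <= 32] <- "apogamous"
  odd <- !is.na(spore_count) & spore_count > 32 & spore_count != 64
  if (any(odd)) {
    warning("spore count(s) ", paste(unique(spore_count[odd]), collapse = ", "),
            " match neither the sexual (64) nor the apogamous (<=32) syndrome")
  }
  out
}

#' Parse a genotype string into an allele multiset
#'
#' Genotype strings concatenate allele labels in canonical order, with a
#' trailing `"*"` when the observed number of distinct alleles is below the
#' ploidy level (unassorted alleles, exact dosage not assertable):
#' `"A1A6D7"`, `"A1D7*"`, `"F7F7F7"`.
#'
#' @param x a genotype string.
#' @return a list with `alleles` (character multiset, canonical order) and
#'   `unassorted` (logical).
#' @export
parse_genotype_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  unassorted <- grepl("\\*$", x)
  body <- sub("\\*$", "", x)
  m <- gregexpr("[A-Z][0-9]+", body)[[1L]]
  if (m[1L] == -1L) stop("cannot parse genotype string: ", x)
  alleles <- regmatches(body, gregexpr("[A-Z][0-9]+", body))[[1L]]
  if (paste(alleles, collapse = "") != body) {
    stop("cannot parse genotype string: ", x)
  }
  list(alleles = sort_alleles(alleles), unassorted = unassorted)
}

#' Canonical genotype string
#'
#' @param alleles character multiset of allele labels.
#' @param unassorted logical; `TRUE` appends `"*"`. `NA` (unknown ploidy) adds
#'   no marker.
#' @return the canonical string (alleles sorted by letter prefix then numeric
#'   suffix).
#' @export
canonical_genotype <- function(alleles, unassorted = FALSE) {
  paste0(paste(sort_alleles(alleles), collapse = ""),
         if (isTRUE(unassorted)) "*" else "")
}

#' Assemble a per-sample, per-locus genotype under a ploidy constraint
#'
#' Implements the published conventions: when the number of distinct observed
#' alleles equals the ploidy the genotype is reported plainly; a single allele
#' in a diploid is completed to a homozygote (`"A7A7"`) when
#' `homozygous_completion` is on; otherwise fewer alleles than the ploidy
#' yield the unassorted flag (`"A1D7*"`). Observing more distinct alleles
#' than the ploidy signals contamination or a wrong ploidy call and is an
#' error. Triploid single-allele observations are never tripled; they carry
#' the unassorted flag.
#'
#' @param alleles character vector of observed allele labels (distinct values
#'   are used; at least one required).
#' @param ploidy 2, 3 or `NA` (unknown).
#' @param homozygous_completion complete a single observed allele to a
#'   diploid homozygote (default `TRUE`).
#' @return a list of class `"genotype"` with `alleles` (multiset),
#'   `unassorted` (logical, `NA` when ploidy unknown and incomplete) and
#'   `canonical` (string).
#' @export
assemble_genotype <- function(alleles, ploidy = NA,
                              homozygous_completion = TRUE) {
  stopifnot(length(alleles) >= 1L)
  distinct <- sort_alleles(unique(alleles))
  n <- length(distinct)
  ploidy <- if (is.na(ploidy)) NA_integer_ else as.integer(ploidy)
  if (!is.na(ploidy) && !ploidy %in% c(2L, 3L)) stop("ploidy must be 2, 3 or NA")
  if (!is.na(ploidy) && n > ploidy) {
    stop("allele count exceeds ploidy (", n, " > ", ploidy, "): ",
         paste(distinct, collapse = ", "))
  }
  if (is.na(ploidy)) {
    multiset <- distinct
    unassorted <- NA
  } else if (n == ploidy) {
    multiset <- distinct
    unassorted <- FALSE
  } else if (n == 1L && ploidy == 2L && homozygous_completion) {
    multiset <- rep(distinct, 2L)
    unassorted <- FALSE
  } else {
    multiset <- distinct
    unassorted <- TRUE
  }
  structure(list(alleles = multiset, unassorted = unassorted,
                 canonical = canonical_genotype(multiset, unassorted)),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype>", x$canonical, "\n")
  invisible(x)
}

#' Assemble genotypes for all samples and loci
#'
#' Builds one genotype per sample and locus having at least one allele call;
#' sample/locus combinations with no calls are reported in the `"missing"`
#' attribute rather than as empty genotypes.
#'
#' @param samples sample table (needs `sample_id` and `ploidy`).
#' @param calls allele-call table (`sample_id`, `locus_id`, `allele_label`).
#' @param homozygous_completion see [assemble_genotype()].
#' @param haploid_loci loci carried in a single copy (the organellar
#'   chloroplast locus): their genotype is the haplotype label itself, no
#'   ploidy constraint or completion; more than one call is an error
#'   (contamination).
#' @return a `data.frame` with columns `sample_id`, `locus_id`, `canonical`,
#'   `unassorted`, `ploidy` and a list column `alleles`; attribute
#'   `"missing"` holds a `data.frame` of sample/locus pairs without calls.
#' @export
genotype_table <- function(samples, calls, homozygous_completion = TRUE,
                           haploid_loci = "cpDNA") {
  stopifnot(all(c("sample_id", "locus_id", "allele_label") %in% names(calls)))
  loci <- unique(calls$locus_id)
  rows <- list()
  missing <- list()
  ploidy_of <- stats::setNames(samples$ploidy, samples$sample_id)
  for (sid in samples$sample_id) {
    for (loc in loci) {
      al <- calls$allele_label[calls$sample_id == sid & calls$locus_id == loc]
      if (length(al) == 0L) {
        missing[[length(missing) + 1L]] <- data.frame(
          sample_id = sid, locus_id = loc, stringsAsFactors = FALSE)
        next
      }
      if (loc %in% haploid_loci) {
        if (length(unique(al)) > 1L) {
          stop("sample ", sid, ": multiple haplotypes at haploid locus ",
               loc, " (", paste(unique(al), collapse = ", "), ")",
               call. = FALSE)
        }
        g <- list(alleles = unique(al), unassorted = FALSE,
                  canonical = unique(al))
      } else {
        g <- tryCatch(
          assemble_genotype(al, ploidy = ploidy_of[[sid]],
                            homozygous_completion = homozygous_completion),
          error = function(e) stop("sample ", sid, ", locus ", loc, ": ",
                                   conditionMessage(e), call. = FALSE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, locus_id = loc, canonical = g$canonical,
        unassorted = g$unassorted,
        ploidy = if (is.null(ploidy_of[[sid]])) NA_integer_ else ploidy_of[[sid]],
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$alleles <- list(g$alleles)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(sample_id = character(), locus_id = character(),
               canonical = character(), unassorted = logical(),
               ploidy = integer(), stringsAsFactors = FALSE)
  attr(out, "missing") <- if (length(missing) > 0L) do.call(rbind, missing) else
    data.frame(sample_id = character(), locus_id = character())
  out
}
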