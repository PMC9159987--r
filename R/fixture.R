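#' Load the packaged Pteris fauriei group genotype fixture
#'
#' The package ships a transcription of the published 72-row genotype table
#' of the *Pteris fauriei* species group: per sample (one representative per
#' genotype entry) the morphology-based taxon, type-match flag, ploidy,
#' reproductive mode, chloroplast (cpDNA) haplotype, the *Knox3* and *IBR3*
#' nuclear genotype strings with the unassorted-allele `"*"` convention, the
#' published maternal-lineage calls, and distribution/elevation. Ditto marks
#' of the source table are already expanded; transcription judgment calls are
#' documented in the provenance file
#' (`system.file("extdata", "pteris_table1_provenance.md", package =
#' "reticulator")`).
#'
#' @return a list with elements
#'   \describe{
#'     \item{samples}{sample metadata `data.frame` (see
#'       [read_sample_table()]), plus `mode` (`"sexual"`/`"apogamous"`/`NA`)
#'       and taxon-level `habitat`.}
#'     \item{calls}{allele-call `data.frame`; nuclear loci `Knox3` and
#'       `IBR3` (one row per distinct allele) and locus `cpDNA` whose
#'       "allele" is the haplotype label.}
#'     \item{genotypes}{genotype `data.frame` (`sample_id`, `locus_id`,
#'       `canonical`, `unassorted`, `ploidy`, list column `alleles`) built
#'       verbatim from the printed genotype strings.}
#'     \item{characters}{long-format character matrix (see
#'       [fixture_character_matrix()]).}
#'     \item{published}{the published hybrid formulas and maternal-lineage
#'       columns, for comparison with re-inferred values.}
#'   }
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "pteris_table1.tsv", package = "reticulator")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "")
  stopifnot(!anyDuplicated(raw$sample_id))

  habitat_map <- c("P. minor" = "open", "P. fauriei" = "semi_shade",
                   "P. latipinna" = "shade")
  mode <- c(apo = "apogamous", sex = "sexual")[raw$mode]
  samples <- data.frame(
    sample_id = raw$sample_id,
    taxon_name = raw$taxon_name,
    matches_type = raw$matches_type == "Y",
    ploidy = suppressWarnings(as.integer(raw$ploidy)),
    spore_count = NA_integer_,
    mode = unname(mode),
    habitat = unname(habitat_map[raw$taxon_name]),
    elevation_class = c(l = "low", h = "high", both = "both")[raw$elevation],
    region = raw$region,
    stringsAsFactors = FALSE)
  samples$elevation_class <- unname(samples$elevation_class)

  calls <- list()
  genotypes <- list()
  for (i in seq_len(nrow(raw))) {
    sid <- raw$sample_id[i]
    ploidy <- samples$ploidy[i]
    for (loc in c("knox3", "ibr3")) {
      gs <- raw[[loc]][i]
      if (gs == "") next
      locus <- c(knox3 = "Knox3", ibr3 = "IBR3")[[loc]]
      # printed strings are kept verbatim as `canonical` (a few IBR3 rows
      # are printed out of sort order in the source)
      g <- parse_genotype_string(gs)
      unassorted <- if (is.na(ploidy)) NA else g$unassorted
      distinct <- unique(g$alleles)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sid, locus_id = locus, allele_label = distinct,
        group_label = allele_group(distinct), read_support = NA_integer_,
        source = "fixture", stringsAsFactors = FALSE)
      genotypes[[length(genotypes) + 1L]] <- cbind(
        data.frame(sample_id = sid, locus_id = locus, canonical = gs,
                   unassorted = unassorted, ploidy = ploidy,
                   stringsAsFactors = FALSE),
        data.frame(alleles = I(list(g$alleles))))
    }
    if (raw$cp_haplotype[i] != "") {
      hap <- raw$cp_haplotype[i]
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sid, locus_id = "cpDNA", allele_label = hap,
        group_label = hap, read_support = NA_integer_, source = "fixture",
        stringsAsFactors = FALSE)
      genotypes[[length(genotypes) + 1L]] <- cbind(
        data.frame(sample_id = sid, locus_id = "cpDNA", canonical = hap,
                   unassorted = FALSE, ploidy = ploidy,
                   stringsAsFactors = FALSE),
        data.frame(alleles = I(list(hap))))
    }
  }
  calls <- do.call(rbind, calls)
  genotypes <- do.call(rbind, genotypes)
  rownames(calls) <- rownames(genotypes) <- NULL

  published <- data.frame(
    sample_id = raw$sample_id,
    hybrid_formula = raw$hybrid_formula,
    maternal_knox3 = raw$maternal_knox3,
    maternal_ibr3 = raw$maternal_ibr3,
    stringsAsFactors = FALSE)

  list(samples = samples, calls = calls, genotypes = genotypes,
       characters = fixture_character_matrix(genotypes),
       published = published)
}

#' Reconstructed morphological character matrix for the fixture
#'
#' The source publication reports allele-character associations (stipe
#' colour, venation form, ...) but not a per-sample character matrix. This
#' function builds a synthetic reconstruction consistent with those reported
#' associations, for exercising the trait-association module: samples
#' carrying allele D4 have red-brown stipes, all others stramineous/green;
#' samples carrying a G-group *Knox3* allele have areolate costal veins
#' (including F x G hybrids, which are reported to show the areolate state),
#' samples carrying F without G have triangular costal veins, all others free
#' venation. Samples without nuclear data are not scored.
#'
#' @param genotypes a fixture genotype table (from [load_fixture()]).
#' @return long-format `data.frame` with columns `sample_id`, `character`,
#'   `state`.
#' @export
fixture_character_matrix <- function(genotypes) {
  kx <- genotypes[genotypes$locus_id == "Knox3", ]
  rows <- lapply(seq_len(nrow(kx)), function(i) {
    al <- unique(kx$alleles[[i]])
    grp <- unique(allele_group(al))
    data.frame(
      sample_id = kx$sample_id[i],
      character = c("stipe_color", "venation"),
      state = c(if ("D4" %in% al) "red_brown" else "stramineous_or_green",
                if ("G" %in% grp) "areolate"
                else if ("F" %in% grp) "triangular" else "free"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
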