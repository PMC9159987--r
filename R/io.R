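#' Read a sample metadata table
#'
#' Reads a tab-separated sample table with a header line. The columns
#' `sample_id` and `taxon_name` are required; the optional columns
#' `matches_type`, `ploidy`, `spore_count`, `habitat`, `elevation_class` and
#' `region` are parsed when present. Unknown or empty values are preserved as
#' `NA` (never silently defaulted).
#'
#' @param path path to a TSV file with a header.
#' @return a `data.frame` with one row per sample. `ploidy` is integer (2, 3
#'   or `NA`), `spore_count` integer, `matches_type` logical, `habitat` one of
#'   `"open"`, `"semi_shade"`, `"shade"` or `NA`, `elevation_class` one of
#'   `"low"`, `"high"`, `"both"` or `NA`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), quote = "")
  required <- c("sample_id", "taxon_name")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicated sample_id in sample table: ", paste(dup, collapse = ", "))
  }
  blank_na <- function(x) {
    x[x %in% c("", "-", "–", "NA", "unknown")] <- NA_character_
    x
  }
  out <- data.frame(sample_id = df$sample_id,
                    taxon_name = df$taxon_name,
                    stringsAsFactors = FALSE)
  n <- nrow(df)
  out$matches_type <- if ("matches_type" %in% names(df)) {
    toupper(blank_na(df$matches_type)) %in% "Y"
  } else rep(NA, n)
  out$ploidy <- if ("ploidy" %in% names(df)) {
    p <- blank_na(toupper(df$ploidy))
    p <- sub("X$", "", p)
    pn <- suppressWarnings(as.integer(p))
    bad <- !is.na(p) & (is.na(pn) | !pn %in% c(2L, 3L))
    if (any(bad)) stop("invalid ploidy value(s): ",
                       paste(unique(df$ploidy[bad]), collapse = ", "))
    pn
  } else rep(NA_integer_, n)
  out$spore_count <- if ("spore_count" %in% names(df)) {
    sc <- suppressWarnings(as.integer(blank_na(df$spore_count)))
    if (any(!is.na(sc) & sc <= 0L)) stop("spore_count must be positive")
    sc
  } else rep(NA_integer_, n)
  out$habitat <- if ("habitat" %in% names(df)) {
    h <- blank_na(df$habitat)
    ok <- is.na(h) | h %in% c("open", "semi_shade", "shade")
    if (!all(ok)) stop("invalid habitat value(s): ",
                       paste(unique(h[!ok]), collapse = ", "))
    h
  } else rep(NA_character_, n)
  out$elevation_class <- if ("elevation_class" %in% names(df)) {
    e <- blank_na(df$elevation_class)
    e[e == "l"] <- "low"; e[e == "h"] <- "high"
    ok <- is.na(e) | e %in% c("low", "high", "both")
    if (!all(ok)) stop("invalid elevation_class value(s): ",
                       paste(unique(e[!ok]), collapse = ", "))
    e
  } else rep(NA_character_, n)
  out$region <- if ("region" %in% names(df)) blank_na(df$region) else
    rep(NA_character_, n)
  rownames(out) <- NULL
  out
}

#' Read / write allele-call tables
#'
#' An allele-call table is a TSV with columns `sample_id`, `locus_id`,
#' `allele_label` and optionally `group_label`, `read_support` and `source`.
#' The triple (sample, locus, allele) must be unique.
#'
#' @param path file path.
#' @return `read_allele_calls()` returns a `data.frame`;
#'   `write_allele_calls()` returns `path` invisibly.
#' @export
read_allele_calls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  required <- c("sample_id", "locus_id", "allele_label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("allele-call table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$sample_id, df$locus_id, df$allele_label, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (sample_id, locus_id, allele_label) in allele calls")
  }
  if (!"group_label" %in% names(df)) df$group_label <- allele_group(df$allele_label)
  if (!"source" %in% names(df)) df$source <- "file"
  if ("read_support" %in% names(df)) {
    df$read_support <- suppressWarnings(as.integer(df$read_support))
  } else df$read_support <- NA_integer_
  df[, c("sample_id", "locus_id", "allele_label", "group_label",
         "read_support", "source")]
}

#' @rdname read_allele_calls
#' @param calls an allele-call `data.frame`.
#' @export
write_allele_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.validate_nucleotides <- function(seqs, gap_ok = TRUE) {
  alphabet <- "ACGTRYSWKMBDHVN"
  if (gap_ok) alphabet <- paste0(alphabet, "-")
  pat <- paste0("[^", alphabet, "]")
  for (i in seq_along(seqs)) {
    m <- regexpr(pat, toupper(seqs[[i]]))
    if (m > 0L) {
      stop("non-IUPAC nucleotide character in record ", i,
           " at position ", as.integer(m))
    }
  }
  invisible(TRUE)
}

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings readers/writers that add strict IUPAC
#' validation: any character outside the IUPAC nucleotide alphabet (plus gap)
#' raises an error reporting the record and position. Round trip is the
#' identity: `read_fasta(write_fasta(x, f))` equals `x`.
#'
#' @param records a named character vector of sequences (names are record
#'   ids).
#' @param path file path.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(records, path) {
  .validate_nucleotides(records)
  x <- Biostrings::DNAStringSet(toupper(records))
  names(x) <- names(records)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(x)
  .validate_nucleotides(out)
  out
}

#' Read and write FASTQ files
#'
#' @param records named character vector of read sequences.
#' @param path file path.
#' @param quality single quality character recycled over all bases when
#'   writing (simulated reads carry no meaningful qualities).
#' @return `read_fastq()` returns a named character vector of sequences.
#' @export
write_fastq <- function(records, path, quality = "I") {
  .validate_nucleotides(records, gap_ok = FALSE)
  x <- Biostrings::DNAStringSet(toupper(records))
  names(x) <- names(records) %||% paste0("read", seq_along(records))
  qual <- Biostrings::BStringSet(vapply(nchar(records), function(n)
    strrep(quality, n), character(1L)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
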