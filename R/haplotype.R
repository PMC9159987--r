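# Haplotype collapsing, lineage-group assignment and the rare-allele filter.

#' Collapse aligned sequences into labelled haplotypes
#'
#' Partitions equal-length (aligned) sequences by exact identity at retained
#' sites and labels haplotypes in order of first appearance as
#' `<prefix><k>`. Under `gap_policy = "sites_with_gaps_excluded"` every
#' alignment column containing a gap in any sequence is dropped before
#' comparison (gaps treated as missing data, excluded pairwise-complete
#' style); under `"gaps_as_missing"` a gap matches any base, and two
#' sequences share a haplotype when they are identical at all mutually
#' ungapped sites (ties to the earlier sequence's haplotype).
#'
#' @param sequences named character vector of aligned sequences.
#' @param gap_policy `"sites_with_gaps_excluded"` (default) or
#'   `"gaps_as_missing"`.
#' @param prefix label prefix (default `"h"`).
#' @return an object of class `"haplotype_table"`: list with `locus_prefix`,
#'   `haplotypes` (named character: label -> representative sequence),
#'   `assignment` (named character: input name -> label) and `members`
#'   (named integer: label -> count).
#' @export
collapse_haplotypes <- function(sequences,
                                gap_policy = c("sites_with_gaps_excluded",
                                               "gaps_as_missing"),
                                prefix = "h") {
  gap_policy <- match.arg(gap_policy)
  if (length(sequences) == 0L) {
    return(structure(list(locus_prefix = prefix,
                          haplotypes = character(0L),
                          assignment = character(0L),
                          members = integer(0L)),
                     class = "haplotype_table"))
  }
  if (length(unique(nchar(sequences))) != 1L) {
    stop("sequences must be aligned to equal length")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  seqs <- toupper(sequences)
  if (gap_policy == "sites_with_gaps_excluded") {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    keep <- colSums(mat == "-") == 0L
    key <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
    labels_idx <- match(key, unique(key))
  } else {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    labels_idx <- integer(length(seqs))
    reps <- list()
    for (i in seq_along(seqs)) {
      hit <- 0L
      for (r in seq_along(reps)) {
        a <- mat[i, ]; b <- reps[[r]]
        cmp <- a != "-" & b != "-"
        if (all(a[cmp] == b[cmp])) { hit <- r; break }
      }
      if (hit == 0L) {
        reps[[length(reps) + 1L]] <- mat[i, ]
        hit <- length(reps)
      }
      labels_idx[i] <- hit
    }
  }
  labs <- paste0(prefix, labels_idx)
  first <- !duplicated(labels_idx)
  haplotypes <- stats::setNames(unname(seqs[first]), labs[first])
  structure(list(locus_prefix = prefix,
                 haplotypes = haplotypes,
                 assignment = stats::setNames(labs, names(seqs)),
                 members = stats::setNames(
                   as.integer(table(factor(labs, levels = labs[first]))),
                   labs[first])),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", length(x$haplotypes), " haplotype(s), ",
      length(x$assignment), " sequence(s)\n", sep = "")
  invisible(x)
}

# pairwise p-distance on equal-length sequences, gaps excluded pairwise
.p_distance <- function(seqs) {
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  d <- matrix(0, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) sum(mat[i, ok] != mat[j, ok]) / sum(ok) else 0
    }
  }
  d
}

#' Assign alleles to lineage groups
#'
#' Either passes a user/fixture-provided allele -> group map through
#' (erroring on unmapped alleles) or clusters allele sequences by
#' single-linkage on pairwise p-distance cut at `threshold`, naming groups by
#' size rank (`G1`, `G2`, ... with ties broken by first appearance). The
#' published groups derive from gene-tree clades; distance clustering is the
#' deterministic substitute used when no map is supplied.
#'
#' @param alleles character vector of allele labels; for
#'   `method = "distance_cluster"` it must be named by label with sequence
#'   values, i.e. `c(A1 = "ACGT...", ...)`.
#' @param method `"provided_map"` or `"distance_cluster"`.
#' @param provided_map named character vector allele -> group (for
#'   `"provided_map"`).
#' @param threshold p-distance cut for `"distance_cluster"` (default 0.05).
#' @return named character vector allele label -> group label (every allele
#'   mapped).
#' @export
assign_groups <- function(alleles, method = c("provided_map",
                                              "distance_cluster"),
                          provided_map = NULL, threshold = 0.05) {
  method <- match.arg(method)
  if (method == "provided_map") {
    labels <- if (is.null(names(alleles))) alleles else names(alleles)
    if (is.null(provided_map)) stop("provided_map is required")
    unmapped <- setdiff(labels, names(provided_map))
    if (length(unmapped) > 0L) {
      stop("allele(s) missing from provided group map: ",
           paste(unmapped, collapse = ", "))
    }
    return(provided_map[labels])
  }
  seqs <- alleles
  if (is.null(names(seqs))) stop("distance_cluster needs named sequences")
  labels <- names(seqs)
  n <- length(seqs)
  if (n == 0L) return(stats::setNames(character(0L), character(0L)))
  d <- .p_distance(unname(seqs))
  parent <- seq_len(n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(min(i + 1L, n), n)) {
      if (j > i && d[i, j] <= threshold) {
        ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1L))
  sizes <- table(roots)
  rank_order <- order(-as.integer(sizes), as.integer(names(sizes)))
  group_names <- stats::setNames(paste0("G", seq_along(rank_order)),
                                 names(sizes)[rank_order])
  stats::setNames(unname(group_names[as.character(roots)]), labels)
}

#' Filter alleles seen in too few samples
#'
#' Amplicon-error control: an allele is retained only when it occurs in at
#' least `min_samples` distinct samples. Dropped alleles are reported with
#' their carrier(s). Idempotent.
#'
#' @param calls allele-call `data.frame` (`sample_id`, `locus_id`,
#'   `allele_label`).
#' @param min_samples minimum number of distinct carrier samples (default 2).
#' @return the retained calls; attribute `"dropped"` is a `data.frame` of
#'   removed alleles (`locus_id`, `allele_label`, `carriers`).
#' @export
filter_rare_alleles <- function(calls, min_samples = 2L) {
  if (nrow(calls) == 0L) {
    attr(calls, "dropped") <- data.frame(locus_id = character(),
                                         allele_label = character(),
                                         carriers = character())
    return(calls)
  }
  key <- paste(calls$locus_id, calls$allele_label, sep = "\r")
  n_samples <- tapply(calls$sample_id, key, function(s) length(unique(s)))
  keep_key <- names(n_samples)[n_samples >= min_samples]
  keep <- key %in% keep_key
  dropped_keys <- unique(key[!keep])
  dropped <- data.frame(
    locus_id = sub("\r.*$", "", dropped_keys),
    allele_label = sub("^.*\r", "", dropped_keys),
    carriers = vapply(dropped_keys, function(k)
      paste(unique(calls$sample_id[key == k]), collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  rownames(dropped) <- NULL
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
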