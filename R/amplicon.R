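# Ploidy-aware amplicon allele calling: demultiplex -> trim -> cluster ->
# retain. A simplified, deterministic stand-in for a merge+denoise+chimera
# toolchain; reads are assumed already merged (see merge_read_pairs for a
# trivial exact-overlap merger).

#' Demultiplex barcoded reads
#'
#' Assigns each read to the sample whose 8-base barcode matches the read's
#' first 8 bases within `max_mismatch` substitutions (default 0: exact).
#' Assigned reads have the barcode stripped; reads matching no barcode (or,
#' with `max_mismatch > 0`, more than one equally well) land in the
#' unassigned bin. Partition property: every input read appears exactly once
#' in the output.
#'
#' @param reads character vector of read sequences (optionally named).
#' @param barcode_map named character vector, sample id -> 8-base barcode.
#' @param max_mismatch allowed barcode mismatches (default 0).
#' @return list with `assigned` (named list of character vectors, one per
#'   sample) and `unassigned` (character vector).
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 0L) {
  if (anyDuplicated(barcode_map)) stop("duplicate barcodes in barcode map")
  if (any(nchar(barcode_map) != 8L)) stop("all barcodes must be 8 bases")
  prefixes <- substr(reads, 1L, 8L)
  assigned <- stats::setNames(vector("list", length(barcode_map)),
                              names(barcode_map))
  for (s in names(barcode_map)) assigned[[s]] <- character(0L)
  unassigned <- character(0L)
  if (max_mismatch == 0L) {
    hit <- match(prefixes, barcode_map)
    for (i in seq_along(reads)) {
      if (is.na(hit[i]) || nchar(reads[i]) < 8L) {
        unassigned <- c(unassigned, reads[i])
      } else {
        s <- names(barcode_map)[hit[i]]
        assigned[[s]] <- c(assigned[[s]], substring(reads[i], 9L))
      }
    }
  } else {
    bc_chars <- strsplit(barcode_map, "", fixed = TRUE)
    for (i in seq_along(reads)) {
      if (nchar(reads[i]) < 8L) { unassigned <- c(unassigned, reads[i]); next }
      pc <- strsplit(prefixes[i], "", fixed = TRUE)[[1L]]
      d <- vapply(bc_chars, function(b) sum(b != pc), integer(1L))
      best <- which(d <= max_mismatch & d == min(d))
      if (length(best) == 1L) {
        s <- names(barcode_map)[best]
        assigned[[s]] <- c(assigned[[s]], substring(reads[i], 9L))
      } else {
        unassigned <- c(unassigned, reads[i])
      }
    }
  }
  list(assigned = assigned, unassigned = unassigned)
}

#' Trim amplification primers from merged reads
#'
#' Reads are expected to start with the forward primer and end with the
#' reverse complement of the reverse primer. Reads matching both ends within
#' `max_mismatches` substitutions are trimmed to the insert; all others are
#' dropped and counted (reads shorter than the two primers are dropped too).
#'
#' @param reads character vector.
#' @param forward_primer,reverse_primer primer sequences (reverse primer as
#'   synthesised, i.e. the function compares against its reverse complement).
#' @param max_mismatches allowed mismatches per primer (default 0).
#' @return character vector of trimmed inserts; attribute `"dropped"` holds
#'   the number of discarded reads.
#' @export
trim_primers <- function(reads, forward_primer, reverse_primer,
                         max_mismatches = 0L) {
  stopifnot(nchar(forward_primer) > 0L, nchar(reverse_primer) > 0L)
  fp <- toupper(forward_primer)
  rp <- revcomp(toupper(reverse_primer))
  nf <- nchar(fp); nr <- nchar(rp)
  fp_chars <- strsplit(fp, "", fixed = TRUE)[[1L]]
  rp_chars <- strsplit(rp, "", fixed = TRUE)[[1L]]
  out <- character(0L)
  dropped <- 0L
  for (r in reads) {
    n <- nchar(r)
    if (n < nf + nr) { dropped <- dropped + 1L; next }
    head_ok <- sum(strsplit(substr(r, 1L, nf), "", fixed = TRUE)[[1L]] !=
                     fp_chars) <= max_mismatches
    tail_ok <- sum(strsplit(substr(r, n - nr + 1L, n), "", fixed = TRUE)[[1L]] !=
                     rp_chars) <= max_mismatches
    if (head_ok && tail_ok) {
      out <- c(out, substr(r, nf + 1L, n - nr))
    } else {
      dropped <- dropped + 1L
    }
  }
  attr(out, "dropped") <- dropped
  out
}

# single-linkage union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster equal-length reads by pairwise identity
#'
#' Single-linkage clustering under pairwise identity >= `identity_threshold`,
#' computed position-wise on equal-length sequences (reads are first binned
#' by length; bins never merge — indel-tolerant alignment is deliberately not
#' implemented). The cluster consensus is the per-column majority base over
#' member reads, ties broken to the lexicographically smallest base. Clusters
#' are sorted by read count (descending), then consensus (ascending), making
#' downstream top-k retention deterministic.
#'
#' @param reads character vector of reads from one sample and locus.
#' @param identity_threshold in (0.5, 1].
#' @return a `data.frame` with columns `consensus`, `read_count` and a list
#'   column `members` (indices into `reads`).
#' @export
cluster_reads <- function(reads, identity_threshold = 0.99) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  empty <- data.frame(consensus = character(), read_count = integer(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (length(reads) == 0L) return(empty)
  out <- list()
  for (len in sort(unique(nchar(reads)))) {
    idx <- which(nchar(reads) == len)
    uni <- unique(reads[idx])
    counts <- as.integer(table(factor(reads[idx], levels = uni)))
    nu <- length(uni)
    parent <- seq_len(nu)
    if (nu > 1L) {
      mat <- matrix(unlist(strsplit(uni, "", fixed = TRUE), use.names = FALSE),
                    nrow = nu, byrow = TRUE)
      max_d <- floor((1 - identity_threshold) * len)
      for (i in seq_len(nu - 1L)) {
        for (j in seq.int(i + 1L, nu)) {
          if (sum(mat[i, ] != mat[j, ]) <= max_d) {
            ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    } else {
      mat <- matrix(strsplit(uni, "", fixed = TRUE)[[1L]], nrow = 1L)
    }
    roots <- vapply(seq_len(nu), function(i) .uf_find(parent, i), integer(1L))
    for (r in unique(roots)) {
      mem_u <- which(roots == r)
      cons <- vapply(seq_len(len), function(p) {
        tab <- tapply(counts[mem_u], mat[mem_u, p], sum)
        names(tab)[order(-tab, names(tab))][1L]
      }, character(1L))
      members <- idx[reads[idx] %in% uni[mem_u]]
      row <- data.frame(consensus = paste(cons, collapse = ""),
                        read_count = sum(counts[mem_u]),
                        stringsAsFactors = FALSE)
      row$members <- list(members)
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$read_count, out$consensus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain read clusters under the ploidy-aware rules
#'
#' Keeps the clusters with the three highest read counts for diploid samples,
#' or the four highest for triploid or ploidy-unknown samples, then removes
#' any retained cluster supported by fewer than `min_reads` reads. Input
#' order (as produced by [cluster_reads()]) is preserved; ties in read count
#' at the top-k boundary resolve to the lexicographically smaller consensus,
#' which is exactly the input sort order.
#'
#' @param clusters a cluster `data.frame` from [cluster_reads()].
#' @param ploidy 2, 3 or `NA` (unknown).
#' @param min_reads minimum reads per retained cluster (default 100).
#' @return the retained subset of `clusters`.
#' @export
retain_clusters <- function(clusters, ploidy, min_reads = 100L) {
  if (nrow(clusters) == 0L) return(clusters)
  k <- if (!is.na(ploidy) && ploidy == 2L) 3L else 4L
  ord <- order(-clusters$read_count, clusters$consensus)
  clusters <- clusters[ord, , drop = FALSE]
  kept <- clusters[seq_len(min(k, nrow(clusters))), , drop = FALSE]
  kept <- kept[kept$read_count >= min_reads, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Merge exactly-overlapping read pairs
#'
#' A deliberately trivial merger: the 3' end of the forward read must overlap
#' the reverse-complemented reverse read exactly over at least `min_overlap`
#' bases. Pairs without such an overlap return `NA`.
#'
#' @param forward,reverse character vectors of paired reads.
#' @param min_overlap minimum exact overlap length.
#' @return character vector of merged reads (`NA` where merging failed).
#' @export
merge_read_pairs <- function(forward, reverse, min_overlap = 10L) {
  stopifnot(length(forward) == length(reverse))
  vapply(seq_along(forward), function(i) {
    f <- forward[i]; r <- revcomp(reverse[i])
    nf <- nchar(f); nr <- nchar(r)
    for (ov in seq.int(min(nf, nr), min_overlap)) {
      if (substr(f, nf - ov + 1L, nf) == substr(r, 1L, ov)) {
        return(paste0(f, substr(r, ov + 1L, nr)))
      }
    }
    NA_character_
  }, character(1L))
}

#' Flag perfect-mosaic chimera clusters
#'
#' Marks clusters whose consensus is a perfect left/right mosaic of two
#' clusters with strictly larger read counts (a simple stand-in for iterative
#' chimera detection).
#'
#' @param clusters a cluster `data.frame` from [cluster_reads()].
#' @return logical vector, `TRUE` for flagged chimeras.
#' @export
flag_chimeras <- function(clusters) {
  n <- nrow(clusters)
  flag <- logical(n)
  if (n < 3L) return(flag)
  cons <- clusters$consensus
  counts <- clusters$read_count
  for (k in seq_len(n)) {
    len <- nchar(cons[k])
    bigger <- which(counts > counts[k] & nchar(cons) == len)
    if (length(bigger) < 2L) next
    for (a in bigger) for (b in setdiff(bigger, a)) {
      if (flag[k]) break
      for (cut in seq_len(len - 1L)) {
        cand <- paste0(substr(cons[a], 1L, cut), substr(cons[b], cut + 1L, len))
        if (cand == cons[k] && cand != cons[a] && cand != cons[b]) {
          flag[k] <- TRUE
          break
        }
      }
    }
  }
  flag
}

#' Call alleles for one sample and locus from trimmed reads
#'
#' Convenience wrapper: cluster, optionally drop flagged chimeras, apply the
#' ploidy-aware retention rules.
#'
#' @inheritParams cluster_reads
#' @inheritParams retain_clusters
#' @param drop_chimeras drop perfect-mosaic clusters before retention.
#' @return retained cluster `data.frame` (the sample's alleles, ranked).
#' @export
call_alleles <- function(reads, ploidy, identity_threshold = 0.99,
                         min_reads = 100L, drop_chimeras = FALSE) {
  cl <- cluster_reads(reads, identity_threshold)
  if (drop_chimeras && nrow(cl) > 0L) cl <- cl[!flag_chimeras(cl), , drop = FALSE]
  retain_clusters(cl, ploidy, min_reads)
}
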