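# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring global state afterwards so
# no function leaks RNG side effects (reproducibility contract).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_sequence <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

# Substitute `n` random sites of `seq` with a different base; returns the
# mutated sequence. Deterministic under the caller's RNG state.
mutate_sequence <- function(seq, n) {
  if (n <= 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sites <- sample.int(length(chars), min(n, length(chars)))
  for (s in sites) {
    chars[s] <- sample(setdiff(DNA_BASES, chars[s]), 1L)
  }
  paste(chars, collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""), character(1L)))
}

hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# Allele labels sort by letter prefix, then numeric suffix as an integer
# (A1 < A6 < A13), matching the published genotype-string convention.
allele_order <- function(labels) {
  prefix <- sub("[0-9]+$", "", labels)
  num <- suppressWarnings(as.integer(sub("^[^0-9]*", "", labels)))
  num[is.na(num)] <- 0L
  order(prefix, num, labels)
}

sort_alleles <- function(labels) labels[allele_order(labels)]

# Leading capital-letter prefix of an allele label is its lineage group
# ("F7" -> "F"); chloroplast haplotype labels map to themselves.
allele_group <- function(labels) {
  grp <- sub("^([A-Z]+).*$", "\\1", labels)
  ifelse(grepl("^[A-Z]", labels), grp, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_set <- function(x) {
  if (length(x) == 0L) "" else paste(x, collapse = ",")
}
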