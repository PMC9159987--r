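# Brute-force oracles and small generators, independent of the package's
# union-find/consensus code paths.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

# all-pairs exact-equality partition: integer labels in order of first
# appearance
brute_equality_partition <- function(seqs) {
  match(seqs, unique(seqs))
}

# all-pairs single-linkage partition at identity >= threshold, via boolean
# adjacency + breadth-first search (no union-find)
brute_single_linkage <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 0L) return(integer(0L))
  mism <- function(a, b) {
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    if (length(ca) != length(cb)) return(Inf)
    sum(ca != cb)
  }
  len <- nchar(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { adj[i, j] <- TRUE; next }
      if (len[i] != len[j]) next
      adj[i, j] <- (1 - mism(seqs[i], seqs[j]) / len[i]) >= threshold
    }
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonicalize a partition so two labelings compare equal iff they induce the
# same grouping
partition_canonical <- function(labels) {
  match(labels, unique(labels))
}

# cluster membership of each read under the package's cluster_reads()
membership_from_clusters <- function(clusters, n_reads) {
  out <- rep(NA_integer_, n_reads)
  for (k in seq_len(nrow(clusters))) out[clusters$members[[k]]] <- k
  out
}

fixture_cached <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- reticulator::load_fixture()
    fx
  }
})

fit_cached <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fx <- fixture_cached()
      fit <<- reticulator::infer_reticulation(fx$genotypes, fx$samples)
    }
    fit
  }
})
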