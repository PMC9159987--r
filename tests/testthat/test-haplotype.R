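test_that("collapse_haplotypes partitions by exact identity with stable labels", {
  ht <- collapse_haplotypes(c(a = "ACGT", b = "ACGT", c = "ACCT"))
  expect_equal(length(ht$haplotypes), 2L)
  expect_equal(unname(ht$assignment), c("h1", "h1", "h2"))
  expect_equal(unname(ht$members), c(2L, 1L))

  single <- collapse_haplotypes(c(x = "AAAA"))
  expect_equal(length(single$haplotypes), 1L)

  expect_error(collapse_haplotypes(c("ACGT", "ACG")), "equal length")

  # label stability: rerun on identical input gives identical labels
  set.seed(5)
  seqs <- random_dna(30L, 25L)[sample.int(30L, 50L, replace = TRUE)]
  names(seqs) <- paste0("s", seq_along(seqs))
  expect_identical(collapse_haplotypes(seqs), collapse_haplotypes(seqs))
})

test_that("gap handling: excluded columns vs gaps-as-missing", {
  seqs <- c(a = "AC-T", b = "ACGT", c = "ACGA")
  # excluding the gapped column: a and b identical at retained sites,
  # c differs at the last site
  ht <- collapse_haplotypes(seqs, gap_policy = "sites_with_gaps_excluded")
  expect_equal(unname(ht$assignment), c("h1", "h1", "h2"))
  # gaps as missing: the gap matches anything, same partition here
  ht2 <- collapse_haplotypes(seqs, gap_policy = "gaps_as_missing")
  expect_equal(unname(ht2$assignment), c("h1", "h1", "h2"))
})

test_that("assign_groups: provided map passes through, errors on gaps", {
  fx <- fixture_cached()
  nuclear <- fx$calls[fx$calls$locus_id != "cpDNA", ]
  map <- stats::setNames(nuclear$group_label, nuclear$allele_label)
  got <- assign_groups(c("F7", "T1"), method = "provided_map",
                       provided_map = map)
  expect_equal(unname(got), c("F", "T"))
  expect_error(assign_groups(c("F7", "E2"), method = "provided_map",
                             provided_map = map["F7"]), "E2")
})

test_that("assign_groups distance clustering recovers two divergent sets", {
  set.seed(9)
  anc <- random_dna(1L, 300L)
  other <- reticulator:::mutate_sequence(anc, 30L)  # ~10% divergent
  grp1 <- vapply(1:3, function(i) reticulator:::mutate_sequence(anc, 2L),
                 character(1L))
  grp2 <- vapply(1:3, function(i) reticulator:::mutate_sequence(other, 2L),
                 character(1L))
  seqs <- stats::setNames(c(grp1, grp2), paste0("al", 1:6))
  got <- assign_groups(seqs, method = "distance_cluster", threshold = 0.05)
  expect_equal(length(unique(got)), 2L)
  expect_equal(length(unique(got[1:3])), 1L)
  expect_equal(length(unique(got[4:6])), 1L)
  # independent oracle: connected components of the <=5% p-distance graph
  # computed by ape
  skip_if_not_installed("ape")
  bin <- ape::as.DNAbin(strsplit(toupper(seqs), ""))
  d <- as.matrix(ape::dist.dna(bin, model = "raw"))
  adj <- d <= 0.05
  comp <- rep(NA_integer_, 6L); k <- 0L
  for (i in 1:6) {
    if (!is.na(comp[i])) next
    k <- k + 1L; q <- i
    while (length(q) > 0L) {
      v <- q[[1L]]; q <- q[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      q <- c(q, which(adj[v, ] & is.na(comp)))
    }
  }
  expect_equal(partition_canonical(comp),
               partition_canonical(match(got, unique(got))))
})

test_that("filter_rare_alleles keeps >=2-sample alleles and is idempotent", {
  calls <- data.frame(
    sample_id = c("s1", "s2", "s3", "s1"),
    locus_id = "Knox3",
    allele_label = c("A1", "A1", "B9", "C2"),
    stringsAsFactors = FALSE)
  out <- filter_rare_alleles(calls)
  expect_setequal(out$allele_label, "A1")     # singleton B9, C2 dropped
  drop <- attr(out, "dropped")
  expect_setequal(drop$allele_label, c("B9", "C2"))
  expect_equal(drop$carriers[drop$allele_label == "B9"], "s3")
  # idempotence
  again <- filter_rare_alleles(out)
  expect_equal(again$allele_label, out$allele_label)
  # empty input
  expect_equal(nrow(filter_rare_alleles(calls[0L, ])), 0L)
})

test_that("collapse_haplotypes matches the brute-force equality partition", {
  for (seed in 1:10) {
    set.seed(seed)
    pool <- random_dna(8L, 30L)
    seqs <- pool[sample.int(8L, 50L, replace = TRUE)]
    names(seqs) <- paste0("s", seq_along(seqs))
    ht <- collapse_haplotypes(seqs)
    got <- match(ht$assignment, unique(ht$assignment))
    expect_equal(partition_canonical(got),
                 partition_canonical(brute_equality_partition(seqs)))
  }
})
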