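test_that("demultiplex assigns by exact barcode and partitions the input", {
  reads <- c(paste0("AAAAAAAA", "ACGTACGT"),
             paste0("CCCCCCCC", "TTTTGGGG"),
             paste0("GGGGGGGG", "ACACACAC"))
  bm <- c(s1 = "AAAAAAAA", s2 = "CCCCCCCC")
  dm <- demultiplex(reads, bm)
  expect_equal(dm$assigned$s1, "ACGTACGT")
  expect_equal(dm$assigned$s2, "TTTTGGGG")
  expect_equal(dm$unassigned, reads[3L])
  # partition: assigned + unassigned == input
  expect_equal(length(unlist(dm$assigned)) + length(dm$unassigned),
               length(reads))
  expect_error(demultiplex(reads, c(s1 = "AAAAAAAA", s2 = "AAAAAAAA")),
               "duplicate")
})

test_that("simulated zero-noise reads demultiplex with 100% assignment", {
  panel <- simulate_parental_panel(3L, seed = 8L)
  nuc <- panel$alleles[panel$alleles$locus_id != "cpDNA", ]
  nuc$sample_id <- paste0(nuc$taxon, "_s1")
  bcs <- generate_barcodes(unique(nuc$sample_id), seed = 4L)
  reads <- simulate_reads(nuc, depth = 60, error_rate = 0,
                          barcode_map = bcs, seed = 21L)
  dm <- demultiplex(reads$sequence, bcs)
  expect_length(dm$unassigned, 0L)
  expect_equal(length(unlist(dm$assigned)), nrow(reads))
  # each read landed with its true sample (barcodes are truth-linked)
  for (s in names(bcs)) {
    expect_equal(length(dm$assigned[[s]]), sum(reads$sample_id == s))
  }
})

test_that("trim_primers trims matching ends and drops the rest", {
  fp <- "ACGTAC"; rp <- "GGTTCC"  # reverse primer as synthesised
  insert <- "TTTTTTTTTT"
  read <- paste0(fp, insert, reticulator:::revcomp(rp))
  expect_equal(as.character(trim_primers(read, fp, rp)), insert)

  no_primer <- paste0("GTGTGT", insert, "ACACAC")
  out <- trim_primers(no_primer, fp, rp, max_mismatches = 0L)
  expect_length(out, 0L)
  expect_equal(attr(out, "dropped"), 1L)

  one_mm <- paste0("TCGTAC", insert, reticulator:::revcomp(rp))
  expect_length(trim_primers(one_mm, fp, rp, max_mismatches = 0L), 0L)
  expect_equal(as.character(trim_primers(one_mm, fp, rp, max_mismatches = 1L)),
               insert)

  short <- "ACG"  # shorter than the primers: dropped, counted
  out <- trim_primers(short, fp, rp)
  expect_length(out, 0L)
  expect_equal(attr(out, "dropped"), 1L)
})

test_that("cluster_reads separates alleles and matches the brute-force oracle", {
  set.seed(101)
  x <- random_dna(1L, 493L)
  y <- reticulator:::mutate_sequence(x, 5L)  # 5 substitutions apart
  reads <- c(rep(x, 200L), rep(y, 150L))
  cl <- cluster_reads(reads, identity_threshold = 0.99)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$read_count, c(200L, 150L))
  expect_setequal(cl$consensus, c(x, y))
  # brute-force all-pairs single-linkage partition agrees
  oracle <- brute_single_linkage(unique(reads), 0.99)
  expect_equal(length(unique(oracle)), 2L)

  # all-identical reads: one cluster, consensus equals the read
  one <- cluster_reads(rep("ACGTACGT", 7L), 0.95)
  expect_equal(nrow(one), 1L)
  expect_equal(one$consensus, "ACGTACGT")
  expect_equal(one$read_count, 7L)

  # empty input: empty cluster set
  expect_equal(nrow(cluster_reads(character(0L))), 0L)
})

test_that("error-free simulated reads recover the true alleles exactly", {
  panel <- simulate_parental_panel(2L, seed = 12L, alleles_per_taxon = 2L)
  nuc <- panel$alleles[panel$alleles$locus_id == "Knox3" &
                         panel$alleles$taxon == "parent_A", ]
  nuc$sample_id <- "sA"
  bcs <- c(sA = "ACACACAC")
  reads <- simulate_reads(nuc, depth = 150, error_rate = 0,
                          barcode_map = bcs, seed = 31L)
  pr <- reticulator:::default_primers()$Knox3
  trimmed <- trim_primers(substring(reads$sequence, 9L), pr[["forward"]],
                          pr[["reverse"]])
  cl <- cluster_reads(trimmed, 0.99)
  expect_equal(nrow(cl), 2L)  # one cluster per true allele
  expect_setequal(cl$consensus, nuc$sequence)
})

test_that("retain_clusters applies the published top-k and min-read rules", {
  mk <- function(counts) {
    df <- data.frame(consensus = random_dna(length(counts), 20L),
                     read_count = as.integer(counts),
                     stringsAsFactors = FALSE)
    df$members <- lapply(seq_along(counts), function(i) i)
    df[order(-df$read_count, df$consensus), ]
  }
  set.seed(77)
  # diploid: keep the three highest
  expect_equal(retain_clusters(mk(c(800, 400, 120, 110)), 2L)$read_count,
               c(800L, 400L, 120L))
  # clusters under 100 reads are removed after top-k
  expect_equal(retain_clusters(mk(c(500, 300, 90)), 2L)$read_count,
               c(500L, 300L))
  # unknown ploidy: top four
  expect_equal(retain_clusters(mk(c(150, 140, 130, 120, 110)), NA)$read_count,
               c(150L, 140L, 130L, 120L))
  # triploid: top four
  expect_equal(retain_clusters(mk(c(900, 500, 400, 200, 150)), 3L)$read_count,
               c(900L, 500L, 400L, 200L))
  expect_equal(nrow(retain_clusters(mk(integer(0L))[0L, ], 2L)), 0L)
})

test_that("retention and clustering are monotone in their thresholds", {
  set.seed(202)
  base <- random_dna(4L, 80L)
  reads <- unlist(lapply(seq_along(base), function(i)
    rep(base[i], c(300, 220, 130, 60)[i])))
  cl <- cluster_reads(reads, 0.9)
  # raising min_reads never increases the number of retained clusters
  kept <- vapply(c(0L, 50L, 100L, 150L, 500L), function(m)
    nrow(retain_clusters(cl, 3L, min_reads = m)), integer(1L))
  expect_true(all(diff(kept) <= 0L))
  # raising the identity threshold never decreases the cluster count
  noisy <- vapply(reads, function(r) reticulator:::mutate_sequence(r, 2L),
                  character(1L), USE.NAMES = FALSE)
  ncl <- vapply(c(0.80, 0.90, 0.95, 0.975, 1.0), function(th)
    nrow(cluster_reads(noisy, th)), integer(1L))
  expect_true(all(diff(ncl) >= 0L))
})

test_that("chimera flagging spots perfect left/right mosaics", {
  a <- strrep("A", 40L); b <- strrep("C", 40L)
  chi <- paste0(substr(a, 1L, 20L), substr(b, 21L, 40L))
  cl <- data.frame(consensus = c(a, b, chi),
                   read_count = c(500L, 400L, 120L), stringsAsFactors = FALSE)
  cl$members <- list(1L, 2L, 3L)
  expect_equal(flag_chimeras(cl), c(FALSE, FALSE, TRUE))
})
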