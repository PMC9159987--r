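test_that("parental panel simulation: minimal panel, distinctness, determinism", {
  p2 <- simulate_parental_panel(2L, seed = 1L)
  expect_equal(length(p2$taxa), 2L)
  expect_equal(length(unique(p2$cp)), 2L)
  expect_equal(length(unique(p2$group_map)), 2L)

  p7 <- simulate_parental_panel(7L, seed = 42L)
  nuc <- p7$alleles[p7$alleles$locus_id != "cpDNA", ]
  # exhaustive pairwise comparison: all nuclear allele sequences distinct
  expect_false(anyDuplicated(nuc$sequence) > 0L)

  expect_identical(simulate_parental_panel(7L, seed = 42L), p7)

  expect_error(simulate_parental_panel(1L), "at least two")
  expect_error(locus_config("x", "biparental", 0L), "> 0")
  expect_error(locus_config("x", "biparental", 10L, mutation_rate = 1.5),
               "mutation_rate")
})

test_that("hybridization conserves maternal cpDNA, alleles and ploidy", {
  panel <- simulate_parental_panel(4L, seed = 3L)
  events <- list(
    hybrid_event("parent_A", "parent_B"),
    hybrid_event("parent_B", "parent_C", maternal_gamete = "unreduced"),
    hybrid_event("parent_C", "parent_D", paternal_gamete = "unreduced",
                 child_mode = "sexual"),
    hybrid_event("parent_D", "parent_A"))
  sim <- simulate_hybridization(panel, events, seed = 9L)

  for (i in seq_len(nrow(sim$truth$events))) {
    ev <- sim$truth$events[i, ]
    child_cp <- sim$alleles[sim$alleles$sample_id == ev$sample_id &
                              sim$alleles$locus_id == "cpDNA", ]
    # cpDNA conservation: child haplotype equals the maternal parent's
    expect_equal(child_cp$allele_label, panel$cp[[ev$maternal_taxon]])
    # ploidy bookkeeping: contributed chromosome sets, always 2 or 3
    nuc <- sim$alleles[sim$alleles$sample_id == ev$sample_id &
                         sim$alleles$locus_id == "Knox3", ]
    expect_equal(sum(nuc$dose), ev$child_ploidy)
    expect_true(ev$child_ploidy %in% c(2L, 3L))
    # allele conservation: child multiset equals the gametes' contribution
    origin <- sim$truth$allele_origin
    contributed <- origin[origin$sample_id == ev$sample_id &
                            origin$locus_id == "Knox3", ]
    expect_setequal(nuc$allele_label, contributed$allele_label)
    expect_setequal(contributed$source_taxon,
                    c(ev$maternal_taxon, ev$paternal_taxon))
  }
  # spore counts are deterministic from the child mode
  expect_equal(sim$samples$spore_count,
               ifelse(sim$samples$mode == "sexual", 64L, 32L))

  # selfing of a homozygous parent reproduces the parental genotype
  selfed <- simulate_hybridization(panel, list(hybrid_event("parent_A",
                                                            "parent_A")),
                                   seed = 1L)
  own <- panel$alleles[panel$alleles$taxon == "parent_A" &
                         panel$alleles$locus_id == "Knox3", ]
  child <- selfed$alleles[selfed$alleles$locus_id == "Knox3", ]
  expect_equal(unique(child$allele_label), own$allele_label)
  expect_equal(child$dose, 2L)

  expect_error(simulate_hybridization(panel,
                                      list(hybrid_event("nobody", "parent_A")),
                                      seed = 1L), "unknown taxon")
  expect_error(hybrid_event("a", "b", maternal_gamete = "unreduced",
                            paternal_gamete = "unreduced"), "ploidy")
})

test_that("read simulation: zero-noise limit, determinism, error calibration", {
  panel <- simulate_parental_panel(2L, seed = 5L)
  nuc <- panel$alleles[panel$alleles$locus_id == "Knox3", ]
  nuc$sample_id <- nuc$taxon
  bcs <- generate_barcodes(unique(nuc$sample_id), seed = 2L)
  expect_true(all(nchar(bcs) == 8L))

  reads0 <- simulate_reads(nuc, depth = 200, error_rate = 0,
                           barcode_map = bcs, seed = 11L)
  # zero-noise: every read equals barcode + primers + source allele
  pr <- reticulator:::default_primers()$Knox3
  for (t in unique(nuc$sample_id)) {
    rs <- reads0$sequence[reads0$sample_id == t]
    src <- nuc$sequence[nuc$sample_id == t]
    expect_true(all(rs == paste0(bcs[[t]], pr[["forward"]], src,
                                 reticulator:::revcomp(pr[["reverse"]]))))
  }
  # determinism: rerun reproduces the read set exactly
  expect_identical(simulate_reads(nuc, depth = 200, error_rate = 0,
                                  barcode_map = bcs, seed = 11L), reads0)

  # per-read mismatch count has mean ~ length * error_rate (binomial),
  # within 3 standard errors over >= 1000 reads
  err <- 0.005
  reads_e <- simulate_reads(nuc, depth = 600, error_rate = err,
                            barcode_map = bcs, seed = 13L)
  expect_gte(nrow(reads_e), 1000L)
  template_of <- stats::setNames(
    paste0(bcs[nuc$sample_id], pr[["forward"]], nuc$sequence,
           reticulator:::revcomp(pr[["reverse"]])),
    paste(nuc$sample_id, nuc$allele_label))
  key <- paste(reads_e$sample_id, sub("^[^|]+\\|[^|]+\\|([^|]+)\\|.*$", "\\1",
                                      reads_e$read_id))
  mism <- vapply(seq_len(nrow(reads_e)), function(i)
    reticulator:::hamming(reads_e$sequence[i], template_of[[key[i]]]),
    numeric(1L))
  L <- nchar(template_of[[1L]])
  se <- sqrt(L * err * (1 - err) / length(mism))
  expect_lt(abs(mean(mism) - L * err), 3 * se)

  dup_bc <- bcs; dup_bc[2L] <- dup_bc[1L]
  expect_error(simulate_reads(nuc, depth = 10, barcode_map = dup_bc,
                              seed = 1L), "duplicate")
})
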