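test_that("parental classification follows the homozygosity and sexual-diploid rules", {
  fit <- fit_cached()
  st <- stats::setNames(fit$statuses$status, fit$statuses$sample_id)
  # homozygous apogamous diploid (G1G1) is parental
  expect_equal(unname(st["Chao2734"]), "parental")
  # sexual diploid with both alleles in group A (A1A6) is parental
  expect_equal(unname(st["Chao2500"]), "parental")
  # apogamous diploid with alleles from two groups (A4D7) is a hybrid
  expect_equal(unname(st["Chao2155"]), "hybrid")
  # apogamous heterozygote within one group is not parental
  expect_equal(unname(st["Chao2482"]), "hybrid")   # F4F5
  # nuclear data missing entirely: not demonstrably parental
  expect_equal(unname(st["Lu32448"]), "hybrid")
  # primary locus missing, fallback homozygous (S25S25)
  expect_equal(unname(st["Kao 03,037"]), "parental")
})

test_that("classification partitions the genotype entries", {
  fit <- fit_cached()
  f <- fit$formulas
  expect_equal(sum(f$status == "parental") +
                 sum(f$status == "hybrid") +
                 sum(f$status == "unresolved"), nrow(f))
})

test_that("co-occurrence matrix reflects the published haplotype-group links", {
  fit <- fit_cached()
  cm <- fit$cooccurrence
  expect_gt(cm$counts["cf", "A"], 0L)
  expect_gt(cm$counts["cb", "A"], 0L)
  expect_gt(cm$counts["ca", "D"], 0L)  # via D7 carriers
  expect_equal(sum(cm$parental_counts > cm$counts), 0L)

  # single-sample matrix has exactly one nonzero cell
  samples <- data.frame(sample_id = "s1", taxon_name = "t1",
                        ploidy = 2L, mode = "apogamous",
                        stringsAsFactors = FALSE)
  g <- data.frame(sample_id = "s1", locus_id = c("Knox3", "cpDNA"),
                  canonical = c("A7A7", "cb"),
                  unassorted = FALSE, ploidy = 2L, stringsAsFactors = FALSE)
  g$alleles <- list(c("A7", "A7"), "cb")
  stat <- data.frame(sample_id = "s1", status = "parental",
                     basis_locus = "Knox3", note = "", stringsAsFactors = FALSE)
  cm1 <- build_cooccurrence(g, samples, stat)
  expect_equal(sum(cm1$counts > 0L), 1L)
  expect_equal(cm1$counts["cb", "A"], 1L)
})

test_that("maternal-lineage cascade reproduces the published calls", {
  fit <- fit_cached()
  expect_equal(fit$maternal[["cf"]]$groups, "A")
  expect_equal(fit$maternal[["cf'"]]$groups, "A")
  expect_equal(fit$maternal[["cb"]]$groups, "A")
  expect_equal(fit$maternal[["ca"]]$groups, "D")
  expect_false(fit$maternal[["ca"]]$ambiguous)
  # universal co-occurrence step (no parental carrier of ck): ck -> H
  expect_equal(fit$maternal[["ck"]]$groups, "H")
  expect_equal(fit$maternal[["ck"]]$basis, "universal")
  # cascade fall-through: haplotype carried only by multi-group hybrids with
  # no universal group -> flagged ambiguity set
  expect_true(fit$maternal[["cs"]]$ambiguous)
  expect_setequal(fit$maternal[["cs"]]$groups, c("B", "C", "D", "H"))
  expect_error(infer_maternal_group("nonesuch", fit$cooccurrence),
               "not present")
})

test_that("hybrid formulas name the published parent pairs", {
  fit <- fit_cached()
  f <- fit$formulas
  # A1A6D7 / cf: maternal P. minor (A1 or A6), paternal P. latipinna
  r <- f[f$sample_id == "Chao2082", ]
  expect_equal(r$maternal, "P. minor")
  expect_equal(r$paternal, "P. latipinna")
  expect_equal(r$maternal_alleles, "A1,A6")
  # F16G1 / cxx: P. arisanensis (maternal) x P. biaurita (paternal)
  r <- f[f$sample_id == "Chao2478", ]
  expect_equal(r$maternal, "P. arisanensis")
  expect_equal(r$paternal, "P. biaurita")
  # F7G1 / ci: the reciprocal cross, P. biaurita maternal
  r <- f[f$sample_id == "Chao1317", ]
  expect_equal(r$maternal, "P. biaurita")
  expect_true(grepl("P. arisanensis", r$paternal))
  # D4D7 / cy: P. wulaiensis maternal, P. latipinna paternal
  r <- f[f$sample_id == "Chao2035", ]
  expect_equal(r$maternal, "P. wulaiensis")
  expect_equal(r$paternal, "P. latipinna")
  # lineages with no sampled parental taxon fall back to unknown/candidates
  r <- f[f$sample_id == "Chao1818", ]  # A1A7D5 / cb
  expect_equal(r$maternal, "P. boninensis")
  expect_true(grepl("P. minor", r$paternal))
  # maternal consistency: the maternal alleles belong to the genotype
  hyb <- f[f$status == "hybrid" & f$maternal_alleles != "", ]
  for (i in seq_len(nrow(hyb))) {
    al <- parse_genotype_string(hyb$genotype[i])$alleles
    m <- strsplit(hyb$maternal_alleles[i], ",")[[1L]]
    expect_true(all(m %in% al))
  }
})

test_that("assign_parentage flags genotypes missing their maternal group", {
  fit <- fit_cached()
  # a genotype with no allele from the maternal group of its haplotype
  got <- assign_parentage(c("G1", "G4"), "cf", fit)  # cf -> A, no A allele
  expect_equal(got$status, "unresolved")
  expect_true(any(grepl("not represented", got$notes)))
})

test_that("reticulogram structure: node/edge invariants and dominance", {
  fit <- fit_cached()
  net <- fit$network
  # parental nodes have no in-edges
  parental_nodes <- net$nodes$node[net$nodes$status == "parental" &
                                     !net$nodes$placeholder]
  expect_false(any(net$edges$to %in% parental_nodes))
  # every edge endpoint exists
  expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes$node))
  # hybrid nodes have both in-edge types or carry the incomplete flag
  for (nd in net$nodes$node[net$nodes$status != "parental"]) {
    tt <- unique(net$edges$type[net$edges$to == nd])
    ok <- all(c("maternal", "paternal") %in% tt) ||
      net$nodes$incomplete[net$nodes$node == nd]
    expect_true(ok)
  }
  # the D7 lineage has the largest out-degree among parental taxa
  s <- summary(fit)
  expect_equal(s$lineage_counts$taxon[1L], "P. latipinna")

  # trivial network: two parents and one diploid hybrid
  samples <- data.frame(sample_id = c("p1", "p2", "h1"),
                        taxon_name = c("T1", "T2", "H"),
                        ploidy = 2L, mode = "apogamous",
                        stringsAsFactors = FALSE)
  g <- data.frame(
    sample_id = rep(c("p1", "p2", "h1"), each = 2L),
    locus_id = rep(c("Knox3", "cpDNA"), 3L),
    canonical = c("A1A1", "ca", "B1B1", "cb", "A1B1", "ca"),
    unassorted = FALSE, ploidy = 2L, stringsAsFactors = FALSE)
  g$alleles <- list(c("A1", "A1"), "ca", c("B1", "B1"), "cb",
                    c("A1", "B1"), "ca")
  fit2 <- infer_reticulation(g, samples)
  expect_equal(nrow(fit2$network$nodes), 3L)
  expect_equal(sort(fit2$network$edges$type), c("maternal", "paternal"))
})

test_that("lineage dominance is data-driven, not hard-coded", {
  fx <- fixture_cached()
  # remove all D7-carrying hybrid entries; the top parental lineage changes
  kx <- fx$genotypes[fx$genotypes$locus_id == "Knox3", ]
  d7_carriers <- kx$sample_id[vapply(kx$alleles, function(a) "D7" %in% a,
                                     logical(1L))]
  fit <- fit_cached()
  st <- stats::setNames(fit$statuses$status, fit$statuses$sample_id)
  drop_ids <- d7_carriers[st[d7_carriers] == "hybrid"]
  keep <- !(fx$samples$sample_id %in% drop_ids)
  fit2 <- infer_reticulation(
    fx$genotypes[!(fx$genotypes$sample_id %in% drop_ids), ],
    fx$samples[keep, ])
  s2 <- summary(fit2)
  expect_false(identical(s2$lineage_counts$taxon[1L], "P. latipinna"))
  # with all D7 hybrids removed, the G1 lineage (P. biaurita) tops the list
  expect_equal(s2$lineage_counts$taxon[1L], "P. biaurita")
  lat <- s2$lineage_counts$n_either[s2$lineage_counts$taxon == "P. latipinna"]
  expect_true(length(lat) == 0L || lat < 18L)
})

test_that("zero-noise simulation: inferred edges equal the simulated events", {
  cfg <- pipeline_config(mode = "simulated", seed = 421L, n_parents = 4L,
                         n_diploid_events = 3L, n_triploid_events = 2L,
                         depth = 220, samples_per_parent = 2L)
  sim <- simulate_reticulate_dataset(cfg)
  called <- process_amplicon_reads(sim$reads$sequence, sim$barcodes,
                                   sim$samples,
                                   identity_threshold = 0.99, min_reads = 100L)
  cp_seqs <- sim$alleles[sim$alleles$locus_id == "cpDNA",
                         c("sample_id", "locus_id", "sequence")]
  cp_seqs$read_count <- NA_integer_
  calls <- label_alleles(rbind(
    called[, c("sample_id", "locus_id", "sequence", "read_count")], cp_seqs))
  gt <- genotype_table(sim$samples, calls)
  fit <- infer_reticulation(gt, sim$samples)
  rec <- evaluate_recovery(fit, sim$truth)
  expect_equal(rec$parent_pair_recovery, 1)
  # the edge set matches the event list: per hybrid, exactly one maternal
  # and one paternal parent taxon, equal to the simulated ones
  f <- fit$formulas
  for (i in seq_len(nrow(sim$truth$events))) {
    ev <- sim$truth$events[i, ]
    row <- f[f$sample_id == ev$sample_id, ]
    expect_equal(row$maternal, ev$maternal_taxon)
    expect_equal(row$paternal, ev$paternal_taxon)
  }
})
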