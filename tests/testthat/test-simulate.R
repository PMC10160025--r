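test_that("config validation rejects malformed inputs", {
  expect_error(synthetic_config(n_genes = 100, gene_length = 2000,
                                chrom_length = 100000), "infeasible")
  bad <- default_sbs_probs(); bad[1] <- bad[1] + 0.01
  expect_error(synthetic_config(sbs_probs = bad), "sum to 1")
  expect_error(synthetic_config(tandem_probs = c("XX>YY" = 1)), "canonical")
  expect_error(synthetic_config(nts_odds = 0), "nts_odds")
})

test_that("reference generation is seed-deterministic and honours GC content", {
  cfg <- synthetic_config(seed = 5, chrom_length = 100000L, n_chroms = 1L,
                          gc_content = 0.5)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(unclass(r1$genome), unclass(r2$genome))
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$origins, r2$origins)

  s <- unclass(r1$genome)[[1]]
  n_gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  # exact binomial test against the configured GC at a 1e-4 level
  expect_gt(stats::binom.test(n_gc, nchar(s), 0.5)$p.value, 1e-4)

  # genes are non-overlapping and origins strictly increasing
  gn <- r1$genes[order(r1$genes$start), ]
  expect_true(all(gn$start[-1] >= gn$end[-nrow(gn)]))
  expect_true(all(diff(r1$origins$pos) > 0))
})

test_that("written reference files round-trip through the readers", {
  dir <- withr::local_tempdir()
  paths <- write_reference(shared_ref, dir)
  g <- read_genome(paths["genome"])
  expect_identical(unclass(g), unclass(shared_ref$genome))
  ori <- read_origins(paths["origins"])
  expect_identical(as.data.frame(ori), as.data.frame(shared_ref$origins))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    genes <- read_genes(paths["genes"])
    expect_equal(genes$start, shared_ref$genes$start)
    expect_equal(genes$end, shared_ref$genes$end)
    expect_identical(genes$strand, shared_ref$genes$strand)
  }
})

test_that("generated mutations are deterministic and match the genome", {
  t1 <- generate_mutations(shared_cfg, shared_ref, shared_index)
  t2 <- generate_mutations(shared_cfg, shared_ref, shared_index)
  expect_identical(t1, t2)
  # every generated ref allele matches the genome: zero rejects on ingest
  rec <- suppressMessages(validate_mutations(t1, shared_ref$genome))
  expect_equal(nrow(attr(rec, "rejected")), 0L)
  expect_equal(nrow(rec), nrow(t1))
})

test_that("a spectrum concentrated on one channel reproduces exactly", {
  probs <- stats::setNames(rep(0, 96), sbs_classes()$label)
  probs["C>T@TCA"] <- 1
  cfg <- synthetic_config(seed = 9, n_isolates = 2,
                          mutations_per_isolate = 50, tandem_fraction = 0,
                          sbs_probs = probs)
  ref <- generate_reference(cfg)
  tab <- generate_mutations(cfg, ref)
  rec <- suppressMessages(validate_mutations(tab, ref$genome))
  sp <- build_spectra(merge_tandems(rec), ref$genome)
  tot <- class_totals(sp$sbs)
  expect_equal(sum(tot), unname(tot["C>T@TCA"]))
  expect_gt(sum(tot), 0)
})

test_that("tandem events exercise merge_tandems and classify canonically", {
  cfg <- synthetic_config(seed = 10, n_isolates = 4,
                          mutations_per_isolate = 100, tandem_fraction = 0.5)
  ref <- generate_reference(cfg)
  tab <- generate_mutations(cfg, ref)
  rec <- suppressMessages(validate_mutations(tab, ref$genome))
  expect_true(all(rec$mclass == "single"))  # emitted as adjacent singles
  mrg <- merge_tandems(rec)
  expect_true(any(mrg$mclass == "tandem"))
  expect_true(all(mrg$mclass != "multi"))  # events are spaced, no run >= 3
  labs <- classify_tandem(mrg[mrg$mclass == "tandem", ])
  expect_true(all(labs %in% names(default_tandem_probs())))
})

test_that("transcriptional bias recovery: odds 2 gives NTS fraction near 2/3", {
  cfg <- synthetic_config(seed = 14, n_chroms = 3L, chrom_length = 100000L,
                          n_genes = 32L, gene_length = 3000L,
                          n_isolates = 1L, mutations_per_isolate = 5500,
                          tandem_fraction = 0, nts_odds = 2)
  ref <- generate_reference(cfg)
  tab <- generate_mutations(cfg, ref)
  rec <- suppressMessages(validate_mutations(tab, ref$genome))
  asn <- assign_strand(merge_tandems(rec), ref$genome, ref$genes)
  n_nts <- sum(asn$strand_call == "NTS")
  n_ts <- sum(asn$strand_call == "TS")
  n <- n_nts + n_ts
  expect_gte(n, 5000)
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(n_nts / n - 2 / 3), 3 * se + 0.01)

  # and the composition-normalized ratio recovers the odds
  ta <- transcriptional_asymmetry(merge_tandems(rec), ref$genome, ref$genes,
                                  min_count = 200)
  tested <- as.data.frame(ta)[ta$tested, ]
  pooled <- sum(tested$n_nts) / sum(tested$e_nts) /
    (sum(tested$n_ts) / sum(tested$e_ts))
  expect_lt(abs(pooled - 2), 0.25)
})

test_that("replicative bias recovery: the generator slope is refit", {
  cfg <- synthetic_config(seed = 15, n_chroms = 2L, chrom_length = 80000L,
                          n_genes = 0L, n_origins = 5L,
                          n_isolates = 1L, mutations_per_isolate = 6000,
                          tandem_fraction = 0, rep_slope = 0.5)
  ref <- generate_reference(cfg)
  tab <- generate_mutations(cfg, ref)
  rec <- suppressMessages(validate_mutations(tab, ref$genome))
  pl <- place_between_origins(rec, ref$origins)
  cp <- cross_profile(pl, c("C>T", "G>A"), n_bins = 10, n_boot = 1000,
                      seed = 6)
  expect_true(cp$ci$slope1[1] <= 0.5 && 0.5 <= cp$ci$slope1[2])

  # null config: slope CI straddles zero
  cfg0 <- synthetic_config(seed = 16, n_chroms = 2L, chrom_length = 80000L,
                           n_genes = 0L, n_origins = 5L,
                           n_isolates = 1L, mutations_per_isolate = 6000,
                           tandem_fraction = 0, rep_slope = 0)
  ref0 <- generate_reference(cfg0)
  tab0 <- generate_mutations(cfg0, ref0)
  rec0 <- suppressMessages(validate_mutations(tab0, ref0$genome))
  pl0 <- place_between_origins(rec0, ref0$origins)
  cp0 <- cross_profile(pl0, c("C>T", "G>A"), n_bins = 10, n_boot = 1000,
                       seed = 6)
  expect_true(cp0$ci$slope1[1] <= 0 && 0 <= cp0$ci$slope1[2])
})
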