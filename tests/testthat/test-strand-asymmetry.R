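test_that("strand assignment follows the NTS definition", {
  g <- toy_genome(c(chrT = paste(rep("ACGTT", 20), collapse = "")))
  genes <- gene_intervals(data.frame(chrom = "chrT", start = 10, end = 40,
                                     strand = "+", name = "gp"))
  # C at a 1-based position inside the + gene: pyrimidine on coding strand
  pos_c <- 12L
  stopifnot(substring(unclass(g)[["chrT"]], pos_c, pos_c) == "C")
  a1 <- assign_strand(make_records("chrT", pos_c, "C", "T"), g, genes)
  expect_identical(a1$strand_call, "NTS")
  # same mutation inside a - strand gene: pyrimidine on template strand
  genes_m <- gene_intervals(transform(as.data.frame(genes), strand = "-"))
  a2 <- assign_strand(make_records("chrT", pos_c, "C", "T"), g, genes_m)
  expect_identical(a2$strand_call, "TS")
  # purine representation of the complementary event flips the call
  pos_g <- 13L
  stopifnot(substring(unclass(g)[["chrT"]], pos_g, pos_g) == "G")
  a3 <- assign_strand(make_records("chrT", pos_g, "G", "A"), g, genes)
  expect_identical(a3$strand_call, "TS")
  # outside any gene
  a4 <- assign_strand(make_records("chrT", 2, "C", "T"), g, genes)
  expect_identical(a4$strand_call, "intergenic")
  # covered by overlapping genes on both strands
  genes2 <- gene_intervals(data.frame(chrom = "chrT", start = c(10, 20),
                                      end = c(40, 50), strand = c("+", "-"),
                                      name = c("gp", "gm")))
  a5 <- assign_strand(make_records("chrT", 25, "C", "T"), g, genes2)
  expect_identical(a5$strand_call, "ambiguous")
})

test_that("per-strand context frequencies match a sliding-window oracle", {
  # single + strand gene with coding sequence TCA
  g <- toy_genome(c(chrT = "GGTCAGG"))
  genes <- gene_intervals(data.frame(chrom = "chrT", start = 2, end = 5,
                                     strand = "+", name = "g1"))
  f <- strand_context_frequencies(g, genes, width = 3)
  expect_equal(unname(f["TCA", "nts"]), 1)
  expect_equal(unname(f["TGA", "ts"]), 1)
  expect_equal(sum(f[, "nts"]), 1)
  # same gene on the - strand swaps the counts
  genes_m <- gene_intervals(transform(as.data.frame(genes), strand = "-"))
  fm <- strand_context_frequencies(g, genes_m, width = 3)
  expect_equal(unname(fm["TGA", "nts"]), 1)
  expect_equal(unname(fm["TCA", "ts"]), 1)

  # random toy genome: totals per 3-mer equal a naive window scan over genes
  ref <- shared_ref
  f2 <- strand_context_frequencies(ref$genome, ref$genes, width = 3)
  naive <- stats::setNames(numeric(64), rownames(f2))
  for (i in seq_len(nrow(ref$genes))) {
    gn <- ref$genes[i, ]
    s <- substring(unclass(ref$genome)[[gn$chrom]], gn$start + 1, gn$end)
    if (gn$strand == "-") s <- oracle_rc(s)
    for (j in 1:(nchar(s) - 2)) {
      k <- substring(s, j, j + 2)
      naive[k] <- naive[k] + 1
    }
  }
  # shared_ref genes are non-overlapping, so masking removes nothing
  expect_equal(f2[, "nts"], naive)
  # NTS count of a 3-mer equals TS count of its reverse complement
  expect_equal(unname(f2[, "nts"]),
               unname(f2[oracle_rc(rownames(f2)), "ts"]))
})

test_that("overlap masking removes shared gene stretches from the denominator", {
  g <- toy_genome(c(chrT = "AAAACCCCGGGGTTTTAAAA"))
  genes <- gene_intervals(data.frame(chrom = "chrT", start = c(0, 8),
                                     end = c(12, 20), strand = c("+", "+"),
                                     name = c("a", "b")))
  f <- strand_context_frequencies(g, genes, width = 3)
  # positions 9-12 (1-based) are covered by both genes and must not count
  expect_equal(sum(f[, "nts"]), (8 - 2) + (8 - 2))
})

test_that("asymmetry test matches hand-computed chi-squared and ratio", {
  r0 <- asymmetry_test(50, 50, 0.5, m = 1)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_raw, 1)
  expect_equal(r0$normalized_ratio, 1)

  r1 <- asymmetry_test(75, 25, 0.5, m = 1)
  expect_equal(r1$chi2, 25)  # (75-50)^2/50 + (25-50)^2/50

  # imbalance fully explained by composition
  r2 <- asymmetry_test(60, 40, 0.6, m = 1)
  expect_equal(r2$chi2, 0, tolerance = 1e-12)
  expect_equal(r2$normalized_ratio, 1)

  # below the count threshold: not tested
  r3 <- asymmetry_test(10, 5, 0.5, m = 1, min_count = 30)
  expect_false(r3$tested)
  expect_true(is.na(r3$chi2))

  # Bonferroni caps at 1
  r4 <- asymmetry_test(55, 45, 0.5, m = 50)
  expect_equal(r4$p_bonf, min(1, r4$p_raw * 50))
})

test_that("swapping every gene strand swaps NTS and TS and inverts ratios", {
  tab <- generate_mutations(shared_cfg, shared_ref, shared_index)
  rec <- suppressMessages(validate_mutations(tab, shared_ref$genome))
  mrg <- merge_tandems(rec)
  genes_f <- shared_ref$genes
  genes_r <- gene_intervals(transform(as.data.frame(genes_f),
                                      strand = ifelse(strand == "+", "-", "+")))
  ta_f <- transcriptional_asymmetry(mrg, shared_ref$genome, genes_f,
                                    min_count = 10)
  ta_r <- transcriptional_asymmetry(mrg, shared_ref$genome, genes_r,
                                    min_count = 10)
  m <- merge(as.data.frame(ta_f), as.data.frame(ta_r), by = "label")
  expect_equal(m$n_nts.x, m$n_ts.y)
  expect_equal(m$n_ts.x, m$n_nts.y)
  ok <- !is.na(m$normalized_ratio.x)
  expect_equal(m$normalized_ratio.x[ok], 1 / m$normalized_ratio.y[ok])
})

test_that("NTS fraction profile reports fractions and flags empty classes", {
  g <- toy_genome(c(chrT = paste(rep("ACGTT", 20), collapse = "")))
  genes <- gene_intervals(data.frame(chrom = "chrT", start = 0, end = 100,
                                     strand = "+", name = "g"))
  # 30 NTS (C>T at C positions, two isolates) and 10 TS (G>A at G positions)
  cpos <- rep(seq(2, 97, by = 5), length.out = 30)
  gpos <- seq(3, 98, by = 5)[1:10]
  rec <- make_records("chrT", c(cpos, gpos),
                      c(rep("C", 30), rep("G", 10)),
                      c(rep("T", 30), rep("A", 10)),
                      isolate = rep(c("i1", "i2"), c(25, 15)))
  asn <- assign_strand(rec, g, genes)
  prof <- nts_fraction_profile(asn)
  lab <- unique(asn$label)
  expect_equal(length(lab), 1L)
  expect_equal(prof$nts_fraction[prof$label == lab], 0.75)
})
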