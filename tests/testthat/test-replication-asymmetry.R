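test_that("inter-origin placement computes fractions and fork zones", {
  ori <- origin_map(data.frame(chrom = "chrT", pos = c(0L, 100L)))
  g25 <- make_records("chrT", 26, "C", "T")  # 0-based 25 between 0 and 100
  p <- place_between_origins(g25, ori)
  expect_equal(p$fraction, 0.25)
  expect_identical(p$zone, "rightward-fork")
  expect_identical(p$top_class, "C>T")

  # exact midpoint is excluded
  pm <- place_between_origins(make_records("chrT", 51, "C", "T"), ori)
  expect_equal(nrow(pm), 0L)
  expect_equal(unname(attr(pm, "excluded")["midpoint"]), 1L)

  # outside the outermost origins is excluded
  po <- place_between_origins(make_records("chrT", 150, "C", "T"), ori)
  expect_equal(nrow(po), 0L)
  expect_equal(unname(attr(po, "excluded")["outside"]), 1L)
})

test_that("binary-search placement agrees with a linear-scan oracle", {
  ori <- shared_ref$origins
  set.seed(3)
  ch <- sample(names(shared_ref$genome), 500, replace = TRUE)
  pos <- sapply(ch, function(c3)
    sample(2:(genome_lengths(shared_ref$genome)[[c3]] - 1L), 1))
  rec <- make_records(ch, pos, "C", "T")  # alleles irrelevant to placement
  p <- place_between_origins(rec, ori)
  # linear scan oracle
  oracle_frac <- function(ch1, pos1) {
    o <- ori$pos[ori$chrom == ch1]
    p0 <- pos1 - 1L
    left <- right <- NA
    for (i in seq_along(o)) if (o[i] <= p0) left <- o[i]
    for (i in rev(seq_along(o))) if (o[i] > p0) right <- o[i]
    if (is.na(left) || is.na(right)) return(NA_real_)
    f <- (p0 - left) / (right - left)
    if (f == 0.5) NA_real_ else f
  }
  want <- mapply(oracle_frac, ch, pos)
  want <- want[!is.na(want)]
  expect_equal(p$fraction, unname(want))
})

test_that("cross profile per-bin fractions sum to one and the null is flat", {
  set.seed(17)
  n <- 4000
  frac <- runif(n)
  member1 <- rbinom(n, 1, 0.5) == 1
  pl <- data.frame(chrom = "chrT", pos = 1L, ref = "C", alt = "T",
                   isolate = "i1", mclass = "single",
                   top_class = ifelse(member1, "C>T", "G>A"),
                   fraction = frac,
                   zone = ifelse(frac < 0.5, "rightward-fork", "leftward-fork"))
  cp <- cross_profile(pl, c("C>T", "G>A"), n_bins = 10, n_boot = 500, seed = 2)
  t <- cp$table
  tot <- t$n_member1 + t$n_member2
  expect_equal(t$fraction1 + (1 - t$fraction1), rep(1, nrow(t)))
  expect_equal(sum(tot), n)
  # null: member-2 slope is the mirror of member 1, CI straddles 0
  expect_equal(cp$fit$member2[["slope"]], -cp$fit$member1[["slope"]])
  expect_true(cp$ci$slope1[1] < 0 && cp$ci$slope1[2] > 0)
})

test_that("cross profile recovers a linear positional bias", {
  set.seed(23)
  n <- 6000
  frac <- runif(n)
  p1 <- 0.25 + 0.5 * frac  # true member-1 slope 0.5
  member1 <- rbinom(n, 1, p1) == 1
  pl <- data.frame(top_class = ifelse(member1, "C>T", "G>A"), fraction = frac)
  cp <- cross_profile(pl, c("C>T", "G>A"), n_bins = 10, n_boot = 1000, seed = 4)
  expect_true(cp$ci$slope1[1] <= 0.5 && 0.5 <= cp$ci$slope1[2])
  expect_equal(cp$fit$slope_diff, 2 * cp$fit$member1[["slope"]])
})

test_that("profiles of complementary relabelings and flipped axes mirror", {
  set.seed(29)
  n <- 3000
  frac <- runif(n)
  member1 <- rbinom(n, 1, 0.3 + 0.4 * frac) == 1
  pl <- data.frame(top_class = ifelse(member1, "C>T", "G>A"), fraction = frac)
  cp <- cross_profile(pl, c("C>T", "G>A"), n_bins = 10, n_boot = 100, seed = 5)

  # relabeling the pair (G>A as member 1) mirrors the profile: slope negated
  cp_sw <- cross_profile(pl, c("G>A", "C>T"), n_bins = 10, n_boot = 100,
                         seed = 5)
  expect_equal(cp_sw$fit$member1[["slope"]], -cp$fit$member1[["slope"]],
               tolerance = 1e-10)

  # flipping the positional axis alone also negates the slope
  pl_f <- transform(pl, fraction = 1 - frac)
  cp_f <- cross_profile(pl_f, c("C>T", "G>A"), n_bins = 10, n_boot = 100,
                        seed = 5)
  expect_equal(cp_f$fit$member1[["slope"]], -cp$fit$member1[["slope"]],
               tolerance = 1e-10)

  # a physical chromosome reversal does both at once (positions flip AND a
  # top-strand C>T reads G>A), so the fitted slope is preserved
  pl_rev <- data.frame(top_class = ifelse(member1, "G>A", "C>T"),
                       fraction = 1 - frac)
  cp_rev <- cross_profile(pl_rev, c("C>T", "G>A"), n_bins = 10, n_boot = 100,
                          seed = 5)
  expect_equal(cp_rev$fit$member1[["slope"]], cp$fit$member1[["slope"]],
               tolerance = 1e-10)
})

test_that("slope-difference CI covers zero at the nominal rate under the null", {
  set.seed(41)
  n_rep <- 500L
  n <- 1500L
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    frac <- runif(n)
    member1 <- rbinom(n, 1, 0.5) == 1
    pl <- data.frame(top_class = ifelse(member1, "C>T", "G>A"),
                     fraction = frac)
    cp <- cross_profile(pl, c("C>T", "G>A"), n_bins = 10, n_boot = 400,
                        seed = i)
    covered[i] <- cp$ci$slope_diff[1] <= 0 && 0 <= cp$ci$slope_diff[2]
  }
  # ~95% nominal; binomial 99% envelope around 0.95 at 500 replicates
  expect_gte(mean(covered), 0.925)
})
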