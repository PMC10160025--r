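# Replicative (leading/lagging) strand asymmetry.
#
# Mutations here are kept as read on the top (reference) strand — pyrimidine
# collapse would destroy replicative strand information. Each mutation is
# placed fractionally between its flanking replication origins; complementary
# substitution pairs (e.g. C>T vs G>A) are profiled along that axis, and a
# leading/lagging bias appears as a "cross": one member's fractional
# abundance rising with distance along the inter-origin interval while its
# complement falls.

COMPLEMENTARY_PAIRS <- list(c("C>T", "G>A"), c("C>A", "G>T"),
                            c("T>C", "A>G"), c("T>A", "A>T"),
                            c("C>G", "G>C"), c("T>G", "A>C"))

#' Place mutations fractionally between flanking replication origins
#'
#' For each single-base record, finds the flanking origins on its chromosome
#' and computes the fractional position \code{(pos - left)/(right - left)} in
#' [0, 1]. Mutations outside the outermost origins, on chromosomes with fewer
#' than two origins, or exactly at the inter-origin midpoint (fraction 0.5,
#' where fork polarity is undefined) are excluded; exclusion counts are kept
#' in the \code{"excluded"} attribute.
#'
#' @param records A \code{mutation_records} data frame (singles are used).
#' @param origins An \code{origin_map}.
#' @return Data frame with the record columns plus \code{top_class} (the
#'   substitution as read on the top strand, e.g. \code{"G>A"}),
#'   \code{fraction}, and \code{zone} (\code{"rightward-fork"} for
#'   fraction < 0.5, \code{"leftward-fork"} for > 0.5).
#' @export
place_between_origins <- function(records, origins) {
  df <- as.data.frame(records)
  df <- df[df$mclass == "single", , drop = FALSE]
  n <- nrow(df)
  fraction <- rep(NA_real_, n)
  excluded <- c(no_origins = 0L, outside = 0L, midpoint = 0L)
  for (ch in unique(df$chrom)) {
    ri <- which(df$chrom == ch)
    ori <- origins$pos[origins$chrom == ch]
    if (length(ori) < 2L) {
      excluded["no_origins"] <- excluded["no_origins"] + length(ri)
      next
    }
    p0 <- df$pos[ri] - 1L  # origins are 0-based
    i <- findInterval(p0, ori)
    inside <- i >= 1L & i < length(ori)
    excluded["outside"] <- excluded["outside"] + sum(!inside)
    idx <- ri[inside]
    ii <- i[inside]
    fraction[idx] <- (p0[inside] - ori[ii]) / (ori[ii + 1L] - ori[ii])
  }
  mid <- !is.na(fraction) & fraction == 0.5
  excluded["midpoint"] <- sum(mid)
  fraction[mid] <- NA_real_
  keep <- which(!is.na(fraction))
  out <- df[keep, , drop = FALSE]
  out$top_class <- if (length(keep)) paste0(out$ref, ">", out$alt) else character(0)
  out$fraction <- fraction[keep]
  out$zone <- if (length(keep)) {
    ifelse(out$fraction < 0.5, "rightward-fork", "leftward-fork")
  } else character(0)
  rownames(out) <- NULL
  structure(out, class = c("origin_placements", "data.frame"),
            excluded = excluded)
}

# least-squares slope/intercept of y on x (closed form)
ls_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(c(slope = NA_real_, intercept = NA_real_))
  b <- sum((x - mx) * (y - my)) / sxx
  c(slope = b, intercept = my - b * mx)
}

# slope of member-1 fraction over bins given cell counts (2 x n_bins)
profile_slope <- function(c1, c2, mids) {
  tot <- c1 + c2
  use <- tot > 0
  if (sum(use) < 2L) return(NA_real_)
  ls_fit(mids[use], (c1 / tot)[use])[["slope"]]
}

#' Fractional-abundance "cross" profile of a complementary substitution pair
#'
#' Bins mutations of one complementary top-strand pair (e.g. \code{C>T} vs
#' \code{G>A}) by their fractional position between origins, computes each
#' member's per-bin fractional abundance, fits an unweighted least-squares
#' line of each member's fraction against the bin midpoint, and estimates a
#' 95 percent bootstrap confidence interval for the member-1 slope and the
#' slope difference by resampling mutations.
#'
#' @param placements Output of [place_between_origins()].
#' @param pair Character vector of the two complementary top-strand classes;
#'   member 1 first (e.g. \code{c("C>T", "G>A")}).
#' @param n_bins Number of equal fractional-position bins (>= 2).
#' @param n_boot Bootstrap replicates for the slope CI.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class \code{cross_profile}: \code{table} (bin,
#'   midpoint, counts and fractions), \code{fit} (slopes/intercepts of both
#'   members, slope difference), \code{ci} (95 percent percentile bootstrap
#'   CIs for the member-1 slope and the slope difference), \code{n}.
#' @export
cross_profile <- function(placements, pair = c("C>T", "G>A"), n_bins = 10L,
                          n_boot = 1000L, seed = 1L) {
  stopifnot(length(pair) == 2L, n_bins >= 2L)
  df <- as.data.frame(placements)
  df <- df[df$top_class %in% pair, , drop = FALSE]
  if (nrow(df) == 0L) stop("no mutations of the requested pair")
  bin <- pmin(pmax(ceiling(df$fraction * n_bins), 1L), n_bins)
  member <- ifelse(df$top_class == pair[1], 1L, 2L)
  c1 <- tabulate(bin[member == 1L], nbins = n_bins)
  c2 <- tabulate(bin[member == 2L], nbins = n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  tot <- c1 + c2
  frac1 <- ifelse(tot > 0, c1 / tot, NA_real_)

  use <- tot > 0
  if (sum(use) < 2L) stop("fewer than 2 non-empty bins: cannot fit")
  fit1 <- ls_fit(mids[use], frac1[use])
  # member 2's fraction is 1 - member 1's in every retained bin
  fit2 <- c(slope = -fit1[["slope"]], intercept = 1 - fit1[["intercept"]])
  slope_diff <- fit1[["slope"]] - fit2[["slope"]]

  # bootstrap: resampling mutations is a multinomial draw over (bin, member)
  n <- nrow(df)
  cells <- c(c1, c2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  draws <- stats::rmultinom(n_boot, n, prob = cells / n)
  slopes <- vapply(seq_len(n_boot), function(j) {
    profile_slope(draws[seq_len(n_bins), j],
                  draws[n_bins + seq_len(n_bins), j], mids)
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  ci_slope <- stats::quantile(slopes, c(0.025, 0.975), names = FALSE)
  structure(list(
    table = data.frame(bin = seq_len(n_bins), midpoint = mids,
                       n_member1 = c1, n_member2 = c2, fraction1 = frac1),
    fit = list(member1 = fit1, member2 = fit2, slope_diff = slope_diff),
    ci = list(slope1 = ci_slope, slope_diff = 2 * ci_slope),
    pair = pair, n = n, n_boot = n_boot, seed = seed
  ), class = "cross_profile")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.cross_profile <- function(x, ...) {
  cat("cross_profile:", x$pair[1], "vs", x$pair[2], "-", x$n, "mutations,",
      nrow(x$table), "bins\n")
  cat(sprintf("member-1 slope %.4f (95%% CI %.4f to %.4f), slope diff %.4f\n",
              x$fit$member1[["slope"]], x$ci$slope1[1], x$ci$slope1[2],
              x$fit$slope_diff))
  invisible(x)
}

#' Plot the complementary-pair cross
#'
#' @param x A \code{cross_profile}.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.cross_profile <- function(x, ...) {
  t <- x$table
  graphics::plot(t$midpoint, t$fraction1, ylim = c(0, 1), type = "b", pch = 19,
                 xlab = "fractional position between origins",
                 ylab = "fractional abundance", ...)
  graphics::lines(t$midpoint, 1 - t$fraction1, type = "b", pch = 1)
  graphics::abline(h = 0.5, lty = 3)
  graphics::legend("topleft", legend = x$pair, pch = c(19, 1), bty = "n")
  invisible(x)
}
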