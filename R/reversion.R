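# Reversion-reporter and canavanine-resistance colony-count arithmetic.

#' Viable cell count from a serial-dilution plate series
#'
#' Estimates the number of viable cells in the plated suspension as the mean
#' of colonies/dilution over countable plates. Plates outside the countable
#' window (too few or too many colonies for reliable counting) are ignored;
#' if no plate is countable, all plates are used with a warning.
#'
#' @param colonies Integer vector of colony counts, one per plate.
#' @param dilutions Numeric vector of dilution factors in (0, 1], same length.
#' @param countable Two-element window of usable colony counts
#'   (default 30-300).
#' @return Estimated viable cells (per plated volume).
#' @export
survivors_from_dilutions <- function(colonies, dilutions,
                                     countable = c(30, 300)) {
  stopifnot(length(colonies) == length(dilutions),
            all(dilutions > 0), all(dilutions <= 1))
  ok <- colonies >= countable[1] & colonies <= countable[2]
  if (!any(ok)) {
    warning("no plate in the countable window; using all plates")
    ok <- rep(TRUE, length(colonies))
  }
  mean(colonies[ok] / dilutions[ok])
}

#' Reversion frequency from revertant and survivor counts
#'
#' The frequency of revertants among surviving plated cells. When no
#' revertant was observed, the maximum estimated reversion frequency is
#' reported instead: the frequency at which a single revertant would have
#' been seen among the cells plated (1/N), flagged as an upper estimate.
#'
#' @param revertants Integer count of revertant colonies (>= 0).
#' @param survivors Positive number of surviving cells plated.
#' @return List: \code{frequency}, \code{is_upper_estimate}.
#' @export
reversion_frequency <- function(revertants, survivors) {
  if (!is.finite(survivors) || survivors <= 0) {
    stop("survivors must be a positive count")
  }
  if (revertants < 0) stop("revertant count must be non-negative")
  if (revertants == 0) {
    list(frequency = 1 / survivors, is_upper_estimate = TRUE)
  } else {
    list(frequency = revertants / survivors, is_upper_estimate = FALSE)
  }
}

# median of values plus whether an upper-estimate value contributes to it
median_with_flag <- function(freq, upper) {
  med <- stats::median(freq)
  o <- order(freq)
  n <- length(freq)
  mid <- if (n %% 2 == 1L) o[(n + 1L) / 2L] else o[c(n / 2L, n / 2L + 1L)]
  list(median = med, uses_upper = any(upper[mid]))
}

#' Fold change of median reversion frequency between two groups
#'
#' Ratio of the median frequency in group \code{a} to that in group \code{b}.
#' If an upper-estimate (zero-revertant) frequency contributes to the
#' denominator median the result is a lower bound ("at least" that fold); if
#' to the numerator median, an upper bound; if to both, a bound of unknown
#' direction.
#'
#' @param freq_a,freq_b Numeric vectors of per-replicate frequencies.
#' @param upper_a,upper_b Logical vectors flagging upper-estimate entries.
#' @param summary Group summary statistic: \code{"median"} (default) or
#'   \code{"mean"}.
#' @return List: \code{fold}, \code{bound} (one of \code{"exact"},
#'   \code{"at_least"}, \code{"at_most"}, \code{"indeterminate"}).
#' @export
fold_change <- function(freq_a, freq_b,
                        upper_a = rep(FALSE, length(freq_a)),
                        upper_b = rep(FALSE, length(freq_b)),
                        summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (length(freq_a) == 0L || length(freq_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (summary == "median") {
    ma <- median_with_flag(freq_a, upper_a)
    mb <- median_with_flag(freq_b, upper_b)
  } else {
    ma <- list(median = mean(freq_a), uses_upper = any(upper_a))
    mb <- list(median = mean(freq_b), uses_upper = any(upper_b))
  }
  if (mb$median == 0) stop("denominator group summary is zero: fold undefined")
  bound <- if (ma$uses_upper && mb$uses_upper) "indeterminate"
  else if (mb$uses_upper) "at_least"
  else if (ma$uses_upper) "at_most"
  else "exact"
  list(fold = ma$median / mb$median, bound = bound)
}

#' Mann-Whitney comparison of two groups of reversion frequencies
#'
#' Pairwise two-tailed Mann-Whitney rank-sum test; exact enumeration at the
#' group sizes typical of these assays (for example, complete separation at
#' n = 6 vs 6 gives p = 2/924, about 0.0022).
#'
#' @param a,b Numeric vectors of frequencies.
#' @return Two-sided p-value.
#' @export
compare_groups_mw <- function(a, b) {
  compare_density_mw(a, b)
}

#' Canavanine-resistance mutation frequency
#'
#' Frequency of CanR mutants from a plating experiment: the number of CanR
#' colonies times the dilution plated on SC, divided by the number of SC
#' colonies times the dilution plated on canavanine.
#'
#' @param canr_colonies CanR colony count.
#' @param dilution_can Dilution plated on canavanine media (in (0, 1]).
#' @param sc_colonies SC (total viable) colony count (> 0).
#' @param dilution_sc Dilution plated on SC media (in (0, 1]).
#' @return List: \code{frequency}, \code{zero_count} (TRUE when no CanR
#'   colony was observed; the frequency is then 0, with no upper-estimate
#'   rule applied).
#' @export
can1_frequency <- function(canr_colonies, dilution_can, sc_colonies,
                           dilution_sc) {
  if (sc_colonies <= 0) stop("SC colony count must be positive")
  if (dilution_can <= 0 || dilution_can > 1 ||
      dilution_sc <= 0 || dilution_sc > 1) {
    stop("dilutions must lie in (0, 1]")
  }
  if (canr_colonies < 0) stop("CanR colony count must be non-negative")
  list(frequency = (canr_colonies * dilution_sc) / (sc_colonies * dilution_can),
       zero_count = canr_colonies == 0)
}
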