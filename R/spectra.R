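#' Build per-isolate single and tandem substitution spectra
#'
#' Counts classified substitutions per isolate over the 96 canonical
#' single-base channels and the 78 canonical doublet channels. Records of
#' class \code{multi} (runs of three or more adjacent substitutions) and
#' singles with unavailable context are excluded and counted in the result's
#' \code{excluded} field.
#'
#' @param records A tandem-merged \code{mutation_records} data frame (see
#'   [merge_tandems()]).
#' @param genome The \code{genome} contexts are read from.
#' @return A list of class \code{spectrum_pair}: \code{sbs} and \code{tandem},
#'   each a \code{mutation_spectrum} (isolate x class count matrix with
#'   per-class mean and sample SD across isolates), plus \code{excluded}
#'   counts.
#' @export
build_spectra <- function(records, genome) {
  df <- as.data.frame(records)
  isolates <- sort(unique(df$isolate))
  if (length(isolates) == 0L) stop("no isolates: cannot build an empty spectrum")

  sng <- df[df$mclass == "single", , drop = FALSE]
  cls <- classify_single(sng, genome)
  no_ctx <- is.na(cls$label)
  sbs_levels <- sbs_classes()$label
  sbs <- count_matrix(sng$isolate[!no_ctx], cls$label[!no_ctx],
                      isolates, sbs_levels)

  tnd <- df[df$mclass == "tandem", , drop = FALSE]
  tlab <- if (nrow(tnd) > 0L) classify_tandem(tnd) else character(0)
  tandem <- count_matrix(tnd$isolate, tlab, isolates, tandem_classes())

  structure(list(
    sbs = mutation_spectrum(sbs, "sbs"),
    tandem = mutation_spectrum(tandem, "tandem"),
    excluded = c(multi = sum(df$mclass == "multi"), no_context = sum(no_ctx))
  ), class = "spectrum_pair")
}

count_matrix <- function(isolate, label, isolates, levels) {
  m <- table(factor(isolate, levels = isolates),
             factor(label, levels = levels))
  matrix(as.integer(m), nrow = length(isolates),
         dimnames = list(isolate = isolates, class = levels))
}

#' Construct a mutation_spectrum from a count matrix
#'
#' @param counts Integer matrix, isolates in rows, classes in columns.
#' @param type \code{"sbs"} or \code{"tandem"}.
#' @return A \code{mutation_spectrum} object.
#' @export
mutation_spectrum <- function(counts, type = c("sbs", "tandem")) {
  type <- match.arg(type)
  stopifnot(is.matrix(counts), all(counts >= 0))
  structure(list(counts = counts, type = type), class = "mutation_spectrum")
}

#' Per-class mean and sample SD across isolates
#'
#' @param object A \code{mutation_spectrum}.
#' @param ... Unused.
#' @return Data frame: class, mean, sd (sample SD, n-1 denominator), total.
#' @export
summary.mutation_spectrum <- function(object, ...) {
  m <- object$counts
  data.frame(class = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             total = colSums(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-isolate total substitution counts
#'
#' @param spectrum A \code{mutation_spectrum}.
#' @return Named numeric vector, one total per isolate.
#' @export
isolate_totals <- function(spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  rowSums(spectrum$counts)
}

#' Pooled per-class totals
#'
#' @param spectrum A \code{mutation_spectrum}.
#' @return Named numeric vector of per-class totals across isolates.
#' @export
class_totals <- function(spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  colSums(spectrum$counts)
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("mutation_spectrum (", x$type, "): ", nrow(x$counts), " isolate(s), ",
      ncol(x$counts), " classes, ", sum(x$counts), " mutations\n", sep = "")
  tot <- class_totals(x)
  top <- sort(tot[tot > 0], decreasing = TRUE)
  if (length(top) > 0) {
    cat("top classes:\n")
    print(utils::head(top, 8))
  }
  invisible(x)
}

#' @export
print.spectrum_pair <- function(x, ...) {
  print(x$sbs); print(x$tandem)
  if (any(x$excluded > 0)) {
    cat("excluded:", paste(names(x$excluded), x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Barplot of a mutation spectrum (mean +/- SD across isolates)
#'
#' @param x A \code{mutation_spectrum}.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the summary data frame plotted.
#' @export
plot.mutation_spectrum <- function(x, ...) {
  s <- summary(x)
  bp <- graphics::barplot(s$mean, names.arg = s$class, las = 2,
                          cex.names = 0.4, ylab = "mean mutations per isolate",
                          main = paste(x$type, "spectrum"), ...)
  graphics::arrows(bp, pmax(s$mean - s$sd, 0), bp, s$mean + s$sd,
                   angle = 90, code = 3, length = 0.01)
  invisible(s)
}

#' Write a spectrum to TSV
#'
#' One row per class: per-isolate counts plus mean and SD columns.
#'
#' @param spectrum A \code{mutation_spectrum}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_spectrum <- function(spectrum, path) {
  m <- t(spectrum$counts)
  s <- summary(spectrum)
  out <- data.frame(class = rownames(m), m, mean = s$mean, sd = s$sd,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fold change of median per-isolate substitution density
#'
#' The ratio of the median per-isolate substitution count in group \code{a}
#' to that in group \code{b} (e.g. a mutant over wild type).
#'
#' @param a,b Numeric vectors of per-isolate total counts.
#' @return The fold change \code{median(a)/median(b)}.
#' @export
median_density_fold <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  mb <- stats::median(b)
  if (mb == 0) stop("median of denominator group is zero: fold undefined")
  stats::median(a) / mb
}

#' Chi-squared comparison of two mutation spectra
#'
#' Two-sided chi-squared test on the 2 x K contingency table of pooled
#' per-class counts from two groups. Classes with zero counts in both groups
#' are dropped; classes whose pooled expected count falls below
#' \code{min_expected} are merged into a single "other" class before testing
#' (asymptotic validity). No continuity correction is applied.
#'
#' @param a,b Named numeric vectors of pooled per-class counts on the same
#'   class ordering (e.g. from [class_totals()], optionally concatenating the
#'   single and tandem spectra).
#' @param min_expected Expected-count floor below which classes are pooled.
#' @return A list: \code{statistic}, \code{df}, \code{p.value},
#'   \code{k} (number of retained classes after pooling).
#' @export
compare_spectra_chi2 <- function(a, b, min_expected = 5) {
  if (length(a) != length(b)) stop("spectra must cover the same classes")
  keep <- a + b > 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("fewer than 2 non-empty classes: test undefined")
  n_a <- sum(a); n_b <- sum(b); n <- n_a + n_b
  exp_pooled <- (a + b) * pmin(n_a, n_b) / n
  low <- exp_pooled < min_expected
  if (any(low) && sum(!low) >= 1L) {
    a <- c(a[!low], other = sum(a[low]))
    b <- c(b[!low], other = sum(b[low]))
  }
  if (length(a) < 2L) stop("fewer than 2 classes after pooling: test undefined")
  m <- rbind(a, b)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), k = ncol(m))
}

#' Pearson concordance between two spectra
#'
#' Pearson correlation of raw per-class counts (matching plots whose axes are
#' mutation counts), with the usual two-sided t-test p-value.
#'
#' @param a,b Numeric vectors of per-class counts on identical class ordering.
#' @return A list: \code{rho}, \code{p.value}, \code{n} (number of classes).
#' @export
correlate_spectra <- function(a, b) {
  if (length(a) != length(b)) stop("spectra must cover the same classes")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a spectrum: correlation undefined")
  }
  ht <- stats::cor.test(a, b, method = "pearson")
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = length(a))
}

#' Mann-Whitney comparison of per-isolate substitution densities
#'
#' Two-sided Mann-Whitney rank-sum test of two groups of per-isolate totals;
#' exact enumeration for small groups, tie-corrected normal approximation for
#' large ones (see [mann_whitney_test()]).
#'
#' @param a,b Numeric vectors of per-isolate totals.
#' @return Two-sided p-value.
#' @export
compare_density_mw <- function(a, b) {
  mann_whitney_test(a, b)$p.value
}
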