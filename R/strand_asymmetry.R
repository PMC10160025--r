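# Transcriptional strand asymmetry.
#
# NTS = the gene's coding (mRNA-like, non-transcribed) strand; TS = the
# template strand. A strand-collapsed mutation is assigned NTS when its
# mutated reference pyrimidine lies on the coding strand. Regions covered by
# more than one gene are masked from both the mutation assignment and the
# per-strand context-frequency denominator, since strand is undefined there.

# 1-based closed IRanges for gene bodies on one chromosome
genes_ir <- function(genes) IRanges::IRanges(genes$start + 1L, genes$end)

# ranges covered by >= 2 genes (1-based closed), per chromosome
overlap_mask <- function(genes) {
  out <- list()
  for (ch in unique(genes$chrom)) {
    ir <- genes_ir(genes[genes$chrom == ch, , drop = FALSE])
    cov <- IRanges::coverage(ir)
    out[[ch]] <- as(IRanges::slice(cov, lower = 2L), "IRanges")
  }
  out
}

# pyrimidine-orientation strand of each record on the reference:
# "+" when the strand-collapsed (canonical) representation reads on the top
# strand, "-" when on the bottom; NA when undefined (palindromic tandems).
pyrimidine_strand <- function(records) {
  df <- as.data.frame(records)
  out <- rep(NA_character_, nrow(df))
  sng <- df$mclass == "single"
  out[sng] <- ifelse(is_pyrimidine(df$ref[sng]), "+", "-")
  tnd <- which(df$mclass == "tandem")
  if (length(tnd) > 0L) {
    ref <- df$ref[tnd]; alt <- df$alt[tnd]
    pal_ref <- ref == revcomp2(ref)
    s <- ifelse(ref %in% DBS_CANONICAL_REFS, "+", "-")
    # palindromic reference: orientation decided by which alt is canonical
    if (any(pal_ref)) {
      canon_alt <- pmin(alt[pal_ref], revcomp2(alt[pal_ref]))
      pal_alt <- alt[pal_ref] == revcomp2(alt[pal_ref])
      s[pal_ref] <- ifelse(pal_alt, NA_character_,
                           ifelse(alt[pal_ref] == canon_alt, "+", "-"))
    }
    out[tnd] <- s
  }
  out
}

#' Assign mutations to the transcribed or non-transcribed strand
#'
#' Each single or tandem record (tandems by their 5' position) is located
#' against the gene set: inside exactly one gene it is called \code{NTS} if
#' its strand-collapsed pyrimidine lies on the gene's coding strand, else
#' \code{TS}; positions covered by two or more genes are \code{ambiguous};
#' positions in no gene are \code{intergenic}.
#'
#' @param records A tandem-merged \code{mutation_records} data frame.
#' @param genome The \code{genome} (for context classification of the output
#'   \code{label} column).
#' @param genes A \code{gene_intervals} data frame.
#' @return Data frame with the record columns plus \code{label} (96/78-channel
#'   class label), \code{strand_call} (\code{NTS}, \code{TS},
#'   \code{intergenic}, \code{ambiguous}) and \code{gene}.
#' @export
assign_strand <- function(records, genome, genes) {
  df <- as.data.frame(records)
  df <- df[df$mclass %in% c("single", "tandem"), , drop = FALSE]
  n <- nrow(df)
  strand_call <- rep("intergenic", n)
  gene_name <- rep(NA_character_, n)
  pyr <- pyrimidine_strand(df)

  for (ch in intersect(unique(df$chrom), unique(genes$chrom))) {
    ri <- which(df$chrom == ch)
    gsub <- genes[genes$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(IRanges::IRanges(df$pos[ri], df$pos[ri]),
                                  genes_ir(gsub))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    nhit <- tabulate(q, nbins = length(ri))
    strand_call[ri[nhit >= 2L]] <- "ambiguous"
    one <- which(nhit == 1L)
    gi <- s[match(one, q)]
    gene_name[ri[one]] <- gsub$name[gi]
    same <- pyr[ri[one]] == gsub$strand[gi]
    strand_call[ri[one]] <- ifelse(is.na(same), "ambiguous",
                                   ifelse(same, "NTS", "TS"))
  }

  lab <- rep(NA_character_, n)
  sng <- df$mclass == "single"
  lab[sng] <- classify_single(df[sng, , drop = FALSE], genome)$label
  if (any(!sng)) lab[!sng] <- classify_tandem(df[!sng, , drop = FALSE])
  cbind(df, label = lab, strand_call = strand_call, gene = gene_name,
        stringsAsFactors = FALSE)
}

#' Per-strand k-mer frequencies over gene bodies
#'
#' Counts occurrences of every k-mer on the non-transcribed (coding) strand
#' across all gene bodies, after masking regions covered by more than one
#' gene. The transcribed-strand count of a k-mer equals the NTS count of its
#' reverse complement.
#'
#' @param genome A \code{genome} object.
#' @param genes A \code{gene_intervals} data frame.
#' @param width K-mer width (3 for trinucleotide contexts, 2 for doublets).
#' @return Matrix with one row per k-mer (4^width rows) and columns
#'   \code{nts}, \code{ts}.
#' @export
strand_context_frequencies <- function(genome, genes, width = 3L) {
  mask <- overlap_mask(genes)
  pieces <- character(0)
  strands <- character(0)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    ir <- IRanges::IRanges(genes$start[i] + 1L, genes$end[i])
    if (!is.null(mask[[ch]]) && length(mask[[ch]]) > 0L) {
      ir <- IRanges::setdiff(ir, mask[[ch]])
    }
    if (length(ir) == 0L) next
    keep <- IRanges::width(ir) >= width
    ir <- ir[keep]
    if (length(ir) == 0L) next
    seqs <- substring(unclass(genome)[[ch]], IRanges::start(ir), IRanges::end(ir))
    pieces <- c(pieces, seqs)
    strands <- c(strands, rep(genes$strand[i], length(seqs)))
  }
  kmers <- sort(do.call(paste0, expand.grid(rep(list(BASES), width))))
  nts <- stats::setNames(numeric(length(kmers)), kmers)
  if (length(pieces) > 0L) {
    dna <- Biostrings::DNAStringSet(pieces)
    neg <- strands == "-"
    if (any(neg)) dna[neg] <- Biostrings::reverseComplement(dna[neg])
    freq <- Biostrings::oligonucleotideFrequency(dna, width = width)
    tot <- colSums(freq)
    nts[names(tot)] <- tot
  }
  ts <- nts[revcomp(kmers)]
  names(ts) <- kmers
  cbind(nts = nts, ts = ts)
}

#' Goodness-of-fit test of an NTS/TS split against a composition expectation
#'
#' One-degree-of-freedom chi-squared test of observed NTS/TS counts against
#' the expected split implied by per-strand context frequencies, with a
#' Bonferroni-corrected p-value and the composition-normalised asymmetry
#' ratio (obs/exp on NTS) / (obs/exp on TS).
#'
#' @param n_nts,n_ts Observed counts on each strand.
#' @param e_fraction_nts Expected NTS fraction (in (0,1)) from the per-strand
#'   frequency of the class's context.
#' @param m Bonferroni family size (number of tested classes).
#' @param min_count Minimum total count to test (default 30).
#' @return A one-row data frame: \code{n_nts}, \code{n_ts}, \code{e_nts},
#'   \code{e_ts}, \code{normalized_ratio}, \code{chi2}, \code{p_raw},
#'   \code{p_bonf}, \code{tested}.
#' @export
asymmetry_test <- function(n_nts, n_ts, e_fraction_nts, m = 1L,
                           min_count = 30L) {
  tot <- n_nts + n_ts
  if (!(e_fraction_nts > 0 && e_fraction_nts < 1)) {
    stop("expected NTS fraction must lie strictly between 0 and 1")
  }
  e_nts <- tot * e_fraction_nts
  e_ts <- tot - e_nts
  ratio <- (n_nts / e_nts) / (n_ts / e_ts)
  if (tot < min_count) {
    return(data.frame(n_nts = n_nts, n_ts = n_ts, e_nts = e_nts, e_ts = e_ts,
                      normalized_ratio = ratio, chi2 = NA_real_,
                      p_raw = NA_real_, p_bonf = NA_real_, tested = FALSE))
  }
  chi2 <- (n_nts - e_nts)^2 / e_nts + (n_ts - e_ts)^2 / e_ts
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(n_nts = n_nts, n_ts = n_ts, e_nts = e_nts, e_ts = e_ts,
             normalized_ratio = ratio, chi2 = chi2, p_raw = p,
             p_bonf = min(1, p * m), tested = TRUE)
}

#' Transcriptional strand asymmetry of every mutation class
#'
#' Assigns mutations to gene strands, pools genic NTS/TS counts per
#' (substitution, context) class (tandems as their own canonical classes),
#' derives the expected NTS fraction of each class from the per-strand
#' frequency of its context over gene bodies, and tests each class with at
#' least \code{min_count} mutations by a two-sided 1-df chi-squared
#' goodness-of-fit test, Bonferroni-corrected over the tested classes.
#'
#' @param records A tandem-merged \code{mutation_records} data frame.
#' @param genome A \code{genome} object.
#' @param genes A \code{gene_intervals} data frame.
#' @param min_count Minimum genic mutations for a class to be tested.
#' @param include_tandems Analyse tandem classes too (default TRUE).
#' @param context_freqs Optional precomputed per-strand context frequencies:
#'   a list with elements \code{tri} and (if tandems are analysed) \code{di}
#'   from [strand_context_frequencies()]. Computed from \code{genome} and
#'   \code{genes} when \code{NULL}; precompute when testing many mutation
#'   sets against one reference.
#' @return An object of class \code{strand_asymmetry}: a data frame with one
#'   row per observed genic class (\code{label}, counts, expectations,
#'   \code{normalized_ratio}, \code{nts_fraction}, test columns), with
#'   attributes \code{m} (family size) and \code{min_count}.
#' @export
transcriptional_asymmetry <- function(records, genome, genes,
                                      min_count = 30L,
                                      include_tandems = TRUE,
                                      context_freqs = NULL) {
  asn <- assign_strand(records, genome, genes)
  if (!include_tandems) asn <- asn[asn$mclass == "single", , drop = FALSE]
  genic <- asn[asn$strand_call %in% c("NTS", "TS") & !is.na(asn$label), ,
               drop = FALSE]
  if (nrow(genic) == 0L) stop("no genic mutations with defined strand")
  freq3 <- if (!is.null(context_freqs$tri)) context_freqs$tri else
    strand_context_frequencies(genome, genes, width = 3L)
  freq2 <- if (!any(genic$mclass == "tandem")) NULL else
    if (!is.null(context_freqs$di)) context_freqs$di else
      strand_context_frequencies(genome, genes, width = 2L)

  tab <- table(genic$label, factor(genic$strand_call, levels = c("NTS", "TS")))
  labs <- rownames(tab)
  ctx <- ifelse(grepl("@", labs), sub("^.*@", "", labs), substr(labs, 1, 2))
  e_frac <- vapply(seq_along(labs), function(i) {
    f <- if (nchar(ctx[i]) == 3L) freq3 else freq2
    num <- f[ctx[i], "nts"]
    den <- num + f[ctx[i], "ts"]
    if (den == 0) NA_real_ else num / den
  }, numeric(1))

  rows <- vector("list", length(labs))
  testable <- !is.na(e_frac) & e_frac > 0 & e_frac < 1
  m <- sum(testable & (tab[, "NTS"] + tab[, "TS"]) >= min_count)
  for (i in seq_along(labs)) {
    if (testable[i]) {
      rows[[i]] <- asymmetry_test(tab[i, "NTS"], tab[i, "TS"], e_frac[i],
                                  m = max(m, 1L), min_count = min_count)
    } else {
      rows[[i]] <- data.frame(n_nts = tab[i, "NTS"], n_ts = tab[i, "TS"],
                              e_nts = NA_real_, e_ts = NA_real_,
                              normalized_ratio = NA_real_, chi2 = NA_real_,
                              p_raw = NA_real_, p_bonf = NA_real_,
                              tested = FALSE)
    }
  }
  out <- cbind(data.frame(label = labs, e_fraction_nts = e_frac,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out$nts_fraction <- with(out, ifelse(n_nts + n_ts > 0,
                                       n_nts / (n_nts + n_ts), NA_real_))
  rownames(out) <- NULL
  structure(out, class = c("strand_asymmetry", "data.frame"),
            m = m, min_count = min_count)
}

#' Fraction of mutations on the non-transcribed strand, per class
#'
#' @param assignments Output of [assign_strand()].
#' @return Data frame: \code{label}, \code{n_nts}, \code{n_ts},
#'   \code{nts_fraction} (\code{NA}, i.e. not determined, where a class has
#'   no genic mutations).
#' @export
nts_fraction_profile <- function(assignments) {
  df <- assignments[!is.na(assignments$label), , drop = FALSE]
  labs <- sort(unique(df$label))
  genic <- df[df$strand_call %in% c("NTS", "TS"), , drop = FALSE]
  tab <- table(factor(genic$label, levels = labs),
               factor(genic$strand_call, levels = c("NTS", "TS")))
  tot <- tab[, "NTS"] + tab[, "TS"]
  data.frame(label = labs,
             n_nts = as.integer(tab[, "NTS"]),
             n_ts = as.integer(tab[, "TS"]),
             nts_fraction = ifelse(tot > 0, tab[, "NTS"] / tot, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.strand_asymmetry <- function(x, ...) {
  cat("strand_asymmetry:", nrow(x), "class(es);", attr(x, "m"),
      "tested (>=", attr(x, "min_count"), "mutations)\n")
  NextMethod()
}

#' Asymmetry ratio vs. mutation count plot
#'
#' @param x A \code{strand_asymmetry} object.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.strand_asymmetry <- function(x, ...) {
  d <- x[x$tested, , drop = FALSE]
  if (nrow(d) == 0L) stop("no tested classes to plot")
  graphics::plot(d$n_nts + d$n_ts, d$normalized_ratio, log = "xy",
                 xlab = "mutations in class", ylab = "NTS/TS normalized ratio",
                 pch = 19, ...)
  graphics::abline(h = 1, lty = 2)
  graphics::text(d$n_nts + d$n_ts, d$normalized_ratio, d$label,
                 pos = 3, cex = 0.6)
  invisible(x)
}
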