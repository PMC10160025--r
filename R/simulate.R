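# Synthetic-data generator: toy genomes, gene/origin annotations and
# per-isolate mutation tables with a controllable 96-channel + tandem
# spectrum, a controllable NTS:TS odds inside genes, and a controllable
# linear leading/lagging bias between origins. Everything is deterministic
# under the config seed.

#' Configuration for the synthetic-data generator
#'
#' @param seed Integer seed; fully determines all generated outputs.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param gc_content GC fraction of the i.i.d. base draws.
#' @param n_genes Genes per chromosome (placed non-overlapping, uniform).
#' @param gene_length Gene length in bp.
#' @param n_origins Replication origins per chromosome (evenly spaced with
#'   jitter).
#' @param n_isolates Number of isolates (independent mutation sets).
#' @param mutations_per_isolate Mutation events per isolate (a tandem counts
#'   as one event); exact count or Poisson mean per \code{count_model}.
#' @param count_model \code{"fixed"} or \code{"poisson"}.
#' @param sbs_probs Named 96-vector of single-class probabilities (names as
#'   in \code{sbs_classes()$label}); must sum to 1. Default: a UV-like
#'   spectrum dominated by C>T at dipyrimidine contexts.
#' @param tandem_probs Named vector of canonical tandem-class probabilities
#'   (subset of [tandem_classes()]); must sum to 1.
#' @param tandem_fraction Fraction of mutation events that are tandems.
#' @param nts_odds NTS:TS odds for genic mutations: a scalar, or a named
#'   vector keyed by substitution type (e.g. \code{"C>T"}). 1 = no
#'   transcriptional bias.
#' @param rep_slope Linear replicative bias coefficient: the top-strand
#'   pyrimidine member of each complementary pair is placed with probability
#'   \code{0.5 + rep_slope * (fraction - 0.5)} along the inter-origin axis.
#'   0 = no replicative bias.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L,
                             chrom_length = 100000L,
                             gc_content = 0.38,
                             n_genes = 20L,
                             gene_length = 1500L,
                             n_origins = 6L,
                             n_isolates = 20L,
                             mutations_per_isolate = 100,
                             count_model = c("fixed", "poisson"),
                             sbs_probs = default_sbs_probs(),
                             tandem_probs = default_tandem_probs(),
                             tandem_fraction = 0.05,
                             nts_odds = 1,
                             rep_slope = 0) {
  count_model <- match.arg(count_model)
  stopifnot(n_chroms >= 1L, chrom_length >= 1000L,
            gc_content > 0, gc_content < 1,
            n_genes >= 0L, gene_length >= 3L, n_origins >= 0L,
            n_isolates >= 1L, mutations_per_isolate >= 0,
            tandem_fraction >= 0, tandem_fraction <= 1,
            all(nts_odds > 0), abs(rep_slope) <= 1)
  if (as.double(n_genes) * gene_length > chrom_length) {
    stop("infeasible packing: n_genes * gene_length exceeds chrom_length")
  }
  check_simplex(sbs_probs, sbs_classes()$label, "sbs_probs")
  check_simplex(tandem_probs, tandem_classes(), "tandem_probs")
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_length = chrom_length, gc_content = gc_content,
                 n_genes = n_genes, gene_length = gene_length,
                 n_origins = n_origins, n_isolates = n_isolates,
                 mutations_per_isolate = mutations_per_isolate,
                 count_model = count_model, sbs_probs = sbs_probs,
                 tandem_probs = tandem_probs,
                 tandem_fraction = tandem_fraction,
                 nts_odds = nts_odds, rep_slope = rep_slope),
            class = "synthetic_config")
}

check_simplex <- function(p, valid, what) {
  if (is.null(names(p)) || !all(names(p) %in% valid)) {
    stop(what, " must be named by canonical class labels")
  }
  if (anyDuplicated(names(p)) || any(p < 0)) stop(what, " is not a valid simplex")
  if (abs(sum(p) - 1) > 1e-9) stop(what, " must sum to 1 (within 1e-9)")
  invisible(TRUE)
}

#' UV-like default single-base spectrum
#'
#' C>T dominated, concentrated at dipyrimidine (5' C or T) contexts as UV
#' photoproduct mutagenesis is, with minor T>C, T>A and C>A components.
#'
#' @return Named 96-vector of probabilities summing to 1.
#' @export
default_sbs_probs <- function() {
  cl <- sbs_classes()
  type_w <- c("C>A" = 0.10, "C>G" = 0.03, "C>T" = 0.55,
              "T>A" = 0.10, "T>C" = 0.14, "T>G" = 0.08)
  w <- type_w[cl$substitution]
  dipyr <- cl$substitution == "C>T" & substr(cl$context, 1, 1) %in% c("C", "T")
  w[dipyr] <- w[dipyr] * 5  # CPD-forming 5' pyrimidine contexts
  w <- w / sum(w)
  stats::setNames(w, cl$label)
}

#' UV-like default tandem spectrum
#'
#' Dominated by CC>TT with the other tandem categories seen after UV
#' (CT>TA, AC>TT) and a small remainder.
#'
#' @return Named vector of canonical tandem-class probabilities summing to 1.
#' @export
default_tandem_probs <- function() {
  c("CC>TT" = 0.45, "CT>TA" = 0.15, "AC>TT" = 0.15,
    "TT>AA" = 0.10, "TA>AT" = 0.05, "CC>AA" = 0.05, "CC>TA" = 0.05)
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  expr
}

#' Generate a toy reference: genome, genes and origins
#'
#' Chromosome sequences are i.i.d. base draws at the configured GC content;
#' genes are placed non-overlapping with uniformly random gaps and random
#' strand; origins are evenly spaced with jitter. Deterministic under the
#' config seed.
#'
#' @param config A \code{synthetic_config}.
#' @return A list of class \code{synthetic_reference}: \code{genome},
#'   \code{genes}, \code{origins}, \code{config}.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    gc <- config$gc_content
    L <- config$chrom_length
    chroms <- paste0("chr", utils::as.roman(seq_len(config$n_chroms)))
    seqs <- vapply(chroms, function(ch) {
      paste(sample(BASES, L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
    g <- genome(seqs)

    genes <- NULL
    if (config$n_genes > 0L) {
      per <- lapply(chroms, function(ch) {
        n <- config$n_genes
        free <- L - n * config$gene_length
        gaps <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
        starts <- gaps + (seq_len(n) - 1L) * config$gene_length
        data.frame(chrom = ch, start = starts,
                   end = starts + config$gene_length,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   name = paste0(ch, "_g", seq_len(n)),
                   stringsAsFactors = FALSE)
      })
      genes <- gene_intervals(do.call(rbind, per))
    } else {
      genes <- gene_intervals(data.frame(chrom = character(0),
                                         start = integer(0), end = integer(0),
                                         strand = character(0),
                                         name = character(0))[0, ])
    }

    origins <- NULL
    if (config$n_origins > 0L) {
      per <- lapply(chroms, function(ch) {
        k <- config$n_origins
        spacing <- L / (k + 1)
        base <- seq(spacing, k * spacing, length.out = k)
        jit <- stats::runif(k, -0.2 * spacing, 0.2 * spacing)
        pos <- sort(unique(as.integer(round(pmin(pmax(base + jit, 0), L - 1)))))
        data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
      })
      origins <- origin_map(do.call(rbind, per))
    } else {
      origins <- origin_map(data.frame(chrom = character(0), pos = integer(0)))
    }

    structure(list(genome = g, genes = genes, origins = origins,
                   config = config),
              class = "synthetic_reference")
  })
}

#' Write a synthetic reference to disk
#'
#' Emits genome FASTA, genes BED6 and origins TSV into a directory.
#'
#' @param reference A \code{synthetic_reference}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(reference, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.bed"),
             origins = file.path(dir, "origins.tsv"))
  write_genome(reference$genome, paths["genome"])
  write_genes_bed(reference$genes, paths["genes"])
  write_origins(reference$origins, paths["origins"])
  invisible(paths)
}

# gene-orientation flag per (position, canonical-orientation strand):
# "NTS" / "TS" when inside exactly one gene, "neutral" otherwise
site_gene_flag <- function(chrom, pos, strand, genes) {
  n <- length(pos)
  flag <- rep("neutral", n)
  for (ch in intersect(unique(chrom), unique(genes$chrom))) {
    ri <- which(chrom == ch)
    gsub <- genes[genes$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos[ri], pos[ri]),
                                  genes_ir(gsub))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    nhit <- tabulate(q, nbins = length(ri))
    one <- which(nhit == 1L)
    gi <- s[match(one, q)]
    flag[ri[one]] <- ifelse(strand[ri[one]] == gsub$strand[gi], "NTS", "TS")
  }
  flag
}

# fractional position between flanking origins; NA outside / <2 origins
site_fraction <- function(chrom, pos, origins) {
  frac <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    ori <- origins$pos[origins$chrom == ch]
    if (length(ori) < 2L) next
    ri <- which(chrom == ch)
    p0 <- pos[ri] - 1L
    i <- findInterval(p0, ori)
    inside <- i >= 1L & i < length(ori)
    idx <- ri[inside]; ii <- i[inside]
    frac[idx] <- (p0[inside] - ori[ii]) / (ori[ii + 1L] - ori[ii])
  }
  frac
}

#' Index candidate mutation sites of a synthetic reference
#'
#' For every pyrimidine-centred trinucleotide context and every canonical
#' tandem reference dinucleotide, lists the genomic sites (position and
#' orientation) where it occurs, annotated with the gene-orientation flag and
#' the fractional position between origins. Build once and pass to
#' [generate_mutations()] when simulating many replicates against the same
#' reference.
#'
#' @param reference A \code{synthetic_reference}.
#' @return A list of class \code{site_index} with components \code{tri} and
#'   \code{di}, each a named list of per-class site data frames.
#' @export
build_site_index <- function(reference) {
  g <- reference$genome
  genes <- reference$genes
  origins <- reference$origins

  index_width <- function(width, keys_plus) {
    # keys_plus: named list canonical key -> c(plus_kmer, minus_kmer)
    per_class <- stats::setNames(vector("list", length(keys_plus)),
                                 names(keys_plus))
    for (ch in names(g)) {
      s <- unclass(g)[[ch]]
      L <- nchar(s)
      # pos is the classified base: 3-mer centred on pos, 2-mer starting at pos
      first <- if (width == 3L) 2L else 1L
      pos <- first:(L - width + first)
      win_start <- if (width == 3L) pos - 1L else pos
      kmer <- substring(s, win_start, win_start + width - 1L)
      by_kmer <- split(pos, kmer)
      for (key in names(keys_plus)) {
        kp <- keys_plus[[key]]
        plus <- by_kmer[[kp[1]]]
        minus <- if (kp[2] == kp[1]) plus else by_kmer[[kp[2]]]
        rows <- data.frame(
          chrom = ch,
          pos = c(plus, minus),
          strand = c(rep("+", length(plus)), rep("-", length(minus))),
          stringsAsFactors = FALSE)
        if (nrow(rows) > 0L) {
          per_class[[key]] <- rbind(per_class[[key]], rows)
        }
      }
    }
    for (key in names(per_class)) {
      df <- per_class[[key]]
      if (is.null(df)) {
        per_class[[key]] <- data.frame(chrom = character(0), pos = integer(0),
                                       strand = character(0),
                                       gflag = character(0), frac = numeric(0))
        next
      }
      df$gflag <- site_gene_flag(df$chrom, df$pos, df$strand, genes)
      df$frac <- site_fraction(df$chrom, df$pos, origins)
      per_class[[key]] <- df
    }
    per_class
  }

  ctxs <- unique(sbs_classes()$context)
  tri_keys <- stats::setNames(lapply(ctxs, function(c3) c(c3, revcomp(c3))), ctxs)
  dins <- DBS_CANONICAL_REFS
  di_keys <- stats::setNames(lapply(dins, function(d) c(d, revcomp2(d))), dins)

  structure(list(tri = index_width(3L, tri_keys),
                 di = index_width(2L, di_keys)),
            class = "site_index")
}

# per-site sampling weight for one class
site_weights <- function(df, odds, rep_slope) {
  o <- odds
  w_tx <- ifelse(df$gflag == "NTS", o / (1 + o),
                 ifelse(df$gflag == "TS", 1 / (1 + o), 0.5))
  f <- ifelse(is.na(df$frac), 0.5, df$frac)
  w_rep <- ifelse(df$strand == "+",
                  0.5 + rep_slope * (f - 0.5),
                  0.5 - rep_slope * (f - 0.5))
  pmax(w_tx * pmin(pmax(w_rep, 0), 1), 0)
}

class_odds <- function(nts_odds, subtype) {
  if (length(nts_odds) == 1L && is.null(names(nts_odds))) return(nts_odds)
  if (!is.null(names(nts_odds)) && subtype %in% names(nts_odds)) {
    return(nts_odds[[subtype]])
  }
  1
}

# sample k site rows by weight, avoiding duplicate positions where possible
sample_sites <- function(df, k, w) {
  n <- nrow(df)
  if (n == 0L || sum(w) == 0) return(integer(0))
  if (k <= n) {
    sample.int(n, k, replace = FALSE, prob = w)
  } else {
    warning("fewer candidate sites than draws; sampling with replacement")
    unique(sample.int(n, k, replace = TRUE, prob = w))
  }
}

#' Generate per-isolate mutation tables from a synthetic reference
#'
#' For each isolate, draws mutation classes from the configured single and
#' tandem spectra and places each at a genomic site whose context matches the
#' class, sampled with weights that realise the configured transcriptional
#' odds (NTS orientation inside genes weighted \code{odds/(1+odds)}, TS
#' \code{1/(1+odds)}) and replicative bias (top-strand pyrimidine orientation
#' weighted \code{0.5 + rep_slope*(fraction - 0.5)} between origins). Tandem
#' events are emitted as two adjacent single-base rows so that
#' [merge_tandems()] is exercised downstream; events are spaced so unrelated
#' mutations are never adjacent. Deterministic under the config seed.
#'
#' @param config A \code{synthetic_config}.
#' @param reference The matching \code{synthetic_reference}.
#' @param index Optional precomputed [build_site_index()] for this reference.
#' @return Data frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{isolate}; 1-based positions; every \code{ref} matches
#'   the reference genome.
#' @export
generate_mutations <- function(config, reference, index = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(reference, "synthetic_reference"))
  if (is.null(index)) index <- build_site_index(reference)
  sbs <- sbs_classes()
  sub_of <- stats::setNames(sbs$substitution, sbs$label)
  ctx_of <- stats::setNames(sbs$context, sbs$label)

  with_seed(derive_seed(config$seed, 1L), {
    all_rows <- vector("list", config$n_isolates)
    for (iso in seq_len(config$n_isolates)) {
      iso_id <- sprintf("iso%03d", iso)
      n_total <- if (config$count_model == "poisson") {
        stats::rpois(1, config$mutations_per_isolate)
      } else as.integer(round(config$mutations_per_isolate))
      if (n_total == 0L) next
      n_tnd <- stats::rbinom(1, n_total, config$tandem_fraction)
      n_sng <- n_total - n_tnd

      events <- list()
      if (n_sng > 0L) {
        cls <- sample(names(config$sbs_probs), n_sng, replace = TRUE,
                      prob = config$sbs_probs)
        for (lab in unique(cls)) {
          k <- sum(cls == lab)
          ctx <- ctx_of[[lab]]
          df <- index$tri[[ctx]]
          if (nrow(df) == 0L) {
            warning("context ", ctx, " absent from genome; class ", lab,
                    " skipped")
            next
          }
          odds <- class_odds(config$nts_odds, sub_of[[lab]])
          rows <- sample_sites(df, k, site_weights(df, odds, config$rep_slope))
          if (length(rows) == 0L) next
          st <- df$strand[rows]
          ref <- ifelse(st == "+", substr(ctx, 2, 2),
                        complement_base(substr(ctx, 2, 2)))
          altb <- substr(sub_of[[lab]], 3, 3)
          alt <- ifelse(st == "+", altb, complement_base(altb))
          events[[length(events) + 1L]] <-
            data.frame(chrom = df$chrom[rows], start = df$pos[rows],
                       width = 1L, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
        }
      }
      if (n_tnd > 0L) {
        tcl <- sample(names(config$tandem_probs), n_tnd, replace = TRUE,
                      prob = config$tandem_probs)
        for (lab in unique(tcl)) {
          k <- sum(tcl == lab)
          d <- substr(lab, 1, 2)
          a <- substr(lab, 4, 5)
          df <- index$di[[d]]
          if (nrow(df) == 0L) {
            warning("dinucleotide ", d, " absent from genome; class ", lab,
                    " skipped")
            next
          }
          odds <- class_odds(config$nts_odds, lab)
          rows <- sample_sites(df, k, site_weights(df, odds, config$rep_slope))
          if (length(rows) == 0L) next
          st <- df$strand[rows]
          ref <- ifelse(st == "+", d, revcomp2(d))
          alt <- ifelse(st == "+", a, revcomp2(a))
          events[[length(events) + 1L]] <-
            data.frame(chrom = df$chrom[rows], start = df$pos[rows],
                       width = 2L, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
        }
      }
      if (length(events) == 0L) next
      ev <- do.call(rbind, events)
      # greedy spacing: keep events at least 2 bp apart so unrelated events
      # never merge into spurious tandem/multi runs
      ev <- ev[order(ev$chrom, ev$start), , drop = FALSE]
      endpos <- ev$start + ev$width - 1L
      keep <- logical(nrow(ev))
      last_chrom <- ""; last_end <- -10L
      for (i in seq_len(nrow(ev))) {
        if (ev$chrom[i] != last_chrom || ev$start[i] > last_end + 1L) {
          keep[i] <- TRUE
          last_chrom <- ev$chrom[i]; last_end <- endpos[i]
        }
      }
      ev <- ev[keep, , drop = FALSE]
      # explode into single-base rows (tandems become adjacent pairs)
      reps <- rep(seq_len(nrow(ev)), ev$width)
      off <- unlist(lapply(ev$width, seq_len)) - 1L
      all_rows[[iso]] <- data.frame(
        chrom = ev$chrom[reps],
        pos = ev$start[reps] + off,
        ref = substr(ev$ref[reps], off + 1L, off + 1L),
        alt = substr(ev$alt[reps], off + 1L, off + 1L),
        isolate = iso_id,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, all_rows)
    if (is.null(out)) {
      out <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        isolate = character(0))
    }
    rownames(out) <- NULL
    out
  })
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2000000000L) + as.integer(offset)
}

#' Simulate reversion-assay revertant counts
#'
#' Revertant counts are Poisson with mean \code{true_freq * survivors} per
#' replicate; deterministic under \code{seed}.
#'
#' @param true_freq True reversion frequency (0 to 1).
#' @param survivors Surviving cells plated per replicate (scalar or vector).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @return Data frame: \code{replicate}, \code{revertants}, \code{survivors}.
#' @export
generate_reversion_counts <- function(true_freq, survivors, n_replicates,
                                      seed = 1L) {
  stopifnot(true_freq >= 0, true_freq <= 1, all(survivors > 0),
            n_replicates >= 1L)
  survivors <- rep_len(survivors, n_replicates)
  with_seed(seed, {
    data.frame(replicate = seq_len(n_replicates),
               revertants = stats::rpois(n_replicates, true_freq * survivors),
               survivors = survivors)
  })
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat("synthetic_reference (seed ", x$config$seed, ")\n", sep = "")
  print(x$genome)
  cat(nrow(x$genes), "gene(s),", nrow(x$origins), "origin(s)\n")
  invisible(x)
}
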