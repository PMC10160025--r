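#' Read and validate a table of called substitutions
#'
#' Ingests per-isolate substitution calls from a tab-delimited table (columns
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{isolate}) or a
#' single-sample VCF (the sample name becomes the isolate). Every record is
#' validated against the reference genome: records whose \code{ref} allele
#' does not match the genome are rejected and collected into a reject report
#' (attribute \code{"rejected"}), never silently dropped. Records on excluded
#' chromosomes (by default the common yeast mitochondrial names) are removed
#' and counted.
#'
#' Positions are 1-based throughout (VCF convention).
#'
#' @param path Path to a TSV mutation table or a \code{.vcf} file.
#' @param genome A \code{genome} object the calls refer to.
#' @param exclude_chroms Chromosome names to drop (mitochondrial filter).
#' @param dedup_shared If \code{TRUE}, a mutation seen at the same site with
#'   the same alleles in more than one isolate (a putative shared ancestral
#'   event) is kept in the first isolate only. Default \code{FALSE}: the
#'   appropriate treatment of shared calls depends on the experimental design,
#'   so all records are kept unless the caller opts in.
#' @return A data frame of class \code{mutation_records} with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{isolate},
#'   \code{mclass} (all \code{"single"} on ingest). Attributes:
#'   \code{"rejected"} (data frame of ref-mismatch records with a reason) and
#'   \code{"n_excluded"} (count removed by the chromosome filter).
#' @export
read_mutations <- function(path, genome,
                           exclude_chroms = c("chrM", "chrMito", "mitochondrion"),
                           dedup_shared = FALSE) {
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    tab <- read_mutations_vcf(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("chrom", "pos", "ref", "alt", "isolate")
    if (!all(need %in% names(tab))) {
      stop("mutation table must have columns: ", paste(need, collapse = ", "))
    }
    tab <- tab[need]
  }
  validate_mutations(tab, genome, exclude_chroms = exclude_chroms,
                     dedup_shared = dedup_shared)
}

read_mutations_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-variant VCF
  iso <- if (ncol(v@gt) >= 2L) colnames(v@gt)[2L] else "sample1"
  data.frame(chrom = fix[, "CHROM"],
             pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"],
             alt = fix[, "ALT"],
             isolate = iso,
             stringsAsFactors = FALSE)
}

#' Validate a mutation table against a genome
#'
#' Core validation behind [read_mutations()], usable on an in-memory table.
#'
#' @inheritParams read_mutations
#' @param tab Data frame with columns chrom, pos, ref, alt, isolate.
#' @return A \code{mutation_records} data frame (see [read_mutations()]).
#' @export
validate_mutations <- function(tab, genome,
                               exclude_chroms = c("chrM", "chrMito", "mitochondrion"),
                               dedup_shared = FALSE) {
  stopifnot(inherits(genome, "genome"))
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  tab$isolate <- as.character(tab$isolate)

  excl <- tab$chrom %in% exclude_chroms
  n_excluded <- sum(excl)
  tab <- tab[!excl, , drop = FALSE]

  reason <- rep(NA_character_, nrow(tab))
  known <- tab$chrom %in% names(genome)
  reason[!known] <- "unknown chromosome"
  w <- nchar(tab$ref)
  bad_allele <- known & (w < 1L | w > 2L | nchar(tab$alt) != w |
                           tab$ref == tab$alt |
                           grepl("[^ACGT]", tab$ref) | grepl("[^ACGT]", tab$alt))
  reason[bad_allele & is.na(reason)] <- "invalid alleles"
  len <- rep(NA_integer_, nrow(tab))
  len[known] <- genome_lengths(genome)[tab$chrom[known]]
  oob <- known & !bad_allele & (tab$pos < 1L | tab$pos > len - (w - 1L))
  reason[oob & is.na(reason)] <- "position out of bounds"
  chk <- is.na(reason)
  if (any(chk)) {
    obs <- genome_slice(genome, tab$chrom[chk], tab$pos[chk], w[chk])
    mism <- obs != tab$ref[chk]
    reason[chk][mism] <- paste0("ref mismatch (genome has ", obs[mism], ")")
  }

  rejected <- cbind(tab[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  rownames(rejected) <- NULL
  out <- tab[is.na(reason), , drop = FALSE]

  if (dedup_shared && nrow(out) > 0L) {
    key <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out$mclass <- ifelse(nchar(out$ref) == 2L, "tandem", "single")
  rownames(out) <- NULL
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " record(s) rejected during validation")
  }
  if (n_excluded > 0L) {
    message(n_excluded, " record(s) dropped by chromosome exclusion filter")
  }
  structure(out, class = c("mutation_records", "data.frame"),
            rejected = rejected, n_excluded = n_excluded)
}

#' Write a mutation table to TSV
#'
#' @param records A \code{mutation_records} data frame (or compatible).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_mutations <- function(records, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "isolate"), names(records))
  utils::write.table(as.data.frame(records)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge adjacent substitutions into tandem records
#'
#' Within each isolate and chromosome, runs of single-base substitutions at
#' strictly consecutive positions are merged: a run of exactly two becomes one
#' tandem (doublet) record; a run of three or more becomes one \code{multi}
#' record, which both spectra exclude. Isolated substitutions stay
#' \code{single}.
#'
#' @param records A \code{mutation_records} data frame of length-1
#'   substitutions.
#' @return A \code{mutation_records} data frame with \code{mclass} in
#'   \code{single}, \code{tandem}, \code{multi}.
#' @export
merge_tandems <- function(records) {
  df <- as.data.frame(records)
  if (nrow(df) == 0L) {
    df$mclass <- character(0)
    return(structure(df, class = c("mutation_records", "data.frame")))
  }
  stopifnot(all(nchar(df$ref) == 1L))
  o <- order(df$isolate, df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  new_run <- c(TRUE, !(df$isolate[-1] == df$isolate[-nrow(df)] &
                         df$chrom[-1] == df$chrom[-nrow(df)] &
                         df$pos[-1] == df$pos[-nrow(df)] + 1L))
  run_id <- cumsum(new_run)
  pieces <- split(df, run_id)
  out <- lapply(pieces, function(p) {
    k <- nrow(p)
    if (k == 1L) {
      p$mclass <- "single"
      p
    } else {
      data.frame(chrom = p$chrom[1], pos = p$pos[1],
                 ref = paste(p$ref, collapse = ""),
                 alt = paste(p$alt, collapse = ""),
                 isolate = p$isolate[1],
                 mclass = if (k == 2L) "tandem" else "multi",
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("mutation_records", "data.frame"))
}

#' @export
print.mutation_records <- function(x, ...) {
  cat("mutation_records:", nrow(x), "record(s),",
      length(unique(x$isolate)), "isolate(s)\n")
  if (nrow(x) > 0L && "mclass" %in% names(x)) {
    print(table(x$mclass))
  }
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L) cat(nrow(rej), "rejected record(s)\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more row(s)\n")
  invisible(x)
}
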