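#' Read a reference genome from FASTA
#'
#' Parses a FASTA file into a \code{genome} object: a named set of uppercase
#' chromosome sequences restricted to the alphabet A, C, G, T, N. Chromosome
#' names are taken verbatim from the FASTA headers up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return An object of class \code{genome}: a named character vector of
#'   uppercase sequences, one element per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "acgt"), fa)
#' g <- read_genome(fa)
#' genome_lengths(g)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA '", path, "': ",
                               conditionMessage(e))
    ),
    warning = function(w) {
      # Biostrings silently drops invalid letters; surface that as an error
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("malformed FASTA '", path, "': ", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) stop("malformed FASTA '", path, "': no records")
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names in '", path, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  names(x) <- nm
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(nm[bad], collapse = ", "))
  }
  structure(x, class = "genome")
}

#' Construct a genome object from named sequences
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @return A \code{genome} object.
#' @export
genome <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  x <- toupper(sequences)
  if (any(grepl("[^ACGTN]", x))) stop("non-ACGTN characters in sequences")
  structure(x, class = "genome")
}

#' Chromosome lengths of a genome
#'
#' @param g A \code{genome} object.
#' @return Named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "genome"))
  vapply(unclass(g), nchar, integer(1))
}

#' @export
print.genome <- function(x, ...) {
  len <- genome_lengths(x)
  cat("genome:", length(x), "chromosome(s),", format(sum(len), big.mark = ","),
      "bp total\n")
  for (i in seq_along(x)) cat(" ", names(x)[i], ":", len[i], "bp\n")
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param g A \code{genome} object.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, \code{path}.
#' @export
write_genome <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(g)) {
    writeLines(paste0(">", names(g)[i]), con)
    s <- unclass(g)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# reverse complement of a character vector of DNA strings (A/C/G/T/N)
revcomp <- function(x) {
  up <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(up, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", toupper(x))

is_pyrimidine <- function(base) base %in% c("C", "T")

#' Trinucleotide context at a genomic position
#'
#' Returns the reference 3-mer centred on \code{pos} (1-based), as read on the
#' top (reference) strand. Positions at a chromosome edge, or whose window
#' contains an N, have no defined context.
#'
#' @param g A \code{genome} object.
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s); recycled against \code{chrom}.
#' @return Character vector of 3-mers; \code{NA} where the context is
#'   unavailable (edge or N in window).
#' @export
get_trinucleotide_context <- function(g, chrom, pos) {
  stopifnot(inherits(g, "genome"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  unknown <- !(chrom %in% names(g))
  if (any(unknown)) stop("unknown chromosome(s): ",
                         paste(unique(chrom[unknown]), collapse = ", "))
  len <- genome_lengths(g)[chrom]
  ok <- pos >= 2L & pos <= len - 1L
  ctx <- rep(NA_character_, n)
  if (any(ok)) {
    ctx[ok] <- substring(unclass(g)[chrom[ok]], pos[ok] - 1L, pos[ok] + 1L)
  }
  ctx[!is.na(ctx) & grepl("N", ctx, fixed = TRUE)] <- NA_character_
  ctx
}

# reference base(s) at pos..pos+width-1 on the top strand
genome_slice <- function(g, chrom, pos, width = 1L) {
  substring(unclass(g)[chrom], pos, pos + width - 1L)
}
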