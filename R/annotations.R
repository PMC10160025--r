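#' Read stranded gene intervals
#'
#' Reads gene bodies (TSS to TES) either from a BED6 file (via rtracklayer)
#' or from a TSV with columns \code{chrom}, \code{start}, \code{end},
#' \code{strand} and optionally \code{name}. Intervals are stored 0-based
#' half-open (BED convention).
#'
#' @param path Path to a \code{.bed} file or a TSV.
#' @return A data frame of class \code{gene_intervals} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{name}.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading BED requires the 'rtracklayer' package")
    }
    gr <- rtracklayer::import(path, format = "BED")
    df <- as.data.frame(gr)
    out <- data.frame(chrom = as.character(df$seqnames),
                      start = df$start - 1L,  # GRanges is 1-based closed
                      end = df$end,
                      strand = as.character(df$strand),
                      name = if ("name" %in% names(df)) df$name else
                        paste0("gene", seq_len(nrow(df))),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    }
    out <- data.frame(chrom = as.character(tab$chrom),
                      start = as.integer(tab$start),
                      end = as.integer(tab$end),
                      strand = as.character(tab$strand),
                      name = if ("name" %in% names(tab)) tab$name else
                        paste0("gene", seq_len(nrow(tab))),
                      stringsAsFactors = FALSE)
  }
  gene_intervals(out)
}

#' Construct a gene_intervals object
#'
#' @param df Data frame with columns chrom, start (0-based), end (exclusive),
#'   strand ("+" or "-"), and optionally name.
#' @return A \code{gene_intervals} data frame.
#' @export
gene_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (!all(df$start < df$end)) stop("gene intervals must satisfy start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (is.null(df$name)) df$name <- paste0("gene", seq_len(nrow(df)))
  rownames(df) <- NULL
  structure(df[c("chrom", "start", "end", "strand", "name")],
            class = c("gene_intervals", "data.frame"))
}

#' Write gene intervals as BED6
#'
#' @param genes A \code{gene_intervals} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_genes_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$name,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read replication-origin coordinates
#'
#' Accepts a TSV with columns \code{chrom}, \code{pos} (0-based midpoint) or a
#' BED file, whose interval midpoints are used. Positions are sorted and must
#' be unique within each chromosome.
#'
#' @param path Path to a TSV or \code{.bed} file.
#' @return An \code{origin_map}: a data frame with columns \code{chrom} and
#'   \code{pos}, sorted, strictly increasing within chromosome.
#' @export
read_origins <- function(path) {
  if (!file.exists(path)) stop("origin file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    df <- data.frame(chrom = as.character(bed[[1]]),
                     pos = as.integer(floor((as.numeric(bed[[2]]) +
                                               as.numeric(bed[[3]])) / 2)),
                     stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos") %in% names(tab))) {
      stop("origin table must have columns: chrom, pos")
    }
    df <- data.frame(chrom = as.character(tab$chrom),
                     pos = as.integer(tab$pos), stringsAsFactors = FALSE)
  }
  origin_map(df)
}

#' Construct an origin_map
#'
#' @param df Data frame with columns chrom and pos (0-based origin midpoints).
#' @return An \code{origin_map} data frame, sorted by chromosome and position.
#' @export
origin_map <- function(df) {
  stopifnot(all(c("chrom", "pos") %in% names(df)))
  df <- df[order(df$chrom, df$pos), c("chrom", "pos"), drop = FALSE]
  dup <- unlist(tapply(df$pos, df$chrom, duplicated, simplify = FALSE))
  if (any(dup)) stop("origin positions must be strictly increasing per chromosome")
  rownames(df) <- NULL
  structure(df, class = c("origin_map", "data.frame"))
}

#' Write origins to TSV
#'
#' @param origins An \code{origin_map}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_origins <- function(origins, path) {
  utils::write.table(as.data.frame(origins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
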