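# Canonical substitution class spaces.
#
# Single-base substitutions are strand-collapsed so the mutated reference base
# is a pyrimidine: 6 substitution types x 16 trinucleotide contexts = 96
# channels. Doublet (tandem) substitutions are collapsed over reverse
# complement onto the standard 78-class space whose reference dinucleotides
# are {AC, AT, CC, CG, CT, GC, TA, TC, TG, TT}.

BASES <- c("A", "C", "G", "T")
SBS_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DBS_CANONICAL_REFS <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")

#' The 96 canonical single-base substitution classes
#'
#' @return Data frame with columns \code{substitution} (e.g. \code{"C>T"}),
#'   \code{context} (pyrimidine-centred 3-mer) and \code{label}
#'   (\code{"C>T@TCA"}), in fixed canonical order.
#' @export
sbs_classes <- function() {
  grid <- expand.grid(up = BASES, sub = SBS_TYPES, down = BASES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$sub, SBS_TYPES), grid$up, grid$down), ]
  ctx <- paste0(grid$up, substr(grid$sub, 1, 1), grid$down)
  data.frame(substitution = grid$sub, context = ctx,
             label = paste0(grid$sub, "@", ctx),
             stringsAsFactors = FALSE, row.names = NULL)
}

# all 144 valid doublet events ref>alt (both positions substituted)
all_doublet_events <- function() {
  refs <- as.vector(outer(BASES, BASES, paste0))
  ev <- expand.grid(ref = refs,
                    a1 = BASES, a2 = BASES, stringsAsFactors = FALSE)
  ev$alt <- paste0(ev$a1, ev$a2)
  ok <- substr(ev$ref, 1, 1) != ev$a1 & substr(ev$ref, 2, 2) != ev$a2
  ev[ok, c("ref", "alt")]
}

revcomp2 <- function(x) {
  # reverse complement of dinucleotides, vectorised
  paste0(complement_base(substr(x, 2, 2)), complement_base(substr(x, 1, 1)))
}

#' Canonicalize a doublet substitution
#'
#' Maps a tandem ref>alt event (as read on either strand) onto its canonical
#' class: the representation whose reference dinucleotide lies in the
#' canonical set \{AC, AT, CC, CG, CT, GC, TA, TC, TG, TT\}; for palindromic
#' reference dinucleotides (AT, CG, GC, TA), the lexicographically smaller of
#' the two equivalent alt dinucleotides.
#'
#' @param ref,alt Dinucleotide reference and alternate alleles (vectorised).
#' @return Canonical class labels, e.g. \code{"AC>TT"} (so \code{GT>AA}
#'   canonicalizes to \code{AC>TT}).
#' @export
canonicalize_tandem <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(all(nchar(ref) == 2L), all(nchar(alt) == 2L))
  rc_ref <- revcomp2(ref)
  rc_alt <- revcomp2(alt)
  flip <- !(ref %in% DBS_CANONICAL_REFS)
  out_ref <- ifelse(flip, rc_ref, ref)
  out_alt <- ifelse(flip, rc_alt, alt)
  pal <- out_ref == revcomp2(out_ref)
  rc_out_alt <- revcomp2(out_alt)
  swap <- pal & rc_out_alt < out_alt
  out_alt[swap] <- rc_out_alt[swap]
  paste0(out_ref, ">", out_alt)
}

#' The 78 canonical doublet substitution classes
#'
#' @return Character vector of the 78 canonical tandem class labels in fixed
#'   order (grouped by reference dinucleotide).
#' @export
tandem_classes <- function() {
  ev <- all_doublet_events()
  lab <- unique(canonicalize_tandem(ev$ref, ev$alt))
  sort(lab)
}

#' Classify single-base substitutions into the 96-channel space
#'
#' Applies pyrimidine strand-collapse: if the reference base is a purine, both
#' the substitution and its trinucleotide context are reverse-complemented
#' before classification.
#'
#' @param records A \code{mutation_records} data frame; only rows with
#'   \code{mclass == "single"} are meaningful here.
#' @param genome The \code{genome} contexts are read from.
#' @return Data frame with one row per input record: \code{substitution},
#'   \code{context}, \code{label} (\code{NA} where the context is unavailable:
#'   chromosome edge or N in the window).
#' @export
classify_single <- function(records, genome) {
  df <- as.data.frame(records)
  ctx <- get_trinucleotide_context(genome, df$chrom, df$pos)
  ref <- toupper(df$ref); alt <- toupper(df$alt)
  pur <- !is_pyrimidine(ref)
  sub <- ifelse(pur,
                paste0(complement_base(ref), ">", complement_base(alt)),
                paste0(ref, ">", alt))
  out_ctx <- ctx
  if (any(pur & !is.na(ctx))) {
    i <- which(pur & !is.na(ctx))
    out_ctx[i] <- revcomp(ctx[i])
  }
  lab <- ifelse(is.na(out_ctx), NA_character_, paste0(sub, "@", out_ctx))
  data.frame(substitution = ifelse(is.na(out_ctx), NA_character_, sub),
             context = out_ctx, label = lab, stringsAsFactors = FALSE)
}

#' Classify tandem substitutions into the 78-channel space
#'
#' @param records A \code{mutation_records} data frame; rows with
#'   \code{mclass == "tandem"} (2-bp ref/alt).
#' @param genome Unused (alleles carry all information); kept for interface
#'   symmetry with [classify_single()].
#' @return Character vector of canonical tandem labels (e.g. \code{"AC>TT"}).
#' @export
classify_tandem <- function(records, genome = NULL) {
  df <- as.data.frame(records)
  canonicalize_tandem(df$ref, df$alt)
}
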