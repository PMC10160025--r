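# Shared fixtures, built in code.

toy_genome <- function(seqs = c(chrT = "ACGTACGTTCAGGA")) {
  genome(seqs)
}

# one small synthetic reference + site index, reused across test files
shared_cfg <- synthetic_config(seed = 42L, n_chroms = 2L,
                               chrom_length = 60000L, n_genes = 15L,
                               gene_length = 1500L, n_origins = 4L,
                               n_isolates = 6L, mutations_per_isolate = 120)
shared_ref <- generate_reference(shared_cfg)
shared_index <- build_site_index(shared_ref)

make_records <- function(chrom, pos, ref, alt, isolate = "i1",
                         mclass = "single") {
  structure(data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                       alt = alt, isolate = isolate, mclass = mclass,
                       stringsAsFactors = FALSE),
            class = c("mutation_records", "data.frame"))
}

# independent reverse-complement oracle: explicit base map, no package code
oracle_rc <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(s, ""), function(ch) paste(rev(unname(map[ch])),
                                             collapse = ""), character(1))
}

# independent strand-collapse oracle: explicit reverse-complement rules
oracle_classify_single <- function(ref, alt, ctx) {
  if (ref %in% c("C", "T")) {
    list(sub = paste0(ref, ">", alt), ctx = ctx)
  } else {
    list(sub = paste0(oracle_rc(ref), ">", oracle_rc(alt)),
         ctx = oracle_rc(ctx))
  }
}

# oracle canonical tandem label: enumerate the reverse-complement pair and
# pick the member whose ref is in the documented canonical set (tie-broken
# lexicographically on alt for palindromic refs)
oracle_canonical_tandem <- function(ref, alt) {
  canon_refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  cand <- list(c(ref, alt), c(oracle_rc(ref), oracle_rc(alt)))
  keep <- Filter(function(x) x[1] %in% canon_refs, cand)
  labs <- sort(unique(vapply(keep, function(x) paste0(x[1], ">", x[2]),
                             character(1))))
  labs[1]
}
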