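# Independent oracles. These deliberately take a different implementation
# route from the package: the filter oracle is a scalar re-statement of the
# three post-alignment rules, and the alignment oracle is an exhaustive
# offset/strand scan delegated to Biostrings::matchPattern.

# Post-alignment filter, re-stated rule by rule on one record: discard
# low-quality (MAPQ < 5), any non-perfect-match CIGAR operation
# (insertion, deletion, skipped region, soft/hard clip), and more than
# three mismatches.
oracle_passes_one <- function(mapq, cigar, nm) {
  if (mapq < 5) return(FALSE)
  ops <- strsplit(gsub("[0-9]", "", cigar), "")[[1L]]
  if (any(ops %in% c("I", "D", "N", "S", "H"))) return(FALSE)
  if (nm > 3) return(FALSE)
  TRUE
}

# All loci of `read` on the catalog with at most `max_mm` mismatches,
# found by exhaustive scan (both strands, every offset).
oracle_align <- function(read, catalog, max_mm = 3) {
  ids <- catalog_ids(catalog)
  out <- list()
  for (gi in seq_along(ids)) {
    subject <- Biostrings::DNAString(catalog$sequences[[gi]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else revcomp(read)
      m <- Biostrings::matchPattern(Biostrings::DNAString(q), subject,
                                    max.mismatch = max_mm, with.indels = FALSE)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m)
      mm <- vapply(starts, function(s)
        Biostrings::neditStartingAt(Biostrings::DNAString(q), subject,
                                    starting.at = s), integer(1))
      out[[length(out) + 1L]] <- data.frame(
        genome_id = ids[gi], pos = starts,
        is_reverse = strand == "-", mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(genome_id = character(0), pos = integer(0),
                      is_reverse = logical(0), mismatches = integer(0)))
  do.call(rbind, out)
}

# Canonical key for comparing hit sets.
hit_key <- function(df) {
  sort(sprintf("%s:%d:%s:%d", df$genome_id, df$pos,
               ifelse(df$is_reverse, "-", "+"), df$mismatches))
}
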