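# Built-in ungapped test aligner. Production alignment is delegated to an
# external short-read aligner (Bowtie2/BWA/Minimap2) whose SAM output is
# consumed via read_sam(); this native aligner exists so that the whole
# pipeline is exercisable on synthetic data with no external binaries.

#' Align reads against a catalog (built-in ungapped aligner)
#'
#' Exact-match seeding on non-overlapping k-mers of the read (plus a k-mer
#' anchored at the read's 3' end), on both strands, against a hash index of
#' all catalog k-mers; every candidate locus is extended by full-length
#' Hamming comparison and reported. Since the number of seeds is at least
#' `floor(read_length / seed_length)`, any locus with fewer mismatches than
#' seeds is guaranteed to be found (pigeonhole); for the default seed length
#' 21 and reads of 84+ bases this covers every locus within the pipeline's
#' 3-mismatch budget.
#'
#' Reported records carry `cigar = "<len>M"`, `mismatches` = Hamming
#' distance, `align_score = len - 5 * mismatches`, and `mapq = 60` for every
#' mapped record, so downstream MAPQ filtering never masks best-alignment
#' selection when testing. Reads with no seed hit (including reads shorter
#' than `seed_length`) yield one unmapped record.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param catalog a `cohort_catalog`; sequences must be N-free (guaranteed
#'   by [normalize_genome()]).
#' @param seed_length k-mer size for seeding, at least 11. Default 21.
#' @return an alignment-record table ([alignment_records()]), one or more
#'   rows per read.
#' @export
builtin_align <- function(reads, catalog, seed_length = 21L) {
  stopifnot(inherits(catalog, "cohort_catalog"))
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop_invalid("builtin_align(): reads must be a named character vector")
  if (seed_length < 11L)
    stop_invalid("builtin_align(): seed_length must be >= 11")
  if (any(grepl("N", catalog$sequences, fixed = TRUE)))
    stop_invalid("builtin_align(): catalog sequences must be N-free (normalize first)")
  hits <- cpp_builtin_align(names(reads), unname(toupper(reads)),
                            catalog$manifest$genome_id,
                            unname(catalog$sequences),
                            as.integer(seed_length))
  alignment_records(
    read_id = hits$read_id,
    genome_id = hits$genome_id,
    pos = hits$pos,
    mapq = ifelse(hits$is_mapped, 60L, 0L),
    cigar = ifelse(hits$is_mapped, sprintf("%dM", hits$read_len), NA_character_),
    mismatches = hits$mismatches,
    align_score = hits$align_score,
    is_mapped = hits$is_mapped,
    is_secondary_or_supplementary = FALSE,
    is_reverse = hits$is_reverse,
    mate = 0L)
}
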