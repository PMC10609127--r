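# Read-level QC and post-alignment filtering. The defaults reproduce the
# pipeline's thresholds exactly: reads shorter than 60 bases or containing
# any N are discarded before alignment; alignment records with MAPQ < 5,
# a non-perfect-match CIGAR (insertion, deletion, skipped region, soft or
# hard clipping) or more than three mismatches are discarded afterwards;
# of a read's surviving alignments only the best is kept.

#' Filtering thresholds
#'
#' @param mapq_min minimum mapping quality; records with MAPQ below this are
#'   low-quality and dropped. Default 5.
#' @param max_mismatches maximum NM-tag mismatch count. Default 3.
#' @param forbidden_cigar_ops CIGAR operations that disqualify a record;
#'   the default forbids insertions, deletions, skipped regions and soft/hard
#'   clips, leaving only match operations (M/=/X).
#' @param read_min_len minimum read length at QC. Default 60.
#' @param max_n_bases maximum number of N bases tolerated in a read at QC.
#'   Default 0.
#' @return a `filter_config` list.
#' @export
filter_config <- function(mapq_min = 5L, max_mismatches = 3L,
                          forbidden_cigar_ops = c("I", "D", "N", "S", "H"),
                          read_min_len = 60L, max_n_bases = 0L) {
  stopifnot(mapq_min >= 0, max_mismatches >= 0, read_min_len >= 1,
            max_n_bases >= 0)
  structure(list(mapq_min = as.integer(mapq_min),
                 max_mismatches = as.integer(max_mismatches),
                 forbidden_cigar_ops = as.character(forbidden_cigar_ops),
                 read_min_len = as.integer(read_min_len),
                 max_n_bases = as.integer(max_n_bases)),
            class = "filter_config")
}

#' Read-level quality control
#'
#' Keep a read iff it is at least `read_min_len` bases long and contains at
#' most `max_n_bases` N characters (defaults: 60 and 0, i.e. any N drops the
#' read).
#'
#' @param sequences character vector of read sequences.
#' @param config a [filter_config()].
#' @return logical vector, `TRUE` = keep.
#' @export
qc_read <- function(sequences, config = filter_config()) {
  if (any(!nzchar(sequences))) stop_invalid("qc_read(): empty sequence")
  nchar(sequences) >= config$read_min_len &
    count_n_bases(sequences) <= config$max_n_bases
}

cigar_ops <- function(cigar) {
  ok <- grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(!ok))
    stop_parse(sprintf("unparsable CIGAR string '%s'", cigar[!ok][1L]))
  gsub("[0-9]+", "", cigar)
}

#' Post-alignment record filter
#'
#' A mapped record passes iff its MAPQ is at least `mapq_min`, its CIGAR
#' contains none of the forbidden operations (so only match operations
#' remain), and its mismatch count is at most `max_mismatches`.
#'
#' @param records mapped alignment-record table ([alignment_records()]).
#' @param config a [filter_config()].
#' @return logical vector, `TRUE` = record survives.
#' @export
passes_filters <- function(records, config = filter_config()) {
  if (nrow(records) == 0L) return(logical(0))
  if (any(!records$is_mapped))
    stop_invalid("passes_filters(): unmapped records in input")
  if (anyNA(records$mismatches))
    stop_invalid("passes_filters(): mismatch count (NM tag) missing on a mapped record")
  ops <- cigar_ops(records$cigar)
  forbidden <- if (length(config$forbidden_cigar_ops) > 0L)
    grepl(sprintf("[%s]", paste(config$forbidden_cigar_ops, collapse = "")), ops)
  else rep(FALSE, nrow(records))
  records$mapq >= config$mapq_min & !forbidden &
    records$mismatches <= config$max_mismatches
}

# Deterministic best-alignment ordering shared by select_best(),
# best_records() and merge_subdb(): higher align_score first (records
# lacking a score rank below any scored record), then fewer mismatches,
# then lexicographically smallest (genome_id, pos).
best_order <- function(records) {
  score_key <- ifelse(is.na(records$align_score), -Inf,
                      as.numeric(records$align_score))
  order(records$read_id, -score_key, records$mismatches,
        records$genome_id, records$pos, method = "radix")
}

#' Select the best alignment of one read
#'
#' Among a read's surviving alignment records, keep only the best one.
#' The ordering is fully deterministic: higher alignment score first
#' (records lacking a score rank below any with one), then fewer
#' mismatches, then smallest (`genome_id`, `pos`).
#'
#' @param records alignment records of a single read (all sharing one
#'   `read_id`); may have zero rows.
#' @return a one-row `data.frame`, or `NULL` for empty input.
#' @export
select_best <- function(records) {
  if (nrow(records) == 0L) return(NULL)
  if (length(unique(records$read_id)) != 1L)
    stop_invalid("select_best(): records with mixed read_ids")
  records[best_order(records)[1L], , drop = FALSE]
}

#' Per-read best surviving alignments of a stream
#'
#' Applies [passes_filters()] to every mapped candidate record (primary,
#' secondary and supplementary alike are treated as mapping positions) and
#' keeps each read's [select_best()] winner.
#'
#' @param records alignment-record table; may contain unmapped records.
#' @param config a [filter_config()].
#' @param ids character vector of valid genome ids; mapped records naming a
#'   genome outside this set raise an error (catalog/alignment mismatch).
#' @return a `data.frame` of one winning record per surviving read, with the
#'   genome id universe attached as attribute `catalog_ids`.
#' @export
best_records <- function(records, config = filter_config(), ids = NULL) {
  mapped <- records[records$is_mapped, , drop = FALSE]
  if (!is.null(ids)) {
    alien <- setdiff(unique(mapped$genome_id), ids)
    if (length(alien) > 0L)
      stop_invalid(sprintf(
        "alignment references genome_id(s) absent from the catalog: %s",
        paste(utils::head(alien, 5L), collapse = ", ")))
  }
  keep <- mapped[passes_filters(mapped, config), , drop = FALSE]
  if (nrow(keep) > 0L) {
    o <- best_order(keep)
    keep <- keep[o, , drop = FALSE]
    keep <- keep[!duplicated(keep$read_id), , drop = FALSE]
    rownames(keep) <- NULL
  }
  attr(keep, "catalog_ids") <- ids
  keep
}

#' Count mapped reads per genome
#'
#' The numerator of the mapping rate: each read contributes at most once,
#' to the genome of its best surviving alignment.
#'
#' @param records alignment-record table for one sample (may contain
#'   unmapped, secondary and supplementary records).
#' @param ids genome id universe (e.g. [catalog_ids()]).
#' @param config a [filter_config()].
#' @param total_reads number of QC-passed reads that entered alignment (the
#'   mapping-rate denominator); must be at least the number of distinct
#'   reads in the stream.
#' @return a `count_result`: list with `per_genome_mapped` (named integer
#'   over all of `ids`), `total_reads` and `reads_kept`.
#' @export
count_mapped <- function(records, ids, config = filter_config(), total_reads) {
  n_reads <- length(unique(records$read_id))
  if (total_reads < n_reads)
    stop_invalid(sprintf(
      "count_mapped(): total_reads (%d) < distinct reads in stream (%d)",
      total_reads, n_reads))
  best <- best_records(records, config, ids)
  counts <- table(factor(best$genome_id, levels = ids))
  count_result(stats::setNames(as.integer(counts), ids),
               total_reads = total_reads)
}

#' Construct a per-genome count result
#'
#' @param per_genome_mapped named integer vector over the catalog's genome
#'   ids.
#' @param total_reads mapping-rate denominator.
#' @return a `count_result` list.
#' @export
count_result <- function(per_genome_mapped, total_reads) {
  if (is.null(names(per_genome_mapped)))
    stop_invalid("count_result(): per_genome_mapped must be named")
  reads_kept <- sum(per_genome_mapped)
  if (reads_kept > total_reads)
    stop_invalid("count_result(): reads_kept exceeds total_reads")
  structure(list(per_genome_mapped = per_genome_mapped,
                 total_reads = as.numeric(total_reads),
                 reads_kept = as.numeric(reads_kept)),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %s of %s reads kept across %d genomes\n",
              format(x$reads_kept, big.mark = ","),
              format(x$total_reads, big.mark = ","),
              length(x$per_genome_mapped)))
  invisible(x)
}
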