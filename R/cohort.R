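# Cohort-level aggregation: pooling per-sample counts, integrating
# sub-database results, ranking genomes by mapping rate, saturation curves,
# and emitting the top-N cohort-specific reference.

#' Pool per-sample counts into a mapping-rate table
#'
#' Cross-sample aggregation is pooled-counts: the pooled numerator is the
#' per-genome sum of mapped reads and the pooled denominator the sum of
#' total reads, which keeps deeply sequenced samples from being diluted by
#' shallow ones (pooling, not averaging of per-sample rates). Rows are
#' sorted by mapping rate descending, ties broken by `genome_id` ascending.
#'
#' @param per_sample list of `count_result`s keyed against the same catalog;
#'   names, if present, become the table's `sample_ids`.
#' @return a `mapping_rate_table`: `data.frame` with columns `genome_id`,
#'   `mapped_reads`, `mapping_rate`, plus attributes `total_reads` and
#'   `sample_ids`.
#' @export
pool_samples <- function(per_sample) {
  if (length(per_sample) == 0L) stop_invalid("pool_samples(): empty sample list")
  stopifnot(all(vapply(per_sample, inherits, logical(1), "count_result")))
  keys <- lapply(per_sample, function(s) names(s$per_genome_mapped))
  for (i in seq_along(keys)[-1L]) {
    if (!setequal(keys[[i]], keys[[1L]])) {
      d <- union(setdiff(keys[[i]], keys[[1L]]), setdiff(keys[[1L]], keys[[i]]))
      stop_invalid(sprintf(
        "pool_samples(): inconsistent genome key sets; symmetric difference: %s",
        paste(utils::head(d, 10L), collapse = ", ")))
    }
  }
  ids <- keys[[1L]]
  mapped <- Reduce(`+`, lapply(per_sample,
                               function(s) s$per_genome_mapped[ids]))
  total <- sum(vapply(per_sample, `[[`, numeric(1), "total_reads"))
  sample_ids <- names(per_sample) %||% paste0("sample", seq_along(per_sample))
  mapping_rate_table(ids, unname(mapped), total, sample_ids)
}

#' Construct a mapping-rate table
#'
#' @param ids genome ids.
#' @param mapped_reads per-genome mapped-read counts, aligned with `ids`.
#' @param total_reads denominator (QC-passed reads entering alignment).
#' @param sample_ids identifiers of the contributing samples.
#' @return a `mapping_rate_table` (see [pool_samples()]).
#' @export
mapping_rate_table <- function(ids, mapped_reads, total_reads,
                               sample_ids = character(0)) {
  if (total_reads <= 0) stop_invalid("mapping_rate_table(): total_reads must be > 0")
  df <- data.frame(genome_id = as.character(ids),
                   mapped_reads = as.numeric(mapped_reads),
                   mapping_rate = as.numeric(mapped_reads) / total_reads,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$mapping_rate, df$genome_id, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, total_reads = as.numeric(total_reads),
            sample_ids = as.character(sample_ids),
            class = c("mapping_rate_table", "data.frame"))
}

#' @export
as.data.frame.mapping_rate_table <- function(x, ...) {
  data.frame(genome_id = x$genome_id, mapped_reads = x$mapped_reads,
             mapping_rate = x$mapping_rate, stringsAsFactors = FALSE)
}

#' Integrate per-read best records across sub-databases
#'
#' When the basic reference database is aligned against as disjoint
#' sub-databases (see [split_catalog()]), each pass yields each read's best
#' surviving alignment within that sub-database. This re-runs best-alignment
#' selection across the per-sub-database winners, so the result is by
#' construction equal to a single monolithic run with the same aligner
#' output.
#'
#' @param per_subdb list of best-record tables (output of [best_records()],
#'   one per sub-database, each carrying its `catalog_ids` attribute).
#' @param config a [filter_config()] (records are already filtered; kept for
#'   interface symmetry with [count_mapped()]).
#' @param total_reads mapping-rate denominator for the sample.
#' @return a `count_result` over the union of the sub-database genome ids.
#' @export
merge_subdb <- function(per_subdb, config = filter_config(), total_reads) {
  if (length(per_subdb) == 0L) stop_invalid("merge_subdb(): empty input")
  id_sets <- lapply(per_subdb, attr, "catalog_ids")
  if (any(vapply(id_sets, is.null, logical(1))))
    stop_invalid("merge_subdb(): best-record tables must carry catalog_ids")
  all_ids <- unlist(id_sets)
  if (anyDuplicated(all_ids))
    stop_invalid(sprintf("merge_subdb(): genome_id(s) shared between sub-databases: %s",
                         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  pooled <- do.call(rbind, lapply(per_subdb, function(df) {
    attr(df, "catalog_ids") <- NULL
    df
  }))
  if (nrow(pooled) > 0L) {
    o <- best_order(pooled)
    pooled <- pooled[o, , drop = FALSE]
    pooled <- pooled[!duplicated(pooled$read_id), , drop = FALSE]
  }
  counts <- table(factor(pooled$genome_id, levels = all_ids))
  count_result(stats::setNames(as.integer(counts), all_ids), total_reads)
}

#' Select the top-N genomes as a cohort-specific reference
#'
#' Takes the first `n` genomes of the ranked table. Genomes with zero mapped
#' reads carry no ranking information and are excluded from the ranking
#' proper; they are used only to pad (in `genome_id` order, with a message)
#' when fewer than `n` genomes have nonzero counts.
#'
#' @param table a `mapping_rate_table`.
#' @param n number of genomes to keep (the pipeline's default output size is
#'   1000).
#' @return a `cohort_reference`: list with `genome_ids` (ranked),
#'   `n`, `cumulative_rate` and the selected table `rows`.
#' @export
top_n_genomes <- function(table, n = 1000L) {
  stopifnot(inherits(table, "mapping_rate_table"))
  if (nrow(table) == 0L) stop_invalid("top_n_genomes(): empty table")
  if (n < 1L) stop_invalid("top_n_genomes(): n must be >= 1")
  nonzero <- table[table$mapped_reads > 0, , drop = FALSE]
  zero <- table[table$mapped_reads == 0, , drop = FALSE]
  take <- min(n, nrow(nonzero))
  sel <- nonzero[seq_len(take), , drop = FALSE]
  if (take < min(n, nrow(table))) {
    pad <- zero[order(zero$genome_id), , drop = FALSE]
    pad <- pad[seq_len(min(n - take, nrow(pad))), , drop = FALSE]
    message(sprintf(
      "top_n_genomes(): only %d genomes have nonzero counts; padding with %d zero-count genomes",
      take, nrow(pad)))
    sel <- rbind(sel, pad)
  }
  rownames(sel) <- NULL
  structure(list(genome_ids = sel$genome_id, n = as.integer(n),
                 cumulative_rate = sum(sel$mapping_rate),
                 rows = as.data.frame(sel)),
            class = "cohort_reference")
}

#' @export
print.cohort_reference <- function(x, ...) {
  cat(sprintf("<cohort_reference> top %d genomes, cumulative mapping rate %.4f\n",
              length(x$genome_ids), x$cumulative_rate))
  invisible(x)
}

#' Cumulative mapping rate captured by the top-k genomes
#'
#' The saturation curve used to choose the reference size N: the mapping-rate
#' mass captured by the k best-ranked genomes, for k = 1..rows. Monotone
#' non-decreasing; its final value is `reads_kept / total_reads`.
#'
#' @param table a `mapping_rate_table`.
#' @return `data.frame` with columns `k` and `cumulative_rate`.
#' @export
saturation_curve <- function(table) {
  stopifnot(inherits(table, "mapping_rate_table"))
  data.frame(k = seq_len(nrow(table)),
             cumulative_rate = cumsum(table$mapping_rate))
}

#' Emit the cohort-specific reference FASTA
#'
#' Writes one FASTA record per selected genome, in ranked order, with
#' sequences byte-identical to the catalog (already gap-free), plus a
#' sidecar TSV with rank, genome_id, mapped_reads and mapping_rate.
#'
#' @param catalog the basic reference `cohort_catalog`.
#' @param ref a `cohort_reference` ([top_n_genomes()]).
#' @param out_fasta output FASTA path.
#' @param out_table optional sidecar TSV path (default: `out_fasta` with a
#'   `.tsv` extension appended).
#' @return invisibly, the emitted sub-catalog.
#' @export
emit_reference <- function(catalog, ref, out_fasta,
                           out_table = paste0(out_fasta, ".tsv")) {
  stopifnot(inherits(ref, "cohort_reference"))
  sub <- catalog_subset(catalog, ref$genome_ids)  # errors on missing ids
  ss <- Biostrings::DNAStringSet(sub$sequences)
  names(ss) <- sub$manifest$genome_id
  Biostrings::writeXStringSet(ss, filepath = out_fasta, width = 80L)
  sidecar <- cbind(rank = seq_len(nrow(ref$rows)), ref$rows)
  utils::write.table(sidecar, out_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sub)
}

#' Write / read a mapping-rate table as TSV
#'
#' @param table a `mapping_rate_table`.
#' @param path TSV path.
#' @return `write_rate_table()` returns `path` invisibly;
#'   `read_rate_table()` returns a `mapping_rate_table`.
#' @export
write_rate_table <- function(table, path) {
  stopifnot(inherits(table, "mapping_rate_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_reads=%s\tsamples=%s",
                     format(attr(table, "total_reads"), scientific = FALSE),
                     paste(attr(table, "sample_ids"), collapse = ",")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# total_reads="))
    stop_parse(sprintf("read_rate_table(): '%s' lacks the total_reads header", path))
  total <- as.numeric(sub("# total_reads=([0-9.eE+]+)\t.*", "\\1", first))
  samples <- strsplit(sub(".*\tsamples=", "", first), ",", fixed = TRUE)[[1L]]
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  mapping_rate_table(df$genome_id, df$mapped_reads, total, samples)
}
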