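# Genome catalog: normalization of raw reference genomes (gap removal,
# segment concatenation) into single-sequence records, manifest I/O, and
# sub-database splitting.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Normalize a raw genome into a single gap-free sequence
#'
#' Assemblies deposited as chromosomes, scaffolds or contigs are reduced to
#' one complete sequence per genome: segments are uppercased, concatenated in
#' input order, and every `N` character (assembly gaps are runs of `N`) is
#' removed. Non-`N` IUPAC ambiguity codes are retained, since removing them
#' would delete real sequence. The result is the form used both for alignment
#' and as a compression reference.
#'
#' @param segments character vector of nucleotide sequences (the genome's
#'   segments, in assembly order). Whitespace is stripped.
#' @param genome_id unique identifier for the genome.
#' @param label free-text taxon/assembly description.
#' @param source optional accession string.
#' @return a `genome_record`: list with `genome_id`, `label`, `sequence`
#'   (uppercase, N-free), `length`, `segment_count`, `source`.
#' @examples
#' normalize_genome(c("ACGTNNNN", "NNGGCC"), "g2")$sequence  # "ACGTGGCC"
#' @export
normalize_genome <- function(segments, genome_id, label = "", source = NA_character_) {
  if (length(segments) == 0L)
    stop_invalid("normalize_genome(): empty segment list")
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop_invalid("normalize_genome(): genome_id must be a non-empty string")
  segments <- gsub("[[:space:]]", "", segments)
  if (any(!nzchar(segments)))
    stop_invalid(sprintf(
      "normalize_genome(): segment %d of '%s' is empty",
      which(!nzchar(segments))[1L], genome_id))
  segments <- toupper(segments)
  at <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), segments)
  bad_idx <- which(at > 0L)
  if (length(bad_idx) > 0L) {
    i <- bad_idx[1L]
    stop_invalid(sprintf(
      "normalize_genome(): non-IUPAC character '%s' in segment %d of '%s'",
      substr(segments[i], at[i], at[i]), i, genome_id))
  }
  seq <- gsub("N", "", paste(segments, collapse = ""), fixed = TRUE)
  if (!nzchar(seq))
    stop_invalid(sprintf(
      "normalize_genome(): genome '%s' is empty after gap removal", genome_id))
  structure(
    list(genome_id = genome_id, label = label, sequence = seq,
         length = nchar(seq), segment_count = length(segments),
         source = source),
    class = "genome_record")
}

#' Build a catalog from genome records
#'
#' @param records list of `genome_record` objects (see [normalize_genome()]).
#' @return a `cohort_catalog`: manifest `data.frame` plus named sequence
#'   vector; iteration order is the manifest order.
#' @export
catalog <- function(records) {
  if (length(records) == 0L) stop_invalid("catalog(): no genome records")
  ids <- vapply(records, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids))
    stop_invalid(sprintf("catalog(): duplicate genome_id '%s'",
                         ids[duplicated(ids)][1L]))
  manifest <- data.frame(
    genome_id = ids,
    label = vapply(records, `[[`, character(1), "label"),
    length = vapply(records, `[[`, integer(1), "length"),
    segment_count = vapply(records, `[[`, integer(1), "segment_count"),
    source = vapply(records, function(r) as.character(r$source), character(1)),
    stringsAsFactors = FALSE)
  sequences <- vapply(records, `[[`, character(1), "sequence")
  names(sequences) <- ids
  structure(list(manifest = manifest, sequences = sequences),
            class = "cohort_catalog")
}

#' @export
print.cohort_catalog <- function(x, ...) {
  cat(sprintf("<cohort_catalog> %d genomes, %s bases\n",
              nrow(x$manifest), format(total_bases(x), big.mark = ",")))
  print(utils::head(x$manifest, 10L))
  invisible(x)
}

#' @export
length.cohort_catalog <- function(x) nrow(x$manifest)

#' Total bases in a catalog
#' @param x a `cohort_catalog`.
#' @return integer-valued numeric, sum of genome lengths.
#' @export
total_bases <- function(x) sum(as.numeric(x$manifest$length))

#' Genome identifiers of a catalog
#' @param x a `cohort_catalog`.
#' @return character vector in manifest order.
#' @export
catalog_ids <- function(x) x$manifest$genome_id

# Subset a catalog to `ids`, in the given order.
catalog_subset <- function(x, ids) {
  missing <- setdiff(ids, x$manifest$genome_id)
  if (length(missing) > 0L)
    stop_invalid(sprintf("genome_id(s) not in catalog: %s",
                         paste(missing, collapse = ", ")))
  idx <- match(ids, x$manifest$genome_id)
  structure(list(manifest = x$manifest[idx, , drop = FALSE],
                 sequences = x$sequences[idx]),
            class = "cohort_catalog")
}

strip_fasta_ext <- function(path) {
  b <- basename(path)
  b <- sub("\\.gz$", "", b)
  sub("\\.(fa|fasta|fna)$", "", b)
}

#' Load a genome catalog from FASTA files
#'
#' Without a manifest, each FASTA file is one genome: all its records are the
#' genome's segments in file order, and the file name (without extension)
#' becomes the `genome_id`. With a manifest, FASTA record IDs are grouped
#' into genomes explicitly, so multi-segment genomes may share a file.
#' All genomes are normalized via [normalize_genome()] (uppercase, gap
#' removal, concatenation).
#'
#' @param fasta_paths character vector of FASTA paths (gzip allowed).
#' @param manifest_path optional TSV with a `genome_id` column and optional
#'   `record_id` (defaults to `genome_id`), `label` and `source` columns.
#'   Row order defines genome order and segment order within a genome.
#' @return a `cohort_catalog`.
#' @export
load_catalog <- function(fasta_paths, manifest_path = NULL) {
  if (length(fasta_paths) == 0L) stop_invalid("load_catalog(): no FASTA paths")
  unreadable <- fasta_paths[!file.exists(fasta_paths)]
  if (length(unreadable) > 0L)
    stop_io(sprintf("load_catalog(): cannot read '%s'", unreadable[1L]))

  read_one <- function(p) {
    ss <- tryCatch(Biostrings::readDNAStringSet(p),
                   error = function(e) stop_parse(sprintf(
                     "load_catalog(): failed to parse FASTA '%s': %s",
                     p, conditionMessage(e))))
    if (length(ss) == 0L)
      stop_parse(sprintf("load_catalog(): no records in '%s'", p))
    ids <- sub("\\s.*$", "", names(ss))
    list(ids = ids, seqs = as.character(ss))
  }
  parsed <- lapply(fasta_paths, read_one)

  if (is.null(manifest_path)) {
    gids <- vapply(fasta_paths, strip_fasta_ext, character(1))
    if (anyDuplicated(gids))
      stop_invalid(sprintf("load_catalog(): duplicate genome_id '%s' (file names collide)",
                           gids[duplicated(gids)][1L]))
    records <- Map(function(p, gid) {
      normalize_genome(p$seqs, gid, label = gid)
    }, parsed, gids)
    return(catalog(records))
  }

  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"genome_id" %in% names(man))
    stop_parse("load_catalog(): manifest lacks a genome_id column")
  if (!"record_id" %in% names(man)) man$record_id <- man$genome_id
  all_ids <- unlist(lapply(parsed, `[[`, "ids"))
  all_seqs <- unlist(lapply(parsed, `[[`, "seqs"))
  if (anyDuplicated(all_ids))
    stop_invalid(sprintf("load_catalog(): duplicate FASTA record id '%s'",
                         all_ids[duplicated(all_ids)][1L]))
  names(all_seqs) <- all_ids
  missing <- setdiff(man$record_id, all_ids)
  if (length(missing) > 0L)
    stop_invalid(sprintf("load_catalog(): manifest record_id(s) not found in FASTA: %s",
                         paste(utils::head(missing, 5L), collapse = ", ")))
  gid_order <- unique(man$genome_id)
  records <- lapply(gid_order, function(gid) {
    rows <- man[man$genome_id == gid, , drop = FALSE]
    normalize_genome(all_seqs[rows$record_id], gid,
                     label = if ("label" %in% names(rows)) rows$label[1L] else gid,
                     source = if ("source" %in% names(rows)) rows$source[1L] else NA_character_)
  })
  catalog(records)
}

#' Load a multi-FASTA where each record is one genome
#'
#' The convention of emitted cohort references ([emit_reference()]) and of
#' [write_catalog()] output: one record per genome, record id = `genome_id`.
#' Records are normalized individually (single segment each).
#'
#' @param path FASTA path (gzip allowed).
#' @return a `cohort_catalog` in record order.
#' @export
load_reference_fasta <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("load_reference_fasta(): no such file '%s'", path))
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop_parse(sprintf(
                   "load_reference_fasta(): failed to parse '%s': %s",
                   path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(ss))
  catalog(Map(normalize_genome, as.character(ss), ids, label = ids))
}

#' Write a catalog as FASTA plus manifest
#'
#' Emits one FASTA record per genome (header = `genome_id`, sequence wrapped
#' at 80 columns) and a tab-separated manifest with columns
#' `genome_id`, `label`, `length`, `segment_count`, `source`. The pair
#' round-trips through [load_catalog()] on (id, sequence, order).
#'
#' @param x a `cohort_catalog`.
#' @param out_fasta,out_manifest output paths.
#' @return invisibly, `x`.
#' @export
write_catalog <- function(x, out_fasta, out_manifest) {
  stopifnot(inherits(x, "cohort_catalog"))
  if (length(x) == 0L) stop_invalid("write_catalog(): empty catalog")
  ss <- Biostrings::DNAStringSet(x$sequences)
  names(ss) <- x$manifest$genome_id
  tryCatch({
    Biostrings::writeXStringSet(ss, filepath = out_fasta, width = 80L)
    utils::write.table(x$manifest, out_manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, error = function(e) stop_io(conditionMessage(e)))
  invisible(x)
}

#' Split a catalog into balanced sub-databases
#'
#' When memory is restricted, a large reference database can be aligned
#' against as `k` sub-databases and the per-read results integrated
#' afterwards (see [merge_subdb()]). The partition is deterministic greedy
#' balancing on total bases: genomes are taken largest-first (ties broken by
#' `genome_id` order) and each is assigned to the currently lightest
#' sub-catalog, since index memory scales with bases rather than genome
#' count.
#'
#' @param x a `cohort_catalog`.
#' @param k number of sub-catalogs, `1 <= k <= length(x)`.
#' @return list of `k` `cohort_catalog`s; a disjoint cover of `x`.
#' @export
split_catalog <- function(x, k) {
  stopifnot(inherits(x, "cohort_catalog"))
  n <- length(x)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n)
    stop_invalid(sprintf("split_catalog(): k must be in [1, %d], got %s",
                         n, as.character(k)))
  k <- as.integer(k)
  ord <- order(-x$manifest$length, x$manifest$genome_id)
  bin_load <- numeric(k)
  assignment <- integer(n)
  for (i in ord) {
    b <- which.min(bin_load)  # ties -> lowest bin index
    assignment[i] <- b
    bin_load[b] <- bin_load[b] + x$manifest$length[i]
  }
  lapply(seq_len(k), function(b) {
    ids <- x$manifest$genome_id[assignment == b]  # preserve manifest order
    catalog_subset(x, ids)
  })
}
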