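# Lightweight 4-line FASTQ reading/writing (gzip-transparent), plus the
# native whole-FASTQ compression entry point used by the CLI.

#' Read / write FASTQ
#'
#' @param path FASTQ path; a `.gz` suffix selects gzip transparently.
#' @return `read_fastq()` returns a list with `ids`, `sequences`,
#'   `qualities` (all character vectors).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("read_fastq(): no such file '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) %% 4L != 0L)
    stop_parse(sprintf("read_fastq(): '%s' line count not a multiple of 4", path))
  idl <- lines[seq(1L, length(lines), 4L)]
  if (any(!startsWith(idl, "@")))
    stop_parse(sprintf("read_fastq(): malformed header in '%s'", path))
  list(ids = sub("^@", "", sub("\\s.*$", "", idl)),
       sequences = lines[seq(2L, length(lines), 4L)],
       qualities = lines[seq(4L, length(lines), 4L)])
}

#' @rdname read_fastq
#' @param ids,sequences,qualities parallel character vectors; `qualities`
#'   defaults to constant `I` (Q40).
#' @export
write_fastq <- function(ids, sequences, path,
                        qualities = strrep("I", nchar(sequences))) {
  stopifnot(length(ids) == length(sequences),
            length(qualities) == length(sequences))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qualities), con)
  invisible(path)
}

# Uncompressed byte size of a FASTQ file (gz-transparent), so ratios are
# always relative to the original plain-text FASTQ.
fastq_plain_bytes <- function(path) {
  if (!grepl("\\.gz$", path)) return(file.size(path))
  con <- gzfile(path)
  on.exit(close(con))
  sum(nchar(readLines(con), type = "bytes") + 1L)
}

#' Compress a FASTQ file with the native reference-based codec
#'
#' Sequences are encoded against `reference` via [encode_reads()] and
#' serialized as a container ([serialize_container()]); read ids and quality
#' strings are passed through untransformed to a gzip entropy stage and
#' appended, so the whole FASTQ round-trips losslessly.
#'
#' @param fastq input FASTQ path (gzip allowed).
#' @param reference a `cohort_catalog`.
#' @param out output archive path.
#' @param max_diffs,seed_length passed to [encode_reads()].
#' @return a `compression_report`; `original_bytes` is the uncompressed
#'   FASTQ size.
#' @export
native_compress_fastq <- function(fastq, reference, out, max_diffs = 3L,
                                  seed_length = 21L) {
  fq <- read_fastq(fastq)
  reads <- stats::setNames(fq$sequences, fq$ids)
  stream <- encode_reads(reads, reference, max_diffs, seed_length)
  seq_blob <- c(CRZ_MAGIC, CRZ_VERSION,
                memCompress(container_payload(stream, reference), type = "gzip"))
  meta_blob <- memCompress(charToRaw(paste(fq$ids, fq$qualities,
                                           sep = "\t", collapse = "\n")),
                           type = "gzip")
  blob <- c(charToRaw("CRZF"), varint_encode(length(seq_blob)), seq_blob,
            meta_blob)
  writeBin(blob, out)
  modes <- vapply(stream$reads, `[[`, character(1), "mode")
  compression_report(fastq_plain_bytes(fastq), file.size(out),
                     method = "native",
                     reads_ref_encoded = sum(modes == "REF"),
                     reads_raw = sum(modes == "RAW"))
}

#' Decompress a native FASTQ archive
#'
#' @param archive path written by [native_compress_fastq()].
#' @param reference the encoding `cohort_catalog` (checksum-verified).
#' @param out output FASTQ path.
#' @return invisibly, `out`.
#' @export
native_decompress_fastq <- function(archive, reference, out) {
  blob <- readBin(archive, "raw", n = file.size(archive))
  if (!identical(blob[1:4], charToRaw("CRZF")))
    stop_corrupt("native_decompress_fastq(): bad magic")
  p <- varint_decode(blob, 5L)
  seq_blob <- blob[p$offset:(p$offset + p$value - 1L)]
  meta_blob <- blob[(p$offset + p$value):length(blob)]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(seq_blob, tmp)
  meta <- strsplit(rawToChar(memDecompress(meta_blob, type = "gzip")),
                   "\n", fixed = TRUE)[[1L]]
  parts <- strsplit(meta, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  quals <- vapply(parts, `[[`, character(1), 2L)
  stream <- read_container(tmp, reference, ids = ids)
  seqs <- decode_reads(stream, reference)
  write_fastq(ids, unname(seqs), out, qualities = quals)
  invisible(out)
}
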