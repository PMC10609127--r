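# Minimal lossless reference-based sequence codec. A read whose best hit on
# the reference has few enough substitutions is stored as (genome, position,
# strand, differences); anything else falls back to its raw sequence. This
# is the mechanism the cohort-specific reference optimizes for: the better
# the reference matches the cohort, the more reads take the cheap REF path.
# The demonstrator covers the sequence stream only; read ids and quality
# strings pass through to the entropy stage untransformed, since the
# reference choice affects only the sequence stream.

#' Encode reads against a reference
#'
#' Each read is aligned with [builtin_align()]; if its best hit has at most
#' `max_diffs` substitutions it becomes a REF record (1-based position,
#' strand, substitution list), otherwise a RAW record carrying the full
#' sequence. Streaming and order-preserving.
#'
#' @param reads named character vector of read sequences.
#' @param reference a `cohort_catalog` (the compression reference).
#' @param max_diffs maximum substitutions for REF encoding; default 3,
#'   mirroring the pipeline's mismatch filter.
#' @param seed_length passed to [builtin_align()].
#' @return an `encoded_reads` object: list of per-read records plus the read
#'   ids, in input order.
#' @export
encode_reads <- function(reads, reference, max_diffs = 3L, seed_length = 21L) {
  stopifnot(inherits(reference, "cohort_catalog"))
  ids <- names(reads)
  if (length(reads) == 0L)
    return(structure(list(reads = list(), ids = character(0)),
                     class = "encoded_reads"))
  hits <- builtin_align(reads, reference, seed_length)
  mapped <- hits[hits$is_mapped, , drop = FALSE]
  best <- if (nrow(mapped) > 0L) {
    o <- best_order(mapped)
    b <- mapped[o, , drop = FALSE]
    b[!duplicated(b$read_id), , drop = FALSE]
  } else mapped
  row_of <- match(ids, best$read_id)
  gidx_of <- match(best$genome_id, reference$manifest$genome_id)

  recs <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- row_of[i]
    seq_i <- toupper(reads[[i]])
    if (is.na(r) || best$mismatches[r] > max_diffs) {
      recs[[i]] <- list(mode = "RAW", sequence = seq_i)
      next
    }
    len <- nchar(seq_i)
    pos <- best$pos[r]
    gi <- gidx_of[r]
    strand <- if (best$is_reverse[r]) "-" else "+"
    if (best$mismatches[r] == 0L) {
      diffs <- data.frame(offset = integer(0), base = character(0),
                          stringsAsFactors = FALSE)
    } else {
      recon <- substr(reference$sequences[[gi]], pos, pos + len - 1L)
      if (strand == "-") recon <- revcomp(recon)
      a <- utf8ToInt(recon); b <- utf8ToInt(seq_i)
      off <- which(a != b) - 1L
      diffs <- data.frame(offset = off,
                          base = strsplit(seq_i, "")[[1L]][off + 1L],
                          stringsAsFactors = FALSE)
    }
    recs[[i]] <- list(mode = "REF", genome_index = gi, pos = pos,
                      strand = strand, length = len, diffs = diffs)
  }
  structure(list(reads = recs, ids = ids), class = "encoded_reads")
}

#' @export
print.encoded_reads <- function(x, ...) {
  modes <- vapply(x$reads, `[[`, character(1), "mode")
  cat(sprintf("<encoded_reads> %d reads (%d REF, %d RAW)\n",
              length(x$reads), sum(modes == "REF"), sum(modes == "RAW")))
  invisible(x)
}

#' Decode an encoded read stream
#'
#' Lossless inverse of [encode_reads()]: REF records take the reference
#' substring, reverse-complement it on the minus strand, and apply the
#' substitution list; RAW records return their sequence. Requires the
#' byte-identical reference used for encoding.
#'
#' @param stream an `encoded_reads` object.
#' @param reference the encoding `cohort_catalog`.
#' @return named character vector of original sequences, original order.
#' @export
decode_reads <- function(stream, reference) {
  stopifnot(inherits(stream, "encoded_reads"),
            inherits(reference, "cohort_catalog"))
  out <- vapply(stream$reads, function(rec) {
    if (rec$mode == "RAW") return(rec$sequence)
    if (rec$genome_index < 1L || rec$genome_index > length(reference))
      stop_corrupt("decode_reads(): genome_index out of range")
    gseq <- reference$sequences[[rec$genome_index]]
    if (rec$pos < 1L || rec$pos + rec$length - 1L > nchar(gseq))
      stop_corrupt("decode_reads(): position beyond reference end")
    s <- substr(gseq, rec$pos, rec$pos + rec$length - 1L)
    if (rec$strand == "-") s <- revcomp(s)
    if (nrow(rec$diffs) > 0L) {
      ch <- strsplit(s, "")[[1L]]
      ch[rec$diffs$offset + 1L] <- rec$diffs$base
      s <- paste(ch, collapse = "")
    }
    s
  }, character(1))
  stats::setNames(out, stream$ids)
}

# --- binary container -------------------------------------------------------

CRZ_MAGIC <- charToRaw("CRZ1")
CRZ_VERSION <- as.raw(1L)

#' Checksum identifying a reference catalog
#'
#' MD5 over the catalog's (genome_id, sequence) pairs; stored in container
#' headers so decoding with a mismatched reference is refused.
#'
#' @param reference a `cohort_catalog`.
#' @return 16-byte raw vector.
#' @export
reference_checksum <- function(reference) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(reference$manifest$genome_id, reference$sequences,
                   sep = "\t"), tmp)
  hex <- unname(tools::md5sum(tmp))
  as.raw(strtoi(substring(hex, seq(1L, 31L, 2L), seq(2L, 32L, 2L)), 16L))
}

pack_2bit <- function(seq) {
  codes <- match(strsplit(seq, "")[[1L]], c("A", "C", "G", "T")) - 1L
  pad <- (4L - length(codes) %% 4L) %% 4L
  codes <- c(codes, rep(0L, pad))
  m <- matrix(codes, nrow = 4L)
  as.raw(m[1L, ] * 64L + m[2L, ] * 16L + m[3L, ] * 4L + m[4L, ])
}

unpack_2bit <- function(bytes, len) {
  v <- as.integer(bytes)
  codes <- c(rbind(v %/% 64L, (v %/% 16L) %% 4L, (v %/% 4L) %% 4L, v %% 4L))
  paste(c("A", "C", "G", "T")[codes[seq_len(len)] + 1L], collapse = "")
}

# Record tags
TAG_RAW_PACKED <- 0L; TAG_RAW_PLAIN <- 1L; TAG_REF_FWD <- 2L; TAG_REF_REV <- 3L

encode_record_raw <- function(rec) {
  if (rec$mode == "RAW") {
    s <- rec$sequence
    if (grepl("^[ACGT]+$", s))
      c(as.raw(TAG_RAW_PACKED), varint_encode(nchar(s)), pack_2bit(s))
    else
      c(as.raw(TAG_RAW_PLAIN), varint_encode(nchar(s)), charToRaw(s))
  } else {
    off <- rec$diffs$offset
    deltas <- if (length(off) > 0L) c(off[1L], diff(off)) else integer(0)
    body <- c(varint_encode(c(rec$genome_index - 1L, rec$pos - 1L,
                              rec$length, nrow(rec$diffs))))
    for (j in seq_along(deltas))
      body <- c(body, varint_encode(deltas[j]), charToRaw(rec$diffs$base[j]))
    c(as.raw(if (rec$strand == "+") TAG_REF_FWD else TAG_REF_REV), body)
  }
}

container_payload <- function(stream, reference) {
  pieces <- c(list(reference_checksum(reference),
                   varint_encode(length(stream$reads))),
              lapply(stream$reads, encode_record_raw))
  do.call(c, pieces)
}

#' Serialize an encoded read stream to a compact container
#'
#' Container layout: 4-byte magic `CRZ1`, a version byte, then a
#' gzip-compressed payload holding the reference MD5 checksum, the read
#' count, and per-read records (varint-coded positions and lengths, 2-bit
#' packed RAW bases, substitution lists).
#'
#' @param stream an `encoded_reads` object.
#' @param reference the encoding `cohort_catalog` (for the header checksum).
#' @param out output path.
#' @return compressed size in bytes (the file size).
#' @export
serialize_container <- function(stream, reference, out) {
  stopifnot(inherits(stream, "encoded_reads"))
  payload <- container_payload(stream, reference)
  blob <- c(CRZ_MAGIC, CRZ_VERSION, memCompress(payload, type = "gzip"))
  tryCatch(writeBin(blob, out), error = function(e) stop_io(conditionMessage(e)))
  file.size(out)
}

#' Read a serialized container back into an encoded read stream
#'
#' Refuses to decode when the reference checksum in the header does not
#' match `reference`. Read ids are not stored in the sequence container;
#' decoded reads are named `read1..readN` unless `ids` is supplied.
#'
#' @param path container path ([serialize_container()]).
#' @param reference the `cohort_catalog` to decode against.
#' @param ids optional read ids to attach.
#' @return an `encoded_reads` object.
#' @export
read_container <- function(path, reference, ids = NULL) {
  if (!file.exists(path)) stop_io(sprintf("read_container(): no such file '%s'", path))
  blob <- readBin(path, "raw", n = file.size(path))
  if (length(blob) < 6L || !identical(blob[1:4], CRZ_MAGIC))
    stop_corrupt("read_container(): bad magic, not a CRZ container")
  if (blob[5L] != CRZ_VERSION)
    stop_corrupt("read_container(): unsupported container version")
  payload <- memDecompress(blob[-(1:5)], type = "gzip")
  if (!identical(payload[1:16], reference_checksum(reference)))
    stop_corrupt("read_container(): reference checksum mismatch; refusing to decode")
  p <- varint_decode(payload, 17L)
  n <- p$value; offset <- p$offset
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    tag <- as.integer(payload[offset]); offset <- offset + 1L
    if (tag %in% c(TAG_RAW_PACKED, TAG_RAW_PLAIN)) {
      p <- varint_decode(payload, offset); len <- p$value; offset <- p$offset
      if (tag == TAG_RAW_PACKED) {
        nb <- ceiling(len / 4)
        s <- unpack_2bit(payload[offset:(offset + nb - 1L)], len)
        offset <- offset + nb
      } else {
        s <- rawToChar(payload[offset:(offset + len - 1L)])
        offset <- offset + len
      }
      recs[[i]] <- list(mode = "RAW", sequence = s)
    } else if (tag %in% c(TAG_REF_FWD, TAG_REF_REV)) {
      p <- varint_decode(payload, offset); gi <- p$value + 1L; offset <- p$offset
      p <- varint_decode(payload, offset); pos <- p$value + 1L; offset <- p$offset
      p <- varint_decode(payload, offset); len <- p$value; offset <- p$offset
      p <- varint_decode(payload, offset); nd <- p$value; offset <- p$offset
      off_acc <- integer(nd); base <- character(nd)
      cur <- 0L
      for (j in seq_len(nd)) {
        p <- varint_decode(payload, offset); offset <- p$offset
        cur <- if (j == 1L) p$value else cur + p$value
        off_acc[j] <- cur
        base[j] <- rawToChar(payload[offset]); offset <- offset + 1L
      }
      recs[[i]] <- list(mode = "REF", genome_index = gi, pos = pos,
                        strand = if (tag == TAG_REF_FWD) "+" else "-",
                        length = len,
                        diffs = data.frame(offset = off_acc, base = base,
                                           stringsAsFactors = FALSE))
    } else {
      stop_corrupt(sprintf("read_container(): unknown record tag %d", tag))
    }
  }
  ids <- ids %||% paste0("read", seq_len(n))
  structure(list(reads = recs, ids = ids), class = "encoded_reads")
}

# --- reports and adapters ---------------------------------------------------

#' Build a compression report
#'
#' @param original_bytes,compressed_bytes byte sizes; the ratio is
#'   `original_bytes / compressed_bytes`.
#' @param method label of the compressor/mode.
#' @param reads_ref_encoded,reads_raw read counts by encoding mode (native
#'   codec only).
#' @param command external command line, when an adapter was used.
#' @return a `compression_report` list.
#' @export
compression_report <- function(original_bytes, compressed_bytes, method,
                               reads_ref_encoded = NA_integer_,
                               reads_raw = NA_integer_,
                               command = NA_character_) {
  if (compressed_bytes < 1) stop_invalid("compression_report(): compressed_bytes must be >= 1")
  structure(list(original_bytes = as.numeric(original_bytes),
                 compressed_bytes = as.numeric(compressed_bytes),
                 ratio = as.numeric(original_bytes) / as.numeric(compressed_bytes),
                 method = method,
                 reads_ref_encoded = reads_ref_encoded,
                 reads_raw = reads_raw, command = command),
            class = "compression_report")
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("<compression_report> %s: %s -> %s bytes (ratio %.2f)\n",
              x$method, format(x$original_bytes, big.mark = ","),
              format(x$compressed_bytes, big.mark = ","), x$ratio))
  invisible(x)
}

#' Compression ratio of two files
#'
#' Ratio = byte size of the original file / byte size of the compressed
#' file.
#'
#' @param original,compressed file paths.
#' @param method report label.
#' @return a `compression_report`.
#' @export
compression_ratio <- function(original, compressed, method = "files") {
  for (p in c(original, compressed))
    if (!file.exists(p)) stop_io(sprintf("compression_ratio(): no such file '%s'", p))
  if (file.size(compressed) < 1)
    stop_io(sprintf("compression_ratio(): '%s' is empty", compressed))
  compression_report(file.size(original), file.size(compressed), method)
}

#' Run an external compressor adapter
#'
#' Adapters invoke an installed external tool, measure the output size, and
#' record the exact command line. `gzip` is the general-purpose baseline;
#' `genozip` is an optional reference-based compressor (invoked with
#' `--best=No_REF` in reference-free mode, or `--best --pair --reference`
#' when a reference FASTA is given). An absent binary raises a classed
#' `cohortref_tool_absent` error naming it, never a crash.
#'
#' @param tool `"gzip"` or `"genozip"`.
#' @param fastq input FASTQ path.
#' @param reference optional reference FASTA path (genozip only).
#' @param out output path; default next to the input.
#' @param keep_output keep the compressed file (default drops it after
#'   measuring).
#' @return a `compression_report`.
#' @export
run_external_compressor <- function(tool = c("gzip", "genozip"), fastq,
                                    reference = NULL, out = NULL,
                                    keep_output = FALSE) {
  tool <- match.arg(tool)
  if (!file.exists(fastq)) stop_io(sprintf("no such FASTQ '%s'", fastq))
  bin <- Sys.which(tool)
  if (!nzchar(bin))
    stop_absent(sprintf("external compressor binary '%s' not found on PATH", tool))
  out <- out %||% tempfile(fileext = if (tool == "gzip") ".gz" else ".genozip")
  if (!keep_output) on.exit(unlink(out), add = TRUE)
  if (tool == "gzip") {
    args <- c("-c", shQuote(fastq))
    status <- system2(bin, args, stdout = out, stderr = FALSE)
    cmd <- paste(c(tool, args, ">", out), collapse = " ")
  } else {
    args <- c(if (is.null(reference)) "--best=No_REF"
              else c("--best", "--pair", "--reference", shQuote(reference)),
              "--force", "--output", shQuote(out), shQuote(fastq))
    status <- system2(bin, args, stdout = FALSE, stderr = FALSE)
    cmd <- paste(c(tool, args), collapse = " ")
  }
  if (!identical(status, 0L) || !file.exists(out) || file.size(out) < 1)
    stop_io(sprintf("external compressor failed: %s", cmd))
  compression_report(file.size(fastq), file.size(out), method = tool,
                     command = cmd)
}
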