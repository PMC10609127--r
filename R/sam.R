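# Minimal plain-text SAM reading/writing. Only the fields the post-alignment
# filters consume are retained: QNAME, FLAG, RNAME, POS, MAPQ, CIGAR and the
# optional NM (edit distance) / AS (alignment score) tags. Coordinates are
# 1-based, per SAM.

#' Construct a table of alignment records
#'
#' The in-memory alignment representation used throughout the package: one
#' row per SAM alignment line, with flag bits decoded into logical columns.
#'
#' @param read_id,genome_id,pos,mapq,cigar,mismatches,align_score,is_mapped,is_secondary_or_supplementary,is_reverse,mate
#'   per-record vectors; `mismatches` follows NM-tag semantics,
#'   `align_score` AS-tag semantics (`NA` when absent), `mate` is 1/2 for
#'   paired data and 0 otherwise.
#' @return a `data.frame` with one row per alignment record.
#' @export
alignment_records <- function(read_id, genome_id, pos, mapq, cigar,
                              mismatches, align_score = NA_integer_,
                              is_mapped = TRUE,
                              is_secondary_or_supplementary = FALSE,
                              is_reverse = FALSE, mate = 0L) {
  df <- data.frame(read_id = as.character(read_id),
                   genome_id = as.character(genome_id),
                   pos = as.integer(pos), mapq = as.integer(mapq),
                   cigar = as.character(cigar),
                   mismatches = as.integer(mismatches),
                   align_score = as.integer(align_score),
                   is_mapped = as.logical(is_mapped),
                   is_secondary_or_supplementary =
                     as.logical(is_secondary_or_supplementary),
                   is_reverse = as.logical(is_reverse),
                   mate = as.integer(mate),
                   stringsAsFactors = FALSE)
  bad_mapq <- df$is_mapped & (is.na(df$mapq) | df$mapq < 0L | df$mapq > 255L)
  if (any(bad_mapq))
    stop_invalid("alignment_records(): MAPQ must be in [0, 255]")
  if (any(df$is_mapped & (is.na(df$pos) | df$pos < 1L)))
    stop_invalid("alignment_records(): mapped records need pos >= 1")
  df
}

# Extract an integer-valued SAM tag ("NM", "AS") from tag-field strings.
extract_sam_tag <- function(tag_strings, tag) {
  hit <- grepl(sprintf("\\b%s:i:", tag), tag_strings)
  out <- rep(NA_integer_, length(tag_strings))
  out[hit] <- as.integer(sub(sprintf(".*\\b%s:i:(-?[0-9]+).*", tag), "\\1",
                             tag_strings[hit]))
  out
}

#' Read a SAM file into an alignment-record table
#'
#' @param path SAM path (plain text; gzip allowed). Header lines are skipped.
#' @return a `data.frame` as produced by [alignment_records()].
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("read_sam(): no such file '%s'", path))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(alignment_records(character(0), character(0), integer(0),
                             integer(0), character(0), integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop_parse(sprintf("read_sam(): malformed SAM line %d in '%s' (%d fields)",
                       which(nf < 11L)[1L], path, min(nf)))
  field <- function(i) vapply(parts, `[[`, character(1), i)
  tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else "",
    character(1))
  flag <- as.integer(field(2))
  if (anyNA(flag))
    stop_parse(sprintf("read_sam(): non-numeric FLAG in '%s'", path))
  is_mapped <- bitwAnd(flag, 4L) == 0L
  paired <- bitwAnd(flag, 1L) > 0L
  mate <- ifelse(paired, ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L), 0L)
  alignment_records(
    read_id = field(1),
    genome_id = ifelse(is_mapped, field(3), NA_character_),
    pos = ifelse(is_mapped, suppressWarnings(as.integer(field(4))), NA_integer_),
    mapq = as.integer(field(5)),
    cigar = ifelse(is_mapped, field(6), NA_character_),
    mismatches = ifelse(is_mapped, extract_sam_tag(tags, "NM"), NA_integer_),
    align_score = ifelse(is_mapped, extract_sam_tag(tags, "AS"), NA_integer_),
    is_mapped = is_mapped,
    is_secondary_or_supplementary =
      bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
    is_reverse = bitwAnd(flag, 16L) > 0L,
    mate = mate)
}

#' Write alignment records as SAM
#'
#' @param records alignment-record table ([alignment_records()]).
#' @param path output path.
#' @param catalog optional `cohort_catalog` used to emit `@SQ` header lines.
#' @param read_seqs optional named character vector of read sequences
#'   (SEQ column; `*` when absent).
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, path, catalog = NULL, read_seqs = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(catalog))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d",
                          catalog$manifest$genome_id, catalog$manifest$length))
  flag <- ifelse(records$is_mapped, 0L, 4L) +
    ifelse(records$is_reverse, 16L, 0L) +
    ifelse(records$is_secondary_or_supplementary, 256L, 0L) +
    ifelse(records$mate > 0L, 1L + ifelse(records$mate == 1L, 64L, 128L), 0L)
  seqs <- if (is.null(read_seqs)) "*" else
    ifelse(is.na(read_seqs[records$read_id]), "*", read_seqs[records$read_id])
  body <- paste(records$read_id, flag,
                ifelse(records$is_mapped, records$genome_id, "*"),
                ifelse(records$is_mapped, records$pos, 0L),
                records$mapq,
                ifelse(records$is_mapped, records$cigar, "*"),
                "*", 0L, 0L, seqs, "*", sep = "\t")
  tag_nm <- ifelse(records$is_mapped & !is.na(records$mismatches),
                   sprintf("\tNM:i:%d", records$mismatches), "")
  tag_as <- ifelse(records$is_mapped & !is.na(records$align_score),
                   sprintf("\tAS:i:%d", records$align_score), "")
  writeLines(c(hdr, paste0(body, tag_nm, tag_as)), path)
  invisible(path)
}
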