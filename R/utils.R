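# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers (and tests) can distinguish failure modes.
stop_cohortref <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cohortref_error", "error"),
                      call = sys.call(-1)))
}

stop_invalid <- function(msg) stop_cohortref(msg, "cohortref_invalid_input")
stop_io <- function(msg) stop_cohortref(msg, "cohortref_io_error")
stop_parse <- function(msg) stop_cohortref(msg, "cohortref_parse_error")
stop_corrupt <- function(msg) stop_cohortref(msg, "cohortref_corrupt_stream")
stop_absent <- function(msg) stop_cohortref(msg, "cohortref_tool_absent")

#' Reverse complement of nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()];
#' handles the full IUPAC alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Unsigned LEB128 varint encoding of non-negative integers (numeric ok).
varint_encode <- function(x) {
  pieces <- lapply(x, function(v) {
    v <- as.numeric(v)
    if (is.na(v) || v < 0) stop_invalid("varint values must be non-negative")
    out <- raw(0)
    repeat {
      byte <- v %% 128
      v <- floor(v / 128)
      if (v > 0) {
        out <- c(out, as.raw(byte + 128))
      } else {
        out <- c(out, as.raw(byte))
        break
      }
    }
    out
  })
  do.call(c, pieces)
}

# Decode one varint from `raw_vec` starting at `offset`; returns
# list(value, next_offset).
varint_decode <- function(raw_vec, offset) {
  v <- 0
  shift <- 1
  repeat {
    if (offset > length(raw_vec)) stop_corrupt("truncated varint in container")
    byte <- as.integer(raw_vec[offset])
    offset <- offset + 1L
    v <- v + (byte %% 128) * shift
    if (byte < 128) break
    shift <- shift * 128
  }
  list(value = v, offset = offset)
}

# Count of N/n characters per sequence.
count_n_bases <- function(x) {
  nchar(x) - nchar(gsub("[Nn]", "", x))
}
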