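# Synthetic microbial communities with known truth: random genomes
# (optionally emitted as gapped segments to exercise normalization), skewed
# lognormal abundance profiles, and paired-end read simulation with
# substitution errors plus optional indel/N injection to exercise the
# post-alignment and QC filters. Everything is deterministic under a seed.

#' Simulate random reference genomes
#'
#' Generates `n` i.i.d. uniform-ACGT genomes. With `gap_fraction > 0` each
#' genome is additionally emitted as 2-4 segments with runs of `N` inserted
#' (gaps are additions, so normalization recovers the original length); the
#' returned truth catalog always holds the normalized, gap-free sequences.
#'
#' @param n number of genomes (>= 1).
#' @param length genome length in bases (>= 1000).
#' @param seed RNG seed.
#' @param gap_fraction fraction of `length` added as N gap characters.
#' @return list with `segments` (named list of character vectors, the raw
#'   per-genome segments) and `catalog` (the truth `cohort_catalog`).
#' @export
simulate_genomes <- function(n, length, seed, gap_fraction = 0) {
  if (n < 1L || length < 1000L)
    stop_invalid("simulate_genomes(): need n >= 1 and length >= 1000")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop_invalid("simulate_genomes(): gap_fraction must be in [0, 1)")
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  segments <- vector("list", n)
  names(segments) <- ids
  for (i in seq_len(n)) {
    seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
    if (gap_fraction > 0) {
      n_gap <- max(1L, round(gap_fraction * length))
      n_seg <- sample(2:4, 1L)
      cuts <- sort(sample.int(length - 1L, n_seg - 1L))
      pieces <- substring(seq, c(1L, cuts + 1L), c(cuts, length))
      # one N run per segment; run lengths partition n_gap
      run_len <- diff(round(seq(0, n_gap, length.out = n_seg + 1L)))
      pieces <- vapply(seq_along(pieces), function(j) {
        if (run_len[j] == 0L) return(pieces[j])
        at <- sample.int(nchar(pieces[j]) - 1L, 1L)
        paste0(substr(pieces[j], 1L, at), strrep("N", run_len[j]),
               substr(pieces[j], at + 1L, nchar(pieces[j])))
      }, character(1))
      segments[[i]] <- pieces
    } else {
      segments[[i]] <- seq
    }
  }
  records <- Map(normalize_genome, segments, ids,
                 label = sprintf("synthetic genome %s", ids))
  list(segments = segments, catalog = catalog(records))
}

#' Construct a community abundance profile
#'
#' @param species ordered genome ids.
#' @param abundance nonnegative relative abundances summing to 1.
#' @return a `community_profile` list.
#' @export
community_profile <- function(species, abundance) {
  if (length(species) == 0L) stop_invalid("community_profile(): empty profile")
  if (length(species) != length(abundance))
    stop_invalid("community_profile(): species/abundance length mismatch")
  if (any(abundance < 0)) stop_invalid("community_profile(): negative abundance")
  if (abs(sum(abundance) - 1) > 1e-9)
    stop_invalid("community_profile(): abundances must sum to 1")
  structure(list(species = as.character(species),
                 abundance = as.numeric(abundance)),
            class = "community_profile")
}

#' Sample a skewed community profile
#'
#' Lognormal(0, sigma) draws, normalized to sum to one and sorted
#' descending. The default sigma of 1.5 gives the skew characteristic of
#' shotgun metagenomes, where a small number of species contributes most of
#' the total abundance.
#'
#' @param n_species number of species.
#' @param sigma lognormal shape (> 0); larger = more skewed.
#' @param seed RNG seed.
#' @param species optional ids (default `g001..`); `species[1]` receives the
#'   largest abundance.
#' @return a `community_profile`.
#' @export
sample_profile <- function(n_species, sigma = 1.5, seed = 1L,
                           species = sprintf("g%03d", seq_len(n_species))) {
  if (n_species < 1L) stop_invalid("sample_profile(): n_species must be >= 1")
  if (sigma <= 0) stop_invalid("sample_profile(): sigma must be > 0")
  set.seed(seed)
  a <- sort(stats::rlnorm(n_species, 0, sigma), decreasing = TRUE)
  community_profile(species, a / sum(a))
}

#' Proportion of abundant species
#'
#' Abundant species are the smallest set of species, ranked by decreasing
#' relative abundance, whose cumulative abundance reaches the threshold
#' (default: the top 80% of total abundance). A species exactly reaching the
#' threshold is included. Returns that set's size as a fraction of all
#' species.
#'
#' @param profile a `community_profile`.
#' @param threshold cumulative abundance threshold in (0, 1]; default 0.8.
#' @return fraction in (0, 1].
#' @export
abundant_species_proportion <- function(profile, threshold = 0.8) {
  stopifnot(inherits(profile, "community_profile"))
  if (threshold <= 0 || threshold > 1)
    stop_invalid("abundant_species_proportion(): threshold must be in (0, 1]")
  a <- sort(profile$abundance, decreasing = TRUE)
  m <- which(cumsum(a) >= threshold - 1e-9)[1L]
  m / length(a)
}

#' Read-simulation parameters
#'
#' @param n_read_pairs number of read pairs to draw.
#' @param read_length read length in bases (default 100, so QC at the
#'   default 60-base minimum passes unless deliberately violated).
#' @param insert_mean,insert_sd fragment-length distribution (default
#'   300 / 30 bases).
#' @param sub_error_rate per-base substitution error rate (default 0.005).
#' @param indel_read_fraction fraction of reads receiving one 1-base indel
#'   (exercises the CIGAR filter; default 0).
#' @param n_base_fraction fraction of reads receiving one N base (exercises
#'   QC; default 0).
#' @param seed RNG seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(n_read_pairs, read_length = 100L,
                            insert_mean = 300, insert_sd = 30,
                            sub_error_rate = 0.005,
                            indel_read_fraction = 0, n_base_fraction = 0,
                            seed = 1L) {
  rates <- c(sub_error_rate, indel_read_fraction, n_base_fraction)
  if (any(rates < 0) || any(rates >= 1))
    stop_invalid("read_sim_config(): rates must be in [0, 1)")
  if (n_read_pairs < 1L || read_length < 1L)
    stop_invalid("read_sim_config(): invalid sizes")
  structure(list(n_read_pairs = as.integer(n_read_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 sub_error_rate = sub_error_rate,
                 indel_read_fraction = indel_read_fraction,
                 n_base_fraction = n_base_fraction,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

# Plant substitution errors: n_err[i] errors in read i at distinct positions.
plant_substitutions <- function(seqs, n_err, read_length) {
  affected <- which(n_err > 0L)
  if (length(affected) == 0L) return(seqs)
  pos_list <- lapply(affected, function(i) sort(sample.int(read_length, n_err[i])))
  idx <- rep(affected, n_err[affected])
  pos <- unlist(pos_list)
  bases <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
  cpp_apply_substitutions(seqs, as.integer(idx), as.integer(pos), bases)
}

#' Simulate paired-end reads from a community
#'
#' Per pair: a genome is drawn proportional to abundance, a fragment start
#' uniformly, and the two mates are read from opposite strands of the
#' fragment ends (mate 1 forward, mate 2 reverse). Substitution errors are
#' i.i.d. per base at `sub_error_rate`; a fraction `indel_read_fraction` of
#' reads receive one 1-base indel (length-preserving, shifting the read
#' tail) and `n_base_fraction` one N base. Truth positions are 1-based on
#' the normalized gap-free genome, matching SAM conventions.
#'
#' @param catalog the truth `cohort_catalog`.
#' @param profile a `community_profile` with species in the catalog.
#' @param config a [read_sim_config()].
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_1.fastq.gz`, `<prefix>_2.fastq.gz` and `<prefix>_truth.tsv`.
#' @param id_prefix prefix of read ids (default `"r"`).
#' @return list with `reads1`, `reads2` (named character vectors), `truth`
#'   (`data.frame`: read_id, genome_id, pos, strand, one row per mate) and,
#'   when `out_prefix` is given, the emitted `paths`.
#' @export
simulate_reads <- function(catalog, profile, config, out_prefix = NULL,
                           id_prefix = "r") {
  stopifnot(inherits(catalog, "cohort_catalog"),
            inherits(profile, "community_profile"),
            inherits(config, "read_sim_config"))
  missing <- setdiff(profile$species, catalog_ids(catalog))
  if (length(missing) > 0L)
    stop_invalid(sprintf("simulate_reads(): profile species not in catalog: %s",
                         paste(missing, collapse = ", ")))
  glen <- stats::setNames(catalog$manifest$length, catalog$manifest$genome_id)
  need <- config$insert_mean + 4 * config$insert_sd
  if (any(glen[profile$species] <= need))
    stop_invalid(sprintf(
      "simulate_reads(): genome lengths must exceed insert_mean + 4*insert_sd (%.0f)",
      need))
  set.seed(config$seed)
  n <- config$n_read_pairs
  rl <- config$read_length
  gid <- profile$species[sample.int(length(profile$species), n, replace = TRUE,
                                    prob = profile$abundance)]
  insert <- pmin(pmax(rl, round(stats::rnorm(n, config$insert_mean,
                                             config$insert_sd))),
                 glen[gid])
  start <- floor(stats::runif(n) * (glen[gid] - insert + 1)) + 1L
  gseq <- catalog$sequences[gid]
  reads1 <- substring(gseq, start, start + rl - 1L)
  pos2 <- start + insert - rl
  reads2 <- revcomp(substring(gseq, pos2, pos2 + rl - 1L))
  base_ids <- paste0(id_prefix, formatC(seq_len(n), width = 7, flag = "0"))

  seqs <- c(reads1, reads2)  # mate 1 block then mate 2 block
  n_err <- stats::rbinom(2L * n, rl, config$sub_error_rate)
  seqs <- plant_substitutions(seqs, n_err, rl)
  if (config$indel_read_fraction > 0) {
    k <- round(config$indel_read_fraction * 2L * n)
    if (k > 0L) {
      which_r <- sample.int(2L * n, k)
      at <- sample.int(rl - 1L, k, replace = TRUE)
      is_del <- stats::runif(k) < 0.5
      extra <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      seqs[which_r] <- ifelse(
        is_del,
        paste0(substr(seqs[which_r], 1L, at - 1L),
               substr(seqs[which_r], at + 1L, rl), extra),
        paste0(substr(seqs[which_r], 1L, at), extra,
               substr(seqs[which_r], at + 1L, rl - 1L)))
    }
  }
  if (config$n_base_fraction > 0) {
    k <- round(config$n_base_fraction * 2L * n)
    if (k > 0L) {
      which_r <- sample.int(2L * n, k)
      at <- sample.int(rl, k, replace = TRUE)
      substr(seqs[which_r], at, at) <- "N"
    }
  }
  reads1 <- stats::setNames(seqs[seq_len(n)], paste0(base_ids, "/1"))
  reads2 <- stats::setNames(seqs[n + seq_len(n)], paste0(base_ids, "/2"))
  truth <- data.frame(
    read_id = c(names(reads1), names(reads2)),
    genome_id = c(gid, gid),
    pos = c(start, pos2),
    strand = rep(c("+", "-"), each = n),
    stringsAsFactors = FALSE)
  out <- list(reads1 = reads1, reads2 = reads2, truth = truth)
  if (!is.null(out_prefix)) {
    paths <- c(r1 = paste0(out_prefix, "_1.fastq.gz"),
               r2 = paste0(out_prefix, "_2.fastq.gz"),
               truth = paste0(out_prefix, "_truth.tsv"))
    write_fastq(names(reads1), unname(reads1), paths[["r1"]])
    write_fastq(names(reads2), unname(reads2), paths[["r2"]])
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
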