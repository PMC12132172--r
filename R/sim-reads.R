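# Toy isoform references and nanopore-like amplicon read simulation.
#
# The real transcripts differ at a short 5' alternative exon (L vs S) and
# at a distal internal exon pair roughly 2 kb downstream, so no single
# short window distinguishes all isoforms; the toy references reproduce
# that geometry on a shared random backbone.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

parse_isoform_id <- function(id) {
  if (!grepl("^[CDE][LS]$", id)) {
    stop("isoform ids must combine an internal-exon variant (C, D, E) and ",
         "a 5' exon variant (L, S), e.g. \"CL\"", call. = FALSE)
  }
  list(internal = substr(id, 1, 1), five = substr(id, 2, 2))
}

#' Generate toy isoform reference sequences
#'
#' Builds ~4.0-4.2 kb sequences that share a constant backbone and differ
#' only at a 5' alternative block (`L`: 150 bp, `S`: 90 bp, unrelated
#' sequences) and at a distal internal alternative block (160 bp, one of
#' `C`, `D`, `E`), separated by a ~2 kb constant spacer. Isoform ids name
#' the two choices, e.g. `"CL"` = internal block C + 5' exon L.
#'
#' @param config a [sim_config()]; only the seed is used.
#' @param isoforms character vector of isoform ids (default the five
#'   expressed isoforms `CL`, `CS`, `DL`, `DS`, `EL`); at least 2.
#' @return named character vector of uppercase DNA sequences.
#' @examples
#' refs <- gen_isoform_references(sim_config(seed = 1))
#' nchar(refs)
#' @export
gen_isoform_references <- function(config,
                                   isoforms = c("CL", "CS", "DL", "DS", "EL")) {
  stopifnot(inherits(config, "sim_config"))
  if (length(isoforms) < 2L) {
    stop("at least 2 isoforms must be requested", call. = FALSE)
  }
  parts <- lapply(isoforms, parse_isoform_id)

  with_seed(config$seed, {
    five_blocks <- list(L = random_dna(150), S = random_dna(90))
    internal_blocks <- list(C = random_dna(160), D = random_dna(160),
                            E = random_dna(160))
    spacer1 <- random_dna(2000)
    spacer2 <- random_dna(1800)
    seqs <- vapply(parts, function(p) {
      paste0(five_blocks[[p$five]], spacer1,
             internal_blocks[[p$internal]], spacer2)
    }, character(1))
    names(seqs) <- isoforms
    seqs
  })
}

#' Simulate long amplicon reads from an isoform composition
#'
#' Reads are drawn multinomially from `composition`, mutated with a
#' uniform per-base error process (60% substitutions, 20% insertions,
#' 20% deletions of `config$per_base_error`), end-trimmed with Gaussian
#' length jitter, and emitted on a random strand. A fraction
#' `config$junk_fraction` of reads is replaced by off-target junk: half
#' truncated fragments (500-2500 bp), half composition-shuffled
#' sequences, exercising the length and identity filter branches
#' respectively.
#'
#' @param references named character vector from
#'   [gen_isoform_references()] (or any uppercase DNA set).
#' @param composition numeric simplex vector over `references` (same
#'   length, sums to 1).
#' @param config a [sim_config()]; supplies `read_count`,
#'   `per_base_error`, `length_jitter_sd`, `junk_fraction` and the seed.
#'
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `isoform` (NA for junk), `strand`,
#'   `is_junk`, `junk_type`).
#' @examples
#' cfg <- sim_config(seed = 1, read_count = 10, per_base_error = 0)
#' refs <- gen_isoform_references(cfg, c("CL", "DL"))
#' rd <- gen_amplicon_reads(refs, c(0.5, 0.5), cfg)
#' rd$truth$isoform
#' @export
gen_amplicon_reads <- function(references, composition, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(composition) != length(references)) {
    stop("`composition` must have one weight per reference", call. = FALSE)
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-6) {
    stop("`composition` must be non-negative and sum to 1", call. = FALSE)
  }
  err <- config$per_base_error
  p_sub <- 0.6 * err; p_ins <- 0.2 * err; p_del <- 0.2 * err

  with_seed(config$seed, {
    n <- config$read_count
    ids <- sprintf("read_%05d", seq_len(n))
    is_junk <- runif(n) < config$junk_fraction
    iso <- names(references)[
      sample.int(length(references), n, replace = TRUE, prob = composition)]
    iso[is_junk] <- NA_character_
    junk_type <- rep(NA_character_, n)
    junk_type[is_junk] <- sample(c("truncated", "shuffled"),
                                 sum(is_junk), replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    reads <- character(n)
    for (i in seq_len(n)) {
      if (is_junk[i]) {
        src <- references[[sample.int(length(references), 1)]]
        if (junk_type[i] == "truncated") {
          len <- sample(500:2500, 1)
          start <- sample.int(nchar(src) - len + 1L, 1)
          s <- substr(src, start, start + len - 1L)
          s <- mutate_sequence(s, p_sub, p_ins, p_del)
        } else {
          s <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
        }
      } else {
        s <- mutate_sequence(references[[iso[i]]], p_sub, p_ins, p_del)
        if (config$length_jitter_sd > 0) {
          trim <- abs(round(rnorm(2, 0, config$length_jitter_sd)))
          if (sum(trim) < nchar(s) - 100) {
            s <- substr(s, 1L + trim[1], nchar(s) - trim[2])
          }
        }
      }
      if (strand[i] == "-") s <- revcomp_cpp(s)
      reads[i] <- s
    }
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, isoform = iso, strand = strand,
                            is_junk = is_junk, junk_type = junk_type,
                            stringsAsFactors = FALSE))
  })
}

#' Write isoform references to FASTA / read them back
#'
#' Thin wrappers around Biostrings for the package's on-disk formats.
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output file path.
#' @return `write_isoform_fasta()` returns `path` invisibly;
#'   `read_isoform_fasta()` returns a named character vector.
#' @export
write_isoform_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' @rdname write_isoform_fasta
#' @export
read_isoform_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write simulated reads to FASTQ / read them back
#'
#' Qualities are uniform Phred+33 scores derived from the per-base error
#' rate (`Q = round(-10 log10(error))`, capped at 40).
#'
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @param per_base_error error rate used to derive the uniform quality.
#' @return `write_reads_fastq()` returns `path` invisibly;
#'   `read_reads_fastq()` returns a named character vector.
#' @export
write_reads_fastq <- function(reads, path, per_base_error = 0.05) {
  q <- min(40L, as.integer(round(-10 * log10(max(per_base_error, 1e-4)))))
  set <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) {
      paste(rep(rawToChar(as.raw(q + 33L)), n), collapse = "")
    }, character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(set, quals)
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(set), sub(" .*", "", names(set)))
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth any list/data.frame of generator ground truth.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
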