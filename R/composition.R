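# Long-read amplicon classification, filtering, composition estimation,
# integer-ratio approximation, composition comparison, TPM.

#' Percent identity of a read against a reference
#'
#' Semi-global alignment (the read is aligned end-to-end, reference end
#' gaps are free) under unit edit costs, computed with a banded dynamic
#' program. Identity is `1 - d / read_length` clamped at 0, where `d` is
#' the optimal edit distance — the edit distance normalized by query
#' length, which is deterministic even when several alignments are
#' co-optimal.
#'
#' @param read,reference uppercase ACGTN sequences (character scalars).
#' @param band half-width of the alignment band (bases); widened
#'   automatically by the length difference. The default tolerates indel
#'   drift far beyond nanopore-scale error rates on ~4 kb reads.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' percent_identity("ACGTACGT", "ACGTACGT")
#' @export
percent_identity <- function(read, reference, band = 150L) {
  check_dna(read, "read")
  check_dna(reference, "reference")
  d <- banded_edit_semiglobal(read, reference, as.integer(band))
  max(0, 1 - d / nchar(read))
}

#' Classify one read to its best-hit isoform reference
#'
#' Scores the read against every reference on the better of the two
#' strands (orientation is chosen by a k-mer vote against the first
#' reference, falling back to aligning both strands when the vote is
#' ambiguous) and assigns the reference with the highest identity.
#' Exact ties (identity difference below 1e-9) are left unassigned with
#' status `"tie"` — unclassified rather than randomly broken.
#'
#' @param read uppercase ACGTN sequence.
#' @param references named character vector of >= 2 references.
#' @param band see [percent_identity()].
#' @param read_id identifier carried into the result.
#' @return one-row data.frame: `read_id`, `best_isoform` (NA on tie),
#'   `identity`, `read_length`, `status` (`"ok"` or `"tie"`).
#' @export
classify_read <- function(read, references, band = 150L,
                          read_id = "read") {
  if (length(references) == 0L) stop("empty reference set", call. = FALSE)
  if (length(references) < 2L) {
    stop("at least 2 references are required", call. = FALSE)
  }
  check_dna(read, "read")
  vote <- kmer_orientation_vote(read, references[[1]], 12L)
  cands <- if (vote > 0) list(read) else if (vote < 0) {
    list(revcomp_cpp(read))
  } else {
    list(read, revcomp_cpp(read))
  }
  ids <- rep(-Inf, length(references))
  for (s in cands) {
    v <- vapply(references, function(ref) {
      percent_identity(s, ref, band = band)
    }, numeric(1))
    ids <- pmax(ids, v)
  }
  ord <- order(ids, decreasing = TRUE)
  tie <- length(ids) >= 2 && (ids[ord[1]] - ids[ord[2]]) < 1e-9
  data.frame(
    read_id = read_id,
    best_isoform = if (tie) NA_character_ else names(references)[ord[1]],
    identity = ids[ord[1]],
    read_length = nchar(read),
    status = if (tie) "tie" else "ok",
    stringsAsFactors = FALSE)
}

#' Classify a set of reads
#'
#' @param reads named character vector of reads.
#' @param references named character vector of >= 2 references.
#' @param band see [percent_identity()].
#' @return data.frame of per-read assignments (see [classify_read()]).
#' @export
classify_reads <- function(reads, references, band = 150L) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(reads))
  out <- lapply(seq_along(reads), function(i) {
    classify_read(reads[[i]], references, band = band, read_id = ids[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply length and identity filters to read assignments
#'
#' A read passes when its length lies in `[min_len, max_len]`, its
#' best-hit identity is at least `min_identity`, and its best hit is
#' unique (not a tie). The failure reason is recorded in `status`:
#' `failed_length` takes precedence over `failed_identity`; ties stay
#' `tie`. Filtering is idempotent.
#'
#' @param assignments data.frame from [classify_reads()].
#' @param min_len,max_len read length window (bp), defaults 3800-4500.
#' @param min_identity identity threshold, default 0.85.
#' @return the assignments with `status` set to one of `passed`,
#'   `failed_length`, `failed_identity`, `tie`.
#' @export
filter_reads <- function(assignments, min_len = 3800, max_len = 4500,
                         min_identity = 0.85) {
  if (min_len <= 0 || max_len <= 0 || min_len >= max_len) {
    stop("need 0 < min_len < max_len", call. = FALSE)
  }
  if (min_identity <= 0) stop("min_identity must be positive", call. = FALSE)
  status <- ifelse(
    assignments$status == "tie", "tie",
    ifelse(assignments$read_length < min_len |
             assignments$read_length > max_len, "failed_length",
           ifelse(assignments$identity < min_identity, "failed_identity",
                  "passed")))
  assignments$status <- status
  assignments
}

#' Estimate isoform composition from passed reads
#'
#' Proportions are the multinomial maximum-likelihood estimate (counts
#' over passed reads); uncertainty comes from a seeded percentile
#' bootstrap over reads.
#'
#' @param assignments filtered assignments (see [filter_reads()]); only
#'   rows with `status == "passed"` contribute.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (NULL leaves the RNG alone).
#' @param isoforms isoform universe; defaults to the sorted distinct
#'   best hits among passed reads.
#' @return a `composition_estimate`: `counts`, `proportions` (sum to 1),
#'   `ci` (2.5% / 97.5% percentile bounds per isoform), `n_passed`,
#'   `n_failed`.
#' @export
estimate_composition <- function(assignments, n_boot = 1000, seed = NULL,
                                 isoforms = NULL) {
  passed <- assignments[assignments$status == "passed", , drop = FALSE]
  n_passed <- nrow(passed)
  if (n_passed == 0L) {
    stop("no passed reads: composition undefined", call. = FALSE)
  }
  if (is.null(isoforms)) isoforms <- sort(unique(passed$best_isoform))
  counts <- table(factor(passed$best_isoform, levels = isoforms))
  props <- as.numeric(counts) / n_passed
  ci <- with_seed(seed, {
    boot <- rmultinom(n_boot, n_passed, props) / n_passed
    t(apply(boot, 1, quantile, probs = c(0.025, 0.975)))
  })
  rownames(ci) <- isoforms
  structure(
    list(counts = setNames(as.integer(counts), isoforms),
         proportions = setNames(props, isoforms),
         ci = ci, n_passed = n_passed,
         n_failed = nrow(assignments) - n_passed,
         n_boot = n_boot),
    class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("Isoform composition from", x$n_passed, "passed reads (",
      x$n_failed, "failed )\n")
  df <- data.frame(count = x$counts,
                   proportion = round(x$proportions, 4),
                   ci_lo = round(x$ci[, 1], 4),
                   ci_hi = round(x$ci[, 2], 4))
  print(df)
  invisible(x)
}

#' Closest small-integer ratio for a two-component composition
#'
#' Finds the coprime pair `(a, b)` with `1 <= a, b <= max_part`
#' minimizing `|p1 - a/(a+b)|`; ties are broken by smaller `a + b`, then
#' smaller `a`. Used to design cRNA co-injection mixtures that mimic a
#' measured composition.
#'
#' @param p two-component proportions, strictly positive, summing to 1.
#' @param max_part largest allowed part (default 9).
#' @return named integer vector `c(a = , b = )`.
#' @examples
#' integer_ratio(c(5, 2) / 7)  # 5:2
#' @export
integer_ratio <- function(p, max_part = 9L) {
  if (length(p) != 2L || any(p <= 0)) {
    stop("`p` must be two strictly positive proportions ",
         "(a zero component has no defined ratio)", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6) stop("`p` must sum to 1", call. = FALSE)
  best <- NULL
  for (a in seq_len(max_part)) {
    for (b in seq_len(max_part)) {
      if (gcd2(a, b) != 1L) next
      err <- abs(p[1] - a / (a + b))
      if (is.null(best) ||
          err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 &&
             (a + b < best$a + best$b ||
                (a + b == best$a + best$b && a < best$a)))) {
        best <- list(a = a, b = b, err = err)
      }
    }
  }
  c(a = best$a, b = best$b)
}

gcd2 <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Compare isoform compositions between groups
#'
#' Fits a group-means linear model with Gaussian error to per-replicate
#' proportions of a focal isoform (proportions, not counts, are
#' modelled — fidelity to the established analysis over compositional
#' purity), tests all pairwise contrasts with Tukey HSD studentized
#' statistics, and Benjamini-Hochberg-adjusts across the contrasts.
#'
#' @param df data.frame with columns `group` and `proportion` (one row
#'   per replicate); >= 2 groups with >= 2 replicates each.
#' @return list with `group_means`, `omnibus` (a `phys_test`), and
#'   `pairwise` contrasts (see [anova_tukey()]).
#' @export
compare_compositions <- function(df) {
  if (!all(c("group", "proportion") %in% names(df))) {
    stop("`df` needs columns group and proportion", call. = FALSE)
  }
  groups <- split(df$proportion, df$group)
  if (length(groups) < 2L) stop("at least 2 groups required", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs >= 2 replicates", call. = FALSE)
  }
  res <- anova_tukey(groups, bh = TRUE)
  res$group_means <- vapply(groups, mean, numeric(1))
  res[c("group_means", "omnibus", "pairwise")]
}

#' Transcripts per million from counts and gene lengths
#'
#' `rate_i = counts_i / length_i`; `TPM_i = 1e6 * rate_i / sum(rate)`.
#'
#' @param counts non-negative integer read counts per gene.
#' @param lengths positive gene lengths (bp).
#' @return TPM vector (sums to 1e6 whenever any count is positive).
#' @examples
#' compute_tpm(c(10, 10), c(1000, 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths must have equal length", call. = FALSE)
  }
  if (any(lengths <= 0)) stop("lengths must be > 0", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (all(counts == 0)) {
    warning("all counts are zero: returning all-zero TPM")
    return(numeric(length(counts)))
  }
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}
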