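# Transcript matching, sensitivity/precision and abundance correlation.

#' Match assembled transcripts against reference transcripts
#'
#' Multi-exon transcripts match when they have the same number of exons and
#' identical internal boundary coordinates (the start of the first exon and
#' the end of the last exon are free). Single-exon transcripts match when
#' their overlap reaches 50% of the shorter exon (`basis = "shorter"`,
#' default), of both exons (`"both"`), or of either exon (`"either"`). Each
#' reference and each assembled transcript is matched at most once; ties are
#' resolved greedily by overlap, then by index (deterministic).
#'
#' @param assembled,reference Lists of exon-chain matrices (two columns,
#'   0-based half-open, sorted).
#' @param assembled_chrom,reference_chrom Optional chromosome vectors; chains
#'   on different chromosomes never match.
#' @param basis Single-exon overlap basis.
#' @return A data.table of matched pairs (`assembled`, `reference` indices).
#' @export
match_transcripts <- function(assembled, reference,
                              assembled_chrom = NULL, reference_chrom = NULL,
                              basis = c("shorter", "both", "either")) {
  basis <- match.arg(basis)
  if (is.null(assembled_chrom)) assembled_chrom <- rep(".", length(assembled))
  if (is.null(reference_chrom)) reference_chrom <- rep(".", length(reference))
  n_ex_a <- vapply(assembled, nrow, integer(1))
  n_ex_r <- vapply(reference, nrow, integer(1))
  key_of <- function(m, chrom) {
    n <- nrow(m)
    if (n == 1L) return(NA_character_)
    paste(chrom, n, paste(m[-1L, 1L], collapse = ","),
          paste(m[-n, 2L], collapse = ","), sep = "|")
  }
  ka <- mapply(key_of, assembled, assembled_chrom)
  kr <- mapply(key_of, reference, reference_chrom)
  pairs <- list()
  # multi-exon: exact internal-structure match, one-to-one by index order
  for (k in unique(stats::na.omit(kr))) {
    ai <- which(!is.na(ka) & ka == k)
    ri <- which(!is.na(kr) & kr == k)
    n <- min(length(ai), length(ri))
    if (n > 0L)
      pairs[[length(pairs) + 1L]] <- data.table(assembled = ai[seq_len(n)],
                                                reference = ri[seq_len(n)])
  }
  # single-exon: reciprocal-overlap rule, greedy by overlap
  sa <- which(n_ex_a == 1L); sr <- which(n_ex_r == 1L)
  if (length(sa) > 0L && length(sr) > 0L) {
    cand <- data.table::CJ(ai = sa, ri = sr)
    cand <- cand[assembled_chrom[ai] == reference_chrom[ri]]
    if (nrow(cand) > 0L) {
      a1 <- vapply(assembled[cand$ai], function(m) m[1L, 1L], numeric(1))
      a2 <- vapply(assembled[cand$ai], function(m) m[1L, 2L], numeric(1))
      r1 <- vapply(reference[cand$ri], function(m) m[1L, 1L], numeric(1))
      r2 <- vapply(reference[cand$ri], function(m) m[1L, 2L], numeric(1))
      ov <- pmax(0, pmin(a2, r2) - pmax(a1, r1))
      la <- a2 - a1; lr <- r2 - r1
      okv <- switch(basis,
        shorter = ov >= 0.5 * pmin(la, lr),
        both    = ov >= 0.5 * la & ov >= 0.5 * lr,
        either  = ov >= 0.5 * la | ov >= 0.5 * lr)
      cand <- cand[okv & ov > 0][order(-ov[okv & ov > 0], ai, ri)]
      used_a <- logical(length(assembled)); used_r <- logical(length(reference))
      for (i in seq_len(nrow(cand))) {
        ai <- cand$ai[i]; ri <- cand$ri[i]
        if (!used_a[ai] && !used_r[ri]) {
          used_a[ai] <- TRUE; used_r[ri] <- TRUE
          pairs[[length(pairs) + 1L]] <- data.table(assembled = ai, reference = ri)
        }
      }
    }
  }
  if (length(pairs) == 0L)
    return(data.table(assembled = integer(), reference = integer()))
  data.table::rbindlist(pairs)
}

#' Sensitivity and precision of a reconstruction
#'
#' `sensitivity = N / M` and `precision = N / M'`, where `N` is the number of
#' matched transcripts, `M` the number of reference transcripts and `M'` the
#' number of assembled transcripts; zero denominators yield 0 with a warning.
#'
#' @param matches Matched-pair table from [match_transcripts()] (or an
#'   integer count `N`).
#' @param M Number of reference (expressed) transcripts.
#' @param M_prime Number of assembled transcripts.
#' @return Named list `sensitivity`, `precision`, `N`, `M`, `M_prime`.
#' @export
reconstruction_metrics <- function(matches, M, M_prime) {
  N <- if (is.numeric(matches)) as.integer(matches) else nrow(matches)
  if (N > min(M, M_prime)) stop("more matches than transcripts")
  if (M == 0L) warning("no reference transcripts; sensitivity set to 0")
  if (M_prime == 0L) warning("no assembled transcripts; precision set to 0")
  list(sensitivity = if (M > 0L) N / M else 0,
       precision = if (M_prime > 0L) N / M_prime else 0,
       N = N, M = M, M_prime = M_prime)
}

#' Pearson correlation between true and estimated abundance
#'
#' Computed on matched transcripts only.
#' @param truth,estimate Equal-length numeric vectors (length >= 2).
#' @param log1p Correlate on a log1p scale instead of the raw scale.
#' @return Pearson r in `[-1, 1]`.
#' @export
abundance_correlation <- function(truth, estimate, log1p = FALSE) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 2L)
  if (log1p) { truth <- log1p(truth); estimate <- log1p(estimate) }
  stats::cor(truth, estimate, method = "pearson")
}

#' Evaluate an assembly against simulator ground truth
#'
#' Convenience wrapper: matches the assembled exon chains against the
#' expressed reference transcripts and reports counts, sensitivity,
#' precision, and Pearson correlations (raw and log1p) between true copy
#' numbers and estimated effective-copy counts on the matched set.
#'
#' @param assembled An `annotation` (or path to an assembled GTF).
#' @param truth An `annotation` with `copies` (or path to a truth GTF).
#' @param abundance Optional abundance table (or path) supplying `eT` per
#'   assembled isoform; defaults to the `eT` attribute carried by
#'   `assembled`.
#' @return A list: `M`, `M_prime`, `N`, `sensitivity`, `precision`,
#'   `pearson_r`, `pearson_r_log1p`.
#' @export
evaluate_assembly <- function(assembled, truth, abundance = NULL) {
  if (is.character(assembled)) assembled <- load_annotation(assembled)
  if (is.character(truth)) truth <- load_annotation(truth)
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  ai <- assembled$isoforms; ri <- truth$isoforms
  if (!"copies" %in% names(ri)) stop("truth annotation lacks copy numbers")
  mt <- match_transcripts(ai$exons, ri$exons, ai$chrom, ri$chrom)
  met <- reconstruction_metrics(mt, M = nrow(ri), M_prime = nrow(ai))
  est <- if (!is.null(abundance)) {
    abundance$eT[match(ai$isoform_id, abundance$isoform_id)]
  } else if ("eT" %in% names(ai)) ai$eT else NULL
  r <- r_log <- NA_real_
  if (!is.null(est) && nrow(mt) >= 2L) {
    y <- as.numeric(ri$copies[mt$reference])
    yhat <- as.numeric(est[mt$assembled])
    if (stats::sd(y) > 0 && stats::sd(yhat) > 0) {
      r <- abundance_correlation(y, yhat)
      r_log <- abundance_correlation(y, yhat, log1p = TRUE)
    }
  }
  c(met, list(pearson_r = r, pearson_r_log1p = r_log))
}
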