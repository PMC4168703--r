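# End-to-end assembly pipeline: alignments -> splice graphs -> size model ->
# per-locus flow assembly -> isoform and abundance tables.

#' Spliced fragment sizes observed in a locus
#'
#' Transcript-coordinate size of each fragment (5' mate start to 3' mate
#' end), measured along the shortest splice-graph path connecting the mates.
#' Used to fit the size model before the flow networks are built.
#'
#' @param fragments `fragments` table.
#' @param graph A `splice_graph`.
#' @param chains Optional precomputed read chains (see
#'   `locus_read_chains()`).
#' @return Numeric vector (NA for fragments that cannot be embedded).
#' @export
fragment_spliced_lengths <- function(fragments, graph, chains = NULL) {
  fr <- fragments[fragments$fragment_id %in% graph$fragment_ids]
  if (nrow(fr) == 0L) return(numeric(0))
  if (is.null(chains)) chains <- lapply(fr$blocks, function(b) map_blocks_to_exons(graph, b))
  dt <- data.table(fragment_id = fr$fragment_id, role = fr$role,
                   start = fr$start, end = fr$end,
                   ok = !vapply(chains, is.null, logical(1)),
                   firstEx = vapply(chains, function(ch) if (is.null(ch)) NA_integer_ else ch[1L], integer(1)),
                   lastEx = vapply(chains, function(ch) if (is.null(ch)) NA_integer_ else ch[length(ch)], integer(1)))
  m5 <- dt[role == "m5"]; m3 <- dt[role == "m3"]
  fx <- merge(m5[, .(fragment_id, start5 = start, A = firstEx, ok5 = ok)],
              m3[, .(fragment_id, end3 = end, B = lastEx, ok3 = ok)],
              by = "fragment_id")
  ex <- graph$exons
  elen <- ex$end - ex$start
  out <- rep(NA_real_, nrow(fx))
  for (i in seq_len(nrow(fx))) {
    if (!fx$ok5[i] || !fx$ok3[i]) next
    paths <- enumerate_connecting_paths(graph, fx$A[i], fx$B[i], max_paths = 8L)
    if (length(paths) == 0L) next
    p <- paths[[1L]]                       # shortest spliced length first
    out[i] <- if (length(p) == 1L) fx$end3[i] - fx$start5[i]
              else (ex$end[fx$A[i]] - fx$start5[i]) +
                   sum(elen[p[-c(1L, length(p))]]) +
                   (fx$end3[i] - ex$start[fx$B[i]])
  }
  out
}

# Estimate the size-selection window from observed sizes: the selection's
# left edge shows as the mode of the (10 bp binned) size histogram — values
# below it are path-measurement artifacts — and the right edge as the upper
# 99.9th percentile.
estimate_size_window <- function(lens) {
  br <- seq(floor(min(lens) / 10) * 10, ceiling(max(lens) / 10) * 10, by = 10)
  h <- hist(lens, breaks = br, plot = FALSE)
  lo <- h$mids[which.max(h$counts)] - 5
  hi <- unname(stats::quantile(lens, 0.999))
  c(lo, hi)
}

#' Assemble transcripts genome-wide from paired-end alignments
#'
#' The full pipeline: load fragments from SAM/BAM, build per-locus splice
#' graphs, fit the Weibull size model on the observed spliced fragment sizes,
#' assemble every locus by min-cost flow ([assemble_locus()]), and collect
#' isoforms, copies and abundance (eT, eTPM, FPKM, TPM) across loci.
#'
#' @param sam_path Path to SAM/BAM, or an existing `fragments` table.
#' @param annotation_path Optional GTF path (or `annotation`) supplying
#'   TSS/TES positions.
#' @param min_mapq Mapping-quality cutoff for input pairs (default 10).
#' @param min_coverage,min_junction_reads Splice-graph thresholds (default 1).
#' @param tau Effectiveness significance level (default 0.05).
#' @param gamma Compression radius in bp; `NULL` (default) uses half the
#'   expected fragment size; 0 restricts clustering to exact duplicates.
#' @param penalties Apply MultiSplice penalties (default TRUE).
#' @param read_length Read length for the penalty sampling window (default:
#'   inferred median mate span).
#' @param model Optional pre-fitted `weibull_size_model` (default: fitted on
#'   the data).
#' @param size_selection Optional `c(lo, hi)` size-selection window of the
#'   library prep. Observed fragment sizes are a windowed sample of the
#'   fragmentation process, so the size model is fitted by truncated maximum
#'   likelihood on this window; when not supplied the window is estimated
#'   from the data (left edge at the mode of the size histogram, right edge
#'   at the 99.9th percentile).
#' @param options Further [assemble_locus()] options.
#' @return An `astroid_result` list: `isoforms` (annotation-style table with
#'   `eT`, `N`, `n_copies`), `abundance` (with eTPM/FPKM/TPM), `copies`,
#'   `model`, `expected_fragment_length`, `n_loci`.
#' @export
astroid_assemble <- function(sam_path, annotation_path = NULL, min_mapq = 10L,
                             min_coverage = 1, min_junction_reads = 1L,
                             tau = 0.05, gamma = NULL, penalties = TRUE,
                             read_length = NULL, model = NULL,
                             size_selection = NULL, options = list()) {
  frs <- if (inherits(sam_path, "fragments")) sam_path
         else load_fragments(sam_path, min_mapq = min_mapq)
  ann <- if (is.null(annotation_path)) NULL
         else if (inherits(annotation_path, "annotation")) annotation_path
         else load_annotation(annotation_path)
  if (nrow(frs) == 0L) stop("no usable fragments")
  graphs <- list()
  for (chr in unique(frs$chrom)) {
    graphs <- c(graphs, build_splice_graph(frs[frs$chrom == chr],
                                           min_coverage = min_coverage,
                                           min_junction_reads = min_junction_reads))
  }
  if (is.null(read_length))
    read_length <- as.integer(stats::median(frs$end - frs$start))
  chains_by_locus <- lapply(graphs, function(g) locus_read_chains(frs, g))
  lens <- unlist(mapply(function(g, ch) fragment_spliced_lengths(frs, g, ch),
                        graphs, chains_by_locus, SIMPLIFY = FALSE))
  lens <- lens[!is.na(lens) & lens > 0]
  if (is.null(model)) {
    win <- size_selection
    if (is.null(win) && length(lens) >= 100L) win <- estimate_size_window(lens)
    model <- fit_size_model(lens, truncation = win)
  }
  len_r <- if (length(lens) > 0) mean(lens) else model$eta
  opts <- modifyList(list(tau = tau, gamma = gamma, penalties = penalties,
                          read_length = read_length, annotation = ann),
                     options)
  iso_parts <- list(); copies <- list(); objective <- 0
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    opts$chains <- chains_by_locus[[gi]]
    res <- assemble_locus(frs, g, model, opts)
    objective <- objective + res$objective
    copies <- c(copies, res$copies)
    if (nrow(res$isoforms) > 0L) {
      it <- data.table::copy(res$isoforms)
      it[, locus_id := res$locus_id]
      iso_parts[[length(iso_parts) + 1L]] <- it
    }
  }
  isoforms <- if (length(iso_parts) > 0L) data.table::rbindlist(iso_parts)
              else empty_assembly("")$isoforms[, locus_id := character(0)][]
  if (nrow(isoforms) > 0L) {
    isoforms[, gene_id := paste0("ASTLOC.", as.integer(factor(locus_id)))]
    isoforms[, isoform_id := paste0(gene_id, ".", seq_len(.N)), by = gene_id]
    isoforms[, strand := "."]
    isoforms[, length := vapply(exons, function(m) sum(m[, 2L] - m[, 1L]), numeric(1))]
  } else {
    isoforms[, `:=`(gene_id = character(0), isoform_id = character(0),
                    strand = character(0), length = numeric(0))]
  }
  abundance <- compute_abundance(
    isoforms[, .(isoform_id, gene_id, length, eT, N)],
    expected_fragment_length = len_r)
  if (nrow(isoforms) > 0L) {
    abundance[, chrom := isoforms$chrom[match(isoform_id, isoforms$isoform_id)]]
    abundance[, strand := "."]
    abundance[, exon_chain := vapply(isoforms$exons[match(isoform_id, isoforms$isoform_id)],
                                     format_exon_chain, character(1))]
  }
  structure(list(isoforms = isoforms, abundance = abundance, copies = copies,
                 model = model, expected_fragment_length = len_r,
                 n_loci = length(graphs), objective = objective),
            class = "astroid_result")
}

#' @export
print.astroid_result <- function(x, ...) {
  cat("astroid assembly:", x$n_loci, "loci,", length(x$copies), "copies,",
      nrow(x$isoforms), "isoform chains (", sum(x$isoforms$eT > 0),
      "with eT > 0 )\n")
  invisible(x)
}

#' Write assembly outputs (GTF, abundance table, per-copy diagnostics)
#'
#' `<prefix>.transcripts.gtf` holds the isoforms with at least one effective
#' copy; `<prefix>.abundance.tsv` the abundance table for all assembled
#' chains; `<prefix>.copies.tsv` one row per reconstructed copy (fragment
#' count, gap lengths, likelihood, p-value, effective flag). Ineffective
#' copies are kept in the diagnostics but contribute nothing to eT.
#'
#' @param result An `astroid_result`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
astroid_write_outputs <- function(result, prefix) {
  iso <- result$isoforms
  gtf <- paste0(prefix, ".transcripts.gtf")
  ab <- paste0(prefix, ".abundance.tsv")
  cpt <- paste0(prefix, ".copies.tsv")
  sel <- data.table::copy(iso[iso$eT > 0L])
  sel[, eTPM := result$abundance$eTPM[match(isoform_id, result$abundance$isoform_id)]]
  write_gtf(sel, gtf)
  write_abundance(result$abundance, ab)
  cp <- data.table(
    locus_id = vapply(result$copies, `[[`, character(1), "locus_id"),
    n_fragments = vapply(result$copies, function(x) length(x$fragment_ids), integer(1)),
    fragments = vapply(result$copies, function(x) paste(x$fragment_ids, collapse = ","), character(1)),
    fragment_lengths = vapply(result$copies, function(x) paste(x$fragment_lengths, collapse = ","), character(1)),
    gap_lengths = vapply(result$copies, function(x) paste(x$gap_lengths, collapse = ","), character(1)),
    likelihood = vapply(result$copies, `[[`, numeric(1), "likelihood"),
    pvalue = vapply(result$copies, `[[`, numeric(1), "pvalue"),
    effective = vapply(result$copies, function(x) isTRUE(x$effective), logical(1)))
  data.table::fwrite(cp, cpt, sep = "\t")
  invisible(c(gtf, ab, cpt))
}

#' Assembled isoforms as an annotation object
#'
#' Restricts to chains with at least one effective copy by default, for
#' direct use with [evaluate_assembly()].
#' @param result An `astroid_result`.
#' @param effective_only Keep only isoforms with `eT > 0` (default TRUE).
#' @return An `annotation` whose isoforms carry `eT`.
#' @export
as_annotation <- function(result, effective_only = TRUE) {
  iso <- data.table::copy(result$isoforms)
  if (effective_only) iso <- iso[iso$eT > 0L]
  out <- iso[, .(isoform_id, gene_id, chrom, strand, exons, length, eT)]
  structure(list(isoforms = out[]), class = "annotation")
}
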