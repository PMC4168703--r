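# RNA-seq simulator: random annotation fixture, copy-number profiles,
# uniform-breakpoint fragmentation with size selection, and SAM emission
# with ground truth.

#' Generate a random transcript annotation fixture
#'
#' Random genes laid out along one synthetic chromosome: 1-10 exons of
#' 80-500 bp separated by 200-2000 bp introns, 1-4 isoforms per gene obtained
#' by skipping random subsets of internal exons (so isoforms of one gene
#' share their terminal exons). Genes are spaced far enough apart to form
#' separate loci.
#'
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @param n_exons_range,exon_len_range,intron_len_range,n_isoforms_range
#'   Integer ranges (inclusive) for the gene architecture.
#' @param chrom Chromosome name.
#' @param gene_spacing Gap between consecutive genes (default 20000).
#' @return An `annotation` object.
#' @export
random_annotation <- function(n_genes = 50L, seed = 1L,
                              n_exons_range = c(1L, 10L),
                              exon_len_range = c(80L, 500L),
                              intron_len_range = c(200L, 2000L),
                              n_isoforms_range = c(1L, 4L),
                              chrom = "sim1", gene_spacing = 20000L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  cursor <- 1000L
  for (g in seq_len(n_genes)) {
    n_ex <- sample(n_exons_range[1L]:n_exons_range[2L], 1L)
    elen <- sample(exon_len_range[1L]:exon_len_range[2L], n_ex, replace = TRUE)
    ilen <- if (n_ex > 1L)
      sample(intron_len_range[1L]:intron_len_range[2L], n_ex - 1L, replace = TRUE)
    else integer(0)
    starts <- cursor + cumsum(c(0L, head(elen, -1L) + ilen))
    ends <- starts + elen
    cursor <- ends[n_ex] + gene_spacing
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("G%04d", g)
    full <- seq_len(n_ex)
    chains <- list(full)
    n_iso <- sample(n_isoforms_range[1L]:n_isoforms_range[2L], 1L)
    if (n_ex >= 3L) {
      tries <- 0L
      while (length(chains) < n_iso && tries < 20L) {
        tries <- tries + 1L
        nskip <- sample(seq_len(max(1L, n_ex - 2L)), 1L)
        skip <- sort(sample(2L:(n_ex - 1L), min(nskip, n_ex - 2L)))
        cand <- setdiff(full, skip)
        if (!any(vapply(chains, identical, logical(1), y = cand)))
          chains[[length(chains) + 1L]] <- cand
      }
    }
    for (i in seq_along(chains)) {
      idx <- chains[[i]]
      rows[[length(rows) + 1L]] <- data.table(
        isoform_id = sprintf("%s.%d", gene_id, i), gene_id = gene_id,
        chrom = chrom, strand = strand,
        exons = list(cbind(start = starts[idx], end = ends[idx])))
    }
  }
  iso <- data.table::rbindlist(rows)
  iso[, length := vapply(exons, function(m) sum(m[, 2L] - m[, 1L]), numeric(1))]
  structure(list(isoforms = iso[]), class = "annotation")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assign random copy numbers to isoforms
#'
#' Each isoform independently receives a copy number uniform on
#' `{0, ..., max_copies}`; deterministic for a fixed seed.
#'
#' @param annotation An `annotation`.
#' @param max_copies Maximum copy number (default 20).
#' @param seed RNG seed.
#' @return An `expression_profile` data.table: `isoform_id`, `gene_id`,
#'   `copies`.
#' @export
simulate_profile <- function(annotation, max_copies = 20L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  iso <- annotation$isoforms
  out <- data.table(isoform_id = iso$isoform_id, gene_id = iso$gene_id,
                    copies = if (max_copies == 0L) rep(0L, nrow(iso))
                             else sample(0L:max_copies, nrow(iso), replace = TRUE))
  data.table::setattr(out, "class", c("expression_profile", class(out)))
  out[]
}

#' Fragment transcript copies and size-select a sequencing library
#'
#' Each drawn transcript copy is cut by a uniform breakpoint (Poisson)
#' process with mean spacing `eta`; fragments whose length falls in
#' `size_range` are retained (hard window by default; optional triangular
#' acceptance probability peaking mid-window). Copies are drawn with
#' replacement, weighted by the profile's copy numbers, until the retained
#' library reaches `target_depth` fragments. Transcript intervals are
#' projected through the isoform's exon chain to genomic blocks.
#'
#' @param profile An `expression_profile`.
#' @param annotation The matching `annotation`.
#' @param eta Mean breakpoint spacing = Weibull scale of the pre-selection
#'   fragment size distribution (default 200).
#' @param size_range Retained length window, default `c(150, 350)`.
#' @param target_depth Number of retained fragments to generate.
#' @param seed RNG seed.
#' @param acceptance `"hard"` (default) or `"triangular"`.
#' @return A `sim_fragments` data.table: `fragment_id`, `isoform_id`,
#'   `gene_id`, `copy_index`, `tx_start`, `tx_end`, `chrom`, `strand`,
#'   `blocks` (list of genomic block matrices).
#' @export
simulate_fragments <- function(profile, annotation, eta = 200,
                               size_range = c(150L, 350L),
                               target_depth = 1000L, seed = 1L,
                               acceptance = c("hard", "triangular")) {
  acceptance <- match.arg(acceptance)
  stopifnot(size_range[1L] < size_range[2L], eta > 0)
  iso <- annotation$isoforms
  expr <- profile[profile$copies > 0L]
  expr <- expr[expr$isoform_id %in% iso$isoform_id]
  ilen <- iso$length[match(expr$isoform_id, iso$isoform_id)]
  ok <- ilen >= size_range[1L]
  if (!any(ok)) stop("no expressed isoform is longer than the size window")
  expr <- expr[ok]; ilen <- ilen[ok]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lo <- size_range[1L]; hi <- size_range[2L]
  parts <- list(); total <- 0L; copy_counter <- 0L
  w <- expr$copies / sum(expr$copies)
  while (total < target_depth) {
    i <- sample.int(nrow(expr), 1L, prob = w)
    L <- ilen[i]
    copy_counter <- copy_counter + 1L
    cuts <- cumsum(rexp(ceiling(L / eta) + 10L, rate = 1 / eta))
    cuts <- cuts[cuts < L]
    b <- unique(as.integer(round(c(0, cuts, L))))
    flen <- diff(b)
    keep <- flen >= lo & flen <= hi
    if (acceptance == "triangular" && any(keep)) {
      mid <- (lo + hi) / 2
      p <- 1 - abs(flen - mid) / (mid - lo)
      keep <- keep & (runif(length(flen)) < pmax(p, 0))
    }
    if (!any(keep)) next
    parts[[length(parts) + 1L]] <- data.table(
      isoform_id = expr$isoform_id[i], gene_id = expr$gene_id[i],
      copy_index = copy_counter,
      tx_start = b[-length(b)][keep], tx_end = b[-1L][keep])
    total <- total + sum(keep)
  }
  out <- data.table::rbindlist(parts)
  out[, fragment_id := sprintf("frag%07d", seq_len(.N))]
  m <- match(out$isoform_id, iso$isoform_id)
  out[, `:=`(chrom = iso$chrom[m], strand = iso$strand[m])]
  out[, blocks := project_intervals(iso$exons[m], tx_start, tx_end)]
  data.table::setcolorder(out, c("fragment_id", "isoform_id", "gene_id",
                                 "copy_index", "tx_start", "tx_end",
                                 "chrom", "strand", "blocks"))
  data.table::setattr(out, "class", c("sim_fragments", class(out)))
  out[]
}

# Project transcript-coordinate intervals [s, e) through exon chains to
# genomic block matrices (0-based half-open).
project_intervals <- function(exon_list, s, e) {
  mapply(function(ex, s1, e1) {
    elen <- ex[, 2L] - ex[, 1L]
    off <- cumsum(c(0L, elen))        # transcript offset at exon starts
    n <- nrow(ex)
    bs <- pmax(s1, off[seq_len(n)])
    be <- pmin(e1, off[-1L])
    hit <- which(be > bs)
    cbind(start = ex[hit, 1L] + (bs[hit] - off[hit]),
          end = ex[hit, 1L] + (be[hit] - off[hit]))
  }, exon_list, s, e, SIMPLIFY = FALSE)
}

#' Write simulated paired-end alignments (SAM) and ground truth (GTF)
#'
#' Samples a read of `read_length` bases from each end of every fragment,
#' projects both through the isoform's exon chain (CIGARs get N operations
#' across introns), and writes a coordinate-sorted SAM file of perfect
#' proper pairs (MAPQ 60) plus a truth GTF of the expressed isoforms
#' annotated with their copy numbers. Round-trips through
#' [load_fragments()] / [load_annotation()].
#'
#' @param fragments A `sim_fragments` table.
#' @param read_length Read length (default 75); must not exceed the shortest
#'   fragment.
#' @param out_sam Output SAM path.
#' @param out_truth_gtf Optional output truth GTF path.
#' @param annotation The `annotation` (required for the truth GTF).
#' @param profile The `expression_profile` (required for the truth GTF).
#' @return Invisibly, the number of read pairs written.
#' @export
emit_alignments <- function(fragments, read_length = 75L, out_sam,
                            out_truth_gtf = NULL, annotation = NULL,
                            profile = NULL) {
  flen <- fragments$tx_end - fragments$tx_start
  if (any(flen < read_length))
    stop("read_length exceeds the shortest fragment length")
  iso <- if (!is.null(annotation)) annotation$isoforms else NULL
  m <- if (!is.null(iso)) match(fragments$isoform_id, iso$isoform_id) else NULL
  exon_list <- if (!is.null(iso)) iso$exons[m] else
    stop("annotation is required to project reads")
  left <- project_intervals(exon_list, fragments$tx_start,
                            fragments$tx_start + read_length)
  right <- project_intervals(exon_list, fragments$tx_end - read_length,
                             fragments$tx_end)
  cigar_of <- function(b) {
    n <- nrow(b)
    ops <- sprintf("%dM", b[, 2L] - b[, 1L])
    if (n == 1L) return(ops)
    gaps <- sprintf("%dN", b[-1L, 1L] - b[-n, 2L])
    paste0(paste0(ops[-n], gaps, collapse = ""), ops[n])
  }
  lpos <- vapply(left, function(b) b[1L, 1L], numeric(1))
  rpos <- vapply(right, function(b) b[1L, 1L], numeric(1))
  rend <- vapply(right, function(b) b[nrow(b), 2L], numeric(1))
  tlen <- rend - lpos
  recs <- data.table(
    qname = rep(fragments$fragment_id, 2L),
    flag = rep(c(99L, 147L), each = nrow(fragments)),
    rname = rep(fragments$chrom, 2L),
    pos = c(lpos, rpos) + 1L,
    mapq = 60L,
    cigar = c(vapply(left, cigar_of, character(1)),
              vapply(right, cigar_of, character(1))),
    rnext = "=",
    pnext = c(rpos, lpos) + 1L,
    tlen = c(tlen, -tlen))
  data.table::setorder(recs, rname, pos)
  chrlens <- recs[, .(len = max(pos) + 2L * read_length + 1000L), by = rname]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrlens$rname, as.integer(chrlens$len)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
                  recs$qname, recs$flag, recs$rname, as.integer(recs$pos),
                  recs$mapq, recs$cigar, recs$rnext, as.integer(recs$pnext),
                  as.integer(recs$tlen))
  writeLines(c(hdr, body), out_sam)
  if (!is.null(out_truth_gtf)) {
    if (is.null(profile)) stop("profile required for the truth GTF")
    expressed <- profile[profile$copies > 0L]
    tru <- iso[iso$isoform_id %in% expressed$isoform_id]
    tru <- data.table::copy(tru)
    tru[, copies := expressed$copies[match(isoform_id, expressed$isoform_id)]]
    write_gtf(tru, out_truth_gtf)
  }
  invisible(nrow(fragments))
}
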