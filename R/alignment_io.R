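#' @useDynLib astroid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats dweibull pweibull rexp runif setNames uniroot optim
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end) everywhere.
# GTF I/O converts to/from 1-based closed at the boundary and nowhere else.

#' Read properly-paired spliced alignments into fragments
#'
#' Parses a SAM or BAM file and returns one fragment per properly mated read
#' pair whose two mates both pass the mapping-quality cutoff. Each fragment is
#' the sampling unit of the copy model: a mate pair of (possibly spliced) read
#' alignments. Secondary and supplementary alignments, unmated reads, and
#' pairs with mates on different chromosomes are discarded (and counted).
#'
#' @param sam_path Path to a SAM or BAM file.
#' @param min_mapq Minimum mapping quality required of both mates (default 10).
#' @return A `data.table` of class `fragments` with two rows per fragment (one
#'   per mate). Columns: `fragment_id`, `read_uid`, `mate` (1/2), `role`
#'   (`"m5"` for the transcript-upstream mate, `"m3"` downstream), `chrom`,
#'   `strand`, `start`, `end` (0-based half-open outer span), `blocks`
#'   (list column of two-column matrices, 0-based half-open), `mapq`,
#'   `spliced`, `junc` (junction signature string). Attributes `n_pairs_input`
#'   and `n_filtered` record the filtering bookkeeping.
#' @export
load_fragments <- function(sam_path, min_mapq = 10L) {
  if (!file.exists(sam_path)) stop("no such file: ", sam_path)
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(sam_path, destination = dest, overwrite = TRUE,
                       indexDestination = TRUE),
      error = function(e) stop("unparseable SAM file: ", conditionMessage(e)))
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "flag"))
  gp <- suppressWarnings(GenomicAlignments::readGAlignmentPairs(
    bam, use.names = TRUE, param = param))
  # number of primary mapped records -> input pair estimate
  cb <- Rsamtools::countBam(bam, param = Rsamtools::ScanBamParam(flag = flag))
  n_pairs_input <- cb$records %/% 2L

  if (length(gp) == 0L) {
    warning("no valid read pairs in ", sam_path)
    return(empty_fragments(n_pairs_input, n_pairs_input))
  }
  f <- GenomicAlignments::first(gp)
  l <- GenomicAlignments::last(gp)
  same_chrom <- as.character(GenomicAlignments::seqnames(f)) ==
    as.character(GenomicAlignments::seqnames(l))
  mq_ok <- !is.na(S4Vectors::mcols(f)$mapq) & !is.na(S4Vectors::mcols(l)$mapq) &
    S4Vectors::mcols(f)$mapq >= min_mapq & S4Vectors::mcols(l)$mapq >= min_mapq
  keep <- same_chrom & mq_ok
  n_filtered <- n_pairs_input - sum(keep)
  if (!any(keep)) {
    warning("no read pairs pass filters in ", sam_path)
    return(empty_fragments(n_pairs_input, n_filtered))
  }
  gp <- gp[keep]; f <- f[keep]; l <- l[keep]

  rows <- function(ga, mate) {
    bl <- GenomicAlignments::grglist(ga)        # 1-based closed blocks
    fl <- unlist(bl, use.names = FALSE)
    nb <- S4Vectors::elementNROWS(bl)
    bs <- GenomicRanges::start(fl) - 1L         # to 0-based half-open
    be <- GenomicRanges::end(fl)
    grp <- rep.int(seq_along(nb), nb)
    blocks <- split.data.frame(cbind(start = bs, end = be), grp)
    first <- cumsum(c(1L, nb[-length(nb)]))
    last <- cumsum(nb)
    # junction signature per read, vectorized over flat block vectors
    junc <- rep("", length(nb))
    sp <- nb > 1L
    if (any(sp)) {
      inner <- grp[-1L] == grp[-length(grp)]
      jd <- data.table(grp = grp[-length(grp)][inner],
                       d = be[-length(be)][inner], a = bs[-1L][inner])
      js <- jd[, .(s = paste(d, a, sep = "-", collapse = ";")), by = grp]
      junc[js$grp] <- js$s
    }
    data.table(
      fragment_id = names(gp),
      mate = mate,
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      strand = as.character(GenomicAlignments::strand(ga)),
      start = bs[first], end = be[last],
      blocks = blocks,
      mapq = as.integer(S4Vectors::mcols(ga)$mapq),
      spliced = sp,
      junc = junc)
  }
  dt <- rbind(rows(f, 1L), rows(l, 2L))
  fr <- fragments_from_reads(dt)
  data.table::setattr(fr, "n_pairs_input", n_pairs_input)
  data.table::setattr(fr, "n_filtered", n_filtered)
  fr
}

junction_signature <- function(blocks) {
  n <- nrow(blocks)
  if (n < 2L) return("")
  paste(blocks[-n, 2L], blocks[-1L, 1L], sep = "-", collapse = ";")
}

#' Assemble a fragments table from per-read rows
#'
#' Internal constructor shared by [load_fragments()] and the simulator.
#' Assigns the `m5`/`m3` roles (genomically left mate is `m5`; the flow model
#' is orientation-symmetric and loci are processed left-to-right) and unique
#' read ids.
#' @param dt data.table with columns fragment_id, mate, chrom, strand, start,
#'   end, blocks, mapq, spliced, junc (two rows per fragment).
#' @return `fragments` data.table.
#' @keywords internal
fragments_from_reads <- function(dt) {
  dt <- data.table::copy(dt)
  data.table::setorder(dt, fragment_id, mate)
  dt[, role := {
    if (.N != 2L) rep(NA_character_, .N)
    else if (start[1L] < start[2L] || (start[1L] == start[2L] && mate[1L] == 1L))
      c("m5", "m3") else c("m3", "m5")
  }, by = fragment_id]
  dt <- dt[!is.na(role)]
  data.table::setorder(dt, start, end, fragment_id, role)
  dt[, read_uid := seq_len(.N)]
  data.table::setattr(dt, "class", c("fragments", class(dt)))
  dt[]
}

empty_fragments <- function(n_pairs_input = 0L, n_filtered = 0L) {
  dt <- data.table(fragment_id = character(), mate = integer(),
                   chrom = character(), strand = character(),
                   start = integer(), end = integer(), blocks = list(),
                   mapq = integer(), spliced = logical(), junc = character(),
                   role = character(), read_uid = integer())
  data.table::setattr(dt, "class", c("fragments", class(dt)))
  data.table::setattr(dt, "n_pairs_input", n_pairs_input)
  data.table::setattr(dt, "n_filtered", n_filtered)
  dt
}

#' Number of fragments in a fragments table
#' @param fragments A `fragments` table.
#' @return Integer count of mate pairs.
#' @export
n_fragments <- function(fragments) {
  length(unique(fragments$fragment_id))
}

#' Load a transcript annotation from GTF
#'
#' Reads exon features from a GTF file, groups them into isoforms and converts
#' coordinates from GTF 1-based closed to the internal 0-based half-open
#' convention. Records without a `transcript_id` are skipped with a warning.
#'
#' @param gtf_path Path to a GTF file.
#' @return An object of class `annotation`: a list with element `isoforms`, a
#'   `data.table` with columns `isoform_id`, `gene_id`, `chrom`, `strand`,
#'   `exons` (list column of sorted two-column matrices, 0-based half-open)
#'   and `length` (spliced length). Extra numeric attributes present on
#'   transcript records (e.g. `copies` in simulator truth files) are carried
#'   through when available.
#' @export
load_annotation <- function(gtf_path) {
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0L) return(empty_annotation())
  ex <- gr[tolower(gr$type) == "exon"]
  if (length(ex) == 0L) return(empty_annotation())
  tid <- ex$transcript_id
  if (any(is.na(tid))) {
    warning(sum(is.na(tid)), " exon records without transcript_id skipped")
    ex <- ex[!is.na(tid)]
    tid <- ex$transcript_id
  }
  if (length(ex) == 0L) return(empty_annotation())
  gid <- if (!is.null(ex$gene_id)) ex$gene_id else tid
  dt <- data.table(
    isoform_id = tid, gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex))
  iso <- dt[, {
    o <- order(start)
    list(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
         exons = list(cbind(start = start[o], end = end[o])))
  }, by = isoform_id]
  iso[, length := vapply(exons, function(m) sum(m[, 2L] - m[, 1L]), numeric(1))]
  # carry copy-number attribute if present (simulator truth GTF)
  tr <- gr[tolower(gr$type) == "transcript"]
  if (length(tr) > 0L && !is.null(tr$copies)) {
    cp <- data.table(isoform_id = tr$transcript_id,
                     copies = suppressWarnings(as.numeric(tr$copies)))
    iso <- merge(iso, cp, by = "isoform_id", all.x = TRUE, sort = FALSE)
  }
  data.table::setorder(iso, gene_id, isoform_id)
  structure(list(isoforms = iso[]), class = "annotation")
}

empty_annotation <- function() {
  structure(list(isoforms = data.table(
    isoform_id = character(), gene_id = character(), chrom = character(),
    strand = character(), exons = list(), length = numeric())),
    class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("annotation:", nrow(x$isoforms), "isoforms,",
      length(unique(x$isoforms$gene_id)), "genes\n")
  invisible(x)
}

#' Write isoforms to GTF
#'
#' Emits one `transcript` record plus per-exon records per isoform,
#' converting internal 0-based half-open coordinates back to GTF 1-based
#' closed. Round-trips through [load_annotation()].
#'
#' @param isoforms A `data.table`/`data.frame` with columns `isoform_id`,
#'   `gene_id`, `chrom`, `strand` and `exons` (list column of two-column
#'   matrices); optional numeric columns `eT`, `eTPM`, `copies` are written as
#'   GTF attributes.
#' @param out_path Output file path.
#' @export
write_gtf <- function(isoforms, out_path) {
  isoforms <- data.table::as.data.table(isoforms)
  con <- file(out_path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 2", con)
  if (nrow(isoforms) == 0L) return(invisible(NULL))
  extra_cols <- intersect(c("eT", "eTPM", "copies"), names(isoforms))
  lines <- character(0)
  for (i in seq_len(nrow(isoforms))) {
    ex <- isoforms$exons[[i]]
    strand <- isoforms$strand[i]
    if (is.na(strand) || !strand %in% c("+", "-")) strand <- "+"
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     isoforms$gene_id[i], isoforms$isoform_id[i])
    for (cc in extra_cols) {
      v <- isoforms[[cc]][i]
      if (!is.na(v)) attrs <- paste0(attrs, sprintf(' %s "%s";', cc, format(v, digits = 10)))
    }
    lines <- c(lines, sprintf("%s\tastroid\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              isoforms$chrom[i], ex[1L, 1L] + 1L,
                              ex[nrow(ex), 2L], strand, attrs))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf("%s\tastroid\texon\t%d\t%d\t.\t%s\t.\t%s",
                                isoforms$chrom[i], ex[j, 1L] + 1L, ex[j, 2L],
                                strand, attrs))
    }
  }
  writeLines(lines, con)
  invisible(NULL)
}

#' Write an abundance table
#'
#' Tab-separated output with fixed column order `isoform_id`, `gene_id`,
#' `chrom`, `strand`, `exon_chain`, `eT`, `eTPM`, `FPKM`, `TPM`, rows ordered
#' by (`gene_id`, `isoform_id`). Refuses to write a table violating the
#' per-million conservation invariant.
#'
#' @param table An abundance `data.table` as produced by [compute_abundance()]
#'   (optionally with `chrom`, `strand`, `exon_chain` columns; missing
#'   descriptive columns are filled with `"."`).
#' @param out_path Output file path.
#' @export
write_abundance <- function(table, out_path) {
  table <- data.table::as.data.table(table)
  req <- c("isoform_id", "gene_id", "eT", "eTPM", "FPKM", "TPM")
  if (!all(req %in% names(table))) stop("missing abundance columns")
  if (nrow(table) > 0L && any(table$eT < 0)) stop("negative eT")
  if (nrow(table) > 0L && sum(table$eT) > 0) {
    s <- sum(table$eTPM)
    if (abs(s - 1e6) > 1e-6 * 1e6) stop("eTPM does not sum to 1e6: ", s)
  }
  for (cc in c("chrom", "strand", "exon_chain"))
    if (!cc %in% names(table))
      data.table::set(table, j = cc, value = rep(".", nrow(table)))
  out <- table[, c("isoform_id", "gene_id", "chrom", "strand", "exon_chain",
                   "eT", "eTPM", "FPKM", "TPM"), with = FALSE]
  data.table::setorder(out, gene_id, isoform_id)
  data.table::fwrite(out, out_path, sep = "\t")
  invisible(NULL)
}

#' Read an abundance table written by [write_abundance()]
#' @param path Path to the TSV file.
#' @return A `data.table`.
#' @export
read_abundance <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' Format an exon chain as a human-readable string
#'
#' Exon intervals are printed 1-based closed (GTF style), comma-separated.
#' @param exons Two-column matrix of 0-based half-open exon intervals.
#' @return A single string, e.g. `"101-200,301-400"`.
#' @export
format_exon_chain <- function(exons) {
  paste(sprintf("%d-%d", exons[, 1L] + 1L, exons[, 2L]), collapse = ",")
}
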