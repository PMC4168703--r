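# Shared fixture builders: everything is generated in code at test time.

# Build a fragments table directly from block specifications.
# spec: list of list(blocks5 = matrix, blocks3 = matrix, mapq = 60)
make_fragments <- function(spec, chrom = "chrT") {
  rows <- list()
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    mapq <- if (is.null(s$mapq)) 60L else s$mapq
    for (side in c("blocks5", "blocks3")) {
      b <- s[[side]]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        fragment_id = sprintf("f%04d", i),
        mate = if (side == "blocks5") 1L else 2L,
        chrom = chrom, strand = "+",
        start = b[1L, 1L], end = b[nrow(b), 2L],
        blocks = list(b), mapq = mapq,
        spliced = nrow(b) > 1L,
        junc = astroid:::junction_signature(b))
    }
  }
  astroid:::fragments_from_reads(data.table::rbindlist(rows))
}

# Unspliced fragment helper: mate pair of read_len-long reads with outer span
# [start, start + flen). The default read length makes the mates abut so a
# lone fragment still gives contiguous coverage (no spurious locus split).
unspliced_frag <- function(start, flen, read_len = NULL, mapq = 60L) {
  if (is.null(read_len)) read_len <- as.integer(ceiling(flen / 2))
  list(blocks5 = cbind(start, start + read_len),
       blocks3 = cbind(start + flen - read_len, start + flen),
       mapq = mapq)
}

# Reads (not pairs) tiling an interval; returned as fragment specs whose two
# mates abut, giving near-uniform coverage of [lo, hi)
tile_frags <- function(lo, hi, flen = 150L, step = 50L, read_len = 75L) {
  starts <- seq(lo, hi - flen, by = step)
  lapply(starts, unspliced_frag, flen = flen, read_len = read_len)
}

# Minimal SAM text writer for hand-made records
write_test_sam <- function(records, path, chrom = "chrT", chrlen = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen))
  writeLines(c(hdr, records), path)
  path
}

sam_pair <- function(qname, chrom, pos5, cigar5, pos3, cigar3, mapq = 50L,
                     tlen = 200L) {
  c(sprintf("%s\t99\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
            qname, chrom, pos5, mapq, cigar5, pos3, tlen),
    sprintf("%s\t147\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
            qname, chrom, pos3, mapq, cigar3, pos5, -tlen))
}

# Reference model used across flow/solver tests
test_model <- function(eta = 250, delta = 1.5) weibull_size_model(eta, delta)

# Exhaustive maximum-likelihood chain-partition oracle for single-path loci.
# Fragments are chained in start order; each chain contributes
# -log d(TSS gap) - sum log d(fragment sizes) - sum log d(between gaps)
# - log d(TES gap) - sum log P(v). Returns the minimal total cost over all
# partitions of the fragments into ordered non-overlapping chains.
chain_partition_oracle <- function(frag_tab, model, tss, tes, max_gap = Inf,
                                   mapq = 60L) {
  n <- nrow(frag_tab)
  o <- order(frag_tab$start5, frag_tab$end3)
  s5 <- frag_tab$start5[o]; e3 <- frag_tab$end3[o]
  d <- function(x) size_density(model, NA, x)
  vcost <- -2 * log(astroid:::read_prob(mapq, model$prob_floor)) # two mates
  flen_cost <- -log(d(e3 - s5))
  best <- Inf
  # state: vector of open chain tail ends; costs accumulated
  rec <- function(i, tails, acc) {
    if (acc >= best) return()
    if (i > n) {
      tot <- acc + sum(-log(d(tes - tails)))
      if (tot < best) best <<- tot
      return()
    }
    # start a new chain
    rec(i + 1L, c(tails, e3[i]),
        acc + -log(d(s5[i] - tss)) + flen_cost[i] + vcost)
    # append to any compatible open chain
    for (j in seq_along(tails)) {
      gap <- s5[i] - tails[j]
      if (gap >= 0 && gap <= max_gap) {
        t2 <- tails; t2[j] <- e3[i]
        rec(i + 1L, t2, acc + -log(d(gap)) + flen_cost[i] + vcost)
      }
    }
  }
  rec(1L, numeric(0), 0)
  best
}

# Random single-exon locus with n fragments (retries offsets of the seed
# until the coverage is one contiguous island); returns the fragments table
# plus the (start, end) summary the chain-partition oracle consumes
random_simple_locus <- function(n, seed, span = NULL) {
  if (is.null(span)) span <- as.integer(n * 150L + 250L)
  for (k in 0:50) {
    set.seed(seed + 100000L * k)
    flen <- sample(150:350, n, replace = TRUE)
    start <- sample(0:(span - max(flen) - 1L), n, replace = TRUE)
    spec <- mapply(function(s, f) unspliced_frag(s, f), start, flen,
                   SIMPLIFY = FALSE)
    frs <- make_fragments(spec)
    gs <- build_splice_graph(frs)
    if (length(gs) == 1L && nrow(gs[[1L]]$exons) == 1L)
      return(list(frags = frs, graph = gs[[1L]],
                  tab = data.frame(start5 = start, end3 = start + flen)))
  }
  stop("could not generate a contiguous single-exon locus")
}

# Abutting-exon graph defined by exon lengths only (sampling-window and
# penalty arithmetic tests)
toy_graph2 <- function(exon_lens) {
  ends <- cumsum(exon_lens)
  starts <- c(0L, ends[-length(ends)])
  ex <- data.table::data.table(start = starts, end = ends,
                               exon_id = seq_along(exon_lens))
  structure(list(exons = ex, ex_start = starts, ex_end = ends,
                 edges = data.table::data.table(from = integer(), to = integer(),
                                                type = character(),
                                                support = integer()),
                 succ = rep(list(integer(0)), length(exon_lens)),
                 jkeys = character(0), locus_id = "toy2", chrom = "chrT",
                 fragment_ids = character(0)),
            class = "splice_graph")
}
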