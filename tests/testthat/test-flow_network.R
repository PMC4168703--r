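make_single_exon_rfn <- function(frag_specs, model = test_model(),
                                 gamma = NULL, span_pad = TRUE) {
  specs <- frag_specs
  frs <- make_fragments(specs)
  g <- build_splice_graph(frs)[[1L]]
  bnd <- infer_boundaries(g)
  rfn <- build_rfn(frs, g, model, bnd$tss, bnd$tes, gamma = gamma)
  list(rfn = rfn, graph = g, frs = frs, bnd = bnd, model = model)
}

test_that("boundary inference uses source/sink exons without annotation", {
  frs <- make_fragments(tile_frags(0L, 500L))
  g <- build_splice_graph(frs)[[1L]]
  b <- infer_boundaries(g)
  expect_equal(b$tss, 0L)
  expect_equal(b$tes, 500L)
})

test_that("boundary inference with annotation collects distinct ends", {
  spec <- c(tile_frags(0L, 300L, flen = 150L, step = 25L))
  spliced <- list(list(blocks5 = rbind(c(25L, 100L), c(200L, 225L)),
                       blocks3 = cbind(210L, 285L)))
  frs <- make_fragments(c(spec, spliced, spliced))
  g <- build_splice_graph(frs)[[1L]]
  ann <- structure(list(isoforms = data.table::data.table(
    isoform_id = c("t1", "t2"), gene_id = "g", chrom = "chrT", strand = "+",
    exons = list(cbind(c(10L, 200L), c(100L, 300L)),
                 cbind(c(40L), c(300L))),
    length = c(190, 260))), class = "annotation")
  b <- infer_boundaries(g, ann)
  expect_equal(b$tss, c(10L, 40L))  # two TSS, one shared TES
  expect_equal(b$tes, 300L)
})

test_that("a one-fragment locus builds the minimal six-edge network", {
  x <- make_single_exon_rfn(list(unspliced_frag(100L, 250L)))
  rfn <- x$rfn
  expect_equal(nrow(rfn$nodes), 6L)  # 2 reads + TSS + TES + source + sink
  expect_equal(nrow(rfn$edges), 6L)
  expect_equal(sum(rfn$edges$kind == "in_fragment"), 1L)
  expect_equal(sum(rfn$edges$kind == "bypass"), 1L)
  ie <- rfn$edges[rfn$edges$kind == "in_fragment"]
  expect_equal(ie$length, 250)
  expect_equal(ie$weight, -log(size_density(x$model, NA, 250)))
  # read vertices have capacity 1
  expect_true(all(rfn$nodes$capacity[rfn$nodes$kind == "read"] == 1L))
  expect_equal(rfn$k, 2L)
})

test_that("non-overlapping fragments gain a between-fragment edge with the right gap", {
  pad <- tile_frags(0L, 500L)
  x <- make_single_exon_rfn(c(list(unspliced_frag(0L, 200L),
                                   unspliced_frag(260L, 200L)), pad))
  rd <- x$rfn$reads
  n3 <- rd$node_id[rd$fragment_id == "f0001" & rd$role == "m3"]
  n5 <- rd$node_id[rd$fragment_id == "f0002" & rd$role == "m5"]
  e <- x$rfn$edges
  bw <- e[e$kind == "between_fragment" & e$tail == n3 & e$head == n5]
  expect_equal(nrow(bw), 1L)
  expect_equal(bw$length, 60)   # 260 - 200
  # overlapping fragments must never be chained (gap would be negative)
  n3b <- rd$node_id[rd$fragment_id == "f0002" & rd$role == "m3"]
  ov5 <- rd$node_id[rd$fragment_id == "f0001" & rd$role == "m5"]
  expect_equal(nrow(e[e$tail == n3b & e$head == ov5]), 0L)
  reads_bw <- e[e$kind == "between_fragment" &
                  e$tail %in% rd$node_id & e$head %in% rd$node_id]
  gap_check <- rd$start[match(reads_bw$head, rd$node_id)] -
    rd$end[match(reads_bw$tail, rd$node_id)]
  expect_true(all(gap_check >= 0))
})

test_that("alternative connecting paths yield parallel in-fragment edges", {
  # exon triple with a skip junction; mates on exon 1 and exon 3
  base <- tile_frags(0L, 300L, flen = 150L, step = 25L)
  spliced <- list(list(blocks5 = rbind(c(25L, 100L), c(200L, 225L)),
                       blocks3 = cbind(210L, 285L)))
  spanning <- list(list(blocks5 = cbind(10L, 85L), blocks3 = cbind(220L, 295L)))
  spec <- c(base, spliced, spliced, spanning)
  frs <- make_fragments(spec)
  g <- build_splice_graph(frs)[[1L]]
  bnd <- infer_boundaries(g)
  rfn <- build_rfn(frs, g, test_model(), bnd$tss, bnd$tes)
  span_id <- sprintf("f%04d", length(spec))
  sp_reads <- rfn$reads[rfn$reads$fragment_id == span_id]
  ie <- rfn$edges[rfn$edges$kind == "in_fragment"]
  span_edges <- ie[ie$tail %in% sp_reads$node_id]
  # two paths 1->3 (skip) and 1->2->3 (through): two parallel edges,
  # different spliced lengths
  expect_equal(nrow(span_edges), 2L)
  expect_equal(sort(span_edges$length), c(185, 285))
})

test_that("the network is a DAG with finite non-negative weights", {
  set.seed(11)
  spec <- lapply(sort(sample(0:2000, 30)), function(s)
    unspliced_frag(s, sample(150:350, 1L)))
  x <- make_single_exon_rfn(spec)
  e <- x$rfn$edges
  expect_true(all(is.finite(e$weight)))
  expect_true(all(e$weight >= 0))
  # forward in transcript coordinates: read tails precede read heads
  reads <- x$rfn$reads
  bw <- e[e$kind == "between_fragment" & e$tail %in% reads$node_id &
            e$head %in% reads$node_id]
  tail_end <- reads$end[match(bw$tail, reads$node_id)]
  head_start <- reads$start[match(bw$head, reads$node_id)]
  expect_true(all(head_start >= tail_end))
  # source has no in-edges, sink no out-edges
  src <- x$rfn$nodes$node_id[x$rfn$nodes$kind == "source"]
  snk <- x$rfn$nodes$node_id[x$rfn$nodes$kind == "sink"]
  expect_equal(sum(e$head == src), 0L)
  expect_equal(sum(e$tail == snk), 0L)
})

test_that("sampling window matches brute-force counting", {
  brute_psi <- function(len_first, len_internal, len_last, R) {
    L <- len_first + sum(len_internal) + len_last
    offs <- 0:(len_first - 1)                  # read start within first exon
    count <- 0L
    for (o in offs) {
      start <- len_first - 1 - o               # bases of first exon covered - 1
      covered_end <- (len_first - 1 - o) + R   # transcript end position
      if (o + 1 >= 1 && covered_end > len_first + sum(len_internal))
        count <- count + 1L
    }
    count
  }
  g <- toy_graph2(c(100L, 30L, 100L))
  expect_equal(sampling_window(g, 1:3, 75L), 44L)
  expect_equal(sampling_window(g, 1:3, 75L),
               brute_psi(100L, 30L, 100L, 75L))
  g2 <- toy_graph2(c(100L, 40L, 40L, 100L))
  expect_equal(sampling_window(g2, 1:4, 75L), 0L)   # internal exons too long
  g3 <- toy_graph2(c(5L, 30L, 100L))
  expect_equal(sampling_window(g3, 1:3, 75L), 5L)
  expect_equal(sampling_window(g3, 1:3, 75L), brute_psi(5L, 30L, 100L, 75L))
})

test_that("MultiSplice penalty scales with capacity and vanishes at psi 0", {
  # direct arithmetic on a synthetic edge table
  g <- toy_graph2(c(100L, 30L, 100L))
  rfn <- list(paths = list(1:3),
              edges = data.table::data.table(
                tail = 1L, head = 2L, kind = "between_fragment", path_id = 1L,
                length = 100, weight = 1, capacity = 2L, edge_id = 1L),
              reads = data.table::data.table(chain = list(1L)))
  out <- apply_multisplice_penalties(rfn, g, read_chains = list(1L),
                                     read_length = 75L)
  # psi = 44 capped at... 44 < len - 1; penalty = -2 * log(1 - 44/100)
  expect_equal(out$edges$weight, 1 - 2 * log(1 - 44 / 100), tolerance = 1e-12)
  # read length too short to span: psi = 0, no penalty
  out2 <- apply_multisplice_penalties(rfn, g, read_chains = list(1L),
                                      read_length = 20L)
  expect_equal(out2$edges$weight, 1)
  # a spanning read suppresses the penalty
  out3 <- apply_multisplice_penalties(rfn, g, read_chains = list(1:3),
                                      read_length = 75L)
  expect_equal(out3$edges$weight, 1)
})

test_that("psi = 10, len = 100 penalties match -log(0.9) and -log(0.81)", {
  g <- toy_graph2(c(10L, 64L, 100L))
  expect_equal(sampling_window(g, 1:3, 75L), 10L)
  mk <- function(cap) list(
    paths = list(1:3),
    edges = data.table::data.table(
      tail = 1L, head = 2L, kind = "between_fragment", path_id = 1L,
      length = 100, weight = 0, capacity = cap, edge_id = 1L),
    reads = data.table::data.table(chain = list(1L)))
  out1 <- apply_multisplice_penalties(mk(1L), g, read_chains = list(1L),
                                      read_length = 75L)
  expect_equal(out1$edges$weight, -log(0.9), tolerance = 1e-12)
  out2 <- apply_multisplice_penalties(mk(2L), g, read_chains = list(1L),
                                      read_length = 75L)
  expect_equal(out2$edges$weight, -log(0.81), tolerance = 1e-12)
})
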