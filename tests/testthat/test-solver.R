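test_that("a network with only the bypass edge carries zero-cost flow", {
  nodes <- data.table::data.table(
    node_id = 1:2, kind = c("source", "sink"), capacity = 5L, cost = 0,
    pos = NA_integer_, members = list(1L, 2L))
  edges <- data.table::data.table(
    tail = 1L, head = 2L, kind = "bypass", path_id = NA_integer_,
    length = NA_real_, weight = 0, capacity = 5L,
    fragment_id = NA_character_, edge_id = 1L)
  rfn <- structure(list(nodes = nodes, edges = edges, paths = list(),
                        reads = data.table::data.table(), k = 5L,
                        locus_id = "empty", compressed = FALSE),
                   class = "read_flow_network")
  sol <- solve_min_cost_flow(rfn)
  expect_equal(sol$total_cost, 0)
})

test_that("a single-fragment locus routes one copy through TSS and TES", {
  frs <- make_fragments(list(unspliced_frag(100L, 250L)))
  g <- build_splice_graph(frs)[[1L]]
  bnd <- infer_boundaries(g)
  m <- test_model()
  rfn <- build_rfn(frs, g, m, bnd$tss, bnd$tes)
  sol <- solve_min_cost_flow(rfn)
  expect_true(sol$reads_covered)
  # the only feasible read routing: TSS -> r5 -> r3 -> TES; objective equals
  # the sum of the three weighted edges plus the two vertex costs
  e <- rfn$edges
  w_exp <- sum(e$weight[e$kind %in% c("in_fragment", "between_fragment")]) +
    sum(rfn$nodes$cost[rfn$nodes$kind == "read"])
  expect_equal(sol$total_cost, w_exp, tolerance = 1e-6)
  copies <- decompose_into_copies(rfn, sol)
  expect_length(copies, 1L)
  expect_length(copies[[1L]]$fragment_ids, 1L)
  expect_length(copies[[1L]]$gap_lengths, 2L)
  expect_equal(copies[[1L]]$fragment_lengths, 250L)
  # the lone fragment spans the whole covered exon: both end gaps are 0
  expect_equal(copies[[1L]]$gap_lengths, c(0L, 0L))
})

test_that("flow through a capacity-2 cluster expands into two distinct copies", {
  frs <- make_fragments(list(unspliced_frag(0L, 250L),
                             unspliced_frag(0L, 250L)))
  g <- build_splice_graph(frs)[[1L]]
  bnd <- infer_boundaries(g)
  rfn <- build_rfn(frs, g, test_model(), bnd$tss, bnd$tes, gamma = 0L)
  expect_true(rfn$compressed)
  sol <- solve_min_cost_flow(rfn)
  copies <- decompose_into_copies(rfn, sol)
  expect_length(copies, 2L)
  used <- unlist(lapply(copies, `[[`, "fragment_ids"))
  expect_equal(sort(used), c("f0001", "f0002"))  # every fragment in <= 1 copy
})

test_that("the min-cost objective equals the exhaustive chain-partition optimum", {
  m <- test_model()
  for (seed in 1:12) {
    loc <- random_simple_locus(n = sample(3:7, 1L), seed = 300 + seed)
    g <- loc$graph
    bnd <- infer_boundaries(g)
    rfn <- build_rfn(loc$frags, g, m, bnd$tss, bnd$tes, max_gap = 10000L)
    sol <- solve_min_cost_flow(rfn)
    oracle <- chain_partition_oracle(loc$tab, m, tss = bnd$tss, tes = bnd$tes,
                                     max_gap = 10000L)
    expect_equal(sol$total_cost, oracle, tolerance = 1e-5)
  }
})

test_that("decomposed copies reproduce the solver objective", {
  set.seed(31)
  spec <- lapply(sort(sample(0:2000, 12)), function(s)
    unspliced_frag(s, sample(150:350, 1L)))
  frs <- make_fragments(spec)
  g <- build_splice_graph(frs)[[1L]]
  bnd <- infer_boundaries(g)
  m <- test_model()
  rfn <- build_rfn(frs, g, m, bnd$tss, bnd$tes)
  sol <- solve_min_cost_flow(rfn)
  copies <- decompose_into_copies(rfn, sol)
  # every read of the locus in exactly one copy
  used <- unlist(lapply(copies, `[[`, "fragment_ids"))
  expect_equal(sort(used), sort(unique(rfn$reads$fragment_id)))
  # recompute the -log-likelihood of the copy set from sizes and gaps
  d <- function(x) size_density(m, NA, x)
  relog <- sum(vapply(copies, function(cp)
    -sum(log(d(c(cp$fragment_lengths, cp$gap_lengths)))), numeric(1))) +
    sum(rfn$nodes$cost[rfn$nodes$kind == "read"])
  expect_equal(relog, sol$total_cost, tolerance = 1e-5)
})

test_that("adding a positive penalty never decreases the objective", {
  set.seed(32)
  spec <- lapply(sort(sample(0:1200, 10)), function(s)
    unspliced_frag(s, sample(150:350, 1L)))
  frs <- make_fragments(spec)
  g <- build_splice_graph(frs)[[1L]]
  bnd <- infer_boundaries(g)
  m <- test_model()
  rfn <- build_rfn(frs, g, m, bnd$tss, bnd$tes)
  base <- solve_min_cost_flow(rfn)$total_cost
  rfn2 <- rfn
  rfn2$edges <- data.table::copy(rfn$edges)
  idx <- which(rfn2$edges$kind == "between_fragment")[1:3]
  rfn2$edges[idx, weight := weight + 0.7]
  expect_gte(solve_min_cost_flow(rfn2)$total_cost + 1e-9, base)
})

test_that("assemble_locus reconstructs a two-isoform gene exactly", {
  # shared terminal exons, one skipped internal exon (the core two-isoform
  # alternative-splicing scenario); fragments simulated from both isoforms
  ann <- structure(list(isoforms = data.table::data.table(
    isoform_id = c("tA", "tB"), gene_id = "g", chrom = "sim1", strand = "+",
    exons = list(cbind(c(0L, 500L, 1000L), c(300L, 800L, 1400L)),
                 cbind(c(0L, 1000L), c(300L, 1400L))),
    length = c(1000, 700))), class = "annotation")
  prof <- data.table::data.table(isoform_id = c("tA", "tB"), gene_id = "g",
                                 copies = c(8L, 8L))
  sim <- simulate_fragments(prof, ann, target_depth = 90L, seed = 77L)
  expect_gte(min(table(sim$isoform_id)), 30L)
  sam <- tempfile(fileext = ".sam")
  emit_alignments(sim, 75L, sam, annotation = ann)
  frs <- load_fragments(sam, min_mapq = 10L)
  res <- suppressWarnings(astroid_assemble(frs, size_selection = c(150, 350)))
  eff <- res$isoforms[res$isoforms$eT > 0L]
  mt <- match_transcripts(eff$exons, ann$isoforms$exons)
  expect_equal(nrow(eff), 2L)       # both isoforms, no false positive
  expect_equal(nrow(mt), 2L)
})

test_that("an empty locus yields an empty result", {
  r <- astroid:::empty_assembly("locus")
  expect_length(r$copies, 0L)
  expect_equal(nrow(r$isoforms), 0L)
})
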