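test_that("unspliced coverage yields one single-exon locus", {
  frs <- make_fragments(tile_frags(0L, 500L))
  gs <- build_splice_graph(frs)
  expect_length(gs, 1L)
  g <- gs[[1L]]
  expect_equal(nrow(g$exons), 1L)
  expect_equal(c(g$exons$start, g$exons$end), c(0L, 500L))
  expect_equal(nrow(g$edges), 0L)
})

test_that("disconnected coverage islands become separate loci", {
  frs <- make_fragments(c(tile_frags(0L, 200L, flen = 150L, step = 25L),
                          tile_frags(10000L, 10200L, flen = 150L, step = 25L)))
  gs <- build_splice_graph(frs)
  expect_length(gs, 2L)
})

test_that("junction donor/acceptor sites split exons and create skip edges", {
  # unspliced coverage over [0,300) plus spliced reads [0,100)+[200,300):
  # expected exons [0,100), [100,200), [200,300) and a junction exon1->exon3
  spec <- tile_frags(0L, 300L, flen = 150L, step = 25L)
  spliced <- list(list(
    blocks5 = rbind(c(25L, 100L), c(200L, 225L)),
    blocks3 = cbind(210L, 285L)))
  frs <- make_fragments(c(spec, spliced, spliced))
  gs <- build_splice_graph(frs)
  expect_length(gs, 1L)
  g <- gs[[1L]]
  expect_equal(g$exons$start, c(0L, 100L, 200L))
  expect_equal(g$exons$end, c(100L, 200L, 300L))
  j <- g$edges[g$edges$type == "junction"]
  expect_equal(nrow(j), 1L)
  expect_equal(c(j$from, j$to), c(1L, 3L))
  # adjacency edges link the abutting split exons
  a <- g$edges[g$edges$type == "adjacent"]
  expect_true(all(c(1L, 2L) %in% a$from))
})

test_that("junctions below the support threshold are not added", {
  spec <- tile_frags(0L, 300L, flen = 150L, step = 25L)
  spliced <- list(list(
    blocks5 = rbind(c(25L, 100L), c(200L, 225L)),
    blocks3 = cbind(210L, 285L)))
  frs <- make_fragments(c(spec, spliced))
  g <- build_splice_graph(frs, min_junction_reads = 2L)[[1L]]
  expect_equal(sum(g$edges$type == "junction"), 0L)
})

# helper: hand-built graph from exon intervals and junction pairs
toy_graph <- function(exons, junctions) {
  ex <- data.table::data.table(start = exons[, 1L], end = exons[, 2L])
  ex$exon_id <- seq_len(nrow(ex))
  ed <- data.table::data.table(from = integer(), to = integer(),
                               type = character(), support = integer())
  n <- nrow(ex)
  ab <- which(ex$end[-n] == ex$start[-1L])
  if (length(ab)) ed <- rbind(ed, data.table::data.table(
    from = ab, to = ab + 1L, type = "adjacent", support = NA_integer_))
  if (nrow(junctions)) ed <- rbind(ed, data.table::data.table(
    from = junctions[, 1L], to = junctions[, 2L], type = "junction",
    support = 1L))
  succ <- lapply(seq_len(n), function(i) sort(unique(ed$to[ed$from == i])))
  structure(list(exons = ex, edges = ed, succ = succ,
                 ex_start = ex$start, ex_end = ex$end,
                 jkeys = paste(ed$from[ed$type == "junction"],
                               ed$to[ed$type == "junction"], sep = ","),
                 locus_id = "toy", chrom = "chrT", fragment_ids = character(0)),
            class = "splice_graph")
}

test_that("path enumeration handles identity, skips, and the two-skip diamond", {
  # linear chain with one skip: exons abut -> adjacency edges + skip junction
  g <- toy_graph(cbind(c(0L, 100L, 200L), c(100L, 200L, 300L)),
                 rbind(c(1L, 3L)))
  expect_equal(enumerate_connecting_paths(g, 2L, 2L), list(2L))
  p <- enumerate_connecting_paths(g, 1L, 3L)
  expect_length(p, 2L)
  expect_equal(p[[1L]], c(1L, 3L))          # shortest spliced length first
  expect_equal(p[[2L]], c(1L, 2L, 3L))
  # 5 exons with independent skips of exon 2 and exon 4 -> 4 paths 1..5
  g2 <- toy_graph(cbind(seq(0L, 400L, 100L), seq(100L, 500L, 100L)),
                  rbind(c(1L, 3L), c(3L, 5L)))
  p2 <- enumerate_connecting_paths(g2, 1L, 5L)
  expect_length(p2, 4L)
  # exhaustive DFS agreement
  bf <- astroid:::enumerate_paths_bruteforce(g2, 1L, 5L)
  key <- function(x) paste(x, collapse = ",")
  expect_setequal(vapply(p2, key, character(1)), vapply(bf, key, character(1)))
})

test_that("path enumeration agrees with exhaustive DFS on random DAGs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:10, 1L)
    exons <- cbind(seq(0L, (n - 1L) * 100L, 100L), seq(100L, n * 100L, 100L))
    cand <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    cand <- cand[cand[, 2L] - cand[, 1L] >= 2L, , drop = FALSE]
    take <- cand[sample(nrow(cand), min(nrow(cand), sample(1:4, 1L))), , drop = FALSE]
    g <- toy_graph(exons, take)
    p <- enumerate_connecting_paths(g, 1L, n, max_paths = 1000L)
    bf <- astroid:::enumerate_paths_bruteforce(g, 1L, n)
    key <- function(x) paste(x, collapse = ",")
    expect_setequal(vapply(p, key, character(1)), vapply(bf, key, character(1)))
  }
})

test_that("max_paths truncates with a warning", {
  g2 <- toy_graph(cbind(seq(0L, 400L, 100L), seq(100L, 500L, 100L)),
                  rbind(c(1L, 3L), c(3L, 5L)))
  expect_warning(p <- enumerate_connecting_paths(g2, 1L, 5L, max_paths = 2L),
                 "truncated")
  expect_length(p, 2L)
})

test_that("spliced_length excludes introns and is additive", {
  g <- toy_graph(cbind(c(0L, 200L), c(100L, 300L)), rbind(c(1L, 2L)))
  expect_equal(spliced_length(g, c(1L, 2L), 50L, 250L), 100L)
  expect_equal(spliced_length(g, 1L, 10L, 90L), 80L)
  expect_equal(spliced_length(g, 1L, 60L, 60L), 0L)
  # additivity over concatenation at a shared boundary point
  a <- spliced_length(g, c(1L, 2L), 50L, 210L)
  b <- spliced_length(g, 2L, 210L, 250L)
  expect_equal(a + b, spliced_length(g, c(1L, 2L), 50L, 250L))
  expect_error(spliced_length(g, 1L, 150L, 250L), "outside")
})

test_that("every junction read used in construction maps onto a graph edge", {
  spec <- c(tile_frags(0L, 300L, flen = 150L, step = 30L),
            list(list(blocks5 = rbind(c(25L, 100L), c(200L, 225L)),
                      blocks3 = cbind(210L, 285L))))
  frs <- make_fragments(spec)
  g <- build_splice_graph(frs)[[1L]]
  jt <- astroid:::junction_table(frs)
  for (i in seq_len(nrow(jt))) {
    di <- match(jt$donor[i], g$exons$end)
    ai <- match(jt$acceptor[i], g$exons$start)
    expect_true(any(g$edges$from == di & g$edges$to == ai &
                      g$edges$type == "junction"))
  }
})
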