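# Splice graph: exons (coverage islands split at junction donor/acceptor
# sites) as vertices, junctions as directed edges; a DAG under genomic order.

#' Build splice graphs from fragment alignments
#'
#' Exons are identified as contiguous genomic regions covered by reads with
#' mean coverage at least `min_coverage`; splice junctions are the inter-block
#' gaps of spliced reads seen at least `min_junction_reads` times. Junction
#' donor/acceptor sites additionally split exons, so every junction endpoint
#' coincides with an exon boundary. One `splice_graph` is returned per locus
#' (weakly connected component of the exon/junction graph, with mate pairs
#' also linking components).
#'
#' @param fragments A `fragments` table on a single chromosome.
#' @param min_coverage Minimum mean read coverage for a region to become an
#'   exon (default 1).
#' @param min_junction_reads Minimum spliced-read support for a junction
#'   (default 1).
#' @return A list of `splice_graph` objects; each has elements `exons`
#'   (data.table `exon_id`, `start`, `end`), `edges` (data.table `from`, `to`,
#'   `type` in junction/adjacent, `support`), `succ` (adjacency list),
#'   `locus_id`, `chrom`, and `fragment_ids` (fragments assigned to the
#'   locus).
#' @export
build_splice_graph <- function(fragments, min_coverage = 1, min_junction_reads = 1L) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(list())
  chrom <- unique(fragments$chrom)
  if (length(chrom) != 1L) stop("fragments must be on a single chromosome")

  all_blocks <- do.call(rbind, fragments$blocks)
  ir <- IRanges::IRanges(start = all_blocks[, 1L] + 1L, end = all_blocks[, 2L])
  cov <- IRanges::coverage(ir)
  islands <- IRanges::slice(cov, lower = 1L, rangesOnly = TRUE)
  if (length(islands) == 0L) return(list())
  mean_cov <- IRanges::viewMeans(IRanges::Views(cov, islands))
  islands <- islands[mean_cov >= min_coverage]
  if (length(islands) == 0L) return(list())
  isl <- data.table(start = IRanges::start(islands) - 1L,
                    end = IRanges::end(islands))

  # junctions from spliced reads
  jdt <- junction_table(fragments)
  if (nrow(jdt) > 0L) jdt <- jdt[support >= min_junction_reads]

  # split islands at junction donor (exon end) and acceptor (exon start) sites
  exons <- split_islands(isl, jdt)
  data.table::setorder(exons, start)
  exons[, exon_id := seq_len(.N)]

  # junction edges: donor coincides with an exon end, acceptor with an exon start
  edges <- data.table(from = integer(), to = integer(), type = character(),
                      support = integer())
  if (nrow(jdt) > 0L) {
    di <- match(jdt$donor, exons$end)
    ai <- match(jdt$acceptor, exons$start)
    ok <- !is.na(di) & !is.na(ai) & di < ai
    if (any(ok))
      edges <- rbind(edges, data.table(from = exons$exon_id[di[ok]],
                                       to = exons$exon_id[ai[ok]],
                                       type = "junction",
                                       support = jdt$support[ok]))
  }
  # adjacency edges between abutting exons (read-through)
  n <- nrow(exons)
  if (n > 1L) {
    ab <- which(exons$end[-n] == exons$start[-1L])
    if (length(ab) > 0L)
      edges <- rbind(edges, data.table(from = ab, to = ab + 1L,
                                       type = "adjacent", support = NA_integer_))
  }

  # loci: weakly connected components over exon edges + mate-pair links
  comp <- locus_components(exons, edges, fragments)
  graphs <- vector("list", max(comp$locus))
  frag_first_exon <- fragment_locus(fragments, exons, comp)
  for (lc in sort(unique(comp$locus))) {
    eid <- comp$exon_id[comp$locus == lc]
    sub_ex <- exons[exon_id %in% eid]
    data.table::setorder(sub_ex, start)
    remap <- setNames(seq_len(nrow(sub_ex)), sub_ex$exon_id)
    sub_ed <- edges[from %in% eid & to %in% eid]
    sub_ed[, `:=`(from = as.integer(remap[as.character(from)]),
                  to = as.integer(remap[as.character(to)]))]
    sub_ex[, exon_id := seq_len(.N)]
    succ <- vector("list", nrow(sub_ex))
    if (nrow(sub_ed) > 0L)
      for (i in seq_len(nrow(sub_ed)))
        succ[[sub_ed$from[i]]] <- c(succ[[sub_ed$from[i]]], sub_ed$to[i])
    succ <- lapply(succ, function(v) sort(unique(v)))
    graphs[[lc]] <- structure(list(
      exons = sub_ex[], edges = sub_ed[], succ = succ,
      ex_start = sub_ex$start, ex_end = sub_ex$end,
      jkeys = if (nrow(sub_ed)) paste(sub_ed$from[sub_ed$type == "junction"],
                                      sub_ed$to[sub_ed$type == "junction"],
                                      sep = ",") else character(0),
      locus_id = paste0(chrom, ":", sub_ex$start[1L], "-", sub_ex$end[nrow(sub_ex)]),
      chrom = chrom,
      fragment_ids = frag_first_exon$fragment_id[frag_first_exon$locus == lc]),
      class = "splice_graph")
  }
  graphs[!vapply(graphs, is.null, logical(1))]
}

junction_table <- function(fragments) {
  sp <- fragments[spliced == TRUE]
  if (nrow(sp) == 0L)
    return(data.table(donor = integer(), acceptor = integer(), support = integer()))
  jl <- lapply(sp$blocks, function(m) {
    n <- nrow(m)
    cbind(donor = m[-n, 2L], acceptor = m[-1L, 1L])
  })
  jm <- do.call(rbind, jl)
  jdt <- data.table(donor = jm[, 1L], acceptor = jm[, 2L])
  jdt[, .(support = .N), by = .(donor, acceptor)]
}

split_islands <- function(isl, jdt) {
  out <- vector("list", nrow(isl))
  donors <- if (nrow(jdt)) jdt$donor else integer()
  acceptors <- if (nrow(jdt)) jdt$acceptor else integer()
  for (i in seq_len(nrow(isl))) {
    s <- isl$start[i]; e <- isl$end[i]
    cuts <- sort(unique(c(donors[donors > s & donors < e],
                          acceptors[acceptors > s & acceptors < e])))
    b <- c(s, cuts, e)
    out[[i]] <- data.table(start = b[-length(b)], end = b[-1L])
  }
  data.table::rbindlist(out)
}

locus_components <- function(exons, edges, fragments) {
  n <- nrow(exons)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  if (nrow(edges) > 0L)
    for (i in seq_len(nrow(edges))) union_(edges$from[i], edges$to[i])
  # mate pairs whose reads land on different exon groups link them
  if (nrow(fragments) > 0L) {
    pos2exon <- function(p) {
      i <- findInterval(p, exons$start)
      i[i < 1L | p >= exons$end[pmax(i, 1L)]] <- NA_integer_
      i
    }
    fr <- fragments[, .(e1 = pos2exon(min(start)), e2 = pos2exon(max(start))),
                    by = fragment_id]
    fr <- fr[!is.na(e1) & !is.na(e2) & e1 != e2]
    if (nrow(fr) > 0L)
      for (i in seq_len(nrow(fr))) union_(fr$e1[i], fr$e2[i])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  data.table(exon_id = exons$exon_id, locus = as.integer(factor(roots)))
}

fragment_locus <- function(fragments, exons, comp) {
  if (nrow(fragments) == 0L)
    return(data.table(fragment_id = character(), locus = integer()))
  pos2exon <- function(p) {
    i <- findInterval(p, exons$start)
    i[i < 1L | p >= exons$end[pmax(i, 1L)]] <- NA_integer_
    i
  }
  fr <- fragments[, .(e1 = pos2exon(start[1L])), by = fragment_id]
  fr[, locus := comp$locus[e1]]
  fr[!is.na(locus), .(fragment_id, locus)]
}

#' @export
print.splice_graph <- function(x, ...) {
  cat("splice_graph", x$locus_id, ":", nrow(x$exons), "exons,",
      sum(x$edges$type == "junction"), "junctions,",
      length(x$fragment_ids), "fragments\n")
  invisible(x)
}

#' Enumerate connecting paths between two exons
#'
#' All distinct DAG paths from `exon_a` to `exon_b`, where consecutive path
#' exons are linked by a junction edge or are genomically abutting. Paths are
#' returned in deterministic order: shortest spliced length first, ties broken
#' lexicographically by exon indices. Enumeration stops (with a warning) at
#' `max_paths`.
#'
#' @param graph A `splice_graph`.
#' @param exon_a,exon_b Exon indices; `exon_a` must not come after `exon_b`.
#' @param max_paths Cap on the number of returned paths (default 64).
#' @return List of integer vectors (possibly empty); `list(exon_a)` itself
#'   when `exon_a == exon_b`.
#' @export
enumerate_connecting_paths <- function(graph, exon_a, exon_b, max_paths = 64L) {
  if (exon_a > exon_b) stop("exon_a must precede exon_b")
  if (exon_a == exon_b) return(list(as.integer(exon_a)))
  res <- list(); truncated <- FALSE
  dfs <- function(path) {
    if (truncated) return()
    v <- path[length(path)]
    if (v == exon_b) { res[[length(res) + 1L]] <<- path; if (length(res) >= max_paths) truncated <<- TRUE; return() }
    for (w in graph$succ[[v]]) {
      if (w > exon_b) next
      dfs(c(path, w))
      if (truncated) return()
    }
  }
  dfs(as.integer(exon_a))
  if (truncated) warning("path enumeration truncated at max_paths = ", max_paths)
  if (length(res) == 0L) return(res)
  elen <- graph$exons$end - graph$exons$start
  sp_len <- vapply(res, function(p) sum(elen[p]), numeric(1))
  keys <- vapply(res, function(p) paste(sprintf("%06d", p), collapse = ","), character(1))
  res[order(sp_len, keys)]
}

#' Spliced (transcript-coordinate) length along an exon path
#'
#' Number of transcript bases from `start_genomic` to `end_genomic` (half-open)
#' along `path`; introns between path exons are excluded. The start must lie
#' in the first exon of the path and the end in the last.
#'
#' @param graph A `splice_graph`.
#' @param path Integer vector of exon indices.
#' @param start_genomic,end_genomic Genomic coordinates (0-based half-open).
#' @return Integer length (0 when `start == end`).
#' @export
spliced_length <- function(graph, path, start_genomic, end_genomic) {
  ex <- graph$exons
  p1 <- path[1L]; pn <- path[length(path)]
  if (start_genomic < ex$start[p1] || start_genomic > ex$end[p1] ||
      end_genomic < ex$start[pn] || end_genomic > ex$end[pn])
    stop("coordinates outside path exons")
  s <- pmax(ex$start[path], start_genomic)
  e <- pmin(ex$end[path], end_genomic)
  as.integer(sum(pmax(0L, e - s)))
}

# Map a read's blocks to its exon chain in the graph; NULL if inconsistent
# (block crossing an exon gap, or an unsupported junction).
map_blocks_to_exons <- function(graph, blocks) {
  exs <- graph$ex_start; exe <- graph$ex_end
  nex <- length(exs)
  n <- nrow(blocks)
  chain <- integer(0)
  prev_ex <- 0L
  for (i in seq_len(n)) {
    bs <- blocks[i, 1L]; be <- blocks[i, 2L]
    f <- findInterval(bs, exs)
    if (f < 1L || bs >= exe[f]) return(NULL)
    cur <- f
    # extend through abutting exons until the block is covered
    while (exe[cur] < be) {
      if (cur + 1L > nex || exs[cur + 1L] != exe[cur]) return(NULL)
      cur <- cur + 1L
    }
    if (i > 1L) {
      # junction between previous block and this one must be a graph edge
      if (exe[prev_ex] != blocks[i - 1L, 2L]) return(NULL)
      if (exs[f] != bs) return(NULL)
      if (!(paste(prev_ex, f, sep = ",") %in% graph$jkeys)) return(NULL)
    }
    chain <- c(chain, f:cur)
    prev_ex <- cur
  }
  chain
}

# Exon chains of all reads of a locus, aligned with the rows of
# fragments[fragment_id %in% graph$fragment_ids]; NULL entries mark reads
# that cannot be embedded.
locus_read_chains <- function(fragments, graph) {
  fr <- fragments[fragments$fragment_id %in% graph$fragment_ids]
  lapply(fr$blocks, function(b) map_blocks_to_exons(graph, b))
}

# Exhaustive-DFS reference used by tests on small graphs.
enumerate_paths_bruteforce <- function(graph, exon_a, exon_b) {
  if (exon_a == exon_b) return(list(as.integer(exon_a)))
  res <- list()
  stack <- list(as.integer(exon_a))
  while (length(stack) > 0L) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- p[length(p)]
    if (v == exon_b) { res[[length(res) + 1L]] <- p; next }
    for (w in graph$succ[[v]]) if (w <= exon_b) stack[[length(stack) + 1L]] <- c(p, w)
  }
  res
}

#' Export a splice graph in DOT format (debug aid)
#' @param graph A `splice_graph`.
#' @param path Output file.
#' @export
write_splice_graph_dot <- function(graph, path) {
  l <- c("digraph splice_graph {",
         sprintf('  e%d [label="[%d,%d)"];', graph$exons$exon_id,
                 graph$exons$start, graph$exons$end),
         if (nrow(graph$edges))
           sprintf("  e%d -> e%d [style=%s];", graph$edges$from, graph$edges$to,
                   ifelse(graph$edges$type == "junction", "solid", "dotted")),
         "}")
  writeLines(l, path)
  invisible(NULL)
}
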