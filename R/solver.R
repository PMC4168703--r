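# Min-cost-flow solving, flow decomposition into transcript copies, and
# per-locus assembly orchestration.

#' Solve the minimum-cost flow on a read flow network
#'
#' Realizes vertex capacities and costs by the standard node-splitting
#' transform, scales costs to integers, and solves with a
#' successive-shortest-path min-cost-flow solver. Every read must originate
#' from exactly one transcript copy, so each read vertex carries a lower
#' bound equal to its capacity; the lower bounds are handled by the standard
#' reduction to node demands with a super source/sink and a return arc from
#' sink to source (which keeps all arc costs non-negative; the zero-cost
#' bypass edge absorbs the surplus of `k` beyond the copies routed through
#' reads). The reported objective is recomputed from the integral flow with
#' the unscaled edge weights and vertex costs.
#'
#' @param rfn A `read_flow_network` (compressed or not).
#' @param k Total flow value (default: number of reads, `rfn$k`).
#' @param cost_scale Integer cost scaling factor (default 1e6).
#' @return A `flow_solution`: list with `flow` (units per edge, in
#'   `rfn$edges` order), `node_flow` (units through each vertex),
#'   `total_cost` (unscaled objective: edge weights plus vertex costs),
#'   `value`, `k`, and `reads_covered` (logical: all read capacity used).
#' @export
solve_min_cost_flow <- function(rfn, k = rfn$k, cost_scale = 1e6) {
  nodes <- rfn$nodes; edges <- rfn$edges
  n <- nrow(nodes)
  # split: node v -> in = v, out = v + n
  is_read <- nodes$kind == "read"
  src <- nodes$node_id[nodes$kind == "source"]
  snk <- nodes$node_id[nodes$kind == "sink"]
  sstar <- 2L * n + 1L; tstar <- 2L * n + 2L
  # flexible split arcs for non-read nodes (vertex cost 0 there)
  free_ids <- nodes$node_id[!is_read]
  tail <- c(free_ids, edges$tail + n, snk + n)
  head <- c(free_ids + n, edges$head, src)
  cap <- c(nodes$capacity[!is_read], edges$capacity, k)
  cost <- round(c(nodes$cost[!is_read], edges$weight, 0) * cost_scale)
  # read split arcs are forced (lower bound = capacity): node demands
  rd <- which(is_read)
  tail <- c(tail, rep(sstar, length(rd)), rd)
  head <- c(head, rd + n, rep(tstar, length(rd)))
  cap <- c(cap, nodes$capacity[rd], nodes$capacity[rd])
  cost <- c(cost, rep(0, 2L * length(rd)))
  demand <- sum(nodes$capacity[rd])
  res <- .mcf_solve_cpp(2L * n + 2L, tail, head, cap, cost, sstar, tstar,
                        demand)
  m_free <- sum(!is_read)
  edge_flow <- res$flow[m_free + seq_len(nrow(edges))]
  node_flow <- numeric(n)
  node_flow[!is_read] <- res$flow[seq_len(m_free)]
  # forced read arcs: routed amount = what actually reached the super sink
  node_flow[rd] <- res$flow[m_free + nrow(edges) + 1L + length(rd) + seq_along(rd)]
  total_cost <- sum(edge_flow * edges$weight) + sum(node_flow * nodes$cost)
  covered <- res$value == demand
  if (!covered) warning("solver left some reads unrouted in ", rfn$locus_id)
  structure(list(flow = edge_flow, node_flow = node_flow,
                 total_cost = total_cost, value = res$value, k = k,
                 reads_covered = covered),
            class = "flow_solution")
}

#' Decompose an optimal flow into transcript copies
#'
#' Strips source-to-sink paths from the positive-flow subgraph (the bypass
#' flow is discarded); each stripped unit becomes a transcript copy whose
#' exon chain is stitched from the edges' splice-graph paths, whose
#' fragments are the in-fragment edges' mate pairs (cluster vertices of a
#' compressed network are expanded into individual member fragments in
#' deterministic order), and whose gap lengths are recomputed in transcript
#' coordinates from the member read positions.
#'
#' Two deterministic stripping strategies are available. The default,
#' `"widest"`, repeatedly removes the maximum-bottleneck path with all its
#' units at once, which concentrates flow on few distinct exon chains: at
#' loci with several alternative-splicing events this parsimony keeps
#' upstream and downstream splice choices paired the way the bulk of the
#' flow pairs them instead of fabricating rare combination chains.
#' `"cheapest"` strips one unit at a time along the lowest-weight positive
#' out-edges (smallest head id on ties).
#'
#' @param rfn The solved `read_flow_network`.
#' @param solution A `flow_solution` from [solve_min_cost_flow()].
#' @param strategy `"widest"` (default) or `"cheapest"`.
#' @return List of `transcript_copy` objects (each with `tss`, `tes` and
#'   `exon_path` fields filled in).
#' @export
decompose_into_copies <- function(rfn, solution,
                                  strategy = c("widest", "cheapest")) {
  strategy <- match.arg(strategy)
  edges <- rfn$edges
  graph <- rfn$graph
  fe <- solution$flow
  # per-node out-edges ordered by (weight, head)
  n <- nrow(rfn$nodes)
  ord <- order(edges$tail, edges$weight, edges$head)
  spl <- split(ord, edges$tail[ord])
  out_idx <- vector("list", n)
  out_idx[as.integer(names(spl))] <- spl
  src <- rfn$nodes$node_id[rfn$nodes$kind == "source"]
  snk <- rfn$nodes$node_id[rfn$nodes$kind == "sink"]
  kind <- edges$kind
  e_head <- edges$head
  e_path <- edges$path_id
  node_pos <- rfn$nodes$pos
  fid_vec <- rfn$frags$fragment_id
  s5_vec <- rfn$frags$start5
  e3_vec <- rfn$frags$end3

  # fragment queues per in-fragment edge (deterministic member order); a
  # used-set guards against the same fragment backing two parallel-path edges
  # of a compressed network
  frag_queue <- vector("list", nrow(edges))
  if (isTRUE(rfn$compressed)) {
    frag_queue[which(kind == "in_fragment")] <-
      edges$frag_list[which(kind == "in_fragment")]
  } else {
    frag_queue[which(kind == "in_fragment")] <-
      as.list(edges$fragment_id[kind == "in_fragment"])
  }
  used <- new.env(parent = emptyenv())
  ex_start <- graph$exons$start
  ex_end <- graph$exons$end
  n_edges <- nrow(edges)

  e_tail <- edges$tail
  copies <- list()
  repeat {
    if (strategy == "widest") {
      pe <- widest_path(n, out_idx, e_head, e_tail, fe, kind, src, snk)
      if (is.null(pe)) break
      path_edges <- pe
      units <- min(fe[path_edges])
      fe[path_edges] <- fe[path_edges] - units
    } else {
      oi <- out_idx[[src]]
      nxt <- oi[fe[oi] > 0 & kind[oi] != "bypass"]
      if (length(nxt) == 0L) break
      path_edges <- integer(0)
      cur_edge <- nxt[1L]
      dead_end <- FALSE
      repeat {
        path_edges <- c(path_edges, cur_edge)
        fe[cur_edge] <- fe[cur_edge] - 1L
        h <- e_head[cur_edge]
        if (h == snk) break
        oi <- out_idx[[h]]
        cand <- oi[fe[oi] > 0]
        if (length(cand) == 0L || length(path_edges) > n_edges) {
          dead_end <- TRUE  # only possible after an infeasible solve
          break
        }
        cur_edge <- cand[1L]
      }
      if (dead_end) next
      units <- 1L
    }
    ek <- kind[path_edges]
    tss_pos <- node_pos[e_head[path_edges[1L]]]
    tes_pos <- node_pos[e_tail[path_edges[length(path_edges)]]]
    in_edges <- path_edges[ek == "in_fragment"]
    # stitch the exon chain from the edges' splice-graph paths (consecutive
    # edge paths share exactly their boundary exon)
    chain <- integer(0)
    for (e in path_edges) {
      pid <- e_path[e]
      if (is.na(pid)) next
      p <- rfn$paths[[pid]]
      if (length(chain) > 0L && p[1L] == chain[length(chain)]) p <- p[-1L]
      chain <- c(chain, p)
    }
    clen <- ex_end[chain] - ex_start[chain]
    coff <- cumsum(c(0L, clen[-length(clen)]))
    cst <- ex_start[chain]
    tx <- function(pos) {
      i <- findInterval(pos, cst)
      i <- pmin(pmax(i, 1L), length(chain))
      coff[i] + pmin(pmax(pos - cst[i], 0L), clen[i])
    }
    for (u in seq_len(units)) {
      # pop one unused member fragment per in-fragment edge
      frag_ids <- character(length(in_edges))
      for (j in seq_along(in_edges)) {
        e <- in_edges[j]
        q <- frag_queue[[e]]
        hit <- NA_character_
        while (length(q) > 0L) {
          cand <- q[1L]; q <- q[-1L]
          if (is.null(used[[cand]])) { hit <- cand; break }
        }
        frag_queue[[e]] <- q
        if (!is.na(hit)) assign(hit, TRUE, envir = used)
        frag_ids[j] <- hit
      }
      keep <- !is.na(frag_ids)
      if (!any(keep)) next
      fidx <- match(frag_ids[keep], fid_vec)
      t5 <- tx(s5_vec[fidx]); t3 <- tx(e3_vec[fidx])
      flens <- pmax(t3 - t5, 1L)
      bounds0 <- c(tx(tss_pos), t3)
      bounds1 <- c(t5, tx(tes_pos))
      gaps <- pmax(bounds1 - bounds0, 0L)
      cp <- transcript_copy(rfn$locus_id, chain, frag_ids[keep], flens, gaps)
      cp$tss <- tss_pos; cp$tes <- tes_pos
      copies[[length(copies) + 1L]] <- cp
    }
  }
  copies
}

# Maximum-bottleneck source->sink path over positive-flow non-bypass edges;
# returns the edge-index path or NULL when no read-carrying flow remains.
# Deterministic: ties prefer the smaller vertex, then the lower-weight edge
# (out_idx is pre-sorted by weight and head).
widest_path <- function(n, out_idx, e_head, e_tail, fe, kind, src, snk) {
  cap <- rep(-Inf, n)
  via <- integer(n)
  done <- rep(FALSE, n)
  cap[src] <- sum(fe) + 1  # effectively unbounded at the source
  repeat {
    u <- which.max(ifelse(done, -Inf, cap))
    if (!is.finite(cap[u]) || cap[u] <= 0) return(NULL)
    if (u == snk) break
    done[u] <- TRUE
    for (e in out_idx[[u]]) {
      if (fe[e] <= 0 || kind[e] == "bypass") next
      v <- e_head[e]
      b <- min(cap[u], fe[e])
      if (b > cap[v]) { cap[v] <- b; via[v] <- e }
    }
  }
  path <- integer(0)
  v <- snk
  while (v != src) {
    e <- via[v]
    path <- c(e, path)
    v <- e_tail[e]
  }
  path
}

#' Assemble one locus end to end
#'
#' Full per-locus pipeline: infer boundaries, build the read flow network,
#' cluster and compress it, apply MultiSplice penalties, solve the min-cost
#' flow, decompose the flow into transcript copies, classify each copy as
#' effective or ineffective at level `tau`, and group copies with identical
#' exon chains into isoforms (terminal coordinates taken from the outermost
#' TSS/TES used by the chain's copies). Isoforms whose effective-copy count
#' is zero are retained in the result but flagged.
#'
#' @param fragments `fragments` table (superset allowed; the locus subset is
#'   selected via the graph).
#' @param graph The locus `splice_graph`.
#' @param model A `weibull_size_model`.
#' @param options List of options: `tau` (0.05), `gamma` (cluster radius;
#'   default half the model's mean fragment size), `compress` (TRUE),
#'   `penalties` (TRUE), `read_length` (75), `max_gap`, `max_paths` (64),
#'   `annotation` (NULL), `paper_literal` (FALSE), `k` (NULL = #reads).
#' @return An `assembly_result`: list with `copies`, `isoforms` (data.table:
#'   `chain_sig`, `exons`, `chrom`, `eT`, `N`, `n_copies`), `objective`,
#'   `solution`, `rfn`, `locus_id`.
#' @export
assemble_locus <- function(fragments, graph, model, options = list()) {
  opt <- modifyList(list(
    tau = 0.05, gamma = NULL, compress = TRUE, penalties = TRUE,
    read_length = 75L, max_gap = default_max_gap(model), max_paths = 64L,
    annotation = NULL, paper_literal = FALSE, k = NULL, chains = NULL),
    options)
  if (is.null(opt$gamma)) {
    mean_frag <- model$eta * gamma(1 + 1 / model_shape(model, NA))
    opt$gamma <- as.integer(round(mean_frag / 2))
  }
  if (length(graph$fragment_ids) == 0L)
    return(empty_assembly(graph$locus_id))
  bnd <- infer_boundaries(graph, opt$annotation)
  net <- build_rfn(fragments, graph, model, bnd$tss, bnd$tes,
                   max_gap = opt$max_gap, max_paths = opt$max_paths,
                   chains = opt$chains,
                   gamma = if (isTRUE(opt$compress)) opt$gamma else NULL)
  if (is.null(net)) return(empty_assembly(graph$locus_id))
  if (isTRUE(opt$penalties))
    net <- apply_multisplice_penalties(net, graph,
                                       read_chains = net$reads$chain,
                                       read_length = opt$read_length)
  sol <- solve_min_cost_flow(net, k = if (is.null(opt$k)) net$k else opt$k)
  copies <- decompose_into_copies(net, sol)
  ex <- graph$exons
  for (i in seq_along(copies)) {
    cp <- copies[[i]]
    iso_len <- sum(ex$end[cp$exon_path] - ex$start[cp$exon_path])
    cp$likelihood <- copy_likelihood(cp, model, iso_len)
    cp$pvalue <- effectiveness_pvalue(model, iso_len, cp$likelihood)
    cp$effective <- if (opt$paper_literal) cp$pvalue <= opt$tau
                    else cp$pvalue > opt$tau
    copies[[i]] <- cp
  }
  isoforms <- group_copies_into_isoforms(copies, graph)
  structure(list(copies = copies, isoforms = isoforms,
                 objective = sol$total_cost, solution = sol, rfn = net,
                 locus_id = graph$locus_id),
            class = "assembly_result")
}

empty_assembly <- function(locus_id) {
  structure(list(copies = list(),
                 isoforms = data.table(chain_sig = character(), exons = list(),
                                       chrom = character(), eT = integer(),
                                       N = integer(), n_copies = integer()),
                 objective = 0, solution = NULL, rfn = NULL,
                 locus_id = locus_id),
            class = "assembly_result")
}

group_copies_into_isoforms <- function(copies, graph) {
  if (length(copies) == 0L) return(empty_assembly(graph$locus_id)$isoforms)
  ex <- graph$exons
  sig <- vapply(copies, function(cp) paste(cp$exon_path, collapse = ","),
                character(1))
  dt <- data.table(
    sig = sig,
    effective = vapply(copies, function(cp) isTRUE(cp$effective), logical(1)),
    nfrag = vapply(copies, function(cp) length(cp$fragment_ids), integer(1)),
    tss = vapply(copies, function(cp) as.integer(cp$tss), integer(1)),
    tes = vapply(copies, function(cp) as.integer(cp$tes), integer(1)))
  agg <- dt[, .(eT = sum(effective), N = sum(nfrag), n_copies = .N,
                tss = min(tss), tes = max(tes)), by = sig]
  agg[, exons := lapply(seq_len(.N), function(i) {
    path <- as.integer(strsplit(sig[i], ",")[[1L]])
    m <- merge_abutting(cbind(ex$start[path], ex$end[path]))
    # outermost TSS/TES among the chain's copies trim the terminal exons
    if (tss[i] > m[1L, 1L] && tss[i] < m[1L, 2L]) m[1L, 1L] <- tss[i]
    if (tes[i] < m[nrow(m), 2L] && tes[i] > m[nrow(m), 1L]) m[nrow(m), 2L] <- tes[i]
    m
  })]
  agg[, chrom := graph$chrom]
  out <- agg[, .(chain_sig = sig, exons, chrom, eT = as.integer(eT),
                 N = as.integer(N), n_copies)]
  data.table::setorder(out, chain_sig)
  out[]
}

merge_abutting <- function(m) {
  if (nrow(m) <= 1L) return(m)
  keep_start <- c(TRUE, m[-1L, 1L] != m[-nrow(m), 2L])
  grp <- cumsum(keep_start)
  cbind(tapply(m[, 1L], grp, min), tapply(m[, 2L], grp, max))
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("assembly_result", x$locus_id, ":", length(x$copies), "copies,",
      nrow(x$isoforms), "isoform chains, objective",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}
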