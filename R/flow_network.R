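# Read flow network: read vertices plus TSS/TES/source/sink, in-fragment and
# between-fragment edges carrying -log size probabilities, and MultiSplice
# penalties on edges whose exon paths no observed read confirms.

#' Infer transcription start/termination sites for a locus
#'
#' Without annotation, the 5' boundary of every source exon (no incoming
#' junction or adjacency edge) is a TSS and the 3' boundary of every sink exon
#' is a TES. With annotation, the outer ends of annotated isoforms overlapping
#' the locus are used, clamped into the covered exons (annotated ends lying
#' upstream/downstream of the covered region snap to the nearest exon
#' boundary); the heuristic is the fallback when no annotated end is usable.
#'
#' @param graph A `splice_graph`.
#' @param annotation Optional `annotation` object.
#' @return List with integer vectors `tss` and `tes` (genomic positions,
#'   0-based).
#' @export
infer_boundaries <- function(graph, annotation = NULL) {
  ex <- graph$exons
  has_in <- unique(graph$edges$to)
  has_out <- unique(graph$edges$from)
  heur_tss <- ex$start[!ex$exon_id %in% has_in]
  heur_tes <- ex$end[!ex$exon_id %in% has_out]
  if (is.null(annotation)) return(list(tss = sort(heur_tss), tes = sort(heur_tes)))
  iso <- annotation$isoforms
  iso <- iso[iso$chrom == graph$chrom]
  lo <- ex$start[1L]; hi <- ex$end[nrow(ex)]
  ov <- vapply(iso$exons, function(m) any(m[, 2L] > lo & m[, 1L] < hi), logical(1))
  iso <- iso[ov]
  if (nrow(iso) == 0L) return(list(tss = sort(heur_tss), tes = sort(heur_tes)))
  clamp_pos <- function(p, is_start) {
    i <- findInterval(p, ex$start)
    if (i >= 1L && p < ex$end[i]) return(p)           # inside an exon
    if (is_start) {
      j <- which(ex$start >= p)[1L]
      if (is.na(j)) NA_integer_ else ex$start[j]      # snap forward
    } else {
      j <- rev(which(ex$end <= p))[1L]
      if (is.na(j)) NA_integer_ else ex$end[j]        # snap backward
    }
  }
  tss <- vapply(iso$exons, function(m) m[1L, 1L], numeric(1))
  tes <- vapply(iso$exons, function(m) m[nrow(m), 2L], numeric(1))
  tss <- unique(vapply(tss, clamp_pos, numeric(1), is_start = TRUE))
  tes <- unique(vapply(tes, clamp_pos, numeric(1), is_start = FALSE))
  tss <- tss[!is.na(tss)]; tes <- tes[!is.na(tes)]
  if (length(tss) == 0L) tss <- heur_tss
  if (length(tes) == 0L) tes <- heur_tes
  list(tss = sort(as.integer(tss)), tes = sort(as.integer(tes)))
}

#' Default horizon for between-fragment edges
#'
#' Gap length beyond which the Weibull survival probability drops below
#' `p`; longer connections contribute no likelihood benefit and only grow the
#' network quadratically.
#' @param model A `weibull_size_model`.
#' @param p Survival cutoff (default 1e-6).
#' @return Integer gap horizon in transcript bases.
#' @export
default_max_gap <- function(model, p = 1e-6) {
  sh <- model_shape(model, NA)
  as.integer(ceiling(stats::qweibull(p, shape = sh, scale = model$eta,
                                     lower.tail = FALSE)))
}

read_prob <- function(mapq, floor_) {
  p <- 1 - 10^(-mapq / 10)
  pmin(pmax(p, floor_), 1 - 1e-15)
}

#' Build the read flow network of one locus
#'
#' One vertex per read (mate), with capacity 1 and vertex cost `-log P(v)`
#' derived from mapping quality; one in-fragment edge per fragment per unique
#' splice-graph path between its mates (weight `-log d(fragment size)`);
#' between-fragment edges from every fragment's 3' read to every downstream
#' fragment's 5' read whose transcript-coordinate gap lies in `[0, max_gap]`,
#' one per unique connecting path (weight `-log d(gap)`); TSS-to-5'-read and
#' 3'-read-to-TES edges weighted the same way (unbounded gap, probability
#' floored); zero-weight virtual edges source to TSS and TES to sink; and one
#' zero-weight bypass edge source to sink that absorbs surplus flow.
#' Fragments that cannot be embedded in any splice-graph path are dropped
#' with a warning.
#'
#' @param fragments `fragments` table restricted to the locus.
#' @param graph The locus `splice_graph`.
#' @param model A `weibull_size_model`.
#' @param tss,tes Integer vectors of TSS/TES genomic positions (see
#'   [infer_boundaries()]).
#' @param max_gap Between-fragment gap horizon (default
#'   [default_max_gap()]).
#' @param max_paths Path-enumeration cap per exon pair (default 64).
#' @param chains Optional precomputed read exon chains from
#'   `locus_read_chains()` (avoids re-mapping reads).
#' @param gamma Optional compression radius. When supplied, the compressed
#'   network is built directly: reads are clustered first
#'   ([partition_reads()] conditions) and duplicated edges are collapsed
#'   group by group while the network is constructed, which avoids ever
#'   materializing the quadratic uncompressed edge set. The result is
#'   identical to `compress_rfn(build_rfn(...), partition_reads(..., gamma))`.
#' @return A `read_flow_network`: list with `nodes`, `edges`, `paths`,
#'   `reads`, `frags`, `k`, `graph`, `locus_id`, and `compressed`.
#' @export
build_rfn <- function(fragments, graph, model, tss, tes,
                      max_gap = default_max_gap(model), max_paths = 64L,
                      chains = NULL, gamma = NULL) {
  fr <- fragments[fragments$fragment_id %in% graph$fragment_ids]
  if (nrow(fr) == 0L) stop("no fragments in locus")
  if (is.null(chains)) chains <- lapply(fr$blocks, function(b) map_blocks_to_exons(graph, b))
  stopifnot(length(chains) == nrow(fr))
  ok_read <- !vapply(chains, is.null, logical(1))
  bad_frag <- unique(fr$fragment_id[!ok_read])
  if (length(bad_frag) > 0L) {
    warning(length(bad_frag), " fragment(s) not embeddable in the splice graph; dropped")
    keep <- !fr$fragment_id %in% bad_frag
    fr <- fr[keep]; chains <- chains[keep]
  }
  if (nrow(fr) == 0L) return(NULL)

  # pre-scan: fragments whose mates admit no compatible connecting path are
  # dropped before any vertex is numbered
  sig <- vapply(chains, paste, character(1), collapse = ",")
  pre <- data.table(fragment_id = fr$fragment_id, role = fr$role, sig = sig,
                    idx = seq_len(nrow(fr)))
  p5 <- pre[role == "m5"]; p3 <- pre[role == "m3"]
  pp <- merge(p5[, .(fragment_id, sig5 = sig, i5 = idx)],
              p3[, .(fragment_id, sig3 = sig, i3 = idx)], by = "fragment_id")
  group_paths <- list()
  dropped_in <- character(0)
  for (gkey in unique(paste(pp$sig5, pp$sig3, sep = "|"))) {
    sub <- pp[paste(sig5, sig3, sep = "|") == gkey]
    ch5 <- chains[[sub$i5[1L]]]; ch3 <- chains[[sub$i3[1L]]]
    A <- ch5[1L]; B <- ch3[length(ch3)]
    compat <- list()
    if (B >= A) for (p in enumerate_connecting_paths(graph, A, B, max_paths)) {
      np <- length(p)
      if (length(ch5) > np || length(ch3) > np) next
      if (!identical(p[seq_along(ch5)], ch5)) next
      if (!identical(p[np - rev(seq_along(ch3)) + 1L], ch3)) next
      compat[[length(compat) + 1L]] <- p
    }
    if (length(compat) == 0L) dropped_in <- c(dropped_in, sub$fragment_id)
    else group_paths[[gkey]] <- compat
  }
  if (length(dropped_in) > 0L) {
    warning(length(dropped_in), " fragment(s) with no mate-connecting path; dropped")
    keep <- !fr$fragment_id %in% dropped_in
    fr <- fr[keep]; chains <- chains[keep]
  }
  if (nrow(fr) == 0L) return(NULL)
  reads <- data.table(
    node_id = seq_len(nrow(fr)),
    read_uid = fr$read_uid, fragment_id = fr$fragment_id, role = fr$role,
    start = fr$start, end = fr$end, mapq = fr$mapq,
    chain = chains,
    chain_sig = vapply(chains, paste, character(1), collapse = ","),
    firstEx = vapply(chains, `[`, integer(1), 1L),
    lastEx = vapply(chains, function(ch) ch[length(ch)], integer(1)))
  n_reads <- nrow(reads)
  iso_len <- sum(graph$exons$end - graph$exons$start)  # nominal length for shape rule

  # optional fused compression: cluster map applied as edges are created
  compressed <- !is.null(gamma)
  if (compressed) {
    part <- cluster_reads_impl(reads, gamma)
    n_clusters <- max(part$cluster_id)
    rmap <- part$cluster_id[match(seq_len(n_reads), part$node_id)]
  } else {
    n_clusters <- n_reads
    rmap <- seq_len(n_reads)
  }

  # node table: read vertices (or clusters), then TSS, TES, source, sink
  n_tss <- length(tss); n_tes <- length(tes)
  tss_ids <- n_clusters + seq_len(n_tss)
  tes_ids <- n_clusters + n_tss + seq_len(n_tes)
  src_id <- n_clusters + n_tss + n_tes + 1L
  snk_id <- src_id + 1L
  read_cost <- -log(read_prob(reads$mapq, model$prob_floor))
  if (compressed) {
    memb <- split(part$node_id, part$cluster_id)
    memb <- lapply(memb, function(m) m[order(reads$start[m], m)])
    cap <- lengths(memb)
    ccost <- vapply(memb, function(m) min(read_cost[m]), numeric(1))
  } else {
    memb <- as.list(seq_len(n_reads))
    cap <- rep(1L, n_reads)
    ccost <- read_cost
  }
  nodes <- data.table(
    node_id = seq_len(snk_id),
    kind = c(rep("read", n_clusters), rep("TSS", n_tss), rep("TES", n_tes),
             "source", "sink"),
    capacity = c(as.integer(cap), rep(n_reads, n_tss + n_tes + 2L)),
    cost = c(ccost, rep(0, n_tss + n_tes + 2L)),
    pos = c(rep(NA_integer_, n_clusters), as.integer(tss), as.integer(tes),
            NA_integer_, NA_integer_))
  nodes$members <- c(unname(memb),
                     as.list(n_clusters + seq_len(n_tss + n_tes + 2L)))

  catalog <- new.env(parent = emptyenv())
  catalog$paths <- list()
  catalog$index <- new.env(parent = emptyenv())
  path_id_of <- function(p) {
    key <- paste(p, collapse = ",")
    id <- catalog$index[[key]]
    if (is.null(id)) {
      id <- length(catalog$paths) + 1L
      catalog$paths[[id]] <- as.integer(p)
      assign(key, id, envir = catalog$index)
    }
    id
  }
  ex <- graph$exons
  elen <- ex$end - ex$start
  midlen <- function(p) if (length(p) <= 2L) 0L else sum(elen[p[-c(1L, length(p))]])

  edge_parts <- list()
  # rmap2 converts read node ids to their cluster ids; TSS/TES/source/sink
  # ids are already in the compressed coordinate system
  rmap2 <- function(v) if (compressed) rmap[v] else v
  add_edges <- function(tail, head, kind, path_id, length_, weight,
                        capacity = 1L, fragment_id = NA_character_) {
    edge_parts[[length(edge_parts) + 1L]] <<- data.table(
      tail = as.integer(tail), head = as.integer(head), kind = kind,
      path_id = as.integer(path_id), length = as.numeric(length_),
      weight = as.numeric(weight), capacity = as.integer(capacity),
      fragment_id = fragment_id)
  }
  # collapse one batch of parallel between-fragment pairs (read node ids)
  # onto cluster pairs before storing
  add_between <- function(tails, heads, path_id, gaps) {
    w <- wt(gaps)
    if (compressed) {
      b <- data.table(tail = rmap[tails], head = rmap[heads], gap = gaps, w = w)
      b <- b[, .(length = gap[which.min(w)], weight = min(w), capacity = .N),
             by = .(tail, head)]
      add_edges(b$tail, b$head, "between_fragment", path_id, b$length,
                b$weight, b$capacity)
    } else {
      add_edges(tails, heads, "between_fragment", path_id, gaps, w)
    }
  }
  wt <- function(len) -log(size_density(model, iso_len, pmax(len, 0)))

  m5 <- reads[role == "m5"]; m3 <- reads[role == "m3"]
  frags <- merge(m5[, .(fragment_id, n5 = node_id, start5 = start, end5 = end,
                        sig5 = chain_sig, first5 = firstEx)],
                 m3[, .(fragment_id, n3 = node_id, start3 = start, end3 = end,
                        sig3 = chain_sig, last3 = lastEx)],
                 by = "fragment_id")

  # --- in-fragment edges ---
  frags[, grp := paste(sig5, sig3, sep = "|")]
  for (g in unique(frags$grp)) {
    sub <- frags[grp == g]
    ch5 <- reads$chain[[sub$n5[1L]]]
    ch3 <- reads$chain[[sub$n3[1L]]]
    A <- ch5[1L]; B <- ch3[length(ch3)]
    for (p in group_paths[[g]]) {
      np <- length(p)
      len <- if (np == 1L) sub$end3 - sub$start5
             else (ex$end[A] - sub$start5) + midlen(p) + (sub$end3 - ex$start[B])
      add_edges(rmap2(sub$n5), rmap2(sub$n3), "in_fragment", path_id_of(p),
                len, wt(len), fragment_id = sub$fragment_id)
    }
  }

  # --- between-fragment edges ---
  g3 <- split(m3, m3$lastEx)
  g5 <- split(m5, m5$firstEx)
  for (Xc in names(g3)) {
    X <- as.integer(Xc)
    a_grp <- g3[[Xc]]
    for (Yc in names(g5)) {
      Y <- as.integer(Yc)
      if (Y < X) next
      b_grp <- g5[[Yc]]
      paths <- enumerate_connecting_paths(graph, X, Y, max_paths)
      for (p in paths) {
        if (length(p) == 1L) {
          s5 <- sort(b_grp$start)
          ordb <- order(b_grp$start)
          lo <- findInterval(a_grp$end - 1L, s5)
          hi <- findInterval(a_grp$end + max_gap, s5)
          cnt <- hi - lo
          sel <- cnt > 0L
          if (!any(sel)) next
          ii <- rep.int(which(sel), cnt[sel])
          jj <- ordb[sequence(cnt[sel], from = lo[sel] + 1L)]
          gap <- b_grp$start[jj] - a_grp$end[ii]
          add_between(a_grp$node_id[ii], b_grp$node_id[jj], path_id_of(p), gap)
        } else {
          C <- midlen(p)
          a <- ex$end[X] - a_grp$end       # >= 0
          b <- b_grp$start - ex$start[Y]   # >= 0
          lim <- max_gap - C
          if (lim < 0) next
          bs <- sort(b); ordb <- order(b)
          cnt <- findInterval(lim - a, bs)
          cnt[cnt < 0L] <- 0L
          sel <- cnt > 0L
          if (!any(sel)) next
          ii <- rep.int(which(sel), cnt[sel])
          jj <- ordb[sequence(cnt[sel], from = 1L)]
          gap <- a[ii] + b[jj] + C
          add_between(a_grp$node_id[ii], b_grp$node_id[jj], path_id_of(p), gap)
        }
      }
    }
  }

  # --- TSS -> m5 and m3 -> TES edges ---
  pos2exon <- function(p, as_end = FALSE) {
    if (as_end) {
      i <- which(ex$start < p & ex$end >= p)[1L]
    } else {
      i <- which(ex$start <= p & ex$end > p)[1L]
    }
    i
  }
  for (ti in seq_along(tss)) {
    tpos <- tss[ti]
    tex <- pos2exon(tpos)
    if (is.na(tex)) next
    for (Yc in names(g5)) {
      Y <- as.integer(Yc)
      if (Y < tex) next
      b_grp <- g5[[Yc]]
      for (p in enumerate_connecting_paths(graph, tex, Y, max_paths)) {
        gap <- if (length(p) == 1L) b_grp$start - tpos
               else (ex$end[tex] - tpos) + midlen(p) + (b_grp$start - ex$start[Y])
        keep <- gap >= 0
        if (!any(keep)) next
        add_edges(tss_ids[ti], rmap2(b_grp$node_id[keep]), "between_fragment",
                  path_id_of(p), gap[keep], wt(gap[keep]))
      }
    }
  }
  for (ti in seq_along(tes)) {
    tpos <- tes[ti]
    tex <- pos2exon(tpos, as_end = TRUE)
    if (is.na(tex)) next
    for (Xc in names(g3)) {
      X <- as.integer(Xc)
      if (X > tex) next
      a_grp <- g3[[Xc]]
      for (p in enumerate_connecting_paths(graph, X, tex, max_paths)) {
        gap <- if (length(p) == 1L) tpos - a_grp$end
               else (ex$end[X] - a_grp$end) + midlen(p) + (tpos - ex$start[tex])
        keep <- gap >= 0
        if (!any(keep)) next
        add_edges(rmap2(a_grp$node_id[keep]), tes_ids[ti], "between_fragment",
                  path_id_of(p), gap[keep], wt(gap[keep]))
      }
    }
  }

  # --- virtual and bypass edges ---
  k <- n_reads
  if (n_tss > 0L) add_edges(src_id, tss_ids, "virtual", NA, NA, 0, n_reads)
  if (n_tes > 0L) add_edges(tes_ids, snk_id, "virtual", NA, NA, 0, n_reads)
  add_edges(src_id, snk_id, "bypass", NA, NA, 0, k)

  edges <- data.table::rbindlist(edge_parts)
  if (compressed) {
    # final collapse of duplicated edges between cluster pairs (the
    # between-fragment batches are already pre-collapsed per group)
    s5 <- frags$start5[match(edges$fragment_id, frags$fragment_id)]
    edges[, .s5 := s5]
    edges <- edges[, {
      i <- which.min(weight)
      list(length = if (all(is.na(length))) NA_real_ else length[i],
           weight = weight[i], capacity = sum(capacity), n_dup = .N,
           frag_list = list(fragment_id[order(.s5, fragment_id)]))
    }, by = .(tail, head, kind, path_id)]
  }
  edges[, edge_id := seq_len(.N)]
  out <- structure(list(nodes = nodes, edges = edges, paths = catalog$paths,
                        reads = reads, frags = frags, k = k, graph = graph,
                        locus_id = graph$locus_id, compressed = compressed),
                   class = "read_flow_network")
  if (compressed) out$partition <- {
    p <- part
    data.table::setattr(p, "gamma", gamma)
    data.table::setattr(p, "class", c("read_partition", class(p)))
    p
  }
  out
}

#' @export
print.read_flow_network <- function(x, ...) {
  cat("read_flow_network", x$locus_id, ":", nrow(x$nodes), "vertices,",
      nrow(x$edges), "edges", if (isTRUE(x$compressed)) "(compressed)", "\n")
  invisible(x)
}

#' Sampling window of a MultiSplice feature
#'
#' Number of read start positions from which a read of length `read_length`
#' covers all exons of the feature (a sequence of at least three adjacent
#' exons): `psi = max(0, min(len_first, R - L_int - 1) -
#' max(1, R - L_int - len_last) + 1)` with `L_int` the total internal-exon
#' length; 0 when the read cannot span the internal exons.
#'
#' @param graph A `splice_graph`.
#' @param feature_exons Integer vector of at least 3 exon indices.
#' @param read_length Read length in bases.
#' @return Integer window size, `>= 0`.
#' @export
sampling_window <- function(graph, feature_exons, read_length) {
  stopifnot(length(feature_exons) >= 3L)
  elen <- graph$exons$end - graph$exons$start
  lf <- elen[feature_exons[1L]]
  ll <- elen[feature_exons[length(feature_exons)]]
  lint <- sum(elen[feature_exons[-c(1L, length(feature_exons))]])
  R <- read_length
  as.integer(max(0L, min(lf, R - lint - 1) - max(1, R - lint - ll) + 1))
}

#' Apply MultiSplice penalties to unconfirmed multi-exon edges
#'
#' For every edge whose exon path contains at least one internal exon and
#' which no observed read alignment confirms by spanning all exons of the
#' corresponding feature `b`, the weight is increased by
#' `-log((1 - psi(b)/len(e))^c_e)` (`psi` capped at `len(e) - 1`); edges with
#' a spanning read, or with `psi(b) = 0`, are unchanged.
#'
#' @param rfn A `read_flow_network` (possibly compressed).
#' @param graph The locus `splice_graph`.
#' @param read_chains Optional list of read exon chains used for the spanning
#'   check (defaults to the network's own reads).
#' @param read_length Read length in bases.
#' @return The network with adjusted edge weights (`penalty` column added).
#' @export
apply_multisplice_penalties <- function(rfn, graph, read_chains = NULL,
                                        read_length = 75L) {
  if (is.null(read_chains)) read_chains <- rfn$reads$chain
  chain_strs <- paste0(",", vapply(read_chains, paste, character(1), collapse = ","), ",")
  edges <- data.table::copy(rfn$edges)
  edges[, penalty := 0]
  pids <- unique(edges$path_id[!is.na(edges$path_id)])
  for (pid in pids) {
    b <- rfn$paths[[pid]]
    if (length(b) < 3L) next
    bstr <- paste0(",", paste(b, collapse = ","), ",")
    if (any(grepl(bstr, chain_strs, fixed = TRUE))) next   # confirmed
    psi <- sampling_window(graph, b, read_length)
    if (psi == 0L) next                                     # P(not confirmed) = 1
    idx <- which(edges$path_id == pid & edges$length > 1)
    if (length(idx) == 0L) next
    psi_eff <- pmin(psi, edges$length[idx] - 1)
    pen <- -edges$capacity[idx] * log(1 - psi_eff / edges$length[idx])
    edges[idx, penalty := pen]
  }
  edges[, weight := weight + penalty]
  rfn$edges <- edges
  rfn
}

#' Export a read flow network in DOT format (debug aid)
#' @param rfn A `read_flow_network`.
#' @param path Output file.
#' @export
write_rfn_dot <- function(rfn, path) {
  lab <- ifelse(rfn$nodes$kind == "read",
                paste0("r", rfn$nodes$node_id),
                paste0(rfn$nodes$kind, rfn$nodes$node_id))
  l <- c("digraph rfn {",
         sprintf('  n%d [label="%s"];', rfn$nodes$node_id, lab),
         sprintf('  n%d -> n%d [label="%.3g"];', rfn$edges$tail, rfn$edges$head,
                 rfn$edges$weight),
         "}")
  writeLines(l, path)
  invisible(NULL)
}
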