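# Compressed flow network: reads clustered under vertex homogeneity, edge
# homogeneity and alignment adjacency; duplicated edges between cluster pairs
# collapse to one edge (min weight, capacity = duplicate count).

#' Partition read vertices into clusters
#'
#' Greedy left-to-right clustering: reads are sorted by (exon chain, mate
#' role, start, end) and a new cluster opens whenever adding a read would
#' place either boundary more than `gamma` bases from the cluster's first
#' member. Reads in one cluster therefore share mate role and exon chain
#' (hence junction set, which also makes member-to-member edges represent the
#' same splice-graph path sets, and rules out intra-cluster edges since
#' in-fragment edges always join opposite roles), and differ by at most
#' `gamma` bases at both boundaries relative to the anchor. Runs in O(|V|)
#' after sorting.
#'
#' @param rfn A `read_flow_network`.
#' @param gamma Compression radius in bases (`gamma >= 0`; 0 clusters exact
#'   duplicates only, which is lossless).
#' @return A `read_partition`: data.table (`node_id`, `cluster_id`) with
#'   attribute `gamma`.
#' @export
partition_reads <- function(rfn, gamma = 0L) {
  stopifnot(gamma >= 0)
  out <- cluster_reads_impl(rfn$reads, gamma)
  data.table::setattr(out, "gamma", gamma)
  data.table::setattr(out, "class", c("read_partition", class(out)))
  out[]
}

cluster_reads_impl <- function(reads, gamma) {
  r <- reads[, .(node_id, chain_sig, role, start, end)]
  data.table::setorder(r, chain_sig, role, start, end, node_id)
  r[, cluster_id := {
    cid <- integer(.N)
    cur <- 1L; a_start <- start[1L]; a_end <- end[1L]
    cid[1L] <- 1L
    if (.N > 1L) for (i in 2L:.N) {
      if (start[i] - a_start > gamma || abs(end[i] - a_end) > gamma) {
        cur <- cur + 1L; a_start <- start[i]; a_end <- end[i]
      }
      cid[i] <- cur
    }
    cid
  }, by = .(chain_sig, role)]
  r[, cluster_id := as.integer(factor(paste(chain_sig, role, cluster_id)))]
  out <- r[, .(node_id, cluster_id)]
  data.table::setorder(out, node_id)
  out
}

#' Compress a read flow network under a partition
#'
#' Each read cluster becomes one vertex whose capacity is the cluster size;
#' duplicated edges between two clusters that represent the same splice-graph
#' path collapse to a single edge carrying the minimum weight of the
#' duplicates and capacity equal to their number. TSS/TES/source/sink
#' vertices are untouched.
#'
#' @param rfn An uncompressed `read_flow_network`.
#' @param partition A `read_partition` from [partition_reads()].
#' @return A compressed `read_flow_network` (`compressed = TRUE`); cluster
#'   membership is kept in `nodes$members` for later flow expansion.
#' @export
compress_rfn <- function(rfn, partition) {
  if (isTRUE(rfn$compressed)) stop("network is already compressed")
  if (!all(sort(partition$node_id) == rfn$reads$node_id))
    stop("partition does not cover the read vertices")
  n_clusters <- max(partition$cluster_id)
  # map: read node -> cluster node id (clusters first, then other vertices)
  old_nodes <- rfn$nodes
  read_ids <- rfn$reads$node_id
  other_ids <- old_nodes$node_id[old_nodes$kind != "read"]
  map <- integer(nrow(old_nodes))
  map[read_ids] <- partition$cluster_id[match(read_ids, partition$node_id)]
  map[other_ids] <- n_clusters + seq_along(other_ids)

  memb <- split(partition$node_id, partition$cluster_id)
  # deterministic member order: by start then node id
  memb <- lapply(memb, function(m) m[order(rfn$reads$start[match(m, rfn$reads$node_id)], m)])
  csize <- lengths(memb)
  ccost <- vapply(memb, function(m) min(old_nodes$cost[m]), numeric(1))
  nodes <- data.table(
    node_id = seq_len(n_clusters + length(other_ids)),
    kind = c(rep("read", n_clusters), old_nodes$kind[other_ids]),
    capacity = c(as.integer(csize), old_nodes$capacity[other_ids]),
    cost = c(ccost, old_nodes$cost[other_ids]),
    pos = c(rep(NA_integer_, n_clusters), old_nodes$pos[other_ids]))
  nodes$members <- c(unname(memb), lapply(other_ids, identity))

  e <- data.table::copy(rfn$edges)
  e[, `:=`(tail = map[tail], head = map[head])]
  # deterministic duplicate order inside collapsed edges: by m5 start
  s5 <- rfn$frags$start5[match(e$fragment_id, rfn$frags$fragment_id)]
  e[, .s5 := s5]
  ce <- e[, .(weight = min(weight), capacity = sum(capacity),
              length = if (all(is.na(length))) NA_real_ else length[which.min(weight)],
              n_dup = .N,
              frag_list = list(fragment_id[order(.s5, fragment_id)])),
          by = .(tail, head, kind, path_id)]
  ce[, edge_id := seq_len(.N)]

  out <- rfn
  out$nodes <- nodes
  out$edges <- ce
  out$node_map <- map
  out$partition <- partition
  out$compressed <- TRUE
  out
}
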