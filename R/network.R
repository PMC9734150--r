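#' Build a correlation-weighted residue contact graph
#'
#' An edge connects residues i and j when (a) their distance is at or below
#' `contact_cutoff` in at least `occupancy_min` of the frames and (b) the
#' absolute dynamic cross-correlation `|C_ij|` is at least `corr_min`. The
#' edge length is `-log |C_ij|`, so strongly correlated pairs are close and
#' path lengths are additive; a perfect `|C| = 1` would give length 0 and
#' is clamped to 1e-6.
#'
#' @param traj an `EnsembleTrajectory` (used for contact occupancies).
#' @param dccm a `CorrelationMatrix` whose labels are a subset of the
#'   trajectory labels.
#' @param contact_cutoff contact distance, Angstrom (default 6).
#' @param occupancy_min minimum fraction of frames in contact (default 0.5).
#' @param corr_min minimum `|C_ij|` for a retained edge (default 0.05).
#' @return a `ResidueGraph`: list with `nodes` (labels) and `edges`
#'   (data.frame `i`, `j` label columns, `occupancy`, `correlation`,
#'   `length`).
#' @export
build_residue_graph <- function(traj, dccm, contact_cutoff = 6,
                                occupancy_min = 0.5, corr_min = 0.05) {
  stopifnot(inherits(traj, "EnsembleTrajectory"), inherits(dccm, "CorrelationMatrix"))
  idx <- match(dccm$labels, traj$labels)
  if (anyNA(idx)) stop_("dccm label(s) not in trajectory: %s",
                        paste(dccm$labels[is.na(idx)], collapse = ", "))
  labels <- dccm$labels
  n <- length(labels)
  f <- n_frames(traj)
  rows <- list()
  clamped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- sqrt(rowSums((matrix(traj$coords[, idx[i], ], ncol = 3) -
                             matrix(traj$coords[, idx[j], ], ncol = 3))^2))
      occ <- mean(dij <= contact_cutoff)
      cc <- dccm$values[i, j]
      if (occ >= occupancy_min && abs(cc) >= corr_min) {
        len <- -log(abs(cc))
        if (len <= 0) { len <- 1e-6; clamped <- clamped + 1L }
        rows[[length(rows) + 1L]] <-
          data.frame(i = labels[i], j = labels[j], occupancy = occ,
                     correlation = cc, length = len)
      }
    }
  }
  if (!length(rows)) stop_("graph has zero edges under the given thresholds")
  if (clamped > 0L)
    message(sprintf("%d edge(s) with |C| = 1 clamped to length 1e-6", clamped))
  residue_graph(do.call(rbind, rows), nodes = labels)
}

#' Construct a residue graph from an edge table
#'
#' @param edges data.frame with character columns `i`, `j` and numeric
#'   `length`; optional `occupancy`, `correlation`.
#' @param nodes node labels (defaults to those appearing in `edges`).
#' @return object of class `ResidueGraph`.
#' @export
residue_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("i", "j", "length") %in% names(edges)))
    stop_("edges need columns i, j, length")
  edges$i <- as.character(edges$i); edges$j <- as.character(edges$j)
  if (any(edges$i == edges$j)) stop_("self-edges are not allowed")
  if (any(!is.finite(edges$length) | edges$length <= 0))
    stop_("edge lengths must be positive and finite")
  nodes <- nodes %||% sort(unique(c(edges$i, edges$j)))
  if (!all(c(edges$i, edges$j) %in% nodes)) stop_("edge endpoint not in node set")
  # canonical order: i before j in node order, dedup
  oi <- match(edges$i, nodes); oj <- match(edges$j, nodes)
  swap <- oi > oj
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  if (anyDuplicated(paste(edges$i, edges$j))) stop_("duplicate edges")
  if (!"occupancy" %in% names(edges)) edges$occupancy <- NA_real_
  if (!"correlation" %in% names(edges)) edges$correlation <- NA_real_
  rownames(edges) <- NULL
  structure(list(nodes = nodes,
                 edges = edges[, c("i", "j", "occupancy", "correlation", "length")]),
            class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat(sprintf("ResidueGraph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# adjacency list: for each node index, matrix of (neighbour index, weight, edge row)
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  ei <- match(graph$edges$i, graph$nodes)
  ej <- match(graph$edges$j, graph$nodes)
  adj <- vector("list", n)
  for (r in seq_along(ei)) {
    adj[[ei[r]]] <- rbind(adj[[ei[r]]], c(ej[r], graph$edges$length[r], r))
    adj[[ej[r]]] <- rbind(adj[[ej[r]]], c(ei[r], graph$edges$length[r], r))
  }
  adj
}

# TRUE if integer sequence a is lexicographically smaller than b
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (t in seq_len(k)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  length(a) < length(b)
}

# single-source Dijkstra with deterministic lexicographic tie-break on the
# node sequence; returns distances, paths (node index vectors) and the edge
# rows used by each path
dijkstra_single <- function(graph, source_idx, adj = graph_adjacency(graph)) {
  n <- length(graph$nodes)
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  paths <- vector("list", n)
  epaths <- vector("list", n)
  dist[source_idx] <- 0
  paths[[source_idx]] <- source_idx
  epaths[[source_idx]] <- integer(0)
  eps <- 1e-12
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]   # ties: smallest index, deterministic
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]; w <- nb[r, 2]; er <- nb[r, 3]
      nd <- dist[u] + w
      tol <- eps * max(1, abs(nd))
      if (nd < dist[v] - tol) {
        dist[v] <- nd
        paths[[v]] <- c(paths[[u]], v)
        epaths[[v]] <- c(epaths[[u]], er)
      } else if (abs(nd - dist[v]) <= tol) {
        candidate <- c(paths[[u]], v)
        if (lex_less(candidate, paths[[v]])) {
          paths[[v]] <- candidate
          epaths[[v]] <- c(epaths[[u]], er)
        }
      }
    }
  }
  list(dist = dist, paths = paths, epaths = epaths)
}

#' Shortest path between two residues
#'
#' Dijkstra's algorithm on the correlation-weighted graph with a
#' deterministic tie-break: among equal-length shortest paths the
#' lexicographically smallest node sequence (in node order) is returned.
#' An unreachable target yields a no-path result, not an error.
#'
#' @param graph a `ResidueGraph`.
#' @param source,target node labels, distinct.
#' @return list with `path` (labels, or `NULL` when unreachable), `length`
#'   (`Inf` when unreachable) and `reachable`.
#' @export
shortest_path <- function(graph, source, target) {
  si <- match(source, graph$nodes); ti <- match(target, graph$nodes)
  if (is.na(si)) stop_("unknown source node: %s", source)
  if (is.na(ti)) stop_("unknown target node: %s", target)
  if (si == ti) stop_("source and target must differ")
  res <- dijkstra_single(graph, si)
  if (!is.finite(res$dist[ti]))
    return(list(path = NULL, length = Inf, reachable = FALSE))
  list(path = graph$nodes[res$paths[[ti]]], length = res$dist[ti],
       reachable = TRUE)
}

# all-pairs shortest paths; returns dist matrix and per-source dijkstra
all_pairs_shortest <- function(graph) {
  n <- length(graph$nodes)
  adj <- graph_adjacency(graph)
  dmat <- matrix(Inf, n, n, dimnames = list(graph$nodes, graph$nodes))
  per <- vector("list", n)
  for (s in seq_len(n)) {
    per[[s]] <- dijkstra_single(graph, s, adj)
    dmat[s, ] <- per[[s]]$dist
  }
  list(dist = dmat, per_source = per)
}

#' Shortest path map (SPM) of a residue graph
#'
#' Accumulates, for every ordered node pair, one count on each edge of the
#' pair's shortest path, then normalizes all edge usages by the maximum.
#' Edges with normalized usage at or above `threshold` form the SPM. The
#' alternative reading that only the first-to-last residue pair is traced
#' is available with `pairs = "endpoints"`. On a disconnected graph the
#' map is computed per component and flagged.
#'
#' @param graph a `ResidueGraph`.
#' @param threshold SPM inclusion threshold on normalized usage
#'   (default 0.3).
#' @param pairs `"all"` (every ordered pair, default) or `"endpoints"`
#'   (first and last node in node order, both directions).
#' @return an `SpmResult`: `edges` (edge table plus `usage`, `in_spm`),
#'   `node_weight` (sum of incident usages), `threshold`, `n_components`.
#' @export
compute_spm <- function(graph, threshold = 0.3, pairs = c("all", "endpoints")) {
  pairs <- match.arg(pairs)
  n <- length(graph$nodes)
  ap <- all_pairs_shortest(graph)
  reach_sets <- lapply(seq_len(n), function(s) which(is.finite(ap$dist[s, ])))
  n_comp <- sum(!duplicated(reach_sets))
  if (n_comp > 1L)
    warning("graph is disconnected; SPM computed per component")
  usage <- numeric(nrow(graph$edges))
  pair_set <- if (pairs == "all") {
    expand.grid(s = seq_len(n), t = seq_len(n))
  } else {
    data.frame(s = c(1L, n), t = c(n, 1L))
  }
  for (r in seq_len(nrow(pair_set))) {
    s <- pair_set$s[r]; t <- pair_set$t[r]
    if (s == t || !is.finite(ap$dist[s, t])) next
    er <- ap$per_source[[s]]$epaths[[t]]
    usage[er] <- usage[er] + 1
  }
  if (max(usage) > 0) usage <- usage / max(usage)
  edges <- graph$edges
  edges$usage <- usage
  edges$in_spm <- usage >= threshold & usage > 0
  nw <- setNames(numeric(n), graph$nodes)
  for (r in seq_len(nrow(edges))) {
    nw[edges$i[r]] <- nw[edges$i[r]] + usage[r]
    nw[edges$j[r]] <- nw[edges$j[r]] + usage[r]
  }
  structure(list(edges = edges, node_weight = nw, threshold = threshold,
                 pairs = pairs, n_components = n_comp),
            class = "SpmResult")
}

#' @export
print.SpmResult <- function(x, ...) {
  cat(sprintf("SpmResult: %d / %d edges in SPM (threshold %.2f, %s pairs)\n",
              sum(x$edges$in_spm), nrow(x$edges), x$threshold, x$pairs))
  invisible(x)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered reachable node pairs; the
#' fraction of reachable pairs is reported so disconnected graphs remain
#' comparable.
#'
#' @param graph a `ResidueGraph` with at least 2 nodes.
#' @return list with `cpl`, `reachable_fraction`, `n_pairs` (reachable).
#' @export
characteristic_path_length <- function(graph) {
  n <- length(graph$nodes)
  if (n < 2L) stop_("need at least 2 nodes")
  d <- all_pairs_shortest(graph)$dist
  up <- d[upper.tri(d)]
  reach <- is.finite(up)
  if (!any(reach)) stop_("no reachable pairs in graph")
  list(cpl = mean(up[reach]), reachable_fraction = mean(reach),
       n_pairs = sum(reach))
}

# graph minus one node and its incident edges
drop_node <- function(graph, node) {
  keep_edges <- graph$edges$i != node & graph$edges$j != node
  edges <- graph$edges[keep_edges, , drop = FALSE]
  nodes <- setdiff(graph$nodes, node)
  if (!nrow(edges)) {
    structure(list(nodes = nodes,
                   edges = edges),
              class = "ResidueGraph")
  } else {
    residue_graph(edges, nodes = nodes)
  }
}

#' Node-weakening analysis (delta-CPL ranking)
#'
#' Removes each candidate node (with its incident edges) in turn and
#' recomputes the characteristic path length over the remaining reachable
#' pairs. Candidates are ranked by `|delta_cpl|`; removals that disconnect
#' the remaining graph are flagged. Large positive `delta_cpl` marks nodes
#' whose loss most degrades allosteric communication.
#'
#' @param graph a `ResidueGraph`.
#' @param candidates node labels to test (default: all nodes).
#' @return a `NodeWeakeningTable`: `baseline_cpl` and a data.frame `table`
#'   with `node`, `cpl_without`, `delta_cpl`, `disconnects`, sorted by
#'   `|delta_cpl|` descending.
#' @export
node_weakening <- function(graph, candidates = graph$nodes) {
  bad <- setdiff(candidates, graph$nodes)
  if (length(bad)) stop_("unknown candidate node(s): %s", paste(bad, collapse = ", "))
  if (length(graph$nodes) - 1L < 2L) stop_("graph minus a node must retain >= 2 nodes")
  base <- characteristic_path_length(graph)
  rows <- lapply(candidates, function(nd) {
    g2 <- drop_node(graph, nd)
    if (!nrow(g2$edges)) {
      data.frame(node = nd, cpl_without = NA_real_, delta_cpl = NA_real_,
                 disconnects = TRUE)
    } else {
      cp <- tryCatch(characteristic_path_length(g2), error = function(e) NULL)
      if (is.null(cp)) {
        data.frame(node = nd, cpl_without = NA_real_, delta_cpl = NA_real_,
                   disconnects = TRUE)
      } else {
        data.frame(node = nd, cpl_without = cp$cpl,
                   delta_cpl = cp$cpl - base$cpl,
                   disconnects = cp$reachable_fraction < 1)
      }
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-abs(tab$delta_cpl), tab$node, na.last = TRUE), ]
  rownames(tab) <- NULL
  structure(list(baseline_cpl = base$cpl, table = tab),
            class = "NodeWeakeningTable")
}

#' @export
print.NodeWeakeningTable <- function(x, ...) {
  cat(sprintf("NodeWeakeningTable: baseline CPL %.4f\n", x$baseline_cpl))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Hop-count graph distance from a node set
#'
#' Unweighted breadth-first distance from any node in `from` to every node
#' of the graph; used to localize flexibility changes around a perturbed
#' site.
#'
#' @param graph a `ResidueGraph`.
#' @param from node labels forming the seed set.
#' @return named integer vector of hop counts (`Inf` if unreachable).
#' @export
hop_distance <- function(graph, from) {
  n <- length(graph$nodes)
  adj <- graph_adjacency(graph)
  dist <- setNames(rep(Inf, n), graph$nodes)
  start <- match(from, graph$nodes)
  if (anyNA(start)) stop_("unknown node(s): %s", paste(from[is.na(match(from, graph$nodes))], collapse = ", "))
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (is.infinite(dist[v])) { dist[v] <- dist[u] + 1; queue <- c(queue, v) }
    }
  }
  dist
}
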