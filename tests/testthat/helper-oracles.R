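# Independent oracles and fixture builders used across the suite.

# shortest path length by exhaustive enumeration of simple paths
brute_shortest <- function(graph, s_lab, t_lab) {
  nodes <- graph$nodes
  len <- matrix(Inf, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(graph$edges))) {
    len[graph$edges$i[r], graph$edges$j[r]] <- graph$edges$length[r]
    len[graph$edges$j[r], graph$edges$i[r]] <- graph$edges$length[r]
  }
  best <- Inf
  visit <- function(u, acc, seen) {
    if (u == t_lab) { best <<- min(best, acc); return(invisible()) }
    for (v in nodes[is.finite(len[u, ])]) {
      if (!(v %in% seen) && acc + len[u, v] < best) {
        visit(v, acc + len[u, v], c(seen, v))
      }
    }
  }
  visit(s_lab, 0, s_lab)
  best
}

brute_cpl <- function(graph) {
  nodes <- graph$nodes
  acc <- c()
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (a < b) {
        d <- brute_shortest(graph, nodes[a], nodes[b])
        if (is.finite(d)) acc <- c(acc, d)
      }
    }
  }
  mean(acc)
}

# random connected weighted graph on n nodes
random_graph <- function(n, p_edge = 0.45) {
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p_edge
    # always keep a random spanning path so connectivity is likely
    perm <- sample(n)
    chain <- cbind(perm[-n], perm[-1])
    edges <- unique(rbind(pairs[keep, , drop = FALSE],
                          t(apply(chain, 1, sort))))
    g <- residue_graph(data.frame(i = paste0("n", edges[, 1]),
                                  j = paste0("n", edges[, 2]),
                                  length = runif(nrow(edges), 0.1, 2)),
                       nodes = paste0("n", seq_len(n)))
    return(g)
  }
}

# chain / ring elastic networks
make_chain <- function(n = 5, spacing = 3.8, cutoff = 4) {
  build_toy_network(cbind((seq_len(n) - 1) * spacing, 0, 0), cutoff = cutoff)
}

# helical chain: enough neighbour springs for a full-rank 3-D Hessian
# (a straight chain is degenerate for pairwise springs)
make_helix <- function(n = 5, radius = 2, rise = 1.5, angle = 100 * pi / 180,
                       cutoff = 5.2) {
  i <- seq_len(n) - 1
  build_toy_network(cbind(radius * cos(i * angle), radius * sin(i * angle),
                          rise * i), cutoff = cutoff)
}

make_ring <- function(n = 8, radius = 6, cutoff = NULL) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  coords <- cbind(radius * cos(th), radius * sin(th), 0)
  side <- sqrt(sum((coords[1, ] - coords[2, ])^2))
  build_toy_network(coords, cutoff = cutoff %||% (side * 1.1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# equilibrium oracle: complex concentration solving (G-c)(Z-c) = K c
equilibrium_complex <- function(G, Z, K) {
  if (Z == 0 || G == 0) return(0)
  stats::uniroot(function(c) (G - c) * (Z - c) - K * c,
                 c(0, min(G, Z)), tol = 1e-14)$root
}

# nonactivated / regulator-bound toy dimer pair used by the qualitative
# allostery properties
dimer_pair <- function() {
  apo <- make_toy_dimer()
  list(apo = apo, bound = stiffen_intersubunit(apo, 5))
}

count_cross_spm <- function(graph, threshold = 0.3) {
  s <- suppressWarnings(compute_spm(graph, threshold = threshold))
  inter <- node_subunit(s$edges$i) != node_subunit(s$edges$j)
  sum(s$edges$in_spm & inter)
}
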