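#' Homophilic two-ring-lattice interaction network
#'
#' Builds the deterministic starting topology: one ring lattice per social
#' identity group (nodes `1..n/2` red, `n/2+1..n` blue), each agent linked to
#' its `k_in` nearest same-group ring neighbours, and red agent `i` linked to
#' blue agents at circulant offsets `i, i+1, ..., i+k_out-1` (so with
#' `k_out = 2` in a 100-agent society, agent 1 is linked to agents 51 and 52,
#' agent 2 to 52 and 53, and so on). The network is homophilic when
#' `k_in > k_out`. No randomness is involved; clustering is later destroyed
#' by [rewire_network()].
#'
#' A ring lattice cannot give every node an odd degree through symmetric
#' nearest-neighbour offsets alone, so for odd `k_in` each agent is linked to
#' its `(k_in-1)/2` nearest neighbours on each side plus its diametrically
#' opposite group member, keeping the lattice regular (requires `n/2` even).
#'
#' @param n number of agents; must be even (two equal identity groups).
#' @param k_in in-group degree per agent; `0 <= k_in < n/2`.
#' @param k_out out-group degree per agent; `0 <= k_out <= n/2`.
#' @return An object of class `social_network`: a list with `n`, `identity`
#'   (character, `"red"`/`"blue"`), `edges` (two-column integer matrix, the
#'   owning endpoint first), `k_in`, `k_out` and the rewiring probability `p`
#'   used so far (0 for the pristine lattice).
#' @export
#' @examples
#' net <- homophilic_lattice(100, 8, 2)
#' net
homophilic_lattice <- function(n, k_in, k_out) {
  if (length(n) != 1 || n < 2 || n %% 2 != 0) {
    stop("`n` must be an even integer >= 2", call. = FALSE)
  }
  g <- n / 2
  if (k_in < 0 || k_in >= g) {
    stop("`k_in` must satisfy 0 <= k_in < n/2", call. = FALSE)
  }
  if (k_out < 0 || k_out > g) {
    stop("`k_out` must satisfy 0 <= k_out <= n/2", call. = FALSE)
  }
  if (k_in %% 2 == 1 && g %% 2 != 0) {
    stop("odd `k_in` needs an even group size (diametric matching)",
         call. = FALSE)
  }

  ring_edges <- function(offset) {
    half <- k_in %/% 2
    e <- NULL
    if (half > 0) {
      i <- rep(seq_len(g), each = half)
      d <- rep(seq_len(half), times = g)
      e <- cbind(offset + i, offset + 1L + (i - 1L + d) %% g)
    }
    if (k_in %% 2 == 1) {
      i <- seq_len(g / 2)
      e <- rbind(e, cbind(offset + i, offset + i + g / 2))
    }
    e
  }

  edges <- rbind(ring_edges(0L), ring_edges(g))
  if (k_out > 0) {
    i <- rep(seq_len(g), each = k_out)
    off <- rep(seq_len(k_out) - 1L, times = g)
    edges <- rbind(edges, cbind(i, g + 1L + (i - 1L + off) %% g))
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL

  structure(
    list(
      n = as.integer(n),
      identity = rep(c("red", "blue"), each = g),
      edges = edges,
      k_in = as.integer(k_in),
      k_out = as.integer(k_out),
      p = 0
    ),
    class = "social_network"
  )
}

#' @export
print.social_network <- function(x, ...) {
  grp <- network_group(x)
  ing <- sum(grp[x$edges[, 1]] == grp[x$edges[, 2]])
  cat(sprintf(
    "<social_network> %d agents (red/blue), %d edges (%d in-group, %d out-group), k_in=%d k_out=%d p=%g\n",
    x$n, nrow(x$edges), ing, nrow(x$edges) - ing, x$k_in, x$k_out, x$p
  ))
  invisible(x)
}

network_group <- function(net) match(net$identity, c("red", "blue"))

#' Count in-group and out-group edges
#'
#' @param net a `social_network`.
#' @return Named integer vector `c(in_group = ..., out_group = ...)`.
#' @export
edge_counts <- function(net) {
  grp <- network_group(net)
  same <- grp[net$edges[, 1]] == grp[net$edges[, 2]]
  c(in_group = sum(same), out_group = sum(!same))
}

#' Rewire network links, preserving homophily
#'
#' Watts-Strogatz style rewiring restricted by link category. Each in-group
#' link is, with probability `p`, re-targeted from its owning endpoint to a
#' uniformly chosen same-group node; each out-group link is, with probability
#' `p`, re-targeted from its owning (red-lattice) endpoint to a uniformly
#' chosen out-group node. Self-loops and duplicate edges are never created;
#' if a draw has no legal target the link is left in place. In-group and
#' out-group edge counts are exactly conserved, so the degree of homophily is
#' maintained while `p -> 1` destroys clustering.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param net a `social_network`.
#' @param p rewiring probability in \[0, 1\].
#' @return The rewired `social_network` (with `p` recorded).
#' @export
rewire_network <- function(net, p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a single probability in [0, 1]", call. = FALSE)
  }
  edges <- net$edges
  out <- net
  out$p <- p
  if (p == 0 || nrow(edges) == 0) {
    return(out)
  }
  grp <- network_group(net)
  adj <- matrix(FALSE, net$n, net$n)
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE

  same_group <- lapply(1:2, function(k) which(grp == k))
  for (e in seq_len(nrow(edges))) {
    if (stats::runif(1) >= p) next
    i <- edges[e, 1]
    j <- edges[e, 2]
    pool <- if (grp[i] == grp[j]) same_group[[grp[i]]] else same_group[[3 - grp[i]]]
    cand <- pool[!adj[i, pool] & pool != i]
    if (length(cand) == 0) next  # no legal target: keep the link
    k <- cand[sample.int(length(cand), 1)]
    adj[i, j] <- adj[j, i] <- FALSE
    adj[i, k] <- adj[k, i] <- TRUE
    edges[e, 2] <- k
  }
  out$edges <- edges
  out
}

#' Convert to an igraph graph
#'
#' @param net a `social_network`.
#' @return An undirected `igraph` graph with vertex attribute `identity`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, net$n - igraph::vcount(g)))
  igraph::set_vertex_attr(g, "identity", value = net$identity)
}

#' Topology diagnostics: clustering coefficient and average path length
#'
#' Global clustering is the average of the local clustering coefficients
#' (nodes with degree < 2 count as 0). The average shortest-path length is
#' computed on the whole graph when connected, otherwise on the largest
#' connected component with `connected = FALSE` flagged in the result.
#'
#' @param net a `social_network` with at least one edge.
#' @return A list with `clustering`, `avg_path_length` and `connected`.
#' @export
network_stats <- function(net) {
  if (nrow(net$edges) == 0) {
    stop("network has no edges", call. = FALSE)
  }
  g <- as_igraph(net)
  cl <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  comp <- igraph::components(g)
  connected <- comp$no == 1
  if (!connected) {
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  list(
    clustering = cl,
    avg_path_length = igraph::mean_distance(g, directed = FALSE),
    connected = connected
  )
}

# CSR adjacency (0-based targets) for the C++ update loop
adjacency_csr <- function(net) {
  nbr <- vector("list", net$n)
  e <- net$edges
  for (row in seq_len(nrow(e))) {
    i <- e[row, 1]
    j <- e[row, 2]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  deg <- lengths(nbr)
  list(
    targets = as.integer(unlist(nbr, use.names = FALSE) - 1L),
    offsets = as.integer(c(0L, cumsum(deg)))
  )
}

#' Write a network as plain-text edge and node tables
#'
#' Edges are written sorted (`node_a < node_b`, then lexicographically) so
#' identical networks produce byte-identical files.
#'
#' @param net a `social_network`.
#' @param edge_file path for the edge CSV (`node_a,node_b`).
#' @param node_file optional path for the node CSV (`node_id,identity`).
#' @return Invisibly, `net`.
#' @export
write_edge_list <- function(net, edge_file, node_file = NULL) {
  e <- cbind(
    pmin(net$edges[, 1], net$edges[, 2]),
    pmax(net$edges[, 1], net$edges[, 2])
  )
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  utils::write.csv(
    data.frame(node_a = e[, 1], node_b = e[, 2]),
    edge_file, row.names = FALSE, quote = FALSE
  )
  if (!is.null(node_file)) {
    utils::write.csv(
      data.frame(node_id = seq_len(net$n), identity = net$identity),
      node_file, row.names = FALSE, quote = FALSE
    )
  }
  invisible(net)
}

#' Read a network from edge and node tables
#'
#' @param edge_file edge CSV with columns `node_a,node_b`.
#' @param node_file node CSV with columns `node_id,identity`.
#' @return A `social_network` (with `k_in`, `k_out` set to the realized
#'   averages and `p` set to `NA`, since the generating parameters are not
#'   stored in the files).
#' @export
read_edge_list <- function(edge_file, node_file) {
  e <- utils::read.csv(edge_file)
  nodes <- utils::read.csv(node_file)
  if (!all(c("node_a", "node_b") %in% names(e)) ||
      !all(c("node_id", "identity") %in% names(nodes))) {
    stop("unexpected columns in edge or node file", call. = FALSE)
  }
  nodes <- nodes[order(nodes$node_id), ]
  net <- structure(
    list(
      n = nrow(nodes),
      identity = as.character(nodes$identity),
      edges = cbind(as.integer(e$node_a), as.integer(e$node_b)),
      k_in = NA_integer_, k_out = NA_integer_, p = NA_real_
    ),
    class = "social_network"
  )
  cnt <- edge_counts(net)
  net$k_in <- 2 * cnt[["in_group"]] / net$n
  net$k_out <- 2 * cnt[["out_group"]] / net$n
  net
}
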