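# All-pairs shortest-path and detour (longest simple path) matrices.

#' All-pairs shortest-path matrix
#'
#' Unweighted shortest-path lengths (edge counts) between every pair of
#' vertices, by breadth-first search from each source.
#'
#' @param g a [molecular_graph()].
#' @return An integer `n x n` matrix: symmetric, zero diagonal, entry 1
#'   exactly where an edge exists.
#' @export
shortest_path_matrix <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  if (any(!is.finite(d))) stop("graph is not connected: unreachable vertex pair")
  dimnames(d) <- NULL
  storage.mode(d) <- "integer"
  d
}

# exact within-block all-pairs detour table by DFS over simple paths
# adj: whole-graph adjacency list; vs: sorted vertex ids of one block
block_detour_table <- function(adj, vs, counter, budget) {
  k <- length(vs)
  loc <- integer(max(vs))
  loc[vs] <- seq_len(k)
  ladj <- lapply(vs, function(v) {
    nb <- adj[[v]]
    sort(loc[nb[nb %in% vs]])
  })
  best <- matrix(0L, k, k)
  visited <- logical(k)
  s <- 0L
  dfs <- function(v, len) {
    counter$steps <- counter$steps + 1L
    if (counter$steps > budget) {
      stop("detour enumeration budget exceeded (", budget,
           " steps); graph too dense for exact detour computation")
    }
    if (len > best[s, v]) best[s, v] <<- len
    visited[v] <<- TRUE
    for (w in ladj[[v]]) if (!visited[w]) dfs(w, len + 1L)
    visited[v] <<- FALSE
  }
  for (s0 in seq_len(max(k - 1L, 1L))) {
    s <- s0
    dfs(s0, 0L)
  }
  best <- pmax(best, t(best))
  dimnames(best) <- list(as.character(vs), as.character(vs))
  best
}

#' All-pairs detour matrix (exact longest simple paths)
#'
#' The detour distance between two vertices is the length of the longest
#' simple path joining them.  The computation is exact: the graph is
#' decomposed into biconnected components (blocks) via its block-cut tree;
#' a simple path between two vertices traverses a unique sequence of blocks
#' and enters/leaves each through fixed cut vertices, so the detour distance
#' is the sum of within-block detour distances along that sequence.  Within
#' each block all simple paths are enumerated by depth-first search.  On a
#' tree every block is a single edge and the detour matrix equals the
#' shortest-path matrix.
#'
#' Enumeration work is counted and the function stops with an error if
#' `budget` DFS steps are exceeded rather than silently approximating;
#' molecular-scale graphs (up to ~40 heavy atoms, cyclomatic number up to
#' ~6) stay far below the default budget.
#'
#' @param g a [molecular_graph()].
#' @param budget maximum number of DFS steps across all blocks.
#' @return An integer `n x n` matrix: symmetric, zero diagonal, entrywise at
#'   least the shortest-path matrix and at most `n - 1`.
#' @export
detour_matrix <- function(g, budget = 5e7) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- g$n_vertices
  D <- matrix(0L, n, n)
  if (n == 1L) return(D)
  ig <- as_igraph(g)
  bc <- igraph::biconnected_components(ig)
  blocks <- lapply(bc$components, function(v) sort(as.integer(v)))
  nb <- length(blocks)
  arts <- sort(as.integer(bc$articulation_points))
  adj <- adjacency_list(g)
  counter <- new.env(parent = emptyenv())
  counter$steps <- 0L
  bdet <- lapply(blocks, function(vs) block_detour_table(adj, vs, counter, budget))

  is_art <- logical(n); is_art[arts] <- TRUE
  art_id <- integer(n); art_id[arts] <- nb + seq_along(arts)
  vert_block <- integer(n)
  for (i in seq_len(nb)) vert_block[blocks[[i]]] <- i
  # block-cut tree: nodes 1..nb are blocks, nb+1.. are cut vertices
  bct_from <- integer(0); bct_to <- integer(0)
  for (i in seq_len(nb)) {
    cuts <- blocks[[i]][is_art[blocks[[i]]]]
    if (length(cuts)) {
      bct_from <- c(bct_from, rep.int(i, length(cuts)))
      bct_to <- c(bct_to, art_id[cuts])
    }
  }
  bct <- igraph::make_graph(rbind(bct_from, bct_to), n = nb + length(arts),
                            directed = FALSE)
  rep_node <- ifelse(is_art, art_id, vert_block)

  for (u in seq_len(n - 1L)) {
    targets <- (u + 1L):n
    vpaths <- igraph::shortest_paths(bct, from = rep_node[u],
                                     to = unique(rep_node[targets]),
                                     output = "vpath")$vpath
    names(vpaths) <- vapply(vpaths, function(p) as.character(as.integer(p)[length(p)]),
                            character(1))
    for (v in targets) {
      nodes <- as.integer(vpaths[[as.character(rep_node[v])]])
      bpos <- which(nodes <= nb)
      total <- 0L
      cur <- u
      for (j in seq_along(bpos)) {
        bi <- nodes[bpos[j]]
        ex <- if (j < length(bpos)) arts[nodes[bpos[j] + 1L] - nb] else v
        total <- total + bdet[[bi]][as.character(cur), as.character(ex)]
        cur <- ex
      }
      D[u, v] <- D[v, u] <- total
    }
  }
  D
}

#' Brute-force detour distance for one vertex pair (test oracle)
#'
#' Exhaustive depth-first enumeration of every simple path between two
#' vertices over the whole graph, independent of the block-decomposition
#' engine.  Exponential; refuses graphs with more than 12 vertices.
#'
#' @param g a [molecular_graph()].
#' @param a,b 1-based vertex indices.
#' @return The maximum simple-path length between `a` and `b`.
#' @export
brute_force_detour <- function(g, a, b) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- g$n_vertices
  if (n > 12L) stop("brute_force_detour is exponential; refusing n > 12")
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(a >= 1L, a <= n, b >= 1L, b <= n)
  if (a == b) return(0L)
  adj <- adjacency_list(g)
  best <- 0L
  visited <- logical(n)
  dfs <- function(v, len) {
    if (v == b) {
      if (len > best) best <<- len
      return(invisible())
    }
    visited[v] <<- TRUE
    for (w in adj[[v]]) if (!visited[w]) dfs(w, len + 1L)
    visited[v] <<- FALSE
  }
  dfs(a, 0L)
  best
}
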