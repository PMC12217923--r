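# Random molecular-scale graphs and synthetic QSPR datasets for testing.

#' Random connected simple graph of molecular scale
#'
#' A uniform random labelled tree (Prüfer-sequence sampling) on `n` vertices
#' plus `extra_edges` distinct non-tree edges drawn uniformly, so the result
#' is connected and simple by construction with cyclomatic number exactly
#' `extra_edges`.  This brackets hydrogen-depleted drug graphs: sparse,
#' connected, ring count roughly 0-6.
#'
#' @param n number of vertices (>= 2).
#' @param extra_edges number of independent cycles; at most
#'   `n (n - 1) / 2 - (n - 1)`.
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param name graph label.
#' @return A [molecular_graph()].
#' @examples
#' g <- random_connected_graph(10, 3, seed = 1)
#' cyclomatic_number(g)
#' @export
random_connected_graph <- function(n, extra_edges = 0L, seed = NULL,
                                   name = "random_graph") {
  n <- as.integer(n); extra_edges <- as.integer(extra_edges)
  stopifnot(n >= 2L, extra_edges >= 0L)
  max_extra <- n * (n - 1L) / 2L - (n - 1L)
  if (extra_edges > max_extra) {
    stop("infeasible edge count: at most ", max_extra,
         " extra edges on ", n, " vertices")
  }
  draw <- function() {
    tree <- igraph::sample_tree(n, method = "prufer")
    te <- igraph::as_edgelist(tree)
    te <- cbind(pmin(te[, 1L], te[, 2L]), pmax(te[, 1L], te[, 2L]))
    edges <- te
    if (extra_edges > 0L) {
      all_pairs <- t(utils::combn(n, 2L))
      key <- function(m) m[, 1L] * (n + 1L) + m[, 2L]
      cand <- all_pairs[!(key(all_pairs) %in% key(te)), , drop = FALSE]
      pick <- sample.int(nrow(cand), extra_edges)
      edges <- rbind(edges, cand[pick, , drop = FALSE])
    }
    molecular_graph(edges, n_vertices = n, name = name)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# evaluate one named index on a graph, computing only the matrix it needs
index_value <- function(g, index) {
  index <- match.arg(index, .index_names)
  if (index %in% c("wiener", "hyper_wiener", "harary")) {
    dm <- shortest_path_matrix(g)
    switch(index, wiener = wiener(dm), hyper_wiener = hyper_wiener(dm),
           harary = harary(dm))
  } else {
    dtm <- detour_matrix(g)
    switch(index, detour = detour_index(dtm),
           detour_harary = detour_harary(dtm))
  }
}

#' Generate a synthetic QSPR dataset from the linear model P = A + b * TI
#'
#' Draws `n_molecules` random connected graphs, computes the chosen
#' topological index for each, and emits
#' `p_i = true_intercept + true_slope * TI_i + e_i` with independent
#' Gaussian noise `e_i ~ N(0, noise_sd^2)` — the generative model the QSPR
#' regression assumes.  If a draw happens to give the index zero variance
#' (all graphs index-equivalent) the graph set is redrawn, up to 20 times.
#'
#' @param n_molecules number of molecules (>= 3).
#' @param true_intercept,true_slope the generating line.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed optional integer seed; the dataset is fully determined by it.
#' @param index which index to use as the predictor (default `"wiener"`).
#' @param n_atoms inclusive range of graph sizes to draw from.
#' @param cyclomatic inclusive range of ring counts to draw from.
#' @return An object of class `qspr_dataset`: a list with numeric vectors
#'   `ti` and `p`, the `index` name and a `truth` list holding the
#'   generating parameters.
#' @examples
#' ds <- generate_qspr_dataset(10, 3, 2, noise_sd = 0, seed = 1)
#' fit_simple_regression(ds$ti, ds$p)$slope  # exactly 2
#' @export
generate_qspr_dataset <- function(n_molecules, true_intercept, true_slope,
                                  noise_sd, seed = NULL, index = "wiener",
                                  n_atoms = c(10L, 28L),
                                  cyclomatic = c(0L, 6L)) {
  n_molecules <- as.integer(n_molecules)
  stopifnot(n_molecules >= 3L, noise_sd >= 0, length(n_atoms) == 2L,
            length(cyclomatic) == 2L, n_atoms[1L] >= 2L, cyclomatic[1L] >= 0L)
  index <- match.arg(index, .index_names)
  draw <- function() {
    for (attempt in seq_len(20L)) {
      ti <- vapply(seq_len(n_molecules), function(i) {
        nv <- sample(n_atoms[1L]:n_atoms[2L], 1L)
        max_extra <- nv * (nv - 1L) / 2L - (nv - 1L)
        ce <- sample(cyclomatic[1L]:min(cyclomatic[2L], max_extra), 1L)
        index_value(random_connected_graph(nv, ce), index)
      }, numeric(1))
      if (stats::var(ti) > 0) {
        p <- true_intercept + true_slope * ti +
          stats::rnorm(n_molecules, 0, noise_sd)
        return(structure(
          list(ti = ti, p = p, index = index,
               truth = list(intercept = true_intercept, slope = true_slope,
                            noise_sd = noise_sd)),
          class = "qspr_dataset"))
      }
      message("degenerate index variance on attempt ", attempt, "; redrawing")
    }
    stop("could not draw graphs with non-degenerate index variance")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @export
print.qspr_dataset <- function(x, ...) {
  cat(sprintf(
    "<qspr_dataset> %d molecules, index = %s, truth: P = %g + %g TI + N(0, %g^2)\n",
    length(x$ti), x$index, x$truth$intercept, x$truth$slope, x$truth$noise_sd))
  invisible(x)
}
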