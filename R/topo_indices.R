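# The five distance-based topological indices.

check_distance_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("expected a square matrix")
  if (any(m != t(m))) stop("matrix must be symmetric")
  if (any(diag(m) != 0)) stop("matrix must have a zero diagonal")
  if (nrow(m) > 1L && any(m[upper.tri(m)] < 1)) {
    stop("off-diagonal entries must be positive (connected graph)")
  }
  invisible(m)
}

#' Wiener index
#'
#' Sum of shortest-path distances over all unordered vertex pairs.
#'
#' @param dm a distance matrix from [shortest_path_matrix()].
#' @return Non-negative integer-valued numeric.
#' @export
wiener <- function(dm) {
  check_distance_matrix(dm)
  sum(as.numeric(dm[upper.tri(dm)]))
}

#' Hyper-Wiener index
#'
#' Sum of `(d + d^2) / 2` over all unordered vertex pairs; always an exact
#' integer because `d(d + 1)` is even.
#'
#' @inheritParams wiener
#' @return Non-negative integer-valued numeric.
#' @export
hyper_wiener <- function(dm) {
  check_distance_matrix(dm)
  d <- as.numeric(dm[upper.tri(dm)])
  sum(d * (d + 1) / 2)
}

#' Harary index
#'
#' Sum of reciprocal shortest-path distances over all unordered vertex pairs.
#'
#' @inheritParams wiener
#' @return Positive real.
#' @export
harary <- function(dm) {
  check_distance_matrix(dm)
  sum(1 / as.numeric(dm[upper.tri(dm)]))
}

#' Detour index
#'
#' Sum of detour (longest simple path) distances over all unordered vertex
#' pairs.  Equals the Wiener index on a tree.
#'
#' @param dtm a detour matrix from [detour_matrix()].
#' @return Non-negative integer-valued numeric.
#' @export
detour_index <- function(dtm) {
  check_distance_matrix(dtm)
  sum(as.numeric(dtm[upper.tri(dtm)]))
}

#' Detour-Harary index
#'
#' Sum of reciprocal detour distances over all unordered vertex pairs.
#'
#' @inheritParams detour_index
#' @return Positive real.
#' @export
detour_harary <- function(dtm) {
  check_distance_matrix(dtm)
  sum(1 / as.numeric(dtm[upper.tri(dtm)]))
}

#' Compute all five indices for one molecule
#'
#' Builds the shortest-path and detour matrices once and evaluates the
#' Wiener, hyper-Wiener, Harary, detour and detour-Harary indices.  Values
#' are kept at full precision; rounding to four decimals happens only in
#' report writers.
#'
#' @param g a [molecular_graph()].
#' @return An object of class `topo_index_set`: a list with numeric fields
#'   `wiener`, `hyper_wiener`, `harary`, `detour`, `detour_harary` and the
#'   molecule `name`.
#' @examples
#' g <- parse_smiles("C1CC1", "cyclopropane")
#' compute_index_set(g)
#' @export
compute_index_set <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  dm <- shortest_path_matrix(g)
  dtm <- detour_matrix(g)
  structure(
    list(wiener = wiener(dm),
         hyper_wiener = hyper_wiener(dm),
         harary = harary(dm),
         detour = detour_index(dtm),
         detour_harary = detour_harary(dtm),
         name = g$name),
    class = "topo_index_set")
}

#' @export
print.topo_index_set <- function(x, ...) {
  cat(sprintf(
    "<topo_index_set> %s\n  W = %d  WW = %d  H = %.4f  D = %d  DH = %.4f\n",
    if (nzchar(x$name)) x$name else "(unnamed)",
    as.integer(x$wiener), as.integer(x$hyper_wiener), x$harary,
    as.integer(x$detour), x$detour_harary))
  invisible(x)
}

#' @export
as.data.frame.topo_index_set <- function(x, ...) {
  data.frame(drug = x$name, wiener = x$wiener, hyper_wiener = x$hyper_wiener,
             harary = x$harary, detour = x$detour,
             detour_harary = x$detour_harary, stringsAsFactors = FALSE)
}

# canonical index column names, in table order (internal)
.index_names <- c("wiener", "hyper_wiener", "harary", "detour", "detour_harary")
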