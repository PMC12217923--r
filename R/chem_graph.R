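# Molecular graphs: hydrogen-depleted, simple, connected, undirected.

#' Construct a molecular graph
#'
#' A molecular graph is the hydrogen-depleted skeleton of a molecule: one
#' vertex per heavy atom, one edge per bond.  The graph must be simple (no
#' self-loops, no parallel edges) and connected; every distance-based index
#' in this package is undefined otherwise.
#'
#' @param edges two-column matrix (or data frame) of 1-based vertex index
#'   pairs, one row per undirected edge.
#' @param n_vertices number of vertices; defaults to the largest index seen
#'   in `edges`.
#' @param name text label for the molecule.
#' @param elements optional character vector of element symbols, one per
#'   vertex.
#' @return An object of class `molecular_graph`: a list with fields `name`,
#'   `n_vertices`, `edges` (canonically ordered, smaller index first) and
#'   `elements`.
#' @examples
#' g <- molecular_graph(rbind(c(1, 2), c(2, 3), c(3, 1)), name = "cyclopropane")
#' cyclomatic_number(g)
#' @export
molecular_graph <- function(edges, n_vertices = NULL, name = "", elements = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("'edges' must have two columns (vertex index pairs)")
  }
  if (any(!is.finite(edges)) || any(edges != round(edges)) || any(edges < 1)) {
    stop("edge endpoints must be positive integers")
  }
  storage.mode(edges) <- "integer"
  if (is.null(n_vertices)) {
    n_vertices <- if (nrow(edges)) max(edges) else 1L
  }
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 1L) stop("'n_vertices' must be >= 1")
  if (nrow(edges) && max(edges) > n_vertices) {
    stop("edge endpoint exceeds 'n_vertices'")
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed in a simple molecular graph")
  }
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- a * (n_vertices + 1L) + b
  if (anyDuplicated(key)) {
    stop("duplicate (parallel) edges are not allowed in a simple molecular graph")
  }
  o <- order(a, b)
  edges <- cbind(a, b)[o, , drop = FALSE]
  dimnames(edges) <- NULL
  if (!is.null(elements)) {
    elements <- as.character(elements)
    if (length(elements) != n_vertices) {
      stop("'elements' must have one symbol per vertex")
    }
  }
  g <- structure(
    list(name = as.character(name), n_vertices = n_vertices,
         edges = edges, elements = elements),
    class = "molecular_graph"
  )
  comp <- graph_components(g)
  if (max(comp) > 1L) {
    frag <- vapply(seq_len(max(comp)), function(k) {
      vs <- which(comp == k)
      if (!is.null(elements)) paste0(elements[vs], collapse = "") else
        paste0("{", paste(vs, collapse = ","), "}")
    }, character(1))
    stop("graph is not connected; fragments: ", paste(frag, collapse = " + "))
  }
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d vertices, %d edges, cyclomatic number %d\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              x$n_vertices, nrow(x$edges), cyclomatic_number(x)))
  invisible(x)
}

#' Cyclomatic number (ring count) of a connected graph
#'
#' `|E| - |V| + 1`, the number of independent cycles.
#'
#' @param g a [molecular_graph()].
#' @return Non-negative integer.
#' @export
cyclomatic_number <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  nrow(g$edges) - g$n_vertices + 1L
}

# igraph view of a molecular_graph (internal)
as_igraph <- function(g) {
  igraph::make_graph(as.vector(t(g$edges)), n = g$n_vertices, directed = FALSE)
}

# adjacency list, neighbours sorted by index (internal; deterministic order)
adjacency_list <- function(g) {
  adj <- vector("list", g$n_vertices)
  for (i in seq_len(g$n_vertices)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges[r, 1L]; b <- g$edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

# connected-component labels without igraph (internal; used during validation)
graph_components <- function(g) {
  n <- g$n_vertices
  comp <- integer(n)
  adj <- adjacency_list(g)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  comp
}

#' Parse a SMILES string into a hydrogen-depleted molecular graph
#'
#' Bond orders are collapsed: single, double, triple and aromatic bonds all
#' become one unweighted edge (the simple-graph convention under which the
#' distance-based indices are defined).  Hydrogens are suppressed.
#'
#' @param smiles a single SMILES string.
#' @param name text label for the molecule.
#' @return A [molecular_graph()] with an `elements` field.
#' @examples
#' parse_smiles("C1CC1", "cyclopropane")  # a triangle
#' @export
parse_smiles <- function(smiles, name = "") {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop("invalid SMILES ", sQuote(smiles), ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  heavy <- which(toupper(elements) != "H")
  if (!length(heavy)) stop("SMILES ", sQuote(smiles), " has no heavy atoms")
  remap <- integer(length(elements))
  remap[heavy] <- seq_along(heavy)
  edges <- matrix(integer(0), ncol = 2L)
  if (!is.null(dim(bb)) && nrow(bb)) {
    a <- as.integer(bb[, 1L]); b <- as.integer(bb[, 2L])
    keep <- a %in% heavy & b %in% heavy
    if (any(keep)) {
      edges <- unique(cbind(pmin(remap[a[keep]], remap[b[keep]]),
                            pmax(remap[a[keep]], remap[b[keep]])))
    }
  }
  tryCatch(
    molecular_graph(edges, n_vertices = length(heavy), name = name,
                    elements = elements[heavy]),
    error = function(e) {
      stop("SMILES ", sQuote(smiles), ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Parse a plain-text adjacency list
#'
#' Each non-comment line holds one edge as two 0-based vertex indices
#' separated by whitespace; `#` starts a comment.  The vertex count is
#' `max(index) + 1`.
#'
#' @param text_lines character vector of lines (e.g. from [readLines()]).
#' @param name text label for the molecule.
#' @return A [molecular_graph()].
#' @export
parse_adjacency <- function(text_lines, name = "") {
  lines <- sub("#.*$", "", text_lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no edges found in adjacency input")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed adjacency line(s): ", paste(lines[bad], collapse = "; "))
  }
  ij <- suppressWarnings(
    matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE))
  if (any(is.na(ij)) || any(ij < 0L)) {
    stop("adjacency indices must be non-negative integers")
  }
  molecular_graph(ij + 1L, n_vertices = max(ij) + 1L, name = name)
}

#' Read an adjacency-list file
#'
#' @param path file path.
#' @param name molecule label; defaults to the file name.
#' @return A [molecular_graph()].
#' @export
read_adjacency <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  parse_adjacency(readLines(path, warn = FALSE), name = name)
}

#' Write a molecular graph as a plain-text adjacency list
#'
#' Inverse of [parse_adjacency()]: indices are written 0-based, one edge per
#' line, with a leading comment naming the molecule.
#'
#' @param g a [molecular_graph()].
#' @param path file path or connection.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(g, path) {
  stopifnot(inherits(g, "molecular_graph"))
  lines <- c(paste0("# ", g$name),
             paste(g$edges[, 1L] - 1L, g$edges[, 2L] - 1L))
  writeLines(lines, path)
  invisible(path)
}

# heavy-atom counts from the molecular formulae of the fifteen drugs
.fixture_heavy_atoms <- c(
  Alprazolam = 22L, Amitriptyline = 21L, Amoxapine = 22L, Buspirone = 28L,
  Clomipramine = 22L, Desipramine = 20L, Desvenlafaxine = 19L, Diazepam = 20L,
  Fluoxetine = 22L, Imipramine = 21L, Lorazepam = 21L, Nortriptyline = 20L,
  Oxazepam = 20L, Protriptyline = 20L, Trimipramine = 22L)

#' Load the fifteen tricyclic antidepressant drug fixtures
#'
#' Each fixture bundles a drug's SMILES structure, its heavy-atom count, its
#' eight physicochemical properties (boiling point, melting point, enthalpy
#' of vaporisation, flash point, molar refractivity, polarizability, surface
#' tension, molar volume) and the published values of the five topological
#' indices.  The published index table prints two rows labelled
#' "Alprazolam"; the second, whose values coincide with Imipramine's (the
#' two skeletons are isomorphic), is carried here as Amitriptyline so that
#' each of the fifteen drugs has exactly one row.
#'
#' @return A list of 15 objects of class `drug_fixture`, in alphabetical
#'   order, each with fields `name`, `structure` (SMILES),
#'   `heavy_atom_count`, `properties` (named numeric, length 8) and
#'   `expected_indices` (named numeric, length 5).
#' @examples
#' fx <- load_drug_fixtures()
#' fx[[6]]$name
#' fx[[6]]$properties[["boiling_point"]]
#' @export
load_drug_fixtures <- function() {
  ext <- system.file("extdata", package = "topoqspr", mustWork = TRUE)
  smi_path <- file.path(ext, "tricyclic_smiles.tsv")
  prop_path <- file.path(ext, "physicochemical_properties.csv")
  idx_path <- file.path(ext, "published_indices.csv")
  for (p in c(smi_path, prop_path, idx_path)) {
    if (!file.exists(p)) stop("fixture file missing: ", p)
  }
  smi_lines <- readLines(smi_path, warn = FALSE)
  smi_lines <- smi_lines[nzchar(trimws(smi_lines)) & !startsWith(smi_lines, "#")]
  smi_parts <- strsplit(smi_lines, "\t", fixed = TRUE)
  if (any(lengths(smi_parts) != 2L)) stop("corrupt SMILES fixture file")
  structures <- vapply(smi_parts, `[[`, "", 1L)
  names(structures) <- vapply(smi_parts, `[[`, "", 2L)
  props <- utils::read.csv(prop_path, stringsAsFactors = FALSE)
  idx <- utils::read.csv(idx_path, stringsAsFactors = FALSE)
  need_prop <- c("drug", "boiling_point", "melting_point", "enthalpy",
                 "flash_point", "molar_refractivity", "polarizability",
                 "surface_tension", "molar_volume")
  need_idx <- c("drug", "wiener", "hyper_wiener", "harary", "detour",
                "detour_harary")
  if (!identical(names(props), need_prop) || !identical(names(idx), need_idx)) {
    stop("corrupt fixture table: unexpected columns")
  }
  drugs <- sort(names(.fixture_heavy_atoms))
  if (!setequal(drugs, props$drug) || !setequal(drugs, idx$drug) ||
      !setequal(drugs, names(structures))) {
    stop("corrupt fixture tables: drug sets disagree")
  }
  lapply(drugs, function(d) {
    pr <- unlist(props[props$drug == d, -1L])
    ei <- unlist(idx[idx$drug == d, -1L])
    structure(
      list(name = d,
           structure = unname(structures[[d]]),
           heavy_atom_count = unname(.fixture_heavy_atoms[[d]]),
           properties = pr,
           expected_indices = ei),
      class = "drug_fixture")
  })
}

#' @export
print.drug_fixture <- function(x, ...) {
  cat(sprintf("<drug_fixture> %s (%d heavy atoms)\n  %s\n",
              x$name, x$heavy_atom_count, x$structure))
  invisible(x)
}
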