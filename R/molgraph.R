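# Classed error helper so callers can test for specific failure modes.
stop_molactivity <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "molactivity_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Molecular graph constructor
#'
#' Builds the simple, undirected, connected graph object on which all
#' activity indices are computed. Vertices are contiguous integers
#' `1..n`; edges are unordered pairs with no self-loops and no
#' duplicates. For chemical inputs use [graph_from_smiles()] or
#' [read_sdf_graphs()], which apply hydrogen suppression before calling
#' this constructor.
#'
#' @param edges two-column matrix (or coercible) of vertex pairs. Labels
#'   may be arbitrary (characters, non-contiguous integers); they are
#'   remapped to `1..n` and the original labels retained.
#' @param name text label for the graph.
#' @return An object of class `molecular_graph` with fields `name`, `n`,
#'   `edges` (two-column integer matrix, `1..n`), and `labels` (original
#'   vertex labels in internal order).
#' @examples
#' p2 <- molecular_graph(rbind(c(0, 1)), name = "P2")
#' p2$n
#' @export
molecular_graph <- function(edges, name = "") {
  if (is.null(dim(edges))) {
    if (length(edges) == 2L) edges <- matrix(edges, ncol = 2L)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L || nrow(edges) < 1L) {
    stop_molactivity("invalid_graph_error",
                     "edges must be a non-empty two-column matrix of vertex pairs")
  }
  labels <- sort(unique(as.vector(edges)))
  u <- match(edges[, 1L], labels)
  v <- match(edges[, 2L], labels)
  if (any(u == v)) {
    stop_molactivity("invalid_graph_error",
                     sprintf("self-loop at vertex '%s'", labels[u[u == v][1L]]))
  }
  key <- paste(pmin(u, v), pmax(u, v))
  if (anyDuplicated(key)) {
    stop_molactivity("invalid_graph_error",
                     sprintf("duplicate edge: %s", key[duplicated(key)][1L]))
  }
  n <- length(labels)
  if (n < 2L) {
    stop_molactivity("degenerate_input_error",
                     "a molecular graph needs at least 2 vertices")
  }
  em <- cbind(as.integer(u), as.integer(v))
  comp <- .components(n, em)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    stop_molactivity(
      "disconnectivity_error",
      sprintf("graph is disconnected (%d components of sizes %s)",
              max(comp), paste(sizes, collapse = ", ")),
      component_sizes = sizes
    )
  }
  structure(
    list(name = as.character(name), n = n, edges = em, labels = labels),
    class = "molecular_graph"
  )
}

# Connected-component labelling by BFS on an adjacency list.
.components <- function(n, edges) {
  adj <- .adjacency_list(n, edges)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      x <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[x]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

.adjacency_list <- function(n, edges) {
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d vertices, %d edges\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' @rdname molecular_graph
#' @details `graph_from_edge_list()` is an alias of [molecular_graph()]
#'   provided for symmetry with the chemical constructors.
#' @export
graph_from_edge_list <- function(edges, name = "") {
  molecular_graph(edges, name = name)
}

# igraph view of a molecular_graph, used by the production distance code.
as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}

#' Vertex degrees of a molecular graph
#' @param g a `molecular_graph`.
#' @return integer vector of length `g$n`.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  tabulate(as.vector(g$edges), nbins = g$n)
}

#' Hydrogen-suppressed graph from a SMILES string
#'
#' Parses a SMILES string and returns the graph on its heavy (non-hydrogen)
#' atoms: one vertex per heavy atom, one edge per bond between heavy atoms.
#' Bond order and aromaticity are deliberately discarded (every bond is a
#' single edge), and charges, isotopes and stereo descriptors are ignored:
#' the activity indices are functions of 2-D connectivity only. Multi-
#' fragment inputs (e.g. salts) are a hard error rather than being reduced
#' to their largest fragment, because the indices are defined for connected
#' graphs only.
#'
#' @param smiles a single SMILES string.
#' @param name text label; defaults to the SMILES itself.
#' @return a [molecular_graph()].
#' @examples
#' g <- graph_from_smiles("OCC1=CC(=O)C(O)=CO1", name = "kojic acid")
#' g$n  # 10 heavy atoms
#' @export
graph_from_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      stop_molactivity("invalid_structure_error",
                       sprintf("SMILES parse failure for '%s': %s",
                               smiles, conditionMessage(e)))
    }
  )
  g <- .graph_from_sdf_record(sdf[[1]], name = name)
  if (is.null(g)) {
    stop_molactivity("invalid_structure_error",
                     sprintf("SMILES '%s' yields no bonds between heavy atoms", smiles))
  }
  g
}

# Shared hydrogen-suppression path for SDF records. Returns NULL when the
# record has no heavy-heavy bonds at all.
.graph_from_sdf_record <- function(sdf, name = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop_molactivity("invalid_structure_error", "empty atom block")
  }
  sym <- gsub("_.*$", "", rownames(ab))
  heavy <- which(sym != "H")
  if (length(heavy) < 2L) {
    stop_molactivity("degenerate_input_error",
                     sprintf("fewer than 2 heavy atoms (%d)", length(heavy)))
  }
  idx <- match(seq_len(nrow(ab)), heavy)  # old index -> new heavy index
  if (is.null(bb) || nrow(bb) == 0L) return(NULL)
  e <- cbind(idx[bb[, 1L]], idx[bb[, 2L]])
  e <- e[stats::complete.cases(e), , drop = FALSE]
  if (nrow(e) == 0L) return(NULL)
  molecular_graph(e, name = name)
}

#' Read a SMILES file
#'
#' One record per line, `SMILES<TAB>name` (name optional); blank lines and
#' lines starting with `#` are skipped.
#'
#' @param path path to a `.smi` file.
#' @return data frame with columns `smiles` and `name`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    smiles = vapply(parts, `[[`, "", 1L),
    name = vapply(parts, function(p) if (length(p) > 1L)
      paste(p[-1L], collapse = " ") else p[[1L]], ""),
    stringsAsFactors = FALSE
  )
}

#' Graphs from all molecules in a SMILES file
#'
#' @inheritParams read_smi
#' @param on_error `"stop"` aborts at the first bad record; `"warn"` skips
#'   bad records with a warning naming the record index.
#' @return list of [molecular_graph()] objects.
#' @export
read_smi_graphs <- function(path, on_error = c("stop", "warn")) {
  on_error <- match.arg(on_error)
  tab <- read_smi(path)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    g <- tryCatch(graph_from_smiles(tab$smiles[i], name = tab$name[i]),
                  molactivity_error = function(e) e)
    if (inherits(g, "condition")) {
      if (on_error == "stop") stop(g)
      warning(sprintf("record %d ('%s') skipped: %s",
                      i, tab$name[i], conditionMessage(g)), call. = FALSE)
    } else {
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

#' Graphs from an SDF/MOL file
#'
#' Reads a V2000 SDF file and applies the same hydrogen suppression as
#' [graph_from_smiles()]. Unreadable or degenerate records are skipped with
#' a warning reporting the record index.
#'
#' @param path path to an SDF file.
#' @return list of [molecular_graph()] objects (record titles as names).
#' @export
read_sdf_graphs <- function(path) {
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) == 0L) return(list())
  out <- list()
  for (i in seq_along(sdfset)) {
    rec <- sdfset[[i]]
    title <- tryCatch(ChemmineR::header(rec)[["Molecule_Name"]],
                      error = function(e) "")
    if (is.null(title) || is.na(title)) title <- ""
    g <- tryCatch(.graph_from_sdf_record(rec, name = title),
                  error = function(e) e)
    if (inherits(g, "condition") || is.null(g)) {
      msg <- if (inherits(g, "condition")) conditionMessage(g) else "no heavy-atom bonds"
      warning(sprintf("SDF record %d skipped: %s", i, msg), call. = FALSE)
    } else {
      out[[length(out) + 1L]] <- g
    }
  }
  out
}
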