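#' All-pairs shortest-path distances
#'
#' Unit-weight shortest-path distances between every pair of vertices,
#' computed by per-vertex breadth-first search.
#'
#' @param g a [molecular_graph()].
#' @return symmetric integer matrix with zero diagonal.
#' @export
all_pairs_distances <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Vertex eccentricities
#'
#' `ec(v)` is the distance from `v` to a vertex farthest from it.
#'
#' @inheritParams all_pairs_distances
#' @param dist optional precomputed distance matrix from
#'   [all_pairs_distances()].
#' @return integer vector of length `g$n`.
#' @export
eccentricities <- function(g, dist = NULL) {
  if (is.null(dist)) dist <- all_pairs_distances(g)
  apply(dist, 1L, max)
}

#' Neighbourhood irregularity index
#'
#' `t(v)` counts the *distinct degree values* occurring among the
#' neighbours of `v` (method `"distinct-values"`, the default). A second
#' reading of the same phrase, the number of neighbours whose degree
#' differs from `deg(v)`, is available as method `"differing-degree"`.
#' The default is fixed by the worked taxifolin example, whose internal
#' score sum 85.8333 is reproduced only by `"distinct-values"`; see the
#' methods vignette.
#'
#' @inheritParams all_pairs_distances
#' @param v vertex index in `1..n`, or `NULL` for all vertices.
#' @param method which reading of the irregularity index to use.
#' @return integer vector (length 1 if `v` is given).
#' @export
irregularity_index <- function(g, v = NULL,
                               method = c("distinct-values", "differing-degree")) {
  method <- match.arg(method)
  deg <- degrees(g)
  adj <- .adjacency_list(g$n, g$edges)
  tv <- function(x) {
    nb <- adj[[x]]
    if (method == "distinct-values") length(unique(deg[nb]))
    else sum(deg[nb] != deg[x])
  }
  if (is.null(v)) vapply(seq_len(g$n), tv, integer(1)) else {
    stopifnot(v >= 1L, v <= g$n)
    tv(as.integer(v))
  }
}

#' Per-vertex activity scores
#'
#' Classifies every vertex as *external* (degree 1, the set S) or
#' *internal* (degree > 1, the set Q) and computes its score:
#' for external `v`, `s(v) = sum over u in S of d(u, v)` (the `u = v`
#' term is 0, so including it is immaterial); for internal `v`,
#' `s(v) = t(v) / deg(v) * ec(v)`.
#'
#' @inheritParams irregularity_index
#' @return data frame with one row per vertex: `vertex`, `degree`,
#'   `irregularity` (`NA` for external vertices), `eccentricity`,
#'   `score`, `klass` (`"external"` or `"internal"`).
#' @export
vertex_scores <- function(g, method = c("distinct-values", "differing-degree")) {
  method <- match.arg(method)
  deg <- degrees(g)
  dist <- all_pairs_distances(g)
  ecc <- eccentricities(g, dist)
  S <- which(deg == 1L)
  tv <- irregularity_index(g, method = method)
  score <- numeric(g$n)
  if (length(S)) {
    score[S] <- colSums(dist[S, S, drop = FALSE])
  }
  Q <- which(deg > 1L)
  score[Q] <- tv[Q] / deg[Q] * ecc[Q]
  data.frame(
    vertex = seq_len(g$n),
    degree = deg,
    irregularity = ifelse(deg > 1L, tv, NA_integer_),
    eccentricity = ecc,
    score = score,
    klass = ifelse(deg == 1L, "external", "internal"),
    stringsAsFactors = FALSE
  )
}

#' External and internal activity of a molecular graph
#'
#' The external activity is
#' `D(G) = (sum over v in S of s(v)) / n^3` and the internal activity is
#' `zeta(G) = (sum over v in Q of s(v)) / n^2`, where S and Q are the
#' external (degree-1) and internal vertices and `s(v)` is defined in
#' [vertex_scores()]. Graphs with at most one end vertex have `D = 0`;
#' graphs with no internal vertex (only `P2`) have `zeta = 0`.
#'
#' @inheritParams vertex_scores
#' @return object of class `activity_result`: a list with `name`, `n`,
#'   `external_numerator` (an integer: twice the sum of distances over
#'   unordered end-vertex pairs), `internal_numerator`, `D` and `zeta`.
#' @examples
#' g <- generate_graph("cycle", 6)
#' compute_activity(g)$zeta  # 9/36 = 0.25
#' @export
compute_activity <- function(g, method = c("distinct-values", "differing-degree")) {
  method <- match.arg(method)
  vs <- vertex_scores(g, method = method)
  ext <- sum(vs$score[vs$klass == "external"])
  int <- sum(vs$score[vs$klass == "internal"])
  structure(
    list(
      name = g$name,
      n = g$n,
      external_numerator = as.integer(round(ext)),
      internal_numerator = int,
      D = ext / g$n^3,
      zeta = int / g$n^2
    ),
    class = "activity_result"
  )
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("<activity_result> %s: n = %d, D = %.9f (%d/n^3), zeta = %.9f (%.4f/n^2)\n",
              if (nzchar(x$name)) x$name else "(unnamed)", x$n,
              x$D, x$external_numerator, x$zeta, x$internal_numerator))
  invisible(x)
}

#' Activity table for a list of graphs
#'
#' @param graphs list of [molecular_graph()] objects.
#' @inheritParams vertex_scores
#' @return data frame with columns `name`, `n`, `external_numerator`,
#'   `internal_numerator`, `D`, `zeta`.
#' @export
activity_table <- function(graphs, method = c("distinct-values", "differing-degree")) {
  method <- match.arg(method)
  rows <- lapply(graphs, function(g) {
    a <- compute_activity(g, method = method)
    data.frame(name = a$name, n = a$n,
               external_numerator = a$external_numerator,
               internal_numerator = a$internal_numerator,
               D = a$D, zeta = a$zeta, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an activity table as CSV
#'
#' `D` and `zeta` are formatted to 9 decimal places to mirror the
#' reference tables; full precision is retained in memory.
#'
#' @param tab data frame from [activity_table()].
#' @param path output file path.
#' @export
write_activity_csv <- function(tab, path) {
  out <- tab
  out$internal_numerator <- sprintf("%.4f", out$internal_numerator)
  out$D <- sprintf("%.9f", out$D)
  out$zeta <- sprintf("%.9f", out$zeta)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
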