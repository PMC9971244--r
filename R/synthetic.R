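# Seeded abstract-graph generators and a brute-force activity oracle.
# The oracle deliberately shares no code with the production path: distances
# come from a hand-written Floyd-Warshall instead of BFS, and the score sums
# are naive loops, so the two routes can check each other in property tests.

#' Generate a graph from a parametric family
#'
#' Deterministic given `(family, n, seed)`. Families: `path` (P_n),
#' `cycle` (C_n, n >= 3), `star` (K_{1,n-1}), `barbell` (two complete
#' graphs of size `floor(n/2)` joined by an edge, odd leftover vertex
#' appended to the bridge), `random_tree` (uniform over labelled trees,
#' via a random Pruefer sequence), and `random_connected` (random tree
#' plus extra random non-tree edges).
#'
#' @param family one of `"path"`, `"cycle"`, `"star"`, `"barbell"`,
#'   `"random_tree"`, `"random_connected"`.
#' @param n number of vertices (>= 2; >= 3 for cycle, >= 4 for barbell).
#' @param seed integer seed for the random families.
#' @param extra_edges for `random_connected`: how many non-tree edges to
#'   add (capped at the number of available non-edges).
#' @return a [molecular_graph()].
#' @examples
#' generate_graph("star", 5)  # K_{1,4}
#' @export
generate_graph <- function(family = c("path", "cycle", "star", "barbell",
                                      "random_tree", "random_connected"),
                           n, seed = 1L, extra_edges = 2L) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    stop_molactivity("spec_error", "n must be an integer >= 2")
  }
  if (family == "cycle" && n < 3L) {
    stop_molactivity("spec_error", "a cycle needs n >= 3")
  }
  if (family == "barbell" && n < 4L) {
    stop_molactivity("spec_error", "a barbell needs n >= 4")
  }
  name <- sprintf("%s_%d_seed%d", family, n, seed)
  edges <- switch(
    family,
    path = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
    cycle = cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L)),
    star = cbind(rep(1L, n - 1L), seq_len(n - 1L) + 1L),
    barbell = .barbell_edges(n),
    random_tree = .with_seed(seed, .pruefer_tree_edges(n)),
    random_connected = .with_seed(seed, {
      e <- .pruefer_tree_edges(n)
      .add_random_edges(e, n, extra_edges)
    })
  )
  molecular_graph(edges, name = name)
}

# Run expr under a local RNG state so generation never disturbs the
# caller's stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.barbell_edges <- function(n) {
  k <- n %/% 2L
  left <- seq_len(k)
  right <- seq_len(n - k - (n %% 2L)) + k
  clique <- function(v) {
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  }
  e <- rbind(clique(left), clique(right), c(k, k + 1L))
  if (n %% 2L == 1L) e <- rbind(e, c(k, n))  # pendant on the bridge
  e
}

# Decode a uniformly random Pruefer sequence: uniform labelled tree on n.
.pruefer_tree_edges <- function(n) {
  if (n == 2L) return(cbind(1L, 2L))
  pr <- sample.int(n, n - 2L, replace = TRUE)
  degree <- tabulate(pr, nbins = n) + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  ptr <- 0L
  leaves <- which(degree == 1L)
  for (i in seq_len(n - 2L)) {
    leaf <- min(leaves)
    v <- pr[i]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, v)
    leaves <- leaves[leaves != leaf]
    degree[v] <- degree[v] - 1L
    if (degree[v] == 1L) leaves <- c(leaves, v)
  }
  edges[n - 1L, ] <- sort(leaves)[1:2]
  edges
}

.add_random_edges <- function(edges, n, extra) {
  have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all_pairs <- t(utils::combn(n, 2L))
  key <- paste(all_pairs[, 1], all_pairs[, 2])
  avail <- which(!(key %in% have))
  extra <- min(as.integer(extra), length(avail))
  if (extra > 0L) {
    pick <- avail[sample.int(length(avail), extra)]
    edges <- rbind(edges, all_pairs[pick, , drop = FALSE])
  }
  edges
}

#' Brute-force activity oracle
#'
#' Independent recomputation of [compute_activity()] for small graphs:
#' Floyd-Warshall distances and naive per-vertex loops, sharing no code
#' with the production implementation. Intended for property tests;
#' refuses graphs with more than 30 vertices.
#'
#' @inheritParams compute_activity
#' @return an `activity_result`, as from [compute_activity()].
#' @export
oracle_activity <- function(g, method = c("distinct-values", "differing-degree")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "molecular_graph"))
  n <- g$n
  if (n > 30L) {
    stop_molactivity("spec_error", "oracle_activity is for graphs with n <= 30")
  }
  inf <- n + 1L
  d <- matrix(inf, n, n)
  diag(d) <- 0L
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1L]; b <- g$edges[i, 2L]
    d[a, b] <- 1L; d[b, a] <- 1L
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  deg <- integer(n)
  for (i in seq_len(nrow(g$edges))) {
    deg[g$edges[i, 1L]] <- deg[g$edges[i, 1L]] + 1L
    deg[g$edges[i, 2L]] <- deg[g$edges[i, 2L]] + 1L
  }
  ext <- 0L
  for (v in seq_len(n)) {
    if (deg[v] != 1L) next
    for (u in seq_len(n)) if (deg[u] == 1L) ext <- ext + d[u, v]
  }
  int <- 0
  for (v in seq_len(n)) {
    if (deg[v] <= 1L) next
    nbd <- integer(0)
    for (i in seq_len(nrow(g$edges))) {
      if (g$edges[i, 1L] == v) nbd <- c(nbd, deg[g$edges[i, 2L]])
      if (g$edges[i, 2L] == v) nbd <- c(nbd, deg[g$edges[i, 1L]])
    }
    tv <- if (method == "distinct-values") length(unique(nbd)) else sum(nbd != deg[v])
    int <- int + tv / deg[v] * max(d[v, ])
  }
  structure(
    list(name = g$name, n = n,
         external_numerator = as.integer(ext),
         internal_numerator = int,
         D = ext / n^3, zeta = int / n^2),
    class = "activity_result"
  )
}

#' Write a graph as an edge-list text file
#'
#' One `u v` pair per line (1-based labels), for debugging generated
#' graphs or feeding them back through [graph_from_edge_list()].
#'
#' @param g a [molecular_graph()].
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  writeLines(sprintf("%d %d", g$edges[, 1L], g$edges[, 2L]), path)
  invisible(path)
}

#' Read an edge-list text file
#'
#' @param path file with one `u v` pair per line; `#` comments allowed.
#' @param name graph name.
#' @return a [molecular_graph()].
#' @export
read_edge_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  e <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  molecular_graph(e, name = name)
}
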