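#' Skeleton graph of a maze
#'
#' A `maze_graph` describes a maze as an undirected graph G(v, e) whose
#' vertices are the maze's dead-ends (degree 1) and intersections
#' (degree >= 3), plus the start and egg cells; maximal runs of plain
#' corridor (degree-2 cells) collapse into single edges. An open arena
#' (no unit-width corridor structure) follows the single-region
#' convention: one vertex of recorded degree 1 and no edges, so its total
#' weighted complexity is 1.
#'
#' @param degrees named or unnamed integer vector of vertex degrees; vertex
#'   ids are `seq_along(degrees)`.
#' @param edges two-column integer matrix of unordered vertex-id pairs
#'   (zero rows allowed only for the single-region convention).
#' @param start_vertex,egg_vertex vertex ids of the start and egg.
#' @param region logical; `TRUE` marks the single-region convention, in
#'   which `degrees` is taken as recorded rather than derived from `edges`.
#' @param cells optional two-column matrix of the (col, row) grid cell
#'   backing each vertex.
#' @return An object of class `maze_graph`.
#' @export
maze_graph <- function(degrees, edges, start_vertex, egg_vertex,
                       region = FALSE, cells = NULL) {
  degrees <- as.integer(degrees)
  nv <- length(degrees)
  if (nv == 0) stop("graph has no vertices")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (!region) {
    if (any(edges < 1 | edges > nv)) stop("edge refers to unknown vertex")
    inc <- tabulate(c(edges[, 1], edges[, 2]), nbins = nv)
    if (!identical(inc, degrees))
      stop("vertex degrees are inconsistent with the edge list")
    if (!graph_is_connected(nv, edges))
      stop("maze graph is disconnected")
  }
  structure(
    list(degrees = degrees, edges = edges,
         start_vertex = as.integer(start_vertex),
         egg_vertex = as.integer(egg_vertex),
         region = region, cells = cells),
    class = "maze_graph")
}

graph_is_connected <- function(nv, edges) {
  if (nv == 1) return(TRUE)
  adj <- adjacency_list(nv, edges)
  seen <- logical(nv); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

adjacency_list <- function(nv, edges) {
  adj <- vector("list", nv)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(x) sort(unique(x)))
}

#' @export
print.maze_graph <- function(x, ...) {
  cat(sprintf("<maze_graph> %d vertices, %d edges%s\n",
              length(x$degrees), nrow(x$edges),
              if (x$region) " (single-region convention)" else ""))
  cat(sprintf("  start vertex %d, egg vertex %d, TC_w = %d\n",
              x$start_vertex, x$egg_vertex, total_weighted_complexity(x)))
  invisible(x)
}

#' Extract the skeleton graph of a maze environment
#'
#' Corridor cells whose 4-connected corridor degree differs from 2 become
#' vertices (dead-ends and intersections); the start and egg cells are
#' always vertices. Chains of degree-2 cells between vertices collapse to
#' single edges. Skeletons are defined for unit-width corridors; an arena
#' containing any open 2 x 2 corridor block (e.g. the bundled barrier-free
#' arena) is treated as a single open region and returns the
#' single-region convention (one vertex of degree 1, no edges).
#'
#' @param env a [grid_environment()].
#' @return A [maze_graph()]. Vertex ids follow column-major grid order.
#' @export
maze_to_graph <- function(env) {
  b <- env$barrier
  nx <- nrow(b); ny <- ncol(b)
  corridor <- !b
  # dead-end/intersection skeletons are defined for unit-width corridors;
  # an arena with any open 2x2 corridor block is a single region
  if (nx > 1 && ny > 1) {
    wide <- corridor[-nx, -ny] & corridor[-1, -ny] &
      corridor[-nx, -1] & corridor[-1, -1]
    if (any(wide)) {
      return(maze_graph(1L, matrix(integer(0), ncol = 2), 1L, 1L,
                        region = TRUE,
                        cells = matrix(env$egg_cell, ncol = 2)))
    }
  }
  deg <- matrix(0L, nx, ny)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    shifted <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) + d[1]; ys <- seq_len(ny) + d[2]
    okx <- xs >= 1 & xs <= nx; oky <- ys >= 1 & ys <= ny
    shifted[okx, oky] <- corridor[xs[okx], ys[oky]]
    deg <- deg + (corridor & shifted)
  }
  is_vertex <- corridor & deg != 2L
  start <- env$start_cells[1, ]
  is_vertex[start[1], start[2]] <- TRUE
  is_vertex[env$egg_cell[1], env$egg_cell[2]] <- TRUE
  vcells <- which(is_vertex, arr.ind = TRUE)   # column-major order
  vid <- matrix(NA_integer_, nx, ny)
  vid[is_vertex] <- seq_len(nrow(vcells))
  dirs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  edges <- matrix(integer(0), ncol = 2)
  for (v in seq_len(nrow(vcells))) {
    for (d in dirs) {
      cur <- c(vcells[v, 1], vcells[v, 2])
      nxt <- cur + d
      if (nxt[1] < 1 || nxt[1] > nx || nxt[2] < 1 || nxt[2] > ny) next
      if (!corridor[nxt[1], nxt[2]]) next
      prev <- cur; cur <- nxt
      # walk through degree-2 pass-through cells until the next vertex
      while (is.na(vid[cur[1], cur[2]])) {
        found <- FALSE
        for (dd in dirs) {
          cand <- cur + dd
          if (cand[1] < 1 || cand[1] > nx || cand[2] < 1 || cand[2] > ny) next
          if (!corridor[cand[1], cand[2]]) next
          if (cand[1] == prev[1] && cand[2] == prev[2]) next
          prev <- cur; cur <- cand; found <- TRUE
          break
        }
        if (!found) stop("corridor chain terminated without a vertex")
      }
      w <- vid[cur[1], cur[2]]
      if (w > v || (w == v && FALSE)) {
        edges <- rbind(edges, c(v, w))
      } else if (w == v) {
        stop("corridor loop attached to a single vertex is not supported")
      }
    }
  }
  edges <- unique(edges)  # two adjacent vertices share at most one corridor here
  maze_graph(tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(vcells)),
             edges,
             start_vertex = vid[start[1], start[2]],
             egg_vertex = vid[env$egg_cell[1], env$egg_cell[2]],
             cells = vcells)
}

#' Read or write a graph sidecar file
#'
#' Sidecars store a [maze_graph()] as JSON:
#' `{"vertices": [{"id":..,"degree":..},...], "edges": [[a,b],...],
#'   "start":.., "egg":..}`.
#'
#' @param path sidecar path.
#' @return `load_graph_sidecar()` returns a [maze_graph()].
#' @export
load_graph_sidecar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ord <- order(j$vertices$id)
  stopifnot(identical(as.integer(j$vertices$id[ord]),
                      seq_along(j$vertices$id)))
  maze_graph(j$vertices$degree[ord],
             matrix(as.integer(j$edges), ncol = 2),
             start_vertex = j$start, egg_vertex = j$egg)
}

#' @rdname load_graph_sidecar
#' @param graph a [maze_graph()].
#' @export
save_graph_sidecar <- function(graph, path) {
  jsonlite::write_json(
    list(vertices = data.frame(id = seq_along(graph$degrees),
                               degree = graph$degrees),
         edges = unname(graph$edges),
         start = graph$start_vertex,
         egg = graph$egg_vertex),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Total weighted complexity of a maze graph
#'
#' The total weighted complexity TC_w of a maze is the sum of the vertex
#' degrees of its skeleton graph. Under the single-region convention a
#' barrier-free arena has TC_w = 1.
#'
#' @param graph a [maze_graph()].
#' @return A nonnegative integer.
#' @export
total_weighted_complexity <- function(graph) {
  stopifnot(inherits(graph, "maze_graph"))
  if (length(graph$degrees) == 0) stop("empty graph")
  sum(graph$degrees)
}

#' Shortest start-to-egg path of a maze graph
#'
#' Breadth-first search from the start vertex; among equal-length paths the
#' predecessor with the lowest vertex id wins, so the result is
#' deterministic (the bundled mazes are acyclic, so their path is unique
#' regardless).
#'
#' @param graph a [maze_graph()].
#' @return Integer vector of vertex ids from start to egg inclusive.
#' @export
shortest_path_vertices <- function(graph) {
  if (graph$region) return(graph$start_vertex)
  nv <- length(graph$degrees)
  adj <- adjacency_list(nv, graph$edges)
  dist <- rep(NA_integer_, nv); pred <- rep(NA_integer_, nv)
  s <- graph$start_vertex
  dist[s] <- 0L; queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {           # neighbours in increasing id order
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; pred[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  e <- graph$egg_vertex
  if (is.na(dist[e])) stop("no path from start to egg in the graph")
  path <- e
  while (path[1] != s) path <- c(pred[path[1]], path)
  path
}

#' Probability of traversing the direct start-to-egg path
#'
#' At each vertex along the shortest start-to-egg path an undirected walker
#' choosing uniformly among the d_i incident corridors continues correctly
#' with probability 1/d_i; the direct-path probability is the product of
#' these reciprocals over the k path vertices.
#'
#' @param graph a [maze_graph()].
#' @return A probability in (0, 1]. Its reciprocal is the effective number
#'   of possible paths.
#' @export
direct_path_probability <- function(graph) {
  path <- shortest_path_vertices(graph)
  prod(1 / graph$degrees[path])
}
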