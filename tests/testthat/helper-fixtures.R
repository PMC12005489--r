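# in-code maze fixtures and small oracles shared across tests

write_maze_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# straight 3x1 corridor: start, open, egg
corridor_env <- function() load_maze(write_maze_lines("S.E"))

# T-shaped corridor: one 3-way intersection, three dead-ends
t_maze_lines <- c(
  "#S#",
  "#.#",
  "..E")
t_env <- function() load_maze(write_maze_lines(t_maze_lines))

# hand-built maze_graph: T junction, degrees {3,1,1,1}
t_graph <- function() {
  maze_graph(degrees = c(3, 1, 1, 1),
             edges = rbind(c(1, 2), c(1, 3), c(1, 4)),
             start_vertex = 2, egg_vertex = 4)
}

# brute-force DFS path finder + degree product oracle
dfs_path_product <- function(graph) {
  nv <- length(graph$degrees)
  adj <- vector("list", nv)
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges[k, 1]; b <- graph$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  best <- NULL
  recurse <- function(v, path) {
    if (v == graph$egg_vertex) {
      if (is.null(best) || length(path) < length(best)) best <<- path
      return()
    }
    for (w in adj[[v]]) if (!w %in% path) recurse(w, c(path, w))
  }
  recurse(graph$start_vertex, graph$start_vertex)
  prod(1 / graph$degrees[best])
}

# random labelled tree on n vertices via a Pruefer sequence
random_tree_graph <- function(n) {
  stopifnot(n >= 3)
  prufer <- sample.int(n, n - 2, replace = TRUE)
  degree <- rep(1L, n) + tabulate(prufer, n)
  edges <- matrix(0L, n - 1, 2)
  deg <- degree
  for (i in seq_len(n - 2)) {
    leaf <- min(which(deg == 1L))
    edges[i, ] <- c(leaf, prufer[i])
    deg[leaf] <- 0L
    deg[prufer[i]] <- deg[prufer[i]] - 1L
  }
  edges[n - 1, ] <- which(deg == 1L)
  ends <- sample.int(n, 2)
  maze_graph(degree, edges, start_vertex = ends[1], egg_vertex = ends[2])
}

# deterministic movement-parameter table: every class moves at speed v
# along its heading with zero noise and zero turning
class_param_matrix_for_test <- function(v = 254) {
  m <- matrix(0, 5, 4)
  m[, 1] <- v
  m
}
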