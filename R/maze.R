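#' Gridded microenvironment for sperm-agent simulations
#'
#' A `grid_environment` represents a bounded 2D arena discretised into square
#' grid cells (40 um by default, matching the length scale used to calibrate
#' the motility parameters). Cells are either corridor (passable) or barrier
#' (impassable). One corridor cell holds the egg; one or more corridor cells
#' form the start region. A visited mask records which corridor cells have
#' been entered by at least one agent.
#'
#' Continuous agent coordinates are in micrometres with the origin at the
#' arena's lower-left corner. Grid cells are half-open intervals
#' `[i*cell, (i+1)*cell)` in each axis, so every interior point maps to
#' exactly one cell. Cell indices are 1-based `(col, row)` pairs with row 1
#' at the bottom.
#'
#' @param barrier logical matrix, `TRUE` for impassable cells. Indexed
#'   `[col, row]` with row 1 at the bottom of the arena.
#' @param start_cells integer matrix with two columns (col, row), the cells
#'   of the designated start region.
#' @param egg_cell integer vector `c(col, row)`, the egg's cell.
#' @param cell_size_um side length of one grid cell in micrometres.
#' @return An object of class `grid_environment`.
#' @export
grid_environment <- function(barrier, start_cells, egg_cell,
                             cell_size_um = 40) {
  stopifnot(is.matrix(barrier), is.logical(barrier))
  start_cells <- matrix(as.integer(start_cells), ncol = 2)
  egg_cell <- as.integer(egg_cell)
  env <- structure(
    list(
      barrier = barrier,
      start_cells = start_cells,
      egg_cell = egg_cell,
      cell_size_um = cell_size_um,
      visited = matrix(FALSE, nrow = nrow(barrier), ncol = ncol(barrier)),
      width_um = nrow(barrier) * cell_size_um,
      height_um = ncol(barrier) * cell_size_um
    ),
    class = "grid_environment"
  )
  validate_environment(env)
  env
}

validate_environment <- function(env) {
  b <- env$barrier
  if (b[env$egg_cell[1], env$egg_cell[2]])
    stop("egg cell lies on a barrier cell")
  for (i in seq_len(nrow(env$start_cells))) {
    sc <- env$start_cells[i, ]
    if (b[sc[1], sc[2]]) stop("start cell lies on a barrier cell")
  }
  comp <- corridor_component(env, env$start_cells[1, ])
  if (!comp[env$egg_cell[1], env$egg_cell[2]])
    stop("egg cell is not reachable from the start region")
  if (!all(comp[!b]))
    stop("corridor is disconnected: some corridor cells are unreachable from the start region")
  invisible(env)
}

# flood fill over 4-connected corridor cells from one cell
corridor_component <- function(env, from) {
  b <- env$barrier
  nx <- nrow(b); ny <- ncol(b)
  seen <- matrix(FALSE, nx, ny)
  queue <- matrix(as.integer(from), ncol = 2)
  seen[from[1], from[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = TRUE]
    queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nxt <- cur + d
      if (nxt[1] >= 1 && nxt[1] <= nx && nxt[2] >= 1 && nxt[2] <= ny &&
          !b[nxt[1], nxt[2]] && !seen[nxt[1], nxt[2]]) {
        seen[nxt[1], nxt[2]] <- TRUE
        queue <- rbind(queue, nxt)
      }
    }
  }
  seen
}

#' @export
print.grid_environment <- function(x, ...) {
  cat(sprintf(
    "<grid_environment> %d x %d cells of %g um (%g x %g um)\n",
    nrow(x$barrier), ncol(x$barrier), x$cell_size_um, x$width_um, x$height_um))
  cat(sprintf("  barrier cells: %d | start cells: %d | egg cell: (%d, %d)\n",
              sum(x$barrier), nrow(x$start_cells),
              x$egg_cell[1], x$egg_cell[2]))
  sp <- search_progress(x)
  cat(sprintf("  searched: %.1f%% (%g um^2)\n",
              100 * sp$fraction, sp$area_um2))
  invisible(x)
}

#' Load a maze environment from an ASCII grid file
#'
#' The file format is one row of glyphs per line: `#` barrier, `.` corridor,
#' `S` start cell (one or more), `E` egg cell (exactly one). The first line
#' of the file is the top row of the arena.
#'
#' @param path path to the maze file.
#' @param cell_size_um grid cell side length in micrometres.
#' @return A [grid_environment()].
#' @seealso [save_maze()], [maze_fixture()]
#' @export
load_maze <- function(path, cell_size_um = 40) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) stop("maze file is empty: ", path)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1)
    stop(sprintf("ragged maze grid: line %d has width %d, expected %d",
                 which(widths != widths[1])[1],
                 widths[widths != widths[1]][1], widths[1]))
  chars <- strsplit(lines, "")
  bad <- vapply(chars, function(cc) any(!cc %in% c("#", ".", "S", "E")),
                logical(1))
  if (any(bad)) {
    ln <- which(bad)[1]
    glyph <- setdiff(chars[[ln]], c("#", ".", "S", "E"))[1]
    stop(sprintf("unknown glyph '%s' on line %d of %s", glyph, ln, path))
  }
  ny <- length(lines)       # rows (top to bottom in file)
  nx <- widths[1]           # columns
  # file row 1 is the TOP of the arena; internal row index 1 is the BOTTOM
  glyph <- matrix("", nrow = nx, ncol = ny)
  for (r in seq_len(ny)) glyph[, ny - r + 1] <- chars[[r]]
  barrier <- glyph == "#"
  starts <- which(glyph == "S", arr.ind = TRUE)
  eggs <- which(glyph == "E", arr.ind = TRUE)
  if (nrow(eggs) != 1)
    stop(sprintf("maze must contain exactly one egg cell 'E' (found %d)",
                 nrow(eggs)))
  if (nrow(starts) < 1) stop("maze must contain at least one start cell 'S'")
  grid_environment(barrier, starts, c(eggs[1, 1], eggs[1, 2]),
                   cell_size_um = cell_size_um)
}

#' Save a maze environment to an ASCII grid file
#'
#' Inverse of [load_maze()]: `load_maze()` followed by `save_maze()`
#' reproduces the grid file byte-for-byte (modulo trailing whitespace).
#'
#' @param env a [grid_environment()].
#' @param path output path.
#' @export
save_maze <- function(env, path) {
  nx <- nrow(env$barrier); ny <- ncol(env$barrier)
  glyph <- matrix(".", nx, ny)
  glyph[env$barrier] <- "#"
  for (i in seq_len(nrow(env$start_cells)))
    glyph[env$start_cells[i, 1], env$start_cells[i, 2]] <- "S"
  glyph[env$egg_cell[1], env$egg_cell[2]] <- "E"
  lines <- vapply(seq_len(ny), function(r)
    paste(glyph[, ny - r + 1], collapse = ""), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled maze environments
#'
#' Three bundled 17 x 17 arenas of 40 um cells (680 x 680 um): `"A"` is the
#' open arena (no internal barriers, egg in the bottom-right corner), `"B"`
#' and `"C"` are acyclic labyrinths of increasing total weighted complexity
#' (22 and 54). Mazes B and C are synthetic reconstructions: labyrinths
#' built to satisfy the published complexity statistics (acyclicity, total
#' weighted complexity, and for maze C a shortest-path degree product of
#' 34,992), not copies of any particular published drawing. Their graph
#' sidecars (see [load_graph_sidecar()]) are bundled alongside.
#'
#' @param name one of `"A"`, `"B"`, `"C"`.
#' @param what `"env"` to load the environment, `"path"` for the grid file
#'   path, `"graph_path"` for the sidecar path (`NA` for maze A).
#' @return A [grid_environment()] or a file path.
#' @export
maze_fixture <- function(name = c("A", "B", "C"),
                         what = c("env", "path", "graph_path")) {
  name <- match.arg(name)
  what <- match.arg(what)
  file <- switch(name,
                 A = "maze_A.txt",
                 B = "maze_B_synthetic.txt",
                 C = "maze_C_synthetic.txt")
  path <- system.file("extdata", "mazes", file, package = "spermsim",
                      mustWork = TRUE)
  if (what == "path") return(path)
  if (what == "graph_path") {
    if (name == "A") return(NA_character_)
    return(sub("\\.txt$", ".json", path))
  }
  load_maze(path)
}

#' Map a continuous position to its containing grid cell
#'
#' @param env a [grid_environment()].
#' @param position numeric `c(x, y)` in micrometres.
#' @return integer `c(col, row)` (1-based).
#' @export
position_cell <- function(env, position) {
  c(floor(position[1] / env$cell_size_um) + 1L,
    floor(position[2] / env$cell_size_um) + 1L)
}

#' Mark the grid cell containing a position as searched
#'
#' A cell counts as distinctly searched once at least one agent has passed
#' through it; marking is idempotent.
#'
#' @param env a [grid_environment()].
#' @param position numeric `c(x, y)` in micrometres; must lie inside the
#'   arena and on a corridor cell (a barrier hit here indicates an engine
#'   bug, so it raises an error).
#' @return The environment with the updated visited mask.
#' @export
mark_visited <- function(env, position) {
  cell <- position_cell(env, position)
  if (cell[1] < 1 || cell[1] > nrow(env$barrier) ||
      cell[2] < 1 || cell[2] > ncol(env$barrier))
    stop("position outside the arena")
  if (env$barrier[cell[1], cell[2]])
    stop("position lies in a barrier cell (engine invariant violated)")
  env$visited[cell[1], cell[2]] <- TRUE
  env
}

#' Search coverage of an environment
#'
#' @param env a [grid_environment()].
#' @return A list with `fraction` (visited corridor cells / total corridor
#'   cells), `area_um2` (visited cells times cell area), and `n_visited`.
#' @export
search_progress <- function(env) {
  corridor <- !env$barrier
  n_vis <- sum(env$visited & corridor)
  list(fraction = n_vis / sum(corridor),
       area_um2 = n_vis * env$cell_size_um^2,
       n_visited = n_vis)
}
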