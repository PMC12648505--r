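#' @title Network graph of the lymphatic vessel skeleton
#' @description Internal constructor for the graph container shared by the
#' measured pipeline and the phantom ground truth.  Nodes carry physical
#' positions and degrees; edges carry ordered paths (um polylines, plus the
#' voxel path when the graph was traced from a skeleton), lengths and class
#' labels in `{capillary_branch, precollector_link, cropped_precollector,
#' border_ambiguous, discarded}`.
#' @keywords internal
new_lymph_graph <- function(node_pos_um, edges_df, paths_um, paths_vox = NULL,
                            spacing_um = NA, origin_um = c(0, 0, 0),
                            dim = NA, roi_bounds_um = NULL) {
  n <- nrow(node_pos_um)
  nodes <- data.frame(id = seq_len(n),
                      z_um = as.numeric(node_pos_um[, 1]),
                      y_um = as.numeric(node_pos_um[, 2]),
                      x_um = as.numeric(node_pos_um[, 3]),
                      degree = integer(n))
  g <- structure(list(nodes = nodes, edges = edges_df, paths = paths_um,
                      paths_vox = paths_vox, spacing_um = spacing_um,
                      origin_um = origin_um, dim = dim,
                      roi_bounds_um = roi_bounds_um),
                 class = "lymph_graph")
  g$nodes$degree <- graph_degrees(g)
  g
}

empty_graph <- function(spacing_um = NA, origin_um = c(0, 0, 0), dim = NA) {
  new_lymph_graph(matrix(numeric(0), 0, 3),
                  data.frame(id = integer(0), from = integer(0), to = integer(0),
                             length_um = numeric(0), class = character(0),
                             layer = integer(0), border = logical(0)),
                  list(), list(), spacing_um, origin_um, dim)
}

#' @export
#' @method print lymph_graph
print.lymph_graph <- function(x, ...) {
  cat(sprintf("<lymph_graph> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (all(is.na(x$edges$class))) "unclassified"
              else paste(names(table(x$edges$class)),
                         table(x$edges$class), collapse = ", ")))
  invisible(x)
}

# degree = number of incident non-discarded edges (self-loops count twice)
graph_degrees <- function(g) {
  n <- nrow(g$nodes)
  keep <- is.na(g$edges$class) | g$edges$class != "discarded"
  tabulate(c(g$edges$from[keep], g$edges$to[keep]), nbins = n)
}

#' Symmetric adjacency (incidence-count) matrix of a graph
#' @param graph a `lymph_graph`.
#' @param include_discarded count discarded edges too (default FALSE).
#' @return a sparse symmetric integer matrix (Matrix package).
#' @export
adjacency_matrix <- function(graph, include_discarded = FALSE) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  if (!include_discarded && nrow(e))
    e <- e[is.na(e$class) | e$class != "discarded", , drop = FALSE]
  if (!nrow(e)) return(Matrix::sparseMatrix(integer(0), integer(0), dims = c(n, n)))
  m <- Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                            x = 1, dims = c(n, n))
  # self-loops were added twice on the diagonal already (from==to counted in
  # both orientations), which matches incidence-count conventions
  m
}

polyline_length <- function(p) {
  if (is.null(p) || nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

skeleton_neighbors <- function(coords, dims) {
  n <- nrow(coords)
  idx <- vox_index(coords, dims)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- vector("list", n)
  hits_i <- integer(0); hits_j <- integer(0)
  for (k in seq_len(nrow(offs))) {
    cc <- sweep(coords, 2, offs[k, ], `+`)
    ok <- cc[, 1] >= 1 & cc[, 1] <= dims[1] & cc[, 2] >= 1 & cc[, 2] <= dims[2] &
      cc[, 3] >= 1 & cc[, 3] <= dims[3]
    if (!any(ok)) next
    j <- match(vox_index(cc[ok, , drop = FALSE], dims), idx)
    found <- !is.na(j)
    hits_i <- c(hits_i, which(ok)[found])
    hits_j <- c(hits_j, j[found])
  }
  split(hits_j, factor(hits_i, levels = seq_len(n)))
}

#' Convert a skeleton into a network graph
#'
#' Nodes are skeleton voxels with a neighbor count different from 2
#' (endpoints and junctions); edges are maximal degree-2 chains with
#' polyline lengths.  The conversion is then repeated: terminal edges and
#' interior edges shorter than `min_edge_length_um` are removed/collapsed
#' and degree-2 nodes merged, until the (node count, edge count) pair
#' converges (guard at 100 iterations).  Pure cycles (components with no
#' junction) are represented by one node carrying a self-loop edge.
#'
#' @param skel a `lymph_skeleton`.
#' @param min_edge_length_um minimum retained edge length (default 10).
#' @param prune_mask optional source `lymph_mask` enabling significance
#'   pruning: a terminal edge shorter than the local vessel radius
#'   (distance to background at its junction) lies entirely inside the
#'   tube -- a thinning artifact of blunt blind ends -- and is removed,
#'   with the convergence iteration re-run.
#' @return a `lymph_graph` with unclassified edges.
#' @export
skeleton_to_graph <- function(skel, min_edge_length_um = 10,
                              prune_mask = NULL) {
  coords <- skel$coords
  dims <- skel$dim
  if (nrow(coords) == 0)
    return(empty_graph(skel$spacing_um, skel$origin_um, dims))
  nbrs <- skeleton_neighbors(coords, dims)
  deg <- lengths(nbrs)
  n <- nrow(coords)
  is_node <- deg != 2L
  node_rows <- which(is_node)
  node_of <- integer(n)
  node_of[node_rows] <- seq_along(node_rows)

  consumed <- logical(n)
  e_from <- integer(0); e_to <- integer(0); e_path <- list()
  for (v in node_rows) {
    for (nb in nbrs[[v]]) {
      if (is_node[nb]) {
        if (idx_lt(coords, v, nb))
          { e_from <- c(e_from, node_of[v]); e_to <- c(e_to, node_of[nb])
            e_path <- c(e_path, list(coords[c(v, nb), , drop = FALSE])) }
        next
      }
      if (consumed[nb]) next
      path <- c(v, nb)
      prev <- v; cur <- nb
      consumed[nb] <- TRUE
      repeat {
        nxt <- nbrs[[cur]]
        nxt <- nxt[nxt != prev]
        if (length(nxt) == 0) break               # dead end chain (shouldn't occur)
        # prefer an unconsumed continuation; a node terminates the chain
        nxt <- nxt[1]
        path <- c(path, nxt)
        if (is_node[nxt]) break
        if (consumed[nxt]) break
        consumed[nxt] <- TRUE
        prev <- cur; cur <- nxt
      }
      w <- path[length(path)]
      if (!is_node[w]) next                        # degenerate; skip
      e_from <- c(e_from, node_of[v]); e_to <- c(e_to, node_of[w])
      e_path <- c(e_path, list(coords[path, , drop = FALSE]))
    }
  }

  # leftover unconsumed degree-2 voxels belong to junction-free pure cycles:
  # promote one voxel per cycle to a node carrying a self-loop edge
  leftover <- which(!consumed & !is_node)
  for (v in leftover) {
    if (consumed[v]) next
    is_node[v] <- TRUE
    node_rows <- c(node_rows, v)
    node_of[v] <- length(node_rows)
    path <- v
    prev <- v; cur <- nbrs[[v]][1]
    while (!is.na(cur) && cur != v) {
      consumed[cur] <- TRUE
      path <- c(path, cur)
      nxt <- nbrs[[cur]]
      nxt <- nxt[nxt != prev][1]
      prev <- cur; cur <- nxt
    }
    path <- c(path, v)
    e_from <- c(e_from, node_of[v]); e_to <- c(e_to, node_of[v])
    e_path <- c(e_path, list(coords[path, , drop = FALSE]))
  }

  node_coords <- coords[node_rows, , drop = FALSE]
  g <- list(node_coords = node_coords, from = e_from, to = e_to, path = e_path)
  g <- converge_graph(g, skel$spacing_um, min_edge_length_um)
  if (!is.null(prune_mask)) {
    for (it in 1:5) {
      pruned <- prune_insignificant_terminals(g, skel, prune_mask)
      if (!pruned$changed) break
      g <- converge_graph(pruned$g, skel$spacing_um, min_edge_length_um)
    }
  }
  finalize_graph(g, skel)
}

# distance (um) from a voxel to the nearest background voxel of the mask
local_radius_um <- function(mask, vox, max_um = 40) {
  dims <- dim(mask$data)
  w <- ceiling(max_um / mask$spacing_um)
  i0 <- pmax(1, vox - w); i1 <- pmin(dims, vox + w)
  sub <- mask$data[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  bg <- which(!sub)
  if (!length(bg)) return(max_um)
  cc <- vox_coords(bg, dim(sub))
  cc <- sweep(cc, 2, vox - i0 + 1)
  min(sqrt(rowSums(sweep(cc, 2, mask$spacing_um, `*`)^2)))
}

prune_insignificant_terminals <- function(g, skel, mask) {
  nn <- nrow(g$node_coords)
  deg <- tabulate(c(g$from, g$to), nbins = nn)
  cand_e <- integer(0); cand_node <- integer(0); cand_len <- numeric(0)
  for (e in seq_along(g$path)) {
    if (g$from[e] == g$to[e]) next
    d1 <- deg[g$from[e]]; d2 <- deg[g$to[e]]
    if (xor(d1 == 1L, d2 == 1L)) {
      jn_end <- if (d1 == 1L) nrow(g$path[[e]]) else 1L
      jnode <- if (d1 == 1L) g$to[e] else g$from[e]
      jvox <- g$path[[e]][jn_end, ]
      len <- path_um_length(g$path[[e]], skel$spacing_um)
      r_loc <- local_radius_um(mask, jvox)
      # shorter than the local vessel diameter: an artifact prong of a
      # blunt blind end, not an anatomical branch
      if (len < 2 * r_loc + 2 * max(skel$spacing_um)) {
        cand_e <- c(cand_e, e); cand_node <- c(cand_node, jnode)
        cand_len <- c(cand_len, len)
      }
    }
  }
  drop <- integer(0)
  for (v in unique(cand_node)) {
    at_v <- which(cand_node == v)
    inc_v <- sum(g$from == v) + sum(g$to == v)
    if (length(at_v) == inc_v - 1L) {
      # all but one incident edge are insignificant prongs: the longest is
      # the continuation of the parent tube and is kept
      at_v <- at_v[-which.max(cand_len[at_v])]
    }
    drop <- c(drop, cand_e[at_v])
  }
  drop <- unique(drop)
  if (length(drop)) {
    g$from <- g$from[-drop]; g$to <- g$to[-drop]; g$path <- g$path[-drop]
  }
  list(g = g, changed = length(drop) > 0)
}

idx_lt <- function(coords, a, b) {
  # deterministic ordering of voxels by (x, y, z) major index
  ca <- coords[a, ]; cb <- coords[b, ]
  if (ca[3] != cb[3]) return(ca[3] < cb[3])
  if (ca[2] != cb[2]) return(ca[2] < cb[2])
  ca[1] < cb[1]
}

# march from the first point of path p along its outward tangent through
# mask foreground; TRUE if the tube exits the volume through an ROI face
mask_exits_face <- function(p, mask, roi_bounds_um, max_um = 120) {
  n <- min(nrow(p), 6L)
  if (n < 2) return(FALSE)
  dir <- p[1, ] - p[n, ]
  nd <- sqrt(sum(dir^2))
  if (nd == 0) return(FALSE)
  dir <- dir / nd
  step <- min(mask$spacing_um) / 2
  pos <- p[1, ]
  dims <- dim(mask$data)
  for (k in seq_len(ceiling(max_um / step))) {
    pos <- pos + dir * step
    vox <- floor((pos - mask$origin_um) / mask$spacing_um) + 1
    if (any(vox < 1) || any(vox > dims)) return(TRUE)   # left through a face
    if (!mask$data[vox[1], vox[2], vox[3]]) return(FALSE)  # tube ended inside
  }
  FALSE
}

# moving-average smoothing of an ordered polyline, endpoints pinned
smooth_polyline <- function(p, window = 5L) {
  n <- nrow(p)
  if (n <= 3) return(p)
  h <- window %/% 2
  out <- p
  for (j in 1:3) {
    cs <- cumsum(c(0, p[, j]))
    i <- seq_len(n)
    lo <- pmax(1L, i - h); hi <- pmin(n, i + h)
    out[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out[1, ] <- p[1, ]; out[n, ] <- p[n, ]
  out
}

path_um_length <- function(path_vox, spacing) {
  if (nrow(path_vox) < 2) return(0)
  sum(sqrt(rowSums(sweep(diff(path_vox), 2, spacing, `*`)^2)))
}

converge_graph <- function(g, spacing, min_len) {
  guard <- 0
  prev_counts <- c(-1L, -1L)
  repeat {
    guard <- guard + 1
    nn <- nrow(g$node_coords); ne <- length(g$path)
    if (identical(prev_counts, c(nn, ne)) || guard > 100) break
    prev_counts <- c(nn, ne)

    len <- vapply(g$path, path_um_length, numeric(1), spacing = spacing)

    # 0) drop degenerate self-loops below the minimum edge length (tiny
    # handles raised by surface noise at blunt caps); long cycles are kept
    tiny_loop <- which(len < min_len & g$from == g$to)
    if (length(tiny_loop)) {
      g$from <- g$from[-tiny_loop]; g$to <- g$to[-tiny_loop]
      g$path <- g$path[-tiny_loop]
      len <- len[-tiny_loop]
    }
    deg <- tabulate(c(g$from, g$to), nbins = nn)

    # 1) drop short terminal edges (spurs)
    term <- which(len < min_len & g$from != g$to &
                    (deg[g$from] == 1L | deg[g$to] == 1L))
    if (length(term)) {
      g$from <- g$from[-term]; g$to <- g$to[-term]; g$path <- g$path[-term]
      len <- len[-term]
      deg <- tabulate(c(g$from, g$to), nbins = nn)
    }

    # 2) contract short interior edges, one at a time
    repeat {
      len <- vapply(g$path, path_um_length, numeric(1), spacing = spacing)
      short <- which(len < min_len & g$from != g$to)
      if (!length(short)) break
      e <- short[1]
      a <- g$from[e]; b <- g$to[e]
      sp <- g$path[[e]]                            # path from a to b
      g$from <- g$from[-e]; g$to <- g$to[-e]; g$path <- g$path[-e]
      for (j in seq_along(g$path)) {
        if (g$from[j] == b) {
          # path starts at b: prepend sp (a..b) without its duplicate b end
          g$path[[j]] <- rbind(sp[-nrow(sp), , drop = FALSE], g$path[[j]])
          g$from[j] <- a
        }
        if (g$to[j] == b) {
          # path ends at b: append reversed sp (b..a) without its b end
          g$path[[j]] <- rbind(g$path[[j]],
                               sp[rev(seq_len(nrow(sp) - 1)), , drop = FALSE])
          g$to[j] <- a
        }
      }
    }

    # 3) merge degree-2 nodes (concatenate their two incident edges)
    nn <- nrow(g$node_coords)
    deg <- tabulate(c(g$from, g$to), nbins = nn)
    for (v in which(deg == 2L)) {
      inc <- which(g$from == v | g$to == v)
      if (length(inc) != 2L) next                  # self-loop at v: leave
      e1 <- inc[1]; e2 <- inc[2]
      # orient e1 to end at v, e2 to start at v
      p1 <- if (g$to[e1] == v) g$path[[e1]] else g$path[[e1]][nrow(g$path[[e1]]):1, , drop = FALSE]
      a <- if (g$to[e1] == v) g$from[e1] else g$to[e1]
      p2 <- if (g$from[e2] == v) g$path[[e2]] else g$path[[e2]][nrow(g$path[[e2]]):1, , drop = FALSE]
      b <- if (g$from[e2] == v) g$to[e2] else g$from[e2]
      g$from[e1] <- a; g$to[e1] <- b
      g$path[[e1]] <- rbind(p1, p2[-1, , drop = FALSE])
      g$from <- g$from[-e2]; g$to <- g$to[-e2]; g$path <- g$path[-e2]
      deg <- tabulate(c(g$from, g$to), nbins = nn)
    }

    # drop isolated nodes and compact ids
    nn <- nrow(g$node_coords)
    deg <- tabulate(c(g$from, g$to), nbins = nn)
    keep <- deg > 0L
    remap <- cumsum(keep)
    g$node_coords <- g$node_coords[keep, , drop = FALSE]
    g$from <- remap[g$from]; g$to <- remap[g$to]
  }
  g
}

finalize_graph <- function(g, skel) {
  # node voxel = first/last voxel of an incident path (kept consistent by
  # construction); store positions in um
  nn <- nrow(g$node_coords)
  node_vox <- g$node_coords
  # node positions may have been superseded by contraction: recover from paths
  if (length(g$path)) {
    for (j in seq_along(g$path)) {
      node_vox[g$from[j], ] <- g$path[[j]][1, ]
      node_vox[g$to[j], ] <- g$path[[j]][nrow(g$path[[j]]), ]
    }
  }
  pos_um <- vox_um(node_vox, skel$spacing_um, skel$origin_um)
  # smooth the voxel polylines (endpoints pinned) before measuring: raw
  # 26-connected chains overestimate the length of oblique lines by up to
  # ~8%; a short moving average is the standard digital-length correction
  paths_um <- lapply(g$path, function(p)
    smooth_polyline(vox_um(p, skel$spacing_um, skel$origin_um)))
  len <- vapply(paths_um, polyline_length, numeric(1))
  ne <- length(g$path)
  edges <- data.frame(id = seq_len(ne),
                      from = if (ne) g$from else integer(0),
                      to = if (ne) g$to else integer(0),
                      length_um = if (ne) len else numeric(0),
                      class = rep(NA_character_, ne),
                      layer = rep(NA_integer_, ne),
                      border = rep(NA, ne))
  roi <- rbind(skel$origin_um, skel$origin_um + skel$dim * skel$spacing_um)
  new_lymph_graph(pos_um, edges, paths_um, g$path, skel$spacing_um,
                  skel$origin_um, skel$dim, roi)
}

#' Classify edges into capillary branches and precollector links
#'
#' "Exiting" edges -- those with at least one endpoint of degree 1 -- are
#' capillary branches (blind-ended initial lymphatics); all other edges are
#' precollector links.  Labels are exhaustive and exclusive.
#'
#' @param graph a converged `lymph_graph`.
#' @return the graph with `edges$class` filled in.
#' @export
classify_edges <- function(graph) {
  if (!nrow(graph$edges)) return(graph)
  deg <- graph_degrees_ignoring_class(graph)
  terminal <- deg[graph$edges$from] == 1L | deg[graph$edges$to] == 1L
  graph$edges$class <- ifelse(terminal, "capillary_branch", "precollector_link")
  graph$nodes$degree <- graph_degrees(graph)
  graph
}

graph_degrees_ignoring_class <- function(g)
  tabulate(c(g$edges$from, g$edges$to), nbins = nrow(g$nodes))

#' Apply ROI-border cropping rules
#'
#' Edges touching the ROI border are reclassified by length: shorter than
#' `capillary_max_um` they are cropped capillaries and `discarded`; longer
#' than `precollector_min_um` they are `cropped_precollector` (retained for
#' density, excluded from capillary statistics); lengths in between get the
#' dedicated `border_ambiguous` class (kept for density, excluded from all
#' per-class statistics) -- the source rules leave this interval unaddressed
#' and silently assigning either group would not be auditable.
#'
#' @param graph a classified `lymph_graph`.
#' @param roi_bounds_um optional 2x3 matrix (rows min,max; columns z,y,x);
#'   defaults to the graph's own grid bounds.
#' @param capillary_max_um,precollector_min_um length cutoffs (25, 300 um).
#' @param mask optional `lymph_mask`: because thinning recedes from blunt
#'   cut surfaces by roughly one vessel radius, a terminal edge whose
#'   *element* (mask tube) continues to the ROI face would otherwise be
#'   missed; with a mask, terminal edges are ray-marched through the
#'   foreground from their endpoint and flagged as border-touching when the
#'   tube exits through a face.
#' @return the graph with border classes applied and degrees updated.
#' @export
apply_border_rules <- function(graph, roi_bounds_um = NULL,
                               capillary_max_um = 25,
                               precollector_min_um = 300, mask = NULL) {
  if (!nrow(graph$edges)) return(graph)
  if (is.null(roi_bounds_um)) roi_bounds_um <- graph$roi_bounds_um
  if (is.null(roi_bounds_um)) stop("ROI bounds unknown; supply roi_bounds_um")
  tol <- if (all(is.finite(graph$spacing_um))) 0.51 * max(graph$spacing_um) else 1e-6
  touches <- vapply(graph$paths, function(p) {
    any(sweep(p, 2, roi_bounds_um[1, ]) < tol) ||
      any(sweep(-p, 2, -roi_bounds_um[2, ]) < tol)
  }, logical(1))
  if (!is.null(mask)) {
    deg <- graph_degrees_ignoring_class(graph)
    for (j in which(!touches)) {
      for (end in c("from", "to")) {
        v <- graph$edges[[end]][j]
        if (deg[v] != 1L) next
        p <- graph$paths[[j]]
        if (graph$edges$from[j] != v) p <- p[nrow(p):1, , drop = FALSE]
        if (mask_exits_face(p, mask, roi_bounds_um)) { touches[j] <- TRUE; break }
      }
    }
  }
  graph$edges$border <- touches
  len <- graph$edges$length_um
  cls <- graph$edges$class
  cls[touches & len < capillary_max_um] <- "discarded"
  cls[touches & len > precollector_min_um] <- "cropped_precollector"
  cls[touches & len >= capillary_max_um & len <= precollector_min_um] <-
    "border_ambiguous"
  graph$edges$class <- cls
  graph$nodes$degree <- graph_degrees(graph)
  graph
}

#' Export a graph as node/edge CSV tables
#' @param graph a `lymph_graph`.
#' @param prefix output path prefix; writes `<prefix>_nodes.csv` and
#'   `<prefix>_edges.csv`.
#' @param config_md5 optional provenance hash recorded in a `config_md5`
#'   column.
#' @return the two paths, invisibly.
#' @export
write_graph_csv <- function(graph, prefix, config_md5 = NA_character_) {
  np <- paste0(prefix, "_nodes.csv"); ep <- paste0(prefix, "_edges.csv")
  nodes <- graph$nodes; nodes$config_md5 <- config_md5
  edges <- graph$edges; edges$config_md5 <- config_md5
  write.csv(nodes, np, row.names = FALSE)
  write.csv(edges, ep, row.names = FALSE)
  invisible(c(np, ep))
}

#' Export a graph as GraphML
#' @param graph a `lymph_graph`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  ig <- igraph::graph_from_data_frame(
    d = cbind(graph$edges[, c("from", "to")],
              graph$edges[, c("id", "length_um", "class")]),
    directed = FALSE,
    vertices = graph$nodes)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
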