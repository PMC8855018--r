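#' Exponential dispersal kernel
#'
#' Movement probability between patches decays exponentially with cost
#' distance, `p_ij = exp(-k * d_ij)`. The decay rate `k` is calibrated so that
#' the probability of covering the taxon's dispersal distance `d*` equals a
#' calibration probability `p*`: `k = -log(p*) / d*`, hence
#' `exp(-k d*) = p*` exactly. `p* = 0.05` at the dispersal distance is the
#' widespread convention for this family of connectivity indices.
#'
#' @param d_star dispersal distance in metres (> 0).
#' @param p_star probability of moving `d_star` (in (0, 1); default 0.05).
#' @return object of class `dispersal_model` with fields `d_star`, `p_star`,
#'   `k` (per metre).
#' @export
dispersal_model <- function(d_star, p_star = 0.05) {
  if (!is.numeric(d_star) || length(d_star) != 1L || d_star <= 0)
    stop("`d_star` must be a single positive distance in metres")
  if (!is.numeric(p_star) || length(p_star) != 1L || p_star <= 0 || p_star >= 1)
    stop("`p_star` must lie strictly between 0 and 1")
  structure(list(d_star = d_star, p_star = p_star,
                 k = -log(p_star) / d_star),
            class = "dispersal_model")
}

#' @rdname dispersal_model
#' @export
calibrate_decay <- function(d_star, p_star = 0.05) dispersal_model(d_star, p_star)$k

#' Per-taxon dispersal-distance presets
#'
#' Flora: 150 m (poorly mobile) and 500 m (moderately mobile).
#' Butterflies/orthopterans: 100 m and 300 m. Highly mobile species are
#' deliberately unsupported: at the landscape scale these graphs describe,
#' such species perceive the whole landscape as connected.
#'
#' @param taxon `"flora"` or `"insects"`.
#' @return named numeric vector of dispersal distances in metres.
#' @export
dispersal_preset <- function(taxon = c("flora", "insects")) {
  taxon <- match.arg(taxon)
  if (taxon == "flora") c(low = 150, moderate = 500) else c(low = 100, moderate = 300)
}

# Build the weighted cell-lattice graph plus one virtual node per patch.
# Movement uses 8-neighbourhood; a step between adjacent cells costs
# mean(cost_u, cost_v) * step_length, with diagonal steps sqrt(2) longer.
# Cells belonging to an extracted patch contribute cost 0 (movement within a
# patch is free, so distances run border to border). Nodata cells are
# impassable and excluded from the graph.
.cell_patch_graph <- function(surface, patches) {
  nr <- nrow(surface$cost); nc <- ncol(surface$cost)
  cost <- surface$cost
  cost[!is.na(patches$label)] <- 0
  passable <- !is.na(cost)
  idx <- which(passable)
  id_of <- integer(nr * nc)
  id_of[idx] <- seq_along(idx)
  res <- surface$resolution

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (sh in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                  c(-1L, 1L, sqrt(2)))) {
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + sh[1]; c2 <- cc + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- passable[nb]
    a <- idx[ok][ok2]; b <- nb[ok2]
    from <- c(from, id_of[a]); to <- c(to, id_of[b])
    w <- c(w, (cost[a] + cost[b]) / 2 * res * sh[3])
  }
  np <- nrow(patches$patches)
  nv <- length(idx)
  # virtual patch nodes nv+1 .. nv+np, tied to member cells with weight 0
  vfrom <- integer(0); vto <- integer(0)
  for (j in seq_len(np)) {
    mem <- id_of[patches$cells[[j]]]
    vfrom <- c(vfrom, rep.int(nv + j, length(mem)))
    vto <- c(vto, mem)
  }
  g <- igraph::make_graph(rbind(c(from, vfrom), c(to, vto)),
                          n = nv + np, directed = FALSE)
  igraph::E(g)$weight <- c(w, numeric(length(vfrom)))
  list(g = g, n_cells = nv, cell_idx = idx, np = np)
}

#' Least-cost distances between habitat patches
#'
#' Computes, for every patch pair, the minimum over all cell paths of the
#' accumulated (resistance x metric length) cost, using 8-neighbourhood moves
#' with diagonal steps weighted by sqrt(2). Distance is 0 at a patch's own
#' cells. Also assigns every passable cell to its least-cost-nearest patch
#' (the cost-weighted Voronoi tessellation used to build the planar graph).
#'
#' @param surface a `cost_surface`.
#' @param patches a `patch_set` on that surface.
#' @return list with `d` (np x np symmetric matrix, `+Inf` for unreachable
#'   pairs), `voronoi` (integer matrix of nearest patch ids, NA for
#'   impassable or unreachable cells).
#' @export
least_cost_distances <- function(surface, patches) {
  stopifnot(inherits(surface, "cost_surface"), inherits(patches, "patch_set"))
  np <- nrow(patches$patches)
  nr <- nrow(surface$cost); nc <- ncol(surface$cost)
  if (np == 0L)
    return(list(d = matrix(numeric(0), 0, 0),
                voronoi = matrix(NA_integer_, nr, nc)))
  cg <- .cell_patch_graph(surface, patches)
  virt <- cg$n_cells + seq_len(np)
  dist_all <- igraph::distances(cg$g, v = virt, algorithm = "dijkstra")
  d <- dist_all[, virt, drop = FALSE]
  dimnames(d) <- list(patches$patches$id, patches$patches$id)
  diag(d) <- 0

  # running argmin over patches for the Voronoi labels
  cur_min <- rep(Inf, cg$n_cells)
  cur_lab <- rep(NA_integer_, cg$n_cells)
  for (j in seq_len(np)) {
    dj <- dist_all[j, seq_len(cg$n_cells)]
    better <- dj < cur_min
    cur_min[better] <- dj[better]
    cur_lab[better] <- j
  }
  voronoi <- matrix(NA_integer_, nr, nc)
  voronoi[cg$cell_idx] <- cur_lab
  list(d = d, voronoi = voronoi)
}

#' Least-cost distances for an explicit edge list
#'
#' Thin wrapper around [least_cost_distances()] returning per-edge distances
#' for a given set of patch adjacency pairs. Unreachable pairs get `+Inf` and
#' are flagged.
#'
#' @param surface a `cost_surface`.
#' @param patches a `patch_set`.
#' @param edges two-column matrix or data.frame of patch id pairs.
#' @return data.frame `from`, `to`, `distance`, `reachable`.
#' @export
least_cost_edge_distances <- function(surface, patches, edges) {
  d <- least_cost_distances(surface, patches)$d
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  dist <- d[cbind(match(edges[, 1], patches$patches$id),
                  match(edges[, 2], patches$patches$id))]
  data.frame(from = edges[, 1], to = edges[, 2], distance = dist,
             reachable = is.finite(dist))
}

#' Planar patch graph
#'
#' Builds the planar, non-thresholded patch graph: nodes are habitat patches
#' (with areas), and edges join patches whose cost-weighted Voronoi regions
#' are adjacent (share a cell edge; 4-neighbourhood region adjacency keeps
#' the graph planar when several regions meet at a point). No edge is pruned
#' by distance. Effective inter-patch distances are all-pairs shortest paths
#' over the planar edges, so the maximum-probability multi-step route equals
#' the least accumulated-distance path.
#'
#' @param surface a `cost_surface`.
#' @param patches a `patch_set`.
#' @param A landscape area in m2; defaults to the full raster extent.
#' @param mode `"planar"` (default) or `"complete"`. Complete mode skips the
#'   Voronoi step and uses direct pairwise least-cost distances; it exists as
#'   a reference/diagnostic mode, not as the default analysis graph.
#' @return object of class `patch_graph`: `nodes` (patch table), `edges`
#'   (`from`, `to`, `distance`), `d` (effective distance matrix), `A`,
#'   `resolution`.
#' @export
build_patch_graph <- function(surface, patches, A = NULL,
                              mode = c("planar", "complete")) {
  mode <- match.arg(mode)
  stopifnot(inherits(patches, "patch_set"))
  np <- nrow(patches$patches)
  if (np < 1L) stop("patch graph requires at least one patch")
  if (is.null(A))
    A <- prod(dim(patches$label)) * patches$resolution^2
  if (A < sum(patches$patches$area_m2) - 1e-9)
    stop("landscape area A smaller than total patch area")
  lc <- least_cost_distances(surface, patches)
  if (mode == "complete") {
    ij <- which(upper.tri(lc$d), arr.ind = TRUE)
    edges <- data.frame(from = ij[, 1], to = ij[, 2],
                        distance = lc$d[ij])
    edges <- edges[is.finite(edges$distance), , drop = FALSE]
    d_eff <- lc$d
  } else {
    edges <- .voronoi_edges(lc$voronoi, lc$d)
    d_eff <- effective_distances(edges, np)
  }
  structure(list(nodes = patches$patches, edges = edges, d = d_eff, A = A,
                 resolution = patches$resolution, mode = mode),
            class = "patch_graph")
}

# 4-neighbourhood adjacency of Voronoi regions -> planar edge list
.voronoi_edges <- function(voronoi, d) {
  nr <- nrow(voronoi); nc <- ncol(voronoi)
  pairs <- NULL
  for (sh in list(c(1L, 0L), c(0L, 1L))) {
    a <- voronoi[seq_len(nr - sh[1]), seq_len(nc - sh[2]), drop = FALSE]
    b <- voronoi[(1L + sh[1]):nr, (1L + sh[2]):nc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a != b
    if (any(ok))
      pairs <- rbind(pairs, cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok])))
  }
  if (is.null(pairs))
    return(data.frame(from = integer(0), to = integer(0),
                      distance = numeric(0)))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  data.frame(from = pairs[, 1], to = pairs[, 2],
             distance = d[pairs])
}

#' All-pairs effective distances over a patch edge list
#'
#' Shortest-path distances over the (planar) edge set; `d[i,i] = 0`,
#' symmetric, `+Inf` between disconnected components.
#'
#' @param edges data.frame `from`, `to`, `distance`.
#' @param n number of patches.
#' @return n x n numeric matrix.
#' @export
effective_distances <- function(edges, n) {
  fin <- is.finite(edges$distance)
  g <- igraph::make_graph(rbind(edges$from[fin], edges$to[fin]), n = n,
                          directed = FALSE)
  igraph::E(g)$weight <- edges$distance[fin]
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Probability of connectivity (PC)
#'
#' `PC = sum_i sum_j a_i a_j p_ij / A^2` with `p_ij = exp(-k d_ij)`,
#' including the `i = j` terms (`p_ii = 1`); unreachable pairs (`d = Inf`)
#' contribute 0. PC is the probability that two organisms placed at random in
#' the landscape both fall into habitat that is mutually reachable.
#'
#' @param graph a `patch_graph`.
#' @param model a `dispersal_model`.
#' @return PC in [0, 1].
#' @export
probability_of_connectivity <- function(graph, model) {
  stopifnot(inherits(graph, "patch_graph"), inherits(model, "dispersal_model"))
  if (graph$A <= 0) stop("landscape area A must be positive")
  .pc_from(graph$nodes$area_m2, graph$d, graph$A, model$k)
}

.pc_from <- function(a, d, A, k) {
  p <- exp(-k * d)
  p[!is.finite(d)] <- 0
  diag(p) <- 1
  as.numeric(t(a) %*% p %*% a) / A^2
}

#' Per-patch importance dPC
#'
#' `dPC_i = 100 (PC - PC') / PC` where PC' is recomputed after removing patch
#' i (its node, incident planar edges, and area) while keeping the landscape
#' area A fixed. Effective distances among the remaining patches are
#' recomputed over the remaining planar edges, so routes that passed through
#' the removed patch are rerouted or lost.
#'
#' @param graph a `patch_graph`.
#' @param model a `dispersal_model`.
#' @param patch_id patches to evaluate (default: all).
#' @return data.frame `id`, `dPC`, sorted by patch id; see
#'   [connectivity_ranking()] for the ranked view.
#' @export
delta_pc <- function(graph, model, patch_id = NULL) {
  stopifnot(inherits(graph, "patch_graph"))
  ids <- graph$nodes$id
  if (is.null(patch_id)) patch_id <- ids
  if (!all(patch_id %in% ids)) stop("unknown patch id")
  pc <- probability_of_connectivity(graph, model)
  if (pc <= 0) stop("PC is zero; dPC undefined")
  a <- graph$nodes$area_m2
  n <- length(ids)
  dpc <- vapply(patch_id, function(pid) {
    i <- match(pid, ids)
    keep <- setdiff(seq_len(n), i)
    if (length(keep) == 0L) return(100)
    e <- graph$edges
    e <- e[e$from != i & e$to != i, , drop = FALSE]
    # reindex to 1..n-1
    e$from <- match(e$from, keep)
    e$to <- match(e$to, keep)
    d2 <- effective_distances(e, length(keep))
    pc2 <- .pc_from(a[keep], d2, graph$A, model$k)
    100 * (pc - pc2) / pc
  }, numeric(1))
  data.frame(id = patch_id, dPC = dpc)
}

#' Connectivity report: PC, dPC and patch ranking
#'
#' @inheritParams delta_pc
#' @return list with `PC`, `dPC` (per patch), and `ranking` (patches sorted
#'   by decreasing dPC).
#' @export
connectivity_ranking <- function(graph, model) {
  dpc <- delta_pc(graph, model)
  list(PC = probability_of_connectivity(graph, model),
       dPC = dpc,
       ranking = dpc[order(-dpc$dPC, dpc$id), , drop = FALSE])
}

#' Assign per-site connectivity values
#'
#' Each site takes the dPC of the habitat patch containing its location. A
#' site falling outside every patch is snapped to the nearest patch within
#' `snap_cells` cells (Euclidean distance between cell centres); beyond that
#' it is flagged missing.
#'
#' @param sites data.frame with `site`, `x`, `y` (planar coordinates).
#' @param patches a `patch_set`.
#' @param dpc data.frame `id`, `dPC` as returned by [delta_pc()].
#' @param snap_cells snap tolerance in cells (default 2).
#' @return data.frame `site`, `patch_id`, `dPC` (NA when unassigned).
#' @export
site_connectivity <- function(sites, patches, dpc, snap_cells = 2) {
  stopifnot(inherits(patches, "patch_set"))
  nr <- patches$dim[1]; nc <- patches$dim[2]
  res <- patches$resolution
  col <- floor((sites$x - patches$origin[1]) / res) + 1L
  row <- nr - floor((sites$y - patches$origin[2]) / res)
  pid <- rep(NA_integer_, nrow(sites))
  inside <- row >= 1L & row <= nr & col >= 1L & col <= nc
  pid[inside] <- patches$label[cbind(row[inside], col[inside])]
  for (i in which(is.na(pid))) {
    best <- Inf; bestj <- NA_integer_
    for (j in seq_len(nrow(patches$patches))) {
      ci <- patches$cells[[j]]
      r <- ((ci - 1L) %% nr) + 1L
      cc <- ((ci - 1L) %/% nr) + 1L
      cx <- patches$origin[1] + (cc - 0.5) * res
      cy <- patches$origin[2] + (nr - r + 0.5) * res
      dj <- sqrt(min((cx - sites$x[i])^2 + (cy - sites$y[i])^2))
      if (dj < best) { best <- dj; bestj <- j }
    }
    if (is.finite(best) && best <= snap_cells * res) pid[i] <- bestj
  }
  data.frame(site = sites$site, patch_id = pid,
             dPC = dpc$dPC[match(pid, dpc$id)])
}
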