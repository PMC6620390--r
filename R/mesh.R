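#' Triangulated synaptic apposition surface (SAS) mesh
#'
#' A SAS mesh is an open triangulated surface representing the apposition
#' between the pre- and postsynaptic membranes of one reconstructed synaptic
#' junction. Vertices are in nanometres; triangles index vertices (1-based).
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in nm.
#' @param triangles Integer matrix, m x 3, vertex indices.
#' @param synapse_id Identifier of the junction this surface belongs to.
#' @return An object of class `sas_mesh`.
#' @export
sas_mesh <- function(vertices, triangles, synapse_id = NA_integer_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3) abort("`vertices` must have 3 columns")
  if (ncol(triangles) != 3) abort("`triangles` must have 3 columns")
  if (nrow(triangles) < 1) abort("mesh has no triangles")
  if (any(!is.finite(vertices))) abort("vertex coordinates must be finite")
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    abort("triangle indices out of range")
  }
  structure(
    list(vertices = vertices, triangles = triangles, synapse_id = synapse_id),
    class = "sas_mesh"
  )
}

#' @export
print.sas_mesh <- function(x, ...) {
  cat(sprintf(
    "<sas_mesh> %d vertices, %d triangles, area %.4g nm^2 (synapse %s)\n",
    nrow(x$vertices), nrow(x$triangles), mesh_area(x), format(x$synapse_id)
  ))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cross3(a, b)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh
#'
#' @param mesh A [sas_mesh()].
#' @return Area in nm^2 (scalar).
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

# Undirected edge table: columns a, b (a < b), count = number of incident
# triangles. Boundary edges have count 1; manifold interior edges count 2.
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e1 <- c(tr[, 1], tr[, 2], tr[, 3])
  e2 <- c(tr[, 2], tr[, 3], tr[, 1])
  a <- pmin(e1, e2)
  b <- pmax(e1, e2)
  key <- (as.double(a) - 1) * nrow(mesh$vertices) + as.double(b)
  ukey <- unique(key)
  idx <- match(key, ukey)
  cnt <- tabulate(idx, length(ukey))
  ua <- floor((ukey - 1) / nrow(mesh$vertices)) + 1
  ub <- ukey - (ua - 1) * nrow(mesh$vertices)
  list(a = as.integer(ua), b = as.integer(ub), count = cnt,
       key = key, idx = idx)
}

is_edge_manifold <- function(mesh) {
  all(mesh_edges(mesh)$count <= 2L)
}

#' Euler characteristic of a mesh
#'
#' Computes V - E + F over referenced vertices, unique undirected edges and
#' triangular faces. For a genus-0 patch with b boundary loops this equals
#' 2 - b (1 for a disk, 0 for an annulus).
#'
#' @param mesh A [sas_mesh()].
#' @param edges Optional precomputed internal edge table (recomputed when
#'   missing).
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh, edges = NULL) {
  ed <- edges %||% mesh_edges(mesh)
  v <- length(unique(as.vector(mesh$triangles)))
  v - length(ed$a) + nrow(mesh$triangles)
}

#' Ordered boundary loops of a mesh
#'
#' Boundary edges (edges with a single incident triangle) are chained into
#' closed vertex cycles. Errors if the boundary is non-manifold (a boundary
#' vertex with more than two boundary edges).
#'
#' @param mesh A [sas_mesh()].
#' @param edges Optional precomputed internal edge table.
#' @return List of integer vectors, each an ordered cycle of vertex indices.
#' @export
boundary_loops <- function(mesh, edges = NULL) {
  ed <- edges %||% mesh_edges(mesh)
  if (any(ed$count > 2L)) {
    bad <- which(ed$count > 2L)
    abort(sprintf(
      "mesh is not edge-manifold: %d edge(s) with >2 incident triangles (first: %d-%d)",
      length(bad), ed$a[bad[1]], ed$b[bad[1]]
    ))
  }
  sel <- ed$count == 1L
  if (!any(sel)) return(list())
  a <- ed$a[sel]
  b <- ed$b[sel]
  verts <- unique(c(a, b))
  k <- length(verts)
  ia <- match(a, verts)
  ib <- match(b, verts)
  deg <- tabulate(c(ia, ib), k)
  if (any(deg != 2L)) {
    abort("non-manifold boundary: boundary vertex without exactly two boundary edges")
  }
  nbr <- matrix(0L, k, 2)
  slot <- integer(k)
  for (i in seq_along(ia)) {
    slot[ia[i]] <- slot[ia[i]] + 1L
    nbr[ia[i], slot[ia[i]]] <- ib[i]
    slot[ib[i]] <- slot[ib[i]] + 1L
    nbr[ib[i], slot[ib[i]]] <- ia[i]
  }
  visited <- logical(k)
  loops <- list()
  for (v0 in seq_len(k)) {
    if (visited[v0]) next
    loop <- integer(0)
    prev <- 0L
    cur <- v0
    repeat {
      loop <- c(loop, cur)
      visited[cur] <- TRUE
      n1 <- nbr[cur, 1]
      nxt <- if (n1 != prev) n1 else nbr[cur, 2]
      prev <- cur
      cur <- nxt
      if (cur == v0) break
    }
    loops[[length(loops) + 1]] <- verts[loop]
  }
  loops
}

boundary_loop_lengths <- function(mesh, loops = NULL) {
  loops <- loops %||% boundary_loops(mesh)
  vapply(loops, function(lp) {
    p <- mesh$vertices[lp, , drop = FALSE]
    q <- mesh$vertices[c(lp[-1], lp[1]), , drop = FALSE]
    sum(sqrt(rowSums((q - p)^2)))
  }, numeric(1))
}

#' Total boundary perimeter of a mesh
#'
#' Sum of the lengths of all boundary loops; interior holes therefore add
#' perimeter.
#'
#' @param mesh A [sas_mesh()].
#' @return Perimeter in nm.
#' @export
mesh_perimeter <- function(mesh) sum(boundary_loop_lengths(mesh))

# Membership of triangles in edge-connected components (union-find over
# triangles sharing an edge).
triangle_components <- function(mesh, edges = NULL) {
  tr <- mesh$triangles
  m <- nrow(tr)
  ed <- edges %||% mesh_edges(mesh)
  tri_id <- rep(seq_len(m), 3L)
  o <- order(ed$idx)
  idx_o <- ed$idx[o]
  tri_o <- tri_id[o]
  first <- !duplicated(idx_o)
  root_for <- tri_o[first][cumsum(first)]
  link_a <- root_for[!first]
  link_b <- tri_o[!first]
  if (!length(link_a)) return(seq_len(m))
  g <- igraph::make_graph(rbind(link_a, link_b), n = m, directed = FALSE)
  memb <- igraph::components(g)$membership
  match(memb, unique(memb))
}

# Split a mesh into its edge-connected component meshes.
split_components <- function(mesh) {
  memb <- triangle_components(mesh)
  lapply(sort(unique(memb)), function(cmp) {
    tr <- mesh$triangles[memb == cmp, , drop = FALSE]
    used <- sort(unique(as.vector(tr)))
    remap <- match(tr, used)
    sas_mesh(
      mesh$vertices[used, , drop = FALSE],
      matrix(remap, ncol = 3),
      synapse_id = mesh$synapse_id
    )
  })
}

# Area-weighted least-squares plane through the mesh vertices.
# Returns centroid, unit normal and in-plane basis (e1, e2).
fit_plane <- function(mesh) {
  v <- mesh$vertices
  ta <- triangle_areas(mesh)
  w <- rep(0, nrow(v))
  for (k in 1:3) {
    acc <- rowsum(ta / 3, mesh$triangles[, k])
    idx <- as.integer(rownames(acc))
    w[idx] <- w[idx] + acc[, 1]
  }
  if (sum(w) <= 0) w <- rep(1, nrow(v))
  w <- w / sum(w)
  ctr <- colSums(v * w)
  d <- sweep(v, 2, ctr)
  cov <- crossprod(d * sqrt(w))
  eg <- eigen(cov, symmetric = TRUE)
  normal <- eg$vectors[, 3]
  list(
    centroid = ctr, normal = normal,
    e1 = eg$vectors[, 1], e2 = eg$vectors[, 2],
    weights = w
  )
}

#' Apply a rigid motion to a mesh
#'
#' @param mesh A [sas_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation in nm.
#' @return The transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  sas_mesh(v, mesh$triangles, synapse_id = mesh$synapse_id)
}
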