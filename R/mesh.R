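# Voxelized finite-volume mesh: cells coincide with image voxels, tissue
# properties are assigned per cell, fluxes live on the faces between
# 6-neighbors, and boundary faces carry the Dirichlet pressure / outflow
# conditions.

#' Build a voxelized mesh from a brain mask
#'
#' Cells are the `TRUE` voxels of `mask`; connectivity is 6-neighbor (face)
#' adjacency. If the mask is not 6-connected the largest connected
#' component is kept with a warning.
#'
#' @param mask logical (or 0/1) 3-D array.
#' @param voxel_size isotropic voxel edge h, mm.
#' @return object of class `ced_mesh`: list with `shape`, `h`, `mask`
#'   (logical array), `cell_id` (integer array, 0 outside), `coords`
#'   (n x 3), `neighbors` (n x 6 cell ids in order -x,+x,-y,+y,-z,+z; 0
#'   where the face is a boundary face), `int_faces` (matrix with columns
#'   `i`, `j`, `axis`: the face between cell i and its +axis neighbor j),
#'   `bnd_faces` (matrix with columns `cell`, `axis`, `side` = -1/+1),
#'   `n_cells`, `face_area` (h^2), `cell_volume` (h^3).
#' @export
build_mesh <- function(mask, voxel_size = 1.2) {
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(length(dim(mask)) == 3, voxel_size > 0)
  if (!any(mask)) stop("empty mask: no cells to mesh")
  comp <- grid_components(mask)
  if (max(comp, na.rm = TRUE) > 1) {
    sizes <- tabulate(comp[mask])
    keep <- which.max(sizes)
    warning("mask is not 6-connected; keeping largest component (",
            sizes[keep], " of ", sum(mask), " voxels)")
    mask <- array(comp == keep & mask, dim(mask))
  }
  shape <- dim(mask)
  cell_id <- array(0L, shape)
  cells <- which(mask)
  cell_id[cells] <- seq_along(cells)
  n <- length(cells)
  co <- arrayInd(cells, shape)

  neighbors <- matrix(0L, n, 6)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (f in 1:6) {
    nb <- co + matrix(offs[f, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
    id <- integer(n)
    id[ok] <- cell_id[nb[ok, , drop = FALSE]]
    neighbors[, f] <- id
  }

  int_list <- vector("list", 3)
  for (a in 1:3) {
    j <- neighbors[, 2 * a]          # +axis neighbor
    has <- which(j > 0L)
    int_list[[a]] <- cbind(i = has, j = j[has], axis = rep(a, length(has)))
  }
  int_faces <- do.call(rbind, int_list)
  colnames(int_faces) <- c("i", "j", "axis")

  bnd_list <- vector("list", 6)
  for (f in 1:6) {
    cellw <- which(neighbors[, f] == 0L)
    bnd_list[[f]] <- cbind(cell = cellw,
                           axis = rep(ceiling(f / 2), length(cellw)),
                           side = rep(if (f %% 2 == 1) -1L else 1L,
                                      length(cellw)))
  }
  bnd_faces <- do.call(rbind, bnd_list)
  colnames(bnd_faces) <- c("cell", "axis", "side")

  structure(list(shape = shape, h = voxel_size, mask = mask,
                 cell_id = cell_id, coords = co, neighbors = neighbors,
                 int_faces = int_faces, bnd_faces = bnd_faces,
                 n_cells = n, face_area = voxel_size^2,
                 cell_volume = voxel_size^3),
            class = "ced_mesh")
}

# label 6-connected components of a logical 3D array (0 outside mask)
grid_components <- function(mask) {
  shape <- dim(mask)
  comp <- array(0L, shape)
  nmax <- prod(shape)
  strides <- c(1L, shape[1], shape[1] * shape[2])
  cur <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    comp[start] <- cur
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      ci <- arrayInd(v, shape)
      for (a in 1:3) for (s in c(-1L, 1L)) {
        x <- ci[a] + s
        if (x < 1L || x > shape[a]) next
        nb <- v + s * strides[a]
        if (mask[nb] && comp[nb] == 0L) {
          comp[nb] <- cur
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  comp
}

#' Refine a voxelized mesh by an integer factor
#'
#' Every cell is split into `factor^3` children; per-cell fields are mapped
#' to the children by nearest-parent (piecewise-constant) assignment,
#' mirroring the voxel-wise property assignment of the coarse mesh. This is
#' the refinement path used for the grid-convergence check.
#'
#' @param mesh a `ced_mesh`.
#' @param fields optional named list of per-cell vectors or n x k matrices
#'   to carry to the refined mesh.
#' @param factor integer >= 2.
#' @return list with `mesh` (refined `ced_mesh`, voxel size h/factor),
#'   `fields` (mapped), and `parent` (coarse cell id of each refined cell).
#' @export
refine_mesh <- function(mesh, fields = list(), factor = 2L) {
  stopifnot(inherits(mesh, "ced_mesh"), factor >= 2, factor == round(factor))
  factor <- as.integer(factor)
  shape2 <- mesh$shape * factor
  # refined mask: repeat each voxel factor times along every axis
  m2 <- mesh$mask[rep(seq_len(mesh$shape[1]), each = factor),
                  rep(seq_len(mesh$shape[2]), each = factor),
                  rep(seq_len(mesh$shape[3]), each = factor)]
  m2 <- array(m2, shape2)
  mesh2 <- build_mesh(m2, mesh$h / factor)
  pco <- (mesh2$coords - 1L) %/% factor + 1L
  parent <- mesh$cell_id[pco]
  mapped <- lapply(fields, function(f) {
    if (is.matrix(f)) f[parent, , drop = FALSE] else f[parent]
  })
  list(mesh = mesh2, fields = mapped, parent = parent)
}

#' Children of a coarse cell in a refined mesh
#'
#' @param parent per-refined-cell coarse ids as returned by [refine_mesh()].
#' @param cell coarse cell id.
#' @return integer vector of refined cell ids.
#' @export
refined_children <- function(parent, cell) which(parent == cell)
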