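## Desk-scale cohort geometry.
##
## The analysis itself is agnostic to anatomy: it operates on arbitrary voxel
## sets defined by masks and an integer-labelled seed atlas.  The synthetic
## cohort therefore uses a compact block layout instead of MNI-space anatomy:
##
##   z-slabs (1-based, bottom to top):
##     1..2          "subcortical" slab holding the 14 seed blocks (2x2x2)
##     3..5          white-matter slab
##     6..8          CSF slab
##     9..nz         "cortical" slab holding 14 target blocks (3x3x3) plus
##                   unstructured gray matter
##
## Seeds 1-7 are the "cerebellar" seven-network seeds (cereb1..cereb7), seeds
## 8-14 the "striatal" ones (stria1..stria7), each with the heuristic network
## name used for the seven-network parcellations.  Target block m is the
## cortical territory of circuit m.

NETWORK_NAMES <- c("visual", "somatomotor", "dorsal attention",
                   "ventral attention", "limbic", "frontoparietal",
                   "default-mode")

seed_names <- function() {
  c(paste0("cereb", 1:7), paste0("stria", 1:7))
}

seed_network <- function() {
  setNames(rep(NETWORK_NAMES, 2), seed_names())
}

## place n cubic blocks of edge `edge` (with >= 1 voxel gap) inside the box
## [1,nx] x [1,ny] x [zlo,zhi]; returns list of index-triple start corners
place_blocks <- function(n, edge, nx, ny, zlo, zhi, gap = 1) {
  step <- edge + gap
  xs <- seq(1L, nx - edge + 1L, by = step)
  ys <- seq(1L, ny - edge + 1L, by = step)
  zs <- seq(zlo, zhi - edge + 1L, by = step)
  slots <- expand.grid(x = xs, y = ys, z = zs)
  if (nrow(slots) < n) return(NULL)
  lapply(seq_len(n), function(i) as.integer(slots[i, ]))
}

block_voxels <- function(corner, edge, dim3) {
  ix <- corner[1]:(corner[1] + edge - 1L)
  iy <- corner[2]:(corner[2] + edge - 1L)
  iz <- corner[3]:(corner[3] + edge - 1L)
  g <- expand.grid(x = ix, y = iy, z = iz)
  ## linear indices, x fastest (R column-major order)
  as.integer(g$x + (g$y - 1L) * dim3[1] + (g$z - 1L) * dim3[1] * dim3[2])
}

#' Lay out seeds, targets and tissue masks on a voxel grid
#'
#' Internal constructor for the synthetic-cohort geometry: places 14 seed
#' blocks in a subcortical slab, 14 cortical target blocks, and white-matter
#' and CSF slabs, and derives the brain/gray/white/csf masks and the
#' integer-labelled seed atlas.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @return a list with masks, atlas labels, per-circuit target voxel indices
#'   and the voxel-to-world affine (3 mm isotropic).
#' @noRd
cohort_geometry <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  cc_assert(length(grid_shape) == 3 && all(grid_shape >= 8), "sizing",
            "grid_shape must be three voxel counts, each >= 8")
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ## tissue slabs are 3 voxels thick so a 1-voxel erosion leaves an interior
  seed_slab <- c(1L, 2L); wm_slab <- c(3L, 5L); csf_slab <- c(6L, 8L)
  cortex_lo <- 9L
  cc_assert(nz >= cortex_lo + 2L, "sizing",
            "grid too small: need at least 3 cortical z-slices (nz >= 11)")

  seed_corners <- place_blocks(14, 2L, nx, ny, seed_slab[1], seed_slab[2])
  cc_assert(!is.null(seed_corners), "sizing",
            "grid too small to place 14 disjoint 2x2x2 seed regions")
  target_corners <- place_blocks(14, 3L, nx, ny, cortex_lo, nz)
  cc_assert(!is.null(target_corners), "sizing",
            "grid too small to place 14 disjoint 3x3x3 cortical targets")

  labels <- array(0L, grid_shape)
  for (m in 1:14) labels[block_voxels(seed_corners[[m]], 2L, grid_shape)] <- m

  zidx <- function(z1, z2) {
    a <- array(FALSE, grid_shape); a[, , z1:z2] <- TRUE; a
  }
  brain <- array(TRUE, grid_shape)
  white <- zidx(wm_slab[1], wm_slab[2])
  csf <- zidx(csf_slab[1], csf_slab[2])
  gray <- brain & !white & !csf

  targets <- lapply(target_corners, block_voxels, edge = 3L,
                    dim3 = grid_shape)
  names(targets) <- seed_names()

  affine <- diag(c(3, 3, 3, 1))
  affine[1:3, 4] <- -1.5 * grid_shape  # roughly centre the grid in mm space

  list(grid_shape = grid_shape,
       masks = list(brain = brain, gray = gray, white = white, csf = csf),
       atlas = seed_atlas(labels, seed_network()),
       targets = targets,
       affine = affine)
}

#' Seed atlas constructor
#'
#' An integer-labelled 3D volume (0 = background, 1..14 = seed regions) plus
#' heuristic circuit names per label.
#'
#' @param labels integer 3D array of seed labels.
#' @param names character vector naming each label (label order).
#' @return an object of class `seed_atlas`.
#' @export
seed_atlas <- function(labels, names) {
  labs <- sort(unique(as.integer(labels[labels > 0])))
  cc_assert(identical(labs, seq_along(names)), "validation",
            "atlas must contain exactly the labels 1..length(names), all nonempty")
  structure(list(labels = labels, names = names), class = "seed_atlas")
}

#' @export
print.seed_atlas <- function(x, ...) {
  cat("<seed_atlas> ", length(x$names), " labels on grid ",
      paste(dim(x$labels), collapse = "x"), "\n", sep = "")
  invisible(x)
}

atlas_label_voxels <- function(atlas, label) {
  idx <- which(atlas$labels == label)
  cc_assert(length(idx) > 0, "atlas",
            paste0("seed label ", label, " is empty in the atlas"))
  idx
}
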