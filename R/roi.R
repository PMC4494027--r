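#' Neighbor offsets for a 3D connectivity scheme
#'
#' @param connectivity 6, 18 or 26.
#' @return integer matrix, one offset per row.
#' @export
connectivity_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Grow a fixed-size contiguous ROI on a z-map
#'
#' Greedy region growth within a binary mask: seed at the mask voxel with
#' the maximum z value, then repeatedly add the frontier voxel (mask voxels
#' adjacent to the current cluster under the chosen connectivity) with the
#' highest z, until exactly `size` voxels are selected. Ties in z are broken
#' by the lowest linear voxel index (x fastest), making the result
#' deterministic. The greedy trace is a prefix chain: the size-k ROI is the
#' first k voxels of the size-(k+1) ROI.
#'
#' @param zmap a [zmap()] or a 3D numeric array.
#' @param mask logical/0-1 3D array on the same grid.
#' @param size requested ROI size in voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param name ROI name.
#' @return object of class `roi`: list with `name`, `voxels` (size x 3
#'   integer matrix of 1-based grid indices, in growth order), `size`,
#'   `connectivity`, `mean_z`, `center_of_mass_mm`.
#' @export
grow_roi <- function(zmap, mask, size, connectivity = 26, name = "roi") {
  z <- if (inherits(zmap, "zmap")) zmap$data else zmap
  vox_mm <- if (inherits(zmap, "zmap")) zmap$voxel_size_mm else c(1, 1, 1)
  origin <- if (inherits(zmap, "zmap")) zmap$origin_mm else c(0, 0, 0)
  d <- dim(z)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), d)) stop("mask grid does not match z-map grid")
  size <- as.integer(size)
  if (size < 1) stop("size must be >= 1")
  nmask <- sum(mask)
  if (nmask < size)
    stop(sprintf("mask has %d voxels, %d requested (deficit %d)",
                 nmask, size, size - nmask))
  offs <- connectivity_offsets(connectivity)

  zv <- as.vector(z)
  lin_of <- function(ix) ix[, 1] + (ix[, 2] - 1L) * d[1] +
    (ix[, 3] - 1L) * d[1] * d[2]
  in_grid <- function(ix) ix[, 1] >= 1L & ix[, 1] <= d[1] &
    ix[, 2] >= 1L & ix[, 2] <= d[2] & ix[, 3] >= 1L & ix[, 3] <= d[3]

  mask_lin <- which(mask)
  # seed: max z in mask, ties -> lowest linear index
  seed <- mask_lin[order(-zv[mask_lin], mask_lin)][1]
  selected <- integer(size)
  selected[1] <- seed
  in_roi <- logical(prod(d)); in_roi[seed] <- TRUE
  # frontier as a logical over linear indices
  frontier <- logical(prod(d))
  add_neighbors <- function(lin) {
    ix <- arrayInd(lin, d)
    nb <- cbind(ix[1] + offs[, 1], ix[2] + offs[, 2], ix[3] + offs[, 3])
    nb <- nb[in_grid(nb), , drop = FALSE]
    nbl <- lin_of(nb)
    nbl <- nbl[mask[nbl] & !in_roi[nbl]]
    frontier[nbl] <<- TRUE
  }
  add_neighbors(seed)
  k <- 1L
  while (k < size) {
    cand <- which(frontier)
    if (length(cand) == 0L)
      stop(sprintf("mask's connected component around the seed has only %d voxels (%d requested)",
                   k, size))
    pick <- cand[order(-zv[cand], cand)][1]
    k <- k + 1L
    selected[k] <- pick
    in_roi[pick] <- TRUE
    frontier[pick] <- FALSE
    add_neighbors(pick)
  }
  vox <- arrayInd(selected, d)
  com <- origin + (colMeans(vox) - 1) * vox_mm
  r <- list(name = name, voxels = vox, size = size,
            connectivity = connectivity,
            mean_z = mean(zv[selected]),
            center_of_mass_mm = com,
            voxel_size_mm = vox_mm, grid_dim = d)
  class(r) <- "roi"
  r
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi '%s': %d voxels (%g mm^3), %d-connectivity, mean z %.3f\n",
              x$name, x$size, x$size * prod(x$voxel_size_mm),
              x$connectivity, x$mean_z))
  invisible(x)
}

#' Linear voxel indices of an ROI
#' @param roi an `roi` object.
#' @export
roi_linear_index <- function(roi) {
  d <- roi$grid_dim
  roi$voxels[, 1] + (roi$voxels[, 2] - 1L) * d[1] +
    (roi$voxels[, 3] - 1L) * d[1] * d[2]
}

#' ROI as a binary mask array
#' @param roi an `roi` object.
#' @export
roi_mask <- function(roi) {
  m <- array(FALSE, dim = roi$grid_dim)
  m[roi_linear_index(roi)] <- TRUE
  m
}

#' Summarize a list of ROIs
#'
#' @param rois list of `roi` objects.
#' @param zmap optional [zmap()] used to (re)compute the mean z.
#' @return data.frame with name, size, volume in mm^3, mean z, and the
#'   center-of-mass world coordinates.
#' @export
summarize_rois <- function(rois, zmap = NULL) {
  if (length(rois) == 0L) stop("no ROIs to summarize")
  rows <- lapply(rois, function(r) {
    mz <- r$mean_z
    if (!is.null(zmap)) {
      if (any(r$voxels > matrix(dim(zmap$data), nrow(r$voxels), 3,
                                byrow = TRUE)))
        stop(sprintf("roi '%s' lies outside the z-map grid", r$name))
      mz <- mean(zmap$data[r$voxels])
    }
    data.frame(name = r$name, size = r$size,
               volume_mm3 = r$size * prod(r$voxel_size_mm),
               mean_z = mz,
               com_x_mm = r$center_of_mass_mm[1],
               com_y_mm = r$center_of_mass_mm[2],
               com_z_mm = r$center_of_mass_mm[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic language-network mask set
#'
#' Builds a named set of disjoint rectangular parcels on a given grid as a
#' synthetic stand-in for published probabilistic group-level language
#' parcels (which are not bundled). Eleven regions by default, mirroring
#' the temporal/frontal naming convention of functional language
#' localizers. Purely synthetic geometry.
#'
#' @param grid_dim length-3 grid dimensions; must accommodate the parcels
#'   (default `c(27, 29, 12)`).
#' @param names region names.
#' @param parcel_vox approximate voxels per parcel (default ~200, matching
#'   the constraint that parcels exceed the largest 150-voxel ROI).
#' @param margin in-plane background margin in voxels between parcels and
#'   the volume edge. Default 5 keeps every parcel voxel outside the
#'   truncation zone of a 6 mm FWHM kernel at 2 mm voxels, mimicking the
#'   background margin around a normalized brain; smaller margins put
#'   parcels into the edge region where smoothing leaves inflated noise
#'   variance.
#' @return named list of logical 3D arrays.
#' @export
language_mask_set <- function(grid_dim = c(27, 29, 12),
                              names = language_region_names(),
                              parcel_vox = 200, margin = 5) {
  n <- length(names)
  # parcel footprint: a x b columns x full-depth slabs, ~parcel_vox voxels
  depth <- grid_dim[3]
  ab <- ceiling(sqrt(parcel_vox / depth))
  a <- ab; b <- ceiling(parcel_vox / (depth * a))
  per_row <- (grid_dim[1] - 2 * margin + 1) %/% (a + 1)
  if (per_row < 1) stop("grid_dim too small for the requested parcels")
  rows_needed <- ceiling(n / per_row)
  if (rows_needed * (b + 1) - 1 > grid_dim[2] - 2 * margin)
    stop("grid_dim too small for the requested parcels")
  out <- vector("list", n); names(out) <- names
  for (i in seq_len(n)) {
    rr <- (i - 1) %/% per_row; cc <- (i - 1) %% per_row
    x0 <- margin + 1 + cc * (a + 1); y0 <- margin + 1 + rr * (b + 1)
    m <- array(FALSE, dim = grid_dim)
    m[x0:(x0 + a - 1), y0:(y0 + b - 1), ] <- TRUE
    out[[i]] <- m
  }
  out
}

#' Canonical region names of the language network mask set
#' @return character vector of 11 region names (7 temporo-parietal,
#'   4 frontal).
#' @export
language_region_names <- function() {
  c("L_angular_gyrus", "L_supramarginal_gyrus", "L_post_STS",
    "L_mid_ant_temporal", "L_ant_temporal",
    "R_post_STS", "R_mid_ant_temporal",
    "L_orb_inf_frontal_gyrus", "L_inf_frontal_gyrus",
    "L_mid_frontal_gyrus", "L_sup_frontal_gyrus")
}

#' Statistical family of each language region
#'
#' Maps region names to the Bonferroni family used at the group level:
#' "temporal" (7 regions) or "frontal" (4 regions).
#'
#' @param names region names.
#' @return named character vector of family labels.
#' @export
language_region_families <- function(names = language_region_names()) {
  fam <- ifelse(grepl("frontal", names), "frontal", "temporal")
  names(fam) <- names
  fam
}
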