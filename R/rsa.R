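#' Pixel-to-millimetre scale at a scan resolution
#'
#' @param dpi dots per inch (> 0).
#' @return mm per pixel, `25.4 / dpi`.
#' @export
px_to_mm <- function(dpi) {
  if (any(dpi <= 0)) stop("dpi must be > 0")
  25.4 / dpi
}

.mask_matrix <- function(mask) {
  m <- if (inherits(mask, "RootMask")) mask$mask else mask
  stopifnot(is.matrix(m))
  storage.mode(m) <- "integer"
  m
}

.mask_dpi <- function(mask, dpi) {
  if (!is.null(dpi)) return(dpi)
  if (inherits(mask, "RootMask")) return(mask$dpi)
  stop("dpi must be supplied for a bare matrix")
}

#' Total root length from a binary mask
#'
#' Morphological (Zhang-Suen) skeleton of the foreground; length is the sum
#' over 8-adjacent skeleton-pixel pairs of the step length (1 px for
#' orthogonal, sqrt(2) px for diagonal steps, corner-corrected), scaled to
#' mm. A single-pixel foreground has zero length.
#'
#' @param mask a `RootMask` or 0/1 matrix.
#' @param dpi scan resolution (taken from the `RootMask` if absent).
#' @return length in mm.
#' @export
root_length <- function(mask, dpi = NULL) {
  m <- .mask_matrix(mask)
  if (sum(m) == 0) stop("empty mask")
  skel <- thin_cpp(m)
  skeleton_length_px(skel) * px_to_mm(.mask_dpi(mask, dpi))
}

#' Projected root area, mean diameter, volume and surface area
#'
#' Area is the foreground pixel count in mm^2. Diameter, volume and surface
#' area use the projected-area cylinder model: `d = area / length`,
#' `V = pi (d/2)^2 L`, `S = pi d L` — the identity `V/S = d/4` holds by
#' construction.
#'
#' @param mask a `RootMask` or 0/1 matrix.
#' @param dpi scan resolution.
#' @param length_mm optionally reuse a precomputed [root_length()].
#' @return named list: `area_mm2`, `length_mm`, `diameter_mm`, `volume_mm3`,
#'   `surface_area_mm2`.
#' @export
root_size_traits <- function(mask, dpi = NULL, length_mm = NULL) {
  m <- .mask_matrix(mask)
  if (sum(m) == 0) stop("empty mask")
  scale <- px_to_mm(.mask_dpi(mask, dpi))
  area <- sum(m) * scale^2
  if (is.null(length_mm)) length_mm <- root_length(mask, dpi)
  if (length_mm <= 0)
    stop("zero skeleton length with non-zero area: derived traits undefined")
  d <- area / length_mm
  list(area_mm2 = area, length_mm = length_mm, diameter_mm = d,
       volume_mm3 = pi * (d / 2)^2 * length_mm,
       surface_area_mm2 = pi * d * length_mm)
}

#' @rdname root_size_traits
#' @export
root_area <- function(mask, dpi = NULL) {
  m <- .mask_matrix(mask)
  sum(m) * px_to_mm(.mask_dpi(mask, dpi))^2
}

#' Bounding extents and convex hull of the root system
#'
#' Rooting width/depth are the horizontal/vertical extents of the foreground
#' in the pixel-centre convention (a filled `w x h` rectangle has extents
#' `(w-1) x (h-1)` px). The convex hull is taken over foreground pixel
#' centres; its area is the shoelace area plus the Pick boundary correction
#' (`+ boundary_lattice_points/2 + 1`), so that a solid convex
#' region has hull area exactly equal to its pixel-count area and the
#' convexity bound `hull_area >= area` holds on every non-degenerate mask.
#' Collinear-only foreground yields hull area 0 with a warning.
#'
#' @param mask a `RootMask` or 0/1 matrix.
#' @param dpi scan resolution.
#' @return named list: `rooting_width_mm`, `rooting_depth_mm`,
#'   `hull_width_mm`, `hull_height_mm`, `hull_area_mm2`.
#' @export
extents_and_hull <- function(mask, dpi = NULL) {
  m <- .mask_matrix(mask)
  if (sum(m) == 0) stop("empty mask")
  scale <- px_to_mm(.mask_dpi(mask, dpi))
  idx <- which(m != 0, arr.ind = TRUE)
  ys <- idx[, 1]; xs <- idx[, 2]
  width <- (max(xs) - min(xs)) * scale
  depth <- (max(ys) - min(ys)) * scale
  pts <- cbind(xs, ys)
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 3) {
    warning("collinear foreground: hull area 0")
    area <- 0
  } else {
    nxt <- c(2:nrow(hp), 1)
    shoelace <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
    # lattice points on the hull boundary: gcd(|dx|, |dy|) per edge
    gcd2 <- function(a, b) ifelse(b == 0, a, Recall(b, a %% b))
    boundary <- sum(gcd2(abs(hp[nxt, 1] - hp[, 1]),
                         abs(hp[nxt, 2] - hp[, 2])))
    area <- (shoelace + boundary / 2 + 1) * scale^2
  }
  list(rooting_width_mm = width, rooting_depth_mm = depth,
       hull_width_mm = (max(hp[, 1]) - min(hp[, 1])) * scale,
       hull_height_mm = (max(hp[, 2]) - min(hp[, 2])) * scale,
       hull_area_mm2 = area)
}

#' Specific root length and specific convex hull area
#'
#' `SRL = length / volume` (mm per mm^3; under the cylinder model this equals
#' `1 / (pi (d/2)^2)`, independent of length) and
#' `specific hull area = hull area / root area` (>= 1, since the hull
#' contains the foreground).
#'
#' @param traits named list containing `length_mm`, `volume_mm3`,
#'   `hull_area_mm2`, `area_mm2`.
#' @return named list: `specific_root_length`, `specific_hull_area`.
#' @export
specific_traits <- function(traits) {
  if (traits$volume_mm3 <= 0 || traits$area_mm2 <= 0)
    stop("zero denominator in specific traits")
  list(specific_root_length = traits$length_mm / traits$volume_mm3,
       specific_hull_area = traits$hull_area_mm2 / traits$area_mm2)
}

#' All root-system-architecture traits of a mask
#'
#' Computes the full 12-trait set: length, volume, diameter, rooting width,
#' rooting depth, convex hull width/height/area, surface area, projected
#' area, specific root length and specific convex hull area — all in mm
#' units at the stated scan resolution.
#'
#' @param mask a `RootMask` or 0/1 matrix.
#' @param dpi scan resolution.
#' @return one-row data.frame of the 12 traits.
#' @export
rsa_traits <- function(mask, dpi = NULL) {
  size <- root_size_traits(mask, dpi)
  hull <- extents_and_hull(mask, dpi)
  spec <- specific_traits(c(size, hull))
  data.frame(length_mm = size$length_mm, volume_mm3 = size$volume_mm3,
             diameter_mm = size$diameter_mm,
             rooting_width_mm = hull$rooting_width_mm,
             rooting_depth_mm = hull$rooting_depth_mm,
             hull_width_mm = hull$hull_width_mm,
             hull_height_mm = hull$hull_height_mm,
             surface_area_mm2 = size$surface_area_mm2,
             area_mm2 = size$area_mm2,
             hull_area_mm2 = hull$hull_area_mm2,
             specific_root_length = spec$specific_root_length,
             specific_hull_area = spec$specific_hull_area)
}

#' Z-score scaling and complete-linkage clustering of a trait table
#'
#' Columns are centred and scaled to unit variance (zero-variance columns
#' dropped with a warning), accessions are clustered by complete-linkage
#' agglomeration on Euclidean distances, and cluster labels are cut at
#' `k_clusters` (or `cut_height`). Traits are clustered the same way for
#' heatmap ordering.
#'
#' @param trait_table numeric matrix or data.frame, accessions x traits,
#'   with rownames.
#' @param k_clusters number of accession clusters to cut (default 2).
#' @param cut_height optional dendrogram height instead of `k_clusters`.
#' @return list: `z` (scaled matrix), `tree` (hclust of accessions),
#'   `trait_tree` (hclust of traits), `clusters` (named integer vector).
#' @export
zscore_cluster <- function(trait_table, k_clusters = 2L, cut_height = NULL) {
  M <- as.matrix(trait_table)
  stopifnot(nrow(M) >= 2)
  sds <- apply(M, 2, sd)
  if (all(sds == 0)) stop("all columns constant")
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance column(s)", sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
  }
  z <- scale(M)
  tree <- hclust(dist(z), method = "complete")
  trait_tree <- if (ncol(z) >= 2)
    hclust(dist(t(z)), method = "complete") else NULL
  clusters <- if (!is.null(cut_height)) cutree(tree, h = cut_height)
  else cutree(tree, k = k_clusters)
  list(z = z, tree = tree, trait_tree = trait_tree, clusters = clusters)
}
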