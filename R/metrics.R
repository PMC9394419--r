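#' Volumetric overlap metrics
#'
#' Dice similarity coefficient `2|P∩G| / (|P| + |G|)`, Jaccard index
#' `|P∩G| / |P∪G|`, volumetric overlap error `VOE = 1 - Jaccard` and
#' signed relative volume difference `RVD = (|P| - |G|) / |G|` (negative
#' when the prediction under-segments) between a predicted and a
#' ground-truth binary mask on the same grid.
#'
#' @param P,G [binary_mask3d()] objects (or plain 0/1 arrays) on the
#'   same grid.
#' @return A scalar.
#' @export
dsc <- function(P, G) {
  m <- mask_pair(P, G)
  s <- sum(m$P) + sum(m$G)
  if (s == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(m$P & m$G) / s
}

#' @rdname dsc
#' @export
jaccard <- function(P, G) {
  m <- mask_pair(P, G)
  u <- sum(m$P | m$G)
  if (u == 0) stop("union of masks is empty", call. = FALSE)
  sum(m$P & m$G) / u
}

#' @rdname dsc
#' @export
voe <- function(P, G) 1 - jaccard(P, G)

#' @rdname dsc
#' @export
rvd <- function(P, G) {
  m <- mask_pair(P, G)
  if (sum(m$G) == 0) stop("ground-truth mask is empty", call. = FALSE)
  (sum(m$P) - sum(m$G)) / sum(m$G)
}

mask_pair <- function(P, G) {
  toarr <- function(x) {
    if (inherits(x, "image3d")) x$data else as.array(x)
  }
  a <- toarr(P); b <- toarr(G)
  if (!all(dim(a) == dim(b)))
    stop("masks must share the same grid", call. = FALSE)
  if (inherits(P, "image3d") && inherits(G, "image3d") &&
      (!all(abs(P$spacing - G$spacing) < 1e-9) ||
       !all(abs(P$origin - G$origin) < 1e-9)))
    stop("masks must share the same grid geometry", call. = FALSE)
  list(P = a == 1, G = b == 1)
}

# boundary voxels: foreground with at least one 6-connected background
# neighbor (voxels on the volume border count as boundary)
boundary_voxels <- function(arr) {
  d <- dim(arr)
  fg <- arr == 1
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- fg
  inner <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
        pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  inner & !nb
}

# exact distance (mm) from every voxel center to the nearest TRUE site
distance_to_sites <- function(sites, spacing) {
  d <- dim(sites)
  sqrt(array(cpp_edt_sq(as.logical(sites), as.integer(d), as.numeric(spacing)), d))
}

#' Surface distance metrics
#'
#' Hausdorff distance (maximum of the two directed maxima) and average
#' symmetric surface distance between the boundary voxel sets of two
#' masks, in physical mm. Surfaces are foreground voxels with at least
#' one 6-connected background neighbor; distances are measured between
#' voxel centers using the exact Euclidean distance transform.
#'
#' @inheritParams dsc
#' @return Named numeric vector `c(hd, assd)` in mm.
#' @export
surface_distances <- function(P, G) {
  m <- mask_pair(P, G)
  if (sum(m$P) == 0 || sum(m$G) == 0)
    stop("surface distances need two non-empty masks", call. = FALSE)
  spacing <- if (inherits(P, "image3d")) P$spacing else c(1, 1, 1)
  bp <- boundary_voxels(m$P)
  bg <- boundary_voxels(m$G)
  dtg <- distance_to_sites(bg, spacing)
  dtp <- distance_to_sites(bp, spacing)
  d_pg <- dtg[bp]   # from each P-surface voxel to the G surface
  d_gp <- dtp[bg]
  c(hd = max(max(d_pg), max(d_gp)),
    assd = (sum(d_pg) + sum(d_gp)) / (length(d_pg) + length(d_gp)))
}

#' Full evaluation report for a mask pair
#'
#' Computes the overlap metrics (DSC, Jaccard, VOE, RVD) and the surface
#' metrics (HD, ASSD) in one pass.
#'
#' @inheritParams dsc
#' @return An object of class `"metrics_report"`: a list with fields
#'   `dsc`, `jaccard`, `voe`, `rvd`, `hd_mm`, `assd_mm`.
#' @export
evaluate_masks <- function(P, G) {
  sd <- surface_distances(P, G)
  structure(list(dsc = dsc(P, G), jaccard = jaccard(P, G),
                 voe = voe(P, G), rvd = rvd(P, G),
                 hd_mm = unname(sd["hd"]), assd_mm = unname(sd["assd"])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation evaluation\n")
  cat(sprintf("  Dice    %7.2f %%    Jaccard %7.2f %%\n",
              100 * x$dsc, 100 * x$jaccard))
  cat(sprintf("  VOE     %7.2f %%    RVD     %+7.2f %%\n",
              100 * x$voe, 100 * x$rvd))
  cat(sprintf("  HD      %7.3f mm   ASSD    %7.3f mm\n", x$hd_mm, x$assd_mm))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(dsc = x$dsc, jaccard = x$jaccard, voe = x$voe, rvd = x$rvd,
             hd_mm = x$hd_mm, assd_mm = x$assd_mm)
}
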