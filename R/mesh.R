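#' Dual reconstruction mesh from ultrasound guidance
#'
#' Fine voxels tile an axis-aligned box enclosing the ultrasound-defined
#' lesion sphere (padded by `pad` cm and clipped to the slab domain);
#' coarse cells tile the remainder of the slab. The coarse lattice is
#' anchored to the faces of the fine box so the two voxel sets partition
#' the domain exactly: every domain point lies in exactly one voxel.
#' Boundary cells are clipped, so coarse volumes can differ from
#' `coarse_edge^3`.
#'
#' @param roi_center Lesion centre (x, y, depth), cm.
#' @param roi_radius Lesion radius from ultrasound, cm.
#' @param domain Slab extents `c(Lx, Ly, Lz)`; x, y span
#'   `[-L/2, L/2]`, z spans `[0, Lz]`.
#' @param fine_edge,coarse_edge Target voxel edges, cm
#'   (`fine_edge < coarse_edge`).
#' @param pad Padding of the fine box around the ROI sphere, cm.
#' @return An object of class `dual_mesh`: `centers` (n x 3, fine voxels
#'   first), `volumes`, per-voxel `bounds_lo`/`bounds_hi`, `n_fine`,
#'   the fine `box`, and the ROI.
#' @export
build_dual_mesh <- function(roi_center, roi_radius, domain = c(9, 9, 5),
                            fine_edge = 0.25, coarse_edge = 1.0, pad = 1.0) {
  stopifnot(fine_edge < coarse_edge, roi_radius > 0)
  lo_dom <- c(-domain[1] / 2, -domain[2] / 2, 0)
  hi_dom <- c(domain[1] / 2, domain[2] / 2, domain[3])
  if (any(roi_center - roi_radius < lo_dom - 1e-9) ||
      any(roi_center + roi_radius > hi_dom + 1e-9))
    stop("ROI sphere extends outside the reconstruction domain")
  half <- roi_radius + pad
  box_lo <- pmax(roi_center - half, lo_dom)
  box_hi <- pmin(roi_center + half, hi_dom)
  # snap box faces onto nearby domain faces: a gap thinner than half a
  # coarse edge would otherwise create sliver cells whose centres fall
  # inside the Green's-function singularity guard zone at the surface
  snap <- box_lo - lo_dom < 0.5 * coarse_edge
  box_lo[snap] <- lo_dom[snap]
  snap <- hi_dom - box_hi < 0.5 * coarse_edge
  box_hi[snap] <- hi_dom[snap]

  axis_fine <- function(lo, hi) {
    n <- max(1L, ceiling((hi - lo) / fine_edge - 1e-9))
    list(n = n, edge = (hi - lo) / n,
         centers = lo + (seq_len(n) - 0.5) * (hi - lo) / n)
  }
  fx <- axis_fine(box_lo[1], box_hi[1])
  fy <- axis_fine(box_lo[2], box_hi[2])
  fz <- axis_fine(box_lo[3], box_hi[3])
  fine <- as.matrix(expand.grid(x = fx$centers, y = fy$centers,
                                z = fz$centers))
  fine_vol <- fx$edge * fy$edge * fz$edge

  # per-axis breakpoints: coarse steps outward from the box faces,
  # clipped at the domain, plus a near-coarse subdivision of the box span
  axis_breaks <- function(dlo, dhi, blo, bhi) {
    below <- rev(seq(blo, dlo, by = -coarse_edge))
    if (below[1] > dlo + 1e-9) {
      # absorb boundary slivers into the neighbouring cell so no coarse
      # cell is thinner than half an edge (thin surface cells would put
      # voxel centres into the Green's-function singularity guard zone)
      if (below[1] - dlo < 0.5 * coarse_edge) below[1] <- dlo
      else below <- c(dlo, below)
    }
    above <- seq(bhi, dhi, by = coarse_edge)
    nl <- length(above)
    if (above[nl] < dhi - 1e-9) {
      if (dhi - above[nl] < 0.5 * coarse_edge) above[nl] <- dhi
      else above <- c(above, dhi)
    }
    nmid <- max(1L, ceiling((bhi - blo) / coarse_edge - 1e-9))
    mid <- seq(blo, bhi, length.out = nmid + 1)
    br <- sort(unique(round(c(below, mid, above), 9)))
    br[c(TRUE, diff(br) > 1e-9)]
  }
  bx <- axis_breaks(lo_dom[1], hi_dom[1], box_lo[1], box_hi[1])
  by <- axis_breaks(lo_dom[2], hi_dom[2], box_lo[2], box_hi[2])
  bz <- axis_breaks(lo_dom[3], hi_dom[3], box_lo[3], box_hi[3])
  cell <- function(br) data.frame(lo = br[-length(br)], hi = br[-1])
  cx <- cell(bx); cy <- cell(by); cz <- cell(bz)
  g <- expand.grid(ix = seq_len(nrow(cx)), iy = seq_len(nrow(cy)),
                   iz = seq_len(nrow(cz)))
  clo <- cbind(cx$lo[g$ix], cy$lo[g$iy], cz$lo[g$iz])
  chi <- cbind(cx$hi[g$ix], cy$hi[g$iy], cz$hi[g$iz])
  ctr <- (clo + chi) / 2
  inside_box <- ctr[, 1] > box_lo[1] & ctr[, 1] < box_hi[1] &
    ctr[, 2] > box_lo[2] & ctr[, 2] < box_hi[2] &
    ctr[, 3] > box_lo[3] & ctr[, 3] < box_hi[3]
  coarse <- ctr[!inside_box, , drop = FALSE]
  coarse_vol <- apply((chi - clo)[!inside_box, , drop = FALSE], 1, prod)

  half_edge <- c(fx$edge, fy$edge, fz$edge) / 2
  fine_lo <- sweep(fine, 2, half_edge)
  fine_hi <- sweep(fine, 2, -half_edge)
  bounds_lo <- rbind(fine_lo, clo[!inside_box, , drop = FALSE])
  bounds_hi <- rbind(fine_hi, chi[!inside_box, , drop = FALSE])

  structure(list(centers = rbind(fine, coarse),
                 volumes = c(rep(fine_vol, nrow(fine)), coarse_vol),
                 bounds_lo = bounds_lo, bounds_hi = bounds_hi,
                 n_fine = nrow(fine),
                 fine_edge = c(fx$edge, fy$edge, fz$edge),
                 box = rbind(lo = box_lo, hi = box_hi),
                 roi = list(center = roi_center, radius = roi_radius),
                 domain = domain),
            class = "dual_mesh")
}
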