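# Similarity metrics between two stimulation settings and their clinical
# outcomes: amplitude ratio, normalized electrode-configuration distance,
# their product (setting similarity), a simplified voxel VTA model with
# Jaccard overlap, and score similarity.

#' Amplitude ratio of two settings
#'
#' `min(A1, A2) / max(A1, A2)`, in (0, 1].
#'
#' @param a1,a2 stimulation amplitudes in mA, both > 0.
#' @return ratio in (0, 1].
#' @export
amp_ratio <- function(a1, a2) {
  if (a1 <= 0 || a2 <= 0) stop("amplitudes must be positive")
  min(a1, a2) / max(a1, a2)
}

#' Normalized electrode-configuration distance
#'
#' Euclidean distance between the two signed 9-entry fraction vectors
#' (E1..E8 plus the case), divided by sqrt(8) — the distance of a full
#' bipolar swap — so the result lies in [0, 1].
#'
#' @param v1,v2 signed fraction vectors of length 9
#'   (see [setting_to_vector()]).
#' @return normalized distance in [0, 1].
#' @export
norm_elec_conf_dist <- function(v1, v2) {
  if (length(v1) != 9L || length(v2) != 9L) {
    stop("fraction vectors must have length 9 (E1..E8, case)")
  }
  sqrt(sum((v1 - v2)^2)) / sqrt(8)
}

#' Stimulation-setting similarity
#'
#' `SetSim = AmpRat * (1 - NormElcConfDist)`: the amplitude ratio of the
#' two settings times one minus their normalized electrode-configuration
#' distance. 1 means identical settings, 0 completely different ones.
#'
#' @param s1,s2 [stim_setting()] objects.
#' @param digits rounding applied to the reported value (published values
#'   are printed to 2 decimals); `NA` for no rounding.
#' @return similarity in [0, 1].
#' @export
setting_similarity <- function(s1, s2, digits = 2) {
  r <- amp_ratio(s1$amplitude, s2$amplitude) *
    (1 - norm_elec_conf_dist(setting_to_vector(s1), setting_to_vector(s2)))
  if (is.na(digits)) r else round(r, digits)
}

#' Simplified voxel volume of tissue activated
#'
#' A deliberately simple geometric stand-in (NOT a finite-element
#' activation model): the activated volume is the union of spheres
#' centered at each active electrode's centroid with radius
#' `k * sqrt(|fraction| * amplitude)`, minus the lead body and its
#' encapsulation shell, voxelized on a fixed global grid so that VTAs of
#' different settings are directly comparable.
#'
#' @param setting a [stim_setting()].
#' @param voxel_mm voxel edge length.
#' @param k_mm_per_sqrt_mA radius scale (mm per sqrt(mA)).
#' @param encapsulation_mm thickness of the peri-lead exclusion shell.
#' @param geometry a [lead_geometry()].
#' @return an object of class `voxel_vta`: voxel index set, voxel size,
#'   `volume_mm3`.
#' @export
vta_model <- function(setting, voxel_mm = 0.25, k_mm_per_sqrt_mA = 1.3,
                      encapsulation_mm = 0.1, geometry = lead_geometry()) {
  stopifnot(inherits(setting, "stim_setting"))
  if (setting$amplitude <= 0) {
    return(new_voxel_vta(integer(0), voxel_mm))
  }
  fr <- setting$fractions[paste0("E", 1:8)]
  act <- which(fr < 0)
  if (!length(act)) return(new_voxel_vta(integer(0), voxel_mm))
  # electrode centroids: rings on the axis, segments at the lead surface
  centers <- t(vapply(act, function(i) {
    lev <- geometry$electrode_level[i]
    ang <- geometry$segment_angle[i]
    z <- lev * geometry$level_spacing_mm
    if (is.na(ang)) c(0, 0, z)
    else c(geometry$lead_radius_mm * cos(ang * pi / 180),
           geometry$lead_radius_mm * sin(ang * pi / 180), z)
  }, numeric(3)))
  radii <- k_mm_per_sqrt_mA * sqrt(abs(fr[act]) * setting$amplitude)
  rmax <- max(radii)
  # fixed global voxel lattice: centers at (i + 0.5) * voxel_mm
  lim <- ceiling((max(abs(centers)) + rmax) / voxel_mm) + 1L
  ax <- (seq(-lim, lim) + 0.5) * voxel_mm
  keep <- NULL
  excl_r2 <- (geometry$lead_radius_mm + encapsulation_mm)^2
  for (e in seq_along(radii)) {
    cx <- centers[e, 1]; cy <- centers[e, 2]; cz <- centers[e, 3]
    r <- radii[e]
    xs <- which(abs(ax - cx) <= r); ys <- which(abs(ax - cy) <= r)
    zs <- which(abs(ax - cz) <= r)
    if (!length(xs) || !length(ys) || !length(zs)) next
    g <- expand.grid(x = xs, y = ys, z = zs)
    d2 <- (ax[g$x] - cx)^2 + (ax[g$y] - cy)^2 + (ax[g$z] - cz)^2
    g <- g[d2 <= r^2, , drop = FALSE]
    if (encapsulation_mm >= 0) {
      rad2 <- ax[g$x]^2 + ax[g$y]^2
      g <- g[rad2 > excl_r2, , drop = FALSE]
    }
    keep <- rbind(keep, g)
  }
  if (is.null(keep) || !nrow(keep)) return(new_voxel_vta(integer(0), voxel_mm))
  # encode each voxel by its integer lattice coordinates relative to the
  # global origin so VTAs from different settings share the grid
  code <- paste(keep$x - lim - 1L, keep$y - lim - 1L, keep$z - lim - 1L)
  new_voxel_vta(unique(code), voxel_mm)
}

new_voxel_vta <- function(voxels, voxel_mm) {
  v <- list(voxels = voxels, voxel_mm = voxel_mm,
            volume_mm3 = length(voxels) * voxel_mm^3)
  class(v) <- "voxel_vta"
  v
}

#' @export
print.voxel_vta <- function(x, ...) {
  cat(sprintf("<voxel_vta> %d voxels @ %.2f mm, %.1f mm^3\n",
              length(x$voxels), x$voxel_mm, x$volume_mm3))
  invisible(x)
}

#' Jaccard index of two voxel VTAs
#'
#' Intersection over union of the two occupied-voxel sets; both VTAs must
#' share the voxel grid and at least one must be non-empty.
#'
#' @param v1,v2 [vta_model()] results.
#' @return Jaccard index in [0, 1].
#' @export
jaccard_index <- function(v1, v2) {
  stopifnot(inherits(v1, "voxel_vta"), inherits(v2, "voxel_vta"))
  if (abs(v1$voxel_mm - v2$voxel_mm) > 1e-12) stop("voxel grids do not match")
  uni <- union(v1$voxels, v2$voxels)
  if (!length(uni)) stop("both VTAs are empty")
  length(intersect(v1$voxels, v2$voxels)) / length(uni)
}

#' Score similarity of two outcome profiles
#'
#' `ScrSim = 1 - ||s1 - s2|| / sqrt(16 * N)`: 1 when every item scores
#' identically, 0 when every item differs by the maximum of 4 points.
#'
#' @param scores1,scores2 equal-length vectors of 0-4 item scores.
#' @return similarity in [0, 1].
#' @export
score_similarity <- function(scores1, scores2) {
  if (length(scores1) != length(scores2)) stop("score lists differ in length")
  n <- length(scores1)
  if (n < 1) stop("need at least one score")
  1 - sqrt(sum((scores1 - scores2)^2)) / sqrt(16 * n)
}

#' Full similarity report between two settings and their outcomes
#'
#' @param s1,s2 [stim_setting()] objects (e.g. standard-of-care vs
#'   algorithm-derived).
#' @param scores1,scores2 optional outcome score vectors.
#' @param voxel_mm voxel size for the VTA stand-in.
#' @return list with `amp_ratio`, `norm_elec_conf_dist`, `set_sim`,
#'   `jaccard_index`, and `score_sim` (NA when scores are not given).
#' @export
similarity_report <- function(s1, s2, scores1 = NULL, scores2 = NULL,
                              voxel_mm = 0.25) {
  ar <- amp_ratio(s1$amplitude, s2$amplitude)
  nd <- norm_elec_conf_dist(setting_to_vector(s1), setting_to_vector(s2))
  jac <- jaccard_index(vta_model(s1, voxel_mm), vta_model(s2, voxel_mm))
  ss <- if (is.null(scores1)) NA_real_ else score_similarity(scores1, scores2)
  list(amp_ratio = ar, norm_elec_conf_dist = nd,
       set_sim = ar * (1 - nd), jaccard_index = jac, score_sim = ss)
}
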