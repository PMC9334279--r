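#' Width of a profile at a fractional level
#'
#' Full width of a 1D sampled amplitude profile at `level` times its maximum:
#' the distance between the two level crossings bracketing the (unique)
#' global maximum, with linear interpolation between samples. Invariant under
#' amplitude rescaling. If the profile never drops below the level on one
#' side (plateau running into the boundary), the width is `NA` and the result
#' carries attribute `unbounded = TRUE`.
#'
#' @param x Sample positions (monotone increasing).
#' @param y Amplitudes (same length as `x`).
#' @param level Fraction of the maximum, in (0, 1).
#' @return Width in the units of `x` (possibly `NA`).
#' @examples
#' x <- seq(-5, 5, by = 0.01)
#' profile_width(x, exp(-x^2 / 2), 0.5)   # FWHM of a unit-sigma Gaussian
#' @export
profile_width <- function(x, y, level = 0.5) {
  stopifnot(length(x) == length(y), level > 0, level < 1)
  im <- which.max(y)
  thr <- level * y[im]
  cross <- function(side) {
    idx <- if (side < 0) rev(seq_len(im - 1)) else seq(im + 1, length.out =
                                                        length(y) - im)
    for (i in idx) {
      if (y[i] < thr) {
        j <- i + ifelse(side < 0, 1L, -1L)    # neighbour still above
        return(x[i] + (x[j] - x[i]) * (thr - y[i]) / (y[j] - y[i]))
      }
    }
    NA_real_
  }
  lo <- cross(-1); hi <- cross(+1)
  w <- hi - lo
  if (is.na(w)) attr(w, "unbounded") <- TRUE
  w
}

# interpolated 1D profile through a voxel along one grid axis
extract_profile <- function(vol, at_idx, axis) {
  d <- dim(vol$data)
  idx <- list(at_idx[1], at_idx[2], at_idx[3])
  idx[[axis]] <- seq_len(d[axis])
  list(x = axis_coords(vol, axis),
       y = vol$data[idx[[1]], idx[[2]], idx[[3]]])
}

#' Focal position and dimensions of a pressure field
#'
#' Locates the global pressure maximum, extracts the axial profile (along the
#' transducer axis) and the two transverse profiles through it, and measures
#' full widths at 50% (FWHM) and 90% (FW90%M) of the maximum pressure. The
#' focal distance is reported from the exit plane (the plane through the bowl
#' rim). The transducer axis must be aligned with a grid axis.
#'
#' @param field A `pressure_field` or a [vox_volume()] of pressure amplitude.
#' @param geom The [transducer_geometry()] that produced the field.
#' @return A list of class `focus_metrics`; see [tidy.focus_metrics()].
#' @export
focus_metrics <- function(field, geom) {
  vol <- if (inherits(field, "pressure_field")) field$p_pp else field
  stopifnot(inherits(vol, "vox_volume"), inherits(geom, "transducer_geometry"))
  ax <- which(abs(abs(geom$axis) - 1) < 1e-9)
  if (length(ax) != 1) {
    stop("transducer axis must be aligned with a grid axis", call. = FALSE)
  }
  d <- dim(vol$data)
  im <- arrayInd(which.max(vol$data), d)
  on_boundary <- any(im == 1L | im == d)
  pos <- vol$origin_m + (as.numeric(im) - 1) * vol$spacing_m
  axial <- extract_profile(vol, im, ax)
  lat_axes <- setdiff(1:3, ax)[d[setdiff(1:3, ax)] > 1]
  width_at <- function(p, lv) profile_width(p$x, p$y, lv)
  lat_w <- function(lv) {
    w <- vapply(lat_axes, function(a) width_at(extract_profile(vol, im, a), lv),
                numeric(1))
    mean(w)
  }
  cap <- bowl_cap_geometry(geom)
  exit_plane <- geom$position_m + cap$cap_depth_m * geom$axis
  focal_dist <- sum((pos - exit_plane) * geom$axis)
  structure(list(
    focal_position_m = pos,
    axial_fwhm_m = width_at(axial, 0.5),
    lateral_fwhm_m = lat_w(0.5),
    axial_fw90_m = width_at(axial, 0.9),
    lateral_fw90_m = lat_w(0.9),
    focal_distance_from_exit_plane_m = focal_dist,
    max_on_boundary = on_boundary), class = "focus_metrics")
}

#' @export
print.focus_metrics <- function(x, ...) {
  cat("<focus_metrics> focus ", signif(x$focal_distance_from_exit_plane_m * 1e3, 4),
      " mm from the exit plane\n", sep = "")
  cat("  FWHM: ", signif(x$lateral_fwhm_m * 1e3, 3), " mm dia x ",
      signif(x$axial_fwhm_m * 1e3, 3), " mm; FW90%M: ",
      signif(x$lateral_fw90_m * 1e3, 3), " mm dia x ",
      signif(x$axial_fw90_m * 1e3, 3), " mm\n", sep = "")
  if (x$max_on_boundary) cat("  WARNING: maximum on grid boundary\n")
  invisible(x)
}

# 26-neighbourhood local maxima above a threshold; returns voxel indices
local_maxima_26 <- function(arr, threshold) {
  d <- dim(arr)
  is_max <- arr >= threshold
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    sh <- arr
    src_i <- pmin(pmax(seq_len(d[1]) + di, 1), d[1])
    src_j <- pmin(pmax(seq_len(d[2]) + dj, 1), d[2])
    src_k <- pmin(pmax(seq_len(d[3]) + dk, 1), d[3])
    sh <- arr[src_i, src_j, src_k, drop = FALSE]
    dim(sh) <- d
    is_max <- is_max & (arr >= sh)
  }
  which(is_max)
}

#' Detect and label intracranial intensity maxima
#'
#' Finds 26-neighbourhood local maxima of the pulse-average intensity map
#' above a prominence threshold, enforces a minimum separation, and labels
#' them by position relative to the skull mask and beam axis:
#' * `i` — geometric focus (always reported, at the geometric focal point);
#' * `ii` — mid-cavity reverberation maximum (brain, away from bone, between
#'   the incident and opposite skull walls);
#' * `iii` — brain tissue interfacing the bone opposite to sonication (brain
#'   voxels within one voxel of skull, beyond the cavity midpoint);
#' * `iv` — skull surface facing the incident waves.
#'
#' Percent transmission is reported against the free-water focal intensity.
#'
#' @param ifield An `intensity_field` (see [intensity_map()]), or a
#'   [vox_volume()] of I_SPPA in W/cm^2.
#' @param mat The `material_grid` (supplies the skull label).
#' @param geom The [transducer_geometry()].
#' @param reference_isppa_w_cm2 Free-water focal intensity for the percent
#'   transmission column (default 5 W/cm^2).
#' @param prominence Fraction of the global maximum below which local maxima
#'   are ignored (default 0.25).
#' @param min_separation_m Minimum distance between reported maxima.
#' @return A tibble with columns `label`, `x_m`, `y_m`, `z_m`,
#'   `isppa_w_cm2`, `p_pp_kpa`, `percent_transmission`.
#' @export
find_local_maxima <- function(ifield, mat, geom,
                              reference_isppa_w_cm2 = 5,
                              prominence = 0.25, min_separation_m = 2e-3) {
  vol <- if (inherits(ifield, "intensity_field")) ifield$isppa_w_cm2 else ifield
  stopifnot(inherits(vol, "vox_volume"), inherits(mat, "material_grid"))
  d <- dim(vol$data)
  arr <- vol$data
  cand <- local_maxima_26(arr, prominence * max(arr))
  ci <- arrayInd(cand, d)
  pos <- sweep((ci - 1) * vol$spacing_m, 2, vol$origin_m, "+")
  val <- arr[cand]
  o <- order(val, decreasing = TRUE)
  cand <- cand[o]; ci <- ci[o, , drop = FALSE]
  pos <- pos[o, , drop = FALSE]; val <- val[o]
  keep <- rep(TRUE, length(val))          # greedy minimum-separation filter
  for (a in seq_along(val)) {
    if (!keep[a]) next
    if (a < length(val)) {
      later <- seq(a + 1, length(val))
      dd <- sqrt(rowSums(sweep(pos[later, , drop = FALSE], 2, pos[a, ])^2))
      keep[later][dd < min_separation_m] <- FALSE
    }
  }
  cand <- cand[keep]; ci <- ci[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]; val <- val[keep]

  skull_idx <- which(mat$label == 2L)
  has_skull <- length(skull_idx) > 0
  focus <- geom$position_m + geom$curvature_radius_m * geom$axis
  s_of <- function(p) drop((p - geom$position_m) %*% geom$axis)

  rows <- list()
  p_at <- function(lin) {       # intensity -> local peak-to-peak pressure
    2 * pressure_from_intensity(
      arr[lin], medium_constants(mat$density_kg_m3[lin],
                                 mat$sound_speed_m_s[lin]))
  }
  add_row <- function(label, lin, p3) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      label = label, x_m = p3[1], y_m = p3[2], z_m = p3[3],
      isppa_w_cm2 = arr[lin], p_pp_kpa = p_at(lin) / 1e3,
      percent_transmission = 100 * arr[lin] / reference_isppa_w_cm2)
  }
  # (i) geometric focus: always reported at the focal point
  fi <- nearest_voxel(vol, focus)
  flin <- fi[1] + d[1] * (fi[2] - 1 + d[2] * (fi[3] - 1))
  add_row("i", flin, vol$origin_m + (fi - 1) * vol$spacing_m)

  if (has_skull) {
    sk_ci <- arrayInd(skull_idx, d)
    sk_pos <- sweep((sk_ci - 1) * vol$spacing_m, 2, vol$origin_m, "+")
    sk_s <- as.numeric(sk_pos %*% geom$axis) -
      sum(geom$position_m * geom$axis)
    s_mid <- mean(range(sk_s))           # cavity midpoint along the beam
    cavity_half <- diff(range(sk_s)) / 2
    dist_to_skull <- function(p3) {
      min(sqrt(rowSums(sweep(sk_pos, 2, p3)^2)))
    }
    lab_of <- function(lin, p3) {
      s <- s_of(p3)
      ds <- dist_to_skull(p3)
      if (mat$label[lin] != 1L) {        # water or bone
        if (ds <= 1.5 * vol$spacing_m && s < s_mid) return("iv")
        return(NA_character_)
      }
      if (ds <= 1.5 * vol$spacing_m && s > s_mid) return("iii")
      # mid-cavity: interior tissue, clear of bone, middle half of the cavity
      if (ds > 2 * vol$spacing_m && abs(s - s_mid) <= cavity_half / 2) {
        return("ii")
      }
      NA_character_
    }
    taken <- character()
    for (a in seq_along(val)) {
      lb <- lab_of(cand[a], pos[a, ])
      if (!is.na(lb) && !(lb %in% taken)) {
        add_row(lb, cand[a], pos[a, ])
        taken <- c(taken, lb)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$label), ]
}
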