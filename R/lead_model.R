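# Lead geometry, exploration points, stimulation settings and the
# coordinate -> fractionalization mapping for a 1-3-3-1 directional lead.

#' Geometry of an 8-electrode directional lead
#'
#' Describes the 1-3-3-1 layout used by directional DBS leads (e.g. the
#' Boston Scientific Cartesia family): a bottom ring (E1), two segmented
#' levels of three electrodes each (E2-E4, E5-E7) and a top ring (E8).
#' The vertical coordinate is measured in level units: integer values sit
#' at level centers (0 = E1, 1 = E2-E4, 2 = E5-E7, 3 = E8). Segment
#' reference angles are fixed at 0, 120 and 240 degrees for the first,
#' second and third electrode of each segmented level.
#'
#' @param level_spacing_mm physical distance between adjacent level centers
#'   (contact plus gap), used only by the voxel VTA model.
#' @param lead_radius_mm lead body radius, used only by the voxel VTA model.
#' @return an object of class `lead_geometry`.
#' @export
lead_geometry <- function(level_spacing_mm = 2.0, lead_radius_mm = 0.65) {
  labels <- paste0("E", 1:8)
  level <- c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L)
  angle <- c(NA, 0, 120, 240, 0, 120, 240, NA)
  g <- list(
    n_levels = 4L,
    segments_per_level = c(1L, 3L, 3L, 1L),
    electrode_labels = labels,
    electrode_level = stats::setNames(level, labels),
    segment_angle = stats::setNames(angle, labels),
    level_spacing_mm = level_spacing_mm,
    lead_radius_mm = lead_radius_mm
  )
  class(g) <- "lead_geometry"
  g
}

#' A point in a 2D stimulation space
#'
#' Ring-stage points live on (vertical position p in [0, 3] level units,
#' amplitude in mA); directional-stage points on (rotation angle theta in
#' [0, 360) degrees, amplitude in mA). Angles are normalized modulo 360.
#'
#' @param stage `"ring"` or `"directional"`.
#' @param coord1 vertical position (ring) or rotation angle (directional).
#' @param amplitude stimulation amplitude in mA, >= 0.
#' @return an object of class `exploration_point`.
#' @export
exploration_point <- function(stage, coord1, amplitude) {
  stage <- match.arg(stage, c("ring", "directional"))
  stopifnot(is.numeric(coord1), length(coord1) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (stage == "ring") {
    if (coord1 < 0 || coord1 > 3) {
      stop("vertical position must lie in [0, 3] level units")
    }
  } else {
    coord1 <- coord1 %% 360
  }
  structure(list(stage = stage, coord1 = coord1, amplitude = amplitude),
            class = "exploration_point")
}

#' A concrete stimulation setting
#'
#' Signed per-electrode current fractions: cathodes negative (summing to
#' -1 when the amplitude is positive), anodes positive (monopolar
#' stimulation puts +1 on the implanted pulse generator case). The percent
#' representation used in settings tables is integer percents summing to
#' 100 on the cathodes.
#'
#' @param amplitude mA, >= 0.
#' @param fractions named numeric of length 9 (`E1`..`E8`, `case`), signed.
#' @param frequency Hz.
#' @param pulse_width microseconds.
#' @param mode `"ring"` or `"directional"`.
#' @return an object of class `stim_setting`.
#' @export
stim_setting <- function(amplitude, fractions, frequency = 130,
                         pulse_width = 60, mode = c("ring", "directional")) {
  mode <- match.arg(mode)
  nm <- c(paste0("E", 1:8), "case")
  if (length(fractions) != 9L) stop("fractions must have length 9 (E1..E8, case)")
  if (is.null(names(fractions))) names(fractions) <- nm
  fractions <- fractions[nm]
  if (anyNA(fractions)) stop("fractions must be named E1..E8 and case")
  if (any(abs(fractions) > 1 + 1e-9)) stop("electrode fractions must lie in [-1, 1]")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude > 0) {
    catsum <- sum(fractions[fractions < 0])
    ansum <- sum(fractions[fractions > 0])
    if (abs(catsum + 1) > 1e-9) stop("cathodic fractions must sum to -1")
    if (abs(ansum - 1) > 1e-9) stop("anodic fractions must sum to +1")
  } else if (any(fractions != 0)) {
    stop("zero-amplitude settings must have all-zero fractions")
  }
  structure(list(amplitude = amplitude, fractions = fractions,
                 frequency = frequency, pulse_width = pulse_width,
                 mode = mode),
            class = "stim_setting")
}

#' @export
print.stim_setting <- function(x, ...) {
  cat(sprintf("<stim_setting> %.1f mA, %g Hz, %g us, %s mode\n  %s\n",
              x$amplitude, x$frequency, x$pulse_width, x$mode,
              format_electrode_config(x)))
  invisible(x)
}

# Largest-remainder rounding of non-negative shares (percent) to integers
# summing to `total`; ties go to the lowest index. Shares equal to zero
# never receive a unit.
largest_remainder <- function(shares, total = 100L) {
  stopifnot(all(shares >= -1e-9))
  shares <- pmax(shares, 0)
  if (sum(shares) == 0) return(rep(0L, length(shares)))
  shares <- shares / sum(shares) * total
  base <- floor(shares + 1e-9)
  rem <- shares - base
  need <- as.integer(round(total - sum(base)))
  out <- as.integer(base)
  if (need > 0) {
    eligible <- which(shares > 0)
    # order by remainder descending, ties by index ascending
    ord <- eligible[order(-rem[eligible], eligible)]
    take <- ord[seq_len(need)]
    out[take] <- out[take] + 1L
  }
  out
}

# Continuous cathodic shares (in percent, before rounding) for a ring point.
ring_shares <- function(p, geometry) {
  lo <- floor(p); hi <- ceiling(p); f <- p - lo
  shares <- stats::setNames(numeric(8), geometry$electrode_labels)
  add_level <- function(shares, lev, pct) {
    idx <- which(geometry$electrode_level == lev)
    shares[idx] <- shares[idx] + pct / length(idx)
    shares
  }
  shares <- add_level(shares, lo, (1 - f) * 100)
  if (hi != lo) shares <- add_level(shares, hi, f * 100)
  shares
}

# Angular split of one segmented level's share across its two segments
# adjacent to theta (linear interpolation between 0/120/240 degrees).
angular_split <- function(theta) {
  theta <- theta %% 360
  k <- floor(theta / 120)
  w_hi <- (theta - 120 * k) / 120
  seg_lo <- as.integer(k) + 1L           # 1,2,3 ~ 0,120,240 deg
  seg_hi <- as.integer((k + 1) %% 3) + 1L
  w <- numeric(3)
  w[seg_lo] <- w[seg_lo] + (1 - w_hi)
  w[seg_hi] <- w[seg_hi] + w_hi
  w
}

shares_to_setting <- function(shares, amplitude, mode, frequency = 130,
                              pulse_width = 60) {
  pct <- largest_remainder(shares, 100L)
  fr <- c(-pct / 100, case = 1)
  names(fr) <- c(paste0("E", 1:8), "case")
  if (amplitude == 0) fr[] <- 0
  s <- stim_setting(amplitude, fr, frequency = frequency,
                    pulse_width = pulse_width, mode = mode)
  s$percents <- stats::setNames(pct, paste0("E", 1:8))
  s
}

#' Map a ring-stage point to a stimulation setting
#'
#' The cathodic current is linearly interpolated between the two levels
#' adjacent to the vertical position `p`; a segmented level's share is
#' split equally across its three segments; the case is the anode
#' (monopolar). Percents are rounded to integers by largest remainder with
#' ties to the lowest electrode index.
#'
#' @param point a ring-stage [exploration_point()].
#' @param geometry a [lead_geometry()].
#' @param a_max safety amplitude ceiling in mA.
#' @return a [stim_setting()] with a `percents` field.
#' @export
ring_point_to_setting <- function(point, geometry = lead_geometry(),
                                  a_max = 5.5) {
  stopifnot(inherits(point, "exploration_point"))
  if (point$stage != "ring") stop("point is not a ring-stage point")
  if (point$coord1 < 0 || point$coord1 > 3) stop("vertical position outside [0, 3]")
  if (point$amplitude > a_max) stop("amplitude exceeds the safety limit")
  shares_to_setting(ring_shares(point$coord1, geometry), point$amplitude,
                    mode = "ring")
}

#' Map a directional-stage point to a stimulation setting
#'
#' The vertical position carried over from the ring stage fixes the split
#' between adjacent levels exactly as in [ring_point_to_setting()]; within
#' each segmented level the level's share is split by linear angular
#' interpolation between the two segment directions adjacent to `theta`.
#' Ring levels (E1, E8) receive their vertical share undirected.
#'
#' @param point a directional-stage [exploration_point()] (coord1 = angle).
#' @param base_vertical vertical position p in [0, 3] fixed by stage 1.
#' @inheritParams ring_point_to_setting
#' @return a [stim_setting()] with a `percents` field.
#' @export
directional_point_to_setting <- function(point, base_vertical,
                                         geometry = lead_geometry(),
                                         a_max = 5.5) {
  stopifnot(inherits(point, "exploration_point"))
  if (point$stage != "directional") stop("point is not a directional-stage point")
  if (base_vertical < 0 || base_vertical > 3) stop("base vertical outside [0, 3]")
  if (point$amplitude > a_max) stop("amplitude exceeds the safety limit")
  theta <- point$coord1 %% 360
  lev_shares <- ring_shares(base_vertical, geometry)
  shares <- stats::setNames(numeric(8), geometry$electrode_labels)
  w <- angular_split(theta)
  for (lev in 0:3) {
    idx <- which(geometry$electrode_level == lev)
    lev_total <- sum(lev_shares[idx])
    if (lev_total == 0) next
    if (length(idx) == 1L) shares[idx] <- lev_total
    else shares[idx] <- lev_total * w
  }
  shares_to_setting(shares, point$amplitude, mode = "directional")
}

#' Signed fraction vector of a setting
#'
#' Deterministic ordering E1..E8 with the case last; cathodes negative,
#' anodes positive. This is the 9-entry vector entering the normalized
#' electrode-configuration distance.
#'
#' @param setting a [stim_setting()].
#' @return numeric vector of length 9.
#' @export
setting_to_vector <- function(setting) {
  stopifnot(inherits(setting, "stim_setting"))
  unname(setting$fractions[c(paste0("E", 1:8), "case")])
}

#' Recover stimulation-space coordinates from a setting
#'
#' Inverse of the fractionalization mapping: the vertical position is the
#' cathodic-share-weighted centroid of levels; the angle is recovered by
#' sector-wise inversion of the linear angular interpolation (falling back
#' to the circular resultant when all three segment directions are active).
#'
#' @param setting a [stim_setting()].
#' @param geometry a [lead_geometry()].
#' @return list with `p` (level units) and `theta` (degrees, `NA` when the
#'   setting has no angular bias).
#' @export
setting_to_point <- function(setting, geometry = lead_geometry()) {
  fr <- setting$fractions
  shares <- pmax(-fr[paste0("E", 1:8)], 0)
  tot <- sum(shares)
  if (tot <= 0) stop("setting has no cathodic current")
  shares <- shares / tot
  p <- sum(shares * geometry$electrode_level)
  seg <- unname(c(shares["E2"] + shares["E5"],
                  shares["E3"] + shares["E6"],
                  shares["E4"] + shares["E7"]))
  theta <- NA_real_
  if (sum(seg > 1e-12) == 1L) {
    theta <- c(0, 120, 240)[which(seg > 1e-12)]
  } else if (sum(seg > 1e-12) == 2L) {
    act <- which(seg > 1e-12)
    pair <- sort(act)
    if (identical(pair, c(1L, 2L))) {
      theta <- 120 * seg[2] / (seg[1] + seg[2])
    } else if (identical(pair, c(2L, 3L))) {
      theta <- 120 + 120 * seg[3] / (seg[2] + seg[3])
    } else {
      theta <- 240 + 120 * seg[1] / (seg[3] + seg[1])
    }
  } else if (sum(seg) > 1e-12) {
    # all three segment directions active: steered only if the circular
    # resultant is substantial; near-equal thirds (incl. integer-percent
    # rounding noise on ring settings) count as angularly symmetric
    ang <- c(0, 120, 240) * pi / 180
    x <- sum(seg * cos(ang)); y <- sum(seg * sin(ang))
    if (sqrt(x^2 + y^2) / sum(seg) > 0.15) {
      theta <- (atan2(y, x) * 180 / pi) %% 360
    }
  }
  list(p = unname(p), theta = unname(theta) %% 360)
}

#' Parse a settings-table electrode configuration string
#'
#' Understands the dialect of published settings tables, e.g.
#' `"E1: -70%, E2, E3, E4: -10%"` (electrodes listed before a colon share
#' the following percent). Both ASCII `-` and Unicode minus are accepted.
#'
#' @param text configuration string.
#' @return named integer vector of cathodic percents over E1..E8
#'   (positive numbers, summing to 100).
#' @export
parse_electrode_config <- function(text) {
  text <- gsub("−", "-", text)
  tokens <- trimws(strsplit(text, ",")[[1]])
  pct <- stats::setNames(integer(8), paste0("E", 1:8))
  pending <- character(0)
  for (tok in tokens) {
    if (grepl(":", tok, fixed = TRUE)) {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      labs <- c(pending, trimws(parts[1]))
      val <- as.numeric(gsub("[%\\s]", "", parts[2], perl = TRUE))
      if (is.na(val)) stop("malformed percent in: ", tok)
      for (lab in labs) {
        if (!lab %in% names(pct)) stop("unknown electrode label: ", lab)
        pct[lab] <- abs(val)
      }
      pending <- character(0)
    } else {
      pending <- c(pending, tok)
    }
  }
  if (length(pending)) stop("dangling electrode labels without a percent")
  if (sum(pct) != 100L) stop("cathodic percents must sum to 100, got ", sum(pct))
  pct
}

#' Format a setting's cathodes in the settings-table dialect
#'
#' @param x a [stim_setting()] or a named percent vector over E1..E8.
#' @return string such as `"E1: -70%, E2: -10%, E3: -10%, E4: -10%"`.
#' @export
format_electrode_config <- function(x) {
  if (inherits(x, "stim_setting")) {
    pct <- round(pmax(-x$fractions[paste0("E", 1:8)], 0) * 100)
  } else {
    pct <- x[paste0("E", 1:8)]
  }
  act <- which(pct > 0)
  if (!length(act)) return("")
  paste(sprintf("E%d: -%d%%", act, as.integer(pct[act])), collapse = ", ")
}

#' Build a setting from a configuration string
#'
#' @param text electrode configuration string in the table dialect.
#' @inheritParams stim_setting
#' @return a [stim_setting()].
#' @export
setting_from_config <- function(text, amplitude, frequency = 130,
                                pulse_width = 60,
                                mode = c("ring", "directional")) {
  mode <- match.arg(mode)
  pct <- parse_electrode_config(text)
  fr <- c(-pct / 100, case = 1)
  names(fr) <- c(paste0("E", 1:8), "case")
  s <- stim_setting(amplitude, fr, frequency, pulse_width, mode)
  s$percents <- pct
  s
}

#' Find stimulation-space coordinates reproducing a percent pattern
#'
#' Searches the ring and directional mappings for a point whose rounded
#' integer percents come closest to `pct`; used to check that published
#' electrode configurations are representable under the coordinate system.
#'
#' @param pct named cathodic percent vector over E1..E8 (summing to 100).
#' @param geometry a [lead_geometry()].
#' @return list with `stage`, `p`, `theta`, and `max_dev` (largest
#'   per-electrode deviation in percentage points).
#' @export
find_point_for_config <- function(pct, geometry = lead_geometry()) {
  pct <- pct[paste0("E", 1:8)]
  shares <- pct / 100
  p_hat <- sum(shares * geometry$electrode_level)
  dev <- function(got) max(abs(as.integer(got) - as.integer(pct)))
  best <- list(stage = "ring", p = p_hat, theta = NA_real_, max_dev = Inf)
  # ring candidate: centroid p (exact for any adjacent-level ring pattern)
  for (p in unique(pmin(pmax(c(p_hat, round(p_hat, 2)), 0), 3))) {
    s <- ring_point_to_setting(exploration_point("ring", p, 1), geometry)
    d <- dev(s$percents)
    if (d < best$max_dev) best <- list(stage = "ring", p = p, theta = NA_real_, max_dev = d)
  }
  # directional candidates: fixed p, scan theta finely
  for (theta in seq(0, 359.75, by = 0.25)) {
    s <- directional_point_to_setting(
      exploration_point("directional", theta, 1), p_hat, geometry)
    d <- dev(s$percents)
    if (d < best$max_dev ||
        (d == best$max_dev && best$stage == "ring" && d > 0)) {
      best <- list(stage = "directional", p = p_hat, theta = theta, max_dev = d)
      if (d == 0) break
    }
  }
  best
}
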