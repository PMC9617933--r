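# Interpolated score maps over a 2D stimulation space, with side-effect
# amplitude boundaries shrinking the admissible region.

#' Create an empty score map
#'
#' A score map holds the explored points of one stage with their total
#' weighted scores, an inverse-distance-weighted (power 2) interpolant
#' over a regular lattice, and per-column amplitude caps induced by
#' observed side effects. Coordinates are normalized before distances are
#' taken: vertical position is scaled by its span, angles are treated
#' circularly (scaled by 360), amplitude is scaled by its span.
#'
#' @param stage `"ring"` or `"directional"`.
#' @param amp_range amplitude bounds in mA, default `c(0.5, 5.5)`.
#' @param n_coord1 lattice resolution along the first coordinate
#'   (default 31 ring positions / 30 angles).
#' @param n_amp lattice resolution along amplitude (default 26).
#' @param se_radius side-effect neighborhood radius: level units (ring) or
#'   degrees (directional); defaults 0.5 / 60.
#' @param amp_step amplitude step in mA; a side effect observed at A caps
#'   the neighborhood at A - `amp_step`.
#' @return an object of class `score_map`.
#' @export
score_map <- function(stage = c("ring", "directional"),
                      amp_range = c(0.5, 5.5),
                      n_coord1 = if (stage == "ring") 31L else 30L,
                      n_amp = 26L,
                      se_radius = if (stage == "ring") 0.5 else 60,
                      amp_step = 0.1) {
  stage <- match.arg(stage)
  coord1_grid <- if (stage == "ring") seq(0, 3, length.out = n_coord1)
                 else seq(0, 360, length.out = n_coord1 + 1L)[seq_len(n_coord1)]
  m <- list(stage = stage,
            coord1_grid = coord1_grid,
            amp_grid = seq(amp_range[1], amp_range[2], length.out = n_amp),
            amp_range = amp_range,
            obs = data.frame(coord1 = numeric(0), amplitude = numeric(0),
                             score = numeric(0), side_effect = logical(0)),
            caps = rep(Inf, n_coord1),
            se_radius = se_radius, amp_step = amp_step)
  class(m) <- "score_map"
  m
}

# Normalized squared distances between one (coord1, amplitude) query and a
# set of points; circular along angles.
.map_dist2 <- function(map, c1, a, c1s, as_) {
  span_a <- diff(map$amp_range)
  da <- (a - as_) / span_a
  if (map$stage == "ring") {
    dc <- (c1 - c1s) / 3
  } else {
    # circular, scaled so the maximal disagreement (180 deg) is 1,
    # consistent with the [0,1] span of the other coordinates
    d <- abs((c1 - c1s) %% 360)
    dc <- pmin(d, 360 - d) / 180
  }
  dc^2 + da^2
}

# circular/linear coord1 distance in native units (for side-effect radius)
.coord1_dist <- function(map, c1, c1s) {
  if (map$stage == "ring") abs(c1 - c1s)
  else { d <- abs((c1 - c1s) %% 360); pmin(d, 360 - d) }
}

#' Record an observation on a score map
#'
#' Appends the point with its total weighted score; a repeat observation
#' within half a lattice cell replaces the earlier one. A side-effect
#' observation at amplitude A caps the admissible amplitude at
#' A - `amp_step` for all first-coordinate values within the side-effect
#' radius (circular distance on the directional stage); caps only ever
#' tighten.
#'
#' @param map a [score_map()].
#' @param point an [exploration_point()] of the map's stage.
#' @param score total weighted score observed there.
#' @param side_effect logical.
#' @return the updated `score_map`.
#' @export
update_map <- function(map, point, score, side_effect = FALSE) {
  stopifnot(inherits(map, "score_map"), inherits(point, "exploration_point"))
  if (point$stage != map$stage) stop("point stage does not match map stage")
  c1 <- point$coord1; a <- point$amplitude
  if (a < map$amp_range[1] - 1e-9 || a > map$amp_range[2] + 1e-9) {
    stop("amplitude outside the stimulation-space bounds")
  }
  if (map$stage == "ring" && (c1 < 0 || c1 > 3)) stop("vertical position outside [0, 3]")
  res_c1 <- if (map$stage == "ring") diff(map$coord1_grid[1:2]) else
    360 / length(map$coord1_grid)
  res_a <- diff(map$amp_grid[1:2])
  if (nrow(map$obs)) {
    dup <- .coord1_dist(map, c1, map$obs$coord1) < res_c1 / 2 &
      abs(a - map$obs$amplitude) < res_a / 2
    map$obs <- map$obs[!dup, , drop = FALSE]
  }
  map$obs <- rbind(map$obs,
                   data.frame(coord1 = c1, amplitude = a, score = score,
                              side_effect = isTRUE(side_effect)))
  rownames(map$obs) <- NULL
  if (isTRUE(side_effect)) {
    near <- .coord1_dist(map, c1, map$coord1_grid) <= map$se_radius + 1e-9
    map$caps[near] <- pmin(map$caps[near], a - map$amp_step)
  }
  map
}

#' Predict the score at a stimulation-space point
#'
#' Inverse-distance-weighted interpolation (power 2) in normalized
#' coordinates; exact at observed points; clipped to [0, 4].
#'
#' @param map a [score_map()] with at least one observation.
#' @param point an [exploration_point()], or a list with `coord1` and
#'   `amplitude`.
#' @return predicted score in [0, 4].
#' @export
predict_score <- function(map, point) {
  if (!nrow(map$obs)) stop("score map has no observations")
  d2 <- .map_dist2(map, point$coord1, point$amplitude,
                   map$obs$coord1, map$obs$amplitude)
  hit <- which(d2 < 1e-18)
  if (length(hit)) return(map$obs$score[hit[1]])
  w <- 1 / d2
  min(max(sum(w * map$obs$score) / sum(w), 0), 4)
}

# Vectorized IDW prediction at many (coord1, amplitude) queries.
.predict_many <- function(map, c1v, av) {
  n <- length(c1v)
  wsum <- numeric(n); wssum <- numeric(n)
  exact <- rep(NA_real_, n)
  for (k in seq_len(nrow(map$obs))) {
    d2 <- .map_dist2(map, c1v, av, map$obs$coord1[k], map$obs$amplitude[k])
    hit <- d2 < 1e-18
    exact[hit] <- map$obs$score[k]
    d2 <- pmax(d2, 1e-18)
    w <- 1 / d2
    wsum <- wsum + w
    wssum <- wssum + w * map$obs$score[k]
  }
  out <- pmin(pmax(wssum / wsum, 0), 4)
  out[!is.na(exact)] <- exact[!is.na(exact)]
  out
}

# Predicted scores and admissibility over the whole lattice.
# Returns list(pred = matrix [n_coord1 x n_amp], admissible = matrix).
map_grid <- function(map) {
  nc <- length(map$coord1_grid); na_ <- length(map$amp_grid)
  pred <- matrix(NA_real_, nc, na_)
  if (nrow(map$obs)) {
    c1v <- rep(map$coord1_grid, times = na_)
    av <- rep(map$amp_grid, each = nc)
    pred <- matrix(.predict_many(map, c1v, av), nc, na_)
  }
  adm <- outer(map$caps, map$amp_grid, function(cap, a) a < cap - 1e-9)
  list(pred = pred, admissible = adm)
}

#' Export a score map as a gridded table
#'
#' @param map a [score_map()] with at least one observation.
#' @param path optional CSV destination; when given the table is also
#'   written there (UTF-8, newline-terminated).
#' @return data.frame with columns `coord1`, `amplitude`, `predicted`,
#'   `admissible` (one row per lattice node).
#' @export
export_map <- function(map, path = NULL) {
  if (!nrow(map$obs)) stop("score map has no observations")
  g <- map_grid(map)
  out <- data.frame(
    coord1 = rep(map$coord1_grid, times = length(map$amp_grid)),
    amplitude = rep(map$amp_grid, each = length(map$coord1_grid)),
    predicted = as.vector(g$pred),
    admissible = as.vector(g$admissible)
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %s stage, %d x %d lattice, %d observation(s), %s\n",
              x$stage, length(x$coord1_grid), length(x$amp_grid), nrow(x$obs),
              if (all(is.infinite(x$caps))) "no side-effect caps"
              else sprintf("%d capped column(s)", sum(is.finite(x$caps)))))
  invisible(x)
}
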