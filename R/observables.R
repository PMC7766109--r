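# Structural observables: radius of gyration, gyration-tensor shape factor,
# P2 orientational order (scalar and x-binned profile), and landmark times of
# an observable trace.

check_unwrapped <- function(positions, box) {
  if (is.null(box)) return(invisible(TRUE))
  d <- abs(diff(positions))
  for (k in 1:3)
    if (any(d[, k] > box[k] / 2))
      stop("positions look periodically wrapped (consecutive jump > box/2); ",
           "unwrap the molecule first")
  invisible(TRUE)
}

#' Radius of gyration
#'
#' Root mean squared distance of the beads to their center of mass,
#' `Rg^2 = mean(|r_i - r_com|^2)`. Coordinates must be unwrapped across
#' periodic images; if `box` is supplied, a consecutive-bead jump longer than
#' half a box edge is rejected as wrapped input.
#'
#' @param positions M x 3 matrix of unwrapped bead coordinates.
#' @param box Optional length-3 box edges used only for the wrap check.
#' @return Scalar Rg (rc units).
#' @export
radius_of_gyration <- function(positions, box = NULL) {
  positions <- rbind(positions)
  stopifnot(nrow(positions) >= 1)
  check_unwrapped(positions, box)
  centered <- sweep(positions, 2, colMeans(positions))
  sqrt(mean(rowSums(centered^2)))
}

#' Gyration tensor, eigenvalues and shape factor
#'
#' Diagonalizes the gyration tensor `S = mean((r - com) (r - com)^T)`; its
#' eigenvalues L1^2 >= L2^2 >= L3^2 sum to Rg^2 and the shape factor is
#' `delta = 1 - 3 (L1^2 L2^2 + L2^2 L3^2 + L1^2 L3^2) / (L1^2 + L2^2 + L3^2)^2`,
#' 0 for equal eigenvalues (sphere-like), 1 for a line, and 0.25 for a flat
#' ring with two equal in-plane eigenvalues.
#'
#' @param positions M x 3 matrix of unwrapped coordinates (M >= 1; all beads
#'   coincident is rejected as shape-undefined).
#' @param box Optional box edges for the wrap check.
#' @return A `gyration_result` list: `Rg`, `eigenvalues` (descending, rc^2)
#'   and `delta`.
#' @export
shape_factor <- function(positions, box = NULL) {
  positions <- rbind(positions)
  check_unwrapped(positions, box)
  centered <- sweep(positions, 2, colMeans(positions))
  S <- crossprod(centered) / nrow(positions)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  tr <- sum(ev)
  if (tr < 1e-24) stop("all beads coincide: shape undefined")
  delta <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[1] * ev[3]) / tr^2
  structure(list(Rg = sqrt(tr), eigenvalues = ev, delta = delta),
            class = "gyration_result")
}

#' @export
print.gyration_result <- function(x, ...) {
  cat(sprintf("Rg = %.4f rc, delta = %.4f (eigenvalues %.4g %.4g %.4g rc^2)\n",
              x$Rg, x$delta, x$eigenvalues[1], x$eigenvalues[2],
              x$eigenvalues[3]))
  invisible(x)
}

#' P2 orientational order parameter
#'
#' Mean second Legendre polynomial `(3 cos^2 theta - 1) / 2` of the angle
#' between each chain vector and the z-axis (the membrane normal): 1 for
#' perfect alignment with z, -0.5 for in-plane chains, 0 for an isotropic
#' distribution. Always between -0.5 and 1.
#'
#' @param vectors K x 3 matrix of chain direction vectors (nonzero rows).
#' @return Scalar order parameter.
#' @export
order_parameter <- function(vectors) {
  vectors <- rbind(vectors)
  n2 <- rowSums(vectors^2)
  if (any(n2 < 1e-24)) stop("zero chain vector")
  cos2 <- vectors[, 3]^2 / n2
  mean((3 * cos2 - 1) / 2)
}

# tail end-to-end vectors and their midpoint x, minimum-imaged within a chain
tail_vectors <- function(system) {
  tp <- system$topology
  if (is.null(tp$tails) || nrow(tp$tails) == 0)
    stop("system has no lipid tails")
  p <- system$state$positions
  L <- system$state$box
  d <- p[tp$tails[, "last"], , drop = FALSE] -
    p[tp$tails[, "first"], , drop = FALSE]
  for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  mid <- (p[tp$tails[, "first"], 1] + 0.5 * d[, 1]) %% L[1]
  list(vectors = d, mid_x = mid)
}

#' x-binned order parameter profile of the membrane
#'
#' Splits the box x-range into bins of width `bin_width`, assigns each lipid
#' tail (end-to-end vector from first to last tail bead) to a bin by its
#' midpoint x, and reports the per-bin P2 average. Empty bins are flagged and
#' carry NA rather than zero.
#'
#' @param system A `dpd_system` containing a bilayer.
#' @param bin_width Bin width along x (rc; must not exceed the box length).
#' @return An `order_profile` tibble: `bin_center`, `p2`, `n_chains`,
#'   `occupied`.
#' @export
order_profile <- function(system, bin_width = 5) {
  Lx <- system$state$box[1]
  if (bin_width <= 0 || bin_width > Lx)
    stop("bin_width must be in (0, Lx]")
  tv <- tail_vectors(system)
  nbin <- max(1L, round(Lx / bin_width))
  edges <- seq(0, Lx, length.out = nbin + 1)
  bin <- pmin(nbin, findInterval(tv$mid_x, edges, rightmost.closed = TRUE))
  p2 <- (3 * tv$vectors[, 3]^2 / rowSums(tv$vectors^2) - 1) / 2
  counts <- tabulate(bin, nbin)
  sums <- vapply(seq_len(nbin), function(b) sum(p2[bin == b]), numeric(1))
  out <- tibble::tibble(
    bin_center = (edges[-1] + edges[-(nbin + 1)]) / 2,
    p2 = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
    n_chains = counts,
    occupied = counts > 0
  )
  class(out) <- c("order_profile", class(out))
  out
}

#' Mean membrane order parameter
#'
#' Mean of the occupied bins of [order_profile()] — the scalar reported in
#' force sweeps.
#'
#' @param system A `dpd_system`.
#' @param bin_width Profile bin width (rc).
#' @return Scalar order parameter.
#' @export
membrane_order <- function(system, bin_width = 5) {
  prof <- order_profile(system, bin_width)
  mean(prof$p2[prof$occupied])
}

#' Brush gyration observables
#'
#' Radius of gyration and shape factor of the whole bottlebrush (all backbone
#' and sidechain beads as one molecule), computed on unwrapped coordinates.
#'
#' @param system A `dpd_system` containing a brush.
#' @return A `gyration_result`.
#' @export
brush_gyration <- function(system) {
  idx <- system$topology$brush
  if (is.null(idx)) stop("system has no brush")
  shape_factor(unwrapped_positions(system)[idx, , drop = FALSE])
}

#' Landmark times of an observable trace
#'
#' Smooths the series with a centered moving average of width
#' `smoothing_window` (time units), then reports T1, the time of the first
#' strict local minimum; T2, the first strict local maximum after T1; and Te,
#' the final time of the series. Monotone traces have no interior landmarks
#' and report T1/T2 as NA.
#'
#' @param time Sample times (tau), strictly increasing and evenly spaced.
#' @param value Observable values at those times.
#' @param smoothing_window Moving-average window in time units.
#' @return A `landmark_times` list: `T1`, `T2`, `Te`.
#' @export
detect_landmarks <- function(time, value, smoothing_window = 5) {
  stopifnot(length(time) == length(value), length(time) >= 3)
  dt <- stats::median(diff(time))
  k <- max(1L, round(smoothing_window / dt))
  if (k %% 2 == 0) k <- k + 1L
  if (length(value) < 3 * k)
    stop("need at least 3x the smoothing window of samples")
  sm <- stats::filter(value, rep(1 / k, k), sides = 2)
  keep <- !is.na(sm)
  sm <- as.numeric(sm[keep])
  tm <- time[keep]
  T1 <- NA_real_; T2 <- NA_real_
  n <- length(sm)
  # strict local extrema at the resolved scale: compare against every sample
  # within half a smoothing window on each side
  h <- max(1L, k %/% 2)
  is_extremum <- function(i, op) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    nb <- sm[setdiff(lo:hi, i)]
    all(op(sm[i], nb))
  }
  i1 <- NULL
  for (i in 2:(n - 1)) {
    if (sm[i] < sm[i - 1] && sm[i] < sm[i + 1] && is_extremum(i, `<`)) {
      T1 <- tm[i]; i1 <- i; break
    }
  }
  if (!is.null(i1) && i1 + 1 < n) {
    for (i in (i1 + 1):(n - 1)) {
      if (sm[i] > sm[i - 1] && sm[i] > sm[i + 1] && is_extremum(i, `>`)) {
        T2 <- tm[i]; break
      }
    }
  }
  structure(list(T1 = T1, T2 = T2, Te = time[length(time)]),
            class = "landmark_times")
}

#' @export
print.landmark_times <- function(x, ...) {
  cat(sprintf("T1 = %s, T2 = %s, Te = %s tau\n",
              format(x$T1), format(x$T2), format(x$Te)))
  invisible(x)
}
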