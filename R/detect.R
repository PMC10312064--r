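# Spot detection and trajectory assembly. Detection is
# Laplacian-of-Gaussian filtering at a scale matched to the expected spot
# radius with subpixel refinement; linking solves the frame-to-frame
# assignment optimally and then closes gaps greedily, mirroring the
# standard quantum-dot tracking workflow (linkage maximum 0.25 µm, gap
# closure maximum 0.5 µm, maximum interframe gap 10 frames).

#' Detection and linking parameters
#'
#' @param pixel_size Pixel size in µm.
#' @param detection_radius Expected spot radius in µm (default 0.25); the
#'   LoG scale is radius / sqrt(2).
#' @param detection_threshold Minimum LoG response at a peak.
#' @param median_prefilter Apply a 3x3 median prefilter (default TRUE).
#' @param quality_threshold Second threshold applied to the peak response
#'   after detection (default 0; the two knobs are separate).
#' @param link_max Maximum frame-to-frame link distance in µm (default 0.25).
#' @param gap_max Maximum gap-closing distance in µm (default 0.5).
#' @param max_frame_gap Maximum number of missed frames a closed gap may
#'   span (default 10).
#' @return A validated list of class `link_config`.
#' @export
link_config <- function(pixel_size, detection_radius = 0.25,
                        detection_threshold = 1, median_prefilter = TRUE,
                        quality_threshold = 0, link_max = 0.25,
                        gap_max = 0.5, max_frame_gap = 10) {
  stopifnot(pixel_size > 0, detection_radius > 0, link_max > 0,
            gap_max > 0, max_frame_gap >= 0)
  if (link_max > gap_max) abort("link_max must not exceed gap_max")
  structure(list(
    pixel_size = pixel_size, detection_radius = detection_radius,
    detection_threshold = detection_threshold,
    median_prefilter = median_prefilter,
    quality_threshold = quality_threshold, link_max = link_max,
    gap_max = gap_max, max_frame_gap = as.integer(max_frame_gap)
  ), class = "link_config")
}

median3x3 <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[ny, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nx, drop = FALSE])
  stack <- vapply(1:3, function(dy) vapply(1:3, function(dx) {
    as.vector(pad[dy:(dy + ny - 1), dx:(dx + nx - 1)])
  }, numeric(ny * nx)), matrix(0, ny * nx, 3))
  dim(stack) <- c(ny * nx, 9)
  matrix(apply(stack, 1, median), ny, nx)
}

log_kernel <- function(sigma_px) {
  h <- max(2L, ceiling(3 * sigma_px))
  g <- expand.grid(y = -h:h, x = -h:h)
  r2 <- g$x^2 + g$y^2
  s2 <- sigma_px^2
  # negative scale-normalized LoG: positive response on bright blobs
  k <- (1 - r2 / (2 * s2)) * exp(-r2 / (2 * s2))
  k <- k - mean(k)                       # zero response on flat images
  matrix(k, 2 * h + 1, 2 * h + 1)
}

#' Detect subpixel spots in an image stack
#'
#' Filters each frame with a Laplacian-of-Gaussian kernel at the scale
#' matching `detection_radius` (optionally after a 3x3 median prefilter),
#' finds strict local maxima of the response above `detection_threshold`,
#' refines each peak by quadratic interpolation of the response in its 3x3
#' neighbourhood, and keeps peaks whose response also passes
#' `quality_threshold`. Empty frames yield no rows.
#'
#' @param stack A list of numeric matrices, or a 3D array (y, x, frame).
#' @param cfg A [link_config()].
#' @return Tibble: frame (0-based), x_um, y_um, intensity (raw image value
#'   at the peak pixel), quality (peak LoG response).
#' @export
detect_spots <- function(stack, cfg) {
  stopifnot(inherits(cfg, "link_config"))
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  if (is.matrix(stack)) stack <- list(stack)
  sigma_px <- cfg$detection_radius / cfg$pixel_size / sqrt(2)
  kern <- log_kernel(sigma_px)
  px <- cfg$pixel_size
  out <- vector("list", length(stack))
  for (f in seq_along(stack)) {
    img <- stack[[f]]
    work <- if (cfg$median_prefilter) median3x3(img) else img
    resp <- EBImage::filter2(work, kern, boundary = "replicate")
    pk <- local_maxima(resp, cfg$detection_threshold)
    if (nrow(pk) == 0) next
    keep_i <- suppress_close_peaks(pk, resp[pk])
    pk <- pk[keep_i, , drop = FALSE]
    qual <- resp[pk]
    keep <- qual >= cfg$quality_threshold
    pk <- pk[keep, , drop = FALSE]; qual <- qual[keep]
    if (nrow(pk) == 0) next
    sub <- function(ri, ci, axis) {
      if (axis == "r") {
        fm <- resp[cbind(ri - 1, ci)]; f0 <- resp[cbind(ri, ci)]
        fp <- resp[cbind(ri + 1, ci)]
      } else {
        fm <- resp[cbind(ri, ci - 1)]; f0 <- resp[cbind(ri, ci)]
        fp <- resp[cbind(ri, ci + 1)]
      }
      # parabola on log response where positive (exact for Gaussian peaks),
      # plain quadratic otherwise
      uselog <- fm > 0 & f0 > 0 & fp > 0
      lm_ <- ifelse(uselog, log(fm), fm)
      l0 <- ifelse(uselog, log(f0), f0)
      lp <- ifelse(uselog, log(fp), fp)
      den <- lm_ - 2 * l0 + lp
      off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (lm_ - lp) / den, 0)
      pmin(pmax(off, -0.5), 0.5)
    }
    dr <- sub(pk[, 1], pk[, 2], "r")
    dc <- sub(pk[, 1], pk[, 2], "c")
    out[[f]] <- tibble::tibble(
      frame = f - 1L,
      x_um = (pk[, 2] - 0.5 + dc) * px,
      y_um = (pk[, 1] - 0.5 + dr) * px,
      intensity = img[pk], quality = qual
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), x_um = double(),
                          y_um = double(), intensity = double(),
                          quality = double())
  }
  res
}

# Optimal square assignment (Jonker-Volgenant shortest augmenting paths).
# Returns, for each row, the assigned column. Forbidden entries should be a
# large finite cost, never Inf.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0) return(integer(0))
  u <- numeric(n); v <- numeric(n)
  p <- integer(n)                       # p[j] = row assigned to column j
  for (i in seq_len(n)) {
    minv <- rep(Inf, n); way <- integer(n)
    used <- rep(FALSE, n)
    j0 <- 0L
    repeat {
      i0 <- if (j0 == 0L) i else p[j0]
      rc <- cost[i0, ] - u[i0] - v
      upd <- !used & rc < minv
      minv[upd] <- rc[upd]; way[upd] <- j0
      free <- which(!used)
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedc <- which(used)
      rows_in_tree <- c(i, p[usedc])
      u[rows_in_tree] <- u[rows_in_tree] + delta
      v[usedc] <- v[usedc] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      used[j0] <- TRUE
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == 0L) i else p[j1]
      if (j1 == 0L) break
      j0 <- j1
    }
  }
  assign <- integer(n)
  assign[p] <- seq_len(n)
  assign
}

# Optimal frame-to-frame matching of two point sets. Costs are squared
# displacements; links beyond link_max are forbidden; every point may stay
# unmatched (track death/birth) at the standard alternative cost of
# 1.05 * link_max^2. Returns an integer vector: for each point in set 1 the
# matched index in set 2, or NA.
match_points <- function(x1, y1, x2, y2, link_max) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  b <- 1.05 * link_max^2
  big <- max(b, 1) * 1e8
  cmat <- d2
  cmat[d2 > link_max^2] <- big
  m <- n1 + n2
  full <- matrix(big, m, m)
  full[seq_len(n1), seq_len(n2)] <- cmat
  full[cbind(seq_len(n1), n2 + seq_len(n1))] <- b
  full[cbind(n1 + seq_len(n2), seq_len(n2))] <- b
  full[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  a <- lap_solve(full)
  link <- a[seq_len(n1)]
  link[link > n2] <- NA_integer_
  link[!is.na(link) & d2[cbind(seq_len(n1), ifelse(is.na(link), 1L, link))] >
         link_max^2] <- NA_integer_
  link
}

#' Assemble localizations into trajectories
#'
#' Links detections in consecutive frames by minimum-total-cost assignment
#' (cost = squared displacement, links beyond `link_max` forbidden), then
#' closes gaps: a track end is joined to a later track start when the
#' number of missed frames is at most `max_frame_gap` and the distance at
#' most `gap_max`, greedily in ascending cost with ties broken by earlier
#' end frame then lower track id. Tracks with a single localization are
#' discarded.
#'
#' @param localizations Tibble with frame, x_um, y_um (plus optional
#'   intensity/quality columns, carried through).
#' @param cfg A [link_config()].
#' @param frame_interval Frame interval in s used to fill `t_s` (default
#'   0.05).
#' @return Trajectory tibble: track_id, frame, t_s, x_um, y_um (+ carried
#'   columns).
#' @export
link_trajectories <- function(localizations, cfg, frame_interval = 0.05) {
  stopifnot(inherits(cfg, "link_config"))
  loc <- dplyr::arrange(tibble::as_tibble(localizations), .data$frame)
  if (nrow(loc) == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = double(), x_um = double(), y_um = double()))
  }
  loc$.row <- seq_len(nrow(loc))
  by_frame <- split(loc, loc$frame)
  frames <- as.integer(names(by_frame))

  tracks <- list()                       # each: list(rows, last_frame, x, y)
  open_idx <- integer(0)                 # tracks whose end is at frame f-1
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- by_frame[[fi]]
    ends <- open_idx[vapply(tracks[open_idx], function(t) t$last_frame,
                            integer(1)) == f - 1L]
    link <- if (length(ends)) {
      ex <- vapply(tracks[ends], function(t) t$x, numeric(1))
      ey <- vapply(tracks[ends], function(t) t$y, numeric(1))
      match_points(ex, ey, cur$x_um, cur$y_um, cfg$link_max)
    } else integer(0)
    taken <- rep(FALSE, nrow(cur))
    for (k in seq_along(ends)) {
      j <- link[k]
      if (!is.na(j)) {
        id <- ends[k]
        tracks[[id]]$rows <- c(tracks[[id]]$rows, cur$.row[j])
        tracks[[id]]$last_frame <- f
        tracks[[id]]$x <- cur$x_um[j]; tracks[[id]]$y <- cur$y_um[j]
        taken[j] <- TRUE
      }
    }
    for (j in which(!taken)) {
      tracks[[length(tracks) + 1L]] <- list(rows = cur$.row[j],
                                            last_frame = f,
                                            x = cur$x_um[j], y = cur$y_um[j])
    }
    open_idx <- seq_along(tracks)
  }

  # gap closing over track segments
  seg_first <- vapply(tracks, function(t) loc$frame[t$rows[1]], integer(1))
  seg_last <- vapply(tracks, function(t) t$last_frame, integer(1))
  fx <- vapply(tracks, function(t) loc$x_um[t$rows[1]], numeric(1))
  fy <- vapply(tracks, function(t) loc$y_um[t$rows[1]], numeric(1))
  lx <- vapply(tracks, function(t) t$x, numeric(1))
  ly <- vapply(tracks, function(t) t$y, numeric(1))
  nseg <- length(tracks)
  cand <- NULL
  if (nseg > 1 && cfg$max_frame_gap >= 1) {
    pairs <- expand.grid(a = seq_len(nseg), b = seq_len(nseg))
    gap <- seg_first[pairs$b] - seg_last[pairs$a] - 1L
    d2 <- (fx[pairs$b] - lx[pairs$a])^2 + (fy[pairs$b] - ly[pairs$a])^2
    ok <- pairs$a != pairs$b & gap >= 1 & gap <= cfg$max_frame_gap &
      d2 <= cfg$gap_max^2
    cand <- data.frame(a = pairs$a[ok], b = pairs$b[ok], cost = d2[ok],
                       end_frame = seg_last[pairs$a[ok]])
    cand <- cand[order(cand$cost, cand$end_frame, cand$a), , drop = FALSE]
  }
  succ <- rep(NA_integer_, nseg)
  has_pred <- rep(FALSE, nseg)
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      a <- cand$a[r]; b <- cand$b[r]
      if (is.na(succ[a]) && !has_pred[b]) {
        succ[a] <- b
        has_pred[b] <- TRUE
      }
    }
  }
  heads <- which(!has_pred)
  out <- vector("list", length(heads))
  tid <- 0L
  for (h in heads) {
    rows <- integer(0)
    k <- h
    while (!is.na(k)) {
      rows <- c(rows, tracks[[k]]$rows)
      k <- succ[k]
    }
    if (length(rows) < 2) next
    tid <- tid + 1L
    d <- loc[rows, , drop = FALSE]
    d$track_id <- tid
    out[[tid]] <- d
  }
  out <- out[seq_len(tid)]
  if (tid == 0L) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = double(), x_um = double(), y_um = double()))
  }
  res <- dplyr::bind_rows(out)
  res$t_s <- res$frame * frame_interval
  res$.row <- NULL
  extra <- setdiff(names(res), .traj_cols)
  dplyr::arrange(res[, c(.traj_cols, extra)], .data$track_id, .data$frame)
}
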