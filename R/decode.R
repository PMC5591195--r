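# Decoder: spot detection, bead-based channel mapping, sliding-window
# trace extraction, overlap filtering.

#' Detect single-molecule spots in one image
#'
#' Local maxima (8-neighbourhood) above an intensity threshold, refined to
#' sub-pixel centres by a 2-D Gaussian fit on a small window around each
#' peak. Peaks closer than `min_separation_px` to one another are both
#' discarded (ambiguous photometry).
#'
#' @param image A 2-D numeric matrix (conventional channel, or the average
#'   of unswept lead frames). Must be non-empty with finite pixels.
#' @param min_separation_px Minimum allowed centre-to-centre distance
#'   (default 5 px).
#' @param threshold Absolute intensity a local maximum must exceed;
#'   `NULL` (default) uses `median(image) + 5 * mad(image)`.
#' @param fit_radius Half-size of the Gaussian fit window (default 3,
#'   i.e. a 7 x 7 window).
#' @return A data frame of class `spot_peaks` with columns `x`, `y`
#'   (sub-pixel centre, 1-based column/row), `sigma`, `fwhm_px`,
#'   `peak_value`, `peak_frame`.
#' @export
detect_spots <- function(image, min_separation_px = 5, threshold = NULL,
                         fit_radius = 3) {
  if (!is.matrix(image) || length(image) == 0)
    invalid_arg("`image` must be a non-empty matrix")
  if (!all(is.finite(image)))
    invalid_arg("`image` contains non-finite pixels")
  if (is.null(threshold))
    threshold <- stats::median(image) + 5 * stats::mad(image)

  H <- nrow(image); W <- ncol(image)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- image
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  is_max <- ctr > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    is_max <- is_max & (ctr >= nb) & !(ctr == nb & (dy < 0 | (dy == 0 & dx < 0)))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(.spot_peaks(data.frame(x = numeric(0), y = numeric(0),
                                  sigma = numeric(0), fwhm_px = numeric(0),
                                  peak_value = numeric(0),
                                  peak_frame = integer(0))))

  refine <- function(r, c) {
    rr <- max(1, r - fit_radius):min(H, r + fit_radius)
    cc <- max(1, c - fit_radius):min(W, c + fit_radius)
    z <- image[rr, cc]
    df <- data.frame(z = as.vector(z),
                     x = rep(cc, each = length(rr)),
                     y = rep(rr, times = length(cc)))
    b0 <- min(df$z); a0 <- image[r, c] - b0
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ b + a * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)), data = df,
        start = list(b = b0, a = a0, x0 = c, y0 = r, s = 1.1),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      if (abs(p[["x0"]] - c) <= 2 && abs(p[["y0"]] - r) <= 2 && p[["s"]] > 0)
        return(c(p[["x0"]], p[["y0"]], abs(p[["s"]])))
    }
    # fallback: background-subtracted centroid
    zb <- pmax(z - b0, 0)
    tot <- sum(zb)
    if (tot <= 0) return(c(c, r, NA_real_))
    c(sum(rep(cc, each = length(rr)) * zb) / tot,
      sum(rep(rr, times = length(cc)) * zb) / tot, NA_real_)
  }

  ref <- t(apply(unname(idx), 1, function(rc) refine(rc[1], rc[2])))
  peaks <- data.frame(x = ref[, 1], y = ref[, 2], sigma = ref[, 3],
                      fwhm_px = ref[, 3] * (2 * sqrt(2 * log(2))),
                      peak_value = image[idx],
                      peak_frame = 1L)

  if (nrow(peaks) > 1) {
    d <- as.matrix(stats::dist(peaks[, c("x", "y")]))
    diag(d) <- Inf
    keep <- apply(d, 1, min) >= min_separation_px
    peaks <- peaks[keep, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  .spot_peaks(peaks)
}

.spot_peaks <- function(df) {
  class(df) <- c("spot_peaks", "data.frame")
  df
}

#' Fit the affine map between the two chip channels
#'
#' Matches left-channel bead peaks to right-channel peaks (nearest neighbour
#' after removing a coarse offset estimated from the modal pairwise
#' displacement) and fits the least-squares affine transform
#' `right = A %*% left + b`.
#'
#' @param left_peaks,right_peaks `spot_peaks` data frames (>= 3 matched
#'   pairs required). Coordinates may be channel-local or absolute, as long
#'   as both are consistent.
#' @param max_match_px Nearest-neighbour acceptance radius after the coarse
#'   offset (default 2 px); unmatched peaks are dropped with a message.
#' @param coarse_offset Optional numeric `c(dx, dy)` overriding the modal
#'   estimate.
#' @return An object of class `channel_map`: linear part `A` (2 x 2),
#'   offset `b`, `residual_rms` (px), `n_pairs`.
#' @export
fit_channel_map <- function(left_peaks, right_peaks, max_match_px = 2,
                            coarse_offset = NULL) {
  if (nrow(left_peaks) < 3 || nrow(right_peaks) < 3)
    insufficient_data("at least 3 bead peaks per channel are required")
  lx <- left_peaks$x; ly <- left_peaks$y
  rx <- right_peaks$x; ry <- right_peaks$y

  if (is.null(coarse_offset)) {
    dx <- outer(rx, lx, "-"); dy <- outer(ry, ly, "-")
    bin <- paste(round(dx / 4), round(dy / 4))
    mode_bin <- names(which.max(table(bin)))
    sel <- bin == mode_bin
    coarse_offset <- c(stats::median(dx[sel]), stats::median(dy[sel]))
  }

  # nearest right peak for each left peak after the coarse shift
  px <- lx + coarse_offset[1]; py <- ly + coarse_offset[2]
  d2 <- outer(px, rx, "-")^2 + outer(py, ry, "-")^2
  j <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_along(j), j)])
  ok <- dist <= max_match_px & !duplicated(j)
  if (sum(!ok) > 0)
    message(sprintf("fit_channel_map: dropped %d unmatched peak(s)", sum(!ok)))
  if (sum(ok) < 3)
    insufficient_data("fewer than 3 matched bead pairs after matching")

  XL <- cbind(lx[ok], ly[ok])
  XR <- cbind(rx[j[ok]], ry[j[ok]])
  fit <- stats::lm(XR ~ XL)
  cf <- stats::coef(fit)             # 3 x 2: intercepts then the two slopes
  A <- unname(t(cf[2:3, , drop = FALSE]))  # 2 x 2 linear part
  b <- as.numeric(cf[1, ])
  res <- XR - (XL %*% t(A) + matrix(b, nrow(XL), 2, byrow = TRUE))
  structure(list(A = A, b = b,
                 residual_rms = sqrt(mean(rowSums(res^2))),
                 n_pairs = sum(ok)),
            class = "channel_map")
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("<channel_map> %d pairs, residual RMS %.4g px\n", x$n_pairs,
              x$residual_rms))
  cat(sprintf("  A = [%.4f %.4f; %.4f %.4f], b = (%.3f, %.3f)\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$b[1], x$b[2]))
  invisible(x)
}

#' Apply a channel map to peak coordinates
#'
#' @param map A [fit_channel_map()] result, or `NULL` for identity.
#' @param peaks A `spot_peaks` data frame (or any data frame with `x`, `y`).
#' @param offset Additional translation `c(dx, dy)` applied after the map
#'   (e.g. the channel column offset when the map was fitted in
#'   channel-local coordinates).
#' @return The peaks with transformed `x`, `y`.
#' @export
apply_channel_map <- function(map, peaks, offset = c(0, 0)) {
  xy <- cbind(peaks$x, peaks$y)
  if (!is.null(map)) {
    stopifnot(inherits(map, "channel_map"))
    xy <- xy %*% t(map$A) + matrix(map$b, nrow(xy), 2, byrow = TRUE)
  }
  peaks$x <- xy[, 1] + offset[1]
  peaks$y <- xy[, 2] + offset[2]
  peaks
}

#' Identity channel map with a pure translation
#'
#' @param dx,dy Translation (px).
#' @return A `channel_map`.
#' @export
translation_map <- function(dx, dy = 0) {
  structure(list(A = diag(2), b = c(dx, dy), residual_rms = 0,
                 n_pairs = 0L),
            class = "channel_map")
}

#' Extract a sub-frame-resolution intensity trace for one molecule
#'
#' For every frame, sums the pixels of `box_px` x `box_px` windows centred
#' (at the rounded peak centre) at `x + (s - 1) * slide_px`,
#' `s = 1..n_steps`, and concatenates the sums in frame order then substep
#' order, yielding `n_frames * n_steps` samples spaced `exposure_ms /
#' n_steps` apart. Background is estimated from the 1-px-wide rows of
#' pixels directly above and below each window (the columns flanking a
#' window sit between adjacent swept spots and are contaminated by their
#' tails, so only the vertical neighbours are used), pooled over all window
#' positions and frames: `I_B` is the mean background pixel scaled to the
#' window area and `sigma_B` the background pixel SD scaled by `box_px`
#' (independent-pixel approximation); the returned `values` are background
#' subtracted.
#'
#' @param stack A [frame_stack()] whose frames are all swept.
#' @param peak A one-row `spot_peaks` data frame (or list with `x`, `y`) in
#'   absolute frame coordinates of the swept channel.
#' @param config A [sweep_config()].
#' @param box_px Odd window size (default 7).
#' @param slide_px Horizontal window displacement per substep; default
#'   `round(spot_spacing_px(config))`. The historical 6-px slide used with
#'   a 7-px spacing can be reproduced by passing `slide_px = 6`.
#' @param unmix Compensate neighbour-spot crosstalk (default `TRUE`).
#'   Adjacent swept spots sit ~2 FWHM apart, so each window captures a
#'   known ~1% of its neighbours' mass; the within-frame window sums are
#'   `w = Q v` with `Q[s, s'] = ` the PSF mass a spot at window `s'`
#'   deposits into window `s` (error-function products from the fitted
#'   FWHM). Solving for `v` removes the crosstalk and simultaneously
#'   compensates the PSF truncation loss of the finite window.
#' @param fwhm_px PSF FWHM used to build the crosstalk matrix when the
#'   peak does not carry a fitted value (default 2.56).
#' @return An object of class `spot_trace`: `values`
#'   (background-subtracted, crosstalk-compensated when `unmix`), `raw`,
#'   `i_b`, `sigma_b`, `substep_ms`, `n_steps`, `n_frames`, `box_px`,
#'   `slide_px`, `peak`.
#' @export
extract_trace <- function(stack, peak, config, box_px = 7, slide_px = NULL,
                          unmix = TRUE, fwhm_px = 2.56) {
  stopifnot(inherits(stack, "frame_stack"), inherits(config, "sweep_config"))
  .check_scalar(box_px, "box_px", min = 1, integerish = TRUE)
  if (box_px %% 2 == 0) invalid_arg("`box_px` must be odd")
  if (is.null(slide_px)) slide_px <- round(spot_spacing_px(config))
  .check_scalar(slide_px, "slide_px", min = 0)

  N <- config$n_steps
  r <- (box_px - 1) / 2
  cx <- round(peak$x[1]); cy <- round(peak$y[1])
  d <- dim(stack$frames[[1]])
  xs <- cx + (seq_len(N) - 1) * slide_px
  if (cy - r - 1 < 1 || cy + r + 1 > d[1] ||
        min(xs) - r - 1 < 1 || max(xs) + r + 1 > d[2])
    invalid_arg(sprintf(
      "extraction window for peak (%g, %g) leaves the image (frame %d x %d px)",
      peak$x[1], peak$y[1], d[1], d[2]))

  rows <- (cy - r):(cy + r)
  bg_rows <- c(cy - r - 1, cy + r + 1)
  nf <- length(stack$frames)

  # column weights: when the slide is smaller than the box, adjacent
  # windows share `box - slide` boundary columns; each window takes half
  # of a shared column so no pixel (and no shot noise) is counted twice
  wx <- rep(1, box_px)
  ov <- max(0, box_px - slide_px)
  if (N > 1 && ov > 0 && ov < box_px) {
    wx[seq_len(ov)] <- 0.5
    wx[box_px + 1 - seq_len(ov)] <- 0.5
  }

  raw <- matrix(0, nf, N)
  ring_sum <- 0; ring_sum2 <- 0; ring_n <- 0
  for (f in seq_len(nf)) {
    fr <- stack$frames[[f]]
    for (s in seq_len(N)) {
      cols <- (xs[s] - r):(xs[s] + r)
      raw[f, s] <- sum(colSums(fr[rows, cols]) * wx)
      rv <- fr[bg_rows, (xs[s] - r - 1):(xs[s] + r + 1)]
      ring_sum <- ring_sum + sum(rv)
      ring_sum2 <- ring_sum2 + sum(rv^2)
      ring_n <- ring_n + length(rv)
    }
  }
  m_px <- ring_sum / ring_n
  var_px <- max(ring_sum2 / ring_n - m_px^2, 0)
  i_b <- box_px * sum(wx) * m_px
  sigma_b <- sqrt(box_px * sum(wx^2)) * sqrt(var_px)

  vals <- raw - i_b
  if (unmix && N >= 1) {
    fw <- peak$fwhm_px[1]
    if (is.null(fw) || !is.finite(fw) || fw <= 0) fw <- fwhm_px
    Q <- .crosstalk_matrix(N, slide_px, fw / (2 * sqrt(2 * log(2))), r, wx)
    Qinv <- solve(Q)
    vals <- vals %*% t(Qinv)
    sigma_b <- sigma_b * mean(rowSums(Qinv))
  }

  structure(list(values = as.vector(t(vals)),  # f1 s1..sN, f2 s1..sN, ...
                 raw = as.vector(t(raw)), i_b = i_b,
                 sigma_b = sigma_b, substep_ms = substep_ms(config),
                 n_steps = N, n_frames = nf, box_px = box_px,
                 slide_px = slide_px,
                 peak = data.frame(x = peak$x[1], y = peak$y[1])),
            class = "spot_trace")
}

# Q[s, s']: PSF mass a unit spot centred at window s' deposits into the
# (column-weighted) box at window s: windows slide_px apart, half-width r,
# Gaussian sigma, column weights wx over the box columns
.crosstalk_matrix <- function(N, slide_px, sigma, r, wx = rep(1, 2 * r + 1)) {
  # weighted x-mass of a unit Gaussian centred at offset d from the window
  offs <- seq.int(-r, r)
  mass_x <- function(d)
    sum(wx * (stats::pnorm((offs + 0.5 - d) / sigma) -
                stats::pnorm((offs - 0.5 - d) / sigma)))
  my <- 2 * stats::pnorm((r + 0.5) / sigma) - 1
  d <- outer(seq_len(N), seq_len(N), function(a, b) (b - a) * slide_px)
  matrix(vapply(as.vector(d), mass_x, numeric(1)), N, N) * my
}

#' @export
print.spot_trace <- function(x, ...) {
  cat(sprintf("<spot_trace> %d samples (%d frames x %d substeps of %g ms)\n",
              length(x$values), x$n_frames, x$n_steps, x$substep_ms))
  cat(sprintf("  I_B = %.4g, sigma_B = %.4g per %dx%d window\n", x$i_b,
              x$sigma_b, x$box_px, x$box_px))
  invisible(x)
}

#' Time axis of a trace (ms)
#'
#' Sample midpoints on the camera clock, accounting for the inter-frame lag.
#'
#' @param trace A [extract_trace()] result.
#' @param frame_lag_ms Inter-frame dead time (default 0; pass the sweep
#'   config's value for absolute experiment time).
#' @return Numeric vector of sample times (ms).
#' @export
trace_times_ms <- function(trace, frame_lag_ms = 0) {
  N <- trace$n_steps
  period <- N * trace$substep_ms + frame_lag_ms
  f <- rep(seq_len(trace$n_frames) - 1, each = N)
  s <- rep(seq_len(N) - 1, times = trace$n_frames)
  f * period + (s + 0.5) * trace$substep_ms
}

#' Average a trace back to whole-frame resolution
#'
#' Block-averages `n` consecutive samples, emulating a conventional camera
#' at `n`-fold lower temporal resolution. The background SD is scaled by
#' `1/sqrt(n)` (independent samples).
#'
#' @param trace A `spot_trace`.
#' @param n Block size; default the trace's `n_steps` (back to 1 frame).
#' @return A `spot_trace` with `length(values)/n` samples.
#' @export
block_average_trace <- function(trace, n = trace$n_steps) {
  .check_scalar(n, "n", min = 1, integerish = TRUE)
  nv <- length(trace$values)
  nb <- floor(nv / n)
  avg <- function(v) colMeans(matrix(v[seq_len(nb * n)], nrow = n))
  out <- trace
  out$values <- avg(trace$values)
  out$raw <- avg(trace$raw)
  out$sigma_b <- trace$sigma_b / sqrt(n)
  out$substep_ms <- trace$substep_ms * n
  out$n_steps <- max(1L, trace$n_steps %/% n)
  out$n_frames <- nb %/% max(1L, trace$n_steps %/% n)
  out
}

#' Drop molecules whose swept footprints overlap
#'
#' Each molecule's footprint is the rectangle swept by its extraction
#' window: `box_px` tall, `sweep_length + box_px` wide, anchored at the
#' peak. Any peak whose footprint intersects another's is removed (both
#' members of an overlapping pair are dropped).
#'
#' @param peaks A `spot_peaks` data frame in swept-channel coordinates.
#' @param config A [sweep_config()].
#' @param box_px Extraction window size (default 7).
#' @return The surviving subset of `peaks`.
#' @export
filter_overlaps <- function(peaks, config, box_px = 7) {
  stopifnot(inherits(config, "sweep_config"))
  n <- nrow(peaks)
  if (n <= 1) return(peaks)
  r <- (box_px - 1) / 2
  L <- sweep_length_px(config)
  x1 <- peaks$x - r; x2 <- peaks$x + L + r
  y1 <- peaks$y - r; y2 <- peaks$y + r
  ox <- outer(x1, x2, "<=") & outer(x2, x1, ">=")
  oy <- outer(y1, y2, "<=") & outer(y2, y1, ">=")
  ov <- ox & oy
  diag(ov) <- FALSE
  peaks[rowSums(ov) == 0, , drop = FALSE]
}

#' Decode a swept stack into per-molecule traces
#'
#' The standard pipeline for blinking/binding movies: detect molecules on
#' the conventional channel (average image), map them into the swept
#' channel, drop molecules whose swept footprints overlap or leave the
#' channel, and extract a sliding-window trace for each survivor.
#'
#' @param stack A [frame_stack()] with `"conventional"` and `"swept"`
#'   channels (layout and sweep config read from the stack unless given).
#' @param config Sweep configuration (default `stack$sweep`).
#' @param map A [fit_channel_map()] result mapping conventional-channel
#'   coordinates to swept-channel coordinates, both channel-local; default
#'   identity (aligned channels).
#' @param box_px,slide_px Passed to [extract_trace()].
#' @param detect_args List of extra arguments for [detect_spots()].
#' @return A list with `traces` (list of `spot_trace`), `peaks` (the
#'   retained swept-channel peaks, absolute coordinates) and
#'   `n_detected`/`n_retained`.
#' @export
decode_stack <- function(stack, config = stack$sweep, map = NULL,
                         box_px = 7, slide_px = NULL, detect_args = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(config)) invalid_arg("no sweep configuration available")
  layout <- stack$layout
  if (is.null(layout) || !all(c("conventional", "swept") %in% layout$channels))
    invalid_arg("stack layout must have conventional and swept channels")

  conv <- channel_image(average_frames(stack), layout, "conventional")
  peaks <- do.call(detect_spots, c(list(conv), detect_args))
  n_det <- nrow(peaks)
  if (n_det == 0)
    return(list(traces = list(), peaks = peaks, n_detected = 0L,
                n_retained = 0L))

  swept_local <- apply_channel_map(map, peaks)
  keep <- .swept_window_fits(swept_local, config, layout, box_px, slide_px)
  swept_local <- swept_local[keep, , drop = FALSE]
  swept_local <- filter_overlaps(swept_local, config, box_px)

  off <- channel_offset(stack$layout, "swept")
  swept_abs <- swept_local
  swept_abs$x <- swept_abs$x + off
  traces <- lapply(seq_len(nrow(swept_abs)), function(i)
    extract_trace(stack, swept_abs[i, ], config, box_px, slide_px))
  list(traces = traces, peaks = swept_abs, n_detected = n_det,
       n_retained = nrow(swept_abs))
}

.swept_window_fits <- function(peaks, config, layout, box_px, slide_px) {
  if (is.null(slide_px)) slide_px <- round(spot_spacing_px(config))
  r <- (box_px - 1) / 2
  reach <- (config$n_steps - 1) * slide_px
  round(peaks$x) - r - 1 >= 1 &
    round(peaks$x) + reach + r + 1 <= layout$width_px &
    round(peaks$y) - r - 1 >= 1 &
    round(peaks$y) + r + 1 <= layout$height_px
}

#' Decode a FRET stack into donor/acceptor trace pairs
#'
#' Molecules are detected on the average of the unswept lead frames in the
#' donor channel, mapped to the acceptor channel, filtered for footprint
#' overlap in both channels, and traces extracted from the swept frames
#' only.
#'
#' @param stack A [frame_stack()] from [render_fret_stack()] (or real data
#'   with the same layout); `stack$meta$n_unswept_lead_frames` must be set.
#' @param config Sweep configuration (default `stack$sweep`).
#' @param map Donor-to-acceptor [fit_channel_map()] in channel-local
#'   coordinates; default identity.
#' @param box_px,slide_px Passed to [extract_trace()].
#' @param detect_args Extra arguments for [detect_spots()].
#' @return A list with `donor` and `acceptor` trace lists (index-matched),
#'   `peaks`, and counts.
#' @export
decode_fret_stack <- function(stack, config = stack$sweep, map = NULL,
                              box_px = 7, slide_px = NULL,
                              detect_args = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  layout <- stack$layout
  if (is.null(layout) || !all(c("donor", "acceptor") %in% layout$channels))
    invalid_arg("stack layout must have donor and acceptor channels")
  n_lead <- stack$meta$n_unswept_lead_frames
  if (is.null(n_lead) || n_lead < 1)
    invalid_arg("stack has no unswept lead frames for molecule selection")

  lead_img <- channel_image(average_frames(stack, seq_len(n_lead)), layout,
                            "donor")
  peaks <- do.call(detect_spots, c(list(lead_img), detect_args))
  n_det <- nrow(peaks)
  swept <- stack_frames(stack, (n_lead + 1):n_frames(stack))
  if (n_det == 0)
    return(list(donor = list(), acceptor = list(), peaks = peaks,
                n_detected = 0L, n_retained = 0L))

  acc_local <- apply_channel_map(map, peaks)
  keep <- .swept_window_fits(peaks, config, layout, box_px, slide_px) &
    .swept_window_fits(acc_local, config, layout, box_px, slide_px)
  peaks <- peaks[keep, , drop = FALSE]
  acc_local <- acc_local[keep, , drop = FALSE]
  surv <- filter_overlaps(peaks, config, box_px)
  sel <- match(interaction(surv$x, surv$y), interaction(peaks$x, peaks$y))
  peaks <- peaks[sel, , drop = FALSE]
  acc_local <- acc_local[sel, , drop = FALSE]

  off_d <- channel_offset(layout, "donor")
  off_a <- channel_offset(layout, "acceptor")
  donor_tr <- lapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]; p$x <- p$x + off_d
    extract_trace(swept, p, config, box_px, slide_px)
  })
  acc_tr <- lapply(seq_len(nrow(peaks)), function(i) {
    p <- acc_local[i, ]; p$x <- p$x + off_a
    extract_trace(swept, p, config, box_px, slide_px)
  })
  list(donor = donor_tr, acceptor = acc_tr, peaks = peaks,
       n_detected = n_det, n_retained = nrow(peaks))
}
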