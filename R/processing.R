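## Vectorized RGB <-> HSV on H x W x 3 arrays in [0, 1]. The value channel
## (V = max of R,G,B) is the one all low-level corrections operate on.

#' @rdname hsv_conversion
#' @export
rgb_to_hsv_array <- function(arr) {
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] == 3)
  r <- arr[, , 1]; g <- arr[, , 2]; b <- arr[, , 3]
  v <- pmax(r, g, b)
  m <- pmin(r, g, b)
  c <- v - m
  s <- ifelse(v > 0, c / v, 0)
  h <- matrix(0, nrow(r), ncol(r))
  nz <- c > 0
  hr <- nz & v == r
  hg <- nz & v == g & !hr
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / c[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / c[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / c[hb] + 4
  out <- array(0, dim(arr))
  out[, , 1] <- h / 6; out[, , 2] <- s; out[, , 3] <- v
  out
}

#' RGB/HSV conversion for image arrays
#'
#' @param arr An H x W x 3 array; RGB channels in \code{[0, 1]} for
#'   \code{rgb_to_hsv_array}, HSV (hue in \code{[0, 1)}) for
#'   \code{hsv_to_rgb_array}. Values V outside \code{[0, 1]} are tolerated
#'   (intermediate states of the equalization pipeline).
#' @return The converted H x W x 3 array.
#' @name hsv_conversion
#' @export
hsv_to_rgb_array <- function(arr) {
  stopifnot(length(dim(arr)) == 3, dim(arr)[3] == 3)
  h <- arr[, , 1] * 6; s <- arr[, , 2]; v <- arr[, , 3]
  c <- v * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- v - c
  hi <- floor(h) %% 6
  r <- ifelse(hi == 0 | hi == 5, c, ifelse(hi == 1 | hi == 4, x, 0))
  g <- ifelse(hi == 0 | hi == 3, x, ifelse(hi == 1 | hi == 2, c, 0))
  b <- ifelse(hi == 2 | hi == 5, x, ifelse(hi == 3 | hi == 4, c, 0))
  out <- array(0, dim(arr))
  out[, , 1] <- r + m; out[, , 2] <- g + m; out[, , 3] <- b + m
  out
}

#' Bundle frames and foreground masks into a frame stack
#'
#' @param frames List of H x W x 3 RGB arrays in \code{[0, 1]} (a single
#'   array is wrapped).
#' @param masks List of H x W logical matrices marking the subject
#'   (foreground); background is the complement.
#' @return Class \code{"frame_stack"}.
#' @export
frame_stack <- function(frames, masks) {
  if (is.array(frames)) frames <- list(frames)
  if (is.matrix(masks)) masks <- list(masks)
  if (length(frames) != length(masks)) stop("frames and masks differ in length")
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d)) stop("all frames must share a shape")
    if (!identical(dim(masks[[i]]), d[1:2])) stop("mask ", i, " misaligned to frames")
  }
  structure(list(frames = frames, masks = masks), class = "frame_stack")
}

.as_stack_list <- function(x) {
  if (inherits(x, "frame_stack")) list(x) else x
}

#' Average subject and background luminance over pigeon stacks
#'
#' Pools the HSV value channel over every frame of every supplied stack and
#' returns the mean within the foreground (subject) masks and within the
#' background, the two targets later imposed on the control stacks.
#'
#' @param pigeon_stacks A [frame_stack()] or list of them.
#' @return Named numeric \code{c(fg_mean, bg_mean)}.
#' @export
compute_target_luminance <- function(pigeon_stacks) {
  stacks <- .as_stack_list(pigeon_stacks)
  if (!length(stacks)) stop("no stacks supplied")
  fg_sum <- bg_sum <- 0; fg_n <- bg_n <- 0
  for (st in stacks) for (i in seq_along(st$frames)) {
    v <- rgb_to_hsv_array(st$frames[[i]])[, , 3]
    mk <- st$masks[[i]]
    fg_sum <- fg_sum + sum(v[mk]); fg_n <- fg_n + sum(mk)
    bg_sum <- bg_sum + sum(v[!mk]); bg_n <- bg_n + sum(!mk)
  }
  if (fg_n == 0 || bg_n == 0) stop("empty foreground or background region")
  c(fg_mean = fg_sum / fg_n, bg_mean = bg_sum / bg_n)
}

#' Match region-wise mean luminance by additive shift
#'
#' Per frame, shifts the HSV value channel additively inside the foreground
#' mask and inside the background so the region means equal the targets
#' exactly, then clips to \code{[0, 1]} (clipping can move the realized mean
#' back off-target for near-saturated frames). Hue and saturation are
#' untouched. The operation is idempotent absent clipping.
#'
#' @param stack A [frame_stack()].
#' @param fg_mean,bg_mean Target means in \code{[0, 1]} (e.g. from
#'   [compute_target_luminance()]).
#' @return The adjusted [frame_stack()].
#' @export
luminance_match <- function(stack, fg_mean, bg_mean) {
  stopifnot(inherits(stack, "frame_stack"))
  if (fg_mean < 0 || fg_mean > 1 || bg_mean < 0 || bg_mean > 1)
    stop("targets must lie in [0, 1]")
  frames <- stack$frames
  for (i in seq_along(frames)) {
    hsv <- rgb_to_hsv_array(frames[[i]])
    v <- hsv[, , 3]
    mk <- stack$masks[[i]]
    if (any(mk)) v[mk] <- v[mk] + (fg_mean - mean(v[mk]))
    if (any(!mk)) v[!mk] <- v[!mk] + (bg_mean - mean(v[!mk]))
    hsv[, , 3] <- pmin(pmax(v, 0), 1)
    frames[[i]] <- hsv_to_rgb_array(hsv)
  }
  frame_stack(frames, stack$masks)
}

# radial-frequency bin index matrix for an H x W FFT grid; bin 1 is DC.
.radial_bins <- function(h, w) {
  fy <- c(0:floor(h / 2), -((ceiling(h / 2) - 1):1)) / h
  fx <- c(0:floor(w / 2), -((ceiling(w / 2) - 1):1)) / w
  r <- sqrt(outer(fy^2, fx^2, `+`))
  round(r * max(h, w)) + 1L
}

.radial_profile <- function(amp, bins, nbins) {
  s <- rowsum(as.vector(amp), as.vector(bins))
  n <- rowsum(rep(1, length(bins)), as.vector(bins))
  prof <- rep(NA_real_, nbins)
  prof[as.integer(rownames(s))] <- s / n
  prof
}

#' Equalize rotationally averaged spatial-frequency content
#'
#' Rescales each frame's 2-D FFT amplitude per radial-frequency annulus so
#' that every frame's rotationally averaged amplitude profile equals the
#' grand-average profile over all supplied frames. Phases — and with them
#' each frame's orientation content — are untouched, as is the DC component
#' (each frame keeps its own mean). Operates on the HSV value channel only;
#' the output values are not clipped, so they may leave \code{[0, 1]}
#' slightly (clipping happens only on file output).
#'
#' Annuli are integer-radius rings on the FFT grid; for non-square frames
#' the radius is computed on normalized frequencies (cycles per pixel)
#' scaled by the larger dimension.
#'
#' @param stacks A [frame_stack()] or list of them (e.g. pigeon and greeble
#'   stacks together); needs at least one frame.
#' @return The same structure with matched frames.
#' @export
spatial_frequency_match <- function(stacks) {
  single <- inherits(stacks, "frame_stack")
  sl <- .as_stack_list(stacks)
  if (!length(sl) || !length(sl[[1]]$frames)) stop("no frames supplied")
  d <- dim(sl[[1]]$frames[[1]])
  bins <- .radial_bins(d[1], d[2])
  nbins <- max(bins)

  ffts <- list(); profs <- list(); where <- list()
  for (si in seq_along(sl)) for (fi in seq_along(sl[[si]]$frames)) {
    v <- rgb_to_hsv_array(sl[[si]]$frames[[fi]])[, , 3]
    F <- stats::fft(v)
    k <- length(ffts) + 1
    ffts[[k]] <- F
    profs[[k]] <- .radial_profile(Mod(F), bins, nbins)
    where[[k]] <- c(si, fi)
  }
  grand <- Reduce(`+`, profs) / length(profs)

  for (k in seq_along(ffts)) {
    gain <- grand / profs[[k]]
    gain[1] <- 1                       # DC preserved per frame
    gain[!is.finite(gain)] <- 1
    Fnew <- ffts[[k]] * gain[bins]
    vnew <- Re(stats::fft(Fnew, inverse = TRUE)) / length(Fnew)
    si <- where[[k]][1]; fi <- where[[k]][2]
    hsv <- rgb_to_hsv_array(sl[[si]]$frames[[fi]])
    hsv[, , 3] <- vnew
    sl[[si]]$frames[[fi]] <- hsv_to_rgb_array(hsv)
  }
  if (single) sl[[1]] else sl
}

#' Frame-by-frame dissimilarity between a video and its control
#'
#' Pearson correlation between the HSV value channels of corresponding
#' frames; one value per frame index. A frame pair in which either frame
#' has zero variance yields \code{NA}.
#'
#' @param stack_a,stack_b Two [frame_stack()]s with equal frame counts and
#'   shapes.
#' @return Numeric vector of per-frame correlations in \code{[-1, 1]}.
#' @export
frame_dissimilarity <- function(stack_a, stack_b) {
  stopifnot(inherits(stack_a, "frame_stack"), inherits(stack_b, "frame_stack"))
  if (length(stack_a$frames) != length(stack_b$frames))
    stop("stacks differ in frame count")
  vapply(seq_along(stack_a$frames), function(i) {
    va <- as.vector(rgb_to_hsv_array(stack_a$frames[[i]])[, , 3])
    vb <- as.vector(rgb_to_hsv_array(stack_b$frames[[i]])[, , 3])
    if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
    cor(va, vb)
  }, numeric(1))
}

#' Read / write a frame stack as PNG files
#'
#' @param paths Character vector of PNG paths (frames, in order).
#' @param mask_paths Optional PNGs of the masks (nonzero = foreground); if
#'   omitted, all-background masks are used.
#' @return [read_frame_stack()]: a [frame_stack()].
#' @export
read_frame_stack <- function(paths, mask_paths = NULL) {
  frames <- lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
  masks <- if (is.null(mask_paths)) {
    lapply(frames, function(f) matrix(FALSE, dim(f)[1], dim(f)[2]))
  } else lapply(mask_paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  })
  frame_stack(frames, masks)
}

#' @rdname read_frame_stack
#' @param stack A [frame_stack()] to write (values clipped to \code{[0,1]}).
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @export
write_frame_stack <- function(stack, dir, prefix = "frame") {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$frames))
  for (i in seq_along(stack$frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%04d.png", prefix, i))
    png::writePNG(pmin(pmax(stack$frames[[i]], 0), 1), paths[i])
  }
  invisible(paths)
}
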