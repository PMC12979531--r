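# smooth pseudo-texture from a few random sinusoids, zero mean, unit-ish range
.texture <- function(h, w, n_waves = 6, amp = 0.05) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  t <- matrix(0, h, w)
  for (i in seq_len(n_waves)) {
    fx <- runif(1, 0.5, 4) / w
    fy <- runif(1, 0.5, 4) / h
    t <- t + sin(2 * pi * (fx * xx + fy * yy) + runif(1, 0, 2 * pi))
  }
  t <- t - mean(t)
  t / max(abs(t)) * amp
}

.mask_from_spec <- function(spec, h, w) {
  if (is.matrix(spec)) {
    if (!all(dim(spec) == c(h, w))) stop("mask does not fit the frame")
    return(spec > 0)
  }
  cx <- spec$cx; cy <- spec$cy; rx <- spec$rx; ry <- spec$ry
  if (cx - rx < 1 || cx + rx > w || cy - ry < 1 || cy + ry > h)
    stop("mask does not fit inside the frame")
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

#' Generate a matched pair of synthetic color frames
#'
#' Produces two RGB frames sharing the same smooth background texture but
#' differing in foreground luminance (and texture), plus the foreground
#' mask — fixtures for the luminance/spatial-frequency equalization tools.
#' The HSV value channel is constructed directly (the red channel carries
#' V), so the masked value-channel means equal the requested targets
#' exactly.
#'
#' @param height,width Frame size in pixels.
#' @param fg_mask_spec Either a logical matrix of the frame size or a list
#'   \code{list(cx, cy, rx, ry)} describing an ellipse that must fit inside
#'   the frame.
#' @param luminance_params List with \code{fg_a}, \code{fg_b} (foreground
#'   value-channel means of the two frames) and \code{bg} (shared
#'   background mean); keep within \code{[0.1, 0.9]} so the texture does
#'   not clip.
#' @param seed Integer seed; identical parameters and seed give a
#'   pixel-identical pair.
#' @return List with \code{frame_a}, \code{frame_b} (H x W x 3 arrays) and
#'   \code{fg_mask} (logical matrix).
#' @export
generate_frame_pair <- function(height = 64, width = 64,
                                fg_mask_spec = list(cx = width / 2,
                                                    cy = height / 2,
                                                    rx = width / 4,
                                                    ry = height / 4),
                                luminance_params = list(fg_a = 0.6,
                                                        fg_b = 0.3,
                                                        bg = 0.45),
                                seed = 1) {
  set.seed(seed)
  mask <- .mask_from_spec(fg_mask_spec, height, width)
  if (!any(mask)) stop("degenerate mask: no foreground pixels")
  bg_tex <- .texture(height, width)
  lp <- luminance_params

  make_frame <- function(fg_mean) {
    v <- lp$bg + bg_tex
    fg_tex <- .texture(height, width)
    fv <- fg_mean + fg_tex[mask]
    v[mask] <- fv - mean(fv) + fg_mean   # exact masked mean
    v <- pmin(pmax(v, 0), 1)
    arr <- array(0, c(height, width, 3))
    arr[, , 1] <- v                       # V = max channel = R
    arr[, , 2] <- 0.65 * v
    arr[, , 3] <- 0.35 * v
    arr
  }
  frame_a <- make_frame(lp$fg_a)
  frame_b <- make_frame(lp$fg_b)
  list(frame_a = frame_a, frame_b = frame_b, fg_mask = mask)
}
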