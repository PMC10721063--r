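#' Direct segment-averaged bispectrum estimate
#'
#' Estimates the third-order spectrum
#' \eqn{B(f_1, f_2) = E[X(f_1)\, X(f_2)\, \overline{X(f_1+f_2)}]}
#' of a real 1-D signal with the direct FFT method: the signal is cut into
#' (possibly overlapping) segments, each segment is mean-removed, tapered and
#' zero-padded to `nfft`, and the triple product is averaged over segments.
#' The frequency index \eqn{f_1+f_2} wraps modulo `nfft`. Nonzero bispectral
#' magnitude at \eqn{(f_1, f_2)} indicates quadratic phase coupling between
#' the components at \eqn{f_1}, \eqn{f_2} and \eqn{f_1+f_2}; for Gaussian or
#' phase-randomized signals the average tends to zero.
#'
#' @param signal Numeric vector (an `encoded_signal` or any real signal).
#' @param nfft FFT length, at least `segment_length` (default 128).
#' @param segment_length Samples per segment (default 128).
#' @param overlap Fractional segment overlap in `[0, 1)` (default 0.5).
#' @param window Taper: `"hann"` (default), `"hamming"`, or `"rectangular"`.
#' @return A `bispectrum` object: complex `nfft` x `nfft` matrix (rows f1,
#'   columns f2, DC first) with attributes `nfft`, `segment_length`,
#'   `overlap`, `window`, `n_segments`.
#' @examples
#' x <- cos(2 * pi * 0.1 * (0:511))
#' B <- estimate_bispectrum(x, nfft = 64, segment_length = 64)
#' attr(B, "n_segments")
#' @export
estimate_bispectrum <- function(signal, nfft = 128L, segment_length = 128L,
                                overlap = 0.5,
                                window = c("hann", "hamming", "rectangular")) {
  window <- match.arg(window)
  x <- as.numeric(signal)
  L <- length(x)
  if (L < segment_length) {
    abort(paste0("signal length ", L, " is shorter than one segment (",
                 segment_length, ")"))
  }
  if (nfft < segment_length) abort("`nfft` must be at least `segment_length`")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")

  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq(1L, L - segment_length + 1L, by = step)
  w <- switch(window,
    hann = as.numeric(signal::hanning(segment_length)),
    hamming = as.numeric(signal::hamming(segment_length)),
    rectangular = rep(1, segment_length)
  )
  # index matrix of (f1 + f2) mod nfft, 1-based
  f <- seq_len(nfft) - 1L
  sum_idx <- (outer(f, f, `+`) %% nfft) + 1L

  acc <- matrix(0 + 0i, nfft, nfft)
  for (s in starts) {
    seg <- x[s:(s + segment_length - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(nfft - segment_length)))
    acc <- acc + outer(X, X) * Conj(matrix(X[sum_idx], nfft, nfft))
  }
  structure(acc / length(starts),
            nfft = as.integer(nfft),
            segment_length = as.integer(segment_length),
            overlap = overlap, window = window,
            n_segments = length(starts),
            class = "bispectrum")
}

#' @export
print.bispectrum <- function(x, ...) {
  cat("<bispectrum> nfft", attr(x, "nfft"),
      "| segments:", attr(x, "n_segments"),
      "x", attr(x, "segment_length"),
      sprintf("(%.0f%% overlap, %s window)\n",
              100 * attr(x, "overlap"), attr(x, "window")))
  invisible(x)
}

#' Principal-domain mask of a bispectrum grid
#'
#' The non-redundant triangle `0 <= f2 <= f1`, `f1 + f2 <= nfft/2` from which
#' the full grid of a real signal's bispectrum can be recovered by symmetry.
#'
#' @param nfft FFT length.
#' @return Logical `nfft` x `nfft` matrix, `TRUE` inside the triangle.
#' @export
principal_domain <- function(nfft) {
  f <- seq_len(nfft) - 1L
  f1 <- matrix(f, nfft, nfft)        # rows
  f2 <- matrix(f, nfft, nfft, byrow = TRUE)
  f2 <= f1 & (f1 + f2) <= nfft %/% 2
}

#' Render a bispectrum estimate as an RGB image
#'
#' Takes the magnitude over the square `[0, Nyquist]^2` region (which contains
#' the principal triangle plus its mirror across the diagonal, keeping the
#' raster square for CNN input), min-max normalizes it, optionally compresses
#' the heavy-tailed magnitudes with a fixed `log1p` curve, resizes bilinearly,
#' and maps through a colormap to 8-bit RGB. Because normalization precedes
#' compression, signals differing only by a global scale render identically.
#' A constant-magnitude estimate renders as a uniform mid-scale image.
#'
#' @param B A `bispectrum` object.
#' @param height,width Output size in pixels (default 224).
#' @param scale `"log1p"` (default) or `"linear"`.
#' @param colormap `"viridis"` (default; any `grDevices::hcl.colors` palette)
#'   or `"gray"` for grayscale replicated across the three channels.
#' @return A `bispectrum_image`: integer `height` x `width` x 3 array in
#'   `[0, 255]`.
#' @export
render_image <- function(B, height = 224L, width = 224L,
                         scale = c("log1p", "linear"), colormap = "viridis") {
  scale <- match.arg(scale)
  nfft <- attr(B, "nfft")
  half <- nfft %/% 2 + 1L
  mag <- Mod(unclass(B))[seq_len(half), seq_len(half)]

  rng <- range(mag)
  v <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else {
    matrix(0.5, nrow(mag), ncol(mag))
  }
  if (scale == "log1p") v <- log1p(255 * v) / log1p(255)

  v <- bilinear_resize(v, height, width)
  v <- pmin(pmax(v, 0), 1)

  px <- if (identical(colormap, "gray")) {
    g <- as.integer(round(255 * v))
    array(g, dim = c(height, width, 3))
  } else {
    ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, colormap))
    rgb <- ramp(as.vector(v))
    array(as.integer(round(rgb)), dim = c(height, width, 3))
  }
  structure(px, scale = scale, colormap = colormap, class = "bispectrum_image")
}

# Separable bilinear interpolation expressed as two small matrix products
# (align-corners sampling); orders of magnitude faster than generic image
# resizing for the thousands of renders a pipeline run performs.
bilinear_resize <- function(m, height, width) {
  weight_matrix <- function(n_out, n_in) {
    if (n_in == 1L) return(matrix(1, n_out, 1))
    pos <- seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2)
    frac <- pos - lo
    W <- matrix(0, n_out, n_in)
    W[cbind(seq_len(n_out), lo + 1)] <- 1 - frac
    W[cbind(seq_len(n_out), lo + 2)] <- frac
    W
  }
  Wr <- weight_matrix(height, nrow(m))
  Wc <- weight_matrix(width, ncol(m))
  Wr %*% m %*% t(Wc)
}

#' @export
print.bispectrum_image <- function(x, ...) {
  d <- dim(x)
  cat("<bispectrum_image>", d[1], "x", d[2], "x", d[3],
      "| scale:", attr(x, "scale"), "| colormap:", attr(x, "colormap"), "\n")
  invisible(x)
}

#' Plot a bispectrum magnitude surface
#'
#' @param object A `bispectrum` object.
#' @param ... Unused.
#' @return A ggplot raster of log-magnitude over the `[0, Nyquist]^2` square.
#' @export
autoplot.bispectrum <- function(object, ...) {
  nfft <- attr(object, "nfft")
  half <- nfft %/% 2 + 1L
  mag <- Mod(unclass(object))[seq_len(half), seq_len(half)]
  df <- tidyr::expand_grid(f1 = seq_len(half) - 1L, f2 = seq_len(half) - 1L)
  df$magnitude <- log1p(as.vector(mag[cbind(df$f1 + 1L, df$f2 + 1L)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$f2,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log1p |B|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "f1 (bins)", y = "f2 (bins)",
                  title = "Bispectrum magnitude")
}
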