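# Daubechies-4 (8-tap) orthonormal analysis filter; sums to sqrt(2).
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)

# One periodized analysis level: x (length N, even) -> list(a, d) length N/2.
dwt_step <- function(x, h) {
  N <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror high-pass
  L <- length(h)
  a <- numeric(N / 2); d <- numeric(N / 2)
  for (n in seq_len(L)) {
    idx <- ((2 * (seq_len(N / 2) - 1) + (n - 1)) %% N) + 1
    a <- a + h[n] * x[idx]
    d <- d + g[n] * x[idx]
  }
  list(a = a, d = d)
}

# Exact adjoint of dwt_step (orthonormal, so adjoint = inverse).
idwt_step <- function(a, d, h) {
  N <- 2 * length(a)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  L <- length(h)
  x <- numeric(N)
  for (n in seq_len(L)) {
    idx <- ((2 * (seq_len(N / 2) - 1) + (n - 1)) %% N) + 1
    contrib <- h[n] * a + g[n] * d
    # scatter-add with possible duplicate indices
    add <- rowsum(contrib, idx)
    x[as.integer(rownames(add))] <- x[as.integer(rownames(add))] + add
  }
  x
}

# Separable 2D periodized DWT of a matrix, `levels` deep.
# Returns list of levels, each with hl, lh, hh, and the final ll.
dwt2 <- function(m, h, levels) {
  out <- vector("list", levels)
  ll <- m
  for (lev in seq_len(levels)) {
    nr <- nrow(ll); nc <- ncol(ll)
    rowt_a <- matrix(0, nr, nc / 2); rowt_d <- matrix(0, nr, nc / 2)
    for (i in seq_len(nr)) {
      s <- dwt_step(ll[i, ], h)
      rowt_a[i, ] <- s$a; rowt_d[i, ] <- s$d
    }
    LL <- matrix(0, nr / 2, nc / 2); LH <- LL; HL <- LL; HH <- LL
    for (j in seq_len(nc / 2)) {
      s <- dwt_step(rowt_a[, j], h)
      LL[, j] <- s$a; HL[, j] <- s$d
      s2 <- dwt_step(rowt_d[, j], h)
      LH[, j] <- s2$a; HH[, j] <- s2$d
    }
    out[[lev]] <- list(hl = HL, lh = LH, hh = HH)
    ll <- LL
  }
  list(levels = out, ll = ll)
}

idwt2 <- function(dec, h) {
  ll <- dec$ll
  for (lev in rev(seq_along(dec$levels))) {
    bands <- dec$levels[[lev]]
    nr2 <- nrow(ll); nc2 <- ncol(ll)
    rowt_a <- matrix(0, 2 * nr2, nc2); rowt_d <- rowt_a
    for (j in seq_len(nc2)) {
      rowt_a[, j] <- idwt_step(ll[, j], bands$hl[, j], h)
      rowt_d[, j] <- idwt_step(bands$lh[, j], bands$hh[, j], h)
    }
    full <- matrix(0, 2 * nr2, 2 * nc2)
    for (i in seq_len(2 * nr2)) {
      full[i, ] <- idwt_step(rowt_a[i, ], rowt_d[i, ], h)
    }
    ll <- full
  }
  ll
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

pad_to_multiple <- function(m, mult) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / mult) * mult; nc2 <- ceiling(nc / mult) * mult
  if (nr2 == nr && nc2 == nc) return(list(m = m, nr = nr, nc = nc))
  out <- matrix(0, nr2, nc2)
  out[1:nr, 1:nc] <- m
  if (nr2 > nr) out[(nr + 1):nr2, 1:nc] <- m[nr:(2 * nr - nr2 + 1), 1:nc]
  if (nc2 > nc) out[, (nc + 1):nc2] <- out[, nc:(2 * nc - nc2 + 1)]
  list(m = out, nr = nr, nc = nc)
}

#' Wavelet threshold denoising of an RGB image
#'
#' Per-channel separable Daubechies-4 wavelet decomposition with soft
#' thresholding of all detail coefficients at the universal threshold
#' \eqn{\sigma \sqrt{2 \ln n}}, where the noise level \eqn{\sigma} is
#' estimated from the median absolute deviation of the finest diagonal band
#' (MAD / 0.6745) — the standard treatment when the contaminating noise is
#' Gaussian and white. The reconstruction is clipped to \[0, 255\].
#'
#' @param image h x w x 3 array with 8-bit values (a h x w matrix is treated
#'   as one channel).
#' @param levels Decomposition depth (default 3).
#' @param threshold Override the universal threshold (single number), e.g.
#'   0 to make the transform a no-op.
#' @return Denoised image, same shape, values in \[0, 255\].
#' @export
wavelet_denoise <- function(image, levels = 3, threshold = NULL) {
  one_channel <- is.matrix(image)
  if (one_channel) image <- array(image, c(dim(image), 1))
  nr <- dim(image)[1]; nc <- dim(image)[2]
  if (nr < 16 || nc < 16) stop("image too small (need at least 16 x 16)")
  if (min(nr, nc) < 2^levels) stop("level too deep for this image size")
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    pad <- pad_to_multiple(image[, , ch], 2^levels)
    dec <- dwt2(pad$m, DB4_H, levels)
    hh1 <- dec$levels[[1]]$hh
    sigma <- stats::median(abs(hh1 - stats::median(hh1))) / 0.6745
    thr <- if (is.null(threshold)) sigma * sqrt(2 * log(nr * nc)) else threshold
    for (lev in seq_along(dec$levels)) {
      dec$levels[[lev]]$hl <- soft_threshold(dec$levels[[lev]]$hl, thr)
      dec$levels[[lev]]$lh <- soft_threshold(dec$levels[[lev]]$lh, thr)
      dec$levels[[lev]]$hh <- soft_threshold(dec$levels[[lev]]$hh, thr)
    }
    rec <- idwt2(dec, DB4_H)[1:nr, 1:nc]
    out[, , ch] <- pmin(pmax(rec, 0), 255)
  }
  if (one_channel) out[, , 1] else out
}

#' Blue-screen foreground segmentation
#'
#' A pixel is background iff its blue channel dominates both others by more
#' than `tau`: `B > R + tau` and `B > G + tau`. The raw mask is cleaned by a
#' 3 x 3 morphological opening and removal of connected foreground components
#' smaller than `min_area` pixels (cleanup skipped when `clean = FALSE` or
#' the image is smaller than the structuring element).
#'
#' @param image h x w x 3 array, 8-bit values.
#' @param tau Chroma-dominance threshold in 8-bit units (default 30).
#' @param min_area Minimum connected foreground component area in pixels.
#' @param clean Apply morphological cleanup.
#' @return Logical h x w matrix (TRUE = plant/foreground) of class
#'   `"foreground_mask"` with attributes `tau` and `cleanup`.
#' @export
segment_blue_screen <- function(image, tau = 30, min_area = 100,
                                clean = TRUE) {
  stopifnot(tau >= 0, length(dim(image)) == 3)
  d <- dim(image)
  R <- matrix(image[, , 1], d[1], d[2])
  G <- matrix(image[, , 2], d[1], d[2])
  B <- matrix(image[, , 3], d[1], d[2])
  bg <- (B > R + tau) & (B > G + tau)
  fg <- !bg
  cleaned <- FALSE
  if (clean && all(dim(fg) >= 3)) {
    m <- EBImage::opening(fg * 1, EBImage::makeBrush(3, shape = "box"))
    lab <- EBImage::bwlabel(m)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0])
      keep <- which(areas >= min_area)
      fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
    } else {
      fg <- m > 0
    }
    cleaned <- TRUE
  }
  structure(fg, class = c("foreground_mask", "matrix", "array"),
            tau = tau, cleanup = cleaned)
}

#' Read / write 8-bit images and masks as PNG
#'
#' Images are h x w x 3 arrays with values 0..255; masks are logical h x w
#' matrices written as 0/255 grayscale.
#'
#' @param path PNG file path.
#' @return `read_image()`: h x w x 3 array 0..255.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' @rdname read_image
#' @param image h x w x 3 array (0..255) for `write_image()`; logical matrix
#'   for `write_mask()`.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname read_image
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}
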