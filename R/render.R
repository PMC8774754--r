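## TEM-like rendering of synthetic cross-sections. Images are plain numeric
## matrices in [0, 1], indexed [x, y] in the mathematical frame (y up); the
## conventional top-left / y-down pixel layout is applied only when writing
## TIFF files.

.BG <- 0.85      # background intensity
.WALL <- 0.2     # tubule wall intensity
.WALLW <- 4      # wall thickness (px)

.drawAnnulus <- function(img, cx, cy, r, wall = .WALLW, value = .WALL,
                         openTowards = NULL, openHalfWidth = pi / 3) {
  w <- nrow(img); h <- ncol(img)
  xr <- max(1L, floor(cx - r - wall)):min(w, ceiling(cx + r + wall))
  yr <- max(1L, floor(cy - r - wall)):min(h, ceiling(cy + r + wall))
  dx <- outer(xr - cx, rep(1, length(yr)))
  dy <- outer(rep(1, length(xr)), yr - cy)
  dd <- sqrt(dx^2 + dy^2)
  m <- abs(dd - r) <= wall / 2
  if (!is.null(openTowards)) {
    ang <- atan2(dy, dx)
    dif <- abs(((ang - openTowards + pi) %% (2 * pi)) - pi)
    m <- m & dif > openHalfWidth
  }
  img[xr, yr][m] <- value
  img
}

.drawDisc <- function(img, cx, cy, r, value = .WALL) {
  w <- nrow(img); h <- ncol(img)
  xr <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  yr <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  dx <- outer(xr - cx, rep(1, length(yr)))
  dy <- outer(rep(1, length(xr)), yr - cy)
  m <- dx^2 + dy^2 <= r^2
  img[xr, yr][m] <- value
  img
}

#' Render a cross-section as a TEM-like grayscale image
#'
#' Draws the section with standard positive TEM contrast (dark structures
#' on a light background): A-tubules as complete annuli, B-tubules as
#' C-shaped annuli opening toward their A-tubule, the central pair as two
#' adjacent annuli near the section center, and optional dynein-arm hook
#' decorations on arm-positive A-tubules (outer hooks outward, inner hooks
#' inward-rotated). Gaussian blur (\code{spec@psfSigma}) and additive
#' Gaussian noise (\code{spec@noiseSd}) are then applied; noise uses the
#' current RNG state unless \code{noiseSeed} is given.
#'
#' @param section a \linkS4class{CrossSection}.
#' @param spec a \linkS4class{SceneSpec} (rendering parameters).
#' @param canvas image side length (px); the default fits the default
#'   geometry with margin. Coordinates are shifted so the section origin maps to the
#'   canvas center.
#' @param cpCenters optional 2 x 2 matrix of central-pair centers (e.g. from
#'   generator truth); by default the pair is placed adjacent to the mean
#'   A-center along +x.
#' @param noiseSeed optional seed for the noise field only.
#' @return numeric matrix in [0, 1], indexed [x, y] (y up), with attribute
#'   \code{hookCenters} (n x 2 matrix of arm-decoration centers, canvas
#'   coordinates) and attribute \code{origin} (the canvas coordinates of the
#'   section frame origin).
#' @export
renderSectionImage <- function(section, spec, canvas = 288L,
                               cpCenters = NULL, noiseSeed = NULL) {
  stopifnot(is(section, "CrossSection"), is(spec, "SceneSpec"))
  d <- doublets(section)
  o <- (canvas + 1) / 2          # section origin -> canvas center
  pts <- rbind(cbind(d$ax, d$ay), cbind(d$bx, d$by))
  if (nrow(pts)) {
    reach <- max(abs(pts)) + max(spec@rA, spec@rB) + .WALLW + 6
    if (2 * reach > canvas)
      .err(sprintf("section does not fit the %d px canvas; need >= %d px",
                   canvas, ceiling(2 * reach)), "axosymCanvasError")
  }
  img <- matrix(.BG, canvas, canvas)
  hooks <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(d))) {
    aC <- c(d$ax[i], d$ay[i]) + o
    bC <- c(d$bx[i], d$by[i]) + o
    img <- .drawAnnulus(img, bC[1], bC[2], d$r_b[i],
                        openTowards = atan2(aC[2] - bC[2], aC[1] - bC[1]))
    img <- .drawAnnulus(img, aC[1], aC[2], d$r_a[i])
    ctr <- c(mean(d$ax), mean(d$ay)) + o
    u <- aC - ctr; u <- u / max(sqrt(sum(u^2)), 1e-9)   # outward
    if (isTRUE(d$oda[i])) {
      hc <- aC + (d$r_a[i] + 3.5) * u
      img <- .drawDisc(img, hc[1], hc[2], 2.5)
      hooks <- rbind(hooks, hc)
    }
    if (isTRUE(d$ida[i])) {
      ru <- drop(.rotmat(110 * pi / 180) %*% u)
      hc <- aC + (d$r_a[i] + 3.5) * ru
      img <- .drawDisc(img, hc[1], hc[2], 2.5)
      hooks <- rbind(hooks, hc)
    }
  }
  if (centralPairCount(section) > 0L) {
    if (is.null(cpCenters)) {
      mid <- if (nrow(d)) c(mean(d$ax), mean(d$ay)) else c(0, 0)
      off <- c(spec@rA + 1, 0)
      cpCenters <- rbind(mid + off, mid - off)[seq_len(min(2L, centralPairCount(section))), , drop = FALSE]
    }
    for (i in seq_len(nrow(cpCenters))) {
      cc <- cpCenters[i, ] + o
      img <- .drawAnnulus(img, cc[1], cc[2], spec@rA * 0.9)
    }
  }
  if (spec@psfSigma > 0) {
    eb <- EBImage::gblur(EBImage::Image(img), sigma = spec@psfSigma)
    img <- EBImage::imageData(eb)
  }
  if (spec@noiseSd > 0) {
    if (!is.null(noiseSeed)) set.seed(noiseSeed)
    img <- img + matrix(stats::rnorm(length(img), 0, spec@noiseSd),
                        nrow(img), ncol(img))
  }
  img[] <- pmin(1, pmax(0, as.numeric(img)))
  attr(img, "hookCenters") <- hooks
  attr(img, "origin") <- c(o, o)
  img
}

#' Write / read a rendered section as 16-bit grayscale TIFF
#'
#' Converts between the package's [x, y] y-up matrix convention and the
#' TIFF top-left, y-down pixel layout.
#'
#' @param img numeric matrix in [0, 1].
#' @param path file path.
#' @return \code{readSectionTiff} returns the image matrix.
#' @export
writeSectionTiff <- function(img, path) {
  ebi <- EBImage::Image(img[, ncol(img):1])   # flip y for display convention
  EBImage::writeImage(ebi, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeSectionTiff
#' @export
readSectionTiff <- function(path) {
  ebi <- EBImage::readImage(path)
  m <- EBImage::imageData(ebi)
  if (length(dim(m)) > 2L) m <- m[, , 1]
  m[, ncol(m):1]
}
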