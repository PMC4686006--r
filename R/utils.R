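# Internal helpers shared across modules.

# FFT sample frequencies in cycles/pixel, numpy-style ordering.
fftFreq <- function(n) {
  c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1)) / n
}

# Shift a matrix by (dr, dc) integer offsets, zero-filling vacated cells.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Bilinear sample of matrix m at points (r, c) (1-based, fractional);
# out-of-grid values read as `fill`.
bilinearSample <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- rep(fill, length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * get(r0, c0) +
    (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) +
    fr * fc * get(r0 + 1, c0 + 1)
}

asBinaryMask <- function(mask) {
  if (is.logical(mask)) return(mask)
  m <- mask > 0.5
  storage.mode(m) <- "logical"
  m
}

stopIfEmptyMask <- function(mask, what = "mask") {
  if (!any(mask)) stop(sprintf("%s is empty", what), call. = FALSE)
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Polygon vertices as an n x 2 matrix of (row, col); open (not repeated).
pointInPolygon <- function(pr, pc, poly) {
  n <- nrow(poly)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterise a polygon (vertices in sub-pixel (row, col) coordinates) onto the
# pixel grid of an nr x nc image: even-odd rule evaluated at pixel centres.
rasterisePolygon <- function(poly, nr, nc) {
  rmin <- max(1L, floor(min(poly[, 1])))
  rmax <- min(nr, ceiling(max(poly[, 1])))
  cmin <- max(1L, floor(min(poly[, 2])))
  cmax <- min(nc, ceiling(max(poly[, 2])))
  out <- matrix(FALSE, nr, nc)
  if (rmin > rmax || cmin > cmax) return(out)
  rs <- rmin:rmax; cs <- cmin:cmax
  grid <- expand.grid(r = rs, c = cs)
  # a pixel belongs to the fill if its centre or any corner of its unit
  # square lies inside the polygon; the corner tests avoid hairline cracks
  # against neighbouring rasterised shapes
  inside <- pointInPolygon(grid$r, grid$c, poly)
  for (dr in c(-0.5, 0.5)) for (dc in c(-0.5, 0.5))
    inside <- inside | pointInPolygon(grid$r + dr, grid$c + dc, poly)
  out[cbind(grid$r, grid$c)] <- inside
  # also mark pixels under the polygon edges themselves, so that rasterised
  # fills meet adjacent rasterised shapes without single-pixel cracks
  closed <- rbind(poly, poly[1L, , drop = FALSE])
  for (i in seq_len(nrow(poly))) {
    a <- closed[i, ]; b <- closed[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len * 4)))
    rr <- round(a[1L] + tt * (b[1L] - a[1L]))
    cc <- round(a[2L] + tt * (b[2L] - a[2L]))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

# Connected components (4-connectivity) and hole count of a binary mask.
maskTopology <- function(mask) {
  mask <- asBinaryMask(mask)
  lab <- EBImage::bwlabel(mask * 1)
  ncomp <- max(lab)
  # holes: background components not touching the border
  bg <- EBImage::bwlabel((!mask) * 1)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  nhole <- length(setdiff(unique(as.vector(bg)), c(0, border)))
  list(components = ncomp, holes = nhole)
}

# Perimeter estimate: total length of EBImage oriented contours of all
# objects in the mask.
maskPerimeter <- function(mask) {
  mask <- asBinaryMask(mask)
  if (!any(mask)) return(0)
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  sum(vapply(oc, function(p) {
    if (nrow(p) < 2) return(0)
    d <- sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2))
    sum(d)
  }, numeric(1)))
}
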