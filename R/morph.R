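# 3D binary morphology on (z,y,x) arrays, built from whole-array shifts.
# 6-connectivity (face neighbours) throughout.

shift_array <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
  if (length(src_z) < 1 || length(src_y) < 1 || length(src_x) < 1) return(out)
  out[src_z + dz, src_y + dy, src_x + dx] <- a[src_z, src_y, src_x]
  out
}

neighbor_offsets_6 <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                           c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

dilate_mask <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    acc <- mask
    for (off in neighbor_offsets_6)
      acc <- acc | shift_array(mask, off[1], off[2], off[3], FALSE)
    mask <- acc
  }
  mask
}

erode_mask <- function(mask, r = 1L) !dilate_mask(!mask, r)

open_mask <- function(mask, r = 1L) dilate_mask(erode_mask(mask, r), r)

close_mask <- function(mask, r = 1L) erode_mask(dilate_mask(mask, r), r)

# Connected-component labelling by iterated minimum-label propagation.
# Returns an integer array: 0 outside the mask, components numbered 1..k
# in decreasing size order.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  repeat {
    nxt <- lab
    for (off in neighbor_offsets_6) {
      sh <- shift_array(lab, off[1], off[2], off[3], Inf)
      nxt <- pmin(nxt, sh)
    }
    nxt[!mask] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab[!mask] <- 0
  ids <- sort(unique(lab[mask]))
  out <- array(0L, d)
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(lab == i), 0)
    ord <- order(sizes, decreasing = TRUE)
    for (k in seq_along(ord)) out[lab == ids[ord[k]]] <- k
  }
  out
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  label_components(mask) == 1L
}

border_mask <- function(d, axes = 1:3) {
  m <- array(FALSE, d)
  if (1 %in% axes) { m[1, , ] <- TRUE; m[d[1], , ] <- TRUE }
  if (2 %in% axes) { m[, 1, ] <- TRUE; m[, d[2], ] <- TRUE }
  if (3 %in% axes) { m[, , 1] <- TRUE; m[, , d[3]] <- TRUE }
  m
}

# Flood-fill the complement from the volume border (optionally restricted to
# in-plane axes); anything unreachable is an enclosed cavity.
flood_background <- function(mask, axes = 1:3) {
  bg <- !mask
  reach <- bg & border_mask(dim(mask), axes)
  offs <- Filter(function(off) which(off != 0) %in% axes,
                 neighbor_offsets_6)
  repeat {
    acc <- reach
    for (off in offs)
      acc <- acc | shift_array(reach, off[1], off[2], off[3], FALSE)
    acc <- acc & bg
    if (identical(acc, reach)) break
    reach <- acc
  }
  reach
}

fill_holes <- function(mask) mask | (!mask & !flood_background(mask))

# Per-axial-slice hole fill: flood the complement within each (y,x) plane
# from the in-plane borders, all slices at once.
fill_holes_slicewise <- function(mask) {
  mask | (!mask & !flood_background(mask, axes = 2:3))
}

# Otsu's threshold: maximize between-class variance of the histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]; mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- ((mu_t * w0[valid] - n * mu[-n_bins][valid])^2) /
    (as.numeric(w0[valid]) * w1[valid])
  mids[which.max(bcv)]
}
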