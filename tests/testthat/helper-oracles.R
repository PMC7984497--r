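# Independent scalar-loop / brute-force reference implementations used to
# cross-check the vectorized package code. These deliberately share no code
# with the package internals.

oracle_sct <- function(dixon, masks, model) {
  d <- dim(dixon$water$data)
  out <- array(NA_real_, d)
  wc <- model$water_center; fc <- model$fat_center
  vx <- fc[1] - wc[1]; vy <- fc[2] - wc[2]
  L2 <- vx^2 + vy^2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!masks$body$data[i, j, k]) { out[i, j, k] <- model$hu_air; next }
    w <- dixon$water$data[i, j, k]; f <- dixon$fat$data[i, j, k]
    px <- w - wc[1]; py <- f - wc[2]
    if (masks$bone$data[i, j, k]) {
      dd <- abs(px * vy - py * vx) / sqrt(L2)
      r <- min(1, max(0, dd / model$d_max))
      out[i, j, k] <- model$hu_spongy + r * (model$hu_cortical - model$hu_spongy)
    } else {
      t <- (px * vx + py * vy) / L2
      t <- min(1, max(0, t))
      out[i, j, k] <- model$hu_muscle + t * (model$hu_fat - model$hu_muscle)
    }
  }
  out
}

oracle_drr <- function(vol, axis, mu_water = 0.02) {
  d <- dim(vol$data)
  ax <- if (axis == "AP") 2L else 3L
  keep <- setdiff(1:3, ax)
  out <- matrix(0, d[keep[1]], d[keep[2]])
  for (a in seq_len(d[keep[1]])) for (b in seq_len(d[keep[2]])) {
    s <- 0
    for (k in seq_len(d[ax])) {
      idx <- c(NA, NA, NA); idx[keep] <- c(a, b); idx[ax] <- k
      hu <- vol$data[idx[1], idx[2], idx[3]]
      s <- s + max(mu_water * (1 + hu / 1000), 0) * vol$spacing[ax]
    }
    out[a, b] <- s
  }
  out
}

oracle_mae <- function(ct, sct, mask) {
  tot <- 0; n <- 0
  d <- dim(ct$data)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask$data[i, j, k]) {
      tot <- tot + abs(sct$data[i, j, k] - ct$data[i, j, k])
      n <- n + 1
    }
  }
  if (n == 0) NA_real_ else tot / n
}

# dose-to-fraction by explicit scan over sorted doses (descending), linear
# interpolation between cumulative-fraction knots
oracle_dx <- function(doses, frac) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  xs <- (1:n) / n
  if (frac <= xs[1]) return(s[1])
  if (frac >= xs[n]) return(s[n])
  hi <- which(xs >= frac)[1]
  lo <- hi - 1
  s[lo] + (s[hi] - s[lo]) * (frac - xs[lo]) / (xs[hi] - xs[lo])
}

oracle_dvh <- function(dose, structure) {
  doses <- dose$data[structure$data]
  vox_cc <- prod(dose$spacing) / 1000
  vol_cc <- length(doses) * vox_cc
  list(d_max = max(doses), d_mean = mean(doses),
       d_95 = oracle_dx(doses, 0.95), d_53 = oracle_dx(doses, 0.53),
       d_1cc = if (vol_cc < 1) max(doses) else oracle_dx(doses, 1 / vol_cc))
}
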