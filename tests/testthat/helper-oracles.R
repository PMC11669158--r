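# Independent brute-force oracles for the morphological and statistical
# operations. These deliberately use naive per-pixel loops (or a different
# library route) so they share no code with the package's implementations.

# grayscale dilation/erosion over explicit (dr, dc) offsets, per-pixel loop
oracle_gray_dilate <- function(img, offsets) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(-Inf, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (k in seq_len(nrow(offsets))) {
      r <- i + offsets[k, 1]; c <- j + offsets[k, 2]
      if (r >= 1 && r <= h && c >= 1 && c <= w)
        out[i, j] <- max(out[i, j], img[r, c])
    }
  }
  out
}

oracle_gray_erode <- function(img, offsets) {
  -oracle_gray_dilate(-img, offsets)
}

oracle_close <- function(img, offsets) {
  oracle_gray_erode(oracle_gray_dilate(img, offsets), offsets)
}

oracle_open <- function(img, offsets) {
  oracle_gray_dilate(oracle_gray_erode(img, offsets), offsets)
}

# offsets of a flat disk of the given radius
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, ])
}

# flat-disk grayscale opening via shifted slices (vectorised but independent
# of both EBImage and the package's line-morphology code path)
oracle_disk_opening <- function(img, radius) {
  offs <- disk_offsets(radius)
  shift <- function(m, dr, dc, fill) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(fill, h, w)
    sr <- max(1, 1 + dr):min(h, h + dr)
    sc <- max(1, 1 + dc):min(w, w + dc)
    out[sr - dr, sc - dc] <- m[sr, sc]
    out
  }
  er <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(offs)))
    er <- pmin(er, shift(img, offs[k, 1], offs[k, 2], Inf))
  di <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(offs)))
    di <- pmax(di, shift(er, offs[k, 1], offs[k, 2], -Inf))
  di
}

# all fixed points of the iterative-intermeans criterion, by exhaustive scan
# over every candidate threshold of a 256-bin histogram
oracle_isodata_fixed_points <- function(values) {
  v <- as.integer(round(values))
  fixed <- integer(0)
  for (t in 0:254) {
    low <- v[v <= t]; high <- v[v > t]
    if (length(low) == 0 || length(high) == 0) next
    if (as.integer(round((mean(low) + mean(high)) / 2)) == t)
      fixed <- c(fixed, t)
  }
  fixed
}

# one-way ANOVA through R's linear-model machinery (independent of the
# package's direct sum-of-squares route)
oracle_anova <- function(table) {
  fit <- stats::aov(value ~ factor(strain), data = table)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       mse_within = s[["Mean Sq"]][2], df_within = s[["Df"]][2])
}

# Sidak step-down adjustment applied directly to a vector of raw p-values
oracle_sidak_stepdown <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, pmax(cummax(adj), p[ord]))
  out <- numeric(m)
  out[ord] <- adj
  out
}

random_image8 <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
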