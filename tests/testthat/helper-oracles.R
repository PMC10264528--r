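# Fixture builders and independent brute-force oracles used across tests.

# digital disk mask: pixel centers within radius r (pixels)
disk_mask <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  cc <- r + pad
  outer(0:(n - 1), 0:(n - 1), function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

# digital ellipse mask, semi-axes a, b in pixels, rotated by ang
ellipse_mask <- function(a, b, ang = 0, pad = 3) {
  n <- 2 * (max(a, b) + pad) + 1
  cc <- max(a, b) + pad
  outer(0:(n - 1), 0:(n - 1), function(i, j) {
    x <- (i - cc) * cos(ang) + (j - cc) * sin(ang)
    y <- -(i - cc) * sin(ang) + (j - cc) * cos(ang)
    (x / a)^2 + (y / b)^2 <= 1
  })
}

# random connected blob: union of chained random disks (no holes)
random_blob_mask <- function(seed, grid = 36, r_range = c(2, 6), n_disks = 4) {
  set.seed(seed)
  m <- matrix(FALSE, grid, grid)
  cx <- grid / 2; cy <- grid / 2
  for (k in seq_len(n_disks)) {
    r <- runif(1, r_range[1], r_range[2])
    ii <- matrix(0:(grid - 1), grid, grid)
    jj <- t(ii)
    m <- m | ((ii - cx)^2 + (jj - cy)^2 <= r^2)
    step <- runif(1, 0, r)
    ang <- runif(1, 0, 2 * pi)
    cx <- min(max(cx + step * cos(ang), r_range[2] + 1), grid - r_range[2] - 2)
    cy <- min(max(cy + step * sin(ang), r_range[2] + 1), grid - r_range[2] - 2)
  }
  m
}

# all pixel-corner points of a mask (pixel units, 0-based centers)
all_corner_points <- function(mask) {
  idx <- which(mask)
  r <- (idx - 1) %% nrow(mask)
  c <- (idx - 1) %/% nrow(mask)
  unique(cbind(c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
               c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)))
}

# brute-force maximum Feret: largest distance over ALL corner pairs
feret_max_oracle <- function(mask) {
  p <- all_corner_points(mask)
  d2 <- outer(p[, 1], p[, 1], "-")^2 + outer(p[, 2], p[, 2], "-")^2
  sqrt(max(d2))
}

# brute-force minimum width: projection span minimized over a fine angle grid
feret_min_oracle <- function(mask, n_angles = 1800) {
  p <- all_corner_points(mask)
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  proj <- p %*% rbind(cos(th), sin(th))
  min(apply(proj, 2, function(x) max(x) - min(x)))
}

# direct-summation population moments
moments_oracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# O(n^2) concordant-pair AUC (ties count one half)
auc_pair_oracle <- function(score, y) {
  pos <- score[y == 1]; neg <- score[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# pair-counting Mann-Whitney U of group a (independent of rank formula)
u_pair_oracle <- function(a, b) {
  cmp <- outer(a, b, function(x, y) (x > y) + 0.5 * (x == y))
  sum(cmp)
}

# uniform HU image wrapper around a mask
uniform_image <- function(mask, hu = -600, spacing = 1) {
  hu_image(matrix(hu, nrow(mask), ncol(mask)), spacing)
}

# rendered fourier blob at a given irregularity, features on the true mask
extract_features_of_blob <- function(irregularity) {
  spec <- nodule_spec(shape_type = if (irregularity > 0) "fourier_blob" else "ellipse",
                      equivalent_diameter = 18,
                      boundary_irregularity = irregularity,
                      attenuation_sd = 0, attenuation_skewness = 0, seed = 33)
  nod <- render_nodule(spec, background_sd = 0, pixel_spacing = 0.35,
                       edge_blend = FALSE)
  suppressMessages(extract_features(nod$image, nod$true_mask))
}
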