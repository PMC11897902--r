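# Independent brute-force oracles. These deliberately share no code
# with the package implementations they check.

# 4-connected component labelling by queue-based flood fill
bfs_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] != 1L || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1] >= 1L && q[1] <= H && q[2] >= 1L && q[2] <= W &&
            mask[q[1], q[2]] == 1L && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# per-ROI area by explicit loops: label, centroid, assign, sum
areas_oracle <- function(mask, centers, radius) {
  lab <- bfs_label(mask)
  areas <- c(0L, 0L, 0L)
  if (max(lab) == 0L) return(areas)
  for (k in seq_len(max(lab))) {
    pts <- which(lab == k, arr.ind = TRUE)
    cen <- colMeans(pts)
    for (r in 1:3) {
      if (sum((cen - centers[r, ])^2) <= radius^2) {
        areas[r] <- areas[r] + nrow(pts)
        break
      }
    }
  }
  areas
}

# mat depth: literal row scan
depth_oracle <- function(mask, row_threshold) {
  n <- 0L
  for (i in seq_len(nrow(mask)))
    if (sum(mask[i, ] == 1L) >= row_threshold) n <- n + 1L
  n
}

# closed-form OLS slope and adjusted R^2 of y on x
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  yhat <- mean(y) + slope * (x - mean(x))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# longest qualifying run by enumerating every observation run
viability_oracle <- function(t, areas, min_area, min_days) {
  n <- length(t)
  o <- order(t); t <- t[o]; areas <- areas[o]
  best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    if (all(areas[i:j] >= min_area)) {
      span <- t[j] - t[i]
      if (span > best) best <- span
    }
  }
  list(viable = best >= min_days, span = best)
}

# EC50 by brute-force grid minimisation of |ll5(x) - target|
ec50_grid_oracle <- function(fit, baseline, max_dose,
                             resolution = 1e-4) {
  xs <- seq(resolution, 2 * max_dose, by = resolution)
  pred <- ll5(xs, fit$b, fit$c, fit$d, fit$e, fit$f)
  xs[which.min(abs(pred - 0.5 * baseline))]
}

# small random binary mask generator
random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
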