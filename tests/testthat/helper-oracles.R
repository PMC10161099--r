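# Independent oracles, implemented from first principles (no calls into the
# package's segmentation/fitting internals).

# Exhaustive flood-fill connected-component count, 4-connectivity.
flood_fill_count <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && !seen[i, j]) {
        count <- count + 1L
        stack <- list(c(i, j))
        seen[i, j] <- TRUE
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            r <- p[1] + d[1]
            cc <- p[2] + d[2]
            if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
                mask[r, cc] && !seen[r, cc]) {
              seen[r, cc] <- TRUE
              stack[[length(stack) + 1]] <- c(r, cc)
            }
          }
        }
      }
    }
  }
  count
}

# Brute-force grayscale white top-hat: exhaustive min-then-max filtering with
# the digital disk dx^2 + dy^2 <= r^2, out-of-bounds pixels ignored.
brute_tophat <- function(x, radius) {
  r <- floor(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(x)
  nc <- ncol(x)
  filt <- function(img, f, init) {
    out <- matrix(init, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        v <- init
        for (k in seq_len(nrow(offs))) {
          a <- i + offs$dr[k]
          b <- j + offs$dc[k]
          if (a >= 1 && a <= nr && b >= 1 && b <= nc) v <- f(v, img[a, b])
        }
        out[i, j] <- v
      }
    }
    out
  }
  eroded <- filt(x, min, Inf)
  opened <- filt(eroded, max, -Inf)
  x - opened
}

# Closed-form simple linear regression via the normal equations.
ols_closed_form <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Draw a binary scene of filled disks (radius r) at given centres.
disk_scene <- function(dim, centers, radius) {
  m <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(dim[1])) {
      for (cc in seq_len(dim[2])) {
        if ((r - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2) {
          m[r, cc] <- 1
        }
      }
    }
  }
  m
}
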