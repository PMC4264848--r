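## Brute-force morphology oracles, kept independent of the package's
## implementation path: direct per-pixel neighbourhood scans with
## symmetric (mirror, edge-included) border reflection.

reflect_index <- function(i, n) {
  i[i < 1] <- 1 - i[i < 1]
  i[i > n] <- 2 * n + 1 - i[i > n]
  i
}

disk_offsets <- function(radius) {
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  g[g$dy^2 + g$dx^2 <= radius^2, ]
}

brute_neighborhood <- function(m, radius, fun) {
  off <- disk_offsets(radius)
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- reflect_index(i + off$dy, nr)
    cj <- reflect_index(j + off$dx, nc)
    out[i, j] <- fun(m[cbind(ri, cj)])
  }
  out
}

brute_erode <- function(m, radius) brute_neighborhood(m, radius, min)
brute_dilate <- function(m, radius) brute_neighborhood(m, radius, max)
brute_open <- function(m, radius) brute_dilate(brute_erode(m, radius), radius)
brute_median <- function(m, radius)
  brute_neighborhood(m, radius, stats::median)
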