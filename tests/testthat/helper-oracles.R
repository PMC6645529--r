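# Shared fixtures and independent oracles (built in code, no stored data).

# cache expensive fixtures across test files
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_phantom <- function() fixture("small_phantom", function()
  make_phantom(shape = c(96, 96, 160), outer_radius = 28, wall = 10))

tiny_phantom <- function() fixture("tiny_phantom", function()
  make_phantom(shape = c(64, 64, 96), outer_radius = 20, wall = 8))

# digital ball mask, centred on a voxel
ball_mask <- function(n = 32, r = 10, voxel_size = 10.4) {
  ctr <- n %/% 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  d <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2)
  binary_mask(array(d <= r, c(n, n, n)), voxel_size)
}

# smooth analytic image rendered exactly under a rigid map (no resampling,
# so intensity-based registration of a rendered pair has its optimum exactly
# at the generating transform)
render_blobs <- function(tf = rigid_transform(), n = 64) {
  R <- cortimap:::euler_matrix(tf$rotation)
  cc <- (n - 1) / 2
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  P <- t(R %*% rbind(g$x - cc, g$y - cc, g$z - cc)) +
    matrix(rep(c(cc, cc, cc) + tf$translation, each = nrow(g)), ncol = 3)
  blobs <- rbind(c(20, 24, 30, 8), c(40, 36, 28, 6),
                 c(30, 44, 40, 5), c(34, 20, 44, 7))
  v <- 0
  for (i in seq_len(nrow(blobs)))
    v <- v + 200 * exp(-((P[, 1] - blobs[i, 1])^2 + (P[, 2] - blobs[i, 2])^2 +
                           (P[, 3] - blobs[i, 3])^2) / (2 * blobs[i, 4]^2))
  volume_image(array(v, c(n, n, n)), 10.4)
}

# exhaustive-search Otsu oracle: maximise between-class variance over every
# candidate bin edge by direct looping over the same histogram
otsu_bruteforce <- function(v, nbins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1L), nbins), nbins)
  best <- -Inf; kbest <- NA
  for (k in seq_len(nbins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):nbins] * centers[(k + 1):nbins]) / n1
    sb <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; kbest <- k }
  }
  edges[kbest + 1L]
}

# all-pairs brute-force symmetric Hausdorff over vertex samples
hausdorff_bruteforce <- function(A, B) {
  h <- function(P, Q) {
    m <- 0
    for (i in seq_len(nrow(P))) {
      d2 <- min((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2 +
                  (Q[, 3] - P[i, 3])^2)
      m <- max(m, d2)
    }
    sqrt(m)
  }
  max(h(A, B), h(B, A))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
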