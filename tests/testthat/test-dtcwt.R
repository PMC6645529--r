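test_that("the filter bank satisfies its structural invariants", {
  bank <- dtcwt_filters()
  expect_length(bank$qshift_a$h0$c, 14)
  expect_length(bank$qshift_b$h0$c, 14)
  expect_lt(filter_bank_pr_error(bank), 1e-8)
  # tree B is the time reverse of tree A
  expect_equal(bank$qshift_b$h0$c, rev(bank$qshift_a$h0$c))
  # lowpass DC gain sqrt(2), highpass zero at DC
  expect_equal(sum(bank$qshift_a$h0$c), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(bank$qshift_a$h1$c), 0, tolerance = 1e-12)
})

test_that("forward + inverse is the identity on arbitrary maps", {
  set.seed(7)
  for (dims in list(c(64, 64), c(80, 96), c(160, 360))) {
    S <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    dec <- dtcwt_forward(S, 4)
    expect_lt(max(abs(dtcwt_inverse(dec) - S)), 1e-8)
  }
  # one level on a 64 x 64 map: exactly 12 real detail component arrays
  dec1 <- dtcwt_forward(matrix(rnorm(64^2), 64, 64), 1)
  expect_length(dec1$details[[1]], 6)
  n_real <- sum(vapply(dec1$details[[1]], function(d) 2L, integer(1)))
  expect_identical(n_real, 12L)
  expect_length(dec1$lowpass, 4)   # four real scaling arrays
})

test_that("constants live entirely in the scaling band", {
  S <- matrix(42, 64, 64)
  dec <- dtcwt_forward(S, 4)
  dmax <- max(vapply(dec$details, function(lv)
    max(vapply(lv, function(d) max(Mod(d)), numeric(1))), numeric(1)))
  expect_lt(dmax, 1e-8 * 42)
  pat <- synthesize_patterns(dec, 0)
  expect_lt(max(abs(pat$low - 42)), 1e-6 * 42)
  expect_lt(max(abs(pat$high)), 1e-6 * 42)
})

test_that("the MAD threshold implements median(|d|)/0.6745", {
  set.seed(8)
  dec <- dtcwt_forward(matrix(rnorm(64^2), 64, 64), 2)
  # engineered pooled coefficients: |median| of components = 0.6745 -> tau 1
  dec1 <- dec
  nval <- sum(vapply(dec1$details, function(lv)
    sum(vapply(lv, length, integer(1))), integer(1))) * 2L
  vals <- seq(0, 2 * 0.6745, length.out = nval)
  k <- 0
  dec1$details <- lapply(dec1$details, function(lv) lapply(lv, function(d) {
    n <- length(d)
    re <- vals[k + seq_len(n)]; k <<- k + n
    im <- vals[k + seq_len(n)]; k <<- k + n
    matrix(complex(real = re, imaginary = im), nrow(d), ncol(d))
  }))
  expect_equal(mad_threshold(dec1), 1.0, tolerance = 1e-9)

  # all-zero details
  dec0 <- dec
  dec0$details <- lapply(dec0$details, function(lv) lapply(lv, function(d) d * 0))
  expect_equal(mad_threshold(dec0), 0)

  # Monte-Carlo consistency of the 0.6745 constant: standard-normal
  # coefficients, n = 1e5 -> tau = 1 +- 0.02
  set.seed(9)
  decn <- dec
  total <- 0
  decn$details <- lapply(decn$details, function(lv) lapply(lv, function(d) {
    n <- length(d)
    total <<- total + 2 * n
    matrix(complex(real = rnorm(n), imaginary = rnorm(n)), nrow(d), ncol(d))
  }))
  reps <- ceiling(1e5 / total)
  taus <- vapply(seq_len(reps), function(i) {
    decn$details <- lapply(decn$details, function(lv) lapply(lv, function(d) {
      n <- length(d)
      matrix(complex(real = rnorm(n), imaginary = rnorm(n)), nrow(d), ncol(d))
    }))
    mad_threshold(decn)
  }, numeric(1))
  expect_equal(mean(taus), 1.0, tolerance = 0.02)
})

test_that("soft thresholding shrinks magnitudes and preserves phase", {
  dec <- dtcwt_forward(matrix(0, 32, 32), 1)
  z <- complex(real = 3, imaginary = 4)       # |z| = 5
  dec$details[[1]][[1]][1, 1] <- z
  th <- soft_threshold(dec, 2)
  zt <- th$details[[1]][[1]][1, 1]
  expect_equal(Mod(zt), 3, tolerance = 1e-12)
  expect_equal(Arg(zt), Arg(z), tolerance = 1e-12)

  dec$details[[1]][[1]][2, 2] <- complex(real = 1.5)
  th2 <- soft_threshold(dec, 2)
  expect_equal(th2$details[[1]][[1]][2, 2], 0 + 0i)  # kill zone

  th0 <- soft_threshold(dec, 0)
  expect_identical(th0$details, dec$details)          # identity at tau = 0
  expect_error(soft_threshold(dec, -1), class = "cortimap_parameter_error")
})

test_that("patterns are linear and sum to the source at tau = 0", {
  set.seed(10)
  S1 <- matrix(rnorm(64 * 96), 64, 96)
  S2 <- matrix(rnorm(64 * 96), 64, 96)
  p1 <- synthesize_patterns(dtcwt_forward(S1), 0)
  p2 <- synthesize_patterns(dtcwt_forward(S2), 0)
  p12 <- synthesize_patterns(dtcwt_forward(2 * S1 - 3 * S2), 0)
  expect_lt(max(abs(p12$low - (2 * p1$low - 3 * p2$low))), 1e-8)
  expect_lt(max(abs(p12$high - (2 * p1$high - 3 * p2$high))), 1e-8)
  expect_lt(max(abs(p1$low + p1$high - S1)), 1e-8)
})

test_that("subband magnitudes are nearly shift invariant", {
  denergy <- function(S) {
    dec <- dtcwt_forward(S, 4)
    sum(vapply(dec$details, function(lv)
      sum(vapply(lv, function(d) sum(Mod(d)^2), numeric(1))), numeric(1)))
  }
  for (base in c(20, 33)) {
    E <- vapply(0:3, function(s) {
      S <- matrix(0, 64, 64); S[32, base + s] <- 1; denergy(S)
    }, numeric(1))
    expect_lt((max(E) - min(E)) / mean(E), 0.05)
    Er <- vapply(0:3, function(s) {
      S <- matrix(0, 64, 64); S[base + s, 32] <- 1; denergy(S)
    }, numeric(1))
    expect_lt((max(Er) - min(Er)) / mean(Er), 0.05)
  }
})

test_that("circular theta shifts by the decimation period commute exactly", {
  set.seed(11)
  S <- matrix(rnorm(64 * 96), 64, 96)
  shift_cols <- function(M, k) M[, ((seq_len(ncol(M)) - 1 - k) %% ncol(M)) + 1]
  p0 <- synthesize_patterns(dtcwt_forward(S), 0)
  p16 <- synthesize_patterns(dtcwt_forward(shift_cols(S, 16)), 0)
  expect_lt(max(abs(p16$low - shift_cols(p0$low, 16))), 1e-6)
  expect_lt(max(abs(p16$high - shift_cols(p0$high, 16))), 1e-6)
})

test_that("one terminal coefficient spans 166.4 um of bone height", {
  span <- coarse_scale_span(levels = 4, voxel_size = 10.4, theta_bin_deg = 1)
  expect_equal(unname(span["z_um"]), 166.4)
  expect_equal(unname(span["theta_rad"]), 16 * pi / 180, tolerance = 1e-12)
})
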