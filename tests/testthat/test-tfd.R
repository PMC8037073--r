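# Choi-Williams distribution: oracle equivalence, marginals, truncation

test_that("fast CWD matches the nested-loop reference on small signals", {
  fs <- 250
  sigs <- list(
    tone8 = tone(8, fs, dur = 64 / fs),
    impulse = {
      x <- numeric(64); x[32] <- 1; x
    },
    noise = {
      set.seed(5); rnorm(64)
    })
  for (nm in names(sigs)) {
    a <- cwd(sigs[[nm]], fs, sigma = 1, n_freq = 64, lag_window = 31,
             time_decimation = 1)
    b <- cwd_reference(sigs[[nm]], fs, sigma = 1, n_freq = 64,
                       lag_window = 31, time_decimation = 1)
    expect_lt(rel_frob(a$values, b$values), 1e-8)
  }
  expect_error(cwd_reference(rnorm(500), fs), "small-instance")
})

test_that("bilinearity zeroes and quadratic amplitude scaling hold", {
  fs <- 250
  z <- cwd(rep(0, 300), fs, n_freq = 64, lag_window = 31)
  expect_identical(max(abs(z$values)), 0)
  x <- tone(10, fs, dur = 300 / fs)
  m1 <- cwd(x, fs, n_freq = 64, lag_window = 31, time_decimation = 1)
  m2 <- cwd(2 * x, fs, n_freq = 64, lag_window = 31, time_decimation = 1)
  expect_lt(rel_frob(m2$values, 4 * m1$values), 1e-10)
})

test_that("argument contracts are enforced", {
  expect_error(cwd(rnorm(300), 250, sigma = 0), "sigma")
  expect_error(cwd(rnorm(50), 250, lag_window = 31), "shorter")
  expect_error(cwd(rnorm(300), 250, n_freq = 16, lag_window = 31), "n_freq")
  expect_error(cwd(rnorm(300), 250, lag_window = 30), "odd")
})

test_that("a tone concentrates at its frequency; an impulse at its time", {
  fs <- 250
  m <- cwd(tone(10, fs, 2), fs, sigma = 1, n_freq = 256, lag_window = 127,
           time_decimation = 1)
  expect_lt(abs(m$freq_axis[which.max(colMeans(m$values))] - 10),
            fs / (2 * 256) + 1e-12)

  x <- numeric(128); x[64] <- 1
  mi <- cwd(x, fs, n_freq = 128, lag_window = 31, time_decimation = 1)
  mt <- marginal_time(mi)
  expect_identical(which.max(mt), 64L)
  expect_gt(sum(mt[61:67]) / sum(mt), 0.5)
})

test_that("time shift translates the distribution (edge-windowed)", {
  fs <- 250; n <- 256; shift <- 16
  x <- tone(12, fs, n / fs) * hann_window(n)
  xs <- c(numeric(shift), x[1:(n - shift)])
  m0 <- cwd(x, fs, n_freq = 64, lag_window = 31, time_decimation = 1)
  m1 <- cwd(xs, fs, n_freq = 64, lag_window = 31, time_decimation = 1)
  keep <- 64:192
  expect_lt(rel_frob(m1$values[keep + shift, ], m0$values[keep, ]), 0.02)
})

test_that("positive-part truncation follows its definition", {
  m <- new_cwd_matrix(matrix(c(1, 0, -2, 3), 2), time_axis = c(0, 1),
                      freq_axis = c(0, 10), fs = 250, sigma = 1,
                      lag_window = 31, time_decimation = 1)
  tm <- truncate_positive(m)
  expect_identical(tm$values, matrix(c(1, 0, 0, 3), 2))
  expect_true(tm$truncated)
  expect_error(truncate_positive(tm), "already")

  pos <- new_cwd_matrix(matrix(c(1, 2, 3, 4), 2), c(0, 1), c(0, 10),
                        250, 1, 31, 1)
  expect_identical(truncate_positive(pos)$values, pos$values)
})

test_that("truncation can only increase the total for a two-tone signal", {
  fs <- 250
  x <- tone(8, fs, 2) + tone(16, fs, 2)
  m <- cwd(x, fs, sigma = 1, n_freq = 256, lag_window = 127,
           time_decimation = 1)
  expect_gte(sum(truncate_positive(m)$values), sum(m$values))
})

test_that("marginals and total power recover the analytic signal's energy", {
  fs <- 250; n <- 500
  x <- tone(10, fs, n / fs) * hann_window(n)
  s <- analytic_signal(x)
  m <- cwd(x, fs, sigma = 1, n_freq = 256, lag_window = 127,
           time_decimation = 1)

  mt <- marginal_time(m)
  cen <- 126:375
  expect_lt(sqrt(mean((mt[cen] - abs(s[cen])^2)^2)) / mean(abs(s[cen])^2),
            0.02)

  expect_lt(abs(total_power(m) - sum(abs(s)^2) / fs) / (sum(abs(s)^2) / fs),
            0.01)

  mf <- marginal_freq(m)
  expect_lt(abs(m$freq_axis[which.max(mf)] - 10), fs / (2 * 256) + 1e-12)
})

test_that("frequency marginal splits mass evenly between two equal tones", {
  fs <- 250; n <- 500
  x <- (tone(8, fs, n / fs) + tone(16, fs, n / fs)) * hann_window(n)
  m <- cwd(x, fs, sigma = 1, n_freq = 256, lag_window = 127,
           time_decimation = 1)
  mf <- marginal_freq(m)
  mass <- function(f0) sum(mf[abs(m$freq_axis - f0) <= 1.5])
  expect_gt(mass(8) / mass(16), 0.8)
  expect_lt(mass(8) / mass(16), 1.25)
})

test_that("time marginal tracks the squared envelope of an AM tone", {
  fs <- 250; n <- 1000
  t <- (0:(n - 1)) / fs
  a <- 1 + 0.6 * sin(2 * pi * 0.8 * t)
  x <- a * sin(2 * pi * 20 * t)
  m <- cwd(x, fs, sigma = 1, n_freq = 256, lag_window = 127,
           time_decimation = 1)
  mt <- marginal_time(m)
  cen <- 251:750
  expect_gt(cor(mt[cen], a[cen]^2), 0.99)
})

test_that("marginals refuse a truncated matrix", {
  m <- truncate_positive(cwd(tone(10, 250, 1), 250, n_freq = 64,
                             lag_window = 31))
  expect_error(marginal_time(m), "truncated")
  expect_error(marginal_freq(m), "truncated")
  expect_error(total_power(m), "truncated")
})

test_that("smaller sigma suppresses the cross-term midband monotonically", {
  fs <- 250
  x <- tone(8, fs, 2) + tone(16, fs, 2)
  mid <- vapply(c(10, 1, 0.1, 0.01), function(sg) {
    m <- cwd(x, fs, sigma = sg, n_freq = 256, lag_window = 127,
             time_decimation = 1)
    band <- m$freq_axis >= 11.5 & m$freq_axis <= 12.5
    mean(abs(m$values[, band]))
  }, 1)
  expect_true(all(diff(mid) < 0))
})
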