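test_that("gray-matter extraction selects the masked voxels in scan order", {
  dat <- array(rnorm(2 * 2 * 1 * 10), dim = c(2, 2, 1, 10))
  aff <- rbind(cbind(diag(c(4, 4, 5)), c(0, 0, 0)), c(0, 0, 0, 1))
  sess <- bold_session(dat, c(4, 4, 5), 2, aff, "sub-01", "rest", 1L)
  gray <- array(c(TRUE, TRUE, FALSE, TRUE), dim = c(2, 2, 1))
  masks <- list(gray = gray,
                white = array(FALSE, c(2, 2, 1)), csf = array(FALSE, c(2, 2, 1)))
  vm <- extract_gray_timeseries(sess, masks)
  expect_equal(ncol(vm$values), 3L)
  # column-major (x fastest) order: voxels (1,1,1), (2,1,1), (2,2,1)
  expect_equal(vm$values[, 1], dat[1, 1, 1, ])
  expect_equal(vm$values[, 2], dat[2, 1, 1, ])
  expect_equal(vm$values[, 3], dat[2, 2, 1, ])
  # node -> mm -> node round trip through the affine is the identity
  nm <- vm$node_map
  back <- t(solve(aff) %*% rbind(nm$x_mm, nm$y_mm, nm$z_mm, 1))[, 1:3] + 1
  expect_equal(cbind(nm$i, nm$j, nm$k), unname(back), tolerance = 1e-10)
  expect_error(extract_gray_timeseries(sess, list(gray = array(FALSE, c(2, 2, 1)))),
               "empty")
  expect_error(extract_gray_timeseries(sess, list(gray = array(TRUE, c(3, 2, 1)))),
               "match")
})

test_that("band-pass keeps in-band sinusoids and rejects DC and 0.2 Hz", {
  n <- 240; tr <- 2
  tt <- seq_len(n) * tr
  rms <- function(x) sqrt(mean(x^2))
  inband <- sin(2 * pi * 0.03 * tt + 0.3)
  dc <- rep(5, n)
  fast <- sin(2 * pi * 0.2 * tt + 1.1)
  vm <- make_vm(cbind(inband, dc, fast), tr = tr)
  out <- bandpass(vm)$values
  expect_gte(rms(out[, 1]), 0.8 * rms(inband))
  expect_lte(rms(out[, 2]), 0.01 * mean(abs(dc)))
  expect_lte(rms(out[, 3]), 0.2 * rms(fast))
  # invalid bands
  expect_error(bandpass(vm, 0.05, 0.01), "band")
  expect_error(bandpass(vm, 0.009, 0.3), "band")
})

test_that("nuisance regression projects exactly and is idempotent", {
  set.seed(42)
  n <- 120
  nuis <- list(motion = matrix(rnorm(n * 6), n, 6),
               global_signal = rnorm(n), white_signal = rnorm(n),
               csf_signal = rnorm(n))
  X <- cbind(1, nuis$motion, nuis$global_signal, nuis$white_signal,
             nuis$csf_signal)
  Y <- matrix(rnorm(n * 10), n, 10)
  # a column equal to the global signal is annihilated
  Y[, 1] <- nuis$global_signal
  # a column orthogonal to all regressors and mean-zero passes through
  ortho <- qr.resid(qr(X), rnorm(n))
  Y[, 2] <- ortho
  vm <- make_vm(Y)
  out <- regress_nuisance(vm, nuis, filter_regressors = FALSE)$values
  expect_lte(max(abs(out[, 1])), 1e-8 * max(abs(nuis$global_signal)))
  expect_equal(out[, 2], ortho, tolerance = 1e-8)
  # residuals match the normal-equations oracle
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(out, unname(Y - X %*% beta), tolerance = 1e-6)
  # residuals are uncorrelated with every regressor
  for (j in 2:ncol(X))
    expect_lte(max(abs(cor(out, X[, j]))), 1e-8)
  # idempotence
  twice <- regress_nuisance(make_vm(out), nuis, filter_regressors = FALSE)$values
  expect_equal(twice, out, tolerance = 1e-8)
})

test_that("regression handles degenerate designs and columns with warnings", {
  set.seed(1)
  n <- 60
  nuis <- list(motion = matrix(rnorm(n * 6), n, 6),
               global_signal = rnorm(n), white_signal = rnorm(n),
               csf_signal = rnorm(n))
  nuis$csf_signal <- nuis$white_signal      # rank-deficient design
  Y <- matrix(rnorm(n * 3), n, 3)
  Y[, 3] <- 7                               # zero-variance column
  expect_warning(expect_warning(
    out <- regress_nuisance(make_vm(Y), nuis, filter_regressors = FALSE),
    "rank deficient"), "zero-variance")
  expect_lte(max(abs(out$values[, 3])), 1e-10)
  expect_error(regress_nuisance(make_vm(Y[1:10, ]), nuis), "length")
})

test_that("preprocess_session filters before regressing", {
  st <- generate_study(small_config(seed = 2, n_subjects = 1,
                                    n_sessions_per_condition = 1, n_volumes = 60))
  s <- st$sessions[[1]]
  vm <- preprocess_session(s$bold, s$masks, s$nuisance)
  expect_true(!is.null(vm$filter))
  expect_true(isTRUE(vm$nuisance_regressed))
  manual <- regress_nuisance(bandpass(extract_gray_timeseries(s$bold, s$masks)),
                             s$nuisance)
  expect_equal(vm$values, manual$values)
})
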