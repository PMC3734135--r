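test_that("identical config and seed give bit-identical studies", {
  cfg <- small_config(seed = 7, n_subjects = 1, n_sessions_per_condition = 1,
                      n_volumes = 30)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(lapply(a$sessions, function(s) s$bold$data),
                   lapply(b$sessions, function(s) s$bold$data))
  expect_identical(a$sessions[[1]]$nuisance, b$sessions[[1]]$nuisance)
  expect_false(identical(a$sessions[[1]]$bold$data,
                         generate_study(small_config(seed = 8, n_subjects = 1,
                                                     n_sessions_per_condition = 1,
                                                     n_volumes = 30))$sessions[[1]]$bold$data))
})

test_that("study design matches the configured acquisition protocol", {
  cfg <- simulation_config(n_subjects = 1, n_sessions_per_condition = 3,
                           n_volumes = 120, tr_seconds = 2, seed = 2)
  st <- generate_study(cfg)
  expect_length(st$sessions, 6L)
  for (s in st$sessions) {
    expect_equal(dim(s$bold$data)[4], 120L)
    expect_equal(s$bold$tr_seconds, 2)
  }
  # alternation starting with rest, then task, session indices per condition
  conds <- vapply(st$sessions, function(s) s$bold$condition, "")
  expect_equal(conds, rep(c("rest", "task"), 3))
  idx <- vapply(st$sessions, function(s) s$bold$session_index, 1L)
  expect_equal(idx, rep(1:3, each = 2))
  # first_condition flag flips the alternation
  cfg2 <- simulation_config(n_subjects = 1, n_sessions_per_condition = 1,
                            first_condition = "task", seed = 2, n_volumes = 20)
  expect_equal(generate_study(cfg2)$sessions[[1]]$bold$condition, "task")
})

test_that("tissue masks are disjoint, gray nonempty, nuisance lengths match", {
  st <- generate_study(small_config(seed = 3, n_subjects = 1,
                                    n_sessions_per_condition = 1, n_volumes = 25))
  m <- st$masks
  expect_true(any(m$gray))
  expect_false(any(m$gray & m$white))
  expect_false(any(m$gray & m$csf))
  expect_false(any(m$white & m$csf))
  nu <- st$sessions[[1]]$nuisance
  expect_equal(dim(nu$motion), c(25L, 6L))
  expect_length(nu$global_signal, 25L)
  expect_length(nu$white_signal, 25L)
  expect_length(nu$csf_signal, 25L)
  # ground-truth hub masks are retrievable and lie in gray matter
  expect_true(any(st$hubs$rest_hub))
  expect_true(all(m$gray[st$hubs$rest_hub]))
  expect_true(all(m$gray[st$hubs$task_hub]))
})

test_that("configuration errors name the offending field", {
  expect_error(simulation_config(n_volumes = 1), "n_volumes")
  expect_error(simulation_config(grid_shape = c(4, 4)), "grid_shape")
  expect_error(simulation_config(ar1_coefficient = 1), "ar1_coefficient")
  expect_error(simulation_config(tr_seconds = 0), "tr_seconds")
  expect_error(hub_spec(c(0, 0, 0), cor_rest = 1), "cor_rest")
})

test_that("planted rest-hub correlation is condition-dependent across seeds", {
  # stronger within-hub coupling at rest than task must show in the raw
  # sample correlations in nearly every replicate
  wins <- 0L
  n_rep <- 100L
  for (seed in seq_len(n_rep)) {
    cfg <- simulation_config(
      n_subjects = 1, n_sessions_per_condition = 1, n_volumes = 200,
      grid_shape = c(10L, 10L, 8L),
      rest_hub_spec = hub_spec(rbind(c(0, -18, 8)), radius_mm = 8,
                               cor_rest = 0.8, cor_task = 0.2),
      seed = seed)
    st <- generate_study(cfg)
    hub <- which(st$hubs$rest_hub)
    mean_r <- function(sess) {
      flat <- matrix(sess$bold$data, ncol = 200)
      r <- cor(t(flat[hub, ]))
      mean(r[upper.tri(r)])
    }
    conds <- vapply(st$sessions, function(s) s$bold$condition, "")
    if (mean_r(st$sessions[[which(conds == "rest")]]) >
        mean_r(st$sessions[[which(conds == "task")]])) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("drift component is band-limited below 0.009 Hz", {
  for (seed in 1:20) {
    set.seed(seed)
    d <- voxnet:::.drift_series(120, 2)
    spec <- Mod(fft(d))^2
    freq <- pmin(0:119, 120 - (0:119)) / (120 * 2)
    frac_low <- sum(spec[freq < 0.009]) / sum(spec)
    expect_gte(frac_low, 0.9)
  }
})
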