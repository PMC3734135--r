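# independent repeated-measures oracle via stats::aov error strata
oracle_aov <- function(tab) {
  tab$subject <- factor(tab$subject)
  tab$condition <- factor(tab$condition)
  tab$session <- factor(tab$session)
  fit <- stats::aov(value ~ condition * session +
                      Error(subject / (condition * session)), data = tab)
  s <- summary(fit)
  grab <- function(stratum, row) {
    d <- s[[stratum]][[1]]
    list(F = d[row, "F value"], df_num = d[row, "Df"],
         p = d[row, "Pr(>F)"], SS = d[row, "Sum Sq"])
  }
  list(condition = grab("Error: subject:condition", "condition"),
       session = grab("Error: subject:session", "session"),
       interaction = grab("Error: subject:condition:session",
                          "condition:session"))
}

test_that("sphere masks follow voxel-center geometry", {
  dim3 <- c(14L, 14L, 10L)
  aff <- voxnet:::.grid_affine(dim3, c(4, 4, 5))
  # radius 0 at an exact voxel center hits exactly that voxel
  idx0 <- c(3, 5, 2)                      # 0-based grid index
  ctr <- as.numeric((aff %*% c(idx0, 1))[1:3])
  m0 <- sphere_mask(roi_spec("pt", ctr, 0), dim3, aff)
  expect_equal(sum(m0), 1L)
  expect_true(m0[idx0[1] + 1, idx0[2] + 1, idx0[3] + 1])
  # center midway between voxel centers, radius below half-spacing: empty
  expect_warning(
    m1 <- sphere_mask(roi_spec("gap", ctr + c(2, 0, 0), 1.9), dim3, aff),
    "empty")
  expect_equal(sum(m1), 0L)
  # 10 mm sphere equals brute-force enumeration over the whole grid
  spec <- roi_spec("sph", c(-9, -7, 8), 10)
  m2 <- sphere_mask(spec, dim3, aff)
  cnt <- 0L
  for (i in 1:14) for (j in 1:14) for (k in 1:10) {
    mm <- (aff %*% c(i - 1, j - 1, k - 1, 1))[1:3]
    inside <- sqrt(sum((mm - c(-9, -7, 8))^2)) <= 10
    cnt <- cnt + inside
    expect_equal(m2[i, j, k], inside)
  }
  expect_equal(sum(m2), cnt)
})

test_that("roi_mean averages the in-mask nodes", {
  st <- generate_study(small_config(seed = 8, n_subjects = 1,
                                    n_sessions_per_condition = 1, n_volumes = 20))
  s <- st$sessions[[1]]
  nm <- extract_gray_timeseries(s$bold, s$masks)$node_map
  mv <- voxnet:::.new_metric_volume("K", rep(3.5, nrow(nm)), nm)
  full <- array(TRUE, dim = attr(nm, "grid_dim"))
  expect_equal(roi_mean(mv, full)$value, 3.5)
  # two-voxel mask valued 1 and 3
  vals <- rep(0, nrow(nm)); vals[5] <- 1; vals[9] <- 3
  mv2 <- voxnet:::.new_metric_volume("K", vals, nm)
  mask <- array(FALSE, dim = attr(nm, "grid_dim"))
  mask[nm$i[5], nm$j[5], nm$k[5]] <- TRUE
  mask[nm$i[9], nm$j[9], nm$k[9]] <- TRUE
  out <- roi_mean(mv2, mask)
  expect_equal(out$value, 2)
  expect_equal(out$n_voxels, 2L)
  # loop-accumulation oracle on a random mask
  set.seed(12)
  vals <- rnorm(nrow(nm))
  mv3 <- voxnet:::.new_metric_volume("x", vals, nm)
  rmask <- array(runif(prod(attr(nm, "grid_dim"))) < 0.3,
                 dim = attr(nm, "grid_dim"))
  acc <- 0; cnt <- 0
  for (r in seq_len(nrow(nm)))
    if (rmask[nm$i[r], nm$j[r], nm$k[r]]) { acc <- acc + vals[r]; cnt <- cnt + 1 }
  expect_equal(roi_mean(mv3, rmask)$value, acc / cnt)
  expect_error(roi_mean(mv3, array(FALSE, dim = attr(nm, "grid_dim"))),
               "no gray-matter node")
})

test_that("repeated-measures ANOVA matches independent oracles", {
  for (seed in 1:8) {
    tab <- rand_anova_table(n_subj = 5, n_sess = 5, effect = 0.4 * (seed %% 3),
                            seed = seed)
    got <- rm_anova_2xS(tab)
    want <- oracle_aov(tab)
    for (i in seq_len(3)) {
      w <- want[[c("condition", "session", "interaction")[i]]]
      expect_equal(got$F[i], w$F, tolerance = 1e-8)
      expect_equal(got$df_num[i], w$df_num)
      expect_equal(got$p[i], w$p, tolerance = 1e-8)
      expect_equal(got$SS[i], w$SS, tolerance = 1e-8)
    }
    # SS decomposition is conservative
    comp <- attr(got, "ss_components")
    expect_equal(sum(comp), attr(got, "ss_total"),
                 tolerance = 1e-8 * max(1, attr(got, "ss_total")))
    # partial eta squared from its own error term
    expect_equal(got$partial_eta_sq, got$SS / (got$SS + got$SS_error))
  }
})

test_that("ANOVA is scale invariant and degrees of freedom match design", {
  tab <- rand_anova_table(n_subj = 5, n_sess = 5, effect = 0.5, seed = 99)
  a1 <- rm_anova_2xS(tab)
  tab2 <- tab; tab2$value <- tab2$value * 1000
  a2 <- rm_anova_2xS(tab2)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
  expect_equal(a1$partial_eta_sq, a2$partial_eta_sq, tolerance = 1e-10)
  expect_equal(a1$df_num, c(1, 4, 4))
  expect_equal(a1$df_den, c(4, 16, 16))
})

test_that("degenerate ANOVA tables are flagged", {
  tab <- rand_anova_table(n_subj = 3, n_sess = 2, seed = 1)
  tab$value <- 1
  expect_warning(flat <- rm_anova_2xS(tab), "degenerate")
  expect_true(all(is.nan(flat$F)))
  # pure condition effect with zero noise: partial eta squared = 1
  tab2 <- rand_anova_table(n_subj = 3, n_sess = 2, seed = 1)
  tab2$value <- ifelse(tab2$condition == "rest", 1, 2)
  w <- capture_warnings(pure <- rm_anova_2xS(tab2))
  expect_match(w, "boundary", all = FALSE)
  expect_equal(pure$partial_eta_sq[1], 1.0)
  expect_equal(pure$F[1], Inf)
  expect_equal(pure$p[1], 0)
  # missing cell errors name the cell
  tab3 <- rand_anova_table(n_subj = 3, n_sess = 2, seed = 2)
  expect_error(rm_anova_2xS(tab3[-1, ]), "subject s1")
})
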