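test_that("distribution summary is the sample mean and N-1 standard deviation", {
  s <- summarize_distribution(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sdev, 1)
  expect_equal(s$n, 3L)
  expect_equal(summarize_distribution(rep(4.2, 5))$sdev, 0)
  expect_error(summarize_distribution(1), class = "motoprofile_data_error")
  expect_error(summarize_distribution(c(1, NA, 3)),
               class = "motoprofile_domain_error")
})

test_that("summary agrees with a naive two-pass oracle", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(sample(2:500, 1), runif(1, -5, 5), runif(1, 0.01, 10))
    s <- summarize_distribution(x)
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    expect_equal(s$mean, m, tolerance = 1e-12)
    expect_equal(s$sdev, sqrt(v), tolerance = 1e-12)
  }
})

test_that("cut-offs are mean + k*sd on each side", {
  expect_equal(derive_acceleration_thresholds(list(mean = 2, sdev = 1)),
               c(accel_t1 = 3, accel_t2 = 4))
  expect_equal(derive_deceleration_thresholds(list(mean = 1, sdev = 0.5)),
               c(decel_t1 = -1.5, decel_t2 = -2))
  # sign symmetry: the braking derivation is the negated throttle one
  s <- list(mean = 1.7, sdev = 0.4)
  expect_equal(unname(derive_deceleration_thresholds(s)),
               -unname(derive_acceleration_thresholds(s)))
  expect_warning(derive_acceleration_thresholds(list(mean = 1, sdev = 0)),
                 "degenerate")
  expect_error(derive_acceleration_thresholds(list(mean = 1, sdev = 1), 2, 2),
               class = "motoprofile_config_error")
})

test_that("thresholds are monotone in mean and sdev", {
  set.seed(22)
  for (rep in 1:20) {
    m <- runif(1, 0, 3); s <- runif(1, 0, 2)
    dm <- runif(1, 0, 1); ds <- runif(1, 0, 1)
    base <- suppressWarnings(derive_acceleration_thresholds(list(mean = m, sdev = s)))
    up <- suppressWarnings(derive_acceleration_thresholds(list(mean = m + dm, sdev = s + ds)))
    expect_true(all(up >= base))
    dbase <- suppressWarnings(derive_deceleration_thresholds(list(mean = m, sdev = s)))
    dup <- suppressWarnings(derive_deceleration_thresholds(list(mean = m + dm, sdev = s + ds)))
    expect_true(all(dup <= dbase))
  }
})

test_that("learning pools the positive side and the braking magnitudes", {
  a <- c(0.5, 1.5, -0.4, -2.0, 0, 2.5, -1.2)
  th <- learn_thresholds(a)
  pos <- summarize_distribution(c(0.5, 1.5, 2.5))
  neg <- summarize_distribution(c(0.4, 2.0, 1.2))
  expect_equal(th$accel_t1, pos$mean + pos$sdev)
  expect_equal(th$accel_t2, pos$mean + 2 * pos$sdev)
  expect_equal(th$decel_t1, -(neg$mean + neg$sdev))
  expect_equal(th$decel_t2, -(neg$mean + 2 * neg$sdev))
  expect_error(learn_thresholds(c(1, 2, 3)), class = "motoprofile_data_error")
})

test_that("gaussian coverage counts values inside mean +/- k sd", {
  expect_equal(gaussian_coverage(c(-1, 0, 1), 1), 1)
  expect_equal(gaussian_coverage(c(1, 2, 6, 9), 0), 0)  # nothing sits on the mean
  expect_error(gaussian_coverage(c(1, 2), -1), class = "motoprofile_domain_error")
})

test_that("threshold sets validate their ordering and survive JSON", {
  expect_error(threshold_set(2, 1, -1, -2), class = "motoprofile_config_error")
  expect_error(threshold_set(1, 2, -2, -1.5),  # decel_t2 must be <= decel_t1
               class = "motoprofile_config_error")
  th <- threshold_set(1.3, 2.5, -6.01, -9.54, source = "unit")
  back <- thresholds_from_json(thresholds_to_json(th))
  expect_equal(unclass(back), unclass(th))

  path <- withr::local_tempfile(fileext = ".json")
  thresholds_to_json(th, path)
  expect_equal(thresholds_from_json(path)$accel_t2, 2.5)
})

test_that("presets carry the published cut-off pairs", {
  m <- threshold_preset("methods")
  expect_equal(c(m$accel_t1, m$accel_t2, m$decel_t1, m$decel_t2),
               c(1.3, 2.5, -6.01, -9.54))
  c2 <- threshold_preset("conclusions")
  expect_equal(c(c2$accel_t1, c2$accel_t2), c(4.73, 7.48))
})
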