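methods_th <- threshold_preset("methods")

test_that("sample classification honors the published boundary conventions", {
  lab <- function(a) as.character(classify_sample(a, methods_th))
  expect_equal(lab(1.0), "normal_accel")
  expect_equal(lab(1.3), "normal_accel")        # boundary closed on normal
  expect_equal(lab(1.31), "aggressive_accel")
  expect_equal(lab(2.5), "aggressive_accel")
  expect_equal(lab(3.0), "dangerous_accel")
  expect_equal(lab(-6.01), "normal_decel")      # boundary closed on normal
  expect_equal(lab(-7.0), "aggressive_decel")
  expect_equal(lab(-9.54), "aggressive_decel")
  expect_equal(lab(-9.55), "dangerous_decel")
  expect_equal(lab(0), "zero")
})

test_that("zero-band ties go to zero before the sign split", {
  got <- classify_sample(c(0.04, -0.05, 0.06), methods_th, zero_eps = 0.05)
  expect_equal(as.character(got), c("zero", "zero", "normal_accel"))
})

test_that("classification matches a literal if/else transcription on random samples", {
  oracle <- function(a, th, eps = 0) {
    if (abs(a) <= eps) return("zero")
    if (a > 0) {
      if (a <= th$accel_t1) return("normal_accel")
      if (a <= th$accel_t2) return("aggressive_accel")
      return("dangerous_accel")
    }
    if (a >= th$decel_t1) return("normal_decel")
    if (a >= th$decel_t2) return("aggressive_decel")
    "dangerous_decel"
  }
  set.seed(31)
  a <- c(runif(200, -12, 12), 0, 1.3, 2.5, -6.01, -9.54)
  expect_equal(as.character(classify_sample(a, methods_th)),
               vapply(a, oracle, character(1), th = methods_th))
  th2 <- learn_thresholds(rnorm(500, 0, 2))
  eps <- 0.1
  expect_equal(as.character(classify_sample(a, th2, eps)),
               vapply(a, oracle, character(1), th = th2, eps = eps))
})

test_that("every sample and reading gets exactly one label", {
  set.seed(32)
  for (rep in 1:10) {
    a <- runif(50, -15, 15)
    th <- suppressWarnings(learn_thresholds(rnorm(100, 0, runif(1, 0.5, 3))))
    lab <- classify_sample(a, th, zero_eps = runif(1, 0, 0.2))
    expect_false(anyNA(lab))
    v <- runif(50, 0, 150)
    pol <- speed_policy(runif(1, 40, 100), runif(1, 1.05, 1.6))
    slab <- classify_speed(v, pol)
    expect_false(anyNA(slab))
  }
})

test_that("raising thresholds or the limit never worsens a label", {
  sev <- function(l) match(sub("_(accel|decel)$", "", l),
                           c("zero", "normal", "aggressive", "dangerous"))
  set.seed(33)
  a <- runif(300, -10, 10)
  th_lo <- threshold_set(1, 2, -1.5, -3)
  th_hi <- threshold_set(1.4, 2.6, -1.5, -3)
  expect_true(all(
    sev(as.character(classify_sample(a[a > 0], th_hi))) <=
      sev(as.character(classify_sample(a[a > 0], th_lo)))
  ))
  v <- runif(300, 0, 150)
  s_lo <- classify_speed(v, speed_policy(70))
  s_hi <- classify_speed(v, speed_policy(90))
  expect_true(all(as.integer(s_hi) <= as.integer(s_lo)))
})

test_that("speed labels split at the limit and the dangerous tier", {
  pol <- speed_policy(80, 1.25)
  expect_equal(as.character(classify_speed(c(80, 81, 100, 100.1, 120), pol)),
               c("normal_speed", "over_speed", "over_speed",
                 "dangerous_speed", "dangerous_speed"))
  expect_error(classify_speed(-1, pol), class = "motoprofile_domain_error")
  expect_error(speed_policy(80, 1), class = "motoprofile_domain_error")
})

test_that("label_trip fans both classifiers over a trip", {
  tr <- make_trip(rep(50, 5))
  ks <- derive_kinematics(tr)
  got <- label_trip(ks, tr$records, methods_th)
  expect_equal(as.character(got$events$event_label), rep("zero", 4))
  expect_equal(as.character(got$speeds$speed_label), rep("normal_speed", 5))
  expect_error(label_trip(ks, tr$records[1:3, ], methods_th),
               class = "motoprofile_data_error")

  empty <- label_trip(tibble::tibble(t = numeric(0), v = numeric(0),
                                     a = numeric(0), dt = numeric(0)),
                      tibble::tibble(t = numeric(0), speed = numeric(0)),
                      methods_th)
  expect_equal(nrow(empty$events), 0L)
  expect_equal(nrow(empty$speeds), 0L)
})
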