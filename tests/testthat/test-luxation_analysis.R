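# Luxation criterion, reaction-force series, sweep bookkeeping.

test_that("reaction series is all zero without contact", {
  t <- seq(0, 50, by = 0.01)
  res <- synthetic_result(t, rcx = rep(0, length(t)),
                          disp_x = rep(0, length(t)))
  ser <- mediolateral_reaction_series(res)
  expect_equal(ser$rcforce_kN, rep(0, length(t)))
  expect_equal(ser$time_s, t)
})

test_that("luxation criterion separates stable, transient and sustained", {
  t <- seq(0, 50, by = 0.01)
  ## positive throughout: stable
  r <- detect_luxation(synthetic_result(t, rcx = rep(0.002, length(t)),
                                        disp_x = rep(-0.2, length(t))))
  expect_false(r$luxated)
  expect_equal(r$direction, "none")
  expect_null(r$onset_time)

  ## positive until t = 12, non-positive after, displacement -6 mm
  rcx <- ifelse(t < 12, 0.002, -0.001)
  disp <- ifelse(t < 12, -0.2, -6)
  r <- detect_luxation(synthetic_result(t, rcx, disp))
  expect_true(r$luxated)
  expect_equal(r$direction, "medial")
  expect_equal(r$onset_time, 12)
  expect_equal(r$max_medial_displacement, 6)

  ## temporary zero touch at 11 s, recovery, complete luxation at 15 s
  rcx <- rep(0.002, length(t))
  rcx[t >= 11 & t < 11.02] <- 0
  rcx[t >= 15] <- -0.001
  disp <- ifelse(t >= 15, -6, -0.2)
  r <- detect_luxation(synthetic_result(t, rcx, disp))
  expect_true(r$luxated)
  expect_equal(r$first_zero_time, 11)
  expect_equal(r$onset_time, 15)
  expect_gte(r$onset_time, r$first_zero_time)

  ## sustained zero force without displacement past the apex: not luxated
  r <- detect_luxation(synthetic_result(t, rcx = rep(0, length(t)),
                                        disp_x = rep(-0.5, length(t))))
  expect_false(r$luxated)

  ## incomplete protocol is rejected
  short <- synthetic_result(seq(0, 50, by = 0.01), rep(1, 5001), rep(0, 5001))
  short$samples <- short$samples[short$samples$time_s <= 20, ]
  expect_error(detect_luxation(short), "full protocol")
})

test_that("detection is invariant to 2x resampling of the series", {
  t1 <- seq(0, 50, by = 0.01)
  t2 <- seq(0, 50, by = 0.005)
  mk <- function(t) {
    rcx <- 0.002 - 0.0001 * pmax(0, t - 8)
    disp <- -pmax(0, t - 8) * 0.2
    synthetic_result(t, rcx, disp)
  }
  r1 <- detect_luxation(mk(t1))
  r2 <- detect_luxation(mk(t2))
  expect_equal(r1$luxated, r2$luxated)
  expect_lt(abs(r1$onset_time - r2$onset_time), 0.01 + 1e-9)
})

test_that("critical and stable-max angles follow their definitions", {
  mk_report <- function(ang, lux) {
    structure(list(luxated = lux, onset_time = if (lux) 10 else NULL,
                   first_zero_time = NULL,
                   direction = if (lux) "medial" else "none",
                   max_medial_displacement = 0, aldfa_deg = ang),
              class = "luxation_report")
  }
  sweep <- structure(list(
    angles = c(100, 101, 102),
    reports = list(`100` = mk_report(100, FALSE),
                   `101` = mk_report(101, TRUE),
                   `102` = mk_report(102, FALSE)),
    critical_angle = 101, stable_max_angle = 102,
    errors = list(), results = NULL), class = "sweep_result")
  ## minimum luxating angle, not a contiguity claim
  expect_equal(critical_angle(sweep), 101)
  expect_equal(stable_max_angle(sweep), 102)
  expect_error(sweep_aldfa(angles = numeric(0)), "non-empty")
})

test_that("a single-angle sweep reproduces the in-sweep verdict", {
  sw <- fixture_default_sweep()
  single <- sweep_aldfa(angles = 103)
  expect_equal(critical_angle(single), 103)
  expect_equal(single$reports[["103"]]$onset_time,
               sw$reports[["103"]]$onset_time)
  expect_null(stable_max_angle(single))
  ## all-stable sweep: no critical angle
  stable <- sweep_aldfa(angles = 95)
  expect_null(critical_angle(stable))
  expect_equal(stable_max_angle(stable), 95)
})

test_that("the shipped reference onset table is context, eight angles", {
  tab <- luxation_reference_times()
  expect_equal(nrow(tab), 8)
  expect_equal(tab$aldfa_deg, 103:110)
  expect_true(all(tab$onset_s > 10 & tab$onset_s < 30))
})
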