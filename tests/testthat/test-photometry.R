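flat_recording <- function(f0_470 = 100, f0_410 = 60, fs = 30,
                           duration_s = 300, tags = 200) {
  n <- duration_s * fs
  photometry_recording(rep(f0_470, n), rep(f0_410, n), fs = fs,
                       event_tags = tags)
}

test_that("dF/F implements the per-tag 2-minute baseline formula", {
  # constant F: dF/F identically zero
  d <- dff(flat_recording(), "470")
  expect_true(all(d$dff == 0))
  expect_equal(unique(d$f0), 100)

  # F = 1.1 F0 on the event window: dF/F = 0.1 exactly
  fs <- 30; n <- 300 * fs
  f <- rep(100, n)
  f[(198 * fs):n] <- 110  # step 2 s before the tag at 200 s
  rec <- photometry_recording(f, rep(60, n), fs = fs, event_tags = 200)
  d2 <- dff(rec, "470", pre_s = 1, post_s = 5)
  # baseline mean includes the last 2 s of the step; F0 accordingly
  f0 <- mean(f[(round((200 - 120) * fs) + 1):(200 * fs)])
  expect_equal(unique(d2$f0), f0)
  expect_equal(max(d2$dff), (110 - f0) / f0, tolerance = 1e-12)

  expect_error(photometry_recording(rep(100, 10), rep(60, 10), fs = 1,
                                    event_tags = 5), "120 s")
})

test_that("dF/F is invariant to a common gain on F and F0", {
  g <- gen_photometry(photo_spec(
    duration_s = 400, noise_sd = 0.005,
    transients = tibble::tibble(t_s = 200.3, amplitude = 0.1,
                                rise_s = 0.2, decay_s = 1),
    event_tags = 200), seed = 4)
  rec <- g$recording
  rec_gain <- photometry_recording(7.3 * rec$f470, 7.3 * rec$f410,
                                   fs = rec$fs,
                                   event_tags = rec$event_tags)
  d1 <- dff(rec, "470")
  d2 <- dff(rec_gain, "470")
  expect_equal(d1$dff, d2$dff, tolerance = 1e-12)
})

test_that("event alignment yields one row per usable tag and flat SEM for
           identical transients", {
  tags <- c(150, 300, 450)
  g <- gen_photometry(photo_spec(
    duration_s = 600,
    transients = tibble::tibble(t_s = tags + 0.2, amplitude = 0.1,
                                rise_s = 0.2, decay_s = 1),
    event_tags = tags), seed = 5)
  al <- event_aligned(g$recording, "470")
  expect_equal(nrow(al$matrix), 3)
  # noiseless identical transients: SEM ~ 0, mean = single-trial shape
  expect_lt(max(al$summary$sem), 1e-6)
  expect_equal(max(al$summary$mean), 0.1, tolerance = 0.02)

  # tags in event-free noise: mean ~ 0
  g0 <- gen_photometry(photo_spec(duration_s = 600, noise_sd = 0.01,
                                  event_tags = tags), seed = 6)
  al0 <- event_aligned(g0$recording, "470")
  expect_lt(max(abs(al0$summary$mean)), 0.02)

  # a tag window that exceeds the recording end is dropped with a warning
  gshort <- gen_photometry(photo_spec(duration_s = 303,
                                      event_tags = c(200, 301)), seed = 7)
  expect_warning(al2 <- event_aligned(gshort$recording, "470"),
                 "skipped")
  expect_equal(nrow(al2$matrix), 1)
})

test_that("AUC integrates the stated window and is additive and linear", {
  # handcrafted trace: dF/F = 0.1 on [0, 3], 0 elsewhere; the sample on
  # the falling edge takes the midpoint value, the exact trapezoidal
  # representation of a step located at a grid point
  fs <- 30
  grid <- seq(-2, 5, by = 1 / fs)
  rect <- ifelse(grid >= 0 & grid < 3, 0.1, 0)
  rect[abs(grid - 3) < 1e-9] <- 0.05
  mat <- matrix(rect, nrow = 1)
  tr <- structure(list(matrix = mat, rel_time_s = grid,
                       summary = tibble::tibble(rel_time_s = grid,
                                                mean = mat[1, ],
                                                sem = 0),
                       channel = "470", n_events = 1, fs = fs),
                  class = "dff_trace")
  a <- auc_dff(tr, 0, 5)
  expect_equal(a$mean_auc, 0.3, tolerance = 1e-9)
  expect_equal(auc_dff(tr, 0, 5)$mean_auc,
               auc_dff(tr, 0, 2.5)$mean_auc +
                 auc_dff(tr, 2.5, 5)$mean_auc,
               tolerance = 1e-9)

  tr2 <- tr; tr2$matrix <- 2 * tr$matrix
  expect_equal(auc_dff(tr2, 0, 5)$mean_auc, 0.6, tolerance = 1e-9)

  z <- tr; z$matrix[] <- 0
  expect_equal(auc_dff(z, 0, 5)$mean_auc, 0)
  expect_error(auc_dff(tr, 3, 3), "empty")
  expect_error(auc_dff(tr, 0, 50), "outside")
})

test_that("transient amplitudes are recovered across the stated range", {
  tags <- c(150, 250, 350, 450)
  for (amp in c(0.02, 0.05, 0.1, 0.2)) {
    g <- gen_photometry(photo_spec(
      duration_s = 600, noise_sd = amp / 10,  # peak SNR 10
      transients = tibble::tibble(t_s = tags + 0.3, amplitude = amp,
                                  rise_s = 0.2, decay_s = 1),
      event_tags = tags), seed = 8)
    al <- event_aligned(g$recording, "470")
    expect_equal(max(al$summary$mean), amp, tolerance = 0.05)
  }
})

test_that("isosbestic regression removes shared motion and nothing else", {
  # pure shared motion: corrected trace ~ 0
  gm <- gen_photometry(photo_spec(duration_s = 500, motion_amp = 0.03,
                                  event_tags = c(200, 350)), seed = 9)
  ic <- isosbestic_check(gm$recording)
  expect_true(ic$correction_applied)
  expect_gt(min(ic$report$correlation), 0.99)
  raw <- event_aligned(gm$recording, "470")
  expect_lt(max(abs(ic$corrected)), 0.01 * max(abs(raw$matrix)))

  # transients with no motion: corrected ~ raw 470 dF/F
  gt <- gen_photometry(photo_spec(
    duration_s = 500, noise_sd = 0.003,
    transients = tibble::tibble(t_s = c(200.3, 350.3), amplitude = 0.1,
                                rise_s = 0.2, decay_s = 1),
    event_tags = c(200, 350)), seed = 10)
  ict <- isosbestic_check(gt$recording)
  rawt <- event_aligned(gt$recording, "470")
  expect_equal(max(ict$corrected), max(rawt$matrix), tolerance = 0.1)

  # constant 410: correction skipped and reported
  n <- 500 * 30
  rec0 <- photometry_recording(rep(100, n) + c(rep(0, 6000), rep(1, n - 6000)),
                               rep(60, n), fs = 30, event_tags = 300)
  ic0 <- isosbestic_check(rec0)
  expect_false(ic0$correction_applied)
  expect_null(ic0$corrected)
})
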