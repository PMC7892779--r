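# A small pre-built epoch set shared across the power tests.
pw_layout <- tiny_layout(7L)
pw_design <- study_design(n_subjects = 6L, trials_per_condition = 6L,
                          sampling_rate = 100, epoch_window = c(-0.2, 0.6),
                          conditions = c("A", "B"))
pw_epochs <- simulate_noise_epochs(pw_design, noise_spec(sd_broadband = 8),
                                   pw_layout, seed = 31)

test_that("trial partitioning is near-equal, exhaustive and seeded", {
  blk <- pool_trials(pw_epochs, 1)
  expect_equal(dim(blk$amp), c(12L, 7L, dim(pw_epochs$amp)[5]))
  p9 <- partition_trials(pw_epochs, 1, k = 3, seed = 1)
  expect_equal(unname(sort(lengths(p9))), c(4L, 4L, 4L))
  # 12 pooled trials -> (4,4,4); union is everything, no duplicates
  all_idx <- sort(unname(unlist(p9)))
  expect_identical(all_idx, 1:12)
  expect_identical(partition_trials(pw_epochs, 1, seed = 5),
                   partition_trials(pw_epochs, 1, seed = 5))
  expect_false(identical(partition_trials(pw_epochs, 1, seed = 5),
                         partition_trials(pw_epochs, 1, seed = 6)))
  # explicit small cases: 9 -> (3,3,3); 10 -> {4,3,3}
  des9 <- study_design(n_subjects = 1L, trials_per_condition = 9L,
                       sampling_rate = 100, epoch_window = c(0, 0.1),
                       conditions = "A")
  ep9 <- simulate_noise_epochs(des9, noise_spec(sd_broadband = 1),
                               tiny_layout(4L), 1)
  expect_equal(lengths(partition_trials(ep9, 1, seed = 2)), c(3L, 3L, 3L),
               ignore_attr = TRUE)
  des10 <- study_design(n_subjects = 1L, trials_per_condition = 10L,
                        sampling_rate = 100, epoch_window = c(0, 0.1),
                        conditions = "A")
  ep10 <- simulate_noise_epochs(des10, noise_spec(sd_broadband = 1),
                                tiny_layout(4L), 1)
  expect_equal(unname(sort(lengths(partition_trials(ep10, 1, seed = 2)))),
               c(3L, 3L, 4L))
  des2 <- study_design(n_subjects = 1L, trials_per_condition = 2L,
                       sampling_rate = 100, epoch_window = c(0, 0.1),
                       conditions = "A")
  ep2 <- simulate_noise_epochs(des2, noise_spec(sd_broadband = 1),
                               tiny_layout(4L), 1)
  expect_error(partition_trials(ep2, 1, seed = 1), "at least 3")
})

test_that("sigma estimation is the plain across-trial SD at one point", {
  blk <- pool_trials(pw_epochs, 2)
  ti <- which.min(abs(blk$time - 0.25))
  for (e in c(1, 4)) {
    expect_equal(estimate_sigma(pw_epochs, 2, pw_layout$id[e], 0.25),
                 sd(blk$amp[, e, ti]), tolerance = 1e-12)
  }
  # all trials identical at the point -> 0; two-point case -> sqrt(2)
  cst <- pw_epochs
  cst$amp[2, , , 1, ti] <- 5
  expect_equal(estimate_sigma(cst, 2, pw_layout$id[1], 0.25), 0)
  two <- pw_epochs
  two$amp[2, , , 1, ti] <- 0
  two$amp[2, 1, 1, 1, ti] <- 2
  expect_equal(estimate_sigma(two, 2, pw_layout$id[1], 0.25),
               sd(c(2, rep(0, 11))), tolerance = 1e-12)
  expect_error(estimate_sigma(pw_epochs, 1, 999, 0.25), "not in layout")
  expect_error(estimate_sigma(pw_epochs, 1, pw_layout$id[1], 9), "outside")
})

test_that("injection shifts the designated partition by the drawn effect", {
  blk <- pool_trials(pw_epochs, 1)
  parts <- partition_trials(pw_epochs, 1, seed = 3)
  spec <- injection_spec("custom", mu = 2, electrode_set = pw_layout$id[1:3],
                         time_window = c(0.1, 0.4), sign = 1,
                         sigma_electrode = pw_layout$id[1])
  # sigma = 0: exact +2 shift inside window/electrodes of partition 1 only
  out <- inject_effect(blk, parts[[1]], spec, sigma = 0, seed = 4)
  tidx <- which(blk$time >= 0.1 - 0.005 & blk$time <= 0.4 + 0.005)
  delta <- out$amp - blk$amp
  expect_equal(unname(delta[parts[[1]], 1:3, tidx]),
               array(2, c(length(parts[[1]]), 3, length(tidx))),
               tolerance = 1e-12)
  expect_true(all(delta[parts[[2]], , ] == 0))
  expect_true(all(delta[parts[[1]], 4:7, ] == 0))
  expect_true(all(delta[parts[[1]], 1:3, -tidx] == 0))
  # mu = 0 with sigma = 0 leaves everything unchanged
  out0 <- inject_effect(blk, parts[[1]],
                        injection_spec("custom", 0,
                                       electrode_set = pw_layout$id[1:2],
                                       time_window = c(0.1, 0.4), sign = -1),
                        sigma = 0, seed = 4)
  expect_equal(out0$amp, blk$amp)
  # SAN convention: negative-going
  san <- injection_spec("SAN", mu = 1.5, electrode_set = pw_layout$id[1:3],
                        time_window = c(0, 0.4),
                        sigma_electrode = pw_layout$id[1])
  outn <- inject_effect(blk, parts[[1]], san, sigma = 0, seed = 4)
  expect_lt(mean(outn$amp[parts[[1]], 1, tidx] - blk$amp[parts[[1]], 1, tidx]),
            0)
  # per-trial draws: CLT bound on the realized mean shift
  out_mc <- inject_effect(blk, 1:12, spec, sigma = 1, seed = 8)
  shift <- mean(out_mc$amp[, 1:3, tidx] - blk$amp[, 1:3, tidx])
  expect_lt(abs(shift - 2), 3 / sqrt(12))
  # per-subject draw: one common value for all trials
  spec_s <- injection_spec("custom", 2, electrode_set = pw_layout$id[1],
                           time_window = c(0.1, 0.4), sign = 1,
                           draw_level = "per_subject")
  outs <- inject_effect(blk, 1:12, spec_s, sigma = 1, seed = 9)
  d <- outs$amp[, 1, tidx[1]] - blk$amp[, 1, tidx[1]]
  expect_equal(length(unique(round(d, 10))), 1L)
  expect_error(inject_effect(blk, parts[[1]],
                             injection_spec("custom", 1,
                                            electrode_set = pw_layout$id[1],
                                            time_window = c(5, 6), sign = 1),
                             sigma = 0, seed = 1), "outside")
})

test_that("default injection specs follow the component conventions", {
  rm_ <- build_region_map(warn = FALSE)
  san <- injection_spec("SAN", 2)
  expect_identical(san$electrode_set, rm_$anterior)
  expect_equal(san$sign, -1)
  expect_equal(san$time_window, c(0, 2.2))
  expect_equal(san$sigma_electrode, 1L)
  expect_equal(san$sigma_time, 0.25)
  p600 <- injection_spec("P600", 1)
  expect_identical(p600$electrode_set, rm_$posterior)
  expect_equal(p600$sign, 1)
  expect_equal(p600$time_window, c(0.5, 0.7))
  expect_error(injection_spec("SAN", -1), "non-negative")
})

test_that("simulation cells are deterministic and sensitive to big effects", {
  spec <- injection_spec("custom", mu = 0, electrode_set = pw_layout$id[1:3],
                         time_window = c(0.1, 0.4), sign = 1,
                         sigma_electrode = pw_layout$id[1])
  c1 <- run_simulation_cell(pw_epochs, spec, n_subjects = 5, repetitions = 6,
                            P = 60, seed = 11)
  c2 <- run_simulation_cell(pw_epochs, spec, n_subjects = 5, repetitions = 6,
                            P = 60, seed = 11)
  expect_identical(c1$detections, c2$detections)
  expect_equal(c1$detection_rate, c1$detections / 6)
  expect_error(run_simulation_cell(pw_epochs, spec, n_subjects = 100),
               "exceeds")
  # an absurdly large effect is always detected
  spec_big <- injection_spec("custom", mu = 40,
                             electrode_set = pw_layout$id[1:3],
                             time_window = c(0.1, 0.4), sign = 1,
                             sigma_electrode = pw_layout$id[1])
  cb <- run_simulation_cell(pw_epochs, spec_big, n_subjects = 6,
                            repetitions = 6, P = 100, seed = 12)
  expect_equal(cb$detections, 6L)
  # the stricter overlap criterion also fires for a targeted effect
  co <- run_simulation_cell(pw_epochs, spec_big, n_subjects = 6,
                            repetitions = 4, P = 100, seed = 13,
                            detect = "overlap")
  expect_equal(co$detections, 4L)
})

test_that("power_grid runs the full factorial and exports", {
  grid <- power_grid(pw_epochs, "SAN", mu_grid = c(0, 30), n_grid = c(4, 6),
                     repetitions = 4, P = 60, seed = 21,
                     time_window = c(0.1, 0.4),
                     electrode_set = pw_layout$id[1:3])
  expect_equal(nrow(grid), 4L)
  expect_true(all(grid$detection_rate >= 0 & grid$detection_rate <= 1))
  # detection at mu = 30 must dominate mu = 0
  r0 <- grid$detection_rate[grid$mu == 0]
  r30 <- grid$detection_rate[grid$mu == 30]
  expect_true(all(r30 >= r0))
  # single-cell grid reduces to run_simulation_cell
  g1 <- power_grid(pw_epochs, "SAN", mu_grid = 30, n_grid = 6,
                   repetitions = 4, P = 60, seed = 22,
                   time_window = c(0.1, 0.4),
                   electrode_set = pw_layout$id[1:3])
  single <- run_simulation_cell(
    pw_epochs,
    injection_spec("SAN", 30, electrode_set = pw_layout$id[1:3],
                   time_window = c(0.1, 0.4)),
    n_subjects = 6, repetitions = 4, P = 60,
    seed = erpperm:::derive_seeds(22, 1))
  expect_equal(g1$detections, single$detections)
  expect_error(power_grid(pw_epochs, "SAN", mu_grid = numeric(0)),
               "non-empty")
  tsv <- tempfile(fileext = ".tsv")
  write_power_grid(grid, tsv)
  back <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(back$detections, grid$detections)
  js <- tempfile(fileext = ".json")
  write_power_grid(grid, js, "json")
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$detections,
               grid$detections)
})

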