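test_that("coordinate correction converts units and cancels shared motion", {
  paired <- tibble::tibble(frame = 0:3,
                           x_focus = c(10, 11, 12, 13), y_focus = 0,
                           z_focus = c(5, 5, 6, 6),
                           x_fiducial = 0, y_fiducial = 10,
                           z_fiducial = 5)
  rel <- correct_coordinates(paired, pixel_size = 106.7, z_step = 300,
                             frame_interval = 30)
  # raw difference (10, -10, 0) px at frame 0 -> (1.067, -1.067, 0) um
  # before centering
  expect_equal(rel$x[1] + mean((10:13) * 106.7 / 1000), 10 * 106.7 / 1000)
  expect_equal(mean(rel$x), 0)
  expect_equal(mean(rel$y), 0)
  expect_equal(rel$t_s, c(0, 30, 60, 90))

  # focus == fiducial -> all-zero track
  same <- tibble::tibble(frame = 0:4, x_focus = 1:5, y_focus = 2:6,
                         z_focus = 1, x_fiducial = 1:5, y_fiducial = 2:6,
                         z_fiducial = 1)
  rel0 <- correct_coordinates(same, 100, 300)
  expect_true(all(abs(c(rel0$x, rel0$y, rel0$z)) < 1e-12))

  # constant offset on both channels changes nothing
  shifted <- paired
  shifted$x_focus <- shifted$x_focus + 7
  shifted$x_fiducial <- shifted$x_fiducial + 7
  expect_equal(correct_coordinates(shifted, 106.7, 300)$x, rel$x)

  expect_error(correct_coordinates(paired[1, ], 106.7, 300), "2 shared")
})

test_that("MSD matches hand-computed values and handles truncation", {
  tr <- rel_track(cbind(0:3, 0), dt = 1)
  out <- compute_msd(tr, dims = 2)
  expect_equal(out$msd, c(1, 4, 9))
  expect_equal(out$n_pairs, 3:1)
  expect_warning(out2 <- compute_msd(tr, max_lag_frames = 10, dims = 2),
                 "truncated")
  expect_equal(out2$msd, out$msd)
  # stationary track -> MSD identically zero
  still <- rel_track(matrix(1, 5, 2))
  expect_true(all(compute_msd(still)$msd == 0))
})

test_that("MSD equals the brute-force double loop, with and without gaps", {
  set.seed(301)
  for (i in 1:60) {
    tr <- random_gappy_track(50, drop = sample(0:10, 1))
    got <- compute_msd(tr, max_lag_frames = 20, dims = 2)
    want <- msd_brute(tr, 20, dims = 2)
    expect_equal(got$msd, want$msd, tolerance = 1e-12)
    expect_equal(got$n_pairs, want$n_pairs)
    # invariant: pairs non-increasing with lag
    expect_true(all(diff(got$n_pairs) <= 0))
  }
})

test_that("gap frames break pairs that span them", {
  # frames 0,2,4: no gap-free pair exists at any lag
  tr <- rel_track(cbind(c(0, 1, 2), 0), frames = c(0L, 2L, 4L), dt = 1)
  out <- compute_msd(tr, dims = 2)
  expect_equal(nrow(out), 0)
})

test_that("non-overlapping mode uses disjoint windows only", {
  tr <- rel_track(cbind(c(0, 1, 3, 6, 10), 0), dt = 1)
  out <- compute_msd(tr, dims = 2, overlapping = FALSE)
  # lag 2: windows (0,2) and (2,4): displacements 3 and 7
  expect_equal(out$msd[out$lag_s == 2], mean(c(9, 49)))
  expect_equal(out$n_pairs[out$lag_s == 2], 2L)
})

test_that("ensemble MSD averages across cells with SEM over cells", {
  c1 <- compute_msd(rel_track(cbind(0:5, 0), dt = 30, cell_id = "a"))
  c2 <- compute_msd(rel_track(cbind(2 * (0:5), 0), dt = 30, cell_id = "b"))
  ens <- ensemble_msd(list(c1, c2))
  expect_equal(ens$mean_msd, (c1$msd + c2$msd) / 2)
  expect_equal(ens$n_cells, rep(2L, nrow(ens)))
  expect_equal(ens$sem, apply(rbind(c1$msd, c2$msd), 2, sd) / sqrt(2))
  # identical curves -> SEM 0; single cell -> flagged sem 0
  expect_true(all(ensemble_msd(list(c1, c1))$sem == 0))
  one <- ensemble_msd(list(c1))
  expect_true(all(!one$sem_defined))
  expect_error(ensemble_msd(list()), "no MSD curves")
})

test_that("ensemble MSD of free 2D diffusion matches 4*D*dt", {
  set.seed(77)
  D <- 2e-3; dt <- 30
  curves <- lapply(1:10, function(i) {
    pos <- cbind(cumsum(rnorm(200, sd = sqrt(2 * D * dt))),
                 cumsum(rnorm(200, sd = sqrt(2 * D * dt))))
    compute_msd(rel_track(pos, dt = dt, cell_id = paste0("c", i)),
                max_lag_frames = 3)
  })
  ens <- ensemble_msd(curves)
  for (k in 1:3) {
    expect_lt(abs(ens$mean_msd[k] - 4 * D * k * dt), 3 * ens$sem[k])
  }
})

test_that("radius of confinement reproduces the hand-worked example", {
  tr <- rel_track(cbind(c(1, -1, 1, -1), 0))
  res <- radius_of_confinement(tr)
  expect_equal(res$sigma2, (4 / 3) / 2)
  expect_equal(res$dr0_2, 1)
  expect_equal(res$rc, sqrt(5 / 4 * (2 * 2 / 3 + 1)))
  expect_equal(res$rc, 1.7078, tolerance = 1e-4)
  # degenerate: identical positions
  deg <- radius_of_confinement(rel_track(matrix(3, 4, 2)))
  expect_equal(deg$rc, 0)
  expect_true(deg$degenerate)
  expect_error(radius_of_confinement(rel_track(matrix(0, 2, 2))), ">= 3")
})

test_that("Rc recovers the radius of uniform ball and disk point clouds", {
  set.seed(99)
  R <- 0.8
  ball <- radius_of_confinement(rel_track(runif_ball_reject(1e5, R)))
  expect_equal(ball$rc, R, tolerance = 0.01)
  disk <- radius_of_confinement(rel_track(runif_disk(1e5, R)))
  expect_equal(disk$rc, sqrt(5 / 4) * R, tolerance = 0.01)
})

test_that("Rc and MSD are scale-equivariant", {
  set.seed(5)
  pos <- matrix(rnorm(60), 30, 2)
  tr1 <- rel_track(pos)
  tr3 <- rel_track(3 * pos)
  expect_equal(radius_of_confinement(tr3)$rc,
               3 * radius_of_confinement(tr1)$rc)
  expect_equal(compute_msd(tr3)$msd, 9 * compute_msd(tr1)$msd)
})

test_that("shared per-frame drift leaves MSD and Rc numerically unchanged", {
  cfg <- sim_config(n_frames = 41, drift_sd = 0, seed = 31)
  cell <- simulate_cell(cfg)
  paired0 <- pair_from_tracks(cell$tracks)
  drift <- matrix(rnorm(3 * cfg$n_frames, sd = 5), cfg$n_frames, 3)
  shifted <- cell$tracks
  idx <- shifted$frame + 1
  shifted$x_px <- shifted$x_px + drift[idx, 1]
  shifted$y_px <- shifted$y_px + drift[idx, 2]
  shifted$z_slice <- shifted$z_slice + drift[idx, 3]
  paired1 <- pair_from_tracks(shifted)
  r0 <- correct_coordinates(paired0, cfg$pixel_size, cfg$z_step)
  r1 <- correct_coordinates(paired1, cfg$pixel_size, cfg$z_step)
  expect_lt(max(abs(compute_msd(r1)$msd - compute_msd(r0)$msd)), 1e-9)
  expect_lt(abs(radius_of_confinement(r1)$rc -
                radius_of_confinement(r0)$rc), 1e-9)
})

test_that("Rc^2 agrees with 5/4 of the MSD plateau on a long confined track", {
  R <- 0.8
  cfg <- sim_config(confinement_radius = R, diffusion_coeff = 6e-3,
                    frame_interval = 16, n_substeps = 16, n_frames = 2e4,
                    seed = 17)
  tr <- rel_track(simulate_confined_track(cfg), dt = 16)
  msd <- compute_msd(tr, max_lag_frames = 200, dims = 2)
  plateau <- mean(msd$msd[msd$lag_s / 16 >= 100])
  rc2 <- radius_of_confinement(tr)$rc^2
  expect_equal(rc2, 5 / 4 * plateau, tolerance = 0.05)
})

test_that("analyze_condition recovers, orders and reports rejections", {
  mk <- function(R, seed) {
    cfg <- sim_config(confinement_radius = R, n_frames = 2001,
                      n_cells = 20, drift_sd = 0.03, seed = seed)
    simulate_cohort(cfg, sprintf("R%02d", round(10 * R)))
  }
  lo <- mk(0.6, 61); hi <- mk(1.0, 62)
  cfg <- sim_config()
  res_lo <- analyze_condition(lo$tracks, cfg$pixel_size, cfg$z_step,
                              max_lag_frames = 5)
  res_hi <- analyze_condition(hi$tracks, cfg$pixel_size, cfg$z_step,
                              max_lag_frames = 5)
  expect_equal(res_lo$summary$mean_rc, 0.6, tolerance = 0.03)
  expect_lt(res_lo$summary$mean_rc, res_hi$summary$mean_rc)
  # determinism
  res_lo2 <- analyze_condition(
    mk(0.6, 61)$tracks, cfg$pixel_size, cfg$z_step, max_lag_frames = 5)
  expect_identical(res_lo$summary, res_lo2$summary)
  # under-sized cohorts warn; an unusable cell is named in the error
  small <- mk(0.6, 63)
  few <- small$tracks[small$tracks$cell_id %in%
                        unique(small$tracks$cell_id)[1:3], ]
  expect_warning(analyze_condition(few, cfg$pixel_size, cfg$z_step,
                                   max_lag_frames = 5), "floor")
  broken <- few[few$frame == 0, ]
  expect_error(
    suppressWarnings(analyze_condition(broken, cfg$pixel_size, cfg$z_step)),
    "no accepted cells")
})
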