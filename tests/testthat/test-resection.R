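mk_cq <- function(site, tp, mock, digest, sample = "rep1") {
  dplyr::bind_rows(
    tibble::tibble(sample = sample, timepoint_h = tp, site = site,
                   treatment = "mock", replicate = seq_along(mock),
                   cq = mock),
    tibble::tibble(sample = sample, timepoint_h = tp, site = site,
                   treatment = "digest", replicate = seq_along(digest),
                   cq = digest))
}

test_that("delta Cq is the digest-minus-mock mean difference", {
  tab <- mk_cq("RS_0.7kb", 3, mock = c(25, 25, 25), digest = c(25, 25, 25))
  expect_equal(delta_cq(tab, "RS_0.7kb", 3), 0)
  tab2 <- mk_cq("RS_0.7kb", 3, mock = 25, digest = 26)
  expect_equal(delta_cq(tab2, "RS_0.7kb", 3), 1)
  tab3 <- mk_cq("RS_0.7kb", 3, mock = c(24, 24, 24),
                digest = c(24.9, 25.0, 25.1))
  expect_equal(delta_cq(tab3, "RS_0.7kb", 3), 1)
  missing <- tab3[tab3$treatment == "mock", ]
  expect_error(delta_cq(missing, "RS_0.7kb", 3), "digest")
})

test_that("the resection fraction formula matches its stated limits", {
  expect_equal(fraction_resected(0, 0, f = 1)$fraction_resected, 1)
  expect_equal(fraction_resected(1, 0, e_rs = 2, e_adh1 = 2,
                                 f = 1)$fraction_resected, 2 / 3)
  expect_equal(fraction_resected(60, 0, f = 1)$fraction_resected, 0,
               tolerance = 1e-12)
  # negative delta Cq (more template after digestion) pushes x above 1
  over <- fraction_resected(-2, 0, f = 1)
  expect_gt(over$fraction_resected, 1)
  expect_true(over$flag_gt1)
  expect_error(fraction_resected(0, 0, f = 0), "f")
  expect_error(fraction_resected(0, 0, e_rs = 2.5), "e_rs")
})

test_that("x is monotone decreasing in delta Cq and increasing in f", {
  dcqs <- seq(-2, 6, by = 0.5)
  xs <- vapply(dcqs, function(d)
    fraction_resected(d, 0, e_rs = 1.9, f = 0.8)$fraction_resected, 1.0)
  expect_true(all(diff(xs) < 0))
  fs <- seq(0.3, 1, by = 0.1)
  xf <- vapply(fs, function(f)
    fraction_resected(1.5, 0, f = f)$fraction_resected, 1.0)
  expect_true(all(diff(xf) < 0))  # larger f -> smaller x
})

test_that("a constant plate offset cancels in x and in the cutting fold", {
  base <- dplyr::bind_rows(
    mk_cq("RS_5kb", 3, c(24, 24.2, 23.8), c(25.5, 25.4, 25.6)),
    mk_cq("control_ADH1", 3, c(22, 22.1, 21.9), c(22.05, 21.95, 22)))
  x0 <- fraction_resected(delta_cq(base, "RS_5kb", 3),
                          delta_cq(base, "control_ADH1", 3))
  shifted <- base
  shifted$cq <- shifted$cq + 3.7
  x1 <- fraction_resected(delta_cq(shifted, "RS_5kb", 3),
                          delta_cq(shifted, "control_ADH1", 3))
  expect_equal(x1$fraction_resected, x0$fraction_resected)

  cut_tab <- tibble::tibble(
    sample = "s", timepoint_h = rep(c(0, 2), each = 2),
    site = rep(c("HO_cut_site", "control_ADH1"), 2),
    treatment = "mock", replicate = 1L, cq = c(25, 22, 27, 22))
  f0 <- cutting_fold_increase(cut_tab, 2)$fold
  cut_tab$cq <- cut_tab$cq + 1.1
  expect_equal(cutting_fold_increase(cut_tab, 2)$fold, f0)
})

test_that("cutting fold is 1 at the control and 2^-k for a k-cycle shift", {
  tab <- tibble::tibble(
    sample = "s", timepoint_h = rep(c(0, 2, 4), each = 2),
    site = rep(c("HO_cut_site", "control_ADH1"), 3),
    treatment = "mock", replicate = 1L,
    cq = c(25, 22, 24, 22, 27, 22))
  expect_equal(cutting_fold_increase(tab, 0)$fold, 1)
  expect_equal(cutting_fold_increase(tab, 2)$fold, 2)   # -1 cycle
  expect_equal(cutting_fold_increase(tab, 4)$fold, 0.25)  # +2 cycles
  expect_error(cutting_fold_increase(tab, 6), "missing")
})

test_that("cut fraction from the fold series is 1 - fold, clipped", {
  folds <- tibble::tibble(timepoint_h = c(0, 2, 4), fold = c(1, 0.1, 1.2))
  f <- cut_fraction_from_fold(folds)
  expect_equal(f$f, c(0, 0.9, 0))
  expect_equal(f$clipped, c(FALSE, FALSE, TRUE))
})

test_that("the generator and estimator are exact inverses at zero noise", {
  truth <- expand.grid(site = c("RS_0.7kb", "RS_5kb", "RS_10kb"),
                       timepoint_h = c(1, 3, 6),
                       stringsAsFactors = FALSE)
  truth$fraction <- c(0.9, 0.5, 0.2, 0.95, 0.7, 0.4, 0.99, 0.85, 0.6)
  truth <- tibble::as_tibble(truth)
  eff <- list(RS_0.7kb = 1.92, RS_5kb = 2, RS_10kb = 1.85,
              control_ADH1 = 1.95)
  sim <- simulate_qpcr(truth, f = 0.8, efficiencies = eff,
                       replicate_sd = 0, seed = 10)
  tc <- resection_timecourse(sim$cq_table, efficiencies = eff, f = 0.8)
  got <- merge(tc$per_replicate, truth,
               by = c("site", "timepoint_h"))
  expect_equal(got$fraction_resected, got$fraction, tolerance = 1e-12)
})

test_that("complete cutting hits the Cq ceiling and is flagged", {
  truth <- tibble::tibble(site = "RS_0.7kb", timepoint_h = 0, fraction = 0)
  sim <- simulate_qpcr(truth, f = 1, replicate_sd = 0, cq_ceiling = 40)
  dig <- sim$cq_table[sim$cq_table$treatment == "digest" &
                        sim$cq_table$site == "RS_0.7kb", ]
  expect_true(all(dig$cq == 40))
  expect_true(all(dig$flag_ceiling))
})

test_that("timecourse summary preserves the resection-front ordering", {
  tps <- c(1, 3, 6)
  front <- tibble::tibble(
    site = rep(c("RS_0.7kb", "RS_5kb", "RS_10kb"), each = 3),
    timepoint_h = rep(tps, 3),
    fraction = c(0.6, 0.85, 0.95,   # 0.7 kb resects first
                 0.25, 0.55, 0.8,   # 5 kb lags
                 0.08, 0.3, 0.6))   # 10 kb last
  reps <- dplyr::bind_rows(lapply(1:3, function(r) {
    tr <- front; tr$sample <- paste0("rep", r); tr
  }))
  sim <- simulate_qpcr(reps, f = 0.9, replicate_sd = 0.05, seed = 22)
  tc <- resection_timecourse(sim$cq_table, f = 0.9)
  for (tp in tps) {
    m <- tc$summary[tc$summary$timepoint_h == tp, ]
    expect_equal(m$n, rep(3L, 3))
    x <- setNames(m$mean_x, m$site)
    expect_gt(x[["RS_0.7kb"]], x[["RS_5kb"]])
    expect_gt(x[["RS_5kb"]], x[["RS_10kb"]])
  }
  # three identical replicates -> SEM 0; single replicate -> flagged
  sim0 <- simulate_qpcr(reps, f = 0.9, replicate_sd = 0, seed = 22)
  tc0 <- resection_timecourse(sim0$cq_table, f = 0.9)
  expect_true(all(tc0$summary$sem_x < 1e-12))
  one <- resection_timecourse(
    sim0$cq_table[sim0$cq_table$sample == "rep1", ], f = 0.9)
  expect_true(all(!one$summary$sem_defined))
})

test_that("cutting-assay rows invert to the generator's cut fraction", {
  f_tbl <- tibble::tibble(timepoint_h = c(0, 1, 3, 6),
                          f = c(0, 0.6, 0.85, 0.9))
  truth <- tibble::tibble(site = "RS_0.7kb", timepoint_h = c(1, 3, 6),
                          fraction = c(0.5, 0.7, 0.9))
  sim <- simulate_qpcr(truth, f = f_tbl, replicate_sd = 0, seed = 4)
  folds <- dplyr::bind_rows(lapply(f_tbl$timepoint_h, function(tp)
    cutting_fold_increase(sim$cq_table, tp)))
  f_est <- cut_fraction_from_fold(folds)
  expect_equal(f_est$f, f_tbl$f, tolerance = 1e-12)
})
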