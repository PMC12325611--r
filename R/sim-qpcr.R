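#' Simulate a qPCR Cq table with known resection fractions
#'
#' Constructs mock/digest Cq replicates whose noiseless delta-Cq values
#' invert exactly, through [fraction_resected()], to the requested true
#' fractions: the control-gene delta-Cq is 0 in expectation (the control
#' amplicon carries no restriction-site dependence) and the
#' restriction-site delta-Cq is
#' `log(2 / (x * f) - 1) / log(E_RS)`. Gaussian noise of sd `replicate_sd`
#' is added per technical replicate. A true fraction of 0 would require an
#' infinite digest Cq (complete cutting of the intact site); those wells
#' are emitted at the documented ceiling `cq_ceiling` and flagged.
#'
#' When `f` is a tibble (`timepoint_h`, `f`), `HO_cut_site` rows are also
#' emitted so that [cutting_fold_increase()] plus
#' [cut_fraction_from_fold()] recover `f` exactly at zero noise.
#'
#' @param truth Tibble with `site`, `timepoint_h`, `fraction` (true
#'   resection fractions in (0, 1]); `sample` optional (biological
#'   replicate label, default `"rep1"`).
#' @param f Cut fraction: scalar in (0, 1] or tibble (`timepoint_h`, `f`).
#' @param efficiencies Named list of per-site efficiencies plus
#'   `control_ADH1` (default 2 everywhere).
#' @param base_cq Baseline mock Cq, cycles.
#' @param replicate_sd Gaussian replicate noise, cycles (0 = noiseless).
#' @param n_reps Technical replicates per well (default 3, the usual
#'   triplicate).
#' @param cq_ceiling Ceiling Cq for unamplifiable wells.
#' @param seed Integer seed.
#' @return List: `cq_table` (standard Cq tibble, plus a `flag_ceiling`
#'   column) and `truth` (the input truth, with the delta-Cq used).
#' @export
simulate_qpcr <- function(truth, f = 1, efficiencies = NULL, base_cq = 25,
                          replicate_sd = 0, n_reps = 3, cq_ceiling = 40,
                          seed = 1L) {
  stopifnot(all(c("site", "timepoint_h", "fraction") %in% names(truth)))
  if (any(truth$fraction < 0 | truth$fraction > 1))
    stop("true fractions must be in [0, 1]", call. = FALSE)
  if (!"sample" %in% names(truth)) truth$sample <- "rep1"
  f_tbl <- if (is.data.frame(f)) f else NULL
  f_at <- function(tp) {
    if (!is.null(f_tbl)) {
      v <- f_tbl$f[match(tp, f_tbl$timepoint_h)]
      if (is.na(v)) stop("no f for timepoint ", tp, call. = FALSE)
      v
    } else f
  }
  eff_at <- function(site) {
    if (is.null(efficiencies)) return(2)
    e <- efficiencies[[site]]
    if (is.null(e)) 2 else e
  }
  with_rng(seed, {
    rows <- list()
    emit <- function(sample, tp, site, treatment, cq, flag = FALSE) {
      noisy <- cq + rnorm(n_reps, sd = replicate_sd)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        sample = sample, timepoint_h = tp, site = site,
        treatment = treatment, replicate = seq_len(n_reps), cq = noisy,
        flag_ceiling = flag)
    }
    for (i in seq_len(nrow(truth))) {
      x <- truth$fraction[i]
      tp <- truth$timepoint_h[i]
      site <- truth$site[i]
      smp <- truth$sample[i]
      fv <- f_at(tp)
      if (x * fv > 0) {
        dcq <- log(2 / (x * fv) - 1) / log(eff_at(site))
        emit(smp, tp, site, "mock", base_cq)
        emit(smp, tp, site, "digest", base_cq + dcq)
      } else {
        emit(smp, tp, site, "mock", base_cq)
        emit(smp, tp, site, "digest", cq_ceiling, flag = TRUE)
      }
    }
    # control gene: digest - mock = 0 in expectation, at every sample/tp
    # (including cutting-assay timepoints such as the 0 h control)
    for (smp in unique(truth$sample)) {
      tps <- unique(c(truth$timepoint_h[truth$sample == smp],
                      if (!is.null(f_tbl)) f_tbl$timepoint_h))
      for (tp in sort(tps)) {
        emit(smp, tp, "control_ADH1", "mock", base_cq)
        emit(smp, tp, "control_ADH1", "digest", base_cq)
      }
    }
    # intact cut-site amplicon for the cutting assay
    if (!is.null(f_tbl)) {
      for (smp in unique(truth$sample)) {
        for (j in seq_len(nrow(f_tbl))) {
          intact <- 1 - f_tbl$f[j]
          cq <- if (intact > 0) base_cq - log2(intact) else cq_ceiling
          emit(smp, f_tbl$timepoint_h[j], "HO_cut_site", "mock", cq,
               flag = intact <= 0)
        }
      }
    }
    tab <- dplyr::bind_rows(rows)
    dcq_used <- ifelse(
      truth$fraction * vapply(truth$timepoint_h, f_at, 1.0) > 0,
      log(2 / (truth$fraction *
               vapply(truth$timepoint_h, f_at, 1.0)) - 1) /
        log(vapply(truth$site, eff_at, 1.0)),
      Inf)
    truth$delta_cq <- dcq_used
    list(cq_table = tab, truth = truth)
  })
}

#' Simulate colony counts for a clonogenic viability assay
#'
#' Each plate receives `n_plated` cells; the permissive plate reports every
#' plated cell as a colony, while the selective plate reports a
#' Binomial(`n_plated`, `viability`) draw — the minimal model of a survival
#' plating experiment (about 100 cells plated per plate, in triplicate).
#'
#' @param viability True survival probability in \[0, 1\].
#' @param n_plated Cells plated per plate (default 100).
#' @param n_plates Number of plate pairs (default 3).
#' @param seed Integer seed.
#' @return Tibble: `plate`, `selective`, `permissive`.
#' @export
simulate_colonies <- function(viability, n_plated = 100, n_plates = 3,
                              seed = 1L) {
  stopifnot(viability >= 0, viability <= 1, n_plated >= 1, n_plates >= 1)
  with_rng(seed, tibble::tibble(
    plate = seq_len(n_plates),
    selective = rbinom(n_plates, n_plated, viability),
    permissive = rep(as.integer(n_plated), n_plates)))
}
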