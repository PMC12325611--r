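#' Mean quantification-cycle difference between digest and mock
#'
#' For one probe site and timepoint, the difference between the mean Cq of
#' the restriction-digested replicates and the mean Cq of the mock-digested
#' replicates. Since the restriction enzyme cannot cut single-stranded DNA,
#' a site that has been resected keeps amplifying after digestion and the
#' difference shrinks toward zero.
#'
#' @param cq_table Cq tibble (`sample`, `timepoint_h`, `site`, `treatment`
#'   in `mock`/`digest`, `replicate`, `cq`).
#' @param site Probe site name (e.g. `"RS_0.7kb"`).
#' @param timepoint Timepoint, h.
#' @param sample Optional sample/replicate label filter.
#' @return Mean digest Cq minus mean mock Cq (cycles).
#' @export
delta_cq <- function(cq_table, site, timepoint, sample = NULL) {
  rows <- cq_table[cq_table$site == site &
                   cq_table$timepoint_h == timepoint, ]
  if (!is.null(sample)) rows <- rows[rows$sample == sample, ]
  for (tr in c("digest", "mock")) {
    if (!any(rows$treatment == tr))
      stop(sprintf("no %s replicates for site %s at %g h", tr, site,
                   timepoint), call. = FALSE)
  }
  mean(rows$cq[rows$treatment == "digest"]) -
    mean(rows$cq[rows$treatment == "mock"])
}

#' Fraction of molecules resected past a restriction site
#'
#' The resection fraction at a probe site is
#' \deqn{x = \frac{2}{\left(\frac{E_{RS}^{\Delta C_q(RS)}}
#'   {E_{ADH1}^{\Delta C_q(ADH1)}} + 1\right) \cdot f}}
#' where the \eqn{\Delta C_q} are digest-minus-mock differences at the
#' restriction site and the control gene, \eqn{E} are the respective primer
#' efficiencies (per-cycle amplification factors, ideal 2), and `f` is the
#' fraction of cells in which the endonuclease has actually cleaved. Values
#' above 1 (possible with noisy Cq or a small `f`) are returned raw with a
#' QC flag, never clamped.
#'
#' @param dcq_rs Delta-Cq (digest - mock) at the restriction-site amplicon.
#' @param dcq_adh1 Delta-Cq at the control gene.
#' @param e_rs,e_adh1 Primer efficiencies, each in (1, 2].
#' @param f Cut fraction in (0, 1].
#' @return One-row tibble: `delta_cq_rs`, `delta_cq_adh1`,
#'   `fraction_resected`, `f_used`, `flag_gt1`.
#' @export
#' @examples
#' fraction_resected(1, 0, e_rs = 2, e_adh1 = 2, f = 1)  # 2/3
fraction_resected <- function(dcq_rs, dcq_adh1, e_rs = 2, e_adh1 = 2,
                              f = 1) {
  check_efficiency(e_rs, "e_rs")
  check_efficiency(e_adh1, "e_adh1")
  if (!is.numeric(f) || length(f) != 1 || f <= 0 || f > 1)
    stop("`f` must be in (0, 1]", call. = FALSE)
  x <- 2 / ((e_rs^dcq_rs / e_adh1^dcq_adh1 + 1) * f)
  tibble::tibble(delta_cq_rs = dcq_rs, delta_cq_adh1 = dcq_adh1,
                 fraction_resected = x, f_used = f, flag_gt1 = x > 1)
}

check_efficiency <- function(e, nm) {
  if (!is.numeric(e) || length(e) != 1 || e <= 1 || e > 2)
    stop(sprintf("`%s` must be an amplification efficiency in (1, 2]", nm),
         call. = FALSE)
}

#' Endonuclease cutting efficiency as qPCR fold change
#'
#' Quantifies loss of the intact cut-site amplicon over time:
#' \deqn{fold_t = 2^{-(\Delta C_t - \Delta C_{t,\mathrm{control}})}}
#' with \eqn{\Delta C_t = C_q(\mathrm{cut site}) - C_q(\mathrm{control
#' gene})} at each timepoint, referenced to the (typically 0 h) control
#' timepoint. Because the primers flank the cut site, cleavage destroys the
#' template and the fold value for the intact amplicon drops below 1.
#'
#' @param cq_table Cq tibble including `HO_cut_site` and `control_ADH1`
#'   rows at both timepoints (treatment ignored; use mock rows or a table
#'   without treatment structure).
#' @param timepoint Timepoint, h.
#' @param control_timepoint Reference timepoint, h (default 0).
#' @param site Name of the cut-site amplicon row.
#' @param control_gene Name of the control-gene row.
#' @return One-row tibble: `timepoint_h`, `fold`.
#' @export
cutting_fold_increase <- function(cq_table, timepoint,
                                  control_timepoint = 0,
                                  site = "HO_cut_site",
                                  control_gene = "control_ADH1") {
  dct <- function(tp) {
    ho <- cq_table$cq[cq_table$site == site & cq_table$timepoint_h == tp]
    ad <- cq_table$cq[cq_table$site == control_gene &
                      cq_table$timepoint_h == tp]
    if (!length(ho) || !length(ad))
      stop(sprintf("missing %s or %s rows at %g h", site, control_gene, tp),
           call. = FALSE)
    mean(ho) - mean(ad)
  }
  fold <- 2^(-(dct(timepoint) - dct(control_timepoint)))
  tibble::tibble(timepoint_h = timepoint, fold = fold)
}

#' Cut fraction from the intact-amplicon fold series
#'
#' Package convention (the literature leaves the conversion unstated): the
#' fold value of the intact cut-site amplicon relative to the 0 h control
#' is the fraction of templates still intact, so the cut fraction is
#' `f = 1 - fold`, clipped into \[0, 1\] with a flag when clipping was
#' needed.
#'
#' @param fold_series Tibble with `timepoint_h` and `fold` (must include
#'   the control timepoint, where fold = 1).
#' @return Tibble: `timepoint_h`, `f`, `clipped`.
#' @export
cut_fraction_from_fold <- function(fold_series) {
  f_raw <- 1 - fold_series$fold
  f <- pmin(pmax(f_raw, 0), 1)
  tibble::tibble(timepoint_h = fold_series$timepoint_h, f = f,
                 clipped = f != f_raw)
}

#' Resection timecourse with replicate aggregation
#'
#' Computes the resection fraction for every site x timepoint of every
#' biological replicate (aggregating technical triplicates at the Cq level
#' first, i.e. mean Cq before delta-Cq), then summarizes across biological
#' replicates as mean and SEM — the layout of a standard resection figure
#' (sites 0.7/5/10 kb from the break, times 0–6 h).
#'
#' @param cq_table Cq tibble; `sample` labels the biological replicate.
#' @param efficiencies Named list/vector of per-site efficiencies plus
#'   `control_ADH1` (default all 2).
#' @param f Either a single cut fraction, or a tibble (`timepoint_h`, `f`)
#'   as from [cut_fraction_from_fold()].
#' @param control_gene Control-gene site name.
#' @return List: `per_replicate` tibble (`sample`, `site`, `timepoint_h`,
#'   `fraction_resected`, `flag_gt1`) and `summary` tibble (`site`,
#'   `timepoint_h`, `mean_x`, `sem_x`, `n`, `sem_defined`).
#' @export
resection_timecourse <- function(cq_table, efficiencies = NULL, f = 1,
                                 control_gene = "control_ADH1") {
  sites <- setdiff(unique(cq_table$site), c(control_gene, "HO_cut_site"))
  if (!length(sites)) stop("no restriction-site rows", call. = FALSE)
  samples <- unique(cq_table$sample)
  site_sets <- lapply(samples, function(s)
    sort(setdiff(unique(cq_table$site[cq_table$sample == s]),
                 c(control_gene, "HO_cut_site"))))
  if (length(unique(vapply(site_sets, paste, "", collapse = ","))) > 1)
    stop("inconsistent site sets across biological replicates",
         call. = FALSE)
  f_at <- function(tp) {
    if (is.data.frame(f)) {
      v <- f$f[match(tp, f$timepoint_h)]
      if (is.na(v)) stop("no f for timepoint ", tp, call. = FALSE)
      v
    } else f
  }
  eff_at <- function(site) {
    if (is.null(efficiencies)) return(2)
    e <- efficiencies[[site]]
    if (is.null(e)) 2 else e
  }
  e_ctrl <- if (is.null(efficiencies)) 2 else {
    e <- efficiencies[[control_gene]]
    if (is.null(e)) 2 else e
  }
  rows <- list()
  for (s in samples) {
    tab <- cq_table[cq_table$sample == s, ]
    for (site in sites) {
      for (tp in sort(unique(tab$timepoint_h[tab$site == site]))) {
        dcq_rs <- delta_cq(tab, site, tp)
        dcq_ad <- delta_cq(tab, control_gene, tp)
        res <- fraction_resected(dcq_rs, dcq_ad, eff_at(site), e_ctrl,
                                 f_at(tp))
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample = s, site = site, timepoint_h = tp,
          fraction_resected = res$fraction_resected,
          flag_gt1 = res$flag_gt1)
      }
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$site, .data$timepoint_h),
    mean_x = mean(.data$fraction_resected),
    sem_x = if (dplyr::n() > 1)
      stats::sd(.data$fraction_resected) / sqrt(dplyr::n()) else 0,
    n = dplyr::n(), .groups = "drop")
  summary$sem_defined <- summary$n > 1
  list(per_replicate = per_rep, summary = summary)
}
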