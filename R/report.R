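#' Published regional V_T summary of the blocking cohort
#'
#' Regional mean +/- SD total distribution volumes at baseline and after
#' oral XBD173 in a seven-subject [11C]PBR28 blocking study of
#' schizophrenia patients (all TSPO high-affinity binders), for the
#' standard 2TCM and the vascular-binding 2TCM1K, together with the
#' percent V_T change printed alongside them.
#'
#' @return data.frame with columns `region`, `model`, `vt_baseline_mean`,
#'   `vt_baseline_sd`, `vt_block_mean`, `vt_block_sd`,
#'   `vt_change_pct_printed`.
#' @export
pbr28_regional_vt <- function() {
  utils::read.delim(system.file("extdata", "pbr28_regional_vt.tsv",
                                package = "occupet"), sep = "\t")
}

#' Published per-subject V_ND estimates of the blocking cohort
#'
#' SIME estimates from the baseline scan and occupancy-plot estimates
#' (2TCM and 2TCM1K, with 95\% CIs) for each of the seven subjects, plus
#' the printed SIME-vs-occupancy-plot relative difference.
#'
#' @return data.frame, one row per subject.
#' @export
pbr28_individual_vnd <- function() {
  utils::read.delim(system.file("extdata", "pbr28_individual_vnd.tsv",
                                package = "occupet"), sep = "\t",
                    check.names = TRUE)
}

#' Percent V_T change between condition means
#'
#' \eqn{100 (m_{base} - m_{block}) / m_{base}}: the relative difference
#' between the mean baseline V_T and the mean post-drug V_T (computed from
#' the two means, never as the mean of per-subject changes). Vectorized.
#'
#' @param mean_baseline,mean_block condition means, mL/cm^3.
#' @return Unrounded percent change; use [format_percent()] for table
#'   display.
#' @examples
#' percent_vt_change(4.72, 2.16)  # 54.2
#' @export
percent_vt_change <- function(mean_baseline, mean_block) {
  if (any(mean_baseline <= 0)) stop("baseline means must be positive")
  100 * (mean_baseline - mean_block) / mean_baseline
}

#' Round a percentage for table display (half-up to integer)
#' @param x percent values.
#' @return integer vector.
#' @export
format_percent <- function(x) {
  as.integer(round_half_up(x, 0))
}

#' Paired two-tailed t-test
#'
#' Thin wrapper around [stats::t.test()] (paired, two-sided) returning the
#' statistic, degrees of freedom (n - 1) and p-value.
#'
#' @param values_a,values_b paired measurements.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1L, p = 1, mean_diff = mean(d)))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Regional V_T change table from fitted cohort results
#'
#' Summarizes per-subject regional V_T into the study-table layout:
#' mean +/- SD at baseline and block, and the percent change computed from
#' the two means.
#'
#' @param fits data.frame with columns `subject`, `region`, `condition`
#'   (`"baseline"`/`"blocking"`), `vt`, and logical `excluded`.
#' @return data.frame per region: means, SDs, `vt_change_pct` (unrounded)
#'   and `vt_change_pct_display`.
#' @export
vt_change_table <- function(fits) {
  need <- c("subject", "region", "condition", "vt", "excluded")
  stopifnot(all(need %in% names(fits)))
  f <- fits[!fits$excluded & is.finite(fits$vt), ]
  agg <- function(cond, fun) {
    x <- f[f$condition == cond, ]
    stats::aggregate(x$vt, list(region = x$region), fun)
  }
  mb <- agg("baseline", mean); sb <- agg("baseline", stats::sd)
  mk <- agg("blocking", mean); sk <- agg("blocking", stats::sd)
  out <- Reduce(function(a, b) merge(a, b, by = "region"),
                list(stats::setNames(mb, c("region", "vt_baseline_mean")),
                     stats::setNames(sb, c("region", "vt_baseline_sd")),
                     stats::setNames(mk, c("region", "vt_block_mean")),
                     stats::setNames(sk, c("region", "vt_block_sd"))))
  out$vt_change_pct <- percent_vt_change(out$vt_baseline_mean,
                                         out$vt_block_mean)
  out$vt_change_pct_display <- format_percent(out$vt_change_pct)
  out
}

#' Run the full synthetic-study pipeline
#'
#' Simulate a cohort, fit the blood models and delay per scan, fit the
#' compartment model(s) to every regional TAC of both conditions, run the
#' individual and population-constrained occupancy plots, optionally run
#' SIME on each baseline scan, and assemble the summary tables.
#' Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @param models compartment models to fit (`"2tcm"` and/or `"2tcm1k"`).
#' @param run_sime whether to run the SIME sweep on each baseline scan
#'   (the dominant cost).
#' @param sime_grid V_ND grid for SIME.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print stage progress to stderr.
#' @return list with `fits` (long data.frame of all regional fits),
#'   `vt_table` (per model), `lassen_individual`, `lassen_population` (per
#'   model), `sime` (per subject, if run), `comparison` (SIME vs Lassen, if
#'   run), `subjects` (the synthetic truth), `config`.
#' @export
run_pipeline <- function(config, models = "2tcm", run_sime = FALSE,
                         sime_grid = seq(0.01, 5, by = 0.01),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d subjects", config$n_subjects)
  subjects <- generate_cohort(config)

  rows <- list(); sime_list <- list()
  for (s in subjects) {
    inputs <- list()
    for (cond in names(s$conditions)) {
      cd <- s$conditions[[cond]]
      say("%s/%s: blood models + delay", s$subject_id, cond)
      bl <- cd$blood
      fct <- calibrate_continuous_to_discrete(
        bl$continuous$time_min, bl$continuous$wholeblood_kBq_per_mL,
        bl$discrete$time_min, bl$discrete$wholeblood_kBq_per_mL)
      wb_t <- c(bl$continuous$time_min,
                bl$discrete$time_min[bl$discrete$time_min > 15])
      wb_y <- c(bl$continuous$wholeblood_kBq_per_mL * fct,
                bl$discrete$wholeblood_kBq_per_mL[bl$discrete$time_min > 15])
      wb <- fit_wholeblood(wb_t, wb_y)
      pob <- fit_pob(bl$discrete$time_min, bl$discrete$plasma_over_blood)
      hplc <- !is.na(bl$discrete$parent_fraction)
      ppf <- fit_parent_fraction(bl$discrete$time_min[hplc],
                                 bl$discrete$parent_fraction[hplc])
      inp0 <- build_input_function(wb, pob, ppf)
      wb_tac <- cd$tacs[, "whole_brain"]
      dl <- fit_delay(inp0, wb_tac, s$schedule, dt = config$dt)
      inp <- build_input_function(wb, pob, ppf, delay = dl$delay)
      inputs[[cond]] <- discretize_input(inp, s$schedule, config$dt)

      for (m in models) {
        say("%s/%s: %s fits", s$subject_id, cond, m)
        for (r in colnames(cd$tacs)) {
          f <- fit_wnlls(cd$tacs[, r], inputs[[cond]], s$schedule, model = m,
                         dt = config$dt)
          rows[[length(rows) + 1]] <- data.frame(
            subject = s$subject_id, region = r, condition = cond, model = m,
            vt = f$vt, cv_vt = f$cv_vt, K1 = f$params[["K1"]],
            k2 = f$params[["k2"]], k3 = f$params[["k3"]],
            k4 = f$params[["k4"]], rss = f$rss, excluded = f$excluded,
            exclusion_reason = if (is.na(f$exclusion_reason)) "" else
              f$exclusion_reason,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (run_sime) {
      say("%s: SIME sweep (%d grid points)", s$subject_id, length(sime_grid))
      base <- s$conditions$baseline
      sime_list[[s$subject_id]] <- sime_vnd(
        as.list(as.data.frame(base$tacs)), inputs$baseline, s$schedule,
        grid = sime_grid, dt = config$dt)
    }
  }
  fits <- do.call(rbind, rows)

  lass_ind <- list(); lass_pop <- list(); vt_tab <- list()
  for (m in models) {
    fm <- fits[fits$model == m, ]
    vt_tab[[m]] <- vt_change_table(fm)
    wide <- merge(
      fm[fm$condition == "baseline" & !fm$excluded,
         c("subject", "region", "vt")],
      fm[fm$condition == "blocking" & !fm$excluded,
         c("subject", "region", "vt")],
      by = c("subject", "region"), suffixes = c("_baseline", "_blocking"))
    names(wide)[3:4] <- c("vt_baseline", "vt_blocking")
    lass_ind[[m]] <- lapply(split(wide, wide$subject), function(d) {
      lassen_individual(d$vt_baseline, d$vt_blocking, regions = d$region)
    })
    lass_pop[[m]] <- lassen_population(wide)
  }

  comparison <- NULL
  if (run_sime && "2tcm" %in% models) {
    ids <- names(lass_ind[["2tcm"]])
    comparison <- compare_sime_lassen(
      vapply(sime_list[ids], `[[`, numeric(1), "vnd"),
      vapply(lass_ind[["2tcm"]][ids], `[[`, numeric(1), "vnd"),
      subjects = ids)
  }

  out <- list(fits = fits, vt_table = vt_tab, lassen_individual = lass_ind,
              lassen_population = lass_pop, sime = sime_list,
              comparison = comparison, subjects = subjects, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(out_dir, "regional_fits.csv"),
                     row.names = FALSE)
    for (m in models) {
      utils::write.csv(vt_tab[[m]],
                       file.path(out_dir, paste0("vt_change_", m, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(lass_pop, function(p) list(vnd = p$vnd, ci = p$ci_vnd,
                                        occupancy = as.list(p$occupancy))),
      file.path(out_dir, "population_occupancy.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}
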