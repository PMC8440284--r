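#' Default regional configuration of the synthetic cohort
#'
#' Thirteen-region atlases reduce, for this tracer's blocking design, to the
#' twelve summary regions used throughout the package. Baseline V_T means
#' (mL/cm^3) are set to the scale of a published seven-subject [11C]PBR28
#' blocking cohort of high-affinity binders; K1 values are plausible
#' TSPO-tracer defaults (lower in white matter), since regional
#' micro-parameters are not published.
#'
#' @return data.frame with columns `region`, `vt_baseline_mean`, `K1`.
#' @export
default_region_table <- function() {
  data.frame(
    region = c("whole_brain", "white_matter", "gray_matter", "occipital_lobe",
               "temporal_lobe", "frontal_lobe", "parietal_lobe", "amygdala",
               "hippocampus", "thalamus", "striatum", "cerebellum"),
    vt_baseline_mean = c(4.72, 4.30, 4.95, 4.76, 4.82, 4.81, 4.64, 6.67,
                         5.25, 5.70, 4.83, 4.87),
    K1 = c(0.095, 0.075, 0.105, 0.100, 0.100, 0.105, 0.100, 0.090,
           0.095, 0.110, 0.100, 0.105),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic blocking cohort
#'
#' Defines the study conditions the generator emulates: a cohort of
#' subjects each scanned at baseline and after a TSPO-blocking drug, with
#' one shared true V_ND, per-subject fractional occupancy drawn from
#' `occupancy_range`, regional baseline V_T heterogeneity at the scale of
#' the published cohort, and count-statistics frame noise.
#'
#' @param n_subjects number of subjects.
#' @param regions region table as from [default_region_table()].
#' @param true_vnd shared non-displaceable volume, mL/cm^3.
#' @param occupancy_range range the per-subject occupancy is drawn from
#'   (uniform); the blocking dose targets 0.66--0.77.
#' @param between_subject_sd log-normal SD (fraction) of the subject-level
#'   specific-binding scale factor.
#' @param outlier_subject if `TRUE`, the last subject's K1 (hence every
#'   regional V_T) is inflated by `outlier_inflation`.
#' @param outlier_inflation multiplicative V_T inflation of the outlier.
#' @param regional_vnd_sd log-normal SD of per-region K1/k2 around
#'   `true_vnd`; 0 (the default) keeps the SIME assumption exact.
#' @param noise_scale overall noise level; 0 gives noiseless data. The
#'   default 0.1 yields late-frame TAC noise of a few percent, typical for
#'   ROI-level data.
#' @param k4,vB micro-parameter defaults shared by all regions.
#' @param schedule a [frame_schedule()].
#' @param dt fine-grid spacing used when integrating the generating model.
#' @param seed integer seed; all generation is deterministic given
#'   (config, seed).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 7, regions = default_region_table(),
                          true_vnd = 1.99, occupancy_range = c(0.66, 0.77),
                          between_subject_sd = 0.25, outlier_subject = FALSE,
                          outlier_inflation = 0.38, regional_vnd_sd = 0,
                          noise_scale = 0.1, k4 = 0.06, vB = 0.05,
                          schedule = default_frame_schedule(), dt = 1 / 60,
                          seed = 1L) {
  stopifnot(n_subjects >= 1, is.data.frame(regions),
            all(c("region", "vt_baseline_mean", "K1") %in% names(regions)))
  if (!is.finite(true_vnd) || true_vnd <= 0) stop("true_vnd must be > 0")
  if (length(occupancy_range) != 2 || any(occupancy_range < 0) ||
      any(occupancy_range > 1) || occupancy_range[1] > occupancy_range[2]) {
    stop("occupancy_range must lie within [0, 1]")
  }
  if (any(regions$vt_baseline_mean < true_vnd)) {
    stop("baseline V_T means must be >= true_vnd in every region")
  }
  if (any(regions$K1 <= 0) || k4 <= 0 || vB < 0 || vB > 0.2) {
    stop("invalid micro-parameter defaults")
  }
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), regions = regions,
         true_vnd = true_vnd, occupancy_range = occupancy_range,
         between_subject_sd = between_subject_sd,
         outlier_subject = isTRUE(outlier_subject),
         outlier_inflation = outlier_inflation,
         regional_vnd_sd = regional_vnd_sd, noise_scale = noise_scale,
         k4 = k4, vB = vB, schedule = schedule, dt = dt,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Manual and HPLC blood sampling times (minutes)
#' @return list with `manual` (12 discrete samples) and `hplc` (metabolite
#'   subset).
#' @export
blood_sample_times <- function() {
  list(manual = c(5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90),
       hplc = c(5, 10, 20, 30, 50, 70, 90))
}

default_blood_truth <- function() {
  list(peak = 18, t_peak = 0.9,
       frac = c(0.72, 0.22, 0.06), lambda = c(4.0, 0.35, 0.012),
       ppf = c(a = 0.85, b = 1.6, c = 120),
       pob = c(r0 = 0.80, d = 0.55, b = 1.2, c = 25))
}

# truth blood components as plain functions of time
blood_truth_functions <- function(truth) {
  A <- truth$frac * truth$peak
  lam <- truth$lambda
  tp <- truth$t_peak
  cb <- function(t) {
    t <- pmax(t, 0)
    out <- numeric(length(t))
    pre <- t < tp
    out[pre] <- sum(A) * t[pre] / tp
    if (any(!pre)) {
      out[!pre] <- colSums(A * exp(-outer(lam, t[!pre] - tp)))
    }
    out
  }
  ppf <- function(t) {
    p <- truth$ppf
    1 - p[["a"]] * t^p[["b"]] / (t^p[["b"]] + p[["c"]])
  }
  pob <- function(t) {
    p <- truth$pob
    p[["r0"]] + p[["d"]] * t^p[["b"]] / (t^p[["b"]] + p[["c"]])
  }
  list(cb = cb, ppf = ppf, pob = pob)
}

#' Generate a synthetic arterial blood data set
#'
#' Emulates the combined automatic-manual sampling protocol: a continuous
#' whole-blood series (1-s sampling for the first 15 min), discrete manual
#' samples at 5--90 min with plasma-over-blood ratios, and parent plasma
#' fractions at the HPLC subset. Whole blood rises linearly to a peak
#' before 2 min and decays tri-exponentially; the parent fraction follows
#' the extended Hill form, declining from 1.
#'
#' @param noise_scale 0 for noiseless series; the default matches
#'   [cohort_config()].
#' @param truth optional list overriding the generating parameters (`peak`,
#'   `t_peak`, `frac`, `lambda`, `ppf`, `pob`).
#' @param seed integer seed.
#' @return list with `discrete` (data.frame `time_min`,
#'   `wholeblood_kBq_per_mL`, `plasma_over_blood`, `parent_fraction`;
#'   parent fraction is `NA` outside the HPLC subset), `continuous`
#'   (data.frame `time_min`, `wholeblood_kBq_per_mL`), `truth` (generating
#'   parameters plus an exact [input_function()]).
#' @export
generate_input_function <- function(noise_scale = 0.1, truth = NULL,
                                    seed = 1L) {
  tr <- utils::modifyList(default_blood_truth(), if (is.null(truth)) list() else truth)
  if (any(unlist(tr[c("peak", "t_peak", "frac", "lambda")]) < 0) ||
      tr$ppf[["a"]] < 0 || tr$ppf[["a"]] > 1 ||
      any(tr$ppf[c("b", "c")] <= 0)) {
    stop("invalid blood truth parameters")
  }
  fns <- blood_truth_functions(tr)
  st <- blood_sample_times()
  t_cont <- seq(1 / 60, 15, by = 1 / 60)

  withr::with_seed(seed, {
    wb_cont <- fns$cb(t_cont)
    wb_disc <- fns$cb(st$manual)
    pob <- fns$pob(st$manual)
    ppf <- fns$ppf(st$hplc)
    if (noise_scale > 0) {
      wb_cont <- pmax(wb_cont + stats::rnorm(length(wb_cont),
                                             sd = 0.3 * noise_scale * sqrt(pmax(wb_cont, 0.1))), 1e-4)
      wb_disc <- pmax(wb_disc + stats::rnorm(length(wb_disc),
                                             sd = 0.3 * noise_scale * sqrt(pmax(wb_disc, 0.1))), 1e-4)
      pob <- pmax(pob + stats::rnorm(length(pob), sd = 0.2 * noise_scale), 0.05)
      ppf <- pmin(pmax(ppf + stats::rnorm(length(ppf), sd = 0.2 * noise_scale),
                       0.01), 1)
    }
    discrete <- data.frame(
      time_min = st$manual,
      wholeblood_kBq_per_mL = wb_disc,
      plasma_over_blood = pob,
      # match() yields NA outside the HPLC subset
      parent_fraction = ppf[match(st$manual, st$hplc)]
    )
    list(
      discrete = discrete,
      continuous = data.frame(time_min = t_cont,
                              wholeblood_kBq_per_mL = wb_cont),
      truth = c(tr, list(input = input_function(fns$cb, fns$pob, fns$ppf))))
  })
}

# per-region micro-parameter truth for one subject
subject_region_truth <- function(config, subj_factor, k1_scale, vnd_region) {
  reg <- config$regions
  vs <- pmax(reg$vt_baseline_mean - config$true_vnd, 0) * subj_factor
  K1 <- reg$K1 * k1_scale
  k2 <- K1 / vnd_region
  k3 <- config$k4 * vs / vnd_region
  data.frame(region = reg$region, K1 = K1, k2 = k2, k3 = k3, k4 = config$k4,
             vB = config$vB, vnd = vnd_region, vs = vs,
             vt_baseline = vnd_region + vs, stringsAsFactors = FALSE)
}

#' Simulate one synthetic subject (baseline + blocking scan)
#'
#' For each region, baseline \eqn{V_T = V_{ND} + V_S} and blocking
#' \eqn{V_T = V_{ND} + (1 - Occ) V_S}: the blocking scan shares K1 and V_B
#' with baseline while the specific-binding rate k3 is scaled by
#' \eqn{(1 - Occ)}; the occupancy is identical across regions within a
#' subject. TACs are the generating 2TCM forward model integrated over the
#' frame schedule plus zero-mean Gaussian frame noise with SD
#' \eqn{\propto \sqrt{C / \Delta t}} (count-statistics proxy). Blood data
#' for the two scans are independent realizations of the same model family.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index; determines the subject's
#'   sub-seed so cohorts are reproducible subject by subject.
#' @return A `synthetic_subject` with per-condition blood data, TAC matrix
#'   (frames x regions), scan metadata, and a complete `truth` record.
#' @export
simulate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"),
            subject_index >= 1, subject_index <= config$n_subjects)
  base_seed <- config$seed + 7919L * as.integer(subject_index)
  nreg <- nrow(config$regions)

  draws <- withr::with_seed(base_seed, {
    list(
      occupancy = stats::runif(1, config$occupancy_range[1],
                               config$occupancy_range[2]),
      subj_factor = stats::rlnorm(1, -config$between_subject_sd^2 / 2,
                                  config$between_subject_sd),
      vnd_region = if (config$regional_vnd_sd > 0) {
        config$true_vnd * stats::rlnorm(nreg, -config$regional_vnd_sd^2 / 2,
                                        config$regional_vnd_sd)
      } else rep(config$true_vnd, nreg),
      blood_jitter = stats::rlnorm(2, 0, 0.08),
      dose = stats::rnorm(2, 320, 25),
      weight = stats::rnorm(1, 80, 8)
    )
  })
  is_outlier <- config$outlier_subject && subject_index == config$n_subjects
  k1_scale <- if (is_outlier) 1 + config$outlier_inflation else 1
  # the outlier's K1 inflation propagates to V_ND and V_S jointly, so every
  # regional V_T is inflated by the same factor while k2, k3, k4 stay put
  truth_pars <- subject_region_truth(config, draws$subj_factor * k1_scale,
                                     k1_scale, draws$vnd_region * k1_scale)
  occ <- draws$occupancy

  conditions <- list()
  for (ci in 1:2) {
    cond <- c("baseline", "blocking")[ci]
    tr <- default_blood_truth()
    tr$peak <- tr$peak * draws$blood_jitter[ci]
    blood <- generate_input_function(noise_scale = config$noise_scale,
                                     truth = tr,
                                     seed = base_seed + 13L * ci)
    tacs <- matrix(NA_real_, nrow = length(config$schedule$start),
                   ncol = nreg, dimnames = list(NULL, truth_pars$region))
    di <- discretize_input(blood$truth$input, config$schedule, config$dt)
    for (r in seq_len(nreg)) {
      k3 <- truth_pars$k3[r] * if (cond == "blocking") 1 - occ else 1
      p <- c(K1 = truth_pars$K1[r], k2 = truth_pars$k2[r], k3 = k3,
             k4 = truth_pars$k4[r], vB = truth_pars$vB[r])
      tacs[, r] <- model_2tcm(p, di, config$schedule, config$dt)
    }
    if (config$noise_scale > 0) {
      noise <- withr::with_seed(base_seed + 100L + ci, {
        sd <- config$noise_scale *
          sqrt(pmax(tacs, 0.05) / config$schedule$duration)
        matrix(stats::rnorm(length(tacs), sd = sd), nrow = nrow(tacs))
      })
      tacs <- tacs + noise
    }
    conditions[[cond]] <- list(
      blood = blood, tacs = tacs,
      injected_dose_MBq = max(draws$dose[ci], 50),
      weight_kg = max(draws$weight, 40))
  }

  vt_base <- truth_pars$vt_baseline
  vt_block <- truth_pars$vnd + (1 - occ) * truth_pars$vs
  structure(
    list(subject_id = sprintf("sub-%02d", subject_index),
         conditions = conditions,
         truth = list(params = truth_pars, occupancy = occ,
                      vnd = config$true_vnd, outlier = is_outlier,
                      vt_baseline = stats::setNames(vt_base, truth_pars$region),
                      vt_blocking = stats::setNames(vt_block, truth_pars$region)),
         schedule = config$schedule),
    class = "synthetic_subject"
  )
}

#' Generate a full synthetic cohort, optionally writing the file tree
#'
#' @param config a [cohort_config()].
#' @param out_dir if given, the TSV/JSON tree the pipeline consumes is
#'   written there (per subject and condition: a blood TSV, a continuous
#'   whole-blood TSV, per-region TAC TSVs and a metadata JSON, plus a
#'   cohort `manifest.json` carrying the complete truth records).
#' @param overwrite refuse to write into an existing directory unless TRUE.
#' @return list of [simulate_subject()] results (invisibly carries the
#'   manifest as attribute `manifest` when `out_dir` is used).
#' @export
generate_cohort <- function(config, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- lapply(seq_len(config$n_subjects), simulate_subject,
                     config = config)
  if (is.null(out_dir)) return(subjects)
  if (dir.exists(out_dir) && !overwrite) {
    stop("output directory exists; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_subjects = config$n_subjects,
                   regions = config$regions$region,
                   true_vnd = config$true_vnd, seed = config$seed,
                   noise_scale = config$noise_scale, files = list(),
                   truth = list())
  for (s in subjects) {
    for (cond in names(s$conditions)) {
      cdir <- file.path(out_dir, s$subject_id, cond)
      dir.create(file.path(cdir, "tacs"), recursive = TRUE,
                 showWarnings = FALSE)
      cd <- s$conditions[[cond]]
      write_blood_tsv(cd$blood$discrete, file.path(cdir, "blood.tsv"))
      utils::write.table(cd$blood$continuous,
                         file.path(cdir, "blood_continuous.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      for (r in colnames(cd$tacs)) {
        write_tac_tsv(s$schedule, cd$tacs[, r],
                      file.path(cdir, "tacs", paste0(r, ".tsv")))
      }
      jsonlite::write_json(
        list(subject_id = s$subject_id, condition = cond,
             injected_dose_MBq = cd$injected_dose_MBq,
             weight_kg = cd$weight_kg),
        file.path(cdir, "meta.json"), auto_unbox = TRUE, digits = NA)
      manifest$files[[paste(s$subject_id, cond, sep = "_")]] <-
        file.path(s$subject_id, cond)
    }
    manifest$truth[[s$subject_id]] <- list(
      occupancy = s$truth$occupancy, vnd = s$truth$vnd,
      outlier = s$truth$outlier,
      vt_baseline = as.list(s$truth$vt_baseline),
      vt_blocking = as.list(s$truth$vt_blocking),
      params = s$truth$params)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  attr(subjects, "manifest") <- manifest
  invisible(subjects)
}

#' Simulate a cohort at the V_T level
#'
#' Lightweight counterpart of [generate_cohort()] for studying the
#' occupancy-plot stage at scale: regional V_T values are produced directly
#' from the same truth structure (shared V_ND, per-subject occupancy and
#' specific-binding scale, optional outlier) with multiplicative log-normal
#' estimation noise whose coefficient of variation `vt_noise_cv` matches
#' the observed accuracy of the TAC-level kinetic fits (~5% at the default
#' noise level).
#'
#' @param config a [cohort_config()] (`noise_scale = 0` switches the V_T
#'   noise off too).
#' @param vt_noise_cv CV of the V_T estimation noise at the default
#'   `noise_scale` of 0.1 (scales linearly with `noise_scale`). The default
#'   0.035 is the standard deviation of relative V_T errors measured on
#'   TAC-level kinetic fits of default-noise synthetic scans after
#'   exclusion (216 regional fits across both conditions).
#' @param seed overrides `config$seed`.
#' @return list with `pairs` (data.frame `subject`, `region`,
#'   `vt_baseline`, `vt_blocking`), `truth` (per-subject occupancy and the
#'   shared V_ND).
#' @export
simulate_vt_table <- function(config, vt_noise_cv = 0.035, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  cv <- vt_noise_cv * config$noise_scale / 0.1
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    rows <- list(); occs <- numeric(config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      occ <- stats::runif(1, config$occupancy_range[1],
                          config$occupancy_range[2])
      fac <- stats::rlnorm(1, -config$between_subject_sd^2 / 2,
                           config$between_subject_sd)
      infl <- if (config$outlier_subject && i == config$n_subjects) {
        1 + config$outlier_inflation
      } else 1
      vs <- pmax(config$regions$vt_baseline_mean - config$true_vnd, 0) * fac
      vb <- (config$true_vnd + vs) * infl
      vk <- (config$true_vnd + (1 - occ) * vs) * infl
      if (cv > 0) {
        vb <- vb * stats::rlnorm(length(vb), -sdlog^2 / 2, sdlog)
        vk <- vk * stats::rlnorm(length(vk), -sdlog^2 / 2, sdlog)
      }
      occs[i] <- occ
      rows[[i]] <- data.frame(subject = sprintf("sub-%02d", i),
                              region = config$regions$region,
                              vt_baseline = vb, vt_blocking = vk,
                              stringsAsFactors = FALSE)
    }
    list(pairs = do.call(rbind, rows),
         truth = list(occupancy = occs, vnd = config$true_vnd))
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "Synthetic subject %s: occupancy %.3f, true V_ND %.3g, %d regions%s\n",
    x$subject_id, x$truth$occupancy, x$truth$vnd, nrow(x$truth$params),
    if (x$truth$outlier) " [outlier]" else ""))
  invisible(x)
}
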