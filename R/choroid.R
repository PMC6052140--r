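#' Synthetic choroidal-thickness cohort specification
#'
#' Parameters of the generative model used for parameter-recovery studies
#' of the reading-experiment statistics. The defaults encode a cohort of
#' 7 subjects x 2 eyes reading under three conditions (dark text on a
#' light background, light text on a dark background, blank screen) with
#' subfoveal choroidal thickness measured at 0, 30 and 60 minutes, 5
#' repeated manual reads per cell.
#'
#' Generative model, per subject `s`, eye `e`, condition `c`:
#' \deqn{\Delta_{60}(s,e,c) = \mu_c + \beta (SE_s - \bar{SE}) 1[c = dark] + b_{s,e,c}}
#' with `b ~ N(0, sd_c)`, `SE_s` the subject's spherical equivalent drawn
#' uniformly on `refraction_range`, and the refraction term centered at
#' the mean of that range so the pooled mean change stays at `mu_c`. The
#' 30-minute change is `effect_30min_fraction` of the 60-minute change;
#' every cell emits `repeats` reads with i.i.d. measurement noise.
#'
#' @param n_subjects number of subjects, `>= 2`.
#' @param effect_60min named vector of true pooled 60-min changes (µm) per
#'   condition. Defaults: dark_text -16.13, light_text +9.96, blank 0.
#' @param effect_30min_fraction 30-min change as a fraction of the 60-min
#'   change.
#' @param between_sd named vector of eye-level SDs (µm) of the true change
#'   per condition (defaults 4.54, 6.51, 0).
#' @param measurement_sd SD (µm) of a single repeated manual read
#'   (default 7, inside the reported 5--10 range).
#' @param repeats reads per (subject, eye, condition, timepoint) cell.
#' @param baseline_mean,baseline_sd subject baseline thickness (µm).
#' @param refraction_slope µm of extra dark-text thinning per diopter of
#'   spherical equivalent (default 1.44 µm/D).
#' @param refraction_intercept intercept (µm) of the published thinning
#'   line; with the default refraction range the centered parameterisation
#'   is consistent with it (1.44 x (-3) - 11.8 = -16.12).
#' @param refraction_range range (D) of spherical equivalents, drawn
#'   uniformly per subject (both eyes share the subject's refraction).
#' @param diurnal_amplitude optional peak-to-trough sinusoidal drift (µm)
#'   over 24 h added to all conditions; 0 (default) reflects time-locked
#'   morning measurement sessions.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 7,
                        effect_60min = c(dark_text = -16.13,
                                         light_text = 9.96,
                                         blank_screen = 0),
                        effect_30min_fraction = 0.5,
                        between_sd = c(dark_text = 4.54,
                                       light_text = 6.51,
                                       blank_screen = 0),
                        measurement_sd = 7,
                        repeats = 5,
                        baseline_mean = 255, baseline_sd = 40,
                        refraction_slope = 1.44,
                        refraction_intercept = -11.8,
                        refraction_range = c(-6.25, 0.25),
                        diurnal_amplitude = 0) {
  stopifnot(n_subjects >= 2, all(between_sd >= 0), measurement_sd >= 0,
            baseline_sd >= 0, repeats >= 1, diurnal_amplitude >= 0)
  if (is.null(names(effect_60min)) ||
      !setequal(names(between_sd), names(effect_60min))) {
    stop("effect_60min and between_sd must be named by the same conditions")
  }
  structure(list(n_subjects = n_subjects, effect_60min = effect_60min,
                 effect_30min_fraction = effect_30min_fraction,
                 between_sd = between_sd[names(effect_60min)],
                 measurement_sd = measurement_sd, repeats = repeats,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 refraction_slope = refraction_slope,
                 refraction_intercept = refraction_intercept,
                 refraction_range = refraction_range,
                 diurnal_amplitude = diurnal_amplitude),
            class = "cohort_spec")
}

#' Simulate a synthetic choroidal-thickness cohort
#'
#' Draws one cohort from the generative model in [cohort_spec] and returns
#' a flat measurement table: one repeated read per row. Deterministic per
#' seed; the caller's RNG state is preserved.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed.
#' @return Data frame with columns `subject`, `eye` (right/left),
#'   `condition`, `timepoint` (0/30/60 min), `thickness` (µm),
#'   `spherical_equivalent` (D).
#' @examples
#' head(simulate_cohort(cohort_spec(), seed = 1))
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_preserved_seed(seed, {
    conds <- names(spec$effect_60min)
    subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
    se <- stats::runif(spec$n_subjects, spec$refraction_range[1],
                       spec$refraction_range[2])
    baseline <- stats::rnorm(spec$n_subjects, spec$baseline_mean,
                             spec$baseline_sd)
    names(se) <- names(baseline) <- subjects
    se_center <- mean(spec$refraction_range)

    cells <- expand.grid(subject = subjects, eye = c("right", "left"),
                         condition = conds, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    mu <- spec$effect_60min[cells$condition] +
      ifelse(cells$condition == "dark_text",
             spec$refraction_slope * (se[cells$subject] - se_center), 0)
    cells$change60 <- mu + stats::rnorm(nrow(cells),
                                        sd = spec$between_sd[cells$condition])

    timepoints <- c(0, 30, 60)
    frac <- c(`0` = 0, `30` = spec$effect_30min_fraction, `60` = 1)
    long <- cells[rep(seq_len(nrow(cells)), each = length(timepoints)), ]
    long$timepoint <- rep(timepoints, times = nrow(cells))
    truth <- baseline[long$subject] +
      frac[as.character(long$timepoint)] * long$change60
    if (spec$diurnal_amplitude > 0) {
      truth <- truth + spec$diurnal_amplitude / 2 *
        sin(2 * pi * long$timepoint / (24 * 60))
    }
    reads <- long[rep(seq_len(nrow(long)), each = spec$repeats), ]
    reads$thickness <- rep(truth, each = spec$repeats) +
      stats::rnorm(nrow(long) * spec$repeats, sd = spec$measurement_sd)
    reads$spherical_equivalent <- se[reads$subject]
    reads$change60 <- NULL
    rownames(reads) <- NULL
    reads[, c("subject", "eye", "condition", "timepoint", "thickness",
              "spherical_equivalent")]
  })
}

validate_choroid_table <- function(table) {
  required <- c("subject", "eye", "condition", "timepoint", "thickness")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(table$thickness)) || any(table$thickness <= 0)) {
    stop("thickness values must be finite and positive")
  }
  table
}

#' Per-eye change from baseline
#'
#' Averages repeated reads per (subject, eye, condition, timepoint) cell
#' first, then subtracts the cell's own baseline (t = 0) mean. Eyes are
#' kept separate; pooled-eye summaries treat the per-eye changes as
#' independent observations (see [condition_effects]).
#'
#' @param table measurement table as produced by [simulate_cohort] or
#'   [read_choroid_csv].
#' @return Data frame with one row per (subject, eye, condition,
#'   timepoint > 0): columns `subject`, `eye`, `condition`, `timepoint`,
#'   `change` (µm) and, when present in the input,
#'   `spherical_equivalent`.
#' @export
change_from_baseline <- function(table) {
  validate_choroid_table(table)
  cell <- stats::aggregate(thickness ~ subject + eye + condition + timepoint,
                           data = table, FUN = mean)
  base <- cell[cell$timepoint == 0,
               c("subject", "eye", "condition", "thickness")]
  names(base)[4] <- "baseline"
  post <- cell[cell$timepoint > 0, ]
  series <- unique(post[, c("subject", "eye", "condition")])
  have <- merge(series, base, by = c("subject", "eye", "condition"),
                all.x = TRUE)
  if (anyNA(have$baseline)) {
    bad <- have[is.na(have$baseline), ]
    stop("missing baseline (t = 0) for series: ",
         paste(sprintf("%s/%s/%s", bad$subject, bad$eye, bad$condition),
               collapse = "; "))
  }
  out <- merge(post, base, by = c("subject", "eye", "condition"))
  out$change <- out$thickness - out$baseline
  if ("spherical_equivalent" %in% names(table)) {
    se <- unique(table[, c("subject", "eye", "spherical_equivalent")])
    out <- merge(out, se, by = c("subject", "eye"))
  }
  out <- out[order(out$condition, out$subject, out$eye, out$timepoint),
             setdiff(names(out), c("thickness", "baseline"))]
  rownames(out) <- NULL
  out
}

#' Paired t-test on within-eye differences
#'
#' Classical two-sided paired t-test (one-sample t on the differences)
#' with `n - 1` degrees of freedom and no multiple-comparison correction.
#'
#' @param differences numeric vector of paired differences (µm).
#' @return List: `t`, `p`, `mean`, `sd`, `n`, `df`.
#' @examples
#' paired_t_test(c(1, 2, 3, 4, 5))
#' @export
paired_t_test <- function(differences) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 2) stop("need at least 2 differences")
  if (stats::sd(differences) == 0) {
    stop("degenerate sample: zero variance among differences")
  }
  fit <- stats::t.test(differences, alternative = "two.sided")
  list(t = unname(fit$statistic), p = fit$p.value,
       mean = mean(differences), sd = stats::sd(differences),
       n = n, df = n - 1L)
}

#' One-way repeated-measures ANOVA over timepoint
#'
#' For one condition (and optionally one eye side), each subject-eye is a
#' repeated unit measured at 0, 30 and 60 minutes (repeated reads averaged
#' per cell first). Classical univariate F with sphericity assumed:
#' `F = MS_time / MS_(time x unit)`. Follow-up two-sided paired t-tests
#' compare 30 and 60 minutes against baseline. Incomplete series are
#' dropped with a warning; fewer than 3 complete series is an error.
#'
#' @param table measurement table.
#' @param condition condition to analyze.
#' @param eyes `"pooled"` (both eyes, each its own unit), `"right"` or
#'   `"left"`.
#' @return List: `F`, `df1`, `df2`, `p`, `n_units`, and `followup` (a
#'   data frame of paired-t results at 30 and 60 min vs. baseline).
#' @export
rm_anova <- function(table, condition, eyes = c("pooled", "right", "left")) {
  eyes <- match.arg(eyes)
  validate_choroid_table(table)
  sub <- table[table$condition == condition, ]
  if (eyes != "pooled") sub <- sub[sub$eye == eyes, ]
  if (!nrow(sub)) stop("no measurements for condition ", condition)
  cell <- stats::aggregate(thickness ~ subject + eye + timepoint,
                           data = sub, FUN = mean)
  cell$unit <- interaction(cell$subject, cell$eye, drop = TRUE)
  counts <- table(cell$unit)
  complete <- names(counts)[counts == 3L]
  if (length(complete) < length(counts)) {
    warning("dropping incomplete series: ",
            paste(setdiff(names(counts), complete), collapse = ", "))
    cell <- cell[cell$unit %in% complete, ]
    cell$unit <- droplevels(cell$unit)
  }
  if (length(complete) < 3L) {
    stop("fewer than 3 complete subject-eye series for condition ", condition)
  }
  cell$time_f <- factor(cell$timepoint)
  fit <- stats::aov(thickness ~ time_f + Error(unit), data = cell)
  within <- summary(fit)[["Error: Within"]][[1]]
  Fval <- within["time_f", "F value"]
  if (!is.finite(Fval) || within["Residuals", "Mean Sq"] == 0) {
    stop("degenerate residual variance in repeated-measures ANOVA")
  }
  wide <- stats::reshape(cell[, c("unit", "timepoint", "thickness")],
                         idvar = "unit", timevar = "timepoint",
                         direction = "wide")
  followup <- do.call(rbind, lapply(c(30, 60), function(tp) {
    d <- wide[[paste0("thickness.", tp)]] - wide[["thickness.0"]]
    tt <- paired_t_test(d)
    data.frame(timepoint = tp, mean_change = tt$mean, sd = tt$sd,
               t = tt$t, p = tt$p, n = tt$n)
  }))
  list(F = unname(Fval),
       df1 = within["time_f", "Df"],
       df2 = within["Residuals", "Df"],
       p = unname(within["time_f", "Pr(>F)"]),
       n_units = length(complete),
       followup = followup)
}

#' Per-condition effect summaries with paired t-tests
#'
#' Mean change from baseline at one timepoint per condition, with the eyes
#' pooled as independent observations (the study's stated choice) or
#' restricted to one side, plus a conservative subject-level mode that
#' averages the two eyes before testing.
#'
#' @param changes output of [change_from_baseline].
#' @param timepoint minutes (default 60).
#' @param pool `"eyes"` (each eye an observation), `"right"`, `"left"`,
#'   or `"subjects"` (eyes averaged within subject first; flagged in the
#'   output).
#' @return Data frame, one row per condition: `condition`, `pooling`,
#'   `n`, `mean_change`, `sd`, `t`, `p`.
#' @export
condition_effects <- function(changes, timepoint = 60,
                              pool = c("eyes", "right", "left", "subjects")) {
  pool <- match.arg(pool)
  sub <- changes[changes$timepoint == timepoint, ]
  if (!nrow(sub)) stop("no changes at timepoint ", timepoint)
  if (pool %in% c("right", "left")) sub <- sub[sub$eye == pool, ]
  if (pool == "subjects") {
    sub <- stats::aggregate(change ~ subject + condition, data = sub,
                            FUN = mean)
  }
  do.call(rbind, lapply(split(sub, sub$condition), function(d) {
    tt <- paired_t_test(d$change)
    data.frame(condition = d$condition[1], pooling = pool, n = tt$n,
               mean_change = tt$mean, sd = tt$sd, t = tt$t, p = tt$p)
  }))
}

#' Regress dark-text choroidal change on refraction
#'
#' Ordinary least squares of the 60-minute change (µm) for the dark-text
#' condition on spherical-equivalent refraction (D), with eyes treated as
#' independent observations. Returns the slope (µm/D), intercept (µm),
#' Pearson R and its two-sided p.
#'
#' @param changes output of [change_from_baseline]; must carry
#'   `spherical_equivalent`.
#' @param condition condition to regress (default `"dark_text"`).
#' @param timepoint minutes (default 60).
#' @return List: `slope`, `intercept`, `R`, `p`, `n`.
#' @export
regress_thinning_on_refraction <- function(changes, condition = "dark_text",
                                           timepoint = 60) {
  if (!"spherical_equivalent" %in% names(changes)) {
    stop("changes table lacks spherical_equivalent")
  }
  sub <- changes[changes$condition == condition &
                   changes$timepoint == timepoint, ]
  if (nrow(sub) < 3) stop("need at least 3 eyes")
  if (length(unique(sub$spherical_equivalent)) < 2) {
    stop("all refractions identical; slope is undefined")
  }
  fit <- stats::lm(change ~ spherical_equivalent, data = sub)
  if (stats::sd(sub$change) == 0) {
    return(list(slope = 0, intercept = mean(sub$change), R = 0, p = 1,
                n = nrow(sub)))
  }
  ct <- stats::cor.test(sub$spherical_equivalent, sub$change)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       R = unname(ct$estimate), p = ct$p.value, n = nrow(sub))
}

#' Full statistics report for a measurement table
#'
#' Runs the complete pipeline: per-condition 30/60-minute effects with
#' paired t-tests (eyes pooled and per side), repeated-measures ANOVAs
#' with follow-up tests, and the thinning-vs-refraction regression when
#' refraction data are present. No multiple-comparison correction is
#' applied anywhere.
#'
#' @param table measurement table.
#' @return Nested list suitable for JSON serialisation.
#' @export
choroid_stats_report <- function(table) {
  validate_choroid_table(table)
  changes <- change_from_baseline(table)
  conds <- unique(table$condition)
  effects <- lapply(c(30, 60), function(tp) {
    lapply(c("eyes", "right", "left"), function(pool) {
      tryCatch(condition_effects(changes, timepoint = tp, pool = pool),
               error = function(e) NULL)
    })
  })
  anovas <- lapply(stats::setNames(conds, conds), function(cc) {
    lapply(stats::setNames(c("pooled", "right", "left"),
                           c("pooled", "right", "left")), function(ey) {
      tryCatch({
        a <- rm_anova(table, cc, eyes = ey)
        a$followup <- NULL
        a
      }, error = function(e) list(error = conditionMessage(e)))
    })
  })
  regression <- if ("spherical_equivalent" %in% names(changes) &&
                    "dark_text" %in% conds) {
    tryCatch(regress_thinning_on_refraction(changes),
             error = function(e) list(error = conditionMessage(e)))
  } else NULL
  list(n_measurements = nrow(table),
       conditions = conds,
       effects = effects,
       rm_anova = anovas,
       regression_dark_text_60min = regression)
}

#' Read / write choroidal measurement tables as CSV
#'
#' Flat CSV with a header row and one repeated read per line, columns
#' `subject, eye, condition, timepoint, thickness, spherical_equivalent`
#' (the last optional). This is also the ingest path for an externally
#' obtained measurement spreadsheet exported to CSV.
#'
#' @param path file path.
#' @return For the reader, a validated measurement data frame.
#' @export
read_choroid_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_choroid_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_choroid_csv
#' @param table measurement table to write.
#' @export
write_choroid_csv <- function(table, path) {
  validate_choroid_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
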