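#' Specify a synthetic scan cohort
#'
#' Defines the generative model for a two-group (control / CHD) cohort of
#' placental scans. Per-component mean ROI weightings follow piecewise-linear
#' gestational-age trajectories with a changepoint at 30 weeks -- the
#' gestation after which group differences are most evident -- plus
#' subject-level random intercepts (shared by a subject's repeat scans) and
#' scan-level measurement noise, renormalised onto the K-simplex. Scalar MRI
#' summaries (mean T2*, mean ADC, ROI volume) follow linear-in-GA models
#' calibrated to published cohort values: control/CHD mean T2* of 58.1/51.1
#' ms with a strong negative GA trend, mean ADC near 0.020/0.0175 mm^2/s
#' (the conventional placental printed scale), ROI volume near 453,000 mm^3
#' rising with GA, and maternal-age medians near 35.0/32.3 years.
#'
#' The default trajectories encode the reported qualitative pattern: the
#' component-4 weighting rises after 30 weeks in controls but not CHD, the
#' component-3 weighting rises after 30 weeks in CHD but not controls, and
#' the late components decline with gestation in both groups.
#'
#' @param n_control_subjects,n_chd_subjects Subjects per group (36 / 12).
#' @param repeat_scan_fraction Fraction of subjects scanned twice (0.39,
#'   giving 50 control and 17 CHD scans at the defaults).
#' @param K Number of components (7).
#' @param baseline Length-K simplex of weightings at 20 weeks.
#' @param slopes_pre,slopes_post K x 2 matrices (columns control, chd) of
#'   weighting change per week before / after the 30-week changepoint.
#' @param sd_subject,sd_measurement Between-subject and scan-level standard
#'   deviations of each weighting (fraction units).
#' @param ga List of per-group GA samplers (normal mean/sd, clipped to
#'   `ga_range`).
#' @param ga_range Allowed GA range in weeks.
#' @param maternal_age Per-group normal mean/sd of maternal age (years).
#' @param t2star,adc,volume Per-group linear-in-GA models for the scalar
#'   summaries: value = `mean` + `slope` * (GA - group mean GA) + N(0, `sd`).
#'   T2* in ms; ADC in mm^2/s; volume in mm^3.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(
    n_control_subjects = 36, n_chd_subjects = 12,
    repeat_scan_fraction = 0.39, K = 7,
    baseline = c(0.20, 0.10, 0.15, 0.10, 0.15, 0.15, 0.15),
    slopes_pre = cbind(control = c(0, 0, 0, 0.002, -0.001, -0.001, 0),
                       chd = c(0, 0.002, 0.002, 0.002, -0.001, -0.001, 0)),
    slopes_post = cbind(control = c(0, 0.002, 0, 0.040, -0.004, -0.008, -0.010),
                        chd = c(0, 0.006, 0.040, 0, -0.006, -0.007, -0.012)),
    sd_subject = 0.02, sd_measurement = 0.01,
    ga = list(control = c(mean = 30, sd = 4), chd = c(mean = 31.5, sd = 4)),
    ga_range = c(20, 42),
    maternal_age = list(control = c(mean = 35.0, sd = 3.0),
                        chd = c(mean = 32.3, sd = 4.5)),
    t2star = list(control = c(mean = 58.1, slope = -2.2, sd = 7.2),
                  chd = c(mean = 51.1, slope = -2.2, sd = 4.5)),
    adc = list(control = c(mean = 0.020, slope = -7e-4, sd = 3.5e-3),
               chd = c(mean = 0.0175, slope = -7e-4, sd = 3.5e-3)),
    volume = list(control = c(mean = 453000, slope = 19000, sd = 131000),
                  chd = c(mean = 512000, slope = 19000, sd = 150000))) {
  baseline <- baseline / sum(baseline)
  if (length(baseline) != K) stop("baseline must have length K")
  if (!all(dim(slopes_pre) == c(K, 2)) || !all(dim(slopes_post) == c(K, 2))) {
    stop("slope matrices must be K x 2 (control, chd)")
  }
  structure(
    list(n_control_subjects = n_control_subjects,
         n_chd_subjects = n_chd_subjects,
         repeat_scan_fraction = repeat_scan_fraction, K = K,
         baseline = baseline, slopes_pre = slopes_pre,
         slopes_post = slopes_post, sd_subject = sd_subject,
         sd_measurement = sd_measurement, ga = ga, ga_range = ga_range,
         maternal_age = maternal_age, t2star = t2star, adc = adc,
         volume = volume),
    class = "cohort_spec"
  )
}

#' Null and single-divergence cohort specifications
#'
#' `null_cohort_spec()` removes every group difference and every trajectory
#' (flat weightings, equal scalar models), for false-positive studies of the
#' testing machinery. Scans are made exchangeable (`sd_subject = 0`): the
#' statistics analyse scans as independent observations, so an exchangeable
#' null isolates the behaviour of the tests themselves from the separate,
#' documented caveat that repeat scans of one subject are correlated.
#' `divergent_cohort_spec()` makes the two groups identical except for a
#' programmed post-30-week divergence of a single component's weighting
#' trajectory, at a default size calibrated so the implied adjusted group
#' comparison reaches the strength reported for diverging placental
#' components at this cohort size.
#'
#' @param K Number of components.
#' @param component Component whose post-30-week CHD slope diverges.
#' @param divergence Added CHD slope (fraction per week) after 30 weeks.
#' @param ... Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(K = 7, ...) {
  z <- matrix(0, K, 2, dimnames = list(NULL, c("control", "chd")))
  eq <- function(m) { m$chd <- m$control; m }
  sp <- cohort_spec(K = K, baseline = rep(1 / K, K), slopes_pre = z,
                    slopes_post = z, sd_subject = 0, ...)
  sp$ga$chd <- sp$ga$control
  sp$maternal_age$chd <- sp$maternal_age$control
  sp$t2star <- eq(sp$t2star)
  sp$adc <- eq(sp$adc)
  sp$volume <- eq(sp$volume)
  sp
}

#' @rdname null_cohort_spec
#' @export
divergent_cohort_spec <- function(component = 3, divergence = 0.04, K = 7,
                                  ...) {
  sp <- cohort_spec(K = K, ...)
  sp$slopes_pre[, "chd"] <- sp$slopes_pre[, "control"]
  sp$slopes_post[, "chd"] <- sp$slopes_post[, "control"]
  sp$ga$chd <- sp$ga$control
  sp$maternal_age$chd <- sp$maternal_age$control
  sp$slopes_post[component, "chd"] <-
    sp$slopes_post[component, "control"] + divergence
  sp
}

# noiseless trajectory weightings at one GA for one group
trajectory_weights <- function(spec, ga, group) {
  g <- if (group == "control") 1 else 2
  w <- spec$baseline +
    spec$slopes_pre[, g] * (min(ga, 30) - 20) +
    spec$slopes_post[, g] * max(ga - 30, 0)
  w <- pmax(w, 0)
  if (sum(w) == 0) w <- rep(1, spec$K)
  w / sum(w)
}

#' Simulate a cohort of scan records
#'
#' Draws subjects, gestational ages (repeat scans share their subject's
#' random component effects and are ordered in GA), and per-scan summary
#' measures from a [cohort_spec()]. With `emit_volumes = TRUE` a small
#' phantom is also generated per scan, with class weights blended toward the
#' scan's mean weightings so image-level and summary-level analyses see the
#' same cohort structure.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param emit_volumes Also generate per-scan phantoms (default FALSE).
#' @param scheme,phantom_shape,components Used only when `emit_volumes`.
#' @return A tibble of scan records (`subject_id`, `scan_id`, `group`,
#'   `ga_weeks`, `maternal_age`, `weight_1..K`, `mean_t2star`, `mean_adc`,
#'   `roi_volume`), or a list `(records, phantoms)` when `emit_volumes`.
#' @examples
#' head(simulate_cohort(cohort_spec(), seed = 1))
#' @export
simulate_cohort <- function(spec, seed = 1, emit_volumes = FALSE,
                            scheme = zebra_scheme("reduced_test"),
                            phantom_shape = c(10, 10, 4),
                            components = NULL) {
  records <- with_local_seed(seed, simulate_cohort_records(spec))
  if (!emit_volumes) return(records)
  if (is.null(components)) {
    grid <- spectral_grid(30, 30)
    components <- default_placenta_components(grid)
  }
  if (components$K != spec$K) stop("components K does not match spec K")
  phantoms <- purrr::map(seq_len(nrow(records)), function(i) {
    w_scan <- as.numeric(records[i, paste0("weight_", seq_len(spec$K))])
    cw <- default_class_weights(spec$K)
    cw <- 0.5 * cw + 0.5 * matrix(w_scan, 4, spec$K, byrow = TRUE)
    cw <- sweep(cw, 1, rowSums(cw), "/")
    make_phantom(phantom_shape, scheme, components, class_weights = cw,
                 snr = 100, seed = seed + i)
  })
  list(records = records, phantoms = phantoms)
}

simulate_cohort_records <- function(spec) {
  groups <- list(
    list(name = "control", n = spec$n_control_subjects),
    list(name = "chd", n = spec$n_chd_subjects)
  )
  rows <- list()
  sid <- 0
  for (g in groups) {
    if (g$n < 1) next
    n_repeat <- round(spec$repeat_scan_fraction * g$n)
    repeated <- seq_len(g$n) <= n_repeat   # deterministic count per group
    ga_par <- spec$ga[[g$name]]
    age_par <- spec$maternal_age[[g$name]]
    for (s in seq_len(g$n)) {
      sid <- sid + 1
      subj_eff <- stats::rnorm(spec$K, 0, spec$sd_subject)
      age <- clamp(stats::rnorm(1, age_par["mean"], age_par["sd"]), 18, 50)
      n_scans <- if (repeated[s]) 2 else 1
      gas <- sort(clamp(stats::rnorm(n_scans, ga_par["mean"], ga_par["sd"]),
                        spec$ga_range[1], min(spec$ga_range[2], 42)))
      for (sc in seq_len(n_scans)) {
        ga <- gas[sc]
        w <- trajectory_weights(spec, ga, g$name) + subj_eff +
          stats::rnorm(spec$K, 0, spec$sd_measurement)
        w <- pmax(w, 0)
        if (sum(w) == 0) w <- rep(1, spec$K)
        w <- w / sum(w)
        sc_row <- c(list(
          subject_id = sprintf("%s_%02d", g$name, s),
          group = g$name, ga_weeks = ga, maternal_age = age
        ), stats::setNames(as.list(w), paste0("weight_", seq_len(spec$K))))
        for (nm in c("t2star", "adc", "volume")) {
          par <- spec[[nm]][[g$name]]
          sc_row[[nm]] <- unname(par["mean"] +
            par["slope"] * (ga - ga_par["mean"]) +
            stats::rnorm(1, 0, par["sd"]))
        }
        rows[[length(rows) + 1]] <- sc_row
      }
    }
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out$t2star <- pmax(out$t2star, 5)
  out$adc <- pmax(out$adc, 1e-4)
  out$volume <- pmax(out$volume, 5e4)
  out |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(scan_id = paste0(.data$subject_id, "_s",
                                   dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::rename(mean_t2star = "t2star", mean_adc = "adc",
                  roi_volume = "volume") |>
    dplyr::relocate("scan_id", .after = "subject_id")
}
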