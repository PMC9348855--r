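#' Noise specification for synthetic datasets
#'
#' Counts carry lognormal noise with coefficient of variation `count_cv`;
#' fractions (donor fraction, Ki67, GFP percentages) carry normal noise on
#' the logit scale with standard deviation `frac_sd`. Defaults are
#' registered constants chosen to emulate the scatter of the chimera
#' timecourses.
#'
#' @param count_cv lognormal CV for counts.
#' @param frac_sd logit-scale SD for fractions.
#' @export
noise_spec <- function(count_cv = 0.2, frac_sd = 0.25) {
  stopifnot(count_cv >= 0, frac_sd >= 0)
  structure(list(count_cv = count_cv, frac_sd = frac_sd),
            class = "noise_spec")
}

.sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

.rlnorm_noise <- function(m, cv) {
  if (cv == 0) return(m)
  sdl <- .sdlog_from_cv(cv)
  m * stats::rlnorm(length(m), -sdl^2 / 2, sdl)
}

.rlogit_noise <- function(m, sd) {
  if (sd == 0) return(m)
  eps <- 1e-9
  stats::plogis(stats::qlogis(pmin(pmax(m, eps), 1 - eps)) +
                  stats::rnorm(length(m), 0, sd))
}

#' Busulfan-chimera study design
#'
#' Default design mirrors the chimera cohort: three BMT age groups between 7
#' and 25 weeks of age, observation ages staggered from 4 weeks post-BMT out
#' to 600 days.
#'
#' @param n_mice total number of mice (split evenly across groups).
#' @param bmt_ages BMT age of each group, days.
#' @param max_age latest observation age, days.
#' @param subset `"CD4"` or `"CD8"`.
#' @param seed seed for the staggered sampling ages.
#' @return data frame with one row per mouse: `mouse_id`, `age_bmt`,
#'   `host_age`, `subset`.
#' @export
chimera_design <- function(n_mice = 100, bmt_ages = c(56, 98, 154),
                           max_age = 600, subset = "CD4", seed = 1) {
  set.seed(seed)
  grp <- rep_len(seq_along(bmt_ages), n_mice)
  age_bmt <- bmt_ages[grp]
  host_age <- vapply(age_bmt, function(tb)
    round(stats::runif(1, tb + 28, max_age)), 0)
  data.frame(mouse_id = sprintf("m%03d", seq_len(n_mice)),
             age_bmt = age_bmt, host_age = host_age,
             subset = subset, stringsAsFactors = FALSE)
}

#' Generate a synthetic busulfan-chimera dataset
#'
#' Solves the model for every mouse (shared kinetic parameters,
#' mouse-specific BMT age), then draws noisy counts (lognormal) and noisy
#' fractions (logit-normal, clamped to (0, 1)).
#'
#' @param p a [kinetic_params()] object (the generating truth).
#' @param influx an [influx_descriptor()].
#' @param design data frame from [chimera_design()].
#' @param noise a [noise_spec()].
#' @param seed integer seed; the generator is a pure function of
#'   `(p, influx, design, noise, seed)`.
#' @param chimerism DP1 donor chimerism.
#' @param a_step cell-age quadrature step, days.
#' @return data frame in the `chimera` CSV schema, with the generation
#'   parameters attached as attribute `"manifest"`.
#' @export
generate_chimera_dataset <- function(p, influx, design, noise = noise_spec(),
                                     seed = 1, chimerism = 0.85, a_step = 1) {
  m <- model_observables(p, influx, design, chimerism, a_step)
  if (any(!is.finite(m$total_count)) || any(m$total_count <= 0))
    stop("model failure at a design point; cannot generate data")
  set.seed(seed)
  out <- data.frame(
    mouse_id = design$mouse_id,
    host_age = design$host_age,
    age_bmt = design$age_bmt,
    subset = design$subset,
    total_count = .rlnorm_noise(m$total_count, noise$count_cv),
    fd = .rlogit_noise(m$fd, noise$frac_sd),
    ki67_host = .rlogit_noise(m$ki67_host, noise$frac_sd),
    ki67_donor = .rlogit_noise(m$ki67_donor, noise$frac_sd),
    stringsAsFactors = FALSE)
  attr(out, "manifest") <- list(
    schema = "chimera", variant = p$variant, seed = seed,
    chimerism = chimerism,
    params = unclass(p)[.variant_parnames(p$variant)],
    noise = unclass(noise))
  out
}

#' Generate a synthetic SP thymocyte timecourse
#'
#' @param descriptor the generating [influx_descriptor()].
#' @param ages sampling ages, days.
#' @param subset subset label.
#' @param noise a [noise_spec()]; `count_cv` applies to SP counts and
#'   `frac_sd` to the logit of the Ki67 fraction.
#' @param seed integer seed.
#' @return data frame in the `sp` CSV schema.
#' @export
generate_sp_timecourse <- function(descriptor,
                                   ages = round(seq(5, 450, length.out = 40)),
                                   subset = "CD4", noise = noise_spec(0.1, 0.2),
                                   seed = 1) {
  set.seed(seed)
  data.frame(
    mouse_age_days = ages,
    subset = subset,
    sp_count = .rlnorm_noise(sp_count_curve(ages, descriptor), noise$count_cv),
    sp_ki67_frac = .rlogit_noise(sp_ki67_curve(ages, descriptor),
                                 noise$frac_sd),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic fate-mapping cohort dataset
#'
#' Emulates tamoxifen time-stamping of naive CD8 cohorts: mice in several
#' host-age groups, each sampled longitudinally; labelled counts decay with
#' time since labelling (= cohort cell age) following the net-loss cohort
#' curve. Mouse-level `N0` is drawn from a lognormal hyperdistribution;
#' `lambda0` is group-specific (or mouse-specific around the group value if
#' `lambda0_mouse_sd > 0`).
#'
#' @param group_ages host age at tamoxifen per group, days.
#' @param lambda0 group-level net loss rate at cell age 0, day^-1 (recycled
#'   to `length(group_ages)`).
#' @param r_lambda decline rate of the net loss with cell age, day^-1.
#' @param n0_meanlog,n0_sdlog hyperdistribution of mouse-level `N0` (log
#'   scale).
#' @param lambda0_mouse_sd optional log-scale SD of mouse-level scatter
#'   around the group `lambda0` (0 = purely group-structured).
#' @param n_mice_per_group,timepoints design: mice per group and sampling
#'   times since labelling (days).
#' @param noise a [noise_spec()]; only `count_cv` is used.
#' @param seed integer seed.
#' @return data frame in the `cohort` CSV schema; true mouse-level
#'   parameters attached as attribute `"truth"`.
#' @export
generate_cohort_dataset <- function(group_ages = c(14, 35, 63),
                                    lambda0 = c(0.06, 0.04, 0.03),
                                    r_lambda = 0.004,
                                    n0_meanlog = log(3e5), n0_sdlog = 0.35,
                                    lambda0_mouse_sd = 0,
                                    n_mice_per_group = 5,
                                    timepoints = c(7, 14, 28, 42, 63, 90),
                                    noise = noise_spec(count_cv = 0.15),
                                    seed = 1) {
  lambda0 <- rep_len(lambda0, length(group_ages))
  set.seed(seed)
  rows <- list(); truth <- list()
  id <- 0
  for (g in seq_along(group_ages)) {
    for (m in seq_len(n_mice_per_group)) {
      id <- id + 1
      n0 <- stats::rlnorm(1, n0_meanlog, n0_sdlog)
      l0 <- lambda0[g] * exp(stats::rnorm(1, 0, lambda0_mouse_sd))
      mu <- cohort_curve(timepoints, n0, l0, r_lambda)
      rows[[id]] <- data.frame(
        mouse_id = sprintf("g%dm%02d", g, m),
        group_age_days = group_ages[g],
        time_since_label_days = timepoints,
        labelled_count = .rlnorm_noise(mu, noise$count_cv),
        stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(mouse_id = rows[[id]]$mouse_id[1],
                                group = g, n0 = n0, lambda0 = l0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "manifest") <- list(schema = "cohort", seed = seed,
                                group_ages = group_ages, lambda0 = lambda0,
                                r_lambda = r_lambda)
  out
}

#' Generate a synthetic Rag-GFP reporter dataset
#'
#' Emulates dual-reporter observations over ages 10-120 days: total GFP+
#' naive cell numbers and the percentages of the naive pool that are
#' GFP+Ki67+ and GFP+Ki67-.
#'
#' @param p a [kinetic_params()] object.
#' @param influx an [influx_descriptor()].
#' @param gfp a [gfp_map()].
#' @param ages mouse ages sampled, days.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param a_step age-grid resolution for the underlying trajectory.
#' @return data frame in the `reporter` CSV schema (percentages in 0-100).
#' @export
generate_reporter_dataset <- function(p, influx, gfp,
                                      ages = round(seq(10, 120, length.out = 25)),
                                      noise = noise_spec(), seed = 1,
                                      a_step = 0.5) {
  traj <- solve_age_structured(p, influx, t_span = c(1, max(ages)),
                               t_out = ages, a_step = a_step)
  pr <- predict_reporter_fractions(traj, gfp)
  set.seed(seed)
  data.frame(
    mouse_age_days = ages,
    gfp_count = .rlnorm_noise(pr$gfp_count, noise$count_cv),
    pct_gfp_ki67pos = 100 * .rlogit_noise(pr$pct_gfp_ki67pos / 100,
                                          noise$frac_sd),
    pct_gfp_ki67neg = 100 * .rlogit_noise(pr$pct_gfp_ki67neg / 100,
                                          noise$frac_sd),
    stringsAsFactors = FALSE)
}
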