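#' Hill-function description of the baseline net loss rate vs mouse age
#'
#' Fate-mapped naive CD8 cohorts show that the net loss rate of cells of age 0
#' (`lambda0`) is higher in young mice and declines to an adult plateau. This
#' is described empirically by a decreasing sigmoid (Hill) function of mouse
#' age `t`:
#' `lambda0(t) = lambda_min + (lambda_max - lambda_min) / (1 + (t/t_half)^h)`.
#' The same object doubles as the neonatal baseline-loss modifier for the
#' age-structured model: cohorts exported at mouse age `t0` inherit a baseline
#' loss rate scaled by `lambda0(t0) / lambda_min`.
#'
#' @param lambda_min adult plateau of the baseline net loss rate (day^-1).
#' @param lambda_max neonatal plateau (day^-1), `>= lambda_min`.
#' @param t_half mouse age of half-decline (days).
#' @param h Hill coefficient (> 0).
#' @return An object of class `lambda0_hill`.
#' @export
lambda0_hill <- function(lambda_min, lambda_max, t_half, h) {
  stopifnot(lambda_max >= lambda_min, lambda_min >= 0, t_half > 0, h > 0)
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max,
                 t_half = t_half, h = h),
            class = "lambda0_hill")
}

#' Evaluate a Hill curve at mouse ages t
#' @param mod a `lambda0_hill` object.
#' @param t mouse age, days.
#' @return `lambda0(t)`, day^-1; monotone non-increasing in `t`.
#' @export
lambda0_at <- function(mod, t) {
  mod$lambda_min +
    (mod$lambda_max - mod$lambda_min) / (1 + (t / mod$t_half)^mod$h)
}

## cohort-entry-time scaling of the baseline loss rate: lambda0(t0)/lambda0(inf)
.modifier_scale <- function(mod, t0) {
  if (is.null(mod)) return(rep(1, length(t0)))
  lambda0_at(mod, pmax(t0, 1)) / mod$lambda_min
}

#' Default neonatal Hill modifier for naive CD8 T cells
#'
#' Registered defaults emulating the reported decline of the CD8 baseline net
#' loss rate: constant until about 3 weeks of age, then falling to an adult
#' plateau roughly 50% lower by 9 weeks.
#'
#' @param lambda_min adult plateau (day^-1).
#' @return A `lambda0_hill` object.
#' @export
default_lambda0_hill <- function(lambda_min = 0.03) {
  lambda0_hill(lambda_min = lambda_min, lambda_max = 2.2 * lambda_min,
               t_half = 36, h = 5)
}

#' @export
print.lambda0_hill <- function(x, ...) {
  cat("Hill curve lambda0(t): lambda_min =", signif(x$lambda_min, 4),
      "lambda_max =", signif(x$lambda_max, 4),
      "t_half =", signif(x$t_half, 4), "d, h =", signif(x$h, 3), "\n")
  invisible(x)
}
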