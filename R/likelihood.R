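#' Model observables at the design points of a chimera dataset
#'
#' Dispatches to the characteristics fast path for the age-structured family
#' (and the neutral model, which is its rate-constant special case) or to the
#' compartmental ODE solver (grouped by BMT age) for density-dependent and
#' RTE/MN variants.
#'
#' @param p a [kinetic_params()] object.
#' @param influx an [influx_descriptor()].
#' @param data chimera observations (`chimera` schema).
#' @param chimerism DP1 donor chimerism.
#' @param a_step cell-age quadrature step (age-structured path), days.
#' @return data frame with model `total_count`, `fd`, `ki67_host`,
#'   `ki67_donor` aligned with rows of `data`.
#' @export
model_observables <- function(p, influx, data, chimerism = 0.85, a_step = 1) {
  if (p$variant %in% c("neutral", "age_loss", "age_division") ||
      (p$variant %in% c("dd_loss", "dd_division") && p$gamma == 0)) {
    pp <- p
    if (pp$variant %in% c("dd_loss", "dd_division"))
      pp$variant <- "neutral"
    return(chimera_observables(pp, influx, data$host_age, data$age_bmt,
                               chimerism = chimerism, a_step = a_step))
  }
  out <- data.frame(total_count = rep(NA_real_, nrow(data)), fd = NA_real_,
                    ki67_host = NA_real_, ki67_donor = NA_real_)
  for (tb in unique(data$age_bmt)) {
    sel <- which(data$age_bmt == tb)
    tt <- sort(unique(data$host_age[sel]))
    traj <- solve_compartmental(p, influx, t_span = c(1, max(tt)),
                                t_out = tt, t_bmt = tb)
    ob <- compartmental_observables(traj, reference_chimerism = chimerism)
    m <- match(data$host_age[sel], ob$t_days)
    out[sel, ] <- ob[m, c("total_count", "fd", "ki67_host", "ki67_donor")]
  }
  out
}

## Precomputed evaluation context for the characteristics fast path: for
## each mouse the age-grid indices, trapezoid weights for the whole pool and
## for the donor (post-BMT entry) sub-integral, and the parameter-free
## influx shape values S(t0), kappa(t0). Model evaluation then needs no
## per-mouse exp() calls unless a neonatal modifier is present.
.chimera_ctx <- function(data, influx, chimerism = 0.85, a_step = 1,
                         bmt_delay = 0) {
  n <- nrow(data)
  a_grid <- seq(0, max(data$host_age) - 1, by = a_step)
  idx <- wt <- wd <- S <- k0 <- t0_all <- g <- vector("list", n)
  for (i in seq_len(n)) {
    front <- data$host_age[i] - 1
    m <- length(which(a_grid <= front))
    a <- a_grid[seq_len(m)]
    w <- rep(a_step, m); w[1] <- a_step / 2
    w[m] <- a_step / 2 + (front - a[m])
    a_star <- min(data$host_age[i] - data$age_bmt[i] - bmt_delay, front)
    md <- length(which(a <= a_star))
    v <- numeric(m)
    if (md >= 2) {
      v[seq_len(md)] <- a_step; v[1] <- a_step / 2
      v[md] <- a_step / 2 + (a_star - a[md])
    } else if (md == 1) v[1] <- a_star - a[1]
    t0 <- data$host_age[i] - a
    idx[[i]] <- seq_len(m); wt[[i]] <- w; wd[[i]] <- v
    S[[i]] <- sp_count_curve(t0, influx)
    k0[[i]] <- sp_ki67_curve(t0, influx)
    t0_all[[i]] <- t0
    g[[i]] <- rep(i, m)
  }
  eps <- 1e-9
  qcl <- function(x) stats::qlogis(pmin(pmax(x, eps), 1 - eps))
  obs <- list(y = c(log(data$total_count), qcl(data$fd),
                    qcl(data$ki67_host), qcl(data$ki67_donor)),
              stream = rep(c("count", "fd", "ki67_host", "ki67_donor"),
                           each = n),
              row = rep(seq_len(n), 4L))
  keep <- !is.na(obs$y)
  g <- unlist(g)
  list(a_grid = a_grid, idx = unlist(idx), wt = unlist(wt), wd = unlist(wd),
       S = unlist(S), k0 = unlist(k0), t0 = unlist(t0_all), g = g,
       ends = cumsum(tabulate(g, n)),
       n = n, chimerism = chimerism, a_step = a_step, obs = obs, keep = keep)
}

## likelihood fast path: model streams and pointwise densities without
## data-frame overhead; must agree with chimera_log_likelihood exactly
.fast_loglik <- function(p, sigmas, ctx) {
  kern <- .age_kernel(p, ctx$a_grid)
  if (is.null(p$neonatal_modifier)) {
    E <- exp(kern$P - kern$D)
    u <- p$psi * ctx$S * E[ctx$idx]
  } else {
    cs <- .modifier_scale(p$neonatal_modifier, ctx$t0)
    u <- p$psi * ctx$S * exp(kern$P[ctx$idx] - cs * kern$D[ctx$idx])
  }
  upos <- u * (kern$khom[ctx$idx] * ctx$k0 + kern$kpart[ctx$idx])
  agg <- function(x) diff(c(0, cumsum(x)[ctx$ends]))   # per-mouse block sums
  tot <- agg(ctx$wt * u)
  kp_tot <- agg(ctx$wt * upos)
  n_post <- agg(ctx$wd * u)
  kp_post <- agg(ctx$wd * upos)
  chi <- ctx$chimerism
  host_n <- (1 - chi) * n_post + (tot - n_post)
  fd <- n_post / tot
  kh <- ((1 - chi) * kp_post + (kp_tot - kp_post)) / host_n
  kd <- kp_post / n_post
  eps <- 1e-9
  ql <- function(x) { x <- pmin(pmax(x, eps), 1 - eps); log(x / (1 - x)) }
  mu <- c(log(pmax(tot, 1e-300)), ql(fd), ql(kh), ql(kd))
  sd <- rep(c(sigmas[["sigma_count"]], sigmas[["sigma_fd"]],
              sigmas[["sigma_ki67"]], sigmas[["sigma_ki67"]]), each = ctx$n)
  z <- (ctx$obs$y - mu) / sd
  v <- -log(sd) - 0.918938533204673 - 0.5 * z * z
  v[!is.finite(mu)] <- -Inf
  structure(v[ctx$keep], stream = ctx$obs$stream[ctx$keep],
            row = ctx$obs$row[ctx$keep])
}

.fast_observables <- function(p, ctx) {
  kern <- .age_kernel(p, ctx$a_grid)
  if (is.null(p$neonatal_modifier)) {
    E <- exp(kern$P - kern$D)
    u <- p$psi * ctx$S * E[ctx$idx]
  } else {
    cs <- .modifier_scale(p$neonatal_modifier, ctx$t0)
    u <- p$psi * ctx$S * exp(kern$P[ctx$idx] - cs * kern$D[ctx$idx])
  }
  upos <- u * (kern$khom[ctx$idx] * ctx$k0 + kern$kpart[ctx$idx])
  tot <- as.numeric(rowsum(ctx$wt * u, ctx$g))
  kp_tot <- as.numeric(rowsum(ctx$wt * upos, ctx$g))
  n_post <- as.numeric(rowsum(ctx$wd * u, ctx$g))
  kp_post <- as.numeric(rowsum(ctx$wd * upos, ctx$g))
  chi <- ctx$chimerism
  host_n <- (1 - chi) * n_post + (tot - n_post)
  data.frame(total_count = tot,
             fd = n_post / tot,
             ki67_host = ((1 - chi) * kp_post + (kp_tot - kp_post)) / host_n,
             ki67_donor = ifelse(n_post > 0, kp_post / n_post, NA_real_))
}

#' Pointwise log likelihood of a chimera dataset
#'
#' The observation model treats each data stream separately: total counts are
#' lognormal around the model count (scale `sigma_count` on the log scale);
#' the normalised donor fraction and the host/donor Ki67+ fractions are
#' normal on the logit scale (scales `sigma_fd`, `sigma_ki67`). Each stream
#' value is one pointwise unit, so a mouse contributes up to four units;
#' missing streams are skipped.
#'
#' @inheritParams model_observables
#' @param sigmas named vector with `sigma_count`, `sigma_fd`, `sigma_ki67`.
#' @param ctx optional precomputed evaluation context (internal fast path;
#'   built automatically when omitted).
#' @return numeric vector of pointwise log densities, one per available
#'   stream value, with attributes `stream` and `row` mapping back to `data`.
#'   A model count <= 0 at an observation yields a `-Inf` contribution.
#' @export
chimera_log_likelihood <- function(p, sigmas, data, influx,
                                   chimerism = 0.85, a_step = 1,
                                   ctx = NULL) {
  fastable <- p$variant %in% c("neutral", "age_loss", "age_division")
  if (fastable) {
    if (is.null(ctx)) ctx <- .chimera_ctx(data, influx, chimerism, a_step)
    return(.fast_loglik(p, sigmas, ctx))
  }
  m <- model_observables(p, influx, data, chimerism, a_step)
  .stream_loglik(m, sigmas, data)
}

.stream_loglik <- function(m, sigmas, data) {
  eps <- 1e-9
  qcl <- function(x) stats::qlogis(pmin(pmax(x, eps), 1 - eps))
  ll <- c(
    count = list(ifelse(m$total_count > 0,
                        stats::dnorm(log(data$total_count),
                                     log(pmax(m$total_count, 1e-300)),
                                     sigmas[["sigma_count"]], log = TRUE),
                        -Inf)),
    fd = list(stats::dnorm(qcl(data$fd), qcl(m$fd),
                           sigmas[["sigma_fd"]], log = TRUE)),
    ki67_host = list(stats::dnorm(qcl(data$ki67_host), qcl(m$ki67_host),
                                  sigmas[["sigma_ki67"]], log = TRUE)),
    ki67_donor = list(stats::dnorm(qcl(data$ki67_donor), qcl(m$ki67_donor),
                                   sigmas[["sigma_ki67"]], log = TRUE)))
  stream <- rep(names(ll), each = nrow(data))
  row <- rep(seq_len(nrow(data)), 4L)
  v <- unlist(ll, use.names = FALSE)
  keep <- !is.na(v)
  ## NA arises only from missing observations; -Inf (model failure) is kept
  structure(v[keep], stream = stream[keep], row = row[keep])
}
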