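# spr_binding: FastStep surface plasmon resonance simulation and fitting.
#
# Binding follows 1:1 Langmuir kinetics,
#   dR/dt = kon * C(t) * (Rmax - R) - koff * R,   koff = kon * Kd,
# integrated exactly over each constant-concentration interval of the
# stepwise injection program (the solution is a single exponential per
# interval). Analyte is supplied by continuous flow, so its concentration
# is not depleted by binding.

#' Stepwise injection program
#'
#' @param conc analyte concentration per step (M).
#' @param duration step length in seconds (scalar or per step).
#' @param start start time of the first step (s).
#' @param dissoc_len length of the final dissociation phase (s).
#' @return an `injection_program`: data.frame (start, end, conc) plus the
#'   dissociation window as attributes.
#' @export
injection_program <- function(conc, duration = 25, start = 0, dissoc_len = 150) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  duration <- rep_len(duration, length(conc))
  if (any(duration <= 0)) stop("step durations must be positive")
  ends <- start + cumsum(duration)
  starts <- c(start, ends[-length(ends)])
  prog <- data.frame(start = starts, end = ends, conc = conc)
  attr(prog, "dissoc_start") <- ends[length(ends)]
  attr(prog, "dissoc_len") <- dissoc_len
  class(prog) <- c("injection_program", "data.frame")
  prog
}

#' Six-step doubling FastStep program
#'
#' The standard single-run program: serial doubling steps (default
#' 0.94, 1.875, 3.75, 7.5, 15, 30 in the given unit) of 25 s each,
#' followed by one dissociation phase.
#'
#' @param c0 first-step concentration (M), default 0.94e-6.
#' @param n number of doubling steps (default 6).
#' @param duration step length (s), default 25.
#' @param dissoc_len dissociation window (s), default 150.
#' @export
faststep_program <- function(c0 = 0.94e-6, n = 6, duration = 25, dissoc_len = 150) {
  injection_program(c0 * 2^(0:(n - 1)), duration = duration,
                    dissoc_len = dissoc_len)
}

#' Equilibrium response of 1:1 binding
#' @param kd dissociation constant (M)
#' @param rmax saturation response (RU)
#' @param conc analyte concentration(s) (M)
#' @export
equilibrium_response <- function(kd, rmax, conc) rmax * conc / (kd + conc)

#' Simulate a FastStep sensorgram
#'
#' Piecewise integration of the Langmuir kinetics over the injection
#' program (exact per-interval exponential solution), with buffer flow
#' (C = 0) after the last step, and optional Gaussian noise.
#'
#' The per-step responses are reported two ways: `step_end_RU`, the
#' (noisy) response at the end of each step, and `eq_RU`, the true
#' equilibrium response the step would reach if held indefinitely. Short
#' steps at slow kinetics do not reach equilibrium; exposing both makes
#' that bias measurable instead of hidden.
#'
#' @param kd dissociation constant (M), > 0.
#' @param kon association rate (1/(M s)); default 1e5, typical of
#'   small-molecule/protein binding when no measured rate is available.
#' @param rmax saturation response (RU), > 0.
#' @param program an `injection_program`.
#' @param noise_sd Gaussian noise sd in RU (default 0).
#' @param seed optional RNG seed for the noise.
#' @param dt output time resolution (s).
#' @return a `sensorgram`: list with `trace` (data.frame time, RU),
#'   `program`, `step_end_RU`, `eq_RU`, `noise_sd`.
#' @export
simulate_faststep <- function(kd, kon = 1e5, rmax, program, noise_sd = 0,
                              seed = NULL, dt = 0.5) {
  if (kd <= 0 || kon <= 0 || rmax <= 0) stop("kd, kon and rmax must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  koff <- kon * kd
  t_end <- attr(program, "dissoc_start") + attr(program, "dissoc_len")
  times <- seq(program$start[1], t_end, by = dt)
  intervals <- rbind(program[, c("start", "end", "conc")],
                     data.frame(start = attr(program, "dissoc_start"),
                                end = t_end, conc = 0))
  R <- numeric(length(times))
  R0 <- 0
  step_end <- numeric(nrow(program))
  for (k in seq_len(nrow(intervals))) {
    iv <- intervals[k, ]
    kobs <- kon * iv$conc + koff
    Rinf <- kon * iv$conc * rmax / kobs
    sel <- times >= iv$start & times <= iv$end
    R[sel] <- Rinf + (R0 - Rinf) * exp(-kobs * (times[sel] - iv$start))
    R0 <- Rinf + (R0 - Rinf) * exp(-kobs * (iv$end - iv$start))
    if (k <= nrow(program)) step_end[k] <- R0
  }
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
  ru <- R + noise
  step_noise <- if (noise_sd > 0) stats::rnorm(nrow(program), 0, noise_sd) else 0
  structure(list(trace = data.frame(time = times, RU = ru),
                 program = program,
                 step_end_RU = step_end + step_noise,
                 eq_RU = equilibrium_response(kd, rmax, program$conc) +
                   if (noise_sd > 0) stats::rnorm(nrow(program), 0, noise_sd) else 0,
                 noise_sd = noise_sd),
            class = "sensorgram")
}

#' Scatchard fit of per-concentration equilibrium responses
#'
#' Least-squares line of bound/free (`RU/C`) against bound (`RU`):
#' slope = -1/Kd, x-intercept = Rmax. Non-saturating data (slope >= 0)
#' yields a fit-failure result rather than an error.
#'
#' @param ru equilibrium response per concentration (RU).
#' @param conc analyte concentrations (M), same length.
#' @return a `binding_fit`: list with `kd` (M), `rmax` (RU), `ok`, `r2`,
#'   `resid_sd`, `n_used`. Non-positive responses are dropped before
#'   fitting (the Scatchard transform requires RU > 0).
#' @export
scatchard_fit <- function(ru, conc) {
  stopifnot(length(ru) == length(conc))
  keep <- ru > 0 & conc > 0
  if (sum(keep) < 3)
    return(structure(list(kd = NA_real_, rmax = NA_real_, ok = FALSE,
                          r2 = NA_real_, resid_sd = NA_real_,
                          n_used = sum(keep)), class = "binding_fit"))
  x <- ru[keep]
  y <- ru[keep] / conc[keep]
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless input fits perfectly
  slope <- stats::coef(fit)[["x"]]
  if (!is.finite(slope) || slope >= 0)
    return(structure(list(kd = NA_real_, rmax = NA_real_, ok = FALSE,
                          r2 = sm$r.squared,
                          resid_sd = sm$sigma, n_used = sum(keep)),
                     class = "binding_fit"))
  structure(list(kd = -1 / slope,
                 rmax = -stats::coef(fit)[["(Intercept)"]] / slope,
                 ok = TRUE, r2 = sm$r.squared,
                 resid_sd = sm$sigma, n_used = sum(keep)),
            class = "binding_fit")
}

#' Direct nonlinear 1:1 saturation fit
#'
#' Fits `RU = Rmax * C / (Kd + C)` by Levenberg-Marquardt least squares;
#' agrees with [scatchard_fit()] on noiseless data.
#'
#' @inheritParams scatchard_fit
#' @export
langmuir_fit <- function(ru, conc) {
  stopifnot(length(ru) == length(conc))
  start <- list(rmax = max(ru) * 1.5, kd = stats::median(conc))
  fit <- tryCatch(
    minpack.lm::nlsLM(ru ~ rmax * conc / (kd + conc), start = start,
                      lower = c(rmax = 0, kd = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(kd = NA_real_, rmax = NA_real_, ok = FALSE,
                          r2 = NA_real_, resid_sd = NA_real_,
                          n_used = length(ru)), class = "binding_fit"))
  cf <- stats::coef(fit)
  ss <- sum(stats::resid(fit)^2)
  structure(list(kd = cf[["kd"]], rmax = cf[["rmax"]], ok = TRUE,
                 r2 = 1 - ss / sum((ru - mean(ru))^2),
                 resid_sd = sqrt(ss / max(1, length(ru) - 2)),
                 n_used = length(ru)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("binding_fit: Kd = %.4g M, Rmax = %.4g RU (r2 = %.4f)\n",
                x$kd, x$rmax, x$r2))
  else cat("binding_fit: fit failure (no saturation)\n")
  invisible(x)
}

#' Simulate a competition SPR series
#'
#' Equilibrium competitive binding of the activator fragment (the species
#' whose mass dominates the signal) against a small-molecule inhibitor:
#' with the analytes supplied by flow at fixed concentrations, fractional
#' occupancy of the activator site is
#' `(T/Kd) / (1 + T/Kd + I/Ki)`. The reported RU reflects activator binding
#' only (rapid inhibitor binding/dissociation is subtracted), read at a
#' fixed time after the end of association (default 10 s).
#'
#' @param kd_tpx2 activator dissociation constant (M).
#' @param tpx2_conc activator concentration co-injected with the inhibitor
#'   (M; default 1e-6).
#' @param ki_inhibitor inhibitor competition constant (M).
#' @param inhibitor_concs inhibitor concentrations (M).
#' @param rmax_tpx2 saturation response of the activator (RU).
#' @param noise_sd Gaussian noise sd (RU).
#' @param seed optional RNG seed.
#' @param read_time_s seconds after association end at which RU is read
#'   (metadata; the equilibrium model is time-free).
#' @return data.frame (conc, RU) with attributes `ru0` (no-inhibitor
#'   signal) and `read_time_s`.
#' @export
simulate_competition <- function(kd_tpx2, tpx2_conc = 1e-6, ki_inhibitor,
                                 inhibitor_concs, rmax_tpx2, noise_sd = 0,
                                 seed = NULL, read_time_s = 10) {
  if (kd_tpx2 <= 0 || tpx2_conc <= 0 || ki_inhibitor <= 0 || rmax_tpx2 <= 0)
    stop("all binding parameters must be > 0")
  if (any(inhibitor_concs < 0)) stop("inhibitor concentrations must be >= 0")
  tt <- tpx2_conc / kd_tpx2
  occ <- tt / (1 + tt + inhibitor_concs / ki_inhibitor)
  if (!is.null(seed)) set.seed(seed)
  ru <- rmax_tpx2 * occ +
    if (noise_sd > 0) stats::rnorm(length(occ), 0, noise_sd) else 0
  out <- data.frame(conc = inhibitor_concs, RU = ru)
  attr(out, "ru0") <- rmax_tpx2 * tt / (1 + tt)
  attr(out, "read_time_s") <- read_time_s
  out
}

#' Competitive-binding IC50 relation
#'
#' For purely competitive binding at fixed free concentrations, the
#' inhibitor concentration halving the activator signal satisfies
#' `IC50 = Ki * (1 + T / Kd)` (the competitive-binding form of the
#' Cheng-Prusoff relation). `ki_from_ic50()` is its inverse.
#'
#' @param ki,ic50 inhibitor constants (M).
#' @param kd activator dissociation constant (M).
#' @param competitor_conc activator concentration (M).
#' @export
cheng_prusoff_ic50 <- function(ki, kd, competitor_conc) {
  ki * (1 + competitor_conc / kd)
}

#' @rdname cheng_prusoff_ic50
#' @export
ki_from_ic50 <- function(ic50, kd, competitor_conc) {
  ic50 / (1 + competitor_conc / kd)
}

#' Four-parameter logistic IC50 fit of a competition series
#'
#' Fits `RU = bottom + (top - bottom) / (1 + (C / IC50)^h)` against
#' inhibitor concentration. A series showing no credible decrease across
#' the range returns a "non-competing" verdict instead of an estimate.
#'
#' @param inhibitor_concs inhibitor concentrations (M), >= 4 values
#'   spanning the transition.
#' @param ru activator RU read per concentration.
#' @return a `competition_fit`: list with `ic50` (M), `top`, `bottom`,
#'   `hill`, `se_ic50`, `competing` (logical verdict), `ok`.
#' @export
ic50_fit <- function(inhibitor_concs, ru) {
  stopifnot(length(inhibitor_concs) == length(ru))
  if (length(ru) < 4) stop("need at least 4 concentrations spanning the transition")
  keep <- inhibitor_concs > 0
  cc <- inhibitor_concs[keep]
  yy <- ru[keep]
  # trend screen: a competing series must show a significant decrease
  trend <- stats::lm(yy ~ log(cc))
  slope <- stats::coef(trend)[[2]]
  pval <- suppressWarnings(summary(trend))$coefficients[2, 4]
  noncompeting <- function(reason) {
    structure(list(ic50 = NA_real_, top = NA_real_, bottom = NA_real_,
                   hill = NA_real_, se_ic50 = NA_real_,
                   competing = FALSE, ok = TRUE, reason = reason),
              class = "competition_fit")
  }
  if (!is.finite(slope) || slope >= 0 || pval > 0.01)
    return(noncompeting("no significant decrease with concentration"))
  # fit on the log10 concentration scale (the usual dose-response form);
  # this also conditions the Jacobian, which is singular in raw molar units
  lc <- log10(cc)
  start <- list(top = max(yy), bottom = 0, lic50 = mean(range(lc)), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
                      start = start,
                      lower = c(top = 0, bottom = 0, lic50 = min(lc) - 2, hill = 0.2),
                      upper = c(top = Inf, bottom = Inf, lic50 = max(lc) + 2, hill = 5),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(noncompeting("logistic fit failed"))
  cf <- stats::coef(fit)
  ic50 <- 10^cf[["lic50"]]
  if (cf[["bottom"]] > cf[["top"]]) return(noncompeting("inverted plateaus"))
  if ((cf[["top"]] - cf[["bottom"]]) < 0.1 * max(cf[["top"]], 1e-12))
    return(noncompeting("fitted decrease below 10% of signal"))
  se_l <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lic50"]], error = function(e) NA_real_)
  structure(list(ic50 = ic50, top = cf[["top"]], bottom = cf[["bottom"]],
                 hill = cf[["hill"]], se_ic50 = log(10) * ic50 * se_l,
                 competing = TRUE, ok = TRUE, reason = ""),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  if (x$competing)
    cat(sprintf("competition_fit: IC50 = %.4g M (se %.2g), top %.3g, bottom %.3g RU\n",
                x$ic50, x$se_ic50, x$top, x$bottom))
  else cat("competition_fit: non-competing (", x$reason, ")\n", sep = "")
  invisible(x)
}

# ---- sensorgram CSV --------------------------------------------------------

#' Write / read a sensorgram as CSV with its step schedule in the header
#' @param s a `sensorgram`
#' @param file path
#' @export
write_sensorgram <- function(s, file) {
  hdr <- c("# ppiscreen sensorgram v1",
           sprintf("# step,%g,%g,%g", s$program$start, s$program$end,
                   s$program$conc),
           sprintf("# dissoc_start,%g", attr(s$program, "dissoc_start")),
           sprintf("# noise_sd,%g", s$noise_sd))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(s$trace, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sensorgram
#' @export
read_sensorgram <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  steps <- do.call(rbind, lapply(strsplit(grep("^# step,", hdr, value = TRUE), ","),
                                 function(p) as.numeric(p[2:4])))
  prog <- injection_program(conc = steps[, 3],
                            duration = steps[, 2] - steps[, 1],
                            start = steps[1, 1])
  noise_sd <- as.numeric(sub("^# noise_sd,", "",
                             grep("^# noise_sd,", hdr, value = TRUE)))
  trace <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  structure(list(trace = trace, program = prog,
                 step_end_RU = NULL, eq_RU = NULL, noise_sd = noise_sd),
            class = "sensorgram")
}
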