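#' Construct a Franz-cell permeation series
#'
#' Receptor-compartment drug concentrations at successive sampling times,
#' together with the cell geometry: receptor volume `V`, withdrawn-aliquot
#' volume `V0` (replaced by blank medium, sink condition) and effective
#' diffusion area `A`. Defaults follow the vertical Franz cell used for
#' mouse-skin work: V = 10 ml, V0 = 1 ml, A = 0.785 cm^2, sampling at 0.5,
#' 1, 2, 3, 4 and 5 h.
#'
#' @param times Sampling times (h), positive ascending.
#' @param concentrations Concentrations (ug/ml) at each sampling.
#' @param V Receptor volume (ml).
#' @param V0 Withdrawn volume (ml).
#' @param A Effective diffusion area (cm^2).
#' @param label Series label.
#' @return An object of class `permeation_series`.
#' @export
permeation_series <- function(times = c(0.5, 1, 2, 3, 4, 5), concentrations,
                              V = 10, V0 = 1, A = 0.785, label = "") {
  stopifnot(length(times) == length(concentrations))
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be positive and strictly ascending")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (!(V >= V0 && V0 > 0)) stop("need V >= V0 > 0")
  if (A <= 0) stop("diffusion area must be positive")
  structure(list(times = times, concentrations = concentrations,
                 V = V, V0 = V0, A = A, label = as.character(label)),
            class = "permeation_series")
}

#' Cumulative permeated amount per unit area
#'
#' Aliquot-corrected cumulative amount at sampling n:
#' \deqn{Q_n = [C_n V + V_0 \sum_{i=1}^{n-1} C_i] / A}
#' The sum term restores the drug removed with the first n-1 withdrawn
#' aliquots (each replaced by blank medium).
#'
#' @param s A [permeation_series()].
#' @return Numeric vector of Q_n (ug/cm^2), one per sampling time.
#' @examples
#' s <- permeation_series(times = 1, concentrations = 10)
#' cumulative_amount(s)   # 10 * 10 / 0.785 = 127.39
#' @export
cumulative_amount <- function(s) {
  stopifnot(inherits(s, "permeation_series"))
  C <- s$concentrations
  prior <- c(0, cumsum(C)[-length(C)])
  (C * s$V + s$V0 * prior) / s$A
}

#' Steady-state flux and lag time from a cumulative-permeation profile
#'
#' Least-squares line Q = Jss t + b over the linear portion of the
#' profile; the slope is the steady-state flux Jss (ug cm^-2 h^-1) and the
#' t-intercept -b/Jss is the lag time (h). The linear portion defaults to
#' all points with t >= 1 h; a negative computed lag time is clamped to 0
#' and flagged.
#'
#' @param times Sampling times (h).
#' @param Qn Cumulative amounts (ug/cm^2), as from [cumulative_amount()].
#' @param window Logical or integer index of points to fit (default
#'   `times >= 1`).
#' @return List with `Jss`, `Tlag`, `intercept`, `fit_window` (indices),
#'   `clamped` (was a negative lag clamped).
#' @export
flux_and_lag <- function(times, Qn, window = NULL) {
  stopifnot(length(times) == length(Qn))
  idx <- if (is.null(window)) which(times >= 1) else
    if (is.logical(window)) which(window) else as.integer(window)
  if (length(idx) < 2) stop("need at least 2 points in the fit window")
  if (length(unique(times[idx])) < 2) stop("singular fit: all times equal")
  fit <- lm(Qn[idx] ~ times[idx])
  b <- unname(coef(fit)[1])
  Jss <- unname(coef(fit)[2])
  Tlag <- if (Jss != 0) -b / Jss else NA_real_
  clamped <- isTRUE(Tlag < -1e-9)
  if (clamped) {
    warning("negative lag time clamped to 0")
    Tlag <- 0
  } else if (isTRUE(Tlag < 0)) {
    Tlag <- 0   # round-off only
  }
  list(Jss = Jss, Tlag = Tlag, intercept = b, fit_window = idx,
       clamped = clamped)
}

#' Enhancement ratio
#'
#' Ratio of the cumulative amount at the final sampling (5 h) in the test
#' formulation to that in the reference solution.
#'
#' @param Q5_test Cumulative amount in the test group (ug/cm^2).
#' @param Q5_reference Cumulative amount in the reference group.
#' @return Dimensionless ER.
#' @examples
#' enhancement_ratio(6088, 4748)   # 1.28
#' @export
enhancement_ratio <- function(Q5_test, Q5_reference) {
  if (Q5_reference <= 0) stop("reference cumulative amount must be positive")
  Q5_test / Q5_reference
}

#' Read permeation series from delimited text
#'
#' Expects columns `time_h` and `conc_ug_ml` (and optionally `label`); the
#' cell geometry is supplied as arguments.
#'
#' @param path File path.
#' @param V,V0,A Cell geometry, see [permeation_series()].
#' @param sep Field separator (default `","`).
#' @return A [permeation_series()] (or a named list of them when the file
#'   has a `label` column with several values).
#' @export
read_permeation_series <- function(path, V = 10, V0 = 1, A = 0.785,
                                   sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("time_h", "conc_ug_ml") %in% names(df)))
    stop("permeation file must have columns: time_h, conc_ug_ml")
  build <- function(d, label) {
    o <- order(d$time_h)
    permeation_series(d$time_h[o], d$conc_ug_ml[o], V = V, V0 = V0, A = A,
                      label = label)
  }
  if ("label" %in% names(df) && length(unique(df$label)) > 1) {
    out <- lapply(split(df, df$label), function(d) build(d, d$label[1]))
    out
  } else {
    build(df, if ("label" %in% names(df)) df$label[1] else "")
  }
}
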