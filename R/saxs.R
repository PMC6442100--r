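#' Allowed reflection sequences for the supported mesophase symmetries
#'
#' Returns, per candidate symmetry, the sequence of N = h^2 + k^2 + l^2
#' values of its allowed reflections: peak positions follow
#' q = 2 pi sqrt(N) / a (for lamellar stacks N = n^2, so q = 2 pi n / d;
#' for 2-D hexagonal N = h^2 + hk + k^2).
#'
#' @return Named list of numeric vectors.
#' @export
saxs_groups <- function() {
  list(
    Pn3m = c(2, 3, 4, 6, 8, 9, 10, 11, 12, 14, 16, 17),
    Im3m = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24),
    Ia3d = c(6, 8, 14, 16, 20, 22, 24, 26, 30, 32, 38, 40),
    hexagonal = c(1, 3, 4, 7, 9, 12, 13, 16, 19, 21, 25, 27),
    lamellar = (1:12)^2
  )
}

#' Construct a SAXS peak list
#'
#' @param q Scattering-vector magnitudes (1/Angstrom), strictly positive
#'   and strictly increasing.
#' @param sample Sample label.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(q, sample = "") {
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be positive and finite")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  structure(list(q = q, sample = as.character(sample)), class = "peak_list")
}

# Zero-intercept least-squares fit of q = (2 pi / a) sqrt(N).
.fit_lattice <- function(q, N) {
  s <- sum(q * sqrt(N)) / sum(N)
  a <- 2 * pi / s
  rel_res <- (q - s * sqrt(N)) / q
  list(a = a, slope = s, residual = sqrt(mean(rel_res^2)))
}

#' Index SAXS peaks against candidate mesophase symmetries
#'
#' For every candidate symmetry the observed peaks are assigned, in order,
#' to a contiguous run of the symmetry's allowed reflection sequence; the
#' run may start up to `max_offset` positions in (so an observed pair can
#' match e.g. the sqrt(6):sqrt(8) reflections with the three lower-angle
#' reflections unobserved). The lattice constant is fitted by zero-intercept
#' least squares on q = 2 pi sqrt(N) / a and the assignment with the
#' smallest RMS relative q-residual wins. Exact ties (which arise for short
#' peak lists, e.g. sqrt(8)/sqrt(6) = sqrt(4)/sqrt(3)) are resolved in
#' favor of the deepest consistent assignment (largest offset), then by a
#' fixed symmetry priority (Pn3m, Im3m, Ia3d, hexagonal, lamellar) — the
#' convention under which GMO cubic-phase patterns reported as 6:8 index as
#' Pn3m.
#'
#' @param peaks A [peak_list()] (>= 2 peaks).
#' @param candidates Character vector of candidate symmetries (default all
#'   of [saxs_groups()]).
#' @param max_offset Maximum number of skipped leading reflections
#'   (default 3).
#' @param residual_cap Maximum acceptable RMS relative residual (default
#'   0.02); above it the peak list is reported unassignable.
#' @param ratio_only If TRUE, skip symmetry assignment and return only the
#'   observed q ratios (for patterns whose printed spacing ratios do not
#'   correspond to a physical indexing).
#' @return An object of class `phase_assignment`: `space_group`,
#'   `lattice_constant` (Angstrom; the repeat distance d for lamellar),
#'   `residual`, `miller_N` (assigned N values), `spacing_ratio`, `offset`.
#' @examples
#' pk <- peak_list(2 * pi * sqrt(c(6, 8)) / 134)
#' index_peaks(pk)   # Pn3m, a = 134
#' @export
index_peaks <- function(peaks, candidates = names(saxs_groups()),
                        max_offset = 3, residual_cap = 0.02,
                        ratio_only = FALSE) {
  stopifnot(inherits(peaks, "peak_list"))
  q <- peaks$q
  if (length(q) < 2) stop("need at least 2 peaks for assignment")
  if (ratio_only) {
    ratio <- q / q[1]
    return(structure(list(space_group = "ratio_only",
                          lattice_constant = NA_real_, residual = NA_real_,
                          miller_N = NULL,
                          spacing_ratio = paste(round(ratio, 2), collapse = ":"),
                          offset = NA_integer_, sample = peaks$sample),
                     class = "phase_assignment"))
  }
  groups <- saxs_groups()
  unknown <- setdiff(candidates, names(groups))
  if (length(unknown)) stop("unsupported symmetry: ",
                            paste(unknown, collapse = ", "))
  priority <- intersect(names(groups), candidates)
  best <- NULL
  for (grp in priority) {
    seqN <- groups[[grp]]
    for (off in 0:max_offset) {
      if (off + length(q) > length(seqN)) break
      N <- seqN[(off + 1):(off + length(q))]
      fit <- .fit_lattice(q, N)
      cand <- list(group = grp, offset = off, N = N, fit = fit,
                   prio = match(grp, priority))
      if (is.null(best)) { best <- cand; next }
      d <- fit$residual - best$fit$residual
      better <- d < -1e-12 ||
        (abs(d) <= 1e-12 && (cand$offset > best$offset ||
           (cand$offset == best$offset && cand$prio < best$prio)))
      if (better) best <- cand
    }
  }
  if (is.null(best)) stop("no candidate symmetry can accommodate ",
                          length(q), " peaks")
  if (best$fit$residual > residual_cap)
    stop(sprintf("unassigned: best candidate %s has RMS relative residual %.3g > cap %.3g",
                 best$group, best$fit$residual, residual_cap))
  ratio_str <- if (best$group == "lamellar")
    paste(sqrt(best$N), collapse = ":")
  else
    paste0("sqrt", paste(best$N, collapse = ":sqrt"))
  structure(list(space_group = best$group,
                 lattice_constant = best$fit$a,
                 residual = best$fit$residual,
                 miller_N = best$N,
                 spacing_ratio = ratio_str,
                 offset = best$offset,
                 sample = peaks$sample),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  if (identical(x$space_group, "ratio_only")) {
    cat(sprintf("<phase_assignment> ratio-only report: q ratios %s\n",
                x$spacing_ratio))
  } else {
    cat(sprintf("<phase_assignment> %s, lattice constant %.2f A (RMS rel. residual %.2g, spacing %s)\n",
                x$space_group, x$lattice_constant, x$residual,
                x$spacing_ratio))
  }
  invisible(x)
}

#' Lattice constant from an assigned peak set
#'
#' Zero-intercept least squares of q against sqrt(N): the slope is
#' 2 pi / a. The standard error of the slope is propagated to a.
#'
#' @param q Peak positions (1/Angstrom).
#' @param N Assigned h^2+k^2+l^2 values (same length as q, >= 2).
#' @return List with `a` (Angstrom), `se` (standard error of a), `slope`.
#' @export
lattice_from_fit <- function(q, N) {
  stopifnot(length(q) == length(N), length(q) >= 2)
  if (any(q <= 0) || any(N <= 0)) stop("q and N must be positive")
  if (anyDuplicated(q) && length(unique(N)) > 1)
    stop("identical q values assigned to distinct reflections are non-physical")
  x <- sqrt(N)
  s <- sum(q * x) / sum(x^2)
  if (s <= 0) stop("non-positive slope")
  resid <- q - s * x
  dof <- length(q) - 1
  se_s <- if (dof > 0) sqrt(sum(resid^2) / dof / sum(x^2)) else 0
  a <- 2 * pi / s
  list(a = a, se = a * se_s / s, slope = s)
}

#' Read SAXS peak lists from delimited text
#'
#' Expects columns `sample` and `q`; one [peak_list()] is returned per
#' sample, peaks sorted ascending.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return Named list of [peak_list()] objects.
#' @export
read_peak_lists <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("sample", "q") %in% names(df)))
    stop("peak file must have columns: sample, q")
  out <- lapply(split(df$q, df$sample), function(q)
    peak_list(sort(q)))
  for (nm in names(out)) out[[nm]]$sample <- nm
  out
}
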