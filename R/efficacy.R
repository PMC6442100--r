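#' Xenograft tumor volume from caliper diameters
#'
#' V = 0.5 L W^2, with L the largest and W the smallest superficial
#' diameter (mm).
#'
#' @param L Largest superficial diameter (mm).
#' @param W Smallest superficial diameter (mm); must not exceed `L`.
#' @return Volume (mm^3). Vectorized.
#' @examples
#' tumor_volume(6, 5)   # 75
#' @export
tumor_volume <- function(L, W) {
  if (any(W <= 0) || any(L <= 0)) stop("diameters must be positive")
  if (any(W > L)) stop("W > L violates the measurement convention (L is the largest diameter)")
  0.5 * L * W^2
}

# round half away from zero at `digits` decimals (matching hand-reported
# percentages, where 10.985 -> 10.99)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tumor inhibitory rate
#'
#' (W_blank - W_test) / W_blank x 100%, on mean terminal tumor weights of
#' the control (blank) and treated groups. Reported rounded to 2 decimals
#' (half-up); the full-precision value is attached as attribute `"exact"`.
#'
#' @param W_blank Mean terminal tumor weight of the control group (g).
#' @param W_test Mean terminal tumor weight of the treated group (g).
#' @return Inhibition rate in percent. Vectorized over `W_test`.
#' @examples
#' inhibition_rate(1.73, 0.62)   # 64.16
#' @export
inhibition_rate <- function(W_blank, W_test) {
  if (any(W_blank <= 0)) stop("control group weight must be positive")
  exact <- (W_blank - W_test) / W_blank * 100
  structure(.round_half_up(exact, 2), exact = exact)
}

# Student-Newman-Keuls stepwise procedure on group means.
# Means are ranked; the studentized range statistic for a stretch of p
# ordered means is q = (max - min) / sqrt(MSE / n_h), compared to the
# 1 - alpha quantile of the studentized range with (p, df_error).
# Stretches inside a non-significant stretch are not tested (declared
# non-significant), per the stepwise logic.
.snk <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  means <- tapply(values, groups, mean)
  fit <- aov(values ~ groups)
  mse <- sum(fit$residuals^2) / fit$df.residual
  dfe <- fit$df.residual
  ord <- order(means)
  lev <- levels(groups)[ord]
  m <- means[ord]
  nh <- k / sum(1 / ns)           # harmonic mean group size
  res <- data.frame(group1 = character(0), group2 = character(0),
                    span = integer(0), q = numeric(0), p = numeric(0),
                    significant = logical(0), tested = logical(0))
  blocked <- matrix(FALSE, k, k)  # inside a non-significant stretch
  for (p_span in k:2) {
    for (i in 1:(k - p_span + 1)) {
      j <- i + p_span - 1
      if (blocked[i, j]) {
        res <- rbind(res, data.frame(group1 = lev[i], group2 = lev[j],
                                     span = p_span, q = NA, p = NA,
                                     significant = FALSE, tested = FALSE))
        next
      }
      qstat <- (m[j] - m[i]) / sqrt(mse / nh)
      pval <- 1 - ptukey(qstat, p_span, dfe)
      sig <- pval < alpha
      if (!sig) {
        for (a in i:j) for (b in a:j) blocked[a, b] <- TRUE
      }
      res <- rbind(res, data.frame(group1 = lev[i], group2 = lev[j],
                                   span = p_span, q = qstat, p = pval,
                                   significant = sig, tested = TRUE))
    }
  }
  res
}

#' Compare treatment groups
#'
#' Two groups are compared by a two-sample t-test; more than two by a
#' one-way ANOVA followed, when the omnibus test is significant at `alpha`,
#' by the Student-Newman-Keuls stepwise multiple-comparison procedure
#' (studentized-range quantiles computed numerically).
#'
#' @param groups Named list of numeric vectors, one per group (each
#'   n >= 2).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Assume equal variances in the two-group t-test
#'   (default TRUE, the classical test).
#' @return A list of class `group_comparison`: `method`, `statistic`,
#'   `p_value`, `significant`, and for > 2 groups `posthoc` (the SNK
#'   table, when run).
#' @export
compare_groups <- function(groups, alpha = 0.05, var_equal = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2)) stop("every group needs n >= 2")
  if (all(vapply(groups, sd, 1) == 0))
    stop("zero within-group variance everywhere; comparison undefined")
  if (is.null(names(groups)))
    names(groups) <- paste0("G", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, 1L)),
                levels = names(groups))
  if (length(groups) == 2) {
    tt <- t.test(groups[[1]], groups[[2]], var.equal = var_equal)
    out <- list(method = "t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, significant = tt$p.value < alpha,
                alpha = alpha, posthoc = NULL)
  } else {
    fit <- aov(values ~ fac)
    tab <- anova(fit)
    pval <- tab[["Pr(>F)"]][1]
    posthoc <- if (pval < alpha) .snk(values, fac, alpha) else NULL
    out <- list(method = "one-way ANOVA + SNK",
                statistic = tab[["F value"]][1], p_value = pval,
                significant = pval < alpha, alpha = alpha,
                posthoc = posthoc)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.3f, p = %.4g (%ssignificant at %g)\n",
              x$method, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  if (!is.null(x$posthoc)) {
    cat("  SNK pairwise results:\n")
    ph <- x$posthoc[x$posthoc$tested, ]
    for (i in seq_len(nrow(ph)))
      cat(sprintf("    %s vs %s (span %d): q = %.3f, p = %.4g%s\n",
                  ph$group1[i], ph$group2[i], ph$span[i], ph$q[i], ph$p[i],
                  if (ph$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Summarize efficacy per group
#'
#' Mean and SD of terminal tumor weights per group, with inhibition rates
#' relative to a designated control group.
#'
#' @param weights Named list of terminal tumor weights (g) per group.
#' @param control Name of the control group.
#' @return Data frame with `group`, `n`, `mean_weight`, `sd_weight`,
#'   `inhibition_rate` (percent; NA for the control).
#' @export
efficacy_summary <- function(weights, control) {
  stopifnot(is.list(weights), control %in% names(weights))
  mw <- vapply(weights, mean, 1)
  out <- data.frame(
    group = names(weights),
    n = vapply(weights, length, 1L),
    mean_weight = unname(mw),
    sd_weight = unname(vapply(weights, sd, 1)),
    inhibition_rate = NA_real_,
    stringsAsFactors = FALSE
  )
  test <- setdiff(names(weights), control)
  out$inhibition_rate[match(test, out$group)] <-
    as.numeric(inhibition_rate(mw[[control]], mw[test]))
  out
}

#' Read tumor measurement and weight tables
#'
#' Measurements: columns `mouse_id`, `group`, `day`, `L_mm`, `W_mm`.
#' Weights: columns `mouse_id`, `group`, `weight_g`.
#'
#' @param path File path.
#' @param sep Field separator (default `","`).
#' @return The data frame, validated.
#' @export
read_tumor_measurements <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "day", "L_mm", "W_mm")
  if (!all(need %in% names(df)))
    stop("measurement table must have columns: ", paste(need, collapse = ", "))
  if (any(df$W_mm > df$L_mm)) stop("W > L in measurement table")
  df
}

#' @rdname read_tumor_measurements
#' @export
read_tumor_weights <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "weight_g")
  if (!all(need %in% names(df)))
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  if (any(df$weight_g <= 0)) stop("weights must be positive")
  df
}
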