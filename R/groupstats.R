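#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided rank-sum comparison of two independent samples. `U` counts the
#' pairs where an `x` value exceeds a `y` value (ties count one half). In
#' exact mode the tie-free null distribution of U is evaluated by the exact
#' convolution recursion of the Mann-Whitney null, and the two-sided p
#' doubles the smaller tail (capped at 1). With ties (or `mode = "normal"`)
#' a midrank normal approximation with tie correction is used. Both `U` and
#' its complement `n1*n2 - U` are reported, since the labelling convention
#' differs between software.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"exact"` (default for moderate tie-free samples) or
#'   `"normal"`.
#' @return A list of class `"rank_sum_test"`: `u`, `u_complement`,
#'   `p_two_sided`, `n1`, `n2`, `mode` (the mode actually used), `tied`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y, mode = c("exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))                    # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tied <- anyDuplicated(c(x, y)) > 0

  if (mode == "exact" && !tied) {
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    used <- "exact"
  } else {
    if (mode == "exact" && tied)
      warning("ties present; falling back to the midrank normal approximation")
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)   # continuity corrected
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    used <- "normal"
  }
  structure(list(u = u, u_complement = n1 * n2 - u, p_two_sided = p,
                 n1 = n1, n2 = n2, mode = used, tied = tied),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum: U(%d,%d) = %g (complement %g), two-sided p = %.4g [%s]\n",
              x$n1, x$n2, x$u, x$u_complement, x$p_two_sided, x$mode))
  invisible(x)
}

#' Pearson and Spearman association between two variables
#'
#' Both coefficients are always computed: Pearson's r with its exact t-based
#' p-value, and Spearman's rho with the two-sided t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither constant.
#' @param kind Which coefficient leads the printed result; both are
#'   returned.
#' @return A list of class `"association_result"`: `pearson_r`,
#'   `p_pearson`, `spearman_rho`, `p_spearman`, `n`, `kind`.
#' @export
association <- function(x, y, kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input")
  pe <- stats::cor.test(x, y, method = "pearson")
  rho <- stats::cor(x, y, method = "spearman")
  p_s <- if (abs(rho) >= 1) 0 else {
    t_s <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t_s), n - 2)
  }
  structure(list(pearson_r = unname(pe$estimate), p_pearson = pe$p.value,
                 spearman_rho = rho, p_spearman = p_s, n = n, kind = kind),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Pearson r(%d) = %.3f, p = %.4g; Spearman rho = %.3f, p = %.4g\n",
              x$n - 2, x$pearson_r, x$p_pearson, x$spearman_rho, x$p_spearman))
  invisible(x)
}

#' Per-listener congruency effect on clarity ratings
#'
#' The match-minus-mismatch difference in mean clarity rating, overall and
#' at each vocoder channel level. Channel-conditional values support
#' cross-level contrasts (e.g. patients' 8-channel effect against controls'
#' 4-channel effect).
#'
#' @param data A `subject_dataset` or a per-trial data frame with columns
#'   `congruency`, `channels`, `rating`.
#' @return A list: `overall` (scalar difference on the rating scale) and
#'   `by_channel` (named vector over 4/8/16).
#' @export
congruency_effect <- function(data) {
  if (inherits(data, "subject_dataset")) data <- data$exp1
  data <- as.data.frame(data)
  if (!all(c("match", "mismatch") %in% data$congruency))
    stop("both congruency levels are required")
  eff <- function(d) mean(d$rating[d$congruency == "match"]) -
    mean(d$rating[d$congruency == "mismatch"])
  chans <- sort(unique(data$channels))
  by_ch <- vapply(chans, function(ch) {
    d <- data[data$channels == ch, ]
    if (!all(c("match", "mismatch") %in% d$congruency))
      stop("missing congruency cell at ", ch, " channels")
    eff(d)
  }, numeric(1))
  list(overall = eff(data[data$congruency != "neutral", ]),
       by_channel = stats::setNames(by_ch, chans))
}
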