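# Inference layer -------------------------------------------------------------
#
# Small-n statistics as applied in DBS parameter-sweep reports: Pearson
# correlation of the physical condition level against the cohort-mean
# feature per level (n = number of levels, so df = n - 2 is tiny and the
# exact two-tailed Student-t significance matters), plus paired t-tests
# between waveforms. Raw two-tailed p-values throughout; no
# multiple-testing correction is applied.

#' Two-tailed p-value of a Pearson correlation
#'
#' `p = 2 * P(T_{n-2} > |rho| * sqrt((n-2)/(1-rho^2)))`. For `df = 3`
#' (five levels, the most common case here) the exact closed form of the
#' Student-t upper tail is used,
#' `S(t) = 1/2 - (1/pi) * (t / (sqrt(3) (1 + t^2/3)) + atan(t/sqrt(3)))`;
#' other df use the numerical tail.
#'
#' @param rho correlation coefficient, `|rho| < 1`.
#' @param n number of paired observations (>= 3).
#' @return Two-tailed p-value.
#' @examples
#' p_from_r(0.945, 5) # 0.015
#' p_from_r(0.894, 7) # 0.007
#' @export
p_from_r <- function(rho, n) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.numeric(n), n >= 3)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  df <- n - 2
  t <- abs(rho) * sqrt(df / (1 - rho^2))
  2 * .t_upper_tail(t, df)
}

.t_upper_tail <- function(t, df) {
  if (df == 3) {
    0.5 - (1 / pi) * (t / (sqrt(3) * (1 + t^2 / 3)) + atan(t / sqrt(3)))
  } else {
    stats::pt(t, df, lower.tail = FALSE)
  }
}

#' Pearson correlation with exact small-n significance
#'
#' Product-moment correlation computed directly from mean-centered sums,
#' with the two-tailed p-value from [p_from_r()] (`p = 0` in the
#' degenerate perfectly collinear limit).
#'
#' @param x condition levels (e.g. amplitude multipliers or Hz).
#' @param y cohort-mean feature per level.
#' @return An object of class `correlation_result` with fields `rho`,
#'   `n`, `t_stat`, `df`, `p_two_tailed`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  cx <- x - mean(x)
  cy <- y - mean(y)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  if (sum(cx^2) == 0 || sum(cy^2) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  rho <- sum(cx * cy) / denom
  rho <- max(-1, min(1, rho))
  df <- n - 2
  if (abs(rho) >= 1 - 1e-15) {
    t_stat <- Inf * sign(rho)
    p <- 0
  } else {
    t_stat <- rho * sqrt(df / (1 - rho^2))
    p <- p_from_r(rho, n)
  }
  structure(list(rho = rho, n = n, t_stat = t_stat, df = df,
                 p_two_tailed = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> rho = %.4g, n = %d (df = %d), t = %.4g, p = %.4g\n",
              x$rho, x$n, x$df, x$t_stat, x$p_two_tailed))
  invisible(x)
}

#' Compare two waveform conditions by t-test
#'
#' Paired by default (the same animals underwent every waveform); a Welch
#' two-sample variant is available. Zero-variance paired differences are
#' reported as a degenerate result: `t = 0, p = 1` when all differences
#' are zero, otherwise `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b per-animal feature values under the two conditions (matched
#'   animal order in paired mode).
#' @param paired paired t-test (default) or Welch two-sample.
#' @return List with `t`, `df`, `p_two_tailed`, `method`, `degenerate`.
#' @export
waveform_ttest <- function(a, b, paired = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (paired) {
    if (length(a) != length(b)) {
      stop("paired test needs equal-length, animal-matched vectors",
           call. = FALSE)
    }
    d <- a - b
    n <- length(d)
    if (n < 2) stop("need at least 2 pairs", call. = FALSE)
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      if (all(d == 0)) {
        return(list(t = 0, df = n - 1, p_two_tailed = 1,
                    method = "paired", degenerate = TRUE))
      }
      return(list(t = sign(mean(d)) * Inf, df = n - 1, p_two_tailed = 0,
                  method = "paired", degenerate = TRUE))
    }
    t <- mean(d) / (sd_d / sqrt(n))
    df <- n - 1
  } else {
    n1 <- length(a)
    n2 <- length(b)
    if (n1 < 2 || n2 < 2) stop("need at least 2 values per group",
                               call. = FALSE)
    v1 <- stats::var(a) / n1
    v2 <- stats::var(b) / n2
    if (v1 + v2 == 0) {
      eq <- mean(a) == mean(b)
      return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                  df = n1 + n2 - 2, p_two_tailed = if (eq) 1 else 0,
                  method = "welch", degenerate = TRUE))
    }
    t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df,
       p_two_tailed = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       method = if (paired) "paired" else "welch", degenerate = FALSE)
}

#' Per-level cohort means of a feature table
#'
#' @param feature_table data frame with at least an animal column, a level
#'   column and the feature column.
#' @param value_col name of the feature column.
#' @param level_col name of the level column (default `"label"`).
#' @param level_order optional character vector fixing the output order
#'   (defaults to order of first appearance).
#' @return Data frame with `level`, `mean`, `sd`, `n` (available-case
#'   counts; missing feature values are dropped per level).
#' @export
level_means <- function(feature_table, value_col, level_col = "label",
                        level_order = NULL) {
  stopifnot(is.data.frame(feature_table),
            value_col %in% names(feature_table),
            level_col %in% names(feature_table))
  lev <- feature_table[[level_col]]
  val <- feature_table[[value_col]]
  keep <- !is.na(val)
  lev <- lev[keep]
  val <- val[keep]
  if (is.null(level_order)) level_order <- unique(feature_table[[level_col]])
  missing_lev <- setdiff(level_order, lev)
  if (length(missing_lev) > 0) {
    stop("no observations for level(s): ",
         paste(missing_lev, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(level_order, function(L) {
    v <- val[lev == L]
    data.frame(level = L, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}
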