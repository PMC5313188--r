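# Reliability and comparison statistics: single-measure absolute-agreement
# intraclass correlation from a two-way ANOVA, systematic-error summaries,
# and t-test comparisons.

#' Single-measure absolute-agreement intraclass correlation
#'
#' Two-way ANOVA decomposition of an n (targets) x k (raters) complete
#' ratings matrix into row, column, and residual mean squares, with the
#' absolute-agreement single-measure ICC
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` and the
#' McGraw-Wong F-based 95\% confidence interval.  The `model` tag records
#' whether raters are treated as random (two-way random, interrater) or
#' fixed (two-way mixed, intrarater); the absolute-agreement point
#' estimate is the same in both.
#'
#' @param ratings n x k numeric matrix, no missing cells, n >= 2, k >= 2.
#' @param model `"two-way-random"` or `"two-way-mixed"`.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci` (lo, hi), `model`,
#'   `ms` (MSR, MSC, MSE), `n`, `k`.  A matrix with (near-)zero total
#'   variance yields `NA` ICC with `degenerate = TRUE`.
#' @export
icc_single <- function(ratings, model = c("two-way-random", "two-way-mixed"),
                       conf = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete (no missing cells)")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  if (stats::var(as.vector(ratings)) < .Machine$double.eps * 100) {
    warning("ratings have (near-)zero total variance; ICC undefined")
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          model = model, ms = c(MSR = 0, MSC = 0, MSE = 0),
                          n = n, k = k, degenerate = TRUE), class = "icc_result"))
  }
  df <- data.frame(y = as.vector(ratings),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- stats::aov(y ~ target + rater, data = df)
  ms <- summary(av)[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  # McGraw & Wong ICC(A,1) confidence bounds
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  Fj <- MSC / MSE
  v <- ((a * Fj + b)^2) /
       ((a^2 * Fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  F_L <- stats::qf(1 - alpha / 2, n - 1, v)
  F_U <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - F_L * MSE) /
        (F_L * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (F_U * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * F_U * MSR)
  structure(list(icc = icc, ci = c(lo = lo, hi = hi), model = model,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k,
                 degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<icc_result> undefined (zero total variance)\n")
  } else {
    cat(sprintf("<icc_result> %s single-measure absolute agreement: %.4f (95%% CI %.4f to %.4f)\n",
                x$model, x$icc, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Systematic-error summary against predetermined phantom truth
#'
#' Absolute differences `|measured - predetermined|` per model and per
#' angle measure, summarized by mean, min, and max over all cells.
#'
#' @param truth,measured matched numeric matrices (models x angle
#'   measures) or matched lists of equal-length named vectors, degrees.
#' @return object of class `error_summary`: `mean`, `min`, `max`
#'   (degrees) and the full `errors` matrix.
#' @export
systematic_error <- function(truth, measured) {
  as_mat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  t_ <- as_mat(truth); m_ <- as_mat(measured)
  if (!all(dim(t_) == dim(m_)))
    stop("truth and measured have mismatched dimensions")
  err <- abs(m_ - t_)
  structure(list(mean = mean(err), min = min(err), max = max(err),
                 errors = err), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> mean %.3f deg (range %.3f to %.3f) over %d cells\n",
              x$mean, x$min, x$max, length(x$errors)))
  invisible(x)
}

#' Compare two groups of angle measurements
#'
#' Student t-test (unpaired with pooled variance, or paired), returning
#' the mean difference `a - b`, its confidence interval, and the
#' two-sided p value.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param paired paired or two-sample comparison.
#' @param conf confidence level.
#' @return list with `difference`, `ci`, `p`, `t`, `df`.
#' @export
compare_groups <- function(a, b, paired = FALSE, conf = 0.95) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (paired && length(a) != length(b)) stop("paired groups must have equal n")
  if (paired && stats::var(a - b) < .Machine$double.eps * 100) {
    # identical (or constantly shifted) pairs: the difference is exact
    d <- mean(a - b)
    return(list(difference = d, ci = c(d, d),
                p = if (abs(d) < .Machine$double.eps * 100) 1 else 0,
                t = NA_real_, df = length(a) - 1))
  }
  if (stats::var(a) + stats::var(b) < .Machine$double.eps * 100)
    stop("degenerate (zero) variance in both groups")
  tt <- stats::t.test(a, b, paired = paired, var.equal = !paired,
                      conf.level = conf)
  diff <- if (paired) mean(a - b) else mean(a) - mean(b)
  list(difference = diff, ci = unname(tt$conf.int), p = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Ratings matrix for one angular definition from simulated trials
#'
#' Pools the anteversion and inclination measurements of one angular
#' definition into a (hip x measure) by rater matrix, the layout used
#' for the per-definition reliability tables.
#'
#' @param trials data.frame from [simulate_raters()].
#' @param definition `"anatomic"`, `"radiographic"`, or `"operative"`.
#' @param trial which trial to use (interrater layout); or set
#'   `rater` to build an intrarater (trial-column) matrix instead.
#' @param rater if given, columns are trials for this rater.
#' @return numeric matrix with raters (or trials) as columns.
#' @export
ratings_matrix <- function(trials, definition = ANGLE_DEFINITIONS,
                           trial = 1, rater = NULL) {
  definition <- match.arg(definition)
  cols <- paste0(definition, c("_av", "_inc"))
  if (is.null(rater)) {
    sub <- trials[trials$trial == trial, ]
    split_by <- sub$rater
  } else {
    sub <- trials[trials$rater == rater, ]
    split_by <- sub$trial
  }
  if (anyNA(sub[, cols])) stop("trials contain failed measurements")
  groups <- split(sub[, cols], split_by)
  m <- do.call(cbind, lapply(groups, function(g) c(g[[1]], g[[2]])))
  colnames(m) <- names(groups)
  m
}
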