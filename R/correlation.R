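#' Pairwise-complete Pearson correlation structure over traits
#'
#' Pearson coefficients on pairwise-complete observations via
#' [stats::cor()]; two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom with
#' the pairwise-complete `n`. Pairs with fewer than 3 complete
#' observations, and all pairs involving a zero-variance trait, are
#' reported missing.
#'
#' @param data data.frame of observations (typically genotype means from
#'   [genotype_means()]; the analysis level is recorded in the result).
#' @param traits character vector of trait columns.
#' @param level metadata string recorded in the result, default
#'   `"genotype_mean"`.
#' @return list of class `correlation_result`: `traits`, `R`, `P`, `N`
#'   (symmetric matrices), `level`, `dropped` (zero-variance traits).
#' @export
correlation_matrix <- function(data, traits, level = "genotype_mean") {
  check_columns(data, traits, "data")
  x <- as.matrix(data[traits])
  storage.mode(x) <- "double"
  variances <- apply(x, 2, stats::var, na.rm = TRUE)
  dropped <- traits[!is.na(variances) & variances == 0]
  if (length(dropped) > 0) {
    message("correlation_matrix: zero-variance trait(s) reported missing: ",
            paste(dropped, collapse = ", "))
  }
  N <- crossprod(!is.na(x))
  R <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  R[N < 3] <- NA_real_
  diag(R)[diag(N) >= 1] <- 1
  tstat <- R * sqrt((N - 2) / pmax(1 - R^2, 0))
  P <- 2 * stats::pt(abs(tstat), df = N - 2, lower.tail = FALSE)
  P[N < 3] <- NA_real_
  P[!is.finite(tstat)] <- 0  # |r| = 1 exactly
  diag(P) <- 0
  P[is.na(R)] <- NA_real_
  structure(list(traits = traits, R = R, P = P, N = N, level = level,
                 dropped = dropped),
            class = "correlation_result")
}

#' Ordinary least-squares regression between two traits
#'
#' Fits `y ~ x` on complete pairs (typically genotype means) and reports
#' the slope, intercept, Pearson r and its two-sided p-value; `r` equals
#' the corresponding [correlation_matrix()] entry.
#'
#' @param data data.frame of observations.
#' @param x,y trait column names (predictor, response).
#' @return data.frame: x, y, slope, intercept, r, p, n.
#' @export
bivariate_regression <- function(data, x, y) {
  check_columns(data, c(x, y), "data")
  d <- data.frame(x = data[[x]], y = data[[y]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 complete pairs")
  if (stats::var(d$x) == 0 || stats::var(d$y) == 0)
    stop("zero-variance trait in regression")
  fit <- stats::lm(y ~ x, data = d)
  ct <- stats::cor.test(d$x, d$y)
  data.frame(x = x, y = y,
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
             stringsAsFactors = FALSE)
}

#' Write a correlation result's matrices as delimited text
#' @param result a `correlation_result`.
#' @param dir output directory.
#' @param prefix file-name prefix, default `"correlation"`.
#' @export
write_correlation_result <- function(result, dir, prefix = "correlation") {
  for (part in c("R", "P", "N")) {
    utils::write.csv(result[[part]],
                     file.path(dir, sprintf("%s_%s.csv", prefix, part)))
  }
  invisible(result)
}
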