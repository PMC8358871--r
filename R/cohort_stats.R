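# Rank-based cohort inference: Mann-Whitney U contrasts and Spearman
# correlation of the CLDN5/nephrin ratio with the filtration slit density.

#' Mann-Whitney U test (two-sided)
#'
#' Reports U = min(U1, U2) with U1 = n1*n2 + n1(n1+1)/2 - R1. The p-value
#' is the exact distribution of U when n1 + n2 <= 12 and the data are
#' tie-free, otherwise a normal approximation with tie and continuity
#' correction.
#'
#' @param a,b numeric sample vectors (non-empty).
#' @param method `"auto"` (default rule above), `"exact"`, or
#'   `"normal_approx"`.
#' @return list of class `mwu_test`: `u_statistic` (min of U1/U2), `u1`,
#'   `u2`, `p_value`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  r1 <- sum(r[seq_len(n1)])
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - r1
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(c(a, b)) > 0L

  use_exact <- switch(method,
    auto = (n1 + n2 <= 12L) && !ties,
    exact = {
      if (ties) stop("exact method requires tie-free data", call. = FALSE)
      TRUE
    },
    normal_approx = FALSE
  )
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  )
  structure(list(u_statistic = min(u1, u2), u1 = u1, u2 = u2,
                 p_value = p,
                 method = if (use_exact) "exact" else "normal_approx",
                 n1 = n1, n2 = n2),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g (%s)\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Spearman rank correlation (two-sided)
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The p-value uses the t reference distribution
#' t = rho * sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees of freedom; a
#' perfect monotone relation (|rho| = 1) is reported with the exact
#' permutation bound p = 2 / n!. R^2 is reported as rho^2.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list of class `spearman_cor`: `rho`, `r_squared`, `p_value`, `n`.
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1 - 1e-12) {
    min(1, 2 / factorial(n))
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, r_squared = rho^2, p_value = p, n = n),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (R^2 = %.3f), p = %.4g, n = %d\n",
              x$rho, x$r_squared, x$p_value, x$n))
  invisible(x)
}

# Parse a contrast spec: c("control", "MCD") or "control:MCD"; group names
# may pool several labels with "+", e.g. "control:MCD+FSGS".
parse_contrast <- function(ct) {
  if (is.character(ct) && length(ct) == 1L) ct <- strsplit(ct, ":")[[1]]
  if (length(ct) != 2L) {
    stop("a contrast must name exactly two groups", call. = FALSE)
  }
  lapply(ct, function(side) strsplit(side, "+", fixed = TRUE)[[1]])
}

#' Cohort-level analysis of ratio and FSD
#'
#' For each contrast, runs two-sided Mann-Whitney tests on the per-sample
#' mean CLDN5/nephrin ratio and mean FSD; across all samples, computes the
#' pooled Spearman correlation of mean ratio versus mean FSD. No
#' multiple-testing correction is applied (per-contrast reporting); this is
#' stated in the report.
#'
#' @param table cohort data.frame with columns `sample_id`, `group`,
#'   `mean_ratio`, `mean_fsd_per_um` (one row per sample).
#' @param contrasts list of contrasts; each either a length-2 character
#'   vector or a string `"a:b"`. Group labels may be pooled with `"+"`
#'   (e.g. `"control:MCD+FSGS"`).
#' @return list of class `cohort_report`: `contrasts` (data.frame of test
#'   results), `correlation` (a [spearman_correlation()] result or NULL if
#'   n < 3), `n_samples`, `note`.
#' @export
cohort_analysis <- function(table, contrasts = list()) {
  need <- c("sample_id", "group", "mean_ratio", "mean_fsd_per_um")
  if (!all(need %in% names(table))) {
    stop("cohort table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$sample_id)) {
    stop("one row per sample required", call. = FALSE)
  }
  groups <- unique(table$group)
  rows <- list()
  for (ct in contrasts) {
    sides <- parse_contrast(ct)
    for (g in unlist(sides)) {
      if (!g %in% groups) stop("unknown group in contrast: ", g, call. = FALSE)
    }
    va <- table[table$group %in% sides[[1]], , drop = FALSE]
    vb <- table[table$group %in% sides[[2]], , drop = FALSE]
    if (nrow(va) == 0L || nrow(vb) == 0L) {
      stop("empty group in contrast", call. = FALSE)
    }
    for (var in c("mean_ratio", "mean_fsd_per_um")) {
      tst <- mann_whitney_u(va[[var]], vb[[var]])
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = paste(sides[[1]], collapse = "+"),
        group_b = paste(sides[[2]], collapse = "+"),
        variable = var,
        u_statistic = tst$u_statistic,
        p_value = tst$p_value,
        method = tst$method,
        n1 = tst$n1, n2 = tst$n2,
        stringsAsFactors = FALSE)
    }
  }
  corr <- if (nrow(table) >= 3L) {
    spearman_correlation(table$mean_ratio, table$mean_fsd_per_um)
  } else {
    NULL
  }
  structure(list(
    contrasts = if (length(rows)) do.call(rbind, rows) else
      data.frame(group_a = character(0), group_b = character(0),
                 variable = character(0), u_statistic = numeric(0),
                 p_value = numeric(0), method = character(0),
                 n1 = integer(0), n2 = integer(0)),
    correlation = corr,
    n_samples = nrow(table),
    note = "two-sided tests; no multiple-testing correction applied"
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d samples\n", x$n_samples))
  if (!is.null(x$correlation)) {
    cat("  pooled ratio-vs-FSD "); print(x$correlation)
  }
  if (nrow(x$contrasts) > 0L) {
    cat("  contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Write a cohort report to JSON (and optionally CSV)
#'
#' @param report a `cohort_report` from [cohort_analysis()].
#' @param json_path output JSON path.
#' @param csv_path optional CSV path for the contrast table.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  out <- list(
    n_samples = report$n_samples,
    note = report$note,
    correlation = if (is.null(report$correlation)) NULL else
      report$correlation[c("rho", "r_squared", "p_value", "n")],
    contrasts = report$contrasts
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(report$contrasts, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
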