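#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) variances, as in Lin's original estimator — agreement combines
#' precision (correlation) and accuracy (closeness to the identity line).
#' Pairs containing `NA` are dropped first. If both variances and the mean
#' gap are zero the pair of vectors is an identical constant and the CCC is
#' defined as 1; a constant against anything that differs only in level
#' scores 0.
#'
#' @param x,y Paired measurements over subjects (equal length, n >= 3 after
#'   dropping incomplete pairs).
#' @return Scalar in [-1, 1].
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("lin_ccc needs at least 3 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(if (all(x == y)) 1 else 0)
  2 * sxy / den
}

# Two-sided Dixon Q critical values (r10 statistic), n = 3..30,
# alpha = 0.10 / 0.05 / 0.01 (Rorabacher 1991).
dixon_q_table <- function(alpha) {
  tab <- list(
    "0.1" = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412,
              0.392, 0.376, 0.361, 0.349, 0.338, 0.329, 0.320, 0.313,
              0.306, 0.300, 0.295, 0.290, 0.285, 0.281, 0.277, 0.273,
              0.269, 0.266, 0.263, 0.260),
    "0.05" = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
               0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
               0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
               0.308, 0.305, 0.301, 0.298),
    "0.01" = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568,
               0.542, 0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442,
               0.433, 0.425, 0.418, 0.411, 0.404, 0.399, 0.393, 0.388,
               0.384, 0.380, 0.376, 0.372))
  key <- as.character(alpha)
  if (!key %in% names(tab))
    stop("Dixon Q critical values tabulated for alpha 0.10, 0.05, 0.01",
         call. = FALSE)
  tab[[key]]
}

#' Dixon's Q outlier test
#'
#' Small-sample outlier screen: Q is the gap between the suspect extreme
#' and its nearest neighbor divided by the range; the suspect is the
#' extreme with the larger gap. Two-sided test against the tabulated
#' critical values (n = 3..30).
#'
#' @param values Numeric vector (3 <= n <= 30; beyond 30 the test is
#'   flagged not applicable with a warning).
#' @param alpha Significance level: 0.10, 0.05 or 0.01.
#' @return A list: `Q`, `suspect` (index into `values`), `significant`,
#'   `critical`, `n`. All-equal values give `Q = NA` and no outlier.
#' @export
#' @examples
#' dixon_q(c(0.1, 0.15, 0.2, 0.9))  # Q = 0.875, significant at 0.05
dixon_q <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop("Dixon's Q needs n >= 3", call. = FALSE)
  if (n > 30L) {
    warning("Dixon's Q is tabulated up to n = 30; flag not applicable",
            call. = FALSE)
    return(list(Q = NA_real_, suspect = NA_integer_, significant = NA,
                critical = NA_real_, n = n))
  }
  rng <- max(values) - min(values)
  if (rng == 0)
    return(list(Q = NA_real_, suspect = NA_integer_, significant = FALSE,
                critical = dixon_q_table(alpha)[n - 2L], n = n))
  s <- sort(values)
  gap_low <- s[2] - s[1]
  gap_high <- s[n] - s[n - 1L]
  if (gap_high >= gap_low) {
    Q <- gap_high / rng
    suspect <- which.max(values)
  } else {
    Q <- gap_low / rng
    suspect <- which.min(values)
  }
  crit <- dixon_q_table(alpha)[n - 2L]
  list(Q = Q, suspect = suspect, significant = Q > crit, critical = crit,
       n = n)
}

#' Per-feature concordance over the setting pairs
#'
#' For every feature and comparison pair, Lin's CCC of scan 1 versus
#' scan 2 across subjects. Identical-setting pairs compare the two repeat
#' scans at the same setting; cross-kernel pairs compare scan 1 at the
#' sharp kernel with scan 2 at the smooth kernel of equal thickness.
#' With `outlier_policy = "dixon-screen"`, subjects flagged by Dixon's Q
#' (alpha 0.05) on the per-subject paired differences of that feature are
#' removed and the screened CCC is reported alongside the raw one.
#'
#' @param features Long feature tibble from [extract_cohort_features()].
#' @param pairs A tibble from [setting_pairs()] (or one of its labels in
#'   `"identical"`, `"cross"`, `"all"`).
#' @param outlier_policy `"none"` or `"dixon-screen"`.
#' @param alpha Dixon screening level.
#' @return A `ccc_records` tibble: `feature`, `class`, `pair`, `type`,
#'   `n`, `ccc`, `ccc_screened`, `n_screened`, `outlier_subjects`.
#' @export
ccc_matrix <- function(features, pairs = setting_pairs("all"),
                       outlier_policy = c("none", "dixon-screen"),
                       alpha = 0.05) {
  outlier_policy <- match.arg(outlier_policy)
  if (is.character(pairs)) pairs <- setting_pairs(pairs)
  known <- setting_pairs("all")$pair
  bad <- setdiff(pairs$pair, known)
  if (length(bad))
    stop("unknown pair label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  feat_meta <- dplyr::distinct(features, .data$feature, .data$class)
  out <- vector("list", nrow(pairs) * nrow(feat_meta))
  idx <- 0L
  for (pi in seq_len(nrow(pairs))) {
    p <- pairs[pi, ]
    xtab <- features |>
      dplyr::filter(.data$scan == 1L, .data$setting == p$setting1) |>
      dplyr::select("subject_id", "feature", x = "value")
    ytab <- features |>
      dplyr::filter(.data$scan == 2L, .data$setting == p$setting2) |>
      dplyr::select("subject_id", "feature", y = "value")
    joined <- dplyr::inner_join(xtab, ytab, by = c("subject_id", "feature"))
    for (fi in seq_len(nrow(feat_meta))) {
      f <- feat_meta$feature[fi]
      sub <- joined[joined$feature == f, ]
      ok <- !is.na(sub$x) & !is.na(sub$y)
      n_ok <- sum(ok)
      ccc <- if (n_ok >= 3L) lin_ccc(sub$x[ok], sub$y[ok]) else NA_real_
      ccc_scr <- NA_real_; n_scr <- NA_integer_; outliers <- NA_character_
      if (outlier_policy == "dixon-screen" && n_ok >= 3L && n_ok <= 30L) {
        dq <- dixon_q(sub$y[ok] - sub$x[ok], alpha = alpha)
        if (isTRUE(dq$significant)) {
          keep <- seq_len(n_ok) != dq$suspect
          outliers <- sub$subject_id[ok][dq$suspect]
          if (sum(keep) >= 3L) {
            ccc_scr <- lin_ccc(sub$x[ok][keep], sub$y[ok][keep])
            n_scr <- sum(keep)
          }
        } else {
          ccc_scr <- ccc; n_scr <- n_ok
        }
      }
      idx <- idx + 1L
      out[[idx]] <- tibble::tibble(
        feature = f, class = feat_meta$class[fi], pair = p$pair,
        type = p$type, n = n_ok, ccc = ccc, ccc_screened = ccc_scr,
        n_screened = n_scr, outlier_subjects = outliers)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("ccc_records", class(res))
  res
}

#' Count reproducible features at CCC cut-offs
#'
#' One row per comparison pair, one column pair (count, percentage of the
#' 89 registry features, percentage rounded to integer) per cut-off;
#' features with an undefined CCC count as non-reproducible. A CCC of 0.85
#' is the study's primary reproducibility threshold.
#'
#' @param records A `ccc_records` tibble covering all 89 features per pair.
#' @param cutoffs Ascending CCC cut-offs.
#' @param use_screened Summarize the Dixon-screened CCCs instead of raw.
#' @return A tibble: `pair`, `type`, then `count_<c>` / `pct_<c>` per
#'   cut-off.
#' @export
summarize_cutoffs <- function(records, cutoffs = c(0.85, 0.90, 0.95),
                              use_screened = FALSE) {
  reg <- feature_registry()
  val_col <- if (use_screened) "ccc_screened" else "ccc"
  cutoffs <- sort(cutoffs)
  out <- list()
  for (p in unique(records$pair)) {
    sub <- records[records$pair == p, ]
    missing <- setdiff(reg$feature, sub$feature)
    if (length(missing))
      stop("records for pair ", p, " lack features: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...", call. = FALSE)
    v <- sub[[val_col]][match(reg$feature, sub$feature)]
    row <- tibble::tibble(pair = p, type = sub$type[1])
    for (ct in cutoffs) {
      cnt <- sum(!is.na(v) & v >= ct)
      row[[sprintf("count_%g", ct)]] <- cnt
      row[[sprintf("pct_%g", ct)]] <- round(100 * cnt / nrow(reg))
    }
    out[[length(out) + 1L]] <- row
  }
  dplyr::bind_rows(out)
}

#' Compare two concordance coefficients by paired subject bootstrap
#'
#' Two-sided p-value for a difference between the CCCs of two paired
#' measurements computed on the same subjects (e.g. a 3D feature versus
#' its 2D analog): subjects are resampled with replacement, both CCCs are
#' recomputed per resample, and the percentile p-value for `delta != 0`
#' is returned. Seeded and deterministic.
#'
#' @param xa,ya Paired values (scan 1 / scan 2) of measurement A.
#' @param xb,yb Paired values of measurement B, same subjects in the same
#'   order.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return A list: `ccc_a`, `ccc_b`, `delta`, `p_value`, `n_boot`.
#' @export
compare_ccc <- function(xa, ya, xb, yb, n_boot = 2000L, seed = 1L) {
  n <- length(xa)
  stopifnot(length(ya) == n, length(xb) == n, length(yb) == n)
  if (n < 5L) stop("compare_ccc needs at least 5 subjects", call. = FALSE)
  ccc_a <- lin_ccc(xa, ya)
  ccc_b <- lin_ccc(xb, yb)
  deltas <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      da <- tryCatch(lin_ccc(xa[idx], ya[idx]), error = function(e) NA_real_)
      db <- tryCatch(lin_ccc(xb[idx], yb[idx]), error = function(e) NA_real_)
      da - db
    }, numeric(1))
  })
  deltas <- deltas[!is.na(deltas)]
  p_lo <- mean(deltas <= 0); p_hi <- mean(deltas >= 0)
  list(ccc_a = ccc_a, ccc_b = ccc_b, delta = ccc_a - ccc_b,
       p_value = min(1, 2 * min(p_lo, p_hi)), n_boot = length(deltas))
}

#' Export the CCC heat-map matrix
#'
#' A features x pairs matrix in registry order (rows grouped by class) with
#' the 6 identical-setting columns before the 3 cross-kernel columns, as
#' CSV. Undefined CCCs stay empty cells, not 0.
#'
#' @param records A `ccc_records` tibble.
#' @param path Output CSV path (optional).
#' @return The wide tibble, invisibly when writing to `path`.
#' @export
export_heatmap <- function(records, path = NULL) {
  reg <- feature_registry()
  cols <- intersect(setting_pairs("all")$pair, unique(records$pair))
  wide <- tibble::tibble(feature = reg$feature, class = reg$class)
  for (p in cols) {
    sub <- records[records$pair == p, ]
    wide[[p]] <- sub$ccc[match(reg$feature, sub$feature)]
  }
  if (!is.null(path)) {
    write_numeric_csv(wide, path)
    return(invisible(wide))
  }
  wide
}

# CSV writer with a stable 10-significant-digit numeric format so that
# identical runs produce byte-identical files; `meta` adds a leading
# comment line (read back with `comment.char = "#"`)
write_numeric_csv <- function(df, path, meta = NULL) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]])) {
      v <- sprintf("%.10g", fmt[[j]])
      v[is.na(fmt[[j]])] <- ""
      fmt[[j]] <- v
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(meta, con)
  utils::write.table(fmt, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
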