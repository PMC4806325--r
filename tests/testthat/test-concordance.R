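test_that("lin_ccc reproduces closed-form values", {
  expect_equal(lin_ccc(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_equal(lin_ccc(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
  # degenerate conventions
  expect_equal(lin_ccc(rep(2, 4), rep(2, 4)), 1)
  expect_equal(lin_ccc(rep(2, 4), rep(5, 4)), 0)
  # NA pairs dropped first; too few left is an error
  expect_equal(lin_ccc(c(1, 2, 3, NA), c(2, 3, 4, 9)), 4 / 7,
               tolerance = 1e-12)
  expect_error(lin_ccc(c(1, NA, 3), c(2, 3, 4)), "at least 3")
})

test_that("lin_ccc is bounded by Pearson correlation and penalizes offsets", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(12); y <- 0.6 * x + rnorm(12, sd = 0.5)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  x <- c(0.3, 1.1, 2.2, 3.4, 4.1)
  cccs <- vapply(c(0, 0.5, 1, 2, 4), function(cshift) lin_ccc(x, x + cshift),
                 numeric(1))
  expect_true(all(diff(cccs) < 0))   # growing offset, shrinking agreement
  expect_equal(cccs[1], 1)
})

test_that("dixon_q reproduces tabulated hand examples", {
  dq <- dixon_q(c(0.1, 0.15, 0.2, 0.9), alpha = 0.05)
  expect_equal(dq$Q, 0.875)
  expect_equal(dq$suspect, 4L)
  expect_equal(dq$critical, 0.829)   # Q_0.05 at n = 4
  expect_true(dq$significant)

  dq3 <- dixon_q(c(1, 2, 3), alpha = 0.05)
  expect_equal(dq3$Q, 0.5)
  expect_equal(dq3$critical, 0.970)
  expect_false(dq3$significant)

  expect_true(is.na(dixon_q(rep(5, 6))$Q))        # all equal: no outlier
  expect_false(isTRUE(dixon_q(rep(5, 6))$significant))
  expect_error(dixon_q(c(1, 2)), "n >= 3")
  expect_warning(res <- dixon_q(rnorm(31)), "n = 30")
  expect_true(is.na(res$Q))
  # low-side suspect
  dql <- dixon_q(c(-5, 1, 1.1, 1.2, 1.3))
  expect_equal(dql$suspect, 1L)
})

test_that("ccc_matrix enumerates the study pairs and scores duplicates as 1", {
  expect_equal(nrow(setting_pairs("identical")), 6)
  expect_equal(nrow(setting_pairs("cross")), 3)
  expect_equal(setting_pairs("all")$pair[1:2],
               c("1.25L vs 1.25L", "1.25S vs 1.25S"))

  # tiny synthetic feature table: scan 2 duplicates scan 1
  set.seed(3)
  subjects <- sprintf("P%d", 1:5)
  labs <- vapply(all_settings(), `[[`, character(1), "label")
  base <- expand.grid(subject_id = subjects, setting = labs,
                      feature = c("A", "B"), stringsAsFactors = FALSE)
  base$class <- "X"
  base$value <- rnorm(nrow(base))
  feats <- dplyr::bind_rows(cbind(base, scan = 1L), cbind(base, scan = 2L))
  rec <- ccc_matrix(feats, setting_pairs("identical"))
  expect_equal(nrow(rec), 6 * 2)
  expect_true(all(rec$ccc == 1))
  expect_error(ccc_matrix(feats, tibble::tibble(pair = "9L vs 9S",
                                                setting1 = "9L",
                                                setting2 = "9S",
                                                type = "cross")),
               "unknown pair")
})

test_that("dixon screening removes a planted outlier subject and lifts the
           screened CCC", {
  set.seed(10)
  subjects <- sprintf("P%02d", 1:12)
  labs <- vapply(all_settings(), `[[`, character(1), "label")
  rows <- list()
  for (s in seq_along(subjects)) for (lab in labs) for (scan in 1:2) {
    v <- 10 + s + (if (scan == 2) rnorm(1, sd = 0.05) else 0) +
      (if (scan == 2 && s == 7) 25 else 0)        # subject 7 breaks retest
    rows[[length(rows) + 1]] <- tibble::tibble(
      subject_id = subjects[s], scan = scan, setting = lab,
      feature = "F1", class = "X", value = v)
  }
  feats <- dplyr::bind_rows(rows)
  rec <- ccc_matrix(feats, setting_pairs("identical"),
                    outlier_policy = "dixon-screen")
  expect_true(all(rec$outlier_subjects == "P07"))
  expect_true(all(rec$ccc_screened > rec$ccc))
  expect_true(all(rec$n_screened == 11))
})

test_that("cut-off summaries count and round as in the study table", {
  reg <- feature_registry()
  mk_rec <- function(vals) {
    tibble::tibble(feature = reg$feature, class = reg$class,
                   pair = "1.25L vs 1.25L", type = "identical",
                   n = 10, ccc = vals, ccc_screened = NA_real_,
                   n_screened = NA_integer_, outlier_subjects = NA_character_)
  }
  all_one <- summarize_cutoffs(mk_rec(rep(1, 89)))
  expect_equal(unname(unlist(all_one[1, c("count_0.85", "count_0.9",
                                          "count_0.95")])), c(89, 89, 89))
  expect_equal(unname(all_one$pct_0.85), 100)

  split_rec <- mk_rec(c(rep(0.84, 40), rep(0.86, 49)))
  s <- summarize_cutoffs(split_rec)
  expect_equal(unname(s$count_0.85), 49)
  expect_equal(unname(s$pct_0.85), 55)            # round(100 * 49 / 89)
  expect_equal(unname(s$count_0.9), 0)

  # counts are non-increasing in the cut-off; NA counts as non-reproducible
  set.seed(2)
  vals <- runif(89); vals[c(3, 40)] <- NA
  s2 <- summarize_cutoffs(mk_rec(vals))
  expect_true(s2$count_0.85 >= s2$count_0.9 && s2$count_0.9 >= s2$count_0.95)
  # missing features are an error, not a silent zero
  expect_error(summarize_cutoffs(mk_rec(rep(1, 89))[-5, ]), "lack features")
})

test_that("paired bootstrap CCC comparison is seeded, calibrated and
           powered", {
  set.seed(11)
  n <- 30
  truth <- rnorm(n, 50, 10)
  xa <- truth + rnorm(n, sd = 1);  ya <- truth + rnorm(n, sd = 1)
  xb <- truth + rnorm(n, sd = 12); yb <- truth + rnorm(n, sd = 12)
  res <- compare_ccc(xa, ya, xb, yb, n_boot = 2000, seed = 42)
  expect_gt(res$ccc_a, res$ccc_b)
  expect_lt(res$p_value, 0.05)                    # power on a real difference
  res2 <- compare_ccc(xa, ya, xb, yb, n_boot = 2000, seed = 42)
  expect_identical(res$p_value, res2$p_value)     # seeded determinism
  same <- compare_ccc(xa, ya, xa, ya, n_boot = 500, seed = 1)
  expect_gt(same$p_value, 0.5)                    # identical statistics
  expect_error(compare_ccc(1:4, 1:4, 1:4, 1:4), "at least 5")
})

test_that("heat-map export is registry-ordered with empty (not zero) gaps", {
  reg <- feature_registry()
  rec <- tidyr::expand_grid(feature = reg$feature,
                            pair = setting_pairs("all")$pair)
  rec <- dplyr::left_join(rec, reg[, c("feature", "class")], by = "feature")
  rec$type <- "x"; rec$n <- 10
  rec$ccc <- 0.9
  rec$ccc[rec$feature == "GLCM_Energy" & rec$pair == "5L vs 5S"] <- NA
  rec$ccc_screened <- NA_real_; rec$n_screened <- NA_integer_
  rec$outlier_subjects <- NA_character_
  wide <- export_heatmap(rec)
  expect_equal(dim(wide), c(89, 11))
  expect_equal(wide$feature, reg$feature)
  expect_equal(names(wide)[3:11], setting_pairs("all")$pair)
  expect_true(is.na(wide[wide$feature == "GLCM_Energy", "5L vs 5S"][[1]]))

  td <- withr::local_tempdir()
  p <- file.path(td, "h.csv")
  export_heatmap(rec, p)
  lines <- readLines(p)
  expect_equal(length(lines), 90)
  expect_match(lines[which(grepl("^GLCM_Energy", lines))], ",$|,,")

  plt <- ggplot2::autoplot(structure(rec, class = c("ccc_records",
                                                    class(rec))))
  expect_s3_class(plt, "ggplot")
})
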