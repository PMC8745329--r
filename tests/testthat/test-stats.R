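make_records <- function(values_by_rep, donor = "d1", timepoint = 2) {
  do.call(rbind, lapply(seq_along(values_by_rep), function(r)
    data.frame(donor = donor, replicate = paste0("r", r),
               surface = "collagen", preset = "vehicle", switch_time = NA,
               timepoint = timepoint,
               P1 = values_by_rep[r], P2 = 0, P3 = 0, P4 = 0, P5 = 0,
               P6 = 0, P7 = 0)))
}

test_that("replicate averaging collapses runs to one record per donor cell", {
  expect_equal(average_replicates(make_records(c(10, 20)))$P1, 15)
  expect_equal(average_replicates(make_records(7))$P1, 7)
  expect_equal(average_replicates(make_records(c(1, 2, 6)))$P1, 3)
  expect_error(average_replicates(make_records(c(1, 2))[0, ]), "no records")
  expect_error(average_replicates(data.frame(P1 = 1)), "missing column")
})

test_that("univariate scaling maps a series onto exactly [0, 10]", {
  expect_equal(as.numeric(univariate_scale(c(2, 4, 6))), c(0, 5, 10))
  expect_warning(out <- univariate_scale(c(7, 7, 7)), "constant")
  expect_equal(as.numeric(out), c(0, 0, 0))
  expect_error(univariate_scale(numeric(0)), "empty")
  # brute-force formula oracle
  set.seed(13)
  x <- rnorm(50, 20, 9)
  expect_equal(as.numeric(univariate_scale(x)),
               (x - min(x)) * 10 / (max(x) - min(x)), tolerance = 1e-12)
  # idempotence: scaling a scaled series returns it unchanged
  s <- as.numeric(univariate_scale(x))
  expect_equal(as.numeric(univariate_scale(s)), s, tolerance = 1e-12)
  # strict monotonicity on non-constant series
  xs <- sort(x)
  expect_true(all(diff(as.numeric(univariate_scale(xs))) > 0))
  # bounds recorded
  expect_equal(unname(attr(univariate_scale(c(2, 4, 6)), "bounds")), c(2, 6))
})

test_that("paired t-test matches its closed form and reference values", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)), list(t = 0, df = 2, p = 1))
  res <- paired_t_test(rep(0, 5), 1:5)
  expect_equal(res$t, 4.242640687, tolerance = 1e-9)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0132356, tolerance = 1e-6)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:2), "equal length")
  expect_warning(res0 <- paired_t_test(c(0, 0, 0), c(1, 1, 1)), "degenerate")
  expect_equal(res0$p, 0)
})

test_that("paired t-test agrees with the stats reference to 1e-10", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    a <- rnorm(n, 10, 3); b <- a + rnorm(n, 0.5, 1)
    mine <- paired_t_test(a, b)
    ref <- t.test(b, a, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("subtraction heatmaps subtract, filter and validate alignment", {
  m <- matrix(c(3, 7, 5, 2), 2, 2, dimnames = list(c("P1", "P2"), c("a", "b")))
  # self-subtraction is zero, filtered or not
  for (filt in c(TRUE, FALSE)) {
    sh <- subtraction_heatmap(m, m, matrix(0.5, 2, 2), filtered = filt)
    expect_true(all(sh$delta == 0))
  }
  # filter semantics on a single cell
  tre <- m; tre["P1", "a"] <- m["P1", "a"] - 4.2
  p <- matrix(1, 2, 2, dimnames = dimnames(m)); p["P1", "a"] <- 0.20
  expect_equal(subtraction_heatmap(tre, m, p)$delta["P1", "a"], 0)
  p["P1", "a"] <- 0.01
  expect_equal(subtraction_heatmap(tre, m, p)$delta["P1", "a"], -4.2)
  # unfiltered keeps the delta regardless of p
  p["P1", "a"] <- 0.99
  expect_equal(subtraction_heatmap(tre, m, p, filtered = FALSE)$delta["P1", "a"],
               -4.2)
  m2 <- m; colnames(m2) <- c("a", "c")
  expect_error(subtraction_heatmap(m, m2, p), "alignment")
  expect_error(subtraction_heatmap(m, m, matrix(0.5, 3, 2)), "alignment")
})

test_that("scaled records stay within [0,10] and remember their bounds", {
  set.seed(3)
  recs <- do.call(rbind, lapply(c("d1", "d2", "d3"), function(d)
    do.call(rbind, lapply(c(2, 6, 10), function(tp) {
      r <- make_records(runif(1, 0, 50), donor = d, timepoint = tp)
      r$P6 <- runif(1, 0, 30); r
    }))))
  sc <- scale_records(average_replicates(recs))
  vals <- as.matrix(sc$records[paste0("P", 1:7)])
  expect_true(all(vals >= 0 & vals <= 10))
  expect_equal(max(sc$records$P1), 10)
  expect_equal(min(sc$records$P1), 0)
  expect_equal(sc$n_donors, 3)
  expect_true("all.P1" %in% names(sc$bounds))
})

test_that("the report writes scaled and per-condition subtraction tables", {
  set.seed(7)
  grid <- expand.grid(donor = c("d1", "d2", "d3"), replicate = c("r1", "r2"),
                      surface = "collagen_TF",
                      preset = c("vehicle", "tirofiban"),
                      timepoint = c(2, 6), stringsAsFactors = FALSE)
  grid$switch_time <- ifelse(grid$preset == "vehicle", NA, 2)
  for (p in paste0("P", 1:7))
    grid[[p]] <- runif(nrow(grid), 0, 50) *
      ifelse(grid$preset == "vehicle", 1, 0.3)
  out <- tempfile("report")
  rep1 <- assemble_report(grid, out, figures = FALSE)
  expect_true(file.exists(file.path(out, "scaled.csv")))
  expect_true(file.exists(file.path(out, "delta_tirofiban_2.csv")))
  expect_named(rep1$subtractions, "tirofiban@2")
  sh <- rep1$subtractions[["tirofiban@2"]]
  # filtered cells with p >= alpha are exactly zero
  expect_true(all(sh$delta[sh$p_values >= sh$alpha] == 0))
  expect_true(all(abs(sh$delta) <= 10))
  # vehicle-only cohort: scaled map only, no subtraction maps
  veh <- grid[grid$preset == "vehicle", ]
  rep2 <- assemble_report(veh, tempfile("rep2"), figures = FALSE)
  expect_length(rep2$subtractions, 0)
})
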