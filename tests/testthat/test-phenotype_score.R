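test_that("profile contrast is scale invariant and matches a window oracle", {
  set.seed(29)
  v <- rpois(400, 20) + 1
  mk <- function(x) {
    tr <- depth_track(list(chr1 = c(numeric(100), x, numeric(1000 - 100 - length(x)))),
                      total_reads = 1e6, normalized = TRUE, scale = 1e6)
    tr
  }
  vp <- data.frame(chrom = "chr1", start = 100L, end = 500L)
  p1 <- profile_contrast(mk(v), mk(3 * v), vp)
  expect_equal(p1$case, p1$control, tolerance = 1e-12)

  p2 <- profile_contrast(mk(v), mk(v), vp, smooth_window = 50)
  # brute-force truncated centered running mean on the unit-mean profile
  u <- v / mean(v)
  n <- length(u)
  oracle <- vapply(seq_len(n), function(i)
    mean(u[max(1, i - 25):min(n, i + 25)]), 0)
  expect_equal(p2$case, oracle, tolerance = 1e-12)

  zero <- mk(numeric(400))
  expect_error(profile_contrast(mk(v), zero, vp), "zero total depth")
})

test_that("panel construction assigns direction by fold-change sign", {
  mkg <- function(frags, total) structure(
    list(group_label = "g", mean_ff = 0.1, n_samples = 1,
         fragments = frags, total_reads = total), class = "group_library")
  win <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  case <- mkg(gintervals("chr1", rep(10, 100), rep(50, 100)), 1e5)
  ctrl <- mkg(gintervals("chr1", rep(10, 200), rep(50, 200)), 1e5)
  pan <- build_panel(case, ctrl, win)
  expect_equal(nrow(pan$down_regions), 1L)  # case is the lower one
  expect_equal(nrow(pan$up_regions), 0L)
})

test_that("a null contrast yields an (almost) empty panel", {
  g <- genome_model()
  ann <- genome_annotation(g)
  tssw <- data.frame(chrom = ann$chrom, start = pmax(0L, ann$tss - 250L),
                     end = ann$tss + 250L)
  set.seed(30)
  sim_group <- function(n, cond) {
    frs <- lapply(seq_len(n), function(i)
      simulate_sample(g, runif(1, 0.08, 0.12), condition = cond,
                      n_reads = 1e5)$fragments)
    structure(list(group_label = cond, mean_ff = 0.1, n_samples = n,
                   fragments = as.data.frame(data.table::rbindlist(frs)),
                   total_reads = n * 1e5), class = "group_library")
  }
  pan <- build_panel(sim_group(20, "control"), sim_group(30, "control"), tssw)
  expect_lte(nrow(pan$up_regions) + nrow(pan$down_regions), 2L)
})

test_that("planted case effects are recovered with the correct sign", {
  g <- genome_model()
  ann <- genome_annotation(g)
  tssw <- data.frame(chrom = ann$chrom, start = pmax(0L, ann$tss - 250L),
                     end = ann$tss + 250L)
  set.seed(31)
  sim_group <- function(n, cond) {
    frs <- lapply(seq_len(n), function(i)
      simulate_sample(g, runif(1, 0.08, 0.12), condition = cond,
                      n_reads = 2e5)$fragments)
    structure(list(group_label = cond, mean_ff = 0.1, n_samples = n,
                   fragments = as.data.frame(data.table::rbindlist(frs)),
                   total_reads = n * 2e5), class = "group_library")
  }
  pan <- build_panel(sim_group(40, "case"), sim_group(100, "control"), tssw)
  truth <- planted_panel(g)
  key <- function(df) paste(df$chrom, df$start)
  n_ok <- sum(key(truth)[truth$direction == "up"] %in% key(pan$up_regions)) +
    sum(key(truth)[truth$direction == "down"] %in% key(pan$down_regions))
  expect_gte(n_ok, 16)
})

test_that("signed sum arithmetic follows the stated rule", {
  expect_equal(signed_sum(numeric(0), numeric(0)), 0)
  expect_equal(signed_sum(c(2, 3), 4), 1)
  expect_equal(signed_sum(c(2, 3)), sum(c(2, 3)))  # empty down set
})

test_that("scoring standardizes, shifts by 4 and clamps at zero", {
  set.seed(32)
  S <- rnorm(200)
  sc <- score_cohort(S)
  expect_equal(sc$adjusted, pmax(0, sc$z + 4))
  expect_equal(sc$z, (S - mean(S)) / sd(S))
  # the adjustment rule on stated values: z = -6 clamps to 0, and a
  # standardized score of 1.596447 reports as 5.596447
  S2 <- c(-6, 1.596447, rnorm(100))
  sc2 <- score_cohort(S2)
  expect_equal(sc2$adjusted[sc2$z <= -4], rep(0, sum(sc2$z <= -4)))
  expect_equal(pmax(0, c(-6, 1.596447) + 4), c(0, 5.596447))
  expect_error(score_cohort(rep(1, 50)), "sigma")
})

test_that("blind and control-only references give the same sample ranking", {
  set.seed(33)
  S <- c(rnorm(990), rnorm(10, mean = 6))  # 1% contaminated cohort
  labels <- c(rep("control", 990), rep("case", 10))
  blind <- score_cohort(S, reference = "blind_all")
  ctrl <- score_cohort(S, reference = "labeled_controls", labels = labels)
  expect_identical(order(blind$z), order(ctrl$z))
})

test_that("quantile calling matches an order-statistic oracle", {
  set.seed(34)
  x <- rnorm(300)
  got <- call_by_quantile(x, q = 0.99)
  # independent type-7 quantile: interpolate the order statistics
  s <- sort(x); h <- (length(x) - 1) * 0.99 + 1
  thr <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(got$threshold, thr, tolerance = 1e-12)
  expect_equal(got$called, x > thr)

  # 100 distinct scores: only the maximum exceeds the 99% threshold
  y <- sample(1:100)
  cl <- call_by_quantile(y, 0.99)
  expect_equal(sum(cl$called), 1L)
  expect_true(cl$called[which.max(y)])
  # all-equal scores: nobody is called (strict inequality)
  expect_equal(sum(call_by_quantile(rep(2.5, 150))$called), 0L)
})

test_that("PPV excludes unknown outcomes from the denominator", {
  # 15 called, 3 lost to follow-up; all 12 evaluable confirmed for one
  # outcome, 3 of 12 for another
  called <- rep(TRUE, 15)
  outcomes <- c(rep(NA, 3), rep("hypothyroidism", 12))
  r <- evaluate_ppv(called, outcomes)
  expect_equal(r$n_evaluable, 12L)
  expect_equal(r$ppv$ppv[r$ppv$outcome == "hypothyroidism"], 1.0)

  outcomes2 <- c(rep(NA, 3), rep("preeclampsia", 3), rep("none", 9))
  r2 <- evaluate_ppv(called, outcomes2)
  expect_equal(r2$ppv$ppv[r2$ppv$outcome == "preeclampsia"], 0.25)

  r3 <- evaluate_ppv(rep(FALSE, 5), rep("none", 5))
  expect_true(is.na(r3$ppv))
  expect_equal(r3$n_called, 0L)
})
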