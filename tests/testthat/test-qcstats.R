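test_that("QC windows keep, reclassify and flag droplets per class", {
  s <- data.frame(
    class = c("SINGLE", "SINGLE", "SINGLE", "EMPTY", "EMPTY", "MULTI",
              "SINGLE"),
    delta_ph = c(0.50, 1.20, 0.10, 0.20, 0.50, 0.90, NA))
  out <- apply_qc(s)
  expect_equal(out$summaries$qc_status,
               c("kept", "reclassified_multi", "reclassified_empty", "kept",
                 "error_hidden_cell", "kept", "excluded_no_trace"))
  expect_equal(out$summaries$qc_class[2], "MULTI")
  expect_equal(out$summaries$qc_class[3], "EMPTY")
  # partition is exhaustive and exclusive
  expect_equal(sum(out$report$kept + out$report$reclassified +
                     out$report$excluded), nrow(s))
})

test_that("QC partition equals a brute-force recount on random summaries", {
  set.seed(91)
  n <- 10000
  s <- data.frame(
    class = sample(c("SINGLE", "EMPTY", "MULTI"), n, replace = TRUE),
    delta_ph = round(runif(n, -0.1, 1.3), 3))
  s$delta_ph[sample(n, 200)] <- NA
  th <- qc_thresholds()
  out <- apply_qc(s, th)$summaries
  # independent recount with plain logical arithmetic
  single <- s$class == "SINGLE" & !is.na(s$delta_ph)
  empty <- s$class == "EMPTY" & !is.na(s$delta_ph)
  expect_equal(sum(out$qc_status == "reclassified_empty"),
               sum(single & s$delta_ph < th$single_min))
  expect_equal(sum(out$qc_status == "reclassified_multi"),
               sum(single & s$delta_ph > th$single_max))
  expect_equal(sum(out$qc_status == "error_hidden_cell"),
               sum(empty & s$delta_ph > th$empty_max))
  expect_equal(sum(out$qc_status == "excluded_no_trace"),
               sum(is.na(s$delta_ph)))
  expect_equal(sum(out$qc_status == "kept"),
               sum(!is.na(s$delta_ph)) -
                 sum(single & (s$delta_ph < th$single_min |
                                 s$delta_ph > th$single_max)) -
                 sum(empty & s$delta_ph > th$empty_max))
  # every droplet lands in exactly one bin
  expect_equal(length(unique(out$qc_status)) <= 5, TRUE)
  expect_equal(nrow(out), n)
})

test_that("QC reclassification reduces occupancy-classification error", {
  # droplets with known truth whose image class is partly corrupted; dpH
  # distributions on the scale the default windows were derived for
  set.seed(71)
  n <- 3000
  truth <- sample(c("SINGLE", "EMPTY", "MULTI"), n, replace = TRUE,
                  prob = c(0.3, 0.5, 0.2))
  dph <- ifelse(truth == "SINGLE", rnorm(n, 0.60, 0.15),
                ifelse(truth == "EMPTY", rnorm(n, 0.12, 0.07),
                       rnorm(n, 1.30, 0.20)))
  image_class <- truth
  flip <- sample(n, 450)  # image pipeline mistakes
  image_class[flip] <- sample(c("SINGLE", "EMPTY", "MULTI"), 450,
                              replace = TRUE)
  out <- apply_qc(data.frame(class = image_class, delta_ph = dph))$summaries
  before <- mean(image_class != truth)
  evaluable <- out$qc_class != "ERROR"
  after <- mean(out$qc_class[evaluable] != truth[evaluable])
  expect_lt(after, before)
})

test_that("rates match a direct recount", {
  s <- data.frame(
    class = c(rep("SINGLE", 25), rep("EMPTY", 60), rep("MULTI", 15)),
    delta_ph = c(runif(22, 0.3, 1.0), 0.1, 1.5, NA,
                 runif(58, 0, 0.3), 0.5, 0.6,
                 runif(15, 1.0, 2.0)),
    position = rep(1, 100))
  out <- apply_qc(s)
  r <- qc_rates(out$summaries)
  pooled <- r[r$position == "pooled", ]
  expect_equal(pooled$kept_single, 22)
  expect_equal(pooled$encapsulation_efficiency, 22 / 100)
  expect_equal(pooled$single_error_rate, 2 / 24)
  expect_equal(pooled$empty_error_rate, 2 / 60)
})

test_that("crosstalk ratio is 1 for identical populations and flat without leakage", {
  times <- seq(0, 180, by = 5)
  nt <- length(times)
  base <- matrix(rep(1000 + 2 * times, each = 6), 6)
  pop <- list(F600 = base, F667 = base * 0.8)
  res <- crosstalk_ratio(pop, pop, times, seed = 1)
  expect_equal(unname(res$ratio[, "F600"]), rep(1, nt), tolerance = 1e-12)
  expect_true(all(res$stable))

  # stable distinct populations: flat ratio, stable verdict over 37 frames
  set.seed(5)
  pos <- list(F600 = matrix(rnorm(10 * nt, 5000, 50), 10),
              F667 = matrix(rnorm(10 * nt, 4000, 50), 10))
  neg <- list(F600 = matrix(rnorm(10 * nt, 500, 10), 10),
              F667 = matrix(rnorm(10 * nt, 400, 10), 10))
  res2 <- crosstalk_ratio(pos, neg, times, seed = 2)
  expect_true(all(res2$stable))

  # exponential equilibration (leakage) is detected as drift
  eq <- exp(-times / 60)
  pos3 <- list(F600 = matrix(rep(500 + 4500 * eq, each = 5), 5),
               F667 = matrix(rep(400 + 3600 * eq, each = 5), 5))
  neg3 <- list(F600 = matrix(rep(500 + 4500 * (1 - eq), each = 5), 5),
               F667 = matrix(rep(400 + 3600 * (1 - eq), each = 5), 5))
  res3 <- crosstalk_ratio(pos3, neg3, times, seed = 3)
  expect_false(any(res3$stable))
  expect_error(crosstalk_ratio(list(F600 = matrix(0, 0, 2),
                                    F667 = matrix(0, 0, 2)),
                               neg3, times), "non-empty")
})

test_that("Poisson design reproduces the encapsulation calculation", {
  d <- poisson_design(0, 143)
  expect_equal(d$p_empty, 1)
  expect_equal(d$p_single, 0)

  d2 <- poisson_design(1.2e7, 143)
  expect_equal(d2$lambda, 1.716, tolerance = 1e-12)
  expect_equal(d2$p_empty, exp(-1.716), tolerance = 1e-12)
  expect_equal(round(d2$p_empty, 2), 0.18)
  expect_equal(d2$p_single, 1.716 * exp(-1.716), tolerance = 1e-12)
  expect_equal(round(d2$p_multi, 2), 0.51)

  for (lam in c(0, 0.5, 1.716, 4, 10)) {
    dd <- poisson_design(lam * 1e9, 1)
    expect_equal(dd$p_empty + dd$p_single + dd$p_multi, 1,
                 tolerance = 1e-12)
  }
  expect_error(poisson_design(-1, 143), "concentration")
})

test_that("droplet volume follows the sphere formula in picolitres", {
  expect_equal(droplet_volume(60), pi * 60^3 / 6 / 1000)
  expect_equal(round(droplet_volume(60), 1), 113.1)
  expect_equal(round(droplet_volume(65)), 144)
  expect_equal(droplet_volume(120) / droplet_volume(60), 8)
  expect_error(droplet_volume(0), "diameter")
})

test_that("polydispersity is the diameter CV in percent", {
  expect_equal(polydispersity(rep(60, 10)), 0)
  set.seed(10)
  x <- rnorm(5000, 0, 1)
  x <- (x - mean(x)) / sd(x)  # exact mean 0, sd 1
  d <- 59.9 + 2.4 * x
  expect_equal(round(polydispersity(d), 1), 4.0)
  expect_lt(polydispersity(d + 10), polydispersity(d))
  expect_error(polydispersity(60), "at least 2")
})

test_that("group comparison matches the reference t-test and legend", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  r <- compare_groups(a, b)
  expect_equal(r$p, 1)
  expect_equal(r$symbol, "ns")
  expect_equal(significance_symbol(0.0005), "***")
  expect_equal(significance_symbol(0.005), "**")
  expect_equal(significance_symbol(0.05), "*")
  expect_equal(significance_symbol(0.2), "ns")

  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    ref <- t.test(x, y, var.equal = TRUE)
    got <- compare_groups(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
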