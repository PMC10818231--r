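test_that("confusion cells tally the four joint label combinations", {
  ids <- sprintf("id%02d", 1:10)
  lab <- label_frame(ids, rep(c("fraud", "valid"), c(6, 4)))
  cm <- build_confusion(lab, lab)
  expect_equal(c(cm$a, cm$b, cm$c, cm$d), c(6, 0, 0, 4))
  flipped <- label_frame(ids, ifelse(lab$label == "fraud", "valid", "fraud"))
  cm2 <- build_confusion(lab, flipped)
  expect_equal(cm2$b + cm2$c, cm2$n)

  set.seed(17)
  ids50 <- sprintf("id%02d", 1:50)
  la <- label_frame(ids50, sample(c("fraud", "valid"), 50, replace = TRUE))
  lb <- label_frame(ids50, sample(c("fraud", "valid"), 50, replace = TRUE))
  cm3 <- build_confusion(la, lb)
  # direct enumeration oracle
  joint <- table(la$label, lb$label)
  expect_equal(cm3$a, joint["fraud", "fraud"][[1]])
  expect_equal(cm3$b, joint["fraud", "valid"][[1]])
  expect_equal(cm3$c, joint["valid", "fraud"][[1]])
  expect_equal(cm3$d, joint["valid", "valid"][[1]])

  expect_error(build_confusion(la, lb[-1, ]), "different",
               class = "surveysieve_data_error")
})

test_that("kappa follows from po and pe with the marginal-product formula", {
  # hand oracle computed straight from the definitions
  oracle <- function(a, b, c, d) {
    n <- a + b + c + d
    po <- (a + d) / n
    pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
    list(kappa = (po - pe) / (1 - pe),
         se = sqrt(po * (1 - po) / (n * (1 - pe)^2)))
  }
  set.seed(4)
  for (i in 1:10) {
    cells <- rpois(4, 40) + 1
    k <- cohen_kappa(confusion_2x2(cells[1], cells[2], cells[3], cells[4]))
    o <- oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(k$kappa, o$kappa)
    expect_equal(k$se, o$se)
    expect_equal(k$ci_low, o$kappa - qnorm(0.975) * o$se)
  }
  expect_equal(cohen_kappa(confusion_2x2(10, 0, 0, 10))$kappa, 1.0)
  expect_equal(cohen_kappa(confusion_2x2(25, 25, 25, 25))$kappa, 0.0)
})

test_that("kappa is invariant under a simultaneous label swap", {
  set.seed(12)
  for (i in 1:8) {
    cells <- rpois(4, 30) + 1
    k1 <- cohen_kappa(confusion_2x2(cells[1], cells[2], cells[3], cells[4]))
    k2 <- cohen_kappa(confusion_2x2(cells[4], cells[3], cells[2], cells[1]))
    expect_equal(k1$kappa, k2$kappa)
    expect_true(k1$kappa <= k1$po + 1e-12)
  }
})

test_that("kappa = 1 exactly when both off-diagonals vanish", {
  expect_equal(cohen_kappa(confusion_2x2(7, 0, 0, 3))$kappa, 1)
  expect_lt(cohen_kappa(confusion_2x2(7, 1, 0, 3))$kappa, 1)
  expect_lt(cohen_kappa(confusion_2x2(7, 0, 2, 3))$kappa, 1)
})

test_that("kappa is undefined at degenerate marginals", {
  expect_error(cohen_kappa(confusion_2x2(0, 0, 0, 10)),
               class = "surveysieve_degenerate_error")
})

test_that("CI width shrinks as 1/sqrt(n) at fixed cell proportions", {
  k1 <- cohen_kappa(confusion_2x2(30, 20, 10, 40))
  k4 <- cohen_kappa(confusion_2x2(120, 80, 40, 160))
  expect_equal(k4$ci_high - k4$ci_low, (k1$ci_high - k1$ci_low) / 2)
})

test_that("interpretation bands cover both published scales", {
  b <- interpret_kappa(c(0.25, 0.13, 1.0, -0.5, 0.85))
  expect_equal(b$landis_koch,
               c("fair", "slight", "almost perfect", "poor", "almost perfect"))
  expect_equal(b$mchugh, c("minimal", "none", "almost perfect", "none",
                           "strong"))
})

test_that("subgroup mean CI uses the normal half-width", {
  est <- mean_ci_normal(0.5, 0.2, 100)
  expect_equal(est$ci_low, 0.5 - qnorm(0.975) * 0.2 / 10)
  zero <- mean_ci_normal(0.7, 0, 25)
  expect_equal(c(zero$ci_low, zero$ci_high), c(0.7, 0.7))
  expect_error(mean_ci_normal(0.5, 0.2, 0), class = "surveysieve_data_error")
})

test_that("chi-square matches the textbook statistic", {
  flat <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  skewed <- chi_square_test(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(skewed$statistic, 20 / 3)

  set.seed(9)
  tab <- matrix(rpois(6, 25) + 1, nrow = 2)
  got <- chi_square_test(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(got$statistic, stat)
  expect_equal(got$p_value, pchisq(stat, df = 2, lower.tail = FALSE))

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)),
               class = "surveysieve_data_error")
})

test_that("t test is the two-sided Welch test", {
  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  got <- t_test(c(0, 1), c(10, 11))
  # hand Welch: means 0.5/10.5, each variance 0.5 with n = 2, df = 2
  expect_equal(got$statistic, -10 / sqrt(0.5))
  expect_equal(got$p_value, 2 * pt(-10 / sqrt(0.5), df = 2))
  expect_error(t_test(1, c(1, 2)), class = "surveysieve_data_error")
})

test_that("Mann-Whitney exact path equals full enumeration for n <= 10", {
  got <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 2 / 6)

  # enumeration oracle over every assignment of pooled values to x
  enum_oracle <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    nx <- length(x)
    u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    us <- apply(utils::combn(length(pooled), nx), 2,
                function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  set.seed(14)
  for (i in 1:12) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    x <- sample(1:8, nx, replace = TRUE)  # ties included
    y <- sample(1:8, ny, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, enum_oracle(x, y))
  }
  # cross-check against the standard implementation on tie-free data
  x <- c(1.2, 3.4, 5.1)
  y <- c(2.2, 6.3, 7.7, 9.1)
  expect_equal(mann_whitney(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  expect_equal(mann_whitney(x, y)$statistic,
               unname(wilcox.test(x, y, exact = TRUE)$statistic))
})

test_that("tied identical samples give the null U value", {
  x <- c(1, 2, 3)
  expect_equal(mann_whitney(x, x)$statistic, length(x)^2 / 2)
})

test_that("normal approximation tracks a permutation oracle at n = 30", {
  set.seed(26)
  x <- round(rnorm(15, 0, 2), 1)
  y <- round(rnorm(15, 0.8, 2), 1)
  got <- mann_whitney(x, y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- got$statistic
  mu <- length(x) * length(y) / 2
  draws <- replicate(1e5, {
    idx <- sample.int(30, 15)
    sum(r[idx]) - 15 * 16 / 2
  })
  p_perm <- min(1, 2 * min(mean(draws <= u_obs + 1e-9),
                           mean(draws >= u_obs - 1e-9)))
  expect_lt(abs(got$p_value - p_perm), 0.01)
})

test_that("exact and approximate Mann-Whitney paths agree on small data", {
  # exhaustive over every achievable U on tie-free data: the corrected
  # normal approximation stays within 0.02 of the exact p at 5 + 5, and
  # within 0.035 at the boundary size 4 + 4 (where the exact distribution
  # takes steps of ~0.03, so closer agreement is unattainable)
  check_gap <- function(nx, ny, bound) {
    n <- nx + ny
    us <- apply(utils::combn(n, nx), 2, function(idx) sum(idx)) -
      nx * (nx + 1) / 2
    mu <- nx * ny / 2
    sigma2 <- nx * ny * (n + 1) / 12
    for (u in 0:(nx * ny)) {
      p_exact <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
      cc <- min(abs(u - mu), 0.5)
      p_approx <- min(1, 2 * pnorm(-(abs(u - mu) - cc) / sqrt(sigma2)))
      expect_lt(abs(p_exact - p_approx), bound)
    }
  }
  check_gap(5, 5, 0.02)
  check_gap(4, 4, 0.035)
})

test_that("compare_variables dispatches the configured test per variable", {
  set.seed(5)
  resp <- make_responses(40,
    age = c(rnorm(20, 30, 3), rnorm(20, 45, 3)),
    vaccine_confident = rep(c(0, 1), 20))
  labs <- label_frame(resp$response_id, rep(c("fraud", "valid"), each = 20))
  out <- compare_variables(resp, labs,
                           c(age = "t_test",
                             vaccine_confident = "chi_square"))
  expect_equal(out$test, c("t_test", "chi_square"))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_lt(out$p_value[out$variable == "age"], 0.001)
})

test_that("windowed fraud series handles full, empty and stepped days", {
  t0 <- as.POSIXct("2021-11-01 09:00:00", tz = "UTC")
  lab <- tibble::tibble(
    response_id = sprintf("r%02d", 1:20),
    start_time = t0 + c(rep(0, 5), rep(10, 15)) * 86400,
    label = c(rep("fraud", 5), rep("valid", 15)),
    method = "multilayer"
  )
  ser <- fraud_proportion_series(lab, window_days = 1)
  expect_equal(ser$prop[ser$date == as.Date("2021-11-01")], 1.0)
  expect_true(is.na(ser$prop[ser$date == as.Date("2021-11-05")]))
  expect_equal(ser$prop[ser$date == as.Date("2021-11-11")], 0.0)

  # step change, window 3: must equal the brute-force windowed tally
  set.seed(61)
  days <- sample(0:13, 120, replace = TRUE)
  lab2 <- tibble::tibble(
    response_id = sprintf("s%03d", 1:120),
    start_time = t0 + days * 86400,
    label = ifelse(days < 7, "valid",
                   sample(c("fraud", "valid"), 120, replace = TRUE,
                          prob = c(0.8, 0.2))),
    method = "multilayer"
  )
  ser2 <- fraud_proportion_series(lab2, window_days = 3)
  for (d in unique(ser2$date)) {
    inside <- abs(as.numeric(as.Date(lab2$start_time)) - as.numeric(d)) <= 1
    want <- if (!any(inside)) NA_real_ else mean(lab2$label[inside] == "fraud")
    expect_equal(ser2$prop[ser2$date == d], want)
  }
})
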