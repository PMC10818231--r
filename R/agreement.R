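#' Cross-classify two binary fraud classifications
#'
#' Builds the 2x2 confusion (classification) table between two methods'
#' labels over the same responses: `a` = both fraud, `b` = A fraud / B valid,
#' `c` = A valid / B fraud, `d` = both valid.
#'
#' @param labels_a,labels_b Data frames with columns `response_id` and
#'   `label` (values `"fraud"`/`"valid"`), or the result objects of
#'   [run_pipeline()] stages (anything [tidy()]-able to that shape). The two
#'   id sets must coincide.
#' @param cells Alternatively, build directly from counts:
#'   `confusion_2x2(a, b, c, d)`.
#' @return A `confusion_2x2` object with fields `a`, `b`, `c`, `d`, `n`.
#' @seealso [cohen_kappa()]
#' @export
build_confusion <- function(labels_a, labels_b) {
  la <- as_label_frame(labels_a)
  lb <- as_label_frame(labels_b)
  only_a <- setdiff(la$response_id, lb$response_id)
  only_b <- setdiff(lb$response_id, la$response_id)
  if (length(only_a) + length(only_b) > 0) {
    abort(paste0(
      "Label sets cover different responses. Only in A: ",
      paste(utils::head(only_a, 5), collapse = ", "), "; only in B: ",
      paste(utils::head(only_b, 5), collapse = ", ")),
      class = "surveysieve_data_error")
  }
  m <- la %>%
    left_join(lb, by = "response_id", suffix = c("_a", "_b"))
  confusion_2x2(
    a = sum(m$label_a == "fraud" & m$label_b == "fraud"),
    b = sum(m$label_a == "fraud" & m$label_b == "valid"),
    c = sum(m$label_a == "valid" & m$label_b == "fraud"),
    d = sum(m$label_a == "valid" & m$label_b == "valid")
  )
}

as_label_frame <- function(x) {
  if (inherits(x, c("realtime_result", "posthoc_result", "platform_result",
                    "fraud_pipeline"))) {
    x <- tidy(x)
  }
  x <- as_tibble(x)
  stopifnot(all(c("response_id", "label") %in% names(x)))
  stopifnot(all(x$label %in% c("fraud", "valid")))
  x[c("response_id", "label")]
}

#' @rdname build_confusion
#' @param a,b,c,d Cell counts (A fraud/B fraud, A fraud/B valid,
#'   A valid/B fraud, A valid/B valid).
#' @export
confusion_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || sum(cells) == 0) {
    abort("Confusion cells must be nonnegative with a positive total.",
          class = "surveysieve_data_error")
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat("<confusion_2x2>  n =", x$n, "\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("A fraud", "A valid"),
                              c("B fraud", "B valid")))
  print(m)
  invisible(x)
}

#' @export
tidy.confusion_2x2 <- function(x, ...) {
  tibble(
    label_a = c("fraud", "fraud", "valid", "valid"),
    label_b = c("fraud", "valid", "fraud", "valid"),
    n = c(x$a, x$b, x$c, x$d)
  )
}

#' Cohen's kappa for two binary classifiers
#'
#' Chance-corrected agreement between the two methods of a
#' [confusion_2x2()]: observed agreement `po = (a + d) / n`, chance
#' agreement from the marginals
#' `pe = ((a+b)/n)((a+c)/n) + ((c+d)/n)((b+d)/n)`, and
#' `kappa = (po - pe) / (1 - pe)`. The standard error uses
#' `se = sqrt(po (1 - po) / (n (1 - pe)^2))` and the interval
#' `kappa +/- z se` at the requested confidence.
#'
#' @param cm A `confusion_2x2` (or anything [build_confusion()] accepts as a
#'   pair via `labels_b`).
#' @param confidence Interval coverage, default 0.95.
#' @return A `kappa_result` with `po`, `pe`, `kappa`, `se`, `ci_low`,
#'   `ci_high`, `confidence`, `n`, and the two qualitative bands of
#'   [interpret_kappa()]. [tidy()] returns it as a one-row tibble.
#' @examples
#' cohen_kappa(confusion_2x2(2627, 934, 2095, 2294))
#' @export
cohen_kappa <- function(cm, confidence = 0.95) {
  stopifnot(inherits(cm, "confusion_2x2"))
  n <- cm$n
  po <- (cm$a + cm$d) / n
  pe <- ((cm$a + cm$b) / n) * ((cm$a + cm$c) / n) +
    ((cm$c + cm$d) / n) * ((cm$b + cm$d) / n)
  if (1 - pe < .Machine$double.eps^0.5) {
    abort("kappa is undefined: chance agreement pe = 1 (degenerate marginals).",
          class = "surveysieve_degenerate_error")
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - confidence) / 2)
  bands <- interpret_kappa(kappa)
  structure(
    list(po = po, pe = pe, kappa = kappa, se = se,
         ci_low = kappa - z * se, ci_high = kappa + z * se,
         confidence = confidence, n = n,
         landis_koch = bands$landis_koch, mchugh = bands$mchugh),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa = %.2f (%g%% CI %.2f-%.2f), n = %d\n",
    x$kappa, 100 * x$confidence, x$ci_low, x$ci_high, x$n))
  cat(sprintf("  po = %.4f, pe = %.4f, se = %.4f\n", x$po, x$pe, x$se))
  cat(sprintf("  agreement: \"%s\" (Landis-Koch) / \"%s\" (McHugh)\n",
              x$landis_koch, x$mchugh))
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
         po = x$po, pe = x$pe, n = x$n, confidence = x$confidence,
         landis_koch = x$landis_koch, mchugh = x$mchugh)
}

#' @export
glance.kappa_result <- function(x, ...) tidy(x)

#' Qualitative interpretation bands for kappa
#'
#' Maps kappa values onto the two conventional qualitative scales. The
#' Landis-Koch scale uses cutpoints 0, 0.20, 0.40, 0.60, 0.80 (slight, fair,
#' moderate, substantial, almost perfect; below 0 poor). The McHugh scale
#' uses 0.20, 0.39, 0.59, 0.79, 0.90 (none, minimal, weak, moderate, strong,
#' almost perfect).
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Tibble with columns `kappa`, `landis_koch`, `mchugh`.
#' @examples
#' interpret_kappa(c(0.25, 0.13, 1.0))
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1))
  band <- function(k, cuts, labels) {
    # value at a cutpoint belongs to the band the cutpoint closes
    labels[findInterval(k, cuts, left.open = TRUE) + 1L]
  }
  lk <- band(kappa, c(0 - 1e-12, 0.20, 0.40, 0.60, 0.80),
             c("poor", "slight", "fair", "moderate", "substantial",
               "almost perfect"))
  mh <- band(kappa, c(0.20, 0.39, 0.59, 0.79, 0.90),
             c("none", "minimal", "weak", "moderate", "strong",
               "almost perfect"))
  tibble(kappa = kappa, landis_koch = lk, mchugh = mh)
}

#' Normal-approximation confidence interval for a subgroup mean
#'
#' Computes `mean +/- z * sd / sqrt(n)` with `z` the standard-normal
#' quantile (1.96 at 95%), the interval used for subgroup point estimates
#' such as vaccine confidence by racial or ethnic group.
#'
#' @param mean,sd,n Vectors of subgroup mean, standard deviation and size.
#' @param confidence Coverage, default 0.95.
#' @param group Optional vector of group labels.
#' @return Tibble `group`, `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#' @examples
#' mean_ci_normal(0.80, 0.40, 571)
#' @export
mean_ci_normal <- function(mean, sd, n, confidence = 0.95, group = NA) {
  if (any(n < 1)) {
    abort("`n` must be at least 1.", class = "surveysieve_data_error")
  }
  stopifnot(all(sd >= 0))
  z <- qnorm(1 - (1 - confidence) / 2)
  half <- z * sd / sqrt(n)
  tibble(group = group, n = as.integer(n), mean = mean, sd = sd,
         ci_low = mean - half, ci_high = mean + half)
}

#' Fraud-vs-valid group comparison tests
#'
#' Thin wrappers returning the uniform one-row comparison shape
#' (`variable`, `test`, `statistic`, `p_value`) used when contrasting
#' fraud-labeled against valid-labeled responses on study variables:
#' Pearson chi-square for categorical variables (no continuity correction by
#' default), Welch two-sample t for normally distributed continuous
#' variables, and Mann-Whitney U otherwise.
#'
#' `mann_whitney()` computes the U statistic for the first sample from rank
#' sums. Its two-sided p-value uses exact enumeration over all assignments of
#' the pooled values when `length(x) + length(y) <= 10` (ties included, via
#' `combn`), and otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param table A 2-row contingency matrix (2 x k counts) for
#'   `chi_square_test()`.
#' @param x,y Numeric samples.
#' @param variable Label recorded in the output.
#' @param correct Yates continuity correction for the chi-square test.
#' @return One-row tibble `variable`, `test`, `statistic`, `p_value`.
#' @examples
#' chi_square_test(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
chi_square_test <- function(table, variable = NA_character_,
                            correct = FALSE) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) {
    abort("Zero expected cell count; merge sparse categories first.",
          class = "surveysieve_data_error")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble(variable = variable, test = "chi_square",
         statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' @rdname chi_square_test
#' @export
t_test <- function(x, y, variable = NA_character_) {
  if (length(x) < 2 || length(y) < 2) {
    abort("t_test needs at least 2 observations per group.",
          class = "surveysieve_data_error")
  }
  ht <- stats::t.test(x, y)  # Welch, two-sided
  tibble(variable = variable, test = "t_test",
         statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' @rdname chi_square_test
#' @export
mann_whitney <- function(x, y, variable = NA_character_) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= 10) {
    p <- mw_exact_p(pooled, nx, u)
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence either way
    } else {
      cc <- min(abs(u - mu), 0.5)  # continuity correction
      p <- min(1, 2 * pnorm(-(abs(u - mu) - cc) / sqrt(sigma2)))
    }
  }
  tibble(variable = variable, test = "mann_whitney",
         statistic = u, p_value = p)
}

# exact two-sided p by full enumeration of which pooled positions form x;
# two-sided p doubles the smaller tail (capped at 1)
mw_exact_p <- function(pooled, nx, u_obs) {
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  lower <- mean(us <= u_obs + 1e-9)
  upper <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

#' Compare labeled groups across configured study variables
#'
#' Runs, for each configured variable, the appropriate fraud-vs-valid
#' comparison over a labeled response table: chi-square for categorical
#' variables, Welch t for normal continuous, Mann-Whitney otherwise.
#'
#' @param responses Response tibble.
#' @param labels Label frame (`response_id`, `label`) or a result object.
#' @param variables Named character vector: column name -> test
#'   (`"chi_square"`, `"t_test"` or `"mann_whitney"`).
#' @return Tibble with one row per variable.
#' @export
compare_variables <- function(responses, labels, variables) {
  lf <- as_label_frame(labels)
  merged <- left_join(responses, lf, by = "response_id")
  rows <- lapply(names(variables), function(v) {
    test <- variables[[v]]
    vals <- merged[[v]]
    lab <- merged$label
    keep <- !is.na(vals) & !is.na(lab)
    vals <- vals[keep]
    lab <- lab[keep]
    if (test == "chi_square") {
      chi_square_test(table(lab, vals), variable = v)
    } else {
      x <- as.numeric(vals[lab == "fraud"])
      y <- as.numeric(vals[lab == "valid"])
      if (test == "t_test") t_test(x, y, variable = v)
      else mann_whitney(x, y, variable = v)
    }
  })
  bind_rows(rows)
}
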