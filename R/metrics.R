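# Evaluation framework: generation / hallucination / effective rates
# with confidence intervals, paired McNemar comparison of two mappers,
# domain-stratified accuracy, cohort set-concordance (Jaccard, overlap
# coefficient), and dual-rater score aggregation with Cohen's kappa.

input_err <- function(msg)
  stop(structure(class = c("trialsql_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))

#' Effective SQL generation rate
#'
#' `generation_rate * (1 - hallucination_rate)`: the fraction of attempts
#' that yield a syntactically valid and hallucination-free query.
#'
#' @param generation_rate,hallucination_rate Proportions in `[0, 1]`.
#' @return The effective rate, in `[0, 1]`.
#' @examples
#' effective_rate(0.958, 0.263)
#' @export
effective_rate <- function(generation_rate, hallucination_rate) {
  if (any(generation_rate < 0 | generation_rate > 1) ||
      any(hallucination_rate < 0 | hallucination_rate > 1))
    input_err("rates must lie in [0, 1]")
  generation_rate * (1 - hallucination_rate)
}

#' Binomial rate with a 95% confidence interval
#'
#' Default interval is the Wald normal approximation
#' `p ± 1.96 sqrt(p(1-p)/n)`, clipped to `[0, 1]`; the better-behaved
#' Wilson score interval is available via `method = "wilson"`.
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @param method `"wald"` or `"wilson"`.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `rate_report`: `numerator`, `denominator`,
#'   `rate`, `ci95 = c(low, high)`, `method`.
#' @examples
#' rate_with_ci(249, 760)
#' @export
rate_with_ci <- function(k, n, method = c("wald", "wilson"), conf = 0.95) {
  method <- match.arg(method)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) || n <= 0 ||
      k < 0 || k > n)
    input_err("need 0 <= k <= n with n > 0")
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(max(0, p - half), min(1, p + half))
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    ci <- c(max(0, centre - half), min(1, centre + half))
  }
  out <- list(numerator = k, denominator = n, rate = p, ci95 = ci,
              method = method)
  class(out) <- "rate_report"
  out
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (95%% CI %.1f%%-%.1f%%, %s)\n",
              x$numerator, x$denominator, 100 * x$rate,
              100 * x$ci95[1], 100 * x$ci95[2], x$method))
  invisible(x)
}

#' Construct a paired 2x2 mapping-correctness table
#'
#' @param both_correct,sys1_only,sys2_only,both_wrong Cell counts
#'   (`sys1_only` = system 1 correct where system 2 is wrong, etc.).
#' @return A list of class `paired_mapping_table` with the four cells and
#'   `total`.
#' @export
paired_mapping_table <- function(both_correct, sys1_only, sys2_only, both_wrong) {
  cells <- c(both_correct = both_correct, sys1_only = sys1_only,
             sys2_only = sys2_only, both_wrong = both_wrong)
  if (any(cells < 0) || any(cells != round(cells)))
    input_err("cell counts must be non-negative integers")
  out <- as.list(cells)
  out$total <- sum(cells)
  class(out) <- "paired_mapping_table"
  out
}

#' Mapping accuracy from a paired table, with optional domain strata
#'
#' Per-system accuracies from the paired 2x2 table (system 1 accuracy =
#' (both_correct + sys1_only) / total), the rescue rate - the share of
#' terms system 2 got wrong that system 1 mapped correctly,
#' `sys1_only / (sys1_only + both_wrong)` - and, if supplied,
#' domain-stratified accuracies.
#'
#' @param table A [paired_mapping_table()].
#' @param domain_strata Optional data.frame with columns `domain`,
#'   `correct`, `total`.
#' @return A list with `sys1`, `sys2`, `rescue` (each a `rate_report`)
#'   and `strata` (data.frame with a `rate` column, or `NULL`).
#' @examples
#' tab <- paired_mapping_table(112, 61, 2, 182)
#' mapping_accuracy(tab)$sys1$rate
#' @export
mapping_accuracy <- function(table, domain_strata = NULL) {
  stopifnot(inherits(table, "paired_mapping_table"))
  if (table$total == 0) input_err("empty paired table")
  out <- list(
    sys1 = rate_with_ci(table$both_correct + table$sys1_only, table$total),
    sys2 = rate_with_ci(table$both_correct + table$sys2_only, table$total),
    rescue = if (table$sys1_only + table$both_wrong > 0)
      rate_with_ci(table$sys1_only, table$sys1_only + table$both_wrong)
    else NULL,
    strata = NULL)
  if (!is.null(domain_strata)) {
    stopifnot(all(c("domain", "correct", "total") %in% names(domain_strata)))
    if (any(domain_strata$total <= 0)) input_err("zero stratum total")
    domain_strata$rate <- domain_strata$correct / domain_strata$total
    out$strata <- domain_strata
  }
  out
}

#' McNemar test on the discordant cells of a paired table
#'
#' Compares two mappers on paired binary outcomes.  The default is the
#' uncorrected chi-squared statistic `(b - c)^2 / (b + c)` on the
#' discordant cells with df = 1 (delegated to [stats::mcnemar.test()]);
#' `correction = TRUE` applies the continuity correction, and
#' `exact = TRUE` uses the exact binomial test (recommended for small
#' discordant counts).
#'
#' @param table A [paired_mapping_table()].
#' @param correction Apply continuity correction (chi-squared variants).
#' @param exact Use the exact binomial test instead.
#' @return A list with `statistic` (`NA` for exact), `p_value`, `b`, `c`,
#'   `method`.
#' @examples
#' mcnemar_test(paired_mapping_table(112, 61, 2, 182))
#' @export
mcnemar_test <- function(table, correction = FALSE, exact = FALSE) {
  stopifnot(inherits(table, "paired_mapping_table"))
  b <- table$sys1_only
  cc <- table$sys2_only
  if (b + cc == 0)
    stop(structure(class = c("trialsql_degenerate_input", "error", "condition"),
                   list(message = "no discordant pairs: McNemar test undefined",
                        call = NULL)))
  if (exact) {
    p <- stats::binom.test(b, b + cc, p = 0.5)$p.value
    return(list(statistic = NA_real_, p_value = p, b = b, c = cc,
                method = "exact binomial"))
  }
  m <- matrix(c(table$both_correct, cc, b, table$both_wrong), nrow = 2)
  ht <- stats::mcnemar.test(m, correct = correction)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, b = b, c = cc,
       method = if (correction) "chi-squared, continuity-corrected"
                else "chi-squared")
}

#' Cohort set-concordance metrics
#'
#' Jaccard index `|A ∩ B| / |A ∪ B|` and overlap coefficient
#' `|A ∩ B| / min(|A|, |B|)` over two patient-ID sets.  A perfect
#' overlap with a low Jaccard signals a correct-but-incomplete cohort
#' (the retrieved patients all belong to the reference set, but most of
#' the reference set is missed).  If either set is empty both metrics
#' are 0, with a warning - the documented convention for complete
#' retrieval failure.
#'
#' @param set_a,set_b Vectors of person IDs (duplicates ignored).
#' @return A list of class `cohort_pair_metrics`: `n_a`, `n_b`,
#'   `n_intersection`, `n_union`, `jaccard`, `overlap`.
#' @examples
#' cohort_concordance(1:3, 1:100)   # subset: overlap 1, jaccard 0.03
#' @export
cohort_concordance <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0L || length(b) == 0L) {
    warning("empty cohort: concordance metrics set to 0")
    out <- list(n_a = length(a), n_b = length(b), n_intersection = 0L,
                n_union = length(a) + length(b), jaccard = 0, overlap = 0)
    class(out) <- "cohort_pair_metrics"
    return(out)
  }
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  out <- list(n_a = length(a), n_b = length(b), n_intersection = i,
              n_union = u, jaccard = i / u, overlap = i / min(length(a), length(b)))
  class(out) <- "cohort_pair_metrics"
  out
}

#' Unweighted Cohen's kappa for two raters
#'
#' @param r1,r2 Equal-length rating vectors (coerced to a common factor).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) > 0)
  lev <- sort(unique(c(r1, r2)))
  t1 <- factor(r1, levels = lev)
  t2 <- factor(r2, levels = lev)
  tab <- table(t1, t2) / length(r1)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Aggregate a dual-rater expert score sheet
#'
#' Items are scored independently by two raters on a 4-point compliance
#' scale (1 = noncompliant, 4 = fully compliant); the item score is the
#' average of the two ratings.  Scores roll up to dimension means ± SD,
#' and inter-rater agreement is unweighted Cohen's kappa over the raw
#' 4-level labels.
#'
#' @param sheet data.frame with columns `criterion_id`, `dimension`,
#'   `rater1`, `rater2` (integer scores 1-4).
#' @return A list with `items` (the sheet plus `item_mean`),
#'   `dimensions` (data.frame: dimension, mean, sd, n) and `kappa`.
#' @export
aggregate_expert_scores <- function(sheet) {
  req <- c("criterion_id", "dimension", "rater1", "rater2")
  stopifnot(all(req %in% names(sheet)), nrow(sheet) >= 1)
  if (all(is.na(sheet$rater2)))
    stop(structure(class = c("trialsql_input_error", "error", "condition"),
                   list(message = "kappa undefined with a single rater", call = NULL)))
  ok <- function(x) all(x %in% 1:4)
  if (!ok(sheet$rater1) || !ok(sheet$rater2))
    input_err("ratings must be integers 1-4")
  sheet$item_mean <- (sheet$rater1 + sheet$rater2) / 2
  dims <- do.call(rbind, lapply(split(sheet, sheet$dimension), function(d)
    data.frame(dimension = d$dimension[1], mean = mean(d$item_mean),
               sd = stats::sd(d$item_mean), n = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(dims) <- NULL
  list(items = sheet, dimensions = dims,
       kappa = cohen_kappa(sheet$rater1, sheet$rater2))
}
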