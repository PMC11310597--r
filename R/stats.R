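## Disproportionality statistics on 2x2 contingency tables.
##
## For a target exposure group and target event, the table is
##        event   other
##  grp     a       b
##  rest    c       d
## ROR = (a d)/(b c) with a Wald interval on the log scale; IC is the
## shrunk log2 observed-to-expected ratio of the BCPNN family, with either
## the credible-interval approximation of Noren et al. or a normal
## interval from the closed-form BCPNN posterior variance (Bate et al.).

#' Construct a 2x2 contingency table
#'
#' @param a Reports with target drug and target event.
#' @param b Reports with target drug, other events.
#' @param c Reports with other drugs and target event.
#' @param d Reports with other drugs, other events.
#' @return A `contingency_table` (named list with `a`, `b`, `c`, `d`, `n`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) <= 0) stop("empty table (N = 0)", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

#' Build the 2x2 table for an exposure group and event
#'
#' With the `rest_of_store` comparator, the non-exposed cells `c`, `d`
#' come from all other reports in the store. The `explicit` comparator
#' takes `c`, `d` from `background` instead, for running a retrieved
#' subset against a full-database background whose totals are known only
#' as counts.
#'
#' The counting unit is the report for term-set events (one case
#' contributes 1 to `a` however many of its PTs match) and the
#' (report, PT) pair for single-PT events, matching how drug-level and
#' PT-level disproportionality are conventionally tabulated.
#'
#' @param store A `faers_store` labeled by [assign_groups()].
#' @param group One or more exposure labels forming the index group.
#' @param event An [smq_terms()] set, or a single PT string.
#' @param comparator `"rest_of_store"` or `"explicit"`.
#' @param background Length-2 numeric `c(c, d)` when `comparator` is
#'   `"explicit"`.
#' @param unit `"report"` or `"report_pt"`; default depends on `event` as
#'   described above.
#' @return A `contingency_table`.
#' @export
build_table <- function(store, group, event,
                        comparator = c("rest_of_store", "explicit"),
                        background = NULL, unit = NULL) {
  stopifnot(inherits(store, "faers_store"))
  comparator <- match.arg(comparator)
  if (!("group" %in% names(store$demo))) {
    stop("store has no exposure labels; run assign_groups() first",
         call. = FALSE)
  }
  demo <- store$demo
  in_group <- demo$group %in% group
  if (!any(in_group)) stop("no exposed reports", call. = FALSE)

  if (inherits(event, "smq_terms")) {
    unit <- unit %||% "report"
    target_keys <- event$keys
  } else if (is.character(event) && length(event) >= 1L) {
    unit <- unit %||% "report_pt"
    target_keys <- unique(norm_key(event))
  } else {
    stop("event must be an smq_terms set or PT string(s)", call. = FALSE)
  }

  if (unit == "report") {
    case_ids <- unique(
      store$reactions[norm_key(pt) %in% target_keys, primaryid])
    is_case <- demo$primaryid %in% case_ids
    a <- sum(in_group & is_case); b <- sum(in_group & !is_case)
    cc <- sum(!in_group & is_case); dd <- sum(!in_group & !is_case)
  } else {
    pairs <- unique(store$reactions[, .(primaryid, key = norm_key(pt))])
    pair_in_group <- pairs$primaryid %in% demo$primaryid[in_group]
    pair_is_target <- pairs$key %in% target_keys
    a <- sum(pair_in_group & pair_is_target)
    b <- sum(pair_in_group & !pair_is_target)
    cc <- sum(!pair_in_group & pair_is_target)
    dd <- sum(!pair_in_group & !pair_is_target)
  }
  if (comparator == "explicit") {
    if (is.null(background) || length(background) != 2L) {
      stop("explicit comparator needs background = c(c, d)", call. = FALSE)
    }
    cc <- background[[1L]]; dd <- background[[2L]]
  }
  contingency_table(a, b, cc, dd)
}

#' Reporting odds ratio with 95\% confidence interval
#'
#' ROR = (a d)/(b c); the interval is
#' exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). With a zero cell the
#' estimate is undefined, so the Haldane-Anscombe correction (0.5 added
#' to every cell) is applied; by default it is applied exactly when some
#' cell is zero, and whether it was applied is returned.
#'
#' @param table A [contingency_table()].
#' @param z Normal quantile for the interval (1.96 for 95\%).
#' @param haldane `NULL` (default: apply only when a cell is zero),
#'   `TRUE` (always) or `FALSE` (never; zero cells then raise an error).
#' @return List with `ror`, `ror_low`, `ror_high`, `haldane_applied`.
#' @export
#' @examples
#' ror(contingency_table(10, 90, 100, 900))
ror <- function(table, z = stats::qnorm(0.975), haldane = NULL) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  any_zero <- any(cells == 0)
  apply_h <- if (is.null(haldane)) any_zero else isTRUE(haldane)
  if (!apply_h && any_zero) {
    stop("zero cell in 2x2 table; use haldane = TRUE (adds 0.5 to each cell)",
         call. = FALSE)
  }
  if (apply_h) cells <- cells + 0.5
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = est,
       ror_low = exp(log(est) - z * se),
       ror_high = exp(log(est) + z * se),
       haldane_applied = apply_h)
}

## Closed-form variance of the IC posterior (Bate et al. 1998 priors:
## alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1)
bate_ic_variance <- function(a, b, c, d) {
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
  v <- (n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
    (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
    (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be))
  v / log(2)^2
}

#' Information component with 95\% interval
#'
#' The IC is the shrunk log2 ratio of observed to expected co-reporting
#' under independence: with E = (a+b)(a+c)/N,
#' IC = log2((a + 0.5)/(E + 0.5)). The default interval is the credible
#' interval approximation of Noren et al.:
#' IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2),
#' IC975 = IC + 2.4 (a+0.5)^(-1/2) - 0.5 (a+0.5)^(-3/2).
#' `method = "bate_variance"` instead uses a normal interval from the
#' closed-form BCPNN posterior variance.
#'
#' @param table A [contingency_table()].
#' @param method `"noren_credible"` (default) or `"bate_variance"`.
#' @param z Normal quantile used by the `bate_variance` interval.
#' @return List with `ic`, `ic_low`, `ic_high`, `expected`, `method`.
#' @export
#' @examples
#' ic(contingency_table(100, 900, 9900, 989100))
ic <- function(table, method = c("noren_credible", "bate_variance"),
               z = stats::qnorm(0.975)) {
  stopifnot(inherits(table, "contingency_table"))
  method <- match.arg(method)
  a <- table$a
  e <- (table$a + table$b) * (table$a + table$c) / table$n
  est <- log2((a + 0.5) / (e + 0.5))
  if (method == "noren_credible") {
    lo <- est - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
    hi <- est + 2.4 * (a + 0.5)^(-0.5) - 0.5 * (a + 0.5)^(-1.5)
  } else {
    sd_ic <- sqrt(bate_ic_variance(table$a, table$b, table$c, table$d))
    lo <- est - z * sd_ic
    hi <- est + z * sd_ic
  }
  list(ic = est, ic_low = lo, ic_high = hi, expected = e, method = method)
}

#' Apply the joint signal rule
#'
#' A drug-event pair is flagged as a signal when the reported case count
#' reaches `min_cases` (3 by default), the lower 95\% ROR bound exceeds 1,
#' and the lower 95\% IC bound exceeds 0. The IC condition guards against
#' the ROR's false positives at small counts.
#'
#' @param n_cases Observed case count `a`.
#' @param ror_low Lower ROR interval bound.
#' @param ic_low Lower IC interval bound.
#' @param min_cases Minimum case count.
#' @return Logical.
#' @export
evaluate_signal <- function(n_cases, ror_low, ic_low, min_cases = 3L) {
  (n_cases >= min_cases) & (ror_low > 1) & (ic_low > 0)
}

#' Full signal evaluation of one 2x2 table
#'
#' Computes ROR and IC with their intervals, the expected count, and the
#' joint signal flag, as a one-row `data.frame` ready to be stacked into
#' a signal table.
#'
#' @param table A [contingency_table()].
#' @param min_cases,z,ic_method,haldane Passed to [evaluate_signal()],
#'   [ror()] and [ic()].
#' @return One-row `data.table`: `a`, `b`, `c`, `d`, `expected`, `ror`,
#'   `ror_low`, `ror_high`, `ic`, `ic_low`, `ic_high`, `is_signal`,
#'   `below_threshold`, `haldane_applied`, `ic_method`.
#' @export
signal_result <- function(table, min_cases = 3L, z = stats::qnorm(0.975),
                          ic_method = "noren_credible", haldane = NULL) {
  r <- ror(table, z = z, haldane = haldane)
  i <- ic(table, method = ic_method, z = z)
  data.table::data.table(
    a = table$a, b = table$b, c = table$c, d = table$d,
    expected = i$expected,
    ror = r$ror, ror_low = r$ror_low, ror_high = r$ror_high,
    ic = i$ic, ic_low = i$ic_low, ic_high = i$ic_high,
    is_signal = evaluate_signal(table$a, r$ror_low, i$ic_low, min_cases),
    below_threshold = table$a < min_cases,
    haldane_applied = r$haldane_applied,
    ic_method = i$method)
}
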