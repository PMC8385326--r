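#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange select group_by summarise ungroup
#'   left_join inner_join bind_rows desc n across all_of
#' @importFrom stats rnbinom rnorm runif rbinom lowess approxfun pt p.adjust
#'   prcomp cor cor.test t.test rgamma sd var setNames quantile
#' @importFrom utils combn head
NULL

# pseudocount used in all linear-scale fold-change denominators
.SIGTRACE_EPS <- 1e-9

stop_sigtrace <- function(msg, class = "sigtrace_error") {
  rlang::abort(msg, class = class)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_sigtrace(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_sigtrace(sprintf("`%s` must be a single positive number.", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == as.integer(x) && x >= min
  if (!ok) stop_sigtrace(sprintf("`%s` must be an integer >= %d.", name, min))
  invisible(as.integer(x))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' throughout the test-suite to quantify recovery of planted cell types by
#' clustering. Values near 1 indicate near-identical partitions; 0 is the
#' expectation under independent random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single numeric value in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_sigtrace("label vectors differ in length.")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
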