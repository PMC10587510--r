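# Friedman rank test, implemented from first principles: within-block
# mid-ranks, the classical chi-square-form statistic with the standard tie
# correction, and an exact permutation p-value by enumeration of all
# (k!)^n within-block rank orders on small designs.

#' Friedman rank statistic
#'
#' For an `n x k` matrix of measurements (`n` blocks, `k` related
#' treatments), ranks each block with mid-ranks for ties and computes
#' `Q = 12 / (n k (k+1)) * sum_j R_j^2 - 3 n (k+1)`, divided by the tie
#' correction `1 - sum(t^3 - t) / (n (k^3 - k))` where `t` runs over the
#' tied-group sizes of every block. A design whose blocks are all
#' completely tied has no rank information: the statistic is 0 with
#' `degenerate = TRUE`.
#'
#' @param design Numeric matrix, blocks in rows, treatments in columns
#'   (`n >= 2`, `k >= 2`, no missing cells).
#' @return A list with `statistic`, `df` (= k - 1), `n`, `k`,
#'   `degenerate`.
#' @examples
#' m <- rbind(c(1, 2, 3), c(2, 4, 6), c(0.1, 0.2, 0.3))
#' friedman_statistic(m)$statistic  # 6: every block agrees on the order
#' @export
friedman_statistic <- function(design) {
  design <- as.matrix(design)
  n <- nrow(design)
  k <- ncol(design)
  if (n < 2 || k < 2) abort("Need at least 2 blocks and 2 treatments")
  if (anyNA(design)) abort("BlockDesign must have no missing cells")

  ranks <- t(apply(design, 1, rank))
  rj <- colSums(ranks)
  q0 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)

  tie_term <- sum(apply(design, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  correction <- 1 - tie_term / (n * (k^3 - k))
  if (correction <= 0) {
    return(list(statistic = 0, df = k - 1, n = n, k = k, degenerate = TRUE))
  }
  list(statistic = q0 / correction, df = k - 1, n = n, k = k,
       degenerate = FALSE)
}

# All permutations of 1:k as a (k! x k) matrix.
rank_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- rank_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    m <- matrix(0L, nrow(sub), k)
    m[, pos] <- k
    m[, -pos] <- sub
    m
  }))
}

# Exact null distribution of Q for an n x k tie-free design: the column
# rank sums R are a sum of n independent uniform permutations of 1:k.
# Accumulates the distribution over R-vectors block by block, collapsing
# duplicate states, then maps each R-vector to its Q value.
exact_null_distribution <- function(n, k) {
  perms <- rank_permutations(k)
  states <- matrix(0, 1, k)
  counts <- 1
  for (b in seq_len(n)) {
    expanded <- states[rep(seq_len(nrow(states)), each = nrow(perms)), ,
                       drop = FALSE] +
      perms[rep(seq_len(nrow(perms)), times = nrow(states)), , drop = FALSE]
    w <- rep(counts, each = nrow(perms))
    key <- apply(expanded, 1, paste, collapse = ",")
    agg <- rowsum(w, key)
    states <- do.call(rbind, lapply(strsplit(rownames(agg), ","), as.numeric))
    counts <- as.numeric(agg)
  }
  q <- 12 / (n * k * (k + 1)) * rowSums(states^2) - 3 * n * (k + 1)
  list(q = q, counts = counts, total = sum(counts))
}

#' Friedman p-value
#'
#' `method = "chisq"`: upper-tail chi-square probability on `k - 1`
#' degrees of freedom. `method = "exact"`: enumerates all `(k!)^n`
#' within-block rank orders (feasible for `n * k <= 12`) and returns the
#' fraction with a statistic at least as large as observed.
#'
#' @param statistic Observed Friedman statistic (>= 0).
#' @param df Degrees of freedom, `k - 1`.
#' @param method `"chisq"` or `"exact"`.
#' @param n Number of blocks (required for `"exact"`).
#' @return A p-value.
#' @examples
#' friedman_pvalue(6, df = 2)                       # ~0.0498
#' friedman_pvalue(6, df = 2, method = "exact", n = 3)
#' @export
friedman_pvalue <- function(statistic, df, method = c("chisq", "exact"),
                            n = NULL) {
  method <- match.arg(method)
  if (statistic < 0) abort("Friedman statistic cannot be negative")
  if (method == "chisq") {
    return(pchisq(statistic, df = df, lower.tail = FALSE))
  }
  if (is.null(n)) abort("The exact method needs the number of blocks `n`")
  k <- df + 1
  if (n * k > 12) {
    abort(sprintf(
      "Exact enumeration of (%d!)^%d rank orders is infeasible (n*k = %d > 12); use method = 'chisq'",
      k, n, n * k))
  }
  null <- exact_null_distribution(n, k)
  sum(null$counts[null$q >= statistic - 1e-9]) / null$total
}

#' Friedman rank test on tidy data
#'
#' Tidy front-end over [friedman_statistic()] and [friedman_pvalue()]:
#' takes long-format data with value, treatment and block columns (or a
#' plain blocks x treatments matrix) and returns a test object.
#' `method = "auto"` (default) uses the exact permutation distribution
#' when `n * k <= 12` and the chi-square approximation otherwise.
#'
#' @param data A data frame in long format, or a numeric matrix (blocks in
#'   rows).
#' @param value,treatment,block Column names (tidy-selected) when `data`
#'   is a data frame.
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @return An object of class `hookah_friedman` with elements `statistic`,
#'   `df`, `p.value`, `method`, `n`, `k`, `degenerate`. Supports [tidy()]
#'   and [glance()].
#' @examples
#' d <- tidyr::expand_grid(block = 1:4, treatment = c("a", "b"))
#' d$value <- ifelse(d$treatment == "b", 2, 1) + stats::runif(8, 0, 0.1)
#' friedman_rank_test(d, value, treatment, block)
#' @export
friedman_rank_test <- function(data, value, treatment, block,
                               method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  if (is.matrix(data)) {
    m <- data
  } else {
    long <- data |>
      select(value = {{ value }}, treatment = {{ treatment }},
             block = {{ block }})
    m <- long |>
      pivot_wider(names_from = "treatment", values_from = "value") |>
      select(-"block") |>
      as.matrix()
    if (anyNA(m)) abort("BlockDesign must have no missing cells")
  }
  st <- friedman_statistic(m)
  if (method == "auto") {
    method <- if (st$n * st$k <= 12) "exact" else "chisq"
  }
  p <- if (st$degenerate) 1 else {
    friedman_pvalue(st$statistic, st$df, method = method, n = st$n)
  }
  structure(list(statistic = st$statistic, df = st$df, p.value = p,
                 method = method, n = st$n, k = st$k,
                 degenerate = st$degenerate),
            class = "hookah_friedman")
}

#' @export
print.hookah_friedman <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: Q = %.4g, df = %d, p = %.4g (%s%s; %d blocks x %d treatments)\n",
    x$statistic, x$df, x$p.value, x$method,
    if (x$degenerate) ", degenerate all-tied design" else "", x$n, x$k))
  invisible(x)
}

#' @export
tidy.hookah_friedman <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method, degenerate = x$degenerate)
}

#' @export
glance.hookah_friedman <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method, n_blocks = x$n, n_treatments = x$k,
         degenerate = x$degenerate)
}
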