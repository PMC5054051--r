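#' Mid-rank Mann-Whitney U statistics
#'
#' Computes the Mann-Whitney U statistics for two samples with the mid-rank
#' tie convention: `u1` is the number of pairs `(a in group1, b in group2)`
#' with `a > b`, counting tied pairs 0.5 each; `u2` is symmetric, and
#' `u1 + u2 = n1 * n2` always. The reported test statistic is
#' `u_min = min(u1, u2)`, which may be half-integer under ties.
#'
#' @param group1,group2 Nonempty numeric vectors.
#' @return An object of class `u_rank_result` with elements `u1`, `u2`,
#'   `u_min`, `n1`, `n2`, and `p_exact_two_tailed` (`NA` until filled by
#'   [mwu_exact()]).
#' @examples
#' mann_whitney_u(c(23, 6, 13, 4), c(17, 5, 0, 5))  # u_min = 5
#' @export
mann_whitney_u <- function(group1, group2) {
  check_group(group1, "group1")
  check_group(group2, "group2")
  u1 <- sum(outer(group1, group2, ">")) +
    0.5 * sum(outer(group1, group2, "=="))
  n1 <- length(group1)
  n2 <- length(group2)
  structure(
    list(u1 = u1, u2 = n1 * n2 - u1, u_min = min(u1, n1 * n2 - u1),
         n1 = n1, n2 = n2, p_exact_two_tailed = NA_real_),
    class = "u_rank_result"
  )
}

check_group <- function(x, name) {
  if (!length(x)) stop("`", name, "` must be nonempty")
  if (!is.numeric(x) || anyNA(x)) {
    stop("`", name, "` must be numeric with no missing values")
  }
}

#' @export
print.u_rank_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (U1 = %g, U2 = %g), n1 = %d, n2 = %d\n",
              x$u_min, x$u1, x$u2, x$n1, x$n2))
  if (!is.na(x$p_exact_two_tailed)) {
    cat(sprintf("exact two-tailed P = %.4g\n", x$p_exact_two_tailed))
  }
  invisible(x)
}

#' Exact two-tailed permutation p-value for the Mann-Whitney U test
#'
#' Enumerates every assignment of the pooled observed values into groups of
#' sizes `n1` and `n2` (`choose(n1 + n2, n1)` assignments) and, under the
#' default `tail = "min-u"` convention, reports the proportion of
#' assignments whose `u_min` is at most the observed `u_min`. Because the
#' permutation null is built from the observed multiset, ties propagate into
#' the null (mid-rank scoring throughout). `tail = "double"` instead doubles
#' the one-tailed probability of the observed direction, capped at 1; for
#' tie-free data the two conventions agree.
#'
#' Complete enumeration is guarded at `choose(n1 + n2, n1) <= 1e6`; beyond
#' that a seeded Monte-Carlo estimate over random assignments is available
#' via `method = "montecarlo"`.
#'
#' @param group1,group2 Nonempty numeric vectors.
#' @param tail `"min-u"` (default) or `"double"`; see Details.
#' @param method `"exact"` (complete enumeration, the default) or
#'   `"montecarlo"`.
#' @param mc_replicates Number of random assignments for the Monte-Carlo
#'   method.
#' @param seed Optional integer seed (Monte-Carlo method only).
#' @return The two-tailed p-value in (0, 1].
#' @examples
#' exact_two_tailed_p(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
exact_two_tailed_p <- function(group1, group2, tail = c("min-u", "double"),
                               method = c("exact", "montecarlo"),
                               mc_replicates = 1e5, seed = NULL) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  obs <- mann_whitney_u(group1, group2)
  pooled <- c(group1, group2)
  n <- length(pooled)
  n1 <- obs$n1
  rk <- rank(pooled)  # mid-ranks; u1 = sum(rk[group1]) - n1 (n1 + 1) / 2
  offset <- n1 * (n1 + 1) / 2

  if (method == "exact") {
    if (choose(n, n1) > 1e6) {
      stop("choose(n1 + n2, n1) exceeds the exhaustive-enumeration guard ",
           "(1e6); use method = \"montecarlo\" with an explicit seed")
    }
    assignments <- utils::combn(n, n1)
    u1_perm <- colSums(matrix(rk[assignments], nrow = n1)) - offset
  } else {
    if (!is.null(seed)) set.seed(seed)
    u1_perm <- vapply(seq_len(mc_replicates), function(i) {
      sum(rk[sample.int(n, n1)]) - offset
    }, numeric(1))
  }
  u_min_perm <- pmin(u1_perm, obs$n1 * obs$n2 - u1_perm)
  eps <- 1e-9
  if (tail == "min-u") {
    mean(u_min_perm <= obs$u_min + eps)
  } else {
    half <- obs$n1 * obs$n2 / 2
    p_one <- if (obs$u1 <= half) {
      mean(u1_perm <= obs$u1 + eps)
    } else {
      mean(u1_perm >= obs$u1 - eps)
    }
    min(1, 2 * p_one)
  }
}

#' Exact Mann-Whitney U test
#'
#' Convenience wrapper returning the mid-rank U statistics together with the
#' exact permutation p-value.
#'
#' @inheritParams exact_two_tailed_p
#' @return A `u_rank_result` with `p_exact_two_tailed` filled in.
#' @examples
#' mwu_exact(c(23, 6, 13, 4), c(17, 5, 0, 5))
#' @export
mwu_exact <- function(group1, group2, tail = c("min-u", "double"),
                      method = c("exact", "montecarlo"),
                      mc_replicates = 1e5, seed = NULL) {
  res <- mann_whitney_u(group1, group2)
  res$p_exact_two_tailed <- exact_two_tailed_p(
    group1, group2, tail = tail, method = method,
    mc_replicates = mc_replicates, seed = seed
  )
  res
}

#' Compare two labelled groups: summaries plus the exact U test
#'
#' Splits `values` by `groups` (exactly two groups required), reports each
#' group's median and range, and runs the exact Mann-Whitney U test between
#' them.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length as `values`, with
#'   exactly two distinct labels.
#' @param ... Passed to [mwu_exact()].
#' @return An object of class `group_comparison`: a list with `summary`
#'   (one row per group: `group`, `median`, `min`, `max`, `n`) and `test`
#'   (a `u_rank_result`). Group 1 is the first label in sorted order.
#' @examples
#' compare_groups(c(23, 6, 13, 4, 17, 5, 0, 5),
#'                rep(c("macaw", "caique"), each = 4))
#' @export
compare_groups <- function(values, groups, ...) {
  stopifnot(length(values) == length(groups))
  labels <- sort(unique(as.character(groups)))
  if (length(labels) != 2L) {
    stop("`groups` must contain exactly two distinct labels, found ",
         length(labels))
  }
  split_vals <- split(values, factor(groups, levels = labels))
  summary <- do.call(rbind, lapply(labels, function(l) {
    cbind(data.frame(group = l, stringsAsFactors = FALSE),
          median_range(split_vals[[l]]))
  }))
  structure(
    list(summary = summary,
         test = mwu_exact(split_vals[[1L]], split_vals[[2L]], ...)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  print(x$test)
  invisible(x)
}
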