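#' Construct an osteometric measurement dataset
#'
#' Two measurements per bone in mm: `(Bd, GLm)` — breadth distal and greatest
#' length medial — for the astragalus, `(BFp, Dp)` — breadth of the proximal
#' articulation and depth of the proximal epiphysis — for the first phalanx.
#' The per-row product `x * y` (mm^2) is the 1-D size summary used for group
#' discrimination.
#'
#' @param element `"astragalus"` or `"phalanx"`.
#' @param x,y Positive measurements in mm.
#' @param ids Optional sample ids (defaults to `o1, o2, ...`).
#' @param truth Optional known group labels (`"big"`/`"small"`), recorded by
#'   the synthetic generator so recovery can be scored.
#' @return A `morpho_dataset`: list with `element`, `data` (data frame `id`,
#'   `x`, `y`, `product`) and `truth`.
#' @export
morpho_dataset <- function(element = c("astragalus", "phalanx"), x, y,
                           ids = NULL, truth = NULL) {
  element <- match.arg(element)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stopf("measurements must be positive finite values (mm)")
  ids <- ids %||% paste0("o", seq_along(x))
  if (anyDuplicated(ids)) stopf("duplicated measurement ids")
  if (!is.null(truth)) {
    if (length(truth) != length(x)) stopf("'truth' must match the number of rows")
    if (!all(truth %in% c("big", "small"))) stopf("'truth' labels must be big/small")
  }
  structure(list(element = element,
                 data = data.frame(id = as.character(ids), x = x, y = y,
                                   product = x * y, stringsAsFactors = FALSE),
                 truth = truth),
            class = "morpho_dataset")
}

#' Read an osteometric measurement TSV
#'
#' Expects the header `id  element  x_mm  y_mm`.
#'
#' @param path Path to the TSV file.
#' @param element Optional: keep only rows of this element.
#' @return A [morpho_dataset()].
#' @export
read_measurements <- function(path, element = NULL) {
  if (!file.exists(path)) stopf("measurement file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "element", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stopf("measurement table must have columns: %s", paste(need, collapse = "\\t"))
  if (!is.null(element)) {
    df <- df[df$element == element, , drop = FALSE]
    if (nrow(df) == 0L) stopf("no rows for element '%s'", element)
  } else {
    if (length(unique(df$element)) > 1L)
      stopf("multiple elements in table; pass 'element' to select one")
    element <- df$element[1L]
  }
  morpho_dataset(element, x = df$x_mm, y = df$y_mm, ids = df$id)
}

#' @export
print.morpho_dataset <- function(x, ...) {
  cat(sprintf("morpho_dataset: %d %s measurements (product range %.1f-%.1f mm^2)\n",
              nrow(x$data), x$element, min(x$data$product), max(x$data$product)))
  invisible(x)
}

#' Split bone measurements into two size groups
#'
#' Deterministic two-means clustering on the log product measure
#' `log(x * y)`: the boundary is initialized at the median, then each row is
#' reassigned to the nearer group mean until a fixed point. The group with the
#' larger mean product is labelled `big`. Working on the log product makes the
#' split invariant to uniform unit rescaling (mm to cm shifts every value by a
#' constant).
#'
#' @param data A [morpho_dataset()] with `n >= 4` rows.
#' @return A `morpho_grouping`: list with `assignment` (named character
#'   vector, `big`/`small` per row), `element`, `group_stats` (per-group mean
#'   and SD of `x`, `y`, `product`), and empty `tests` (filled by
#'   [test_group_difference()]).
#' @export
classify_size_groups <- function(data) {
  stopifnot(inherits(data, "morpho_dataset"))
  v <- log(data$data$product)
  n <- length(v)
  if (n < 4L) stopf("size classification requires n >= 4 measurements")
  if (diff(range(v)) == 0)
    stopf("all product measures are identical; no size separation is definable")
  small <- v <= stats::median(v)
  if (all(small) || !any(small)) {                 # heavy ties at the median
    small <- rank(v, ties.method = "first") <= n %/% 2L
  }
  for (it in 1:100) {
    ms <- mean(v[small]); mb <- mean(v[!small])
    if (ms > mb) { small <- !small; ms <- mean(v[small]); mb <- mean(v[!small]) }
    new_small <- abs(v - ms) <= abs(v - mb)
    if (identical(new_small, small)) break
    small <- new_small
  }
  assignment <- ifelse(small, "small", "big")
  names(assignment) <- data$data$id
  gs <- lapply(split(data$data[, c("x", "y", "product")], assignment),
               function(d) rbind(mean = colMeans(d), sd = apply(d, 2, stats::sd)))
  structure(list(assignment = assignment, element = data$element,
                 group_stats = gs, tests = NULL, n_perms = NULL, seed = NULL),
            class = "morpho_grouping")
}

#' Permutation tests of size-group separation
#'
#' For each statistic — `x`, `y` and the product `x * y` — a two-sided
#' permutation test on the difference of group means. All `choose(n, n_big)`
#' group relabelings are enumerated when there are at most 20000 of them;
#' otherwise `n_perms` Monte-Carlo relabelings are drawn. With `B` the number
#' of (enumerated or sampled) relabelings whose absolute mean difference
#' reaches the observed one, `p = (B + 1) / (total + 1)` — for exhaustive
#' enumeration the observed labeling is counted both in `B` and in the `+1`,
#' a deliberately conservative convention that keeps `p > 0` always.
#'
#' @param data A [morpho_dataset()].
#' @param grouping A `morpho_grouping` from [classify_size_groups()], or a
#'   `big`/`small` label vector of the same length as the data.
#' @param n_perms Monte-Carlo permutations when enumeration is infeasible;
#'   default 10000.
#' @param seed Integer seed (used only on the Monte-Carlo path).
#' @return The grouping with `tests` filled: data frame with `statistic`,
#'   `p_value`, `method` (`exact`/`monte_carlo`), `n_perms`.
#' @export
test_group_difference <- function(data, grouping, n_perms = 10000, seed = NULL) {
  stopifnot(inherits(data, "morpho_dataset"))
  if (inherits(grouping, "morpho_grouping")) {
    g <- grouping$assignment
  } else {
    g <- as.character(grouping)
    if (!all(g %in% c("big", "small")))
      stopf("'grouping' labels must be big/small")
    names(g) <- data$data$id
    grouping <- structure(list(assignment = g, element = data$element,
                               group_stats = NULL, tests = NULL,
                               n_perms = NULL, seed = NULL),
                          class = "morpho_grouping")
  }
  if (length(g) != nrow(data$data))
    stopf("grouping has %d labels but data has %d rows", length(g), nrow(data$data))
  big <- g == "big"
  n <- length(g); n1 <- sum(big)
  if (n1 < 2L || n - n1 < 2L)
    stopf("both groups need >= 2 members (big = %d, small = %d)", n1, n - n1)
  Y <- as.matrix(data$data[, c("x", "y", "product")])
  obs <- abs(colMeans(Y[big, , drop = FALSE]) - colMeans(Y[!big, , drop = FALSE]))
  tol <- 1e-8 * (1 + obs)
  total_sum <- colSums(Y)
  # |mean difference| for the relabeling selecting rows `ix` as "big"
  absdiff <- function(ix) {
    s1 <- colSums(Y[ix, , drop = FALSE])
    abs(s1 / n1 - (total_sum - s1) / (n - n1))
  }
  M <- choose(n, n1)
  if (M <= 20000) {
    combs <- utils::combn(n, n1)
    B <- rep(0L, 3L)
    for (c_i in seq_len(ncol(combs)))
      B <- B + (absdiff(combs[, c_i]) >= obs - tol)
    p <- (B + 1) / (ncol(combs) + 1)
    method <- "exact"; reps <- ncol(combs)
  } else {
    B <- rep(0L, 3L)
    with_seed(seed, {
      for (r in seq_len(n_perms))
        B <- B + (absdiff(sample.int(n, n1)) >= obs - tol)
    })
    p <- (B + 1) / (n_perms + 1)
    method <- "monte_carlo"; reps <- n_perms
  }
  grouping$tests <- data.frame(statistic = c("x", "y", "product"),
                               p_value = unname(p), method = method,
                               n_perms = reps)
  grouping$n_perms <- reps
  grouping$seed <- seed
  grouping
}

#' @export
print.morpho_grouping <- function(x, ...) {
  cat(sprintf("morpho_grouping (%s): big = %d, small = %d\n",
              x$element, sum(x$assignment == "big"), sum(x$assignment == "small")))
  if (!is.null(x$tests)) {
    cat(sprintf("  %s permutation tests (%d relabelings):\n",
                x$tests$method[1L], x$tests$n_perms[1L]))
    for (i in seq_len(nrow(x$tests)))
      cat(sprintf("    %-8s p = %.3g\n", x$tests$statistic[i], x$tests$p_value[i]))
  }
  invisible(x)
}

#' Scatterplot of a measurement dataset, colored by size group
#'
#' @param x A [morpho_dataset()].
#' @param grouping Optional `morpho_grouping` (or label vector) to color by.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.morpho_dataset <- function(x, grouping = NULL, ...) {
  lab <- if (x$element == "astragalus") c("Bd (mm)", "GLm (mm)")
         else c("BFp (mm)", "Dp (mm)")
  col <- "grey30"
  if (!is.null(grouping)) {
    g <- if (inherits(grouping, "morpho_grouping")) grouping$assignment else grouping
    col <- ifelse(g == "big", "firebrick", "steelblue")
  }
  graphics::plot(x$data$x, x$data$y, xlab = lab[1L], ylab = lab[2L],
                 pch = 19, col = col, main = sprintf("%s measurements", x$element), ...)
  invisible(x)
}
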