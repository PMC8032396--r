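# Observed Hd and S for a set of rows, given a fixed haplotype assignment.
# rowhap: integer haplotype index per row; keymat: haplotype x retained-column
# character matrix. Returns c(Hd, S).
hap_stats <- function(rowhap, keymat) {
  m <- length(rowhap)
  cnt <- tabulate(rowhap, nrow(keymat))
  cnt <- cnt[cnt > 0L]
  Hd <- m / (m - 1) * (1 - sum((cnt / m)^2))
  u <- unique(rowhap)
  S <- if (length(u) == 1L) 0L
       else count_segregating(keymat[u, , drop = FALSE])
  c(Hd = Hd, S = S)
}

# Group rows of a sequence matrix on a fixed set of columns; returns the
# per-row haplotype index and the distinct-key matrix.
hap_index <- function(seqs, retained) {
  sub <- seqs[, retained, drop = FALSE]
  keys <- do.call(paste0, as.data.frame(sub, stringsAsFactors = FALSE))
  ukeys <- unique(keys)
  list(rowhap = match(keys, ukeys),
       keymat = do.call(rbind, strsplit(ukeys, "")))
}

#' Bootstrap null distributions of diversity conditional on a sample size
#'
#' Each replicate draws `m` sequences from the modern cohort uniformly *with
#' replacement* and computes haplotype diversity `Hd` and the number of
#' segregating sites `S` on the draw. Replicates in which all `m` draws carry
#' one haplotype contribute `Hd = 0, S = 0` (a valid outcome, not an error).
#' The retained-column mask is fixed once — either from `retained_sites` or
#' from the modern cohort itself under `policy` — so every replicate is
#' computed on the same columns and is comparable to an observed value
#' computed on that mask.
#'
#' @param modern An [aligned_set()] (the large, typically modern, cohort).
#' @param m Resample size (>= 2), normally the ancient cohort size.
#' @param n_reps Number of bootstrap replicates; default 10000.
#' @param seed Integer seed or `NULL`.
#' @param policy Haplotype-calling policy used when `retained_sites` is `NULL`.
#' @param retained_sites Optional integer vector of alignment columns to use
#'   as the fixed mask (e.g. the complete-deletion mask of a larger
#'   partition).
#' @return List with numeric vectors `Hd` and `S` of length `n_reps`, plus
#'   `m`, `n_reps`, `policy`.
#' @export
bootstrap_null <- function(modern, m, n_reps = 10000, seed = NULL,
                           policy = c("complete_deletion", "strict"),
                           retained_sites = NULL) {
  stopifnot(inherits(modern, "aligned_set"))
  policy <- match.arg(policy)
  n <- nrow(modern$seqs)
  if (m < 2) stopf("resample size m must be >= 2")
  if (n < 2) stopf("the resampled cohort must have >= 2 samples")
  if (n_reps < 1) stopf("n_reps must be >= 1")
  if (is.null(retained_sites)) {
    ht <- call_haplotypes(modern, policy)
    rowhap <- ht$row_haplotype
    keymat <- ht$key_matrix
  } else {
    hi <- hap_index(modern$seqs, retained_sites)
    rowhap <- hi$rowhap
    keymat <- hi$keymat
  }
  with_seed(seed, {
    Hd <- numeric(n_reps)
    S <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, m, replace = TRUE)
      st <- hap_stats(rowhap[idx], keymat)
      Hd[r] <- st[[1L]]
      S[r] <- st[[2L]]
    }
    list(Hd = Hd, S = S, m = as.integer(m), n_reps = as.integer(n_reps),
         policy = policy)
  })
}

#' Percentile of an observed value within a null distribution
#'
#' Midrank convention:
#' `100 * (#{null < observed} + 0.5 * #{null == observed}) / length(null)`.
#' Symmetric under sign flips and well-behaved under the heavy ties that
#' discrete statistics take on small resamples.
#'
#' @param observed A single observed value.
#' @param null_vector Non-empty numeric vector of null replicates.
#' @return Percentile in `[0, 100]`.
#' @examples
#' percentile_of(3, c(1, 2, 3, 4))  # 62.5
#' @export
percentile_of <- function(observed, null_vector) {
  if (length(null_vector) == 0L) stopf("null_vector must be non-empty")
  if (length(observed) != 1L || !is.finite(observed))
    stopf("'observed' must be a single finite value")
  100 * (sum(null_vector < observed) + 0.5 * sum(null_vector == observed)) /
    length(null_vector)
}

#' The paper-style three-way partition set for camelid data
#'
#' Builds the named partitions used by [temporal_diversity_test()]: all
#' samples; large animals (ancient `size_class = "big"` vs modern *Lama*
#' taxa); small animals (ancient `size_class = "small"` vs modern *Vicugna*
#' taxa). Ancient samples with `size_class = "unknown"` are excluded from the
#' two size partitions by construction.
#'
#' @param lama_taxa Taxon labels defining the modern *Lama* (guanaco + llama)
#'   cohort.
#' @param vicugna_taxa Taxon labels defining the modern *Vicugna*
#'   (vicuna + alpaca) cohort.
#' @return Named list of partitions, each a list with `ancient` and `modern`
#'   filter argument lists for [subset.aligned_set()].
#' @export
camelid_partitions <- function(lama_taxa = c("L_guanicoe", "L_g_guanicoe",
                                             "L_g_cacsilensis", "L_glama"),
                               vicugna_taxa = c("V_vicugna", "V_v_vicugna",
                                                "V_v_mensalis", "V_pacos")) {
  list(
    all = list(ancient = list(), modern = list()),
    big_Lama = list(ancient = list(size_class = "big"),
                    modern = list(taxa = lama_taxa)),
    small_Vicugna = list(ancient = list(size_class = "small"),
                         modern = list(taxa = vicugna_taxa))
  )
}

#' Bootstrap-rarefaction test of ancient vs modern diversity
#'
#' The headline temporal comparison. For each partition the ancient cohort's
#' haplotype diversity `Hd` and segregating-site count `S` are computed and
#' placed within null distributions obtained by resampling the partition's
#' modern cohort with replacement, `n_reps` times, at the ancient sample size
#' `m` — a bootstrap rarefaction that corrects the raw comparison for the
#' uneven sample sizes of the two strata. A percentile near 100 means the
#' ancient cohort is more diverse than nearly all size-matched modern
#' resamples, the signature of maternal lineages present in the ancient
#' population but lost from the modern one.
#'
#' Under `complete_deletion` the column mask is computed once per partition on
#' the union of its ancient and modern rows, and both the observed ancient
#' statistics and every bootstrap replicate use that mask, so all values are
#' computed over identical columns.
#'
#' @param aset An [aligned_set()] containing both strata.
#' @param partitions Named list of partitions, each
#'   `list(ancient = <filters>, modern = <filters>)` with filters as argument
#'   lists for [subset.aligned_set()] (the stratum filter is added
#'   automatically). Default: the single all-samples partition. Use
#'   [camelid_partitions()] for the three-way large/small design (its size
#'   partitions require dataset-specific taxon labels).
#' @param n_reps Bootstrap replicates per partition; default 10000.
#' @param seed Integer seed; partition `i` uses `seed + i`.
#' @param policy Haplotype-calling policy.
#' @return A `temporal_comparison`: list of `resampling_result` objects (one
#'   per partition), each with elements `partition`, `m`, `n_reps`, `seed`,
#'   and `stats` — for `Hd` and `S` the observed ancient value, the null
#'   vector and the midrank percentile.
#' @examples
#' pool <- simulate_pool(K = 8, L = 60, seed = 7)
#' aset <- sample_cohorts(pool, n_ancient = 12, n_modern = 60, loss = 0.5,
#'                        miss_rate = 0, deam_rate = 0, seed = 8)
#' tc <- temporal_diversity_test(aset, n_reps = 500, seed = 9)
#' summary(tc)
#' @export
temporal_diversity_test <- function(aset, partitions = NULL, n_reps = 10000,
                                    seed = NULL,
                                    policy = c("complete_deletion", "strict")) {
  stopifnot(inherits(aset, "aligned_set"))
  policy <- match.arg(policy)
  if (is.null(partitions))
    partitions <- list(all = list(ancient = list(), modern = list()))
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    stopf("'partitions' must be a named list")
  results <- vector("list", length(partitions))
  names(results) <- names(partitions)
  for (i in seq_along(partitions)) {
    pname <- names(partitions)[i]
    p <- partitions[[i]]
    anc <- tryCatch(
      do.call(subset, c(list(aset, stratum = "ancient"), p$ancient)),
      error = function(e) stopf("partition '%s' (ancient): %s", pname,
                                conditionMessage(e)))
    mod <- tryCatch(
      do.call(subset, c(list(aset, stratum = "modern"), p$modern)),
      error = function(e) stopf("partition '%s' (modern): %s", pname,
                                conditionMessage(e)))
    m <- nrow(anc$seqs)
    if (m < 2) stopf("partition '%s': ancient cohort has %d sample(s), need >= 2", pname, m)
    if (nrow(mod$seqs) < 2)
      stopf("partition '%s': modern cohort has %d sample(s), need >= 2",
            pname, nrow(mod$seqs))
    dropped <- if (length(p$ancient))
      sum(aset$meta$stratum == "ancient") - m else 0L
    if (dropped > 0L)
      message(sprintf("partition '%s': %d ancient sample(s) excluded by the size filter",
                      pname, dropped))
    combined <- rbind(anc$seqs, mod$seqs)
    if (policy == "complete_deletion") {
      keep <- colSums(combined == "-" | combined == "N") == 0L
      if (!any(keep))
        stopf("partition '%s': complete_deletion removed every column", pname)
      retained <- which(keep)
    } else retained <- seq_len(ncol(combined))
    anc_hi <- hap_index(anc$seqs, retained)
    obs <- hap_stats(anc_hi$rowhap, anc_hi$keymat)
    child_seed <- if (is.null(seed)) NULL else as.integer(seed) + i
    nl <- bootstrap_null(mod, m = m, n_reps = n_reps, seed = child_seed,
                         policy = policy, retained_sites = retained)
    results[[i]] <- structure(list(
      partition = pname, m = m, n_reps = as.integer(n_reps),
      seed = child_seed, policy = policy,
      retained_sites = retained,
      stats = list(
        Hd = list(observed = unname(obs[1L]), null = nl$Hd,
                  percentile = percentile_of(obs[1L], nl$Hd)),
        S = list(observed = unname(obs[2L]), null = as.numeric(nl$S),
                 percentile = percentile_of(obs[2L], nl$S)))),
      class = "resampling_result")
  }
  structure(results, class = "temporal_comparison")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("partition '%s': m = %d ancient vs bootstrap null (%d reps)\n",
              x$partition, x$m, x$n_reps))
  cat(sprintf("  Hd observed = %.4f  -> percentile %5.1f\n",
              x$stats$Hd$observed, x$stats$Hd$percentile))
  cat(sprintf("  S  observed = %d  -> percentile %5.1f\n",
              as.integer(x$stats$S$observed), x$stats$S$percentile))
  invisible(x)
}

#' @export
print.temporal_comparison <- function(x, ...) {
  cat("Bootstrap-rarefaction comparison of ancient vs modern diversity\n")
  for (r in x) print(r)
  invisible(x)
}

#' @export
summary.temporal_comparison <- function(object, ...) {
  do.call(rbind, lapply(object, function(r)
    data.frame(partition = r$partition, m = r$m, n_reps = r$n_reps,
               Hd_observed = r$stats$Hd$observed,
               Hd_percentile = r$stats$Hd$percentile,
               S_observed = r$stats$S$observed,
               S_percentile = r$stats$S$percentile)))
}

#' Plot the bootstrap null distributions with the observed values marked
#'
#' One histogram per statistic (`Hd`, `S`): the null distribution of
#' size-matched modern resamples, the 95th-percentile upper bound (dashed
#' black) and the observed ancient value (dashed red).
#'
#' @param x A `resampling_result` or `temporal_comparison`.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.resampling_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (s in c("Hd", "S")) {
    st <- x$stats[[s]]
    graphics::hist(st$null, main = sprintf("%s (%s)", s, x$partition),
                   xlab = sprintf("%s of %d-sample modern resamples", s, x$m),
                   col = "grey85", border = "white", ...)
    graphics::abline(v = stats::quantile(st$null, 0.95), lty = 2)
    graphics::abline(v = st$observed, lty = 2, col = "red")
  }
  invisible(x)
}

#' @export
plot.temporal_comparison <- function(x, ...) {
  for (r in x) plot(r, ...)
  invisible(x)
}
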