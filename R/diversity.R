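#' Collapse an alignment into haplotypes
#'
#' Groups samples with identical sequences over a set of retained alignment
#' columns. Under the default `complete_deletion` policy every column
#' containing a gap (`-`) or missing base (`N`) in *any* sample is dropped
#' before grouping, mirroring the column masking a haplotype-network workflow
#' applies; under `strict` no columns are dropped and `-`/`N` are literal
#' character states. The number of segregating (polymorphic) sites `S` is the
#' count of retained columns with at least two distinct states under the
#' active policy.
#'
#' Haplotypes are ordered by descending total count, ties broken by the first
#' appearance (input order) of their earliest member.
#'
#' @param aset An [aligned_set()] with `n >= 1` samples.
#' @param policy `"complete_deletion"` (default) or `"strict"`.
#' @return A `haplotype_table`: list with `keys` (haplotype strings over the
#'   retained columns), `members` (list of sample-id vectors; these partition
#'   the input ids), `counts` (data frame: `total`, `ancient`, `modern`,
#'   `taxon_major`), `n`, `retained_sites` (original column indices), `S`,
#'   `policy`, `key_matrix` (haplotypes x retained columns), and
#'   `row_haplotype` (haplotype index of each input row).
#' @examples
#' seqs <- do.call(rbind, strsplit(c("ACGT", "ACGA", "ACGA", "TCGA"), ""))
#' meta <- data.frame(id = paste0("s", 1:4), stratum = "modern",
#'                    taxon = "t", size_class = "unknown", site = "x")
#' ht <- call_haplotypes(aligned_set(seqs, meta))
#' ht$counts$total  # 2, 1, 1
#' ht$S             # 2 (columns 1 and 4)
#' @export
call_haplotypes <- function(aset, policy = c("complete_deletion", "strict")) {
  stopifnot(inherits(aset, "aligned_set"))
  policy <- match.arg(policy)
  seqs <- aset$seqs
  n <- nrow(seqs)
  if (n < 1L) stopf("at least one sample is required")
  if (policy == "complete_deletion") {
    keep <- colSums(seqs == "-" | seqs == "N") == 0L
    if (!any(keep))
      stopf("policy 'complete_deletion' removed every alignment column; no haplotypes can be called")
    retained <- which(keep)
  } else {
    retained <- seq_len(ncol(seqs))
  }
  sub <- seqs[, retained, drop = FALSE]
  keys_all <- do.call(paste0, as.data.frame(sub, stringsAsFactors = FALSE))
  ukeys <- unique(keys_all)
  hap_of <- match(keys_all, ukeys)
  total <- tabulate(hap_of, length(ukeys))
  first_idx <- match(seq_along(ukeys), hap_of)
  ord <- order(-total, first_idx)
  rank_of <- match(seq_along(ukeys), ord)       # old index -> new rank
  hap_of <- rank_of[hap_of]
  keys <- ukeys[ord]
  total <- total[ord]
  hap_f <- factor(hap_of, levels = seq_along(keys))
  members <- split(aset$ids, hap_f)
  names(members) <- NULL
  strat <- factor(aset$meta$stratum, levels = STRATA)
  cnt_strat <- table(hap_f, strat)
  taxon_major <- vapply(split(aset$meta$taxon, hap_f), function(tx) {
    tt <- sort(table(tx), decreasing = TRUE)
    names(tt)[1L]
  }, "")
  key_matrix <- do.call(rbind, strsplit(keys, ""))
  if (is.null(key_matrix)) key_matrix <- matrix(character(0), 0L, 0L)
  S <- count_segregating(key_matrix)
  structure(list(
    keys = keys, members = members,
    counts = data.frame(total = total,
                        ancient = as.integer(cnt_strat[, "ancient"]),
                        modern = as.integer(cnt_strat[, "modern"]),
                        taxon_major = unname(taxon_major)),
    n = n, retained_sites = retained, S = S, policy = policy,
    key_matrix = key_matrix, row_haplotype = hap_of, ids = aset$ids),
    class = "haplotype_table")
}

# segregating sites of a (haplotypes x sites) character matrix: columns with
# >= 2 distinct states (states taken literally, incl. N/- under strict policy)
count_segregating <- function(km) {
  if (nrow(km) <= 1L || ncol(km) == 0L) return(0L)
  ref <- km[rep.int(1L, nrow(km)), , drop = FALSE]
  sum(colSums(km != ref) > 0L)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes from %d samples (%d columns retained, policy=%s)\n",
              length(x$keys), x$n, length(x$retained_sites), x$policy))
  cat(sprintf("  segregating sites S = %d\n", x$S))
  invisible(x)
}

#' @export
as.data.frame.haplotype_table <- function(x, ...) {
  data.frame(haplotype = paste0("H", seq_along(x$keys)),
             key = x$keys, total = x$counts$total,
             ancient = x$counts$ancient, modern = x$counts$modern,
             taxon_major = x$counts$taxon_major)
}

#' Haplotype (gene) diversity, Nei's unbiased estimator
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the sample frequency of
#' haplotype `i`. This equals, exactly, the fraction of unordered sample pairs
#' carrying different haplotypes, and is 1 for an all-distinct cohort of any
#' size — the property that makes a fully distinct ancient mitogenome cohort
#' report Hd = 1.00.
#'
#' @param counts Integer vector of haplotype counts (total `n >= 2`), or a
#'   `haplotype_table` from [call_haplotypes()].
#' @return Hd in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(2, 2, 1))  # 0.8
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "haplotype_table")) counts <- counts$counts$total
  if (!is.numeric(counts) || any(counts < 0))
    stopf("'counts' must be non-negative haplotype counts")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stopf("haplotype diversity requires n >= 2 samples")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Nucleotide diversity with pairwise deletion
#'
#' For every unordered pair of sequences the per-site difference
#' `d = (#mismatches) / (#sites where both have a base in {A,C,G,T})` is
#' computed — sites with a gap or `N` in either member of the pair are
#' excluded from that comparison only ("pairwise deletion"). `pi` is the mean
#' of `d` over all pairs; a pair with zero comparable sites is dropped from
#' the mean (with a message noting how many were dropped).
#'
#' @param aset An [aligned_set()] with `n >= 2`.
#' @return Nucleotide diversity per site in `[0, 1]`, with attribute
#'   `excluded_pairs` (number of pairs with no comparable sites).
#' @export
nucleotide_diversity <- function(aset) {
  stopifnot(inherits(aset, "aligned_set"))
  n <- nrow(aset$seqs)
  if (n < 2L) stopf("nucleotide diversity requires n >= 2 samples")
  m <- matrix(match(aset$seqs, DNA_BASES), n, aset$L)
  tot <- 0
  used <- 0L
  skipped <- 0L
  for (i in seq_len(n - 1L)) {
    xi <- m[i, ]
    for (j in seq.int(i + 1L, n)) {
      xj <- m[j, ]
      valid <- !is.na(xi) & !is.na(xj)
      nc <- sum(valid)
      if (nc == 0L) { skipped <- skipped + 1L; next }
      tot <- tot + sum(xi[valid] != xj[valid]) / nc
      used <- used + 1L
    }
  }
  if (used == 0L)
    stopf("no pair of sequences shares a comparable site; pi is undefined")
  if (skipped > 0L)
    message(sprintf("nucleotide_diversity: %d pair(s) with zero comparable sites excluded", skipped))
  structure(tot / used, excluded_pairs = skipped)
}

#' Summarize the diversity of a cohort
#'
#' Bundles the statistics reported per cohort: sample size `n`, number of
#' distinct haplotypes `h`, haplotype diversity `Hd`, segregating sites `S`
#' (under `policy`), and nucleotide diversity `pi` (always with pairwise
#' deletion, independent of `policy`).
#'
#' @param aset An [aligned_set()] with `n >= 2`.
#' @param policy Haplotype-calling policy, see [call_haplotypes()].
#' @return A `diversity_summary`: list with `n`, `h`, `Hd`, `S`, `pi`,
#'   `policy`.
#' @export
diversity_summary <- function(aset, policy = c("complete_deletion", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(aset, "aligned_set"))
  if (nrow(aset$seqs) < 2L) stopf("diversity_summary requires n >= 2 samples")
  ht <- call_haplotypes(aset, policy)
  structure(list(n = ht$n, h = length(ht$keys),
                 Hd = haplotype_diversity(ht),
                 S = ht$S,
                 pi = as.numeric(nucleotide_diversity(aset)),
                 policy = policy),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("diversity_summary (policy=%s)\n", x$policy))
  cat(sprintf("  n = %d   h = %d   Hd = %.4f   S = %d   pi = %.5f\n",
              x$n, x$h, x$Hd, x$S, x$pi))
  invisible(x)
}
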