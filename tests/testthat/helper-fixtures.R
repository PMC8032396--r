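# Fixtures built in code, plus the independent oracles the tests compare
# against. Oracles are deliberately naive (enumeration / brute force) and
# share no code with the implementation.

make_aset <- function(seqs, stratum = "modern", taxon = "t",
                      size_class = "unknown", site = "x", ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  m <- do.call(rbind, strsplit(seqs, ""))
  meta <- data.frame(id = ids,
                     stratum = rep_len(stratum, length(seqs)),
                     taxon = rep_len(taxon, length(seqs)),
                     size_class = rep_len(size_class, length(seqs)),
                     site = rep_len(site, length(seqs)),
                     stringsAsFactors = FALSE)
  aligned_set(m, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_seqs <- function(n, L, p_missing = 0) {
  alpha <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    s <- sample(alpha, L, replace = TRUE)
    if (p_missing > 0) {
      miss <- runif(L) < p_missing
      s[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
}

# Hd oracle: fraction of unordered sample pairs with different haplotypes.
oracle_hd_paircount <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  n <- length(labels)
  diff_pairs <- 0L
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      if (labels[i] != labels[j]) diff_pairs <- diff_pairs + 1L
  diff_pairs / choose(n, 2)
}

# pi oracle: triple loop over pairs and sites with pairwise deletion.
oracle_pi_bruteforce <- function(seqs) {
  mats <- strsplit(seqs, "")
  n <- length(mats)
  base <- c("A", "C", "G", "T")
  total <- 0; used <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    a <- mats[[i]]; b <- mats[[j]]
    comp <- 0L; mism <- 0L
    for (s in seq_along(a)) {
      if (a[s] %in% base && b[s] %in% base) {
        comp <- comp + 1L
        if (a[s] != b[s]) mism <- mism + 1L
      }
    }
    if (comp > 0L) { total <- total + mism / comp; used <- used + 1L }
  }
  total / used
}

# Exhaustive union-of-MSTs oracle over a complete graph given by distance
# matrix d: enumerate every spanning tree, keep those of minimum total
# weight, return the sorted union of their edges as "i-j" strings.
# spanning_subsets can be precomputed (depends on h only).
oracle_mst_union <- function(d, spanning = NULL) {
  h <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  if (is.null(spanning)) spanning <- spanning_tree_subsets(h)
  w <- apply(spanning, 2, function(sel) sum(d[pairs[sel, , drop = FALSE]]))
  best <- which(w == min(w))
  union_edges <- unique(unlist(lapply(best, function(b) {
    sel <- spanning[, b]
    paste(pairs[sel, 1L], pairs[sel, 2L], sep = "-")
  })))
  sort(union_edges)
}

# All subsets of h-1 edges of K_h that form a spanning tree, as a logical
# matrix (one column per subset, rows indexed like upper.tri pairs).
spanning_tree_subsets <- function(h) {
  pairs <- which(upper.tri(matrix(0, h, h)), arr.ind = TRUE)
  ne <- nrow(pairs)
  combs <- utils::combn(ne, h - 1L)
  keep <- logical(ncol(combs))
  for (ci in seq_len(ncol(combs))) {
    parent <- seq_len(h)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in combs[, ci]) {
      a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    keep[ci] <- ok
  }
  out <- matrix(FALSE, ne, sum(keep))
  kept <- combs[, keep, drop = FALSE]
  for (ci in seq_len(ncol(kept))) out[kept[, ci], ci] <- TRUE
  out
}

# msn edge set as sorted "i-j" strings (ignoring weights), for comparison
# with oracle_mst_union.
msn_edge_strings <- function(d, epsilon = 0) {
  e <- msn_edges(d, epsilon)
  sort(paste(e$from, e$to, sep = "-"))
}

# Exhaustive two-part split of points minimizing within-group sum of squares
# (1-D); returns a logical vector (TRUE = member of the low-mean group).
oracle_best_split <- function(v) {
  n <- length(v)
  best <- NULL; best_ss <- Inf
  for (k in 1:(2^(n - 1) - 1)) {           # non-trivial splits, up to symmetry
    sel <- as.logical(bitwAnd(k, 2^(0:(n - 1))) > 0)
    if (!any(sel) || all(sel)) next
    ss <- sum((v[sel] - mean(v[sel]))^2) + sum((v[!sel] - mean(v[!sel]))^2)
    if (ss < best_ss) { best_ss <- ss; best <- sel }
  }
  if (mean(v[best]) > mean(v[!best])) best <- !best
  best
}

write_fasta_raw <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_meta_raw <- function(ids, path, stratum = "modern", taxon = "t",
                           size_class = "unknown", site = "x") {
  df <- data.frame(id = ids, stratum = rep_len(stratum, length(ids)),
                   taxon = rep_len(taxon, length(ids)),
                   size_class = rep_len(size_class, length(ids)),
                   site = rep_len(site, length(ids)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
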