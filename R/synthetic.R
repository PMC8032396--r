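#' Simulate a pool of related mitochondrial haplotypes
#'
#' Generates `K` distinct haplotypes on a locus of length `L` by a
#' copy-and-mutate chain: the root sequence is uniform over `{A,C,G,T}^L`,
#' and each subsequent haplotype copies a uniformly chosen existing haplotype
#' and applies `max(1, Poisson(mu))` substitutions at distinct random sites
#' (each to a random different base). Haplotype frequencies are drawn from a
#' symmetric Dirichlet with concentration `alpha`. This stands in for a
#' compiled control-region alignment: the downstream statistics consume the
#' haplotype frequency structure, not genealogy branch lengths, so a full
#' coalescent is deliberately not simulated.
#'
#' @param K Number of distinct haplotypes (>= 1).
#' @param L Locus length in bp; default 300, the length of a hypervariable-I
#'   control-region alignment.
#' @param mu Mean number of new mutations per derived haplotype (> 0).
#' @param alpha Dirichlet concentration for haplotype frequencies (> 0).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `haplotype_pool`: list with `sequences` (character vector of
#'   length `K`), `seq_matrix` (`K x L` character matrix), `freqs` (simplex
#'   vector), `genealogy` (parent index per haplotype, `NA` for the root),
#'   `K`, `L`.
#' @examples
#' pool <- simulate_pool(K = 5, L = 50, mu = 2, seed = 1)
#' pool$freqs
#' @export
simulate_pool <- function(K, L = 300, mu = 1.5, alpha = 1, seed = NULL) {
  if (!is.numeric(K) || K < 1) stopf("K must be >= 1")
  if (!is.numeric(L) || L < 1) stopf("L must be >= 1")
  if (!is.numeric(mu) || mu <= 0) stopf("mu must be > 0")
  if (!is.numeric(alpha) || alpha <= 0) stopf("alpha must be > 0")
  K <- as.integer(K); L <- as.integer(L)
  with_seed(seed, {
    seqm <- matrix(NA_character_, K, L)
    seqm[1L, ] <- sample(DNA_BASES, L, replace = TRUE)
    keys <- paste(seqm[1L, ], collapse = "")
    parent <- rep(NA_integer_, K)
    if (K > 1L) for (k in 2L:K) {
      done <- FALSE
      for (try in 1:100) {
        p <- sample.int(k - 1L, 1L)
        M <- max(1L, stats::rpois(1L, mu))
        M <- min(M, L)
        sites <- sample.int(L, M)
        child <- seqm[p, ]
        for (s in sites)
          child[s] <- sample(setdiff(DNA_BASES, child[s]), 1L)
        key <- paste(child, collapse = "")
        if (!key %in% keys) {
          seqm[k, ] <- child
          keys <- c(keys, key)
          parent[k] <- p
          done <- TRUE
          break
        }
      }
      if (!done)
        stopf("could not generate %d distinct haplotypes at L=%d (collision retries exhausted)", K, L)
    }
    freqs <- stats::rgamma(K, shape = alpha)
    freqs <- freqs / sum(freqs)
    structure(list(sequences = keys, seq_matrix = seqm, freqs = freqs,
                   genealogy = parent, K = K, L = L),
              class = "haplotype_pool")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: K=%d haplotypes, L=%d bp\n", x$K, x$L))
  invisible(x)
}

#' Apply ancient-DNA style degradation to consensus sequences
#'
#' Emulates the damage pattern of postmortem DNA: deamination-driven C->T
#' substitutions in the 5' half and G->A in the 3' half (each with probability
#' `deam_rate` per eligible site), followed by missing-data masking where each
#' site becomes `N` with probability
#' `miss_rate * (1 + (end_bias - 1) * w)`, `w` ramping linearly from 1 at the
#' alignment ends to 0 at the centre (clipped below 1). Substitution artifacts
#' are applied before masking. Operates on consensus rows, not reads: here the
#' damage only stress-tests the missing-data policies downstream.
#'
#' @param rows Character matrix over `{A,C,G,T}` (samples x sites).
#' @param miss_rate Baseline per-site probability of `N` in `[0, 1)`.
#' @param end_bias Multiplier (>= 1) for `miss_rate` at the alignment ends.
#' @param deam_rate Per-site artifact probability in `[0, 1)`.
#' @param seed Integer seed or `NULL`.
#' @return The degraded character matrix, same dimensions.
#' @export
degrade <- function(rows, miss_rate = 0, end_bias = 1, deam_rate = 0,
                    seed = NULL) {
  if (!is.matrix(rows) || !is.character(rows))
    stopf("'rows' must be a character matrix")
  if (!all(rows %in% DNA_BASES))
    stopf("'rows' must contain only A, C, G, T")
  if (miss_rate < 0 || miss_rate >= 1) stopf("miss_rate must be in [0, 1)")
  if (deam_rate < 0 || deam_rate >= 1) stopf("deam_rate must be in [0, 1)")
  if (end_bias < 1) stopf("end_bias must be >= 1")
  n <- nrow(rows); L <- ncol(rows)
  if (n == 0L || L == 0L) return(rows)
  with_seed(seed, {
    if (deam_rate > 0) {
      five <- matrix(rep(seq_len(L) <= floor(L / 2), each = n), n, L)
      u <- matrix(stats::runif(n * L), n, L)
      rows[rows == "C" & five & u < deam_rate] <- "T"
      rows[rows == "G" & !five & u < deam_rate] <- "A"
    }
    if (miss_rate > 0) {
      i <- seq_len(L)
      w <- if (L == 1L) 1 else 1 - 2 * pmin(i - 1L, L - i) / (L - 1L)
      rho <- pmin(miss_rate * (1 + (end_bias - 1) * w), 1 - 1e-12)
      v <- matrix(stats::runif(n * L), n, L)
      rows[v < matrix(rho, n, L, byrow = TRUE)] <- "N"
    }
    rows
  })
}

#' Draw stratified ancient/modern cohorts from a haplotype pool
#'
#' Ancient samples are drawn iid from the full pool. Modern samples are drawn
#' from the pool after removing `floor(loss * K)` haplotypes chosen uniformly
#' without replacement (frequencies renormalized) — the simplest model of
#' maternal-lineage extinction between the two time strata. Ancient rows are
#' then passed through [degrade()].
#'
#' @param pool A [simulate_pool()] result.
#' @param n_ancient,n_modern Cohort sizes (>= 1). Defaults 41 and 808, the
#'   strata sizes of a two-period control-region dataset.
#' @param loss Fraction in `[0, 1]` of pool haplotypes unavailable to the
#'   modern cohort; at least one haplotype must survive.
#' @param miss_rate,end_bias,deam_rate Damage parameters for the ancient rows,
#'   see [degrade()].
#' @param seed Integer seed or `NULL`.
#' @return An [aligned_set()] with `stratum` set per cohort (ids `a###` /
#'   `m###`), `taxon = "simulated"`, `size_class = "unknown"`.
#' @export
sample_cohorts <- function(pool, n_ancient = 41, n_modern = 808, loss = 0,
                           miss_rate = 0.01, end_bias = 4, deam_rate = 0.005,
                           seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (n_ancient < 1 || n_modern < 1) stopf("cohort sizes must be >= 1")
  if (loss < 0 || loss > 1) stopf("loss must be in [0, 1]")
  K <- pool$K
  n_remove <- floor(loss * K)
  if (n_remove >= K)
    stopf("loss=%g removes all %d haplotypes; no modern lineage survives", loss, K)
  with_seed(seed, {
    anc_idx <- sample.int(K, n_ancient, replace = TRUE, prob = pool$freqs)
    surv <- if (n_remove > 0)
      sort(sample.int(K, K - n_remove)) else seq_len(K)
    pfreq <- pool$freqs[surv] / sum(pool$freqs[surv])
    mod_idx <- surv[sample.int(length(surv), n_modern, replace = TRUE, prob = pfreq)]
    anc <- pool$seq_matrix[anc_idx, , drop = FALSE]
    mod <- pool$seq_matrix[mod_idx, , drop = FALSE]
    anc <- degrade(anc, miss_rate, end_bias, deam_rate, seed = NULL)
    ids <- c(sprintf("a%04d", seq_len(n_ancient)),
             sprintf("m%04d", seq_len(n_modern)))
    meta <- data.frame(
      id = ids,
      stratum = rep(c("ancient", "modern"), c(n_ancient, n_modern)),
      taxon = "simulated", size_class = "unknown", site = "synthetic_pool",
      stringsAsFactors = FALSE)
    aligned_set(rbind(anc, mod), meta)
  })
}

#' Simulate two bivariate-normal osteometric size groups
#'
#' Draws `n_big` + `n_small` bone measurements (mm) from two bivariate normal
#' distributions with common covariance `sd^2 * [[1, rho], [rho, 1]]`. The
#' true group labels are recorded so classifier recovery can be scored.
#' Default means are astragalus-scale (Bd, GLm) values for large (Lama) and
#' small (Vicugna) camelids.
#'
#' @param n_big,n_small Group sizes (either may be 0 for a single group).
#' @param mean_big,mean_small Length-2 mean vectors in mm: `(Bd, GLm)` for the
#'   astragalus, `(BFp, Dp)` for the first phalanx.
#' @param sd Common per-axis standard deviation (> 0), mm.
#' @param rho Correlation between the two measurements, in (-1, 1).
#' @param element `"astragalus"` or `"phalanx"`.
#' @param seed Integer seed or `NULL`.
#' @return A [morpho_dataset()] with `truth` labels attached.
#' @export
simulate_morphometrics <- function(n_big = 20, n_small = 20,
                                   mean_big = c(30, 42),
                                   mean_small = c(22, 32),
                                   sd = 1.5, rho = 0.6,
                                   element = c("astragalus", "phalanx"),
                                   seed = NULL) {
  element <- match.arg(element)
  if (length(mean_big) != 2L || length(mean_small) != 2L)
    stopf("group means must be 2-vectors (mm)")
  if (!is.numeric(sd) || sd <= 0) stopf("sd must be > 0")
  if (!is.numeric(rho) || abs(rho) >= 1)
    stopf("invalid covariance: rho must be in (-1, 1)")
  if (n_big + n_small < 1) stopf("at least one measurement is required")
  Sigma <- sd^2 * matrix(c(1, rho, rho, 1), 2L)
  with_seed(seed, {
    draw <- function(n, mu) {
      if (n == 0L) return(matrix(numeric(0), 0L, 2L))
      MASS::mvrnorm(n, mu, Sigma)
    }
    xb <- draw(n_big, mean_big)
    xs <- draw(n_small, mean_small)
    xy <- rbind(xb, xs)
    if (any(xy <= 0))
      stopf("simulated a non-positive measurement; means are too small relative to sd")
    ids <- c(sprintf("b%03d", seq_len(n_big)), sprintf("s%03d", seq_len(n_small)))
    truth <- rep(c("big", "small"), c(n_big, n_small))
    morpho_dataset(element, x = xy[, 1L], y = xy[, 2L], ids = ids, truth = truth)
  })
}
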