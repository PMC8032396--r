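#' Pairwise Hamming distances between haplotypes
#'
#' @param table A `haplotype_table` from [call_haplotypes()].
#' @return Symmetric integer matrix of Hamming distances over the retained
#'   columns, zero diagonal, dimnames `H1..Hh`. Off-diagonal entries are
#'   >= 1 because haplotype keys are distinct by construction.
#' @export
haplotype_distances <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  km <- table$key_matrix
  h <- nrow(km)
  d <- matrix(0L, h, h)
  if (h > 1L) for (i in seq_len(h - 1L)) {
    di <- colSums(t(km[seq.int(i + 1L, h), , drop = FALSE]) != km[i, ])
    d[i, seq.int(i + 1L, h)] <- di
    d[seq.int(i + 1L, h), i] <- di
  }
  dimnames(d) <- list(paste0("H", seq_len(h)), paste0("H", seq_len(h)))
  d
}

#' Minimum-spanning-network edge set of a distance matrix
#'
#' An edge `(i, j)` with weight `w = d[i, j]` belongs to the network iff
#' `w <= T[i, j] + epsilon`, where `T[i, j]` is the minimax path weight (the
#' smallest possible maximum edge weight over all `i`-`j` paths). With
#' `epsilon = 0` this is exactly the union of all minimum spanning trees of
#' `d` (cycle property); `epsilon = Inf` yields the complete graph. The edge
#' set depends only on `d`, so no tie-breaking order is involved.
#'
#' @param d Symmetric numeric matrix with zero diagonal (`h >= 1`).
#' @param epsilon Relaxation parameter (>= 0); default 0.
#' @return Data frame with columns `from`, `to` (indices, `from < to`) and
#'   `weight`, ordered by (weight, from, to). Empty for `h = 1`.
#' @export
msn_edges <- function(d, epsilon = 0) {
  d <- as.matrix(d)
  h <- nrow(d)
  if (h != ncol(d) || any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0))
    stopf("'d' must be a symmetric matrix with zero diagonal")
  if (epsilon < 0) stopf("epsilon must be >= 0")
  if (h == 1L)
    return(data.frame(from = integer(0), to = integer(0), weight = numeric(0)))
  # minimax closure (Floyd-Warshall on the (max, min) semiring)
  T <- d
  for (k in seq_len(h)) {
    via <- pmax(matrix(T[, k], h, h), matrix(T[k, ], h, h, byrow = TRUE))
    T <- pmin(T, via)
  }
  diag(T) <- 0
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- d[idx] <= T[idx] + epsilon
  e <- data.frame(from = idx[keep, 1L], to = idx[keep, 2L],
                  weight = d[idx][keep])
  e <- e[order(e$weight, e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Build a minimum spanning network of haplotypes
#'
#' The network analogue of a haplotype-frequency figure: nodes are haplotypes
#' (with total and per-stratum counts), edges connect haplotypes whose
#' Hamming distance cannot be improved upon by any alternative path (see
#' [msn_edges()]); edge weight is the number of mutations crossed. The
#' `epsilon = 0` network contains every minimum spanning tree of the distance
#' matrix and is connected. No median (Steiner) vertices are inferred.
#'
#' @param table A `haplotype_table`.
#' @param epsilon Relaxation parameter, see [msn_edges()].
#' @return A `haplo_network`: list with `nodes` (data frame: `hap`, `key`,
#'   `total`, `ancient`, `modern`, `taxon_major`), `edges` (`from`/`to` as
#'   `H`-labels plus `weight`), `epsilon`.
#' @export
build_msn <- function(table, epsilon = 0) {
  stopifnot(inherits(table, "haplotype_table"))
  d <- haplotype_distances(table)
  e <- msn_edges(d, epsilon)
  nodes <- as.data.frame(table)
  edges <- data.frame(from = rownames(d)[e$from], to = rownames(d)[e$to],
                      weight = e$weight)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d haplotypes, %d edges (epsilon = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Plot a minimum spanning network
#'
#' Simple base-graphics rendering: nodes positioned by classical MDS of the
#' edge-path structure, circle area proportional to haplotype frequency,
#' filled by the ancient fraction of carriers.
#'
#' @param x A `haplo_network`.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.haplo_network <- function(x, ...) {
  h <- nrow(x$nodes)
  adj <- matrix(max(x$edges$weight, 1) * h, h, h,
                dimnames = list(x$nodes$hap, x$nodes$hap))
  diag(adj) <- 0
  for (r in seq_len(nrow(x$edges)))
    adj[x$edges$from[r], x$edges$to[r]] <-
      adj[x$edges$to[r], x$edges$from[r]] <- x$edges$weight[r]
  xy <- if (h > 2) stats::cmdscale(stats::as.dist(adj), k = 2)
        else cbind(seq_len(h), 0)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Minimum spanning network (%d haplotypes)", h))
  for (r in seq_len(nrow(x$edges))) {
    i <- match(x$edges$from[r], x$nodes$hap)
    j <- match(x$edges$to[r], x$nodes$hap)
    graphics::segments(xy[i, 1], xy[i, 2], xy[j, 1], xy[j, 2], col = "grey60")
  }
  frac_anc <- x$nodes$ancient / pmax(x$nodes$total, 1L)
  graphics::points(xy, pch = 21, cex = 1 + 2 * sqrt(x$nodes$total / max(x$nodes$total)),
                   bg = grDevices::rgb(1 - frac_anc, 0.4, frac_anc))
  invisible(x)
}

#' Two-layer temporal haplotype network
#'
#' Splits the haplotypes into an ancient and a modern layer (membership from
#' the per-stratum counts), connects each layer internally by its own minimum
#' spanning network, and links haplotypes present in both layers by vertical
#' ties. The accounting identity
#' `shared + private_ancient + private_modern = total haplotypes` holds
#' exactly; the shared count is the quantitative signal of lineage continuity
#' between the strata.
#'
#' @param table A `haplotype_table` built from a cohort containing both
#'   strata.
#' @return A `temporal_network`: list with `layers` (haplotype indices per
#'   stratum), `shared` (indices in both), `counts`
#'   (`shared`, `private_ancient`, `private_modern`, `total`), `edges`
#'   (within-layer MSN edge data frames, indices global), `nodes`.
#' @export
build_temporal <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  anc <- which(table$counts$ancient > 0L)
  mod <- which(table$counts$modern > 0L)
  if (length(anc) == 0L || length(mod) == 0L)
    stopf("both strata must be present (ancient haplotypes: %d, modern: %d)",
          length(anc), length(mod))
  shared <- intersect(anc, mod)
  d <- haplotype_distances(table)
  layer_edges <- function(ix) {
    e <- msn_edges(d[ix, ix, drop = FALSE])
    data.frame(from = ix[e$from], to = ix[e$to], weight = e$weight)
  }
  counts <- c(shared = length(shared),
              private_ancient = length(setdiff(anc, mod)),
              private_modern = length(setdiff(mod, anc)),
              total = length(table$keys))
  structure(list(layers = list(ancient = anc, modern = mod), shared = shared,
                 counts = counts,
                 edges = list(ancient = layer_edges(anc),
                              modern = layer_edges(mod)),
                 nodes = as.data.frame(table)),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("temporal_network: %d haplotypes (%d ancient-layer, %d modern-layer)\n",
              x$counts[["total"]], length(x$layers$ancient), length(x$layers$modern)))
  cat(sprintf("  shared = %d, private ancient = %d, private modern = %d\n",
              x$counts[["shared"]], x$counts[["private_ancient"]],
              x$counts[["private_modern"]]))
  invisible(x)
}

# ---- export -------------------------------------------------------------

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

graphml_write <- function(nodes, edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="total" for="node" attr.name="total" attr.type="int"/>')
  w('  <key id="count_ancient" for="node" attr.name="count_ancient" attr.type="int"/>')
  w('  <key id="count_modern" for="node" attr.name="count_modern" attr.type="int"/>')
  w('  <key id="taxon_major" for="node" attr.name="taxon_major" attr.type="string"/>')
  w('  <key id="weight" for="edge" attr.name="weight" attr.type="int"/>')
  w('  <graph id="G" edgedefault="undirected">')
  for (i in seq_len(nrow(nodes))) {
    w('    <node id="%s">', nodes$hap[i])
    w('      <data key="total">%d</data>', nodes$total[i])
    w('      <data key="count_ancient">%d</data>', nodes$ancient[i])
    w('      <data key="count_modern">%d</data>', nodes$modern[i])
    w('      <data key="taxon_major">%s</data>', xml_escape(nodes$taxon_major[i]))
    w('    </node>')
  }
  for (i in seq_len(nrow(edges))) {
    w('    <edge source="%s" target="%s">', edges$from[i], edges$to[i])
    w('      <data key="weight">%d</data>', as.integer(edges$weight[i]))
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Export a haplotype network to GraphML or a TSV edge list
#'
#' GraphML carries per-node attributes (`total`, `count_ancient`,
#' `count_modern`, `taxon_major`) and the integer edge `weight` (mutations
#' crossed). The TSV alternative is a plain `hap_i  hap_j  weight` edge list.
#' For a `temporal_network` the two within-layer edge sets are exported as
#' one graph.
#'
#' @param net A `haplo_network` or `temporal_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  UseMethod("export_network")
}

#' @export
export_network.default <- function(net, path, format = c("graphml", "tsv")) {
  stopf("export_network: unsupported object of class '%s'", class(net)[1L])
}

#' @export
export_network.haplo_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") return(graphml_write(net$nodes, net$edges, path))
  tsv_dump(stats::setNames(net$edges, c("hap_i", "hap_j", "weight")), path)
}

#' @export
export_network.temporal_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  lab <- function(e) data.frame(from = paste0("H", e$from),
                                to = paste0("H", e$to), weight = e$weight)
  edges <- rbind(lab(net$edges$ancient), lab(net$edges$modern))
  if (format == "graphml") return(graphml_write(net$nodes, edges, path))
  tsv_dump(stats::setNames(edges, c("hap_i", "hap_j", "weight")), path)
}
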