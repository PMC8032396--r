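test_that("haplotype distances are per-site mismatch counts", {
  ht <- call_haplotypes(make_aset(c("ACGA", "ACGT", "TCGA", "ACGA")))
  d <- haplotype_distances(ht)
  # order: ACGA (count 2), then ACGT, TCGA
  expect_equal(unname(d["H1", "H2"]), 1)
  expect_equal(unname(d["H1", "H3"]), 1)
  expect_equal(unname(d["H2", "H3"]), 2)
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] >= 1))
  # single haplotype: 1x1 zero matrix, no edges
  h1 <- call_haplotypes(make_aset(rep("ACGT", 3)))
  expect_equal(dim(haplotype_distances(h1)), c(1, 1))
  expect_equal(nrow(build_msn(h1)$edges), 0)
})

test_that("two haplotypes connect by a single edge at their distance", {
  ht <- call_haplotypes(make_aset(c("AAAA", "AATT")))
  net <- build_msn(ht)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 2)
})

test_that("epsilon relaxation grows the network up to the complete graph", {
  d <- matrix(c(0, 1, 3,
                1, 0, 1,
                3, 1, 0), 3, 3)
  expect_equal(nrow(msn_edges(d, 0)), 2)
  expect_equal(nrow(msn_edges(d, Inf)), 3)   # complete graph on 3 nodes
  e2 <- msn_edges(d, 2)
  expect_equal(nrow(e2), 3)
})

test_that("MSN at epsilon 0 is the union of both MSTs in a tied square", {
  # 4-cycle with unit sides and heavy diagonals: all four side edges are in
  # some MST, neither diagonal is
  d <- matrix(2, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1; d[2, 3] <- d[3, 2] <- 1
  d[3, 4] <- d[4, 3] <- 1; d[4, 1] <- d[1, 4] <- 1
  expect_equal(msn_edge_strings(d), c("1-2", "1-4", "2-3", "3-4"))
  expect_equal(msn_edge_strings(d), oracle_mst_union(d))
})

test_that("MSN equals the exhaustive union of minimum spanning trees (h <= 5)", {
  set.seed(41)
  for (h in 3:5) {
    spanning <- spanning_tree_subsets(h)
    for (rep in 1:10) {
      d <- matrix(0, h, h)
      d[upper.tri(d)] <- sample(1:5, h * (h - 1) / 2, replace = TRUE)
      d <- d + t(d)
      expect_equal(msn_edge_strings(d), oracle_mst_union(d, spanning))
    }
  }
})

test_that("the MSN edge set ignores sample order", {
  set.seed(42)
  seqs <- rand_seqs(12, 20)
  a <- build_msn(call_haplotypes(make_aset(seqs)))
  perm <- sample(12)
  b <- build_msn(call_haplotypes(make_aset(seqs[perm], ids = paste0("s", perm))))
  canon <- function(net) {
    key_of <- setNames(net$nodes$key, net$nodes$hap)
    e <- data.frame(a = key_of[net$edges$from], b = key_of[net$edges$to],
                    w = net$edges$weight)
    swap <- e$a > e$b
    tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
    e <- e[order(e$a, e$b), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(a), canon(b))
})

test_that("temporal layers account for shared and private haplotypes", {
  # ancient carries {H1, H2}; modern carries {H2, H3, H4}
  aset <- make_aset(c("AAAA", "AACC", "AACC", "CCCC", "GGGG"),
                    stratum = c("ancient", "ancient", "modern", "modern", "modern"))
  tn <- build_temporal(call_haplotypes(aset))
  expect_equal(unname(tn$counts["shared"]), 1)
  expect_equal(unname(tn$counts["private_ancient"]), 1)
  expect_equal(unname(tn$counts["private_modern"]), 2)
  expect_equal(unname(tn$counts["total"]), 4)
  # disjoint strata share nothing
  dj <- make_aset(c("AAAA", "CCCC"), stratum = c("ancient", "modern"))
  expect_equal(unname(build_temporal(call_haplotypes(dj))$counts["shared"]), 0)
  # a single-stratum table cannot be layered
  expect_error(build_temporal(call_haplotypes(make_aset(c("AAAA", "CCCC")))),
               "both strata")
})

test_that("haplotype sharing shrinks as lineage loss grows", {
  shared_frac <- sapply(c(0, 0.8), function(lam) {
    mean(sapply(1:8, function(s) {
      pool <- simulate_pool(K = 10, L = 60, seed = 700 + s)
      coh <- sample_cohorts(pool, n_ancient = 30, n_modern = 60, loss = lam,
                            miss_rate = 0, deam_rate = 0, seed = 750 + s)
      tn <- build_temporal(call_haplotypes(coh))
      tn$counts[["shared"]] / tn$counts[["total"]]
    }))
  })
  expect_gt(shared_frac[1], shared_frac[2])
})

test_that("GraphML export round-trips nodes, edges and count attributes", {
  skip_if_not_installed("xml2")
  aset <- make_aset(c("AAAA", "AACC", "AACC", "CCCC", "GGGG"),
                    stratum = c("ancient", "ancient", "modern", "modern", "modern"))
  net <- build_msn(call_haplotypes(aset))
  p <- tempfile(fileext = ".graphml")
  export_network(net, p, "graphml")
  doc <- xml2::read_xml(p)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  expect_setequal(xml2::xml_attr(nodes, "id"), net$nodes$hap)
  expect_equal(length(edges), nrow(net$edges))
  totals <- as.integer(xml2::xml_text(
    xml2::xml_find_all(doc, ".//g:node/g:data[@key='total']", ns)))
  expect_equal(sum(totals), 5)  # node counts conserve the cohort size
  ws <- as.integer(xml2::xml_text(
    xml2::xml_find_all(doc, ".//g:edge/g:data[@key='weight']", ns)))
  expect_setequal(ws, net$edges$weight)
})

test_that("TSV edge list export writes one line per edge", {
  net <- build_msn(call_haplotypes(make_aset(c("AAAA", "AATT"))))
  p <- tempfile(fileext = ".tsv")
  export_network(net, p, "tsv")
  lines <- readLines(p)
  expect_equal(lines[1], "hap_i\thap_j\tweight")
  expect_equal(length(lines), 2)
  expect_error(export_network(net, tempfile(), "gexf"), "arg")
})
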