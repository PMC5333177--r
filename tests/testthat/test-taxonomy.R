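test_that("lineages merge into a prefix tree with root depth 0", {
  tree <- human_like_tree()
  expect_equal(unname(tree$depth[["Cellular Organisms"]]), 0L)
  expect_equal(unname(tree$depth[["Eukaryota"]]), 1L)
  expect_equal(unname(tree$depth[["Vertebrata"]]), 5L)
  expect_equal(unname(tree$depth[["Mammalia"]]), 7L)
  expect_equal(unname(tree$depth[["Hominidae"]]), 13L)
  expect_equal(unname(tree$depth[["Homo"]]), 14L)
  # every lineage is recoverable as a root-to-node parent path
  org <- human_like_organisms()
  for (i in seq_len(nrow(org))) {
    lin <- strsplit(org$lineage[i], ";")[[1]]
    walked <- tree$org_taxon[[org$org_code[i]]]
    while (!is.na(tree$parent[[walked[1]]]))
      walked <- c(tree$parent[[walked[1]]], walked)
    expect_equal(walked, lin)
  }
})

test_that("conflicting parents for one taxon are a construction error", {
  org <- data.frame(
    org_code = c("a", "b"),
    name = c("a", "b"),
    lineage = c("Root;X;Leaf1", "Root;Y;Leaf1;Leaf2"),
    stringsAsFactors = FALSE)
  expect_error(build_taxonomy(org), "conflicting parents")
})

test_that("lca_depth matches ancestor-set intersection on random trees", {
  tree <- human_like_tree()
  expect_equal(lca_depth(tree, "hsa", "hsa"), 14L)  # self-LCA = N
  expect_equal(lca_depth(tree, "hsa", "pps"), 13L)
  expect_equal(lca_depth(tree, "hsa", "mdo"), 7L)
  expect_equal(lca_depth(tree, "mdo", "pps"), 7L)
  expect_equal(lca_depth(tree, "hsa", "dme"), 3L)
  expect_error(lca_depth(tree, "hsa", "xyz"), "unknown organism")

  set.seed(42)
  for (rep in 1:20) {
    cfg <- sim_config(seed = rep, lineage_depth = sample(3:10, 1),
                      branching = sample(1:3, 1))
    org <- make_taxonomy(cfg)
    tr <- build_taxonomy(org)
    pair <- sample(org$org_code, 2)
    # oracle: deepest shared member of the two full ancestor sets
    lin1 <- strsplit(org$lineage[org$org_code == pair[1]], ";")[[1]]
    lin2 <- strsplit(org$lineage[org$org_code == pair[2]], ";")[[1]]
    shared <- intersect(lin1, lin2)
    oracle <- max(match(shared, lin1)) - 1L
    expect_equal(lca_depth(tr, pair[1], pair[2]), oracle)
  }
})

test_that("PAI is the LCA depth over ortholog organisms", {
  tree <- human_like_tree()
  r <- compute_pai(tree, "hsa", "pps", gene_id = "g")
  expect_equal(r$pai, 13L)
  expect_equal(r$taxon_name, "Hominidae")
  r <- compute_pai(tree, "hsa", c("pps", "mdo"))
  expect_equal(r$pai, 7L)
  expect_equal(r$taxon_name, "Mammalia")
  # no ortholog outside the reference: terminal depth
  r <- compute_pai(tree, "hsa", character(0))
  expect_equal(r$pai, 14L)
  expect_equal(r$taxon_name, "Homo")
  # reference-organism entries (paralogs) are ignored
  r <- compute_pai(tree, "hsa", c("hsa", "pps"))
  expect_equal(r$pai, 13L)
  expect_error(compute_pai(tree, "hsa", "nope"), "unknown organism")
})

test_that("adding ortholog species never increases PAI", {
  set.seed(7)
  cfg <- sim_config(seed = 7, lineage_depth = 8, branching = 2)
  tr <- build_taxonomy(make_taxonomy(cfg))
  orgs <- setdiff(names(tr$org_taxon), "ref")
  for (rep in 1:25) {
    base <- sample(orgs, sample(0:4, 1))
    extra <- sample(setdiff(orgs, base), 1)
    p0 <- compute_pai(tr, "ref", base)$pai
    p1 <- compute_pai(tr, "ref", c(base, extra))$pai
    expect_lte(p1, p0)
  }
})

test_that("min-over-species equals deepest covering ancestor", {
  # equivalence of the two PAI formulations, brute-forced on random trees
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, lineage_depth = 6, branching = 2)
    org <- make_taxonomy(cfg)
    tr <- build_taxonomy(org)
    others <- setdiff(org$org_code, "ref")
    set.seed(seed + 100)
    chosen <- sample(others, sample(1:5, 1))
    ref_lin <- strsplit(org$lineage[org$org_code == "ref"], ";")[[1]]
    covers <- vapply(seq_along(ref_lin), function(k) {
      anc <- ref_lin[k]
      all(vapply(chosen, function(o) {
        anc %in% strsplit(org$lineage[org$org_code == o], ";")[[1]]
      }, TRUE))
    }, TRUE)
    oracle <- max(which(covers)) - 1L
    expect_equal(compute_pai(tr, "ref", chosen)$pai, oracle)
  }
})

test_that("taxon_name_at validates its depth range", {
  tree <- human_like_tree()
  expect_equal(taxon_name_at(tree, "hsa", 0), "Cellular Organisms")
  expect_equal(taxon_name_at(tree, "hsa", 1), "Eukaryota")
  expect_equal(taxon_name_at(tree, "hsa", 14), "Homo")
  expect_error(taxon_name_at(tree, "hsa", 15), "outside")
  expect_error(taxon_name_at(tree, "hsa", -1), "outside")
})
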