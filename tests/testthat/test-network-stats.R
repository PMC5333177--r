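make_net <- function(gene_ids, edge_pairs, compounds = character(0)) {
  nodes <- data.frame(
    node_id = c(gene_ids, compounds),
    type = c(rep("gene", length(gene_ids)),
             rep("compound", length(compounds))),
    gene_id = c(gene_ids, rep("", length(compounds))),
    label = c(gene_ids, compounds), stringsAsFactors = FALSE)
  edges <- if (length(edge_pairs) == 0)
    data.frame(from = character(0), to = character(0),
               interaction = character(0), stringsAsFactors = FALSE)
  else data.frame(from = vapply(edge_pairs, `[`, "", 1),
                  to = vapply(edge_pairs, `[`, "", 2),
                  interaction = "", stringsAsFactors = FALSE)
  gene_network(nodes, edges)
}

test_that("gene set PAI is the arithmetic mean with its edge cases", {
  expect_equal(gene_set_pai(rep(0, 6)), 0)
  expect_equal(gene_set_pai(rep(14, 3)), 14)
  expect_equal(gene_set_pai(c(7, 13)), 10)
  expect_error(gene_set_pai(numeric(0)), "empty")
  set.seed(3)
  x <- sample(0:14, 25, replace = TRUE)
  expect_gte(gene_set_pai(x), min(x))
  expect_lte(gene_set_pai(x), max(x))
})

test_that("network PAI matches hand evaluation of sum(PAI*d)/(2N)", {
  # two genes joined by one edge: (4*1 + 6*1) / (2*2)
  n1 <- make_net(c("a", "b"), list(c("a", "b")))
  expect_equal(network_pai(n1, c(a = 4, b = 6)), 2.5)

  # single isolated gene: degree 0
  n2 <- make_net("a", list())
  expect_equal(network_pai(n2, c(a = 9)), 0)

  # star: center PAI 2 degree 3, three leaves PAI 0
  n3 <- make_net(c("c", "l1", "l2", "l3"),
                 list(c("c", "l1"), c("c", "l2"), c("c", "l3")))
  expect_equal(network_pai(n3, c(c = 2, l1 = 0, l2 = 0, l3 = 0)),
               6 / 8)

  # path a-b-c: degrees 1,2,1
  n4 <- make_net(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
  expect_equal(network_pai(n4, c(a = 3, b = 5, c = 7)),
               (3 * 1 + 5 * 2 + 7 * 1) / 6)

  # compound edges count toward gene degree, compounds not toward N
  n5 <- make_net(c("a", "b"), list(c("a", "x"), c("b", "x")), "x")
  expect_equal(network_pai(n5, c(a = 4, b = 8)), (4 + 8) / 4)

  expect_error(network_pai(make_net("a", list()), c(zz = 1)), "missing")
})

test_that("k-regular gene-only networks tie the two PAI statistics", {
  # ring = 2-regular: network PAI = (2/2) * gene set PAI
  ids <- sprintf("g%d", 1:6)
  ring <- make_net(ids, lapply(1:6, function(i)
    c(ids[i], ids[i %% 6 + 1])))
  pai <- stats::setNames(sample(0:14, 6, replace = TRUE), ids)
  expect_equal(network_pai(ring, pai), gene_set_pai(pai))
})

test_that("summary picks oldest/youngest/median taxa on the reference lineage", {
  tree <- human_like_tree()
  net <- make_net(c("n1", "n2", "n3"), list())
  mk <- function(node, pai_orgs) compute_pai(tree, "hsa", pai_orgs)
  res <- list(n1 = compute_pai(tree, "hsa", "dme"),      # PAI 3
              n2 = compute_pai(tree, "hsa", "mdo"),      # PAI 7
              n3 = compute_pai(tree, "hsa", "pps"))      # PAI 13
  s <- pai_summary(net, res, tree, "hsa")
  expect_equal(s$oldest_taxon, "Metazoa")
  expect_equal(s$median_taxon, "Mammalia")
  expect_equal(s$youngest_taxon, "Hominidae")
  expect_equal(s$gene_set_pai, mean(c(3, 7, 13)))
  expect_equal(s$total_orthologs, 3)

  # single gene: all three taxa coincide
  s1 <- pai_summary(make_net("n1", list()), res["n1"], tree, "hsa")
  expect_equal(s1$oldest_taxon, s1$youngest_taxon)
  expect_equal(s1$oldest_taxon, s1$median_taxon)

  # even count: median is the lower middle value
  res2 <- list(n1 = compute_pai(tree, "hsa", "dme"),     # 3
               n2 = compute_pai(tree, "hsa", "mdo"))     # 7
  s2 <- pai_summary(make_net(c("n1", "n2"), list()), res2, tree, "hsa")
  expect_equal(s2$median_taxon, "Metazoa")
})

test_that("phylogenetic profile marks ortholog presence, no empty rows", {
  m <- phylogenetic_profile(c("g1", "g2"),
                            list(g1 = "mmu", g2 = c("mmu", "dme")))
  expect_equal(rownames(m), c("dme", "mmu"))
  expect_equal(colnames(m), c("g1", "g2"))
  expect_equal(m["mmu", "g1"], "+")
  expect_equal(m["dme", "g1"], "-")
  expect_equal(m["dme", "g2"], "+")
  expect_false(any(apply(m, 1, function(r) all(r == "-"))))

  empty <- phylogenetic_profile(c("g1", "g2"),
                                list(g1 = character(0), g2 = character(0)))
  expect_equal(nrow(empty), 0)

  set.seed(14)
  genes <- sprintf("g%d", 1:8)
  orgs <- sprintf("o%d", 1:6)
  omap <- lapply(genes, function(g) sample(orgs, sample(0:4, 1)))
  names(omap) <- genes
  m2 <- phylogenetic_profile(genes, omap)
  for (g in genes) for (o in rownames(m2))
    expect_equal(unname(m2[o, g]), if (o %in% omap[[g]]) "+" else "-")
})
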