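random_hits <- function(n) {
  data.frame(query_gene = sprintf("q%02d", sample(20, n, replace = TRUE)),
             subject_gene = sprintf("s%02d", sample(20, n, replace = TRUE)),
             sw_score = round(stats::runif(n, 0, 1000)),
             identity = round(stats::runif(n), 3),
             stringsAsFactors = FALSE)
}

test_that("score/identity filtering is an inclusive row predicate", {
  cfg <- filter_config(sw_min = 500, identity_min = 0.5)
  one <- data.frame(query_gene = "a", subject_gene = "b",
                    sw_score = 500, identity = 0.5,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_hits(one, cfg)), 1)  # boundary is retained
  one$sw_score <- 499
  one$identity <- 0.9
  expect_equal(nrow(filter_hits(one, filter_config(sw_min = 500,
                                                   identity_min = 0))), 0)

  set.seed(101)
  h <- random_hits(200)
  got <- filter_hits(h, cfg)
  keep <- vapply(seq_len(nrow(h)), function(i)
    h$sw_score[i] >= 500 && h$identity[i] >= 0.5, TRUE)
  expect_equal(unrowname(got), unrowname(h[keep, ]))
})

test_that("raising thresholds never adds a hit (monotonicity)", {
  set.seed(5)
  h <- random_hits(150)
  for (rep in 1:10) {
    sw1 <- runif(1, 0, 800); sw2 <- sw1 + runif(1, 0, 200)
    id1 <- runif(1); id2 <- min(1, id1 + runif(1, 0, 0.3))
    lo <- filter_hits(h, filter_config(sw_min = sw1, identity_min = id1))
    hi <- filter_hits(h, filter_config(sw_min = sw2, identity_min = id2))
    key <- function(d) paste(d$query_gene, d$subject_gene, d$sw_score,
                             d$identity)
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("domain ranking counts genes and breaks ties lexicographically", {
  dom <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g1"),
    domain_id = c("D1", "D1", "D1", "D2", "D2", "D3"),
    stringsAsFactors = FALSE)
  expect_equal(rank_domains(c("g1", "g2", "g3"), dom), c("D1", "D2", "D3"))
  tie <- data.frame(gene_id = c("g1", "g2", "g1", "g2"),
                    domain_id = c("Db", "Db", "Da", "Da"),
                    stringsAsFactors = FALSE)
  expect_equal(rank_domains(c("g1", "g2"), tie), c("Da", "Db"))

  set.seed(33)
  genes <- sprintf("g%02d", 1:12)
  dom_r <- data.frame(
    gene_id = sample(genes, 60, replace = TRUE),
    domain_id = sprintf("D%02d", sample(8, 60, replace = TRUE)),
    stringsAsFactors = FALSE)
  got <- rank_domains(genes, dom_r)
  counts <- vapply(got, function(d)
    length(unique(dom_r$gene_id[dom_r$domain_id == d])), 0)
  expect_true(all(diff(counts) <= 0))
  for (i in seq_len(length(got) - 1))
    if (counts[i] == counts[i + 1]) expect_true(got[i] < got[i + 1])
})

test_that("simple domain filter requires the top-T domains", {
  dom <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    domain_id = c("D1", "D2", "D1", "D9"),
                    stringsAsFactors = FALSE)
  cand <- c("g1", "g2", "g3")
  expect_equal(domain_filter_simple(cand, c("D1", "D2"), 0, dom), cand)
  expect_equal(domain_filter_simple(cand, c("D1", "D2"), 2, dom), "g1")
  # T beyond the ranking length degrades to "contains the whole ranking"
  expect_equal(domain_filter_simple(cand, c("D1", "D2"), 5, dom), "g1")
  expect_equal(domain_filter_simple(cand, c("D1"), 1, dom), c("g1", "g2"))

  set.seed(12)
  genes <- sprintf("g%02d", 1:15)
  dom_r <- data.frame(gene_id = sample(genes, 50, replace = TRUE),
                      domain_id = sprintf("D%d", sample(5, 50, TRUE)),
                      stringsAsFactors = FALSE)
  ranking <- rank_domains(genes, dom_r)
  for (T in 0:6) {
    got <- domain_filter_simple(genes, ranking, T, dom_r)
    need <- ranking[seq_len(min(T, length(ranking)))]
    want <- genes[vapply(genes, function(g)
      all(need %in% dom_r$domain_id[dom_r$gene_id == g]), TRUE)]
    expect_equal(got, want)
  }
})

test_that("detailed domain filter keeps genes with any required domain", {
  dom <- data.frame(gene_id = c("g1", "g1", "g2"),
                    domain_id = c("D5", "D9", "D7"),
                    stringsAsFactors = FALSE)
  expect_equal(domain_filter_detailed(c("g1", "g2", "g3"), "D5", dom), "g1")
  # a candidate with no required domain at all is dropped
  expect_equal(domain_filter_detailed("g3", "D5", dom), character(0))
  expect_equal(domain_filter_detailed(c("g1", "g2"), character(0), dom),
               c("g1", "g2"))

  set.seed(21)
  genes <- sprintf("g%02d", 1:12)
  dom_r <- data.frame(gene_id = sample(genes, 40, replace = TRUE),
                      domain_id = sprintf("D%d", sample(6, 40, TRUE)),
                      stringsAsFactors = FALSE)
  req <- c("D1", "D4")
  got <- domain_filter_detailed(genes, req, dom_r)
  want <- genes[vapply(genes, function(g)
    length(intersect(dom_r$domain_id[dom_r$gene_id == g], req)) > 0, TRUE)]
  expect_equal(got, want)
})

test_that("clustering returns connected components of qualifying links", {
  ds <- toy_datastore()
  net <- toy_network()
  # hsa:1-hsa:2 paralog hit (sw 700, id 0.6) links n1,n2; hsa:3 singleton
  cl <- cluster_network_genes(net, ds, filter_config(sw_min = 500,
                                                     identity_min = 0.5))
  expect_equal(length(cl$clusters), 2)
  expect_equal(cl$membership[["hsa:1"]], cl$membership[["hsa:2"]])
  expect_false(cl$membership[["hsa:1"]] == cl$membership[["hsa:3"]])
  # strict thresholds: everything singleton
  cl2 <- cluster_network_genes(net, ds, filter_config(sw_min = 2000,
                                                      identity_min = 0.99))
  expect_equal(length(cl2$clusters), 3)

  bad_net <- gene_network(
    data.frame(node_id = "nx", type = "gene", gene_id = "hsa:99",
               label = "", stringsAsFactors = FALSE),
    data.frame(from = character(0), to = character(0),
               interaction = character(0), stringsAsFactors = FALSE))
  expect_error(cluster_network_genes(bad_net, ds, filter_config()),
               "hsa:99")
})

test_that("clustering equals brute-force components on random instances", {
  set.seed(9)
  for (rep in 1:8) {
    n <- 15
    genes <- sprintf("hsa:%02d", 1:n)
    org <- human_like_organisms()
    gdf <- data.frame(gene_id = genes, org_code = "hsa", label = genes,
                      annotation = "", stringsAsFactors = FALSE)
    m <- sample(5:20, 1)
    pair <- replicate(m, sample(genes, 2))
    hits <- data.frame(query_gene = pair[1, ], subject_gene = pair[2, ],
                       sw_score = sample(c(100, 900), m, replace = TRUE),
                       identity = runif(m, 0.5, 1),
                       stringsAsFactors = FALSE)
    ds <- new_datastore(org, gdf, hits, empty_domains_df())
    net <- gene_network(
      data.frame(node_id = genes, type = "gene", gene_id = genes,
                 label = genes, stringsAsFactors = FALSE),
      data.frame(from = character(0), to = character(0),
                 interaction = character(0), stringsAsFactors = FALSE))
    cfg <- filter_config(sw_min = 500, identity_min = 0.5)
    cl <- cluster_network_genes(net, ds, cfg)
    keep <- hits$sw_score >= 500 & hits$identity >= 0.5
    oracle <- components_oracle(genes, hits$query_gene[keep],
                                hits$subject_gene[keep])
    # same partition: co-membership agrees for every pair
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(cl$membership[[genes[i]]] == cl$membership[[genes[j]]],
                   oracle[[genes[i]]] == oracle[[genes[j]]])
    }
  }
})

test_that("cluster count never rises as thresholds are lowered", {
  sim <- simulate_datastore(sim_config(seed = 8, n_genes = 10,
                                       lineage_depth = 6, codon_length = 30,
                                       paralog_pairs = cbind(c(1, 3, 5),
                                                             c(2, 4, 6))))
  counts <- vapply(c(0.95, 0.8, 0.6, 0.3, 0), function(idm) {
    cl <- cluster_network_genes(sim$network, sim$datastore,
                                filter_config(sw_min = 0,
                                              identity_min = idm))
    length(cl$clusters)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("collapsing clusters merges nodes, edges and drops self-loops", {
  ds <- toy_datastore()
  net <- toy_network()
  # all singletons: isomorphic to input
  cl_single <- cluster_network_genes(net, ds,
                                     filter_config(sw_min = 2000,
                                                   identity_min = 0.99))
  out <- collapse_clusters(net, cl_single)
  expect_equal(nrow(out$nodes), nrow(net$nodes))
  expect_equal(nrow(out$edges), nrow(net$edges))

  # {hsa:1, hsa:2} merge: n1-n2 edge becomes a self-loop and is dropped
  cl <- cluster_network_genes(net, ds, filter_config())
  out2 <- collapse_clusters(net, cl)
  expect_equal(nrow(out2$nodes), length(cl$clusters) +
                 sum(net$nodes$type != "gene"))
  merged <- out2$nodes$node_id[grepl("\\+", out2$nodes$label)]
  expect_length(merged, 1)
  expect_false(any(out2$edges$from == out2$edges$to))
  # reachability preserved: merged cluster still reaches hsa:3's cluster
  single <- out2$nodes$node_id[out2$nodes$type == "gene" &
                                 out2$nodes$gene_id == "hsa:3"]
  g <- igraph::graph_from_data_frame(out2$edges[1:2], directed = FALSE,
                                     vertices = out2$nodes$node_id)
  d <- igraph::distances(g, v = merged, to = single)
  expect_true(is.finite(d[1, 1]))
})

test_that("collapse of a triangle with a two-gene cluster gives 2 nodes, 1 edge", {
  org <- human_like_organisms()
  genes <- sprintf("hsa:%d", 1:3)
  gdf <- data.frame(gene_id = genes, org_code = "hsa", label = genes,
                    annotation = "", stringsAsFactors = FALSE)
  hits <- data.frame(query_gene = "hsa:1", subject_gene = "hsa:2",
                     sw_score = 900, identity = 0.9,
                     stringsAsFactors = FALSE)
  ds <- new_datastore(org, gdf, hits, empty_domains_df())
  net <- gene_network(
    data.frame(node_id = genes, type = "gene", gene_id = genes,
               label = genes, stringsAsFactors = FALSE),
    data.frame(from = c("hsa:1", "hsa:2", "hsa:1"),
               to = c("hsa:2", "hsa:3", "hsa:3"),
               interaction = "", stringsAsFactors = FALSE))
  cl <- cluster_network_genes(net, ds, filter_config())
  out <- collapse_clusters(net, cl)
  expect_equal(nrow(out$nodes), 2)
  expect_equal(nrow(out$edges), 1)
})
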