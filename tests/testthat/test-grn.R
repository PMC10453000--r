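test_that("class_template_scores: planted marker, conventions, hand case", {
  w <- small_world()
  tmpl <- class_template_scores(w$expr, w$labels)
  expect_equal(colnames(tmpl), sort(unique(w$labels)))
  expect_true(all(tmpl >= -1 & tmpl <= 1))
  # planted marker scores maximal and positive for its own class
  s <- tmpl["TF_c01_01", ]
  expect_gt(s["class01"], 0)
  expect_equal(names(which.max(s)), "class01")

  # constant gene scores 0 for every class
  m <- w$expr[1:5, ]
  m[1, ] <- 7
  tmpl0 <- class_template_scores(m, w$labels)
  expect_equal(unname(tmpl0[1, ]), rep(0, ncol(tmpl0)))

  # 4-sample hand case: values 1,2,9,10; classes B,B,A,A
  mh <- matrix(c(1, 2, 9, 10), nrow = 1, dimnames = list("g", NULL))
  th <- class_template_scores(rbind(mh, mh), c("B", "B", "A", "A"))
  x <- c(1, 2, 9, 10); ind <- c(0, 0, 1, 1)
  r_hand <- sum((x - mean(x)) * (ind - mean(ind))) /
    sqrt(sum((x - mean(x))^2) * sum((ind - mean(ind))^2))
  expect_equal(unname(th["g", "A"]), r_hand, tolerance = 1e-12)
  expect_equal(unname(th["g", "B"]), -r_hand, tolerance = 1e-12)

  expect_error(class_template_scores(w$expr, rep("one", ncol(w$expr))),
               "2 classes")
  expect_error(class_template_scores(w$expr[, 1:11],
                                     c(rep("a", 10), "b")),
               "< 2 samples")
})

test_that("reconstruct_network: null retention, perfect pair, empty gold", {
  # i.i.d. noise corpus: at z_threshold 2, at most 10% of decoy edges survive
  set.seed(31)
  n_genes <- 60
  expr <- matrix(exp(rnorm(n_genes * 200, log(100), 0.5)), nrow = n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 sprintf("s%03d", 1:200)))
  gold <- data.frame(tf = sprintf("g%02d", sample(n_genes, 100, TRUE)),
                     target = sprintf("g%02d", sample(n_genes, 100, TRUE)))
  gold <- unique(gold[gold$tf != gold$target, ])
  net <- reconstruct_network(expr, gold, z_threshold = 2)
  expect_lte(nrow(net), 0.10 * nrow(gold))

  # one perfectly co-varying pair: retained with the maximum weight
  expr2 <- expr
  expr2["g02", ] <- 3 * expr2["g01", ]
  gold2 <- rbind(gold, data.frame(tf = "g01", target = "g02"))
  net2 <- reconstruct_network(expr2, gold2, z_threshold = 2)
  expect_true(any(net2$tf == "g01" & net2$target == "g02"))
  best <- which(net2$tf == "g01" & net2$target == "g02")
  expect_equal(net2$weight[best], max(net2$weight))
  expect_equal(net2$sign[best], 1)

  empty <- reconstruct_network(expr, gold[0, ], z_threshold = 2)
  expect_equal(nrow(empty), 0)

  # genes absent from the matrix are skipped with a warning
  goldx <- rbind(gold, data.frame(tf = "nosuch", target = "g01"))
  expect_warning(reconstruct_network(expr, goldx), "absent")
})

test_that("every retained edge is a gold pair and pruning is monotone", {
  w <- small_world()
  key <- paste(w$gold$tf, w$gold$target)
  for (thr in c(1, 2, 4)) {
    net <- reconstruct_network(w$expr, w$gold, z_threshold = thr)
    expect_true(all(paste(net$tf, net$target) %in% key))
  }
  n_edges <- vapply(c(0.5, 1, 2, 3, 5),
                    function(t) nrow(reconstruct_network(w$expr, w$gold, t)),
                    0L)
  expect_true(all(diff(n_edges) <= 0))
})

test_that("detect_communities: components, determinism, empty input", {
  # two disconnected 5-gene hubs -> exactly 2 communities = components
  edges <- data.frame(tf = c(rep("A", 4), rep("B", 4)),
                      target = c(paste0("a", 1:4), paste0("b", 1:4)),
                      rho = 0.9, weight = 3, sign = 1)
  net <- structure(edges, class = c("grn_network", "data.frame"))
  part <- detect_communities(net, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[c("A", paste0("a", 1:4))])), 1)
  expect_equal(length(unique(part[c("B", paste0("b", 1:4))])), 1)

  expect_identical(part, detect_communities(net, seed = 1))
  expect_length(detect_communities(net[0, ], seed = 1), 0)
})

test_that("assign_subnetworks: enrichment, exclusivity, brute-force hypergeometric", {
  tw <- trained_world()
  w <- tw$w
  # each class GRN recovers its planted hub genes (Jaccard on the small world)
  for (ci in 1:6) {
    cl <- sprintf("class%02d", ci)
    planted <- planted_genes_of(w$truth, cl)
    g <- tw$grns[[cl]]$genes
    expect_gt(length(intersect(g, planted)) / length(union(g, planted)), 0.7)
    # edges connect member genes only
    expect_true(all(tw$grns[[cl]]$edges$tf %in% g))
    expect_true(all(tw$grns[[cl]]$edges$target %in% g))
  }
  # a community of pure background genes is assigned to no class
  bg_in_grns <- unlist(lapply(tw$grns, function(g) grep("^BG", g$genes,
                                                        value = TRUE)))
  expect_length(bg_in_grns, 0)

  # hypergeometric p equals the exact tail sum on a 20-gene toy universe
  genes <- sprintf("t%02d", 1:20)
  tmpl <- matrix(0, 20, 2, dimnames = list(genes, c("X", "Y")))
  tmpl[1:6, "X"] <- seq(1, 0.5, length.out = 6)     # top_k=6 set = t01..t06
  tmpl[7:20, "X"] <- seq(0.4, 0, length.out = 14)
  tmpl[, "Y"] <- rev(tmpl[, "X"])
  part <- setNames(c(rep(1L, 5), rep(2L, 15)), genes)  # community 1 = t01..t05
  K <- 6; N <- 20; m <- 5; k <- 5                      # overlap = 5
  p_brute <- sum(vapply(k:min(K, m), function(i)
    choose(K, i) * choose(N - K, m - i), 0)) / choose(N, m)
  p_code <- phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  expect_equal(p_code, p_brute, tolerance = 1e-12)
  net0 <- structure(data.frame(tf = character(0), target = character(0),
                               rho = numeric(0), weight = numeric(0),
                               sign = numeric(0)),
                    class = c("grn_network", "data.frame"))
  grns <- assign_subnetworks(part, tmpl, net0, top_k = 6, alpha = 0.05)
  expect_setequal(grns$X$genes, genes[1:5])  # p_brute * 4 tests < 0.05
})

test_that("grn_metrics conservation and empty GRNs", {
  tw <- trained_world()
  m <- grn_metrics(tw$grns)
  expect_equal(sum(m$targets_per_tf$n_targets), sum(m$summary$n_edges))
  expect_equal(sum(m$regulators_per_target$n_regulators),
               sum(m$summary$n_edges))
  # TF with edges to {a, b} contributes 2 to the distribution
  g1 <- tw$grns[[1]]
  tf1 <- g1$edges$tf[1]
  expect_equal(m$targets_per_tf$n_targets[m$targets_per_tf$tf == tf1 &
                                            m$targets_per_tf$class == g1$class],
               sum(g1$edges$tf == tf1))

  empty <- structure(list(class = "none", genes = character(0),
                          edges = g1$edges[0, ],
                          importance = numeric(0)), class = "class_grn")
  m0 <- grn_metrics(list(none = empty))
  expect_equal(m0$summary$n_nodes, 0L)
  expect_equal(m0$summary$n_edges, 0L)
})

test_that("export_network round-trips through GraphML", {
  tw <- trained_world()
  g1 <- tw$grns[[1]]
  path <- tempfile(fileext = ".graphml")
  export_network(g1, path, hash = "deadbeef")
  back <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(back)$name, g1$genes)
  expect_equal(igraph::ecount(back), nrow(g1$edges))
  # influence attribute equals independently computed degree
  deg <- table(c(g1$edges$tf, g1$edges$target))
  for (v in igraph::V(back)$name) {
    expected <- if (v %in% names(deg)) as.numeric(deg[[v]]) else 0
    expect_equal(igraph::V(back)$influence[igraph::V(back)$name == v],
                 expected)
  }
  expect_equal(igraph::graph_attr(back, "config_hash"), "deadbeef")
  # edge weights preserved
  back_edges <- igraph::as_data_frame(back)
  key <- paste(g1$edges$tf, g1$edges$target)
  expect_setequal(paste(back_edges$from, back_edges$to), key)
  expect_equal(sort(back_edges$weight), sort(g1$edges$weight),
               tolerance = 1e-9)

  # empty GRN -> valid zero-node GraphML
  empty <- structure(list(class = "none", genes = character(0),
                          edges = g1$edges[0, ], importance = numeric(0)),
                     class = "class_grn")
  p0 <- tempfile(fileext = ".graphml")
  export_network(empty, p0)
  expect_equal(igraph::vcount(igraph::read_graph(p0, format = "graphml")), 0)
})
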