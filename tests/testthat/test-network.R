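test_that("descriptor hubs sum the ROAVs of their key compounds", {
  # printed ROAVs of the four sweet-tagged RS key compounds
  nm <- c("styrene", "caryophyllene", "alpha-ionone", "beta-ocimene")
  roav <- c(16.26, 7.54, 4.19, 3.75)
  res <- structure(
    data.frame(compound = nm, content = 1, threshold = 1, oav = 1,
               has_threshold = TRUE, roav = roav, category = "key",
               stringsAsFactors = FALSE),
    group = "RS", class = c("roav_result", "data.frame"))
  thr <- toy_thresholds(nm, rep(0.01, 4),
                        c("sweet;balsam", "sweet;woody", "sweet;floral",
                          "floral;sweet"))
  net <- build_flavor_network(res, thr)
  sweet <- net$descriptor_nodes
  expect_equal(sweet$summed_roav[sweet$descriptor == "sweet"], 31.74)
  expect_equal(sweet$degree[sweet$descriptor == "sweet"], 4)
})

test_that("network is bipartite, conserves ROAV over edges, keys only", {
  p <- rosa_group_profiles()
  thr <- rosa_odor_thresholds()
  res <- compute_roav(p$RS, thr)
  net <- build_flavor_network(res, thr)
  key <- classify_roav(res)$key
  expect_setequal(net$compound_nodes$compound, key$compound)
  expect_true(all(net$edges$compound %in% net$compound_nodes$compound))
  expect_true(all(net$edges$descriptor %in%
                    net$descriptor_nodes$descriptor))
  expect_equal(length(intersect(net$edges$compound,
                                net$edges$descriptor)), 0)
  # per-descriptor conservation and the global identity
  for (d in net$descriptor_nodes$descriptor) {
    expect_equal(net$descriptor_nodes$summed_roav[
                   net$descriptor_nodes$descriptor == d],
                 sum(net$edges$weight[net$edges$descriptor == d]))
  }
  ndesc <- lengths(thr$descriptors[match(key$compound, thr$compound)])
  expect_equal(sum(net$descriptor_nodes$summed_roav),
               sum(key$roav * ndesc))
})

test_that("duplicate descriptors collapse to one edge; trivial network works", {
  res <- structure(
    data.frame(compound = "solo", content = 10, threshold = 0.1, oav = 100,
               has_threshold = TRUE, roav = 100, category = "key",
               stringsAsFactors = FALSE),
    group = "g", class = c("roav_result", "data.frame"))
  thr <- toy_thresholds("solo", 0.1, "Sweet; sweet ;SWEET")
  net <- build_flavor_network(res, thr)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$descriptor_nodes$summed_roav, 100)
  expect_equal(nrow(net$compound_nodes) + nrow(net$descriptor_nodes), 2)
})

test_that("a key compound without descriptors stays as an isolated node", {
  res <- structure(
    data.frame(compound = c("a", "b"), content = c(10, 5),
               threshold = c(0.1, 0.1), oav = c(100, 50),
               has_threshold = TRUE, roav = c(100, 50), category = "key",
               stringsAsFactors = FALSE),
    group = "g", class = c("roav_result", "data.frame"))
  thr <- toy_thresholds(c("a", "b"), c(0.1, 0.1), c("fruity", ""))
  expect_warning(net <- build_flavor_network(res, thr), "isolated")
  expect_true("b" %in% net$compound_nodes$compound)
  expect_false("b" %in% net$edges$compound)
})

test_that("GraphML and edge-list export round-trip through igraph", {
  p <- rosa_group_profiles()
  thr <- rosa_odor_thresholds()
  net <- build_flavor_network(compute_roav(p$RR, thr), thr)
  gml <- tempfile(fileext = ".graphml")
  csv <- tempfile(fileext = ".csv")
  write_flavor_network(net, csv, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g),
               nrow(net$compound_nodes) + nrow(net$descriptor_nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  edges <- utils::read.csv(csv)
  expect_equal(nrow(edges), nrow(net$edges))
})
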