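# builds a small study and returns the per-group families for one layer
assembled_fixture <- function(seed = 81, layer_name = "rna", ...) {
  st <- simulate_study(n_features = 40, n_per_group = 30, n_diff_edges = 4,
                       n_null_edges = 10, seed = seed, ...)
  st$layer$layer_name <- layer_name
  act <- percolation_scan(st$layer, st$labels, st$net)
  list(st = st, act = act)
}

test_that("a single layer integrates to itself", {
  fx <- assembled_fixture()
  fam <- fx$act$families[["g2"]]
  net <- integrate_layers(list(rna = fam), "g2")
  expect_s3_class(net, "differential_network")
  expect_equal(names(net$layers), "rna")
  expect_identical(net$layers$rna$edges, fam$differential)
  expect_identical(net$layers$rna$nodes, fam$nodes)
})

test_that("cross-layer mapping aligns nodes without merging statistics", {
  fx1 <- assembled_fixture(81, "rna")
  fx2 <- assembled_fixture(82, "prot")
  f1 <- fx1$act$families[["g2"]]
  f2 <- fx2$act$families[["g2"]]
  id1 <- f1$nodes[1]; id2 <- f2$nodes[1]
  mp <- layer_mapping(c("rna", "rna"), c(id1, "NOPE"),
                      c("prot", "prot"), c(id2, "ALSO_NOPE"))
  expect_warning(net <- integrate_layers(list(rna = f1, prot = f2), "g2", mp),
                 "skipped 1 mapping pair")
  expect_equal(nrow(net$alignment), 1)
  expect_equal(net$alignment$id_a, id1)
  # per-layer edge statistics preserved untouched
  expect_identical(net$layers$rna$edges, f1$differential)
  expect_identical(net$layers$prot$edges, f2$differential)
})

test_that("multi-layer edge counts are additive and order-invariant", {
  fams <- lapply(1:4, function(i)
    assembled_fixture(90 + i, paste0("layer", i))$act$families[["g2"]])
  names(fams) <- paste0("layer", 1:4)
  net <- integrate_layers(fams, "g2")
  per_layer <- vapply(fams, function(f) nrow(f$differential), 1L)
  expect_equal(sum(vapply(net$layers, function(l) nrow(l$edges), 1L)),
               sum(per_layer))
  perm <- integrate_layers(fams[c(3, 1, 4, 2)], "g2")
  for (nm in names(fams))
    expect_identical(perm$layers[[nm]], net$layers[[nm]])
})

test_that("TSV export has one row per differential edge", {
  fx <- assembled_fixture()
  net <- integrate_layers(list(rna = fx$act$families[["g2"]]), "g2")
  n_edges <- nrow(net$layers$rna$edges)
  expect_gt(n_edges, 0)
  path <- tempfile(fileext = ".tsv")
  export_network(net, path, "tsv")
  tab <- read.delim(path)
  expect_equal(nrow(tab), n_edges)
  expect_true(all(c("layer", "group", "source", "target", "p_adj") %in%
                    names(tab)))
})

test_that("JSON export round-trips the full structure", {
  fx <- assembled_fixture()
  net <- integrate_layers(list(rna = fx$act$families[["g2"]]), "g2")
  path <- tempfile(fileext = ".json")
  export_network(net, path, "json")
  back <- import_network_json(path)
  expect_equal(back$group, net$group)
  expect_equal(names(back$layers), names(net$layers))
  expect_equal(back$layers$rna$nodes, net$layers$rna$nodes)
  expect_equal(back$layers$rna$edges, net$layers$rna$edges,
               tolerance = 1e-12)
  # an empty network is legal JSON
  empty <- integrate_layers(
    list(rna = build_edge_family(fx$st$layer, fx$st$labels, net = fx$st$net,
                                 tau = 1e6)[["g2"]]), "g2")
  p2 <- tempfile(fileext = ".json")
  export_network(empty, p2, "json")
  expect_equal(sum(vapply(import_network_json(p2)$layers,
                          function(l) nrow(l$edges), 1L)), 0)
  expect_error(export_network(empty, tempfile(), "tsv"),
               class = "diffnetx_error_empty_network")
})

test_that("GraphML export passes structural schema validation", {
  fx1 <- assembled_fixture(81, "rna")
  fx2 <- assembled_fixture(82, "prot")
  f1 <- fx1$act$families[["g2"]]; f2 <- fx2$act$families[["g2"]]
  mp <- layer_mapping("rna", f1$nodes[1], "prot", f2$nodes[1])
  net <- integrate_layers(list(rna = f1, prot = f2), "g2", mp)
  path <- tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  expect_true(validate_graphml(path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  n_expected <- nrow(f1$differential) + nrow(f2$differential) + 1
  expect_equal(length(edges), n_expected)
  # thickness proxy is -log10(p_adj), capped
  th <- as.numeric(xml2::xml_text(xml2::xml_find_all(
    doc, ".//d1:edge/d1:data[@key='e_thickness']", ns)))
  expect_true(all(th <= 10))
  # a malformed document fails validation
  bad <- tempfile(fileext = ".graphml")
  writeLines(c('<?xml version="1.0"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<graph id="g"><node id="a"/>',
               '<edge source="a" target="missing"/></graph></graphml>'), bad)
  expect_error(validate_graphml(bad),
               class = "diffnetx_error_invalid_graphml")
})

test_that("bootstrap frequencies are selection proportions in [0, 1]", {
  st <- simulate_study(n_features = 24, n_per_group = 25, n_diff_edges = 3,
                       n_null_edges = 6, seed = 85)
  one <- bootstrap_stability(st$layer, st$labels, st$net, n_boot = 1,
                             seed = 1)
  expect_true(all(one$frequency %in% c(0, 1)))
  freq <- bootstrap_stability(st$layer, st$labels, st$net, n_boot = 10,
                              seed = 2)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  expect_error(bootstrap_stability(st$layer, st$labels, st$net, n_boot = 0),
               class = "diffnetx_error_bad_nboot")
})

test_that("a saturated signal is selected in every bootstrap resample", {
  st <- simulate_study(n_features = 16, n_per_group = 200, n_diff_edges = 2,
                       n_null_edges = 4, beta3 = 2, noise_sd = 0.1,
                       seed = 86)
  freq <- bootstrap_stability(st$layer, st$labels, st$net, n_boot = 20,
                              seed = 3, alpha_adj = 0.01)
  planted <- st$truth[st$truth$differential, ]
  for (i in seq_len(nrow(planted))) {
    hit <- freq[freq$source == planted$source[i] &
                  freq$target == planted$target[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$frequency, 1)
  }
})

test_that("edge stability grows with sample size on the same signal", {
  mean_planted_freq <- function(n_per_group, seed) {
    st <- simulate_study(n_features = 16, n_per_group = n_per_group,
                         n_diff_edges = 2, n_null_edges = 4, beta3 = 0.8,
                         noise_sd = 0.8, seed = seed)
    freq <- bootstrap_stability(st$layer, st$labels, st$net, n_boot = 12,
                                seed = seed)
    planted <- st$truth[st$truth$differential, ]
    keys <- paste(pmin(planted$source, planted$target),
                  pmax(planted$source, planted$target))
    fk <- paste(pmin(freq$source, freq$target),
                pmax(freq$source, freq$target))
    found <- freq$frequency[match(keys, fk)]
    mean(ifelse(is.na(found), 0, found))
  }
  small <- mean(sapply(1:3, function(s) mean_planted_freq(10, 100 + s)))
  large <- mean(sapply(1:3, function(s) mean_planted_freq(100, 200 + s)))
  expect_lt(small, large)
})
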