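filter_study <- function(seed, ...) {
  st <- simulate_study(seed = seed, ...)
  list(x = t(st$layer$values), y = st$labels, net = st$net, truth = st$truth)
}

test_that("planted differential pairs are recovered across seeded runs", {
  hits <- sapply(1:15, function(s) {
    fs <- filter_study(400 + s, n_features = 100, n_diff_edges = 3,
                       n_null_edges = 20, n_per_group = 100, beta3 = 1,
                       noise_sd = 0.5)
    m <- fit_filter(fs$x, fs$y, fs$net)
    planted <- fs$truth[fs$truth$differential, ]
    pk <- paste(pmin(planted$source, planted$target),
                pmax(planted$source, planted$target))
    mk <- paste(pmin(m$pairs$numerator, m$pairs$denominator),
                pmax(m$pairs$numerator, m$pairs$denominator))
    all(pk %in% mk)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the feature budget caps singles and ratios jointly", {
  fs <- filter_study(401)
  m1 <- fit_filter(fs$x, fs$y, fs$net, max_features = 1, keep_single = FALSE)
  expect_equal(nrow(m1$pairs), 1)
  expect_equal(length(m1$single_features), 0)
  expect_equal(ncol(transform_features(m1, fs$x)), 1)
  # with singles, each new edge costs up to 3 features
  m3 <- fit_filter(fs$x, fs$y, fs$net, max_features = 3, keep_single = TRUE)
  expect_equal(ncol(transform_features(m3, fs$x)), 3)
  expect_equal(nrow(m3$pairs), 1)
  # ranked best-first: the kept edge has the smallest adjusted p
  mall <- fit_filter(fs$x, fs$y, fs$net)
  expect_equal(m1$pairs$p_adj[1], min(mall$pairs$p_adj))
  # the documented cohort settings are ordinary configuration values
  for (cap in c(40, 50)) {
    mcap <- fit_filter(fs$x, fs$y, fs$net, max_features = cap)
    expect_lte(ncol(transform_features(mcap, fs$x)), cap)
  }
})

test_that("unlimited budget emits one ratio per edge plus distinct singles", {
  fs <- filter_study(402)
  m <- fit_filter(fs$x, fs$y, fs$net)
  z <- transform_features(m, fs$x)
  n_singles <- length(unique(c(m$pairs$numerator, m$pairs$denominator)))
  expect_equal(length(m$single_features), n_singles)
  expect_equal(ncol(z), nrow(m$pairs) + n_singles)
  m0 <- fit_filter(fs$x, fs$y, fs$net, keep_single = FALSE)
  z0 <- transform_features(m0, fs$x)
  expect_equal(ncol(z0), nrow(m0$pairs))
  expect_lt(ncol(z0), ncol(z))
})

test_that("transform computes ratios with the response as numerator", {
  m <- structure(list(single_features = c("A", "B"),
                      pairs = data.frame(numerator = "A", denominator = "B",
                                         p_adj = 0.01, stat = 5,
                                         stringsAsFactors = FALSE),
                      keep_single = TRUE, max_features = Inf,
                      tau = 0, quantile = 0.5, correction = "bonferroni",
                      alpha_adj = 0.05),
                 class = "edge_filter_model")
  x <- matrix(c(4, 2), 1, 2, dimnames = list("s1", c("A", "B")))
  z <- transform_features(m, x)
  expect_equal(unname(z["s1", ]), c(4, 2, 2.0))
  expect_equal(colnames(z), c("A", "B", "A:B"))
  # zero denominator flags the cell, no infinities
  x0 <- matrix(c(4, 0), 1, 2, dimnames = list("s1", c("A", "B")))
  expect_true(is.na(transform_features(m, x0)[, "A:B"]))
  # missing feature is a named error
  expect_error(transform_features(m, x[, "A", drop = FALSE]),
               class = "diffnetx_error_missing_feature")
  # predict() is the transform
  expect_identical(predict(m, x), transform_features(m, x))
})

test_that("an empty model yields a zero-column matrix with the right rows", {
  m <- structure(list(single_features = character(0),
                      pairs = data.frame(numerator = character(0),
                                         denominator = character(0),
                                         p_adj = numeric(0), stat = numeric(0),
                                         stringsAsFactors = FALSE),
                      keep_single = FALSE, max_features = Inf,
                      tau = 0, quantile = 0.5, correction = "bonferroni",
                      alpha_adj = 0.05),
                 class = "edge_filter_model")
  x <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("s", 1:3), c("A", "B")))
  z <- transform_features(m, x)
  expect_equal(dim(z), c(3, 0))
})

test_that("transform output is a pure function of the model and each row", {
  fs <- filter_study(403)
  m <- fit_filter(fs$x, fs$y, fs$net)
  z_all <- transform_features(m, fs$x)
  # schema identical for any data with the same columns
  other <- fs$x[sample(nrow(fs$x), 10), ]
  z_other <- transform_features(m, other)
  expect_identical(colnames(z_other), colnames(z_all))
  # a row's derived features do not depend on the other rows
  scrambled <- fs$x
  scrambled[-1, ] <- scrambled[sample(2:nrow(fs$x)), ]
  z_scr <- transform_features(m, scrambled)
  expect_identical(z_scr[1, ], z_all[1, ])
})

test_that("filter models serialize to versioned JSON and back", {
  fs <- filter_study(404)
  m <- fit_filter(fs$x, fs$y, fs$net, max_features = 9)
  path <- tempfile(fileext = ".json")
  write_filter_model(m, path)
  back <- read_filter_model(path)
  expect_equal(back$pairs, m$pairs, tolerance = 1e-12)
  expect_identical(back$single_features, m$single_features)
  expect_identical(transform_features(back, fs$x),
                   transform_features(m, fs$x))
  m_inf <- fit_filter(fs$x, fs$y, fs$net)
  p2 <- tempfile(fileext = ".json")
  write_filter_model(m_inf, p2)
  expect_identical(read_filter_model(p2)$max_features, Inf)
})

test_that("zero differential edges produce a valid empty selection", {
  set.seed(405)
  # label-free data: permuted groups carry no structure
  fs <- filter_study(406, n_diff_edges = 2, n_null_edges = 10,
                     n_features = 30, beta3 = 0)
  m <- fit_filter(fs$x, fs$y, fs$net, alpha_adj = 1e-6)
  z <- transform_features(m, fs$x)
  expect_equal(nrow(z), nrow(fs$x))
  expect_equal(ncol(z), nrow(m$pairs) +
                 if (m$keep_single) length(m$single_features) else 0)
})
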