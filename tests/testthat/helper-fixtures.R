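# Shared fixtures and independent oracles, built in code at test time.

# random edge list (no self-loops); returns data.frame(source, target)
random_edge_list <- function(n_edges, n_vertices, prefix = "V") {
  ids <- sprintf("%s%04d", prefix, seq_len(n_vertices))
  src <- sample(ids, n_edges, replace = TRUE)
  tgt <- sample(ids, n_edges, replace = TRUE)
  fix <- src == tgt
  while (any(fix)) {
    tgt[fix] <- sample(ids, sum(fix), replace = TRUE)
    fix <- src == tgt
  }
  data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
}

write_edge_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent normal-equations oracle for the two-group interaction test:
# nested-model F comparing u ~ v + k against u ~ v + k + v:k, solved with
# explicit crossproducts (no lm machinery).
oracle_interaction_F <- function(u, v, k01) {
  rss_of <- function(X) {
    b <- solve(crossprod(X), crossprod(X, u))
    sum((u - X %*% b)^2)
  }
  n <- length(u)
  rss_full <- rss_of(cbind(1, v, k01, v * k01))
  rss_red <- rss_of(cbind(1, v, k01))
  Fstat <- (rss_red - rss_full) / (rss_full / (n - 4))
  list(F = Fstat, p = stats::pf(Fstat, 1, n - 4, lower.tail = FALSE))
}

# small two-group dataset with an optional interaction effect
make_edge_data <- function(n_per_group, beta3 = 0, sd = 1, beta = c(0, 1, 0)) {
  n <- 2 * n_per_group
  v <- rnorm(n)
  k <- rep(c(0, 1), each = n_per_group)
  u <- beta[1] + beta[2] * v + beta[3] * k + beta3 * v * k + rnorm(n, 0, sd)
  list(u = u, v = v, k = k)
}

# brute-force re-run of the full per-quantile pipeline using formula-based
# lm() fits and explicit set logic; independent of the package internals
oracle_scan_counts <- function(layer, labels, net, grid, alpha_adj = 0.05,
                               correction = "bonferroni") {
  groups <- labels$groups
  summ <- sapply(groups, function(g) {
    ids <- names(labels$assignment)[labels$assignment == g]
    apply(layer$values[, intersect(ids, layer$sample_ids), drop = FALSE], 1,
          median, na.rm = TRUE)
  })
  pooled <- summ[is.finite(summ)]
  edges <- net$edges[net$edges$source %in% layer$feature_ids &
                       net$edges$target %in% layer$feature_ids, ]
  kvec <- labels$assignment[intersect(layer$sample_ids,
                                      names(labels$assignment))]
  samples <- names(kvec)
  vapply(grid, function(q) {
    tau <- quantile(pooled, q, type = 7, names = FALSE)
    active <- lapply(groups, function(g)
      rownames(summ)[!is.na(summ[, g]) & summ[, g] >= tau])
    names(active) <- groups
    in_group <- lapply(active, function(a)
      which(edges$source %in% a & edges$target %in% a))
    common <- Reduce(intersect, in_group)
    total <- 0L
    for (g in groups) {
      idx <- setdiff(in_group[[g]], common)
      if (length(idx) == 0) next
      p <- vapply(idx, function(i) {
        a <- edges$source[i]; b <- edges$target[i]
        uu <- if (a > b) a else b
        vv <- if (a > b) b else a
        df <- data.frame(u = layer$values[uu, samples],
                         v = layer$values[vv, samples],
                         k = factor(kvec))
        fit <- lm(u ~ v * k, data = df)
        summary(fit)$coefficients[4, 4]
      }, 1)
      total <- total + sum(adjust_pvalues(p, correction) < alpha_adj)
    }
    total
  }, 1L)
}
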