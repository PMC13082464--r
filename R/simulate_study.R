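# Synthetic multi-feature study generator: a full expression layer, group
# labels and a matching reference network with planted differential edges.
# This is the fixture-free test bed for the percolation scan, the feature
# filter and the nested cross-validation demonstration.
#
# An edge only becomes testable when its activation differs between groups
# (edges active in every group are removed as common). Planted differential
# edges therefore combine a group shift of the response entity with a changed
# coupling slope:
#   u = mu_u + b1 (v - mu_v) + b2 k + b3 (v - mu_v) k + e
# with mu_u drawn from a narrow band just below the covariate band, so that
# one activation threshold in between captures every planted edge in the
# second group. Null edges come in three flavours: group-shifted but with an
# unchanged slope (these enter the tested family and probe specificity),
# highly expressed in both groups (removed as common), and low-abundance
# noise pairs (excluded by the percolation floor).

#' Generate a synthetic study with planted differential edges
#'
#' @param n_features Total number of features (default 80); features not
#'   used by any edge are independent fillers.
#' @param n_per_group Samples per group (default 40).
#' @param n_diff_edges Planted differential edges (default 8).
#' @param n_null_edges Reference-network edges with no differential coupling
#'   (default 30), split roughly equally between group-shifted null pairs,
#'   always-active pairs and low-abundance pairs.
#' @param beta1,beta2,beta3 Generating coefficients: baseline coupling
#'   slope, group main effect on the response entity, and differential
#'   interaction strength (defaults 1, 2, 1 -- the strong-signal regime).
#' @param noise_sd Residual SD on the expression scale (default 0.5).
#' @param groups Two group labels (default `c("g1", "g2")`).
#' @param seed Optional integer seed.
#' @return List with `layer` ([expression_layer()]), `labels`
#'   ([group_labels()]), `net` ([reference_network()]) and `truth` (data
#'   frame of the network's edges with a `differential` flag and a `class`
#'   column: `diff`, `null_shifted`, `null_common`, `null_low`).
#' @export
simulate_study <- function(n_features = 80, n_per_group = 40,
                           n_diff_edges = 8, n_null_edges = 30,
                           beta1 = 1, beta2 = 2, beta3 = 1, noise_sd = 0.5,
                           groups = c("g1", "g2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- 2 * (n_diff_edges + n_null_edges)
  if (n_features < need)
    stop_diffnetx(sprintf("need >= %d features for %d edges", need,
                          n_diff_edges + n_null_edges),
                  "diffnetx_error_bad_config")
  stopifnot(length(groups) == 2)
  feats <- sprintf("F%03d", seq_len(n_features))
  n <- 2L * n_per_group
  samples <- sprintf("S%03d", seq_len(n))
  k <- rep(c(0, 1), each = n_per_group)
  values <- matrix(NA_real_, n_features, n,
                   dimnames = list(feats, samples))

  pos <- 1L
  take <- function(m) {
    out <- feats[pos:(pos + m - 1L)]
    pos <<- pos + m
    out
  }
  truth <- NULL
  add_edge <- function(a, b, differential, class) {
    truth <<- rbind(truth, data.frame(source = a, target = b,
                                      differential = differential,
                                      class = class,
                                      stringsAsFactors = FALSE))
  }
  # response band (8, 8.6) sits below the covariate band (10, 12): any
  # threshold between them activates the response only where it is shifted
  gen_pair <- function(a, b, mu_u, mu_v, b2, b3) {
    v <- stats::rnorm(n, mu_v, 1)
    u <- mu_u + beta1 * (v - mu_v) + b2 * k + b3 * (v - mu_v) * k +
      stats::rnorm(n, 0, noise_sd)
    values[a, ] <<- u
    values[b, ] <<- v
  }
  for (i in seq_len(n_diff_edges)) {
    pr <- take(2)
    gen_pair(pr[1], pr[2], stats::runif(1, 8, 8.6), stats::runif(1, 10, 12),
             beta2, beta3)
    add_edge(pr[1], pr[2], TRUE, "diff")
  }
  n_sh <- ceiling(n_null_edges / 3)
  n_low <- floor(n_null_edges / 3)
  for (i in seq_len(n_null_edges)) {
    pr <- take(2)
    if (i <= n_sh) {
      gen_pair(pr[1], pr[2], stats::runif(1, 8, 8.6),
               stats::runif(1, 10, 12), beta2, 0)
      add_edge(pr[1], pr[2], FALSE, "null_shifted")
    } else if (i <= n_sh + n_low) {
      gen_pair(pr[1], pr[2], stats::runif(1, 2, 5), stats::runif(1, 2, 5),
               0, 0)
      add_edge(pr[1], pr[2], FALSE, "null_low")
    } else {
      gen_pair(pr[1], pr[2], stats::runif(1, 10, 12),
               stats::runif(1, 10, 12), 0, 0)
      add_edge(pr[1], pr[2], FALSE, "null_common")
    }
  }
  if (pos <= n_features) {
    rest <- feats[pos:n_features]
    mus <- stats::runif(length(rest), 2, 12)
    values[rest, ] <- mus + matrix(stats::rnorm(length(rest) * n),
                                   length(rest), n)
  }

  layer <- expression_layer(values, "synthetic")
  labels <- group_labels(stats::setNames(groups[k + 1], samples))
  net <- reference_network(truth$source, truth$target)
  list(layer = layer, labels = labels, net = net, truth = truth)
}
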