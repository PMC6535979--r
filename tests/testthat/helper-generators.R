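# Shared test generators and independent oracles.

# Random binary decision tree of the given maximum depth. Internal
# nodes split on vocabulary terms; leaves carry a random action.
random_tree <- function(depth, p_leaf = 0.35) {
  terms <- c("Pregnant", "High risk", "Age", "Chest pain", "Head trauma",
             "Nodule size", "Fever", "Suspected PE")
  actions <- c("VQ SPECT", "CTPA", "CT head", "MRI brain", "X-ray knee")
  build <- function(d) {
    if (d <= 0 || stats::runif(1) < p_leaf) {
      return(decision_leaf(sample(actions, 1L),
                           sample(c("recommend", "not_recommend"), 1L)))
    }
    decision_node(condition(sample(terms, 1L)), build(d - 1L), build(d - 1L))
  }
  # force at least one split so flattening yields conditioned statements
  decision_node(condition(sample(terms, 1L)), build(depth - 1L), build(depth - 1L))
}

# Independent oracle: enumerate root-to-leaf paths of a tree by explicit
# stack walking (no recursion shared with the implementation).
enumerate_paths <- function(tree) {
  paths <- list()
  stack <- list(list(node = tree, path = character(0)))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (inherits(node, "decision_leaf")) {
      paths[[length(paths) + 1L]] <- top$path
    } else {
      # push false branch first so true branch pops first (depth-first,
      # true branch first), matching the documented leaf order
      stack[[length(stack) + 1L]] <-
        list(node = node$no, path = c(top$path, paste0("!", node$condition$term)))
      stack[[length(stack) + 1L]] <-
        list(node = node$yes, path = c(top$path, node$condition$term))
    }
  }
  paths
}

# Exact half-up percentage oracle using integer arithmetic only:
# round_half_up(100 * n / total, 1) without floating point.
pct_oracle <- function(n, total) {
  num <- 1000 * n
  q <- num %/% total
  r <- num %% total
  if (2 * r >= total) q <- q + 1
  q / 10
}

# Strip any temporal component from an action (used to build bundles
# from statements whose schedules would otherwise fail compilation).
strip_action_temporal <- function(x) {
  x$action$temporal <- NULL
  x
}
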