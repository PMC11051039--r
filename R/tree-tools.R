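# Internal helpers for walking fitted rpart trees. All rpart models in this
# package are grown with maxcompete = 0 and maxsurrogate = 0, so the rows of
# fit$splits align one-to-one with the internal nodes of fit$frame in frame
# order — that alignment is relied on here.

# Returns a data.frame describing every node of the tree:
#   node      rpart node number (root 1, children 2k / 2k+1)
#   is_leaf   logical
#   var       split variable name (NA for leaves)
#   threshold split point (NA for leaves)
#   left_lt   TRUE when the left child takes x < threshold (ncat == -1),
#             FALSE when the left child takes x >= threshold
parse_tree <- function(fit) {
  frame <- fit$frame
  nodes <- as.integer(row.names(frame))
  is_leaf <- frame$var == "<leaf>"
  out <- data.frame(node = nodes, is_leaf = is_leaf,
                    var = NA_character_, threshold = NA_real_,
                    left_lt = NA, stringsAsFactors = FALSE)
  if (any(!is_leaf)) {
    sp <- fit$splits
    internal <- which(!is_leaf)
    stopifnot(nrow(sp) >= length(internal))
    out$var[internal] <- as.character(frame$var[internal])
    out$threshold[internal] <- sp[seq_along(internal), "index"]
    out$left_lt[internal] <- sp[seq_along(internal), "ncat"] < 0
  }
  out
}

# Logical membership of each row of `data` (a data.frame with the model's
# feature columns) at node number `node`, derived by replaying the splits
# along the path from the root.
node_membership <- function(tree_df, data, node) {
  keep <- rep(TRUE, nrow(data))
  path <- node
  while (node > 1L) {
    parent <- node %/% 2L
    prow <- tree_df[tree_df$node == parent, ]
    x <- data[[prow$var]]
    goes_left <- if (prow$left_lt) x < prow$threshold else x >= prow$threshold
    keep <- keep & (if (node %% 2L == 0L) goes_left else !goes_left)
    node <- parent
  }
  keep
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Per-internal-node split statistics on a given training set: feature name,
# information gain (bits) and coverage (training samples reaching the node).
tree_split_stats <- function(fit, data, y) {
  tree_df <- parse_tree(fit)
  internal <- tree_df[!tree_df$is_leaf, , drop = FALSE]
  if (!nrow(internal)) {
    return(data.frame(var = character(), gain = numeric(),
                      coverage = integer()))
  }
  member <- lapply(internal$node, node_membership, tree_df = tree_df,
                   data = data)
  res <- lapply(seq_len(nrow(internal)), function(i) {
    m <- member[[i]]
    node <- internal$node[i]
    left_node <- 2L * node
    ml <- node_membership(tree_df, data, left_node)
    yl <- y[m & ml]
    yr <- y[m & !ml]
    yn <- y[m]
    n_node <- length(yn)
    gain <- entropy_bits(table(yn)) -
      (length(yl) / n_node) * entropy_bits(table(yl)) -
      (length(yr) / n_node) * entropy_bits(table(yr))
    data.frame(var = internal$var[i], gain = gain, coverage = n_node,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
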