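#' SMOTE minority oversampling
#'
#' Upsamples every non-majority class to the majority count. Each synthetic
#' sample is built by picking a random minority sample x, one of its
#' k nearest same-class neighbors z (Euclidean distance), and returning
#' `x + r (z - x)` with `r ~ Uniform(0, 1)` — a point on the segment between
#' the two originals. Original rows are passed through unchanged, synthetic
#' rows are appended and flagged.
#'
#' @param values numeric matrix (samples x features).
#' @param labels class label per row.
#' @param k_neighbors number of nearest neighbors to draw from (default 5);
#'   clamped, with a warning, to (class size - 1) for very small classes.
#' @param seed integer seed; the balanced set is reproducible from it.
#' @return object of class `balanced_set`: list with `values`, `labels`,
#'   `synthetic` (logical flag per row).
#' @export
smote_balance <- function(values, labels, k_neighbors = 5L, seed = 1L) {
  values <- as.matrix(values)
  labels <- as.character(labels)
  stopifnot(nrow(values) == length(labels))
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least two classes to balance")
  majority <- max(counts)
  deficits <- majority - counts
  if (any(counts == 1L & deficits > 0)) {
    stop("class '", names(counts)[counts == 1L & deficits > 0][1],
         "' has a single sample: no neighbor exists for interpolation")
  }
  if (all(deficits == 0)) {
    return(structure(list(values = values, labels = labels,
                          synthetic = rep(FALSE, nrow(values))),
                     class = "balanced_set"))
  }
  synth_vals <- list()
  synth_labs <- character(0)
  withr::with_seed(derive_seed(seed, "smote"), {
    for (cl in names(counts)[deficits > 0]) {
      idx <- which(labels == cl)
      n_cl <- length(idx)
      need <- as.integer(deficits[[cl]])
      k <- k_neighbors
      if (k > n_cl - 1L) {
        warning("smote_balance: clamping k_neighbors from ", k, " to ",
                n_cl - 1L, " for class '", cl, "'")
        k <- n_cl - 1L
      }
      sub <- values[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(sub))
      diag(d) <- Inf
      # k nearest same-class neighbors of each minority sample
      nn <- apply(d, 1L, function(row) order(row)[seq_len(k)])
      nn <- matrix(nn, nrow = k)
      base_pick <- sample.int(n_cl, need, replace = TRUE)
      nb_pick <- vapply(base_pick, function(i) nn[sample.int(k, 1L), i],
                        integer(1))
      r <- stats::runif(need)
      new_rows <- sub[base_pick, , drop = FALSE] +
        r * (sub[nb_pick, , drop = FALSE] - sub[base_pick, , drop = FALSE])
      synth_vals[[cl]] <- new_rows
      synth_labs <- c(synth_labs, rep(cl, need))
    }
  })
  synth <- do.call(rbind, synth_vals)
  structure(list(values = rbind(values, synth),
                 labels = c(labels, synth_labs),
                 synthetic = c(rep(FALSE, nrow(values)), rep(TRUE, nrow(synth)))),
            class = "balanced_set")
}
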