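#' Simulation configuration for synthetic labeled expression matrices
#'
#' Describes a cells x genes matrix of nonnegative log-normalized-style
#' expression values with `L` classes, a handful of planted marker genes
#' carrying class-dependent mean shifts, Gaussian per-cell noise truncated at
#' zero, and Bernoulli dropout (independent zeroing) emulating scRNA-seq
#' sparsity.
#'
#' @param n_cells_per_class integer vector, one positive count per class.
#' @param n_genes positive integer, number of genes.
#' @param planted_genes list of planted markers; each element is
#'   `list(gene = <1-based gene index>, shift = <numeric length L>)` giving
#'   the additive mean shift of that gene in each class.
#' @param baseline_mean nonnegative baseline expression mean shared by all
#'   genes and classes.
#' @param noise_sd positive standard deviation of the Gaussian noise.
#' @param dropout_rate probability in `[0, 1)` that any entry is zeroed.
#' @param class_names character vector of class names (length L).
#' @param seed integer seed; the matrix is bit-reproducible from the config.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells_per_class = imbalance_preset("endothelial")$n_cells_per_class,
                              n_genes = 2000L,
                              planted_genes = default_planted_genes(n_genes, length(n_cells_per_class)),
                              baseline_mean = 2,
                              noise_sd = 1,
                              dropout_rate = 0.3,
                              class_names = c("active", "former", "never"),
                              seed = 1L) {
  cfg <- structure(
    list(n_cells_per_class = as.integer(n_cells_per_class),
         n_genes = as.integer(n_genes),
         planted_genes = planted_genes,
         baseline_mean = baseline_mean,
         noise_sd = noise_sd,
         dropout_rate = dropout_rate,
         class_names = as.character(class_names),
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  L <- length(cfg$n_cells_per_class)
  if (L < 2L || any(cfg$n_cells_per_class < 1L)) {
    stop("invalid field 'n_cells_per_class': need >= 2 positive class counts")
  }
  if (length(cfg$class_names) != L || anyDuplicated(cfg$class_names)) {
    stop("invalid field 'class_names': need ", L, " unique names")
  }
  if (length(cfg$n_genes) != 1L || is.na(cfg$n_genes) || cfg$n_genes < 1L) {
    stop("invalid field 'n_genes': need a positive integer")
  }
  if (!is.numeric(cfg$baseline_mean) || cfg$baseline_mean < 0) {
    stop("invalid field 'baseline_mean': must be nonnegative")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("invalid field 'noise_sd': must be positive")
  }
  if (!is.numeric(cfg$dropout_rate) || cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("invalid field 'dropout_rate': must lie in [0, 1)")
  }
  if (length(cfg$planted_genes)) {
    idx <- vapply(cfg$planted_genes, function(p) as.integer(p$gene), integer(1))
    if (anyDuplicated(idx) || any(idx < 1L) || any(idx > cfg$n_genes)) {
      stop("invalid field 'planted_genes': gene indices must be unique and within 1..n_genes")
    }
    shifts <- lapply(cfg$planted_genes, `[[`, "shift")
    if (any(lengths(shifts) != L)) {
      stop("invalid field 'planted_genes': each shift vector must have one entry per class")
    }
    informative <- vapply(shifts, function(s) length(unique(s)) > 1L, logical(1))
    if (!any(informative)) {
      stop("invalid field 'planted_genes': at least one planted gene needs two unequal class means")
    }
  }
  invisible(cfg)
}

#' Default planted-marker layout: 15 markers, 5 up-shifted per class
#'
#' Marker genes are spread evenly over the gene index range; marker `i` gets
#' a +3 (in units of `noise_sd`, applied by the caller via the shift values)
#' mean shift in class `((i - 1) %% L) + 1` and no shift elsewhere.
#'
#' @param n_genes number of genes in the target matrix.
#' @param n_classes number of classes L.
#' @param n_markers number of planted markers (default 15).
#' @param shift per-marker additive shift in its target class (default 3).
#' @return a list suitable for `simulation_config(planted_genes = )`.
#' @export
default_planted_genes <- function(n_genes, n_classes, n_markers = 15L, shift = 3) {
  if (n_markers < 1L) return(list())
  idx <- unique(round(seq(1L, n_genes, length.out = n_markers)))
  lapply(seq_along(idx), function(i) {
    s <- rep(0, n_classes)
    s[((i - 1L) %% n_classes) + 1L] <- shift
    list(gene = as.integer(idx[i]), shift = s)
  })
}

#' Class-imbalance presets matching the four lung cell-type cohorts
#'
#' Returns the active/former/never smoker cell counts of the named cell-type
#' cohort (endothelial 6521/7189/29829, epithelial 37905/47945/148499,
#' immune 41801/34853/113189, stromal 3415/2342/10274), rescaled to `total`
#' cells with largest-remainder rounding so the counts always sum to `total`.
#'
#' @param cell_type one of "endothelial", "epithelial", "immune", "stromal".
#' @param total total number of cells after rescaling (default 1500).
#' @param ... further arguments passed to [simulation_config()].
#' @return a `simulation_config` whose `n_cells_per_class` holds the scaled
#'   counts in (active, former, never) order.
#' @export
imbalance_preset <- function(cell_type, total = 1500L, ...) {
  presets <- list(
    endothelial = c(active = 6521, former = 7189, never = 29829),
    epithelial  = c(active = 37905, former = 47945, never = 148499),
    immune      = c(active = 41801, former = 34853, never = 113189),
    stromal     = c(active = 3415, former = 2342, never = 10274)
  )
  if (!cell_type %in% names(presets)) {
    stop("unknown cell type '", cell_type, "'; valid names: ",
         paste(names(presets), collapse = ", "))
  }
  counts <- presets[[cell_type]]
  scaled <- counts / sum(counts) * total
  # largest-remainder rounding preserves the total exactly
  n <- floor(scaled)
  rem <- total - sum(n)
  if (rem > 0) {
    order_rem <- order(scaled - n, decreasing = TRUE)
    n[order_rem[seq_len(rem)]] <- n[order_rem[seq_len(rem)]] + 1
  }
  n <- as.integer(n)
  if (any(n < 1L)) stop("total too small: a class would receive zero cells")
  simulation_config(n_cells_per_class = n,
                    class_names = names(counts), ...)
}

#' Generate a labeled expression matrix from a simulation config
#'
#' Non-planted genes are class-independent noise around `baseline_mean`;
#' planted gene g has mean `baseline_mean + shift[g][class]` in each class.
#' Values are Gaussian with `noise_sd`, truncated at zero, then zeroed
#' independently with probability `dropout_rate`. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [labeled_matrix()] with ENSG-style synthetic gene identifiers.
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  L <- length(config$n_cells_per_class)
  n <- sum(config$n_cells_per_class)
  p <- config$n_genes
  labels <- rep(config$class_names, times = config$n_cells_per_class)
  withr::with_seed(derive_seed(config$seed, "simulate"), {
    values <- matrix(stats::rnorm(n * p, mean = config$baseline_mean,
                                  sd = config$noise_sd), nrow = n, ncol = p)
    for (pg in config$planted_genes) {
      values[, pg$gene] <- values[, pg$gene] +
        rep(pg$shift, times = config$n_cells_per_class)
    }
    values[values < 0] <- 0
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * p) < config$dropout_rate, nrow = n)
      values[drop] <- 0
    }
  })
  labeled_matrix(values, gene_ids = synthetic_gene_ids(p),
                 labels = labels, class_names = config$class_names)
}

#' Synthesize ENSG-style gene identifiers
#' @param n_genes number of identifiers.
#' @return character vector like "ENSG00000000001".
#' @export
synthetic_gene_ids <- function(n_genes) {
  sprintf("ENSG%011d", seq_len(n_genes))
}

#' Indices of planted marker genes in a config
#' @param config a `simulation_config`.
#' @return integer vector of 1-based gene indices.
#' @export
planted_gene_indices <- function(config) {
  vapply(config$planted_genes, function(p) as.integer(p$gene), integer(1))
}
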