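# Fixtures built in code; nothing is read from disk.

# Small handmade matrix: rows are genes, values chosen so that detection at
# tau = 6 (log2 scale) gives known calls. 2^6 - 1 = 63 is the linear
# detection boundary.
tiny_matrix <- function() {
  vals <- rbind(
    Sncg = c(500, 800, 40), # detected in cells 1-2 only
    Rho  = c(10, 1000, 5), # detected in cell 2 only
    Glul = c(3, 2, 1), # never detected
    Gap43 = c(120, 90, 70) # detected everywhere
  )
  colnames(vals) <- c("c1", "c2", "c3")
  expr_matrix(vals, "mas5_linear")
}

# Bare value grid of an expr_matrix (class and scale tag stripped).
values_of <- function(m) {
  v <- unclass(m)
  attr(v, "scale_tag") <- NULL
  v
}

# Identity probe map for gene-named matrices.
identity_map <- function(m) {
  data.frame(
    probe_id = rownames(m), gene_symbol = rownames(m),
    stringsAsFactors = FALSE
  )
}

# A log2_already matrix from an explicit value grid.
log2_matrix <- function(vals) {
  if (is.null(rownames(vals))) rownames(vals) <- paste0("p", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("c", seq_len(ncol(vals)))
  expr_matrix(vals, "log2_already")
}

# Low-noise simulation in which planted on/off patterns survive detection
# exactly: separation 10 with all dispersions far below it.
clean_sim_config <- function(seed = 5, ...) {
  sim_config(
    n_probes = 1200, n_cells_per_type = c(5L, 4L, 3L),
    n_types_target = 2L, frac_noise_probes = 0.7,
    noise_sd_mean = 0.1, noise_sd_sd = 0.02,
    info_sd_mean = 0.5, info_sd_sd = 0.05,
    n_markers_per_type = 20L, n_pan_markers = 8L,
    detection_high = 13, detection_low = 3,
    baseline_noise = 3, baseline_info = 8,
    marker_tech_sd = 0.1, seed = seed, ...
  )
}

# Default-geometry dataset shared across test files (computed once).
.shared <- new.env(parent = emptyenv())
shared_default_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- generate_dataset(sim_config(seed = 101))
  }
  .shared$sim
}

# Brute-force UPGMA oracle: each round, enumerate every cluster pair and
# average the ORIGINAL pairwise distances over members (no Lance-Williams
# update), with the same lexicographic tie-break as the implementation.
brute_force_upgma <- function(d) {
  labels <- rownames(d)
  clusters <- lapply(labels, identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    best_d <- Inf
    best_key <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(min(clusters[[i]]), min(clusters[[j]]))),
          collapse = "\r"
        )
        if (avg < best_d - 1e-9 ||
          (abs(avg - best_d) <= 1e-9 && key < best_key)) {
          best_d <- avg
          best <- c(i, j)
          best_key <- key
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# Partition of leaves after each merge of a cell_dendrogram, for comparison
# with the brute-force oracle.
dendrogram_partitions <- function(dend) {
  n <- length(dend$labels)
  out <- vector("list", n - 1L)
  for (k in seq.int(n - 1L, 1L)) {
    cl <- cut_tree(dend, k)
    out[[n - k]] <- unname(lapply(
      split(names(cl), unclass(cl)),
      sort
    ))
  }
  out
}

# Canonical form of a partition (order-free) for set comparison.
canon <- function(partition) {
  paste(sort(vapply(partition, paste, character(1), collapse = ",")),
    collapse = "|"
  )
}

random_distance_matrix <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 2)
  d + t(d)
}
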