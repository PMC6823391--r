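#' Pearson-correlation distance between cells
#'
#' Distance `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of
#' the two cells' log2 expression profiles over the given probes (typically
#' the variance-filter survivors). Anti-correlated cells are maximally
#' distant (`d = 2`); correlation of profiles, not of ranks.
#'
#' @param matrix An [expr_matrix()].
#' @param probes Optional character vector restricting the profile to these
#'   probe ids (e.g. `filter_result$retained_probe_ids`).
#' @return Symmetric cell-by-cell distance matrix with zero diagonal.
#' @export
correlation_distance <- function(matrix, probes = NULL) {
  stopifnot(is_expr_matrix(matrix))
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(matrix))
    if (length(miss)) {
      stop("probe(s) not in matrix: ", paste(utils::head(miss, 5), collapse = ", "),
        call. = FALSE
      )
    }
    matrix <- matrix[probes, , drop = FALSE]
  }
  if (ncol(matrix) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (nrow(matrix) < 2L) stop("need at least 2 probes", call. = FALSE)
  x <- as_log2(matrix)
  sds <- apply(x, 2, stats::sd)
  flat <- colnames(x)[sds == 0]
  if (length(flat)) {
    stop(
      "cell(s) with zero variance over the selected probes: ",
      paste(flat, collapse = ", "),
      call. = FALSE
    )
  }
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

#' Agglomerative average-linkage (UPGMA) clustering
#'
#' Each cell starts as its own cluster; the pair of clusters with the
#' smallest average inter-cluster distance is merged repeatedly, the merge
#' height being that average. When several pairs tie exactly, the pair whose
#' lexicographically smallest member cell id is least (then the smaller
#' partner id) is merged, so results are platform-independent. Average
#' linkage admits no height inversions.
#'
#' @param distances Symmetric distance matrix with cell ids as dimnames, or
#'   a [stats::dist] object.
#' @return A `cell_dendrogram`: hclust-style `merge`/`height`/`order`/
#'   `labels`, plus a readable `merges` data.frame
#'   (`member_a`, `member_b`, `height`, `node_id`).
#' @export
average_linkage <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  n <- nrow(distances)
  if (n < 2L) stop("need at least 2 cells to cluster", call. = FALSE)
  labels <- rownames(distances)
  if (is.null(labels)) labels <- paste0("cell", seq_len(n))

  D <- distances
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity) # row/col index -> leaf indices
  code <- -seq_len(n) # hclust code: -leaf or +merge row
  min_id <- labels # lexicographically smallest member id per cluster
  sizes <- rep(1L, n)

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merges_df <- data.frame(
    member_a = character(n - 1L), member_b = character(n - 1L),
    height = numeric(n - 1L), node_id = character(n - 1L),
    stringsAsFactors = FALSE
  )

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    dmin <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dij <- D[active[i], active[j]]
        if (dij < dmin) dmin <- dij
      }
    }
    # collect exact ties, pick by lexicographic member-id rule
    best <- NULL
    best_key <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (D[active[i], active[j]] == dmin) {
          ids <- sort(c(min_id[active[i]], min_id[active[j]]))
          key <- paste(ids, collapse = "\r")
          if (is.null(best_key) || key < best_key) {
            best_key <- key
            best <- c(i, j)
          }
        }
      }
    }
    ai <- active[best[1]]
    aj <- active[best[2]]
    merge[step, ] <- c(code[ai], code[aj])
    height[step] <- dmin
    merges_df[step, ] <- list(
      min_id[ai], min_id[aj], dmin, paste0("node_", step)
    )
    # Lance-Williams average-linkage update onto ai
    others <- setdiff(active, c(ai, aj))
    if (length(others)) {
      newd <- (sizes[ai] * D[ai, others] + sizes[aj] * D[aj, others]) /
        (sizes[ai] + sizes[aj])
      D[ai, others] <- newd
      D[others, ai] <- newd
    }
    members[[ai]] <- c(members[[ai]], members[[aj]])
    sizes[ai] <- sizes[ai] + sizes[aj]
    code[ai] <- step
    min_id[ai] <- min(min_id[ai], min_id[aj])
    active <- setdiff(active, aj)
  }

  order <- dend_order(merge, n)
  structure(
    list(
      merge = merge, height = height, order = order, labels = labels,
      merges = merges_df
    ),
    class = "cell_dendrogram"
  )
}

# leaf order by left-to-right traversal of the merge tree
dend_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) {
      return(-node)
    }
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

#' @export
print.cell_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<cell_dendrogram> %d leaves, %d merges, heights %.4f .. %.4f\n",
    length(x$labels), nrow(x$merge),
    min(x$height), max(x$height)
  ))
  invisible(x)
}

#' @export
as.hclust.cell_dendrogram <- function(x, ...) {
  structure(
    list(
      merge = x$merge, height = x$height, order = x$order,
      labels = x$labels, method = "average",
      dist.method = "1 - Pearson correlation",
      call = match.call()
    ),
    class = "hclust"
  )
}

#' @export
plot.cell_dendrogram <- function(x, ...) {
  graphics::plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via the ultrametric tree implied by
#' the dendrogram.
#'
#' @param dendrogram A `cell_dendrogram`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
export_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; each remaining subtree is a cluster.
#' Clusters are labelled `1..k` in decreasing size, ties broken by the
#' lexicographically smallest member cell id.
#'
#' @param dendrogram A `cell_dendrogram`.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A `cluster_assignment`: named integer vector (cell id to cluster
#'   label) with attribute `k`.
#' @export
cut_tree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "cell_dendrogram"))
  n <- length(dendrogram$labels)
  if (k < 1L || k > n) {
    stop(sprintf("k must lie in [1, %d], got %s", n, format(k)), call. = FALSE)
  }
  group <- seq_len(n) # leaf -> provisional group
  node_group <- integer(n - 1L) # merge row -> group it landed in
  n_apply <- n - k
  for (s in seq_len(n_apply)) {
    pick <- function(node) {
      if (node < 0L) group[-node] else node_group[node]
    }
    ga <- pick(dendrogram$merge[s, 1L])
    gb <- pick(dendrogram$merge[s, 2L])
    group[group == gb] <- ga
    node_group[node_group == gb] <- ga
    node_group[s] <- ga
  }
  # relabel by decreasing size, ties by smallest member id
  ids <- dendrogram$labels
  grps <- unique(group)
  size <- vapply(grps, function(g) sum(group == g), integer(1))
  min_member <- vapply(grps, function(g) min(ids[group == g]), character(1))
  ord <- order(-size, min_member)
  relabel <- stats::setNames(seq_along(grps), grps[ord])
  out <- relabel[as.character(group)]
  structure(stats::setNames(as.integer(out), ids),
    k = as.integer(k), class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- attr(x, "k")
  cat(sprintf("<cluster_assignment> %d cells in %d cluster(s)\n", length(x), k))
  print(table(cluster = unclass(x)))
  invisible(x)
}

#' Genes enriched in one cluster
#'
#' Contrasts detection prevalence inside a cluster against all other cells:
#' `score = in-prevalence - out-prevalence`. Genes pass when their
#' in-cluster prevalence reaches `min_in_prev` and their out-of-cluster
#' prevalence stays at or below `max_out_prev`; results are sorted by score
#' (descending), ties alphabetically. With a probe map, the best-scoring
#' probe represents each symbol.
#'
#' @param matrix An [expr_matrix()].
#' @param assignment A `cluster_assignment` from [cut_tree()] (or any named
#'   label vector).
#' @param cluster_label The cluster to profile.
#' @param tau_det Detection threshold (log2 units).
#' @param min_in_prev,max_out_prev Prevalence gates (defaults 0.75 / 0.25).
#' @param probe_map Optional probe-to-symbol map.
#' @param all Return every gene with its scores instead of only passers.
#' @return Data.frame `gene`, `probe_id`, `in_prev`, `out_prev`, `score`
#'   (plus `passes` when `all = TRUE`).
#' @export
cluster_enriched_genes <- function(matrix, assignment, cluster_label,
                                   tau_det = 6, min_in_prev = 0.75,
                                   max_out_prev = 0.25, probe_map = NULL,
                                   all = FALSE) {
  stopifnot(is_expr_matrix(matrix))
  cells_in <- names(assignment)[assignment == cluster_label]
  if (!length(cells_in)) {
    stop("cluster '", cluster_label, "' is empty", call. = FALSE)
  }
  cells_out <- setdiff(colnames(matrix), cells_in)
  if (!length(cells_out)) {
    stop("no out-of-cluster cells to contrast against", call. = FALSE)
  }
  miss <- setdiff(cells_in, colnames(matrix))
  if (length(miss)) {
    stop("cluster cell(s) not in matrix: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  calls <- detect_calls(matrix, tau_det)
  in_prev <- rowMeans(calls[, cells_in, drop = FALSE])
  out_prev <- rowMeans(calls[, cells_out, drop = FALSE])
  df <- data.frame(
    gene = unname(probe_symbols(rownames(matrix), probe_map)),
    probe_id = rownames(matrix),
    in_prev = unname(in_prev),
    out_prev = unname(out_prev),
    score = unname(in_prev - out_prev),
    stringsAsFactors = FALSE
  )
  # collapse symbol collisions onto the best-scoring probe
  df <- df[order(-df$score, df$gene, df$probe_id), ]
  df <- df[!duplicated(df$gene), ]
  df$passes <- df$in_prev >= min_in_prev & df$out_prev <= max_out_prev
  if (!all) {
    df <- df[df$passes, setdiff(names(df), "passes")]
  }
  rownames(df) <- NULL
  df
}
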