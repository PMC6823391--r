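# Internal helpers shared across modules.

# Normalize a group specification to a named vector cell_id -> group label.
# Accepts a named character vector or an annotation data.frame.
group_vector <- function(groups, cells = NULL) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(groups$group, groups$cell_id)
  } else if (is.character(groups) && !is.null(names(groups))) {
    g <- groups
  } else {
    stop("`groups` must be a named character vector or an annotation data.frame",
      call. = FALSE
    )
  }
  if (!is.null(cells)) {
    miss <- setdiff(cells, names(g))
    if (length(miss)) {
      stop("no group annotation for cell(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    g <- g[cells]
  }
  g
}

# Resolve gene symbols to probe ids. With probe_map = NULL the matrix rownames
# are taken to be gene symbols (RNA-seq style). Returns a named list
# gene -> character vector of probe ids (possibly empty).
resolve_probes <- function(matrix, genes, probe_map = NULL) {
  if (is.null(probe_map)) {
    out <- lapply(genes, function(g) intersect(g, rownames(matrix)))
  } else {
    out <- lapply(genes, function(g) {
      intersect(probe_map$probe_id[probe_map$gene_symbol == g], rownames(matrix))
    })
  }
  stats::setNames(out, genes)
}

# Map every probe id to a symbol (identity where unmapped / no map).
probe_symbols <- function(probe_ids, probe_map = NULL) {
  if (is.null(probe_map)) {
    return(stats::setNames(probe_ids, probe_ids))
  }
  sym <- stats::setNames(probe_map$gene_symbol, probe_map$probe_id)[probe_ids]
  unmapped <- is.na(sym)
  sym[unmapped] <- probe_ids[unmapped]
  stats::setNames(unname(sym), probe_ids)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b Cluster label vectors of equal length (factors, integers or
#'   characters). If both are named, `b` is aligned to `a`'s names.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  } # degenerate: both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
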