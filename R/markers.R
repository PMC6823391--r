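#' Prevalence-based marker calls over a cell subset
#'
#' Counts, for every gene with at least one detected cell, how many of the
#' given cells detect it. Genes detected in at least `min_cells` cells are
#' `majority_subset` markers (the study rule: expression within 7 or more of
#' the 14 profiled cells); genes detected in fewer (but at least one) are
#' `restricted_subset` candidates. Reports are ordered by prevalence
#' (descending), then symbol.
#'
#' @param matrix An [expr_matrix()].
#' @param cells Cell ids to screen (default: all cells in the matrix).
#' @param tau_det Detection threshold, log2 units.
#' @param min_cells Detection count separating majority from restricted
#'   markers (default 7).
#' @param probe_map Optional probe-to-symbol map; symbol collisions are
#'   collapsed onto the most-prevalent probe.
#' @return Data.frame `gene`, `probe_id`, `n_cells_detected`,
#'   `n_cells_total`, `prevalence`, `category`.
#' @export
prevalence_markers <- function(matrix, cells = NULL, tau_det = 6,
                               min_cells = 7L, probe_map = NULL) {
  stopifnot(is_expr_matrix(matrix))
  if (is.null(cells)) cells <- colnames(matrix)
  if (!length(cells)) stop("`cells` must be nonempty", call. = FALSE)
  miss <- setdiff(cells, colnames(matrix))
  if (length(miss)) {
    stop("cell(s) not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (min_cells > length(cells)) {
    stop(sprintf(
      "min_cells (%d) exceeds the number of cells screened (%d)",
      min_cells, length(cells)
    ), call. = FALSE)
  }
  calls <- detect_calls(matrix, tau_det)[, cells, drop = FALSE]
  n_det <- rowSums(calls)
  df <- data.frame(
    gene = unname(probe_symbols(rownames(matrix), probe_map)),
    probe_id = rownames(matrix),
    n_cells_detected = unname(n_det),
    n_cells_total = length(cells),
    stringsAsFactors = FALSE
  )
  df <- df[df$n_cells_detected >= 1L, , drop = FALSE]
  df$prevalence <- df$n_cells_detected / df$n_cells_total
  df$category <- ifelse(df$n_cells_detected >= min_cells,
    "majority_subset", "restricted_subset"
  )
  df <- df[order(-df$prevalence, df$gene, df$probe_id), ]
  df <- df[!duplicated(df$gene), ]
  rownames(df) <- NULL
  df
}

#' Seed-gene correlate screen
#'
#' Ranks every other probe by the Pearson correlation of its log2 expression
#' profile with the seed gene's profile across the given cells (the "correlate
#' score"), and keeps those at or above `r_threshold` (the study used > 0.53
#' for the melanopsin screen). Probes with zero variance are assigned r = 0,
#' so any positive threshold excludes them. The screen runs over all probes
#' of the matrix — restrict `matrix` beforehand (e.g. to filter survivors)
#' for a filtered screen.
#'
#' @param matrix An [expr_matrix()].
#' @param seed_gene Gene symbol (or probe id when `probe_map` is `NULL`).
#'   With several mapped probes, the highest-variance probe carries the seed
#'   profile.
#' @param r_threshold Minimum correlate score to report.
#' @param cells Cell ids defining the dataset screened (default: all).
#' @param probe_map Optional probe-to-symbol map; symbol collisions among
#'   correlates are collapsed onto the best-correlated probe.
#' @param dataset Free label recorded on the result (e.g. `"tdTomato"`).
#' @return A `correlate_list`: data.frame `gene`, `probe_id`, `r` sorted by
#'   descending r (ties by symbol), with attributes `seed_gene`,
#'   `r_threshold`, `dataset`.
#' @export
seed_correlates <- function(matrix, seed_gene, r_threshold = 0.53,
                            cells = NULL, probe_map = NULL,
                            dataset = "dataset") {
  stopifnot(is_expr_matrix(matrix))
  if (is.null(cells)) cells <- colnames(matrix)
  x <- as_log2(matrix)[, cells, drop = FALSE]
  seed_probes <- resolve_probes(matrix, seed_gene, probe_map)[[1]]
  if (!length(seed_probes)) {
    stop("seed gene '", seed_gene, "' maps to no probe in the matrix",
      call. = FALSE
    )
  }
  vars <- apply(x[seed_probes, , drop = FALSE], 1, stats::var)
  if (max(vars) == 0) {
    stop("seed gene '", seed_gene, "' has zero variance over the given cells",
      call. = FALSE
    )
  }
  seed_probe <- seed_probes[which.max(vars)]
  seed_profile <- x[seed_probe, ]
  probe_sd <- sqrt(rowSums((x - rowMeans(x))^2))
  r <- rep(0, nrow(x)) # zero-variance probes score 0 by convention
  ok <- probe_sd > 0
  r[ok] <- as.vector(stats::cor(seed_profile, t(x[ok, , drop = FALSE])))
  df <- data.frame(
    gene = unname(probe_symbols(rownames(x), probe_map)),
    probe_id = rownames(x),
    r = r,
    stringsAsFactors = FALSE
  )
  df <- df[df$probe_id != seed_probe & df$gene !=
    unname(probe_symbols(seed_probe, probe_map)), , drop = FALSE]
  df <- df[df$r >= r_threshold, , drop = FALSE]
  df <- df[order(-df$r, df$gene, df$probe_id), ]
  df <- df[!duplicated(df$gene), ]
  rownames(df) <- NULL
  structure(df,
    seed_gene = seed_gene, seed_probe = seed_probe,
    r_threshold = r_threshold, dataset = dataset,
    class = c("correlate_list", "data.frame")
  )
}

#' @export
print.correlate_list <- function(x, ...) {
  cat(sprintf(
    "<correlate_list> seed %s (probe %s), r >= %g, dataset '%s': %d gene(s)\n",
    attr(x, "seed_gene"), attr(x, "seed_probe"),
    attr(x, "r_threshold"), attr(x, "dataset"), nrow(x)
  ))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Genes correlated with a seed in two datasets
#'
#' Symbol-level intersection of two correlate lists, reporting both r
#' values, sorted by the smaller of the two (descending). Lists built from
#' different seed genes trigger a warning, not an error — the operation is
#' generic.
#'
#' @param list_a,list_b `correlate_list` objects from [seed_correlates()].
#' @return Data.frame `gene`, `r_a`, `r_b`, sorted by `pmin(r_a, r_b)`
#'   descending.
#' @export
cross_dataset_intersection <- function(list_a, list_b) {
  stopifnot(
    inherits(list_a, "correlate_list"),
    inherits(list_b, "correlate_list")
  )
  if (!identical(attr(list_a, "seed_gene"), attr(list_b, "seed_gene"))) {
    warning("correlate lists have different seed genes: ",
      attr(list_a, "seed_gene"), " vs ", attr(list_b, "seed_gene"),
      call. = FALSE
    )
  }
  common <- intersect(list_a$gene, list_b$gene)
  out <- data.frame(
    gene = common,
    r_a = list_a$r[match(common, list_a$gene)],
    r_b = list_b$r[match(common, list_b$gene)],
    stringsAsFactors = FALSE
  )
  out <- out[order(-pmin(out$r_a, out$r_b), out$gene), ]
  rownames(out) <- NULL
  out
}

#' Genes restricted to a set of functional classes
#'
#' Same prevalence-contrast rule as [cluster_enriched_genes()], but the
#' in-group is defined by functional-class annotations (e.g. the
#' direction-selective classes) instead of a tree cluster.
#'
#' @param matrix An [expr_matrix()].
#' @param annotations Annotation data.frame with `cell_id` and
#'   `functional_class`.
#' @param class_set Functional classes forming the in-group.
#' @param tau_det,min_in_prev,max_out_prev,probe_map,all As in
#'   [cluster_enriched_genes()].
#' @return Data.frame as for [cluster_enriched_genes()], with a `category`
#'   column set to `"class_restricted"`.
#' @export
class_restricted_genes <- function(matrix, annotations, class_set,
                                   tau_det = 6, min_in_prev = 0.75,
                                   max_out_prev = 0.25, probe_map = NULL,
                                   all = FALSE) {
  if (!length(class_set)) stop("`class_set` must be nonempty", call. = FALSE)
  ann <- annotations[annotations$cell_id %in% colnames(matrix), ]
  in_cells <- ann$cell_id[ann$functional_class %in% class_set]
  out_cells <- setdiff(colnames(matrix), in_cells)
  if (!length(in_cells)) {
    stop("no cells annotated with class(es): ",
      paste(class_set, collapse = ", "),
      call. = FALSE
    )
  }
  if (!length(out_cells)) {
    stop("class_set covers every cell; no out-group to contrast", call. = FALSE)
  }
  lab <- stats::setNames(
    ifelse(colnames(matrix) %in% in_cells, "in", "out"),
    colnames(matrix)
  )
  df <- cluster_enriched_genes(matrix, lab, "in",
    tau_det = tau_det,
    min_in_prev = min_in_prev, max_out_prev = max_out_prev,
    probe_map = probe_map, all = all
  )
  df$category <- "class_restricted"
  df
}

#' Co-detection overlap of two genes
#'
#' Partitions the given cells into the exhaustive 2x2 table of detection
#' calls for two genes (both detected, one only, neither), as used to count
#' cells co-expressing two transcription factors.
#'
#' @param matrix An [expr_matrix()].
#' @param gene_a,gene_b Gene symbols (or probe ids without a map). A gene
#'   counts as detected if any mapped probe is called.
#' @param cells Cell ids (default: all).
#' @param tau_det Detection threshold, log2 units.
#' @param probe_map Optional probe-to-symbol map.
#' @return A `coexpression_overlap` list: counts `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither` and the cell ids in each category.
#' @export
coexpression_overlap <- function(matrix, gene_a, gene_b, cells = NULL,
                                 tau_det = 6, probe_map = NULL) {
  stopifnot(is_expr_matrix(matrix))
  if (is.null(cells)) cells <- colnames(matrix)
  if (!length(cells)) stop("`cells` must be nonempty", call. = FALSE)
  probes <- resolve_probes(matrix, c(gene_a, gene_b), probe_map)
  unmapped <- names(probes)[vapply(probes, length, integer(1)) == 0L]
  if (length(unmapped)) {
    stop("gene(s) not resolvable to any probe: ",
      paste(unique(unmapped), collapse = ", "),
      call. = FALSE
    )
  }
  calls <- detect_calls(matrix, tau_det)[, cells, drop = FALSE]
  det <- function(p) {
    if (length(p) == 1L) calls[p, ] else apply(calls[p, , drop = FALSE], 2, any)
  }
  a <- det(probes[[1]])
  b <- det(probes[[2]])
  if (identical(gene_a, gene_b)) b <- a
  out <- list(
    gene_a = gene_a, gene_b = gene_b,
    n_both = sum(a & b), n_a_only = sum(a & !b),
    n_b_only = sum(!a & b), n_neither = sum(!a & !b),
    cells = list(
      both = cells[a & b], a_only = cells[a & !b],
      b_only = cells[!a & b], neither = cells[!a & !b]
    )
  )
  class(out) <- "coexpression_overlap"
  out
}

#' @export
print.coexpression_overlap <- function(x, ...) {
  cat(sprintf(
    "<coexpression_overlap> %s / %s: both %d, %s-only %d, %s-only %d, neither %d\n",
    x$gene_a, x$gene_b, x$n_both, x$gene_a, x$n_a_only,
    x$gene_b, x$n_b_only, x$n_neither
  ))
  invisible(x)
}

#' Detection profile of a gene panel
#'
#' Reports, gene by gene in the given order, how many of the cells detect
#' each panel gene (e.g. sodium/potassium channel subunit panels), together
#' with the underlying gene-by-cell call grid. Unmapped panel genes are
#' reported, not fatal — unless the entire panel is unmapped.
#'
#' @param matrix An [expr_matrix()].
#' @param gene_panel Character vector of gene symbols, in display order.
#' @param cells Cell ids (default: all).
#' @param tau_det Detection threshold, log2 units.
#' @param probe_map Optional probe-to-symbol map.
#' @return A list: `report` (data.frame `gene`, `n_cells_detected`,
#'   `n_cells_total`, `prevalence`, `category = "panel"`), `calls`
#'   (gene-by-cell logical matrix), `unmapped` (character).
#' @export
panel_query <- function(matrix, gene_panel, cells = NULL, tau_det = 6,
                        probe_map = NULL) {
  stopifnot(is_expr_matrix(matrix))
  if (is.null(cells)) cells <- colnames(matrix)
  if (!length(cells)) stop("`cells` must be nonempty", call. = FALSE)
  probes <- resolve_probes(matrix, gene_panel, probe_map)
  mapped <- gene_panel[vapply(probes, length, integer(1)) > 0L]
  unmapped <- setdiff(gene_panel, mapped)
  if (!length(mapped)) {
    stop("no panel gene maps to any probe in the matrix", call. = FALSE)
  }
  calls <- detect_calls(matrix, tau_det)[, cells, drop = FALSE]
  gene_call <- function(g) {
    p <- probes[[g]]
    if (length(p) == 1L) calls[p, ] else apply(calls[p, , drop = FALSE], 2, any)
  }
  grid <- matrix(FALSE, length(mapped), length(cells),
    dimnames = list(mapped, cells)
  )
  for (g in mapped) grid[g, ] <- gene_call(g)
  report <- data.frame(
    gene = mapped,
    n_cells_detected = unname(rowSums(grid)),
    n_cells_total = length(cells),
    stringsAsFactors = FALSE
  )
  report$prevalence <- report$n_cells_detected / report$n_cells_total
  report$category <- "panel"
  list(report = report, calls = grid, unmapped = unmapped)
}
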