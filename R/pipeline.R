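#' Pipeline configuration
#'
#' Bundles every knob of the marker-discovery pipeline. Exactly one input
#' source must be given: file paths (`matrix_path`, and optionally
#' `annotations_path` / `probe_map_path`) or a [sim_config()] for a
#' synthetic run. The defaults are the study constants: detection threshold
#' 6 (log2), SD cutoff 2.5 in both groups, tree cut at k = 4, correlate
#' threshold 0.53, majority rule at 7 cells.
#'
#' @param matrix_path,annotations_path,probe_map_path Input files read with
#'   [read_matrix()], [read_annotations()], [read_probe_map()].
#' @param sim A [sim_config()] for a synthetic run.
#' @param scale_tag Scale of the stored matrix (passed to [read_matrix()]).
#' @param tau_det Detection threshold, log2-signal units.
#' @param sd_threshold Dual-group SD cutoff (default 2.5).
#' @param strict_sd Strict inequality in the SD filter.
#' @param k Number of clusters cut from the tree (default 4).
#' @param r_threshold Correlate-score cutoff (default 0.53).
#' @param min_cells Majority-marker detection count (default 7).
#' @param min_in_prev,max_out_prev Prevalence gates for enrichment screens.
#' @param qc A [qc_rule()], or `NULL` to skip the QC stage.
#' @param seed_genes Gene symbols to run correlate screens for.
#' @param class_sets Named list of functional-class sets for
#'   [class_restricted_genes()] screens (no-ops when annotations carry no
#'   class labels).
#' @param seed Integer seed (governs the synthetic generator).
#' @param output_dir Optional directory for the report bundle.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(matrix_path = NULL, annotations_path = NULL,
                            probe_map_path = NULL, sim = NULL,
                            scale_tag = NULL,
                            tau_det = 6, sd_threshold = 2.5,
                            strict_sd = TRUE, k = 4L, r_threshold = 0.53,
                            min_cells = 7L, min_in_prev = 0.75,
                            max_out_prev = 0.25, qc = qc_rule(),
                            seed_genes = character(),
                            class_sets = list(), seed = 1L,
                            output_dir = NULL) {
  if (is.null(matrix_path) == is.null(sim)) {
    stop("give exactly one of `matrix_path` or `sim`", call. = FALSE)
  }
  if (!is.null(sim)) validate_sim_config(sim)
  stopifnot(
    tau_det >= 0, sd_threshold >= 0, k >= 1, min_cells >= 1,
    r_threshold >= -1, r_threshold <= 1,
    min_in_prev >= 0, min_in_prev <= 1,
    max_out_prev >= 0, max_out_prev <= 1
  )
  structure(
    list(
      matrix_path = matrix_path, annotations_path = annotations_path,
      probe_map_path = probe_map_path, sim = sim, scale_tag = scale_tag,
      tau_det = tau_det, sd_threshold = sd_threshold,
      strict_sd = strict_sd, k = as.integer(k),
      r_threshold = r_threshold, min_cells = as.integer(min_cells),
      min_in_prev = min_in_prev, max_out_prev = max_out_prev,
      qc = qc, seed_genes = seed_genes, class_sets = class_sets,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full marker-discovery pipeline
#'
#' Executes the stages in order — input (or simulation), library QC,
#' per-group SDs with the mixture diagnosis, the dual-group SD filter,
#' correlation-distance average-linkage clustering with the k-cut,
#' cluster-enrichment screens, prevalence markers over the target cells,
#' and any configured seed-gene correlate and class-restricted screens —
#' and collects every result plus a run manifest. Reruns with the same
#' configuration and seed are bit-identical. No cell or gene is silently
#' dropped; QC failures are reported, not removed. Errors propagate with
#' the failing stage's name.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `marker_pipeline` list: `qc`, `sd_table`, `mixture_target`,
#'   `mixture_comparison`, `suggested_threshold`, `filter`, `distances`,
#'   `dendrogram`, `assignment`, `enriched` (per cluster), `markers`
#'   (prevalence over target cells), `correlates` (per seed gene),
#'   `class_restricted` (per class set), `truth` (synthetic runs only),
#'   and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)

  if (!is.null(config$sim)) {
    say("stage input: generating synthetic dataset (seed %d)", config$sim$seed)
    sim <- with_stage("input", generate_dataset(config$sim))
    mat <- sim$matrix
    ann <- sim$annotations
    probe_map <- sim$probe_map
    truth <- sim$truth
  } else {
    say("stage input: reading %s", config$matrix_path)
    mat <- with_stage("input", read_matrix(config$matrix_path, config$scale_tag))
    ann <- if (!is.null(config$annotations_path)) {
      with_stage("input", read_annotations(config$annotations_path))
    } else {
      data.frame(
        cell_id = colnames(mat), dataset = "dataset", group = "target",
        functional_class = "unknown", qc_pass = NA, stringsAsFactors = FALSE
      )
    }
    probe_map <- if (!is.null(config$probe_map_path)) {
      with_stage("input", read_probe_map(config$probe_map_path))
    } else {
      NULL
    }
    truth <- NULL
  }

  qc_tab <- NULL
  if (!is.null(config$qc)) {
    say("stage qc: screening %d cells", ncol(mat))
    qc_tab <- with_stage("qc", library_qc(mat, probe_map, config$qc))
    ann$qc_pass <- qc_tab$qc_pass[match(ann$cell_id, qc_tab$cell_id)]
    n_fail <- sum(!qc_tab$qc_pass)
    if (n_fail) {
      say(
        "stage qc: %d cell(s) flagged (reported, not dropped): %s",
        n_fail, paste(qc_tab$cell_id[!qc_tab$qc_pass], collapse = ", ")
      )
    }
  }

  say("stage filter: per-group SDs for %d probes", nrow(mat))
  sd_tab <- with_stage("filter", per_group_sd(mat, ann))
  mix_t <- with_stage("filter", fit_sd_mixture(sd_tab$sd_target))
  mix_c <- with_stage("filter", fit_sd_mixture(sd_tab$sd_comparison))
  filt <- with_stage(
    "filter",
    dual_sd_filter(sd_tab, config$sd_threshold, config$strict_sd)
  )
  say(
    "stage filter: %d of %d probes retained at SD %s %g",
    filt$n_retained, filt$n_input, if (config$strict_sd) ">" else ">=",
    config$sd_threshold
  )

  say("stage cluster: %d cells, k = %d", ncol(mat), config$k)
  dists <- with_stage(
    "cluster",
    correlation_distance(mat, filt$retained_probe_ids)
  )
  dend <- with_stage("cluster", average_linkage(dists))
  assign <- with_stage("cluster", cut_tree(dend, config$k))
  enriched <- with_stage("cluster", lapply(
    stats::setNames(seq_len(config$k), paste0("cluster_", seq_len(config$k))),
    function(cl) {
      cluster_enriched_genes(mat, assign, cl,
        tau_det = config$tau_det,
        min_in_prev = config$min_in_prev,
        max_out_prev = config$max_out_prev,
        probe_map = probe_map
      )
    }
  ))

  target_cells <- ann$cell_id[ann$group == "target"]
  markers <- NULL
  if (length(target_cells) >= config$min_cells) {
    say(
      "stage screens: prevalence markers over %d target cells",
      length(target_cells)
    )
    markers <- with_stage("screens", prevalence_markers(
      mat,
      cells = target_cells, tau_det = config$tau_det,
      min_cells = config$min_cells, probe_map = probe_map
    ))
  }

  correlates <- lapply(
    stats::setNames(config$seed_genes, config$seed_genes),
    function(g) {
      say("stage screens: correlates of %s at r >= %g", g, config$r_threshold)
      with_stage("screens", seed_correlates(
        mat, g,
        r_threshold = config$r_threshold,
        probe_map = probe_map, dataset = unique(ann$dataset)[1]
      ))
    }
  )

  class_restricted <- list()
  if (length(config$class_sets) &&
    any(ann$functional_class != "unknown")) {
    class_restricted <- lapply(config$class_sets, function(cs) {
      say("stage screens: class-restricted genes for {%s}", paste(cs, collapse = ", "))
      with_stage("screens", class_restricted_genes(
        mat, ann, cs,
        tau_det = config$tau_det,
        min_in_prev = config$min_in_prev,
        max_out_prev = config$max_out_prev, probe_map = probe_map
      ))
    })
  }

  manifest <- list(
    package = "rgcmarkers",
    version = as.character(utils::packageVersion("rgcmarkers")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = list(
      tau_det = config$tau_det, sd_threshold = config$sd_threshold,
      strict_sd = config$strict_sd, k = config$k,
      r_threshold = config$r_threshold, min_cells = config$min_cells,
      min_in_prev = config$min_in_prev, max_out_prev = config$max_out_prev,
      log2_transform = "log2(x + 1) unless log2_already",
      sd_denominator = "n - 1",
      distance = "1 - Pearson r",
      linkage = "average (UPGMA), lexicographic tie-break",
      cluster_labels = "decreasing size, ties by smallest member id",
      qc = if (is.null(config$qc)) NULL else unclass(config$qc),
      seed_genes = config$seed_genes,
      sim = if (is.null(config$sim)) NULL else unclass(config$sim)
    ),
    inputs = list(
      matrix_path = config$matrix_path,
      annotations_path = config$annotations_path,
      probe_map_path = config$probe_map_path
    ),
    n_probes = nrow(mat), n_cells = ncol(mat)
  )

  out <- list(
    matrix = mat, annotations = ann, probe_map = probe_map,
    qc = qc_tab, sd_table = sd_tab,
    mixture_target = mix_t, mixture_comparison = mix_c,
    suggested_threshold = suggest_threshold(mix_t),
    filter = filt, distances = dists, dendrogram = dend,
    assignment = assign, enriched = enriched, markers = markers,
    correlates = correlates, class_restricted = class_restricted,
    truth = truth, manifest = manifest
  )
  class(out) <- "marker_pipeline"

  if (!is.null(config$output_dir)) {
    write_pipeline_bundle(out, config$output_dir)
    say("report bundle written to %s", config$output_dir)
  }
  out
}

#' @export
print.marker_pipeline <- function(x, ...) {
  cat("<marker_pipeline>\n")
  cat(sprintf(
    "  %d probes x %d cells; %d retained by SD filter (threshold %g)\n",
    x$manifest$n_probes, x$manifest$n_cells,
    x$filter$n_retained, x$filter$threshold
  ))
  k <- attr(x$assignment, "k")
  sizes <- table(unclass(x$assignment))
  cat(sprintf(
    "  k = %d clusters of sizes [%s]\n", k,
    paste(as.integer(sizes), collapse = ", ")
  ))
  if (!is.null(x$qc)) {
    cat(sprintf("  QC: %d / %d cells pass\n", sum(x$qc$qc_pass), nrow(x$qc)))
  }
  if (!is.null(x$markers)) {
    cat(sprintf(
      "  %d majority-subset marker gene(s) at >= %d cells\n",
      sum(x$markers$category == "majority_subset"),
      x$manifest$parameters$min_cells
    ))
  }
  for (g in names(x$correlates)) {
    cat(sprintf(
      "  %s correlates at r >= %g: %d gene(s)\n",
      g, attr(x$correlates[[g]], "r_threshold"), nrow(x$correlates[[g]])
    ))
  }
  invisible(x)
}

#' @export
summary.marker_pipeline <- function(object, ...) {
  print(object)
  cat("\nSD mixture (target group):\n")
  print(object$mixture_target)
  cat(sprintf(
    "suggested SD threshold %.3f (operative %.2f)\n",
    object$suggested_threshold, object$filter$threshold
  ))
  invisible(object)
}

#' Write the pipeline report bundle
#'
#' Writes the QC table, SD/filter table, mixture report, Newick tree,
#' cluster assignment, enrichment/marker/correlate tables, and the JSON run
#' manifest into a directory. Everything is a plain-text artifact.
#'
#' @param result A `marker_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_bundle <- function(result, dir) {
  stopifnot(inherits(result, "marker_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name),
      sep = "\t",
      quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(result$qc)) tsv(result$qc, "qc.tsv")
  tsv(result$filter$table, "sd_filter.tsv")
  mix <- function(m) {
    list(
      weights = m$weights, means = m$means, sds = m$sds,
      log_likelihood = m$log_likelihood, n_iter = m$n_iter,
      converged = m$converged
    )
  }
  jsonlite::write_json(
    list(
      target = mix(result$mixture_target),
      comparison = mix(result$mixture_comparison),
      suggested_threshold = result$suggested_threshold
    ),
    file.path(dir, "sd_mixture.json"),
    auto_unbox = TRUE, digits = NA
  )
  export_newick(result$dendrogram, file.path(dir, "dendrogram.nwk"))
  tsv(
    data.frame(
      cell_id = names(result$assignment),
      cluster = as.integer(result$assignment)
    ),
    "clusters.tsv"
  )
  for (cl in names(result$enriched)) {
    tsv(result$enriched[[cl]], sprintf("enriched_%s.tsv", cl))
  }
  if (!is.null(result$markers)) tsv(result$markers, "prevalence_markers.tsv")
  for (g in names(result$correlates)) {
    tsv(as.data.frame(result$correlates[[g]]), sprintf("correlates_%s.tsv", g))
  }
  for (cs in names(result$class_restricted)) {
    tsv(result$class_restricted[[cs]], sprintf("class_restricted_%s.tsv", cs))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' Reorder an expression matrix by dendrogram leaf order
#'
#' Returns the matrix with its columns in the dendrogram's left-to-right
#' leaf order (and optionally its rows in a given gene order) — the numeric
#' export behind an expression heatmap. Values are unchanged.
#'
#' @param matrix An [expr_matrix()].
#' @param dendrogram A `cell_dendrogram` whose leaves are exactly the
#'   matrix's cells.
#' @param gene_order Optional row (probe) order.
#' @return The reordered [expr_matrix()].
#' @export
render_ordered_matrix <- function(matrix, dendrogram, gene_order = NULL) {
  stopifnot(is_expr_matrix(matrix), inherits(dendrogram, "cell_dendrogram"))
  if (!setequal(dendrogram$labels, colnames(matrix))) {
    stop("dendrogram leaves and matrix cells differ", call. = FALSE)
  }
  cells <- dendrogram$labels[dendrogram$order]
  out <- matrix[, cells, drop = FALSE]
  if (!is.null(gene_order)) {
    miss <- setdiff(gene_order, rownames(matrix))
    if (length(miss)) {
      stop("gene_order contains unknown probe(s): ",
        paste(utils::head(miss, 5), collapse = ", "),
        call. = FALSE
      )
    }
    out <- out[gene_order, , drop = FALSE]
  }
  out
}
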