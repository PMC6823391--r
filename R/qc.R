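#' Library quality-control rule
#'
#' A QC rule gates single-cell libraries on marker genes: every `required`
#' gene must be detected (the default *Sncg* is a pan-RGC gene) and no
#' `excluded` contaminant gene may be detected (defaults: *Rho*, rod
#' photoreceptors; *Glul*, Mueller glia). Detection is a log2-signal
#' threshold call, the in-silico analogue of a presence/absence PCR screen.
#'
#' @param required Gene symbols that must be detected for a cell to pass.
#' @param excluded Gene symbols whose detection fails a cell.
#' @param tau_det Detection threshold in log2-signal units.
#' @return A `qc_rule` object.
#' @export
qc_rule <- function(required = "Sncg", excluded = c("Rho", "Glul"), tau_det = 6) {
  overlap <- intersect(required, excluded)
  if (length(overlap)) {
    stop("gene(s) both required and excluded: ", paste(overlap, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.finite(tau_det)) stop("tau_det must be finite", call. = FALSE)
  structure(
    list(required = required, excluded = excluded, tau_det = tau_det),
    class = "qc_rule"
  )
}

#' @export
print.qc_rule <- function(x, ...) {
  cat(sprintf(
    "<qc_rule> require {%s}, exclude {%s}, tau_det = %g\n",
    paste(x$required, collapse = ", "),
    paste(x$excluded, collapse = ", "), x$tau_det
  ))
  invisible(x)
}

#' Binary detection calls
#'
#' A probe is called "detected" in a cell when its log2 signal reaches
#' `tau_det`; linear-scale matrices are transformed as `log2(x + 1)` first
#' (see [as_log2()]).
#'
#' @param matrix An [expr_matrix()].
#' @param tau_det Detection threshold, log2-signal units.
#' @return Logical probe-by-cell matrix.
#' @export
detect_calls <- function(matrix, tau_det = 6) {
  stopifnot(is_expr_matrix(matrix))
  as_log2(matrix) >= tau_det
}

#' Gate cell libraries on required and contaminant marker genes
#'
#' A cell passes when every required gene is detected and no excluded gene
#' is detected. A gene counts as detected if any of its mapped probes is
#' called at the rule's threshold (a deliberate OR, conservative for
#' presence screening). Cells are reported, never silently dropped.
#'
#' @param matrix An [expr_matrix()].
#' @param probe_map Probe-to-symbol map (data.frame `probe_id`,
#'   `gene_symbol`), or `NULL` when rownames are gene symbols.
#' @param rule A [qc_rule()].
#' @return Data.frame with `cell_id`, `qc_pass`, and `reasons` (semicolon-
#'   separated violated clauses, empty for passing cells).
#' @export
library_qc <- function(matrix, probe_map = NULL, rule = qc_rule()) {
  stopifnot(inherits(rule, "qc_rule"))
  genes <- c(rule$required, rule$excluded)
  if (!length(genes)) { # vacuous rule: every cell passes
    return(data.frame(
      cell_id = colnames(matrix), qc_pass = TRUE, reasons = "",
      stringsAsFactors = FALSE, row.names = NULL
    ))
  }
  probes <- resolve_probes(matrix, genes, probe_map)
  absent <- genes[vapply(probes, length, integer(1)) == 0L]
  if (length(absent)) {
    stop("QC rule gene(s) not resolvable to any probe: ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  calls <- detect_calls(matrix, rule$tau_det)
  gene_detected <- function(g) {
    p <- probes[[g]]
    if (length(p) == 1L) calls[p, ] else apply(calls[p, , drop = FALSE], 2, any)
  }
  det <- vapply(genes, gene_detected, logical(ncol(matrix)))
  if (ncol(matrix) == 1L) det <- matrix(det, nrow = 1L, dimnames = list(NULL, genes))
  reasons <- vapply(seq_len(ncol(matrix)), function(i) {
    bad <- c(
      sprintf("required gene %s not detected", rule$required[!det[i, rule$required]]),
      sprintf("excluded gene %s detected", rule$excluded[det[i, rule$excluded]])
    )
    paste(bad, collapse = "; ")
  }, character(1))
  data.frame(
    cell_id = colnames(matrix),
    qc_pass = !nzchar(reasons),
    reasons = reasons,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
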