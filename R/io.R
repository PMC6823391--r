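#' Controlled vocabulary of functional cell classes
#'
#' Functional classes assigned to electrophysiologically characterized retinal
#' ganglion cells (direction-selective, orientation-selective, alpha types,
#' intrinsically photosensitive and related classes), plus `"other"` and
#' `"unknown"` fallbacks.
#'
#' @return Character vector of admissible `functional_class` labels.
#' @export
functional_classes <- function() {
  c(
    "ON_alpha", "OFF_transient_alpha", "OFF_sustained_alpha",
    "ON_DS", "ONOFF_DS", "ON_OS",
    "ON_transient_RF", "OFF_transient_RF",
    "PixON", "J_RGC", "LED", "SbC", "size_selector",
    "other", "unknown"
  )
}

#' Read a tab-delimited expression matrix
#'
#' Reads a probe-by-cell expression table in the series-matrix-like dialect:
#' tab-delimited, first row holds cell identifiers, first column holds probe
#' identifiers, and any line starting with `!` (series-matrix metadata) is
#' ignored. A metadata line of the form `!scale_tag=<tag>` written by
#' [write_matrix()] is honoured when `scale_tag` is not supplied.
#'
#' @param path Path to the file.
#' @param scale_tag Scale of the stored values (see [expr_matrix()]). If
#'   `NULL`, taken from a `!scale_tag=` header line, defaulting to
#'   `"mas5_linear"`.
#' @return A validated [expr_matrix()] with row/column order as in the file.
#' @export
read_matrix <- function(path, scale_tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "!")]
  if (is.null(scale_tag)) {
    tag_line <- grep("^!scale_tag=", meta, value = TRUE)
    scale_tag <- if (length(tag_line)) {
      sub("^!scale_tag=", "", tag_line[1])
    } else {
      "mas5_linear"
    }
  }
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  cell_ids <- header[-1]
  body <- fields[-1]
  n_col <- length(cell_ids)
  probe_ids <- vapply(body, `[[`, character(1), 1L)
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup)) {
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup)) {
    stop("duplicate cell id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  values <- matrix(NA_real_, length(body), n_col,
    dimnames = list(probe_ids, cell_ids)
  )
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col + 1L) {
      stop(sprintf(
        "row for probe '%s' has %d fields, expected %d",
        probe_ids[i], length(row), n_col + 1L
      ), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf(
        "non-numeric value '%s' at probe '%s', cell '%s'",
        row[j + 1L], probe_ids[i], cell_ids[j]
      ), call. = FALSE)
    }
    values[i, ] <- v
  }
  expr_matrix(values, scale_tag)
}

#' Write an expression matrix
#'
#' Serializes an [expr_matrix()] in the dialect read by [read_matrix()],
#' recording the scale tag in a `!scale_tag=` header line. Values are written
#' with full double precision, so `read_matrix(write_matrix(m))` reproduces
#' `m` exactly.
#'
#' @param matrix An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  validate_expr_matrix(matrix)
  con <- tryCatch(file(path, open = "wt"), condition = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(sprintf("!scale_tag=%s", scale_tag(matrix)), con)
  writeLines(paste(c("ID_REF", colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix)) {
    vals <- formatC(unclass(matrix), format = "g", digits = 17)
    body <- apply(cbind(rownames(matrix), vals), 1, paste, collapse = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a cell annotation table
#'
#' Reads a delimited table with columns `cell_id`, `dataset`, `group`
#' (`target` or `comparison`), and optionally `functional_class` and
#' `qc_pass`. Unknown functional-class tokens are mapped to `"other"` with a
#' warning; a `cell_id` occurring twice within one dataset is an error.
#'
#' @param path Path to a tab- or comma-delimited file (delimiter sniffed from
#'   the header line).
#' @return A data.frame of cell annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  ann <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    comment.char = "!", quote = "\""
  )
  validate_annotations(ann)
}

#' Validate a cell annotation table
#'
#' @param ann Data.frame with at least `cell_id`, `dataset`, `group`.
#' @return The validated (possibly class-normalized) data.frame.
#' @export
validate_annotations <- function(ann) {
  need <- c("cell_id", "dataset", "group")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  bad_grp <- setdiff(unique(ann$group), c("target", "comparison"))
  if (length(bad_grp)) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
      " (expected 'target' or 'comparison')",
      call. = FALSE
    )
  }
  key <- paste(ann$dataset, ann$cell_id, sep = "\r")
  dup <- unique(ann$cell_id[duplicated(key)])
  if (length(dup)) {
    stop("cell id(s) annotated twice within one dataset: ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(ann$functional_class)) {
    unknown <- !(ann$functional_class %in% functional_classes()) &
      !is.na(ann$functional_class)
    if (any(unknown)) {
      warning(
        "unknown functional_class token(s) mapped to 'other': ",
        paste(unique(ann$functional_class[unknown]), collapse = ", "),
        call. = FALSE
      )
      ann$functional_class[unknown] <- "other"
    }
  } else {
    ann$functional_class <- rep("unknown", nrow(ann))
  }
  if (is.null(ann$qc_pass)) ann$qc_pass <- rep(NA, nrow(ann))
  ann
}

#' Write a cell annotation table
#'
#' @param ann Annotation data.frame as returned by [read_annotations()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a probe-to-gene-symbol map
#'
#' Two-column tab-delimited table (`probe_id`, `gene_symbol`). Many probes may
#' map to one symbol, but each probe maps to at most one symbol; unmapped
#' probes are simply absent. Symbols listed in `aliases` are normalized to
#' their standard spelling (by default the `Mfab` spelling of *Mafb* seen in
#' some gene lists).
#'
#' @param path Path to the map file.
#' @param aliases Named character vector, `names()` being the variant spelling
#'   and values the normalized symbol.
#' @return Data.frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path, aliases = c(Mfab = "Mafb")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, comment.char = "!"
  )
  if (!all(c("probe_id", "gene_symbol") %in% names(map))) {
    stop("probe map needs columns 'probe_id' and 'gene_symbol'", call. = FALSE)
  }
  dup <- unique(map$probe_id[duplicated(map$probe_id)])
  if (length(dup)) {
    stop("probe id(s) mapped more than once: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  hit <- map$gene_symbol %in% names(aliases)
  if (any(hit)) map$gene_symbol[hit] <- unname(aliases[map$gene_symbol[hit]])
  map[, c("probe_id", "gene_symbol")]
}
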