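test_that("prevalence markers split majority from restricted at min_cells", {
  # 3 genes over 14 cells: detected in 7, 3, and 0 cells
  on <- 2^10 - 1
  off <- 2
  vals <- rbind(
    Pcp4 = c(rep(on, 7), rep(off, 7)),
    Chrm1 = c(rep(on, 3), rep(off, 11)),
    Silent = rep(off, 14)
  )
  colnames(vals) <- sprintf("c%02d", 1:14)
  m <- expr_matrix(vals, "mas5_linear")
  rep_ <- prevalence_markers(m, min_cells = 7)
  expect_identical(rep_$gene, c("Pcp4", "Chrm1")) # undetected genes absent
  expect_identical(rep_$category, c("majority_subset", "restricted_subset"))
  expect_equal(rep_$prevalence, c(0.5, 3 / 14))
  expect_equal(rep_$n_cells_total, c(14L, 14L))

  expect_error(prevalence_markers(m, min_cells = 15), "min_cells")
  expect_error(prevalence_markers(m, cells = character(0)), "nonempty")
})

test_that("planted pan markers report as majority subset with prevalence 1", {
  d <- generate_dataset(clean_sim_config(seed = 30))
  tgt <- d$annotations$cell_id[d$annotations$group == "target"]
  rep_ <- prevalence_markers(d$matrix,
    cells = tgt, min_cells = 7,
    probe_map = d$probe_map
  )
  pan <- d$probe_map$gene_symbol[match(
    names(d$truth$probe_role)[d$truth$probe_role == "pan_marker"],
    d$probe_map$probe_id
  )]
  got <- rep_[rep_$gene %in% pan, ]
  expect_equal(nrow(got), length(pan))
  expect_true(all(got$category == "majority_subset"))
  expect_equal(got$prevalence, rep(1, length(pan)))
  # no noise probe reaches the majority rule
  noise <- d$probe_map$gene_symbol[match(
    names(d$truth$probe_role)[d$truth$probe_role == "noise"],
    d$probe_map$probe_id
  )]
  expect_length(intersect(rep_$gene[rep_$category == "majority_subset"], noise), 0)
})

test_that("a duplicated seed profile ranks first with r = 1", {
  set.seed(4)
  base <- matrix(rnorm(60, 8, 2), 10, 6,
    dimnames = list(paste0("p", 1:10), paste0("c", 1:6))
  )
  base["p2", ] <- base["p1", ] # p2 duplicates the seed probe p1
  m <- log2_matrix(base)
  cl <- seed_correlates(m, "p1", r_threshold = 0.5)
  expect_identical(cl$probe_id[1], "p2")
  expect_equal(cl$r[1], 1)
  expect_false("p1" %in% cl$probe_id) # seed itself excluded

  # an impossible threshold empties the list
  expect_equal(nrow(seed_correlates(m, "p1", r_threshold = 1 + 1e-9)), 0L)

  # zero-variance seed is a named hard error
  base["p3", ] <- 5
  expect_error(seed_correlates(log2_matrix(base), "p3"), "p3.*zero variance")
})

test_that("correlate screens recover a planted co-regulated module", {
  # larger cell panel: chance correlations stay below the 0.53 bar
  cfg <- sim_config(
    n_probes = 3000, n_cells_per_type = c(30L, 20L, 20L),
    n_types_target = 2L, n_markers_per_type = 40L, n_pan_markers = 10L,
    seed = 77
  )
  d <- generate_dataset(cfg)
  role <- d$truth$probe_role
  seed_probe <- names(role)[role == "marker_of_target_1"][1]
  seed_gene <- d$probe_map$gene_symbol[d$probe_map$probe_id == seed_probe]
  cl <- seed_correlates(d$matrix, seed_gene,
    r_threshold = 0.53,
    probe_map = d$probe_map
  )
  module <- d$probe_map$gene_symbol[match(
    setdiff(names(role)[role == "marker_of_target_1"], seed_probe),
    d$probe_map$probe_id
  )]
  expect_true(all(module %in% cl$gene))
  noise <- d$probe_map$gene_symbol[match(
    names(role)[role == "noise"], d$probe_map$probe_id
  )]
  expect_length(intersect(cl$gene, noise), 0)
})

test_that("tightening the correlate threshold only shrinks the list", {
  d <- generate_dataset(clean_sim_config(seed = 41))
  seed_gene <- "Sncg"
  lo <- seed_correlates(d$matrix, seed_gene,
    r_threshold = 0.3,
    probe_map = d$probe_map
  )
  hi <- seed_correlates(d$matrix, seed_gene,
    r_threshold = 0.8,
    probe_map = d$probe_map
  )
  expect_true(all(hi$gene %in% lo$gene))
  expect_true(all(lo$r >= 0.3))
  expect_true(!is.unsorted(rev(lo$r)))
})

test_that("cross-dataset intersection matches the enumeration oracle", {
  mk <- function(genes, rs, seed = "Pvalb", dataset = "a") {
    structure(
      data.frame(
        gene = genes, probe_id = genes, r = rs,
        stringsAsFactors = FALSE
      ),
      seed_gene = seed, r_threshold = 0.5, dataset = dataset,
      class = c("correlate_list", "data.frame")
    )
  }
  a <- mk(c("A", "B"), c(0.9, 0.6))
  b <- mk(c("B", "C"), c(0.7, 0.8), dataset = "b")
  both <- cross_dataset_intersection(a, b)
  expect_identical(both$gene, "B")
  expect_equal(both$r_a, 0.6)
  expect_equal(both$r_b, 0.7)

  # commutative up to the (r_a, r_b) order
  swapped <- cross_dataset_intersection(b, a)
  expect_identical(swapped$gene, both$gene)
  expect_equal(swapped$r_a, both$r_b)

  expect_equal(nrow(cross_dataset_intersection(
    mk("A", 0.9), mk("Z", 0.8)
  )), 0L)
  full <- cross_dataset_intersection(a, a)
  expect_identical(full$gene, c("A", "B"))

  expect_warning(
    cross_dataset_intersection(a, mk("B", 0.7, seed = "Opn4")),
    "different seed genes"
  )
})

test_that("class-restricted screens find markers of an annotated class", {
  cfg <- clean_sim_config(seed = 50)
  d <- generate_dataset(cfg, type_classes = c(
    target_1 = "ONOFF_DS", target_2 = "OFF_sustained_alpha",
    comparison_1 = "other"
  ))
  hits <- class_restricted_genes(d$matrix, d$annotations, "ONOFF_DS",
    probe_map = d$probe_map
  )
  planted <- d$probe_map$gene_symbol[match(
    names(d$truth$probe_role)[d$truth$probe_role == "marker_of_target_1"],
    d$probe_map$probe_id
  )]
  expect_true(all(planted %in% hits$gene))
  expect_true(all(hits$category == "class_restricted"))
  # ubiquitous genes are excluded under the default gates
  bg <- d$probe_map$gene_symbol[match(
    names(d$truth$probe_role)[d$truth$probe_role == "background_informative"],
    d$probe_map$probe_id
  )]
  expect_length(intersect(hits$gene, bg), 0)

  expect_error(
    class_restricted_genes(
      d$matrix, d$annotations,
      c("ONOFF_DS", "OFF_sustained_alpha", "other")
    ),
    "every cell"
  )
  expect_error(
    class_restricted_genes(d$matrix, d$annotations, "J_RGC"),
    "no cells"
  )
})

test_that("co-detection overlap partitions the cells exhaustively", {
  on <- 2^9
  off <- 1
  vals <- rbind(
    Kcnip2 = c(on, on, on, off, off, off),
    Mafb = c(off, off, on, on, off, off)
  )
  colnames(vals) <- paste0("c", 1:6)
  m <- expr_matrix(vals, "mas5_linear")
  ov <- coexpression_overlap(m, "Kcnip2", "Mafb")
  expect_equal(
    c(ov$n_both, ov$n_a_only, ov$n_b_only, ov$n_neither),
    c(1L, 2L, 1L, 2L)
  )
  expect_identical(ov$cells$both, "c3")
  expect_equal(ov$n_both + ov$n_a_only + ov$n_b_only + ov$n_neither, 6L)

  self <- coexpression_overlap(m, "Kcnip2", "Kcnip2")
  expect_equal(self$n_a_only, 0L)
  expect_equal(self$n_b_only, 0L)
  expect_equal(self$n_both, 3L)

  expect_error(coexpression_overlap(m, "Kcnip2", "Nope"), "Nope")
})

test_that("panel queries report per-gene detection in panel order", {
  on <- 2^9
  off <- 1
  vals <- rbind(
    Scn5a = c(on, rep(off, 13)), # the one-cell pattern
    Kcng4 = c(on, on, rep(off, 12)),
    Scn1a = rep(on, 14)
  )
  colnames(vals) <- sprintf("c%02d", 1:14)
  m <- expr_matrix(vals, "mas5_linear")
  res <- panel_query(m, c("Scn1a", "Scn5a", "Kcnq1", "Kcng4"))
  expect_identical(res$report$gene, c("Scn1a", "Scn5a", "Kcng4")) # panel order
  expect_equal(
    res$report$n_cells_detected[res$report$gene == "Scn5a"], 1
  )
  expect_identical(res$unmapped, "Kcnq1")
  expect_equal(dim(res$calls), c(3L, 14L))
  expect_true(all(res$report$category == "panel"))

  expect_error(panel_query(m, c("Nope1", "Nope2")), "no panel gene")
  expect_error(panel_query(m, "Scn5a", cells = character(0)), "nonempty")
})
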