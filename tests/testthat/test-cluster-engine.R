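test_that("correlation distance matches hand-computed Pearson values", {
  x <- rbind(
    c(1, 2, 3, 4),
    2 * c(1, 2, 3, 4) + 3, # affine in cell 1 -> r = 1
    c(1, 2, 3, 10)
  )
  m <- log2_matrix(t(x))
  colnames(m) <- c("cellA", "cellB", "cellC")
  d <- correlation_distance(m)
  expect_equal(d["cellA", "cellB"], 0)
  expect_equal(d["cellA", "cellC"], 1 - 14 / sqrt(250)) # hand arithmetic
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  m2 <- log2_matrix(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(correlation_distance(m2)["a", "b"], 2) # r = -1
})

test_that("a zero-variance cell is a named hard error", {
  m <- log2_matrix(cbind(ok = c(1, 2, 3), flatcell = c(5, 5, 5)))
  expect_error(correlation_distance(m), "flatcell")
})

test_that("two cells merge once at their distance", {
  d <- matrix(c(0, 0.37, 0.37, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  dend <- average_linkage(d)
  expect_equal(nrow(dend$merge), 1L)
  expect_equal(dend$height, 0.37)
  expect_identical(sort(dend$merges$member_a), "a")
  expect_error(average_linkage(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("average linkage equals the brute-force agglomeration oracle", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    d <- random_distance_matrix(n)
    dend <- average_linkage(d)
    oracle <- brute_force_upgma(d)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-9)
    got <- dendrogram_partitions(dend)
    for (s in seq_along(got)) {
      expect_identical(canon(got[[s]]), canon(oracle$partitions[[s]]))
    }
  }
})

test_that("merge heights never invert", {
  set.seed(55)
  for (rep in 1:40) {
    d <- random_distance_matrix(sample(3:12, 1))
    expect_true(all(diff(average_linkage(d)$height) >= -1e-12))
  }
})

test_that("heights agree with hclust average linkage on random input", {
  set.seed(77)
  for (rep in 1:10) {
    d <- random_distance_matrix(sample(4:10, 1))
    dend <- average_linkage(d)
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(dend$height, ref$height, tolerance = 1e-12)
    # the k-cut partitions match too (labels may differ)
    for (k in c(2, 3)) {
      expect_equal(
        adjusted_rand_index(cut_tree(dend, k), cutree(ref, k)[dend$labels]),
        1
      )
    }
  }
})

test_that("exact ties are broken by the lexicographically least member id", {
  # four equidistant cells: the first merge must pick the (a, b) pair
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  dend <- average_linkage(d)
  expect_identical(unlist(dend$merges[1, c("member_a", "member_b")],
    use.names = FALSE
  ), c("a", "b"))
  expect_identical(dend$merges$member_a[2], "a")
})

test_that("tree cutting spans singletons to one cluster and refines", {
  set.seed(31)
  d <- random_distance_matrix(9)
  dend <- average_linkage(d)
  expect_equal(max(cut_tree(dend, 1)), 1L)
  all_single <- cut_tree(dend, 9)
  expect_equal(sort(unique(as.integer(all_single))), 1:9)
  expect_error(cut_tree(dend, 0), "k must lie")
  expect_error(cut_tree(dend, 10), "k must lie")

  # refinement: every (k+1)-cluster sits inside one k-cluster
  for (k in 1:8) {
    a <- cut_tree(dend, k)
    b <- cut_tree(dend, k + 1)
    tab <- table(unclass(b), unclass(a)[names(b)])
    expect_true(all(rowSums(tab > 0) == 1L))
  }
})

test_that("cluster labels are ordered by decreasing size", {
  d <- shared_default_sim()
  sd_tab <- per_group_sd(d$matrix, d$annotations)
  keep <- dual_sd_filter(sd_tab, 2.5)$retained_probe_ids
  dend <- average_linkage(correlation_distance(d$matrix, keep))
  cl <- cut_tree(dend, 4)
  sizes <- as.integer(table(unclass(cl)))
  expect_identical(sizes, sort(sizes, decreasing = TRUE))
  expect_identical(sizes, c(9L, 7L, 4L, 1L))
  expect_equal(adjusted_rand_index(cl, d$truth$cell_type), 1)
})

test_that("newick export round-trips through ape with the same leaves", {
  d <- random_distance_matrix(6)
  dend <- average_linkage(d)
  nwk <- export_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, dend$labels)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(dend, path)
  expect_setequal(ape::read.tree(path)$tip.label, dend$labels)
})

test_that("cluster-enriched genes recover planted markers exactly when clean", {
  d <- generate_dataset(clean_sim_config(seed = 8))
  role <- d$truth$probe_role
  # cluster on the planted structure directly; the dual filter has its own tests
  keep <- names(role)[role != "noise"]
  dend <- average_linkage(correlation_distance(d$matrix, keep))
  cl <- cut_tree(dend, 3)
  expect_equal(adjusted_rand_index(cl, d$truth$cell_type), 1)
  role <- d$truth$probe_role
  for (t in c("target_1", "target_2", "comparison_1")) {
    lab <- unique(cl[names(cl) %in% names(d$truth$cell_type)[
      d$truth$cell_type == t
    ]])
    hits <- cluster_enriched_genes(d$matrix, cl, lab, probe_map = d$probe_map)
    planted <- sort(d$probe_map$gene_symbol[match(
      names(role)[role == paste0("marker_of_", t)], d$probe_map$probe_id
    )])
    expect_true(all(planted %in% hits$gene))
    expect_equal(hits$score[hits$gene %in% planted], rep(1, length(planted)))
    noise_genes <- d$probe_map$gene_symbol[match(
      names(role)[role == "noise"], d$probe_map$probe_id
    )]
    expect_length(intersect(hits$gene, noise_genes), 0)
  }
})

test_that("enrichment screen honours vacuous and degenerate thresholds", {
  d <- generate_dataset(clean_sim_config(seed = 12))
  cl <- setNames(
    ifelse(d$annotations$group == "target", 1L, 2L),
    d$annotations$cell_id
  )
  everything <- cluster_enriched_genes(d$matrix, cl, 1L,
    min_in_prev = 0, max_out_prev = 1, probe_map = d$probe_map
  )
  expect_equal(nrow(everything), length(unique(d$probe_map$gene_symbol)))

  # a ubiquitously detected gene scores 0 and fails the defaults
  bg <- names(d$truth$probe_role)[d$truth$probe_role == "background_informative"][1]
  row <- everything[everything$probe_id == bg, ]
  expect_equal(row$score, 0)
  hits <- cluster_enriched_genes(d$matrix, cl, 1L, probe_map = d$probe_map)
  expect_false(bg %in% hits$probe_id)

  expect_error(
    cluster_enriched_genes(d$matrix, cl, 99L),
    "empty"
  )
})
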