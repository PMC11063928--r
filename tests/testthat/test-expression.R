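test_that("QC removes by each rule with the stated strict boundaries", {
  cfg <- default_config()
  base <- matrix(3L, nrow = 600, ncol = 7,
                 dimnames = list(c("MT-1", sprintf("G%03d", 1:599)),
                                 paste0("c", 1:7)))
  # c1 normal; c2 high mito (0.12); c3 boundary mito (0.10);
  # c4 low umi (1199); c5 boundary umi (1200, 600 genes);
  # c6 low genes (499); c7 doublet
  m <- base
  m[, 2] <- 0L
  m[2:600, 2] <- 2L # 599 genes, 1198 non-mito
  m[1, 2] <- round(1198 * 0.12 / 0.88) # mito fraction ~0.1201 > 0.10
  m[, 3] <- 0L
  m[2:600, 3] <- 2L
  m[1, 3] <- round(1198 * 0.10 / 0.90) # 133 -> 133/1331 = 0.0999 <= 0.10
  m[, 4] <- 0L
  m[2:600, 4] <- 2L
  m[2, 4] <- 1L # total 1197 + 0 mito... 599 genes, umi 1197 < 1200
  m[, 5] <- 2L # 600 genes, 1200 umi exactly, mito 2/1200
  m[, 6] <- 0L
  m[2:499, 6] <- 3L # 498 genes < 500, umi 1494 >= 1200
  em <- expression_matrix(m, cell_meta = tibble::tibble(
    cell_id = paste0("c", 1:7),
    doublet_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    n_heavy_chains = 1L, n_light_chains = 1L
  ))
  res <- qc_filter_cells(em, cfg)
  kept <- res$matrix$cells$cell_id
  expect_setequal(kept, c("c1", "c3", "c5"))
  rep <- res$report
  expect_equal(rep$n_removed[rep$rule == "high_mito_fraction"], 1L)
  expect_equal(rep$n_removed[rep$rule == "low_umi_or_genes"], 2L)
  expect_equal(rep$n_removed[rep$rule == "doublet"], 1L)
  expect_equal(rep$n_cells[rep$rule == "retained"], 3L)
})

test_that("QC on an all-passing matrix is the identity with an empty report", {
  m <- expression_matrix(
    matrix(3L, 600, 3, dimnames = list(sprintf("G%03d", 1:600), paste0("c", 1:3))),
    cell_meta = tibble::tibble(cell_id = paste0("c", 1:3), doublet_flag = FALSE,
                               n_heavy_chains = 1L, n_light_chains = 1L)
  )
  res <- qc_filter_cells(m, default_config())
  expect_equal(ncol(res$matrix$counts), 3)
  expect_equal(sum(res$report$n_removed, na.rm = TRUE), 0)
  expect_error(qc_filter_cells(list(cells = tibble::tibble(cell_id = "c")),
                               default_config()),
               "mito_fraction")
})

test_that("gene prevalence filter uses a strict 'fewer than' boundary", {
  counts <- matrix(0L, 3, 12,
                   dimnames = list(c("in9", "in10", "dense"), paste0("c", 1:12)))
  counts["in9", 1:9] <- 1L
  counts["in10", 1:10] <- 1L
  counts["dense", ] <- 2L
  m <- expression_matrix(counts)
  out <- filter_genes(m, default_config())
  expect_setequal(out$genes$gene, c("in10", "dense"))
  # an all-zero gene is always removed
  counts2 <- rbind(counts, zero = 0L)
  expect_false("zero" %in% filter_genes(expression_matrix(counts2),
                                        default_config())$genes$gene)
})

test_that("normalization scales to the median library and log-transforms", {
  counts <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  m <- expression_matrix(counts)
  x <- normalize_log(m)
  # totals 6 and 12, median 9: by-hand values
  expect_equal(x[, "a"], log1p(c(1, 2, 3) * 9 / 6), ignore_attr = TRUE)
  expect_equal(x[, "b"], log1p(c(2, 4, 6) * 9 / 12), ignore_attr = TRUE)
  # proportional cells become identical
  expect_equal(unname(x[, "a"]), unname(x[, "b"]))
  # zero-total cell is a contract violation
  counts[, 2] <- 0
  expect_error(normalize_log(expression_matrix(counts)), "zero-total")
})

test_that("HVG selection ranks a dominant-dispersion gene first, deterministically", {
  set.seed(1)
  x <- matrix(rnorm(100 * 50, 5, 0.1), 100, 50,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:50)))
  x["g042", ] <- rnorm(50, 5, 3) # 30x the sd of everything else
  expect_equal(select_hvg(x, 1), "g042")
  expect_setequal(select_hvg(x, 100), rownames(x))
  expect_error(select_hvg(x, 101), "101")
  expect_identical(select_hvg(x, 10), select_hvg(x, 10))
})

test_that("HVG selection recovers most planted module genes", {
  sim <- simulate_expression(expression_config(seed = 4))
  m <- filter_genes(qc_filter_cells(sim$matrix, default_config())$matrix,
                    default_config())
  x <- normalize_log(m)
  hvg <- select_hvg(x, 200)
  truth <- sim$truth$modules
  module_genes <- truth$gene[!is.na(truth$true_module)]
  module_genes <- intersect(module_genes, rownames(x))
  expect_gte(mean(module_genes %in% hvg), 0.9)
})

test_that("adjacency is |cor|^power with zero diagonal", {
  x <- rbind(a = 1:10, b = 2 * (1:10) + 5, c = -(1:10))
  adj <- build_adjacency(x, power = 6)
  expect_equal(adj["a", "b"], 1) # perfectly correlated
  expect_equal(adj["a", "c"], 1) # anti-correlated, unsigned
  expect_equal(diag(adj), c(a = 0, b = 0, c = 0))
  # zero-variance gene: adjacency 0 with a warning
  x2 <- rbind(x, flat = rep(1, 10))
  expect_warning(adj2 <- build_adjacency(x2, 6), "zero-variance")
  expect_equal(unname(adj2["flat", "a"]), 0)
})

test_that("independent genes have near-zero adjacency at power 6", {
  set.seed(7)
  x <- matrix(rnorm(50 * 1000), 50, 1000,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  adj <- build_adjacency(x, 6)
  expect_lt(mean(adj[upper.tri(adj)]), 0.01)
})

test_that("TOM matches the hand-computed example and its edge cases", {
  a <- matrix(0.5, 3, 3)
  diag(a) <- 0
  tom <- compute_tom(a)
  expect_equal(tom[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5)) # = 0.5
  expect_equal(diag(tom), rep(1, 3))
  # all-zero adjacency gives the identity
  z <- matrix(0, 4, 4)
  expect_equal(compute_tom(z), diag(4))
  # symmetry and range on a random valid adjacency
  set.seed(2)
  r <- matrix(runif(25), 5, 5)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  tr <- compute_tom(r)
  expect_equal(tr, t(tr))
  expect_true(all(tr >= 0 & tr <= 1 + 1e-12))
})

test_that("module cutting partitions genes and recovers planted blocks", {
  set.seed(3)
  base1 <- rnorm(40)
  base2 <- rnorm(40)
  x <- rbind(
    matrix(rep(base1, each = 4), 4, byrow = FALSE) * matrix(runif(4, 1, 3), 4, 40),
    matrix(rep(base2, each = 5), 5, byrow = FALSE) * matrix(runif(5, 1, 3), 5, 40)
  )
  rownames(x) <- c(paste0("blockA_", 1:4), paste0("blockB_", 1:5))
  tom <- compute_tom(build_adjacency(x, 6))
  mods <- cut_modules(tom, k = 2)
  expect_setequal(mods$gene, rownames(x))
  got <- split(mods$gene, mods$module_id)
  truthA <- paste0("blockA_", 1:4)
  truthB <- paste0("blockB_", 1:5)
  j <- max(jaccard(got[[1]], truthA), jaccard(got[[2]], truthA))
  expect_equal(j, 1)
  expect_equal(sort(unname(lengths(got))), c(4L, 5L))
  # k = gene count means singletons
  singletons <- cut_modules(tom, k = nrow(x))
  expect_equal(dplyr::n_distinct(singletons$module_id), nrow(x))
  expect_error(cut_modules(tom, k = nrow(x) + 1), "cannot cut")
})

test_that("module scores follow the l2-normalization closed forms", {
  # single-gene module expressed in exactly one cell: that cell scores 1
  x <- matrix(0, 1, 4, dimnames = list("g1", paste0("c", 1:4)))
  x[1, 2] <- 7
  s <- score_modules(x, tibble::tibble(gene = "g1", module_id = 1L))
  expect_equal(unname(s[1, ]), c(0, 1, 0, 0))
  # identical genes: every cell scores 1/sqrt(n_cells)
  n <- 16
  x2 <- matrix(5, 3, n, dimnames = list(paste0("g", 1:3), paste0("c", 1:n)))
  s2 <- score_modules(x2, tibble::tibble(gene = paste0("g", 1:3), module_id = 1L))
  expect_equal(unname(s2[1, ]), rep(1 / sqrt(n), n))
  # all-zero gene contributes zero, scores stay in [0, 1]
  x3 <- rbind(x2, g4 = 0)
  s3 <- score_modules(x3, tibble::tibble(gene = paste0("g", 1:4), module_id = 1L))
  expect_true(all(s3 >= 0 & s3 <= 1))
  expect_equal(unname(s3[1, ]), rep(3 / 4 / sqrt(n), n))
})

test_that("percent-deviance statistic matches the group-means oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 60
    labels <- sample(c("u", "v", "w"), n, replace = TRUE)
    scores <- matrix(runif(2 * n), 2, n,
                     dimnames = list(c("m1", "m2"), NULL))
    res <- tidy(test_module_association(scores, labels))
    for (i in seq_len(nrow(res))) {
      y <- scores[res$module_id[i], ]
      ind <- as.integer(labels == res$cluster_id[i])
      expect_lt(abs(res$percent_deviance_difference[i] -
                      oracle_percent_deviance(y, ind)), 1e-10)
    }
  }
})

test_that("percent-deviance statistic hits its extremes", {
  labels <- rep(c("a", "b"), each = 10)
  # deterministic 0/1 function of membership: statistic 100
  perfect <- matrix(as.numeric(labels == "a"), 1, 20,
                    dimnames = list("m1", NULL))
  res <- tidy(test_module_association(perfect, labels))
  expect_equal(res$percent_deviance_difference, c(100, 100))
  # constant scores: 0 everywhere, with a warning
  const <- matrix(0.5, 1, 20, dimnames = list("m1", NULL))
  expect_warning(res0 <- test_module_association(const, labels), "constant")
  expect_equal(tidy(res0)$percent_deviance_difference, c(0, 0))
  expect_error(test_module_association(perfect, rep("a", 20)), "2 clusters")
  # bounded in [0, 100] and glance summarises the maximum
  g <- glance(test_module_association(perfect, labels))
  expect_equal(g$max_percent_deviance, 100)
})

test_that("gene-set scores match hand arithmetic and sign expectations", {
  x <- matrix(c(
    2, 2, 0, 0,
    4, 4, 0, 0,
    1, 1, 1, 1
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("s1", "s2", "bg"), paste0("c", 1:4)))
  labels <- c("A", "A", "B", "B")
  res <- gene_set_score(x, list(set = c("s1", "s2")), labels)
  a <- res[res$cluster_id == "A", ]
  b <- res[res$cluster_id == "B", ]
  expect_equal(a$mean_expression, 3) # mean of 2,2,4,4
  expect_equal(b$mean_expression, 0)
  expect_gt(a$log2_fold_change, 0)
  expect_lt(b$log2_fold_change, 0)
  # identical expression everywhere: log2FC exactly 0
  flat <- gene_set_score(x, list(set = "bg"), labels)
  expect_equal(flat$log2_fold_change, c(0, 0))
  expect_error(gene_set_score(x, list(nope = "missing_gene"), labels), "nope")
})
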