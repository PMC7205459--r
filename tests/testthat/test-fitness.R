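# The fitness statistic, site filtering, proportion aggregation and
# replicate pooling.

test_that("fitness score hits its analytic anchor points", {
  # equal proportions are the neutral point, ln(d)/ln(d) = 1
  expect_equal(fitness_score(0.001, 0.001, 10), 1)
  # a lineage depleted by the full expansion factor scores exactly 0
  expect_identical(fitness_score(0.001, 0.001 / 1024, 10), 0)
  # frozen from an independent high-precision evaluation of the formula
  expect_equal(fitness_score(0.001, 0.002, 10), 1.1001590, tolerance = 1e-6)
})

test_that("neutral identity holds to 1e-12 across the open domain", {
  for (g in c(1, 5, 10, 14)) {
    n <- c(1e-8, 1e-5, 0.001, 0.01, 0.1, 0.5, 0.9, 0.999)
    expect_true(all(abs(fitness_score(n, n, g) - 1) < 1e-12))
  }
})

test_that("fitness is strictly increasing in the t2 proportion", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      n1 <- stats::runif(1, 1e-6, 0.5)
      n2 <- sort(stats::runif(50, 1e-8, 0.9))
      w <- fitness_score(n1, n2, 10)
      expect_true(all(diff(w) > 0))
    }
  })
})

test_that("rare-gene limit of the score recovers the true fitness", {
  # a lineage expanding as d^w inside a reference expanding as d
  d <- 2^10
  n1 <- 1e-5
  for (w in c(0.2, 0.5, 0.8, 1.0, 1.2)) {
    n2 <- n1 * d^w / (n1 * d^w + (1 - n1) * d)
    expect_equal(fitness_score(n1, n2, 10), w, tolerance = 1e-3)
  }
})

test_that("fitness score rejects out-of-domain proportions", {
  expect_error(fitness_score(0, 0.5, 10), "n_t1")
  expect_error(fitness_score(0.5, 0, 10), "n_t2")
  expect_error(fitness_score(0.5, 0.5, 0), "generations")
})

test_that("site filter keeps exactly the sites at or above the threshold", {
  tab <- tiny_sites(c(10, 20, 30), c(1, 2, 7))
  expect_equal(filter_sites(tab)$position, c(20L, 30L))
  expect_equal(nrow(filter_sites(tiny_sites(integer(), integer()))), 0L)
  all_pass <- tiny_sites(c(5, 6), c(2, 9))
  expect_identical(filter_sites(all_pass), all_pass)
  expect_error(filter_sites(tab, min_reads = 0), "min_reads")
})

test_that("replicate pooling sums read evidence site-wise", {
  a <- tiny_sites(10, 3)
  b <- tiny_sites(10, 5)
  expect_equal(pool_replicates(list(a, b))$reads, 8L)
  # identical replicates triple counts, leaving proportions unchanged
  tab <- tiny_sites(c(10, 50), c(4, 6))
  pooled <- pool_replicates(list(tab, tab, tab))
  expect_equal(pooled$reads, c(12L, 18L))
  expect_equal(pooled$reads / sum(pooled$reads), tab$reads / sum(tab$reads))
  # disjoint positions form a union with original counts
  u <- pool_replicates(list(tiny_sites(1, 2), tiny_sites(9, 7)))
  expect_equal(u$position, c(1L, 9L))
  expect_equal(u$reads, c(2L, 7L))
  expect_error(pool_replicates(list()), "non-empty")
})

test_that("gene proportions match hand counts and include intergenic reads", {
  ann <- tiny_annotation()
  tab <- tiny_sites(c(20, 150), c(30, 70))
  p <- gene_read_proportions(tab, ann)
  expect_equal(p$n[p$gene_id == "geneA"], 0.3)
  expect_equal(p$n[p$gene_id == "geneB"], 0.7)
  # intergenic reads enlarge the denominator
  tab2 <- dplyr::bind_rows(tab, tiny_sites(250, 100))
  p2 <- gene_read_proportions(tab2, ann)
  expect_equal(p2$n[p2$gene_id == "geneA"], 30 / 200)
  # genic denominator mode ignores them
  p3 <- gene_read_proportions(tab2, ann, denominator = "genic")
  expect_equal(p3$n[p3$gene_id == "geneA"], 0.3)
  # a gene without filtered reads
  expect_equal(p$n[p$gene_id == "geneC"], 0)
  expect_equal(p$site_count[p$gene_id == "geneC"], 0L)
  expect_error(gene_read_proportions(tiny_sites(integer(), integer()), ann),
               "denominator")
})

test_that("proportion aggregation agrees with a brute-force sum", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n_genes <- sample(2:6, 1)
      starts <- sort(sample.int(900, n_genes)) * 1L
      ann <- tibble::tibble(
        gene_id = sprintf("g%d", seq_len(n_genes)),
        contig = "tig1",
        start = starts,
        end = pmin(starts + sample(10:80, n_genes, replace = TRUE), 1000L),
        strand = "+", type = "gene", essential = FALSE, excluded = FALSE
      )
      ann <- ann[ann$end < c(ann$start[-1], 1001L), ]  # keep non-overlapping
      tab <- random_sites(sample(5:40, 1))
      p <- gene_read_proportions(tab, ann)
      for (g in seq_len(nrow(ann))) {
        expect_equal(
          p$n[p$gene_id == ann$gene_id[g]],
          brute_gene_reads(tab, ann[g, ]) / sum(tab$reads)
        )
      }
    }
  })
})

test_that("excluded feature classes get no row but feed the denominator", {
  ann <- tiny_annotation()
  ann$excluded[ann$gene_id == "geneB"] <- TRUE
  tab <- tiny_sites(c(20, 150), c(30, 70))
  p <- gene_read_proportions(tab, ann)
  expect_false("geneB" %in% p$gene_id)
  expect_equal(p$n[p$gene_id == "geneA"], 0.3)
})

test_that("condition fitness flags pseudocounted and no_data genes", {
  ann <- tiny_annotation()
  t1 <- gene_read_proportions(tiny_sites(c(20, 150, 250), c(50, 50, 20)), ann)
  # geneA vanishes at t2: pseudocounted, conservative W < 1
  t2 <- gene_read_proportions(tiny_sites(c(150, 250), c(100, 30)), ann)
  sc <- compute_condition_fitness(t1, t2, 10, "c")
  a <- sc[sc$gene_id == "geneA", ]
  expect_equal(a$flag, "pseudocounted")
  expect_lt(a$fitness, 1)
  # absent from the input library: no_data
  t1b <- gene_read_proportions(tiny_sites(c(150, 250), c(100, 30)), ann)
  t2b <- gene_read_proportions(tiny_sites(c(20, 150, 250), c(50, 50, 20)), ann)
  scb <- compute_condition_fitness(t1b, t2b, 10, "c")
  expect_equal(scb$flag[scb$gene_id == "geneA"], "no_data")
  expect_true(is.na(scb$fitness[scb$gene_id == "geneA"]))
  # essential genes are omitted
  expect_false("geneC" %in% sc$gene_id)
})

test_that("mismatched gene universes are a configuration error", {
  ann <- tiny_annotation()
  t1 <- gene_read_proportions(tiny_sites(20, 10), ann)
  ann2 <- ann
  ann2$gene_id[1] <- "other"
  t2 <- gene_read_proportions(tiny_sites(20, 10), ann2)
  expect_error(compute_condition_fitness(t1, t2, 10), "universe")
})

test_that("designed fitness is recovered where the score can resolve it", {
  # scaled-down recovery run; the w = 0 class sits on the pseudocount
  # floor (its expected post-selection read count is below one read), so
  # for that class only strong depletion, not the exact value, is checked
  ann <- simulate_genome(400, essential_fraction = 0, seed = 51)
  lib <- simulate_library(ann, 4000, seed = 52)
  truth <- design_fitness_classes(ann, classes = c(0, 0.5, 0.9, 1.1),
                                  frac_per_class = 0.1, seed = 53)
  neutral <- stats::setNames(rep(1, 400), ann$gene_id)
  t1 <- pool_replicates(lapply(1:3, function(r) {
    simulate_selection(lib, ann, neutral, 1, 3e5, seed = 60 + r)
  }))
  t2 <- simulate_selection(lib, ann, truth, 10, 3e5, seed = 70)
  sc <- compute_condition_fitness(
    gene_read_proportions(filter_sites(t1), ann),
    gene_read_proportions(filter_sites(t2), ann), 10, "sim"
  )
  t1p <- gene_read_proportions(filter_sites(t1), ann)
  res <- sc |>
    dplyr::inner_join(truth, by = "gene_id") |>
    dplyr::inner_join(dplyr::select(t1p, "gene_id", "site_count"),
                      by = "gene_id") |>
    dplyr::filter(.data$site_count >= 5)
  cls <- res |>
    dplyr::summarise(mean_w = mean(fitness), .by = "w") |>
    dplyr::arrange(w)
  for (w in c(0.5, 0.9, 1.0, 1.1))
    expect_lt(abs(cls$mean_w[cls$w == w] - w), 0.05)
  expect_lt(cls$mean_w[cls$w == 0], 0.3)
  expect_gt(cls$mean_w[cls$w == 0], 0)
})
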