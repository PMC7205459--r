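# The synthetic library generator: genome layout, site placement,
# selection dynamics.

test_that("simulated genomes are deterministic, non-overlapping and sized", {
  a1 <- simulate_genome(100, seed = 1)
  a2 <- simulate_genome(100, seed = 1)
  expect_identical(a1, a2)
  expect_false(identical(a1, simulate_genome(100, seed = 2)))
  # genes never overlap and stay inside the genome
  expect_true(all(a1$start[-1] > a1$end[-nrow(a1)]))
  expect_true(all(a1$start >= 1))
  expect_lte(max(a1$end), attr(a1, "genome_length"))
  expect_equal(sum(a1$essential), ceiling(0.15 * 100))
})

test_that("a single gene with no intergenic space spans the contig", {
  a <- simulate_genome(1, mean_gene_length = 100, intergenic_fraction = 0,
                       essential_fraction = 0, seed = 0)
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 1L)
  expect_equal(a$end, attr(a, "genome_length"))
})

test_that("genomes that cannot host the genes raise a sizing error", {
  expect_error(simulate_genome(50, mean_gene_length = 1000,
                               genome_length = 1000, seed = 1),
               "genome")
})

test_that("libraries place distinct sites outside essential genes", {
  ann <- simulate_genome(200, essential_fraction = 0.2, seed = 5)
  lib <- simulate_library(ann, 3000, seed = 6)
  expect_equal(nrow(lib), 3000L)
  expect_false(any(duplicated(lib$position)))
  expect_true(all(lib$reads >= 1))
  ess <- ann[ann$essential, ]
  in_ess <- vapply(lib$position, function(p) {
    any(p >= ess$start & p <= ess$end)
  }, logical(1))
  expect_false(any(in_ess))
  # determinism under a fixed seed; different seeds move the sites
  expect_identical(lib, simulate_library(ann, 3000, seed = 6))
  expect_false(identical(lib$position,
                         simulate_library(ann, 3000, seed = 7)$position))
})

test_that("empty and oversubscribed libraries are handled", {
  ann <- simulate_genome(10, seed = 2)
  expect_equal(nrow(simulate_library(ann, 0)), 0L)
  expect_error(
    simulate_library(ann, attr(ann, "genome_length") + 1L, seed = 1),
    "distinct sites"
  )
})

test_that("selection conserves sequencing depth exactly", {
  ann <- simulate_genome(50, essential_fraction = 0, seed = 8)
  lib <- simulate_library(ann, 500, seed = 9)
  w <- design_fitness_classes(ann, seed = 10)
  for (depth in c(1e3, 1e5)) {
    sel <- simulate_selection(lib, ann, w, 10, depth, seed = 11)
    expect_equal(sum(sel$reads), depth)
  }
})

test_that("a gene with sites but no fitness value is a configuration error", {
  ann <- simulate_genome(20, essential_fraction = 0, seed = 3)
  lib <- simulate_library(ann, 200, seed = 4)
  w <- stats::setNames(rep(1, 19), ann$gene_id[-1])
  expect_error(simulate_selection(lib, ann, w, 10, 1000, seed = 1),
               ann$gene_id[1])
})

test_that("neutral selection preserves composition in expectation", {
  ann <- simulate_genome(50, essential_fraction = 0, seed = 21)
  lib <- simulate_library(ann, 400, seed = 22)
  neutral <- stats::setNames(rep(1, 50), ann$gene_id)
  depth <- 2e4
  input_n <- gene_read_proportions(lib, ann)$n
  draws <- vapply(1:200, function(r) {
    sel <- simulate_selection(lib, ann, neutral, 10, depth, seed = 1000 + r)
    gene_read_proportions(sel, ann)$n
  }, numeric(50))
  mean_n <- rowMeans(draws)
  se <- sqrt(input_n * (1 - input_n) / depth / 200)
  expect_true(all(abs(mean_n - input_n) <= 3 * se + 1e-12))
})

test_that("generations = 0 is pure resampling in expectation", {
  ann <- simulate_genome(10, essential_fraction = 0, seed = 31)
  lib <- simulate_library(ann, 100, seed = 32)
  w <- stats::setNames(stats::runif(10, 0, 2), ann$gene_id)
  e <- expected_proportions(lib, ann, w, generations = 0)
  expect_equal(e$expected, lib$reads / sum(lib$reads))
})

test_that("doubling generations squares each lineage's relative expansion", {
  ann <- simulate_genome(10, essential_fraction = 0, seed = 41)
  lib <- simulate_library(ann, 100, seed = 42)
  w <- design_fitness_classes(ann, classes = c(0.5, 2), frac_per_class = 0.3,
                              seed = 43)
  e1 <- expected_proportions(lib, ann, w, generations = 5)
  e2 <- expected_proportions(lib, ann, w, generations = 10)
  # expansion factor of site i relative to site 1
  rel1 <- (e1$expected / e1$expected[1]) / (lib$reads / lib$reads[1])
  rel2 <- (e2$expected / e2$expected[1]) / (lib$reads / lib$reads[1])
  expect_equal(rel2, rel1^2)
})

test_that("a rare fully-arrested gene drops by the expansion factor", {
  # one gene holding 0.1% of the library with w = 0 over 10 generations:
  # expected proportion ~ 0.001/1024 (up to the tiny renormalisation)
  ann <- tiny_annotation()
  ann$essential <- FALSE
  lib <- tiny_sites(c(20, 150), c(1, 999))
  e <- expected_proportions(lib, ann,
                            c(geneA = 0, geneB = 1, geneC = 1),
                            generations = 10)
  expected_a <- 0.001 * 1 / (0.001 * 1 + 0.999 * 1024)
  expect_equal(e$expected[1], expected_a, tolerance = 1e-12)
  expect_equal(e$expected[1], 0.001 / 1024, tolerance = 1e-2)
})

test_that("selection output is byte-identical under a fixed seed", {
  ann <- simulate_genome(20, essential_fraction = 0, seed = 61)
  lib <- simulate_library(ann, 150, seed = 62)
  w <- stats::setNames(rep(1, 20), ann$gene_id)
  s1 <- simulate_selection(lib, ann, w, 10, 5000, seed = 63)
  s2 <- simulate_selection(lib, ann, w, 10, 5000, seed = 63)
  expect_identical(s1, s2)
})

test_that("bottlenecked selection still conserves depth", {
  ann <- simulate_genome(20, essential_fraction = 0, seed = 71)
  lib <- simulate_library(ann, 150, seed = 72)
  w <- stats::setNames(rep(1, 20), ann$gene_id)
  sel <- simulate_selection(lib, ann, w, 10, 5000, seed = 73,
                            bottleneck = 500)
  expect_equal(sum(sel$reads), 5000)
  # a tight bottleneck loses lineages
  expect_lt(nrow(sel), nrow(lib))
})

test_that("simulated experiments round-trip through disk for the pipeline", {
  conds <- list(ctrl = 1, drug = 0.6)
  exp <- simulate_experiment(n_genes = 40, n_sites = 400, conditions = conds,
                             depth_t1 = 2e4, depth_t2 = 2e4, seed = 81)
  expect_equal(nrow(exp$manifest), 5L)  # 3 t1 replicates + 2 conditions
  expect_setequal(unique(exp$truth$condition), c("ctrl", "drug"))
  d <- withr::local_tempdir()
  write_experiment(exp, d)
  man <- read_manifest(file.path(d, "manifest.tsv"))
  expect_true(all(file.exists(man$file)))
  ann <- read_gff(file.path(d, "annotation.gff3"))
  expect_equal(nrow(ann), 40L)
  tab <- read_insertions(man$file[1])
  expect_equal(tab[, 1:3], exp$samples[[man$sample_id[1]]],
               ignore_attr = TRUE)
})

test_that("fingerprint groups carry their designed structure", {
  fit <- simulate_fingerprint_groups(seed = 91)
  groups <- attr(fit, "groups")
  expect_equal(nrow(groups), 3 * 5 + 10)
  m <- as.matrix(fit)
  expect_equal(dim(m), c(25L, 8L))
  # within-group profiles correlate strongly by construction
  g1 <- groups$gene_id[!is.na(groups$group) & groups$group == "group1"]
  cc <- stats::cor(t(m[g1, ]))
  expect_gt(min(cc[upper.tri(cc)]), 0.8)
})
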