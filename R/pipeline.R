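# End-to-end driver: annotation + manifest + insertion tables in,
# fitness matrix / phenotype calls / clustering out, with every
# parameter, count and seed logged. All stages are deterministic, so a
# rerun with the same config reproduces the outputs byte for byte.

#' Pipeline configuration
#'
#' @param annotation Path to the GFF3 annotation.
#' @param manifest Path to the sample manifest (see [read_manifest()]).
#' @param out_dir Output directory.
#' @param min_reads Minimum reads per insertion site (default 2).
#' @param generations Selective window in doublings; `NULL` (default)
#'   derives it per condition from the manifest as
#'   `generations(t2) - max(generations(t1))`.
#' @param denominator `"all"` or `"genic"` read-proportion denominator.
#' @param metric,linkage Clustering parameters (see [cluster_profiles()]).
#' @param strong_low,strong_high,moderate_low,moderate_high Phenotype
#'   thresholds; must nest around 1.
#' @param write_heatmap Also render the clustered heatmap to
#'   `heatmap.pdf` (default TRUE).
#' @param seed Integer seed, recorded in the log (the analysis itself is
#'   deterministic).
#' @return A `tn_config` list.
#' @export
tn_config <- function(annotation, manifest, out_dir,
                      min_reads = 2, generations = NULL,
                      denominator = "all",
                      metric = "euclidean", linkage = "complete",
                      strong_low = 0.75, strong_high = 1.25,
                      moderate_low = 0.9, moderate_high = 1.1,
                      write_heatmap = TRUE, seed = 1L) {
  structure(
    list(
      annotation = annotation, manifest = manifest, out_dir = out_dir,
      min_reads = min_reads, generations = generations,
      denominator = denominator, metric = metric, linkage = linkage,
      strong_low = strong_low, strong_high = strong_high,
      moderate_low = moderate_low, moderate_high = moderate_high,
      write_heatmap = write_heatmap, seed = as.integer(seed)
    ),
    class = "tn_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are the arguments of [tn_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `tn_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("annotation", "manifest", "out_dir")) {
    if (!is.null(y[[k]]) && !grepl("^(/|[A-Za-z]:)", y[[k]]))
      y[[k]] <- file.path(dirname(path), y[[k]])
  }
  do.call(tn_config, y)
}

#' Validate a pipeline configuration
#'
#' Never throws: returns a report listing every violated invariant. The
#' report is empty exactly when the configuration is valid.
#'
#' @param config A `tn_config` list.
#' @return A tibble `field`, `problem` (zero rows when valid).
#' @export
validate_config <- function(config) {
  probs <- list()
  bad <- function(field, problem) probs[[length(probs) + 1L]] <<-
    tibble(field = field, problem = problem)
  for (k in c("annotation", "manifest")) {
    p <- config[[k]]
    if (is.null(p) || !is.character(p) || length(p) != 1L) {
      bad(k, "path missing")
    } else if (!file.exists(p)) {
      bad(k, sprintf("file does not exist: %s", p))
    }
  }
  if (is.null(config$out_dir)) bad("out_dir", "path missing")
  if (is.null(config$min_reads) || config$min_reads < 1)
    bad("min_reads", "must be >= 1")
  if (!is.null(config$generations) && config$generations < 1)
    bad("generations", "must be >= 1 when given")
  if (!config$denominator %in% c("all", "genic"))
    bad("denominator", "must be 'all' or 'genic'")
  if (!config$metric %in% c("euclidean", "correlation"))
    bad("metric", "must be 'euclidean' or 'correlation'")
  if (!config$linkage %in% c("complete", "average", "ward"))
    bad("linkage", "must be 'complete', 'average' or 'ward'")
  thr <- c(config$strong_low, config$moderate_low, 1,
           config$moderate_high, config$strong_high)
  if (any(is.na(thr)) || any(diff(thr) <= 0) || thr[1] <= 0)
    bad("thresholds",
        "must satisfy 0 < strong_low < moderate_low < 1 < moderate_high < strong_high")
  if (length(probs) == 0)
    return(tibble(field = character(), problem = character()))
  dplyr::bind_rows(probs)
}

#' Run the full profiling pipeline
#'
#' Stages: read annotation and manifest; pool all t1 replicates into one
#' reference; pool t2 replicates per condition; filter sites; compute
#' read proportions and fitness scores; assemble the matrix; classify
#' phenotypes; cluster fingerprints. Writes to `config$out_dir`:
#' `fitness_matrix.tsv`, `phenotypes.tsv`, `summary.json`,
#' `leaf_order.tsv`, `tree.nwk` (when the ape package is available),
#' optionally `heatmap.pdf`, and `run.log` with per-stage counts. Every
#' table records the package version and a hash of the configuration.
#'
#' @param config A `tn_config` list (see [tn_config()], [read_config()]).
#' @return Invisibly, a list with `matrix` (`tn_fitness`), `phenotypes`,
#'   `cluster` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (nrow(v) > 0)
    abort(c("Invalid configuration:",
            stats::setNames(sprintf("%s: %s", v$field, v$problem),
                            rep("x", nrow(v)))))
  cfg_hash <- rlang::hash(unclass(config))
  log_lines <- character()
  note <- function(...) log_lines[[length(log_lines) + 1L]] <<- sprintf(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  note("tnprof %s  config_hash=%s  seed=%d",
       packageVersion("tnprof"), cfg_hash, config$seed)

  ann <- stage("annotation", read_gff(config$annotation))
  note("annotation: %d features (%d essential, %d excluded) from %s",
       nrow(ann), sum(ann$essential), sum(ann$excluded), config$annotation)
  man <- stage("manifest", read_manifest(config$manifest))
  note("manifest: %d samples, %d conditions from %s", nrow(man),
       length(unique(man$condition[man$timepoint == "t2"])), config$manifest)

  tables <- stage("read_insertions", lapply(
    stats::setNames(man$file, man$sample_id), read_insertions
  ))
  for (id in names(tables))
    note("sample %s: %d sites, %d reads", id, nrow(tables[[id]]),
         sum(tables[[id]]$reads))

  t1_ids <- man$sample_id[man$timepoint == "t1"]
  gen_t1 <- max(man$generations[man$timepoint == "t1"])
  t1_pool <- stage("pool_t1", pool_replicates(tables[t1_ids]))
  t1_filt <- filter_sites(t1_pool, config$min_reads)
  note("t1 reference: pooled %d replicates -> %d sites, %d pass the >=%d-read filter",
       length(t1_ids), nrow(t1_pool), nrow(t1_filt), config$min_reads)
  t1_prop <- stage("proportions_t1",
                   gene_read_proportions(t1_filt, ann, config$denominator))

  man_t2 <- man[man$timepoint == "t2", ]
  scores <- list()
  for (cond in unique(man_t2$condition)) {
    rows <- man_t2[man_t2$condition == cond, ]
    pooled <- stage(cond, pool_replicates(tables[rows$sample_id]))
    filt <- filter_sites(pooled, config$min_reads)
    gens <- config$generations %||% (rows$generations[1] - gen_t1)
    prop <- stage(cond, gene_read_proportions(filt, ann, config$denominator))
    sc <- stage(cond, compute_condition_fitness(t1_prop, prop,
                                                generations = gens,
                                                condition = cond))
    note("condition %s: %d sites filtered to %d; generations=%g; %d genes scored, %d pseudocounted, %d no_data",
         cond, nrow(pooled), nrow(filt), gens, sum(sc$flag != "no_data"),
         sum(sc$flag == "pseudocounted"), sum(sc$flag == "no_data"))
    scores[[cond]] <- sc
  }

  fit <- stage("build_matrix", build_matrix(scores))
  phen <- stage("classify", classify_phenotypes(
    fit,
    strong = c(config$strong_low, config$strong_high),
    moderate = c(config$moderate_low, config$moderate_high),
    annotation = ann
  ))
  cl <- stage("cluster", cluster_profiles(fit, config$metric, config$linkage))
  cnt <- glance(phen)
  note("phenotypes: %d essential / %d strong / %d moderate / %d none",
       cnt$n_essential, cnt$n_strong, cnt$n_moderate, cnt$n_none)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  meta <- sprintf("config_hash=%s version=%s", cfg_hash,
                  packageVersion("tnprof"))
  write_fitness_matrix(fit, out("fitness_matrix.tsv"), comments = meta)

  phen_tab <- dplyr::mutate(
    as_tibble(phen),
    triggering_conditions = purrr::map_chr(
      .data$triggering_conditions, paste, collapse = ","
    )
  )
  writeLines(sprintf("# tnprof phenotype calls %s", meta), out("phenotypes.tsv"))
  readr::write_tsv(phen_tab, out("phenotypes.tsv"), append = TRUE,
                   col_names = TRUE, progress = FALSE)

  writeLines(c(sprintf("# tnprof leaf order %s", meta),
               cl$leaf_order), out("leaf_order.tsv"))
  if (!is.null(cl$hclust) && requireNamespace("ape", quietly = TRUE))
    ape::write.tree(ape::as.phylo(cl$hclust), out("tree.nwk"))
  if (isTRUE(config$write_heatmap))
    plot_fitness_heatmap(fit, cl, out("heatmap.pdf"))

  jsonlite::write_json(
    list(
      version = as.character(packageVersion("tnprof")),
      config_hash = cfg_hash,
      parameters = unclass(config)[setdiff(names(unclass(config)),
                                           c("annotation", "manifest", "out_dir"))],
      counts = as.list(cnt)
    ),
    out("summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  writeLines(log_lines, out("run.log"))
  invisible(list(matrix = fit, phenotypes = phen, cluster = cl,
                 out_dir = config$out_dir))
}

#' Write a ready-to-run synthetic demo dataset
#'
#' Simulates a 500-gene genome under five conditions — one untreated
#' (all genes neutral) and four stress conditions with designed fitness
#' classes — writes it to `dir` and returns a configuration that
#' [run_pipeline()] can execute directly.
#'
#' @param dir Dataset/output directory.
#' @param n_genes,n_sites,depth Scale of the simulated screen.
#' @param seed Integer seed.
#' @return A `tn_config` whose `out_dir` is `file.path(dir, "results")`.
#' @export
simulate_demo <- function(dir, n_genes = 500, n_sites = 5000,
                          depth = 2e5, seed = 1L) {
  ann0 <- simulate_genome(n_genes, essential_fraction = 0.15, seed = seed)
  conds <- list(untreated = 1)
  for (k in seq_len(4)) {
    conds[[sprintf("stress%d", k)]] <- design_fitness_classes(
      ann0, classes = c(0, 0.5, 0.9, 1.1), frac_per_class = 0.1,
      seed = seed + 10L * k
    )
  }
  exp <- simulate_experiment(
    n_genes = n_genes, n_sites = n_sites, conditions = conds,
    essential_fraction = 0.15, depth_t1 = depth, depth_t2 = depth,
    seed = seed
  )
  write_experiment(exp, dir)
  tn_config(
    annotation = file.path(dir, "annotation.gff3"),
    manifest = file.path(dir, "manifest.tsv"),
    out_dir = file.path(dir, "results"),
    seed = seed
  )
}
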