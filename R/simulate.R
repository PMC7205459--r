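# Synthetic transposon libraries under selection: the generator behind all
# parameter-recovery tests. Growth is modelled per insertion site (one
# lineage per unique site); sequencing is a multinomial draw over expanded
# lineage masses.

#' Simulate a compact bacterial gene annotation
#'
#' Lays out `n_genes` non-overlapping genes on a single contig, separated
#' by intergenic gaps that together make up `intergenic_fraction` of the
#' genome. Gene lengths are gamma-distributed around `mean_gene_length`.
#' A fraction of genes is flagged essential; these will receive no
#' insertion sites from [simulate_library()].
#'
#' @param n_genes Number of genes (>= 1).
#' @param mean_gene_length Mean gene length in bases.
#' @param intergenic_fraction Fraction of the genome outside genes, in `[0, 1)`.
#' @param essential_fraction Fraction of genes flagged essential, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the annotation exactly.
#' @param genome_length Optional fixed genome length; an error is raised if
#'   the drawn genes do not fit. By default the genome is sized to the genes.
#' @param contig Contig name.
#' @return An annotation tibble (`gene_id`, `contig`, `start`, `end`,
#'   `strand`, `type`, `essential`, `excluded`) with attribute
#'   `genome_length`. Coordinates are 1-based inclusive.
#' @export
simulate_genome <- function(n_genes, mean_gene_length = 1000,
                            intergenic_fraction = 0.1,
                            essential_fraction = 0.15,
                            seed = 1L, genome_length = NULL,
                            contig = "tig1") {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  for (f in c(intergenic_fraction, essential_fraction))
    if (f < 0 || f >= 1) abort("Fractions must lie in [0, 1).")
  withr::with_seed(seed, {
    len <- pmax(90L, as.integer(round(rgamma(n_genes, shape = 4,
                                             rate = 4 / mean_gene_length))))
    total_genic <- sum(len)
    if (is.null(genome_length)) {
      genome_length <- as.integer(ceiling(total_genic / (1 - intergenic_fraction)))
    } else if (total_genic > genome_length) {
      abort(sprintf(
        "Genes need %d bases but the genome is only %d bases long.",
        total_genic, as.integer(genome_length)
      ))
    }
    spare <- genome_length - total_genic
    gaps <- if (spare > 0) {
      as.vector(rmultinom(1, spare, rep(1, n_genes + 1L)))
    } else {
      rep(0L, n_genes + 1L)
    }
    start <- cumsum(gaps[seq_len(n_genes)]) +
      cumsum(c(0L, len[-n_genes])) + 1L
    essential <- rep(FALSE, n_genes)
    n_ess <- ceiling(essential_fraction * n_genes)
    if (n_ess > 0) essential[sample.int(n_genes, n_ess)] <- TRUE
    ann <- tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      contig = contig,
      start = as.integer(start),
      end = as.integer(start + len - 1L),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      type = "gene",
      essential = essential,
      excluded = FALSE
    )
  })
  attr(ann, "genome_length") <- as.integer(genome_length)
  ann
}

#' Simulate a dense transposon insertion library
#'
#' Places `n_sites` distinct insertion positions uniformly at random over
#' the genome, excluding essential genes (which by construction yield no
#' viable mutants). Each site receives a log-normal abundance mass — the
#' library skew — and the returned read counts are a multinomial draw of
#' `depth` reads over those masses (every site keeps at least one read so
#' that the library lists exactly `n_sites` unique insertions).
#'
#' @param annotation Annotation from [simulate_genome()] or [read_gff()].
#' @param n_sites Number of unique insertion sites.
#' @param seed Integer seed.
#' @param depth Total reads in the library table; default 50 per site.
#' @param meanlog,sdlog Parameters of the log-normal per-site abundance
#'   prior (defaults 0 and 1).
#' @return Insertion table `contig`, `position`, `reads`, sorted by
#'   position.
#' @export
simulate_library <- function(annotation, n_sites, seed = 1L,
                             depth = NULL, meanlog = 0, sdlog = 1) {
  check_annotation(annotation)
  genome_length <- attr(annotation, "genome_length") %||% max(annotation$end)
  contig <- annotation$contig[1]
  if (n_sites == 0L)
    return(tibble(contig = character(), position = integer(), reads = integer()))
  ok <- rep(TRUE, genome_length)
  ess <- dplyr::filter(annotation, .data$essential)
  for (i in seq_len(nrow(ess))) ok[ess$start[i]:ess$end[i]] <- FALSE
  avail <- which(ok)
  if (n_sites > length(avail))
    abort(sprintf(
      "Cannot place %d distinct sites: only %d positions lie outside essential genes.",
      n_sites, length(avail)
    ))
  if (is.null(depth)) depth <- 50 * n_sites
  withr::with_seed(seed, {
    pos <- sort(sample(avail, n_sites))
    mass <- rlnorm(n_sites, meanlog, sdlog)
    reads <- pmax(1L, as.vector(rmultinom(1, depth, mass)))
  })
  tibble(contig = contig, position = as.integer(pos), reads = as.integer(reads))
}

#' Simulate growth under selection followed by sequencing
#'
#' Each insertion site is one mutant lineage. Over `generations`
#' doublings, a lineage in gene *g* multiplies by `2^(w_g * generations)`;
#' intergenic lineages are neutral (`w = 1`). The returned table is a
#' multinomial draw of `depth` reads over the expanded lineage masses, so
#' counts always sum exactly to `depth` (sites drawing zero reads are
#' dropped, as they would be invisible to sequencing).
#'
#' @param library Insertion table of the starting library.
#' @param annotation Matching annotation.
#' @param true_fitness Named numeric vector (or data frame `gene_id`, `w`)
#'   of per-gene relative fitness; every gene that carries sites must have
#'   an entry. All `w >= 0`; `w = 1` is neutral.
#' @param generations Doublings between the two sampled timepoints (>= 0).
#' @param depth Total reads to draw (>= 1).
#' @param seed Integer seed.
#' @param bottleneck Optional inoculum size; if given, the library is
#'   first subsampled to `bottleneck` cells before growth. Default `NULL`
#'   (no bottleneck, matching an inoculum large enough not to lose
#'   lineages).
#' @return Insertion table `contig`, `position`, `reads`.
#' @export
simulate_selection <- function(library, annotation, true_fitness,
                               generations, depth, seed = 1L,
                               bottleneck = NULL) {
  check_insertions(library)
  check_annotation(annotation)
  if (generations < 0) abort("`generations` must be >= 0.")
  if (depth < 1) abort("`depth` must be >= 1.")
  w_site <- site_fitness(library, annotation, true_fitness)
  mass <- library$reads * 2^(w_site * generations)
  withr::with_seed(seed, {
    if (!is.null(bottleneck)) {
      cells <- as.vector(rmultinom(1, bottleneck, library$reads))
      mass <- cells * 2^(w_site * generations)
    }
    reads <- as.vector(rmultinom(1, depth, mass))
  })
  out <- tibble(
    contig = library$contig,
    position = library$position,
    reads = as.integer(reads)
  )
  dplyr::filter(out, .data$reads > 0L)
}

#' Expected read proportions after selection
#'
#' Analytic counterpart of [simulate_selection()]: the expected share of
#' sequencing reads for each site after deterministic exponential growth,
#' before any multinomial noise.
#'
#' @inheritParams simulate_selection
#' @return Tibble `contig`, `position`, `expected` (proportions summing to 1).
#' @export
expected_proportions <- function(library, annotation, true_fitness,
                                 generations) {
  check_insertions(library)
  w_site <- site_fitness(library, annotation, true_fitness)
  mass <- library$reads * 2^(w_site * generations)
  tibble(
    contig = library$contig,
    position = library$position,
    expected = mass / sum(mass)
  )
}

site_fitness <- function(library, annotation, true_fitness) {
  if (is.data.frame(true_fitness)) {
    if (!all(c("gene_id", "w") %in% names(true_fitness)))
      abort("`true_fitness` data frame needs columns gene_id and w.")
    true_fitness <- stats::setNames(true_fitness$w, true_fitness$gene_id)
  }
  if (any(!is.finite(true_fitness)) || any(true_fitness < 0))
    abort("All fitness values must be finite and >= 0.")
  gr_sites <- GenomicRanges::GRanges(
    library$contig, IRanges::IRanges(library$position, width = 1L)
  )
  gr_genes <- GenomicRanges::GRanges(
    annotation$contig, IRanges::IRanges(annotation$start, annotation$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  # genes do not overlap, so each site maps to at most one gene
  gene_of <- rep(NA_character_, nrow(library))
  gene_of[S4Vectors::queryHits(hits)] <-
    annotation$gene_id[S4Vectors::subjectHits(hits)]
  genic <- !is.na(gene_of)
  missing <- setdiff(unique(gene_of[genic]), names(true_fitness))
  if (length(missing) > 0)
    abort(sprintf(
      "No fitness value for gene(s) carrying insertion sites: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  w <- rep(1, nrow(library))
  w[genic] <- unname(true_fitness[gene_of[genic]])
  w
}

#' Designed fitness classes for a recovery experiment
#'
#' Assigns each non-essential gene a true fitness value: a fixed fraction
#' of genes per non-neutral class, the remainder neutral. Mirrors the
#' structure of real chemical-genomic screens, where most genes show no
#' phenotype in a given condition.
#'
#' @param annotation Annotation tibble.
#' @param classes Non-neutral fitness values to design in.
#' @param frac_per_class Fraction of non-essential genes assigned to each
#'   non-neutral class (default 0.1).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `w` covering every non-essential gene.
#' @export
design_fitness_classes <- function(annotation,
                                   classes = c(0, 0.5, 0.9, 1.1),
                                   frac_per_class = 0.1, seed = 1L) {
  check_annotation(annotation)
  if (length(classes) * frac_per_class >= 1)
    abort("Class fractions must leave room for neutral genes.")
  genes <- annotation$gene_id[!annotation$essential & !annotation$excluded]
  n_per <- floor(frac_per_class * length(genes))
  withr::with_seed(seed, {
    shuffled <- sample(genes)
  })
  w <- rep(1, length(genes))
  names(w) <- shuffled
  for (k in seq_along(classes)) {
    idx <- ((k - 1) * n_per + 1):(k * n_per)
    w[idx] <- classes[k]
  }
  tibble(gene_id = names(w), w = unname(w)) |>
    dplyr::arrange(.data$gene_id)
}

#' Simulate a full Tn-seq profiling experiment
#'
#' Generates a genome, a transposon library, replicate reference samples
#' (1 generation of neutral outgrowth, i.e. a composition-preserving
#' resample of the library) and one selected sample per condition, each
#' grown for `generations_t2 - generations_t1` doublings under the
#' condition's designed per-gene fitness.
#'
#' @param n_genes,mean_gene_length,intergenic_fraction,essential_fraction
#'   Passed to [simulate_genome()].
#' @param n_sites Unique insertion sites in the library.
#' @param conditions Named list: one entry per condition, each a data
#'   frame `gene_id`, `w` (e.g. from [design_fitness_classes()]) or a
#'   single number applied to all genes.
#' @param depth_t1,depth_t2 Sequencing depth per reference / selected
#'   sample.
#' @param generations_t1,generations_t2 Generations of growth of the
#'   reference (default 1) and the selected samples (default 11); their
#'   difference is the selective window entering the fitness equation.
#' @param n_input_replicates Reference library replicates (default 3).
#' @param seed Integer seed; all per-sample seeds derive from it.
#' @return A list: `annotation`, `library`, `truth` (long tibble
#'   `gene_id`, `condition`, `w`), `samples` (named list of insertion
#'   tables), `manifest` (sample metadata tibble with empty `file`
#'   column, filled by [write_experiment()]).
#' @export
simulate_experiment <- function(n_genes = 500, n_sites = 5000,
                                conditions,
                                mean_gene_length = 1000,
                                intergenic_fraction = 0.1,
                                essential_fraction = 0.15,
                                depth_t1 = 2e5, depth_t2 = 2e5,
                                generations_t1 = 1, generations_t2 = 11,
                                n_input_replicates = 3, seed = 1L) {
  if (generations_t2 <= generations_t1)
    abort("`generations_t2` must exceed `generations_t1`.")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    abort("`conditions` must be a fully named list.")
  ann <- simulate_genome(n_genes, mean_gene_length, intergenic_fraction,
                         essential_fraction, seed = seed)
  lib <- simulate_library(ann, n_sites, seed = seed + 1L)
  ne_genes <- ann$gene_id[!ann$essential]
  neutral <- stats::setNames(rep(1, length(ne_genes)), ne_genes)

  samples <- list()
  manifest <- list()
  for (r in seq_len(n_input_replicates)) {
    id <- sprintf("t1_rep%d", r)
    samples[[id]] <- simulate_selection(
      lib, ann, neutral, generations = generations_t1,
      depth = depth_t1, seed = seed + 100L + r
    )
    manifest[[id]] <- tibble(
      sample_id = id, condition = "input", timepoint = "t1",
      generations = generations_t1, replicate = r, file = NA_character_
    )
  }
  truth <- list()
  for (k in seq_along(conditions)) {
    cond <- names(conditions)[k]
    w <- conditions[[k]]
    if (is.numeric(w) && length(w) == 1L)
      w <- tibble(gene_id = ne_genes, w = w)
    id <- sprintf("t2_%s", cond)
    samples[[id]] <- simulate_selection(
      lib, ann, w, generations = generations_t2 - generations_t1,
      depth = depth_t2, seed = seed + 200L + k
    )
    manifest[[id]] <- tibble(
      sample_id = id, condition = cond, timepoint = "t2",
      generations = generations_t2, replicate = 1L, file = NA_character_
    )
    truth[[cond]] <- dplyr::mutate(w, condition = cond, .after = "gene_id")
  }
  list(
    annotation = ann,
    library = lib,
    truth = dplyr::bind_rows(truth),
    samples = samples,
    manifest = dplyr::bind_rows(manifest)
  )
}

#' Write a simulated experiment to disk
#'
#' Emits the annotation as GFF3, each sample as a tab-separated insertion
#' table, the sample manifest as TSV and the ground-truth fitness ledger
#' as TSV, ready for [run_pipeline()].
#'
#' @param experiment Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. The manifest written there has its `file`
#'   column filled with paths relative to the manifest location.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gff(experiment$annotation, file.path(dir, "annotation.gff3"))
  man <- experiment$manifest
  man$file <- paste0(man$sample_id, ".tsv")
  for (i in seq_len(nrow(man)))
    write_insertions(experiment$samples[[man$sample_id[i]]],
                     file.path(dir, man$file[i]))
  write_manifest(man, file.path(dir, "manifest.tsv"))
  readr::write_tsv(experiment$truth, file.path(dir, "true_fitness.tsv"))
  invisible(dir)
}

#' Simulate gene fingerprints with designed co-functional groups
#'
#' Builds a fitness matrix directly at the profile level: each group of
#' genes shares one condition-response vector, observed with independent
#' Gaussian noise; background genes are neutral plus noise. Used to test
#' that clustering and correlation ranking recover designed pathway
#' structure.
#'
#' @param n_groups Number of co-functional groups.
#' @param genes_per_group Genes per group.
#' @param n_conditions Conditions (columns).
#' @param n_background Neutral background genes.
#' @param response_sd Spread of each group's shared response around 1.
#' @param noise_sd Per-cell observation noise (default 0.03).
#' @param seed Integer seed.
#' @return A [build_matrix()] fitness matrix; attribute `groups` maps
#'   `gene_id` to its designed group (`NA` for background).
#' @export
simulate_fingerprint_groups <- function(n_groups = 3, genes_per_group = 5,
                                        n_conditions = 8, n_background = 10,
                                        response_sd = 0.25, noise_sd = 0.03,
                                        seed = 1L) {
  withr::with_seed(seed, {
    resp <- replicate(n_groups, 1 + stats::rnorm(n_conditions, 0, response_sd))
    rows <- list()
    groups <- list()
    for (g in seq_len(n_groups)) {
      for (i in seq_len(genes_per_group)) {
        id <- sprintf("grp%d_g%d", g, i)
        rows[[id]] <- resp[, g] + stats::rnorm(n_conditions, 0, noise_sd)
        groups[[id]] <- sprintf("group%d", g)
      }
    }
    for (i in seq_len(n_background)) {
      id <- sprintf("bg_%02d", i)
      rows[[id]] <- 1 + stats::rnorm(n_conditions, 0, noise_sd)
      groups[[id]] <- NA_character_
    }
  })
  conds <- sprintf("cond%02d", seq_len(n_conditions))
  long <- purrr::imap(rows, function(v, id) {
    tibble(gene_id = id, condition = conds, fitness = v, flag = "ok")
  }) |>
    dplyr::bind_rows()
  fit <- build_matrix(long)
  attr(fit, "groups") <- tibble(
    gene_id = names(groups),
    group = unlist(groups)
  )
  fit
}
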