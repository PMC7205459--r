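# Per-gene conditional fitness from Tn-seq read counts.

#' Tn-seq gene fitness score
#'
#' Compares a gene's share of mapped transposon reads before (`n_t1`) and
#' after (`n_t2`) growth, normalised by the expansion of the rest of the
#' population over the same interval:
#'
#' \deqn{W = \frac{\ln(N_{t2}\, d / N_{t1})}{\ln((1 - N_{t2})\, d / (1 - N_{t1}))},
#'       \qquad d = 2^{\mathrm{generations}}}
#'
#' `W = 1` is the neutral point (the gene's mutants kept pace with the
#' population), `W < 1` a fitness defect, `W > 1` an advantage. A lineage
#' whose abundance drops by the full expansion factor `d` scores exactly 0.
#'
#' @param n_t1 Gene read proportion at the first timepoint; in (0, 1).
#' @param n_t2 Gene read proportion at the second timepoint; in (0, 1).
#'   A proportion of exactly zero is not accepted here: genes that lose all
#'   reads are pseudocounted upstream (see [compute_condition_fitness()]).
#' @param generations Doublings of the population between the two
#'   timepoints. Default 10, i.e. an expansion factor of 2^10 = 1024
#'   (sampling after 1 generation untreated and 11 generations treated).
#' @return Numeric vector of fitness scores, recycled over the inputs.
#' @examples
#' fitness_score(0.001, 0.001)        # neutral -> 1
#' fitness_score(0.001, 0.001 / 1024) # complete growth arrest -> 0
#' @export
fitness_score <- function(n_t1, n_t2, generations = 10) {
  if (length(generations) != 1L || !is.finite(generations) || generations < 1)
    abort("`generations` must be a single value >= 1.")
  if (any(!is.finite(n_t1)) || any(n_t1 <= 0) || any(n_t1 >= 1))
    abort("`n_t1` must lie strictly inside (0, 1); a gene absent from the input library has no defined fitness.")
  if (any(!is.finite(n_t2)) || any(n_t2 <= 0) || any(n_t2 >= 1))
    abort("`n_t2` must lie strictly inside (0, 1); pseudocount zero-read genes before scoring.")
  d <- 2^generations
  log(n_t2 * d / n_t1) / log((1 - n_t2) * d / (1 - n_t1))
}

#' Keep insertion sites supported by a minimum number of reads
#'
#' Unique insertion sites with fewer than `min_reads` reads are treated as
#' noise (spurious junctions, index hopping) and removed before any
#' proportion is computed. Row order is preserved.
#'
#' @param sites Insertion table: a data frame with columns `contig`,
#'   `position`, `reads`.
#' @param min_reads Minimum read count for a site to be kept (default 2).
#' @return The filtered insertion table.
#' @export
filter_sites <- function(sites, min_reads = 2) {
  check_insertions(sites)
  if (length(min_reads) != 1L || is.na(min_reads) || min_reads < 1)
    abort("`min_reads` must be a single value >= 1.")
  out <- dplyr::filter(sites, .data$reads >= min_reads)
  attr(out, "sample_id") <- attr(sites, "sample_id")
  out
}

#' Sum insertion tables site-wise across replicates
#'
#' Replicate samples of the same library are pooled by summing read counts
#' at each site (union of positions). Pooling read evidence before
#' filtering and proportion computation is variance-optimal for
#' multinomially sampled counts.
#'
#' @param tables A list of insertion tables sharing a contig namespace.
#' @return One insertion table with site-wise summed counts, sorted by
#'   contig and position.
#' @export
pool_replicates <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L || is.data.frame(tables))
    abort("`tables` must be a non-empty list of insertion tables.")
  purrr::walk(tables, check_insertions)
  dplyr::bind_rows(tables) |>
    dplyr::summarise(reads = sum(.data$reads), .by = c("contig", "position")) |>
    dplyr::arrange(.data$contig, .data$position)
}

#' Per-gene read proportions
#'
#' Aggregates filtered insertion reads over gene intervals and expresses
#' each gene's total as a fraction `N` of the sample's filtered reads.
#' Genes flagged as excluded from profiling (tRNA, rRNA, transposon
#' features) receive no row, although their reads still count towards the
#' `"all"` denominator. Genes without any filtered read get `N = 0`.
#'
#' @param sites A filtered insertion table (see [filter_sites()]).
#' @param annotation Gene annotation, e.g. from [read_gff()] or
#'   [simulate_genome()].
#' @param denominator `"all"` (default) divides by every filtered read in
#'   the sample, intergenic included; `"genic"` divides by reads falling in
#'   non-excluded genes only.
#' @return A tibble with one row per non-excluded gene: `gene_id`,
#'   `essential`, `site_count`, `reads`, `n`. The total used as denominator
#'   is stored in attribute `total_reads`.
#' @export
gene_read_proportions <- function(sites, annotation,
                                  denominator = c("all", "genic")) {
  check_insertions(sites)
  check_annotation(annotation)
  denominator <- match.arg(denominator)
  if (nrow(sites) == 0L || sum(sites$reads) == 0)
    abort("Insertion table has no reads: proportion denominator undefined.")

  genes <- dplyr::filter(annotation, !.data$excluded)
  hits <- overlap_sites(sites, genes)
  per_gene <- hits |>
    dplyr::summarise(
      site_count = dplyr::n(),
      reads = sum(.data$reads),
      .by = "gene_id"
    )
  out <- genes |>
    dplyr::select("gene_id", "essential") |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      site_count = dplyr::coalesce(.data$site_count, 0L),
      reads = dplyr::coalesce(.data$reads, 0L)
    )
  total <- if (denominator == "all") sum(sites$reads) else sum(out$reads)
  if (total == 0)
    abort("No reads fall inside non-excluded genes: genic denominator undefined.")
  out$n <- out$reads / total
  attr(out, "total_reads") <- total
  attr(out, "denominator") <- denominator
  attr(out, "sample_id") <- attr(sites, "sample_id")
  out
}

#' Fitness scores for one condition
#'
#' Applies the fitness equation gene by gene, comparing reference (`t1`)
#' and selected (`t2`) read proportions computed by
#' [gene_read_proportions()] on the same annotation. Essential genes carry
#' no usable insertions and are omitted. Flags record how each score was
#' obtained:
#'
#' * `ok` — both proportions positive, score as defined;
#' * `pseudocounted` — the gene had reads at t1 but none at t2; one
#'   pseudo-read is added to its t2 total (and to the t2 denominator), so
#'   the reported score is a conservative lower bound on the defect;
#' * `no_data` — the gene had no reads in the reference library; fitness
#'   is undefined (`NA`).
#'
#' @param t1,t2 Per-gene proportion tables for reference and selected
#'   samples (same gene universe).
#' @param generations Population doublings between t1 and t2 (default 10).
#' @param condition Condition label carried into the result.
#' @return A tibble `gene_id`, `condition`, `fitness`, `flag` with one row
#'   per non-essential, non-excluded gene.
#' @export
compute_condition_fitness <- function(t1, t2, generations = 10,
                                      condition = NA_character_) {
  for (nm in c("gene_id", "essential", "n"))
    if (!all(nm %in% names(t1), nm %in% names(t2)))
      abort("`t1` and `t2` must be outputs of gene_read_proportions().")
  if (!setequal(t1$gene_id, t2$gene_id))
    abort("`t1` and `t2` cover different gene universes; recompute both from the same annotation.")
  total2 <- attr(t2, "total_reads")
  if (is.null(total2)) abort("`t2` is missing its `total_reads` attribute.")

  j <- dplyr::inner_join(
    dplyr::select(t1, "gene_id", "essential", n1 = "n"),
    dplyr::select(t2, "gene_id", n2 = "n"),
    by = "gene_id"
  ) |>
    dplyr::filter(!.data$essential)

  flag <- dplyr::case_when(
    j$n1 == 0 ~ "no_data",
    j$n2 == 0 ~ "pseudocounted",
    TRUE ~ "ok"
  )
  # one pseudo-read into the gene total and into the sample total
  n2_eff <- ifelse(j$n2 == 0, 1 / (total2 + 1), j$n2)
  w <- rep(NA_real_, nrow(j))
  score_me <- flag != "no_data"
  w[score_me] <- fitness_score(j$n1[score_me], n2_eff[score_me], generations)
  tibble(
    gene_id = j$gene_id,
    condition = condition,
    fitness = w,
    flag = flag
  )
}

# -- internal helpers ---------------------------------------------------

check_insertions <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x) || !all(c("contig", "position", "reads") %in% names(x)))
    abort(sprintf("`%s` must be a data frame with columns contig, position, reads.", arg))
  invisible(x)
}

check_annotation <- function(x) {
  need <- c("gene_id", "contig", "start", "end", "essential", "excluded")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    abort("`annotation` must have columns gene_id, contig, start, end, essential, excluded.")
  invisible(x)
}

# site -> gene assignment over 1-based inclusive gene intervals
overlap_sites <- function(sites, genes) {
  gr_sites <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$position, width = 1L)
  )
  gr_genes <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  tibble(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    position = sites$position[S4Vectors::queryHits(hits)],
    reads = sites$reads[S4Vectors::queryHits(hits)]
  )
}
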