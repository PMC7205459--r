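# Phenotypic fingerprints: the gene x condition fitness matrix and the
# operations on it (phenotype thresholds, hierarchical clustering,
# correlation-neighbour ranking).

#' Assemble a gene-by-condition fitness matrix
#'
#' Binds per-condition score tables (from [compute_condition_fitness()])
#' into one phenotypic-fingerprint object. Every gene must be scored in
#' every condition; two concentrations of one drug are two distinct
#' condition columns and are never merged.
#'
#' @param scores A long tibble `gene_id`, `condition`, `fitness`, `flag`,
#'   or a list of such tibbles.
#' @return A `tn_fitness` object: the long tibble with gene and condition
#'   order recorded in attributes. Coerce with [as.matrix()] for a wide
#'   genes-by-conditions numeric matrix (`NA` where flag is `no_data`).
#' @export
build_matrix <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- dplyr::bind_rows(scores)
  need <- c("gene_id", "condition", "fitness", "flag")
  if (!all(need %in% names(scores)))
    abort("`scores` must have columns gene_id, condition, fitness, flag.")
  scores <- as_tibble(scores)[, need]
  if (anyDuplicated(scores[, c("gene_id", "condition")]))
    abort("Duplicate (gene, condition) score; condition labels must be unique.")
  genes <- unique(scores$gene_id)
  conds <- unique(scores$condition)
  n_expected <- length(genes) * length(conds)
  if (nrow(scores) != n_expected)
    abort(sprintf(
      "Incomplete matrix: %d scores for %d genes x %d conditions; every gene needs a score (possibly no_data) in every condition.",
      nrow(scores), length(genes), length(conds)
    ))
  bad <- scores$flag == "no_data" & !is.na(scores$fitness)
  if (any(bad)) abort("no_data cells must have NA fitness.")
  structure(scores,
    class = c("tn_fitness", class(scores)),
    gene_ids = genes, conditions = conds
  )
}

#' @export
as.matrix.tn_fitness <- function(x, ...) {
  genes <- attr(x, "gene_ids")
  conds <- attr(x, "conditions")
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  m[cbind(match(x$gene_id, genes), match(x$condition, conds))] <- x$fitness
  m
}

#' @export
print.tn_fitness <- function(x, ...) {
  cat(sprintf(
    "<tn_fitness> %d genes x %d conditions (%d pseudocounted, %d no_data cells)\n",
    length(attr(x, "gene_ids")), length(attr(x, "conditions")),
    sum(x$flag == "pseudocounted"), sum(x$flag == "no_data")
  ))
  NextMethod()
}

#' @method glance tn_fitness
#' @export
glance.tn_fitness <- function(x, ...) {
  tibble(
    n_genes = length(attr(x, "gene_ids")),
    n_conditions = length(attr(x, "conditions")),
    n_ok = sum(x$flag == "ok"),
    n_pseudocounted = sum(x$flag == "pseudocounted"),
    n_no_data = sum(x$flag == "no_data"),
    median_fitness = stats::median(x$fitness, na.rm = TRUE)
  )
}

#' Classify genes by phenotype strength
#'
#' A gene shows a *strong* phenotype if its fitness falls below
#' `strong[1]` or above `strong[2]` in at least one condition; otherwise a
#' *moderate* phenotype if fitness falls below `moderate[1]` or above
#' `moderate[2]` in at least one condition; otherwise *none*. Defaults are
#' the conventional 0.75/1.25 and 0.9/1.1 cutoffs. Fitness advantages
#' count the same as defects. Genes with no scored condition are
#' classified `none` with a warning.
#'
#' @param fit A `tn_fitness` matrix.
#' @param strong,moderate Lower/upper fitness bounds of the two bands.
#' @param annotation Optional annotation; if given, its essential genes
#'   are appended as category `essential` so summary counts cover the
#'   whole genome.
#' @return A `tn_phenotypes` tibble: `gene_id`, `category`,
#'   `triggering_conditions` (list-column of condition labels that drove
#'   the call). Use [glance()] for the four-way summary counts.
#' @export
classify_phenotypes <- function(fit, strong = c(0.75, 1.25),
                                moderate = c(0.9, 1.1),
                                annotation = NULL) {
  stopifnot(inherits(fit, "tn_fitness"))
  if (!(strong[1] < moderate[1] && moderate[1] < 1 &&
        1 < moderate[2] && moderate[2] < strong[2]))
    abort("Thresholds must nest: strong[1] < moderate[1] < 1 < moderate[2] < strong[2].")
  calls <- as_tibble(fit) |>
    dplyr::mutate(
      is_strong = !is.na(.data$fitness) &
        (.data$fitness < strong[1] | .data$fitness > strong[2]),
      is_moderate = !is.na(.data$fitness) &
        (.data$fitness < moderate[1] | .data$fitness > moderate[2])
    ) |>
    dplyr::summarise(
      any_strong = any(.data$is_strong),
      any_moderate = any(.data$is_moderate),
      all_na = all(is.na(.data$fitness)),
      strong_conds = list(.data$condition[.data$is_strong]),
      moderate_conds = list(.data$condition[.data$is_moderate]),
      .by = "gene_id"
    )
  if (any(calls$all_na))
    warn(sprintf("%d gene(s) have no scored condition; classified as 'none'.",
                 sum(calls$all_na)))
  out <- tibble(
    gene_id = calls$gene_id,
    category = dplyr::case_when(
      calls$any_strong ~ "strong",
      calls$any_moderate ~ "moderate",
      TRUE ~ "none"
    ),
    triggering_conditions = purrr::pmap(
      list(calls$any_strong, calls$strong_conds, calls$moderate_conds),
      function(s, sc, mc) if (s) sc else mc
    )
  )
  out$triggering_conditions[out$category == "none"] <- list(character())
  if (!is.null(annotation)) {
    check_annotation(annotation)
    ess <- annotation$gene_id[annotation$essential & !annotation$excluded]
    ess <- setdiff(ess, out$gene_id)
    if (length(ess) > 0)
      out <- dplyr::bind_rows(out, tibble(
        gene_id = ess, category = "essential",
        triggering_conditions = list(character())
      ))
  }
  structure(out,
    class = c("tn_phenotypes", class(out)),
    thresholds = list(strong = strong, moderate = moderate)
  )
}

#' @method glance tn_phenotypes
#' @export
glance.tn_phenotypes <- function(x, ...) {
  tibble(
    n_essential = sum(x$category == "essential"),
    n_strong = sum(x$category == "strong"),
    n_moderate = sum(x$category == "moderate"),
    n_none = sum(x$category == "none"),
    n_total = nrow(x)
  )
}

#' Hierarchically cluster phenotypic fingerprints
#'
#' Groups genes whose fitness profiles behave similarly across all
#' conditions. Unscored cells are imputed to the neutral value 1 before
#' distances are computed, so absent evidence creates no artificial
#' distance. Rows enter the agglomeration in lexicographic gene order,
#' which fixes tie-breaking and makes the tree deterministic.
#'
#' @param fit A `tn_fitness` matrix with at least one gene.
#' @param metric `"euclidean"` (default) or `"correlation"`
#'   (distance `1 - r`). A zero-variance profile has no defined
#'   correlation; under the correlation metric such rows are placed at
#'   maximal distance (2) from everything, with a warning.
#' @param linkage `"complete"` (default), `"average"` or `"ward"`
#'   (Ward's criterion on squared distances, `ward.D2`).
#' @return A `tn_clust` object: `hclust` (the stats::hclust tree, `NULL`
#'   for a single gene), `leaf_order` (gene ids in dendrogram order),
#'   `metric`, `linkage`.
#' @export
cluster_profiles <- function(fit, metric = c("euclidean", "correlation"),
                             linkage = c("complete", "average", "ward")) {
  stopifnot(inherits(fit, "tn_fitness"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- as.matrix(fit)
  n_imputed <- sum(is.na(m))
  m[is.na(m)] <- 1
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) == 1L) {
    return(structure(
      list(hclust = NULL, leaf_order = rownames(m),
           metric = metric, linkage = linkage, n_imputed = n_imputed),
      class = "tn_clust"
    ))
  }
  d <- profile_dist(m, metric)
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(
    list(hclust = hc, leaf_order = rownames(m)[hc$order],
         metric = metric, linkage = linkage, n_imputed = n_imputed),
    class = "tn_clust"
  )
}

profile_dist <- function(m, metric) {
  if (metric == "euclidean") return(dist(m))
  v <- apply(m, 1, stats::var)
  r <- suppressWarnings(cor(t(m)))
  if (any(v == 0)) {
    warn(sprintf(
      "%d zero-variance profile(s) have no defined correlation; assigned maximal distance.",
      sum(v == 0)
    ))
    r[v == 0, ] <- -1
    r[, v == 0] <- -1
  }
  stats::as.dist(1 - r)
}

#' @export
print.tn_clust <- function(x, ...) {
  cat(sprintf("<tn_clust> %d genes, %s distance, %s linkage\n",
              length(x$leaf_order), x$metric, x$linkage))
  invisible(x)
}

#' @method tidy tn_clust
#' @export
tidy.tn_clust <- function(x, ...) {
  if (is.null(x$hclust))
    return(tibble(merge1 = integer(), merge2 = integer(), height = double()))
  tibble(
    merge1 = x$hclust$merge[, 1],
    merge2 = x$hclust$merge[, 2],
    height = x$hclust$height
  )
}

#' @method glance tn_clust
#' @export
glance.tn_clust <- function(x, ...) {
  tibble(
    n_genes = length(x$leaf_order),
    metric = x$metric,
    linkage = x$linkage,
    max_height = if (is.null(x$hclust)) NA_real_ else max(x$hclust$height),
    n_imputed = x$n_imputed
  )
}

#' Rank correlation neighbours of a gene
#'
#' Computes the Pearson correlation between the query gene's fingerprint
#' and every other gene's, over conditions where both are scored
#' (pairwise-complete; no neutral imputation here). Genes whose profiles
#' track the query's across conditions are candidates for shared
#' function.
#'
#' @param fit A `tn_fitness` matrix with at least 3 conditions.
#' @param gene_id Query gene.
#' @return A tibble `gene_id`, `r`, sorted by decreasing `r` with ties
#'   broken lexicographically; the query itself is excluded. Attribute
#'   `query` holds the query gene id.
#' @export
correlation_neighbors <- function(fit, gene_id) {
  stopifnot(inherits(fit, "tn_fitness"))
  m <- as.matrix(fit)
  if (ncol(m) < 3)
    abort("Correlation neighbours need at least 3 conditions.")
  if (!gene_id %in% rownames(m))
    abort(sprintf("Gene '%s' is not in the matrix.", gene_id))
  q <- m[gene_id, ]
  if (all(is.na(q)))
    abort(sprintf("Gene '%s' has no scored condition.", gene_id))
  others <- setdiff(rownames(m), gene_id)
  r <- suppressWarnings(
    as.vector(cor(q, t(m[others, , drop = FALSE]),
                  use = "pairwise.complete.obs"))
  )
  out <- tibble(gene_id = others, r = r) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$gene_id)
  attr(out, "query") <- gene_id
  out
}
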