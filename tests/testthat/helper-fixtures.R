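# Fixtures are built in code; nothing binary ships with the package.

tiny_annotation <- function() {
  ann <- tibble::tibble(
    gene_id = c("geneA", "geneB", "geneC"),
    contig = "tig1",
    start = c(11L, 101L, 301L),
    end = c(60L, 200L, 420L),
    strand = c("+", "-", "+"),
    type = "gene",
    essential = c(FALSE, FALSE, TRUE),
    excluded = FALSE
  )
  attr(ann, "genome_length") <- 500L
  ann
}

tiny_sites <- function(position, reads, contig = "tig1") {
  tibble::tibble(contig = contig, position = as.integer(position),
                 reads = as.integer(reads))
}

# random small insertion table for property checks
random_sites <- function(n, max_pos = 1000L, max_reads = 20L) {
  pos <- sample.int(max_pos, n)
  tiny_sites(pos, sample.int(max_reads, n, replace = TRUE))
}

# a fitness matrix with given wide values (genes x conditions)
matrix_fixture <- function(m, flag = "ok") {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m), gene_id = rownames(m)),
    -gene_id, names_to = "condition", values_to = "fitness"
  )
  long$flag <- ifelse(is.na(long$fitness), "no_data", flag)
  build_matrix(long)
}

random_profile_matrix <- function(n_genes, n_conds, sd = 0.2) {
  m <- matrix(1 + stats::rnorm(n_genes * n_conds, 0, sd), n_genes, n_conds,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_conds))))
  m
}

write_gff_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
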