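# On-disk formats. GFF3 goes through rtracklayer; tables are plain
# tab-separated UTF-8. Coordinates are 1-based inclusive on disk and in
# memory (the GFF3 convention); nothing downstream converts.

#' Read a gene annotation from GFF3
#'
#' Loads gene-type features plus the RNA and mobile-element classes that
#' are excluded from fitness profiling (their reads still count in the
#' read-proportion denominator). An `essential=true` attribute on a
#' feature marks it as essential; essentiality can also be supplied later
#' by flagging `annotation$essential` directly.
#'
#' @param path GFF3 file.
#' @param exclude_types Feature types loaded but excluded from profiling
#'   (default tRNA and rRNA).
#' @param transposon_regex Regular expression matched (case-insensitively)
#'   against feature type and Name to flag transposon-related genes as
#'   excluded.
#' @return Annotation tibble `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `type`, `essential`, `excluded`. If the file declares
#'   `##sequence-region`, the length is kept as attribute `genome_length`
#'   and coordinates are validated against it.
#' @export
read_gff <- function(path, exclude_types = c("tRNA", "rRNA"),
                     transposon_regex = "transpos") {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  prescan_gff(path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep_types <- c("gene", exclude_types)
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  sel <- type %in% keep_types |
    grepl(transposon_regex, type, ignore.case = TRUE)
  gr <- gr[sel]
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)

  id <- as.character(m$ID %||% rep(NA_character_, length(gr)))
  if ("Name" %in% names(m)) {
    nm <- as.character(m$Name)
    id <- ifelse(is.na(id), nm, id)
  }
  if ("locus_tag" %in% names(m))
    id <- ifelse(is.na(id), as.character(m$locus_tag), id)
  if (anyNA(id)) abort("GFF3 feature without ID/Name/locus_tag attribute.")
  if (anyDuplicated(id))
    abort(sprintf("Duplicate gene_id in GFF3: %s",
                  paste(unique(id[duplicated(id)])[1:min(3, sum(duplicated(id)))],
                        collapse = ", ")))

  essential <- rep(FALSE, length(gr))
  if ("essential" %in% names(m))
    essential <- tolower(as.character(m$essential)) %in% c("true", "1", "yes")
  name_attr <- if ("Name" %in% names(m)) as.character(m$Name) else id
  excluded <- type %in% exclude_types |
    grepl(transposon_regex, type, ignore.case = TRUE) |
    grepl(transposon_regex, name_attr, ignore.case = TRUE)

  ann <- tibble(
    gene_id = id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    essential = essential,
    excluded = excluded
  ) |>
    dplyr::arrange(.data$contig, .data$start)

  # rtracklayer does not surface the ##sequence-region pragma; scan for it
  pragma <- grep("^##sequence-region", readLines(path, warn = FALSE),
                 value = TRUE)
  if (length(pragma) == 1L) {
    sl <- as.integer(strsplit(trimws(pragma), "\\s+")[[1]][4])
    if (!is.na(sl)) {
      if (any(ann$end > sl))
        abort("Feature coordinates exceed the declared sequence-region length.")
      attr(ann, "genome_length") <- sl
    }
  }
  ann
}

# cheap line-level validation so coordinate errors carry a line number
prescan_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      abort(sprintf("GFF3 parse error at line %d: fewer than 8 fields.", i))
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      abort(sprintf("GFF3 parse error at line %d: non-numeric coordinates.", i))
    if (e < s)
      abort(sprintf("GFF3 parse error at line %d: end (%d) < start (%d).", i, e, s))
  }
  invisible(TRUE)
}

#' Write a gene annotation to GFF3
#'
#' @param annotation Annotation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  check_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    annotation$contig,
    IRanges::IRanges(annotation$start, annotation$end),
    strand = ifelse(annotation$strand %in% c("+", "-"), annotation$strand, "*")
  )
  S4Vectors::mcols(gr)$source <- "tnprof"
  S4Vectors::mcols(gr)$type <- annotation$type
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$essential <- tolower(as.character(annotation$essential))
  rtracklayer::export(gr, path, format = "gff3")
  # make the file self-describing and stable: declare the genome length,
  # drop the volatile ##date stamp rtracklayer adds
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "##date")]
  gl <- attr(annotation, "genome_length")
  if (!is.null(gl)) {
    region <- sprintf("##sequence-region %s 1 %d",
                      as.character(annotation$contig[1]), as.integer(gl))
    lines <- append(lines, region, after = 1L)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an insertion-site read-count table
#'
#' Three tab-separated columns `contig`, `position`, `reads`; a header
#' line is optional. Positions are 1-based; duplicate positions within a
#' contig and negative read counts are rejected rather than repaired.
#'
#' @param path TSV file.
#' @param sample_id Sample label attached to the table (defaults to the
#'   file name without extension).
#' @return Insertion tibble `contig`, `position`, `reads` with attribute
#'   `sample_id`.
#' @export
read_insertions <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(sprintf("Insertion table not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  f <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(f) >= 2 && is.na(suppressWarnings(as.numeric(f[2])))
  x <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("contig", "position", "reads"),
    col_types = readr::cols(
      readr::col_character(), readr::col_double(), readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  names(x) <- c("contig", "position", "reads")
  if (anyNA(x$position) || anyNA(x$reads) ||
      any(x$position != floor(x$position)) || any(x$reads != floor(x$reads)))
    abort(sprintf("Non-integer position or read count in %s.", path))
  if (any(x$position < 1)) abort(sprintf("Position < 1 in %s.", path))
  if (any(x$reads < 0)) abort(sprintf("Negative read count in %s.", path))
  dups <- duplicated(x[, c("contig", "position")])
  if (any(dups))
    abort(sprintf("Duplicate insertion position in %s (e.g. %s:%d).",
                  path, x$contig[dups][1], as.integer(x$position[dups][1])))
  x$position <- as.integer(x$position)
  x$reads <- as.integer(x$reads)
  attr(x, "sample_id") <- sample_id %||%
    sub("\\.[^.]*$", "", basename(path))
  x
}

#' @rdname read_insertions
#' @param sites Insertion tibble to write.
#' @export
write_insertions <- function(sites, path) {
  check_insertions(sites)
  readr::write_tsv(sites[, c("contig", "position", "reads")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' The manifest maps samples to conditions and growth parameters:
#' columns `sample_id`, `condition`, `timepoint` (`t1` reference or `t2`
#' selected), `generations`, `replicate`, `file` (insertion table path,
#' relative paths resolved against the manifest location). All `t1`
#' samples form the common reference pool; every `t2` sample must have
#' grown for more generations than any `t1` sample.
#'
#' @param path Manifest file: TSV, or YAML (a list of row records) when
#'   the extension is `.yml`/`.yaml`.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    rows <- yaml::read_yaml(path)
    x <- dplyr::bind_rows(lapply(rows, as_tibble))
  } else {
    x <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  }
  need <- c("sample_id", "condition", "timepoint", "generations",
            "replicate", "file")
  if (!all(need %in% names(x)))
    abort(sprintf("Manifest must have columns: %s.", paste(need, collapse = ", ")))
  x <- x[, need]
  if (!all(x$timepoint %in% c("t1", "t2")))
    abort("Manifest timepoint must be 't1' or 't2'.")
  if (!any(x$timepoint == "t1"))
    abort("Manifest has no t1 reference sample.")
  if (!any(x$timepoint == "t2"))
    abort("Manifest has no t2 selected sample.")
  if (max(x$generations[x$timepoint == "t1"]) >=
      min(x$generations[x$timepoint == "t2"]))
    abort("Every t2 sample must have more generations than any t1 sample.")
  if (anyDuplicated(x$sample_id))
    abort("Duplicate sample_id in manifest.")
  rel <- !grepl("^(/|[A-Za-z]:)", x$file)
  x$file[rel] <- file.path(dirname(path), x$file[rel])
  x
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to write (as TSV).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Write or read a fitness matrix
#'
#' Tab-separated, genes as rows: a `gene_id` column, one value column per
#' condition and one `flag_<condition>` sidecar column per condition.
#' Cells flagged `no_data` are written as `NA`. Leading `#` comment lines
#' carry provenance (package version, optional config hash) and are
#' ignored on read; write/read is an exact round trip.
#'
#' @param fit A fitness matrix from [build_matrix()].
#' @param path Output file.
#' @param comments Extra comment lines (without the leading `#`).
#' @return `path` invisibly; `read_fitness_matrix()` returns the fitness
#'   matrix.
#' @export
write_fitness_matrix <- function(fit, path, comments = character()) {
  stopifnot(inherits(fit, "tn_fitness"))
  vals <- tidyr::pivot_wider(
    as_tibble(fit)[, c("gene_id", "condition", "fitness")],
    names_from = "condition", values_from = "fitness"
  )
  flags <- tidyr::pivot_wider(
    as_tibble(fit)[, c("gene_id", "condition", "flag")],
    names_from = "condition", values_from = "flag",
    names_prefix = "flag_"
  )
  wide <- dplyr::left_join(vals, flags, by = "gene_id")
  hdr <- c(sprintf("# tnprof %s fitness matrix", packageVersion("tnprof")),
           sprintf("# %s", comments))
  writeLines(hdr, path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_fitness_matrix
#' @export
read_fitness_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("Fitness matrix not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", progress = FALSE,
                       show_col_types = FALSE)
  flag_cols <- grep("^flag_", names(x), value = TRUE)
  conds <- sub("^flag_", "", flag_cols)
  if (!all(conds %in% names(x)))
    abort("Malformed fitness matrix: flag columns do not match value columns.")
  vals <- tidyr::pivot_longer(x[, c("gene_id", conds)], -"gene_id",
                              names_to = "condition", values_to = "fitness")
  flags <- tidyr::pivot_longer(x[, c("gene_id", flag_cols)], -"gene_id",
                               names_to = "condition", values_to = "flag") |>
    dplyr::mutate(condition = sub("^flag_", "", .data$condition))
  long <- dplyr::left_join(vals, flags, by = c("gene_id", "condition"))
  if (any(long$flag != "no_data" & !is.finite(long$fitness)))
    abort("Non-finite fitness value not flagged no_data.")
  build_matrix(long)
}
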