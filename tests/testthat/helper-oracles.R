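# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# exhaustive per-entry read sum for a gene interval
brute_gene_reads <- function(sites, ann_row) {
  total <- 0L
  for (i in seq_len(nrow(sites))) {
    if (sites$contig[i] == ann_row$contig &&
        sites$position[i] >= ann_row$start &&
        sites$position[i] <= ann_row$end) {
      total <- total + sites$reads[i]
    }
  }
  total
}

# textbook Pearson correlation: covariance over product of sds
pearson_oracle <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# naive O(n^3) agglomerative clustering; returns merge heights and the
# cophenetic matrix (tree comparison is done on those, which are
# invariant to the bookkeeping order of merges)
naive_agglomerate <- function(d, method = c("complete", "average")) {
  method <- match.arg(method)
  D <- as.matrix(d)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  heights <- numeric(n - 1)
  link <- function(A, B) {
    vals <- D[A, B, drop = FALSE]
    if (method == "complete") max(vals) else mean(vals)
  }
  for (step in seq_len(n - 1)) {
    k <- length(members)
    best_i <- NA; best_j <- NA; best_h <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        h <- link(members[[i]], members[[j]])
        if (h < best_h) { best_h <- h; best_i <- i; best_j <- j }
      }
    }
    heights[step] <- best_h
    for (a in members[[best_i]]) for (b in members[[best_j]]) {
      coph[a, b] <- best_h
      coph[b, a] <- best_h
    }
    members[[best_i]] <- c(members[[best_i]], members[[best_j]])
    members[[best_j]] <- NULL
  }
  list(height = heights, cophenetic = coph)
}

# positions of each group's genes are consecutive in the leaf order
is_contiguous <- function(leaf_order, genes) {
  pos <- sort(match(genes, leaf_order))
  all(diff(pos) == 1)
}
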