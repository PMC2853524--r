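#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of gene expression time courses, cut to `k`
#' clusters (the published analysis used k = 12 over 549 profiles). Profiles
#' are z-scored per gene by default so clusters group temporal shapes rather
#' than absolute levels; the distance is 1 - Pearson correlation between
#' profiles with average linkage (both configurable). The procedure is
#' deterministic: identical inputs give identical assignments.
#'
#' @param expr an `expression_matrix` (control rows are excluded).
#' @param k number of clusters, `1 <= k <=` number of genes.
#' @param distance `"correlation"` (1 - r) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param standardize z-score each profile first.
#' @return a `cluster_assignment`: list with `cluster` (named integer vector,
#'   labels 1..k in decreasing cluster size), `k`, `tree` (the `hclust`
#'   merge history), `sizes`, and `mean_profiles` (k x time matrix of
#'   per-cluster arithmetic means of the raw profiles).
#' @export
hierarchical_clusters <- function(expr, k, distance = c("correlation", "euclidean"),
                                  linkage = "average", standardize = TRUE) {
  distance <- match.arg(distance)
  vals <- expr$values[setdiff(rownames(expr$values), expr$control_rows), ,
                      drop = FALSE]
  n <- nrow(vals)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")",
                  call. = FALSE)
  if (any(!is.finite(vals))) stop("profiles must be finite", call. = FALSE)

  z <- vals
  if (standardize) {
    mu <- rowMeans(z); sdv <- apply(z, 1, stats::sd)
    sdv[sdv == 0] <- 1  # flat profiles stay flat (all-zero) after scaling
    z <- (z - mu) / sdv
  }
  d <- if (distance == "correlation") {
    flat <- apply(z, 1, stats::sd) == 0
    if (any(flat)) {
      # correlation with a flat profile is undefined; treat flat profiles as
      # mutually identical and maximally distant from the rest
      cm <- matrix(0, n, n)
      ok <- !flat
      if (sum(ok) > 1) cm[ok, ok] <- stats::cor(t(z[ok, , drop = FALSE]))
      cm[flat, flat] <- 1
      diag(cm) <- 1
      stats::as.dist(1 - cm)
    } else {
      stats::as.dist(1 - stats::cor(t(z)))
    }
  } else {
    stats::dist(z)
  }
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  # relabel clusters by decreasing size (published colour names are not
  # reproducible; size rank is a stable convention)
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- stats::setNames(as.integer(relab[as.character(raw)]), rownames(vals))
  mp <- cluster_means(vals, cl, k)
  structure(list(cluster = cl, k = k, tree = tree,
                 sizes = as.integer(table(cl)),
                 mean_profiles = mp, times = expr$times),
            class = "cluster_assignment")
}

cluster_means <- function(vals, cl, k) {
  mp <- matrix(NA_real_, nrow = k, ncol = ncol(vals),
               dimnames = list(paste0("cluster", seq_len(k)), colnames(vals)))
  for (c in seq_len(k)) {
    members <- names(cl)[cl == c]
    mp[c, ] <- colMeans(vals[members, , drop = FALSE])
  }
  mp
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d genes in %d clusters (sizes %s)\n",
              length(x$cluster), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Mean expression profile per cluster
#'
#' Arithmetic mean of the member profiles (on the raw log2 scale), with
#' member counts -- the data behind an average-profile panel.
#'
#' @param expr an `expression_matrix` covering the assignment's genes.
#' @param assignment a `cluster_assignment`.
#' @return list with `mean_profiles` (cluster x time) and `sizes`.
#' @export
cluster_profiles <- function(expr, assignment) {
  genes <- names(assignment$cluster)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing))
    stop("expression matrix lacks clustered genes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  vals <- expr$values[genes, , drop = FALSE]
  list(mean_profiles = cluster_means(vals, assignment$cluster, assignment$k),
       sizes = as.integer(table(assignment$cluster)))
}

#' Genome-order track of cluster membership and correlation class
#'
#' Joins cluster ids and flux-expression correlation onto a chromosomal gene
#' order -- the tabular form of a two-track genome map (cluster membership
#' above, correlation class below). Genes missing from the order are
#' appended at the end with a warning.
#'
#' @param assignment a `cluster_assignment`.
#' @param report a classified `correlation_report` (see [classify()]), or
#'   `NULL` for a cluster-only track.
#' @param gene_order character vector of gene ids in chromosomal order
#'   (e.g. by SCO number).
#' @return data.frame: `position`, `gene`, `cluster`, and (when a report is
#'   given) `r` and `class`.
#' @export
genome_track <- function(assignment, report = NULL, gene_order) {
  genes <- names(assignment$cluster)
  ordered <- intersect(gene_order, genes)
  leftover <- setdiff(genes, ordered)
  if (length(leftover))
    warning(length(leftover), " genes missing from the order file; appended at the end")
  all_genes <- c(ordered, sort(leftover))
  out <- data.frame(position = seq_along(all_genes), gene = all_genes,
                    cluster = unname(assignment$cluster[all_genes]),
                    stringsAsFactors = FALSE)
  if (!is.null(report)) {
    p <- report$profiles
    idx <- match(all_genes, p$gene)
    out$r <- p$r[idx]
    out$class <- if ("class" %in% names(p)) p$class[idx] else NA_character_
  }
  out
}
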