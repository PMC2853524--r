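#' Gene expression time-series matrix
#'
#' @param values gene x time numeric matrix of log2 expression, rownames =
#'   gene ids.
#' @param times sampling times (h), one per column.
#' @param control_rows optional character vector of negative-control row ids
#'   (a subset of the rownames).
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, times, control_rows = character(0)) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene-id rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (length(times) != ncol(values))
    stop("times must have one entry per column", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  bad <- setdiff(control_rows, rownames(values))
  if (length(bad))
    stop("control_rows not present in the matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  colnames(values) <- paste0("t", times)
  structure(list(values = values, times = as.numeric(times),
                 control_rows = control_rows),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d times (%g-%g h), %d controls\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times),
              length(x$control_rows)))
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' First column gene id, remaining columns time points; the header encodes
#' hours (`t20`, `20`, `20h`, ... all accepted).
#'
#' @param path a TSV file.
#' @param control_rows optional control row ids.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path, control_rows = character(0)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column and time columns",
                          call. = FALSE)
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop("non-numeric expression value at row ", bad, ", column '",
           names(vals)[j], "'", call. = FALSE)
    }
  }
  times <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", names(vals))))
  if (anyNA(times))
    stop("cannot parse time points from header: ",
         paste(names(vals)[is.na(times)], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, times, control_rows = control_rows)
}

#' Write an expression matrix as TSV
#'
#' @param expr an `expression_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste0("t", expr$times)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Match genes to their dominant reaction
#'
#' Each gene in the model's gene-reaction map is assigned to exactly one
#' reaction: when a gene catalyzes several reactions, the one with the
#' largest time-averaged absolute predicted flux wins (ties broken by
#' lexicographic reaction id, for determinism). Genes all of whose reactions
#' carry zero flux throughout are still mapped (to the lexicographically
#' first reaction) but flagged in the `"zero_flux"` attribute.
#'
#' @param model a `metabolic_model`.
#' @param fluxTS a `flux_time_series` covering the model's reactions.
#' @param per_timepoint if `TRUE`, match on per-timepoint maximum |flux|
#'   summed over time rather than the time-mean (an alternative reading of
#'   "maximum predicted flux"; default `FALSE`).
#' @param tol fluxes below this magnitude count as zero.
#' @return named character vector: gene id -> reaction id, with attribute
#'   `"zero_flux"` listing the all-zero genes.
#' @export
match_genes <- function(model, fluxTS, per_timepoint = FALSE, tol = 1e-9) {
  grm <- gene_reaction_map(model)
  fm <- fluxTS$flux_matrix
  missing_rxn <- setdiff(unique(unlist(grm)), rownames(fm))
  if (length(missing_rxn))
    stop("flux time series lacks reactions: ", paste(missing_rxn, collapse = ", "),
         call. = FALSE)
  out <- character(0); zero <- character(0)
  for (g in names(grm)) {
    rids <- sort(grm[[g]])
    sub <- abs(fm[rids, , drop = FALSE])
    sc <- if (per_timepoint) {
      # number of time points at which the reaction dominates the gene's set
      wins <- apply(sub, 2, which.max)
      vapply(seq_along(rids), function(j) sum(wins == j), numeric(1))
    } else {
      rowMeans(sub, na.rm = TRUE)
    }
    best <- rids[which.max(sc)]  # which.max takes the first (lexicographic) tie
    out[[g]] <- best
    if (all(abs(fm[rids, , drop = FALSE]) <= tol, na.rm = TRUE))
      zero <- c(zero, g)
  }
  attr(out, "zero_flux") <- zero
  out
}

# align expression columns onto flux times by nearest neighbour within max_gap
align_times <- function(flux_times, expr_times, max_gap = 1) {
  idx <- integer(0); jdx <- integer(0)
  for (k in seq_along(flux_times)) {
    d <- abs(expr_times - flux_times[k])
    j <- which.min(d)
    if (d[j] <= max_gap) { idx <- c(idx, k); jdx <- c(jdx, j) }
  }
  if (length(idx) < length(flux_times))
    warning(length(flux_times) - length(idx),
            " flux time points had no expression sample within ", max_gap,
            " h and were dropped")
  list(flux = idx, expr = jdx)
}

#' Correlate predicted flux with observed expression
#'
#' For every matched gene, computes the Pearson correlation between the
#' matched reaction's flux profile and the gene's log2 expression profile on
#' the shared time grid (expression samples aligned to flux times by nearest
#' neighbour within `max_gap` hours). Genes whose predicted flux is constant
#' over time (zero standard deviation, which includes all-zero flux) carry
#' no correlation information and are excluded with a reason, as are genes
#' with constant expression.
#'
#' @param fluxTS a `flux_time_series`.
#' @param expr an `expression_matrix`.
#' @param matching gene -> reaction map from [match_genes()].
#' @param max_gap alignment tolerance in hours.
#' @param tol flux magnitudes below this are treated as zero.
#' @return a `correlation_report`: list with `profiles` (data.frame: gene,
#'   reaction, r, excluded, reason) and `n_times_used`.
#' @export
correlate <- function(fluxTS, expr, matching, max_gap = 1, tol = 1e-9) {
  genes <- intersect(names(matching), rownames(expr$values))
  if (!length(genes)) stop("no matched genes present in the expression matrix",
                           call. = FALSE)
  al <- align_times(fluxTS$times, expr$times, max_gap)
  if (length(al$flux) < 3L)
    stop("fewer than 3 overlapping time points between flux and expression",
         call. = FALSE)
  zero_flux <- attr(matching, "zero_flux")
  r <- rep(NA_real_, length(genes))
  excluded <- logical(length(genes))
  reason <- rep(NA_character_, length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    f <- fluxTS$flux_matrix[matching[[g]], al$flux]
    e <- expr$values[g, al$expr]
    if (g %in% zero_flux) {
      excluded[i] <- TRUE; reason[i] <- "zero flux"
    } else if (stats::sd(f, na.rm = TRUE) <= tol) {
      excluded[i] <- TRUE; reason[i] <- "constant flux"
    } else if (stats::sd(e) == 0) {
      excluded[i] <- TRUE; reason[i] <- "constant expression"
    } else {
      r[i] <- stats::cor(f, e, use = "complete.obs")
    }
  }
  structure(list(profiles = data.frame(gene = genes,
                                       reaction = unname(matching[genes]),
                                       r = r, excluded = excluded,
                                       reason = reason,
                                       stringsAsFactors = FALSE),
                 n_times_used = length(al$flux)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  p <- x$profiles
  cat(sprintf("correlation_report: %d genes (%d excluded) on %d time points\n",
              nrow(p), sum(p$excluded), x$n_times_used))
  if ("class" %in% names(p)) print(table(p$class))
  invisible(x)
}

#' Classify genes by flux-expression correlation
#'
#' Labels every non-excluded gene `correlated` (r > `high`), `anticorrelated`
#' (r < `low`) or `uncorrelated` (in between), with counts and fractions.
#' Defaults are the +/-0.5 thresholds.
#'
#' @param report a `correlation_report`.
#' @param low,high class thresholds, `low < high`.
#' @return the report with a `class` column added to `profiles` and a
#'   `class_counts` element (named counts and `fractions` attribute over the
#'   non-excluded genes).
#' @export
classify <- function(report, low = -0.5, high = 0.5) {
  stopifnot(low < high)
  p <- report$profiles
  cls <- rep(NA_character_, nrow(p))
  cls[!p$excluded & p$r > high] <- "correlated"
  cls[!p$excluded & p$r < low] <- "anticorrelated"
  cls[!p$excluded & p$r >= low & p$r <= high] <- "uncorrelated"
  p$class <- cls
  counts <- c(correlated = sum(cls == "correlated", na.rm = TRUE),
              uncorrelated = sum(cls == "uncorrelated", na.rm = TRUE),
              anticorrelated = sum(cls == "anticorrelated", na.rm = TRUE))
  attr(counts, "fractions") <- counts / max(1L, sum(counts))
  report$profiles <- p
  report$class_counts <- counts
  report$thresholds <- c(low = low, high = high)
  report
}

#' Genes whose matched reaction never carries flux
#'
#' The zero-flux screen: genes whose matched reaction has |flux| <= `tol` at
#' every time point. In the published analysis these are the genes "not used
#' for biomass production according to the model"; expression dynamics in
#' this set flag candidate model gaps.
#'
#' @param matching gene -> reaction map from [match_genes()].
#' @param fluxTS a `flux_time_series`.
#' @param tol zero-flux tolerance.
#' @return character vector of gene ids.
#' @export
zero_flux_genes <- function(matching, fluxTS, tol = 1e-9) {
  fm <- fluxTS$flux_matrix
  keep <- vapply(names(matching), function(g)
    all(abs(fm[matching[[g]], ]) <= tol, na.rm = TRUE), logical(1))
  names(matching)[keep]
}

#' Essentiality screen with expression summary
#'
#' Partitions matched genes into `essential` (matched reaction carries
#' non-zero flux at every time point -- required under all modeled
#' conditions), `non_essential` (the rest), and negative `controls` (from the
#' expression matrix), and reports the median log2 expression of each group.
#' Essential genes whose median expression falls below `low_cutoff` are
#' flagged: high-confidence flux predictions with no transcriptional support
#' warrant individual follow-up.
#'
#' @param fluxTS a `flux_time_series`.
#' @param expr an `expression_matrix`.
#' @param matching gene -> reaction map from [match_genes()].
#' @param low_cutoff log2 expression threshold for the low-expressed flag.
#' @param tol zero-flux tolerance.
#' @return list with `essential_genes`, `median_essential`,
#'   `median_non_essential`, `median_controls` (NA when a group is empty),
#'   `low_expressed_essential`, `low_expressed_non_essential`, `low_cutoff`.
#' @export
essential_expression_summary <- function(fluxTS, expr, matching,
                                         low_cutoff = 5.0, tol = 1e-9) {
  fm <- fluxTS$flux_matrix
  genes <- intersect(names(matching), rownames(expr$values))
  genes <- setdiff(genes, expr$control_rows)
  essential <- genes[vapply(genes, function(g)
    all(abs(fm[matching[[g]], ]) > tol, na.rm = TRUE), logical(1))]
  non_essential <- setdiff(genes, essential)
  med <- function(ids) if (length(ids)) stats::median(expr$values[ids, , drop = FALSE])
                       else NA_real_
  gene_median <- function(ids) apply(expr$values[ids, , drop = FALSE], 1, stats::median)
  low_ess <- if (length(essential)) essential[gene_median(essential) < low_cutoff]
             else character(0)
  low_non <- if (length(non_essential)) non_essential[gene_median(non_essential) < low_cutoff]
             else character(0)
  list(essential_genes = essential,
       non_essential_genes = non_essential,
       median_essential = med(essential),
       median_non_essential = med(non_essential),
       median_controls = med(expr$control_rows),
       low_expressed_essential = low_ess,
       low_expressed_non_essential = low_non,
       low_cutoff = low_cutoff)
}
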