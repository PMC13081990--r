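# Neuron-class expression profiles, detection calls, and comparisons to
# external reference tables.
#
# A gene's soft counts exist only in the worms where it was imaged; genes
# absent from a worm's matrix are treated as not imaged there (missing, not
# zero) throughout.

#' Build neuron-class expression profiles across worms
#'
#' Per (class, gene): the mean soft count over all annotated cells of that
#' class across the worms in which the gene was imaged. The default pools
#' cells across worms (cell-weighted mean); `per_worm = TRUE` instead
#' averages per-worm class means. Classes with zero annotated cells are
#' omitted, as are (class, gene) pairs imaged in zero worms.
#'
#' @param matrices list of `cell_gene_matrix`, one per worm, with
#'   `neuron_class` populated (see [attach_classes()]).
#' @param per_worm average per-worm means instead of pooling cells.
#' @return data.frame `class, gene, mean, n_cells, n_worms`.
#' @export
class_profiles <- function(matrices, per_worm = FALSE) {
  long <- do.call(rbind, lapply(matrices, function(m) {
    keep <- m$cell_meta$neuron_class != "unassigned"
    if (!any(keep)) return(NULL)
    v <- m$values[keep, , drop = FALSE]
    data.frame(worm_id = rep(m$cell_meta$worm_id[keep], ncol(v)),
               class = rep(m$cell_meta$neuron_class[keep], ncol(v)),
               gene = rep(m$gene_names, each = nrow(v)),
               count = as.numeric(v))
  }))
  if (is.null(long))
    return(data.frame(class = character(), gene = character(),
                      mean = numeric(), n_cells = integer(),
                      n_worms = integer()))
  key <- interaction(long$class, long$gene, drop = TRUE)
  rows <- lapply(split(long, key), function(g) {
    mu <- if (per_worm) {
      mean(vapply(split(g$count, g$worm_id), mean, 0))
    } else mean(g$count)
    data.frame(class = g$class[1], gene = g$gene[1], mean = mu,
               n_cells = nrow(g), n_worms = length(unique(g$worm_id)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$class, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Call per-class detections and per-cell observations
#'
#' A gene is detected in a class iff the class mean soft count is
#' `>= class_cutoff` (default 1.0, inclusive). A cell observes a gene iff
#' its soft count is `>= cell_cutoff` (default 0.5). The summary reports
#' genes detected per class (mean +/- SD over classes) and, among detected
#' (class, gene) pairs, the percentage of that class's cells observing the
#' gene (mean +/- SD over pairs).
#'
#' @param profile data.frame from [class_profiles()].
#' @param matrices the same list of `cell_gene_matrix` objects.
#' @param class_cutoff class-mean detection cutoff (default 1.0 counts).
#' @param cell_cutoff per-cell observation cutoff (default 0.5 counts).
#' @return list with `calls` (data.frame `class, gene, detected,
#'   frac_cells_observed`) and `summary` (`genes_per_class_mean/sd`,
#'   `pct_cells_observed_mean/sd`).
#' @export
call_detections <- function(profile, matrices, class_cutoff = 1.0,
                            cell_cutoff = 0.5) {
  stopifnot(class_cutoff > 0, cell_cutoff > 0)
  calls <- profile
  calls$detected <- calls$mean >= class_cutoff
  obs <- do.call(rbind, lapply(matrices, function(m) {
    keep <- m$cell_meta$neuron_class != "unassigned"
    if (!any(keep)) return(NULL)
    v <- m$values[keep, , drop = FALSE]
    data.frame(class = rep(m$cell_meta$neuron_class[keep], ncol(v)),
               gene = rep(m$gene_names, each = nrow(v)),
               observed = as.numeric(v) >= cell_cutoff)
  }))
  frac <- rep(NA_real_, nrow(calls))
  if (!is.null(obs)) {
    key_obs <- paste(obs$class, obs$gene, sep = "\r")
    agg <- tapply(obs$observed, key_obs, mean)
    frac <- as.numeric(agg[paste(calls$class, calls$gene, sep = "\r")])
  }
  calls$frac_cells_observed <- frac
  per_class <- tapply(calls$detected, calls$class, sum)
  det <- calls[calls$detected & !is.na(calls$frac_cells_observed), ]
  list(calls = calls,
       summary = list(
         genes_per_class_mean = mean(per_class),
         genes_per_class_sd = stats::sd(per_class),
         pct_cells_observed_mean = 100 * mean(det$frac_cells_observed),
         pct_cells_observed_sd = 100 * stats::sd(det$frac_cells_observed)))
}

#' Venn overlap of detected gene-neuron pairs against a reference
#'
#' A (class, gene) pair counts as reference-detected iff its reference
#' value is `>= ref_cutoff`; the comparison runs over the intersection of
#' the two class and gene namespaces.
#'
#' @param calls the `calls` data.frame from [call_detections()].
#' @param reference data.frame `class, gene, value` (see
#'   [read_reference_profile()]).
#' @param ref_cutoff reference detection cutoff; the default accepts any
#'   positive reference expression (an "unfiltered" export).
#' @return list `both, ours_only, ref_only, n_classes, n_genes`.
#' @export
overlap_pairs <- function(calls, reference, ref_cutoff = 1e-12) {
  classes <- intersect(unique(calls$class), unique(reference$class))
  genes <- intersect(unique(calls$gene), unique(reference$gene))
  if (!length(classes) || !length(genes))
    stop("no shared class/gene namespace between calls and reference")
  ours <- calls[calls$class %in% classes & calls$gene %in% genes &
                  calls$detected, c("class", "gene")]
  refd <- reference[reference$class %in% classes &
                      reference$gene %in% genes &
                      reference$value >= ref_cutoff, c("class", "gene")]
  key <- function(df) paste(df$class, df$gene, sep = "\r")
  a <- unique(key(ours)); b <- unique(key(refd))
  list(both = length(intersect(a, b)),
       ours_only = length(setdiff(a, b)),
       ref_only = length(setdiff(b, a)),
       n_classes = length(classes), n_genes = length(genes))
}

#' Compare whole-worm totals to a bulk expression profile
#'
#' Per gene: total soft counts summed over all cells of a worm, averaged
#' across the worms in which that gene was imaged; reported with the rank
#' correlation of `log1p(total)` against `log1p(bulk)`.
#'
#' @param matrices list of `cell_gene_matrix`, one per worm.
#' @param bulk data.frame `gene, value` (one value per gene), or a
#'   `class, gene, value` reference with a single class.
#' @param method correlation method (default `"spearman"`).
#' @param use_log1p transform both sides by `log1p` before correlating
#'   (rank methods are unaffected; relevant for `"pearson"`).
#' @return list `table` (data.frame `gene, total, bulk`) and `correlation`
#'   (NA when fewer than 3 shared genes).
#' @export
bulk_comparison <- function(matrices, bulk, method = "spearman",
                            use_log1p = TRUE) {
  if (!"gene" %in% names(bulk)) stop("bulk profile needs a 'gene' column")
  totals <- do.call(rbind, lapply(matrices, function(m)
    data.frame(gene = m$gene_names, total = colSums(m$values))))
  mean_tot <- tapply(totals$total, totals$gene, mean)
  df <- data.frame(gene = names(mean_tot), total = as.numeric(mean_tot))
  df <- merge(df, bulk[c("gene", "value")], by = "gene")
  names(df)[names(df) == "value"] <- "bulk"
  corr <- if (nrow(df) < 3) NA_real_ else {
    a <- df$total; b <- df$bulk
    if (use_log1p) { a <- log1p(a); b <- log1p(b) }
    stats::cor(a, b, method = method)
  }
  list(table = df, correlation = corr)
}
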