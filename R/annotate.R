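# Mapping manually curated neuron-name coordinates onto segmented nuclei.

#' Map neuron annotations to nucleus labels
#'
#' Each annotation maps to the mask label at its rounded voxel; if that
#' voxel is background, to the nearest nonzero label within `search_radius`
#' voxels (Euclidean over z, y, x). Annotations with no label in range are
#' reported unmapped. Two annotations landing on the same label are a
#' conflict: the label is left unannotated and the conflict reported,
#' mirroring the exclusion of uncertain identifications.
#'
#' @param annotations data.frame with `neuron_name, x, y, z` (1-based
#'   pixels / slice units) as from [read_annotation_table()].
#' @param mask a `label_mask`.
#' @param search_radius fallback search radius in voxels (default 3).
#' @return data.frame `label, neuron_name` (the accepted mapping), with
#'   attributes `unmapped` (character names) and `conflicts` (data.frame
#'   `label, neuron_name`).
#' @export
map_annotations <- function(annotations, mask, search_radius = 3) {
  d <- dim(mask)
  hit <- rep(NA_integer_, nrow(annotations))
  unmapped <- character()
  for (i in seq_len(nrow(annotations))) {
    z <- round(annotations$z[i]); y <- round(annotations$y[i])
    x <- round(annotations$x[i])
    if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) {
      warning("annotation '", annotations$neuron_name[i],
              "' lies outside the volume")
      unmapped <- c(unmapped, annotations$neuron_name[i])
      next
    }
    v <- mask[z, y, x]
    if (v == 0 && search_radius > 0) {
      r <- ceiling(search_radius)
      zr <- max(1, z - r):min(d[1], z + r)
      yr <- max(1, y - r):min(d[2], y + r)
      xr <- max(1, x - r):min(d[3], x + r)
      sub <- mask[zr, yr, xr, drop = FALSE]
      nz <- which(sub > 0, arr.ind = TRUE)
      if (nrow(nz)) {
        pts <- cbind(zr[nz[, 1]], yr[nz[, 2]], xr[nz[, 3]])
        dist <- sqrt((pts[, 1] - annotations$z[i])^2 +
                       (pts[, 2] - annotations$y[i])^2 +
                       (pts[, 3] - annotations$x[i])^2)
        if (min(dist) <= search_radius)
          v <- sub[nz[which.min(dist), , drop = FALSE]]
      }
    }
    if (v == 0) unmapped <- c(unmapped, annotations$neuron_name[i])
    else hit[i] <- as.integer(v)
  }
  df <- data.frame(label = hit, neuron_name = annotations$neuron_name)
  df <- df[!is.na(df$label), , drop = FALSE]
  # conflicts are order-independent: any label hit twice is dropped outright
  dup_labels <- unique(df$label[duplicated(df$label)])
  conflicts <- df[df$label %in% dup_labels, , drop = FALSE]
  df <- df[!df$label %in% dup_labels, , drop = FALSE]
  rownames(df) <- rownames(conflicts) <- NULL
  attr(df, "unmapped") <- unmapped
  attr(df, "conflicts") <- conflicts
  df
}

#' Attach neuron classes to a cell-by-gene matrix
#'
#' Metadata-only: populates `neuron_class` for mapped labels and leaves
#' every other cell `"unassigned"`; numeric values are never altered.
#'
#' @param matrix a `cell_gene_matrix`.
#' @param mapping data.frame `label, neuron_name` from [map_annotations()].
#' @return the annotated `cell_gene_matrix`.
#' @export
attach_classes <- function(matrix, mapping) {
  stopifnot(inherits(matrix, "cell_gene_matrix"))
  idx <- match(matrix$cell_meta$label, mapping$label)
  cls <- mapping$neuron_name[idx]
  matrix$cell_meta$neuron_class <- ifelse(is.na(cls), "unassigned", cls)
  matrix
}
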