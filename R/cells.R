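# Single-cell phenotyping from segmentation feature tables: derived
# features and z-scores, kNN-graph community detection, and the four-way
# phenotype rule on PanCK / Vimentin / cell area.

.cell_features <- c("area", "major_axis", "minor_axis", "eccentricity",
                    "solidity", "extent", "orientation", "aspect_ratio",
                    "PanCK", "Vimentin")

#' Derive aspect ratio and z-scores for a cell feature table
#'
#' Adds `aspect_ratio = major_axis / minor_axis` and a `z_<feature>` column
#' for every morphological feature and marker intensity present, z-scored
#' across the whole table. Rows with a non-positive minor axis cannot have
#' an aspect ratio and are excluded (with a warning; excluded row indices
#' in the `excluded` attribute).
#'
#' @param cells Data frame with (a subset of) columns `area`, `major_axis`,
#'   `minor_axis`, `eccentricity`, `solidity`, `extent`, `orientation`,
#'   `PanCK`, `Vimentin`.
#' @param sd_type `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1).
#' @return The table with `aspect_ratio` and `z_*` columns appended.
#' @export
derive_features <- function(cells, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("major_axis", "minor_axis") %in% names(cells)))
  bad <- which(!(cells$minor_axis > 0) | cells$major_axis < cells$minor_axis)
  if (length(bad)) {
    warning(sprintf("%d cell(s) with invalid axes excluded", length(bad)),
            call. = FALSE)
    cells <- cells[-bad, , drop = FALSE]
  }
  cells$aspect_ratio <- cells$major_axis / cells$minor_axis
  feats <- intersect(.cell_features, names(cells))
  n <- nrow(cells)
  for (f in feats) {
    x <- cells[[f]]
    s <- if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else sd(x)
    cells[[paste0("z_", f)]] <- if (s > 0) (x - mean(x)) / s else x * 0
  }
  attr(cells, "excluded") <- bad
  attr(cells, "sd_type") <- sd_type
  cells
}

#' Cluster cells on a kNN graph of the z-scored feature space
#'
#' Builds a symmetrized k-nearest-neighbor graph from Euclidean distances
#' in the z-normalized feature space and partitions it by Louvain
#' modularity optimization at the given resolution. Deterministic for a
#' fixed seed.
#'
#' @param cells Data frame from [derive_features()] (its `z_*` columns are
#'   used), or a numeric matrix of features.
#' @param k_neighbors Neighbors per cell (default 15).
#' @param resolution Modularity resolution (default 0.1; low values favor
#'   few, large communities).
#' @param seed Integer seed (mandatory).
#' @return Integer cluster labels (1-based), one per row.
#' @export
cluster_cells <- function(cells, k_neighbors = 15, resolution = 0.1, seed) {
  stopifnot(!missing(seed))
  z <- if (is.matrix(cells)) cells else
    as.matrix(cells[, grep("^z_", names(cells)), drop = FALSE])
  if (!ncol(z)) stop_mechisto("no z_* feature columns; run derive_features()",
                              "mechisto_format_error")
  n <- nrow(z)
  if (n < k_neighbors + 1) {
    stop_mechisto(sprintf("need >= k_neighbors + 1 = %d cells, got %d",
                          k_neighbors + 1, n), "mechisto_format_error")
  }
  d <- as.matrix(stats::dist(z))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k_neighbors + 1)]))
  edges <- cbind(rep(seq_len(n), k_neighbors), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  labels <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  as.integer(labels)
}

#' Assign the four phenotypes to clusters
#'
#' Rule: "high"/"low" for a feature means the cluster mean z-score is
#' above/at-or-below the across-cluster median of those means. PanCK
#' decides epithelial vs non-epithelial (ties broken toward the marker
#' axis: a cluster mean exactly at the PanCK median counts as high),
#' Vimentin confirms (clusters where Vimentin agrees in direction with
#' PanCK are flagged ambiguous), and cell area splits large vs small:
#' epithelial-large, epithelial-small, stroma (non-epithelial large),
#' immune (non-epithelial small).
#'
#' @param cells Data frame with `z_PanCK`, `z_Vimentin`, `z_area` columns.
#' @param clusters Integer cluster labels, one per row.
#' @return Data frame with one row per cluster: `cluster`, mean z-scores,
#'   `phenotype`, `ambiguous` flag; plus a `cell_phenotype` attribute with
#'   the per-cell labels.
#' @export
assign_phenotypes <- function(cells, clusters) {
  stopifnot(nrow(cells) == length(clusters),
            all(c("z_PanCK", "z_Vimentin", "z_area") %in% names(cells)))
  cl <- sort(unique(clusters))
  means <- t(vapply(cl, function(k) {
    sel <- clusters == k
    c(PanCK = mean(cells$z_PanCK[sel]),
      Vimentin = mean(cells$z_Vimentin[sel]),
      area = mean(cells$z_area[sel]))
  }, numeric(3)))
  if (length(cl) == 1L) {
    hi_ck <- TRUE; hi_vim <- FALSE; hi_area <- TRUE
  } else {
    hi_ck <- means[, "PanCK"] >= median(means[, "PanCK"])
    hi_vim <- means[, "Vimentin"] > median(means[, "Vimentin"])
    hi_area <- means[, "area"] > median(means[, "area"])
  }
  phenotype <- ifelse(hi_ck,
                      ifelse(hi_area, "epithelial-large", "epithelial-small"),
                      ifelse(hi_area, "stroma", "immune"))
  out <- data.frame(cluster = cl, means, phenotype = phenotype,
                    ambiguous = hi_ck == hi_vim)
  attr(out, "cell_phenotype") <- phenotype[match(clusters, cl)]
  out
}
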