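# Unfolding heat maps, hierarchical clustering, and structure colouring.

.residue_labels <- function(matrix) {
  with(tibble::as_tibble(matrix),
       unique(sprintf("%s:%d:%s", chain, position, wt)))
}

#' Standard unfolding heat map
#'
#' Wild-type residues on the y axis in structure order, the 20 mutant
#' residues on the x axis in alphabetical order. Cells follow a diverging
#' blue-white-red scale anchored at propensity 0 (blue, fully folded),
#' 0.5 (neutral, folding-unfolding equilibrium) and 1 (red, fully
#' unfolded); each cell is annotated with its propensity to two decimals;
#' missing cells render grey.
#'
#' @param matrix An `ums_matrix`.
#' @param annotate Draw numeric annotations (default TRUE; turn off for
#'   large scans).
#' @param text_size Annotation text size.
#' @return A ggplot object.
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(6, seed = 1))
#' m <- build_propensity_matrix(estimate_ddg_toy(s), s)
#' plot_unfolding_heatmap(m)
plot_unfolding_heatmap <- function(matrix, annotate = TRUE, text_size = 2.4) {
  if (nrow(matrix) == 0) abort("Empty propensity matrix.")
  df <- tibble::as_tibble(matrix) |>
    dplyr::mutate(residue = sprintf("%s:%d:%s", .data$chain, .data$position,
                                    .data$wt))
  # structure order top-to-bottom
  df$residue <- factor(df$residue, levels = rev(unique(df$residue)))
  df$mut <- factor(df$mut, levels = amino_acids())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mut, y = .data$residue,
                                        fill = .data$u)) +
    ggplot2::geom_tile(color = "grey85") +
    unfolding_fill_scale() +
    ggplot2::labs(x = "Mutant residue", y = "Wild-type residue",
                  fill = "Unfolding\npropensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (annotate) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$u), "", sprintf("%.2f", .data$u))),
      size = text_size)
  }
  p
}

#' The diverging unfolding colour scale
#'
#' Blue at 0, neutral white at 0.5, red at 1; missing cells grey. Exposed
#' so other layers can reuse the exact anchors.
#'
#' @return A ggplot2 fill scale.
#' @export
unfolding_fill_scale <- function() {
  ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                high = "#B2182B", midpoint = 0.5,
                                limits = c(0, 1), na.value = "grey70")
}

#' @method autoplot ums_matrix
#' @export
autoplot.ums_matrix <- function(object, ...) plot_unfolding_heatmap(object, ...)

#' Hierarchically cluster the propensity matrix
#'
#' Agglomerative hierarchical clustering applied independently to the rows
#' (residue positions) and the columns (mutant residues) of the propensity
#' matrix, grouping mutations by similarity of their unfolding profiles.
#' Missing cells are imputed as 0.5 (the equilibrium value) for distance
#' computation only, with a message. Defaults are Euclidean distance with
#' complete linkage; both are recorded in the result. `stats::hclust`
#' resolves merge ties deterministically by original index order, so leaf
#' orders are reproducible.
#'
#' @param matrix An `ums_matrix` with at least 2 rows.
#' @param metric A `stats::dist` method (e.g. `"euclidean"`, `"manhattan"`).
#' @param linkage A `stats::hclust` method (e.g. `"complete"`, `"average"`).
#' @param standardize Scale each residue row to zero mean / unit variance
#'   before clustering rows (default FALSE: raw propensities are clustered).
#' @return Object of class `ums_clusters`: list with `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order` (leaf label orders), `metric`,
#'   `linkage`, `standardize`.
#' @export
cluster_matrix <- function(matrix, metric = "euclidean", linkage = "complete",
                           standardize = FALSE) {
  wide <- propensity_wide(matrix)
  m <- as.matrix(wide[, amino_acids()])
  rownames(m) <- wide$residue
  if (nrow(m) < 2) abort("Clustering needs at least 2 residue rows.")
  if (anyNA(m)) {
    inform(sprintf("Imputing %d missing cell(s) as 0.5 for clustering.",
                   sum(is.na(m))))
    m[is.na(m)] <- 0.5
  }
  ok_metric <- c("euclidean", "maximum", "manhattan", "canberra", "binary",
                 "minkowski")
  ok_linkage <- c("ward.D", "ward.D2", "single", "complete", "average",
                  "mcquitty", "median", "centroid")
  if (!metric %in% ok_metric) {
    abort(sprintf("Unknown distance metric '%s'.", metric))
  }
  if (!linkage %in% ok_linkage) {
    abort(sprintf("Unknown linkage method '%s'.", linkage))
  }
  mr <- if (standardize) t(scale(t(m))) else m
  mr[!is.finite(mr)] <- 0 # constant rows scale to NaN
  row_h <- hclust(dist(mr, method = metric), method = linkage)
  col_h <- hclust(dist(t(m), method = metric), method = linkage)
  structure(
    list(row_hclust = row_h, col_hclust = col_h,
         row_order = row_h$labels[row_h$order],
         col_order = col_h$labels[col_h$order],
         metric = metric, linkage = linkage, standardize = standardize),
    class = "ums_clusters")
}

#' @export
print.ums_clusters <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d residues x %d mutants (%s distance, %s linkage)\n",
              length(x$row_order), length(x$col_order), x$metric, x$linkage))
  invisible(x)
}

# hclust -> segment tibble for drawing a dendrogram with geom_segment
.dendrogram_segments <- function(h) {
  dd <- as.dendrogram(h)
  # walk the dendrogram collecting parent-child segments
  segs <- list()
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      return(c(x = attr(node, "x") %||% 0, h = 0))
    }
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    xs <- vapply(kids, `[[`, 0, "x")
    hs <- vapply(kids, `[[`, 0, "h")
    height <- attr(node, "height")
    # horizontal bar
    segs[[length(segs) + 1]] <<- data.frame(
      x = min(xs), xend = max(xs), y = height, yend = height)
    # vertical drops to each child
    for (i in seq_along(xs)) {
      segs[[length(segs) + 1]] <<- data.frame(
        x = xs[i], xend = xs[i], y = height, yend = hs[i])
    }
    c(x = mean(range(xs)), h = height)
  }
  # leaf x coordinates = order positions
  dd <- stats::dendrapply(dd, function(n) {
    if (stats::is.leaf(n)) {
      attr(n, "x") <- match(attr(n, "label"), h$labels[h$order])
    }
    n
  })
  walk(dd)
  dplyr::bind_rows(segs)
}

#' Clustered unfolding heat map
#'
#' The heat map with rows and columns permuted to the dendrogram leaf
#' orders of [cluster_matrix()]; with `dendrograms = TRUE` (and the
#' patchwork package available) the row and column trees are drawn in the
#' margins.
#'
#' @param matrix An `ums_matrix`.
#' @param clusters Optional precomputed `ums_clusters`; computed with
#'   defaults otherwise.
#' @param annotate,text_size Passed to the cell annotations.
#' @param dendrograms Draw marginal dendrograms (default TRUE).
#' @return A ggplot / patchwork object.
#' @export
plot_clustered_heatmap <- function(matrix, clusters = NULL, annotate = TRUE,
                                   text_size = 2.4, dendrograms = TRUE) {
  clusters <- clusters %||% cluster_matrix(matrix)
  df <- tibble::as_tibble(matrix) |>
    dplyr::mutate(residue = sprintf("%s:%d:%s", .data$chain, .data$position,
                                    .data$wt))
  df$residue <- factor(df$residue, levels = clusters$row_order)
  df$mut <- factor(df$mut, levels = clusters$col_order)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mut, y = .data$residue,
                                        fill = .data$u)) +
    ggplot2::geom_tile(color = "grey85") +
    unfolding_fill_scale() +
    ggplot2::labs(
      x = "Mutant residue (clustered)", y = "Wild-type residue (clustered)",
      fill = "Unfolding\npropensity",
      caption = sprintf("%s distance, %s linkage", clusters$metric,
                        clusters$linkage)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (annotate) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$u), "", sprintf("%.2f", .data$u))),
      size = text_size)
  }
  if (!dendrograms || !requireNamespace("patchwork", quietly = TRUE)) {
    return(p)
  }
  col_seg <- .dendrogram_segments(clusters$col_hclust)
  row_seg <- .dendrogram_segments(clusters$row_hclust)
  bare <- ggplot2::theme_void()
  top <- ggplot2::ggplot(col_seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(
      limits = c(0.5, length(clusters$col_order) + 0.5), expand = c(0, 0)) +
    bare
  side <- ggplot2::ggplot(row_seg) +
    ggplot2::geom_segment(ggplot2::aes(y = .data$x, yend = .data$xend,
                                       x = .data$y, xend = .data$yend)) +
    ggplot2::scale_y_continuous(
      limits = c(0.5, length(clusters$row_order) + 0.5), expand = c(0, 0)) +
    ggplot2::scale_x_reverse() +
    bare
  patchwork::wrap_plots(
    patchwork::plot_spacer(), top, side, p,
    widths = c(1, 5), heights = c(1, 5))
}

#' Foldability profile bar plot
#'
#' @param object An `ums_foldability` profile.
#' @param cutoff Critical cutoff drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ums_foldability
#' @export
autoplot.ums_foldability <- function(object, cutoff = 17.1, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$foldability,
                                   fill = .data$foldability)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", midpoint = 9.5,
                                  limits = c(0, 19)) +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::labs(x = "Residue position", y = "Foldability (0-19)",
                  fill = "Foldability") +
    ggplot2::theme_minimal()
}

#' Export per-residue attributes for UCSF Chimera
#'
#' Writes a Chimera `defattr`-dialect attribute file mapping each residue
#' to its foldability, so the 3D structure can be coloured from 0 (blue,
#' stable everywhere) to 19 (red, every substitution unfolds). Each data
#' line is `<TAB>:<position>.<chain><TAB><value>` with values at full
#' precision.
#'
#' @param profile An `ums_foldability` tibble.
#' @param attribute_name Attribute name declared in the header.
#' @param path Optional output file.
#' @return The attribute file text (invisibly when `path` is given).
#' @export
#' @examples
#' s <- read_structure(make_toy_structure(4, seed = 1))
#' p <- foldability_profile(build_propensity_matrix(estimate_ddg_toy(s), s))
#' cat(export_residue_attributes(p))
export_residue_attributes <- function(profile, attribute_name = "foldability",
                                      path = NULL) {
  stopifnot(is.character(attribute_name), length(attribute_name) == 1)
  header <- c(
    sprintf("attribute: %s", attribute_name),
    "match mode: 1-to-1",
    "recipient: residues")
  data_lines <- sprintf("\t:%d.%s\t%s", profile$position, profile$chain,
                        vapply(profile$foldability, format, "", digits = 15))
  text <- paste0(paste(c(header, data_lines), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", text), path)
    return(invisible(text))
  }
  text
}
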