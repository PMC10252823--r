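# Figures: SEA_B credible-interval boxes, PCA biplot, niche projections.

#' Plot Bayesian ellipse-area credible intervals
#'
#' One column of nested 50/75/95% credible boxes per community, with the
#' SEA_B median (point) and SEA_C (cross) overlaid.
#'
#' @param ellipses named list of `ellipse_estimate` objects (e.g.
#'   `results$ellipses`).
#' @return a ggplot object.
#' @export
plot_seab <- function(ellipses) {
  df <- do.call(rbind, lapply(names(ellipses), function(k) {
    e <- ellipses[[k]]
    ci <- e$credible_intervals
    data.frame(community = k, level = c(95, 75, 50),
               lower = c(ci$`95`[1], ci$`75`[1], ci$`50`[1]),
               upper = c(ci$`95`[2], ci$`75`[2], ci$`50`[2]),
               median = e$sea_b_median, sea_c = e$sea_c)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$community)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                   linewidth = factor(-.data$level)),
      colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$sea_c), shape = 4,
                        colour = "red", size = 2) +
    ggplot2::scale_linewidth_discrete(range = c(1, 4), guide = "none") +
    ggplot2::labs(y = "Standard ellipse area (per-mil squared)",
                  x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' PCA biplot of environmental variables
#'
#' Scores on the first two components with variable loading arrows.
#'
#' @param pca a `pca_result`.
#' @param groups optional factor colouring the score points.
#' @return a ggplot object.
#' @export
plot_pca_biplot <- function(pca, groups = NULL) {
  sc <- as.data.frame(pca$scores[, 1:2])
  names(sc) <- c("PC1", "PC2")
  if (!is.null(groups)) sc$group <- groups
  lo <- as.data.frame(pca$loadings[, 1:2]) * max(abs(sc[1:2])) * 0.9
  names(lo) <- c("PC1", "PC2")
  lo$variable <- rownames(pca$loadings)
  ve <- pca$variance_explained
  g <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  g <- if (is.null(groups)) g + ggplot2::geom_point() else
    g + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  g +
    ggplot2::geom_segment(data = lo,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                       yend = .data$PC2),
                          arrow = ggplot2::arrow(length =
                                                   ggplot2::unit(2, "mm")),
                          colour = "grey30") +
    ggplot2::geom_text(data = lo,
                       ggplot2::aes(label = .data$variable), size = 3,
                       vjust = -0.5) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' Pairwise projections of niche hypervolume clouds
#'
#' Scatter of the uniform clouds of two hypervolumes over all dimension
#' pairs, for a visual check of overlap.
#'
#' @param h1,h2 `hypervolume` objects.
#' @param labels length-2 labels for the two communities.
#' @return a ggplot object.
#' @export
plot_niche_projection <- function(h1, h2, labels = c("A", "B")) {
  nm <- colnames(h1$data)
  pairs <- utils::combn(seq_along(nm), 2)
  df <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    rbind(
      data.frame(x = h1$cloud[, i], y = h1$cloud[, j],
                 community = labels[1],
                 panel = paste(nm[i], "vs", nm[j])),
      data.frame(x = h2$cloud[, i], y = h2$cloud[, j],
                 community = labels[2],
                 panel = paste(nm[i], "vs", nm[j])))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$community)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

save_figures <- function(results, out_dir) {
  try_png <- function(name, plot, width = 7, height = 5) {
    tryCatch({
      grDevices::png(file.path(out_dir, name), width = width * 100,
                     height = height * 100, res = 100)
      print(plot)
      grDevices::dev.off()
    }, error = function(e) {
      warning("figure ", name, " skipped: ", conditionMessage(e),
              call. = FALSE)
      try(grDevices::dev.off(), silent = TRUE)
    })
  }
  if (length(results$ellipses)) {
    try_png("seab_intervals.png", plot_seab(results$ellipses))
  }
  if (!is.null(results$envstats)) {
    try_png("pca_biplot.png", plot_pca_biplot(results$envstats$pca))
  }
  ref <- results$config$reference_area
  if (!is.null(results$hypervolumes) && ref %in% names(results$hypervolumes)) {
    other <- setdiff(names(results$hypervolumes), ref)
    if (length(other)) {
      try_png("niche_projection.png",
              plot_niche_projection(results$hypervolumes[[other[1]]],
                                    results$hypervolumes[[ref]],
                                    labels = c(other[1], ref)))
    }
  }
  invisible()
}
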