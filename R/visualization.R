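#' Figure configuration
#'
#' Rendering parameters shared by all figure generators. Only the
#' output path is required; everything else has conventional defaults.
#' The numeric content of a figure is exposed through its manifest and
#' is invariant to the rendering-only parameters (dpi, size).
#'
#' @param output_path Where the image is written.
#' @param image_format `"png"`, `"svg"` or `"pdf"`.
#' @param dpi Raster resolution (>= 50; PNG only).
#' @param width,height Figure size in inches.
#' @param point_size Plotting character expansion.
#' @param color_tp,color_fp,color_unknown,color_reference,color_map,color_second
#'   Series colors (true positive green, false positive red, unknown
#'   grey, reference light grey, by convention).
#' @return A list of class `"figure_config"`.
#' @export
figure_config <- function(output_path,
                          image_format = c("png", "svg", "pdf"),
                          dpi = 150, width = 7, height = 7,
                          point_size = 1,
                          color_tp = "forestgreen", color_fp = "firebrick",
                          color_unknown = "grey40",
                          color_reference = "grey80",
                          color_map = "steelblue",
                          color_second = "darkorange") {
  image_format <- match.arg(image_format)
  if (!is.numeric(dpi) || dpi < 50) abort_usage("dpi must be >= 50")
  if (width <= 0 || height <= 0) abort_usage("width and height must be positive")
  structure(list(output_path = output_path, image_format = image_format,
                 dpi = dpi, width = width, height = height,
                 point_size = point_size,
                 colors = c(tp = color_tp, fp = color_fp,
                            unknown = color_unknown,
                            reference = color_reference,
                            map = color_map, second = color_second)),
            class = "figure_config")
}

open_device <- function(cfg) {
  switch(cfg$image_format,
    png = grDevices::png(cfg$output_path, width = cfg$width * cfg$dpi,
                         height = cfg$height * cfg$dpi, res = cfg$dpi),
    svg = grDevices::svg(cfg$output_path, width = cfg$width,
                         height = cfg$height),
    pdf = grDevices::pdf(cfg$output_path, width = cfg$width,
                         height = cfg$height)
  )
}

finish_figure <- function(cfg, manifest) {
  grDevices::dev.off()
  if (!file.exists(cfg$output_path) || file.size(cfg$output_path) == 0)
    abort_data("figure was not written to '%s'", cfg$output_path)
  invisible(list(path = cfg$output_path, manifest = manifest))
}

mirror_points <- function(df, series) {
  if (nrow(df) == 0)
    return(data.frame(x = integer(), y = integer(),
                      series = character(), stringsAsFactors = FALSE))
  data.frame(x = c(df$res1, df$res2), y = c(df$res2, df$res1),
             series = series, stringsAsFactors = FALSE)
}

#' Contact map scatter figure
#'
#' The classic contact map: predicted pairs as points in residue-index
#' space, mirrored across the diagonal. When a reference map (e.g. from
#' [contacts_from_structure()]) is given, the map's points are colored
#' by their match status (true positive / false positive / unknown) and
#' the reference contacts are drawn underneath in their own color. A
#' second map can be overlaid for side-by-side comparison.
#'
#' Every point plotted is recorded in the returned manifest (`x`, `y`,
#' `series`), which is the figure's testable data contract; numeric
#' assertions should run against the manifest, never against pixels.
#'
#' @param map A non-empty [contact_map()].
#' @param reference Optional reference map for status coloring.
#' @param second Optional second prediction to overlay.
#' @param cfg A [figure_config()].
#' @return Invisibly, `list(path, manifest)`.
#' @export
contact_map_figure <- function(map, reference = NULL, second = NULL,
                               cfg = figure_config(tempfile(fileext = ".png"))) {
  stopifnot(inherits(map, "contact_map"))
  if (length(map) == 0) abort_usage("cannot plot an empty contact map")
  if (!is.null(reference) && all(map$contacts$status == "unknown")) {
    resolved <- seq_len(max(c(map$contacts$res1, map$contacts$res2,
                              reference$contacts$res1,
                              reference$contacts$res2)))
    map <- match_contacts(map, reference, resolved)
  }
  parts <- list()
  if (!is.null(reference))
    parts$reference <- mirror_points(reference$contacts, "reference")
  if (!is.null(reference)) {
    st <- map$contacts$status
    lab <- c(true_positive = "tp", false_positive = "fp",
             unknown = "unknown")[st]
    for (s in unique(lab))
      parts[[s]] <- mirror_points(map$contacts[lab == s, , drop = FALSE], s)
  } else {
    parts$map <- mirror_points(map$contacts, "map")
  }
  if (!is.null(second))
    parts$second <- mirror_points(second$contacts, "second")
  manifest <- do.call(rbind, unname(parts))
  rownames(manifest) <- NULL

  lim <- c(1, max(manifest$x, manifest$y))
  open_device(cfg)
  graphics::plot(NA, xlim = lim, ylim = lim, xlab = "residue index",
                 ylab = "residue index", main = map$id, asp = 1)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  for (s in unique(manifest$series)) {
    pts <- manifest[manifest$series == s, , drop = FALSE]
    graphics::points(pts$x, pts$y, pch = 16, cex = cfg$point_size,
                     col = cfg$colors[[s]])
  }
  finish_figure(cfg, manifest)
}

#' Sequence coverage figure
#'
#' Plots the per-column depth of an alignment (number of sequences with
#' a non-gap character at each column). Horizontal guide lines at a
#' depth of 1x and 5x the alignment length are drawn when they fall
#' within the depth range, as quick depth-adequacy marks for
#' co-evolution analysis.
#'
#' @param aln A [sequence_file()] alignment.
#' @param cfg A [figure_config()].
#' @return Invisibly, `list(path, manifest)`; the manifest carries
#'   `column`, `depth` and the `guides` drawn.
#' @export
sequence_coverage_figure <- function(aln,
                                     cfg = figure_config(tempfile(fileext = ".png"))) {
  depth <- per_column_depth(aln)
  L <- length(depth)
  guides <- c(1, 5) * L
  guides <- guides[guides <= max(depth)]
  manifest <- list(column = seq_len(L), depth = depth, guides = guides)

  open_device(cfg)
  graphics::plot(seq_len(L), depth, type = "l", lwd = 2,
                 col = cfg$colors[["map"]],
                 xlab = "alignment column", ylab = "sequence depth",
                 ylim = c(0, max(depth)), main = aln$id)
  for (g in guides)
    graphics::abline(h = g, lty = 3, col = "grey50")
  finish_figure(cfg, manifest)
}

#' Stepwise precision evaluation figure
#'
#' Plots precision against the L-factor grid of an
#' [evaluate_prediction()] result. Factors at which precision is
#' undefined (no classifiable contact) appear as gaps in the curve, not
#' as zeros. The y axis is fixed to `[0, 1]`.
#'
#' @param results An `"evaluation_result"` data frame.
#' @param cfg A [figure_config()].
#' @return Invisibly, `list(path, manifest)`; the manifest carries the
#'   `(factor, precision)` pairs (`NA` marking gaps).
#' @export
precision_evaluation_figure <- function(results,
                                        cfg = figure_config(tempfile(fileext = ".png"))) {
  stopifnot(is.data.frame(results),
            all(c("factor", "precision") %in% names(results)))
  if (nrow(results) == 0) abort_usage("empty evaluation results")
  if (any(diff(results$factor) <= 0))
    abort_usage("factors must be strictly increasing")
  manifest <- data.frame(factor = results$factor,
                         precision = results$precision)

  open_device(cfg)
  graphics::plot(manifest$factor, manifest$precision, type = "b", pch = 16,
                 lwd = 2, col = cfg$colors[["map"]],
                 xlab = "L-factor (top floor(f x L) contacts)",
                 ylab = "precision", ylim = c(0, 1))
  finish_figure(cfg, manifest)
}
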