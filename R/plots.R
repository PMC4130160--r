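#' Plot fitted movement tracks over the field of view
#'
#' Draws each particle's fitted straight track at its field-of-view
#' position, exaggerated for visibility (default 50-fold), with green start
#' and red end points. The plotted displacement is the negated correcting
#' shift, i.e. the apparent particle motion.
#'
#' @param tracks list of [LinearTrack-class] objects.
#' @param coords n x 2 matrix of particle positions (pixels).
#' @param nFrames number of movie frames spanned.
#' @param exaggeration display magnification of the tracks.
#' @return a ggplot object.
#' @export
plotTracks <- function(tracks, coords, nFrames, exaggeration = 50) {
  df <- do.call(rbind, lapply(seq_along(tracks), function(p) {
    s1 <- evaluateTrack(tracks[[p]], 1)
    sF <- evaluateTrack(tracks[[p]], nFrames)
    data.frame(x0 = coords[p, 1] - exaggeration * s1[1],
               y0 = coords[p, 2] - exaggeration * s1[2],
               x1 = coords[p, 1] - exaggeration * sF[1],
               y1 = coords[p, 2] - exaggeration * sF[2])
  }))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = x0, y = y0,
                                       xend = x1, yend = y1),
                          colour = "white", linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(x = x0, y = y0),
                        colour = "green3", size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = x1, y = y1),
                        colour = "red2", size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "X (px)", y = "Y (px)",
                  title = sprintf("Fitted tracks (%gx exaggerated)",
                                  exaggeration)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.background =
                     ggplot2::element_rect(fill = "grey25"))
}

#' Plot per-frame damage parameters and relative weights
#'
#' Two-panel figure: fitted relative B-factors and intercepts per movie
#' frame, and the stacked per-shell relative weights against frequency.
#'
#' @param models list of [FrameDamageModel-class], one per frame.
#' @param weights a [FrameWeightTable-class].
#' @return a list of two ggplot objects (`params`, `weights`).
#' @export
plotFrameWeights <- function(models, weights) {
  pd <- data.frame(
    frame = vapply(models, function(m) m@frame, integer(1)),
    value = c(vapply(models, bFactor, numeric(1)),
              vapply(models, cIntercept, numeric(1))),
    what = rep(c("relative B-factor (A^2)", "intercept C"),
               each = length(models)))
  p1 <- ggplot2::ggplot(pd, ggplot2::aes(x = frame, y = value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "movie frame", y = NULL) +
    ggplot2::theme_minimal()
  W <- weightMatrix(weights)
  wd <- data.frame(
    nu = rep(shellFrequencies(weights), each = nrow(W)),
    frame = factor(rep(seq_len(nrow(W)), ncol(W))),
    w = as.vector(W))
  p2 <- ggplot2::ggplot(wd, ggplot2::aes(x = nu, y = w,
                                         fill = frame)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "frequency (1/A)", y = "relative weight") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  list(params = p1, weights = p2)
}

utils::globalVariables(c("x0", "y0", "x1", "y1", "frame", "value", "what",
                         "nu", "w"))
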