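#' Dose color map
#'
#' One color per dose, ordered with dose; the same map is used by the band
#' plot and the pie-chart matrix so colors are comparable across displays.
#'
#' @param m number of doses.
#' @return character vector of m colors.
#' @export
fraDoseColors <- function(m) {
    grDevices::hcl.colors(max(m, 2L), palette = "Zissou 1")[seq_len(m)]
}

#' Dose positions on a plotting axis
#'
#' log10 positions with a zero dose (the unstimulated control) placed one
#' decade below the smallest nonzero dose and labeled "0"; log10(0) is
#' undefined but the control must remain visible.
#'
#' @param doses numeric dose values.
#' @param mode \code{"log10"} or \code{"linear"}.
#' @param zeroOffsetDecades decades below the smallest nonzero dose at which
#'   a zero dose is drawn.
#' @return numeric axis positions.
#' @export
dosePositions <- function(doses, mode = c("log10", "linear"),
                          zeroOffsetDecades = 1) {
    mode <- match.arg(mode)
    if (mode == "linear") return(doses)
    pos <- log10(doses)
    if (any(doses == 0)) {
        nz <- doses[doses > 0]
        if (length(nz) == 0L) return(seq_along(doses))  # all-zero pathological
        pos[doses == 0] <- log10(min(nz)) - zeroOffsetDecades
    }
    pos
}

#' Band layout for the FRC heterogeneity plot
#'
#' Pure geometry for the band display: at each reference dose i, the
#' off-diagonal typical fractions v[i, j] become bands around the curve
#' point (dose_i, r_i) — fractions for doses j > i stacked above the curve
#' (outward in increasing j), fractions for j < i below (outward in
#' decreasing j). Band thickness is v[i, j] in curve units and the band
#' color is the color of dose j. Total thickness above plus below at dose i
#' is 1 - v[i, i].
#'
#' Returned as a data.frame of vertical extents per (reference dose, typical
#' dose) so tests can assert on geometry without parsing images; the plot
#' function interpolates these extents linearly between doses to draw
#' ribbons.
#'
#' @param frc an \linkS4class{FRCResult} carrying a heterogeneity matrix.
#' @return data.frame with columns \code{doseIndex}, \code{typicalDose},
#'   \code{side} ("above"/"below"), \code{ymin}, \code{ymax},
#'   \code{thickness}.
#' @export
frcBandLayout <- function(frc) {
    stopifnot(is(frc, "FRCResult"))
    v <- fractionValues(heterogeneity(frc))
    m <- nrow(v)
    r <- frc@values
    out <- list()
    for (i in seq_len(m)) {
        top <- r[i]
        for (j in seq_len(m)[-i][seq_len(m)[-i] > i]) {
            out[[length(out) + 1L]] <- data.frame(
                doseIndex = i, typicalDose = j, side = "above",
                ymin = top, ymax = top + v[i, j], thickness = v[i, j])
            top <- top + v[i, j]
        }
        bot <- r[i]
        for (j in rev(seq_len(i - 1L))) {
            out[[length(out) + 1L]] <- data.frame(
                doseIndex = i, typicalDose = j, side = "below",
                ymin = bot - v[i, j], ymax = bot, thickness = v[i, j])
            bot <- bot - v[i, j]
        }
    }
    if (length(out) == 0L)
        return(data.frame(doseIndex = integer(0), typicalDose = integer(0),
                          side = character(0), ymin = numeric(0),
                          ymax = numeric(0), thickness = numeric(0)))
    do.call(rbind, out)
}

#' Wedge layout for the pie-chart heterogeneity matrix
#'
#' Pure geometry for the pie display: one pie per stimulation dose (row of
#' the typical-fraction matrix), wedge angles proportional to v[i, j],
#' starting at 12 o'clock and proceeding clockwise in dose order. Wedge
#' angles in each pie sum to 360 degrees.
#'
#' @param v a \linkS4class{TypicalFractionMatrix}.
#' @return data.frame with columns \code{row}, \code{typicalDose},
#'   \code{start}, \code{end}, \code{angle} (degrees).
#' @export
pieWedgeLayout <- function(v) {
    stopifnot(is(v, "TypicalFractionMatrix"))
    vals <- fractionValues(v)
    m <- nrow(vals)
    out <- do.call(rbind, lapply(seq_len(m), function(i) {
        ang <- 360 * vals[i, ]
        end <- cumsum(ang)
        data.frame(row = i, typicalDose = seq_len(m),
                   start = c(0, end[-m]), end = end, angle = ang)
    }))
    rownames(out) <- NULL
    out
}

.openDevice <- function(file, width, height) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
        png = grDevices::png(file, width = width, height = height,
                             units = "in", res = 150),
        svg = grDevices::svg(file, width = width, height = height),
        pdf = grDevices::pdf(file, width = width, height = height),
        stop("unsupported image format '", ext, "'; use png, svg, or pdf"))
}

#' Plot the FRC with cell-to-cell heterogeneity bands
#'
#' The signature display of fractional response analysis: the FRC as a black
#' curve over (log) dose, surrounded by colored bands whose thickness at
#' each reference dose equals the fraction of that dose's cells with
#' responses typical for other doses — doses higher than the reference above
#' the curve, lower below, colored by the dose they refer to. If the result
#' carries bootstrap bands, the r quantile envelope is drawn as dashed
#' lines. Optionally a mean-response curve is overlaid on a secondary axis.
#'
#' @param frc an \linkS4class{FRCResult}.
#' @param file output image path (extension selects png/svg/pdf); \code{NULL}
#'   draws on the current device.
#' @param colors one color per dose; default \code{\link{fraDoseColors}}.
#' @param doseAxis \code{"log10"} (zero dose drawn one decade below the
#'   smallest nonzero dose) or \code{"linear"}.
#' @param meanOverlay optional numeric vector (one mean response per dose)
#'   drawn in red against a right-hand axis.
#' @param width,height device size in inches.
#' @return the band layout data.frame, invisibly.
#' @export
plotFRC <- function(frc, file = NULL, colors = NULL,
                    doseAxis = c("log10", "linear"), meanOverlay = NULL,
                    width = 6, height = 4.5) {
    doseAxis <- match.arg(doseAxis)
    m <- length(frc@doseLevels)
    if (is.null(colors)) colors <- fraDoseColors(m)
    if (length(colors) < m) stop("need at least ", m, " colors")
    if (!is.null(file)) {
        .openDevice(file, width, height)
        on.exit(grDevices::dev.off())
    }
    xs <- dosePositions(frc@doseLevels, doseAxis)
    lay <- frcBandLayout(frc)
    ylim <- range(1 - 0.05, frc@values + 0.05,
                  if (nrow(lay)) c(lay$ymin, lay$ymax))
    graphics::plot(NA, xlim = range(xs), ylim = ylim, xaxt = "n",
                   xlab = if (doseAxis == "log10") "dose (log10)" else
                       "dose",
                   ylab = "fractional response, r",
                   main = "Fractional response curve")
    graphics::axis(1, at = xs, labels = format(frc@doseLevels, trim = TRUE))
    # ribbons: linear interpolation of per-dose band extents; a band for
    # typical dose j has zero thickness at reference doses where j is not
    # on that side, so ribbons taper naturally
    if (nrow(lay)) {
        for (j in seq_len(m)) {
            for (side in c("above", "below")) {
                lo <- hi <- rep(NA_real_, m)
                sel <- lay$typicalDose == j & lay$side == side
                if (!any(sel)) next
                lo[lay$doseIndex[sel]] <- lay$ymin[sel]
                hi[lay$doseIndex[sel]] <- lay$ymax[sel]
                at <- which(!is.na(lo))
                closed <- if (side == "above") frc@values else frc@values
                lo[-at] <- closed[-at]; hi[-at] <- closed[-at]
                keep <- seq(max(1L, min(at) - 1L), min(m, max(at) + 1L))
                graphics::polygon(c(xs[keep], rev(xs[keep])),
                                  c(lo[keep], rev(hi[keep])),
                                  col = grDevices::adjustcolor(colors[j],
                                                               0.6),
                                  border = NA)
            }
        }
    }
    if (length(frc@bands)) {
        graphics::lines(xs, frc@bands$frcLower, lty = 2)
        graphics::lines(xs, frc@bands$frcUpper, lty = 2)
    }
    graphics::lines(xs, frc@values, lwd = 2)
    graphics::points(xs, frc@values, pch = 16)
    if (!is.null(meanOverlay)) {
        stopifnot(length(meanOverlay) == m)
        usr <- graphics::par("usr")
        scaled <- usr[3] + (meanOverlay - min(meanOverlay)) /
            diff(range(meanOverlay)) * (usr[4] - usr[3])
        graphics::lines(xs, scaled, col = "red", lwd = 2)
        graphics::axis(4, at = pretty(scaled),
                       labels = signif(min(meanOverlay) +
                           (pretty(scaled) - usr[3]) /
                           (usr[4] - usr[3]) * diff(range(meanOverlay)), 3),
                       col.axis = "red")
    }
    invisible(lay)
}

#' Plot the typical-fraction matrix as pie charts
#'
#' One pie per stimulation dose: wedge angles proportional to the fractions
#' of that dose's cells typical for each dose, wedge colors keyed to doses
#' with the same map as \code{\link{plotFRC}}.
#'
#' @param v a \linkS4class{TypicalFractionMatrix}.
#' @param file output image path or \code{NULL} for the current device.
#' @param colors one color per dose.
#' @param width,height device size in inches.
#' @return the wedge layout data.frame, invisibly.
#' @export
plotHeterogeneityPies <- function(v, file = NULL, colors = NULL,
                                  width = 7, height = 2.2) {
    m <- nrow(fractionValues(v))
    if (is.null(colors)) colors <- fraDoseColors(m)
    if (length(colors) < m) stop("need at least ", m, " colors")
    if (!is.null(file)) {
        .openDevice(file, width, height)
        on.exit(grDevices::dev.off())
    }
    lay <- pieWedgeLayout(v)
    op <- graphics::par(mfrow = c(1, m), mar = c(0.5, 0.5, 2, 0.5))
    # restore par before any dev.off() handler so no null device is opened
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    lab <- rownames(fractionValues(v))
    for (i in seq_len(m)) {
        graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
                       asp = 1, axes = FALSE, xlab = "", ylab = "",
                       main = paste("dose", lab[i]))
        rows <- lay[lay$row == i & lay$angle > 0, ]
        for (k in seq_len(nrow(rows))) {
            # start at 12 o'clock, clockwise
            th <- seq(90 - rows$start[k], 90 - rows$end[k],
                      length.out = max(8L, ceiling(rows$angle[k]))) *
                pi / 180
            graphics::polygon(c(0, cos(th), 0), c(0, sin(th), 0),
                              col = colors[rows$typicalDose[k]],
                              border = "white")
        }
    }
    invisible(lay)
}

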