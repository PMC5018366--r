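#' @import ggplot2
#' @importFrom grDevices png pdf dev.off hcl.colors
#' @importFrom graphics persp
NULL

#' Available plot kinds
#'
#' The closed set of figure kinds understood by [renderPlots()]: the
#' single-agent fit panel, then matrix / contour / 3-D surface views of the
#' combination data, the model reference and the synergy distribution, plus
#' the synergy-mapped response surface.
#'
#' @format Character vector.
#' @export
PLOT_KINDS <- c(
  "single_agent_fit",
  "combination_matrix", "combination_contour", "combination_surface",
  "reference_matrix", "reference_contour", "reference_surface",
  "synergy_matrix", "synergy_contour", "synergy_surface",
  "synergy_mapped_surface"
)

.tileData <- function(dosesA, dosesB, values) {
  data.frame(
    ai = rep(seq_along(dosesA), each = length(dosesB)),
    bi = rep(seq_along(dosesB), times = length(dosesA)),
    doseA = rep(dosesA, each = length(dosesB)),
    doseB = rep(dosesB, times = length(dosesA)),
    value = as.numeric(values)
  )
}

.surfaceData <- function(x) {
  if (is(x, "CombinationExperiment")) {
    list(
      d = .tileData(dosesA(x), dosesB(x), meanResponse(x)),
      fill = "response", diverging = FALSE,
      title = sprintf("Combination response: %s", experimentName(x))
    )
  } else if (is(x, "ReferenceSurface")) {
    list(
      d = .tileData(dosesA(x), dosesB(x), surfaceValues(x)),
      fill = "response", diverging = FALSE,
      title = sprintf("%s reference surface", modelName(x))
    )
  } else if (is(x, "SynergyDistribution")) {
    list(
      d = .tileData(dosesA(x), dosesB(x), surfaceValues(x)),
      fill = "synergy", diverging = TRUE,
      title = sprintf("Synergy distribution (%s)", modelName(x))
    )
  } else {
    stop("cannot plot objects of class ", class(x)[1])
  }
}

# symmetric fill limits so synergy and antagonism are visually comparable
.symLimits <- function(v) {
  m <- max(abs(v))
  if (m == 0) m <- 1
  c(-m, m)
}

.doseAxes <- function(dosesA, dosesB, agents = c(a = "Drug A", b = "Drug B")) {
  list(
    scale_x_continuous(
      breaks = seq_along(dosesA), labels = format(dosesA, digits = 3),
      expand = c(0, 0)
    ),
    scale_y_continuous(
      breaks = seq_along(dosesB), labels = format(dosesB, digits = 3),
      expand = c(0, 0)
    ),
    labs(x = paste(agents["a"], "dose"), y = paste(agents["b"], "dose"))
  )
}

#' Heatmap of a response or synergy matrix
#'
#' Dose axes are drawn as categorical ticks labeled with the
#' concentrations (checkerboard grids are rarely uniform in log dose).
#' Synergy distributions use a diverging palette centered at zero with
#' symmetric limits (`max |value|` on both sides); response surfaces a
#' sequential palette on \[0, max\].
#'
#' @param x a [CombinationExperiment-class] (mean response),
#'   [ReferenceSurface-class] or [SynergyDistribution-class].
#' @param agents axis label names, `c(a = ..., b = ...)`.
#' @return A `ggplot` object.
#' @export
plotSurfaceMatrix <- function(x, agents = c(a = "Drug A", b = "Drug B")) {
  if (is(x, "CombinationExperiment")) agents <- agentNames(x)
  s <- .surfaceData(x)
  p <- ggplot(s$d, aes(x = .data$ai, y = .data$bi, fill = .data$value)) +
    geom_tile() +
    .doseAxes(unique(s$d$doseA), unique(s$d$doseB), agents) +
    ggtitle(s$title) +
    theme_minimal()
  if (s$diverging) {
    p + scale_fill_gradient2(
      name = "synergy\n(% points)",
      low = "#2166AC", mid = "#FFFFFF", high = "#B2182B",
      midpoint = 0, limits = .symLimits(s$d$value)
    )
  } else {
    p + scale_fill_viridis_c(name = "% control", limits = c(
      min(0, min(s$d$value)), max(100, max(s$d$value))
    ))
  }
}

#' Contour plot of a response or synergy matrix
#'
#' Same data and color conventions as [plotSurfaceMatrix()], drawn as filled
#' contours over the dose-index grid.
#'
#' @inheritParams plotSurfaceMatrix
#' @return A `ggplot` object.
#' @export
plotSurfaceContour <- function(x, agents = c(a = "Drug A", b = "Drug B")) {
  if (is(x, "CombinationExperiment")) agents <- agentNames(x)
  s <- .surfaceData(x)
  p <- ggplot(s$d, aes(x = .data$ai, y = .data$bi, z = .data$value)) +
    geom_contour_filled(bins = 12) +
    geom_contour(colour = "grey30", bins = 12, linewidth = 0.2) +
    .doseAxes(unique(s$d$doseA), unique(s$d$doseB), agents) +
    ggtitle(s$title) +
    theme_minimal()
  p
}

#' Single-agent dose-response data and fits
#'
#' Replicate points and the fitted Hill curves for both agents, on a log
#' dose axis with the zero-dose controls shown at a pseudo-dose one decade
#' below the lowest tested concentration.
#'
#' @param exp a [CombinationExperiment-class].
#' @param curves list with [HillCurve-class] elements `a` and `b`, e.g. from
#'   [fitSingleAgents()].
#' @return A `ggplot` object faceted by agent.
#' @export
plotSingleAgentFit <- function(exp, curves) {
  s <- extractSingleAgents(exp)
  nm <- agentNames(exp)
  pseudo <- function(d) {
    d0 <- min(d[d > 0]) / 10
    ifelse(d == 0, d0, d)
  }
  pts <- rbind(
    data.frame(
      agent = unname(nm["a"]), dose = rep(pseudo(s$a$doses),
        each = nrow(s$a$replicateResponses)
      ),
      response = as.numeric(s$a$replicateResponses)
    ),
    data.frame(
      agent = unname(nm["b"]), dose = rep(pseudo(s$b$doses),
        each = nrow(s$b$replicateResponses)
      ),
      response = as.numeric(s$b$replicateResponses)
    )
  )
  curveFrame <- function(curve, doses, agent) {
    dd <- exp(seq(log(min(doses[doses > 0]) / 10), log(max(doses)),
      length.out = 200
    ))
    data.frame(
      agent = unname(agent), dose = dd,
      response = hillResponse(curve, dd)
    )
  }
  lines <- rbind(
    curveFrame(curves$a, s$a$doses, nm["a"]),
    curveFrame(curves$b, s$b$doses, nm["b"])
  )
  ggplot(pts, aes(x = .data$dose, y = .data$response)) +
    geom_point(alpha = 0.7) +
    geom_line(data = lines, colour = "#B2182B") +
    scale_x_log10() +
    facet_wrap(~agent, scales = "free_x") +
    labs(x = "dose", y = "response (% control)") +
    ggtitle(sprintf("Single-agent fits: %s", experimentName(exp))) +
    theme_minimal()
}

# 3-D perspective surface; facet colors either encode height (sequential)
# or an overlay matrix on a zero-centered diverging scale.
.drawSurface3D <- function(dosesA, dosesB, values, overlay = NULL,
                           main = "", zlab = "% control") {
  z <- t(values) # persp: x = rows, so transpose to put drug A on x
  nx <- nrow(z)
  ny <- ncol(z)
  facet <- (z[-1, -1] + z[-nx, -1] + z[-1, -ny] + z[-nx, -ny]) / 4
  if (is.null(overlay)) {
    pal <- hcl.colors(64, "viridis")
    idx <- cut(facet, breaks = seq(min(facet), max(facet),
      length.out = 65
    ), include.lowest = TRUE, labels = FALSE)
  } else {
    ov <- t(overlay)
    facet <- (ov[-1, -1] + ov[-nx, -1] + ov[-1, -ny] + ov[-nx, -ny]) / 4
    pal <- hcl.colors(64, "Blue-Red 2")
    lim <- .symLimits(facet)
    idx <- cut(facet, breaks = seq(lim[1], lim[2], length.out = 65),
      include.lowest = TRUE, labels = FALSE
    )
  }
  persp(seq_len(nx), seq_len(ny), z,
    col = pal[idx], theta = 35, phi = 25,
    xlab = "drug A (dose rank)", ylab = "drug B (dose rank)", zlab = zlab,
    main = main, ticktype = "simple", border = "grey30"
  )
}

#' Render publication figure files for one experiment
#'
#' Writes one PNG or PDF per requested plot kind (and per model for the
#' model-dependent kinds), with deterministic names
#' `<experiment>_<model>_<kind>.<ext>` (model omitted for the single-agent
#' and combination kinds, which do not depend on it). Available kinds:
#' `single_agent_fit`; matrix/contour/surface views of the combination
#' data, each reference surface and each synergy distribution; and
#' `synergy_mapped_surface`, the dose-response surface colored by synergy
#' so hotspots are read directly off the response landscape.
#'
#' @param exp a [CombinationExperiment-class].
#' @param curves fitted curves, as from [fitSingleAgents()].
#' @param refs named list of [ReferenceSurface-class] per model.
#' @param dists named list of [SynergyDistribution-class] per model.
#' @param kinds subset of `PLOT_KINDS` (default: all).
#' @param outDir output directory (created if needed).
#' @param format `"png"` or `"pdf"`.
#' @param dpi resolution for PNG output.
#' @param width,height device size in inches.
#' @return Character vector of the files written.
#' @export
renderPlots <- function(exp, curves, refs, dists, kinds = PLOT_KINDS,
                        outDir = ".", format = c("png", "pdf"), dpi = 150,
                        width = 6, height = 5) {
  format <- match.arg(format)
  unknown <- setdiff(kinds, PLOT_KINDS)
  if (length(unknown)) {
    stop("unknown plot kind(s): ", paste(unknown, collapse = ", "))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  name <- experimentName(exp)
  files <- character(0)

  open <- function(path) {
    if (format == "png") {
      png(path, width = width, height = height, units = "in", res = dpi)
    } else {
      pdf(path, width = width, height = height)
    }
  }
  emit <- function(fname, drawFun) {
    path <- file.path(outDir, fname)
    open(path)
    tryCatch(drawFun(), finally = dev.off())
    files <<- c(files, path)
  }
  ggEmit <- function(fname, p) emit(fname, function() print(p))

  for (kind in kinds) {
    if (kind == "single_agent_fit") {
      ggEmit(
        sprintf("%s_%s.%s", name, kind, format),
        plotSingleAgentFit(exp, curves)
      )
    } else if (kind == "combination_matrix") {
      ggEmit(sprintf("%s_%s.%s", name, kind, format), plotSurfaceMatrix(exp))
    } else if (kind == "combination_contour") {
      ggEmit(sprintf("%s_%s.%s", name, kind, format), plotSurfaceContour(exp))
    } else if (kind == "combination_surface") {
      emit(sprintf("%s_%s.%s", name, kind, format), function() {
        .drawSurface3D(dosesA(exp), dosesB(exp), meanResponse(exp),
          main = sprintf("Combination response: %s", name)
        )
      })
    } else if (kind %in% c("reference_matrix", "reference_contour",
      "reference_surface")) {
      for (m in names(refs)) {
        fname <- sprintf("%s_%s_%s.%s", name, m, kind, format)
        if (kind == "reference_matrix") {
          ggEmit(fname, plotSurfaceMatrix(refs[[m]], agentNames(exp)))
        } else if (kind == "reference_contour") {
          ggEmit(fname, plotSurfaceContour(refs[[m]], agentNames(exp)))
        } else {
          local({
            mm <- m
            emit(fname, function() {
              .drawSurface3D(dosesA(exp), dosesB(exp),
                surfaceValues(refs[[mm]]),
                main = sprintf("%s reference", mm)
              )
            })
          })
        }
      }
    } else {
      for (m in names(dists)) {
        fname <- sprintf("%s_%s_%s.%s", name, m, kind, format)
        if (kind == "synergy_matrix") {
          ggEmit(fname, plotSurfaceMatrix(dists[[m]], agentNames(exp)))
        } else if (kind == "synergy_contour") {
          ggEmit(fname, plotSurfaceContour(dists[[m]], agentNames(exp)))
        } else if (kind == "synergy_surface") {
          local({
            mm <- m
            emit(fname, function() {
              .drawSurface3D(dosesA(exp), dosesB(exp),
                surfaceValues(dists[[mm]]),
                main = sprintf("Synergy (%s)", mm), zlab = "synergy (% points)"
              )
            })
          })
        } else { # synergy_mapped_surface
          local({
            mm <- m
            emit(fname, function() {
              .drawSurface3D(dosesA(exp), dosesB(exp), meanResponse(exp),
                overlay = surfaceValues(dists[[mm]]),
                main = sprintf("Response surface mapped with synergy (%s)", mm)
              )
            })
          })
        }
      }
    }
  }
  files
}
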