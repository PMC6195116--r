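#' Color schemes for Ramachandran-number maps
#'
#' Builds a continuous color scheme over a display range.  Two schemes are
#' tailored to the structural meaning of the Ramachandran number:
#' \describe{
#'   \item{`"SecondaryStructure"`}{potential alpha-helices (R near 0.34)
#'     red, beta-sheets (near 0.52) blue, ppII helices (near 0.60) cyan, on
#'     a white background.}
#'   \item{`"Chirality"`}{right-twisting backbones (R below 0.5) in reds,
#'     left-twisting (above 0.5) in blues, white at the achiral midpoint.}
#' }
#' Any palette name known to [grDevices::hcl.colors()] (e.g. `"Greys"`) is
#' also accepted.  Anchor stops of the built-in schemes can be overridden
#' via `stops`.
#'
#' @param name Scheme name: `"SecondaryStructure"`, `"Chirality"`, or an
#'   `hcl.colors` palette name.
#' @param vmin,vmax Display range mapped onto the scheme (defaults 0 and 1;
#'   use -1, 1 for signed maps).
#' @param stops Optional override: a data.frame with columns `pos` (strictly
#'   increasing, on the normalized \[0, 1\] scale of the display range) and
#'   `col` (colors understood by [grDevices::col2rgb()]).
#'
#' @return An object of class `"color_scheme"`.
#'
#' @examples
#' colormap_value(0.34, color_scheme("SecondaryStructure"))  # red-dominant
#' colormap_value(0.52, color_scheme("SecondaryStructure"))  # blue-dominant
#'
#' @export
color_scheme <- function(name = "SecondaryStructure", vmin = 0, vmax = 1,
                         stops = NULL) {
  stopifnot(is.character(name), length(name) == 1L, vmax > vmin)
  if (is.null(stops)) {
    stops <- switch(name,
      Chirality = data.frame(
        pos = c(0, 0.5, 1),
        col = c("#8B0000", "#FFFFFF", "#00008B")),
      SecondaryStructure = data.frame(
        pos = c(0, 0.34, 0.45, 0.52, 0.60, 1),
        col = c("#FFFFFF", "#FF0000", "#FFFFFF", "#0000FF", "#00FFFF",
                "#FFFFFF")),
      Greys = data.frame(pos = c(0, 1), col = c("#FFFFFF", "#000000")),
      {
        if (!name %in% grDevices::hcl.pals())
          stop(sprintf("unknown color scheme '%s'", name))
        cols <- grDevices::hcl.colors(64L, name)
        data.frame(pos = seq(0, 1, length.out = 64L), col = cols)
      })
  }
  stopifnot(is.data.frame(stops), all(c("pos", "col") %in% names(stops)),
            all(diff(stops$pos) > 0), min(stops$pos) >= 0, max(stops$pos) <= 1)
  structure(list(name = name, stops = stops, vmin = vmin, vmax = vmax),
            class = "color_scheme")
}

#' Map values to colors under a scheme
#'
#' Linearly interpolates each value between the scheme's anchor stops.
#' Values outside `[vmin, vmax]` are clamped with a warning; `NA` maps to
#' `NA` (rendered as background).
#'
#' @param r Numeric vector of Ramachandran numbers (or deviations, signed
#'   values, ...).
#' @param scheme A [color_scheme()].
#'
#' @return A matrix with one row per value and columns `red`, `green`,
#'   `blue` in \[0, 1\].  Use [scheme_colors()] for hex strings.
#'
#' @export
colormap_value <- function(r, scheme) {
  stopifnot(inherits(scheme, "color_scheme"))
  r <- as.numeric(r)
  out_of_range <- !is.na(r) & (r < scheme$vmin | r > scheme$vmax)
  if (any(out_of_range))
    warning(sprintf("%d value(s) outside [%g, %g] clamped to the display range",
                    sum(out_of_range), scheme$vmin, scheme$vmax))
  x <- (pmin(pmax(r, scheme$vmin), scheme$vmax) - scheme$vmin) /
    (scheme$vmax - scheme$vmin)
  anchors <- t(grDevices::col2rgb(scheme$stops$col)) / 255
  rgb <- vapply(c("red", "green", "blue"), function(ch) {
    stats::approx(scheme$stops$pos, anchors[, ch], xout = x, rule = 2)$y
  }, numeric(length(x)))
  rgb <- matrix(rgb, ncol = 3L, dimnames = list(NULL, c("red", "green", "blue")))
  rgb[is.na(r), ] <- NA_real_
  rgb
}

#' @rdname colormap_value
#' @param n Number of colors when sampling the scheme into a palette.
#' @return `scheme_colors()` returns a character vector of hex colors
#'   sampling the scheme evenly over its display range.
#' @export
scheme_colors <- function(scheme, n = 256L) {
  v <- seq(scheme$vmin, scheme$vmax, length.out = n)
  m <- colormap_value(v, scheme)
  grDevices::rgb(m[, 1L], m[, 2L], m[, 3L])
}

#' Draw a map product to an image file
#'
#' Renders a residue map, deviation map or histogram series as a heatmap:
#' models (frames) on the horizontal axis, residues or the R axis vertical,
#' cells colored through the scheme, undefined cells left as background.  A
#' CSV sidecar with the exact matrix is always written next to the image
#' (same path, `.csv` extension), so the figure can be re-rendered without
#' re-parsing the PDB.
#'
#' @param map A `"residue_map"`, `"histogram_series"` or
#'   `"conditioned_stack"` matrix.
#' @param scheme A [color_scheme()]; defaults to `"SecondaryStructure"` for
#'   residue maps and `"Greys"` for histogram products.
#' @param out Output image path; the extension selects the format (`.png`
#'   or `.svg`).
#' @param xlabel,ylabel,title Axis and title texts; sensible defaults are
#'   derived from the map type.
#' @param width,height Image size in pixels (png) or inches (svg).
#'
#' @return Invisibly, a character vector with the image and CSV paths.
#'
#' @export
draw_map <- function(map, scheme = NULL, out,
                     xlabel = "Frame #", ylabel = NULL, title = NULL,
                     width = NULL, height = NULL) {
  stopifnot(is.matrix(map), nrow(map) > 0L, ncol(map) > 0L)
  is_hist <- inherits(map, "histogram_series") ||
    inherits(map, "conditioned_stack")
  if (is.null(scheme)) {
    vmax <- if (is_hist) max(map, 1e-12, na.rm = TRUE) else 1
    scheme <- if (is_hist) color_scheme("Greys", vmin = 0, vmax = vmax)
      else color_scheme("SecondaryStructure")
  }
  if (is.null(ylabel))
    ylabel <- if (inherits(map, "histogram_series")) "R"
      else if (inherits(map, "conditioned_stack")) "condition"
      else "Residue #"
  if (is.null(title)) {
    what <- attr(map, "what")
    title <- if (is.null(what)) "" else what
    chain <- attr(map, "chain")
    if (!is.null(chain)) title <- sprintf("%s (chain '%s')", title, chain)
  }

  fmt <- tolower(tools::file_ext(out))
  if (!fmt %in% c("png", "svg"))
    stop("`out` must end in .png or .svg")
  csv <- sub(sprintf("\\.%s$", fmt), ".csv", out)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)

  # columns = models -> x axis; rows (residues / bins) -> y axis
  z <- t(unclass(map))
  if (fmt == "png") {
    if (is.null(width)) width <- max(480L, 60L + 8L * nrow(z))
    if (is.null(height)) height <- max(360L, 60L + 8L * ncol(z))
    grDevices::png(out, width = width, height = height, type = "cairo")
  } else {
    if (is.null(width)) width <- 7
    if (is.null(height)) height <- 5
    grDevices::svg(out, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(4.5, 4.5, 2.5, 1))
  on.exit(graphics::par(op), add = TRUE)

  if (inherits(map, "histogram_series")) {
    edges <- attr(map, "bin_edges")
    ymid <- (edges[-1L] + edges[-length(edges)]) / 2
    graphics::image(x = seq_len(nrow(z)), y = ymid, z = z,
                    col = scheme_colors(scheme),
                    zlim = c(scheme$vmin, scheme$vmax),
                    xlab = xlabel, ylab = ylabel, main = title, axes = FALSE,
                    useRaster = FALSE)
    graphics::axis(1, at = pretty(seq_len(nrow(z))))
    graphics::axis(2, at = seq(min(edges), max(edges), by = 0.2))
  } else {
    graphics::image(x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z,
                    col = scheme_colors(scheme),
                    zlim = c(scheme$vmin, scheme$vmax),
                    xlab = xlabel, ylab = ylabel, main = title, axes = FALSE,
                    useRaster = FALSE)
    graphics::axis(1, at = pretty(seq_len(nrow(z))))
    yat <- pretty(seq_len(ncol(z)))
    yat <- yat[yat >= 1 & yat <= ncol(z)]
    graphics::axis(2, at = yat, labels = colnames(z)[yat])
  }
  graphics::box()
  write_map_csv(map, csv)
  invisible(c(image = out, csv = csv))
}
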