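#' One-command multi-angle picture workflow
#'
#' Runs the full analysis the command-line tool exposes: for every PDB file
#' (a single file or every `*.pdb` in a directory) and every chain in it,
#' writes the five-panel product set as image plus CSV sidecar:
#' \enumerate{
#'   \item per-model Ramachandran-number histogram series,
#'   \item per-residue map in the `"Chirality"` scheme,
#'   \item per-residue map in the `"SecondaryStructure"` scheme,
#'   \item deviation-from-first-frame (D1) map,
#'   \item deviation-from-previous-frame (D-1) map.
#' }
#' With `signed = TRUE` the signed Ramachandran number replaces the
#' unsigned one throughout (maps span -1..1 and histograms bin over
#' \[-1, 1\]).  Output files are named `<pdbstem>.<chain>.<product>.<ext>`.
#' Files are processed independently — no pooling across files or chains.
#'
#' @param pdb Path to a PDB file or a directory of `.pdb` files.
#' @param out_dir Output directory (created if needed; default `"."`).
#' @param signed Use signed Ramachandran numbers throughout.
#' @param cmap Colormap for the histogram panel (default `"Greys"`).
#' @param bin_width Histogram bin width (default 0.01).
#' @param format Image format, `"png"` or `"svg"`.
#' @param break_cutoff Chain-break C-N distance cutoff in Angstrom.
#' @param verbose Print progress messages.
#'
#' @return Invisibly, a character vector of all files written.  Unparseable
#'   inputs are skipped with a message; an error is raised if every input
#'   fails.
#'
#' @export
run_map_pipeline <- function(pdb, out_dir = ".", signed = FALSE,
                             cmap = "Greys", bin_width = 0.01,
                             format = c("png", "svg"), break_cutoff = 2.0,
                             verbose = TRUE) {
  format <- match.arg(format)
  if (!file.exists(pdb)) stop(sprintf("input not found: %s", pdb))
  files <- if (dir.exists(pdb)) {
    list.files(pdb, pattern = "\\.pdb$", full.names = TRUE,
               ignore.case = TRUE)
  } else pdb
  if (length(files) == 0L) stop(sprintf("no .pdb files found in %s", pdb))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  vmin <- if (signed) -1 else 0
  written <- character()
  failed <- 0L
  for (f in files) {
    tab <- tryCatch(read_ensemble(f, break_cutoff = break_cutoff),
                    error = function(e) {
                      message(sprintf("skipping %s: %s", f, conditionMessage(e)))
                      NULL
                    })
    if (is.null(tab)) { failed <- failed + 1L; next }
    stem <- sub("\\.pdb$", "", basename(f), ignore.case = TRUE)
    for (ch in unique(tab$chain)) {
      dest <- function(product) {
        file.path(out_dir, sprintf("%s.%s.%s.%s", stem, ch, product, format))
      }
      if (verbose) message(sprintf("%s chain '%s': writing MAP set", stem, ch))
      hs <- build_histogram_series(tab, ch, bin_width, signed = signed)
      p <- draw_map(hs, color_scheme(cmap, 0, max(hs, 1e-12)),
                    out = dest("histogram"))
      written <- c(written, p)
      rm <- build_residue_map(tab, ch, signed = signed)
      p <- draw_map(rm, color_scheme("Chirality", vmin, 1),
                    out = dest("map-chirality"))
      written <- c(written, p)
      p <- draw_map(rm, color_scheme("SecondaryStructure", vmin, 1),
                    out = dest("map-secondarystructure"))
      written <- c(written, p)
      d1 <- build_deviation_map(tab, ch, "first", signed = signed)
      p <- draw_map(d1, color_scheme("Greys", 0, if (signed) 2 else 1),
                    out = dest("d1"))
      written <- c(written, p)
      dp <- build_deviation_map(tab, ch, "previous", signed = signed)
      p <- draw_map(dp, color_scheme("Greys", 0, if (signed) 2 else 1),
                    out = dest("dprev"))
      written <- c(written, p)
    }
  }
  if (failed == length(files))
    stop("all input files failed to parse")
  invisible(unname(written))
}
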