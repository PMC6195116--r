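#' Per-residue Ramachandran-number map
#'
#' Arranges the Ramachandran numbers of one chain as a residue-by-model
#' matrix — the per-residue "multi-angle picture".  Each column is one model
#' (frame) and each row one residue, so secondary-structure stretches appear
#' as horizontal bands and conformational transitions as color changes along
#' a row.  Undefined values (chain termini, breaks, missing atoms) are kept
#' as `NA` cells so the residue axis stays aligned.
#'
#' @param table An `"ensemble_table"` from [compute_dihedrals()].
#' @param chain Chain identifier; must exist in `table`.
#' @param signed Use the signed Ramachandran number instead of the unsigned
#'   one.
#'
#' @return A numeric matrix of class `"residue_map"` with residue labels as
#'   row names and model labels as column names; attribute `what` records
#'   which quantity fills the cells.
#'
#' @seealso [build_histogram_series()], [build_deviation_map()], [draw_map()]
#' @export
build_residue_map <- function(table, chain, signed = FALSE) {
  tab <- select_chain(table, chain)
  models <- unique(tab$model)
  res <- unique(tab[c("resid", "ins")])
  res <- res[order(res$resid, res$ins), , drop = FALSE]
  labs <- residue_label(res$resid, res$ins)
  m <- matrix(NA_real_, nrow(res), length(models),
              dimnames = list(labs, models))
  val <- if (signed) tab$Rsigned else tab$R
  i <- match(residue_label(tab$resid, tab$ins), labs)
  j <- match(tab$model, models)
  m[cbind(i, j)] <- val
  structure(m, class = c("residue_map", "matrix"),
            what = if (signed) "Rsigned" else "R", chain = chain)
}

#' Per-model histogram series of Ramachandran numbers
#'
#' For each model, bins the defined Ramachandran numbers of one chain on a
#' fixed grid over \[0, 1\] (or \[-1, 1\] for signed values) and normalizes
#' by the number of defined observations in that model, giving the
#' per-model distribution P'(R).  Stacking the columns side by side shows at
#' a glance how the backbone's conformational makeup — e.g. an alpha-helix
#' band near 0.34 or a beta band near 0.52 — evolves over frames.
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed so that
#' R = 1 is counted.  Models without a single defined value give an all-zero
#' column and are listed in the `empty_models` attribute.
#'
#' @inheritParams build_residue_map
#' @param bin_width Bin width on the R axis; must divide the range evenly
#'   (default 0.01, i.e. 100 bins on \[0, 1\]).
#'
#' @return A bins-by-models matrix of class `"histogram_series"`, rows named
#'   by bin midpoint, with attributes `bin_edges` and `empty_models`.
#'
#' @export
build_histogram_series <- function(table, chain, bin_width = 0.01,
                                   signed = FALSE) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L,
            bin_width > 0, bin_width <= 1)
  lo <- if (signed) -1 else 0
  nb <- (1 - lo) / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("`bin_width` must divide the R range evenly")
  nb <- round(nb)
  edges <- lo + bin_width * (0:nb)
  tab <- select_chain(table, chain)
  models <- unique(tab$model)
  val <- if (signed) tab$Rsigned else tab$R
  m <- matrix(0, nb, length(models),
              dimnames = list(sprintf("%g", (edges[-1L] + edges[-(nb + 1L)]) / 2),
                              models))
  empty <- character()
  for (k in seq_along(models)) {
    v <- val[tab$model == models[k]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) { empty <- c(empty, models[k]); next }
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    cnt <- tabulate(idx, nbins = nb)
    m[, k] <- cnt / sum(cnt)
  }
  structure(m, class = c("histogram_series", "matrix"),
            bin_edges = edges, empty_models = empty, chain = chain,
            what = if (signed) "Rsigned" else "R")
}

#' Per-residue deviation map
#'
#' Applies the structural-deviation metrics [deviation_from_first()]
#' (`mode = "first"`, D1) or [deviation_from_previous()]
#' (`mode = "previous"`, D-1) to every residue's Ramachandran-number series,
#' yielding a residue-by-model matrix.  D1 maps show where and when the
#' backbone drifted from its starting conformation; D-1 maps show
#' frame-to-frame flexibility, making rigid segments stand out as
#' near-zero rows even in otherwise disordered trajectories.
#'
#' @inheritParams build_residue_map
#' @param mode `"first"` for D1 or `"previous"` for D-1.
#'
#' @return A `"residue_map"` matrix of deviations in \[0, 1\] (or \[0, 2\]
#'   for signed input); first column all zero by definition.
#'
#' @export
build_deviation_map <- function(table, chain, mode = c("first", "previous"),
                                signed = FALSE) {
  mode <- match.arg(mode)
  m <- build_residue_map(table, chain, signed = signed)
  if (ncol(m) < 2L)
    warning("deviation map of a single-model ensemble is all zero")
  f <- if (mode == "first") deviation_from_first else deviation_from_previous
  dev <- vapply(seq_len(nrow(m)), function(i) f(m[i, ]), numeric(ncol(m)))
  out <- if (is.matrix(dev)) t(dev) else matrix(dev, nrow(m), ncol(m))
  dimnames(out) <- dimnames(m)
  structure(out, class = c("residue_map", "matrix"),
            what = if (mode == "first") "D1" else "Dprev",
            chain = attr(m, "chain"))
}

#' Residue-type and neighbor-conditioned histogram stacks
#'
#' Groups defined Ramachandran numbers by a per-residue condition and builds
#' one normalized histogram per condition value, suitable for side-by-side
#' stacking.  Conditions:
#' \describe{
#'   \item{`"residue"`}{the residue's own type — one R-line per amino acid.}
#'   \item{`"preceding"`}{the type of the *next* residue (reading N to C):
#'     row `PRO` then collects residues that sit before a proline, the
#'     classic pre-proline context.}
#'   \item{`"following"`}{the type of the *previous* residue: row `GLY`
#'     collects residues that follow a glycine.}
#' }
#' Neighbors are taken within a chain and model, and only between residues
#' with consecutive numbering, so sequence gaps never create false contexts.
#' Condition values present in the table but with no defined observations
#' are kept as all-zero rows (listed in the `empty_conditions` attribute)
#' rather than dropped, so stacks over the same table stay comparable.
#'
#' @inheritParams build_histogram_series
#' @param condition `"residue"`, `"preceding"` or `"following"`.
#' @param chain Restrict to one chain, or `NULL` (default) to pool all
#'   chains of the table (grouping is still per chain for adjacency).
#'
#' @return A conditions-by-bins matrix of class `"conditioned_stack"`, rows
#'   named by condition value (sorted), with attribute `bin_edges`.
#'
#' @export
build_conditioned_stack <- function(table,
                                    condition = c("residue", "preceding",
                                                  "following"),
                                    bin_width = 0.01, chain = NULL,
                                    signed = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(table, "ensemble_table"))
  tab <- if (is.null(chain)) table else select_chain(table, chain)
  lo <- if (signed) -1 else 0
  nb <- round((1 - lo) / bin_width)
  if (abs((1 - lo) / bin_width - nb) > 1e-9)
    stop("`bin_width` must divide the R range evenly")
  edges <- lo + bin_width * (0:nb)

  val <- if (signed) tab$Rsigned else tab$R
  grp <- split(seq_len(nrow(tab)), paste(tab$model, tab$chain))
  cond <- rep(NA_character_, nrow(tab))
  for (ix in grp) {
    rn <- tab$resname[ix]
    rid <- tab$resid[ix]
    cond[ix] <- switch(condition,
      residue = rn,
      preceding = c(ifelse(diff(rid) == 1L, rn[-1L], NA), NA),
      following = c(NA, ifelse(diff(rid) == 1L, rn[-length(rn)], NA)))
  }
  levels <- sort(unique(tab$resname))
  m <- matrix(0, length(levels), nb,
              dimnames = list(levels,
                              sprintf("%g", (edges[-1L] + edges[-(nb + 1L)]) / 2)))
  empty <- character()
  for (k in seq_along(levels)) {
    v <- val[!is.na(cond) & cond == levels[k]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) { empty <- c(empty, levels[k]); next }
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    cnt <- tabulate(idx, nbins = nb)
    m[k, ] <- cnt / sum(cnt)
  }
  structure(m, class = c("conditioned_stack", "matrix"),
            bin_edges = edges, empty_conditions = empty,
            condition = condition, what = if (signed) "Rsigned" else "R")
}

#' Export a map matrix as CSV
#'
#' Writes any map product (residue map, histogram series, conditioned stack)
#' as a plain rows-by-columns CSV with axis labels, sufficient to re-render
#' the image without re-parsing the PDB.  Output bytes are deterministic for
#' identical inputs.
#'
#' @param x A `"residue_map"`, `"histogram_series"` or `"conditioned_stack"`.
#' @param file Output path.
#' @export
write_map_csv <- function(x, file) {
  stopifnot(is.matrix(x))
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(csv_row_label(x), colnames(x))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

csv_row_label <- function(x) {
  if (inherits(x, "histogram_series")) "R_bin_mid"
  else if (inherits(x, "conditioned_stack")) "condition"
  else "residue"
}

select_chain <- function(table, chain) {
  stopifnot(inherits(table, "ensemble_table"))
  if (!chain %in% table$chain)
    stop(sprintf("chain '%s' not found; available chains: %s", chain,
                 paste(unique(table$chain), collapse = ", ")))
  table[table$chain == chain, , drop = FALSE]
}
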