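#' Per-residue structural deviation along a trajectory
#'
#' Two complementary metrics describe how much a residue's backbone state,
#' summarized by its Ramachandran number, has changed over an ordered series
#' of models (frames): the deviation from the first frame,
#' \eqn{D_1 = |R_t - R_1|}, and the deviation from the previous frame,
#' \eqn{D_{-1} = |R_t - R_{t-1}|}.  `D1` highlights cumulative drift away
#' from the starting conformation; `D-1` highlights frame-to-frame
#' fluctuation.  Both are zero for the first frame by definition and lie in
#' \[0, 1\] because Ramachandran numbers do.
#'
#' `NA` entries (undefined dihedrals) propagate: any difference involving an
#' `NA` is `NA`.  The first element is 0 by definition regardless.
#'
#' @param series Numeric vector of Ramachandran numbers for one residue,
#'   ordered by model/frame.  May contain `NA`.
#'
#' @return A numeric vector of the same length as `series`.
#'
#' @examples
#' deviation_from_first(c(0.3, 0.5, 0.3))     # 0, 0.2, 0.0
#' deviation_from_previous(c(0.3, 0.5, 0.3))  # 0, 0.2, 0.2
#'
#' @export
deviation_from_first <- function(series) {
  series <- as.numeric(series)
  if (length(series) == 0L) stop("`series` must be non-empty")
  c(0, abs(series[-1L] - series[1L]))
}

#' @rdname deviation_from_first
#' @export
deviation_from_previous <- function(series) {
  series <- as.numeric(series)
  if (length(series) == 0L) stop("`series` must be non-empty")
  c(0, abs(diff(series)))
}
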