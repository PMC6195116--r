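#' Read backbone atoms from a (multi-model) PDB file
#'
#' Parses fixed-column `ATOM` records, keeping only the three backbone atoms
#' that define the phi/psi dihedrals (N, CA, C).  Structures separated by
#' `MODEL` keywords become distinct models (frames); a file without `MODEL`
#' records yields a single model.  `HETATM`, sidechain and hydrogen records
#' are ignored.
#'
#' Conventions for the corner cases the PDB format allows:
#' \itemize{
#'   \item Alternate locations: the highest-occupancy location wins; ties go
#'     to the first occurrence in the file.
#'   \item Insertion codes: residues are ordered after their base residue
#'     number and the code is kept in the residue label.
#'   \item Model numbering: the `MODEL` serial is used verbatim as the frame
#'     label, even when serials have gaps; models without serials are
#'     numbered sequentially from 1.
#' }
#'
#' @param file Path to a PDB file, or PDB-format text (a single string
#'   containing newlines, or a character vector of lines).
#'
#' @return An object of class `"pdb_models"`: a list with one element per
#'   model, each a named list of chains; every chain is a list with
#'   `chain_id`, `resid` (integer), `ins` (insertion code, `""` if none),
#'   `resname`, and `xyz`, a list of three n-by-3 coordinate matrices named
#'   `N`, `CA`, `C` (rows of `NA` where an atom is absent).  Model labels are
#'   stored in `names()`.
#'
#' @seealso [compute_dihedrals()], [read_ensemble()]
#' @export
read_pdb_models <- function(file) {
  lines <- read_text_lines(file)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  "
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM records found in input")

  # assign each ATOM line the label of the preceding MODEL record
  model_lab <- rep(NA_character_, length(lines))
  if (any(is_model)) {
    serial <- trimws(substr(lines[is_model], 7L, 80L))
    serial[serial == ""] <- as.character(seq_len(sum(is_model)))[serial == ""]
    idx <- cumsum(is_model)
    model_lab <- ifelse(idx > 0L, serial[pmax(idx, 1L)], NA_character_)
  }
  model_lab[is.na(model_lab)] <- "1"

  al <- lines[is_atom]
  name <- trimws(substr(al, 13L, 16L))
  keep <- name %in% c("N", "CA", "C")
  if (!any(keep)) stop("no backbone N/CA/C atoms found in ATOM records")
  al <- al[keep]
  name <- name[keep]

  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  resid <- suppressWarnings(as.integer(substr(al, 23L, 26L)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad)) {
    lineno <- which(is_atom)[keep][bad[1L]]
    stop(sprintf("malformed ATOM record at line %d: %s", lineno,
                 trimws(lines[lineno])))
  }
  occ <- suppressWarnings(as.numeric(substr(al, 55L, 60L)))
  occ[is.na(occ)] <- 1

  atoms <- data.frame(
    model = model_lab[is_atom][keep],
    chain = substr(al, 22L, 22L),
    resid = resid,
    ins = trimws(substr(al, 27L, 27L)),
    resname = trimws(substr(al, 18L, 20L)),
    name = name,
    x = x, y = y, z = z, occ = occ,
    ord = seq_along(al),
    stringsAsFactors = FALSE
  )

  # altloc / duplicate-atom resolution: highest occupancy, ties first-in-file
  atoms <- atoms[order(-atoms$occ, atoms$ord), , drop = FALSE]
  atoms <- atoms[!duplicated(atoms[c("model", "chain", "resid", "ins", "name")]), ,
                 drop = FALSE]
  atoms <- atoms[order(atoms$ord), , drop = FALSE]

  model_order <- unique(model_lab[is_atom][keep])
  out <- lapply(model_order, function(m) {
    ma <- atoms[atoms$model == m, , drop = FALSE]
    chains <- unique(ma$chain)
    chs <- lapply(chains, function(cid) {
      ca <- ma[ma$chain == cid, , drop = FALSE]
      res <- unique(ca[c("resid", "ins", "resname")])
      res <- res[order(res$resid, res$ins), , drop = FALSE]
      key <- paste(res$resid, res$ins)
      xyz <- lapply(c("N", "CA", "C"), function(at) {
        m3 <- matrix(NA_real_, nrow(res), 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
        sel <- ca[ca$name == at, , drop = FALSE]
        i <- match(paste(sel$resid, sel$ins), key)
        m3[i, ] <- as.matrix(sel[c("x", "y", "z")])
        m3
      })
      names(xyz) <- c("N", "CA", "C")
      list(chain_id = cid, resid = res$resid, ins = res$ins,
           resname = res$resname, xyz = xyz)
    })
    names(chs) <- chains
    chs
  })
  names(out) <- model_order
  structure(out, class = "pdb_models")
}

#' @export
print.pdb_models <- function(x, ...) {
  nres <- sum(vapply(x[[1L]], function(ch) length(ch$resid), 1L))
  cat(sprintf("pdb_models: %d model(s); model %s has %d chain(s), %d residue(s)\n",
              length(x), names(x)[1L], length(x[[1L]]), nres))
  invisible(x)
}

read_text_lines <- function(file) {
  pdb_record <- "^(ATOM  |HETATM|MODEL |ENDMDL|HEADER|TITLE |REMARK|SEQRES|CRYST1|EXPDTA|TER|END)"
  if (length(file) == 1L && !grepl("\n", file, fixed = TRUE) &&
      !grepl(pdb_record, file)) {
    if (!file.exists(file)) stop(sprintf("file not found: %s", file))
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Torsion angle defined by four points
#'
#' Standard IUPAC sign convention: looking down the p2-p3 axis, the angle is
#' positive for a clockwise rotation of the p3-p4 bond relative to the p1-p2
#' bond.  The result is wrapped to \[-180, 180), so an exactly trans
#' arrangement reports -180.
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates (length 3 each).
#'
#' @return The torsion in degrees, or `NA` for degenerate geometry
#'   (zero-length bonds or collinear consecutive triples).
#'
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)) # trans: -180
#' dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))  # cis: 0
#'
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-10 || sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) return(NA_real_)
  ang <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  ang
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Compute per-residue phi/psi dihedrals and Ramachandran numbers
#'
#' For residue i, phi is the torsion over atoms C(i-1)-N(i)-CA(i)-C(i) and
#' psi over N(i)-CA(i)-C(i)-N(i+1).  The first residue of a chain has no phi
#' and the last no psi.  A broken peptide bond — a C(i-1) to N(i) distance
#' greater than `break_cutoff` — makes phi(i) and psi(i-1) undefined, as do
#' missing atoms.  Residues with undefined dihedrals are kept as rows with
#' `NA` values so that the residue axis stays aligned across models.
#'
#' @param models A `"pdb_models"` object from [read_pdb_models()].
#' @param break_cutoff Maximum C-N peptide-bond length in Angstrom before a
#'   chain break is declared (default 2.0; the bond itself is ~1.33).
#' @param bounds An [angle_bounds()] object used for the R columns.
#'
#' @return An `"ensemble_table"`: a data.frame with one row per
#'   (model, chain, residue) and columns `model`, `chain`, `resid`, `ins`,
#'   `resname`, `phi`, `psi`, `R`, `Rsigned`.  `R` is defined iff both
#'   dihedrals are, and always equals `ramachandran_number(phi, psi)`.
#'
#' @seealso [read_ensemble()] to go from a file to the table in one call,
#'   [write_ensemble_csv()] for serialization.
#' @export
compute_dihedrals <- function(models, break_cutoff = 2.0,
                              bounds = angle_bounds()) {
  stopifnot(inherits(models, "pdb_models"))
  rows <- list()
  for (m in names(models)) {
    for (ch in models[[m]]) {
      n <- length(ch$resid)
      N <- ch$xyz$N; CA <- ch$xyz$CA; C <- ch$xyz$C
      # peptide-bond continuity between residue i and i+1
      linked <- rep(FALSE, max(n - 1L, 0L))
      if (n > 1L) {
        d <- sqrt(rowSums((N[-1L, , drop = FALSE] -
                           C[-n, , drop = FALSE])^2))
        linked <- !is.na(d) & d <= break_cutoff
      }
      phi <- psi <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (i > 1L && linked[i - 1L])
          phi[i] <- dihedral_angle(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
        if (i < n && linked[i])
          psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, chain = ch$chain_id, resid = ch$resid, ins = ch$ins,
        resname = ch$resname, phi = phi, psi = psi,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$phi) & !is.na(tab$psi)
  tab$R <- tab$Rsigned <- NA_real_
  tab$R[ok] <- ramachandran_number(tab$phi[ok], tab$psi[ok], bounds)
  tab$Rsigned[ok] <- signed_ramachandran_number(tab$phi[ok], tab$psi[ok], bounds)
  rownames(tab) <- NULL
  class(tab) <- c("ensemble_table", "data.frame")
  tab
}

#' Read a PDB file straight into an ensemble table
#'
#' Convenience wrapper chaining [read_pdb_models()] and
#' [compute_dihedrals()].
#'
#' @inheritParams read_pdb_models
#' @inheritParams compute_dihedrals
#' @return An `"ensemble_table"` data.frame; see [compute_dihedrals()].
#' @export
read_ensemble <- function(file, break_cutoff = 2.0, bounds = angle_bounds()) {
  compute_dihedrals(read_pdb_models(file), break_cutoff, bounds)
}

#' Write an ensemble table as CSV
#'
#' Serializes with the canonical header
#' `model,chain,resid,resname,phi,psi,R,Rsigned`; insertion codes are folded
#' into the resid label (e.g. `52A`).
#'
#' @param table An `"ensemble_table"` from [compute_dihedrals()].
#' @param file Output path.
#' @export
write_ensemble_csv <- function(table, file) {
  stopifnot(inherits(table, "ensemble_table"))
  out <- data.frame(model = table$model, chain = table$chain,
                    resid = residue_label(table$resid, table$ins),
                    resname = table$resname,
                    phi = table$phi, psi = table$psi,
                    R = table$R, Rsigned = table$Rsigned,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

residue_label <- function(resid, ins) {
  paste0(resid, ifelse(is.na(ins) | ins == "", "", ins))
}
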