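# Fixtures built in code: small PDB texts and synthetic ensemble tables.

# two-model dialanine: one chain, two residues, backbone atoms only
dialanine_pdb <- function() {
  model <- function(m, dz) {
    coords <- matrix(c(
      0.000, 0.000, 0.000,   # N   1
      1.458, 0.000, 0.000,   # CA  1
      2.005, 1.424, 0.000,   # C   1
      3.332, 1.536, 0.000,   # N   2
      4.040, 2.790, 0.100,   # CA  2
      5.520, 2.600, 0.200),  # C   2
      ncol = 3L, byrow = TRUE)
    coords[, 3L] <- coords[, 3L] + dz
    ats <- c(" N  ", " CA ", " C  ")
    c(sprintf("MODEL     %4d", m),
      sprintf("ATOM  %5d %4s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
              1:6, rep(ats, 2L), rep(1:2, each = 3L),
              coords[, 1L], coords[, 2L], coords[, 3L], 1, 0),
      "ENDMDL")
  }
  paste(c(model(1L, 0), model(2L, 0.5), "END"), collapse = "\n")
}

# a synthetic ensemble table (already ordered by model, chain, resid)
make_table <- function(model, chain, resid, resname = "GLY",
                       phi = NA_real_, psi = NA_real_, R = NULL,
                       Rsigned = NULL) {
  n <- max(length(model), length(chain), length(resid), length(R))
  tab <- data.frame(model = as.character(rep_len(model, n)),
                    chain = rep_len(chain, n),
                    resid = rep_len(resid, n), ins = "",
                    resname = rep_len(resname, n),
                    phi = rep_len(phi, n), psi = rep_len(psi, n),
                    stringsAsFactors = FALSE)
  tab$R <- if (is.null(R)) ramachandran_number(tab$phi, tab$psi) else
    rep_len(R, n)
  tab$Rsigned <- if (is.null(Rsigned)) tab$R else rep_len(Rsigned, n)
  class(tab) <- c("ensemble_table", "data.frame")
  tab
}

# table from explicit (phi, psi): R columns derived, keeping the invariant
table_from_angles <- function(model, chain, resid, phi, psi,
                              resname = "GLY") {
  n <- max(length(model), length(resid), length(phi))
  tab <- data.frame(model = as.character(rep_len(model, n)),
                    chain = rep_len(chain, n), resid = rep_len(resid, n),
                    ins = "", resname = rep_len(resname, n),
                    phi = rep_len(phi, n), psi = rep_len(psi, n),
                    stringsAsFactors = FALSE)
  tab$R <- ramachandran_number(tab$phi, tab$psi)
  tab$Rsigned <- signed_ramachandran_number(tab$phi, tab$psi)
  class(tab) <- c("ensemble_table", "data.frame")
  tab
}
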