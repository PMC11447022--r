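# Constructed structure fixtures and plain-text writers (synthetic models,
# built in code at test time).

write_toy_pdb <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    name <- if (nchar(a$elety) < 4) sprintf(" %-3s", a$elety) else a$elety
    lines[i] <- sprintf(
      "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name, a$altloc %||% "", a$resid, a$chain, a$resno, "",
      a$x, a$y, a$z, a$occupancy %||% 1, 0, a$element)
  }
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(atoms, path) {
  hdr <- c("data_toy", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    alt <- a$altloc %||% "."
    if (!nzchar(alt)) alt <- "."
    sprintf("ATOM %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
            i, a$element, a$elety, alt, a$resid, a$chain,
            a$resno, a$x, a$y, a$z, a$occupancy %||% 1, a$resno, a$resid,
            a$chain, a$elety)
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# k conformational states that differ by a NON-rigid deformation with a
# prescribed minimum (superposed) RMSD from the base template
make_conformer_states <- function(p = 8, k = 2, sep = 5, seed = 31) {
  set.seed(seed)
  base <- matrix(rnorm(p * 3, sd = 3), p, 3)
  states <- list(base)
  for (s in 2:k) {
    E <- matrix(rnorm(p * 3), p, 3)
    cand <- base + E
    for (it in 1:6) {
      r <- gamdr::kabsch(base, cand)$rmsd
      E <- E * (sep / r)
      cand <- base + E
    }
    states[[s]] <- cand
  }
  states
}

# a small two-chain model: chain A = three-residue backbone stretch plus an
# Asp/Arg pair, chain B = short "helix" whose tip can be displaced
toy_model_atoms <- function() {
  bb <- function(chain, resno, resid, x0) {
    tibble::tibble(
      chain = chain, resno = resno, resid = resid,
      elety = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = x0 + c(0, 1.2, 2.4, 3.0), y = c(0.2, 1.0, 0.4, 1.2) + resno,
      z = c(0, 0.5, 0.1, 0.8), occupancy = 1, altloc = "")
  }
  dplyr::bind_rows(
    bb("A", 1, "GLY", 0), bb("A", 2, "ALA", 4), bb("A", 3, "SER", 8),
    tibble::tibble(chain = "A", resno = 4, resid = "ASP",
                   elety = c("N", "CA", "CB", "CG", "OD1", "OD2"),
                   element = c("N", "C", "C", "C", "O", "O"),
                   x = c(12, 13, 13.5, 14.2, 15.1, 13.9),
                   y = c(4, 4.5, 5.8, 6.4, 6.1, 7.4),
                   z = c(0, 0.6, 0.4, 1.3, 2.1, 1.4),
                   occupancy = 1, altloc = ""),
    tibble::tibble(chain = "A", resno = 5, resid = "ARG",
                   elety = c("N", "CA", "CZ", "NH1", "NH2", "NE"),
                   element = c("N", "C", "C", "N", "N", "N"),
                   x = c(16, 17, 16.5, 15.8, 17.2, 16.2),
                   y = c(5, 5.5, 7.8, 8.5, 8.4, 6.6),
                   z = c(0, 0.4, 1.8, 2.5, 1.2, 1.5),
                   occupancy = 1, altloc = ""),
    tibble::tibble(chain = "B", resno = 1:6, resid = "ALA",
                   elety = "CA", element = "C",
                   x = cos(seq(0, 5) * 1.7) * 2.3 + 25,
                   y = sin(seq(0, 5) * 1.7) * 2.3,
                   z = seq(0, 5) * 1.5,
                   occupancy = 1, altloc = ""))
}

toy_structure_model <- function(atoms = toy_model_atoms()) {
  gamdr:::as_structure_model(atoms, model_id = "toy")
}
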