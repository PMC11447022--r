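#' Atomic structure model
#'
#' A `structure_model` is a tibble of atoms with columns `chain`, `resno`,
#' `insert`, `resid`, `elety` (atom name), `element`, `x`, `y`, `z`,
#' `occupancy`, `altloc`. Keys `(chain, resno, insert, elety)` are unique
#' after the alternate-location policy is applied.
#'
#' @name structure_model
NULL

as_structure_model <- function(df, model_id = "model", source = NA_character_,
                               format = NA_character_) {
  df <- tibble::as_tibble(df)
  for (col in c("insert", "altloc")) if (!col %in% names(df)) df[[col]] <- ""
  if (!"occupancy" %in% names(df)) df$occupancy <- 1
  if (!"element" %in% names(df)) df$element <- guess_element(df$elety)
  if (!"resid" %in% names(df)) df$resid <- "UNK"
  df$insert[is.na(df$insert)] <- ""
  df$altloc[is.na(df$altloc)] <- ""
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "occupancy", "altloc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite coordinates")
  }
  key <- paste(df$chain, df$resno, df$insert, df$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, insert, atom-name) keys after altloc policy")
  }
  structure(df[need], model_id = model_id, source = source, format = format,
            class = c("structure_model", class(tibble::tibble())))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, chains: %s\n", nrow(x),
              paste(sort(unique(x$chain)), collapse = " ")))
  NextMethod()
}

guess_element <- function(elety) {
  e <- sub("^[0-9']*", "", elety)
  one <- toupper(substr(e, 1, 1))
  ifelse(one %in% c("C", "N", "O", "S", "P", "H", "F", "K", "I"), one,
         toupper(substr(e, 1, 2)))
}

atomic_mass <- function(element) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, FE = 55.845, ZN = 65.38, MG = 24.305, NA. = 22.99)
  m <- tbl[toupper(element)]
  m[is.na(m)] <- 12
  unname(m)
}

#' Parse a PDB or mmCIF coordinate file
#'
#' Reads the first model; for atoms with alternate locations only the
#' highest-occupancy conformer is kept (ties resolved towards altloc "A").
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return a [structure_model].
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  df <- tibble::tibble(
    chain = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resid = as.character(a$resid),
    elety = as.character(a$elety),
    element = {
      el <- toupper(as.character(a$elesy))
      el[is.na(el) | el == ""] <- guess_element(a$elety[is.na(el) | el == ""])
      el
    },
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)))
  # altloc policy: highest occupancy, ties towards "A" (then alphabetical)
  df$.ord <- seq_len(nrow(df))
  df <- df |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  df$.ord <- NULL
  as_structure_model(df, model_id = basename(path), source = path,
                     format = format)
}

#' Select atoms of a structure model
#'
#' @param model a [structure_model].
#' @param chain,resno,elety,resid optional filters (vectors; `resno` may be
#'   any integer vector, e.g. `100:150`).
#' @param heavy_only drop hydrogens.
#' @return the filtered [structure_model] rows (plain tibble).
#' @export
str_select <- function(model, chain = NULL, resno = NULL, elety = NULL,
                       resid = NULL, heavy_only = FALSE) {
  df <- tibble::as_tibble(model)
  if (!is.null(chain)) df <- df[df$chain %in% chain, ]
  if (!is.null(resno)) df <- df[df$resno %in% resno, ]
  if (!is.null(elety)) df <- df[df$elety %in% elety, ]
  if (!is.null(resid)) df <- df[df$resid %in% resid, ]
  if (heavy_only) df <- df[df$element != "H", ]
  df
}

sel_rows <- function(model, sel) {
  if (is.null(sel)) return(tibble::as_tibble(model))
  if (is.data.frame(sel)) return(tibble::as_tibble(sel))
  do.call(str_select, c(list(model), sel))
}

coords_of <- function(df) cbind(df$x, df$y, df$z)

# pair atoms across two models by (mapped chain, resno, insert, elety)
pair_atoms <- function(dfA, dfB, chain_map = NULL) {
  if (is.null(chain_map)) {
    shared <- intersect(unique(dfA$chain), unique(dfB$chain))
    chain_map <- stats::setNames(shared, shared)
  }
  dfA <- dfA[dfA$chain %in% names(chain_map), ]
  dfB <- dfB[dfB$chain %in% unname(chain_map), ]
  dfA$.mapped <- unname(chain_map[dfA$chain])
  key_a <- paste(dfA$.mapped, dfA$resno, dfA$insert, dfA$elety)
  key_b <- paste(dfB$chain, dfB$resno, dfB$insert, dfB$elety)
  ib <- match(key_a, key_b)
  ok <- !is.na(ib)
  list(A = dfA[ok, , drop = FALSE], B = dfB[ib[ok], , drop = FALSE],
       n_dropped = sum(!ok) + (nrow(dfB) - sum(ok)))
}

#' Matched C-alpha RMSD between two models
#'
#' Pairs C-alpha atoms sharing (mapped chain, residue number, insertion
#' code) across the two models, then reports the Kabsch-minimised RMSD and
#' the number of pairs. Unmatched residues are dropped with a message.
#'
#' @param modelA,modelB [structure_model] objects.
#' @param chain_map named character vector mapping chains of A to chains of
#'   B (default: identity on shared chain ids).
#' @return a `superposition_result` (fields `rmsd`, `n_pairs`, ...).
#' @export
matched_ca_rmsd <- function(modelA, modelB, chain_map = NULL) {
  caA <- str_select(modelA, elety = "CA")
  caA <- caA[caA$resid != "CA", ] # exclude calcium ions
  caB <- str_select(modelB, elety = "CA")
  caB <- caB[caB$resid != "CA", ]
  pr <- pair_atoms(caA, caB, chain_map)
  if (nrow(pr$A) < 3) stop("fewer than 3 matched C-alpha pairs")
  if (pr$n_dropped > 0) {
    message(pr$n_dropped, " unmatched C-alpha atoms dropped from the pairing")
  }
  kabsch(coords_of(pr$A), coords_of(pr$B))
}

#' Displacement of a named atom between two superposed models
#'
#' Superposes B onto A on the stated selection (paired by chain, residue
#' and atom name), then reports the distance between the two copies of the
#' named atom — the standard way of quoting, e.g., a helix-tip displacement
#' between receptor states.
#'
#' @param modelA,modelB [structure_model] objects.
#' @param atom list with `chain`, `resno`, `elety` identifying the atom.
#' @param superpose_selection selection list (see [str_select()]) defining
#'   the alignment anchor; default all paired atoms.
#' @param chain_map optional chain mapping, as in [matched_ca_rmsd()].
#' @return displacement in A, with attribute `superposition`.
#' @export
atom_displacement <- function(modelA, modelB, atom,
                              superpose_selection = NULL, chain_map = NULL) {
  anchorA <- sel_rows(modelA, superpose_selection)
  anchorB <- sel_rows(modelB, superpose_selection)
  pr <- pair_atoms(anchorA, anchorB, chain_map)
  if (nrow(pr$A) < 3) stop("superposition selection yields < 3 paired atoms")
  sp <- kabsch(coords_of(pr$A), coords_of(pr$B))
  aA <- sel_rows(modelA, atom); aB <- sel_rows(modelB, atom)
  if (nrow(aA) != 1 || nrow(aB) != 1) {
    stop("atom key must identify exactly one atom in each model")
  }
  moved <- apply_superposition(coords_of(aB), sp)
  out <- sqrt(sum((coords_of(aA) - moved)^2))
  attr(out, "superposition") <- sp
  out
}

charged_group <- function(model, res, role = c("acidic", "basic")) {
  role <- match.arg(role)
  df <- sel_rows(model, res)
  if (nrow(df) == 0) stop("residue not found")
  resid <- df$resid[1]
  atoms <- switch(role,
    acidic = switch(resid, ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                    stop("not an acidic residue: ", resid)),
    basic = switch(resid, ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                   HIS = c("ND1", "NE2"),
                   stop("not a basic residue: ", resid)))
  centers <- switch(role,
    acidic = switch(resid, ASP = "CG", GLU = "CD"),
    basic = switch(resid, ARG = "CZ", LYS = "NZ", HIS = "CE1"))
  g <- df[df$elety %in% atoms, ]
  if (nrow(g) == 0) stop("missing side-chain atoms for ", resid)
  list(atoms = g, center = df[df$elety %in% centers, ])
}

#' Salt-bridge detection between an acidic and a basic residue
#'
#' Minimum distance over the charged-group atoms (carboxylate oxygens of
#' Asp/Glu against guanidinium/amine nitrogens of Arg/Lys/His), or the
#' distance between the charge-centre atoms (`method = "centers"`: CG/CD
#' for Asp/Glu, CZ/NZ for Arg/Lys). The bridge is formed when the distance
#' is within `cutoff`.
#'
#' @param model a [structure_model].
#' @param acidic,basic selection lists (`chain`, `resno`).
#' @param cutoff distance cutoff, A (default 4.0 between charge centres).
#' @param method `"atoms"` (minimum over charged atoms) or `"centers"`.
#' @return tibble with `distance` (A) and `formed`.
#' @export
salt_bridge <- function(model, acidic, basic, cutoff = 4.0,
                        method = c("atoms", "centers")) {
  method <- match.arg(method)
  ga <- charged_group(model, acidic, "acidic")
  gb <- charged_group(model, basic, "basic")
  if (method == "centers") {
    if (nrow(ga$center) == 0 || nrow(gb$center) == 0) {
      stop("charge-centre atom missing")
    }
    d <- sqrt(sum((colMeans(coords_of(ga$center)) -
                     colMeans(coords_of(gb$center)))^2))
  } else {
    ca <- coords_of(ga$atoms); cb <- coords_of(gb$atoms)
    d <- min(sqrt(pmax(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                         2 * ca %*% t(cb), 0)))
  }
  tibble::tibble(distance = d, formed = d <= cutoff)
}

#' Minimum distance between two atom selections
#'
#' @param model a [structure_model].
#' @param a,b selection lists (see [str_select()]).
#' @return minimum pairwise distance, A.
#' @export
structure_distance <- function(model, a, b) {
  ca <- coords_of(sel_rows(model, a)); cb <- coords_of(sel_rows(model, b))
  if (nrow(ca) == 0 || nrow(cb) == 0) stop("empty selection")
  min(sqrt(pmax(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                  2 * ca %*% t(cb), 0)))
}

#' Rigid-body motion of a domain between two models
#'
#' Superposes B onto A on the anchor selection, then fits the moving-domain
#' atoms of the aligned B onto their A counterparts: the reported angle is
#' the trace angle of that Kabsch rotation, `acos((tr R - 1)/2)`, and the
#' displacement is the mass-centre shift of the moving domain after anchor
#' alignment.
#'
#' @param modelA,modelB [structure_model] objects.
#' @param anchor,moving selection lists defining the two domains.
#' @param chain_map optional chain mapping.
#' @return object of class `domain_motion`: `angle_deg` in `[0, 180]`,
#'   `displacement` (A), pair counts.
#' @export
domain_motion <- function(modelA, modelB, anchor, moving, chain_map = NULL) {
  prA <- pair_atoms(sel_rows(modelA, anchor), sel_rows(modelB, anchor),
                    chain_map)
  if (nrow(prA$A) < 3) stop("anchor selection yields < 3 paired atoms")
  sp <- kabsch(coords_of(prA$A), coords_of(prA$B))
  prM <- pair_atoms(sel_rows(modelA, moving), sel_rows(modelB, moving),
                    chain_map)
  if (nrow(prM$A) < 3) stop("moving selection yields < 3 paired atoms")
  mB <- apply_superposition(coords_of(prM$B), sp)
  fit <- kabsch(coords_of(prM$A), mB)
  w <- atomic_mass(prM$A$element)
  comA <- colSums(coords_of(prM$A) * w) / sum(w)
  comB <- colSums(mB * w) / sum(w)
  structure(list(angle_deg = rotation_angle(fit$rotation),
                 displacement = sqrt(sum((comA - comB)^2)),
                 n_anchor = nrow(prA$A), n_moving = nrow(prM$A)),
            class = "domain_motion")
}

#' @export
print.domain_motion <- function(x, ...) {
  cat(sprintf(
    "<domain_motion> rotation %.2f deg, mass-centre displacement %.2f A (%d anchor / %d moving atoms)\n",
    x$angle_deg, x$displacement, x$n_anchor, x$n_moving))
  invisible(x)
}

#' Residue-level interface contacts between two groups
#'
#' All heavy-atom pairs across two disjoint selections within `cutoff`,
#' aggregated to residue pairs with the minimum atom distance and the
#' number of contacting atom pairs (brute-force all-pairs enumeration).
#'
#' @param model a [structure_model].
#' @param group_a,group_b disjoint selection lists.
#' @param cutoff heavy-atom distance cutoff, A.
#' @return tibble of residue-pair contacts sorted by distance (possibly
#'   empty).
#' @export
interface_contacts <- function(model, group_a, group_b, cutoff = 4.5) {
  da <- sel_rows(model, group_a); da <- da[da$element != "H", ]
  db <- sel_rows(model, group_b); db <- db[db$element != "H", ]
  if (nrow(da) == 0 || nrow(db) == 0) stop("empty selection")
  ka <- paste(da$chain, da$resno, da$insert, da$elety)
  kb <- paste(db$chain, db$resno, db$insert, db$elety)
  if (length(intersect(ka, kb)) > 0) stop("groups must be disjoint")
  ca <- coords_of(da); cb <- coords_of(db)
  D <- sqrt(pmax(outer(rowSums(ca^2), rowSums(cb^2), "+") -
                   2 * ca %*% t(cb), 0))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble::tibble(chain_a = character(), resno_a = integer(),
                          resid_a = character(), chain_b = character(),
                          resno_b = integer(), resid_b = character(),
                          min_dist = numeric(), n_atom_pairs = integer()))
  }
  tibble::tibble(
    chain_a = da$chain[hit[, 1]], resno_a = da$resno[hit[, 1]],
    resid_a = da$resid[hit[, 1]],
    chain_b = db$chain[hit[, 2]], resno_b = db$resno[hit[, 2]],
    resid_b = db$resid[hit[, 2]],
    dist = D[hit]) |>
    dplyr::group_by(.data$chain_a, .data$resno_a, .data$resid_a,
                    .data$chain_b, .data$resno_b, .data$resid_b) |>
    dplyr::summarise(min_dist = min(.data$dist),
                     n_atom_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$min_dist)
}
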