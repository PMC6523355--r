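# interface: optional pocket import from a standard PDB file.

# light fixed-width validation so malformed records fail with a line number
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop_plafep(sprintf("PDB parse error at line %d: record shorter than the coordinate columns", i),
                  "plafep_parse_error")
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz)))) {
      stop_plafep(sprintf("PDB parse error at line %d: non-numeric coordinates", i),
                  "plafep_parse_error")
    }
  }
  sum(rec)
}

#' Coarse-grain a binding pocket from a PDB file
#'
#' Places one repulsive wall sphere at each C-alpha of the selected
#' residues and the calcium-like anchor at the calcium HETATM if one is
#' present, otherwise at the selection centroid.  The packaged synthetic
#' fixture (`make_fixture("mini_pdb")`) is the default stand-in; any
#' standard PDB works.
#'
#' @param pdb_path Path to a PDB file (ATOM/HETATM records, wwPDB
#'   fixed-width columns).
#' @param selection Residue numbers to keep, or `"all"`.
#' @param wall_radius Wall sphere radius, A.
#' @param ... Further [environment_model()] arguments (well depth etc.).
#' @return A `ts_pocket` [environment_model()].
#' @export
#' @examples
#' pocket_from_pdb(make_fixture("mini_pdb"))
pocket_from_pdb <- function(pdb_path, selection = "all", wall_radius = 2.5,
                            ...) {
  if (!file.exists(pdb_path)) {
    stop_plafep(sprintf("PDB file not found: %s", pdb_path),
                "plafep_config_error")
  }
  n_rec <- validate_pdb_lines(pdb_path)
  if (n_rec == 0) {
    stop_plafep("empty selection: file contains no ATOM/HETATM records",
                "plafep_selection_error")
  }
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  if (!identical(selection, "all")) {
    ca <- ca[ca$resno %in% selection, , drop = FALSE]
  }
  if (nrow(ca) == 0) {
    stop_plafep("empty selection: no C-alpha atoms matched",
                "plafep_selection_error")
  }
  walls <- tibble(x = ca$x, y = ca$y, z = ca$z, radius = wall_radius)
  het <- atoms[atoms$type == "HETATM" &
                 (toupper(trimws(atoms$resid)) == "CA" |
                    toupper(trimws(atoms$elesy %||% "")) == "CA"), ,
               drop = FALSE]
  anchor <- if (nrow(het) > 0) {
    c(het$x[1], het$y[1], het$z[1])
  } else {
    c(mean(ca$x), mean(ca$y), mean(ca$z))
  }
  environment_model("ts_pocket", anchor_position = anchor,
                    wall_spheres = walls, ...)
}
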