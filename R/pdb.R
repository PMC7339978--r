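#' Bondi van der Waals radii (Angstrom) by element symbol
#'
#' Elements not in the table fall back to 1.70 Angstrom (carbon-like) with a
#' warning from [read_pdb()].
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii_table <- function() {
  c("H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80,
    "P" = 1.80, "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98,
    "SE" = 1.90, "ZN" = 1.39, "FE" = 2.05, "MG" = 1.73, "CA" = 2.31,
    "NA" = 2.27, "K" = 2.75, "MN" = 2.05, "CU" = 1.40)
}

.default_vdw <- 1.70

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records into an atom table with assigned van der Waals
#' radii. Alternate locations are resolved to the highest-occupancy copy,
#' elements missing from the records are inferred from atom names, and files
#' compressed with gzip are read transparently. Parsing is delegated to
#' \pkg{bio3d}; this function adds record validation (malformed fixed-width
#' coordinate fields raise an error naming the offending line), altloc
#' resolution and radius assignment.
#'
#' @param file Path to a PDB file (optionally gzip-compressed), or a character
#'   vector of PDB-format lines.
#' @param id Structure identifier; defaults to the file name.
#' @return An object of class `cf_structure`: a list with elements `id` and
#'   `atoms`, a data frame with one row per atom (columns `serial`,
#'   `atom_name`, `residue_name`, `residue_number`, `ins`, `chain_id`, `x`,
#'   `y`, `z`, `element`, `occupancy`, `is_hetero`, `vdw_radius`).
#' @export
read_pdb <- function(file, id = NULL) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(if (grepl("\\.gz$", file)) gzfile(file) else file,
                       warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(file))
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "structure"
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records: empty model")
  bad <- which(rec & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d: %s",
                 bad[1], substr(lines[bad[1]], 1, 30)))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE, multi = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altlocs: keep highest occupancy per (chain, resno, ins, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
    i[which.max(at$o[i])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- .element_from_name(at$elety[miss])
  tab <- vdw_radii_table()
  r <- unname(tab[elem])
  if (anyNA(r)) {
    warning(sprintf("unknown element(s) %s: using default vdW radius %.2f A",
                    paste(unique(elem[is.na(r)]), collapse = ", "),
                    .default_vdw))
    r[is.na(r)] <- .default_vdw
  }
  atoms <- data.frame(
    serial = at$eleno, atom_name = at$elety, residue_name = at$resid,
    residue_number = at$resno, ins = at$insert, chain_id = at$chain,
    x = at$x, y = at$y, z = at$z, element = elem, occupancy = at$o,
    is_hetero = at$type == "HETATM", vdw_radius = r,
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates after parsing")
  }
  structure(list(id = id, atoms = atoms), class = "cf_structure")
}

.element_from_name <- function(name) {
  # strip digits and leading whitespace; two-letter halogens/metals first
  nm <- toupper(gsub("[0-9' ]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "SE", "ZN", "FE", "MG", "MN", "CU"),
                two, substr(nm, 1, 1))
  out
}

#' Construct a structure from an atom table
#'
#' Lower-level constructor used by the synthetic fixtures.
#'
#' @param atoms Data frame with the columns documented in [read_pdb()].
#' @param id Structure identifier.
#' @return A `cf_structure` object.
#' @export
as_structure <- function(atoms, id = "structure") {
  need <- c("serial", "atom_name", "residue_name", "residue_number",
            "chain_id", "x", "y", "z", "element", "vdw_radius")
  if (!all(need %in% names(atoms))) {
    stop("atom table missing columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  }
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  if (nrow(atoms) == 0L) stop("empty atom table")
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive")
  structure(list(id = id, atoms = atoms), class = "cf_structure")
}

#' @export
print.cf_structure <- function(x, ...) {
  cat(sprintf("<cf_structure '%s': %d atoms, chains %s>\n", x$id,
              nrow(x$atoms),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Select atoms from a structure
#'
#' @param struct A `cf_structure`.
#' @param chain Optional chain id(s).
#' @param resno Optional residue numbers (use `lo:hi` for a range).
#' @param atom_names Optional atom names (e.g. `"CA"`).
#' @param residue_names Optional residue names (e.g. `"GOL"`).
#' @param hetero Optional logical: keep only HETATM (`TRUE`) or ATOM
#'   (`FALSE`) records.
#' @return A `cf_structure` containing the matching subset.
#' @export
select_atoms <- function(struct, chain = NULL, resno = NULL,
                         atom_names = NULL, residue_names = NULL,
                         hetero = NULL) {
  stopifnot(inherits(struct, "cf_structure"))
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(resno)) keep <- keep & a$residue_number %in% resno
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  if (!is.null(residue_names)) keep <- keep & a$residue_name %in% residue_names
  if (!is.null(hetero)) keep <- keep & a$is_hetero == hetero
  structure(list(id = struct$id, atoms = a[keep, , drop = FALSE]),
            class = "cf_structure")
}

#' Atom coordinates as an n x 3 matrix
#'
#' @param struct A `cf_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(struct) {
  stopifnot(inherits(struct, "cf_structure"))
  as.matrix(struct$atoms[, c("x", "y", "z")])
}
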