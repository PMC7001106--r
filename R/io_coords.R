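# Coordinate readers for the two standard fixed-column formats the pipeline
# touches.  PDB parsing is delegated to bio3d (the R standard for PDB), with a
# fixed-width pre-check so malformed records fail with a line number; GRO has
# no installed R reader and is parsed here by column.

# map three-letter amino acid codes to one-letter for residue labels ("R504")
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

residue_label_of <- function(resid, resno) {
  one <- unname(AA3TO1[toupper(resid)])
  ifelse(is.na(one), paste0(resid, resno), paste0(one, resno))
}

#' Read a coordinate file into a membrane system
#'
#' Supports PDB (`ATOM`/`HETATM` fixed columns, Angstrom, converted to nm on
#' read) and GRO (fixed columns, already nm).  Roles are assigned from the
#' record context: PDB `ATOM` records become `protein`, `HETATM` records
#' `ligand`; GRO residues named like amino acids become `protein`, everything
#' else `ligand`.  Species is the residue name; residue labels use the
#' one-letter + residue-number convention (`"R504"`).
#'
#' @param path Path to the file.
#' @param dialect `"PDB"` or `"GRO"`. Default guesses from the file extension.
#' @param box Optional box override (nm); otherwise taken from the file
#'   (GRO box line, PDB CRYST1) or a generous bounding box if absent.
#' @return A [membrane_system()] holding the single frame of coordinates.
#' @export
read_coordinates <- function(path, dialect = NULL, box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      pdb = "PDB", ent = "PDB", gro = "GRO",
                      stop("cannot guess dialect from extension of ", path))
  }
  dialect <- match.arg(toupper(dialect), c("PDB", "GRO"))
  if (dialect == "PDB") read_pdb_system(path, box) else read_gro_system(path, box)
}

read_pdb_system <- function(path, box = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(atom_idx)) stop("parse error: no ATOM/HETATM records in ", path)
  short <- atom_idx[nchar(lines[atom_idx]) < 54]
  if (length(short)) {
    stop("parse error in ", path, " line ", short[1],
         ": ATOM/HETATM record truncated (needs coordinate columns 31-54)")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  coords <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  role <- ifelse(at$type == "ATOM", "protein", "ligand")
  particles <- data.frame(
    id = seq_len(nrow(at)),
    role = role,
    species = at$resid,
    residue_label = residue_label_of(at$resid, at$resno),
    chain = ifelse(is.na(at$chain), "", at$chain),
    stringsAsFactors = FALSE
  )
  if (is.null(box)) {
    cr <- lines[startsWith(lines, "CRYST1")]
    if (length(cr)) {
      box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                          substr(cr[1], 25, 33))) / 10
    }
    if (is.null(box) || any(!is.finite(box)) || any(box <= 0)) {
      box <- apply(coords, 2, function(v) diff(range(v))) + 2
    }
  }
  membrane_system(particles, coords, box)
}

read_gro_system <- function(path, box = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("parse error in ", path, ": fewer than 3 lines")
  n_at <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n_at) || n_at < 1) stop("parse error in ", path, " line 2: bad atom count")
  if (length(lines) < 2 + n_at) {
    stop("parse error in ", path, ": expected ", n_at, " atom records")
  }
  atom_lines <- lines[3:(2 + n_at)]
  # GRO fixed columns: resno(1-5) resname(6-10) atomname(11-15) serial(16-20)
  # x(21-28) y(29-36) z(37-44), nm
  short <- which(nchar(atom_lines) < 44)
  if (length(short)) {
    stop("parse error in ", path, " line ", 2 + short[1],
         ": GRO record truncated (needs 44 columns)")
  }
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(atom_lines, a, b)))
    if (anyNA(v)) {
      stop("parse error in ", path, " line ", 2 + which(is.na(v))[1],
           ": non-numeric field in columns ", a, "-", b)
    }
    v
  }
  resno <- as.integer(trimws(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  coords <- cbind(num(21, 28), num(29, 36), num(37, 44))
  role <- ifelse(toupper(resname) %in% names(AA3TO1), "protein", "ligand")
  particles <- data.frame(
    id = seq_len(n_at),
    role = role,
    species = resname,
    residue_label = residue_label_of(resname, resno),
    chain = "",
    stringsAsFactors = FALSE
  )
  if (is.null(box)) {
    if (length(lines) < 2 + n_at + 1) {
      stop("parse error in ", path, ": missing box line after atom records")
    }
    bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + n_at + 1]),
                                               "\\s+")[[1]]))
    if (length(bx) < 3 || anyNA(bx[1:3]) || any(bx[1:3] <= 0)) {
      stop("parse error in ", path, " line ", 2 + n_at + 1, ": bad box line")
    }
    box <- bx[1:3]
  }
  membrane_system(particles, coords, box)
}
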