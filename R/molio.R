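# PDB input: atom records and the ordered atom selections (C-alpha for
# proteins, phosphorus for nucleic acids) whose sequence order drives the
# edge-flow signs.

.water_resids <- c("HOH", "WAT", "H2O", "DOD", "SOL")
.ion_resids <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "FE2",
                 "NI", "CU", "CO", "CD", "HG", "BR", "IOD", "CS", "LI",
                 "SR", "BA", "RB", "F", "SO4", "PO4")

#' Read atom records from a PDB file
#'
#' Fixed-column PDB parsing is delegated to \pkg{bio3d}; this wrapper selects
#' one model (for NMR-style multi-model files) and returns a flat record
#' table in file order.  Both ATOM and HETATM records are retained at this
#' layer; filtering happens in [select_atoms()].
#'
#' @param path Path to a PDB file.
#' @param model Model number to read (default 1, the first).
#' @return `data.frame` with one row per atom: `type`, `eleno`, `elety`
#'   (atom name), `alt` (alternate location), `resid`, `chain`, `resno`,
#'   `insert`, `o` (occupancy), `elesy` (element), `x`, `y`, `z`, `index`
#'   (file order).
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  n_models <- nrow(pdb$xyz)
  model <- as.integer(model)
  if (model < 1L || model > n_models)
    stop("model ", model, " not present ('", path, "' has ",
         n_models, " model", if (n_models > 1) "s", ")")
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  if (nrow(xyz) != nrow(at))
    stop("coordinate/record count mismatch in '", path, "'")
  rec <- data.frame(
    type = at$type, eleno = at$eleno, elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid, chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    o = ifelse(is.na(at$o), 1, at$o),
    elesy = ifelse(is.na(at$elesy), "", at$elesy),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    index = seq_len(nrow(at)),
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(rec[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  rec
}

#' Select and order atoms into a point cloud
#'
#' Filters atom records to the selection the analysis needs and orders them
#' by chain appearance (file order of first occurrence), residue number and
#' insertion code — the chain-sequence order that defines the edge-flow
#' signs.  Waters and common monatomic ions are always excluded.  Alternate
#' locations are collapsed to the highest-occupancy conformer (ties broken
#' towards altloc "A").
#'
#' @param records Atom table from [read_pdb()].
#' @param mode One of `"calpha"` (protein C-alpha atoms, ATOM records),
#'   `"phosphorus"` (nucleic-acid backbone P atoms, ATOM or HETATM),
#'   `"heavy"` (all non-hydrogen atoms) or `"names"` (explicit atom-name
#'   list via `atom_names`).
#' @param atom_names Character vector of atom names, used when
#'   `mode = "names"`.
#' @return A [point_cloud()] with ids `"chain:resno[insert]:name"`.
#' @export
select_atoms <- function(records,
                         mode = c("calpha", "phosphorus", "heavy", "names"),
                         atom_names = NULL) {
  mode <- match.arg(mode)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a nonempty atom table from read_pdb()")
  r <- records[!(records$resid %in% .water_resids) &
               !(records$resid %in% .ion_resids), , drop = FALSE]
  keep <- switch(mode,
    calpha = r$elety == "CA" & r$type == "ATOM",
    phosphorus = r$elety == "P",
    heavy = !(toupper(r$elesy) == "H" |
              (r$elesy == "" & grepl("^H", r$elety))),
    names = {
      if (is.null(atom_names)) stop("mode 'names' requires 'atom_names'")
      r$elety %in% atom_names
    })
  r <- r[keep, , drop = FALSE]
  if (nrow(r) == 0L) stop("atom selection '", mode, "' is empty")
  # collapse altlocs: highest occupancy wins, ties resolved towards "A"
  key <- paste(r$chain, r$resno, r$insert, r$elety, sep = "\r")
  r <- r[order(key, -r$o, r$alt, r$index), , drop = FALSE]
  r <- r[!duplicated(paste(r$chain, r$resno, r$insert, r$elety, sep = "\r")), ,
         drop = FALSE]
  # chain-sequence order: chains in order of first appearance in the file
  chain_levels <- unique(records$chain[order(records$index)])
  r <- r[order(match(r$chain, chain_levels), r$resno, r$insert, r$index), ,
         drop = FALSE]
  ids <- paste0(r$chain, ":", r$resno, r$insert, ":", r$elety)
  point_cloud(as.matrix(r[, c("x", "y", "z")]), ids = ids)
}

#' Write a point cloud as TSV
#'
#' Columns `id`, `x`, `y`, `z`; row order is the sequence order.
#'
#' @param points A [point_cloud()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_points_tsv <- function(points, path) {
  stopifnot(inherits(points, "point_cloud"))
  tab <- data.frame(id = points$ids, x = points$coords[, 1L],
                    y = points$coords[, 2L], z = points$coords[, 3L])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a point cloud from TSV
#'
#' Inverse of [write_points_tsv()]: expects columns `id`, `x`, `y`, `z`.
#'
#' @param path Input file path.
#' @return A [point_cloud()].
#' @export
read_points_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y", "z") %in% names(tab)))
    stop("'", path, "' must have columns id, x, y, z")
  point_cloud(as.matrix(tab[, c("x", "y", "z")]), ids = as.character(tab$id))
}

#' Folding table for a set of DNA/chromatin structures
#'
#' Reproduces the atomic-level DNA folding analysis: for each PDB file the
#' phosphorus atoms are selected and TI/AI computed at each cutoff distance.
#' Typical inputs are a B-DNA helix, a nucleosome and a tetranucleosome,
#' whose TI/AI increase with the degree of chain folding; a bare helix forms
#' no 2-simplices below ~12 Angstrom and therefore has TI = 0 there.
#'
#' @param paths Named character vector of PDB file paths.
#' @param cutoffs Numeric vector of Rips cutoffs in Angstrom
#'   (default `c(10, 12, 14, 16, 18, 20)`).
#' @param mode Atom selection mode (default `"phosphorus"`).
#' @return `data.frame` with columns `structure`, `cutoff`, `n_atoms`,
#'   `TI`, `AI`, `n_edges`, `n_triangles`.
#' @export
dna_folding_table <- function(paths, cutoffs = c(10, 12, 14, 16, 18, 20),
                              mode = "phosphorus") {
  stopifnot(length(paths) >= 1L)
  nm <- names(paths) %||% basename(paths)
  rows <- list()
  for (i in seq_along(paths)) {
    pc <- select_atoms(read_pdb(paths[[i]]), mode = mode)
    for (co in cutoffs) {
      sc <- structure_inconsistency(pc, cutoff = co)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = nm[i], cutoff = co, n_atoms = length(pc),
        TI = sc$TI, AI = sc$AI,
        n_edges = sc$n_edges, n_triangles = sc$n_triangles)
    }
  }
  do.call(rbind, rows)
}
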