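#' Structure-preparation configuration
#'
#' Collects the knobs used by [read_structure()], [compute_sasa()],
#' [assign_partial_charges()] and [filter_by_resolution()].
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param sphere_points Number of deterministic Fibonacci-lattice points per
#'   atom for SASA integration (default 960; must be at least 100).
#' @param charge_source `"lookup"` for the bundled residue/atom template
#'   table, or `"external_file"` to read per-atom charges from a delimited
#'   file.
#' @param max_resolution Resolution cutoff in Angstrom for
#'   [filter_by_resolution()] (default 3.0; structures at the cutoff are
#'   kept).
#' @param on_unknown_element `"warn"` to assign `fallback_radius` to atoms
#'   with an unrecognised element symbol, `"error"` to stop.
#' @param fallback_radius Radius in Angstrom for unknown elements (default
#'   1.7).
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(probe_radius = 1.4, sphere_points = 960,
                        charge_source = c("lookup", "external_file"),
                        max_resolution = 3.0,
                        on_unknown_element = c("warn", "error"),
                        fallback_radius = 1.7) {
  stopifnot(probe_radius > 0, sphere_points >= 100, max_resolution > 0)
  structure(
    list(probe_radius = probe_radius, sphere_points = as.integer(sphere_points),
         charge_source = match.arg(charge_source),
         max_resolution = max_resolution,
         on_unknown_element = match.arg(on_unknown_element),
         fallback_radius = fallback_radius),
    class = "prep_config"
  )
}

# scan header text for an experimental resolution; NA when absent
scan_resolution <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "mmcif") {
    for (key in c("_refine.ls_d_res_high", "_reflns.d_resolution_high")) {
      hit <- grep(key, lines, fixed = TRUE, value = TRUE)
      if (length(hit)) {
        val <- suppressWarnings(as.numeric(sub(".*\\s", "", trimws(hit[1]))))
        if (!is.na(val)) return(val)
      }
    }
  } else {
    hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(hit)) {
      val <- suppressWarnings(as.numeric(regmatches(
        hit[1], regexpr("[0-9]+\\.?[0-9]*", sub("RESOLUTION\\.", "", hit[1])))))
      if (!is.na(val) && length(val)) return(val)
    }
  }
  NA_real_
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 5L, warn = FALSE)
  if (any(grepl("^data_|^loop_|^_atom_site", head))) "mmcif" else "pdb"
}

#' Read and annotate a macromolecular structure
#'
#' Parses an mmCIF or PDB file into a flat atom tibble, resolves alternate
#' locations to the highest-occupancy conformer (ties broken by label order),
#' classifies every atom into an entity class (protein, nucleic, ligand, ion,
#' water), assigns van der Waals radii from the bundled element table and
#' records the experimental resolution when the header carries one.
#'
#' @param path Path to an mmCIF or PDB file.
#' @param format `"auto"` (default), `"mmcif"` or `"pdb"`.
#' @param config A [prep_config()].
#' @param id Structure identifier stored in the metadata; defaults to the
#'   file name without extension.
#' @return An `annotated_structure`: a list with
#'   \describe{
#'     \item{atoms}{tibble with one row per atom: `serial`, `atom_name`,
#'       `element`, `x`, `y`, `z`, `chain`, `residue_name`, `residue_seq`,
#'       `insert`, `entity_class`, `is_hetatm`, `is_backbone`, `occupancy`,
#'       `vdw_radius`, `partial_charge`, `sasa`.}
#'     \item{metadata}{list with `id` and `resolution` (Angstrom or `NA`).}
#'   }
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           config = prep_config(), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  elem <- trimws(at$elesy)
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- element_from_atom_name(at$elety[miss])
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = normalize_element(elem),
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_name = toupper(trimws(at$resid)),
    residue_seq = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    alt = ifelse(is.na(at$alt), "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    is_hetatm = at$type == "HETATM"
  )
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  res_id <- paste(atoms$chain, atoms$residue_seq, atoms$insert, atoms$residue_name)
  n_in_res <- as.integer(table(res_id)[res_id])
  atoms$entity_class <- classify_entity(atoms$residue_name, atoms$is_hetatm, n_in_res)
  atoms$is_backbone <- atoms$entity_class == "protein" &
    atoms$atom_name %in% c("N", "CA", "C", "O")
  atoms$vdw_radius <- vdw_radius(atoms$element,
                                 fallback = config$fallback_radius,
                                 on_unknown = config$on_unknown_element)
  atoms$partial_charge <- NA_real_
  atoms$sasa <- NA_real_
  new_annotated_structure(
    atoms,
    metadata = list(id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id,
                    resolution = scan_resolution(path, format))
  )
}

new_annotated_structure <- function(atoms, metadata) {
  structure(list(atoms = tibble::as_tibble(atoms), metadata = metadata),
            class = "annotated_structure")
}

#' @export
print.annotated_structure <- function(x, ...) {
  res <- residue_table(x)
  cat("<annotated_structure> ", x$metadata$id, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), "; residues: ", nrow(res),
      "; chains: ", length(unique(x$atoms$chain)), "\n", sep = "")
  cat("  resolution: ",
      if (is.na(x$metadata$resolution)) "not recorded"
      else paste0(x$metadata$resolution, " A"), "\n", sep = "")
  cls <- table(x$atoms$entity_class)
  cat("  entity atoms:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# keep the highest-occupancy alternate location per (chain, residue, atom);
# ties resolved by label (file) order
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$residue_seq, atoms$insert, atoms$atom_name)
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  keep <- !duplicated(key[ord])
  atoms[sort(seq_len(nrow(atoms))[ord][keep]), , drop = FALSE]
}

normalize_element <- function(elem) {
  out <- toupper(trimws(elem))
  # canonical case: first upper, rest lower (Cl, Br, Fe ...)
  ifelse(nchar(out) > 1,
         paste0(substr(out, 1, 1), tolower(substr(out, 2, nchar(out)))),
         out)
}

# fallback element inference from a PDB atom name
element_from_atom_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- substr(nm, 1, 1)
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU", "NI", "CO")
  out[two %in% known2 & nchar(nm) <= 2] <- two[two %in% known2 & nchar(nm) <= 2]
  out
}

#' Per-residue summary table of a structure
#'
#' @param structure An `annotated_structure`.
#' @return Tibble with one row per residue: `chain`, `residue_seq`, `insert`,
#'   `residue_name`, `entity_class`, `n_atoms`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  dplyr::summarise(
    dplyr::group_by(a, .data$chain, .data$residue_seq, .data$insert,
                    .data$residue_name, .data$entity_class),
    n_atoms = dplyr::n(), .groups = "drop"
  )
}

#' Keep structures at or better than a resolution cutoff
#'
#' Structures whose recorded resolution is less than or equal to
#' `config$max_resolution` are kept; structures lacking a recorded resolution
#' are dropped and counted in a message.
#'
#' @param structures A list of `annotated_structure` objects.
#' @param config A [prep_config()].
#' @return The filtered list.
#' @export
filter_by_resolution <- function(structures, config = prep_config()) {
  res <- vapply(structures, function(s) {
    r <- s$metadata$resolution
    if (is.null(r)) NA_real_ else r
  }, numeric(1))
  n_missing <- sum(is.na(res))
  if (n_missing > 0) {
    message(n_missing, " structure(s) dropped: no recorded resolution")
  }
  structures[!is.na(res) & res <= config$max_resolution]
}

#' Write per-atom annotations as a JSON-lines sidecar
#'
#' Emits one JSON object per atom (serial, chain, residue, element, entity
#' class, radius, charge, SASA); coordinates stay in the original structure
#' file.
#'
#' @param structure An `annotated_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atom_annotations <- function(structure, path) {
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    writeLines(jsonlite::toJSON(as.list(a[i, c(
      "serial", "atom_name", "element", "chain", "residue_name",
      "residue_seq", "insert", "entity_class", "vdw_radius",
      "partial_charge", "sasa")]), auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}
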