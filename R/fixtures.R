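# Deterministic synthetic-fixture generators: everything the stack consumes
# (structures with placed ligands, learnable voxel datasets, progress curves,
# dose-response and melt curves, mutation tables) can be built at desk scale
# with no downloads. All generators are pure functions of their arguments
# and seed.

#' Build an ideal-helix toy structure with placed hetero atoms
#'
#' Generates an alpha-helical peptide backbone (N, CA, C, O and a CB stub
#' per residue; 1.5 Angstrom rise, 100 degrees per residue) and places
#' ligand/ion/nucleic/water atoms at exact requested distances from named
#' residue atoms, along the outward radial direction so the placed atom is
#' closest to its target residue. Optionally writes a minimal, standards-
#' valid mmCIF file.
#'
#' @param n_res Number of residues (>= 3).
#' @param residues Three-letter residue names, recycled (default `"ALA"`).
#' @param placements List of hetero-atom placements:
#'   `list(element =, residue =, distance =, atom = "CB", class = "ligand")`;
#'   `class` is one of ligand, ion, nucleic, water and controls the emitted
#'   residue record (`LIG`/`NA`/`DA`/`HOH`).
#' @param jitter Gaussian coordinate noise in Angstrom (default 0).
#' @param seed Seed for the jitter.
#' @param resolution Optional resolution in Angstrom recorded in the file
#'   header and metadata.
#' @param path Optional path of an mmCIF file to write.
#' @param id Structure id.
#' @return An `annotated_structure` (radii and entity classes populated;
#'   charges/SASA via [annotate_structure()]).
#' @export
make_toy_structure <- function(n_res, residues = "ALA", placements = list(),
                               jitter = 0, seed = 1L, resolution = NA_real_,
                               path = NULL, id = "toy") {
  stopifnot(n_res >= 3)
  residues <- rep_len(toupper(residues), n_res)
  delta <- 100 * pi / 180
  rise <- 1.5
  radius <- 2.3
  rows <- list()
  serial <- 0L
  add_atom <- function(name, element, xyz, resno, resname, het = FALSE) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      serial = serial, atom_name = name, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], chain = if (het) "B" else "A",
      residue_name = resname, residue_seq = resno, insert = "",
      occupancy = 1, is_hetatm = het)
  }
  for (i in seq_len(n_res)) {
    ang <- i * delta
    ca <- c(radius * cos(ang), radius * sin(ang), rise * i)
    tangent <- c(-radius * delta * sin(ang), radius * delta * cos(ang), rise)
    tangent <- tangent / sqrt(sum(tangent^2))
    # backbone N/C placed so the virtual C-beta points outward from the
    # helix axis, as side chains do
    outward <- c(cos(ang), sin(ang), 0)
    Npos <- ca - 1.46 * (0.86 * tangent + 0.5 * outward)
    Cpos <- ca + 1.52 * (0.86 * tangent - 0.5 * outward)
    b <- cross3(tangent, outward)
    Opos <- Cpos + 1.23 * b
    add_atom("N", "N", Npos, i, residues[i])
    add_atom("CA", "C", ca, i, residues[i])
    add_atom("C", "C", Cpos, i, residues[i])
    add_atom("O", "O", Opos, i, residues[i])
    if (residues[i] != "GLY") {
      add_atom("CB", "C", virtual_cbeta(Npos, ca, Cpos), i, residues[i])
    }
  }
  atoms <- dplyr::bind_rows(rows)
  if (jitter > 0) {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng), add = TRUE)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), sd = jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), sd = jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), sd = jitter)
  }
  het_resno <- n_res
  for (pl in placements) {
    cls <- pl$class %||% "ligand"
    atom <- pl$atom %||% "CB"
    target <- atoms[atoms$residue_seq == pl$residue & atoms$atom_name == atom &
                      !atoms$is_hetatm, , drop = FALSE]
    if (nrow(target) != 1) stop("placement target ", pl$residue, "/", atom,
                                " not found")
    t_xyz <- c(target$x, target$y, target$z)
    # deterministic direction search: among a fixed candidate set, keep
    # directions where the placed atom's nearest structure atom is the
    # target at exactly the requested distance, and maximize the clearance
    # to every other atom
    dirs <- fibonacci_sphere(200)
    best_dir <- NULL
    best_clear <- -Inf
    others <- atoms[!(atoms$residue_seq == pl$residue &
                        atoms$atom_name == atom & !atoms$is_hetatm), ]
    for (di in seq_len(nrow(dirs))) {
      pos_c <- t_xyz + pl$distance * dirs[di, ]
      clear <- min(sqrt((others$x - pos_c[1])^2 + (others$y - pos_c[2])^2 +
                          (others$z - pos_c[3])^2))
      if (clear > best_clear) {
        best_clear <- clear
        best_dir <- dirs[di, ]
      }
    }
    if (best_clear < pl$distance - 1e-9) {
      stop("infeasible placement: no direction keeps residue ", pl$residue,
           "/", atom, " as the nearest atom at ", pl$distance,
           " A (best clearance ", round(best_clear, 3), " A)")
    }
    pos <- t_xyz + pl$distance * best_dir
    resname <- switch(cls, ligand = "LIG", ion = toupper(pl$element),
                      nucleic = "DA", water = "HOH")
    het_resno <- het_resno + 1L
    rows_np <- tibble::tibble(
      serial = max(atoms$serial) + 1L,
      atom_name = toupper(pl$element), element = pl$element,
      x = pos[1], y = pos[2], z = pos[3],
      chain = if (cls == "nucleic") "N" else "B",
      residue_name = resname, residue_seq = het_resno, insert = "",
      occupancy = 1, is_hetatm = cls != "nucleic")
    atoms <- dplyr::bind_rows(atoms, rows_np)
  }
  n_in_res <- as.integer(table(paste(atoms$chain, atoms$residue_seq))[
    paste(atoms$chain, atoms$residue_seq)])
  atoms$entity_class <- classify_entity(atoms$residue_name, atoms$is_hetatm,
                                        n_in_res)
  atoms$is_backbone <- atoms$entity_class == "protein" &
    atoms$atom_name %in% c("N", "CA", "C", "O")
  atoms$vdw_radius <- vdw_radius(atoms$element)
  atoms$partial_charge <- NA_real_
  atoms$sasa <- NA_real_
  s <- new_annotated_structure(atoms, metadata = list(id = id,
                                                      resolution = resolution))
  if (!is.null(path)) write_mmcif(s, path)
  s
}

#' Write an annotated structure as a minimal mmCIF file
#'
#' Emits the `_atom_site` loop (plus `_struct.title` and, when present,
#' `_refine.ls_d_res_high`) with the category items standard readers
#' require.
#'
#' @param structure An `annotated_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(structure, path) {
  a <- structure$atoms
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$metadata$id)),
    "#",
    paste0("_struct.title '", structure$metadata$id, "'"),
    "#"
  )
  if (!is.na(structure$metadata$resolution)) {
    lines <- c(lines,
               sprintf("_refine.ls_d_res_high %.2f", structure$metadata$resolution),
               "#")
  }
  lines <- c(lines, "loop_",
             "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
             "_atom_site.label_atom_id", "_atom_site.label_alt_id",
             "_atom_site.label_comp_id", "_atom_site.label_asym_id",
             "_atom_site.label_entity_id", "_atom_site.label_seq_id",
             "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num")
  recs <- sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(a$is_hetatm, "HETATM", "ATOM"), a$serial, a$element, a$atom_name,
    a$residue_name, a$chain, a$residue_seq,
    ifelse(a$insert == "", "?", a$insert),
    a$x, a$y, a$z, a$occupancy, 0, a$residue_seq, a$residue_name, a$chain,
    a$atom_name)
  writeLines(c(lines, recs, "#"), path)
  invisible(path)
}

# fixed per-class atom motifs for the pseudo-residue dataset; class
# templates depend only on the class index, never on the user seed
pseudo_class_motif <- function(class_index, n_min = 4L, n_max = 9L) {
  rng <- local_rng(202600L + class_index)
  on.exit(restore_rng(rng))
  n_atoms <- sample(n_min:n_max, 1)
  elements <- sample(c("C", "H", "O", "N", "S", "P", "Cl"), n_atoms,
                     replace = TRUE)
  tibble::tibble(
    element = elements,
    fx = stats::runif(n_atoms, -6, 6),
    fy = stats::runif(n_atoms, -6, 6),
    fz = stats::runif(n_atoms, -6, 6),
    vdw_radius = vdw_radius(elements),
    partial_charge = round(stats::runif(n_atoms, -0.5, 0.5), 2),
    sasa = round(stats::runif(n_atoms, 0, 30), 1))
}

#' Generate the learnable 20-class pseudo-residue voxel dataset
#'
#' Each amino-acid class gets a fixed, distinct atom motif (class-specific
#' element composition and geometry, drawn once from a class-keyed RNG);
#' instances jitter the motif coordinates with Gaussian noise and are
#' voxelized through the real [voxelize()] path. Labels are balanced. This
#' is the desk-scale learnability surrogate for the PDB-scale masked-residue
#' task.
#'
#' @param n_per_class Instances per class (>= 10 for a meaningful split).
#' @param noise_sigma Coordinate jitter standard deviation in Angstrom.
#' @param seed Seed for the jitter.
#' @param config A [voxel_config()].
#' @param permute_labels If `TRUE`, labels are randomly permuted across the
#'   dataset (chance-level control).
#' @return A `voxel_dataset` with `labels` in 1..20 and metadata rows.
#' @export
make_pseudo_residue_dataset <- function(n_per_class, noise_sigma = 0.3,
                                        seed = 1L, config = voxel_config(),
                                        permute_labels = FALSE) {
  stopifnot(n_per_class >= 1)
  motifs <- lapply(1:20, pseudo_class_motif)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  n_total <- 20L * n_per_class
  ds <- voxel_dataset(config)
  ds$grids <- vector("list", n_total)
  ds$labels <- integer(n_total)
  meta <- vector("list", n_total)
  i <- 0L
  for (cls in 1:20) {
    for (rep_i in seq_len(n_per_class)) {
      i <- i + 1L
      m <- motifs[[cls]]
      if (noise_sigma > 0) {
        m$fx <- m$fx + stats::rnorm(nrow(m), sd = noise_sigma)
        m$fy <- m$fy + stats::rnorm(nrow(m), sd = noise_sigma)
        m$fz <- m$fz + stats::rnorm(nrow(m), sd = noise_sigma)
        m$fx <- pmin(pmax(m$fx, -config$box_edge / 2), config$box_edge / 2)
        m$fy <- pmin(pmax(m$fy, -config$box_edge / 2), config$box_edge / 2)
        m$fz <- pmin(pmax(m$fz, -config$box_edge / 2), config$box_edge / 2)
      }
      ds$grids[[i]] <- voxelize(m, config)
      ds$labels[i] <- cls
      meta[[i]] <- tibble::tibble(
        structure_id = "pseudo", chain = "A", residue_seq = i, insert = "",
        wt_aa = cls, interface_flag = FALSE, interface_kind = "")
    }
  }
  if (permute_labels) ds$labels <- sample(ds$labels)
  ds$meta <- dplyr::bind_rows(meta)
  ds
}

#' Simulate noisy progress curves from a kinetic scheme
#'
#' Triplicate (by default) observations of the scheme observable at the
#' assay design's substrate levels and times, with multiplicative Gaussian
#' noise.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named values for the floating rates (true parameters).
#' @param design An [assay_design()].
#' @param noise_frac Multiplicative noise fraction (0 for exact curves).
#' @param seed Seed for the noise.
#' @return Tibble: `substrate_uM`, `replicate`, `time_min`, `product_uM`.
#' @export
make_kinetics_curves <- function(scheme, rates, design = assay_design(),
                                 noise_frac = 0.02, seed = 1L) {
  m <- model_observable(scheme, rates, design)
  out <- tidyr::crossing(replicate = seq_len(design$replicates),
                         m)[, c("substrate_uM", "replicate", "time_min", "model")]
  out <- dplyr::arrange(out, .data$substrate_uM, .data$replicate, .data$time_min)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  eps <- if (noise_frac > 0) stats::rnorm(nrow(out), 0, noise_frac) else 0
  out$product_uM <- out$model * (1 + eps)
  out$model <- NULL
  out
}

#' Generate a Hill-shaped dose-response curve
#'
#' @param a,d,b,c Hill parameters (maximum, background, coefficient, EC50).
#' @param x Concentrations; default 9 log-spaced points around `c` plus 0.
#' @param noise_sd Additive Gaussian noise SD on the signal.
#' @param seed Seed.
#' @return Tibble: `conc`, `signal`.
#' @export
make_dose_response <- function(a = 100, d = 5, b = 1.5, c = 20,
                               x = NULL, noise_sd = 0, seed = 1L) {
  if (is.null(x)) x <- c(0, exp(seq(log(c / 50), log(c * 50), length.out = 9)))
  y <- d + (a - d) * ifelse(x > 0, x^b / (c^b + x^b), 0)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng))
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  tibble::tibble(conc = x, signal = y)
}

#' Generate a Boltzmann-shaped thermal melt curve
#'
#' @param tm Midpoint temperature, deg C.
#' @param slope Transition slope, deg C.
#' @param f_min,f_max Baseline and plateau fluorescence.
#' @param temps Temperature series (default 20-95 deg C in 0.5 steps).
#' @param noise_sd Additive noise SD.
#' @param seed Seed.
#' @return Tibble: `temp_C`, `signal`.
#' @export
make_melt_curve <- function(tm = 52.8, slope = 1.8, f_min = 100, f_max = 1200,
                            temps = seq(20, 95, by = 0.5), noise_sd = 0,
                            seed = 1L) {
  y <- f_min + (f_max - f_min) / (1 + exp((tm - temps) / slope))
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    on.exit(restore_rng(rng))
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  tibble::tibble(temp_C = temps, signal = y)
}

#' Generate a mutation table with planted prediction profiles
#'
#' Builds `n` single point mutations with planted log-odds scores and
#' experimental dTm values whose population correlation with the scores is
#' `rho` (1 gives an exactly linear relation), plus the matching prediction
#' profiles so [zero_shot_benchmark()] can be run without a trained model.
#'
#' @param n Number of mutations.
#' @param rho Planted correlation between log-odds and dTm.
#' @param seed Seed.
#' @param structure_id Structure id used in the table.
#' @return List with `table` (tibble `structure, chain, position, wt, mut,
#'   dTm`) and `profiles` (named list keyed `"<structure>|<chain>|<position>"`
#'   of 20-probability vectors whose log-odds equal the planted scores).
#' @export
make_mutation_table <- function(n, rho = 1, seed = 1L, structure_id = "fix") {
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  wt <- sample(1:20, n, replace = TRUE)
  mut <- vapply(wt, function(w) sample(setdiff(1:20, w), 1), integer(1))
  z <- stats::rnorm(n)
  log_odds_true <- z
  dTm <- if (rho >= 1) z else rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
  profiles <- vector("list", n)
  keys <- character(n)
  for (i in seq_len(n)) {
    p <- rep(1, 20)
    p[mut[i]] <- exp(log_odds_true[i])   # p[mut]/p[wt] = exp(planted score)
    p <- p / sum(p)
    keys[i] <- paste(structure_id, "A", i, sep = "|")
    profiles[[i]] <- stats::setNames(p, aa_alphabet())
  }
  names(profiles) <- keys
  list(
    table = tibble::tibble(structure = structure_id, chain = "A",
                           position = seq_len(n), wt = aa_alphabet()[wt],
                           mut = aa_alphabet()[mut], dTm = dTm),
    profiles = profiles)
}
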