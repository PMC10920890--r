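# deterministic molecule-fixed orthonormal frame: axes derive from atom
# displacement vectors (farthest atom from the centroid, then the atom with
# the largest orthogonal component), so a rigid motion of the coordinates
# rotates the frame identically and SASA sampling is rigid-motion invariant
molecular_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(diag(3))
  center <- colMeans(xyz)
  rel <- sweep(xyz, 2, center)
  d2 <- rowSums(rel^2)
  i1 <- which.max(d2)
  if (d2[i1] < 1e-16) return(diag(3))
  e1 <- rel[i1, ] / sqrt(d2[i1])
  perp <- rel - outer(as.vector(rel %*% e1), e1)
  p2 <- rowSums(perp^2)
  i2 <- which.max(p2)
  if (p2[i2] < 1e-16) {
    # collinear molecule: occlusion is symmetric about e1, any completion works
    ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- ref - sum(ref * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
  } else {
    e2 <- perp[i2, ] / sqrt(p2[i2])
  }
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rbind(e1, e2, e3)
}

# deterministic Fibonacci lattice on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Compute per-atom solvent-accessible surface area
#'
#' Shrake-Rupley style SASA with a deterministic Fibonacci-lattice point set:
#' for each atom, `sphere_points` points are placed on the sphere of radius
#' `vdw_radius + probe_radius`; a point is accessible if it lies outside the
#' expanded sphere of every other atom. SASA is the accessible fraction times
#' the sphere area. Every atom of every entity class (ligands, ions, nucleic
#' acids) participates as an occluder, so protein:non-protein burial is
#' accounted for. Waters occlude too when present in the structure. The
#' lattice directions are anchored to a molecule-fixed frame, so rigidly
#' moving the structure leaves every per-atom SASA unchanged.
#'
#' @param structure An `annotated_structure` with coordinates and radii.
#' @param config A [prep_config()]; `probe_radius` and `sphere_points` are
#'   used.
#' @return The structure with `atoms$sasa` populated (Angstrom^2).
#' @export
compute_sasa <- function(structure, config = prep_config()) {
  a <- structure$atoms
  n <- nrow(a)
  if (n == 0) return(structure)
  xyz <- cbind(a$x, a$y, a$z)
  # lattice directions expressed in a molecule-fixed frame
  pts <- fibonacci_sphere(config$sphere_points) %*% molecular_frame(xyz)
  rad <- a$vdw_radius + config$probe_radius
  max_rad <- max(rad)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rad[i]
    # neighbours whose expanded spheres can reach atom i's test sphere
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + rad)^2 & seq_len(n) != i)
    if (!length(nb)) {
      sasa[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p <- sweep(p, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 > rad[j]^2
    }
    sasa[i] <- 4 * pi * ri^2 * mean(accessible)
  }
  structure$atoms$sasa <- sasa
  structure
}

# bundled simplified charge template (residue, atom, charge)
charge_template <- function() {
  path <- system.file("extdata", "charge_template.csv", package = "voxdesign",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

#' Assign per-atom partial charges
#'
#' With `charge_source = "lookup"` charges come from the bundled
#' residue/atom-name template table (a simplified additive set in which every
#' neutral residue sums to 0 e and charged residues to their formal charge);
#' atoms without a template entry get 0.0 with a single summary warning. With
#' `charge_source = "external_file"` charges are read from a delimited file
#' with columns `chain,residue_seq,atom_name,charge` (typically produced by a
#' dedicated charge program) and every structure atom must be present.
#'
#' @param structure An `annotated_structure`.
#' @param config A [prep_config()]; `charge_source` selects the mode.
#' @param charge_file Path to the per-atom charge file when
#'   `charge_source = "external_file"`.
#' @return The structure with `atoms$partial_charge` populated (e units).
#' @export
assign_partial_charges <- function(structure, config = prep_config(),
                                   charge_file = NULL) {
  a <- structure$atoms
  if (config$charge_source == "lookup") {
    tmpl <- charge_template()
    key <- paste(a$residue_name, a$atom_name)
    q <- tmpl$charge[match(key, paste(tmpl$residue, tmpl$atom))]
    n_miss <- sum(is.na(q))
    if (n_miss > 0) {
      warning(n_miss, " atom(s) had no charge-template entry; assigned 0.0 e")
      q[is.na(q)] <- 0
    }
    structure$atoms$partial_charge <- q
  } else {
    if (is.null(charge_file)) stop("charge_source = 'external_file' needs a charge_file")
    ext <- utils::read.csv(charge_file, stringsAsFactors = FALSE)
    need <- c("chain", "residue_seq", "atom_name", "charge")
    if (!all(need %in% names(ext))) {
      stop("charge file must have columns ", paste(need, collapse = ", "))
    }
    key <- paste(a$chain, a$residue_seq, a$atom_name)
    q <- ext$charge[match(key, paste(ext$chain, ext$residue_seq, ext$atom_name))]
    if (anyNA(q)) {
      missing_keys <- utils::head(key[is.na(q)], 10)
      stop("charge file is missing ", sum(is.na(q)), " atom(s); first keys: ",
           paste(missing_keys, collapse = "; "))
    }
    structure$atoms$partial_charge <- q
  }
  structure
}

#' Fully annotate a structure in one call
#'
#' Convenience pipeline: [assign_partial_charges()] then [compute_sasa()].
#'
#' @inheritParams assign_partial_charges
#' @return Annotated structure with charges and SASA populated.
#' @export
annotate_structure <- function(structure, config = prep_config(),
                               charge_file = NULL) {
  structure <- assign_partial_charges(structure, config, charge_file)
  compute_sasa(structure, config)
}
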