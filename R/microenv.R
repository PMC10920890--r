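#' Microenvironment sampling configuration
#'
#' @param contact_cutoff Interface contact cutoff in Angstrom (default 5.0,
#'   inclusive at the boundary).
#' @param residue_cap Maximum residues sampled per chain (default 200).
#' @param chain_fraction Fraction of the chain used when it binds before the
#'   cap (default 0.5); the per-chain target is
#'   `min(residue_cap, ceiling(chain_fraction * L))`.
#' @param include_water_as_nonprotein Count crystallographic waters as
#'   non-protein entities for interface flagging (default `FALSE`).
#' @param include_ions_as_nonprotein Count ions for interface flagging
#'   (default `TRUE`).
#' @param truncate_interface If `TRUE`, interface residues beyond the
#'   per-chain target are truncated (in sequence order); default `FALSE`
#'   keeps all of them.
#' @param split_train_fraction Training fraction for [split_dataset()]
#'   (default 0.9).
#' @param box_edge Microenvironment cube edge in Angstrom (default 20).
#' @param seed Integer seed for the sampling and splitting RNG.
#' @return A list of class `sampling_config`.
#' @export
sampling_config <- function(contact_cutoff = 5.0, residue_cap = 200L,
                            chain_fraction = 0.5,
                            include_water_as_nonprotein = FALSE,
                            include_ions_as_nonprotein = TRUE,
                            truncate_interface = FALSE,
                            split_train_fraction = 0.9,
                            box_edge = 20, seed = 1L) {
  stopifnot(contact_cutoff > 0, residue_cap >= 1,
            chain_fraction > 0, chain_fraction <= 1,
            split_train_fraction > 0, split_train_fraction < 1,
            box_edge > 0)
  structure(
    list(contact_cutoff = contact_cutoff, residue_cap = as.integer(residue_cap),
         chain_fraction = chain_fraction,
         include_water_as_nonprotein = include_water_as_nonprotein,
         include_ions_as_nonprotein = include_ions_as_nonprotein,
         truncate_interface = truncate_interface,
         split_train_fraction = split_train_fraction,
         box_edge = box_edge, seed = as.integer(seed)),
    class = "sampling_config"
  )
}

# non-protein entity classes that count for interface flagging
nonprotein_classes <- function(config) {
  cls <- c("ligand", "nucleic")
  if (config$include_ions_as_nonprotein) cls <- c(cls, "ion")
  if (config$include_water_as_nonprotein) cls <- c(cls, "water")
  cls
}

#' Find protein residues at protein:non-protein interfaces
#'
#' A protein residue is flagged when any of its atoms lies within
#' `contact_cutoff` (inclusive) of any atom whose entity class is ligand,
#' nucleic or (by default) ion; waters are excluded by default. Distances are
#' plain atom-to-atom Euclidean distances.
#'
#' @param structure An `annotated_structure`.
#' @param config A [sampling_config()].
#' @return Tibble of flagged residues: `chain`, `residue_seq`, `insert`,
#'   `residue_name`, and `interface_kind` (comma-separated subset of
#'   `ligand,nucleic,ion` naming the contacted classes).
#' @export
find_interface_residues <- function(structure, config = sampling_config()) {
  a <- structure$atoms
  prot <- a[a$entity_class == "protein", , drop = FALSE]
  np <- a[a$entity_class %in% nonprotein_classes(config), , drop = FALSE]
  empty <- tibble::tibble(chain = character(), residue_seq = integer(),
                          insert = character(), residue_name = character(),
                          interface_kind = character())
  if (nrow(prot) == 0 || nrow(np) == 0) return(empty)
  # inclusive at the cutoff; the 1e-9 guard keeps atoms placed at exactly
  # the boundary inside despite floating-point representation of d^2
  cut2 <- config$contact_cutoff^2 + 1e-9
  # all-pairs squared distances protein x non-protein (small n at desk scale)
  d2 <- outer(prot$x, np$x, "-")^2 + outer(prot$y, np$y, "-")^2 +
    outer(prot$z, np$z, "-")^2
  hit <- d2 <= cut2
  if (!any(hit)) return(empty)
  res_key <- paste(prot$chain, prot$residue_seq, prot$insert, sep = "\r")
  rows <- which(rowSums(hit) > 0)
  recs <- lapply(split(rows, res_key[rows]), function(idx) {
    kinds <- sort(unique(np$entity_class[colSums(hit[idx, , drop = FALSE]) > 0]))
    i <- idx[1]
    tibble::tibble(chain = prot$chain[i], residue_seq = prot$residue_seq[i],
                   insert = prot$insert[i], residue_name = prot$residue_name[i],
                   interface_kind = paste(kinds, collapse = ","))
  })
  out <- dplyr::bind_rows(recs)
  dplyr::arrange(out, .data$chain, .data$residue_seq, .data$insert)
}

#' Sample residues from one chain with interface priority
#'
#' The per-chain target is `min(residue_cap, ceiling(chain_fraction * L))`
#' where `L` is the number of protein residues in the chain. All interface
#' residues of the chain come first (sequence order); remaining slots are
#' backfilled by seeded uniform sampling without replacement from the
#' non-interface residues (draw order). If the interface residues alone
#' exceed the target they are all kept unless
#' `config$truncate_interface = TRUE`.
#'
#' @param structure An `annotated_structure`.
#' @param chain_id Chain identifier.
#' @param config A [sampling_config()]; `seed` drives the backfill draw.
#' @return Tibble of sampled residues: `chain`, `residue_seq`, `insert`,
#'   `residue_name`, `wt_aa` (class index 1-20 or `NA` for nonstandard),
#'   `interface_flag`, `interface_kind`.
#' @export
sample_residues <- function(structure, chain_id, config = sampling_config()) {
  res <- residue_table(structure)
  res <- res[res$chain == chain_id & res$entity_class == "protein", , drop = FALSE]
  if (nrow(res) == 0) stop("no protein residues in chain '", chain_id, "'")
  res <- dplyr::arrange(res, .data$residue_seq, .data$insert)
  iface <- find_interface_residues(structure, config)
  iface <- iface[iface$chain == chain_id, , drop = FALSE]
  key <- function(d) paste(d$residue_seq, d$insert, sep = "\r")
  is_iface <- key(res) %in% key(iface)
  L <- nrow(res)
  target <- min(config$residue_cap, ceiling(config$chain_fraction * L))
  iface_res <- res[is_iface, , drop = FALSE]
  rest <- res[!is_iface, , drop = FALSE]
  if (nrow(iface_res) >= target) {
    picked_iface <- if (config$truncate_interface) iface_res[seq_len(target), , drop = FALSE] else iface_res
    picked_rest <- rest[0, , drop = FALSE]
  } else {
    picked_iface <- iface_res
    n_fill <- target - nrow(iface_res)
    rng <- local_rng(config$seed)
    draw <- sample.int(nrow(rest), n_fill)
    restore_rng(rng)
    picked_rest <- rest[draw, , drop = FALSE]
  }
  out <- dplyr::bind_rows(picked_iface, picked_rest)
  out$wt_aa <- aa_index(out$residue_name)
  out$interface_flag <- key(out) %in% key(iface)
  out$interface_kind <- ifelse(out$interface_flag,
                               iface$interface_kind[match(key(out), key(iface))], "")
  out[, c("chain", "residue_seq", "insert", "residue_name", "wt_aa",
          "interface_flag", "interface_kind")]
}

# scoped RNG helpers: seed without clobbering the caller's RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Build the backbone-oriented local frame of a residue
#'
#' The frame origin is the C-alpha. +z points from the C-alpha toward the
#' virtual C-beta constructed from N, CA, C by ideal tetrahedral geometry
#' (bond 1.522 Angstrom, N-CA-CB and C-CA-CB angles 110.4 degrees), so the
#' side chain lies along +z. +x is the component of (N - CA) orthogonal to
#' z; +y = z x x (right-handed).
#'
#' @param N,CA,C Numeric 3-vectors of backbone coordinates (Angstrom).
#' @return List with `origin` (3-vector) and `axes` (3x3 matrix whose rows
#'   are the unit x, y, z axes).
#' @export
build_frame <- function(N, CA, C) {
  N <- as.numeric(N); CA <- as.numeric(CA); C <- as.numeric(C)
  stopifnot(length(N) == 3, length(CA) == 3, length(C) == 3)
  u_n <- N - CA
  u_c <- C - CA
  if (sqrt(sum(u_n^2)) < 1e-8 || sqrt(sum(u_c^2)) < 1e-8) {
    stop("degenerate backbone frame: coincident atoms")
  }
  n <- u_n / sqrt(sum(u_n^2))
  c_ <- u_c / sqrt(sum(u_c^2))
  w <- cross3(n, c_)
  if (sqrt(sum(w^2)) < 1e-8) stop("degenerate backbone frame: collinear N, CA, C")
  bis <- -(n + c_)
  u <- bis / sqrt(sum(bis^2))
  w <- w / sqrt(sum(w^2))
  theta <- 110.4 * pi / 180
  alpha <- cos(theta) / sum(u * n)  # dot(u, n) == dot(u, c) by symmetry
  if (abs(alpha) > 1) stop("degenerate backbone frame: tetrahedral construction infeasible")
  beta <- sqrt(1 - alpha^2)
  z <- alpha * u + beta * w
  z <- z / sqrt(sum(z^2))
  x <- u_n - sum(u_n * z) * z
  if (sqrt(sum(x^2)) < 1e-8) stop("degenerate backbone frame: N - CA parallel to z")
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  list(origin = CA, axes = rbind(x = x, y = y, z = z))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# virtual C-beta position implied by a frame (used by fixtures/tests)
virtual_cbeta <- function(N, CA, C, bond = 1.522) {
  f <- build_frame(N, CA, C)
  CA + bond * f$axes["z", ]
}

#' Extract a center-masked, frame-oriented residue microenvironment
#'
#' Builds the residue's backbone frame, transforms all atoms of the
#' structure into frame coordinates, keeps the atoms inside the axis-aligned
#' cube of edge `box_edge` (inclusive bounds), removes every atom of the
#' center residue, and drops waters. Ligand, ion, cofactor and nucleic-acid
#' atoms are retained as content regardless of the interface toggles.
#'
#' @param structure An `annotated_structure` (annotate first for meaningful
#'   charge/SASA channels).
#' @param chain,residue_seq,insert Identify the center residue.
#' @param config A [sampling_config()]; `box_edge` and the interface toggles
#'   are used.
#' @return A `microenvironment`: list with `key` (chain, residue_seq,
#'   insert, residue_name, wt_aa), `frame`, `atoms` (tibble in frame
#'   coordinates with `fx, fy, fz`), `box_edge`, `interface_flag`,
#'   `interface_kind`.
#' @export
extract_microenvironment <- function(structure, chain, residue_seq,
                                     insert = "", config = sampling_config()) {
  a <- structure$atoms
  in_res <- a$chain == chain & a$residue_seq == residue_seq & a$insert == insert
  if (!any(in_res)) stop("residue ", chain, residue_seq, insert, " not found")
  res_atoms <- a[in_res, , drop = FALSE]
  bb <- function(nm) {
    i <- which(res_atoms$atom_name == nm)
    if (!length(i)) stop("residue ", chain, residue_seq, insert,
                         " lacks backbone atom ", nm)
    c(res_atoms$x[i[1]], res_atoms$y[i[1]], res_atoms$z[i[1]])
  }
  frame <- build_frame(bb("N"), bb("CA"), bb("C"))
  content <- a[!in_res & a$entity_class != "water", , drop = FALSE]
  rel <- cbind(content$x - frame$origin[1],
               content$y - frame$origin[2],
               content$z - frame$origin[3])
  fc <- rel %*% t(frame$axes)
  half <- config$box_edge / 2
  keep <- abs(fc[, 1]) <= half & abs(fc[, 2]) <= half & abs(fc[, 3]) <= half
  content <- content[keep, , drop = FALSE]
  content$fx <- fc[keep, 1]; content$fy <- fc[keep, 2]; content$fz <- fc[keep, 3]
  iface <- find_interface_residues(structure, config)
  hit <- iface$chain == chain & iface$residue_seq == residue_seq & iface$insert == insert
  structure(
    list(key = list(structure_id = structure$metadata$id, chain = chain,
                    residue_seq = residue_seq, insert = insert,
                    residue_name = res_atoms$residue_name[1],
                    wt_aa = aa_index(res_atoms$residue_name[1])),
         frame = frame,
         atoms = tibble::as_tibble(content),
         box_edge = config$box_edge,
         interface_flag = any(hit),
         interface_kind = if (any(hit)) iface$interface_kind[which(hit)[1]] else ""),
    class = "microenvironment"
  )
}

#' @export
print.microenvironment <- function(x, ...) {
  cat("<microenvironment> ", x$key$structure_id, " ", x$key$chain,
      x$key$residue_seq, x$key$insert, " (", x$key$residue_name, ")\n", sep = "")
  cat("  atoms in ", x$box_edge, " A cube: ", nrow(x$atoms),
      "; interface: ", x$interface_flag,
      if (nzchar(x$interface_kind)) paste0(" [", x$interface_kind, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Stratified 90:10 train/test split
#'
#' Splits items into train and test sets independently within the interface
#' and non-interface strata, with the per-stratum train count rounded to the
#' nearest integer, seeded and deterministic.
#'
#' @param items A list of microenvironments, or any list paired with
#'   `interface_flags`.
#' @param config A [sampling_config()]; `split_train_fraction` and `seed`.
#' @param interface_flags Optional logical vector; defaults to each item's
#'   `interface_flag`.
#' @return List with `train` and `test` integer index vectors (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(items, config = sampling_config(),
                          interface_flags = NULL) {
  n <- length(items)
  stopifnot(n >= 1)
  if (is.null(interface_flags)) {
    interface_flags <- vapply(items, function(e) isTRUE(e$interface_flag), logical(1))
  }
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng))
  train <- integer(0)
  for (stratum in unique(interface_flags)) {
    idx <- which(interface_flags == stratum)
    n_train <- round(config$split_train_fraction * length(idx))
    train <- c(train, sort(sample(idx, n_train)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}
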