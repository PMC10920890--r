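#' Voxelization configuration
#'
#' @param box_edge Cube edge in Angstrom (default 20).
#' @param resolution Voxel edge in Angstrom (default 1.0);
#'   `box_edge / resolution` must be a positive integer.
#' @param sigma_scale Factor mapping an atom's van der Waals radius to its
#'   Gaussian sigma (default 0.5).
#' @param truncation Gaussian support radius in multiples of sigma (default
#'   3); contributions beyond it are dropped.
#' @param drop_unchanneled If `TRUE`, atoms whose element has no element
#'   channel (metals, Se, ...) are dropped entirely instead of contributing
#'   to the charge/SASA channels only.
#' @param normalize If `TRUE`, each atom's Gaussian is mass-normalized
#'   (integrates to 1) instead of having unit amplitude at the center.
#' @return A list of class `voxel_config`.
#' @export
voxel_config <- function(box_edge = 20, resolution = 1.0, sigma_scale = 0.5,
                         truncation = 3, drop_unchanneled = FALSE,
                         normalize = FALSE) {
  n <- box_edge / resolution
  stopifnot(sigma_scale > 0, truncation > 0,
            abs(n - round(n)) < 1e-9, n >= 1)
  structure(
    list(box_edge = box_edge, resolution = resolution,
         n_voxel = as.integer(round(n)), sigma_scale = sigma_scale,
         truncation = truncation, drop_unchanneled = drop_unchanneled,
         normalize = normalize),
    class = "voxel_config"
  )
}

# voxel center coordinate of 1-based index i along one axis
voxel_centers <- function(config) {
  (seq_len(config$n_voxel) - 0.5) * config$resolution - config$box_edge / 2
}

#' Voxelize a microenvironment into a 20x20x20x9 tensor
#'
#' Each atom contributes a Gaussian `g(v) = exp(-||v - x||^2 / (2 sigma^2))`
#' with `sigma = sigma_scale * vdw_radius`, evaluated at voxel centers within
#' `truncation * sigma` of the atom, added to its element channel (C, H, O,
#' N, S, P, X-halogen). The same Gaussian field scaled by the atom's partial
#' charge and SASA is added to channels 8 and 9. Contributions sum over
#' atoms.
#'
#' @param env A `microenvironment` (atoms in frame coordinates), or a tibble
#'   with columns `fx, fy, fz, element, vdw_radius, partial_charge, sasa`.
#' @param config A [voxel_config()].
#' @return A numeric array of dimension `c(n, n, n, 9)` with
#'   `n = box_edge / resolution`; `dimnames` carry the channel names. The
#'   value at `[i, j, k, c]` is centered at frame coordinate
#'   `((i - 0.5) * resolution - box_edge / 2, ...)`.
#' @export
voxelize <- function(env, config = voxel_config()) {
  atoms <- if (inherits(env, "microenvironment")) env$atoms else env
  n <- config$n_voxel
  grid <- array(0, dim = c(n, n, n, 9),
                dimnames = list(NULL, NULL, NULL, voxel_channels()))
  if (nrow(atoms) == 0) return(grid)
  bad <- !is.finite(atoms$fx) | !is.finite(atoms$fy) | !is.finite(atoms$fz) |
    !is.finite(atoms$vdw_radius)
  if (any(bad)) {
    stop("non-finite coordinates/values for atom(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  q <- atoms$partial_charge
  s <- atoms$sasa
  q[is.na(q)] <- 0
  s[is.na(s)] <- 0
  if (!all(is.finite(q)) || !all(is.finite(s))) {
    stop("non-finite charge/SASA value in microenvironment atoms")
  }
  centers <- voxel_centers(config)
  chan <- element_channel(atoms$element)
  for (i in seq_len(nrow(atoms))) {
    if (config$drop_unchanneled && is.na(chan[i])) next
    sigma <- config$sigma_scale * atoms$vdw_radius[i]
    rmax <- config$truncation * sigma
    pos <- c(atoms$fx[i], atoms$fy[i], atoms$fz[i])
    ix <- which(abs(centers - pos[1]) <= rmax)
    iy <- which(abs(centers - pos[2]) <= rmax)
    iz <- which(abs(centers - pos[3]) <= rmax)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (centers[ix] - pos[1])^2
    dy2 <- (centers[iy] - pos[2])^2
    dz2 <- (centers[iz] - pos[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > rmax^2] <- 0  # spherical truncation
    if (config$normalize) g <- g / (2 * pi * sigma^2)^1.5
    if (!is.na(chan[i])) {
      grid[ix, iy, iz, chan[i]] <- grid[ix, iy, iz, chan[i]] + g
    }
    if (q[i] != 0) grid[ix, iy, iz, 8] <- grid[ix, iy, iz, 8] + q[i] * g
    if (s[i] != 0) grid[ix, iy, iz, 9] <- grid[ix, iy, iz, 9] + s[i] * g
  }
  grid
}

#' In-memory voxel dataset container
#'
#' Holds voxel tensors with aligned labels and metadata. Tensors are stored
#' in one contiguous array `(n, n, n, channels, N)`; labels use the fixed
#' alphabetical amino-acid order of [aa_alphabet()] (1-based in R).
#'
#' @param config A [voxel_config()].
#' @param n_channels Number of channels (default 9).
#' @return An empty `voxel_dataset`.
#' @export
voxel_dataset <- function(config = voxel_config(), n_channels = 9L) {
  structure(
    list(config = config, grids = list(), labels = integer(0),
         meta = tibble::tibble(structure_id = character(), chain = character(),
                               residue_seq = integer(), insert = character(),
                               wt_aa = integer(), interface_flag = logical(),
                               interface_kind = character())),
    class = "voxel_dataset"
  )
}

#' @export
length.voxel_dataset <- function(x) length(x$grids)

#' @export
print.voxel_dataset <- function(x, ...) {
  cat("<voxel_dataset> ", length(x), " grids of ",
      paste(c(rep(x$config$n_voxel, 3), 9), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Voxelize a collection of microenvironments into a dataset
#'
#' Appends tensors, labels and metadata rows to a [voxel_dataset()] in input
#' order. Already-written items (tracked through the dataset's length, the
#' resume token) are skipped on re-runs, so a partially filled container can
#' be resumed without duplicates.
#'
#' @param envs List of `microenvironment` objects.
#' @param config A [voxel_config()].
#' @param out A `voxel_dataset` to append to (default: new empty one).
#' @param resume_from 1-based index of the first item to write; defaults to
#'   `length(out) + 1`, the resume token of a previous partial run.
#' @return The updated `voxel_dataset`; `attr(., "n_written")` holds the
#'   count written by this call.
#' @export
batch_voxelize <- function(envs, config = voxel_config(), out = NULL,
                           resume_from = NULL) {
  if (is.null(out)) out <- voxel_dataset(config)
  if (is.null(resume_from)) resume_from <- length(out) + 1L
  n_written <- 0L
  idx <- seq_along(envs)
  idx <- idx[idx >= resume_from]
  for (i in idx) {
    e <- envs[[i]]
    out$grids[[i]] <- voxelize(e, config)
    out$labels[i] <- e$key$wt_aa
    out$meta <- dplyr::bind_rows(out$meta, tibble::tibble(
      structure_id = e$key$structure_id %||% "", chain = e$key$chain,
      residue_seq = as.integer(e$key$residue_seq), insert = e$key$insert,
      wt_aa = as.integer(e$key$wt_aa),
      interface_flag = isTRUE(e$interface_flag),
      interface_kind = e$interface_kind %||% ""))
    n_written <- n_written + 1L
  }
  attr(out, "n_written") <- n_written
  out
}

#' Write / read a voxel dataset directory
#'
#' On-disk layout: `grids.rds` (tensor array list), `labels.csv` +
#' `meta.csv` (plain-text metadata) and `config.json` (self-describing
#' voxelization parameters, including the fixed class order).
#'
#' @param dataset A `voxel_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or the restored `voxel_dataset` (read).
#' @export
write_voxel_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset$grids, file.path(dir, "grids.rds"))
  utils::write.csv(data.frame(label = dataset$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$meta), file.path(dir, "meta.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$class_order <- aa_alphabet()
  cfg$channels <- voxel_channels()
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_voxel_dataset
#' @export
read_voxel_dataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- voxel_config(box_edge = cfg$box_edge, resolution = cfg$resolution,
                         sigma_scale = cfg$sigma_scale, truncation = cfg$truncation,
                         drop_unchanneled = isTRUE(cfg$drop_unchanneled),
                         normalize = isTRUE(cfg$normalize))
  ds <- voxel_dataset(config)
  ds$grids <- readRDS(file.path(dir, "grids.rds"))
  ds$labels <- utils::read.csv(file.path(dir, "labels.csv"))$label
  ds$meta <- tibble::as_tibble(utils::read.csv(file.path(dir, "meta.csv"),
                                               stringsAsFactors = FALSE))
  ds
}

#' Subset a voxel dataset by item index
#'
#' @param dataset A `voxel_dataset`.
#' @param idx Integer indices of items to keep.
#' @return The subsetted `voxel_dataset`.
#' @export
voxel_subset <- function(dataset, idx) {
  dataset$grids <- dataset$grids[idx]
  dataset$labels <- dataset$labels[idx]
  if (nrow(dataset$meta)) dataset$meta <- dataset$meta[idx, , drop = FALSE]
  dataset
}

`%||%` <- function(a, b) if (is.null(a)) b else a
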