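# shared fixture builders (pure code, no stored data)

# small annotated helix with one ligand near residue 3
fixture_structure <- function(n_res = 6, lig_dist = 4.0, annotate = TRUE) {
  s <- make_toy_structure(
    n_res,
    placements = list(list(element = "P", residue = 3, distance = lig_dist)))
  if (annotate) s <- suppressWarnings(annotate_structure(s))
  s
}

# brute-force voxel oracle: evaluate every atom's Gaussian at all voxel
# centers directly (vectorized over the grid, loop over atoms)
brute_voxelize <- function(atoms, config = voxel_config()) {
  n <- config$n_voxel
  cen <- (seq_len(n) - 0.5) * config$resolution - config$box_edge / 2
  grid <- array(0, dim = c(n, n, n, 9))
  if (nrow(atoms) == 0) return(grid)
  gx <- rep(cen, times = n * n)
  gy <- rep(rep(cen, each = n), times = n)
  gz <- rep(cen, each = n * n)
  for (i in seq_len(nrow(atoms))) {
    sigma <- config$sigma_scale * atoms$vdw_radius[i]
    d2 <- (gx - atoms$fx[i])^2 + (gy - atoms$fy[i])^2 + (gz - atoms$fz[i])^2
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > (config$truncation * sigma)^2] <- 0
    ch <- element_channel(atoms$element[i])
    if (!is.na(ch)) grid[, , , ch] <- grid[, , , ch] + array(g, c(n, n, n))
    q <- atoms$partial_charge[i]
    sa <- atoms$sasa[i]
    if (!is.na(q) && q != 0) grid[, , , 8] <- grid[, , , 8] + q * array(g, c(n, n, n))
    if (!is.na(sa) && sa != 0) grid[, , , 9] <- grid[, , , 9] + sa * array(g, c(n, n, n))
  }
  grid
}

# random frame-coordinate atom tibble for voxelizer tests
random_atoms <- function(n, seed, elements = c("C", "H", "O", "N", "S", "P", "Cl")) {
  set.seed(seed)
  el <- sample(elements, n, replace = TRUE)
  tibble::tibble(
    element = el,
    fx = runif(n, -9, 9), fy = runif(n, -9, 9), fz = runif(n, -9, 9),
    vdw_radius = vdw_radius(el),
    partial_charge = round(runif(n, -1, 1), 3),
    sasa = round(runif(n, 0, 50), 2))
}

# reduced-size training setup shared by resnet tests
tiny_model <- function(n_voxel = 8, width = 4, blocks = 1, classes = 5, seed = 1) {
  build_model(model_config(n_voxel = n_voxel, in_channels = 3,
                           n_residual_blocks = blocks, base_width = width,
                           n_classes = classes, seed = seed))
}

random_grid_dataset <- function(n_items, n_voxel = 8, channels = 3,
                                classes = 5, seed = 1) {
  set.seed(seed)
  ds <- voxel_dataset(voxel_config(box_edge = n_voxel, resolution = 1))
  ds$grids <- lapply(seq_len(n_items), function(i) {
    array(rnorm(n_voxel^3 * channels, sd = 0.5) +
            rep(seq_len(channels) * (i %% classes + 1) / 10,
                each = n_voxel^3),
          dim = c(n_voxel, n_voxel, n_voxel, channels))
  })
  ds$labels <- (seq_len(n_items) %% classes) + 1L
  ds$meta <- tibble::tibble(structure_id = "r", chain = "A",
                            residue_seq = seq_len(n_items), insert = "",
                            wt_aa = ds$labels, interface_flag = FALSE,
                            interface_kind = "")
  ds
}

# reduced assay design for fast kinetic unit tests
small_design <- function() {
  assay_design(substrate_uM = c(31.25, 125, 500),
               times_min = c(60, 180), replicates = 1L)
}
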