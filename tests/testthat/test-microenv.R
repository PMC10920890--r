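test_that("interface flagging is an all-pairs 5 A contact scan, inclusive", {
  s49 <- make_toy_structure(6, placements = list(
    list(element = "P", residue = 5, distance = 4.9)))
  hits <- find_interface_residues(s49)
  expect_equal(hits$residue_seq, 5L)
  expect_equal(hits$interface_kind, "ligand")

  s51 <- make_toy_structure(6, placements = list(
    list(element = "P", residue = 5, distance = 5.1)))
  expect_equal(nrow(find_interface_residues(s51)), 0)

  # boundary is inclusive at exactly the cutoff
  s50 <- make_toy_structure(6, placements = list(
    list(element = "P", residue = 5, distance = 5.0)))
  expect_equal(find_interface_residues(s50)$residue_seq, 5L)

  # no non-protein atoms -> empty set
  expect_equal(nrow(find_interface_residues(make_toy_structure(5))), 0)

  # oracle: brute-force distance scan over all protein/non-protein pairs
  s <- make_toy_structure(8, placements = list(
    list(element = "P", residue = 2, distance = 3.0),
    list(element = "N", residue = 7, distance = 4.5, class = "nucleic")))
  a <- s$atoms
  prot <- a[a$entity_class == "protein", ]
  np <- a[a$entity_class %in% c("ligand", "nucleic", "ion"), ]
  d <- sqrt(outer(prot$x, np$x, "-")^2 + outer(prot$y, np$y, "-")^2 +
              outer(prot$z, np$z, "-")^2)
  expected <- sort(unique(prot$residue_seq[rowSums(d <= 5) > 0]))
  expect_equal(sort(find_interface_residues(s)$residue_seq), expected)
})

test_that("water and ion toggles control interface flagging", {
  s <- make_toy_structure(5, placements = list(
    list(element = "O", residue = 2, distance = 3.0, class = "water"),
    list(element = "Zn", residue = 4, distance = 3.0, class = "ion")))
  default_hits <- find_interface_residues(s)
  expect_true(4L %in% default_hits$residue_seq)    # ion counted
  expect_false(2L %in% default_hits$residue_seq)   # water ignored
  no_ion <- find_interface_residues(
    s, sampling_config(include_ions_as_nonprotein = FALSE))
  expect_equal(nrow(no_ion), 0)
  with_water <- find_interface_residues(
    s, sampling_config(include_water_as_nonprotein = TRUE))
  expect_true(all(c(2L, 4L) %in% with_water$residue_seq))
})

test_that("per-chain sampling honors the 200-or-half-chain target", {
  s100 <- make_toy_structure(100)
  keys <- sample_residues(s100, "A", sampling_config(seed = 3))
  expect_equal(nrow(keys), 50)          # half-chain branch
  expect_equal(anyDuplicated(keys$residue_seq), 0)

  s30 <- make_toy_structure(30, placements = list(
    list(element = "P", residue = 10, distance = 4.0),
    list(element = "P", residue = 20, distance = 4.0)))
  k1 <- sample_residues(s30, "A", sampling_config(seed = 9))
  k2 <- sample_residues(s30, "A", sampling_config(seed = 9))
  expect_identical(k1, k2)              # seeded determinism
  expect_equal(nrow(k1), 15)
  # interface residues lead, in sequence order
  iface <- find_interface_residues(s30)$residue_seq
  expect_gte(length(iface), 2)
  expect_equal(k1$residue_seq[seq_along(iface)], iface)
  expect_true(all(k1$interface_flag[seq_along(iface)]))
  expect_true(all(iface %in% k1$residue_seq))
})

test_that("interface residues beyond the target are kept unless truncated", {
  # every residue within 5 A of a central ligand on a tiny chain
  s <- make_toy_structure(4, placements = list(
    list(element = "P", residue = 2, distance = 2.0, atom = "CA")))
  cfg <- sampling_config(residue_cap = 1, chain_fraction = 0.25, seed = 1)
  n_iface <- nrow(find_interface_residues(s, cfg))
  expect_gt(n_iface, 1)
  kept <- sample_residues(s, "A", cfg)
  expect_equal(nrow(kept), n_iface)     # non-truncating default
  trunc_cfg <- sampling_config(residue_cap = 1, chain_fraction = 0.25,
                               truncate_interface = TRUE, seed = 1)
  expect_equal(nrow(sample_residues(s, "A", trunc_cfg)), 1)
})

test_that("backbone frames are orthonormal, tetrahedral and equivariant", {
  set.seed(21)
  for (i in 1:20) {
    # realistic backbone geometry (bond lengths ~1.46/1.52, angle ~111
    # degrees), randomly placed and oriented with small perturbations
    CA <- rnorm(3, sd = 5)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    ang <- (111 + rnorm(1, sd = 4)) * pi / 180
    N <- CA + (1.46 + rnorm(1, sd = 0.02)) * u
    C <- CA + (1.52 + rnorm(1, sd = 0.02)) * (cos(ang) * u + sin(ang) * v)
    f <- build_frame(N, CA, C)
    A <- f$axes
    expect_lt(max(abs(A %*% t(A) - diag(3))), 1e-9)   # orthonormal
    expect_equal(det(A), 1, tolerance = 1e-9)          # right-handed
    # rigid rotation of the backbone rotates all axes by exactly R
    th <- runif(1, 0, pi)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    f2 <- build_frame(R %*% N, R %*% CA, R %*% C)
    expect_lt(max(abs(f2$axes - f$axes %*% t(R))), 1e-9)
  }
  expect_error(build_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("+z points at the side chain (independent C-beta construction)", {
  s <- make_toy_structure(5)
  a <- s$atoms
  for (res in 2:4) {
    at <- function(nm) unlist(a[a$residue_seq == res & a$atom_name == nm,
                                c("x", "y", "z")])
    f <- build_frame(at("N"), at("CA"), at("C"))
    # independent oracle: the standard fixed-coefficient C-beta construction
    # from the N, C(alpha), C frame (Gram-Schmidt form used across the field)
    b <- at("CA") - at("N")
    c_ <- at("C") - at("CA")
    aa <- voxdesign:::cross3(b, c_)
    cb_oracle <- at("CA") - 0.58273431 * aa + 0.56802827 * b - 0.54067466 * c_
    u <- cb_oracle - at("CA"); u <- u / sqrt(sum(u^2))
    expect_gt(sum(f$axes["z", ] * u), 0.99)
    # and the fixture's own CB stub lies along +z
    cb <- at("CB")
    v <- cb - at("CA"); v <- v / sqrt(sum(v^2))
    expect_gt(sum(f$axes["z", ] * v), 0.99)
  }
})

test_that("microenvironments are center-masked and cube-bounded", {
  s <- fixture_structure(8, lig_dist = 3.0)
  env <- extract_microenvironment(s, "A", 3)
  # no atom of the center residue remains
  expect_false(any(env$atoms$residue_seq == 3 & env$atoms$chain == "A" &
                     env$atoms$entity_class == "protein"))
  # all frame coordinates within the half-edge, inclusive
  expect_true(all(abs(env$atoms$fx) <= 10 + 1e-12))
  expect_true(all(abs(env$atoms$fz) <= 10 + 1e-12))
  # ligand content is retained with its entity class
  expect_true(any(env$atoms$entity_class == "ligand"))
  expect_true(env$interface_flag)
  expect_equal(env$interface_kind, "ligand")

  # a residue whose own atoms are the only atoms -> empty microenvironment
  s3 <- make_toy_structure(3)
  s1res <- s3
  s1res$atoms <- s3$atoms[s3$atoms$residue_seq == 2, ]
  env2 <- extract_microenvironment(s1res, "A", 2)
  expect_equal(nrow(env2$atoms), 0)
})

test_that("cube membership keeps 9.9 and drops 10.1 along an axis", {
  # place a probe atom at a controlled frame-x offset from residue 2's frame
  s <- make_toy_structure(3)
  a <- s$atoms
  at <- function(nm) unlist(a[a$residue_seq == 2 & a$atom_name == nm,
                              c("x", "y", "z")])
  f <- build_frame(at("N"), at("CA"), at("C"))
  for (off in c(9.9, 10.1)) {
    world <- f$origin + off * f$axes["x", ]
    probe <- s
    probe$atoms <- dplyr::bind_rows(a, tibble::tibble(
      serial = max(a$serial) + 1L, atom_name = "P", element = "P",
      x = world[1], y = world[2], z = world[3], chain = "B",
      residue_name = "LIG", residue_seq = 99L, insert = "", occupancy = 1,
      is_hetatm = TRUE, entity_class = "ligand", is_backbone = FALSE,
      vdw_radius = 1.8, partial_charge = 0, sasa = 0))
    env <- extract_microenvironment(probe, "A", 2)
    expect_equal(any(env$atoms$element == "P"), off < 10)
  }
})

test_that("waters are excluded from microenvironment content, ions kept", {
  s <- make_toy_structure(5, placements = list(
    list(element = "O", residue = 3, distance = 4.0, class = "water"),
    list(element = "Zn", residue = 3, distance = 4.5, class = "ion")))
  env <- extract_microenvironment(s, "A", 3)
  expect_false(any(env$atoms$entity_class == "water"))
  expect_true(any(env$atoms$entity_class == "ion"))
})

test_that("stratified splits are exact, disjoint, exhaustive, seeded", {
  flags <- rep(c(TRUE, FALSE), c(300, 700))
  items <- as.list(seq_len(1000))
  sp <- split_dataset(items, sampling_config(seed = 4), interface_flags = flags)
  expect_equal(length(sp$train), 900)
  expect_equal(length(sp$test), 100)
  expect_equal(sum(flags[sp$train]), 270)
  expect_equal(sum(flags[sp$test]), 30)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(1000))
  sp2 <- split_dataset(items, sampling_config(seed = 4), interface_flags = flags)
  expect_identical(sp, sp2)
  # degenerate single item: round-to-nearest puts it in train
  sp1 <- split_dataset(list(1), sampling_config(seed = 1),
                       interface_flags = FALSE)
  expect_equal(sp1$train, 1L)
  expect_length(sp1$test, 0)
})
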