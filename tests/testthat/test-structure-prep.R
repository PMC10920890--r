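test_that("mmCIF fixtures round-trip with entity classes and resolution", {
  path <- withr::local_tempfile(fileext = ".cif")
  s <- make_toy_structure(3, resolution = 2.0, path = path)
  s2 <- read_structure(path)

  expect_equal(nrow(residue_table(s2)), 3)
  expect_true(all(s2$atoms$entity_class == "protein"))
  expect_equal(s2$metadata$resolution, 2.0)
  # round trip preserves atoms, elements, coordinates to 3 decimals
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$element, s$atoms$element)
  expect_lt(max(abs(s2$atoms$x - s$atoms$x)), 5e-4)
  expect_lt(max(abs(s2$atoms$z - s$atoms$z)), 5e-4)
})

test_that("HETATM small molecules and waters are classified separately", {
  path <- withr::local_tempfile(fileext = ".cif")
  make_toy_structure(4, placements = list(
    list(element = "P", residue = 2, distance = 6, class = "ligand"),
    list(element = "O", residue = 3, distance = 7, class = "water"),
    list(element = "Zn", residue = 4, distance = 8, class = "ion")),
    path = path)
  s <- read_structure(path)
  cls <- s$atoms$entity_class
  expect_equal(sum(cls == "ligand"), 1)
  expect_equal(sum(cls == "water"), 1)
  expect_equal(sum(cls == "ion"), 1)
  expect_equal(s$atoms$element[cls == "ion"], "Zn")
})

test_that("resolution filter keeps <= cutoff and drops unrecorded", {
  mk <- function(res) make_toy_structure(3, resolution = res)
  ss <- list(mk(1.5), mk(3.0), mk(3.2), mk(NA_real_))
  expect_message(kept <- filter_by_resolution(ss), "no recorded resolution")
  expect_equal(vapply(kept, function(s) s$metadata$resolution, numeric(1)),
               c(1.5, 3.0))
  expect_equal(filter_by_resolution(list()), list())
})

test_that("isolated atom SASA matches the closed-form sphere area", {
  s <- new_annotated_structure(
    tibble::tibble(serial = 1L, atom_name = "C1", element = "C",
                   x = 0, y = 0, z = 0, chain = "A", residue_name = "LIG",
                   residue_seq = 1L, insert = "", occupancy = 1,
                   is_hetatm = TRUE, entity_class = "ligand",
                   is_backbone = FALSE, vdw_radius = 1.7,
                   partial_charge = 0, sasa = NA_real_),
    metadata = list(id = "one", resolution = NA_real_))
  s <- compute_sasa(s)
  expect_equal(s$atoms$sasa, 4 * pi * 3.1^2, tolerance = 1e-10)
})

test_that("two-sphere SASA matches dense numerical integration within 2%", {
  two <- function(d) new_annotated_structure(
    tibble::tibble(serial = 1:2, atom_name = c("C1", "C2"),
                   element = "C", x = c(0, d), y = 0, z = 0, chain = "A",
                   residue_name = "LIG", residue_seq = 1:2, insert = "",
                   occupancy = 1, is_hetatm = TRUE, entity_class = "ligand",
                   is_backbone = FALSE, vdw_radius = 1.7,
                   partial_charge = 0, sasa = NA_real_),
    metadata = list(id = "two", resolution = NA_real_))
  s <- compute_sasa(two(2.0), prep_config(sphere_points = 2000))
  # closed form for two equal spheres: accessible cap area
  # h = depth of the buried cap on the expanded sphere of radius R = 3.1
  R <- 3.1
  h <- R - 1.0   # cap height cut at plane x = d/2 = 1
  exact <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(s$atoms$sasa[1], exact, tolerance = 0.02)
  expect_equal(s$atoms$sasa[2], exact, tolerance = 0.02)
})

test_that("a fully enclosed atom has zero SASA and occlusion is monotone", {
  # center atom surrounded by a dense shell of neighbors
  pts <- voxdesign:::fibonacci_sphere(80) * 2.0
  atoms <- tibble::tibble(
    serial = seq_len(81L), atom_name = "C", element = "C",
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]),
    chain = "A", residue_name = "LIG", residue_seq = seq_len(81L),
    insert = "", occupancy = 1, is_hetatm = TRUE, entity_class = "ligand",
    is_backbone = FALSE, vdw_radius = 1.7, partial_charge = 0,
    sasa = NA_real_)
  s <- compute_sasa(new_annotated_structure(
    atoms, metadata = list(id = "shell", resolution = NA_real_)))
  expect_equal(s$atoms$sasa[1], 0)

  # occlusion monotonicity: total SASA of complex <= sum of isolated parts
  st <- fixture_structure(4, annotate = FALSE)
  prot <- st; prot$atoms <- st$atoms[st$atoms$entity_class == "protein", ]
  lig <- st; lig$atoms <- st$atoms[st$atoms$entity_class == "ligand", ]
  tot <- sum(compute_sasa(st)$atoms$sasa)
  parts <- sum(compute_sasa(prot)$atoms$sasa) + sum(compute_sasa(lig)$atoms$sasa)
  expect_lte(tot, parts + 1e-9)
})

test_that("SASA is invariant under rigid motion at fixed sphere sampling", {
  s <- fixture_structure(4, annotate = FALSE)
  s1 <- compute_sasa(s)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + 5; s$atoms$y <- xyz[, 2] - 3; s$atoms$z <- xyz[, 3] + 1
  s2 <- compute_sasa(s)
  expect_lt(max(abs(s1$atoms$sasa - s2$atoms$sasa)), 1e-6)
})

test_that("lookup charges come from the template with 0.0 fallback", {
  s <- fixture_structure(4, annotate = FALSE)
  expect_warning(s <- assign_partial_charges(s), "no charge-template entry")
  a <- s$atoms
  # backbone N of a standard residue has the template value
  expect_equal(a$partial_charge[a$atom_name == "N" & a$residue_seq == 1][1], -0.47)
  # the LIG phosphorus has no template entry -> 0.0
  expect_equal(a$partial_charge[a$entity_class == "ligand"], 0)
})

test_that("every neutral residue of the shipped template sums to ~0 e", {
  tmpl <- voxdesign:::charge_template()
  sums <- tapply(tmpl$charge, tmpl$residue, sum)
  expected <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, `NA` = 1, K = 1,
                CL = -1, MG = 2, ZN = 2, CA = 2, MN = 2, FE = 2)
  for (res in names(sums)) {
    want <- if (res %in% names(expected)) expected[[res]] else 0
    expect_lt(abs(sums[[res]] - want), 0.01)
  }
  # all 20 standard residues are present
  expect_true(all(aa_alphabet() %in% tmpl$residue))
})

test_that("external charge files pass through and report missing atoms", {
  s <- fixture_structure(3, annotate = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  ext <- data.frame(chain = s$atoms$chain, residue_seq = s$atoms$residue_seq,
                    atom_name = s$atoms$atom_name, charge = 0)
  ext$charge[1] <- 1.0
  write.csv(ext, f, row.names = FALSE)
  s2 <- assign_partial_charges(s, prep_config(charge_source = "external_file"),
                               charge_file = f)
  expect_equal(s2$atoms$partial_charge[1], 1.0)

  write.csv(ext[-(1:3), ], f, row.names = FALSE)
  expect_error(
    assign_partial_charges(s, prep_config(charge_source = "external_file"),
                           charge_file = f),
    "missing 3 atom")
})

test_that("atom annotations serialize to JSON lines", {
  s <- suppressWarnings(annotate_structure(fixture_structure(3, annotate = FALSE)))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_atom_annotations(s, f)
  lines <- readLines(f)
  expect_equal(length(lines), nrow(s$atoms))
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$entity_class, "protein")
  expect_gt(rec$vdw_radius, 0)
})
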