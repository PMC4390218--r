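formats <- data.frame(format = c("gmsh", "vtu", "abaqus_inp"),
                      ext = c("msh", "vtu", "inp"),
                      stringsAsFactors = FALSE)

test_that("meshes round-trip losslessly through every format", {
  meshes <- list(linear_cube = make_patch_cube(1, 2, order = 1),
                 quadratic_skull = test_skull(order = 2))
  for (mi in seq_along(meshes)) {
    m <- meshes[[mi]]
    for (r in seq_len(nrow(formats))) {
      p <- file.path(withr::local_tempdir(),
                     paste0("m.", formats$ext[r]))
      write_mesh(m, p, formats$format[r])
      m2 <- read_mesh(p, formats$format[r])
      expect_lt(max(abs(m$nodes - m2$nodes)), 1e-12)
      expect_identical(unname(m$elems), unname(m2$elems))
      expect_identical(lapply(m$patches, unname)[sort(names(m$patches))],
                       lapply(m2$patches, unname)[sort(names(m2$patches))])
      # second write of the read-back mesh is bitwise identical
      p2 <- file.path(withr::local_tempdir(), basename(p))
      write_mesh(m2, p2, formats$format[r])
      expect_identical(readLines(p2), readLines(p))
    }
  }
})

test_that("format is inferred from the file extension", {
  m <- make_patch_cube(1, 1)
  p <- file.path(withr::local_tempdir(), "m.msh")
  write_mesh(m, p)
  expect_s3_class(read_mesh(p), "tet_mesh")
  expect_error(write_mesh(m, "mesh.xyz"), "infer")
})

test_that("a minimal single-tetrahedron file loads correctly", {
  tet <- single_tet()
  for (r in seq_len(nrow(formats))) {
    p <- file.path(withr::local_tempdir(), paste0("t.", formats$ext[r]))
    write_mesh(tet, p, formats$format[r])
    expect_warning(m <- read_mesh(p, formats$format[r]), "patch")
    expect_identical(nrow(m$elems), 1L)
    expect_identical(m$order, 1L)
    expect_identical(nrow(boundary_faces(m)), 4L)
    expect_length(m$patches, 0L)
  }
})

test_that("missing files and malformed content raise format errors", {
  expect_error(read_mesh("no_such_file.msh"), "not found")
  td <- withr::local_tempdir()
  # gmsh file with an unsupported cell type (hexahedron, type 5)
  p <- file.path(td, "bad.msh")
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat",
               "$Nodes", "1 1 1 1", "3 1 0 1", "1", "0 0 0", "$EndNodes",
               "$Elements", "1 1 1 1", "3 1 5 1", "1 1 1 1 1 1 1 1 1",
               "$EndElements"), p)
  expect_error(read_mesh(p), "unsupported")
  # inp with no tetrahedra
  p2 <- file.path(td, "bad.inp")
  writeLines(c("*NODE", "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0"), p2)
  expect_error(read_mesh(p2), "tetrahedra")
})

test_that("mixed element orders in one file are rejected", {
  td <- withr::local_tempdir()
  m4 <- make_patch_cube(1, 1, order = 1)
  m10 <- make_patch_cube(1, 1, order = 2)
  p <- file.path(td, "mixed.inp")
  con <- file(p, "w")
  writeLines("*NODE", con)
  writeLines(paste(seq_len(nrow(m10$nodes)), m10$nodes[, 1], m10$nodes[, 2],
                   m10$nodes[, 3], sep = ", "), con)
  writeLines("*ELEMENT, TYPE=C3D4, ELSET=a", con)
  writeLines(paste(1, paste(m4$elems[1, ], collapse = ", "), sep = ", "), con)
  writeLines("*ELEMENT, TYPE=C3D10, ELSET=b", con)
  writeLines(paste(2, paste(m10$elems[1, ], collapse = ", "), sep = ", "), con)
  close(con)
  expect_error(read_mesh(p), "mixed")
})

test_that("field export writes valid XML with the named arrays", {
  mesh <- make_patch_cube(1, 2, order = 2)
  mat <- material()
  # zero solution
  zero <- list(u = matrix(0, nrow(mesh$nodes), 3),
               vm_node = numeric(nrow(mesh$nodes)),
               vm_elem = numeric(nrow(mesh$elems)))
  p <- file.path(withr::local_tempdir(), "zero.vtu")
  write_field_vtk(mesh, zero, p)
  doc <- xml2::read_xml(p)
  arr <- xml2::xml_find_all(doc, "//DataArray[@Name]")
  expect_true(all(c("displacement", "von_mises", "von_mises_cell") %in%
                    xml2::xml_attr(arr, "Name")))
  vals <- as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(doc, "//DataArray[@Name='von_mises']"))),
    "\\s+")[[1]])
  expect_true(all(vals == 0))
  # patch-test solution has a constant cell field
  setup <- uniaxial_setup(mesh, 2)
  sol <- solve_mesh(mesh, mat, setup$loads, setup$constraints)
  p2 <- file.path(withr::local_tempdir(), "uni.vtu")
  write_field_vtk(mesh, sol, p2)
  doc2 <- xml2::read_xml(p2)
  cellvm <- as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(doc2, "//DataArray[@Name='von_mises_cell']"))),
    "\\s+")[[1]])
  expect_lt(diff(range(cellvm)), 1e-9)
  # size mismatch is an error
  expect_error(write_field_vtk(make_patch_cube(1, 1), sol, p2),
               "dimensions")
})

test_that("STL surface export writes one facet per boundary face", {
  m <- test_skull(order = 1)
  p <- file.path(withr::local_tempdir(), "s.stl")
  write_surface_stl(m, p)
  lines <- readLines(p)
  expect_identical(sum(grepl("^facet normal", lines)),
                   nrow(boundary_faces(m)))
})
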