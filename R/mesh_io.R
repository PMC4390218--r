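#' @title Mesh file input/output
#' @description Readers and writers for the three supported tetrahedral
#'   mesh formats — Gmsh `.msh` (v4.1 ASCII), VTK `.vtu` (XML ASCII) and
#'   Abaqus `.inp` (NODE/ELEMENT/ELSET subset) — plus STL surface export
#'   and VTK field output for stress maps. Patch names are carried as Gmsh
#'   physical groups, VTU cell-data tags, and Abaqus element sets. Only
#'   tetrahedral volume cells (4- or 10-node) and named triangular surface
#'   cells are supported; anything else is a format error.
#' @name mesh_io
NULL

.fmt_num <- function(x) formatC(x, format = "g", digits = 17)

.infer_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         msh = "gmsh", vtu = "vtu", inp = "abaqus_inp",
         stop("cannot infer mesh format from extension of '", path, "'"))
}

#' Write a mesh to file
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @param format one of `"gmsh"`, `"vtu"`, `"abaqus_inp"`; inferred from
#'   the file extension (.msh/.vtu/.inp) when missing.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(format)) format <- .infer_format(path)
  format <- match.arg(format, c("gmsh", "vtu", "abaqus_inp"))
  switch(format,
         gmsh = .write_gmsh(mesh, path),
         vtu = .write_vtu(mesh, path),
         abaqus_inp = .write_inp(mesh, path))
  invisible(path)
}

#' Read a mesh from file
#'
#' @param path input file path.
#' @param format one of `"gmsh"`, `"vtu"`, `"abaqus_inp"`; inferred from
#'   the extension when missing.
#' @return a [tet_mesh()]; element order is inferred from the nodes per
#'   cell. A file without surface tags loads with an empty patch table and
#'   a warning.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- .infer_format(path)
  format <- match.arg(format, c("gmsh", "vtu", "abaqus_inp"))
  mesh <- switch(format,
                 gmsh = .read_gmsh(path),
                 vtu = .read_vtu(path),
                 abaqus_inp = .read_inp(path))
  if (length(mesh$patches) == 0L)
    warning("no surface patch tags found in '", path,
            "'; patch table is empty")
  mesh
}

## ---- Gmsh 4.1 ASCII ----

# internal (VTK) <-> gmsh tet10 mid-node permutation (last two swapped)
.gmsh_tet10_perm <- c(1:8, 10L, 9L)

.write_gmsh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  pn <- names(mesh$patches)
  k <- length(pn)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  if (k) {
    w("$PhysicalNames"); w(as.character(k))
    for (s in seq_len(k)) w(sprintf("2 %d \"%s\"", s, pn[s]))
    w("$EndPhysicalNames")
  }
  bb <- paste(.fmt_num(c(apply(mesh$nodes, 2, min),
                         apply(mesh$nodes, 2, max))), collapse = " ")
  w("$Entities")
  w(sprintf("0 0 %d 1", k))
  for (s in seq_len(k)) w(sprintf("%d %s 1 %d 0", s, bb, s))
  w(sprintf("1 %s 0 0", bb))
  w("$EndEntities")
  n <- nrow(mesh$nodes)
  w("$Nodes")
  w(sprintf("1 %d 1 %d", n, n))
  w(sprintf("3 1 0 %d", n))
  writeLines(as.character(seq_len(n)), con)
  writeLines(paste(.fmt_num(mesh$nodes[, 1]), .fmt_num(mesh$nodes[, 2]),
                   .fmt_num(mesh$nodes[, 3])), con)
  w("$EndNodes")
  ne <- nrow(mesh$elems)
  nf <- sum(vapply(mesh$patches, nrow, 1L))
  w("$Elements")
  w(sprintf("%d %d 1 %d", k + 1L, ne + nf, ne + nf))
  tag <- 1L
  tri_type <- if (mesh$order == 1L) 2L else 9L
  for (s in seq_len(k)) {
    f <- mesh$patches[[s]]
    w(sprintf("2 %d %d %d", s, tri_type, nrow(f)))
    if (nrow(f))
      writeLines(paste(seq.int(tag, length.out = nrow(f)),
                       apply(f, 1L, paste, collapse = " ")), con)
    tag <- tag + nrow(f)
  }
  tet_type <- if (mesh$order == 1L) 4L else 11L
  elems <- if (mesh$order == 2L)
    mesh$elems[, .gmsh_tet10_perm, drop = FALSE] else mesh$elems
  w(sprintf("3 1 %d %d", tet_type, ne))
  writeLines(paste(seq.int(tag, length.out = ne),
                   apply(elems, 1L, paste, collapse = " ")), con)
  w("$EndElements")
}

.gmsh_section <- function(lines, name) {
  a <- which(lines == paste0("$", name))
  if (length(a) == 0L) return(NULL)
  b <- which(lines == paste0("$End", name))
  lines[(a + 1L):(b - 1L)]
}

.read_gmsh <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  tok <- function(s) as.numeric(strsplit(s, "\\s+")[[1]])

  phys <- list()
  pl <- .gmsh_section(lines, "PhysicalNames")
  if (!is.null(pl)) {
    for (s in pl[-1L]) {
      m <- regmatches(s, regexec('^(\\d+)\\s+(\\d+)\\s+"(.*)"$', s))[[1]]
      if (length(m) == 4L && m[2] == "2")
        phys[[m[4]]] <- as.integer(m[3])
    }
  }
  surf2phys <- integer(0)
  el <- .gmsh_section(lines, "Entities")
  if (!is.null(el)) {
    h <- tok(el[1L])
    i <- 2L + h[1] + h[2]            # skip points and curves
    for (s in seq_len(h[3])) {
      v <- tok(el[i])
      stag <- as.integer(v[1])
      nphys <- as.integer(v[8])
      surf2phys[as.character(stag)] <- if (nphys >= 1L) as.integer(v[9]) else NA_integer_
      i <- i + 1L
    }
  }

  nl <- .gmsh_section(lines, "Nodes")
  if (is.null(nl)) stop("gmsh file has no $Nodes section")
  h <- tok(nl[1L])
  nblocks <- h[1]; ntot <- h[2]
  tags <- integer(ntot); coords <- matrix(0, ntot, 3L)
  i <- 2L; at <- 0L
  for (b in seq_len(nblocks)) {
    bh <- tok(nl[i]); nb <- bh[4]; i <- i + 1L
    if (nb > 0) {
      tags[at + seq_len(nb)] <- as.integer(nl[i:(i + nb - 1L)])
      i <- i + nb
      cc <- do.call(rbind, lapply(nl[i:(i + nb - 1L)], tok))
      coords[at + seq_len(nb), ] <- cc[, 1:3, drop = FALSE]
      i <- i + nb
      at <- at + nb
    }
  }
  nodemap <- integer(max(tags)); nodemap[tags] <- seq_along(tags)

  elsec <- .gmsh_section(lines, "Elements")
  if (is.null(elsec)) stop("gmsh file has no $Elements section")
  h <- tok(elsec[1L])
  i <- 2L
  tets <- list(); tris <- list(); tri_ent <- integer(0)
  orders <- integer(0)
  for (b in seq_len(h[1])) {
    bh <- tok(elsec[i]); i <- i + 1L
    etag <- as.integer(bh[2]); etype <- as.integer(bh[3]); nb <- bh[4]
    if (nb == 0) next
    rows <- do.call(rbind, lapply(elsec[i:(i + nb - 1L)], tok))
    i <- i + nb
    conn <- matrix(as.integer(rows[, -1L, drop = FALSE]), nrow = nb)
    if (etype %in% c(4L, 11L)) {
      if (etype == 11L) conn <- conn[, .gmsh_tet10_perm, drop = FALSE]
      orders <- c(orders, if (etype == 4L) 1L else 2L)
      tets[[length(tets) + 1L]] <- conn
    } else if (etype %in% c(2L, 9L)) {
      tris[[length(tris) + 1L]] <- conn
      tri_ent <- c(tri_ent, etag)
    } else {
      stop("unsupported gmsh element type ", etype,
           " (only 4/10-node tetrahedra and 3/6-node triangles)")
    }
  }
  if (length(tets) == 0L) stop("gmsh file contains no tetrahedra")
  if (length(unique(orders)) > 1L)
    stop("mixed linear and quadratic elements are not supported")
  elems <- do.call(rbind, tets)
  elems[] <- nodemap[elems]
  patches <- list()
  if (length(tris)) {
    id2name <- names(phys)
    for (s in seq_along(tris)) {
      ptag <- surf2phys[as.character(tri_ent[s])]
      nm <- if (!is.na(ptag) && length(w <- which(unlist(phys) == ptag)))
        id2name[w[1L]] else paste0("surface_", tri_ent[s])
      f <- tris[[s]]; f[] <- nodemap[f]
      patches[[nm]] <- rbind(patches[[nm]], f)
    }
  }
  tet_mesh(coords, elems, patches)
}

## ---- VTK XML unstructured grid (.vtu) ----

.vtu_cell_types <- c(tet4 = 10L, tet10 = 24L, tri3 = 5L, tri6 = 22L)

.write_vtu_file <- function(path, nodes, cell_list, point_data = list(),
                            cell_data = list(), field_strings = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  conn <- unlist(lapply(cell_list, function(cl) as.integer(t(cl$conn)) - 1L))
  sizes <- unlist(lapply(cell_list, function(cl)
    rep(ncol(cl$conn), nrow(cl$conn))))
  types <- unlist(lapply(cell_list, function(cl)
    rep(cl$type, nrow(cl$conn))))
  ncell <- length(types)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  if (!is.null(field_strings)) {
    bytes <- unlist(lapply(field_strings, function(s)
      c(as.integer(charToRaw(s)), 0L)))
    w('    <FieldData>')
    w(sprintf('      <DataArray type="String" Name="PatchNames" NumberOfTuples="%d" format="ascii">',
              length(field_strings)))
    w("        ", paste(bytes, collapse = " "))
    w('      </DataArray>')
    w('    </FieldData>')
  }
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">',
            nrow(nodes), ncell))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste("         ", .fmt_num(nodes[, 1]), .fmt_num(nodes[, 2]),
                   .fmt_num(nodes[, 3])), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w("          ", paste(conn, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  w("          ", paste(cumsum(sizes), collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(types, collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      ncomp <- if (is.null(dim(v))) 1L else ncol(v)
      w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, ncomp))
      if (ncomp == 1L) writeLines(paste("         ", .fmt_num(v)), con)
      else writeLines(paste("         ",
        apply(matrix(.fmt_num(v), ncol = ncomp), 1L, paste, collapse = " ")), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      tp <- if (is.integer(v)) "Int32" else "Float64"
      w(sprintf('        <DataArray type="%s" Name="%s" format="ascii">', tp, nm))
      writeLines(paste("         ", if (is.integer(v)) v else .fmt_num(v)), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
}

.write_vtu <- function(mesh, path) {
  tet_t <- if (mesh$order == 1L) .vtu_cell_types[["tet4"]] else .vtu_cell_types[["tet10"]]
  tri_t <- if (mesh$order == 1L) .vtu_cell_types[["tri3"]] else .vtu_cell_types[["tri6"]]
  cells <- list(list(conn = mesh$elems, type = tet_t))
  pid <- rep(0L, nrow(mesh$elems))
  for (s in seq_along(mesh$patches)) {
    f <- mesh$patches[[s]]
    if (nrow(f) == 0L) next
    cells[[length(cells) + 1L]] <- list(conn = f, type = tri_t)
    pid <- c(pid, rep(s, nrow(f)))
  }
  .write_vtu_file(path, mesh$nodes, cells,
                  cell_data = list(patch_id = as.integer(pid)),
                  field_strings = if (length(mesh$patches))
                    names(mesh$patches) else NULL)
}

.vtu_array <- function(piece, name, where) {
  xp <- sprintf(".//%s/DataArray[@Name='%s']", where, name)
  nd <- xml2::xml_find_first(piece, xp)
  if (inherits(nd, "xml_missing")) return(NULL)
  as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
}

.read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pnode <- xml2::xml_find_first(doc, ".//Piece/Points/DataArray")
  coords <- matrix(as.numeric(strsplit(trimws(xml2::xml_text(pnode)),
                                       "\\s+")[[1]]), ncol = 3L, byrow = TRUE)
  conn <- as.integer(.vtu_array(doc, "connectivity", "Cells")) + 1L
  offs <- as.integer(.vtu_array(doc, "offsets", "Cells"))
  types <- as.integer(.vtu_array(doc, "types", "Cells"))
  pid <- .vtu_array(doc, "patch_id", "CellData")
  nm_nd <- xml2::xml_find_first(doc, ".//FieldData/DataArray[@Name='PatchNames']")
  pnames <- character(0)
  if (!inherits(nm_nd, "xml_missing")) {
    bytes <- as.integer(strsplit(trimws(xml2::xml_text(nm_nd)), "\\s+")[[1]])
    splits <- cumsum(bytes == 0L)
    pnames <- vapply(split(bytes, c(0L, utils::head(splits, -1L))),
                     function(b) rawToChar(as.raw(b[b != 0L])), "")
  }
  starts <- c(1L, utils::head(offs, -1L) + 1L)
  bad <- setdiff(unique(types), unname(.vtu_cell_types))
  if (length(bad))
    stop("unsupported VTK cell type(s): ", paste(bad, collapse = ", "))
  get_cells <- function(tp, width) {
    sel <- which(types == tp)
    if (!length(sel)) return(NULL)
    m <- matrix(0L, length(sel), width)
    for (r in seq_along(sel))
      m[r, ] <- conn[starts[sel[r]]:offs[sel[r]]]
    m
  }
  t4 <- get_cells(10L, 4L); t10 <- get_cells(24L, 10L)
  if (!is.null(t4) && !is.null(t10))
    stop("mixed linear and quadratic elements are not supported")
  elems <- if (!is.null(t4)) t4 else t10
  if (is.null(elems)) stop("vtu file contains no tetrahedra")
  tri <- if (!is.null(t4)) get_cells(5L, 3L) else get_cells(22L, 6L)
  patches <- list()
  if (!is.null(tri) && !is.null(pid)) {
    tsel <- which(types %in% c(5L, 22L))
    tpid <- as.integer(pid[tsel])
    for (s in sort(unique(tpid[tpid > 0L]))) {
      nm <- if (s <= length(pnames)) pnames[s] else paste0("patch_", s)
      patches[[nm]] <- tri[tpid == s, , drop = FALSE]
    }
  }
  tet_mesh(coords, elems, patches)
}

#' Write a solved field to a VTK file
#'
#' Writes the volume mesh with nodal displacement vectors and nodal Von
#' Mises stress as point data, and the per-element Von Mises stress as
#' cell data — the inputs for standard stress-map visualisation in any VTK
#' viewer.
#'
#' @param mesh a [tet_mesh()].
#' @param solution a `fem_solution` (with stresses attached, as returned by
#'   [solve_mesh()]), or a list with fields `u` (n x 3), `vm_node` (n),
#'   `vm_elem` (m).
#' @param path output `.vtu` path.
#' @return invisibly `path`.
#' @export
write_field_vtk <- function(mesh, solution, path) {
  u <- solution$u
  vm_node <- if (!is.null(solution$stress)) solution$stress$vm_node
             else solution$vm_node
  vm_elem <- if (!is.null(solution$stress)) solution$stress$vm_elem
             else solution$vm_elem
  if (is.null(u) || is.null(vm_node) || is.null(vm_elem))
    stop("solution must provide displacements and Von Mises fields")
  if (nrow(u) != nrow(mesh$nodes) || length(vm_node) != nrow(mesh$nodes) ||
      length(vm_elem) != nrow(mesh$elems))
    stop("solution dimensions do not match the mesh")
  tet_t <- if (mesh$order == 1L) .vtu_cell_types[["tet4"]] else .vtu_cell_types[["tet10"]]
  .write_vtu_file(path, mesh$nodes,
                  list(list(conn = mesh$elems, type = tet_t)),
                  point_data = list(displacement = u, von_mises = vm_node),
                  cell_data = list(von_mises_cell = as.numeric(vm_elem)))
  invisible(path)
}

## ---- Abaqus .inp subset ----

.write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("*HEADING")
  w(if (!is.null(mesh$metadata$label)) mesh$metadata$label else "biteFEM mesh")
  w("*NODE")
  writeLines(paste(seq_len(nrow(mesh$nodes)),
                   .fmt_num(mesh$nodes[, 1]), .fmt_num(mesh$nodes[, 2]),
                   .fmt_num(mesh$nodes[, 3]), sep = ", "), con)
  vt <- if (mesh$order == 1L) "C3D4" else "C3D10"
  w(sprintf("*ELEMENT, TYPE=%s, ELSET=volume", vt))
  writeLines(paste(seq_len(nrow(mesh$elems)),
                   apply(mesh$elems, 1L, paste, collapse = ", "), sep = ", "),
             con)
  tt <- if (mesh$order == 1L) "S3" else "STRI65"
  eid <- nrow(mesh$elems)
  for (nm in names(mesh$patches)) {
    f <- mesh$patches[[nm]]
    if (nrow(f) == 0L) next
    w(sprintf("*ELEMENT, TYPE=%s, ELSET=%s", tt, nm))
    writeLines(paste(eid + seq_len(nrow(f)),
                     apply(f, 1L, paste, collapse = ", "), sep = ", "), con)
    eid <- eid + nrow(f)
  }
}

.read_inp <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "**")]
  kw <- which(startsWith(lines, "*"))
  nodes <- NULL; tets <- list(); patches <- list(); orders <- integer(0)
  label <- NULL
  for (s in seq_along(kw)) {
    from <- kw[s] + 1L
    to <- if (s < length(kw)) kw[s + 1L] - 1L else length(lines)
    head <- toupper(lines[kw[s]])
    if (startsWith(head, "*HEADING")) {
      if (from <= to) label <- lines[from]
    } else if (startsWith(head, "*NODE") && !startsWith(head, "*NODE OUTPUT")) {
      if (from > to) next
      vals <- do.call(rbind, lapply(lines[from:to], function(s)
        as.numeric(strsplit(s, "[,\\s]+")[[1]])))
      nodes <- vals
    } else if (startsWith(head, "*ELEMENT")) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", head)
      elset <- if (grepl("ELSET=", head))
        sub(".*ELSET=([^,[:space:]]+).*", "\\1", lines[kw[s]]) else NULL
      if (from > to) next
      vals <- do.call(rbind, lapply(lines[from:to], function(s)
        as.integer(strsplit(s, "[,\\s]+")[[1]])))
      conn <- vals[, -1L, drop = FALSE]
      if (type %in% c("C3D4", "C3D10")) {
        orders <- c(orders, if (type == "C3D4") 1L else 2L)
        tets[[length(tets) + 1L]] <- conn
      } else if (type %in% c("S3", "STRI3", "STRI65")) {
        nm <- if (is.null(elset)) paste0("patch_", length(patches) + 1L)
              else elset
        patches[[nm]] <- rbind(patches[[nm]], conn)
      } else {
        stop("unsupported Abaqus element type ", type)
      }
    }
    # other keywords (e.g. *HEADING, *ELSET) are ignored
  }
  if (is.null(nodes)) stop("inp file has no *NODE section")
  if (length(tets) == 0L) stop("inp file contains no tetrahedra")
  if (length(unique(orders)) > 1L)
    stop("mixed linear and quadratic elements are not supported")
  ids <- as.integer(nodes[, 1L])
  nodemap <- integer(max(ids)); nodemap[ids] <- seq_along(ids)
  elems <- do.call(rbind, tets); elems[] <- nodemap[elems]
  patches <- lapply(patches, function(f) {
    f[] <- nodemap[f]; f
  })
  tet_mesh(nodes[, 2:4, drop = FALSE], elems, patches,
           metadata = if (is.null(label)) list() else list(label = label))
}

#' Export the boundary surface as ASCII STL
#'
#' Writes the (corner-node) boundary triangles with outward normals;
#' mid-edge nodes of quadratic meshes are not written (STL is linear).
#'
#' @param mesh a [tet_mesh()].
#' @param path output `.stl` path.
#' @return invisibly `path`.
#' @export
write_surface_stl <- function(mesh, path) {
  bnd <- boundary_faces(mesh)
  p1 <- mesh$nodes[bnd[, 1L], , drop = FALSE]
  p2 <- mesh$nodes[bnd[, 2L], , drop = FALSE]
  p3 <- mesh$nodes[bnd[, 3L], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nrm <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid biteFEM", con)
  block <- paste0(
    "facet normal ", .fmt_num(nx / nrm), " ", .fmt_num(ny / nrm), " ",
    .fmt_num(nz / nrm), "\n outer loop\n  vertex ",
    .fmt_num(p1[, 1]), " ", .fmt_num(p1[, 2]), " ", .fmt_num(p1[, 3]),
    "\n  vertex ",
    .fmt_num(p2[, 1]), " ", .fmt_num(p2[, 2]), " ", .fmt_num(p2[, 3]),
    "\n  vertex ",
    .fmt_num(p3[, 1]), " ", .fmt_num(p3[, 2]), " ", .fmt_num(p3[, 3]),
    "\n endloop\nendfacet")
  writeLines(block, con)
  writeLines("endsolid biteFEM", con)
  invisible(path)
}
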