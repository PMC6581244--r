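# Mesh readers and writers: VTK XML unstructured grids (.vtu, cell type 24)
# and Abaqus input decks (.inp, C3D10 with element sets per region). Both
# dialects use the same within-element node order as tet_mesh10.

.region_to_code <- function(region) match(region, .region_levels)

#' Write a mesh (VTU or Abaqus INP)
#'
#' Format is chosen from the file extension. VTU files can carry additional
#' per-element (`cell_data`) and per-node (`point_data`) arrays, e.g. the
#' material field or a solved displacement field; the region tag is always
#' written. INP files encode regions as element sets.
#'
#' @param mesh A `tet_mesh10`.
#' @param path Output path ending in `.vtu` or `.inp`.
#' @param cell_data Named list of numeric vectors (length = elements) or
#'   matrices (rows = elements).
#' @param point_data Named list of numeric vectors/matrices (rows = nodes).
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, cell_data = list(), point_data = list()) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtu = .write_vtu(mesh, path, cell_data, point_data),
         inp = .write_inp(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param path `.vtu` or `.inp` file.
#' @return A `tet_mesh10`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtu = .read_vtu(path),
         inp = .read_inp(path),
         stop("unsupported mesh format: .", ext))
}

.num_block <- function(x, per_line = 6) {
  paste(vapply(split(x, ceiling(seq_along(x) / per_line)),
               function(r) paste(format(r, digits = 17, scientific = TRUE,
                                        trim = TRUE), collapse = " "),
               character(1)), collapse = "\n")
}

.write_vtu <- function(mesh, path, cell_data, point_data) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$conn)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M))
  w('<Points>')
  w('<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(.num_block(as.vector(t(mesh$nodes))))
  w('</DataArray>')
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  w(.num_block(as.vector(t(mesh$conn)) - 1L, per_line = 10))
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  w(.num_block(10L * seq_len(M), per_line = 10))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(.num_block(rep(24L, M), per_line = 20))
  w('</DataArray>')
  w('</Cells>')
  cd <- c(list(region = .region_to_code(mesh$region)), cell_data)
  w('<CellData>')
  for (nm in names(cd)) {
    v <- cd[[nm]]
    ncomp <- if (is.matrix(v)) ncol(v) else 1L
    w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              nm, ncomp))
    w(.num_block(if (is.matrix(v)) as.vector(t(v)) else v))
    w('</DataArray>')
  }
  w('</CellData>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      ncomp <- if (is.matrix(v)) ncol(v) else 1L
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, ncomp))
      w(.num_block(if (is.matrix(v)) as.vector(t(v)) else v))
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
}

.read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts <- num(xml2::xml_find_first(piece, ".//Points/DataArray"))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  arrays <- xml2::xml_find_all(piece, ".//Cells/DataArray")
  names(arrays) <- xml2::xml_attr(arrays, "Name")
  types <- num(arrays[["types"]])
  if (!all(types == 24))
    stop("unsupported cell types in VTU (only quadratic tetrahedra, type 24)")
  conn <- matrix(num(arrays[["connectivity"]]) + 1L, ncol = 10, byrow = TRUE)
  cdat <- xml2::xml_find_all(piece, ".//CellData/DataArray")
  names(cdat) <- xml2::xml_attr(cdat, "Name")
  region <- if ("region" %in% names(cdat))
    .region_levels[num(cdat[["region"]])] else "diaphysis"
  tet_mesh10(nodes, conn, region)
}

.write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("*HEADING")
  w("infantfem tet10 mesh")
  w("*NODE")
  writeLines(sprintf("%d, %.17g, %.17g, %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  for (reg in unique(mesh$region)) {
    idx <- which(mesh$region == reg)
    w(sprintf("*ELEMENT, TYPE=C3D10, ELSET=%s", toupper(reg)))
    writeLines(paste0(idx, ", ",
                      apply(mesh$conn[idx, , drop = FALSE], 1, paste,
                            collapse = ", ")), con)
  }
}

.read_inp <- function(path) {
  lines <- readLines(path)
  i <- 1
  nodes <- NULL
  conn <- NULL
  elid <- integer(0)
  region <- character(0)
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (grepl("^\\*NODE", ln, ignore.case = TRUE)) {
      i <- i + 1
      rows <- list()
      while (i <= n && !startsWith(trimws(lines[i]), "*")) {
        rows[[length(rows) + 1]] <- as.numeric(strsplit(lines[i], ",")[[1]])
        i <- i + 1
      }
      tab <- do.call(rbind, rows)
      nodes <- matrix(NA_real_, max(tab[, 1]), 3)
      nodes[tab[, 1], ] <- tab[, 2:4]
    } else if (grepl("^\\*ELEMENT", ln, ignore.case = TRUE)) {
      type <- sub(".*TYPE=([A-Za-z0-9]+).*", "\\1", ln, ignore.case = TRUE)
      if (toupper(type) != "C3D10")
        stop("unsupported element type in INP: ", type)
      elset <- if (grepl("ELSET=", ln, ignore.case = TRUE))
        tolower(sub(".*ELSET=([A-Za-z0-9_]+).*", "\\1", ln, ignore.case = TRUE))
      else "diaphysis"
      i <- i + 1
      while (i <= n && !startsWith(trimws(lines[i]), "*")) {
        v <- as.numeric(strsplit(lines[i], ",")[[1]])
        elid <- c(elid, v[1])
        conn <- rbind(conn, v[2:11])
        region <- c(region, elset)
        i <- i + 1
      }
    } else i <- i + 1
  }
  if (is.null(nodes) || is.null(conn)) stop("no mesh found in INP file")
  ord <- order(elid)
  region <- region[ord]
  if (!all(region %in% .region_levels)) region[!region %in% .region_levels] <- "diaphysis"
  tet_mesh10(nodes, matrix(as.integer(conn[ord, ]), ncol = 10), region)
}
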