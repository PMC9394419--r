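#' Read and write 3D volumes (NIfTI and NRRD)
#'
#' Axis-aligned 3D scalar volumes with spacing and origin preserved
#' through a round-trip. NIfTI (`.nii`, `.nii.gz`) goes through RNifti;
#' NRRD (`.nrrd`) through a minimal NRRD0004 reader/writer (raw or gzip
#' encodings, axis-aligned space directions). Volumes whose voxels are
#' all 0/1 are returned as [binary_mask3d()].
#'
#' @param path File path; the extension selects the format.
#' @return `read_volume()`: an [image3d()] or [binary_mask3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- volume_format(path)
  vol <- if (ext == "nifti") read_nifti_volume(path) else read_nrrd_volume(path)
  if (all(vol$data %in% c(0, 1)))
    binary_mask3d(vol$data, vol$spacing, vol$origin)
  else vol
}

#' @rdname read_volume
#' @param vol An [image3d()] or [binary_mask3d()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image3d"))
  ext <- volume_format(path)
  if (ext == "nifti") write_nifti_volume(vol, path) else write_nrrd_volume(vol, path)
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("unsupported volume extension (use .nii, .nii.gz or .nrrd): ",
       basename(path), call. = FALSE)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  X <- RNifti::xform(img)
  lin <- X[1:3, 1:3]
  if (max(abs(lin - diag(diag(lin)))) > 1e-4 || any(diag(lin) <= 0))
    stop("only axis-aligned RAS NIfTI volumes are supported", call. = FALSE)
  arr <- array(as.numeric(img), dim(img)[1:3])
  image3d(arr, spacing = diag(lin), origin = X[1:3, 4])
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  X <- diag(4)
  X[1:3, 1:3] <- diag(vol$spacing)
  X[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(X, code = 2L)
  RNifti::sform(img) <- structure(X, code = 2L)
  RNifti::writeNifti(img, path)
}

# --- minimal NRRD0004 (detached headers, non-axis-aligned frames and
#     exotic encodings are out of scope; raw and gzip are supported) ---

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(nm) {
    if (is.null(fields[[nm]])) stop("NRRD header missing field: ", nm, call. = FALSE)
    fields[[nm]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("only 3D NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  typ <- tolower(need("type"))
  rtype <- switch(typ,
                  "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" =
                    list(what = "integer", size = 1L, signed = FALSE),
                  "short" = , "int16" = , "signed short" =
                    list(what = "integer", size = 2L, signed = TRUE),
                  "int" = , "int32" = , "signed int" =
                    list(what = "integer", size = 4L, signed = TRUE),
                  "float" = list(what = "numeric", size = 4L, signed = TRUE),
                  "double" = list(what = "numeric", size = 8L, signed = TRUE),
                  stop("unsupported NRRD type: ", typ, call. = FALSE))
  enc <- tolower(need("encoding"))
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    M <- do.call(rbind, dirs)
    if (max(abs(M - diag(diag(M)))) > 1e-9 || any(diag(M) <= 0))
      stop("only axis-aligned NRRD space directions are supported", call. = FALSE)
    spacing <- diag(M)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  n <- prod(sizes)
  raw_payload <- readBin(con, "raw", n = n * rtype$size + 1024L)
  if (enc %in% c("gzip", "gz")) raw_payload <- memDecompress(raw_payload, "gzip")
  else if (!enc %in% c("raw")) stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  vals <- readBin(raw_payload, rtype$what, n = n, size = rtype$size,
                  signed = rtype$signed, endian = "little")
  if (length(vals) < n) stop("truncated NRRD data block", call. = FALSE)
  image3d(array(as.numeric(vals), sizes), spacing = spacing, origin = origin)
}

parse_nrrd_vectors <- function(txt) {
  chunks <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  lapply(chunks, function(ch)
    as.numeric(strsplit(gsub("[()]", "", ch), ",")[[1]]))
}

write_nrrd_volume <- function(vol, path, encoding = c("gzip", "raw")) {
  encoding <- match.arg(encoding)
  is_mask <- all(vol$data %in% c(0, 1))
  typ <- if (is_mask) "unsigned char" else "double"
  hdr <- c("NRRD0004",
           "# minimal axis-aligned NRRD written by trusfit",
           paste0("type: ", typ),
           "dimension: 3",
           "space: right-anterior-superior",
           paste0("sizes: ", paste(dim(vol$data), collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                          vol$spacing[1], vol$spacing[2], vol$spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", encoding),
           paste0("space origin: ",
                  sprintf("(%.9g,%.9g,%.9g)",
                          vol$origin[1], vol$origin[2], vol$origin[3])),
           "")
  payload <- if (is_mask)
    writeBin(as.integer(vol$data), raw(), size = 1L, endian = "little")
  else
    writeBin(as.numeric(vol$data), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  invisible(path)
}

#' Read and write 3D Slicer markups JSON
#'
#' Control-point documents following the 3D Slicer markups schema. The
#' coordinate frame declared in the file (`RAS` or `LPS`) is honored:
#' points are converted to RAS internally (LPS negates x and y) and
#' written back in the requested frame.
#'
#' @param path Path of the markups `.json` file.
#' @return `read_markups()`: a list of class `"markup_document"` with
#'   `points` (n x 3 matrix, RAS mm), `labels`, and the source
#'   `coordinate_system`.
#' @export
read_markups <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$markups) || length(doc$markups) < 1L)
    stop("no markups in ", path, call. = FALSE)
  mk <- doc$markups[[1]]
  frame <- mk$coordinateSystem
  if (is.null(frame)) stop("markups file lacks a coordinateSystem tag", call. = FALSE)
  frame <- toupper(frame)
  if (!frame %in% c("RAS", "LPS"))
    stop("unsupported coordinate system: ", frame, call. = FALSE)
  cps <- mk$controlPoints
  if (is.null(cps) || length(cps) == 0L) stop("markups contain no control points")
  pts <- t(vapply(cps, function(cp) as.numeric(unlist(cp$position)), numeric(3)))
  labels <- vapply(cps, function(cp)
    if (is.null(cp$label)) "" else as.character(cp$label), character(1))
  if (frame == "LPS") pts[, 1:2] <- -pts[, 1:2]
  structure(list(points = pts, labels = labels, coordinate_system = frame),
            class = "markup_document")
}

#' @rdname read_markups
#' @param points n x 3 matrix of control points in RAS mm.
#' @param labels Optional character vector of point labels.
#' @param coordinate_system Frame to declare in the file (`"LPS"`, the
#'   3D Slicer default, or `"RAS"`).
#' @param type Markups node type.
#' @export
write_markups <- function(points, path, labels = NULL,
                          coordinate_system = c("LPS", "RAS"),
                          type = "Fiducial") {
  coordinate_system <- match.arg(coordinate_system)
  pts <- base::matrix(as.numeric(as.matrix(points)), ncol = 3L)
  if (is.null(labels)) labels <- sprintf("F-%d", seq_len(nrow(pts)))
  out <- pts
  if (coordinate_system == "LPS") out[, 1:2] <- -out[, 1:2]
  cps <- lapply(seq_len(nrow(out)), function(i)
    list(id = as.character(i), label = labels[i],
         position = as.numeric(out[i, ]),
         orientation = c(-1, 0, 0, 0, -1, 0, 0, 0, 1),
         selected = TRUE, locked = FALSE, visibility = TRUE,
         positionStatus = "defined"))
  doc <- list(
    `@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json",
    markups = list(list(type = type, coordinateSystem = coordinate_system,
                        coordinateUnits = "mm", controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Group markup points into annotated slices
#'
#' Assigns each 3D control point to the nearest axial plane of a
#' reference volume (third axis = superior-inferior) and builds one
#' [annotated_slice()] per occupied plane from the in-plane (x, y)
#' coordinates. Regions can be encoded in the point labels (containing
#' `base`, `mid` or `apex`); otherwise the most inferior occupied plane
#' is the apex, the most superior the base, and the rest mid-gland.
#'
#' @param doc A `markup_document` from [read_markups()], or an n x 3
#'   point matrix in RAS mm.
#' @param reference An [image3d()] supplying the axial plane geometry.
#' @param model Slice model assigned to mid slices (base/apex always use
#'   the superellipse).
#' @return List of [annotated_slice()] objects ordered by z.
#' @export
markups_to_slices <- function(doc, reference,
                              model = c("superellipse", "bspline")) {
  model <- match.arg(model)
  pts <- if (inherits(doc, "markup_document")) doc$points
         else base::matrix(as.numeric(as.matrix(doc)), ncol = 3L)
  labels <- if (inherits(doc, "markup_document")) doc$labels
            else rep("", nrow(pts))
  zc <- axis_coords(reference, 3L)
  ks <- vapply(pts[, 3], function(z) which.min(abs(zc - z)), integer(1))
  groups <- split(seq_len(nrow(pts)), ks)
  z_of <- vapply(groups, function(ii) zc[ks[ii[1]]], numeric(1))
  ord <- order(z_of)
  groups <- groups[ord]; z_of <- z_of[ord]
  region_of <- function(ii, pos) {
    lab <- tolower(paste(labels[ii], collapse = " "))
    if (grepl("base", lab)) return("base")
    if (grepl("apex", lab)) return("apex")
    if (grepl("mid", lab)) return("mid")
    if (pos == 1L) "apex" else if (pos == length(groups)) "base" else "mid"
  }
  lapply(seq_along(groups), function(g) {
    ii <- groups[[g]]
    region <- region_of(ii, g)
    annotated_slice(pts[ii, 1:2, drop = FALSE], z_mm = z_of[g],
                    region = region,
                    model = if (region == "mid") model else "superellipse",
                    slice_index = ks[ii[1]])
  })
}

#' Write or read a 3D prostate model as JSON
#'
#' Persists the annotated z positions, regions and per-slice parameter
#' vectors together with the in-plane grid geometry, so a reconstruction
#' can be rebuilt or refined later.
#'
#' @param model A [prostate_model()].
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "prostate_model"))
  doc <- list(
    z_spacing = model$z_spacing,
    grid = list(nx = model$grid$nx, ny = model$grid$ny,
                spacing = model$grid$spacing, origin = model$grid$origin),
    slices = lapply(seq_along(model$z), function(i)
      list(z = model$z[i], region = model$regions[i],
           params = as.list(se_params(model$params[[i]])))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  g <- doc$grid
  grid <- slice_grid(g$nx, g$ny, spacing = unlist(g$spacing),
                     origin = unlist(g$origin))
  entries <- lapply(doc$slices, function(s)
    list(z = s$z, region = s$region, par = as_superellipse(unlist(s$params))))
  prostate_model(entries, grid, z_spacing = doc$z_spacing)
}

#' Write or read an affine transform as a 4x4 matrix text file
#'
#' Plain whitespace-separated 4x4 homogeneous matrix (rows = lines),
#' mapping fixed physical mm to moving physical mm.
#'
#' @param T An [affine3d()].
#' @param path Output text file.
#' @export
write_transform <- function(T, path) {
  M <- as_matrix4(T)
  writeLines(apply(M, 1L, function(r) paste(sprintf("%.12g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  M <- as.matrix(utils::read.table(path))
  if (!all(dim(M) == c(4L, 4L))) stop("transform file must hold a 4x4 matrix")
  affine3d(M[1:3, 1:3], translation = M[1:3, 4], center = c(0, 0, 0))
}
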