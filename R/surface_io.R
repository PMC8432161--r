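# Readers/writers for the file formats the pipeline exchanges with
# FreeSurfer, Slicer and spreadsheet tools. All coordinates are mm in
# scanner RAS; vertex and triangle indices are 1-based inside R and
# converted to the formats' 0-based convention on write/read.

TRIANGLE_MAGIC <- c(0xFF, 0xFF, 0xFE)
CURV_MAGIC <- c(0xFF, 0xFF, 0xFF)

#' Construct a hemisphere surface
#'
#' A triangulated cortical hemisphere surface: an `n x 3` matrix of vertex
#' coordinates (mm, scanner RAS) and an `m x 3` matrix of 1-based triangle
#' vertex indices. Paired gray/white surfaces of one hemisphere share the
#' same vertex count and triangle list.
#'
#' @param vertices numeric matrix `n x 3`, coordinates in mm.
#' @param triangles integer matrix `m x 3`, 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @param surface_kind `"white"`, `"pial"` or `"mid"`.
#' @param check validate mesh invariants (index range, every vertex used,
#'   single edge-connected component).
#' @return object of class `hemi_surface`.
#' @export
hemi_surface <- function(vertices, triangles,
                         hemisphere = c("left", "right"),
                         surface_kind = c("white", "pial", "mid"),
                         check = TRUE) {
  hemisphere <- match.arg(hemisphere)
  surface_kind <- match.arg(surface_kind)
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  triangles <- matrix(as.integer(triangles), ncol = 3)
  s <- structure(list(vertices = vertices, triangles = triangles,
                      hemisphere = hemisphere, surface_kind = surface_kind),
                 class = "hemi_surface")
  if (check) validate_surface(s)
  s
}

validate_surface <- function(s) {
  nv <- nrow(s$vertices)
  tr <- s$triangles
  if (any(tr < 1L) || any(tr > nv))
    stop("triangle indices out of range [1, ", nv, "]")
  if (!all(seq_len(nv) %in% tr))
    stop("mesh has isolated vertices (not referenced by any triangle)")
  g <- mesh_graph(s)
  if (igraph::components(g)$no != 1L)
    stop("mesh is not edge-connected as a single component")
  invisible(s)
}

n_vertices <- function(surface) nrow(surface$vertices)

#' @export
print.hemi_surface <- function(x, ...) {
  cat(sprintf("<hemi_surface: %s %s, %d vertices, %d triangles>\n",
              x$hemisphere, x$surface_kind,
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Construct a per-vertex overlay
#'
#' @param values numeric vector, one scalar per vertex; `NA` marks masked
#'   vertices.
#' @param name feature identifier.
#' @param units free-text units.
#' @return object of class `lp_overlay` (a numeric vector with attributes).
#' @export
overlay <- function(values, name = "overlay", units = "") {
  v <- as.numeric(values)
  if (any(!is.finite(v) & !is.na(v)))
    stop("overlay values must be finite or NA")
  structure(v, name = name, units = units, class = "lp_overlay")
}

overlay_values <- function(x) as.numeric(unclass(x))

check_overlay_length <- function(values, surface) {
  if (length(values) != n_vertices(surface))
    stop(sprintf("overlay length %d does not match surface vertex count %d",
                 length(values), n_vertices(surface)))
  invisible(values)
}

# ---- FreeSurfer binary surface ------------------------------------------

read_int24 <- function(raw3) {
  sum(as.integer(raw3) * c(65536L, 256L, 1L))
}

#' Read a FreeSurfer binary surface file
#'
#' @param path file in FreeSurfer triangle-surface format.
#' @param hemisphere,surface_kind metadata attached to the result (the file
#'   format does not record them).
#' @param check validate mesh invariants.
#' @return a [hemi_surface()].
#' @export
read_surface <- function(path, hemisphere = "left", surface_kind = "white",
                         check = TRUE) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 3L || read_int24(raw[1:3]) != 16777214L)
    stop("not a FreeSurfer triangle surface (bad magic number): ", path)
  # comment string terminated by "\n\n"
  i <- 4L
  nl <- which(raw == as.raw(0x0A))
  stop_at <- nl[which(diff(nl) == 1L)[1]]
  if (is.na(stop_at)) stop("malformed surface file (unterminated comment)")
  i <- stop_at + 2L
  con <- rawConnection(raw[i:length(raw)])
  on.exit(close(con))
  counts <- readBin(con, "integer", n = 2, size = 4, endian = "big")
  nv <- counts[1]; nf <- counts[2]
  if (nv <= 0 || nf <= 0) stop("malformed surface file (bad counts)")
  coords <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  tris <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(coords) < 3 * nv || length(tris) < 3 * nf)
    stop("truncated surface file: ", path)
  hemi_surface(matrix(coords, ncol = 3, byrow = TRUE),
               matrix(tris, ncol = 3, byrow = TRUE) + 1L,
               hemisphere = hemisphere, surface_kind = surface_kind,
               check = check)
}

#' Write a FreeSurfer binary surface file
#'
#' @param surface a [hemi_surface()].
#' @param path output path.
#' @export
write_surface <- function(surface, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(TRIANGLE_MAGIC), con)
  writeChar("created by lesionplan\n\n", con, eos = NULL)
  writeBin(c(nrow(surface$vertices), nrow(surface$triangles)),
           con, size = 4, endian = "big")
  writeBin(as.numeric(t(surface$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(surface$triangles) - 1L), con, size = 4,
           endian = "big")
  invisible(path)
}

# ---- FreeSurfer curv overlay --------------------------------------------

#' Read a per-vertex overlay (FreeSurfer curv or MGH format)
#'
#' Format is detected from the magic number. The overlay length is checked
#' against `surface` when one is supplied.
#'
#' @param path curv ("new format") or MGH overlay file.
#' @param surface optional [hemi_surface()] for the length check.
#' @param name feature identifier for the result.
#' @return an [overlay()].
#' @export
read_overlay <- function(path, surface = NULL, name = basename(path)) {
  head <- readBin(path, "raw", n = 3)
  vals <- if (read_int24(head) == 16777215L) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 3)
    hd <- readBin(con, "integer", n = 3, size = 4, endian = "big")
    readBin(con, "numeric", n = hd[1] * hd[3], size = 4, endian = "big")
  } else {
    m <- read_mgh(path)
    as.numeric(m$data)
  }
  if (!is.null(surface)) check_overlay_length(vals, surface)
  overlay(vals, name = name)
}

#' Write an overlay in FreeSurfer curv format
#'
#' @param x an [overlay()] or numeric vector.
#' @param path output path.
#' @param n_faces face count recorded in the header (informational).
#' @export
write_curv <- function(x, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(CURV_MAGIC), con)
  writeBin(c(length(x), as.integer(n_faces), 1L), con, size = 4,
           endian = "big")
  writeBin(as.numeric(x), con, size = 4, endian = "big")
  invisible(path)
}

# ---- MGH ----------------------------------------------------------------

#' Read an MGH file (volume or per-vertex overlay)
#'
#' @param path uncompressed `.mgh` file.
#' @return list with `data` (array `width x height x depth x frames`,
#'   dropped to the used dimensions), `vox2ras` (4x4, 0-based voxel indices)
#'   or `NULL` when the RAS flag is unset.
#' @export
read_mgh <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (!identical(v, 1L)) stop("not an MGH file (version != 1): ", path)
  dims <- readBin(con, "integer", n = 4, size = 4, endian = "big")
  type <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  readBin(con, "integer", n = 1, size = 4, endian = "big") # dof
  good_ras <- readBin(con, "integer", n = 1, size = 2, endian = "big")
  vox2ras <- NULL
  used <- 30L
  if (good_ras == 1L) {
    spacing <- readBin(con, "numeric", n = 3, size = 4, endian = "big")
    mdc <- matrix(readBin(con, "numeric", n = 9, size = 4, endian = "big"), 3)
    pxyz <- readBin(con, "numeric", n = 3, size = 4, endian = "big")
    d <- mdc %*% diag(spacing)
    centre <- dims[1:3] / 2
    vox2ras <- rbind(cbind(d, pxyz - d %*% centre), c(0, 0, 0, 1))
    used <- used + 60L
  }
  readBin(con, "raw", n = 284L - used)
  n <- prod(dims)
  data <- switch(as.character(type),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "1" = readBin(con, "integer", n = n, size = 4, endian = "big"),
    "3" = readBin(con, "numeric", n = n, size = 4, endian = "big"),
    "4" = readBin(con, "integer", n = n, size = 2, endian = "big"),
    stop("unsupported MGH data type: ", type))
  list(data = array(as.numeric(data), dim = dims), vox2ras = vox2ras)
}

#' Write data in MGH format
#'
#' Vectors are written as `n x 1 x 1` overlays; 3-d arrays as volumes.
#'
#' @param data numeric vector or array (up to 4-d).
#' @param path output path.
#' @param vox2ras optional 4x4 voxel(0-based)-to-RAS affine stored in the
#'   header.
#' @export
write_mgh <- function(data, path, vox2ras = NULL) {
  dims <- dim(data)
  if (is.null(dims)) dims <- c(length(data), 1L, 1L, 1L)
  dims <- c(dims, rep(1L, 4 - length(dims)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  writeBin(c(3L, 0L), con, size = 4, endian = "big")  # float, dof
  if (is.null(vox2ras)) {
    writeBin(0L, con, size = 2, endian = "big")
    writeBin(raw(284L - 30L), con)
  } else {
    writeBin(1L, con, size = 2, endian = "big")
    d <- vox2ras[1:3, 1:3]
    spacing <- sqrt(colSums(d^2))
    mdc <- sweep(d, 2, spacing, "/")
    pxyz <- vox2ras[1:3, 4] + d %*% (dims[1:3] / 2)
    writeBin(as.numeric(spacing), con, size = 4, endian = "big")
    writeBin(as.numeric(mdc), con, size = 4, endian = "big")
    writeBin(as.numeric(pxyz), con, size = 4, endian = "big")
    writeBin(raw(284L - 90L), con)
  }
  writeBin(as.numeric(data), con, size = 4, endian = "big")
  invisible(path)
}

# ---- NIfTI-1 (read-only, for intensity volumes) -------------------------

#' Read an uncompressed or gzipped NIfTI-1 volume
#'
#' Minimal single-file (`.nii`/`.nii.gz`) reader returning the image array
#' and the sform/qform-free affine assembled from srow fields (sform
#' required). Intensity scaling (`scl_slope`/`scl_inter`) is applied.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array) and `vox2ras` (4x4, 0-based voxels).
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  sz <- readBin(hdr[1:4], "integer", size = 4)
  endian <- if (sz == 348L) .Platform$endian else
    setdiff(c("big", "little"), .Platform$endian)
  gi <- function(off, n, size = 4, what = "integer")
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  dim0 <- gi(40, 8, 2)
  ndim <- dim0[1]
  dims <- dim0[2:(1 + max(ndim, 1))]
  datatype <- gi(70, 1, 2)
  scl_slope <- gi(112, 1, 4, "numeric"); scl_inter <- gi(116, 1, 4, "numeric")
  vox_offset <- gi(108, 1, 4, "numeric")
  srow <- matrix(gi(280, 12, 4, "numeric"), nrow = 3, byrow = TRUE)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1,
                             signed = FALSE)),
    "4" = readBin(con, "integer", n = n, size = 2, endian = endian),
    "8" = readBin(con, "integer", n = n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype))
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0)
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = dims),
       vox2ras = rbind(srow, c(0, 0, 0, 1)))
}

# ---- Electrode contacts -------------------------------------------------

CONTACT_LABELS <- c("SOZ", "irritative", "uninvolved")

make_contacts <- function(df) {
  need <- c("electrode", "contact", "x", "y", "z", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("contact table missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[need]
  df$contact <- as.integer(df$contact)
  for (v in c("x", "y", "z")) df[[v]] <- as.numeric(df[[v]])
  bad <- setdiff(unique(df$label), CONTACT_LABELS)
  if (length(bad))
    stop("unknown contact label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CONTACT_LABELS, collapse = ", "))
  if (any(!is.finite(as.matrix(df[c("x", "y", "z")]))))
    stop("contact coordinates must be finite")
  class(df) <- c("electrode_set", "data.frame")
  df
}

#' Read electrode contact coordinates
#'
#' Accepts either a plain CSV with columns
#' `electrode,contact,x,y,z,label` or a Slicer markups fiducial file
#' (`.fcsv`). In FCSV the fiducial `label` column is parsed as
#' `<electrode>-<contact>` and the `desc` column must carry the
#' neurophysiology label (`SOZ`, `irritative` or `uninvolved`).
#'
#' @param path CSV or FCSV file.
#' @return data.frame of class `electrode_set` with columns
#'   `electrode, contact, x, y, z, label` (coordinates in mm).
#' @export
read_contacts <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "# Markups fiducial file")) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    f <- utils::read.csv(text = lines, header = FALSE,
                         stringsAsFactors = FALSE)
    # columns: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
    parts <- strsplit(as.character(f[[12]]), "-", fixed = TRUE)
    make_contacts(data.frame(
      electrode = vapply(parts, `[`, "", 1),
      contact = vapply(parts, function(p) p[length(p)], ""),
      x = f[[2]], y = f[[3]], z = f[[4]],
      label = as.character(f[[13]]),
      stringsAsFactors = FALSE))
  } else {
    make_contacts(utils::read.csv(path, stringsAsFactors = FALSE))
  }
}

#' Write electrode contacts as CSV
#' @param contacts an `electrode_set`.
#' @param path output CSV path.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.csv(as.data.frame(contacts), path, row.names = FALSE)
  invisible(path)
}

# ---- Affine transforms --------------------------------------------------

#' Construct/validate a 4x4 affine transform
#'
#' @param matrix 4x4 numeric; last row must be `(0,0,0,1)` and the matrix
#'   invertible.
#' @param source_space,target_space free-text labels.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, source_space = "", target_space = "") {
  m <- base::matrix(as.numeric(matrix), 4, 4)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine last row must be (0,0,0,1)")
  if (abs(det(m)) < 1e-12) stop("affine matrix is not invertible")
  structure(list(matrix = m, source_space = source_space,
                 target_space = target_space),
            class = "affine_transform")
}

#' Read a 4x4 whitespace-delimited affine text file
#' @param path text file with 4 rows of 4 numbers.
#' @inheritParams affine_transform
#' @return an [affine_transform()].
#' @export
read_affine <- function(path, source_space = "", target_space = "") {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!all(dim(m) == c(4, 4))) stop("affine file must be 4x4: ", path)
  affine_transform(m, source_space, target_space)
}

#' Write a 4x4 affine as whitespace-delimited text
#' @param affine an [affine_transform()] or 4x4 matrix.
#' @param path output path.
#' @export
write_affine <- function(affine, path) {
  m <- if (inherits(affine, "affine_transform")) affine$matrix else affine
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply an affine to points
#' @param affine an [affine_transform()].
#' @param points `n x 3` matrix of coordinates.
#' @return transformed `n x 3` matrix.
#' @export
apply_affine <- function(affine, points) {
  m <- if (inherits(affine, "affine_transform")) affine$matrix else affine
  pts <- base::matrix(as.numeric(points), ncol = 3)
  out <- cbind(pts, 1) %*% t(m)
  out[, 1:3, drop = FALSE]
}

# ---- Cohort table -------------------------------------------------------

INDICATION_LEVELS <- c("lesion-negative", "discordance", "not-definitive")
OUTCOME_LEVELS <- c("focal", "mTLE", "diffuse", "likely-focal")
CONCORDANCE_LEVELS <- c("yes", "no", "not-applicable")
SURGERY_LEVELS <- c("yes", "no", "thermocoagulation",
                    "thermocoagulation+laser")
HISTOLOGY_LEVELS <- c("FCD IIA", "FCD IIB", "FCD II", "HS", "nondiagnostic",
                      "other", "not-applicable")
SEIZURE_FREE_LEVELS <- c("yes", "no", "not-applicable")

normalize_enum <- function(x, map, levels, column, patient) {
  key <- tolower(trimws(x))
  out <- map[key]
  out[is.na(out) & key %in% tolower(levels)] <-
    levels[match(key[is.na(out) & key %in% tolower(levels)],
                 tolower(levels))]
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("cannot map %s value '%s' for patient %s",
                 column, x[bad[1]], patient[bad[1]]))
  unname(out)
}

#' Read a cohort record table
#'
#' One row per patient with the clinical summary columns: sEEG indication,
#' sEEG outcome, automated cluster count, concordance between clusters and
#' the seizure onset zone, surgery, histology, seizure outcome and
#' follow-up. Cell spellings from the clinical table (e.g. `"TC & laser"`,
#' `"non-diag"`, `"n.a."`) are normalized to closed enumerations.
#'
#' @param path CSV file.
#' @return data.frame of class `patient_cohort`, one `PatientRecord` row per
#'   patient; empty input gives a zero-row table.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(df) <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(df))))
  if (nrow(df) == 0)
    return(structure(data.frame(), class = c("patient_cohort",
                                             "data.frame")))
  pid <- as.character(df$patient)
  rec <- data.frame(
    patient_id = pid,
    seeg_indication = normalize_enum(df$seeg_indication,
      c("lesion-negative" = "lesion-negative",
        "discordance" = "discordance",
        "not definitive" = "not-definitive"),
      INDICATION_LEVELS, "seeg_indication", pid),
    seeg_outcome = normalize_enum(df$seeg_outcome,
      c("focal" = "focal", "mtle" = "mTLE", "diffuse" = "diffuse",
        "diffuse (rasmussen)" = "diffuse", "likely focal" = "likely-focal"),
      OUTCOME_LEVELS, "seeg_outcome", pid),
    n_clusters = as.integer(df$n_clusters),
    concordance = normalize_enum(df$concordance,
      c("y" = "yes", "n" = "no", "n.a." = "not-applicable",
        "na" = "not-applicable"),
      CONCORDANCE_LEVELS, "concordance", pid),
    surgery = normalize_enum(df$surgery,
      c("y" = "yes", "n" = "no", "tc" = "thermocoagulation",
        "tc & laser" = "thermocoagulation+laser"),
      SURGERY_LEVELS, "surgery", pid),
    histology = normalize_enum(df$histology,
      c("fcd iia" = "FCD IIA", "fcd iib" = "FCD IIB", "fcd ii" = "FCD II",
        "hs" = "HS", "non-diag" = "nondiagnostic", "other" = "other",
        "n.a." = "not-applicable", "na" = "not-applicable"),
      HISTOLOGY_LEVELS, "histology", pid),
    seizure_free = normalize_enum(df$outcome,
      c("seizure-free" = "yes", "not seizure-free" = "no",
        "n.a." = "not-applicable", "na" = "not-applicable"),
      SEIZURE_FREE_LEVELS, "seizure_free", pid),
    followup_months = suppressWarnings(as.integer(df$followup_months)),
    stringsAsFactors = FALSE)
  bad <- (rec$concordance == "not-applicable") != (rec$seeg_outcome != "focal")
  if (any(bad))
    stop("concordance must be not-applicable exactly for non-focal sEEG ",
         "outcomes; violated for patient(s) ",
         paste(rec$patient_id[bad], collapse = ", "))
  if (any(is.na(rec$n_clusters) | rec$n_clusters < 0))
    stop("n_clusters must be a non-negative integer")
  structure(rec, class = c("patient_cohort", "data.frame"))
}

#' Path of the packaged 34-patient cohort fixture
#' @return file path of the installed cohort CSV.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "table1_cohort.csv", package = "lesionplan",
              mustWork = TRUE)
}

#' Load the packaged 34-patient cohort table
#' @return `patient_cohort` data.frame with 34 records.
#' @export
table1_fixture <- function() read_cohort_table(cohort_fixture_path())
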