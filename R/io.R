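# File formats: ASCII STL / PLY / OBJ meshes (PLY carries an optional
# per-vertex scalar as the `quality` property), recording CSV, landmark and
# result JSON. All geometry files are mm.

#' Read a triangulated surface mesh
#'
#' Supported by extension: `.stl` (ASCII), `.ply` (ASCII; a per-vertex
#' `quality` property is returned as attribute `quality`), `.obj`.
#'
#' @param path File path.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format '.", ext, "' (stl, ply, obj)"))
}

#' Write a triangulated surface mesh
#'
#' `.ply` (ASCII, optional per-vertex scalar written as the `quality`
#' property) or `.stl` (ASCII). A [scalar_field()] can be passed to attach
#' its values to a PLY.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path (`.ply` or `.stl`).
#' @param field Optional [scalar_field()] or numeric vector (PLY only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, field = NULL) {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  ext <- tolower(tools::file_ext(path))
  if (!is.null(field)) {
    if (inherits(field, "scalar_field")) field <- field$values
    if (length(field) != nrow(mesh$vertices))
      stop("field must have one value per vertex")
  }
  switch(ext,
         ply = write_ply(mesh, path, field),
         stl = {
           if (!is.null(field))
             warning("STL cannot carry a scalar field; writing geometry only")
           write_stl(mesh, path)
         },
         stop("unsupported mesh format '.", ext, "' (ply, stl)"))
  invisible(path)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    stop("parse error in ", path, ": not an ASCII STL (line 1)")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0)
    stop("parse error in ", path, ": vertex count not a multiple of 3")
  nums <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                          `[`, 2:4))),
                 ncol = 3, byrow = TRUE)
  if (any(is.na(nums))) stop("parse error in ", path, ": bad vertex line")
  # merge duplicate vertices shared by adjacent facets
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- nums[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / sqrt(rowSums(n^2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid tmjmech", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid tmjmech", con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("parse error in ", path, ": missing ply magic (line 1)")
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop("parse error in ", path, ": no end_header")
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header)))
    stop("parse error in ", path, ": only ASCII PLY supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("parse error in ", path, ": element counts")
  # vertex property names in declaration order
  vstart <- grep("^element vertex", header)[1]
  vend <- grep("^element", header)
  vend <- min(c(vend[vend > vstart], endh))
  props <- sub("^property\\s+\\S+\\s+", "",
               grep("^property", header[vstart:vend], value = TRUE))
  body <- lines[(endh + 1):length(lines)]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(body[seq_len(nv)]), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- props[seq_len(ncol(vdat))]
  fdat <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(fdat, function(r) {
    if (as.integer(r[1]) != 3) stop("only triangular PLY faces supported")
    as.integer(r[2:4]) + 1L
  }, integer(3)))
  nrmls <- if (all(c("nx", "ny", "nz") %in% colnames(vdat)))
    vdat[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  m <- triangle_mesh(vdat[, c("x", "y", "z"), drop = FALSE], faces,
                     normals = nrmls)
  if ("quality" %in% colnames(vdat))
    attr(m, "quality") <- vdat[, "quality"]
  m
}

write_ply <- function(mesh, path, field = NULL) {
  v <- mesh$vertices
  has_n <- !is.null(mesh$normals)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (has_n) hdr <- c(hdr, "property float nx", "property float ny",
                      "property float nz")
  if (!is.null(field)) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  dat <- v
  if (has_n) dat <- cbind(dat, mesh$normals)
  if (!is.null(field)) dat <- cbind(dat, field)
  writeLines(apply(dat, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(paste("3", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop("parse error in ", path, ": no vertices or faces")
  verts <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                           `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(r) {
    if (length(r) != 4) stop("only triangular OBJ faces supported")
    as.integer(sub("/.*", "", r[2:4]))
  }, integer(3)))
  triangle_mesh(verts, faces)
}

#' Read a function-assessment recording from CSV
#'
#' Expects a header `t,force,LT,RT,LM,RM` (time in seconds starting at the
#' first sample, force in N, EMG in arbitrary units). Extra columns are
#' ignored with a warning. The time column must be uniform within 1e-6 s;
#' the sample rate is inferred from it.
#'
#' @param path CSV path.
#' @param task_side `"left"` or `"right"`.
#' @return A [bite_recording()].
#' @export
read_recording_csv <- function(path, task_side) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "force", "LT", "RT", "LM", "RM")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra) > 0)
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  t <- df$t
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6) || dt[1] <= 0)
    stop("time column is not uniformly increasing (tolerance 1e-6 s)")
  fs <- 1 / mean(dt)
  mk <- function(col, units = "") uniform_series(df[[col]], fs, t[1], units)
  bite_recording(mk("force", "N"),
                 list(LT = mk("LT"), RT = mk("RT"),
                      LM = mk("LM"), RM = mk("RM")),
                 task_side = task_side)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording_csv()].
#'
#' @param rec A [bite_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  if (!inherits(rec, "bite_recording")) stop("rec must be a bite_recording")
  df <- data.frame(t = series_times(rec$force), force = rec$force$values,
                   LT = rec$emg$LT$values, RT = rec$emg$RT$values,
                   LM = rec$emg$LM$values, RM = rec$emg$RM$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read landmark selection sets from JSON
#'
#' Format: `{"name": [[x, y, z], ...], ...}` in mm, one inner list entry
#' per observer repetition.
#'
#' @param path JSON path.
#' @return Named list of matrices (one row per repetition).
#' @export
read_landmarks_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(raw, function(m) {
    m <- as_landmark_matrix(m)
    m
  })
}

#' Write a processed task to JSON
#'
#' Stores the IC ratios and final bite force (`ic_temporalis`,
#' `ic_masseter`, `final_bite_force_N`, `task_side`); the force curve goes
#' to a sibling CSV when `curve_path` is given.
#'
#' @param task A `processed_task` from [process_recording()].
#' @param path Output JSON path.
#' @param curve_path Optional CSV path for the force curve (`t,force_N`).
#' @return `path`, invisibly.
#' @export
write_task_json <- function(task, path, curve_path = NULL) {
  if (!inherits(task, "processed_task")) stop("task must be a processed_task")
  jsonlite::write_json(
    list(ic_temporalis = task$ic_temporalis,
         ic_masseter = task$ic_masseter,
         final_bite_force_N = task$final_bite_force,
         task_side = task$task_side),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curve_path)) {
    utils::write.csv(data.frame(t = series_times(task$force_curve),
                                force_N = task$force_curve$values),
                     curve_path, row.names = FALSE)
  }
  invisible(path)
}
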