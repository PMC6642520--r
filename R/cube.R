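#' Volumetric scalar field on a regular grid (Gaussian cube)
#'
#' Container for cube-file data: electron densities, Fukui fields, the dual
#' descriptor.  Lengths are in bohr; `values` is the flattened scalar field
#' in the cube convention where the z index varies fastest.
#'
#' @param origin numeric length-3, grid origin (bohr).
#' @param axes 3x3 numeric matrix; row i is the voxel step along grid axis i
#'   (bohr).
#' @param counts integer length-3 `(nx, ny, nz)`, all positive.
#' @param atoms data.frame with columns `number` (atomic number), `charge`
#'   (nuclear charge) and `x`, `y`, `z` (bohr); may have zero rows.
#' @param values numeric vector of length `nx*ny*nz`, z-fastest.
#' @return An object of class `volumetric_grid`.
#' @examples
#' g <- volumetric_grid(c(0, 0, 0), diag(3), c(2, 2, 2),
#'                      values = rep(1, 8))
#' grid_integral(g)  # 8 unit voxels of 1.0
#' @export
volumetric_grid <- function(origin, axes, counts, atoms = NULL, values) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  counts <- as.integer(counts)
  values <- as.numeric(values)
  if (length(origin) != 3L) stop("origin must have length 3", call. = FALSE)
  if (length(counts) != 3L || any(counts <= 0L))
    stop("counts must be three positive integers", call. = FALSE)
  if (abs(det(axes)) <= 0)
    stop("axes are singular: zero voxel volume", call. = FALSE)
  if (length(values) != prod(counts))
    stop(sprintf("expected %d values, got %d", prod(counts), length(values)),
         call. = FALSE)
  if (is.null(atoms))
    atoms <- data.frame(number = integer(0), charge = numeric(0),
                        x = numeric(0), y = numeric(0), z = numeric(0))
  stopifnot(is.data.frame(atoms),
            all(c("number", "charge", "x", "y", "z") %in% names(atoms)))
  structure(
    list(origin = origin, axes = axes, counts = counts, atoms = atoms,
         values = values),
    class = "volumetric_grid")
}

#' @export
print.volumetric_grid <- function(x, ...) {
  cat(sprintf("<volumetric_grid %dx%dx%d, %d atoms, integral %.6g>\n",
              x$counts[1], x$counts[2], x$counts[3], nrow(x$atoms),
              grid_integral(x)))
  invisible(x)
}

#' Voxel volume of a grid (bohr^3)
#' @param g a [volumetric_grid].
#' @export
voxel_volume <- function(g) abs(det(g$axes))

#' Integrate a scalar field over its grid
#'
#' Riemann sum: `sum(values) * |det(axes)|`.  Used to verify Fukui-field
#' normalization (an exact one-electron field integrates to 1).
#'
#' @param g a [volumetric_grid].
#' @return The integral in (field unit) x bohr^3.
#' @export
grid_integral <- function(g) {
  stopifnot(inherits(g, "volumetric_grid"))
  sum(g$values) * voxel_volume(g)
}

#' Read a Gaussian cube file
#'
#' Layout: two comment lines; `natoms origin_x origin_y origin_z`; three
#' `n axis_x axis_y axis_z` lines; `natoms` atom lines
#' (`number charge x y z`); then the values, z index fastest, any whitespace
#' layout.  A negative atom count (the orbital-cube convention, where an
#' extra orbital-index record follows) is rejected: this reader handles
#' scalar fields only.
#'
#' @param text a file path, a character vector of lines, or one string with
#'   embedded newlines.
#' @return A [volumetric_grid].
#' @seealso [write_cube()]
#' @export
read_cube <- function(text) {
  lines <- .as_lines(text)
  if (length(lines) < 6L) stop("truncated cube header", call. = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])
  hdr <- num(lines[3])
  natoms <- as.integer(hdr[1])
  if (is.na(natoms)) stop("malformed cube header", call. = FALSE)
  if (natoms < 0)
    stop("negative atom count: orbital cubes are not supported", call. = FALSE)
  origin <- hdr[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    v <- num(lines[3 + i])
    counts[i] <- as.integer(v[1])
    axes[i, ] <- v[2:4]
  }
  if (any(is.na(counts)) || any(counts <= 0L))
    stop("non-positive grid counts", call. = FALSE)
  atoms <- data.frame(number = integer(0), charge = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  if (natoms > 0) {
    if (length(lines) < 6L + natoms) stop("truncated atom list", call. = FALSE)
    rows <- t(vapply(lines[6 + seq_len(natoms)], num, numeric(5)))
    atoms <- data.frame(number = as.integer(rows[, 1]), charge = rows[, 2],
                        x = rows[, 3], y = rows[, 4], z = rows[, 5])
  }
  body <- lines[-seq_len(6L + natoms)]
  values <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(body[nzchar(trimws(body))]), "[[:space:]]+"),
    use.names = FALSE)))
  if (any(is.na(values))) stop("non-numeric cube value", call. = FALSE)
  nexp <- prod(counts)
  if (length(values) < nexp)
    stop(sprintf("truncated value section: %d of %d values",
                 length(values), nexp), call. = FALSE)
  if (length(values) > nexp)
    stop("surplus values in cube body", call. = FALSE)
  volumetric_grid(origin, axes, counts, atoms, values)
}

#' Write a Gaussian cube file
#'
#' Emits the layout [read_cube()] parses: values z-fastest, `%13.5E`
#' formatting, six per line.  Round-tripping reproduces the header exactly
#' and the values to the 5-decimal mantissa.
#'
#' @param grid a [volumetric_grid].
#' @param path optional output file; when `NULL` the lines are returned.
#' @param comment two header comment lines.
#' @return Invisibly (or visibly when `path` is `NULL`) the character vector
#'   of file lines.
#' @export
write_cube <- function(grid, path = NULL,
                       comment = c("cdftkit volumetric grid", "scalar field")) {
  stopifnot(inherits(grid, "volumetric_grid"))
  comment <- rep_len(as.character(comment), 2L)
  f3 <- function(...) sprintf("%5d%12.6f%12.6f%12.6f", ...)
  out <- c(
    comment,
    f3(nrow(grid$atoms), grid$origin[1], grid$origin[2], grid$origin[3]),
    vapply(1:3, function(i) f3(grid$counts[i], grid$axes[i, 1],
                               grid$axes[i, 2], grid$axes[i, 3]),
           character(1)))
  if (nrow(grid$atoms) > 0) {
    out <- c(out, sprintf("%5d%12.6f%12.6f%12.6f%12.6f",
                          grid$atoms$number, grid$atoms$charge,
                          grid$atoms$x, grid$atoms$y, grid$atoms$z))
  }
  vals <- sprintf("%13.5E", grid$values)
  idx <- seq_along(vals)
  out <- c(out, vapply(split(vals, ceiling(idx / 6)), paste0,
                       character(1), collapse = ""))
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
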