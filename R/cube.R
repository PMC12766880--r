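# Gaussian cube file I/O.  Layout: two comment lines; atom count + origin;
# three axis lines (count, step vector); per-atom lines (Z, charge, x, y, z);
# then values in z-fastest order, at most 6 per line.  All lengths in Bohr.
# The positive-atom-count convention is used throughout (no orbital cubes).

#' Write a scalar field as a Gaussian cube file
#'
#' @param field a `scalar_field` (from [density_field()] / [esp_field()]).
#' @param geom the molecular geometry.
#' @param path output file path.
#' @param comment1,comment2 the two header comment lines.
#' @export
write_cube <- function(field, geom, path, comment1 = "vqerdm scalar field",
                       comment2 = "values in z-fastest order") {
  grid <- field$grid
  xyz <- angstrom_to_bohr(geom$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment1, comment2), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(xyz),
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (k in 1:3) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$counts[k],
                       grid$axes[k, 1], grid$axes[k, 2], grid$axes[k, 3]), con)
  }
  for (a in seq_len(nrow(xyz))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", geom$Z[a],
                       as.numeric(geom$Z[a]), xyz[a, 1], xyz[a, 2], xyz[a, 3]),
               con)
  }
  vals <- as.vector(field$values)    # z fastest by construction
  n <- length(vals)
  idx <- seq(1, n, by = 6)
  lines <- vapply(idx, function(i) {
    paste(sprintf("%14.6E", vals[i:min(i + 5, n)]), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @return list with `field` (a `scalar_field`), `Z`, `coords_bohr`.
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- num(lines[3])
  n_at <- as.integer(hdr[1])
  if (n_at < 0) stop("negative atom count (orbital cube) not supported")
  origin <- hdr[2:4]
  counts <- integer(3)
  axes <- matrix(0, 3, 3)
  for (k in 1:3) {
    v <- num(lines[3 + k])
    counts[k] <- as.integer(v[1])
    axes[k, ] <- v[2:4]
  }
  Z <- integer(n_at)
  coords <- matrix(0, n_at, 3)
  for (a in seq_len(n_at)) {
    v <- num(lines[6 + a])
    Z[a] <- as.integer(v[1])
    coords[a, ] <- v[3:5]
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[-seq_len(6 + n_at)]), "\\s+")))
  if (length(vals) != prod(counts)) stop("cube value count mismatch")
  field <- structure(list(grid = grid_spec(origin, axes, counts),
                          values = array(vals, rev(counts))),
                     class = "scalar_field")
  list(field = field, Z = Z, coords_bohr = coords)
}
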