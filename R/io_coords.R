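#' Coordinate tables
#'
#' Particle coordinates are kept in a plain data.frame with columns
#' `tomo_id` (character), `x`, `y`, `z` (0-based voxel indices) and optional
#' `score` (in \[0,1\]) and `label` (integer). This is the interchange format
#' between candidate proposal, embedding-based selection, detection and
#' evaluation.
#'
#' @param tomo_id character vector (recycled).
#' @param x,y,z numeric voxel coordinates (0-based).
#' @param score optional numeric scores in \[0,1\].
#' @param label optional integer class labels.
#' @return a data.frame of class `coord_table`.
#' @export
coord_table <- function(tomo_id = character(), x = numeric(), y = numeric(),
                        z = numeric(), score = NULL, label = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  df <- data.frame(tomo_id = rep_len(as.character(tomo_id), n),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   score = if (is.null(score)) rep(NA_real_, n)
                           else as.numeric(score),
                   label = if (is.null(label)) rep(NA_integer_, n)
                           else as.integer(label),
                   stringsAsFactors = FALSE)
  class(df) <- c("coord_table", "data.frame")
  df
}

#' Validate a coordinate table against a volume's bounds
#'
#' Checks the half-open bound 0 <= x < W (and likewise y, z).
#'
#' @param table a [coord_table()].
#' @param dims integer vector (W, H, D).
#' @export
validate_coords <- function(table, dims) {
  bad <- table$x < 0 | table$x >= dims[1] |
         table$y < 0 | table$y >= dims[2] |
         table$z < 0 | table$z >= dims[3]
  if (any(bad))
    stop(sum(bad), " coordinate(s) outside the volume bounds")
  invisible(table)
}

coord_cols <- c("tomo_id", "x", "y", "z", "score", "label")

#' Write a coordinate table
#'
#' `tsv` writes a tab-separated file with header
#' `tomo_id x y z score label`; numeric values keep full double precision.
#' `box3d` writes a headerless `x y z` triple per line (EMAN-style 3D box),
#' dropping scores and labels.
#'
#' @param table a [coord_table()].
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"box3d"`.
#' @export
write_coords <- function(table, path, dialect = c("tsv", "box3d")) {
  dialect <- match.arg(dialect)
  if (dialect == "box3d") {
    write.table(table[, c("x", "y", "z")], path, sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  df <- as.data.frame(table)[, coord_cols]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coordinate table written by [write_coords()]
#'
#' @param path input path.
#' @param dialect `"tsv"` or `"box3d"`.
#' @param tomo_id tomogram id to assign when reading `box3d` files.
#' @return a [coord_table()].
#' @export
read_coords <- function(path, dialect = c("tsv", "box3d"), tomo_id = "tomo") {
  dialect <- match.arg(dialect)
  if (dialect == "box3d") {
    df <- read.table(path, header = FALSE,
                     col.names = c("x", "y", "z"))
    return(coord_table(tomo_id, df$x, df$y, df$z))
  }
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c(tomo_id = "character"))
  if (!identical(names(df), coord_cols))
    stop("unexpected coordinate file header; expected: ",
         paste(coord_cols, collapse = " "))
  if (nrow(df) == 0)
    return(coord_table())
  coord_table(df$tomo_id, df$x, df$y, df$z,
              score = df$score, label = df$label)
}
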