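#' Coerce to a localization coordinate matrix
#'
#' Normalizes the accepted localization-table representations (data frame with
#' x/y/z columns — unit suffixes like `"x [nm]"` accepted —, 3-column numeric
#' matrix) to an n x 3 numeric matrix in nm. Row order is preserved: the row
#' index is the point identity used by all label vectors. Tables without a `z`
#' column are treated as 2D and given a constant z of 0, which yields a
#' single-voxel-thick grid (3x3 neighbourhoods) downstream.
#'
#' @param table The input table.
#' @return Numeric matrix with columns `x`, `y`, `z`; attribute `is2d` set if
#'   z was absent.
#' @export
as_localizations <- function(table) {
  if (is.matrix(table) && is.numeric(table)) {
    if (ncol(table) != 3L) stop("coordinate matrix must have 3 columns (x, y, z)")
    xyz <- table
    colnames(xyz) <- c("x", "y", "z")
  } else {
    df <- as.data.frame(table)
    map <- detect_columns(names(df))
    if (any(is.na(map[c("x", "y")])))
      stop("could not find x/y coordinate columns; candidates were: ",
           paste(names(df), collapse = ", "))
    is2d <- is.na(map["z"])
    z <- if (is2d) rep(0, nrow(df)) else as.numeric(df[[map["z"]]])
    xyz <- cbind(x = as.numeric(df[[map["x"]]]),
                 y = as.numeric(df[[map["y"]]]), z = z)
    if (is2d) attr(xyz, "is2d") <- TRUE
  }
  if (nrow(xyz) > 0L && !all(is.finite(xyz)))
    stop("localization coordinates must be finite; drop or fix non-finite rows ",
         "(read_localizations() does this automatically)")
  xyz
}

# header dialect detection: "x", "x [nm]", "x_nm", "X" ...
detect_columns <- function(nms, column_map = NULL) {
  norm <- tolower(gsub("\\s*\\[.*\\]\\s*$", "", trimws(nms)))
  norm <- gsub("_nm$", "", norm)
  find <- function(key) {
    i <- which(norm == key)
    if (length(i) >= 1L) i[1L] else NA_integer_
  }
  map <- c(x = find("x"), y = find("y"), z = find("z"))
  if (!is.null(column_map)) {
    for (ax in names(column_map)) {
      i <- if (is.character(column_map[[ax]])) match(column_map[[ax]], nms)
           else as.integer(column_map[[ax]])
      map[ax] <- i
    }
  }
  map
}

#' Read a localization table from a delimited text file
#'
#' Reads CSV/TSV localization exports. Coordinate columns are auto-detected
#' from the header, accepting the plain `x, y, z` dialect as well as
#' ThunderSTORM-style `"x [nm]", "y [nm]", "z [nm]"`; an explicit
#' `column_map` overrides detection. Rows with non-finite coordinates are
#' dropped (with a message). Extra columns (frame, precision, ...) are
#' carried through untouched.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named list/vector mapping `x`, `y`, `z` to
#'   column names or indices.
#' @param sep Field separator; default `NULL` auto-detects comma vs tab.
#' @return A data frame whose first three columns are the numeric coordinates
#'   named `x`, `y`, `z` (nm), followed by any extra input columns; attribute
#'   `is2d` is `TRUE` if no z column was present (z set to 0).
#' @export
read_localizations <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("data.table", quietly = TRUE)) {
    df <- as.data.frame(data.table::fread(path, sep = sep %||% "auto",
                                          data.table = FALSE))
  } else {
    if (is.null(sep)) {
      first <- readLines(path, n = 1L)
      sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
    }
    df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty localization table: ", path)
  }
  map <- detect_columns(names(df), column_map)
  if (any(is.na(map[c("x", "y")])))
    stop("missing coordinate columns in ", path,
         "; header candidates: ", paste(names(df), collapse = ", "))
  is2d <- is.na(map["z"])
  extra <- setdiff(seq_along(df), map[!is.na(map)])
  out <- data.frame(x = as.numeric(df[[map["x"]]]),
                    y = as.numeric(df[[map["y"]]]),
                    z = if (is2d) 0 else as.numeric(df[[map["z"]]]))
  ok <- is.finite(out$x) & is.finite(out$y) & is.finite(out$z)
  if (!all(ok)) message(sum(!ok), " rows with non-finite coordinates dropped")
  out <- cbind(out[ok, , drop = FALSE], df[ok, extra, drop = FALSE])
  rownames(out) <- NULL
  if (is2d) attr(out, "is2d") <- TRUE
  out
}

#' Write clustering results to CSV
#'
#' Writes the input table with an appended integer `cluster_id` column (-1 =
#' noise) and, optionally, a per-cluster summary table (id, localization and
#' voxel counts, centroid, convex-hull effective radius).
#'
#' @param table The localization table that was clustered (data frame).
#' @param fit A [focal3d()] result whose labels match `table` row-for-row.
#' @param path Output CSV path for the labeled table.
#' @param summary_path Optional output CSV path for the per-cluster summary.
#' @return Invisibly, the labeled data frame.
#' @export
write_results <- function(table, fit, path, summary_path = NULL) {
  stopifnot(inherits(fit, "focal3d"))
  df <- as.data.frame(table)
  if (nrow(df) != length(fit$labels))
    stop("labels length (", length(fit$labels),
         ") does not match table rows (", nrow(df), ")")
  df$cluster_id <- fit$labels
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- summary(fit)$clusters
    out <- data.frame(id = sm$id,
                      n_localizations = sm$n_localizations,
                      n_voxels = sm$n_voxels,
                      centroid_x = sm$centroid_x,
                      centroid_y = sm$centroid_y,
                      centroid_z = sm$centroid_z,
                      effective_radius = sm$effective_radius)
    utils::write.csv(out, summary_path, row.names = FALSE)
  }
  invisible(df)
}
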