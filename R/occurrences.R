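#' Read occurrence records from delimited text
#'
#' Reads a delimited text file of georeferenced observations (GBIF /
#' Darwin-Core style) into a standardized record table. Coordinate fields
#' that fail to parse as numbers (e.g. `"NA"`, empty strings) are retained
#' as missing values so that [clean_occurrences()] can log their removal —
#' nothing is dropped at this stage.
#'
#' @param path Path to a delimited text file with a header row.
#' @param taxon_col,lon_col,lat_col Names of the columns holding the taxon
#'   name, x/longitude and y/latitude. Defaults follow Darwin Core.
#' @param delim Field delimiter (default comma).
#' @param source Free-text provenance tag stored with each record.
#' @return A data frame of class `ps_occurrences` with columns
#'   `taxon`, `lon`, `lat`, `source`.
#' @export
read_occurrences <- function(path,
                             taxon_col = "species",
                             lon_col = "decimalLongitude",
                             lat_col = "decimalLatitude",
                             delim = ",",
                             source = basename(path)) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  for (col in c(taxon_col, lon_col, lat_col)) {
    if (!col %in% names(raw)) {
      stop("mapped column not found in header: '", col, "'")
    }
  }
  rec <- data.frame(
    taxon = trimws(raw[[taxon_col]]),
    lon = suppressWarnings(as.numeric(raw[[lon_col]])),
    lat = suppressWarnings(as.numeric(raw[[lat_col]])),
    source = source,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$taxon))) stop("empty taxon name in occurrence file")
  message(nrow(rec), " occurrence record(s) read from ", path)
  class(rec) <- c("ps_occurrences", "data.frame")
  rec
}

#' Clean occurrence records
#'
#' Applies the standard occurrence filters for gridded analyses: records
#' with missing coordinates are dropped, records with an exact-zero latitude
#' or longitude are dropped (a common GBIF placeholder for "no coordinate"),
#' and — when a boundary is supplied — records falling outside the study
#' area are dropped. Every removal is logged with its reason; the order of
#' the surviving records is preserved.
#'
#' Zero is matched by exact equality only; no tolerance is applied.
#'
#' @param records A `ps_occurrences` data frame (or any data frame with
#'   `taxon`, `lon`, `lat` columns).
#' @param bnd Optional `ps_boundary` study-area polygon in the same planar
#'   coordinate system as the records.
#' @return A list with elements `records` (the survivors, class preserved)
#'   and `rejected` (a data frame with columns `row`, `taxon`, `lon`, `lat`,
#'   `reason`).
#' @export
clean_occurrences <- function(records, bnd = NULL) {
  stopifnot(is.data.frame(records), all(c("taxon", "lon", "lat") %in% names(records)))
  if (!is.null(bnd) && !inherits(bnd, "ps_boundary")) {
    stop("invalid boundary geometry: expected a ps_boundary object")
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  miss <- is.na(records$lon) | is.na(records$lat) | !is.finite(records$lon) | !is.finite(records$lat)
  reason[miss] <- "missing coordinate"
  zero <- !miss & (records$lon == 0 | records$lat == 0)
  reason[zero] <- "zero coordinate"
  if (!is.null(bnd)) {
    cand <- which(is.na(reason))
    if (length(cand)) {
      ins <- point_in_boundary(records$lon[cand], records$lat[cand], bnd)
      reason[cand[!ins]] <- "outside boundary"
    }
  }
  drop <- !is.na(reason)
  rejected <- data.frame(row = which(drop),
                         taxon = records$taxon[drop],
                         lon = records$lon[drop],
                         lat = records$lat[drop],
                         reason = reason[drop],
                         stringsAsFactors = FALSE)
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, rejected = rejected)
}

#' Build a regular square analysis grid
#'
#' Lays a grid of half-open square cells `[x0, x0+s) x [y0, y0+s)` over a
#' rectangular extent, anchored at the lower-left corner. When a boundary
#' polygon is given, only cells whose intersection with the polygon has
#' positive area are retained (cells merely touching an edge are not).
#'
#' Cell identifiers are `"r<row>_c<col>"` with zero-based indices, row 0 at
#' the bottom; each point of the plane belongs to exactly one cell.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in planar units
#'   (meters). If `NULL`, taken from the bounding box of `bnd`.
#' @param bnd Optional `ps_boundary`; cells not overlapping it are dropped.
#' @param cell_size Cell edge length in the same units (default 10000, i.e.
#'   a 10 x 10 km grid).
#' @return An object of class `ps_grid`: list with `origin`, `cell_size`,
#'   `n_rows`, `n_cols`, and a `cells` data frame (`cell_id`, `row`, `col`,
#'   `x0`, `y0`) of retained cells in row-major order.
#' @export
build_grid <- function(extent = NULL, bnd = NULL, cell_size = 10000) {
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (is.null(extent)) {
    if (is.null(bnd)) stop("either extent or a boundary is required")
    xy <- do.call(rbind, lapply(bnd$polygons, function(p) do.call(rbind, p)))
    extent <- c(min(xy[, 1L]), max(xy[, 1L]), min(xy[, 2L]), max(xy[, 2L]))
  }
  stopifnot(length(extent) == 4L, all(is.finite(extent)))
  if (extent[2L] <= extent[1L] || extent[4L] <= extent[3L]) {
    stop("degenerate extent: xmax must exceed xmin and ymax exceed ymin")
  }
  spanx <- extent[2L] - extent[1L]
  spany <- extent[4L] - extent[3L]
  n_cols <- max(1L, as.integer(ceiling(spanx / cell_size - 1e-9)))
  n_rows <- max(1L, as.integer(ceiling(spany / cell_size - 1e-9)))
  if (n_cols == 1L && n_rows == 1L) {
    warning("cell_size covers the whole extent: grid has a single cell")
  }
  cells <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  cells <- cells[order(cells$row, cells$col), c("row", "col")]
  cells$x0 <- extent[1L] + cells$col * cell_size
  cells$y0 <- extent[3L] + cells$row * cell_size
  cells$cell_id <- sprintf("r%d_c%d", cells$row, cells$col)
  if (!is.null(bnd)) {
    if (!inherits(bnd, "ps_boundary")) stop("invalid boundary geometry")
    eps <- 1e-8 * cell_size^2
    keep <- vapply(seq_len(nrow(cells)), function(i) {
      .boundary_rect_area(bnd, cells$x0[i], cells$x0[i] + cell_size,
                          cells$y0[i], cells$y0[i] + cell_size) > eps
    }, logical(1L))
    cells <- cells[keep, , drop = FALSE]
    if (nrow(cells) == 0L) stop("no grid cell overlaps the boundary")
  }
  rownames(cells) <- NULL
  structure(list(origin = extent[c(1L, 3L)], cell_size = cell_size,
                 n_rows = n_rows, n_cols = n_cols,
                 cells = cells[, c("cell_id", "row", "col", "x0", "y0")],
                 boundary = bnd),
            class = "ps_grid")
}

#' Locate planar points in a grid
#'
#' Half-open assignment: a point on a shared lower/left cell edge belongs to
#' the cell with the larger index, so each point maps to exactly one cell.
#'
#' @param x,y Planar coordinates.
#' @param grid A `ps_grid`.
#' @return Character vector of cell ids; `NA` for points outside every
#'   retained cell (including points beyond the extent).
#' @keywords internal
locate_cells <- function(x, y, grid) {
  s <- grid$cell_size
  col <- floor((x - grid$origin[1L]) / s)
  row <- floor((y - grid$origin[2L]) / s)
  id <- sprintf("r%d_c%d", as.integer(row), as.integer(col))
  id[!(id %in% grid$cells$cell_id) |
       col < 0 | row < 0 | col >= grid$n_cols | row >= grid$n_rows] <- NA_character_
  id
}

#' Rasterize occurrence records to a presence-absence matrix
#'
#' Bins cleaned records into grid cells and collapses duplicates: any number
#' of records of one taxon in one cell becomes a single presence. Taxa with
#' no surviving record are absent from the result; retained grid cells in
#' which no taxon occurs are flagged as having no records and excluded from
#' the incidence matrix (they are reported, not analyzed — the "white cells"
#' of a diversity map).
#'
#' @param records Cleaned occurrence records (`taxon`, `lon`, `lat`).
#' @param grid A `ps_grid` in the same planar coordinate system.
#' @return A `ps_presence` object; see [presence_matrix()].
#' @export
rasterize_presence <- function(records, grid) {
  stopifnot(inherits(grid, "ps_grid"), is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("no occurrence records to rasterize")
  }
  ids <- locate_cells(records$lon, records$lat, grid)
  off <- is.na(ids)
  skipped <- records[off, , drop = FALSE]
  if (any(off)) {
    warning(sum(off), " record(s) outside the grid were skipped")
  }
  keep <- which(!off)
  if (!length(keep)) stop("all records fall outside the grid")
  taxa <- sort(unique(records$taxon[keep]))
  cell_ids <- grid$cells$cell_id
  inc <- matrix(0L, length(cell_ids), length(taxa),
                dimnames = list(cell_ids, taxa))
  inc[cbind(match(ids[keep], cell_ids), match(records$taxon[keep], taxa))] <- 1L
  presence_matrix(inc, grid = grid, skipped = skipped)
}

#' Construct a presence-absence matrix object
#'
#' The central data object of the pipeline: a binary cells x taxa incidence
#' matrix. Row sums are per-cell taxon richness; column sums are per-taxon
#' range sizes (number of occupied cells). All-zero taxon columns are
#' removed; all-zero cell rows are moved aside as "no records" cells and
#' excluded from analysis.
#'
#' @param incidence Binary matrix (cells x taxa) with dimnames.
#' @param grid Optional `ps_grid` the rows refer to.
#' @param skipped Optional data frame of records that could not be binned.
#' @return An object of class `ps_presence`: list with `incidence` (binary
#'   matrix over analyzable cells), `empty_cells` (character), `grid`,
#'   `skipped`.
#' @export
presence_matrix <- function(incidence, grid = NULL, skipped = NULL) {
  stopifnot(is.matrix(incidence))
  if (is.null(rownames(incidence)) || is.null(colnames(incidence))) {
    stop("incidence matrix needs cell ids as rownames and taxa as colnames")
  }
  if (!all(incidence %in% c(0L, 1L))) stop("incidence matrix must be binary")
  storage.mode(incidence) <- "integer"
  if (anyDuplicated(rownames(incidence))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(incidence))) stop("duplicate taxon names")
  zero_taxa <- colSums(incidence) == 0L
  incidence <- incidence[, !zero_taxa, drop = FALSE]
  empty <- rownames(incidence)[rowSums(incidence) == 0L]
  incidence <- incidence[rowSums(incidence) > 0L, , drop = FALSE]
  if (ncol(incidence) == 0L || nrow(incidence) == 0L) {
    stop("presence matrix has no occupied cell / taxon")
  }
  structure(list(incidence = incidence, empty_cells = empty,
                 grid = grid, skipped = skipped),
            class = "ps_presence")
}

#' Per-taxon range sizes (number of occupied cells)
#' @param x A `ps_presence` object.
#' @return Named integer vector.
#' @export
taxon_ranges <- function(x) {
  stopifnot(inherits(x, "ps_presence"))
  colSums(x$incidence)
}

#' Per-cell taxon richness (TR)
#' @param x A `ps_presence` object.
#' @return Named integer vector over analyzable cells.
#' @export
taxon_richness <- function(x) {
  stopifnot(inherits(x, "ps_presence"))
  rowSums(x$incidence)
}

#' @export
print.ps_grid <- function(x, ...) {
  cat(sprintf("<ps_grid> %d x %d cells of %g m (%d retained)\n",
              x$n_rows, x$n_cols, x$cell_size, nrow(x$cells)))
  invisible(x)
}

#' @export
print.ps_presence <- function(x, ...) {
  cat(sprintf("<ps_presence> %d analyzable cells x %d taxa, %d presences",
              nrow(x$incidence), ncol(x$incidence), sum(x$incidence)))
  if (length(x$empty_cells)) cat(sprintf(" (+%d empty cells)", length(x$empty_cells)))
  cat("\n")
  invisible(x)
}
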