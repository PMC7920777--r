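# Output writers: plain CSV and GeoJSON for mapping. All writers are
# deterministic (fixed row order, no timestamps) so reruns are
# byte-identical.

#' Write a presence matrix as sparse (cell_id, taxon) pairs
#' @param x A `ps_presence` object.
#' @param path Output CSV path.
#' @export
write_presence_csv <- function(x, path) {
  stopifnot(inherits(x, "ps_presence"))
  idx <- which(x$incidence == 1L, arr.ind = TRUE)
  df <- data.frame(cell_id = rownames(x$incidence)[idx[, 1L]],
                   taxon = colnames(x$incidence)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$cell_id, df$taxon), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write grid cells (with optional per-cell properties) as GeoJSON
#'
#' Each retained cell becomes a square Polygon feature in planar
#' coordinates; rows of `properties` are matched to cells by `cell_id`.
#'
#' @param grid A `ps_grid`.
#' @param properties Optional data frame with a `cell_id` column.
#' @param path Output path.
#' @export
write_cells_geojson <- function(grid, path, properties = NULL) {
  stopifnot(inherits(grid, "ps_grid"))
  s <- grid$cell_size
  feats <- lapply(seq_len(nrow(grid$cells)), function(i) {
    c0 <- grid$cells[i, ]
    ring <- list(c(c0$x0, c0$y0), c(c0$x0 + s, c0$y0),
                 c(c0$x0 + s, c0$y0 + s), c(c0$x0, c0$y0 + s),
                 c(c0$x0, c0$y0))
    props <- list(cell_id = c0$cell_id)
    if (!is.null(properties)) {
      j <- match(c0$cell_id, properties$cell_id)
      if (!is.na(j)) {
        extra <- as.list(properties[j, setdiff(names(properties), "cell_id"),
                                    drop = FALSE])
        extra <- lapply(extra, function(v) if (is.factor(v)) as.character(v) else v)
        props <- c(props, extra)
      }
    }
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a turnover matrix as CSV
#' @param turnover A `ps_turnover` / `dist` object.
#' @param path Output path.
#' @export
write_turnover_csv <- function(turnover, path) {
  m <- as.matrix(turnover)
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bioregion dendrogram as Newick
#' @param regions A `ps_bioregions` object.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(regions, path) {
  stopifnot(inherits(regions, "ps_bioregions"))
  ape::write.tree(ape::as.phylo(regions$dendrogram), path)
  invisible(path)
}
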