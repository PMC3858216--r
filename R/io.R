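## TIFF stack and table I/O.
##
## Stacks are H x W x n_frames arrays of counts.  On disk they are 16-bit
## multi-page TIFFs; counts are stored as value/65535 as required by the tiff
## package and restored on read.

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @return H x W x n_frames array of counts (0..65535 scale).
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]   # collapse accidental RGB
    m * 65535
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a stack as 16-bit multi-page TIFF
#'
#' @param stack H x W x n_frames array (counts; clipped to 0..65535).
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  if (length(dim(stack)) == 2) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(stack[, , f], 0), 65535) / 65535
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Write the geometry table for a list of segmented cells
#' @param geometries list of [cell_geometry] objects.
#' @param path CSV output path (NULL: just return the data.frame).
#' @return the geometry data.frame, invisibly when written.
#' @export
geometry_table <- function(geometries, path = NULL) {
  df <- do.call(rbind, lapply(geometries, function(g) {
    data.frame(cell_id = g$cell_id, center_x_px = g$center[1],
               center_y_px = g$center[2], p_um = g$p_um,
               p_sd_um = g$p_sd_um, axis_rad = g$axis_rad,
               eccentricity = g$eccentricity,
               degenerate_axis = g$degenerate_axis, area_px2 = g$area_px2)
  }))
  if (is.null(df))
    df <- data.frame(cell_id = integer(), center_x_px = numeric(),
                     center_y_px = numeric(), p_um = numeric(),
                     p_sd_um = numeric(), axis_rad = numeric(),
                     eccentricity = numeric(), degenerate_axis = logical(),
                     area_px2 = numeric())
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
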