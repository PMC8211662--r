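#' 3D embryo geometry table
#'
#' A per-cell table of 3D nuclear positions (micrometres), lineage labels and
#' boolean marker states, the starting point of the angular-asymmetry
#' analysis (segmentation itself is upstream of this package). The hypoblast
#' compartment is the set of cells with `lineage == "HYP"`, emulating GATA6+
#' cells lining the basal-distal side of the epiblast.
#'
#' @param df data.frame with columns `cell_id`, `x_um`, `y_um`, `z_um`,
#'   `lineage`, marker columns (`CER1`, `GATA6`, `OCT4`, `LEFTY1`, `pSMAD15`;
#'   logical or 0/1), and optionally `embryo_id`, `stage_dpf`.
#' @return The validated data.frame with class `embryo_geometry`.
#' @export
embryo_geometry <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("cell_id", "x_um", "y_um", "z_um", "lineage")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pos <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(pos))) stop("positions must be finite")
  ok_lin <- c("EPI", "HYP", "CTB", "STB", "UNASSIGNED")
  if (!all(df$lineage %in% ok_lin))
    stop("lineage values must be among ", paste(ok_lin, collapse = ", "))
  for (mk in intersect(geometry_markers(), names(df))) {
    v <- df[[mk]]
    if (!is.logical(v)) {
      if (!all(v %in% c(0, 1))) stop("marker column ", mk, " must be logical or 0/1")
      df[[mk]] <- as.logical(v)
    }
  }
  if (!"embryo_id" %in% names(df)) df$embryo_id <- "embryo01"
  if (!"stage_dpf" %in% names(df)) df$stage_dpf <- NA_integer_
  class(df) <- c("embryo_geometry", "data.frame")
  df
}

geometry_markers <- function() c("CER1", "GATA6", "OCT4", "LEFTY1", "pSMAD15")

#' Positions of an embryo geometry as a matrix
#' @param g an [embryo_geometry].
#' @return n x 3 numeric matrix (micrometres).
#' @export
positions <- function(g) {
  stopifnot(inherits(g, "embryo_geometry"))
  as.matrix(g[, c("x_um", "y_um", "z_um")])
}

#' Read / write embryo geometry CSV
#'
#' CSV columns: `cell_id,x_um,y_um,z_um,lineage,CER1,GATA6,OCT4,LEFTY1,pSMAD15`
#' (booleans encoded 0/1), plus optional `embryo_id`, `stage_dpf`.
#'
#' @param path CSV file path.
#' @return [embryo_geometry] for the reader; invisibly the path for the writer.
#' @export
read_geometry_csv <- function(path) {
  embryo_geometry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_geometry_csv
#' @param g an [embryo_geometry] to write.
#' @export
write_geometry_csv <- function(g, path) {
  stopifnot(inherits(g, "embryo_geometry"))
  out <- as.data.frame(g)
  for (mk in intersect(geometry_markers(), names(out)))
    out[[mk]] <- as.integer(out[[mk]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
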