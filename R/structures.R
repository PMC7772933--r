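#' 3D structures
#'
#' A `structure3d` holds one 3D coordinate per bead together with the bin
#' table and a free-text label (e.g. time point or resolution).
#'
#' @param coords n x 3 numeric matrix of bead coordinates.
#' @param bins bin table with n rows (synthetic bins if omitted).
#' @param label character label.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(coords, bins = NULL, label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop_fmt("coordinates must be n x 3")
  if (any(!is.finite(coords))) stop_fmt("coordinates must be finite")
  if (is.null(bins)) bins <- make_bins(nrow(coords))
  if (nrow(bins) != nrow(coords))
    stop_fmt("%d bins for %d beads", nrow(bins), nrow(coords))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, bins = bins, label = label),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("3D structure: %d beads%s\n", nrow(x$coords),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

coords_of <- function(x) {
  if (inherits(x, "structure3d")) return(x$coords)
  if (inherits(x, "lattice_conformation")) return(unclass_coords(x))
  if (inherits(x, "lattice_fit")) return(unclass_coords(x$conformation))
  as.matrix(x)
}

#' Write a 3D structure to TSV or PDB
#'
#' TSV has header `bin_index chrom start end x y z` and round-trips exactly.
#' PDB writes one pseudo-atom (CA) per bead on chain A with sequential
#' residue numbers; coordinates are uniformly scaled so that `max(|coord|)
#' <= 999` fits the fixed-width columns, and the scale factor is recorded in
#' a `REMARK 250 COORDSCALE` line so it can be inverted on reading.
#'
#' @param structure a [structure3d()] (or any structure-bearing object).
#' @param path output path.
#' @param format `"tsv"` or `"pdb"` (default: guessed from the extension).
#' @export
write_structure <- function(structure, path, format = NULL) {
  format <- format %||% (if (grepl("\\.pdb$", path, ignore.case = TRUE))
                           "pdb" else "tsv")
  format <- match.arg(format, c("tsv", "pdb"))
  xyz <- coords_of(structure)
  bins <- if (inherits(structure, "structure3d")) structure$bins
          else make_bins(nrow(xyz))
  n <- nrow(xyz)
  if (format == "tsv") {
    df <- data.frame(bin_index = bins$index %||% (seq_len(n) - 1L),
                     chrom = bins$chrom, start = bins$start, end = bins$end,
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    scale <- min(1, 999 / max(abs(xyz), 1e-12))
    bio3d::write.pdb(file = path, xyz = as.vector(t(xyz * scale)),
                     resno = seq_len(n), resid = rep("BEA", n),
                     elety = rep("CA", n), chain = rep("A", n),
                     eleno = seq_len(n), elesy = rep("C", n),
                     o = rep(1, n), b = rep(0, n))
    lines <- readLines(path)
    writeLines(c(sprintf("REMARK 250 COORDSCALE %.17g", scale), lines), path)
  }
  message(sprintf("wrote %d beads to %s (%s)", n, path, format))
  invisible(path)
}

#' Read a 3D structure from TSV or PDB
#'
#' Inverts [write_structure()]; for PDB the `REMARK 250 COORDSCALE` factor
#' is applied so coordinates come back on the original scale (to the 3
#' decimals the PDB format retains).
#'
#' @param path input path.
#' @param format `"tsv"` or `"pdb"` (default: guessed from the extension).
#' @param bins optional bin table (PDB files carry no genomic intervals).
#' @return A [structure3d()].
#' @export
read_structure <- function(path, format = NULL, bins = NULL) {
  format <- format %||% (if (grepl("\\.pdb$", path, ignore.case = TRUE))
                           "pdb" else "tsv")
  format <- match.arg(format, c("tsv", "pdb"))
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    bins <- bins %||% bin_table(df$chrom, df$start, df$end)
    return(structure3d(cbind(df$x, df$y, df$z), bins))
  }
  scale <- 1
  rem <- grep("^REMARK 250 COORDSCALE", readLines(path), value = TRUE)
  if (length(rem)) scale <- as.numeric(sub(".*COORDSCALE ", "", rem[1]))
  pdb <- bio3d::read.pdb(path)
  xyz <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)[order(pdb$atom$resno), ]
  structure3d(xyz / scale, bins)
}
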